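#' Read a ternary experimental signature
#'
#' Reads a two-column whitespace/tab-separated table of gene identifier and
#' discretized regulation value, where \code{1} is up-regulation, \code{0}
#' unchanged and \code{-1} down-regulation. Only the direction of change is
#' used by the analysis; discretizing fold changes into this ternary form is
#' the caller's job. If the first line's second field is non-numeric it is
#' treated as a header and skipped. A gene repeated with the same value is
#' collapsed with a warning; repeated with conflicting values it is an
#' error.
#'
#' @param path Path to the signature file.
#' @return A named integer vector (values in \code{-1, 0, 1}, names are gene
#'   identifiers) with attribute \code{source} recording \code{path}.
#' @seealso [map_signature()]
#' @examples
#' f <- tempfile()
#' writeLines(c("GeneX\t1", "GeneY\t0", "GeneZ\t-1"), f)
#' read_signature(f)
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) {
    stop("signature file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  genes <- character(0)
  vals <- integer(0)
  first_data_line <- TRUE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "" || startsWith(line, "#")) next
    # tolerate the Unicode minus sign some tables use
    line <- gsub("−", "-", line)
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (length(fields) != 2L) {
      stop("malformed signature line ", i, " in ", path,
           ": expected 2 fields, got ", length(fields), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(fields[[2]]))
    if (first_data_line && is.na(v)) {
      message("skipping header line in ", path, ": ", line)
      first_data_line <- FALSE
      next
    }
    first_data_line <- FALSE
    if (is.na(v) || v != as.integer(v) || !as.integer(v) %in% c(-1L, 0L, 1L)) {
      stop("invalid regulation value '", fields[[2]], "' on line ", i, " of ",
           path, ": must be -1, 0 or 1", call. = FALSE)
    }
    genes <- c(genes, fields[[1]])
    vals <- c(vals, as.integer(v))
  }
  if (anyDuplicated(genes)) {
    for (g in unique(genes[duplicated(genes)])) {
      gv <- unique(vals[genes == g])
      if (length(gv) > 1L) {
        stop("gene '", g, "' appears with conflicting values in ", path,
             call. = FALSE)
      }
      warning("gene '", g, "' duplicated with identical value in ", path,
              "; collapsed", call. = FALSE)
    }
    keep <- !duplicated(genes)
    genes <- genes[keep]
    vals <- vals[keep]
  }
  sig <- vals
  names(sig) <- genes
  attr(sig, "source") <- path
  sig
}

#' Write a ternary signature to a two-column file
#'
#' @param sig Named integer vector as returned by [read_signature()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_signature <- function(sig, path) {
  writeLines(paste(names(sig), as.integer(sig), sep = "\t"), path)
  invisible(path)
}

#' Map a signature onto a causal network
#'
#' Restricts a signature to the genes present in the CCG entity set and
#' reports coverage. When some genes are absent from the network a warning
#' of the form \code{"N of M signature genes (P\%) not present in causal
#' network"} is emitted: sparse public causal knowledge makes incomplete
#' coverage the norm, and the analysis simply cannot use the unmapped genes.
#' Zero-valued genes are retained; they contribute nothing to any score but
#' enter the permutation null's composition.
#'
#' @param sig Named integer vector with values in \code{-1, 0, 1}.
#' @param ccg A [create_ccg()] object.
#' @return An object of class \code{mapped_signature}: a list with
#'   \code{mapped} (the restricted named vector), \code{n_unmapped},
#'   \code{n_signature}, and the mapped-value counts \code{q_plus},
#'   \code{q_minus}, \code{q_zero}.
#' @export
map_signature <- function(sig, ccg) {
  stopifnot(inherits(ccg, "ccg"))
  if (length(sig) > 0 && (is.null(names(sig)) || !all(sig %in% c(-1L, 0L, 1L)))) {
    stop("signature must be a named vector with values in {-1, 0, 1}",
         call. = FALSE)
  }
  src <- attr(sig, "source")
  keep <- names(sig) %in% ccg$entities
  mapped <- sig[keep]
  attributes(mapped) <- list(names = names(sig)[keep])
  n_unmapped <- sum(!keep)
  if (n_unmapped > 0) {
    warning(sprintf("%d of %d signature genes (%.1f%%) not present in causal network",
                    n_unmapped, length(sig), 100 * n_unmapped / length(sig)),
            call. = FALSE)
  }
  structure(list(mapped = mapped,
                 n_unmapped = n_unmapped,
                 n_signature = length(sig),
                 q_plus = sum(mapped == 1L),
                 q_minus = sum(mapped == -1L),
                 q_zero = sum(mapped == 0L),
                 source = src),
            class = "mapped_signature")
}

#' @export
print.mapped_signature <- function(x, ...) {
  cat("Mapped signature: ", length(x$mapped), " of ", x$n_signature,
      " genes on the network (", x$q_plus, " up, ", x$q_minus, " down, ",
      x$q_zero, " unchanged)\n", sep = "")
  invisible(x)
}

# Accept either a mapped_signature or a bare named vector in internal code.
as_mapped_values <- function(msig) {
  if (inherits(msig, "mapped_signature")) msig$mapped else msig
}
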