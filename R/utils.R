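# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the state on exit. `seed = NULL` evaluates `code` under the
#' current RNG stream unchanged.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Sign (+1/-1) -> SIF relation token and back.
sign_to_relation <- function(sign) {
  ifelse(sign > 0L, "Activates", "Inhibits")
}

sign_label <- function(sign) ifelse(sign > 0L, "+", "-")

check_sign <- function(sign) {
  if (length(sign) != 1L || !sign %in% c(1L, -1L)) {
    stop("hypothesis sign must be +1 or -1", call. = FALSE)
  }
  as.integer(sign)
}
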