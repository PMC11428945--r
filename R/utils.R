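#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are reproducible
#' without clobbering the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG stream untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Fans a single pipeline seed out to per-stage seeds via a counter-based
#' mix, so stages can be rerun independently yet reproducibly. Result is
#' always a valid 32-bit R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483629)
}

stop_user <- function(...) stop(..., call. = FALSE)

#' Format a numeric at fixed significant digits for deterministic output
#' @noRd
fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(signif(x, digits), format = "g", digits = digits))
}
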