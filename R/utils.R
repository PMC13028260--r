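#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a local, restorable RNG seed
#'
#' Used so that seeded package operations do not disturb the caller's RNG
#' stream. `seed = NULL` leaves the current stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' One-hot encode binary labels
#' @param y integer vector with values in {0, 1} (1 = malignant).
#' @return n x 2 matrix of class indicators, column 1 = benign.
#' @noRd
one_hot <- function(y) {
  stopifnot(all(y %in% c(0, 1)))
  cbind(1 - y, y)
}
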