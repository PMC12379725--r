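# Small numeric helpers shared across the package. Photon state is stored as
# N x 3 matrices, so row-wise vector algebra is the common currency here.

#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * (x[-1] - x[-n])) / 2
}

# cumulative trapezoid, same length as x, starting at 0
#' @noRd
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * (x[-1] - x[-n])) / 2)
}

#' @noRd
dot_rows <- function(a, b) {
  rowSums(a * b)
}

#' @noRd
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @noRd
norm_rows <- function(a) {
  sqrt(rowSums(a * a))
}

#' @noRd
normalize_rows <- function(a) {
  a / norm_rows(a)
}

#' @noRd
row3 <- function(v, n) {
  matrix(v, nrow = n, ncol = 3, byrow = TRUE)
}

#' @noRd
is_unit3 <- function(v, tol = 1e-12) {
  is.numeric(v) && length(v) == 3 && all(is.finite(v)) &&
    abs(sqrt(sum(v^2)) - 1) <= tol
}

#' @noRd
stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# mm^-1 -> m^-1 conversion at the configuration boundary; everything internal
# is SI.
#' @noRd
per_mm <- function(x) x * 1e3
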