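#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx dnorm pnorm integrate quantile rnorm runif rlnorm
#'   sd var setNames uniroot update
#' @importFrom utils read.csv write.csv packageVersion
NULL

stop_wbam <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "wbam_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Row-wise cross product of two n-by-3 matrices
#' @noRd
cross3 <- function(u, v) {
  cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
}

#' Central finite differences along rows of a matrix (one-sided at the ends)
#' @noRd
finite_diff <- function(x, fs) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop_wbam("wbam_length_error", "need at least 2 samples to differentiate")
  d <- matrix(0, n, ncol(x))
  if (n > 2L) d[2:(n - 1L), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2L), , drop = FALSE]) * (fs / 2)
  d[1L, ] <- (x[2L, ] - x[1L, ]) * fs
  d[n, ] <- (x[n, ] - x[n - 1L, ]) * fs
  d
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
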