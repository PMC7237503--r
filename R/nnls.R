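#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min || A x - b ||_2` subject to `x >= 0` with the classical
#' Lawson-Hanson active-set algorithm. Used by [correctMid()], where the
#' non-negativity constraint prevents negative isotopologue fractions on
#' noisy data.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol dual-feasibility tolerance (default scaled from `A`).
#' @param maxIter iteration cap.
#' @return List with `x` (the solution) and `resnorm` (squared residual
#'   norm).
#' @export
nnlsSolve <- function(A, b, tol = NULL, maxIter = 10 * ncol(A)^2 + 100) {
  A <- as.matrix(A); b <- as.numeric(b)
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(abs(A)) * max(1, max(abs(b)))
  passive <- logical(n)
  x <- numeric(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol)) {
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > maxIter) {
        warning("NNLS iteration cap reached; returning current iterate")
        x[x < 0] <- 0
        return(list(x = x, resnorm = sum((A %*% x - b)^2)))
      }
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, resnorm = sum((A %*% x - b)^2))
}
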