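#' Orthonormal discrete-time Laguerre basis
#'
#' Builds the basis used to expand the fluorescence impulse response.  The
#' discrete-time Laguerre functions are generated by the standard two-term
#' recurrence
#' \deqn{\phi_0(n) = \sqrt{1-\alpha^2}\,\alpha^{n}}
#' \deqn{\phi_j(n) = \alpha\,\phi_j(n-1) + \alpha\,\phi_{j-1}(n)
#'                   - \phi_{j-1}(n-1)}
#' and are orthonormal on the half line; on a finite grid of `n_samples`
#' points they remain orthonormal to machine precision provided the slowest
#' function has decayed by the end of the grid, which is verified here.
#'
#' @param order Number of basis functions L (columns).
#' @param alpha Laguerre scale parameter in (0, 1); larger alpha gives slower
#'   basis decay (longer memory).
#' @param n_samples Number of time samples N (rows).
#' @param ortho_tol Maximum allowed deviation of the Gram matrix from the
#'   identity before the basis is rejected.
#'
#' @return An object of class `laguerre_basis`: list with `order`, `alpha`,
#'   and the N x L matrix `basis` with orthonormal columns.
#' @export
laguerre_basis <- function(order, alpha, n_samples, ortho_tol = 1e-6) {
  stopifnot(order >= 1, n_samples >= order)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  L <- as.integer(order)
  N <- as.integer(n_samples)
  phi <- matrix(0, N, L)
  phi[, 1] <- sqrt(1 - alpha^2) * alpha^(seq_len(N) - 1)
  if (L > 1) {
    for (j in 2:L) {
      prev <- phi[, j - 1]
      cur <- numeric(N)
      cur[1] <- alpha * prev[1]
      for (n in 2:N) {
        cur[n] <- alpha * cur[n - 1] + alpha * prev[n] - prev[n - 1]
      }
      phi[, j] <- cur
    }
  }
  gram_err <- max(abs(crossprod(phi) - diag(L)))
  if (gram_err > ortho_tol) {
    stop(sprintf(paste0(
      "Laguerre basis not orthonormal on %d samples (Gram deviation %.2e): ",
      "alpha = %.3f is too large for this window; reduce alpha or the order, ",
      "or lengthen the window"), N, gram_err, alpha))
  }
  structure(list(order = L, alpha = alpha, n_samples = N, basis = phi),
            class = "laguerre_basis")
}

#' @export
print.laguerre_basis <- function(x, ...) {
  cat(sprintf("Laguerre basis: L = %d, alpha = %.3f, N = %d\n",
              x$order, x$alpha, x$n_samples))
  invisible(x)
}
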