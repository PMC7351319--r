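#' Lawson-Hanson nonnegative least squares
#'
#' Minimizes `||A x - b||^2` subject to `x >= 0` by the classic active-set
#' algorithm.  Used internally to solve the dual of the constrained
#' least-squares deconvolution; exposed because it is generally useful and
#' directly testable.
#'
#' @param A Numeric matrix (m rows may be < or > than columns; here typically
#'   L x m with few rows and many columns).
#' @param b Numeric vector, length `nrow(A)`.
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @param max_iter Safety iteration cap.
#' @return List with `x` (the solution), `residual`, and `iterations`.
#' @export
nnls <- function(A, b, tol = NULL, max_iter = 10L * ncol(A) + 100L) {
  m <- ncol(A)
  x <- numeric(m)
  if (is.null(tol)) tol <- 1e-10 * max(abs(crossprod(A, b)), .Machine$double.eps)
  passive <- logical(m)
  r <- b            # residual b - A x
  w <- as.numeric(crossprod(A, r))
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      qr_p <- qr(A[, P, drop = FALSE])
      z_p <- qr.coef(qr_p, b)
      z_p[is.na(z_p)] <- 0   # rank-deficient columns contribute nothing
      if (all(z_p > 0)) {
        x[] <- 0
        x[P] <- z_p
        break
      }
      # step from x toward z until the first passive variable hits zero
      xp <- x[P]
      neg <- z_p <= 0
      alpha <- min(xp[neg] / (xp[neg] - z_p[neg]))
      x[P] <- xp + alpha * (z_p - xp)
      drop_idx <- P[x[P] <= tol * max(1, max(abs(x)))]
      x[drop_idx] <- 0
      passive[drop_idx] <- FALSE
      if (!any(passive)) { x[] <- 0; break }
    }
    r <- b - A %*% x
    w <- as.numeric(crossprod(A, r))
  }
  list(x = x, residual = as.numeric(r), iterations = iter)
}

#' Precomputed constrained least-squares deconvolver
#'
#' Builds, once per (IRF, basis) pair, everything the per-waveform solve
#' needs: the convolution design matrix `V` whose columns are the IRF
#' convolved with each Laguerre function, its Cholesky factor, and the
#' whitened constraint matrix enforcing a nonnegative, non-increasing decay.
#' This makes repeated deconvolution of many waveforms cheap.
#'
#' @param irf Sampled IRF (same grid as the waveforms; any nonnegative kernel
#'   is accepted, e.g. a discrete delta for testing).
#' @param basis A [laguerre_basis()] with `n_samples == length(irf)`.
#' @return Object of class `cls_deconvolver`.
#' @export
cls_deconvolver <- function(irf, basis) {
  stopifnot(inherits(basis, "laguerre_basis"), length(irf) == basis$n_samples)
  N <- basis$n_samples
  L <- basis$order
  B <- basis$basis
  # causal discrete convolution of the IRF with each basis function
  V <- apply(B, 2, function(col) {
    full <- stats::convolve(irf, rev(col), type = "open")
    full[seq_len(N)]
  })
  Q <- crossprod(V)
  R <- tryCatch(chol(Q), error = function(e) {
    chol(Q + diag(1e-12 * sum(diag(Q)) / L, L))
  })
  # constraints G c >= 0: h = B c >= 0 (N rows) and -diff(h) >= 0 (N-1 rows)
  G <- rbind(B, -diff(B))
  Wt <- backsolve(R, t(G), transpose = TRUE)   # W' where W = G R^-1, (L x m)
  structure(list(irf = irf, basis = basis, V = V, R = R, G = G, Wt = Wt),
            class = "cls_deconvolver")
}

#' Constrained least-squares deconvolution of one channel waveform
#'
#' Finds the Laguerre coefficients c minimizing
#' `||waveform - (IRF (*) basis) c||^2` subject to the linear constraints
#' that the fitted fluorescence impulse response `h = basis c` is
#' nonnegative and non-increasing.  The quadratic program is solved exactly
#' through its dual, a nonnegative least-squares problem handled by [nnls()].
#'
#' @param waveform Background-subtracted channel waveform.
#' @param decon A [cls_deconvolver()] (preferred for batch work), or NULL.
#' @param irf,basis Alternative to `decon`: build a one-shot deconvolver.
#' @param zero_tol Waveforms whose maximum absolute amplitude is below this
#'   are returned as flagged empty fits with zero coefficients.
#' @return Object of class `decay_fit`: list with `coefficients`,
#'   `fitted_firf` (h), `reconvolution`, `residual_rms`, `integral` (area of
#'   the measured channel curve, in volt x sample units), `avg_lifetime_ns`
#'   (filled by the caller via [average_lifetime()]), and `empty` flag.
#' @export
deconvolve_cls <- function(waveform, decon = NULL, irf = NULL, basis = NULL,
                           zero_tol = 1e-12) {
  if (is.null(decon)) decon <- cls_deconvolver(irf, basis)
  N <- decon$basis$n_samples
  stopifnot(length(waveform) == N)
  L <- decon$basis$order
  if (max(abs(waveform)) < zero_tol) {
    h <- numeric(N)
    return(structure(list(coefficients = numeric(L), fitted_firf = h,
                          reconvolution = numeric(N), residual_rms = 0,
                          integral = 0, empty = TRUE), class = "decay_fit"))
  }
  b <- as.numeric(crossprod(decon$V, waveform))
  ub <- backsolve(decon$R, b, transpose = TRUE)
  c0 <- backsolve(decon$R, ub)
  g0 <- as.numeric(decon$G %*% c0)
  scale <- max(abs(decon$basis$basis %*% c0))
  if (min(g0) >= -1e-12 * max(scale, 1)) {
    cc <- c0
  } else {
    sol <- nnls(decon$Wt, -ub)
    cc <- backsolve(decon$R, ub + decon$Wt %*% sol$x)
  }
  h <- as.numeric(decon$basis$basis %*% cc)
  # snap solver-tolerance-level constraint violations to feasibility
  h[h < 0 & h > -1e-9 * max(abs(h), 1)] <- 0
  recon <- as.numeric(decon$V %*% cc)
  structure(list(coefficients = as.numeric(cc), fitted_firf = h,
                 reconvolution = recon,
                 residual_rms = sqrt(mean((waveform - recon)^2)),
                 integral = sum(waveform), empty = FALSE),
            class = "decay_fit")
}

#' Average fluorescence lifetime of a fitted decay
#'
#' First moment of the fitted fluorescence impulse response on the channel
#' time grid: `tau_avg = sum(t * h) / sum(h)`.  Scale-invariant in h.
#'
#' @param fit A `decay_fit`, or a numeric vector taken directly as h.
#' @param sampling_ns Sample interval of the grid, ns.
#' @return Lifetime in ns; `NA` (flagged via attribute `undefined`) when the
#'   decay integral is zero.
#' @export
average_lifetime <- function(fit, sampling_ns = 0.08) {
  h <- if (inherits(fit, "decay_fit")) fit$fitted_firf else as.numeric(fit)
  s <- sum(h)
  if (s <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  t <- (seq_along(h) - 1) * sampling_ns
  sum(t * h) / s
}

#' Spectral intensity ratios from channel decay integrals
#'
#' Each included channel's decay-curve integral divided by the sum of the
#' included channels' integrals.  By default channels 1-3 form both the
#' numerators and the denominator (channel 4 is excluded from analysis).
#'
#' @param integrals Numeric vector of per-channel decay integrals (>= 0).
#' @return Vector of fractions summing to 1, same length as `integrals`;
#'   `NA`s with attribute `undefined` when all integrals are zero.
#' @export
intensity_ratio <- function(integrals) {
  stopifnot(all(integrals >= 0 | is.na(integrals)))
  s <- sum(integrals)
  if (!is.finite(s) || s <= 0) {
    out <- rep(NA_real_, length(integrals))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  integrals / s
}
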