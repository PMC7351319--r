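# Independent oracles used by the tests.  These deliberately share no code
# with the implementation paths they check.

# Closed-form truncated first moment of exp(-t/tau) on the sampled grid:
# the estimand of the first-moment average-lifetime estimator on a finite
# observation window.
truncated_moment <- function(tau, tgrid) {
  w <- exp(-tgrid / tau)
  sum(tgrid * w) / sum(w)
}

# Interior-point (log-barrier) quadratic-program oracle with exact KKT
# refinement, for min 0.5||V c - y||^2 s.t. h = B c >= 0 and diff(h) <= 0.
# Independent of the dual-NNLS production solver.
qp_oracle <- function(V, y, B, eps = 1e-11) {
  G <- rbind(B, -diff(B))
  Q <- crossprod(V)
  b <- as.numeric(crossprod(V, y))
  L <- ncol(V)
  m <- nrow(G)
  # strictly feasible start: the first Laguerre function is positive and
  # strictly decreasing
  cc <- c(1, rep(0, L - 1))
  stopifnot(all(G %*% cc > 0))
  cc <- cc * max(1e-3, sqrt(sum(b^2)) / sum(diag(Q)))
  t_bar <- 1
  while (m / t_bar > eps) {
    for (it in 1:80) {
      g <- as.numeric(G %*% cc)
      grad <- t_bar * (Q %*% cc - b) - as.numeric(crossprod(G, 1 / g))
      hess <- t_bar * Q + crossprod(G / g)
      step <- tryCatch(solve(hess, -grad), error = function(e) NULL)
      if (is.null(step)) break
      lambda2 <- -sum(grad * step)
      if (lambda2 / 2 < 1e-13 * (1 + abs(sum(cc * grad)))) break
      s <- 1
      repeat {
        cand <- cc + s * step
        if (all(G %*% cand > 0)) break
        s <- s / 2
        if (s < 1e-14) break
      }
      f0 <- t_bar * (0.5 * sum(cc * (Q %*% cc)) - sum(b * cc)) - sum(log(g))
      repeat {
        cand <- cc + s * step
        gc2 <- as.numeric(G %*% cand)
        if (all(gc2 > 0)) {
          f1 <- t_bar * (0.5 * sum(cand * (Q %*% cand)) - sum(b * cand)) -
            sum(log(gc2))
          if (f1 <= f0 + 1e-4 * s * sum(grad * step)) break
        }
        s <- s / 2
        if (s < 1e-14) break
      }
      if (s < 1e-14) break
      cc <- cc + s * step
    }
    t_bar <- t_bar * 20
  }
  # exact active-set refinement from the barrier solution
  g <- as.numeric(G %*% cc)
  scale <- max(abs(g), 1e-12)
  active <- which(g < 1e-6 * scale)
  for (round in 1:60) {
    if (length(active) == 0) {
      sol <- solve(Q, b)
      lam <- numeric(0)
    } else {
      Ga <- G[active, , drop = FALSE]
      kkt <- rbind(cbind(Q, t(Ga)),
                   cbind(Ga, matrix(0, length(active), length(active))))
      rhs <- c(b, rep(0, length(active)))
      sol_full <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
      if (is.null(sol_full)) break
      sol <- sol_full[seq_len(L)]
      lam <- -sol_full[-seq_len(L)]
    }
    viol <- as.numeric(G %*% sol)
    if (length(lam) && any(lam < -1e-9)) {
      active <- active[-which.min(lam)]
      next
    }
    if (any(viol < -1e-9 * scale)) {
      active <- sort(unique(c(active, which.min(viol))))
      next
    }
    return(list(coefficients = as.numeric(sol),
                fitted = as.numeric(B %*% sol)))
  }
  list(coefficients = as.numeric(cc), fitted = as.numeric(B %*% cc))
}

# Brute-force histology label assignment: scan every annotated pixel of the
# map for each point.
brute_assign <- function(points, map, radius = 10,
                         codes = annotation_codes(fine = TRUE)) {
  ann <- which(unclass(map) != 0L, arr.ind = TRUE)
  vals <- map[ann]
  out <- character(nrow(points))
  for (i in seq_len(nrow(points))) {
    x <- points$x[i]; y <- points$y[i]
    xr <- round(x); yr <- round(y)
    if (xr >= 1 && xr <= ncol(map) && yr >= 1 && yr <= nrow(map) &&
        map[yr, xr] != 0L) {
      out[i] <- condition_of(map[yr, xr], codes)
      next
    }
    d <- sqrt((ann[, "col"] - x)^2 + (ann[, "row"] - y)^2)
    ok <- d <= radius
    out[i] <- if (any(ok)) condition_of(vals[ok][which.min(d[ok])], codes)
    else NA_character_
  }
  out
}

# Brute-force heterogeneity flag: binary-disparate annotated conditions
# within the radius.
brute_heterogeneous <- function(points, map, radius = 10,
                                codes = annotation_codes(fine = TRUE)) {
  ann <- which(unclass(map) != 0L, arr.ind = TRUE)
  grp <- group_of(map[ann], codes)
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt((ann[, "col"] - points$x[i])^2 + (ann[, "row"] - points$y[i])^2)
    length(unique(grp[d <= radius])) >= 2
  }, logical(1))
}

# Pairwise-comparison AUC: P(pos > neg) + 0.5 P(tie), by exhaustive pairs.
pairwise_auc <- function(scores, labels) {
  p <- scores[as.logical(labels)]
  n <- scores[!as.logical(labels)]
  cmp <- outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
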