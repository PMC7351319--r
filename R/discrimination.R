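#' Wilcoxon rank-sum significance test
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum p-value.  Exact enumeration
#' when the smaller sample has at most `exact_max` values and there are no
#' ties; midrank handling with a continuity-corrected normal approximation
#' otherwise.
#'
#' @param a,b Numeric samples (both nonempty).
#' @param exact_max Largest `min(n_a, n_b)` for which the exact null
#'   distribution is enumerated.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && min(length(a), length(b)) <= exact_max
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  unname(res$p.value)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted one half -- identical to the trapezoidal
#' area under the ROC curve and to `U / (n1 * n0)`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical or 0/1); TRUE/1 = positive.
#' @return AUC in [0, 1]; NA with attribute `undefined` if only one class
#'   is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  r <- rank(scores)   # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision of the precision-recall curve
#'
#' Step-interpolated average precision
#' `AP = sum_n (R_n - R_{n-1}) P_n` over descending score thresholds;
#' tied scores enter as one threshold group.
#'
#' @inheritParams roc_auc
#' @return AP in (0, 1]; NA with attribute `undefined` if no positives.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)        # last index of each tie group
  tp <- cumsum(l)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Cohen's d standardized effect size
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled standard deviation
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return Signed d; take `abs()` for the magnitude.  NA (flagged
#'   `undefined`) when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  (mean(a) - mean(b)) / sp
}

#' Fisher linear discriminant direction for two classes
#'
#' One-dimensional discriminant maximizing between-class over within-class
#' variance: `w` solves `S_w w = mu_pos - mu_neg`, computed through the
#' singular value decomposition of the pooled within-class scatter.  A
#' singular scatter (duplicated or constant features) takes a ridge path
#' (`epsilon = 1e-6 * trace`) with a warning.  The sign is fixed so the
#' positive class (cancer) has the higher mean score; the returned vector
#' has unit norm.
#'
#' @param features n x p numeric matrix.
#' @param labels Binary labels; TRUE/1 = positive class.
#' @param ridge Relative ridge added when the scatter is singular.
#' @return Unit-norm weight vector of length p.
#' @export
fit_lda <- function(features, labels, ridge = 1e-6) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  stopifnot(nrow(features) == length(labels), sum(labels) > 0, sum(!labels) > 0)
  xp <- features[labels, , drop = FALSE]
  xn <- features[!labels, , drop = FALSE]
  sw <- crossprod(scale(xp, scale = FALSE)) + crossprod(scale(xn, scale = FALSE))
  dmu <- colMeans(xp) - colMeans(xn)
  sv <- svd(sw)
  tol <- max(sv$d) * 1e-10
  if (any(sv$d < tol)) {
    warning("singular within-class scatter: applying ridge")
    sw <- sw + diag(ridge * sum(diag(sw)) / ncol(sw), ncol(sw))
    sv <- svd(sw)
  }
  w <- sv$v %*% (crossprod(sv$u, dmu) / sv$d)
  w <- as.numeric(w)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) return(rep(0, ncol(features)))
  w <- w / nrm
  if (sum((xp %*% w)) / nrow(xp) < sum((xn %*% w)) / nrow(xn)) w <- -w
  w
}

#' Min-max scaled LDA scores for one scan
#'
#' Projects the scan's feature rows on the fitted discriminant direction
#' and min-max scales the projection to [0, 1] within the scan.  The scaled
#' score is *not* a probability.
#'
#' @param features n x p matrix (same columns the weights were fitted on).
#' @param weights Discriminant direction from [fit_lda()].
#' @return Numeric scores with min 0 and max 1; all 0.5 (flagged via
#'   attribute `constant`) when the projection is constant.
#' @export
lda_scores <- function(features, weights) {
  proj <- as.numeric(as.matrix(features) %*% weights)
  rng <- range(proj)
  if (diff(rng) == 0) {
    out <- rep(0.5, length(proj))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (proj - rng[1]) / diff(rng)
}

#' Single-parameter and LDA discrimination report for one patient scan
#'
#' For each of the six FLIm parameters (average lifetime and intensity
#' ratio, CH1-3): Wilcoxon rank-sum p-value, ROC-AUC, and average precision
#' for cancer vs healthy, each computed on the points passing that
#' parameter's own outlier mask.  `auc` and `ap` score the raw parameter
#' with cancer as the positive class (a parameter that is *lower* in cancer
#' gives AUC < 0.5); `auc_oriented` / `ap_oriented` are direction-agnostic
#' (parameter sign chosen so AUC >= 0.5), which is what cross-parameter
#' comparisons such as "LDA beats the best single parameter" use.  The
#' six-parameter LDA is fitted per scan on the points passing every mask,
#' its min-max scaled score evaluated with cancer as the positive class
#' (already oriented by construction).
#'
#' @param points Filtered data.frame from [apply_filters()] with `group`.
#' @param context Context string recorded in the report.
#' @param patient Patient identifier recorded in the report.
#' @return data.frame of class `discrimination_report`, one row per
#'   parameter plus one `lda` row: columns `patient`, `context`,
#'   `parameter`, `n_healthy`, `n_cancer`, `p_value`, `auc`, `ap`.  LDA
#'   weights are attached as attribute `lda_weights`.  When a class is
#'   missing the report is flagged `non_discriminable` and metric columns
#'   are NA.
#' @export
patient_report <- function(points, context = NA_character_,
                           patient = NA_integer_) {
  params <- flim_parameters()
  ready <- points[points$analysis_ready, , drop = FALSE]
  empty_row <- function(param, nh, nc) {
    data.frame(patient = patient, context = context, parameter = param,
               n_healthy = nh, n_cancer = nc,
               p_value = NA_real_, auc = NA_real_, ap = NA_real_,
               auc_oriented = NA_real_, ap_oriented = NA_real_)
  }
  nh_all <- sum(ready$group == "healthy")
  nc_all <- sum(ready$group == "cancer")
  if (nh_all == 0 || nc_all == 0) {
    out <- do.call(rbind, lapply(c(params, "lda"), empty_row,
                                 nh = nh_all, nc = nc_all))
    attr(out, "non_discriminable") <- TRUE
    class(out) <- c("discrimination_report", "data.frame")
    return(out)
  }
  rows <- vector("list", length(params) + 1L)
  for (j in seq_along(params)) {
    p <- params[j]
    mask <- ready[[paste0("mad_pass_", p)]]
    sub <- ready[!is.na(mask) & mask, , drop = FALSE]
    pos <- sub$group == "cancer"
    if (sum(pos) == 0 || sum(!pos) == 0) {
      rows[[j]] <- empty_row(p, sum(!pos), sum(pos))
      next
    }
    v <- sub[[p]]
    a <- roc_auc(v, pos)
    sgn <- if (!is.na(a) && a < 0.5) -1 else 1
    rows[[j]] <- data.frame(
      patient = patient, context = context, parameter = p,
      n_healthy = sum(!pos), n_cancer = sum(pos),
      p_value = rank_sum_test(v[pos], v[!pos]),
      auc = a,
      ap = average_precision(v, pos),
      auc_oriented = max(a, 1 - a),
      ap_oriented = average_precision(sgn * v, pos))
  }
  sub <- ready[ready$mad_pass_all, , drop = FALSE]
  pos <- sub$group == "cancer"
  if (sum(pos) > 0 && sum(!pos) > 0) {
    feats <- as.matrix(sub[, params])
    # the three intensity ratios sum to 1, so the scatter is always rank
    # deficient by one and the ridge path is the expected route here
    w <- suppressWarnings(fit_lda(feats, pos))
    sc <- lda_scores(feats, w)
    a <- roc_auc(sc, pos)
    ap <- average_precision(sc, pos)
    rows[[length(params) + 1L]] <- data.frame(
      patient = patient, context = context, parameter = "lda",
      n_healthy = sum(!pos), n_cancer = sum(pos),
      p_value = rank_sum_test(sc[pos], sc[!pos]),
      auc = a, ap = ap, auc_oriented = a, ap_oriented = ap)
  } else {
    rows[[length(params) + 1L]] <- empty_row("lda", sum(!pos), sum(pos))
    w <- rep(NA_real_, length(params))
  }
  out <- do.call(rbind, rows)
  attr(out, "lda_weights") <- stats::setNames(w, params)
  class(out) <- c("discrimination_report", "data.frame")
  out
}

#' Cohort-level summary of per-patient discrimination reports
#'
#' @param reports List of [patient_report()] data.frames.
#' @return data.frame with per-context, per-parameter mean oriented AUC /
#'   AP across discriminable patients, plus the mean
#'   LDA-minus-best-single-parameter AUC and AP gains (both on the
#'   oriented scale).
#' @export
cohort_summary <- function(reports) {
  all <- do.call(rbind, lapply(reports, as.data.frame))
  all <- all[!is.na(all$auc), , drop = FALSE]
  if (nrow(all) == 0) return(data.frame())
  agg <- stats::aggregate(cbind(auc_oriented, ap_oriented) ~ context + parameter,
                          data = all, FUN = mean)
  names(agg)[names(agg) == "auc_oriented"] <- "mean_auc"
  names(agg)[names(agg) == "ap_oriented"] <- "mean_ap"
  gains <- do.call(rbind, lapply(split(all, list(all$context, all$patient),
                                       drop = TRUE), function(d) {
    lda <- d[d$parameter == "lda", ]
    single <- d[d$parameter != "lda", ]
    if (nrow(lda) == 0 || nrow(single) == 0) return(NULL)
    data.frame(context = lda$context[1],
               auc_gain = lda$auc_oriented - max(single$auc_oriented),
               ap_gain = lda$ap_oriented - max(single$ap_oriented))
  }))
  if (!is.null(gains) && nrow(gains) > 0) {
    g <- stats::aggregate(cbind(auc_gain, ap_gain) ~ context, data = gains,
                          FUN = mean)
    agg <- merge(agg, g, by = "context", all.x = TRUE)
  }
  agg
}

#' Per-parameter Cohen's d between imaging contexts
#'
#' Effect sizes of context change (e.g. in vivo pre-resection vs ex vivo)
#' on each FLIm parameter, computed over pooled healthy-epithelium
#' measurements -- the analysis used in place of p-values when samples are
#' large.
#'
#' @param measurements data.frame with parameter columns plus `context`
#'   and `group`; only `group == "healthy"` rows are compared.
#' @return data.frame `parameter`, `context_a`, `context_b`, `cohens_d`
#'   (magnitude).
#' @export
context_effect_sizes <- function(measurements) {
  m <- measurements[measurements$group == "healthy", , drop = FALSE]
  ctxs <- unique(m$context)
  params <- flim_parameters()
  out <- list()
  for (p in params) {
    for (i in seq_along(ctxs)) {
      for (j in seq_along(ctxs)) {
        if (j <= i) next
        a <- m[[p]][m$context == ctxs[i]]
        b <- m[[p]][m$context == ctxs[j]]
        if (length(a) < 2 || length(b) < 2) next
        out[[length(out) + 1L]] <- data.frame(
          parameter = p, context_a = ctxs[i], context_b = ctxs[j],
          cohens_d = abs(cohens_d(a, b)))
      }
    }
  }
  do.call(rbind, out)
}
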