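#' Statistical analysis configuration
#'
#' The per-segment alpha is Bonferroni-adjusted over the number of
#' segments: `adjusted_alpha = alpha / n_segments` (0.0005 for the
#' defaults), and segment-level effects are gated at the conventional
#' "large" Cliff's delta threshold.
#'
#' @param alpha familywise two-sided alpha.
#' @param n_segments number of along-tract segments.
#' @param large_effect Cliff's delta magnitude threshold.
#' @return List of class `stats_config` with `adjusted_alpha`.
#' @export
stats_config <- function(alpha = 0.05, n_segments = 100L,
                         large_effect = 0.474) {
  stopifnot(alpha > 0, alpha < 1, n_segments >= 1)
  structure(list(alpha = alpha, n_segments = as.integer(n_segments),
                 adjusted_alpha = alpha / n_segments,
                 large_effect = large_effect, two_sided = TRUE),
            class = "stats_config")
}

#' Assemble the long-format segment table
#'
#' One row per (subject, hemisphere, segment, metric): `subject`,
#' `hemisphere` (0 = healthy, 1 = pathological), `segment` (1-based,
#' caudal to cortical), `metric`, `value` (per-segment median),
#' `peritumoral` flag. Flagged-missing segments are dropped listwise; a
#' complete cohort of 65 subjects therefore yields 13,000 rows per metric.
#'
#' @param profiles nested list: `profiles[[subject]][[hemisphere]]` with
#'   hemisphere names `"healthy"` and `"pathological"`, each a named list
#'   of [segment_medians()] profiles (or plain numeric vectors) per
#'   metric.
#' @param peritumoral list (per subject) of logical vectors, or `NULL`.
#' @return `data.frame` in deterministic (subject, hemisphere, metric,
#'   segment) order.
#' @export
assemble_table <- function(profiles, peritumoral = NULL) {
  rows <- list()
  for (i in seq_along(profiles)) {
    subj <- profiles[[i]]
    if (!all(c("healthy", "pathological") %in% names(subj))) {
      stop("subject ", i, " is missing a hemisphere")
    }
    peri <- if (is.null(peritumoral)) NULL else peritumoral[[i]]
    for (hemi in c("healthy", "pathological")) {
      hcode <- if (hemi == "healthy") 0L else 1L
      for (metric in names(subj[[hemi]])) {
        p <- subj[[hemi]][[metric]]
        v <- if (inherits(p, "segment_profile")) p$median else as.numeric(p)
        n <- length(v)
        keep <- !is.na(v)
        pp <- if (is.null(peri)) rep(FALSE, n) else peri
        rows[[length(rows) + 1]] <- data.frame(
          subject = i, hemisphere = hcode, segment = seq_len(n)[keep],
          metric = metric, value = v[keep], peritumoral = pp[keep]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$hemisphere, out$metric, out$segment), ]
  rownames(out) <- NULL
  out
}

#' Hemisphere linear mixed model
#'
#' `value ~ hemisphere + (1 | subject)` fit by REML (lmerTest); the fixed
#' effect is the pathological-minus-healthy difference with
#' Satterthwaite-approximated two-sided p-value and a Wald 95% CI.
#' Residual diagnostics (fitted/residual pairs and normal QQ data) are
#' returned for inspection.
#'
#' @param records an [assemble_table()] data frame.
#' @param metric metric name to model.
#' @param subset `"all"` or `"peritumoral"` (peritumoral-flagged rows
#'   only).
#' @return List of class `hemisphere_lmm`: `estimate`, `se`, `ci`
#'   (95% Wald), `p`, `df`, `n_obs`, `converged`, `diagnostics`.
#' @export
fit_hemisphere_lmm <- function(records, metric, subset = c("all",
                                                           "peritumoral")) {
  subset <- match.arg(subset)
  d <- records[records$metric == metric, , drop = FALSE]
  if (subset == "peritumoral") d <- d[d$peritumoral, , drop = FALSE]
  if (length(unique(d$subject)) < 2L) stop("need at least 2 subjects")
  if (length(unique(d$hemisphere)) < 2L) {
    stop("both hemisphere levels must be present")
  }
  fit <- lmerTest::lmer(value ~ hemisphere + (1 | subject), data = d,
                        REML = TRUE)
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || length(msgs) == 0
  co <- summary(fit)$coefficients
  est <- co["hemisphere", "Estimate"]
  se <- co["hemisphere", "Std. Error"]
  p <- co["hemisphere", "Pr(>|t|)"]
  df <- co["hemisphere", "df"]
  ci <- est + c(-1, 1) * qnorm(0.975) * se
  res <- stats::residuals(fit)
  structure(list(estimate = est, se = se, ci = ci, p = p, df = df,
                 n_obs = nrow(d), converged = converged,
                 metric = metric, subset = subset,
                 diagnostics = list(fitted = stats::fitted(fit),
                                    residuals = res,
                                    qq = stats::qqnorm(res, plot.it = FALSE)),
                 model = fit),
            class = "hemisphere_lmm")
}

#' @export
print.hemisphere_lmm <- function(x, ...) {
  cat(sprintf(
    "hemisphere effect (%s, %s): %.4g [%.4g, %.4g], p = %.3g (n = %d)%s\n",
    x$metric, x$subset, x$estimate, x$ci[1], x$ci[2], x$p, x$n_obs,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Segment-wise Bonferroni-corrected paired t-tests
#'
#' For each segment, a two-sided paired t-test of pathological vs healthy
#' per-subject values; the decision compares p against the
#' Bonferroni-adjusted alpha. Segments with fewer than 3 complete pairs,
#' or zero variance of the paired differences, are untestable (`NA`
#' decision), never significant.
#'
#' @param records an [assemble_table()] data frame.
#' @param metric metric name.
#' @param config a [stats_config()].
#' @return `data.frame` with `segment`, `t`, `p`, `significant`,
#'   `n_pairs`, `mean_diff`.
#' @export
segmentwise_tests <- function(records, metric, config = stats_config()) {
  d <- records[records$metric == metric, , drop = FALSE]
  ns <- config$n_segments
  out <- data.frame(segment = seq_len(ns), t = NA_real_, p = NA_real_,
                    significant = NA, n_pairs = 0L, mean_diff = NA_real_)
  subj <- sort(unique(d$subject))
  si <- match(d$subject, subj)
  mk <- function(h) {
    m <- matrix(NA_real_, length(subj), ns)
    sel <- d$hemisphere == h & d$segment <= ns
    m[cbind(si[sel], d$segment[sel])] <- d$value[sel]
    m
  }
  diffs <- mk(1L) - mk(0L)           # pathological minus healthy
  n <- colSums(!is.na(diffs))
  mu <- colMeans(diffs, na.rm = TRUE)
  sdd <- apply(diffs, 2, sd, na.rm = TRUE)
  out$n_pairs <- n
  testable <- n >= 3L & is.finite(sdd) & sdd > 0
  out$mean_diff[n > 0] <- mu[n > 0]
  tval <- mu / (sdd / sqrt(n))
  pval <- 2 * pt(-abs(tval), df = pmax(n - 1, 1))
  out$t[testable] <- tval[testable]
  out$p[testable] <- pval[testable]
  # zero-variance or under-supported segments stay untestable (NA), not 0
  out$significant[testable] <- pval[testable] < config$adjusted_alpha
  out
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)` by exhaustive
#' pair comparison; in `[-1, 1]`, antisymmetric in its arguments.
#'
#' @param x,y non-empty numeric samples.
#' @return Scalar delta.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  d <- outer(x, y, "-")
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Per-segment Cliff's deltas between hemispheres
#'
#' Delta of pathological vs healthy values across subjects, per segment.
#'
#' @param records an [assemble_table()] data frame.
#' @param metric metric name.
#' @param n_segments number of segments.
#' @return Numeric vector of deltas (`NA` where a hemisphere is empty).
#' @export
segmentwise_cliffs_delta <- function(records, metric, n_segments = 100L) {
  d <- records[records$metric == metric, , drop = FALSE]
  vapply(seq_len(n_segments), function(s) {
    x <- d$value[d$hemisphere == 1L & d$segment == s]
    y <- d$value[d$hemisphere == 0L & d$segment == s]
    if (length(x) == 0 || length(y) == 0) return(NA_real_)
    cliffs_delta(x, y)
  }, numeric(1))
}

#' Classify segments as tumorous
#'
#' A segment is predicted tumorous iff it is Bonferroni-significant and
#' `|delta| >= large_effect`. Untestable segments (NA decision) yield NA
#' and are excluded from downstream confusion counts.
#'
#' @param decisions logical vector (from [segmentwise_tests()]
#'   `significant`).
#' @param deltas aligned numeric vector of Cliff's deltas.
#' @param config a [stats_config()].
#' @return Integer vector: 1 tumorous, 0 non-tumorous, NA untestable.
#' @export
classify_segments <- function(decisions, deltas, config = stats_config()) {
  if (length(decisions) != length(deltas)) {
    stop("decisions and deltas must be aligned")
  }
  out <- as.integer(decisions & abs(deltas) >= config$large_effect)
  out[is.na(decisions)] <- NA_integer_
  out
}

#' Sensitivity and specificity of tumorous-segment detection
#'
#' `sensitivity = TP / (TP + FN)`; `specificity = TN / (TN + FP)`;
#' zero-denominator rates are `NA` (flagged undefined). NA predictions
#' are excluded.
#'
#' @param predicted integer/logical predictions (1 = tumorous).
#' @param truth aligned ground-truth flags.
#' @return List of class `confusion_metrics`: `sensitivity`,
#'   `specificity`, `counts` (TP, FP, TN, FN), `n_evaluated`.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  keep <- !is.na(predicted) & !is.na(truth)
  p <- as.logical(predicted[keep])
  t_ <- as.logical(truth[keep])
  tp <- sum(p & t_); fp <- sum(p & !t_)
  tn <- sum(!p & !t_); fn <- sum(!p & t_)
  structure(list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    n_evaluated = sum(keep)),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.3f, specificity %.3f (TP %d FP %d TN %d FN %d)\n",
              x$sensitivity, x$specificity, x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  invisible(x)
}

#' Interface-class summaries of hemispheric differences
#'
#' Mean (pathological - healthy) per metric within the segment classes
#' healthy-only, lesional-only, external interface and internal interface,
#' the classes partitioning each subject's evaluated segments according to
#' the subject's peritumoral labels.
#'
#' @param records an [assemble_table()] data frame.
#' @param labels list (per subject) of [label_peritumoral()] results.
#' @return `data.frame` with `metric`, `class`, `mean_diff`, `n`.
#' @export
interface_summaries <- function(records, labels) {
  metrics <- unique(records$metric)
  classes <- c("healthy", "lesional", "interface_external",
               "interface_internal")
  acc <- list()
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    ns <- length(lab$peritumoral)
    cls <- rep("healthy", ns)
    cls[lab$peritumoral] <- "lesional"
    cls[lab$interface_internal] <- "interface_internal"
    cls[lab$interface_external] <- "interface_external"
    d <- records[records$subject == i, , drop = FALSE]
    for (metric in metrics) {
      dm <- d[d$metric == metric, ]
      v0 <- dm[dm$hemisphere == 0L, ]
      v1 <- dm[dm$hemisphere == 1L, ]
      seg <- intersect(v0$segment, v1$segment)
      dif <- v1$value[match(seg, v1$segment)] -
        v0$value[match(seg, v0$segment)]
      acc[[length(acc) + 1]] <- data.frame(
        metric = metric, class = cls[seg], diff = dif)
    }
  }
  all <- do.call(rbind, acc)
  out <- expand.grid(metric = metrics, class = classes,
                     stringsAsFactors = FALSE)
  out$mean_diff <- NA_real_
  out$n <- 0L
  for (r in seq_len(nrow(out))) {
    sel <- all$metric == out$metric[r] & all$class == out$class[r]
    out$n[r] <- sum(sel)
    if (out$n[r] > 0) out$mean_diff[r] <- mean(all$diff[sel])
  }
  out
}
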