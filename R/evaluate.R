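#' Evaluation configuration
#'
#' @param threshold Operating confidence cutoff; positive iff the per-image
#'   maximum confidence is greater than or equal to it (default 0.61, the
#'   modelled operating point).
#' @param pretest_probability Pre-test fracture probability used for
#'   post-test updates (default 0.47).
#' @param bootstrap_samples Bootstrap replicates for AUC confidence
#'   intervals (default 1e5; scale down for quick runs).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(threshold = 0.61, pretest_probability = 0.47,
                        bootstrap_samples = 1e5, ci_level = 0.95, seed = 1L) {
  stopifnot(threshold > 0, threshold < 1,
            pretest_probability > 0, pretest_probability < 1,
            bootstrap_samples >= 1, ci_level > 0, ci_level < 1)
  structure(list(threshold = threshold,
                 pretest_probability = pretest_probability,
                 bootstrap_samples = as.integer(bootstrap_samples),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "eval_config")
}

#' Image-level decision from a confidence map
#'
#' Records the maximum per-pixel confidence of the radiograph and compares
#' it (inclusively) against the operating threshold.
#'
#' @param map Confidence-map matrix with values in `[0, 1]`.
#' @param threshold Operating cutoff (default 0.61).
#' @param image_id,view,cast Metadata carried through to the prediction.
#' @return List with `image_id`, `view`, `max_confidence`, `decision`,
#'   `cast`.
#' @export
image_decision <- function(map, threshold = 0.61, image_id = NA_character_,
                           view = NA_character_, cast = FALSE) {
  stopifnot(is.matrix(map))
  if (any(map < 0) || any(map > 1)) stop("confidence map must lie in [0, 1]")
  mx <- max(map)
  list(image_id = image_id, view = view, max_confidence = mx,
       decision = mx >= threshold, cast = isTRUE(cast))
}

#' Examination-level decision from the two view predictions
#'
#' Either-rule: positive iff either view's maximum confidence reaches the
#' threshold. Mean-rule: positive iff the mean of the two maxima reaches it.
#'
#' @param pa,lat Image predictions (lists with `max_confidence`) for the
#'   postero-anterior and lateral views.
#' @param rule `"either"` (either view above threshold) or `"mean"`
#'   (confidence average).
#' @param threshold Operating cutoff (default 0.61).
#' @param exam_id Identifier carried through.
#' @return List with `exam_id`, `rule`, `score`, `decision`.
#' @export
exam_decision <- function(pa, lat, rule = c("either", "mean"),
                          threshold = 0.61, exam_id = NA_character_) {
  rule <- match.arg(rule)
  a <- pa$max_confidence; b <- lat$max_confidence
  if (rule == "either") {
    dec <- (a >= threshold) || (b >= threshold)
    score <- max(a, b)
  } else {
    score <- mean(c(a, b))
    dec <- score >= threshold
  }
  list(exam_id = exam_id, rule = rule, score = score, decision = dec)
}

#' Confusion matrix from binary predictions
#'
#' Fracture is the positive class.
#'
#' @param preds Logical (or 0/1) predictions.
#' @param truths Logical (or 0/1) ground truth of the same length.
#' @return An object of class `confusion_matrix` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(preds, truths) {
  preds <- as.logical(preds); truths <- as.logical(truths)
  if (length(preds) != length(truths)) stop("length mismatch")
  confusion_matrix(tp = sum(preds & truths), fp = sum(preds & !truths),
                   tn = sum(!preds & !truths), fn = sum(!preds & truths))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(actual = c("fracture", "normal"),
                              predicted = c("fracture", "normal")))
  print(m)
  invisible(x)
}

wald_ci <- function(p, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(max(0, p - z * se), min(1, p + z * se))
}

#' Diagnostic metric panel from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, PPV and NPV with Wald (normal
#' approximation) confidence intervals truncated to `[0, 1]`, plus positive
#' and negative likelihood ratios with log-method intervals. A metric with a
#' zero denominator is reported as `NA` (undefined), not zero.
#'
#' @param cm A [confusion_matrix()].
#' @param ci_level Confidence level (default 0.95).
#' @return A data frame of class `diagnostic_report`: columns `metric`,
#'   `estimate`, `lo`, `hi`, `n` (denominator).
#' @export
diagnostic_metrics <- function(cm, ci_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  prop_row <- function(metric, num, den) {
    if (den == 0) return(data.frame(metric = metric, estimate = NA_real_,
                                    lo = NA_real_, hi = NA_real_, n = 0L))
    p <- num / den
    ci <- wald_ci(p, den, ci_level)
    data.frame(metric = metric, estimate = p, lo = ci[1], hi = ci[2], n = den)
  }
  rows <- rbind(prop_row("sensitivity", tp, tp + fn),
                prop_row("specificity", tn, tn + fp),
                prop_row("accuracy", tp + tn, total),
                prop_row("ppv", tp, tp + fp),
                prop_row("npv", tn, tn + fn))

  sens <- if (tp + fn > 0) tp / (tp + fn) else NA
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  lr_row <- function(metric, lr, se_log) {
    if (!is.finite(lr) || is.na(lr))
      return(data.frame(metric = metric, estimate = NA_real_, lo = NA_real_,
                        hi = NA_real_, n = total))
    ci <- exp(log(lr) + c(-1, 1) * z * se_log)
    data.frame(metric = metric, estimate = lr, lo = ci[1], hi = ci[2],
               n = total)
  }
  lrp <- if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec) else NA
  se_lrp <- if (!is.na(lrp) && tp > 0 && fp > 0)
    sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)) else NA
  lrn <- if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec else NA
  se_lrn <- if (!is.na(lrn) && fn > 0 && tn > 0)
    sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)) else NA
  rows <- rbind(rows, lr_row("lr_pos", lrp, se_lrp), lr_row("lr_neg", lrn, se_lrn))
  class(rows) <- c("diagnostic_report", "data.frame")
  attr(rows, "cm") <- cm
  rows
}

#' @export
print.diagnostic_report <- function(x, ...) {
  y <- as.data.frame(x)
  fmt <- function(v, lr) ifelse(is.na(v), "--",
                                ifelse(lr, signif(v, 2), sprintf("%.2f", v)))
  lr <- y$metric %in% c("lr_pos", "lr_neg")
  cat(sprintf("%-12s %s (%s-%s)\n", y$metric, fmt(y$estimate, lr),
              fmt(y$lo, lr), fmt(y$hi, lr)), sep = "")
  invisible(x)
}

#' Positive and negative likelihood ratios
#'
#' `LR+ = sens / (1 - spec)`, `LR- = (1 - sens) / spec`.
#'
#' @param sens,spec Sensitivity and specificity in `[0, 1]`.
#' @return List with `lr_pos` and `lr_neg` (`NA` where the respective
#'   denominator vanishes).
#' @export
likelihood_ratios <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  list(lr_pos = if (spec < 1) sens / (1 - spec) else NA_real_,
       lr_neg = if (spec > 0) (1 - sens) / spec else NA_real_)
}

#' Post-test probability from a likelihood ratio
#'
#' Odds-form Bayes update: `post = o * lr / (1 + o * lr)` with pre-test odds
#' `o = pretest / (1 - pretest)`.
#'
#' @param pretest Pre-test probability in (0, 1).
#' @param lr Likelihood ratio (> 0).
#' @return Post-test probability.
#' @export
posttest_probability <- function(pretest, lr) {
  stopifnot(pretest > 0, pretest < 1, lr > 0)
  o <- pretest / (1 - pretest) * lr
  o / (1 + o)
}

# AUC via the rank (Mann-Whitney) identity; equals the trapezoidal area
# under the empirical ROC curve with tie handling.
auc_rank <- function(confidences, truths) {
  n1 <- sum(truths); n0 <- sum(!truths)
  r <- rank(confidences)
  (sum(r[truths]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and bootstrap AUC
#'
#' The ROC curve is swept over the observed confidence values (decision rule:
#' positive iff confidence >= threshold); the AUC is the trapezoidal area
#' under it. The confidence interval is the percentile interval over a
#' seeded case-resampling bootstrap; resampling is done at the level of
#' `units` (e.g. examinations), the natural independence unit, so that the
#' two views of one examination stay together.
#'
#' @param confidences Per-image (or per-exam) scores.
#' @param truths Logical ground truth.
#' @param cfg An [eval_config()] (bootstrap size, CI level, seed).
#' @param units Resampling unit identifiers (default: each case its own).
#' @return List with `roc` (data frame `threshold, fpr, tpr`), `auc`, and
#'   `ci` (bootstrap percentile interval).
#' @export
roc_auc <- function(confidences, truths, cfg = eval_config(),
                    units = seq_along(confidences)) {
  truths <- as.logical(truths)
  stopifnot(length(confidences) == length(truths))
  if (all(truths) || !any(truths))
    stop("ROC analysis needs both classes present")
  n1 <- sum(truths); n0 <- sum(!truths)

  thr <- sort(unique(confidences), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(confidences >= t & truths) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(confidences >= t & !truths) / n0, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  # close the curve at (1, 1) if the smallest threshold does not reach it
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    auc <- auc + (1 - roc$fpr[nrow(roc)]) * (roc$tpr[nrow(roc)] + 1) / 2

  uids <- unique(units)
  by_unit <- split(seq_along(confidences), match(units, uids))
  reps <- withr::with_seed(cfg$seed, {
    vapply(seq_len(cfg$bootstrap_samples), function(i) {
      u <- sample.int(length(uids), replace = TRUE)
      idx <- unlist(by_unit[u], use.names = FALSE)
      t <- truths[idx]
      if (all(t) || !any(t)) return(NA_real_)
      auc_rank(confidences[idx], t)
    }, numeric(1))
  })
  alpha <- (1 - cfg$ci_level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  list(roc = roc, auc = auc, ci = ci)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement with marginal-product expected agreement.
#'
#' @param labels_a,labels_b Equal-length logical (or 0/1) label vectors.
#' @return Kappa coefficient.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.logical(labels_a); b <- as.logical(labels_b)
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Per-group confusion breakdown
#'
#' Tallies a confusion matrix per level of a grouping factor (e.g. radiograph
#' system manufacturer) plus the overall total; the per-group counts
#' partition the totals.
#'
#' @param preds,truths Logical vectors.
#' @param groups Grouping vector of the same length.
#' @return Data frame with one row per group and a final `Total` row, columns
#'   `group, tp, fp, tn, fn`.
#' @export
group_confusions <- function(preds, truths, groups) {
  stopifnot(length(preds) == length(truths), length(preds) == length(groups))
  rows <- lapply(split(seq_along(preds), groups), function(idx) {
    cm <- confusion(preds[idx], truths[idx])
    data.frame(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
  })
  out <- cbind(group = names(rows), do.call(rbind, rows))
  tot <- confusion(preds, truths)
  out <- rbind(out, data.frame(group = "Total", tp = tot$tp, fp = tot$fp,
                               tn = tot$tn, fn = tot$fn))
  rownames(out) <- NULL
  out
}

#' Full test-set evaluation across strata
#'
#' Computes the diagnostic panel for five strata -- all single radiographs,
#' lateral only, postero-anterior only, either-rule examinations, mean-rule
#' examinations -- for all cases and for the no-cast subgroup, mirroring the
#' reporting layout of a two-view diagnostic study. AUC bootstrap resampling
#' is at the examination level throughout.
#'
#' @param predictions Data frame with columns `image_id, exam_id, view,
#'   max_confidence, cast, truth` (one row per radiograph), e.g. from
#'   [predict_exams()].
#' @param cfg An [eval_config()].
#' @param group_col Optional name of an additional column of `predictions`
#'   (e.g. `manufacturer`): adds a per-group examination-level confusion
#'   breakdown.
#' @return List with `reports` (long data frame: stratum, subgroup, metric,
#'   estimate, lo, hi, n), `auc` (per stratum/subgroup), `confusions`, and
#'   optionally `group_breakdown`.
#' @export
evaluate_testset <- function(predictions, cfg = eval_config(),
                             group_col = NULL) {
  req <- c("image_id", "exam_id", "view", "max_confidence", "cast", "truth")
  missing_cols <- setdiff(req, names(predictions))
  if (length(missing_cols))
    stop("predictions are missing columns: ", paste(missing_cols, collapse = ", "))
  pr <- predictions
  pr$truth <- as.logical(pr$truth)
  pr$cast <- as.logical(pr$cast)

  exams <- split(pr, pr$exam_id)
  bad <- names(exams)[vapply(exams, function(e)
    !setequal(e$view, c("postero_anterior", "lateral")) || nrow(e) != 2,
    logical(1))]
  if (length(bad))
    stop("examinations without exactly one view of each projection: ",
         paste(bad, collapse = ", "))
  exam_df <- do.call(rbind, lapply(exams, function(e) {
    pa <- e[e$view == "postero_anterior", ]
    lat <- e[e$view == "lateral", ]
    data.frame(exam_id = e$exam_id[1],
               score_either = max(pa$max_confidence, lat$max_confidence),
               score_mean = mean(c(pa$max_confidence, lat$max_confidence)),
               cast = any(e$cast), truth = e$truth[1],
               stringsAsFactors = FALSE)
  }))

  strata <- list(
    all_radiographs = list(score = pr$max_confidence, truth = pr$truth,
                           cast = pr$cast, unit = pr$exam_id),
    lateral = with(pr[pr$view == "lateral", ],
                   list(score = max_confidence, truth = truth, cast = cast,
                        unit = exam_id)),
    postero_anterior = with(pr[pr$view == "postero_anterior", ],
                            list(score = max_confidence, truth = truth,
                                 cast = cast, unit = exam_id)),
    exam_either = list(score = exam_df$score_either, truth = exam_df$truth,
                       cast = exam_df$cast, unit = exam_df$exam_id),
    exam_mean = list(score = exam_df$score_mean, truth = exam_df$truth,
                     cast = exam_df$cast, unit = exam_df$exam_id))

  reports <- list(); aucs <- list(); cms <- list()
  for (snm in names(strata)) {
    s <- strata[[snm]]
    for (sub in c("all", "no_cast")) {
      keep <- if (sub == "all") rep(TRUE, length(s$score)) else !s$cast
      if (!any(keep)) next
      score <- s$score[keep]; truth <- s$truth[keep]
      dec <- score >= cfg$threshold
      cm <- confusion(dec, truth)
      rep_df <- diagnostic_metrics(cm, cfg$ci_level)
      rep_df <- cbind(stratum = snm, subgroup = sub, as.data.frame(rep_df))
      reports[[paste(snm, sub)]] <- rep_df
      cms[[paste(snm, sub)]] <- cm
      if (any(truth) && !all(truth)) {
        ra <- roc_auc(score, truth, cfg, units = s$unit[keep])
        aucs[[paste(snm, sub)]] <- data.frame(
          stratum = snm, subgroup = sub, auc = ra$auc,
          lo = ra$ci[1], hi = ra$ci[2])
      }
    }
  }
  out <- list(reports = do.call(rbind, c(reports, list(make.row.names = FALSE))),
              auc = do.call(rbind, c(aucs, list(make.row.names = FALSE))),
              confusions = cms)
  if (!is.null(group_col)) {
    if (!group_col %in% names(pr)) stop("no column named ", group_col)
    gmap <- tapply(pr[[group_col]], pr$exam_id, function(x) x[1])
    dec <- exam_df$score_either >= cfg$threshold
    out$group_breakdown <- group_confusions(dec, exam_df$truth,
                                            unname(gmap[exam_df$exam_id]))
  }
  out
}
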