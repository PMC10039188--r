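test_that("image decisions use the inclusive maximum-confidence rule", {
  expect_false(image_decision(matrix(0, 5, 5), 0.61)$decision)
  m <- matrix(0.1, 5, 5); m[3, 4] <- 0.61
  d <- image_decision(m, 0.61)
  expect_true(d$decision)
  expect_identical(d$max_confidence, 0.61)
  withr::with_seed(1, r <- matrix(runif(400), 20))
  mx <- -Inf
  for (i in 1:20) for (j in 1:20) mx <- max(mx, r[i, j])  # brute-force scan
  expect_identical(image_decision(r, 0.5)$max_confidence, mx)
})

test_that("examination rules combine the two views as specified", {
  pa <- list(max_confidence = 0.9)
  lat <- list(max_confidence = 0.1)
  expect_true(exam_decision(pa, lat, "either", 0.61)$decision)
  expect_false(exam_decision(pa, lat, "mean", 0.61)$decision)

  withr::with_seed(2, {
    a <- runif(1000); b <- runif(1000); t <- 0.61
    for (i in seq_len(50)) {           # spot-check against direct re-evaluation
      k <- sample(1000, 1)
      e <- exam_decision(list(max_confidence = a[k]),
                         list(max_confidence = b[k]), "either", t)
      expect_identical(e$decision, a[k] >= t || b[k] >= t)
      m <- exam_decision(list(max_confidence = a[k]),
                         list(max_confidence = b[k]), "mean", t)
      expect_identical(m$decision, mean(c(a[k], b[k])) >= t)
    }
    either <- vapply(seq_len(1000), function(k)
      exam_decision(list(max_confidence = a[k]), list(max_confidence = b[k]),
                    "either", t)$decision, logical(1))
    expect_identical(either, a >= t | b >= t)
  })
})

test_that("confusion counting matches a brute-force tally", {
  cm <- confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(c(cm$fp, cm$fn), c(0L, 0L))
  cm2 <- confusion(rep(FALSE, 10), c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_identical(cm2$tp, 0L)
  expect_identical(cm2$fn, 6L)
  withr::with_seed(3, {
    p <- runif(200) > 0.5; t <- runif(200) > 0.4
    cm3 <- confusion(p, t)
    tally <- c(0, 0, 0, 0)
    for (i in 1:200) {
      if (p[i] && t[i]) tally[1] <- tally[1] + 1
      else if (p[i]) tally[2] <- tally[2] + 1
      else if (t[i]) tally[4] <- tally[4] + 1
      else tally[3] <- tally[3] + 1
    }
    expect_identical(c(cm3$tp, cm3$fp, cm3$tn, cm3$fn), as.integer(tally))
  })
})

test_that("metric identities hold and degenerate denominators give NA", {
  cm <- confusion_matrix(tp = 17, fp = 0, tn = 21, fn = 5)
  rep <- diagnostic_metrics(cm)
  spec_row <- rep[rep$metric == "specificity", ]
  expect_identical(spec_row$estimate, 1)
  expect_identical(spec_row$hi, 1)
  sens <- rep[rep$metric == "sensitivity", ]
  expect_identical(sens$estimate * (cm$tp + cm$fn), as.numeric(cm$tp))
  # accuracy is the prevalence-weighted convex combination of sens and spec
  prev <- (cm$tp + cm$fn) / (cm$tp + cm$fp + cm$tn + cm$fn)
  acc <- rep[rep$metric == "accuracy", ]$estimate
  expect_equal(acc, prev * sens$estimate +
                 (1 - prev) * rep[rep$metric == "specificity", ]$estimate)
  # LR+ undefined at perfect specificity
  expect_true(is.na(rep[rep$metric == "lr_pos", ]$estimate))

  empty_pos <- diagnostic_metrics(confusion_matrix(0, 3, 7, 0))
  expect_true(is.na(empty_pos[empty_pos$metric == "sensitivity", ]$estimate))
  expect_identical(empty_pos[empty_pos$metric == "ppv", ]$estimate, 0)
  no_pred_pos <- diagnostic_metrics(confusion_matrix(0, 0, 7, 2))
  expect_true(is.na(no_pred_pos[no_pred_pos$metric == "ppv", ]$estimate))
})

test_that("point estimates sit inside their confidence intervals", {
  withr::with_seed(4, for (i in 1:20) {
    cm <- confusion_matrix(rpois(1, 40) + 1, rpois(1, 10) + 1,
                           rpois(1, 30) + 1, rpois(1, 8) + 1)
    rep <- diagnostic_metrics(cm)
    ok <- !is.na(rep$estimate)
    expect_true(all(rep$estimate[ok] >= rep$lo[ok] - 1e-12))
    expect_true(all(rep$estimate[ok] <= rep$hi[ok] + 1e-12))
  })
})

test_that("likelihood ratios follow their defining identities", {
  expect_equal(likelihood_ratios(0.90, 0.90)$lr_pos, 9)
  expect_equal(signif(likelihood_ratios(0.86, 0.89)$lr_pos, 2), 7.8)
  expect_identical(likelihood_ratios(1, 0.5)$lr_neg, 0)
  expect_true(is.na(likelihood_ratios(0.9, 1)$lr_pos))
})

test_that("post-test probability follows the odds-form update", {
  expect_equal(posttest_probability(0.5, 1), 0.5)
  o <- 0.47 / 0.53
  expect_equal(posttest_probability(0.47, 7.8), o * 7.8 / (1 + o * 7.8))
  expect_gt(posttest_probability(0.47, 1e9), 1 - 1e-8)
})

test_that("AUC equals the normalized Mann-Whitney statistic, with ties", {
  withr::with_seed(5, {
    conf <- round(runif(100), 1)            # heavy ties
    truth <- runif(100) < 0.5
  })
  cfg <- eval_config(bootstrap_samples = 10, seed = 1)
  r <- roc_auc(conf, truth, cfg)
  expect_equal(r$auc, pairwise_auc(conf, truth), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(truth, conf, quiet = TRUE,
                                              direction = "<",
                                              levels = c(FALSE, TRUE)))),
               tolerance = 1e-12)
})

test_that("AUC is 1 under perfect separation and near 1/2 under independence", {
  cfg <- eval_config(bootstrap_samples = 10, seed = 1)
  sep <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE), cfg)
  expect_identical(sep$auc, 1)
  withr::with_seed(6, {
    conf <- runif(2000); truth <- runif(2000) < 0.5
  })
  expect_lt(abs(roc_auc(conf, truth, cfg)$auc - 0.5), 0.05)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE), cfg), "both classes")
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  withr::with_seed(7, {
    conf <- c(rbeta(400, 4, 2), rbeta(400, 2, 4))
    truth <- rep(c(TRUE, FALSE), each = 400)
  })
  cfg <- eval_config(bootstrap_samples = 400, seed = 9)
  w <- function(idx) {
    r <- roc_auc(conf[idx], truth[idx], cfg)
    r$ci[2] - r$ci[1]
  }
  small <- w(c(1:50, 401:450))              # n = 100
  large <- w(c(1:200, 401:600))             # n = 400, superset
  expect_gt(small, large)
  expect_gt(small / large, 1.2)
  expect_lt(small / large, 3.5)
})

test_that("Cohen's kappa reproduces hand-computed agreement", {
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  expect_identical(cohen_kappa(a, a), 1)
  b <- rep(c(TRUE, FALSE), each = 10)
  expect_identical(cohen_kappa(b, !b), -1)
  # arbitrary 2x2 table: kappa from the direct formula
  x <- c(rep(TRUE, 30), rep(TRUE, 10), rep(FALSE, 5), rep(FALSE, 55))
  y <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 55))
  po <- 85 / 100
  pe <- (40 / 100) * (35 / 100) + (60 / 100) * (65 / 100)
  expect_equal(cohen_kappa(x, y), (po - pe) / (1 - pe))
})

test_that("test-set evaluation reports all strata with consistent counts", {
  pr <- stub_prediction_table(40, seed = 21)
  cfg <- eval_config(threshold = 0.5, bootstrap_samples = 50, seed = 2)
  ev <- evaluate_testset(pr, cfg)
  ns <- ev$reports[ev$reports$metric == "accuracy" &
                     ev$reports$subgroup == "all", c("stratum", "n")]
  expect_identical(ns$n[ns$stratum == "all_radiographs"], 80L)
  expect_identical(ns$n[ns$stratum == "lateral"], 40L)
  expect_identical(ns$n[ns$stratum == "postero_anterior"], 40L)
  expect_identical(ns$n[ns$stratum == "exam_either"], 40L)
  expect_identical(ns$n[ns$stratum == "exam_mean"], 40L)

  # a perfect predictor scores 1.0 everywhere
  perfect <- pr
  perfect$max_confidence <- ifelse(perfect$truth, 0.95, 0.05)
  evp <- evaluate_testset(perfect, cfg)
  props <- evp$reports[evp$reports$metric %in%
                         c("sensitivity", "specificity", "accuracy",
                           "ppv", "npv"), ]
  expect_true(all(props$estimate == 1))
  expect_true(all(evp$auc$auc == 1))
})

test_that("the either rule dominates the mean rule and each single view", {
  pr <- stub_prediction_table(60, seed = 33)
  cfg <- eval_config(threshold = 0.5, bootstrap_samples = 10, seed = 1)
  ev <- evaluate_testset(pr, cfg)
  sens <- function(s) {
    r <- ev$reports
    r[r$stratum == s & r$subgroup == "all" & r$metric == "sensitivity",
      ]$estimate
  }
  expect_gte(sens("exam_either"), sens("exam_mean"))
  expect_gte(sens("exam_either"), max(sens("lateral"), sens("postero_anterior")))
})

test_that("per-group confusion counts partition the totals", {
  withr::with_seed(8, {
    p <- runif(120) > 0.4
    t <- runif(120) > 0.5
    g <- sample(c("A", "B", "C"), 120, TRUE)
  })
  br <- group_confusions(p, t, g)
  tot <- br[br$group == "Total", ]
  parts <- br[br$group != "Total", ]
  for (col in c("tp", "fp", "tn", "fn"))
    expect_identical(sum(parts[[col]]), tot[[col]])
})
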