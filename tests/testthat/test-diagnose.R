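# Adequacy rule, slide classifiers, cascade fusion and metric arithmetic.

feat_vec <- function(...) {
  v <- stats::setNames(numeric(104), registry_default()$name)
  args <- list(...)
  for (nm in names(args)) v[nm] <- args[[nm]]
  v
}

test_that("the adequacy rule reproduces its printed boundary cases", {
  expect_true(tbs1_rule(feat_vec()))                       # 0 < 60
  expect_false(tbs1_rule(feat_vec(`N-TFECA` = 6)))         # 60 < 60 fails
  expect_true(tbs1_rule(feat_vec(`N-TFECA` = 5, `N-TFECB` = 1)))  # 55
  expect_error(tbs1_rule(feat_vec(`N-PTCA` = -1)), "negative")
  expect_error(decision_rule_params(GLOB_CELL = 0), "positive")
})

test_that("the rule is monotone: raising any count never turns an
           inadequate slide adequate", {
  violations <- with_seed(1234, {
    bad <- 0L
    for (i in 1:10000) {
      counts <- stats::rpois(4, 3)
      v <- feat_vec(`N-PTCA` = counts[1], `N-PTCB` = counts[2],
                    `N-TFECA` = counts[3], `N-TFECB` = counts[4])
      if (!tbs1_rule(v)) {
        j <- sample(4, 1)
        nm <- c("N-PTCA", "N-PTCB", "N-TFECA", "N-TFECB")[j]
        v[nm] <- v[nm] + sample(1:5, 1)
        if (tbs1_rule(v)) bad <- bad + 1L
      }
    }
    bad
  })
  expect_identical(violations, 0L)
})

test_that("cascade fusion is exactly the published three-case mapping", {
  for (w in c("I", "II", "V", "VI"))
    for (g in list(0L, 1L, NA_integer_)) {
      out <- cascade_fuse(w, g)
      if (w == "V" && !is.na(g)) {
        expect_identical(out, if (g == 0) "II" else "VI")
      } else {
        expect_identical(out, w)
      }
    }
})

test_that("Wald intervals and sensitivities reproduce the published
           ambiguous-lesion table to print precision", {
  t3 <- matrix(c(16, 27 + 17 + 34, 122 + 2 + 82 + 56, 27 + 1 + 28 + 15), 1,
               dimnames = list("III", c("I", "II", "V", "VI")))
  s3 <- metrics_from_counts(t3, positive_set = c("V", "VI"))
  expect_equal(round(subset(s3, metric == "sensitivity")$value * 100, 2),
               77.99)
  ci3 <- subset(s3, metric == "sensitivity")
  expect_equal(round(c(ci3$conf_low, ci3$conf_high), 4), c(0.7406, 0.8192))

  t4 <- matrix(c(0, 27, 31 + 54 + 25, 57 + 1 + 91 + 6), 1,
               dimnames = list("IV", c("I", "II", "V", "VI")))
  s4 <- subset(metrics_from_counts(t4, positive_set = c("V", "VI")),
               metric == "sensitivity")
  expect_equal(round(s4$value * 100, 2), 90.75)
  expect_equal(round(c(s4$conf_low, s4$conf_high), 4), c(0.8743, 0.9408))

  tot <- t3 + t4
  st <- subset(metrics_from_counts(tot, positive_set = c("V", "VI")),
               metric == "sensitivity")
  expect_equal(round(st$value * 100, 2), 83.17)
  expect_equal(round(c(st$conf_low, st$conf_high), 4), c(0.8044, 0.8591))
})

test_that("zero positives give sensitivity 0 with a degenerate interval", {
  t0 <- matrix(c(10, 5, 0, 0), 1,
               dimnames = list("III", c("I", "II", "V", "VI")))
  s <- subset(metrics_from_counts(t0, positive_set = c("V", "VI")),
              metric == "sensitivity")
  expect_equal(s$value, 0)
  expect_equal(c(s$conf_low, s$conf_high), c(0, 0))
})

test_that("metrics equal a brute-force per-sample recount on random
           confusion tables", {
  labs <- c("I", "II", "V", "VI")
  for (rep in 1:100) {
    counts <- with_seed(rep, matrix(stats::rpois(16, 6), 4,
                                    dimnames = list(labs, labs)))
    m <- metrics_from_counts(counts, positive_set = c("V", "VI"),
                             truth_positive = c("V", "VI"))
    # expand to per-sample records and recount
    truth <- rep(rep(labs, times = 4), times = as.vector(t(counts)))
    pred <- rep(rep(labs, each = 4), times = as.vector(counts))
    # rebuild in matching order: iterate cells explicitly instead
    truth <- c(); pred <- c()
    for (i in 1:4) for (j in 1:4) {
      truth <- c(truth, rep(labs[i], counts[i, j]))
      pred <- c(pred, rep(labs[j], counts[i, j]))
    }
    tpos <- truth %in% c("V", "VI"); ppos <- pred %in% c("V", "VI")
    expect_equal(subset(m, metric == "sensitivity")$value,
                 sum(tpos & ppos) / sum(tpos))
    expect_equal(subset(m, metric == "specificity")$value,
                 sum(!tpos & !ppos) / sum(!tpos))
    expect_equal(subset(m, metric == "accuracy")$value,
                 mean(truth == pred))
    expect_equal(subset(m, metric == "precision")$value,
                 sum(tpos & ppos) / sum(ppos))
  }
})

test_that("slide classifier training: CV benchmark, class ordering
           determinism and data errors", {
  cfg <- synth_config(patch_size = 64L, nuclei_range = c(4L, 8L))
  slides <- cached("gbt_slides", function()
    render_cohort(300, cfg, seed = 21, n_tiles = 2))
  truth <- vapply(slides, `[[`, character(1), "true_tbs")
  keep <- truth != "I"
  fm <- feature_matrix(lapply(which(keep), function(i)
    features_from_truth(slides[[i]], seed = i)))
  labs <- truth[keep]

  small_grid <- default_wsi_grid()[c(1, 5), ]
  fit3 <- train_wsi_gbt(fm, labs, n_classes = 3, grid = small_grid,
                        seed = 0)
  expect_gte(fit3$cv_accuracy, 0.85)
  fit3b <- train_wsi_gbt(fm, labs, n_classes = 3, grid = small_grid,
                         seed = 0)
  expect_identical(glance(fit3), glance(fit3b))
  expect_identical(dim(tidy(fit3)), dim(tidy(fit3b)))

  fit2 <- train_wsi_gbt(fm, labs, n_classes = 2, grid = small_grid,
                        seed = 0)
  expect_gte(fit2$cv_accuracy, fit3$cv_accuracy)

  few <- c(rep("II", 20), rep("V", 3))
  expect_error(train_wsi_gbt(fm[1:23, ], few, grid = small_grid),
               "fewer than")
})

test_that("stage ordering: the classifier is never consulted on an
           inadequate slide", {
  cfg <- synth_config(patch_size = 64L, nuclei_range = c(4L, 8L))
  slides <- cached("gbt_slides", function()
    render_cohort(300, cfg, seed = 21, n_tiles = 2))
  truth <- vapply(slides, `[[`, character(1), "true_tbs")
  keep <- truth != "I"
  fm <- feature_matrix(lapply(which(keep), function(i)
    features_from_truth(slides[[i]], seed = i)))
  fit <- train_wsi_gbt(fm, truth[keep], grid = default_wsi_grid()[1, ],
                       seed = 0)

  inadequate <- feat_vec()  # all counts zero
  attr(inadequate, "registry_version") <- "v1"
  r <- predict_tbs(inadequate, fit)
  expect_identical(r$final, "I")
  expect_false(r$classifier_invoked)

  adequate <- features_from_truth(slides[[which(keep)[1]]], seed = 1)
  r2 <- predict_tbs(adequate, fit)
  expect_true(r2$classifier_invoked)
  expect_true(r2$final %in% fit$classes)
  expect_gte(max(r2$probs), 1 / 3)

  bad <- adequate
  attr(bad, "registry_version") <- "v999"
  expect_error(predict_tbs(bad, fit), "registry version")
})

test_that("gene classifier learns the fixture's logistic link and rejects
           degenerate labels", {
  cfg <- synth_config(patch_size = 64L, nuclei_range = c(4L, 8L))
  slides <- cached("gbt_slides", function()
    render_cohort(300, cfg, seed = 21, n_tiles = 2))
  truth <- vapply(slides, `[[`, character(1), "true_tbs")
  braf <- vapply(slides, `[[`, numeric(1), "braf")
  fm <- feature_matrix(lapply(seq_along(slides), function(i)
    features_from_truth(slides[[i]], seed = i)))
  idx <- with_seed(5, sample.int(length(slides)))
  tr <- idx[1:200]; te <- idx[201:length(idx)]
  fit <- train_gene_gbt(fm[tr, ], braf[tr], seed = 0)
  pred <- predict_gene(fm[te, ], fit)
  balacc <- mean(c(mean(pred$gene_pred[braf[te] == 1] == 1),
                   mean(pred$gene_pred[braf[te] == 0] == 0)))
  expect_gte(balacc, 0.75)
  fitb <- train_gene_gbt(fm[tr, ], braf[tr], seed = 0)
  expect_identical(predict_gene(fm[te, ], fitb), pred)
  expect_error(train_gene_gbt(fm[tr, ], rep(0, 200)), "both BRAF")
})
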