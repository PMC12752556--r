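# Slide-level diagnosis: the Bethesda-I adequacy rule, gradient-boosted
# whole-slide classifiers (3-class and 2-class), the BRAF gene classifier,
# the cascade fusion step, and evaluation metrics with Wald intervals.

#' Adequacy decision-rule parameters
#'
#' The rule weights epithelial group counts by the average cells per group:
#' `AVG_A` cells for the large-group classes (PTCA, TFECA), `AVG_B` for the
#' small-group classes (PTCB, TFECB), against the total-cell adequacy
#' threshold `GLOB_CELL`. Published defaults: 10, 5 and 60 (the
#' six-groups-of-ten follicular-cell adequacy convention).
#'
#' @param AVG_A cells per large group (default 10).
#' @param AVG_B cells per small group (default 5).
#' @param GLOB_CELL adequacy cell-count threshold (default 60).
#' @return object of class `decision_rule_params`.
#' @export
decision_rule_params <- function(AVG_A = 10, AVG_B = 5, GLOB_CELL = 60) {
  if (AVG_A <= 0 || AVG_B <= 0 || GLOB_CELL <= 0)
    stop("rule parameters must be strictly positive", call. = FALSE)
  structure(list(AVG_A = AVG_A, AVG_B = AVG_B, GLOB_CELL = GLOB_CELL),
            class = "decision_rule_params")
}

# Left-hand side of the adequacy rule on a named feature vector.
adequacy_lhs <- function(features, params = decision_rule_params()) {
  n <- function(r) features[[paste0("N-", r)]]
  counts <- c(n("PTCA"), n("TFECA"), n("PTCB"), n("TFECB"))
  if (any(counts < 0)) stop("negative role counts", call. = FALSE)
  params$AVG_A * (n("PTCA") + n("TFECA")) +
    params$AVG_B * (n("PTCB") + n("TFECB"))
}

#' The Bethesda-I (nondiagnostic) adequacy rule
#'
#' Returns `TRUE` (slide is TBS I) when the weighted epithelial group count
#' `AVG_A * (N-PTCA + N-TFECA) + AVG_B * (N-PTCB + N-TFECB)` is strictly
#' below `GLOB_CELL`. The grouping follows the parameter definitions:
#' `AVG_A` is the average cell count of a PTCA/TFECA group and `AVG_B` of a
#' PTCB/TFECB group, so each weight multiplies the sum of its two group
#' counts; with the default 60 threshold this is the conventional "six
#' groups of ten follicular cells" adequacy minimum.
#'
#' @param features named numeric vector (or one-row data frame) containing
#'   `N-PTCA`, `N-TFECA`, `N-PTCB`, `N-TFECB`; counts must be non-negative.
#' @param params a [decision_rule_params()].
#' @return logical: `TRUE` means nondiagnostic (TBS I).
#' @export
tbs1_rule <- function(features, params = decision_rule_params()) {
  adequacy_lhs(features, params) < params$GLOB_CELL
}

default_wsi_grid <- function() {
  expand.grid(max_depth = c(3L, 5L, 7L), eta = c(0.05, 0.1, 0.3),
              nrounds = c(100L, 300L), subsample = c(0.8, 1.0),
              KEEP.OUT.ATTRS = FALSE)
}

# Stratified fold assignment, deterministic under the current RNG state.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train a whole-slide gradient-boosted classifier with grid-search CV
#'
#' Stratified 5-fold cross-validation over a hyper-parameter grid; the best
#' configuration (highest mean CV accuracy, ties to the first grid row) is
#' refit on all data. For the 2-class model the TBS V and VI labels are
#' merged into `"V+VI"` before training.
#'
#' @param features feature tibble/matrix whose columns include the registry
#'   feature names (a `slide_id` column is ignored).
#' @param labels character vector over `"II"`, `"V"`, `"VI"`.
#' @param n_classes 3 (II/V/VI) or 2 (II vs V+VI).
#' @param grid hyper-parameter grid (data frame with `max_depth`, `eta`,
#'   `nrounds`, `subsample`).
#' @param search_budget maximum number of grid rows evaluated (first rows
#'   kept; `Inf` = all).
#' @param folds number of CV folds.
#' @param fold_assign optional precomputed fold assignment (integer vector
#'   in `1..folds`), so two models can be compared on the same split.
#' @param seed RNG seed; identical data and seed give identical chosen
#'   hyper-parameters and fits.
#' @param registry registry whose version is stamped on the model.
#' @return object of class `wsi_gbt` with the booster, label levels, CV
#'   report (`cv_report`), and chosen configuration (`best`).
#' @export
train_wsi_gbt <- function(features, labels, n_classes = 3L,
                          grid = default_wsi_grid(), search_budget = Inf,
                          folds = 5L, fold_assign = NULL, seed = 0L,
                          registry = registry_default()) {
  stopifnot(n_classes %in% c(2L, 3L))
  labels <- as.character(labels)
  if (!all(labels %in% c("II", "V", "VI")))
    stop("labels must be II, V or VI", call. = FALSE)
  if (n_classes == 2L) labels[labels %in% c("V", "VI")] <- "V+VI"
  X <- as.matrix(features[, registry$name, drop = FALSE])
  lev <- sort(unique(labels))
  tab <- table(labels)
  if (any(tab < folds))
    stop("class ", names(tab)[which.min(tab)], " has fewer than ", folds,
         " samples", call. = FALSE)
  y <- match(labels, lev) - 1L
  if (is.finite(search_budget)) grid <- grid[seq_len(min(nrow(grid),
                                                         search_budget)), ]
  with_seed(seed, {
    fold <- fold_assign %||% stratified_folds(labels, folds)
    report <- vector("list", nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      g <- grid[gi, ]
      accs <- numeric(folds)
      for (f in seq_len(folds)) {
        tr <- fold != f
        bst <- xgboost::xgb.train(
          params = list(objective = "multi:softprob",
                        num_class = length(lev), max_depth = g$max_depth,
                        eta = g$eta, subsample = g$subsample, nthread = 1,
                        seed = seed),
          data = xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                                      nthread = 1),
          nrounds = g$nrounds, verbose = 0)
        pr <- predict_prob_matrix(bst, X[!tr, , drop = FALSE], length(lev))
        accs[f] <- mean(max.col(pr, ties.method = "first") - 1L == y[!tr])
      }
      report[[gi]] <- cbind(g, fold_acc = t(accs), cv_accuracy = mean(accs))
    }
    report <- tibble::as_tibble(do.call(rbind, report))
    best_i <- which.max(report$cv_accuracy)
    g <- grid[best_i, ]
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(lev),
                    max_depth = g$max_depth, eta = g$eta,
                    subsample = g$subsample, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = g$nrounds, verbose = 0)
    structure(list(booster = booster, classes = lev, n_classes = n_classes,
                   cv_report = report, best = g,
                   cv_accuracy = report$cv_accuracy[best_i],
                   registry_version = registry_version(registry),
                   feature_names = registry$name),
              class = "wsi_gbt")
  })
}

#' Train the BRAF-V600E gene classifier
#'
#' Binary gradient-boosted model on the same slide feature vectors.
#'
#' @param features feature tibble/matrix (registry columns).
#' @param braf 0/1 labels; both values must be present.
#' @param nrounds,max_depth,eta boosting parameters.
#' @param seed RNG seed.
#' @param registry registry whose version is stamped on the model.
#' @return object of class `gene_gbt`.
#' @export
train_gene_gbt <- function(features, braf, nrounds = 80L, max_depth = 3L,
                           eta = 0.2, seed = 0L,
                           registry = registry_default()) {
  braf <- as.integer(braf)
  if (length(unique(braf)) < 2)
    stop("both BRAF labels (0 and 1) must be present", call. = FALSE)
  X <- as.matrix(features[, registry$name, drop = FALSE])
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = braf, nthread = 1),
    nrounds = nrounds, verbose = 0))
  structure(list(booster = booster,
                 registry_version = registry_version(registry),
                 feature_names = registry$name),
            class = "gene_gbt")
}

#' Predict BRAF status for slide feature vectors
#' @param features feature tibble/matrix or single named vector.
#' @param model a [train_gene_gbt()] fit.
#' @param threshold probability cut for calling a mutation.
#' @return tibble with `gene_prob` and `gene_pred` (0/1).
#' @export
predict_gene <- function(features, model, threshold = 0.5) {
  stopifnot(inherits(model, "gene_gbt"))
  X <- features_as_matrix(features, model$feature_names)
  p <- as.numeric(stats::predict(model$booster,
                                 xgboost::xgb.DMatrix(X, nthread = 1)))
  tibble::tibble(gene_prob = p, gene_pred = as.integer(p >= threshold))
}

features_as_matrix <- function(features, feature_names) {
  if (is.numeric(features) && is.null(dim(features)))
    features <- as.data.frame(as.list(features), check.names = FALSE)
  as.matrix(features[, feature_names, drop = FALSE])
}

#' Two-stage Bethesda prediction for one slide
#'
#' Stage 1 evaluates the adequacy rule; only on a pass is the whole-slide
#' classifier invoked. The returned `final` label is the pre-cascade result
#' (`TBS_I` or the classifier's prediction); apply [cascade_fuse()] with a
#' gene prediction to resolve `TBS_V`.
#'
#' @param features named slide feature vector (or one-row tibble) carrying
#'   a `registry_version` attribute compatible with the model.
#' @param wsi_model a [train_wsi_gbt()] fit.
#' @param rule_params a [decision_rule_params()].
#' @return list of class `tbs_result`: `stage1` (`"TBS_I"` or `"PASS"`),
#'   `wsi_pred` (`NA` when stage 1 fires), `probs` (named classifier
#'   probabilities or `NULL`), `final`, `classifier_invoked`, `adeq_lhs`.
#' @export
predict_tbs <- function(features, wsi_model, rule_params = decision_rule_params()) {
  stopifnot(inherits(wsi_model, "wsi_gbt"))
  ver <- attr(features, "registry_version")
  if (!is.null(ver) && !identical(ver, wsi_model$registry_version))
    stop("feature registry version ", ver, " does not match model version ",
         wsi_model$registry_version, call. = FALSE)
  lhs <- adequacy_lhs(features, rule_params)
  if (lhs < rule_params$GLOB_CELL) {
    return(structure(list(stage1 = "TBS_I", wsi_pred = NA_character_,
                          probs = NULL, final = "I",
                          classifier_invoked = FALSE, adeq_lhs = lhs),
                     class = "tbs_result"))
  }
  X <- features_as_matrix(features, wsi_model$feature_names)
  pr <- predict_prob_matrix(wsi_model$booster, X,
                            length(wsi_model$classes))
  pr <- stats::setNames(as.numeric(pr[1, ]), wsi_model$classes)
  k <- which.max(pr)
  structure(list(stage1 = "PASS", wsi_pred = names(pr)[k], probs = pr,
                 final = names(pr)[k], classifier_invoked = TRUE,
                 adeq_lhs = lhs),
            class = "tbs_result")
}

#' Cascade fusion of the whole-slide and gene predictions
#'
#' The gene call is consulted only when the whole-slide classifier outputs
#' TBS V: `V + 0 -> II`, `V + 1 -> VI`; every other prediction passes
#' through, as does TBS V when no gene prediction is available.
#'
#' @param wsi_pred character vector of slide predictions (`"I"`, `"II"`,
#'   `"V"`, `"VI"`, `"V+VI"`).
#' @param gene_pred integer 0/1 vector, `NA` for absent.
#' @return character vector of final labels.
#' @export
cascade_fuse <- function(wsi_pred, gene_pred = NA_integer_) {
  gene_pred <- rep_len(gene_pred, length(wsi_pred))
  out <- wsi_pred
  sel <- wsi_pred == "V" & !is.na(gene_pred)
  out[sel & gene_pred == 0] <- "II"
  out[sel & gene_pred == 1] <- "VI"
  out
}

#' Wald confidence interval for a binomial proportion
#'
#' `p +/- z * sqrt(p (1 - p) / n)`, clipped to `[0, 1]`;
#' `z = 1.959964` at `alpha = 0.05`.
#'
#' @param p observed proportion.
#' @param n sample size.
#' @param alpha two-sided level.
#' @return numeric `c(lower, upper)`.
#' @export
wald_ci <- function(p, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}

#' Evaluation metrics from a confusion table, with Wald intervals
#'
#' `counts` is an integer table with true labels on rows and predicted
#' labels on columns. A prediction is called positive when it falls in
#' `positive_set`; a sample is truth-positive when its row label is in
#' `truth_positive` (default: every row, matching sensitivity panels where
#' all tabulated samples are known positives). Metrics with an undefined
#' denominator are reported as `NA`.
#'
#' @param counts matrix/table with dimnames (rows = true, cols = predicted).
#' @param positive_set predicted labels counted as positive calls.
#' @param truth_positive row labels counted as truth-positive.
#' @param alpha level for the Wald intervals.
#' @return tibble with `metric`, `value`, `n`, `conf_low`, `conf_high`.
#' @export
metrics_from_counts <- function(counts, positive_set,
                                truth_positive = rownames(counts),
                                alpha = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  rn <- rownames(counts); cn <- colnames(counts)
  pos_row <- rn %in% truth_positive
  pos_col <- cn %in% positive_set
  tp <- sum(counts[pos_row, pos_col, drop = FALSE])
  fn <- sum(counts[pos_row, !pos_col, drop = FALSE])
  fp <- sum(counts[!pos_row, pos_col, drop = FALSE])
  tn <- sum(counts[!pos_row, !pos_col, drop = FALSE])
  total <- sum(counts)
  diag_sum <- if (!is.null(rn) && !is.null(cn) && any(rn %in% cn))
    sum(counts[cbind(rn[rn %in% cn], rn[rn %in% cn])]) else NA_real_

  row_of <- function(metric, num, den) {
    if (is.na(den) || den == 0)
      return(tibble::tibble(metric = metric, value = NA_real_, n = den,
                            conf_low = NA_real_, conf_high = NA_real_))
    p <- num / den
    ci <- wald_ci(p, den, alpha)
    tibble::tibble(metric = metric, value = p, n = den,
                   conf_low = ci[["lower"]], conf_high = ci[["upper"]])
  }
  sens <- row_of("sensitivity", tp, tp + fn)
  prec <- row_of("precision", tp, tp + fp)
  f1 <- if (!is.na(sens$value) && !is.na(prec$value) &&
            (sens$value + prec$value) > 0) {
    tibble::tibble(metric = "f1", n = NA_real_,
                   value = 2 * sens$value * prec$value /
                     (sens$value + prec$value),
                   conf_low = NA_real_, conf_high = NA_real_)
  } else {
    tibble::tibble(metric = "f1", value = NA_real_, n = NA_real_,
                   conf_low = NA_real_, conf_high = NA_real_)
  }
  dplyr::bind_rows(
    sens,
    row_of("specificity", tn, tn + fp),
    row_of("accuracy", diag_sum, if (is.na(diag_sum)) NA_real_ else total),
    prec,
    dplyr::mutate(sens, metric = "recall"),
    f1[, c("metric", "value", "n", "conf_low", "conf_high")]
  )
}

#' @export
print.tbs_result <- function(x, ...) {
  cat("<tbs_result> stage1 ", x$stage1, ", final TBS ", x$final,
      " (adequacy LHS ", x$adeq_lhs, ")\n", sep = "")
  invisible(x)
}

#' @export
print.wsi_gbt <- function(x, ...) {
  cat("<wsi_gbt> ", x$n_classes, "-class (", paste(x$classes, collapse = "/"),
      "), CV accuracy ", round(x$cv_accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-configuration cross-validation report of a slide classifier
#' @param x a `wsi_gbt` fit.
#' @param ... unused.
#' @return the CV report tibble (one row per grid configuration).
#' @exportS3Method generics::tidy
tidy.wsi_gbt <- function(x, ...) x$cv_report

#' One-row summary of a slide classifier fit
#' @param x a `wsi_gbt` fit.
#' @param ... unused.
#' @return tibble with the chosen configuration and CV accuracy.
#' @exportS3Method generics::glance
glance.wsi_gbt <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$best),
                   tibble::tibble(cv_accuracy = x$cv_accuracy,
                                  n_classes = x$n_classes))
}
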