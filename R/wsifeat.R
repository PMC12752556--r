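# Slide-level feature aggregation: turns per-cell calls, detections and
# nuclear morphometry into the 104-attribute slide feature vector consumed
# by the diagnosis classifiers.
#
# The default registry is this package's documented composition reaching
# exactly 104 attributes, built only from the statistic families the
# slide-level symbols name: per-role object counts (N-*), mean/median
# classification probabilities (AVG-P-*, MEDI-P-*), mean/median detection
# scores (AVG-SC-*, MEDI-SC-*), global mean/median nuclear morphology
# (AVG-*-NUCLEAR, MEDI-*-NUCLEAR over the 19 features), per-role areas
# (AVG-AREA-*, MEDI-AREA-*), and three totals (TOTAL-DET, TOTAL-CLUSTER,
# ADEQ-LHS). Empty roles use a 0 sentinel, not missing values, so the tree
# models need no missing handling.

#' The default, versioned slide feature registry
#'
#' @return object of class `feature_registry`: a tibble of ordered feature
#'   names (104 under version `"v1"`) with a `version` attribute.
#' @export
registry_default <- function() {
  rl <- roles()
  nm <- c(paste0("N-", rl),
          paste0("AVG-P-", rl), paste0("MEDI-P-", rl),
          paste0("AVG-SC-", rl), paste0("MEDI-SC-", rl),
          paste0("AVG-", morpho_feature_names(), "-NUCLEAR"),
          paste0("MEDI-", morpho_feature_names(), "-NUCLEAR"),
          paste0("AVG-AREA-", rl), paste0("MEDI-AREA-", rl),
          "TOTAL-DET", "TOTAL-CLUSTER", "ADEQ-LHS")
  stopifnot(length(nm) == 104, !anyDuplicated(nm))
  structure(tibble::tibble(name = nm), version = "v1",
            class = c("feature_registry", "tbl_df", "tbl", "data.frame"))
}

registry_version <- function(registry) attr(registry, "version") %||% "v1"

#' Aggregate per-cell calls into the slide feature vector
#'
#' Role statistics are computed over `final_class` roles; calls with
#' `final_class == "REJECTED"` must be excluded before calling (they do not
#' enter the next step). Cluster-kind detections contribute to counts,
#' scores and areas but not to the global nuclear morphology statistics,
#' which pool nucleus-kind objects only.
#'
#' @param calls tibble with one row per accepted cell: `detection_id`,
#'   `final_class`, `prob` (classification probability of the called
#'   class), `score` (detection score), `kind`, and the 19 morphometry
#'   feature columns (whose `area` doubles as the per-call area).
#' @param registry a [registry_default()] (or compatible) registry.
#' @param rule_params a [decision_rule_params()] for the adequacy
#'   left-hand side.
#' @param schema a [class_schema()].
#' @return named numeric vector of length `nrow(registry)` (104 for the
#'   default), carrying a `registry_version` attribute.
#' @export
aggregate_slide_features <- function(calls, registry = registry_default(),
                                     rule_params = decision_rule_params(),
                                     schema = class_schema()) {
  if (nrow(calls) > 0 && anyDuplicated(calls$detection_id))
    stop("duplicate detection references in calls", call. = FALSE)
  if (nrow(calls) > 0 && any(calls$final_class == "REJECTED"))
    stop("REJECTED calls must be excluded before aggregation", call. = FALSE)
  rl <- roles()
  v <- stats::setNames(numeric(nrow(registry)), registry$name)

  role <- if (nrow(calls)) role_of_class(calls$final_class, schema)
  else character(0)
  med <- function(x) if (length(x)) stats::median(x) else 0
  avg <- function(x) if (length(x)) mean(x) else 0
  for (r in rl) {
    sel <- role == r
    v[paste0("N-", r)] <- sum(sel)
    v[paste0("AVG-P-", r)] <- avg(calls$prob[sel])
    v[paste0("MEDI-P-", r)] <- med(calls$prob[sel])
    v[paste0("AVG-SC-", r)] <- avg(calls$score[sel])
    v[paste0("MEDI-SC-", r)] <- med(calls$score[sel])
    v[paste0("AVG-AREA-", r)] <- avg(calls$area[sel])
    v[paste0("MEDI-AREA-", r)] <- med(calls$area[sel])
  }
  nuc <- if (nrow(calls)) calls[calls$kind == "nucleus", , drop = FALSE]
  else calls
  for (f in morpho_feature_names()) {
    col <- if (nrow(nuc)) nuc[[f]] else numeric(0)
    v[paste0("AVG-", f, "-NUCLEAR")] <- avg(col)
    v[paste0("MEDI-", f, "-NUCLEAR")] <- med(col)
  }
  v["TOTAL-DET"] <- nrow(calls)
  v["TOTAL-CLUSTER"] <- if (nrow(calls)) sum(calls$kind == "cluster") else 0
  v["ADEQ-LHS"] <- adequacy_lhs(v, rule_params)
  attr(v, "registry_version") <- registry_version(registry)
  v
}

#' Bind slide feature vectors into a feature matrix
#' @param feature_list list of vectors from [aggregate_slide_features()].
#' @param slide_ids optional identifiers.
#' @return tibble with `slide_id` plus one column per feature.
#' @export
feature_matrix <- function(feature_list, slide_ids = NULL) {
  m <- do.call(rbind, feature_list)
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(
    tibble::tibble(slide_id = slide_ids %||% seq_along(feature_list)), out)
  out
}
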