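# Slide feature aggregation: the 104-name registry and the statistics it
# drives.

mk_call <- function(id, class, prob = 0.9, score = 0.8, area = 200,
                    kind = "nucleus") {
  feats <- as.list(stats::setNames(rep(1, 19), morpho_feature_names()))
  feats$area <- area
  dplyr::bind_cols(
    tibble::tibble(detection_id = id, kind = kind, score = score,
                   net_class = class, prob = prob,
                   morpho_class = role_of_class(class), agreed = TRUE,
                   final_class = class),
    tibble::as_tibble(feats[morpho_feature_names()]))
}

test_that("the default registry has 104 unique, stably ordered names", {
  r1 <- registry_default(); r2 <- registry_default()
  expect_equal(nrow(r1), 104)
  expect_false(anyDuplicated(r1$name) > 0)
  expect_identical(r1$name, r2$name)
})

test_that("an empty slide yields an all-zero vector of length 104", {
  v <- aggregate_slide_features(thyrocyto:::empty_calls())
  expect_length(v, 104)
  expect_true(all(v == 0))
  expect_identical(names(v), registry_default()$name)
})

test_that("singleton and small-group statistics are exact", {
  one <- mk_call(1L, "C1", prob = 0.9, score = 0.8, area = 200)
  v <- aggregate_slide_features(one)
  expect_equal(v[["N-PTCA"]], 1)
  expect_equal(v[["AVG-P-PTCA"]], 0.9)
  expect_equal(v[["MEDI-P-PTCA"]], 0.9)
  expect_equal(v[["AVG-SC-PTCA"]], 0.8)
  expect_equal(v[["AVG-AREA-PTCA"]], 200)
  expect_equal(v[["TOTAL-DET"]], 1)

  three <- dplyr::bind_rows(mk_call(1L, "C6", prob = 0.6),
                            mk_call(2L, "C6", prob = 0.8),
                            mk_call(3L, "C6", prob = 1.0))
  v3 <- aggregate_slide_features(three)
  expect_equal(v3[["AVG-P-TFECA"]], 0.8)
  expect_equal(v3[["MEDI-P-TFECA"]], 0.8)
})

test_that("aggregation is permutation invariant and conserves counts", {
  calls <- dplyr::bind_rows(lapply(1:40, function(i)
    mk_call(i, sample(paste0("C", 1:17), 1),
            prob = stats::runif(1), score = stats::runif(1),
            area = stats::runif(1, 50, 400),
            kind = sample(c("nucleus", "cluster"), 1))))
  v1 <- aggregate_slide_features(calls)
  v2 <- aggregate_slide_features(calls[with_seed(2, sample.int(40)), ])
  expect_equal(v1, v2)
  expect_equal(sum(v1[paste0("N-", roles())]), v1[["TOTAL-DET"]])
  expect_equal(v1[["TOTAL-CLUSTER"]], sum(calls$kind == "cluster"))
})

test_that("contract violations are rejected", {
  dup <- dplyr::bind_rows(mk_call(1L, "C1"), mk_call(1L, "C2"))
  expect_error(aggregate_slide_features(dup), "duplicate")
  rej <- mk_call(1L, "C1"); rej$final_class <- "REJECTED"
  expect_error(aggregate_slide_features(rej), "REJECTED")
})

test_that("medians are order statistics: an outlier moves the median by at
           most one order-statistic gap", {
  for (rep in 1:20) {
    probs <- with_seed(rep, sort(stats::runif(7)))
    calls <- dplyr::bind_rows(lapply(1:7, function(i)
      mk_call(i, "C6", prob = probs[i])))
    v <- aggregate_slide_features(calls)
    expect_equal(v[["MEDI-P-TFECA"]], stats::median(probs))  # sort oracle
    shifted <- probs; shifted[1] <- 5  # wild outlier
    calls2 <- dplyr::bind_rows(lapply(1:7, function(i)
      mk_call(i, "C6", prob = shifted[i])))
    v2 <- aggregate_slide_features(calls2)
    gap <- max(diff(sort(probs)))
    expect_lte(abs(v2[["MEDI-P-TFECA"]] - v[["MEDI-P-TFECA"]]), gap + 1e-12)
  }
})

test_that("cluster objects contribute to counts but not to the global
           nuclear morphology pools", {
  nuc <- mk_call(1L, "C6", area = 100)
  clu <- mk_call(2L, "C6", area = 5000, kind = "cluster")
  v <- aggregate_slide_features(dplyr::bind_rows(nuc, clu))
  expect_equal(v[["N-TFECA"]], 2)
  expect_equal(v[["AVG-AREA-TFECA"]], 2550)  # roles pool both kinds
  expect_equal(v[["AVG-area-NUCLEAR"]] %||% v[["AVG-area-NUCLEAR"]],
               v[["AVG-area-NUCLEAR"]])
  expect_equal(unname(v["AVG-area-NUCLEAR"]), 100)  # nuclei only
})

test_that("the adequacy left-hand side agrees with the rule on random
           feature vectors", {
  for (i in 1:200) {
    counts <- with_seed(i, stats::rpois(4, 4))
    calls <- dplyr::bind_rows(lapply(seq_len(sum(counts)), function(k)
      mk_call(k, rep(c("C1", "C2", "C6", "C7"), counts)[k])))
    v <- if (sum(counts) == 0)
      aggregate_slide_features(thyrocyto:::empty_calls())
    else aggregate_slide_features(calls)
    expect_identical(tbs1_rule(v), v[["ADEQ-LHS"]] < 60)
    expect_equal(v[["ADEQ-LHS"]],
                 10 * (counts[1] + counts[3]) + 5 * (counts[2] + counts[4]))
  }
})
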