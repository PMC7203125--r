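test_that("growth calls threshold on a multiple of background", {
  expect_false(call_growth(0, background = 20))
  expect_true(call_growth(2000, background = 20))
  expect_equal(call_growth(c(59.9, 60, NA), background = 20),
               c(FALSE, TRUE, NA))
  expect_error(call_growth(10, background = 0),
               class = "giscreen_input_error")
})

test_that("parent exclusion keeps the 12/36 boundary and drops below it", {
  progeny <- tibble::tibble(parent = c("a", "b", "c", "d"),
                            viable = c(12, 11, 36, 0),
                            attempted = c(36, 36, 36, 0))
  got <- exclude_parents(progeny)
  expect_equal(got$excluded, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(got$qc_note[4], "no attempted crosses")
  expect_error(exclude_parents(tibble::tibble(viable = 2, attempted = 1)),
               class = "giscreen_input_error")
})

test_that("SL support pools replicates and thresholds at four", {
  calls <- tibble::tibble(gene_a = "A", gene_b = "B",
                          growth = rep(c(FALSE, TRUE), c(5, 11)))
  got <- score_sl(calls)
  expect_equal(got$support, 5)
  expect_equal(got$n_replicates_scored, 16)
  expect_true(got$likely_sl)

  calls3 <- calls
  calls3$growth <- rep(c(FALSE, TRUE), c(3, 13))
  expect_false(score_sl(calls3)$likely_sl)
  expect_true(score_sl(calls3, threshold = 3)$likely_sl)

  # orientation invariance: relabeling (A,B) -> (B,A) changes nothing
  swapped <- calls
  swapped$gene_a <- "B"; swapped$gene_b <- "A"
  mixed <- dplyr::bind_rows(calls[1:8, ], swapped[9:16, ])
  expect_equal(score_sl(mixed)$support, got$support)
  expect_equal(nrow(score_sl(mixed)), 1)

  # unscored pair is missing, not viable
  missing <- tibble::tibble(gene_a = "A", gene_b = "B", growth = NA)
  expect_true(is.na(score_sl(missing)$likely_sl))
})

test_that("raising the SL threshold never enlarges the likely-SL set", {
  set.seed(31)
  pairs <- enumerate_pairs(sprintf("G%d", 1:8))
  calls <- tidyr::expand_grid(pair_id = pairs$pair_id, rep = 1:16)
  calls <- dplyr::left_join(calls, pairs, by = "pair_id")
  calls$growth <- runif(nrow(calls)) > 0.25
  sets <- lapply(3:5, function(th) {
    s <- score_sl(calls, threshold = th)
    s$pair_id[which(s$likely_sl)]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("false-negative estimator reproduces the sentinel arithmetic", {
  est <- estimate_false_negative_rate(77, 202)
  expect_equal(est$percent, 38)
  expect_equal(est$rate, 77 / 202)

  expect_equal(estimate_false_negative_rate(0, 150)$percent, 0)
  expect_error(estimate_false_negative_rate(1, 0),
               class = "giscreen_undefined_rate")
  expect_error(estimate_false_negative_rate(5, 4),
               class = "giscreen_input_error")
})

test_that("screen QC excludes bad parents and reports rates per mating type", {
  cfg <- small_config(n_media = 1, p_fp = 0.6)  # parents mostly failing
  sc <- small_screen(cfg, media = character(0))
  qc <- screen_qc(sc$binary)
  # with 60% per-replicate failure most parents fall below 1/3 viability
  expect_gt(nrow(qc$excluded_parents), 0)
  # the excluded parent's own crosses (same side: a parent strain is one
  # marker orientation) are gone from the support denominator
  excl <- qc$excluded_parents[1, ]
  side_col <- if (excl$side == "bait") "bait_gene" else "hit_gene"
  left <- qc$calls[qc$calls$cross_set == excl$cross_set &
                     qc$calls$mating_type == excl$mating_type &
                     qc$calls[[side_col]] == excl$gene, ]
  expect_equal(nrow(left), 0)

  ok <- screen_qc(small_screen(small_config(n_media = 1),
                               media = character(0))$binary)
  expect_equal(nrow(ok$excluded_parents), 0)
  expect_s3_class(ok$fn_by_mating_type, "data.frame")
  expect_equal(sort(ok$fn_by_mating_type$mating_type), c("a", "alpha"))
  expect_null(ok$contamination)  # no single-parent/empty sentinels by default
})

test_that("confidence classification follows the ordered rule table", {
  expect_equal(as.character(classify_confidence(c("SL", "SL"))),
               "high_confidence_SL")
  expect_equal(as.character(classify_confidence(c("SL", "V"))),
               "high_confidence_viable")   # viable tetrad overrides
  expect_equal(as.character(classify_confidence(c("V"))),
               "high_confidence_viable")
  expect_equal(as.character(classify_confidence(c("MD"))), "uncertain")
  expect_equal(as.character(classify_confidence(character())), "uncertain")
  expect_equal(as.character(classify_confidence(c("SL", "RV"))),
               "uncertain")  # conflicting tetrads
  expect_equal(attr(classify_confidence(c("V")), "rule"), "tetrad_viable")
  expect_error(classify_confidence("dead"), class = "giscreen_input_error")

  # pure function: same inputs, same class
  expect_identical(classify_confidence(c("ambiguous", "SL")),
                   classify_confidence(c("ambiguous", "SL")))

  # rule table is data and overridable
  strict <- list(list(name = "always_uncertain", class = "uncertain",
                      predicate = function(o) TRUE))
  expect_equal(as.character(classify_confidence(c("V"), strict)), "uncertain")
})

test_that("evidence reconciliation attaches classes and provenance", {
  sl <- tibble::tibble(gene_a = c("A", "C"), gene_b = c("B", "D"),
                       pair_id = c("A:B", "C:D"),
                       n_replicates_scored = c(16, 16),
                       support = c(9, 0), likely_sl = c(TRUE, FALSE))
  ev <- tibble::tibble(gene_a = c("A", "C"), gene_b = c("B", "D"),
                       pair_id = c("A:B", "C:D"),
                       documented_sl = c(TRUE, FALSE),
                       tetrad_outcomes = list(c("SL", "SL"), "V"),
                       model_prediction = c("SL", "not_simulated"))
  rec <- reconcile_evidence(sl, ev)
  expect_equal(rec$confidence_class,
               c("high_confidence_SL", "high_confidence_viable"))
  expect_equal(attr(rec, "rules"),
               c("tetrad_viable", "tetrad_sl_unconflicted",
                 "default_uncertain"))
})

test_that("venn partition counts all seven regions against a brute-force oracle", {
  k <- c("A:B", "C:D", "E:F")
  same <- venn_partition(k, k, k)
  expect_equal(unname(same["all_three"]), 3)
  expect_equal(sum(same), 3)

  disj <- venn_partition(c("A:B"), c("C:D", "E:F"), c("G:H", "I:J", "K:L"))
  expect_equal(unname(disj[c("documented_only", "observed_only",
                             "predicted_only")]), c(1, 2, 3))
  expect_equal(sum(disj), 6)

  set.seed(17)
  universe <- sprintf("P%02d", 1:30)
  for (i in 1:20) {
    d <- sample(universe, sample(0:20, 1))
    o <- sample(universe, sample(0:20, 1))
    p <- sample(universe, sample(0:20, 1))
    got <- venn_partition(d, o, p)
    u <- unique(c(d, o, p))
    oracle <- c(0, 0, 0, 0, 0, 0, 0)
    names(oracle) <- names(got)
    for (x in u) {
      ind <- c(x %in% d, x %in% o, x %in% p)
      region <- c("documented_only", "observed_only", "predicted_only",
                  "documented_observed", "documented_predicted",
                  "observed_predicted", "all_three")[
                    match(paste(ind, collapse = ""),
                          c("TRUEFALSEFALSE", "FALSETRUEFALSE",
                            "FALSEFALSETRUE", "TRUETRUEFALSE",
                            "TRUEFALSETRUE", "FALSETRUETRUE",
                            "TRUETRUETRUE"))]
      oracle[region] <- oracle[region] + 1
    }
    expect_equal(got, oracle)
    expect_equal(sum(got), length(u))
  }
})
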