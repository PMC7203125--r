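test_that("wild-type normalization satisfies its defining contracts", {
  scheme <- tiny_scheme()
  lin <- tibble::tibble(lineage_id = c("L1", "L2"),
                        content = "double_mutant",
                        gene_a = c("A", "A"), gene_b = c("B", "C"))
  layout <- build_plate_layout(lin, scheme, "p1")

  # every colony identical to WT -> all normalized sizes 1
  key <- paste(layout$plate, layout$row, layout$col)
  rates <- stats::setNames(rep(2, nrow(layout)), key)
  sizes <- linear_sizes(layout, rates, s0 = 1)
  norm <- normalize_sizes(sizes, layout, per_time = TRUE)
  expect_equal(norm$size, rep(1, nrow(norm)))

  # hand arithmetic: WT sizes {2, 4}, mutant 6 at one time -> 6/3 = 2
  wt_pos <- which(layout$content == "wt_control")[1:2]
  mut_pos <- which(layout$content == "double_mutant")[1]
  one_t <- tibble::tibble(
    plate = "p1", media = "YPD",
    row = layout$row[c(wt_pos, mut_pos)],
    col = layout$col[c(wt_pos, mut_pos)],
    time_h = c(12, 12, 12), size = c(2, 4, 6))
  # restrict layout to those three positions so WT mean is 3
  lay3 <- layout[c(wt_pos, mut_pos), ]
  got <- normalize_sizes(one_t, lay3, per_time = TRUE)
  expect_equal(got$size, c(2 / 3, 4 / 3, 2))

  # scale invariance: doubling all raw sizes changes nothing
  noisy <- sizes
  set.seed(1)
  noisy$size <- noisy$size * exp(rnorm(nrow(noisy), 0, 0.1))
  n1 <- normalize_sizes(noisy, layout, per_time = TRUE)
  noisy2 <- noisy; noisy2$size <- noisy2$size * 2
  n2 <- normalize_sizes(noisy2, layout, per_time = TRUE)
  expect_equal(n1$size, n2$size)
  s1 <- normalize_sizes(noisy, layout, per_time = FALSE)
  s2 <- normalize_sizes(noisy2, layout, per_time = FALSE)
  expect_equal(s1$size, s2$size)

  # errors: no WT controls / non-positive WT mean
  no_wt <- layout; no_wt$content[no_wt$content == "wt_control"] <- "empty"
  expect_error(normalize_sizes(sizes, no_wt), class = "giscreen_qc_error")
  zero <- sizes
  zero$size[paste(zero$row, zero$col) %in%
              paste(layout$row[layout$content == "wt_control"],
                    layout$col[layout$content == "wt_control"])] <- 0
  expect_error(normalize_sizes(zero, layout), class = "giscreen_qc_error")
})

test_that("growth-rate fitting is exact on lines and matches the lm oracle", {
  const <- fit_growth_rate(c(12, 24, 36, 48, 60), rep(5, 5))
  expect_equal(const$r, 0)
  expect_equal(const$s0, 5)

  line <- fit_growth_rate(c(12, 24, 36, 48, 60), c(10, 20, 30, 40, 50))
  expect_equal(line$r, 10 / 12)
  expect_equal(line$s0, 0, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:5) {
    t <- c(12, 24, 36, 48, 60)
    s <- 3 * t + 7 + rnorm(5, 0, 2)
    mine <- fit_growth_rate(t, s)
    oracle <- stats::lm(s ~ t)
    expect_equal(mine$r, unname(coef(oracle)["t"]))
    expect_equal(mine$s0, unname(coef(oracle)["(Intercept)"]))
    expect_equal(mine$sigma, summary(oracle)$sigma)
  }

  expect_error(fit_growth_rate(c(12, 12, 12), c(1, 2, 3)),
               class = "giscreen_degenerate_error")
  expect_error(fit_growth_rate(12, 1), class = "giscreen_input_error")
})

test_that("vectorized fitting agrees with the single-colony fitter", {
  set.seed(11)
  grid <- tidyr::expand_grid(plate = c("p1", "p2"), media = "YPD",
                             row = 1:3, col = 1:2)
  sizes <- tidyr::expand_grid(grid, time_h = c(12, 24, 36, 48, 60))
  sizes$size <- runif(nrow(sizes), 0, 100)
  fits <- fit_growth_rates(sizes)
  for (i in seq_len(nrow(fits))) {
    sub <- sizes[sizes$plate == fits$plate[i] & sizes$row == fits$row[i] &
                   sizes$col == fits$col[i], ]
    ref <- fit_growth_rate(sub$time_h, sub$size)
    expect_equal(fits$r[i], ref$r)
    expect_equal(fits$s0[i], ref$s0)
    expect_equal(fits$sigma[i], ref$sigma)
  }
})

test_that("edge correction equalizes group means and skips degenerate plates", {
  scheme <- tiny_scheme()
  lin <- tibble::tibble(lineage_id = c("L1", "L2"),
                        content = "double_mutant",
                        gene_a = c("A", "A"), gene_b = c("B", "C"))
  layout <- build_plate_layout(lin, scheme, "p1")
  # mutant array: rows 3-6, cols 1-4; L1 block rows 3-4, L2 block rows 5-6.
  # ring = rows 3,6 and cols 1,4 -> here every mutant position is on the
  # ring except none (4 cols all on ring); use a wider scheme instead.
  scheme8 <- plate_scheme(n_rows = 6, n_cols = 8, wt_rows = c("A", "B"))
  lin4 <- tibble::tibble(lineage_id = sprintf("L%d", 1:8),
                         content = "double_mutant",
                         gene_a = "A", gene_b = sprintf("B%d", 1:8))
  layout8 <- build_plate_layout(lin4, scheme8, "p1")
  mutant <- layout8$content == "double_mutant"
  ring <- layout8$row %in% range(layout8$row[mutant]) |
    layout8$col %in% range(layout8$col[mutant])

  base <- rep(NA_real_, nrow(layout8))
  base[layout8$content == "wt_control"] <- 2
  base[mutant] <- 1
  key <- paste(layout8$plate, layout8$row, layout8$col)

  # already equal -> factor 1, rates unchanged
  sizes_eq <- linear_sizes(layout8, stats::setNames(base, key))
  fits_eq <- fit_growth_rates(sizes_eq)
  adj_eq <- correct_edge_effects(fits_eq, layout8)
  expect_true(all(adj_eq$edge_factor == 1))
  expect_equal(adj_eq$r, adj_eq$r_raw)

  # edge uniformly 1.2x internal -> post-correction means equal to 1e-9
  uplift <- base
  uplift[mutant & ring] <- 1.2
  sizes_up <- linear_sizes(layout8, stats::setNames(uplift, key))
  adj <- correct_edge_effects(fit_growth_rates(sizes_up), layout8)
  m_edge <- mean(adj$r[adj$is_edge])
  m_int <- mean(adj$r[adj$content == "double_mutant" & !adj$is_edge])
  expect_lt(abs(m_edge - m_int), 1e-9 * abs(m_int))
  # internal rates untouched
  expect_equal(adj$r[adj$content == "double_mutant" & !adj$is_edge],
               adj$r_raw[adj$content == "double_mutant" & !adj$is_edge])

  # non-positive group mean -> correction skipped with QC flag
  dead <- base
  dead[mutant & ring] <- 0
  dead_sizes <- linear_sizes(layout8, stats::setNames(dead, key))
  adj_dead <- correct_edge_effects(fit_growth_rates(dead_sizes), layout8)
  expect_true(all(!adj_dead$edge_corrected[adj_dead$content ==
                                             "double_mutant"]))
  expect_equal(adj_dead$r, adj_dead$r_raw)
})

test_that("an injected edge multiplier is recovered as its reciprocal", {
  cfg <- sim_config(panel = small_panel(), n_sl_pairs = 0,
                    n_epistatic_pairs = 0, media = default_media()[1, ],
                    edge_multiplier = 1.3, slow_fraction = 0, wt_like_sd = 0,
                    p_fn = 0, p_fp = 0)
  sc <- small_screen(cfg)
  norm <- normalize_sizes(sc$colony_sizes, sc$layouts, per_time = FALSE)
  adj <- correct_edge_effects(fit_growth_rates(norm), sc$layouts)
  factors <- unique(adj[adj$edge_corrected,
                        c("plate", "media", "edge_factor")])
  expect_true(all(abs(factors$edge_factor - 1 / 1.3) < 0.02))
})

test_that("jackknife filter removes only clear single outliers", {
  expect_equal(jackknife_filter(c(1, 1, 1, 1))$removed, integer(0))

  out <- jackknife_filter(c(1.0, 1.01, 0.99, 0.0))
  expect_equal(out$removed, 4L)
  expect_equal(out$keep, c(TRUE, TRUE, TRUE, FALSE))

  # two-low/two-high quad: no single outlier, nothing removed
  expect_equal(jackknife_filter(c(1, 0, 1, 0))$removed, integer(0))

  # < 3 values: nothing removed
  expect_equal(jackknife_filter(c(5, 0))$removed, integer(0))

  # property: quads whose max deviation is within m MADs are never touched
  set.seed(99)
  for (i in 1:200) {
    quad <- runif(4, 0.9, 1.1)
    med <- median(quad)
    if (max(abs(quad - med)) <= 3 * median(abs(quad - med))) {
      expect_equal(jackknife_filter(quad)$removed, integer(0))
    }
  }
})

test_that("vectorized quad aggregation matches the reference jackknife", {
  set.seed(5)
  n_quads <- 50
  fits <- tidyr::expand_grid(lineage_id = sprintf("L%02d", seq_len(n_quads)),
                             tech = 1:4)
  fits$plate <- "p1"; fits$media <- "YPD"
  fits$content <- "double_mutant"; fits$gene_a <- "A"; fits$gene_b <- "B"
  fits$r <- runif(nrow(fits), 0.5, 1.5)
  # inject outliers into some quads
  drop_idx <- which(fits$tech == 2 & as.integer(substr(fits$lineage_id, 2, 3)) %% 3 == 0)
  fits$r[drop_idx] <- 0
  agg <- aggregate_quads(fits)
  for (lid in unique(fits$lineage_id)) {
    quad <- fits$r[fits$lineage_id == lid]
    ref <- jackknife_filter(quad)
    expect_equal(agg$r_quad[agg$lineage_id == lid],
                 mean(quad[ref$keep]),
                 info = lid)
    expect_equal(agg$n_removed[agg$lineage_id == lid],
                 length(ref$removed), info = lid)
  }
})

test_that("fitness scores are clamped ratios with a positive reference", {
  expect_equal(fitness_score(0.8, 0.8), 1)
  expect_equal(fitness_score(0, 0.8), 0)
  expect_equal(fitness_score(0.6, 0.8), 0.75)
  expect_equal(fitness_score(-0.2, 0.8), 0)  # shrinking colony = no growth
  expect_error(fitness_score(1, 0), class = "giscreen_invalid_reference")
  expect_error(fitness_score(1, -1), class = "giscreen_invalid_reference")
})

test_that("the fitness pipeline is invariant to per-plate rescaling", {
  sc <- small_screen(small_config(n_media = 1))
  ref <- compute_fitness(sc$colony_sizes, sc$layouts)$fitness

  rescaled <- sc$colony_sizes
  plates <- unique(rescaled$plate)
  scale <- stats::setNames(c(2, 0.5, 10, 1, 3.7, 0.01, 5, 1.5,
                             rep(1, length(plates)))[seq_along(plates)],
                           plates)
  rescaled$size <- rescaled$size * scale[rescaled$plate]
  got <- compute_fitness(rescaled, sc$layouts)$fitness
  expect_equal(got$W, ref$W, tolerance = 1e-12)
})

test_that("noiseless simulation is recovered exactly by the pipeline", {
  sc <- small_screen(small_noiseless())
  fit <- compute_fitness(sc$colony_sizes, sc$layouts,
                         screen_config(edge_correct = FALSE))
  truth <- sc$truth
  doubles <- fit$fitness[fit$fitness$content == "double_mutant", ]
  w_true <- truth$pairs$w_ab[match(pair_key(doubles$gene_a, doubles$gene_b),
                                   truth$pairs$pair_id)]
  expect_lt(max(abs(doubles$W - w_true)), 1e-9)

  singles <- fit$singles
  w_single_true <- truth$genes$w[match(singles$gene, truth$genes$gene)]
  expect_lt(max(abs(singles$w_single - w_single_true)), 1e-9)

  gi <- compute_gi(fit)
  eps_true <- truth$pairs$epsilon[match(gi$pair_id, truth$pairs$pair_id)]
  expect_lt(max(abs(gi$epsilon - eps_true)), 1e-9)
})
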