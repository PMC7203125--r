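#' Normalize colony sizes to in-plate wild-type controls
#'
#' Plate-to-plate variation is multiplicative (pinning density, agar batch,
#' imaging gain), so sizes are divided by a wild-type reference computed from
#' the control colonies on the same plate.
#'
#' Two variants:
#' * `per_time = TRUE` — at each imaging time every size on the plate is
#'   divided by the mean wild-type size at that time; afterwards the mean WT
#'   size is exactly 1 at every time point. This makes *sizes* directly
#'   comparable across plates, but it also flattens the common time trend, so
#'   rates fitted to such series no longer carry growth information.
#' * `per_time = FALSE` — every size on the plate is divided by one scalar,
#'   the mean wild-type size over all control colonies and times. This removes
#'   the plate effect while preserving the linear time structure, and is what
#'   the rate-fitting pipeline uses.
#'
#' @param sizes Colony-size tibble (see [read_colony_sizes()]).
#' @param layout Layout tibble resolving positions to content.
#' @param per_time Per-time-point division (TRUE) or one scalar per plate.
#' @return `sizes` with the `size` column normalized.
#' @export
normalize_sizes <- function(sizes, layout, per_time = TRUE) {
  x <- dplyr::left_join(sizes, layout[, c("plate", "row", "col", "content")],
                        by = c("plate", "row", "col"))
  if (anyNA(x$content)) {
    gs_abort("positions missing from layout", "giscreen_parse_error")
  }
  no_wt <- x |>
    dplyr::group_by(.data$plate, .data$media) |>
    dplyr::summarise(has_wt = any(.data$content == "wt_control"),
                     .groups = "drop")
  if (!all(no_wt$has_wt)) {
    gs_abort("plate without wild-type controls", "giscreen_qc_error")
  }
  grp <- if (per_time) c("plate", "media", "time_h") else c("plate", "media")
  ref <- x |>
    dplyr::filter(.data$content == "wt_control") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(wt_mean = mean(.data$size), .groups = "drop")
  if (any(ref$wt_mean <= 0)) {
    gs_abort("wild-type mean size <= 0", "giscreen_qc_error")
  }
  x <- dplyr::left_join(x, ref, by = grp)
  x$size <- x$size / x$wt_mean
  x[, names(sizes)]
}

#' Fit a linear growth model to one colony time series
#'
#' Ordinary least squares for `s_t = r * t + s0`: colony area grows
#' approximately linearly over the imaging window, so the slope `r`
#' (area units per hour) is the growth rate.
#'
#' @param times Imaging times in hours (>= 2 distinct values).
#' @param sizes Colony sizes (same length).
#' @return List with `r`, `s0`, `sigma` (residual sd, NA for n = 2) and
#'   `n_points`.
#' @export
fit_growth_rate <- function(times, sizes) {
  if (length(times) != length(sizes) || length(times) < 2) {
    gs_abort("need >= 2 paired (time, size) observations",
             "giscreen_input_error")
  }
  tb <- mean(times); sb <- mean(sizes)
  sxx <- sum((times - tb)^2)
  if (sxx == 0) {
    gs_abort("all times equal: degenerate design", "giscreen_degenerate_error")
  }
  r <- sum((times - tb) * (sizes - sb)) / sxx
  s0 <- sb - r * tb
  n <- length(times)
  rss <- sum((sizes - r * times - s0)^2)
  sigma <- if (n > 2) sqrt(rss / (n - 2)) else NA_real_
  list(r = r, s0 = s0, sigma = sigma, n_points = n)
}

#' Fit growth rates for every colony of a size table
#'
#' Vectorized closed-form OLS, grouped by (plate, media, row, col).
#'
#' @param sizes Colony-size tibble.
#' @return Tibble with one row per colony: position keys plus `r`, `s0`,
#'   `sigma`, `n_points`.
#' @export
fit_growth_rates <- function(sizes) {
  fits <- sizes |>
    dplyr::group_by(.data$plate, .data$media, .data$row, .data$col) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      tb = mean(.data$time_h),
      sb = mean(.data$size),
      sxx = sum((.data$time_h - tb)^2),
      sxy = sum((.data$time_h - tb) * (.data$size - sb)),
      r = .data$sxy / .data$sxx,
      s0 = .data$sb - .data$r * .data$tb,
      rss = sum((.data$size - .data$r * .data$time_h - .data$s0)^2),
      sigma = ifelse(.data$n_points > 2,
                     sqrt(pmax(.data$rss, 0) / (.data$n_points - 2)),
                     NA_real_),
      .groups = "drop"
    )
  if (any(fits$n_points < 2 | fits$sxx == 0)) {
    gs_abort("colony series with < 2 distinct time points",
             "giscreen_degenerate_error")
  }
  fits[, c("plate", "media", "row", "col", "r", "s0", "sigma", "n_points")]
}

#' Correct edge effects by equalizing group mean rates
#'
#' Colonies on the outermost occupied ring of the mutant array grow faster
#' (more nutrients, less crowding). Per plate, rates of edge-adjacent mutant
#' colonies are multiplied by (mean internal rate / mean edge rate) so the two
#' group means match; internal rates are untouched. If either group is missing
#' or has non-positive mean rate the plate is skipped with a QC flag.
#'
#' The group means are computed over *growing* colonies only (fitted rate
#' above `live_fraction` of the plate's median mutant rate): dead positions
#' carry near-zero slopes and would otherwise drag whichever group holds more
#' of them. The factor is then applied to every edge-adjacent mutant rate.
#'
#' @param fits Fit tibble from [fit_growth_rates()].
#' @param layout Layout tibble.
#' @param live_fraction Fraction of the plate's median mutant rate below
#'   which a colony is treated as dead for the group means.
#' @return `fits` with `content`/`lineage_id`/`gene_a`/`gene_b` joined and
#'   added columns `is_edge`, `is_live`, `edge_factor`, `edge_corrected`,
#'   `r_raw`; `r` holds the corrected rate.
#' @export
correct_edge_effects <- function(fits, layout, live_fraction = 0.25) {
  x <- dplyr::left_join(fits,
                        layout[, c("plate", "row", "col", "content",
                                   "lineage_id", "gene_a", "gene_b")],
                        by = c("plate", "row", "col"))
  mutant <- c("double_mutant", "monogenic", "single_parent")
  x <- x |>
    dplyr::group_by(.data$plate, .data$media) |>
    dplyr::mutate(
      is_mutant = .data$content %in% mutant,
      rmin = min(.data$row[.data$is_mutant]),
      rmax = max(.data$row[.data$is_mutant]),
      cmin = min(.data$col[.data$is_mutant]),
      cmax = max(.data$col[.data$is_mutant]),
      is_edge = .data$is_mutant &
        (.data$row %in% c(.data$rmin, .data$rmax) |
           .data$col %in% c(.data$cmin, .data$cmax)),
      is_live = .data$is_mutant &
        .data$r > live_fraction * pmax(median(.data$r[.data$is_mutant]), 0),
      mean_edge = mean(.data$r[.data$is_edge & .data$is_live]),
      mean_int = mean(.data$r[.data$is_mutant & !.data$is_edge &
                                .data$is_live]),
      edge_corrected = is.finite(.data$mean_edge) &
        is.finite(.data$mean_int) &
        .data$mean_edge > 0 & .data$mean_int > 0,
      edge_factor = ifelse(.data$edge_corrected,
                           .data$mean_int / .data$mean_edge, 1),
      r_raw = .data$r,
      r = ifelse(.data$is_edge & .data$edge_corrected,
                 .data$r * .data$edge_factor, .data$r)
    ) |>
    dplyr::ungroup()
  x[, c("plate", "media", "row", "col", "content", "lineage_id", "gene_a",
        "gene_b", "r", "r_raw", "s0", "sigma", "n_points", "is_edge",
        "is_live", "edge_factor", "edge_corrected")]
}

#' Jackknife filter for technical quadruplicates
#'
#' Removes at most one outlier from the 2-4 technical replicate rates of a
#' quadruplicate. The value with the largest absolute deviation from the quad
#' median is removed iff (a) the leave-one-out sd of the remaining values is
#' below `tau_sd` times the full sd, and (b) its deviation exceeds
#' `mad_multiplier` times the (raw, unscaled) median absolute deviation of the
#' quad. With fewer than 3 values nothing is removed.
#'
#' @param rates Numeric vector of 2-4 finite rates.
#' @param tau_sd Leave-one-out sd collapse threshold (default 0.5).
#' @param mad_multiplier Deviation threshold in MAD units (default 3).
#' @return List with `keep` (logical mask) and `removed` (index, possibly
#'   empty).
#' @export
jackknife_filter <- function(rates, tau_sd = 0.5, mad_multiplier = 3) {
  stopifnot(is.numeric(rates), all(is.finite(rates)),
            length(rates) >= 2, length(rates) <= 4)
  keep <- rep(TRUE, length(rates))
  if (length(rates) < 3) {
    return(list(keep = keep, removed = integer(0)))
  }
  med <- median(rates)
  dev <- abs(rates - med)
  mad_q <- median(dev)
  cand <- which.max(dev)
  full_sd <- sd(rates)
  cond_b <- dev[cand] > mad_multiplier * mad_q
  cond_a <- full_sd > 0 && sd(rates[-cand]) < tau_sd * full_sd
  if (cond_a && cond_b) {
    keep[cand] <- FALSE
    return(list(keep = keep, removed = cand))
  }
  list(keep = keep, removed = integer(0))
}

## Vectorized quad aggregation: same criteria as jackknife_filter(), applied
## per (plate, media, lineage) group without per-group R calls. The remaining
## (n-1)-value sd is computed from group sums:
##   var_rest = (sum(x^2) - x^2 - (sum(x) - x)^2 / (n - 1)) / (n - 2)
aggregate_quads <- function(fits, tau_sd = 0.5, mad_multiplier = 3) {
  fits |>
    dplyr::group_by(.data$plate, .data$media, .data$lineage_id) |>
    dplyr::mutate(
      n_tech = dplyr::n(),
      med = median(.data$r),
      dev = abs(.data$r - .data$med),
      mad_q = median(.data$dev),
      full_sd = sd(.data$r),
      sum_r = sum(.data$r),
      sumsq_r = sum(.data$r^2),
      is_cand = dplyr::row_number() == which.max(.data$dev),
      loo_var = (.data$sumsq_r - .data$r^2 -
                   (.data$sum_r - .data$r)^2 / (.data$n_tech - 1)) /
        pmax(.data$n_tech - 2, 1),
      removed = .data$is_cand & .data$n_tech >= 3 &
        .data$dev > mad_multiplier * .data$mad_q &
        .data$full_sd > 0 &
        sqrt(pmax(.data$loo_var, 0)) < tau_sd * .data$full_sd
    ) |>
    dplyr::summarise(
      content = .data$content[1],
      gene_a = .data$gene_a[1],
      gene_b = .data$gene_b[1],
      r_quad = mean(.data$r[!.data$removed]),
      n_tech = .data$n_tech[1],
      n_removed = sum(.data$removed),
      .groups = "drop"
    )
}

#' Fitness score of a mutant relative to wild type
#'
#' `W = max(0, r_mutant) / r_WT`: negative fitted slopes (shrinking colonies)
#' mean no growth and are clamped to zero; the reference is the mean
#' wild-type rate on the same plate.
#'
#' @param r_mutant Mutant growth rate(s).
#' @param r_wt Wild-type reference rate (> 0).
#' @return Numeric W, same length as `r_mutant`.
#' @export
fitness_score <- function(r_mutant, r_wt) {
  if (any(!is.finite(r_wt)) || any(r_wt <= 0)) {
    gs_abort("wild-type reference rate must be > 0",
             "giscreen_invalid_reference")
  }
  pmax(0, r_mutant) / r_wt
}

#' Default analysis configuration
#'
#' All tunable thresholds of the scoring pipeline in one place; every run
#' carries its configuration in its output.
#'
#' @param sl_threshold Minimum no-growth replicates to call likely SL.
#' @param exclusion_fraction Parent excluded iff viable/attempted is below
#'   this fraction.
#' @param bin_width Histogram bin width for the consensus interaction score.
#' @param min_replicates Minimum biological replicates for a consensus value.
#' @param tau_sd,mad_multiplier Jackknife quadruplicate filter thresholds.
#' @param presence_factor Growth call threshold as a multiple of the
#'   background (dead-position) size.
#' @param edge_correct Apply the per-plate edge-effect correction?
#' @param clamp_negative_rates Clamp negative fitted slopes to 0 for fitness.
#' @return Named list of class `screen_config`.
#' @export
screen_config <- function(sl_threshold = 4, exclusion_fraction = 1 / 3,
                          bin_width = 0.05, min_replicates = 4,
                          tau_sd = 0.5, mad_multiplier = 3,
                          presence_factor = 3, edge_correct = TRUE,
                          clamp_negative_rates = TRUE) {
  structure(list(sl_threshold = sl_threshold,
                 exclusion_fraction = exclusion_fraction,
                 bin_width = bin_width, min_replicates = min_replicates,
                 tau_sd = tau_sd, mad_multiplier = mad_multiplier,
                 presence_factor = presence_factor,
                 edge_correct = edge_correct,
                 clamp_negative_rates = clamp_negative_rates),
            class = "screen_config")
}

#' Compute fitness scores for every lineage of a screen
#'
#' Per plate and media: normalize sizes by the plate-level wild-type factor,
#' fit linear growth rates, optionally equalize edge/internal mean rates,
#' jackknife-filter each quadruplicate, average the kept technical rates, and
#' divide by the mean wild-type rate of the same plate.
#'
#' @param sizes Colony-size tibble.
#' @param layout Layout tibble covering every plate in `sizes`.
#' @param config A [screen_config()].
#' @return List with `fitness` (per lineage x media: `r_quad`, `r_wt`, `W`,
#'   QC counts), `singles` (per gene x media single-mutant fitness from
#'   `single_parent` reference positions) and `wt_rates` per plate.
#' @export
compute_fitness <- function(sizes, layout, config = screen_config()) {
  norm <- normalize_sizes(sizes, layout, per_time = FALSE)
  fits <- fit_growth_rates(norm)
  if (isTRUE(config$edge_correct)) {
    fits <- correct_edge_effects(fits, layout)
  } else {
    fits <- dplyr::left_join(fits,
                             layout[, c("plate", "row", "col", "content",
                                        "lineage_id", "gene_a", "gene_b")],
                             by = c("plate", "row", "col"))
    fits$is_edge <- NA
    fits$edge_factor <- 1
    fits$edge_corrected <- FALSE
  }
  wt_rates <- fits |>
    dplyr::filter(.data$content == "wt_control") |>
    dplyr::group_by(.data$plate, .data$media) |>
    dplyr::summarise(r_wt = mean(.data$r), .groups = "drop")
  if (any(wt_rates$r_wt <= 0)) {
    gs_abort("plate with non-positive mean wild-type rate",
             "giscreen_invalid_reference")
  }
  mutant <- fits |>
    dplyr::filter(.data$content %in% c("double_mutant", "monogenic",
                                       "single_parent"))
  quads <- aggregate_quads(mutant, config$tau_sd, config$mad_multiplier)
  quads <- dplyr::left_join(quads, wt_rates, by = c("plate", "media"))
  r_eff <- if (isTRUE(config$clamp_negative_rates)) {
    pmax(0, quads$r_quad)
  } else {
    quads$r_quad
  }
  quads$W <- r_eff / quads$r_wt

  # single-mutant fitness comes from the parent-strain reference positions
  # (lineage ids prefixed "single_"); single_parent sentinel positions on
  # cross plates, when present, are dead controls and are excluded
  singles <- quads |>
    dplyr::filter(.data$content == "single_parent",
                  startsWith(.data$lineage_id, "single_")) |>
    dplyr::group_by(.data$media, gene = .data$gene_a) |>
    dplyr::summarise(w_single = mean(.data$W), .groups = "drop")

  list(fitness = quads, singles = singles, wt_rates = wt_rates,
       config = config)
}
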