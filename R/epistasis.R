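#' Genetic interaction score under the multiplicative model
#'
#' `epsilon = W_AB - W_A * W_B`: the deviation of double-mutant fitness from
#' the product of the single-mutant fitnesses. Negative values are aggravating
#' interactions (the genes may buffer each other, e.g. redundant functions);
#' positive values are alleviating. A synthetic-lethal pair of individually
#' healthy genes has epsilon near -1.
#'
#' @param w_a,w_b Single-mutant fitness scores (>= 0).
#' @param w_ab Double-mutant fitness score (>= 0).
#' @return Numeric epsilon, vectorized.
#' @export
gi_score <- function(w_a, w_b, w_ab) {
  if (any(c(w_a, w_b, w_ab) < 0, na.rm = TRUE)) {
    gs_abort("fitness scores must be >= 0", "giscreen_input_error")
  }
  w_ab - w_a * w_b
}

## Zero-anchored left-closed bin index: k such that x in [k*w, (k+1)*w).
## The 1e-9 nudge keeps values that are an fp-rounding error below a bin
## boundary (e.g. 0.5/0.1 = 4.9999...) in the bin they mathematically belong
## to; real data never sit within 1e-9*w of a boundary by construction.
gi_bin_index <- function(x, bin_width) {
  floor(x / bin_width + 1e-9)
}

#' Consensus interaction score across biological replicates
#'
#' Biological replicates of the same genotype vary considerably; the consensus
#' is a mode estimator robust to outlier replicates. Scores are binned on a
#' zero-anchored grid of left-closed, right-open bins of width `bin_width`;
#' the consensus is the midpoint of the bin holding the most replicates. Ties
#' are broken toward the bin whose midpoint is smallest in absolute value,
#' then toward the lower (more negative) bin, so the outcome is deterministic.
#'
#' @param scores Numeric vector of replicate epsilon values (>= 1 finite).
#' @param bin_width Bin width (default 0.05).
#' @return List with `consensus` (bin midpoint), `bin_width`, `n` and
#'   `bin_counts` (tibble: `k`, `lower`, `upper`, `count`).
#' @export
consensus_gi <- function(scores, bin_width = 0.05) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0) {
    gs_abort("no finite scores to form a consensus", "giscreen_no_data")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    gs_abort("bin_width must be > 0", "giscreen_config_error")
  }
  k <- gi_bin_index(scores, bin_width)
  counts <- table(k)
  kk <- as.numeric(names(counts))
  cnt <- as.integer(counts)
  mids <- (kk + 0.5) * bin_width
  top <- which(cnt == max(cnt))
  # tie rule: smallest |midpoint|, then the lower bin
  top <- top[order(abs(mids[top]), mids[top])]
  best <- top[1]
  list(consensus = mids[best], bin_width = bin_width, n = length(scores),
       bin_counts = tibble::tibble(k = kk, lower = kk * bin_width,
                                   upper = (kk + 1) * bin_width,
                                   count = cnt))
}

#' Flag extreme interaction scores within one media
#'
#' Empirical 2.5/5/95/97.5 percentile thresholds (linear interpolation of
#' order statistics) over the consensus distribution of a media; values at or
#' beyond a threshold are flagged. With fewer than `min_n` values, or when the
#' distribution is degenerate (5th and 95th percentiles coincide), no flags
#' are set and a QC note is attached.
#'
#' @param values Numeric consensus scores for one media.
#' @param min_n Minimum count for stable quantiles (default 20).
#' @return Tibble with logical columns `bottom2_5`, `bottom5`, `top5`,
#'   `top2_5` (one row per value); attribute `qc_note` when flags are
#'   suppressed.
#' @export
flag_extreme_gi <- function(values, min_n = 20) {
  n <- length(values)
  empty <- tibble::tibble(bottom2_5 = rep(FALSE, n), bottom5 = FALSE,
                          top5 = FALSE, top2_5 = FALSE)
  if (n < min_n) {
    attr(empty, "qc_note") <- sprintf(
      "only %d consensus values (< %d): quantile flags suppressed", n, min_n)
    return(empty)
  }
  qs <- quantile(values, c(0.025, 0.05, 0.95, 0.975), type = 7, names = FALSE)
  if (qs[2] >= qs[3]) {
    attr(empty, "qc_note") <- "degenerate score distribution: no flags"
    return(empty)
  }
  tibble::tibble(bottom2_5 = values <= qs[1], bottom5 = values <= qs[2],
                 top5 = values >= qs[3], top2_5 = values >= qs[4])
}

#' Per-replicate genetic interaction records
#'
#' Joins each double-mutant lineage's fitness with the single-mutant fitness
#' of both genes on the same media and computes epsilon. Lineages on media
#' lacking a single-mutant reference for either gene are dropped with a count
#' in the `n_dropped` attribute.
#'
#' @param fit Output of [compute_fitness()].
#' @return Tibble with `gene_a`, `gene_b`, `pair_id`, `media`, `lineage_id`,
#'   `w_a`, `w_b`, `w_ab`, `epsilon`.
#' @export
compute_gi <- function(fit) {
  doubles <- fit$fitness |>
    dplyr::filter(.data$content == "double_mutant")
  gi <- doubles |>
    dplyr::left_join(dplyr::rename(fit$singles, w_a = "w_single"),
                     by = c("media", gene_a = "gene")) |>
    dplyr::left_join(dplyr::rename(fit$singles, w_b = "w_single"),
                     by = c("media", gene_b = "gene"))
  dropped <- sum(is.na(gi$w_a) | is.na(gi$w_b))
  gi <- gi[!is.na(gi$w_a) & !is.na(gi$w_b), ]
  gi$pair_id <- pair_key(gi$gene_a, gi$gene_b)
  gi$w_ab <- gi$W
  gi$epsilon <- gi$w_ab - gi$w_a * gi$w_b
  out <- gi[, c("gene_a", "gene_b", "pair_id", "media", "lineage_id",
                "w_a", "w_b", "w_ab", "epsilon")]
  attr(out, "n_dropped") <- dropped
  out
}

#' Consensus table with extreme-score flags, per media
#'
#' Applies [consensus_gi()] per (pair, media); pairs with fewer than
#' `min_replicates` biological replicates get `NA` consensus (reported as
#' missing, not zero). Extreme flags are computed per media over the non-NA
#' consensus values with [flag_extreme_gi()].
#'
#' @param gi Per-replicate records from [compute_gi()].
#' @param bin_width Histogram bin width.
#' @param min_replicates Minimum replicate count for a consensus value.
#' @return Tibble: `gene_a`, `gene_b`, `pair_id`, `media`, `consensus`,
#'   `n_replicates`, `bottom2_5`, `bottom5`, `top5`, `top2_5`.
#' @export
consensus_gi_table <- function(gi, bin_width = 0.05, min_replicates = 4) {
  cons <- gi |>
    dplyr::group_by(.data$gene_a, .data$gene_b, .data$pair_id, .data$media) |>
    dplyr::summarise(
      n_replicates = sum(is.finite(.data$epsilon)),
      consensus = if (sum(is.finite(.data$epsilon)) >= min_replicates) {
        consensus_gi(.data$epsilon, bin_width)$consensus
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  flagged <- cons |>
    dplyr::group_by(.data$media) |>
    dplyr::group_modify(function(df, key) {
      ok <- !is.na(df$consensus)
      flags <- flag_extreme_gi(df$consensus[ok])
      out <- tibble::tibble(bottom2_5 = rep(FALSE, nrow(df)), bottom5 = FALSE,
                            top5 = FALSE, top2_5 = FALSE)
      out[ok, ] <- flags
      dplyr::bind_cols(df, out)
    }) |>
    dplyr::ungroup()
  dplyr::arrange(flagged, .data$media, .data$gene_a, .data$gene_b)
}
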