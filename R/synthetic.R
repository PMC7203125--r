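#' Default media panel with wild-type growth rates
#'
#' Six phenotyping media: rich glucose (YPD, reference), galactose (YPG) and
#' raffinose (YPR) with mass doubling times of roughly 100, 150 and 200 min
#' respectively — linear colony growth rates scale inversely with doubling
#' time — plus YPD with the checkpoint-activating drugs benomyl (spindle
#' assembly), camptothecin (DNA damage) and hydroxyurea (replication stress),
#' modeled as a 0.8x stress factor on the YPD rate. Only relative rates
#' matter for the fitness ratio W.
#'
#' @param ypd_rate Wild-type YPD growth rate in area units per hour.
#' @param drug_factor Multiplier on the YPD rate for the three drug media.
#' @return Tibble with columns `media`, `wt_rate`.
#' @export
default_media <- function(ypd_rate = 24, drug_factor = 0.8) {
  tibble::tibble(
    media = c("YPD", "YPG", "YPR", "YPD+Ben", "YPD+CPT", "YPD+HU"),
    wt_rate = c(ypd_rate, ypd_rate * 100 / 150, ypd_rate * 100 / 200,
                rep(ypd_rate * drug_factor, 3))
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic screen generator. Defaults emulate the study
#' conditions: a 36-gene panel crossed in 4 independent cross sets with both
#' mating types (16 biological replicates per pair), quadruplicate pinning at
#' 384 density with wild-type rows A/B/I/J, six media, imaging at 12-60 h,
#' 29 truly synthetic-lethal pairs, a 38% false-negative and 2%
#' false-positive process, and multiplicative plate and edge effects.
#'
#' @param panel Gene panel.
#' @param n_sl_pairs Number of truly synthetic-lethal pairs.
#' @param n_epistatic_pairs Number of additional pairs with nonzero epsilon.
#' @param epsilon_sd SD of the epistatic-pair epsilon distribution.
#' @param media Media tibble (see [default_media()]).
#' @param times Imaging times in hours.
#' @param p_fn Per-replicate false-negative probability (a true-SL lineage
#'   grows anyway: suppressors, disomy, gene conversion, contamination).
#' @param p_fp Per-replicate false-positive probability (a viable lineage
#'   fails: pinning mishap).
#' @param contamination_rate Growth probability at single-parent/empty
#'   sentinel positions.
#' @param measurement_sd Additive size noise per imaging point (area units).
#' @param s0_mean,s0_sd Colony intercept (initial pinned mass) distribution.
#' @param background_mean,background_sd Dead-position background size.
#' @param plate_sdlog SD of the log-normal per-plate multiplier.
#' @param edge_multiplier Rate multiplier for mutant colonies on the
#'   outermost occupied ring.
#' @param n_cross_sets,mating_types Crossing design (see [cross_design()]).
#' @param missing_parents Optional tibble (`cross_set`, `mating_type`,
#'   `side`, `gene`) of parents never generated; their crosses become
#'   single-parent or empty sentinel positions.
#' @param slow_fraction,slow_range Fraction of genes with a slow-growth
#'   single-mutant fitness, drawn uniformly from `slow_range`.
#' @param wt_like_sd SD of the near-wild-type single-mutant fitness mode.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(panel = default_gene_panel(), n_sl_pairs = 29,
                       n_epistatic_pairs = 60, epsilon_sd = 0.08,
                       media = default_media(),
                       times = c(12, 24, 36, 48, 60),
                       p_fn = 0.38, p_fp = 0.02, contamination_rate = 0.02,
                       measurement_sd = 8, s0_mean = 40, s0_sd = 5,
                       background_mean = 20, background_sd = 4,
                       plate_sdlog = 0.10, edge_multiplier = 1.2,
                       n_cross_sets = 4, mating_types = c("a", "alpha"),
                       missing_parents = NULL,
                       slow_fraction = 0.15, slow_range = c(0.5, 0.85),
                       wt_like_sd = 0.03) {
  if (p_fn < 0 || p_fn > 1 || p_fp < 0 || p_fp > 1 ||
      contamination_rate < 0 || contamination_rate > 1) {
    gs_abort("error rates must lie in [0, 1]", "giscreen_config_error")
  }
  if (any(media$wt_rate <= 0) || length(times) < 2) {
    gs_abort("media rates must be positive and >= 2 imaging times given",
             "giscreen_config_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Noise-free variant of a simulation configuration
#'
#' All error rates and noise terms zero, plate and edge multipliers 1: the
#' simulator output then encodes the truth exactly and the analysis pipeline
#' must recover it exactly.
#'
#' @param ... Passed to [sim_config()].
#' @return A [sim_config()].
#' @export
noiseless_config <- function(...) {
  sim_config(p_fn = 0, p_fp = 0, contamination_rate = 0, measurement_sd = 0,
             s0_sd = 0, background_sd = 0, plate_sdlog = 0,
             edge_multiplier = 1, ...)
}

#' Draw the ground truth of a synthetic screen
#'
#' Single-mutant fitness per gene (most near 1, a slow-growth tail), a set of
#' truly synthetic-lethal pairs (W_AB = 0), a set of epistatic pairs with
#' epsilon drawn from a centered normal, and multiplicative fitness
#' W_AB = W_A * W_B + epsilon (clipped at 0) for the rest. The (config, seed)
#' pair fully determines the result.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `truth_table`: `genes` (gene, w), `pairs` (pair-level
#'   truth), `media`, `config`, `seed`.
#' @export
make_truth <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  panel <- gene_panel(config$panel)
  n <- length(panel)
  slow <- runif(n) < config$slow_fraction
  w <- ifelse(slow,
              runif(n, config$slow_range[1], config$slow_range[2]),
              pmin(1.1, pmax(0.85, rnorm(n, 1, config$wt_like_sd))))
  genes <- tibble::tibble(gene = panel, w = w)

  pairs <- enumerate_pairs(panel)
  n_pairs <- nrow(pairs)
  if (config$n_sl_pairs + config$n_epistatic_pairs > n_pairs) {
    gs_abort("requested SL + epistatic pairs exceed available pairs",
             "giscreen_config_error")
  }
  idx <- sample.int(n_pairs, config$n_sl_pairs + config$n_epistatic_pairs)
  sl_idx <- idx[seq_len(config$n_sl_pairs)]
  ep_idx <- setdiff(idx, sl_idx)
  pairs$sl <- seq_len(n_pairs) %in% sl_idx
  pairs$epsilon_drawn <- 0
  pairs$epsilon_drawn[ep_idx] <- rnorm(length(ep_idx), 0, config$epsilon_sd)
  wa <- genes$w[match(pairs$gene_a, genes$gene)]
  wb <- genes$w[match(pairs$gene_b, genes$gene)]
  pairs$w_a <- wa
  pairs$w_b <- wb
  pairs$w_ab <- ifelse(pairs$sl, 0, pmax(0, wa * wb + pairs$epsilon_drawn))
  # effective epsilon after SL encoding and clipping
  pairs$epsilon <- pairs$w_ab - wa * wb
  structure(list(genes = genes, pairs = pairs, media = config$media,
                 config = config, seed = seed),
            class = "truth_table")
}

## Growth probability for one lineage at the haploid-selection stage.
lineage_growth_prob <- function(content, sl, cfg) {
  dplyr::case_when(
    content == "double_mutant" & sl ~ cfg$p_fn,
    content == "double_mutant" ~ 1 - cfg$p_fp,
    content == "monogenic" ~ cfg$p_fn,
    TRUE ~ cfg$contamination_rate   # single_parent / empty sentinels
  )
}

#' Simulate a full colony-array screen from a truth table
#'
#' Two stages, mirroring the experimental workflow:
#'
#' 1. *Haploid selection (binary)* — one viability draw per replicate lineage:
#'    a truly SL lineage grows with probability `p_fn`, a viable one fails
#'    with `p_fp`, monogenic sentinels grow with `p_fn`, single-parent and
#'    empty sentinels with the contamination rate. The draw is shared by all
#'    media and technical quadruplicates of the lineage (the master plate is
#'    pinned once).
#' 2. *Phenotyping* — lineages are arrayed in quadruplicate 2x2 blocks on
#'    384-density plates with wild-type rows A/B/I/J, plus one reference
#'    plate of the single-mutant parent strains. Growing colonies get linear
#'    size series `s_t = r t + s0 + noise` with
#'    `r = wt_rate(media) * W * plate_effect * edge_effect`; dead positions
#'    get background-level sizes. SL escape colonies grow like their fitter
#'    single parent; contaminants like wild type.
#'
#' @param truth A [make_truth()] result.
#' @param seed Integer seed (fully determines the output given `truth`).
#' @param media Character vector of media to phenotype (default: all in the
#'   truth table); `character(0)` skips phenotyping (binary stage only).
#' @param scheme Plate scheme for phenotyping.
#' @return List of class `simulated_screen`: `binary` (per-lineage growth),
#'   `colony_sizes`, `layouts`, `truth`, `seed`.
#' @export
simulate_screen <- function(truth, seed = 1,
                            media = NULL, scheme = plate_scheme()) {
  stopifnot(inherits(truth, "truth_table"))
  cfg <- truth$config
  set.seed(seed)
  design <- cross_design(truth$genes$gene, cfg$n_cross_sets,
                         cfg$mating_types)
  lineages <- enumerate_design(design)

  # never-generated parents turn their crosses into sentinel positions
  mp <- cfg$missing_parents
  if (!is.null(mp) && nrow(mp) > 0) {
    bait_gone <- paste(lineages$cross_set, lineages$mating_type,
                       lineages$bait_gene) %in%
      paste(mp$cross_set[mp$side == "bait"], mp$mating_type[mp$side == "bait"],
            mp$gene[mp$side == "bait"])
    hit_gone <- paste(lineages$cross_set, lineages$mating_type,
                      lineages$hit_gene) %in%
      paste(mp$cross_set[mp$side == "hit"], mp$mating_type[mp$side == "hit"],
            mp$gene[mp$side == "hit"])
    lineages$content[bait_gone & hit_gone] <- "empty"
    lineages$content[xor(bait_gone, hit_gone)] <- "single_parent"
    sp <- lineages$content == "single_parent"
    lineages$gene_a[sp] <- ifelse(bait_gone[sp], lineages$hit_gene[sp],
                                  lineages$bait_gene[sp])
    lineages$gene_b[sp] <- NA_character_
    lineages$pair_id[lineages$content != "double_mutant"] <- NA_character_
  }

  pt <- truth$pairs
  lineages$sl <- pt$sl[match(lineages$pair_id, pt$pair_id)]
  lineages$sl[is.na(lineages$sl)] <- FALSE
  lineages$truth_viable <- lineages$content == "double_mutant" & !lineages$sl
  p_grow <- lineage_growth_prob(lineages$content, lineages$sl, cfg)
  lineages$growth <- runif(nrow(lineages)) < p_grow
  binary <- lineages

  media <- media %||% cfg$media$media
  out <- list(binary = binary, colony_sizes = NULL, layouts = NULL,
              truth = truth, seed = seed)
  class(out) <- "simulated_screen"
  if (length(media) == 0) {
    return(out)
  }
  media_tbl <- cfg$media[cfg$media$media %in% media, ]
  if (nrow(media_tbl) < length(media)) {
    gs_abort("media not present in the truth table's media panel",
             "giscreen_config_error")
  }

  # phenotyping layouts: one plate series per (cross set, mating type),
  # plus one reference plate of single-mutant parent strains
  layouts <- lineages |>
    dplyr::group_by(.data$cross_set, .data$mating_type) |>
    dplyr::group_map(function(df, key) {
      assign_plates(df[, c("lineage_id", "content", "gene_a", "gene_b")],
                    scheme,
                    plate_prefix = sprintf("cs%d_%s_p", key$cross_set,
                                           key$mating_type))
    }) |>
    dplyr::bind_rows()
  # reference plate: cycle the gene list over all blocks so each gene's
  # replicates spread across row-pairs (edge and interior both sampled)
  sm_genes <- rep(truth$genes$gene, length.out = scheme$capacity)
  sm <- tibble::tibble(
    lineage_id = sprintf("single_%s_%02d", sm_genes,
                         stats::ave(seq_along(sm_genes), sm_genes,
                                    FUN = seq_along)),
    content = "single_parent",
    gene_a = sm_genes, gene_b = NA_character_)
  layouts <- dplyr::bind_rows(layouts, assign_plates(sm, scheme, "sm_p"))

  # per-position growth flag and fitness
  pos <- layouts
  m <- match(pos$lineage_id, lineages$lineage_id)
  is_sm <- !is.na(pos$lineage_id) & startsWith(pos$lineage_id, "single_")
  pos$grows <- dplyr::case_when(
    pos$content == "wt_control" ~ TRUE,
    is_sm ~ TRUE,
    is.na(pos$lineage_id) ~ FALSE,
    TRUE ~ lineages$growth[m]
  )
  wg <- truth$genes$w[match(pos$gene_a, truth$genes$gene)]
  wgb <- truth$genes$w[match(pos$gene_b, truth$genes$gene)]
  wab <- pt$w_ab[match(pair_key(pos$gene_a, pos$gene_b), pt$pair_id)]
  sl_here <- lineages$sl[m]
  pos$W <- dplyr::case_when(
    pos$content == "wt_control" ~ 1,
    !pos$grows ~ 0,
    is_sm ~ wg,
    pos$content == "monogenic" ~ wg,                 # escape = single mutant
    pos$content == "double_mutant" & sl_here ~ pmax(wg, wgb),  # SL escape
    pos$content == "double_mutant" ~ wab,
    pos$content == "single_parent" ~ 1,              # contaminant ~ WT
    TRUE ~ 0
  )

  # edge predicate: outermost occupied ring of the mutant array, per plate
  mutant_contents <- c("double_mutant", "monogenic", "single_parent")
  pos <- pos |>
    dplyr::group_by(.data$plate) |>
    dplyr::mutate(
      is_mutant = .data$content %in% mutant_contents,
      is_edge = .data$is_mutant &
        (.data$row %in% range(.data$row[.data$is_mutant]) |
           .data$col %in% range(.data$col[.data$is_mutant]))
    ) |>
    dplyr::ungroup()

  # expand positions x media; one plate multiplier per (plate, media)
  colonies <- tidyr::expand_grid(media = media_tbl$media,
                                 idx = seq_len(nrow(pos)))
  colonies <- dplyr::bind_cols(
    colonies["media"],
    pos[colonies$idx, c("plate", "row", "col", "content", "lineage_id",
                        "grows", "W", "is_edge")]
  )
  plate_media <- unique(colonies[, c("plate", "media")])
  plate_media$plate_effect <- rlnorm(nrow(plate_media), 0, cfg$plate_sdlog)
  colonies <- dplyr::left_join(colonies, plate_media, by = c("plate", "media"))
  colonies$wt_rate <- media_tbl$wt_rate[match(colonies$media,
                                              media_tbl$media)]
  colonies$r_true <- ifelse(
    colonies$grows,
    colonies$wt_rate * colonies$W * colonies$plate_effect *
      ifelse(colonies$is_edge, cfg$edge_multiplier, 1),
    0)
  colonies$s0 <- rnorm(nrow(colonies), cfg$s0_mean, cfg$s0_sd)

  times <- cfg$times
  sizes <- tidyr::expand_grid(cidx = seq_len(nrow(colonies)),
                              time_h = times)
  cc <- colonies[sizes$cidx, ]
  noise <- if (cfg$measurement_sd > 0) {
    rnorm(nrow(sizes), 0, cfg$measurement_sd)
  } else {
    0
  }
  bg_noise <- if (cfg$background_sd > 0) {
    rnorm(nrow(sizes), 0, cfg$background_sd)
  } else {
    0
  }
  sizes$size <- ifelse(
    cc$grows,
    pmax(0, cc$r_true * sizes$time_h + cc$s0 + noise),
    pmax(0, cfg$background_mean + bg_noise))
  colony_sizes <- tibble::tibble(plate = cc$plate, media = cc$media,
                                 row = cc$row, col = cc$col,
                                 time_h = sizes$time_h, size = sizes$size)

  out$colony_sizes <- colony_sizes
  out$layouts <- layouts
  out$positions <- pos
  out
}
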