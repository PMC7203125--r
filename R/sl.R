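#' Binary growth call from a final colony size
#'
#' A colony is scored present (growth) when its final-time size reaches
#' `presence_factor` times the plate's background (dead-position) level —
#' the automated analogue of the visual present/absent scoring of selection
#' plates. `NA` sizes yield `NA` (no call).
#'
#' @param final_size Final-time colony size(s).
#' @param background Background size level of the plate (> 0).
#' @param presence_factor Multiple of background that counts as growth.
#' @return Logical vector.
#' @export
call_growth <- function(final_size, background, presence_factor = 3) {
  if (!is.finite(background) || background <= 0) {
    gs_abort("background level must be a positive number",
             "giscreen_input_error")
  }
  final_size >= presence_factor * background
}

#' Exclude parent strains with poor progeny viability
#'
#' A parent line whose crosses mostly fail produces spurious synthetic-lethal
#' calls, so parents with viable/attempted below `exclusion_fraction`
#' (default 1/3, i.e. fewer than 12 of 36 viable) are excluded; the boundary
#' case 12/36 is kept. Parents with zero attempted crosses are excluded with
#' a QC note.
#'
#' @param progeny Tibble with one row per parent: arbitrary key columns plus
#'   `viable` and `attempted` counts.
#' @param exclusion_fraction Exclusion threshold on viable/attempted.
#' @return `progeny` with added `viable_fraction`, `excluded`, `qc_note`.
#' @export
exclude_parents <- function(progeny, exclusion_fraction = 1 / 3) {
  stopifnot(all(c("viable", "attempted") %in% names(progeny)))
  if (any(progeny$viable > progeny$attempted)) {
    gs_abort("viable exceeds attempted", "giscreen_input_error")
  }
  frac <- ifelse(progeny$attempted > 0,
                 progeny$viable / progeny$attempted, NA_real_)
  progeny$viable_fraction <- frac
  progeny$excluded <- progeny$attempted == 0 |
    (!is.na(frac) & frac < exclusion_fraction)
  progeny$qc_note <- ifelse(progeny$attempted == 0,
                            "no attempted crosses", NA_character_)
  progeny
}

## Per-parent progeny viability from the binary growth table. A parent is one
## side (bait or hit) of one cross set and mating type; attempted/viable are
## counted over its double-mutant crosses (monogenic sentinels are expected
## dead and excluded from both counts).
parent_viability <- function(binary) {
  doubles <- binary[binary$content == "double_mutant", ]
  bait <- doubles |>
    dplyr::group_by(.data$cross_set, .data$mating_type,
                    gene = .data$bait_gene) |>
    dplyr::summarise(side = "bait", attempted = dplyr::n(),
                     viable = sum(.data$growth), .groups = "drop")
  hit <- doubles |>
    dplyr::group_by(.data$cross_set, .data$mating_type,
                    gene = .data$hit_gene) |>
    dplyr::summarise(side = "hit", attempted = dplyr::n(),
                     viable = sum(.data$growth), .groups = "drop")
  dplyr::bind_rows(bait, hit)
}

#' Count synthetic-lethality support per gene pair
#'
#' Pools binary no-growth calls across cross sets, mating types and marker
#' orientations (the unit of evidence is the unordered pair, irrespective of
#' which parent carried which marker). Support is the number of no-growth
#' replicates among those actually scored; a pair reaches `likely_sl` at
#' `threshold` or more (default 4). Pairs with zero scored replicates are
#' reported with `NA` (missing, not viable).
#'
#' @param calls Tibble with columns `gene_a`, `gene_b` (canonical),
#'   and logical `growth` (NA = not scored); typically the `double_mutant`
#'   rows of a binary screen table after parent exclusion.
#' @param threshold Minimum no-growth count for a likely-SL call.
#' @return Tibble per pair: `gene_a`, `gene_b`, `pair_id`,
#'   `n_replicates_scored`, `support`, `likely_sl`.
#' @export
score_sl <- function(calls, threshold = 4) {
  # canonicalize so support pooling is orientation-invariant
  a <- pmin(calls$gene_a, calls$gene_b)
  b <- pmax(calls$gene_a, calls$gene_b)
  calls$gene_a <- a
  calls$gene_b <- b
  out <- calls |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      n_replicates_scored = sum(!is.na(.data$growth)),
      support = sum(!.data$growth, na.rm = TRUE),
      .groups = "drop"
    )
  out$pair_id <- pair_key(out$gene_a, out$gene_b)
  out$likely_sl <- ifelse(out$n_replicates_scored == 0, NA,
                          out$support >= threshold)
  out[, c("gene_a", "gene_b", "pair_id", "n_replicates_scored", "support",
          "likely_sl")]
}

#' Estimate the false-negative rate from sentinel positions
#'
#' Monogenic crosses (both parents deleted for the same gene) cannot produce
#' progeny carrying both resistance markers, so any colony at such a position
#' is a false negative in the screen sense (suppressor, disomy, gene
#' conversion, contamination). The rate is simply growing/total over the
#' sentinel positions.
#'
#' @param n_growing Number of sentinel positions that produced a colony.
#' @param n_total Total sentinel positions monitored (> 0).
#' @return List with `rate`, `percent` (rounded to nearest integer),
#'   `n_growing`, `n_total`.
#' @export
estimate_false_negative_rate <- function(n_growing, n_total) {
  if (length(n_total) != 1 || !is.finite(n_total) || n_total <= 0) {
    gs_abort("false-negative rate undefined: no sentinel positions",
             "giscreen_undefined_rate")
  }
  if (n_growing < 0 || n_growing > n_total) {
    gs_abort("n_growing must lie in [0, n_total]", "giscreen_input_error")
  }
  rate <- n_growing / n_total
  list(rate = rate, percent = round(100 * rate),
       n_growing = as.integer(n_growing), n_total = as.integer(n_total))
}

#' Screen-level quality control summary
#'
#' Applies the parent-exclusion rule, then summarizes the sentinel positions:
#' the false-negative rate from monogenic crosses (pooled and per mating
#' type, since the two mating types can differ) and the contamination rate
#' from single-parent and empty positions.
#'
#' @param binary Binary screen table (one row per lineage) with columns
#'   `cross_set`, `mating_type`, `bait_gene`, `hit_gene`, `content`, `growth`.
#' @param config A [screen_config()].
#' @return List with `excluded_parents`, `fn` (pooled + per mating type),
#'   `contamination` (or NULL if no such sentinels), and `calls`: the
#'   double-mutant calls with excluded parents removed, ready for
#'   [score_sl()].
#' @export
screen_qc <- function(binary, config = screen_config()) {
  parents <- exclude_parents(parent_viability(binary),
                             config$exclusion_fraction)
  excl <- parents[parents$excluded, ]
  doubles <- binary[binary$content == "double_mutant", ]
  if (nrow(excl) > 0) {
    bait_key <- paste(doubles$cross_set, doubles$mating_type,
                      doubles$bait_gene)
    hit_key <- paste(doubles$cross_set, doubles$mating_type, doubles$hit_gene)
    drop_bait <- paste(excl$cross_set[excl$side == "bait"],
                       excl$mating_type[excl$side == "bait"],
                       excl$gene[excl$side == "bait"])
    drop_hit <- paste(excl$cross_set[excl$side == "hit"],
                      excl$mating_type[excl$side == "hit"],
                      excl$gene[excl$side == "hit"])
    doubles <- doubles[!(bait_key %in% drop_bait | hit_key %in% drop_hit), ]
  }

  mono <- binary[binary$content == "monogenic", ]
  fn_pooled <- if (nrow(mono) > 0) {
    estimate_false_negative_rate(sum(mono$growth), nrow(mono))
  } else {
    NULL
  }
  fn_by_mt <- if (nrow(mono) > 0) {
    mono |>
      dplyr::group_by(.data$mating_type) |>
      dplyr::summarise(n_growing = sum(.data$growth),
                       n_total = dplyr::n(),
                       rate = .data$n_growing / .data$n_total,
                       percent = round(100 * .data$rate),
                       .groups = "drop")
  } else {
    NULL
  }
  sent <- binary[binary$content %in% c("single_parent", "empty"), ]
  contamination <- if (nrow(sent) > 0) {
    list(rate = mean(sent$growth), n_growing = sum(sent$growth),
         n_total = nrow(sent))
  } else {
    NULL
  }
  list(excluded_parents = excl, parents = parents,
       fn = fn_pooled, fn_by_mating_type = fn_by_mt,
       contamination = contamination, calls = doubles)
}

#' Closed vocabulary of tetrad-analysis outcomes
#'
#' `SL` (all double-mutant spores dead), `V` (viable), `RV` (reduced
#' viability), `ambiguous` (variable results or poor spore viability),
#' `MD` (possible meiotic defect — too few viable spores to score).
#'
#' @return Character vector of valid tokens.
#' @export
tetrad_vocabulary <- function() c("SL", "V", "RV", "ambiguous", "MD")

#' Default confidence-classification rule table
#'
#' Ordered rules, first match wins; tetrad analysis is the gold standard, so
#' it overrides screen and documentation evidence:
#' 1. any unambiguous viable tetrad -> `high_confidence_viable`;
#' 2. an unambiguous SL tetrad with no conflicting (V or RV) tetrad ->
#'    `high_confidence_SL`;
#' 3. otherwise (ambiguous, MD, RV-only or no tetrad data) -> `uncertain`.
#'
#' The table is data: supply your own list of rules (each a list with `name`,
#' `class` and `predicate(outcomes)`) to override.
#'
#' @return List of rules.
#' @export
default_confidence_rules <- function() {
  list(
    list(name = "tetrad_viable", class = "high_confidence_viable",
         predicate = function(outcomes) any(outcomes == "V")),
    list(name = "tetrad_sl_unconflicted", class = "high_confidence_SL",
         predicate = function(outcomes) {
           any(outcomes == "SL") && !any(outcomes %in% c("V", "RV"))
         }),
    list(name = "default_uncertain", class = "uncertain",
         predicate = function(outcomes) TRUE)
  )
}

#' Classify a gene pair's evidence into a confidence class
#'
#' Deterministic function of the tetrad outcomes and the rule table; the
#' matched rule's name is attached for provenance.
#'
#' @param tetrad_outcomes Character vector of outcomes from
#'   [tetrad_vocabulary()] (empty = no tetrad data).
#' @param rules Rule table (see [default_confidence_rules()]).
#' @return Character class with attribute `rule`.
#' @export
classify_confidence <- function(tetrad_outcomes = character(),
                                rules = default_confidence_rules()) {
  bad <- setdiff(tetrad_outcomes, tetrad_vocabulary())
  if (length(bad) > 0) {
    gs_abort(paste0("unknown tetrad outcome token(s): ",
                    paste(bad, collapse = ", ")),
             "giscreen_input_error")
  }
  for (rule in rules) {
    if (isTRUE(rule$predicate(tetrad_outcomes))) {
      return(structure(rule$class, rule = rule$name))
    }
  }
  structure("uncertain", rule = "fallthrough")
}

#' Reconcile screen calls with curated evidence
#'
#' Joins the screen's SL support with a curated evidence table (documented SL
#' status, tetrad outcomes, model predictions) and derives a confidence class
#' per pair. The rule table used is recorded in the `rules` attribute.
#'
#' @param sl SL support table from [score_sl()].
#' @param evidence Evidence tibble from [read_evidence()] (or equivalent).
#' @param rules Confidence rule table.
#' @return Tibble with screen support, evidence fields, `confidence_class`
#'   and `confidence_rule`.
#' @export
reconcile_evidence <- function(sl, evidence,
                               rules = default_confidence_rules()) {
  merged <- dplyr::full_join(
    sl, evidence[, setdiff(names(evidence), c("gene_a", "gene_b"))],
    by = "pair_id")
  cls <- lapply(merged$tetrad_outcomes, function(x) {
    classify_confidence(x %||% character(), rules)
  })
  merged$confidence_class <- vapply(cls, as.character, character(1))
  merged$confidence_rule <- vapply(cls, function(x) attr(x, "rule"),
                                   character(1))
  attr(merged, "rules") <- vapply(rules, function(r) r$name, character(1))
  merged
}

#' Three-set Venn partition of SL pair sets
#'
#' Counts the seven regions of the Venn diagram comparing documented,
#' observed and model-predicted synthetic-lethal pair sets.
#'
#' @param documented,observed,predicted Character vectors of canonical pair
#'   ids (see [pair_key()]).
#' @return Named integer vector: `documented_only`, `observed_only`,
#'   `predicted_only`, `documented_observed`, `documented_predicted`,
#'   `observed_predicted`, `all_three`; sums to the union size.
#' @export
venn_partition <- function(documented, observed, predicted) {
  documented <- unique(documented); observed <- unique(observed)
  predicted <- unique(predicted)
  u <- unique(c(documented, observed, predicted))
  d <- u %in% documented; o <- u %in% observed; p <- u %in% predicted
  c(documented_only = sum(d & !o & !p),
    observed_only = sum(!d & o & !p),
    predicted_only = sum(!d & !o & p),
    documented_observed = sum(d & o & !p),
    documented_predicted = sum(d & !o & p),
    observed_predicted = sum(!d & o & p),
    all_three = sum(d & o & p))
}
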