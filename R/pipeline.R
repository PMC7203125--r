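#' Analyze a colony-array screen end to end
#'
#' Runs the full scoring pipeline on a simulated or read-in screen:
#' parent-exclusion QC and sentinel-based false-negative/contamination
#' estimation, synthetic-lethality support counting and thresholding from the
#' binary stage, and — when colony time courses are present — wild-type
#' normalization, growth-rate fitting, edge correction, quadruplicate
#' filtering, fitness and interaction scoring, and the histogram-mode
#' consensus with per-media extreme flags.
#'
#' @param screen A `simulated_screen`, or a list with elements `binary`
#'   (per-lineage growth table) and optionally `colony_sizes` + `layouts`.
#' @param config A [screen_config()].
#' @return List with `sl`, `qc`, and when time courses are present `fitness`,
#'   `gi`, `consensus`; the configuration is echoed in `config`.
#' @export
analyze_screen <- function(screen, config = screen_config()) {
  qc <- screen_qc(screen$binary, config)
  sl <- score_sl(qc$calls, config$sl_threshold)
  out <- list(sl = sl, qc = qc, config = config)
  if (!is.null(screen$colony_sizes) && nrow(screen$colony_sizes) > 0) {
    fit <- compute_fitness(screen$colony_sizes, screen$layouts, config)
    gi <- compute_gi(fit)
    out$fitness <- fit
    out$gi <- gi
    out$consensus <- consensus_gi_table(gi, config$bin_width,
                                        config$min_replicates)
  }
  out
}
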