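#' Read a colony-size time-course table
#'
#' Reads the delimited export of a plate imager: one row per (plate, media,
#' position, imaging time). The dialect is UTF-8 comma- or tab-separated
#' (auto-detected from the header line) with columns `plate`, `media`, `row`,
#' `col`, `time_h`, `size`; `row` may be a letter (A..) or a 1-based number.
#' The reader is total over this dialect: every malformed input raises a typed
#' condition (`giscreen_parse_error`, `giscreen_duplicate_error`) carrying the
#' offending line numbers — nothing is silently dropped.
#'
#' @param path File path.
#' @param layout Optional layout tibble (see [build_plate_layout()]); when
#'   given, rows at positions unknown to the layout are an error.
#' @return Tibble with columns `plate`, `media`, `row` (integer), `col`,
#'   `time_h`, `size`, sorted by plate/position/time. One colony time series
#'   per distinct (plate, media, row, col).
#' @export
read_colony_sizes <- function(path, layout = NULL) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    gs_abort("empty file: no header line", "giscreen_parse_error")
  }
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  required <- c("plate", "media", "row", "col", "time_h", "size")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    gs_abort(paste0("missing required columns: ",
                    paste(missing, collapse = ", ")),
             "giscreen_parse_error")
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(plate = character(), media = character(),
                          row = integer(), col = integer(),
                          time_h = double(), size = double()))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1

  num <- function(x) suppressWarnings(as.numeric(x))
  col_i <- suppressWarnings(as.integer(raw$col))
  time_h <- num(raw$time_h)
  size <- num(raw$size)
  row_idx <- match(toupper(raw$row), LETTERS)
  row_num <- suppressWarnings(as.integer(raw$row))
  row_i <- ifelse(is.na(row_idx), row_num, row_idx)

  bad <- is.na(col_i) | is.na(time_h) | is.na(size) | is.na(row_i) |
    size < 0 | !nzchar(raw$plate %||% "")
  if (any(bad)) {
    gs_abort(paste0("malformed rows (non-numeric fields or negative size) ",
                    "at line(s): ",
                    paste(head(line_no[bad], 10), collapse = ", ")),
             "giscreen_parse_error")
  }
  out <- tibble::tibble(plate = raw$plate, media = raw$media,
                        row = as.integer(row_i), col = col_i,
                        time_h = time_h, size = size)
  key <- paste(out$plate, out$media, out$row, out$col, out$time_h)
  if (anyDuplicated(key)) {
    gs_abort(paste0("duplicate (plate, position, time) records at line(s): ",
                    paste(head(line_no[duplicated(key)], 10), collapse = ", ")),
             "giscreen_duplicate_error")
  }
  if (!is.null(layout)) {
    lkey <- paste(layout$plate, layout$row, layout$col)
    unknown <- !(paste(out$plate, out$row, out$col) %in% lkey)
    if (any(unknown)) {
      gs_abort(paste0("rows at positions unknown to the layout at line(s): ",
                      paste(head(line_no[unknown], 10), collapse = ", ")),
               "giscreen_parse_error")
    }
  }
  dplyr::arrange(out, .data$plate, .data$media, .data$row, .data$col,
                 .data$time_h)
}

#' Write a colony-size table in the documented dialect
#'
#' @param sizes Tibble as returned by [read_colony_sizes()].
#' @param path Output path (.csv or .tsv chooses the delimiter).
#' @return `path`, invisibly.
#' @export
write_colony_sizes <- function(sizes, path) {
  out <- sizes[, c("plate", "media", "row", "col", "time_h", "size")]
  out$row <- row_to_letter(out$row)
  if (grepl("\\.tsv$", path)) readr::write_tsv(out, path)
  else readr::write_csv(out, path)
  invisible(path)
}

#' Write / read a plate layout config
#'
#' Structured JSON with grid dimensions, wild-type rows and explicit
#' position-to-content records; round-trips bit-exactly.
#'
#' @param layout Layout tibble.
#' @param scheme The [plate_scheme()] the layout was built with.
#' @param path File path.
#' @return `path` invisibly, or for the reader a list with `layout` tibble and
#'   `scheme`.
#' @export
write_layout <- function(layout, scheme, path) {
  positions <- layout
  positions$row <- row_to_letter(positions$row)
  obj <- list(n_rows = scheme$n_rows, n_cols = scheme$n_cols,
              wt_rows = row_to_letter(scheme$wt_rows),
              positions = positions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layout <- tibble::as_tibble(obj$positions)
  layout$row <- letter_to_row(layout$row)
  layout$col <- as.integer(layout$col)
  for (cl in c("lineage_id", "gene_a", "gene_b")) {
    if (!cl %in% names(layout)) layout[[cl]] <- NA_character_
    layout[[cl]] <- as.character(layout[[cl]])
  }
  scheme <- plate_scheme(obj$n_rows, obj$n_cols, wt_rows = obj$wt_rows)
  list(layout = layout[, c("plate", "row", "col", "content", "lineage_id",
                           "gene_a", "gene_b")],
       scheme = scheme)
}

#' Symmetric pair-by-pair matrix from a per-pair table
#'
#' Genes are ordered alphabetically along both axes; cell (i, j) and (j, i)
#' both carry the pair's value; the diagonal and pairs absent from `df` are NA.
#'
#' @param df Tibble with `gene_a`, `gene_b` and the value column.
#' @param value Name of the value column.
#' @param genes Gene universe (default: genes present in `df`).
#' @return Numeric matrix with dimnames.
#' @export
pair_matrix <- function(df, value, genes = NULL) {
  genes <- sort(genes %||% unique(c(df$gene_a, df$gene_b)))
  m <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  ia <- match(df$gene_a, genes); ib <- match(df$gene_b, genes)
  v <- as.numeric(df[[value]])
  m[cbind(ia, ib)] <- v
  m[cbind(ib, ia)] <- v
  m
}

#' Write / read a gene-by-gene matrix as TSV
#'
#' First column `gene` holds row names; numeric values round-trip exactly
#' (shortest round-trip decimal representation).
#'
#' @param m Matrix with dimnames.
#' @param path File path.
#' @return `path` invisibly / the matrix.
#' @export
write_pair_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene
  m
}

#' Write the result tables of an analyzed screen
#'
#' Emits (a) the tidy per-replicate score table, (b) the per-pair consensus
#' table, (c) symmetric gene-by-gene matrices for binary SL support and for
#' the consensus interaction score per media, and optionally (d) heatmap
#' figures. Re-reading (a)-(c) with [read_results()] reproduces the values
#' bit-exactly.
#'
#' @param results List with elements `gi` (per-replicate records), `consensus`
#'   and `sl` as produced by [analyze_screen()].
#' @param path_prefix Path prefix for all files.
#' @param heatmaps Also write PNG heatmaps of the consensus matrices?
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, path_prefix, heatmaps = FALSE) {
  files <- character()
  wr <- function(df, suffix) {
    f <- paste0(path_prefix, suffix)
    readr::write_csv(df, f)
    files <<- c(files, f)
  }
  wr(results$gi, "_replicate_scores.csv")
  wr(results$consensus, "_consensus.csv")
  wr(results$sl, "_sl_support.csv")

  genes <- sort(unique(c(results$sl$gene_a, results$sl$gene_b)))
  m_sl <- pair_matrix(results$sl, "support", genes)
  f <- paste0(path_prefix, "_matrix_sl_support.tsv")
  write_pair_matrix(m_sl, f)
  files <- c(files, f)

  for (md in unique(results$consensus$media)) {
    sub <- results$consensus[results$consensus$media == md, ]
    m <- pair_matrix(sub, "consensus", genes)
    tag <- gsub("[^A-Za-z0-9]+", "_", md)
    f <- paste0(path_prefix, "_matrix_gi_", tag, ".tsv")
    write_pair_matrix(m, f)
    files <- c(files, f)
    if (isTRUE(heatmaps)) {
      fp <- paste0(path_prefix, "_gi_", tag, ".png")
      g <- plot_gi_heatmap(sub, title = md)
      ggplot2::ggsave(fp, g, width = 7, height = 6, dpi = 120)
      files <- c(files, fp)
    }
  }
  invisible(files)
}

#' @rdname write_results
#' @param path_prefix Path prefix used when writing.
#' @export
read_results <- function(path_prefix) {
  rd <- function(suffix) {
    readr::read_csv(paste0(path_prefix, suffix), show_col_types = FALSE,
                    progress = FALSE)
  }
  list(gi = rd("_replicate_scores.csv"),
       consensus = rd("_consensus.csv"),
       sl = rd("_sl_support.csv"))
}

#' Heatmap of consensus genetic-interaction scores
#'
#' Gene-by-gene tile plot, alphabetical on both axes, diverging palette
#' (negative = aggravating, red; positive = alleviating, green).
#'
#' @param consensus Consensus table for one media.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_gi_heatmap <- function(consensus, title = NULL) {
  genes <- sort(unique(c(consensus$gene_a, consensus$gene_b)))
  both <- dplyr::bind_rows(
    consensus[, c("gene_a", "gene_b", "consensus")],
    stats::setNames(consensus[, c("gene_b", "gene_a", "consensus")],
                    c("gene_a", "gene_b", "consensus"))
  )
  both$gene_a <- factor(both$gene_a, levels = genes)
  both$gene_b <- factor(both$gene_b, levels = rev(genes))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$gene_a, y = .data$gene_b,
                                     fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "grey95",
                                  high = "#1a9850", midpoint = 0,
                                  na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus ε",
                  title = title) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Read a curated evidence table
#'
#' CSV with columns `gene_a`, `gene_b`, `documented_sl` (logical),
#' `documented_source` (`manual`/`HTP`/empty), `tetrad_outcomes`
#' (semicolon-separated tokens from the closed vocabulary SL, V, RV,
#' ambiguous, MD; empty = not tested) and `model_prediction`
#' (`SL`/`V`/`not_simulated`).
#'
#' @param path File path.
#' @return Tibble with canonical pairs and a list-column `tetrad_outcomes`.
#' @export
read_evidence <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene_a", "gene_b", "documented_sl", "tetrad_outcomes",
                "model_prediction")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    gs_abort(paste0("evidence table missing columns: ",
                    paste(missing, collapse = ", ")),
             "giscreen_parse_error")
  }
  a <- pmin(df$gene_a, df$gene_b); b <- pmax(df$gene_a, df$gene_b)
  df$gene_a <- a; df$gene_b <- b
  df$pair_id <- pair_key(a, b)
  outcomes <- strsplit(ifelse(is.na(df$tetrad_outcomes), "",
                              df$tetrad_outcomes), ";")
  outcomes <- lapply(outcomes, function(x) trimws(x[nzchar(trimws(x))]))
  bad <- unique(unlist(outcomes))
  bad <- setdiff(bad, tetrad_vocabulary())
  if (length(bad) > 0) {
    gs_abort(paste0("unknown tetrad outcome token(s): ",
                    paste(bad, collapse = ", ")),
             "giscreen_input_error")
  }
  pred <- df$model_prediction
  okp <- is.na(pred) | pred %in% c("SL", "V", "not_simulated")
  if (!all(okp)) {
    gs_abort("model_prediction must be SL, V or not_simulated",
             "giscreen_input_error")
  }
  df$tetrad_outcomes <- outcomes
  df
}
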