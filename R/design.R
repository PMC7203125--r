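#' Default gene panel of nonessential cell-cycle regulators
#'
#' Thirty-six nonessential budding-yeast cell-cycle regulator genes: START
#' activators and inhibitors (CLN1-3, BCK2, WHI3, WHI5, SWI4/6, NRM1, YHP1,
#' YOX1), B-type cyclins and their antagonists (CLB1/2/3/5/6, SIC1, CDH1),
#' spindle/DNA checkpoint components (BUB1-3, MAD1-3, SWE1), mitotic-exit
#' regulators (LTE1, SPO12, MSN5, CDC55), transcription factors (FKH1/2, SWI5,
#' PCL1/9) and chaperones feeding into Cln3 (SSA1, YDJ1).
#'
#' @return Character vector of 36 gene symbols, alphabetical.
#' @export
default_gene_panel <- function() {
  c("BCK2", "BUB1", "BUB2", "BUB3", "CDC55", "CDH1", "CLB1", "CLB2", "CLB3",
    "CLB5", "CLB6", "CLN1", "CLN2", "CLN3", "FKH1", "FKH2", "LTE1", "MAD1",
    "MAD2", "MAD3", "MSN5", "NRM1", "PCL1", "PCL9", "SIC1", "SPO12", "SSA1",
    "SWE1", "SWI4", "SWI5", "SWI6", "WHI3", "WHI5", "YDJ1", "YHP1", "YOX1")
}

#' Validate a gene panel
#'
#' A panel is an ordered set of unique, non-empty gene symbols. The order is
#' fixed (alphabetical by default) so that derived plate layouts are
#' reproducible.
#'
#' @param genes Character vector of gene symbols.
#' @param sort_genes Sort alphabetically (the canonical order)?
#' @return Validated character vector.
#' @export
gene_panel <- function(genes = default_gene_panel(), sort_genes = TRUE) {
  genes <- as.character(genes)
  if (length(genes) == 0 || anyNA(genes) || any(!nzchar(genes))) {
    gs_abort("gene panel must be a non-empty set of non-empty symbols",
             "giscreen_invalid_panel")
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    gs_abort(paste0("duplicate gene symbols in panel: ",
                    paste(dup, collapse = ", ")),
             "giscreen_invalid_panel")
  }
  if (sort_genes) genes <- sort(genes)
  genes
}

#' Canonical unordered pair key
#'
#' Gene pairs are unordered: equality ignores orientation. The canonical form
#' stores the lexicographically smaller symbol first; the key is
#' `"<gene_a>:<gene_b>"`.
#'
#' @param gene_a,gene_b Character vectors of gene symbols (recycled).
#' @return Character vector of canonical pair keys.
#' @export
pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = ":")
}

#' Enumerate all unordered gene pairs of a panel
#'
#' All n(n-1)/2 distinct unordered pairs, canonically ordered (alphabetical
#' within pair and across rows). For the default 36-gene panel this is the 630
#' double-mutant combinations a full pairwise cross generates.
#'
#' @param panel Character vector of gene symbols (validated by [gene_panel()]).
#' @return Tibble with columns `gene_a`, `gene_b`, `pair_id`.
#' @export
enumerate_pairs <- function(panel = default_gene_panel()) {
  panel <- gene_panel(panel)
  if (length(panel) < 2) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          pair_id = character()))
  }
  cmb <- utils::combn(panel, 2)
  tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ],
                 pair_id = pair_key(cmb[1, ], cmb[2, ]))
}

#' Crossing design for a pairwise deletion screen
#'
#' Encodes how biological replicates arise: independent cross sets (parent
#' strain sets), both mating types collected per cross, and the two reciprocal
#' marker orientations implied by the ordered (bait, hit) pair within each
#' cross. Default: 4 cross sets x 2 mating types, giving up to
#' 4 x 2 x 2 = 16 biological replicates per unordered gene pair.
#'
#' @param panel Gene panel.
#' @param n_cross_sets Number of independent cross sets (>= 1).
#' @param mating_types Subset of `c("a", "alpha")`.
#' @return Object of class `cross_design`.
#' @export
cross_design <- function(panel = default_gene_panel(), n_cross_sets = 4,
                         mating_types = c("a", "alpha")) {
  panel <- gene_panel(panel)
  n_cross_sets <- as.integer(n_cross_sets)
  if (is.na(n_cross_sets) || n_cross_sets < 1) {
    gs_abort("n_cross_sets must be >= 1", "giscreen_config_error")
  }
  mating_types <- unique(as.character(mating_types))
  if (length(mating_types) == 0 || !all(mating_types %in% c("a", "alpha"))) {
    gs_abort("mating_types must be a non-empty subset of {a, alpha}",
             "giscreen_config_error")
  }
  structure(list(panel = panel, n_cross_sets = n_cross_sets,
                 mating_types = mating_types),
            class = "cross_design")
}

#' Enumerate every replicate lineage of a crossing design
#'
#' One lineage per (cross set, mating type, ordered bait x hit gene pair),
#' including the monogenic self-crosses that serve as false-negative sentinels.
#' For the default design this is 4 x 2 x 36 x 36 = 10,368 lineages; restricting
#' to distinct non-monogenic unordered pairs gives 16 biological replicates per
#' pair (two marker orientations per cross set and mating type).
#'
#' @param design A [cross_design()].
#' @return Tibble with one row per lineage: `cross_set`, `mating_type`,
#'   `bait_gene`, `hit_gene`, `content` (`"double_mutant"` or `"monogenic"`),
#'   canonical `gene_a`/`gene_b`, `pair_id` (NA for monogenic), `lineage_id`.
#' @export
enumerate_design <- function(design = cross_design()) {
  stopifnot(inherits(design, "cross_design"))
  out <- tidyr::expand_grid(
    cross_set = seq_len(design$n_cross_sets),
    mating_type = design$mating_types,
    bait_gene = design$panel,
    hit_gene = design$panel
  )
  out$content <- ifelse(out$bait_gene == out$hit_gene,
                        "monogenic", "double_mutant")
  out$gene_a <- pmin(out$bait_gene, out$hit_gene)
  out$gene_b <- pmax(out$bait_gene, out$hit_gene)
  out$pair_id <- ifelse(out$content == "double_mutant",
                        pair_key(out$bait_gene, out$hit_gene), NA_character_)
  out$lineage_id <- sprintf("cs%d_%s_%s.%s", out$cross_set, out$mating_type,
                            out$bait_gene, out$hit_gene)
  out
}

#' Plate scheme: grid geometry, wild-type rows and quadruplicate blocks
#'
#' The default 384-density phenotyping layout: a 16 x 24 grid (rows A-P,
#' columns 1-24) with rows A, B, I and J reserved for in-plate wild-type
#' controls. Each source lineage is pinned in quadruplicate as a 2x2 block;
#' successive non-WT rows are paired, so the default capacity is
#' 6 row-pairs x 12 column-pairs = 72 lineages per plate.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param wt_rows Row letters reserved for wild-type controls.
#' @return Object of class `plate_scheme`.
#' @export
plate_scheme <- function(n_rows = 16, n_cols = 24,
                         wt_rows = c("A", "B", "I", "J")) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1 || n_cols < 2 || n_cols %% 2 != 0) {
    gs_abort("plate scheme needs n_rows >= 1 and an even n_cols >= 2",
             "giscreen_config_error")
  }
  wt_idx <- match(wt_rows, LETTERS[seq_len(n_rows)])
  if (anyNA(wt_idx)) {
    gs_abort("wt_rows outside the plate grid", "giscreen_config_error")
  }
  mutant_rows <- setdiff(seq_len(n_rows), wt_idx)
  if (length(mutant_rows) %% 2 != 0) {
    gs_abort("scheme must leave an even number of mutant rows for 2x2 blocks",
             "giscreen_config_error")
  }
  capacity <- (length(mutant_rows) / 2) * (n_cols / 2)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 wt_rows = sort(wt_idx), mutant_rows = mutant_rows,
                 capacity = as.integer(capacity)),
            class = "plate_scheme")
}

#' Build one plate layout from a list of lineages
#'
#' Assigns each lineage a 2x2 quadruplicate block in block order (row-pair
#' major, column-pair minor), tags wild-type rows, and marks unused blocks
#' empty. Lineage tags (`double_mutant`, `monogenic`, `single_parent`) are
#' carried through unchanged.
#'
#' @param lineages Tibble with columns `lineage_id`, `content`, `gene_a`,
#'   `gene_b` (NA allowed), or NULL for a plate of controls only.
#' @param scheme A [plate_scheme()].
#' @param plate_id Identifier written into the layout.
#' @return Tibble layout: `plate`, `row` (1-based integer), `col`, `content`,
#'   `lineage_id`, `gene_a`, `gene_b`. Every grid position appears exactly once.
#' @export
build_plate_layout <- function(lineages = NULL, scheme = plate_scheme(),
                               plate_id = "plate01") {
  stopifnot(inherits(scheme, "plate_scheme"))
  n_lin <- if (is.null(lineages)) 0L else nrow(lineages)
  if (n_lin > scheme$capacity) {
    gs_abort(sprintf("%d lineages exceed plate capacity %d",
                     n_lin, scheme$capacity),
             "giscreen_capacity_error")
  }
  grid <- tidyr::expand_grid(row = seq_len(scheme$n_rows),
                             col = seq_len(scheme$n_cols))
  grid$plate <- plate_id
  grid$content <- ifelse(grid$row %in% scheme$wt_rows, "wt_control", "empty")
  grid$lineage_id <- NA_character_
  grid$gene_a <- NA_character_
  grid$gene_b <- NA_character_

  if (n_lin > 0) {
    mr <- scheme$mutant_rows
    n_col_pairs <- scheme$n_cols / 2
    for (i in seq_len(n_lin)) {
      block <- i - 1L
      rp <- block %/% n_col_pairs   # row-pair index, 0-based
      cp <- block %% n_col_pairs
      rows <- mr[c(2 * rp + 1, 2 * rp + 2)]
      cols <- c(2 * cp + 1, 2 * cp + 2)
      sel <- grid$row %in% rows & grid$col %in% cols
      grid$content[sel] <- lineages$content[i]
      grid$lineage_id[sel] <- lineages$lineage_id[i]
      grid$gene_a[sel] <- lineages$gene_a[i]
      grid$gene_b[sel] <- if ("gene_b" %in% names(lineages)) {
        lineages$gene_b[i]
      } else {
        NA_character_
      }
    }
  }
  grid[, c("plate", "row", "col", "content", "lineage_id", "gene_a", "gene_b")]
}

#' Distribute lineages over as many plates as needed
#'
#' @param lineages Tibble as for [build_plate_layout()].
#' @param scheme A [plate_scheme()].
#' @param plate_prefix Prefix for generated plate ids.
#' @return Single tibble with all plate layouts stacked.
#' @export
assign_plates <- function(lineages, scheme = plate_scheme(),
                          plate_prefix = "p") {
  n <- nrow(lineages)
  n_plates <- max(1L, ceiling(n / scheme$capacity))
  chunks <- split(seq_len(n), ceiling(seq_len(n) / scheme$capacity))
  layouts <- purrr::imap(chunks, function(idx, k) {
    build_plate_layout(lineages[idx, , drop = FALSE], scheme,
                       plate_id = sprintf("%s%02d", plate_prefix,
                                          as.integer(k)))
  })
  if (n == 0) {
    layouts <- list(build_plate_layout(NULL, scheme,
                                       plate_id = paste0(plate_prefix, "01")))
  }
  dplyr::bind_rows(layouts)
}

#' Convert between row letters and 1-based row indices
#'
#' Internal representation is 1-based integers; letters appear only at I/O.
#' @param row Letter vector or integer vector.
#' @return The other representation.
#' @export
row_to_letter <- function(row) LETTERS[as.integer(row)]

#' @rdname row_to_letter
#' @export
letter_to_row <- function(row) {
  idx <- match(toupper(as.character(row)), LETTERS)
  # numeric rows pass through so readers accept either dialect
  num <- suppressWarnings(as.integer(row))
  out <- ifelse(is.na(idx), num, idx)
  if (anyNA(out)) {
    gs_abort("unrecognized row labels", "giscreen_parse_error")
  }
  as.integer(out)
}
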