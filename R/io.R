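#' Load a per-transcript table
#'
#' Reads a delimited file with one row per detected transcript and returns a
#' validated transcript table: columns `cell`, `gene`, `x`, `y` (micrometres)
#' and integer z-plane index `z` (0 when the data have a single plane).
#' Unmapped extra columns are dropped; row order is preserved.
#'
#' @param path CSV/TSV file (gzip accepted, by extension).
#' @param columns named character vector mapping the canonical names
#'   `cell`, `gene`, `x`, `y` and optionally `z` to the file's column names.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @param blank_prefix prefix identifying blank (negative-control) probes;
#'   matching genes are flagged in the `blank` column but treated as ordinary
#'   genes by every test.
#' @return data.frame of class `transcript_table` with columns
#'   `cell, gene, x, y, z, blank` (and `region` once [assign_regions()] ran).
#' @export
load_transcripts <- function(path,
                             columns = c(cell = "cell", gene = "gene",
                                         x = "x", y = "y", z = "z"),
                             sep = ",", blank_prefix = "Blank") {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell", "gene", "x", "y")
  for (nm in need) {
    cn <- columns[[nm]]
    if (is.null(cn) || !cn %in% names(raw))
      stop("missing required column '", if (is.null(cn)) nm else cn,
           "' in ", path)
  }
  tab <- data.frame(cell = as.character(raw[[columns[["cell"]]]]),
                    gene = as.character(raw[[columns[["gene"]]]]),
                    x = suppressWarnings(as.numeric(raw[[columns[["x"]]]])),
                    y = suppressWarnings(as.numeric(raw[[columns[["y"]]]])),
                    stringsAsFactors = FALSE)
  zc <- if ("z" %in% names(columns)) columns[["z"]] else NULL
  tab$z <- if (!is.null(zc) && !is.na(zc) && zc %in% names(raw)) {
    as.integer(raw[[zc]])
  } else 0L
  bad <- which(!is.finite(tab$x) | !is.finite(tab$y))
  if (length(bad))
    stop("non-finite coordinate at row ", bad[1], " of ", path)
  if (any(tab$z < 0, na.rm = TRUE)) stop("negative z-plane index")
  as_transcript_table(tab, blank_prefix = blank_prefix)
}

#' Construct a transcript table from a data.frame
#'
#' @param df data.frame with columns `cell, gene, x, y` and optional `z`.
#' @param blank_prefix prefix marking blank probes.
#' @return validated `transcript_table`.
#' @export
as_transcript_table <- function(df, blank_prefix = "Blank") {
  stopifnot(all(c("cell", "gene", "x", "y") %in% names(df)))
  if (is.null(df$z)) df$z <- 0L
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite transcript coordinates")
  df$cell <- as.character(df$cell)
  df$gene <- as.character(df$gene)
  df$z <- as.integer(df$z)
  df$blank <- startsWith(df$gene, blank_prefix)
  attr(df, "blank_prefix") <- blank_prefix
  class(df) <- c("transcript_table", "data.frame")
  df
}

#' Filter cells by transcript-count criteria
#'
#' Keeps only cells that have at least one z-plane with `min_per_plane`
#' transcripts or more, and `min_total` transcripts overall. With both
#' thresholds 0 the input is returned unchanged. Idempotent.
#'
#' @param table transcript table.
#' @param min_per_plane minimum transcript count required in the best z-plane
#'   (default 20, the usual quality gate for multi-plane tissue data).
#' @param min_total minimum whole-cell transcript count.
#' @return filtered transcript table; the number of removed cells is reported
#'   via `message()`.
#' @export
filter_cells <- function(table, min_per_plane = 20L, min_total = 0L) {
  stopifnot(min_per_plane >= 0, min_total >= 0)
  if (min_per_plane == 0 && min_total == 0) return(table)
  per_plane <- tapply(rep(1L, nrow(table)),
                      list(table$cell, table$z), sum, default = 0L)
  best <- apply(per_plane, 1, max)
  total <- tapply(rep(1L, nrow(table)), table$cell, sum)
  keep_cells <- names(best)[best >= min_per_plane &
                              total[names(best)] >= min_total]
  removed <- length(unique(table$cell)) - length(keep_cells)
  if (removed > 0)
    message("filter_cells: removed ", removed, " cell(s)")
  out <- table[table$cell %in% keep_cells, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permute gene labels within each cell
#'
#' Builds the permutation baseline for false-positive-rate estimation: within
#' every cell the multiset of gene labels is reassigned uniformly at random
#' across that cell's transcript coordinates. Coordinates, z-planes and cell
#' membership are untouched, so the spatial texture of the data is preserved
#' while all gene-gene relationships are destroyed.
#'
#' @param table transcript table.
#' @param seed integer seed; the permutation is reproducible.
#' @return transcript table with shuffled `gene` (and `blank`) columns.
#' @export
permute_gene_labels <- function(table, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  idx <- split(seq_len(nrow(table)), table$cell)
  gene <- table$gene
  for (ii in idx) {
    if (length(ii) > 1) gene[ii] <- gene[sample(ii)]
  }
  out <- table
  out$gene <- gene
  out$blank <- startsWith(gene, attr(table, "blank_prefix") %||% "Blank")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load cell metadata (type labels and centroids)
#'
#' @param path CSV with columns `cell_id, cell_type, centroid_x, centroid_y`
#'   (extra columns kept).
#' @return data.frame with one row per cell.
#' @export
load_cell_meta <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot("cell_id" %in% names(meta))
  meta$cell_id <- as.character(meta$cell_id)
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id in metadata")
  meta
}
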