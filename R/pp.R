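#' Per-cell null probability of transcript proximity
#'
#' The chance that a random pair of transcripts in the cell lies within
#' distance `d`, estimated from all unordered pairs of transcripts regardless
#' of gene identity: (# pairs with Euclidean distance <= d) / (N choose 2).
#'
#' @param x,y transcript coordinates (micrometres) of one cell (one z-plane).
#' @param d distance threshold (micrometres), closed (`<= d`).
#' @return probability in `[0, 1]`.
#' @export
estimate_null_prob <- function(x, y, d) {
  n <- length(x)
  if (n < 2) stop("null probability undefined: fewer than 2 transcripts")
  cnt <- .pair_counts_cpp(as.numeric(x), as.numeric(y),
                          rep(1L, n), 1L, d, integer(0))
  cnt$n_prox / choose(n, 2)
}

#' Count proximal cross-gene transcript pairs in one cell
#'
#' For every gene pair (i < j) co-expressed in the cell, counts `K`, the
#' number of transcript pairs (one transcript from each gene) within `d`, and
#' `T = t_i * t_j`, the number of possible such pairs. The default
#' `method = "grid"` uses a fixed-radius grid-hash neighbor search (Rcpp); the
#' `"naive"` method is the all-pairs distance-matrix scan kept as an
#' independent oracle — both return identical integers.
#'
#' @param x,y,gene coordinates and gene labels of one cell's transcripts
#'   (one z-plane).
#' @param d distance threshold (closed).
#' @param method `"grid"` or `"naive"`.
#' @param region optional factor of region labels (levels Nuc, PN, Cyt, CP);
#'   when present, each proximal cross-gene pair contributes 1/2 per member
#'   to that member's region tally.
#' @return list with `pairs` (data.frame `gene_a, gene_b, K, T` and region
#'   tally columns when regions given; `gene_a < gene_b` lexicographically
#'   within the cell's gene set order) and `n_prox` (all-gene proximal pair
#'   count, the numerator of [estimate_null_prob()]).
#' @export
count_pair_proximity <- function(x, y, gene, d, method = c("grid", "naive"),
                                 region = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) == length(gene))
  glev <- sort(unique(as.character(gene)))
  gi <- match(as.character(gene), glev)
  n <- length(x)
  ng <- length(glev)
  reg_int <- if (!is.null(region)) {
    as.integer(factor(as.character(region), levels = .REGIONS))
  } else integer(0)

  if (method == "grid") {
    cnt <- .pair_counts_cpp(as.numeric(x), as.numeric(y), gi, ng, d, reg_int)
    K <- cnt$K; pi_ <- cnt$pair_i; pj_ <- cnt$pair_j; rt <- cnt$region
    n_prox <- cnt$n_prox
  } else {
    if (n >= 2) {
      D <- as.matrix(dist(cbind(x, y)))
      ut <- upper.tri(D)
      prox <- ut & D <= d
      n_prox <- sum(prox)
      idx <- which(prox, arr.ind = TRUE)
      a <- pmin(gi[idx[, 1]], gi[idx[, 2]])
      b <- pmax(gi[idx[, 1]], gi[idx[, 2]])
      cross <- a != b
      a <- a[cross]; b <- b[cross]
      if (length(a)) {
        key <- paste(a, b)
        tb <- table(key)
        ab <- do.call(rbind, strsplit(names(tb), " "))
        pi_ <- as.integer(ab[, 1]); pj_ <- as.integer(ab[, 2])
        K <- as.numeric(tb)
      } else pi_ <- pj_ <- K <- numeric(0)
      if (length(reg_int)) {
        rt <- matrix(0, length(pi_), 4)
        ra <- reg_int[idx[, 1]][cross]; rb <- reg_int[idx[, 2]][cross]
        kk <- match(paste(a, b), paste(pi_, pj_))
        for (q in seq_along(kk)) {
          if (!is.na(ra[q])) rt[kk[q], ra[q]] <- rt[kk[q], ra[q]] + 0.5
          if (!is.na(rb[q])) rt[kk[q], rb[q]] <- rt[kk[q], rb[q]] + 0.5
        }
      } else rt <- matrix(0, length(pi_), 4)
    } else {
      n_prox <- 0; pi_ <- pj_ <- K <- numeric(0); rt <- matrix(0, 0, 4)
    }
  }

  # complete the pair universe: every co-expressed pair, K = 0 included
  tcount <- tabulate(gi, nbins = ng)
  expressed <- which(tcount > 0)
  if (length(expressed) < 2) {
    pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                        K = numeric(0), T = numeric(0))
    pairs[.REGIONS] <- numeric(0)
    return(list(pairs = pairs, n_prox = n_prox))
  }
  cmb <- combn(expressed, 2)
  Kfull <- numeric(ncol(cmb))
  rtfull <- matrix(0, ncol(cmb), 4)
  if (length(pi_)) {
    pos <- match(paste(pi_, pj_), paste(cmb[1, ], cmb[2, ]))
    Kfull[pos] <- K
    if (nrow(rt)) rtfull[pos, ] <- rt
  }
  pairs <- data.frame(gene_a = glev[cmb[1, ]], gene_b = glev[cmb[2, ]],
                      K = Kfull, T = as.numeric(tcount[cmb[1, ]]) *
                        as.numeric(tcount[cmb[2, ]]),
                      stringsAsFactors = FALSE)
  colnames(rtfull) <- .REGIONS
  pairs <- cbind(pairs, as.data.frame(rtfull))
  list(pairs = pairs, n_prox = n_prox)
}

# restrict a cell's transcripts to the subnuclear compartment
.nucleus_subset <- function(cell_df) {
  if (is.null(cell_df$region))
    stop("nucleus_only requires region-annotated transcripts")
  keep <- cell_df$region == "Nuc" |
    (cell_df$region == "PN" & isTRUE_vec(cell_df$in_nucleus))
  cell_df[keep & !is.na(keep), , drop = FALSE]
}

isTRUE_vec <- function(v) if (is.null(v)) FALSE else v %in% TRUE

#' Proximal-pair test for a single cell
#'
#' Tests, for every co-expressed gene pair in the cell, whether its
#' transcripts are within distance `d` of each other more often than expected
#' from the cell's own background proximity rate. The p-value is the exact
#' upper-tail binomial probability `P(X >= K | T, p_null)`.
#'
#' In `mode = "3d"` each z-plane is treated as an independent, identically
#' distributed replicate: pairs are never formed across planes, the null
#' probability is the transcript-count-weighted mean of per-plane null
#' probabilities (`p = sum_z l_z p_z / sum_z l_z`), and `K` and `T` are
#' summed over planes. Planes with fewer than 2 transcripts are skipped.
#'
#' @param cell_df transcript table rows of one cell.
#' @param d distance threshold (micrometres).
#' @param mode `"2d"` (planes ignored, all transcripts in one plane) or
#'   `"3d"` (per-plane counting with pooled null).
#' @param nucleus_only restrict the test (including null estimation) to
#'   subnuclear transcripts: region `Nuc` plus `PN` transcripts lying inside
#'   the nucleus. Requires [assign_regions()] annotation.
#' @param min_transcripts minimum transcripts for the cell to be testable.
#' @param method neighbor-search backend, see [count_pair_proximity()].
#' @return data.frame: `gene_a, gene_b, K, T, p_null, pvalue` plus region
#'   tally columns, or `NULL` when the cell has no usable plane.
#' @export
pp_test_cell <- function(cell_df, d, mode = c("2d", "3d"),
                         nucleus_only = FALSE, min_transcripts = 2L,
                         method = "grid") {
  mode <- match.arg(mode)
  if (nucleus_only) cell_df <- .nucleus_subset(cell_df)
  if (nrow(cell_df) < max(2L, min_transcripts)) return(NULL)
  planes <- if (mode == "2d") list(cell_df) else
    split(cell_df, cell_df$z)
  num <- den <- 0
  acc <- NULL
  n_usable <- 0L
  for (pl in planes) {
    l_z <- nrow(pl)
    if (l_z < 2) next
    n_usable <- n_usable + 1L
    cnt <- count_pair_proximity(pl$x, pl$y, pl$gene, d, method = method,
                                region = pl$region)
    p_z <- cnt$n_prox / choose(l_z, 2)
    num <- num + l_z * p_z
    den <- den + l_z
    acc <- if (is.null(acc)) cnt$pairs else
      .merge_pair_counts(acc, cnt$pairs)
  }
  if (n_usable == 0L) return(NULL)
  p_null <- num / den
  res <- acc
  if (nrow(res) == 0) return(NULL)
  pv <- pbinom(res$K - 1, res$T, p_null, lower.tail = FALSE)
  if (p_null == 0) {
    pv <- ifelse(res$K > 0, 0, 1)
    if (any(res$K > 0))
      warning("zero null probability with K > 0 observed")
  }
  res$p_null <- p_null
  res$pvalue <- pv
  res[c("gene_a", "gene_b", "K", "T", "p_null", "pvalue", .REGIONS)]
}

# sum K, T and region tallies of two per-plane pair tables
.merge_pair_counts <- function(a, b) {
  key_a <- paste(a$gene_a, a$gene_b)
  key_b <- paste(b$gene_a, b$gene_b)
  allk <- union(key_a, key_b)
  out <- data.frame(gene_a = sub(" .*", "", allk),
                    gene_b = sub(".* ", "", allk),
                    stringsAsFactors = FALSE)
  for (col in c("K", "T", .REGIONS)) {
    va <- a[[col]][match(allk, key_a)]; va[is.na(va)] <- 0
    vb <- b[[col]][match(allk, key_b)]; vb[is.na(vb)] <- 0
    out[[col]] <- va + vb
  }
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Proximal-pair test across a dataset
#'
#' Runs [pp_test_cell()] on every cell and binarizes the results into a
#' pair-by-cell indicator object: `X[pair, cell] = 1` iff the pair's PP
#' p-value in that cell is below `alpha_pp`. Cells failing the minimum
#' transcript precondition are excluded (and counted in the returned object).
#'
#' @inheritParams pp_test_cell
#' @param table transcript table.
#' @param alpha_pp per-cell significance threshold (default 0.01).
#' @param genes optional gene panel (default: all genes observed).
#' @param min_expr minimal per-cell transcript count for a gene to count as
#'   expressed (default 1).
#' @return object of class `pp_indicators`: list with `genes`, `cells`,
#'   `pairs` (pair universe, i < j), logical matrix `X` (pairs x cells),
#'   logical matrix `E` (genes x cells, expression indicators), `N_c`
#'   (per-cell significant-pair counts), `results` (long per-cell PP table)
#'   and `params`.
#' @export
pp_test_dataset <- function(table, d, mode = c("2d", "3d"), alpha_pp = 0.01,
                            nucleus_only = FALSE, min_transcripts = 2L,
                            min_expr = 1L, genes = NULL, method = "grid") {
  mode <- match.arg(mode)
  genes <- if (is.null(genes)) sort(unique(table$gene)) else sort(genes)
  ng <- length(genes)
  cmb <- if (ng >= 2) combn(ng, 2) else matrix(integer(0), 2, 0)
  pair_key <- paste(genes[cmb[1, ]], genes[cmb[2, ]])
  cells <- unique(table$cell)
  res_list <- list()
  kept <- character(0)
  for (cid in cells) {
    r <- pp_test_cell(table[table$cell == cid, , drop = FALSE], d,
                      mode = mode, nucleus_only = nucleus_only,
                      min_transcripts = min_transcripts, method = method)
    if (is.null(r)) next
    r$cell_id <- cid
    kept <- c(kept, cid)
    res_list[[cid]] <- r
  }
  n_skipped <- length(cells) - length(kept)
  if (n_skipped > 0)
    message("pp_test_dataset: skipped ", n_skipped, " cell(s)")
  nc <- length(kept)
  X <- matrix(FALSE, length(pair_key), nc,
              dimnames = list(pair_key, kept))
  E <- matrix(FALSE, ng, nc, dimnames = list(genes, kept))
  counts <- table(factor(table$gene, levels = genes), table$cell)
  if (nc > 0) E[, kept] <- counts[, kept, drop = FALSE] >= min_expr
  for (cid in kept) {
    r <- res_list[[cid]]
    sig <- r$pvalue < alpha_pp
    if (any(sig))
      X[paste(r$gene_a, r$gene_b)[sig], cid] <- TRUE
  }
  results <- if (length(res_list)) do.call(rbind, res_list) else NULL
  rownames(results) <- NULL
  structure(list(genes = genes, cells = kept,
                 pairs = data.frame(gene_a = genes[cmb[1, ]],
                                    gene_b = genes[cmb[2, ]],
                                    stringsAsFactors = FALSE),
                 X = X, E = E, N_c = colSums(X),
                 results = results,
                 params = list(d = d, mode = mode, alpha_pp = alpha_pp,
                               nucleus_only = nucleus_only,
                               min_transcripts = min_transcripts,
                               min_expr = min_expr),
                 n_skipped = n_skipped),
            class = "pp_indicators")
}

#' @export
print.pp_indicators <- function(x, ...) {
  cat("pp_indicators:", length(x$genes), "genes x", length(x$cells),
      "cells;", sum(x$X), "significant pair-cell events (alpha_pp =",
      x$params$alpha_pp, ", d =", x$params$d, "um,", x$params$mode, ")\n")
  invisible(x)
}
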