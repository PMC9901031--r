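#' Cell-type association of proximal pairs
#'
#' For every gene pair and every cell type, tests whether the cells in which
#' the pair is a significant proximal pair (set O) are over-represented among
#' the cells of that type (set M), with an upper-tail hypergeometric test on
#' `|M intersect O|` given `|M|`, `|O|` and the total cell count. P-values
#' are Bonferroni-corrected over all (pair, type) combinations.
#'
#' @param ind `pp_indicators`.
#' @param meta cell metadata with `cell_id` and `cell_type`; every cell in
#'   `ind` must be typed.
#' @param pairs optional subset of pairs (data.frame `gene_a, gene_b`),
#'   e.g. the significant rows of a d-colocalization map; default all pairs
#'   with support > 0.
#' @param alpha significance level on the corrected p-value (default 0.05).
#' @return data.frame `gene_a, gene_b, cell_type, overlap, m, o, u, pvalue,
#'   p_bonferroni, significant`.
#' @export
celltype_association <- function(ind, meta, pairs = NULL, alpha = 0.05) {
  ct <- setNames(as.character(meta$cell_type), meta$cell_id)[ind$cells]
  if (anyNA(ct)) stop("untyped cell(s) in indicator object")
  types <- sort(unique(ct))
  U <- length(ind$cells)
  if (is.null(pairs)) {
    keep <- rowSums(ind$X) > 0
    pairs <- ind$pairs[keep, , drop = FALSE]
  }
  pkey <- paste(pairs$gene_a, pairs$gene_b)
  ikey <- paste(ind$pairs$gene_a, ind$pairs$gene_b)
  rows <- match(pkey, ikey)
  if (anyNA(rows)) stop("pair(s) absent from indicator object")
  out <- expand.grid(pair = seq_along(rows), cell_type = types,
                     stringsAsFactors = FALSE)
  out$gene_a <- pairs$gene_a[out$pair]
  out$gene_b <- pairs$gene_b[out$pair]
  m <- vapply(types, function(tt) sum(ct == tt), numeric(1))
  o <- rowSums(ind$X)[rows]
  ov <- matrix(0, length(rows), length(types))
  for (t_i in seq_along(types)) {
    sel <- ct == types[t_i]
    ov[, t_i] <- rowSums(ind$X[rows, sel, drop = FALSE])
  }
  out$overlap <- ov[cbind(out$pair, match(out$cell_type, types))]
  out$m <- m[match(out$cell_type, types)]
  out$o <- o[out$pair]
  out$u <- U
  out$pvalue <- ifelse(out$o == 0, 1,
                       phyper(out$overlap - 1, out$m, U - out$m, out$o,
                              lower.tail = FALSE))
  out$p_bonferroni <- pmin(1, out$pvalue * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  out$pair <- NULL
  out[order(out$gene_a, out$gene_b, out$cell_type), ]
}

#' Conditional hypergeometric p-value for set association
#'
#' Tests the association between a cell-type set M and a proximal-pair cell
#' set O beyond what is explained by a third set E (high-expression cells of
#' one gene): the probability that a random set O' of size `|O|`, drawn
#' conditional on `|O' intersect E| = alpha` and with `|M intersect E| =
#' gamma` fixed, overlaps M in at least `lambda` cells. This is the
#' upper tail of a multivariate hypergeometric distribution over the
#' partition {M∩E, M\\E, E\\M, rest}.
#'
#' @param u total number of cells `|U|`.
#' @param m_size,e_size,o_size sizes of M, E, O.
#' @param gamma `|M intersect E|`.
#' @param alpha_overlap `|E intersect O|`.
#' @param lambda observed `|M intersect O|`.
#' @return p-value in `[0, 1]`; `lambda = 0` gives 1.
#' @export
conditional_hypergeom_pvalue <- function(u, m_size, e_size, o_size,
                                         gamma, alpha_overlap, lambda) {
  if (gamma > min(m_size, e_size))
    stop("inconsistent counts: gamma > min(|M|, |E|)")
  if (alpha_overlap > min(e_size, o_size))
    stop("inconsistent counts: alpha > min(|E|, |O|)")
  if (lambda > min(m_size, o_size))
    stop("inconsistent counts: lambda > min(|M|, |O|)")
  if (m_size > u || e_size > u || o_size > u)
    stop("inconsistent counts: set larger than |U|")
  if (o_size - alpha_overlap > u - e_size)
    stop("inconsistent counts: |O \\ E| > |U \\ E|")
  if (lambda == 0) return(1)
  rest <- u - m_size - e_size + gamma          # |U \ (M u E)|
  ldenom <- lchoose(e_size, alpha_overlap) +
    lchoose(u - e_size, o_size - alpha_overlap)
  total <- 0
  for (k in lambda:min(m_size, o_size)) {
    for (beta in 0:min(k, gamma, alpha_overlap)) {
      t1 <- lchoose(gamma, beta)                       # from M∩E
      t2 <- lchoose(m_size - gamma, k - beta)          # from M\E
      t3 <- lchoose(e_size - gamma, alpha_overlap - beta)  # from E\M
      t4 <- lchoose(rest, o_size - alpha_overlap - k + beta)  # from rest
      term <- t1 + t2 + t3 + t4 - ldenom
      if (is.finite(term)) total <- total + exp(term)
    }
  }
  min(1, total)
}

#' Per-type marker genes by expression-type association
#'
#' For each gene and cell type, the high-expression cell set E holds the
#' `|M|` cells with the highest per-cell transcript count of the gene (ties
#' broken deterministically by cell id), where M is the set of cells of that
#' type. Genes are ranked per type by the upper-tail hypergeometric p-value
#' of `|E intersect M|`; the top `top_k` genes are that type's markers.
#'
#' @param table transcript table.
#' @param meta cell metadata with `cell_id`, `cell_type`.
#' @param top_k markers per type (default 10).
#' @param cells optional cell universe (default: cells present in `table`).
#' @return list: `markers` (named list of character vectors, one per type)
#'   and `expr_sets` (function `(gene, size)` returning the high-expression
#'   cell set, reused by [categorize_pairs()]).
#' @export
find_markers <- function(table, meta, top_k = 10L, cells = NULL) {
  if (is.null(cells)) cells <- unique(table$cell)
  counts <- table(table$gene, table$cell)
  counts <- counts[, intersect(colnames(counts), cells), drop = FALSE]
  genes <- rownames(counts)[rowSums(counts) > 0]
  ct <- setNames(as.character(meta$cell_type), meta$cell_id)[colnames(counts)]
  types <- sort(unique(ct))
  U <- length(ct)
  # deterministic ranking: count desc, cell id asc
  expr_set <- function(gene, size) {
    v <- counts[gene, ]
    ord <- order(-as.numeric(v), colnames(counts))
    colnames(counts)[ord][seq_len(min(size, length(ord)))]
  }
  markers <- list()
  for (tt in types) {
    M <- colnames(counts)[ct == tt]
    pv <- vapply(genes, function(g) {
      E <- expr_set(g, length(M))
      phyper(length(intersect(E, M)) - 1, length(M), U - length(M),
             length(E), lower.tail = FALSE)
    }, numeric(1))
    markers[[tt]] <- genes[order(pv, genes)][seq_len(min(top_k, length(genes)))]
  }
  list(markers = markers, expr_sets = expr_set)
}

#' Categorize d-colocalized pairs by cell-type specificity
#'
#' Three categories per the decision flow: Category 3 when the pair is not
#' significantly associated with any cell type (Bonferroni-corrected
#' hypergeometric p >= `alpha`); Category 2 when it is associated with a type
#' and the association survives conditioning on the high-expression cells of
#' each gene in turn (both conditional tests significant) and neither gene is
#' a marker of that type — specificity beyond either gene's expression;
#' Category 1 otherwise (explainable by expression specificity or marker
#' status). `legacy_labels = TRUE` swaps the labels 1 and 2 for the
#' alternative labeling convention.
#'
#' @param map `dcoloc_map` (or any data.frame with `gene_a`, `gene_b`) of
#'   the pairs to categorize.
#' @param ind `pp_indicators`.
#' @param table transcript table (for expression ranking).
#' @param meta cell metadata with `cell_id`, `cell_type`.
#' @param alpha significance level for all tests (default 0.05).
#' @param top_k_markers markers per type (default 10).
#' @param restrict_types optional character vector: restrict the cell
#'   universe to these types (two-way specificity tests).
#' @param legacy_labels swap category labels 1 and 2.
#' @return data.frame `gene_a, gene_b, category, cell_type, assoc_p,
#'   cond_p_a, cond_p_b, marker_a, marker_b` (type columns `NA` for
#'   category 3; the most significant associated type is reported).
#' @export
categorize_pairs <- function(map, ind, table, meta, alpha = 0.05,
                             top_k_markers = 10L, restrict_types = NULL,
                             legacy_labels = FALSE) {
  if (!is.null(restrict_types)) {
    meta <- meta[meta$cell_type %in% restrict_types, , drop = FALSE]
    keep <- ind$cells %in% meta$cell_id
    ind$cells <- ind$cells[keep]
    ind$X <- ind$X[, keep, drop = FALSE]
    ind$E <- ind$E[, keep, drop = FALSE]
    ind$N_c <- ind$N_c[keep]
    table <- table[table$cell %in% meta$cell_id, , drop = FALSE]
  }
  assoc <- celltype_association(ind, meta, pairs = map[c("gene_a", "gene_b")],
                                alpha = alpha)
  mk <- find_markers(table, meta, top_k = top_k_markers, cells = ind$cells)
  ct <- setNames(as.character(meta$cell_type), meta$cell_id)[ind$cells]
  ikey <- paste(ind$pairs$gene_a, ind$pairs$gene_b)
  out <- data.frame(gene_a = map$gene_a, gene_b = map$gene_b,
                    category = NA_integer_, cell_type = NA_character_,
                    assoc_p = NA_real_, cond_p_a = NA_real_,
                    cond_p_b = NA_real_, marker_a = NA, marker_b = NA,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    ga <- out$gene_a[r]; gb <- out$gene_b[r]
    arows <- assoc[assoc$gene_a == ga & assoc$gene_b == gb, , drop = FALSE]
    sig <- arows[arows$significant, , drop = FALSE]
    if (nrow(sig) == 0) { out$category[r] <- 3L; next }
    best <- sig[which.min(sig$p_bonferroni), ]
    tt <- best$cell_type
    out$cell_type[r] <- tt
    out$assoc_p[r] <- best$p_bonferroni
    M <- ind$cells[ct == tt]
    O <- ind$cells[ind$X[ikey == paste(ga, gb), ]]
    cond_p <- vapply(c(ga, gb), function(g) {
      E <- mk$expr_sets(g, length(M))
      conditional_hypergeom_pvalue(
        u = length(ind$cells), m_size = length(M), e_size = length(E),
        o_size = length(O), gamma = length(intersect(M, E)),
        alpha_overlap = length(intersect(E, O)),
        lambda = length(intersect(M, O)))
    }, numeric(1))
    out$cond_p_a[r] <- cond_p[1]
    out$cond_p_b[r] <- cond_p[2]
    out$marker_a[r] <- ga %in% mk$markers[[tt]]
    out$marker_b[r] <- gb %in% mk$markers[[tt]]
    stringent <- all(cond_p < alpha) && !out$marker_a[r] && !out$marker_b[r]
    out$category[r] <- if (stringent) 2L else 1L
  }
  if (legacy_labels) {
    sw <- out$category
    out$category[sw == 1L] <- 2L
    out$category[sw == 2L] <- 1L
  }
  out
}

#' Fixed-radius neighbor graph over cell centroids
#'
#' @param meta cell metadata with `cell_id`, `centroid_x`, `centroid_y`.
#' @param radius neighborhood radius in micrometres (default 100).
#' @return object of class `neighbor_graph`: list with `cells`, `xy`,
#'   `neighbors` (list of integer index vectors, symmetric, no self-edges).
#' @export
build_neighbor_graph <- function(meta, radius = 100) {
  stopifnot(all(c("centroid_x", "centroid_y") %in% names(meta)))
  xy <- cbind(meta$centroid_x, meta$centroid_y)
  n <- nrow(xy)
  nb <- vector("list", n)
  if (n >= 2 && radius > 0) {
    cnt <- .pair_counts_cpp(xy[, 1], xy[, 2], seq_len(n), n, radius,
                            integer(0))
    if (length(cnt$pair_i)) {
      for (e in seq_along(cnt$pair_i)) {
        i <- cnt$pair_i[e]; j <- cnt$pair_j[e]
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  structure(list(cells = as.character(meta$cell_id), xy = xy,
                 neighbors = lapply(nb, function(v)
                   sort(unique(as.integer(v)))),
                 radius = radius),
            class = "neighbor_graph")
}

# Bernoulli log-likelihood under the neighborhood-weighted model
.spatial_loglik <- function(w, p_global, s, p_local, has_nb, eps = 1e-9) {
  q <- ifelse(has_nb, w * p_local + (1 - w) * p_global, p_global)
  q <- pmin(1 - eps, pmax(eps, q))
  sum(s * log(q) + (1 - s) * log(1 - q))
}

#' Spatial-modulation likelihood-ratio statistic for one indicator vector
#'
#' Tests whether the cells supporting a pair (binary `s`) are non-randomly
#' placed in the tissue. Null model: `s_c ~ Bernoulli(p_global)` with
#' `p_global = mean(s)` (its MLE). Alternative: `s_c ~ Bernoulli(w *
#' p_local_c + (1 - w) * p_global)` where `p_local_c` is the fraction of
#' `c`'s neighbors with `s = 1`; `w` and `p_global` are fitted by bounded
#' maximum likelihood (multistart L-BFGS-B). Cells without neighbors use
#' `p_global` in place of the local term. Returns `llr = l(H1) - l(H0) >= 0`.
#'
#' @param s binary vector, one entry per graph cell.
#' @param graph `neighbor_graph`.
#' @param eps probability clamp (default 1e-9).
#' @return list `llr, w, p_global, p_local` (class `spatial_model`).
#' @export
spatial_modulation_llr <- function(s, graph, eps = 1e-9) {
  s <- as.numeric(s)
  n <- length(s)
  stopifnot(n == length(graph$cells))
  if (all(s == s[1]))
    return(structure(list(llr = 0, w = 0, p_global = mean(s),
                          p_local = rep(mean(s), n)),
                     class = "spatial_model"))
  has_nb <- lengths(graph$neighbors) > 0
  p_local <- vapply(seq_len(n), function(i) {
    nb <- graph$neighbors[[i]]
    if (length(nb)) mean(s[nb]) else NA_real_
  }, numeric(1))
  p_local[!has_nb] <- 0  # unused (has_nb gates it)
  pg0 <- mean(s)
  ll0 <- .spatial_loglik(0, pg0, s, p_local, has_nb, eps)
  obj <- function(par) -.spatial_loglik(par[1], par[2], s, p_local, has_nb, eps)
  best <- NULL
  for (w0 in c(0.1, 0.9)) for (g0 in c(0.1, 0.9)) {
    fit <- tryCatch(
      optim(c(w0, g0), obj, method = "L-BFGS-B",
            lower = c(0, eps), upper = c(1, 1 - eps),
            control = list(factr = 1e3)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  # the null is nested (w = 0), so the fitted model can never do worse
  ll1 <- max(-best$value, ll0)
  structure(list(llr = ll1 - ll0, w = best$par[1], p_global = best$par[2],
                 p_local = p_local), class = "spatial_model")
}

#' Scan a d-colocalization map for spatially modulated pairs
#'
#' Computes the spatial-modulation LLR for every pair in `map`, then derives
#' a significance threshold by permutation: each pair's indicator vector is
#' permuted across cells `n_perm` times, the LLR recomputed, and the
#' threshold set to the highest LLR seen on any permuted vector (max over
#' pairs and permutations). Pairs with observed LLR above the threshold are
#' flagged.
#'
#' @param ind `pp_indicators`.
#' @param map `dcoloc_map` (or data.frame with `gene_a`, `gene_b`) of pairs
#'   to scan, typically the significant CPB pairs.
#' @param graph `neighbor_graph` over the same cells as `ind`.
#' @param n_perm permutations per pair (default 10).
#' @param seed RNG seed for the permutations.
#' @return list: `pairs` (data.frame `gene_a, gene_b, llr, w, p_global,
#'   flagged`), `threshold`, `n_perm`, `seed`.
#' @export
spatial_modulation_scan <- function(ind, map, graph, n_perm = 10L, seed = 1L) {
  stopifnot(identical(as.character(graph$cells), as.character(ind$cells)))
  ikey <- paste(ind$pairs$gene_a, ind$pairs$gene_b)
  mkey <- paste(map$gene_a, map$gene_b)
  rows <- match(mkey, ikey)
  if (anyNA(rows)) stop("map pair(s) absent from indicator object")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  llr <- w <- pg <- numeric(length(rows))
  thr <- 0
  for (q in seq_along(rows)) {
    s <- as.numeric(ind$X[rows[q], ])
    fit <- spatial_modulation_llr(s, graph)
    llr[q] <- fit$llr; w[q] <- fit$w; pg[q] <- fit$p_global
    for (r in seq_len(n_perm)) {
      sp <- sample(s)
      thr <- max(thr, spatial_modulation_llr(sp, graph)$llr)
    }
  }
  list(pairs = data.frame(gene_a = map$gene_a, gene_b = map$gene_b,
                          llr = llr, w = w, p_global = pg,
                          flagged = llr > thr, stringsAsFactors = FALSE),
       threshold = thr, n_perm = n_perm, seed = seed)
}
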