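#' Gene-by-gene colocalization matrix
#'
#' Symmetric matrix of `-log10(p + 1e-64)` from a d-colocalization map (the
#' pseudocount handles zero/floored p-values); diagonal 0. Input to
#' [gcc_cluster()].
#'
#' @param map `dcoloc_map` covering the pair universe of a gene panel.
#' @param genes optional gene order (default: sorted union of map genes).
#' @return numeric matrix with gene dimnames.
#' @export
coloc_matrix <- function(map, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(c(map$gene_a, map$gene_b)))
  n <- length(genes)
  M <- matrix(0, n, n, dimnames = list(genes, genes))
  ia <- match(map$gene_a, genes)
  ib <- match(map$gene_b, genes)
  v <- -log10(map$pvalue + 1e-64)
  M[cbind(ia, ib)] <- v
  M[cbind(ib, ia)] <- v
  M
}

#' Global Colocalization Clustering (GCC)
#'
#' Finds gene modules in a d-colocalization map: the `-log10` p-value matrix
#' is clustered hierarchically (Ward criterion on Euclidean row distances),
#' the dendrogram is cut into `n_clusters` flat clusters, and a cluster is
#' reported as a module when the fraction of its internal gene pairs that
#' are significant at `alpha` (its density) reaches `min_density`.
#'
#' @param map `dcoloc_map`.
#' @param n_clusters number of flat clusters to cut.
#' @param min_density minimum internal significant-pair density (default 0.7).
#' @param alpha CPB significance threshold defining "significant pair"
#'   (default 1e-3).
#' @return data.frame `module_id, genes, n_genes, density, region` (dominant
#'   primary region of internal significant pairs when the map is annotated,
#'   else `NA`); zero rows when nothing qualifies.
#' @export
gcc_cluster <- function(map, n_clusters = 6L, min_density = 0.7,
                        alpha = 1e-3) {
  M <- coloc_matrix(map)
  if (nrow(M) < 3) stop("GCC needs at least 3 genes")
  if (all(M == 0)) {
    return(data.frame(module_id = integer(0), genes = character(0),
                      n_genes = integer(0), density = numeric(0),
                      region = character(0)))
  }
  hc <- hclust(dist(M), method = "ward.D2")
  cl <- cutree(hc, k = min(n_clusters, nrow(M)))
  key <- paste(map$gene_a, map$gene_b)
  rows <- list()
  for (k in sort(unique(cl))) {
    genes <- names(cl)[cl == k]
    if (length(genes) < 2) next
    cmb <- combn(sort(genes), 2)
    pk <- paste(cmb[1, ], cmb[2, ])
    pv <- map$pvalue[match(pk, key)]
    pv[is.na(pv)] <- 1
    dens <- mean(pv < alpha)
    if (dens < min_density) next
    region <- NA_character_
    if ("primary_region" %in% names(map)) {
      pr <- map$primary_region[match(pk, key)][pv < alpha]
      pr <- pr[!is.na(pr)]
      if (length(pr)) region <- names(sort(table(pr), decreasing = TRUE))[1]
    }
    rows[[length(rows) + 1]] <- data.frame(
      module_id = length(rows) + 1L, genes = paste(sort(genes), collapse = ","),
      n_genes = length(genes), density = dens, region = region,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(module_id = integer(0), genes = character(0),
                      n_genes = integer(0), density = numeric(0),
                      region = character(0)))
  out <- do.call(rbind, rows)
  out[order(-out$n_genes, -out$density), ]
}

#' Per-cell colocalization graphs
#'
#' One graph per cell: nodes are genes, edges are the gene pairs whose PP
#' p-value in that cell is below `alpha` (the FSM edge threshold, typically
#' looser than the CPB indicator threshold).
#'
#' @param ind `pp_indicators` (its `results` slot holds per-cell p-values).
#' @param alpha per-cell edge threshold (default 0.05).
#' @return object of class `cell_graphs`: list with `genes`, `cells`,
#'   `edge_sets` (per cell, character vector of edge keys `"a|b"`,
#'   `a < b`) and `edge_cells` (edge key -> integer cell indices).
#' @export
cell_graphs <- function(ind, alpha = 0.05) {
  res <- ind$results
  if (is.null(res)) stop("indicator object carries no per-cell results")
  sig <- res[res$pvalue < alpha, , drop = FALSE]
  keys <- paste(sig$gene_a, sig$gene_b, sep = "|")
  cidx <- match(sig$cell_id, ind$cells)
  edge_sets <- rep(list(character(0)), length(ind$cells))
  sp <- split(keys, cidx)
  for (nm in names(sp)) edge_sets[[as.integer(nm)]] <- sort(sp[[nm]])
  edge_cells <- lapply(split(cidx, keys), function(v) sort(unique(v)))
  structure(list(genes = ind$genes, cells = ind$cells,
                 edge_sets = edge_sets, edge_cells = edge_cells,
                 alpha = alpha),
            class = "cell_graphs")
}

.edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# level-wise frequent gene-clique mining; exact by the Apriori join identity:
# clique(prefix+u+v) = clique(prefix+u) & clique(prefix+v) & edge(u, v)
.freq_cliques <- function(graphs, min_support, max_size = Inf) {
  ec <- graphs$edge_cells
  sup <- lengths(ec)
  keep <- names(ec)[sup >= min_support]
  levels <- list()
  if (!length(keep)) return(levels)
  cur <- lapply(keep, function(k) {
    g <- strsplit(k, "|", fixed = TRUE)[[1]]
    list(genes = sort(g), cells = ec[[k]])
  })
  levels[["2"]] <- cur
  k <- 2L
  while (length(cur) >= 2 && k < max_size) {
    sigs <- vapply(cur, function(e) paste(e$genes, collapse = "\r"),
                   character(1))
    ord <- order(sigs)
    cur <- cur[ord]; sigs <- sigs[ord]
    prefixes <- vapply(cur, function(e)
      paste(e$genes[-length(e$genes)], collapse = "\r"), character(1))
    nxt <- list()
    seen <- character(0)
    groups <- split(seq_along(cur), prefixes)
    for (grp in groups) {
      if (length(grp) < 2) next
      for (a in seq_len(length(grp) - 1)) for (b in (a + 1):length(grp)) {
        A <- cur[[grp[a]]]; B <- cur[[grp[b]]]
        u <- A$genes[length(A$genes)]; v <- B$genes[length(B$genes)]
        ek <- .edge_key(u, v)
        if (is.null(ec[[ek]])) next
        cells <- intersect(intersect(A$cells, B$cells), ec[[ek]])
        if (length(cells) < min_support) next
        genes <- sort(unique(c(A$genes, v)))
        sg <- paste(genes, collapse = "\r")
        if (sg %in% seen) next
        seen <- c(seen, sg)
        nxt[[length(nxt) + 1]] <- list(genes = genes, cells = cells)
      }
    }
    if (!length(nxt)) break
    k <- k + 1L
    levels[[as.character(k)]] <- nxt
    cur <- nxt
  }
  levels
}

# level-wise frequent edge-set mining (itemset semantics: a cell supports an
# edge set iff it contains every edge)
.freq_edgesets <- function(graphs, min_support, max_edges = 12L) {
  ec <- graphs$edge_cells
  keep <- names(ec)[lengths(ec) >= min_support]
  levels <- list()
  if (!length(keep)) return(levels)
  keep <- sort(keep)
  cur <- lapply(keep, function(k) list(items = k, cells = ec[[k]]))
  levels[["1"]] <- cur
  k <- 1L
  while (length(cur) >= 2 && k < max_edges) {
    prefixes <- vapply(cur, function(e)
      paste(e$items[-length(e$items)], collapse = "\r"), character(1))
    nxt <- list()
    groups <- split(seq_along(cur), prefixes)
    for (grp in groups) {
      if (length(grp) < 2) next
      for (a in seq_len(length(grp) - 1)) for (b in (a + 1):length(grp)) {
        A <- cur[[grp[a]]]; B <- cur[[grp[b]]]
        cells <- intersect(A$cells, B$cells)
        if (length(cells) < min_support) next
        items <- sort(unique(c(A$items, B$items)))
        nxt[[length(nxt) + 1]] <- list(items = items, cells = cells)
      }
    }
    if (!length(nxt)) break
    # dedupe (join can produce a set via several parents)
    sg <- vapply(nxt, function(e) paste(e$items, collapse = "\r"), character(1))
    nxt <- nxt[!duplicated(sg)]
    k <- k + 1L
    levels[[as.character(k)]] <- nxt
    cur <- nxt
  }
  levels
}

.edge_nodes <- function(keys) {
  unique(unlist(strsplit(keys, "|", fixed = TRUE)))
}

.edges_connected <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  nodes <- unique(unlist(parts))
  comp <- setNames(seq_along(nodes), nodes)
  for (p in parts) {
    ca <- comp[p[1]]; cb <- comp[p[2]]
    if (ca != cb) comp[comp == cb] <- ca
  }
  length(unique(comp)) == 1
}

#' Frequent subgraph mining over per-cell colocalization graphs
#'
#' Finds gene networks whose every edge is a proximal pair simultaneously in
#' many cells. Because each gene occurs at most once per graph, labeled
#' subgraph mining reduces exactly to frequent edge-set mining (Apriori,
#' level-wise with support pruning) with a connectivity constraint — or to
#' frequent clique mining when `clique_only = TRUE`. Support of a module is
#' the number of cells containing every one of its edges. Maximal frequent
#' results are reported, sorted by decreasing support.
#'
#' @param graphs `cell_graphs`.
#' @param min_nodes minimum genes per module (>= 2).
#' @param min_support minimum number of supporting cells (>= 1).
#' @param clique_only mine complete subgraphs only.
#' @param max_size expansion cap (genes for cliques, edges otherwise);
#'   guards against pathological dense inputs.
#' @return data.frame `genes, n_genes, n_edges, support, edges`
#'   (comma-joined); zero rows when nothing qualifies.
#' @export
fsm_mine <- function(graphs, min_nodes = 3L, min_support = 1L,
                     clique_only = FALSE, max_size = 12L) {
  stopifnot(min_nodes >= 2, min_support >= 1)
  empty <- data.frame(genes = character(0), n_genes = integer(0),
                      n_edges = integer(0), support = integer(0),
                      edges = character(0))
  if (min_support > length(graphs$cells)) return(empty)
  rows <- list()
  if (clique_only) {
    levels <- .freq_cliques(graphs, min_support, max_size)
    all_sets <- unlist(levels, recursive = FALSE)
    if (!length(all_sets)) return(empty)
    gsets <- lapply(all_sets, `[[`, "genes")
    keep <- lengths(gsets) >= min_nodes
    all_sets <- all_sets[keep]; gsets <- gsets[keep]
    if (!length(all_sets)) return(empty)
    maximal <- .maximal_sets(gsets)
    for (i in which(maximal)) {
      g <- gsets[[i]]
      cmb <- combn(g, 2)
      rows[[length(rows) + 1]] <- data.frame(
        genes = paste(g, collapse = ","), n_genes = length(g),
        n_edges = ncol(cmb), support = length(all_sets[[i]]$cells),
        edges = paste(.edge_key(cmb[1, ], cmb[2, ]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  } else {
    levels <- .freq_edgesets(graphs, min_support, max_size)
    all_sets <- unlist(levels, recursive = FALSE)
    if (!length(all_sets)) return(empty)
    esets <- lapply(all_sets, `[[`, "items")
    ok <- vapply(esets, function(e)
      length(.edge_nodes(e)) >= min_nodes && .edges_connected(e), logical(1))
    all_sets <- all_sets[ok]; esets <- esets[ok]
    if (!length(all_sets)) return(empty)
    maximal <- .maximal_sets(esets)
    for (i in which(maximal)) {
      e <- esets[[i]]
      nodes <- sort(.edge_nodes(e))
      rows[[length(rows) + 1]] <- data.frame(
        genes = paste(nodes, collapse = ","), n_genes = length(nodes),
        n_edges = length(e), support = length(all_sets[[i]]$cells),
        edges = paste(e, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, -out$n_genes, out$genes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE for sets not strictly contained in any other listed set
.maximal_sets <- function(sets) {
  n <- length(sets)
  maximal <- rep(TRUE, n)
  sizes <- lengths(sets)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sizes[j] > sizes[i] && all(sets[[i]] %in% sets[[j]])) {
        maximal[i] <- FALSE
        break
      }
    }
  }
  maximal
}

#' Support histogram of all k-gene cliques
#'
#' For every k-gene subset forming a complete colocalization subgraph in at
#' least one cell, the number of supporting cells.
#'
#' @param graphs `cell_graphs`.
#' @param k clique size (>= 2).
#' @return data.frame `genes, support`, sorted by decreasing support; zero
#'   rows when no k-clique occurs.
#' @export
support_histogram <- function(graphs, k = 4L) {
  stopifnot(k >= 2)
  levels <- .freq_cliques(graphs, min_support = 1L, max_size = k)
  lev <- levels[[as.character(k)]]
  if (is.null(lev))
    return(data.frame(genes = character(0), support = integer(0)))
  out <- data.frame(
    genes = vapply(lev, function(e) paste(e$genes, collapse = ","),
                   character(1)),
    support = vapply(lev, function(e) length(e$cells), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$genes), ]
  rownames(out) <- NULL
  out
}
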