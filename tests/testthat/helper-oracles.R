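# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational paths.

# Poisson-Binomial survival by exhaustive enumeration over all 2^m outcomes
oracle_pb_sf <- function(probs, k) {
  m <- length(probs)
  if (k <= 0) return(1)
  if (k > m) return(0)
  masks <- 0:(2^m - 1)
  bits <- vapply(masks, function(mm) as.integer(intToBits(mm))[1:m],
                 integer(m))
  bits <- matrix(bits, nrow = m)
  pr <- apply(bits, 2, function(b) prod(ifelse(b == 1, probs, 1 - probs)))
  sum(pr[colSums(bits) >= k])  # sum() accumulates in long double
}

# all-pairs K/T oracle for one cell, straight from the definitions
oracle_pair_counts <- function(x, y, gene, d) {
  n <- length(x)
  n_prox <- 0
  K <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= d) {
      n_prox <- n_prox + 1
      if (gene[i] != gene[j]) {
        key <- paste(sort(c(gene[i], gene[j])), collapse = " ")
        K[[key]] <- (K[[key]] %||% 0) + 1
      }
    }
  }
  list(n_prox = n_prox, K = K)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# conditional hypergeometric tail by exhaustive enumeration: concrete sets
# with the given intersection sizes, all O' of size o with |O' n E| = alpha
oracle_cond_hyper <- function(u, m, e, o, gamma, alpha, lambda) {
  stopifnot(u <= 14)
  M <- seq_len(m)
  E <- c(seq_len(gamma), if (e > gamma) (m + 1):(m + e - gamma))
  all_o <- combn(u, o)
  hits <- total <- 0
  for (col in seq_len(ncol(all_o))) {
    Op <- all_o[, col]
    if (length(intersect(Op, E)) != alpha) next
    total <- total + 1
    if (length(intersect(Op, M)) >= lambda) hits <- hits + 1
  }
  if (total == 0) return(NA_real_)
  hits / total
}

# dense two-stage grid-search oracle for the spatial-modulation MLE
oracle_grid_llr <- function(s, meta, radius, n_grid = 200, eps = 1e-9) {
  s <- as.numeric(s)
  n <- length(s)
  D <- as.matrix(dist(cbind(meta$centroid_x, meta$centroid_y)))
  adj <- D <= radius & upper.tri(D) | D <= radius & lower.tri(D)
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  pl <- ifelse(deg > 0, as.numeric(adj %*% s) / pmax(deg, 1), 0)
  has_nb <- deg > 0
  ll_at <- function(w, pg_vec) {
    # cells with neighbors
    q <- outer(pg_vec * (1 - w), rep(1, sum(has_nb))) +
      matrix(w * pl[has_nb], length(pg_vec), sum(has_nb), byrow = TRUE)
    q <- pmin(pmax(q, eps), 1 - eps)  # matrix first: pmin/pmax keep dims
    ll <- log(q) %*% s[has_nb] + log(1 - q) %*% (1 - s[has_nb])
    # neighborless cells depend on pg only
    pgc <- pmin(1 - eps, pmax(eps, pg_vec))
    ll + log(pgc) * sum(s[!has_nb]) + log(1 - pgc) * sum(1 - s[!has_nb])
  }
  search <- function(w_lo, w_hi, g_lo, g_hi) {
    ws <- seq(w_lo, w_hi, length.out = n_grid)
    gs <- seq(g_lo, g_hi, length.out = n_grid)
    best <- c(-Inf, NA, NA)
    for (w in ws) {
      ll <- ll_at(w, gs)
      i <- which.max(ll)
      if (ll[i] > best[1]) best <- c(ll[i], w, gs[i])
    }
    best
  }
  b1 <- search(0, 1, eps, 1 - eps)
  dw <- 1 / (n_grid - 1)
  b2 <- search(max(0, b1[2] - dw), min(1, b1[2] + dw),
               max(eps, b1[3] - dw), min(1 - eps, b1[3] + dw))
  dw2 <- 2 * dw / (n_grid - 1)
  b3 <- search(max(0, b2[2] - dw2), min(1, b2[2] + dw2),
               max(eps, b2[3] - dw2), min(1 - eps, b2[3] + dw2))
  pg0 <- min(1 - eps, max(eps, mean(s)))
  ll0 <- sum(s * log(pg0) + (1 - s) * log(1 - pg0))
  max(b3[1], b2[1], b1[1], ll0) - ll0
}

# clique support oracle: candidate gene sets from the union graph (igraph),
# support counted directly against per-cell edge sets
oracle_clique_supports <- function(graphs, min_size, max_size) {
  all_edges <- names(graphs$edge_cells)
  parts <- do.call(rbind, strsplit(all_edges, "|", fixed = TRUE))
  g <- igraph::graph_from_edgelist(parts, directed = FALSE)
  cl <- igraph::cliques(g, min = min_size, max = max_size)
  res <- list()
  for (cc in cl) {
    genes <- sort(names(cc))
    need <- apply(combn(genes, 2), 2, paste, collapse = "|")
    sup <- sum(vapply(graphs$edge_sets, function(es) all(need %in% es),
                      logical(1)))
    if (sup > 0)
      res[[paste(genes, collapse = ",")]] <- sup
  }
  res
}

# a tiny deterministic cell: n uniform transcripts, random gene labels
random_cell <- function(n, n_genes, r = 10, genes = sprintf("g%02d", 1:n_genes)) {
  rr <- r * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  data.frame(cell = "c1", gene = sample(genes, n, replace = TRUE),
             x = rr * cos(th), y = rr * sin(th), z = 0L,
             stringsAsFactors = FALSE)
}
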