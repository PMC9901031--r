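#' Exact Poisson-Binomial survival function
#'
#' `P(S >= k)` for `S` a sum of independent Bernoulli variables with success
#' probabilities `probs`, computed by exact dynamic-programming convolution
#' (no normal/Poisson approximation). Monotone non-increasing in `k`.
#'
#' @param probs vector of success probabilities in `[0, 1]`.
#' @param k non-negative integer.
#' @return probability; 0 when `k > length(probs)`.
#' @export
poisson_binomial_sf <- function(probs, k) {
  stopifnot(k >= 0, all(probs >= 0), all(probs <= 1))
  m <- length(probs)
  if (k == 0) return(1)
  if (k > m) return(0)
  dp <- c(1, numeric(m))  # dp[j+1] = P(S = j) after processing i terms
  for (p in probs) {
    dp <- dp * (1 - p) + c(0, dp[-(m + 1)]) * p
  }
  # tail summed smallest-first to limit cancellation
  sum(rev(dp[(k + 1):(m + 1)]))
}

.P_FLOOR <- 1e-300  # smallest reportable p-value

# pairs x cells matrix of "both genes expressed" indicators
.coexpr_matrix <- function(ind) {
  ia <- match(ind$pairs$gene_a, ind$genes)
  ib <- match(ind$pairs$gene_b, ind$genes)
  ind$E[ia, , drop = FALSE] & ind$E[ib, , drop = FALSE]
}

#' Unconditional Poisson-Binomial (UPB) aggregation test
#'
#' Aggregates per-cell proximal-pair indicators into a per-pair p-value. Each
#' cell contributes a shared Bernoulli parameter `p_0^c = N_c / (number of
#' expressed pairs in c)` — the fraction of the cell's expressed gene pairs
#' that were significant proximal pairs. For a pair, the p-value is the
#' Poisson-Binomial upper tail over the cells where both its genes are
#' expressed, evaluated at the pair's support.
#'
#' @param ind `pp_indicators` from [pp_test_dataset()].
#' @return data.frame `gene_a, gene_b, support, n_coexpressed_cells, pvalue`.
#' @export
upb_test <- function(ind) {
  co <- .coexpr_matrix(ind)
  n_expr_pairs <- colSums(co)
  p0 <- ifelse(n_expr_pairs > 0, ind$N_c / n_expr_pairs, 0)
  .pb_aggregate(ind, co, function(pair_row, cells_idx) p0[cells_idx])
}

#' Conditional Poisson-Binomial (CPB) aggregation test
#'
#' Like [upb_test()] but with gene-pair-dependent per-cell success
#' probabilities that de-emphasize pairs of promiscuously proximal genes.
#' With `z_i` the total number of proximal-pair events involving gene `i`
#' across all cells, the prior that a detected proximal pair is (i, j) is
#' `Pi_ij = z_i z_j / sum_{i<j} z_i z_j`, and cell `c` with `N_c` significant
#' pairs contributes `p_ij^c = 1 - (1 - Pi_ij)^{N_c}`. Cells where either
#' gene is unexpressed contribute neither to the support nor to the
#' convolution. P-values are floored at 1e-300.
#'
#' @param ind `pp_indicators`.
#' @return `dcoloc_map` data.frame: `gene_a, gene_b, support,
#'   n_coexpressed_cells, pvalue` (region annotation added by
#'   [annotate_map()]).
#' @export
cpb_test <- function(ind) {
  co <- .coexpr_matrix(ind)
  ia <- match(ind$pairs$gene_a, ind$genes)
  ib <- match(ind$pairs$gene_b, ind$genes)
  # z_i: proximal-pair events involving gene i, over all pairs and cells
  ev <- rowSums(ind$X)
  z <- numeric(length(ind$genes))
  for (g in seq_along(ind$genes))
    z[g] <- sum(ev[ia == g | ib == g])
  denom <- sum(z[ia] * z[ib])
  if (denom == 0) {
    warning("no proximal-pair events anywhere; all CPB p-values are 1")
    Pi <- numeric(nrow(ind$pairs))
  } else {
    Pi <- z[ia] * z[ib] / denom
  }
  N_c <- ind$N_c
  .pb_aggregate(ind, co, function(pr, cells_idx)
    1 - (1 - Pi[pr])^N_c[cells_idx])
}

# shared aggregation loop for UPB/CPB
.pb_aggregate <- function(ind, co, prob_fun) {
  np <- nrow(ind$pairs)
  support <- rowSums(ind$X & co)  # support only counts co-expressed cells
  ncoexp <- rowSums(co)
  pv <- numeric(np)
  for (pr in seq_len(np)) {
    cells_idx <- which(co[pr, ])
    if (!length(cells_idx)) { pv[pr] <- 1; next }
    probs <- pmin(prob_fun(pr, cells_idx), 1 - 1e-12)
    pv[pr] <- poisson_binomial_sf(probs, support[pr])
  }
  out <- data.frame(gene_a = ind$pairs$gene_a, gene_b = ind$pairs$gene_b,
                    support = support, n_coexpressed_cells = ncoexp,
                    pvalue = pmax(pv, .P_FLOOR),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, -out$support, out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  class(out) <- c("dcoloc_map", "data.frame")
  out
}

#' Annotate a d-colocalization map with subcellular regions
#'
#' Sums each pair's proximal-pair region tallies over all cells and reports
#' the primary (argmax) and secondary regions. Ties are broken by the fixed
#' region priority Nuc > PN > Cyt > CP (and reported via `message()`). Pairs
#' with no proximal pair anywhere stay unassigned (`NA`).
#'
#' @param map `dcoloc_map` from [cpb_test()]/[upb_test()].
#' @param ind `pp_indicators` whose `results` carry region tallies
#'   (requires [assign_regions()] before the PP run).
#' @return `map` with `primary_region` and `secondary_region` columns.
#' @export
annotate_map <- function(map, ind) {
  res <- ind$results
  if (is.null(res) || !all(.REGIONS %in% names(res)))
    stop("indicators carry no region tallies; run assign_regions() first")
  key <- paste(res$gene_a, res$gene_b)
  tal <- rowsum(as.matrix(res[.REGIONS]), key)
  mkey <- paste(map$gene_a, map$gene_b)
  map$primary_region <- NA_character_
  map$secondary_region <- NA_character_
  hit <- match(mkey, rownames(tal))
  n_tied <- 0L
  for (r in which(!is.na(hit))) {
    v <- tal[hit[r], ]
    if (sum(v) == 0) next
    # order() is stable: region priority order breaks ties
    o <- order(-v)
    if (sum(v == max(v)) > 1) n_tied <- n_tied + 1L
    map$primary_region[r] <- .REGIONS[o[1]]
    if (v[o[2]] > 0) map$secondary_region[r] <- .REGIONS[o[2]]
  }
  if (n_tied > 0)
    message("annotate_map: ", n_tied, " pair(s) had tied region tallies; ",
            "priority order Nuc>PN>Cyt>CP applied")
  map
}

#' Permutation-based false positive rate
#'
#' Compares detection counts on real data with counts on a gene-label-
#' permuted baseline computed with identical parameters:
#' `FPR = detections(permuted) / detections(real)` at each p-value threshold.
#'
#' @param real,permuted `dcoloc_map` objects over the same gene panel.
#' @param thresholds p-value thresholds.
#' @return data.frame `threshold, n_real, n_permuted, fpr` (`fpr` is `NA`
#'   when the real map has no detections at that threshold).
#' @export
estimate_fpr <- function(real, permuted, thresholds = c(1e-2, 1e-3, 1e-5)) {
  if (!setequal(unique(c(real$gene_a, real$gene_b)),
                unique(c(permuted$gene_a, permuted$gene_b))))
    stop("real and permuted maps cover different gene panels")
  n_real <- vapply(thresholds, function(t) sum(real$pvalue < t), numeric(1))
  n_perm <- vapply(thresholds, function(t) sum(permuted$pvalue < t), numeric(1))
  data.frame(threshold = thresholds, n_real = n_real, n_permuted = n_perm,
             fpr = ifelse(n_real > 0, n_perm / n_real, NA_real_))
}

#' Blank-probe false-positive diagnostics
#'
#' Blank probes target no real RNA, so any significant pair involving one is
#' a false positive. Reports the observed fraction of significant pairs
#' involving at least one blank, and the fraction expected if significant
#' pairs were drawn at random from the panel:
#' `expected = 1 - C(n - b, 2) / C(n, 2)` for `n` genes of which `b` blank.
#'
#' @param map `dcoloc_map`.
#' @param blank_genes character vector of blank probe names.
#' @param threshold significance threshold on `pvalue`.
#' @return list `observed` (NA when no significant pairs), `expected`,
#'   `n_significant`.
#' @export
blank_probe_fpr <- function(map, blank_genes, threshold = 1e-3) {
  n <- length(unique(c(map$gene_a, map$gene_b)))
  b <- length(blank_genes)
  expected <- 1 - choose(n - b, 2) / choose(n, 2)
  sig <- map[map$pvalue < threshold, , drop = FALSE]
  observed <- if (nrow(sig) == 0) NA_real_ else
    mean(sig$gene_a %in% blank_genes | sig$gene_b %in% blank_genes)
  list(observed = observed, expected = expected, n_significant = nrow(sig))
}

#' Top gene pairs by whole-cell co-expression
#'
#' The classical (non-spatial) counterpart of a d-colocalization map: Pearson
#' correlation of per-cell transcript counts (summed over z-planes), ranked.
#' Useful to show which colocalized pairs are invisible to co-expression.
#'
#' @param table transcript table (>= 3 cells).
#' @param top_k number of pairs to return.
#' @return data.frame `gene_a, gene_b, r`, sorted by decreasing correlation.
#' @export
coexpression_map <- function(table, top_k = 100L) {
  counts <- table(table$gene, table$cell)
  if (ncol(counts) < 3) stop("co-expression needs at least 3 cells")
  m <- t(unclass(counts))  # cells x genes
  keep <- apply(m, 2, sd) > 0
  if (any(!keep))
    warning(sum(!keep), " zero-variance gene(s) excluded from co-expression")
  m <- m[, keep, drop = FALSE]
  r <- cor(m)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(gene_a = colnames(m)[ut[, 1]],
                    gene_b = colnames(m)[ut[, 2]],
                    r = r[ut], stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$gene_a, out$gene_b), ]
  head(out, top_k)
}

#' Hypergeometric overlap of two pair sets
#'
#' Upper-tail hypergeometric p-value for the overlap of set A (e.g.
#' d-colocalized pairs) with set B (e.g. functionally related pairs) in a
#' universe of `universe_size` gene pairs.
#'
#' @param setA,setB character vectors of pair keys (e.g. `"g1|g2"`, any
#'   consistent encoding).
#' @param universe_size number of possible pairs, usually `choose(n, 2)`.
#' @return p-value `P(X >= |A intersect B|)`.
#' @export
overlap_enrichment <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  ov <- length(intersect(setA, setB))
  if (ov > min(length(setA), length(setB)))
    stop("overlap exceeds the smaller set")  # unreachable via set algebra
  if (length(setA) > universe_size || length(setB) > universe_size)
    stop("set larger than the universe")
  phyper(ov - 1, length(setA), universe_size - length(setA), length(setB),
         lower.tail = FALSE)
}

#' Gene-centric RNA-RNA interaction enrichment
#'
#' For each gene, asks whether its top `top_k` d-colocalization partners have
#' unusually high precomputed RNA-RNA interaction (RRI) scores. The
#' background is a Gaussian fitted to the RRI scores of the gene's
#' non-colocalized pairs (CPB p-value > `background_p_cutoff`); the Gaussian
#' upper-tail probability beyond `score_threshold` is the success probability
#' of an exact binomial test on the number of top-`top_k` partners exceeding
#' the threshold. Benjamini-Hochberg q-values are computed across genes.
#'
#' @param map `dcoloc_map`.
#' @param rri_scores data.frame `gene_a, gene_b, score`.
#' @param score_threshold RRI score counted as "high" (default 35).
#' @param top_k number of top partners tested per gene (default 10).
#' @param background_p_cutoff CPB p-value above which a pair is background
#'   (default 0.01).
#' @param fdr q-value threshold used for the `significant` flag (default 0.2).
#' @return data.frame `gene, n_high, success_prob, pvalue, qvalue,
#'   significant`; genes with fewer than 3 background pairs or degenerate
#'   (zero-variance) backgrounds are skipped with a warning.
#' @export
rri_enrichment <- function(map, rri_scores, score_threshold = 35,
                           top_k = 10L, background_p_cutoff = 0.01,
                           fdr = 0.2) {
  skey <- paste(pmin(rri_scores$gene_a, rri_scores$gene_b),
                pmax(rri_scores$gene_a, rri_scores$gene_b))
  mkey <- paste(pmin(map$gene_a, map$gene_b), pmax(map$gene_a, map$gene_b))
  score <- rri_scores$score[match(mkey, skey)]
  if (anyNA(score)) stop("rri_scores do not cover all map pairs")
  genes <- sort(unique(c(map$gene_a, map$gene_b)))
  rows <- list()
  skipped <- character(0)
  for (g in genes) {
    sel <- map$gene_a == g | map$gene_b == g
    sub <- map[sel, , drop = FALSE]
    ssc <- score[sel]
    bg <- ssc[sub$pvalue > background_p_cutoff]
    if (length(bg) < 3 || sd(bg) == 0) { skipped <- c(skipped, g); next }
    succ <- pnorm(score_threshold, mean(bg), sd(bg), lower.tail = FALSE)
    o <- order(sub$pvalue, -sub$support)
    top <- head(ssc[o], top_k)
    n_high <- sum(top > score_threshold)
    pv <- pbinom(n_high - 1, length(top), succ, lower.tail = FALSE)
    rows[[g]] <- data.frame(gene = g, n_high = n_high, success_prob = succ,
                            pvalue = pv, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped gene(s) with degenerate RRI background: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(out)) return(out)
  out$qvalue <- p.adjust(out$pvalue, "BH")
  out$significant <- out$qvalue <= fdr
  out
}

#' @importFrom stats pnorm
NULL
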