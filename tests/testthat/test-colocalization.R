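# small helper: build a pp_indicators object directly from an X matrix
make_ind <- function(X, genes, E = NULL) {
  cells <- colnames(X) %||% sprintf("c%d", seq_len(ncol(X)))
  cmb <- combn(length(genes), 2)
  pairs <- data.frame(gene_a = genes[cmb[1, ]], gene_b = genes[cmb[2, ]],
                      stringsAsFactors = FALSE)
  stopifnot(nrow(pairs) == nrow(X))
  rownames(X) <- paste(pairs$gene_a, pairs$gene_b)
  colnames(X) <- cells
  if (is.null(E)) E <- matrix(TRUE, length(genes), ncol(X),
                              dimnames = list(genes, cells))
  structure(list(genes = genes, cells = cells, pairs = pairs,
                 X = X, E = E, N_c = colSums(X), results = NULL,
                 params = list(alpha_pp = 0.01)),
            class = "pp_indicators")
}

test_that("Poisson-Binomial survival matches exhaustive enumeration", {
  expect_equal(poisson_binomial_sf(c(0.1, 0.2, 0.3), 2), 0.098)
  expect_equal(poisson_binomial_sf(c(0.1, 0.2, 0.3), 0), 1)
  expect_equal(poisson_binomial_sf(c(0.1, 0.2), 3), 0)
  set.seed(101)
  worst <- 0
  for (rep in 1:20) {
    m <- sample(2:15, 1)
    probs <- runif(m)
    k <- sample(0:m, 1)
    worst <- max(worst, abs(poisson_binomial_sf(probs, k) -
                              oracle_pb_sf(probs, k)))
  }
  expect_lt(worst, 1e-12)
  # equal probabilities reduce to the binomial survival function
  expect_equal(poisson_binomial_sf(rep(0.37, 12), 5),
               pbinom(4, 12, 0.37, lower.tail = FALSE))
  # monotone non-increasing in k
  ps <- runif(6)
  pv <- vapply(0:6, function(k) poisson_binomial_sf(ps, k), numeric(1))
  expect_true(all(diff(pv) <= 0))
})

test_that("UPB uses the expressed-pair fraction per cell", {
  # one cell, 4 expressed genes (6 pairs), 2 significant: p_0^c = 1/3
  genes <- c("A", "B", "C", "D")
  X <- matrix(FALSE, 6, 3)
  X[1, 1] <- X[2, 1] <- TRUE        # cell 1: pairs AB, AC significant
  ind <- make_ind(X, genes)
  res <- upb_test(ind)
  ab <- res[res$gene_a == "A" & res$gene_b == "B", ]
  # support 1 over three cells with p_0 = (1/3, 0, 0)
  expect_equal(ab$pvalue, 1 / 3)
  expect_equal(res$pvalue[res$support == 0], rep(1, sum(res$support == 0)))
  # 5 genes -> 10 pairs; per-cell p_0 = (0.1, 0.2, 0.3) by construction
  X3 <- matrix(FALSE, 10, 3)
  X3[1, 1] <- TRUE                  # cell1: 1/10
  X3[1:2, 2] <- TRUE                # cell2: 2/10
  X3[1:3, 3] <- TRUE                # cell3: 3/10
  ind3 <- make_ind(X3, c("A", "B", "C", "D", "E"))
  ab3 <- upb_test(ind3)
  expect_equal(ab3$pvalue[ab3$gene_a == "A" & ab3$gene_b == "B"],
               oracle_pb_sf(c(0.1, 0.2, 0.3), 3))
})

test_that("CPB prior and per-cell probabilities follow the closed forms", {
  # z = (A:2, B:1, C:1) -> Pi_AB = 2/(2+2+1) = 0.4
  genes <- c("A", "B", "C")
  X <- matrix(FALSE, 3, 2, dimnames = list(NULL, c("c1", "c2")))
  X[1, 1] <- TRUE   # AB in cell 1
  X[2, 2] <- TRUE   # AC in cell 2
  ind <- make_ind(X, genes)
  # z_A = 2, z_B = 1, z_C = 1; denom = z_A z_B + z_A z_C + z_B z_C = 5
  # N_c = (1, 1); p_AB^c = 1 - 0.6^1 = 0.4 in both cells
  res <- cpb_test(ind)
  ab <- res[res$gene_a == "A" & res$gene_b == "B", ]
  expect_equal(ab$pvalue, oracle_pb_sf(c(0.4, 0.4), 1))
  # closed form for the Bernoulli parameter: 1 - (1 - 0.4)^3 = 0.784
  expect_equal(1 - (1 - 0.4)^3, 0.784)
  # a pair of never-proximal genes (z z = 0) gets p-value 1
  X2 <- matrix(FALSE, 3, 2)
  X2[1, ] <- TRUE   # only AB ever fires: z_C = 0
  res2 <- cpb_test(make_ind(X2, genes))
  expect_equal(res2$pvalue[res2$gene_a == "B" & res2$gene_b == "C"], 1)
  # all-zero indicators warn and give all-ones
  expect_warning(res3 <- cpb_test(make_ind(matrix(FALSE, 3, 2), genes)),
                 "no proximal-pair events")
  expect_true(all(res3$pvalue == 1))
})

test_that("cells lacking expression are excluded from support and convolution", {
  genes <- c("A", "B", "C")
  X <- matrix(FALSE, 3, 4)
  X[1, 1:2] <- TRUE        # AB fires in cells 1, 2
  X[2, 1] <- TRUE          # AC fires in cell 1
  E <- matrix(TRUE, 3, 4, dimnames = list(genes, NULL))
  E[2, 3:4] <- FALSE       # B unexpressed in cells 3-4
  ind <- make_ind(X, genes, E)
  res <- cpb_test(ind)
  ab <- res[res$gene_a == "A" & res$gene_b == "B", ]
  expect_equal(ab$n_coexpressed_cells, 2)
  expect_equal(ab$support, 2)
  # z = (A:3, B:2, C:1), denom = 3*2 + 3*1 + 2*1 = 11, Pi_AB = 6/11;
  # N_c = (2, 1, 0, 0); convolution over the two co-expressed cells only
  probs <- 1 - (1 - 6 / 11)^c(2, 1)
  expect_equal(ab$pvalue, oracle_pb_sf(probs, 2))
})

test_that("CPB ranking matches UPB when all genes are exchangeable", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:8)
  X <- matrix(runif(28 * 60) < 0.1, 28, 60)
  ind <- make_ind(X, genes)
  cp <- cpb_test(ind)
  up <- upb_test(ind)
  key <- function(m) paste(m$gene_a, m$gene_b)
  # exchangeable simulation: orderings agree strongly (not exactly: the
  # empirical z_i vary by sampling noise)
  r <- cor(rank(cp$pvalue[order(key(cp))]), rank(up$pvalue[order(key(up))]),
           method = "spearman")
  expect_gt(r, 0.95)
})

test_that("adding a supporting cell never increases the CPB p-value", {
  set.seed(13)
  genes <- sprintf("g%02d", 1:6)
  X <- matrix(runif(15 * 30) < 0.15, 15, 30)
  X[1, 1] <- FALSE
  base <- cpb_test(make_ind(X, genes))
  X2 <- X; X2[1, 1] <- TRUE
  more <- cpb_test(make_ind(X2, genes))
  key <- function(m) paste(m$gene_a, m$gene_b)
  pair1 <- paste(genes[1], genes[2])
  expect_lte(more$pvalue[key(more) == pair1],
             base$pvalue[key(base) == pair1])
})

test_that("region annotation aggregates tallies with the fixed tie order", {
  res <- data.frame(cell_id = c("c1", "c2", "c1"),
                    gene_a = c("A", "A", "A"), gene_b = c("B", "B", "C"),
                    Nuc = c(6, 4, 0), PN = c(2, 1, 0), Cyt = 0,
                    CP = c(0, 0, 0))
  ind <- make_ind(matrix(FALSE, 3, 2), c("A", "B", "C"))
  ind$results <- res
  map <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                    pvalue = c(1e-5, 1e-4, 0.5), support = c(2, 1, 0))
  ann <- annotate_map(map, ind)
  expect_equal(ann$primary_region, c("Nuc", NA, NA))
  expect_equal(ann$secondary_region, c("PN", NA, NA))
  # tie broken by priority Nuc > PN > Cyt > CP, and reported
  ind$results$Nuc <- c(5, 0, 0); ind$results$PN <- c(2, 3, 0)
  expect_message(ann2 <- annotate_map(map, ind), "tie")
  expect_equal(ann2$primary_region[1], "Nuc")
})

test_that("permutation FPR is the detection-count ratio", {
  real <- data.frame(gene_a = "A", gene_b = letters[2:11],
                     pvalue = c(rep(1e-6, 10)))
  perm <- data.frame(gene_a = "A", gene_b = letters[2:11],
                     pvalue = c(1e-6, rep(0.5, 9)))
  fpr <- estimate_fpr(real, perm, thresholds = 1e-3)
  expect_equal(fpr$fpr, 0.1)
  expect_equal(fpr$n_real, 10)
  perm0 <- transform(perm, pvalue = 0.5)
  expect_equal(estimate_fpr(real, perm0, 1e-3)$fpr, 0)
  none <- transform(real, pvalue = 0.5)
  expect_true(is.na(estimate_fpr(none, perm, 1e-3)$fpr))
  expect_error(estimate_fpr(real, transform(perm, gene_b = LETTERS[2:11]),
                            1e-3), "panel")
})

test_that("blank-probe false-positive fractions use the closed form", {
  map <- data.frame(gene_a = c("g1", "g2", "Blank-1"),
                    gene_b = c("g2", "g3", "g3"),
                    pvalue = c(1e-9, 1e-9, 1e-9))
  # small panel: expected fraction from the combinatorial identity
  bp <- blank_probe_fpr(map, "Blank-1", threshold = 1e-3)
  n <- 4; b <- 1
  expect_equal(bp$expected, 1 - choose(n - b, 2) / choose(n, 2))
  expect_equal(bp$observed, 1 / 3)
  # the published-panel scale check: n = 140 genes, b = 10 blanks
  expect_equal(1 - choose(130, 2) / choose(140, 2),
               blank_probe_fpr(data.frame(gene_a = sprintf("x%03d", 1:139),
                                          gene_b = sprintf("x%03d", 2:140),
                                          pvalue = 1),
                               sprintf("x%03d", 131:140))$expected)
  map_none <- transform(map, pvalue = 1)
  expect_true(is.na(blank_probe_fpr(map_none, "Blank-1")$observed))
  map_clean <- map[1:2, ]
  expect_equal(blank_probe_fpr(map_clean, "Blank-1", 1e-3)$observed, 0)
})

test_that("co-expression map ranks correlated genes first", {
  set.seed(3)
  cells <- sprintf("c%d", 1:30)
  tab <- do.call(rbind, lapply(cells, function(cc) {
    n1 <- rpois(1, 20)
    data.frame(cell = cc,
               gene = c(rep("A", n1), rep("B", n1),
                        rep("C", rpois(1, 20)), rep("D", rpois(1, 20))),
               x = 0, y = 0)
  }))
  top <- coexpression_map(as_transcript_table(tab), top_k = 2)
  expect_equal(top$gene_a[1], "A")
  expect_equal(top$gene_b[1], "B")
  expect_equal(top$r[1], 1)
  expect_equal(nrow(coexpression_map(as_transcript_table(tab), 0)), 0)
  expect_error(coexpression_map(as_transcript_table(tab[tab$cell %in%
    cells[1:2], ])), "3 cells")
})

test_that("pair-set overlap enrichment equals the hypergeometric tail", {
  U <- 12
  A <- sprintf("p%02d", 1:3)
  B <- sprintf("p%02d", 2:5)
  p <- overlap_enrichment(A, B, U)
  # enumeration oracle: distribution of |A ∩ B'| over random B' of size |B|
  ov <- length(intersect(A, B))
  cnt <- 0
  allB <- combn(U, length(B))
  for (col in seq_len(ncol(allB)))
    if (length(intersect(allB[, col], 1:3)) >= ov) cnt <- cnt + 1
  expect_equal(p, cnt / ncol(allB))
  expect_equal(overlap_enrichment(A, sprintf("q%02d", 1:5), U), 1)  # disjoint
  # identical sets: only the all-overlap outcome counts
  expect_equal(overlap_enrichment(A, A, 100), 1 / choose(100, 3))
})

test_that("RRI enrichment computes gene-centric binomial tails", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:16)
  cmb <- combn(genes, 2)
  map <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                    support = 0L, pvalue = runif(ncol(cmb), 0.2, 1))
  # make g01's top-10 partners colocalized with high RRI scores
  sel <- which(map$gene_a == "g01" | map$gene_b == "g01")
  map$pvalue[sel[1:10]] <- 1e-8
  scores <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                       score = rnorm(ncol(cmb), 20, 5))
  skey <- paste(scores$gene_a, scores$gene_b)
  hot <- paste(map$gene_a, map$gene_b)[sel[1:10]]
  scores$score[match(hot, skey)] <- 60
  res <- rri_enrichment(map, scores, score_threshold = 35, top_k = 10)
  g1 <- res[res$gene == "g01", ]
  expect_equal(g1$n_high, 10)
  expect_lt(g1$pvalue, 1e-6)
  expect_true(g1$significant)
  # p-value equals the exact binomial tail at the fitted success probability
  expect_equal(g1$pvalue,
               pbinom(9, 10, g1$success_prob, lower.tail = FALSE))
  # zero high-scoring partners: p-value 1
  cold <- res[res$n_high == 0, ]
  expect_true(all(cold$pvalue == 1))
  # degenerate background: all scores identical -> gene skipped with warning
  scores2 <- transform(scores, score = 10)
  expect_warning(r2 <- rri_enrichment(map, scores2), "degenerate")
  expect_null(r2)
})
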