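# build an indicator object with chosen per-pair supporting cells
ind_from_sets <- function(genes, cells, fire = list()) {
  cmb <- combn(length(genes), 2)
  pairs <- data.frame(gene_a = genes[cmb[1, ]], gene_b = genes[cmb[2, ]],
                      stringsAsFactors = FALSE)
  X <- matrix(FALSE, nrow(pairs), length(cells),
              dimnames = list(paste(pairs$gene_a, pairs$gene_b), cells))
  for (key in names(fire)) X[key, fire[[key]]] <- TRUE
  E <- matrix(TRUE, length(genes), length(cells),
              dimnames = list(genes, cells))
  structure(list(genes = genes, cells = cells, pairs = pairs, X = X, E = E,
                 N_c = colSums(X), results = NULL,
                 params = list(alpha_pp = 0.01)),
            class = "pp_indicators")
}

test_that("cell-type association matches the hypergeometric tail", {
  cells <- sprintf("c%02d", 1:20)
  meta <- data.frame(cell_id = cells,
                     cell_type = rep(c("T1", "T2"), each = 10))
  ind <- ind_from_sets(c("A", "B", "C"), cells,
                       fire = list("A B" = cells[1:6]))
  res <- celltype_association(ind, meta, pairs = ind$pairs)
  ab_t1 <- res[res$gene_a == "A" & res$gene_b == "B" &
                 res$cell_type == "T1", ]
  # all 6 supporting cells are type T1: P(X >= 6), X ~ Hypergeom(20,10,6)
  expect_equal(ab_t1$pvalue,
               phyper(5, 10, 10, 6, lower.tail = FALSE))
  # enumeration oracle on the same instance
  allO <- combn(20, 6)
  frac <- mean(apply(allO, 2, function(o) sum(o <= 10) >= 6))
  expect_equal(ab_t1$pvalue, frac)
  expect_equal(ab_t1$p_bonferroni, min(1, ab_t1$pvalue * nrow(res)))
  # empty O: p-value 1
  ab_t2 <- res[res$gene_a == "A" & res$gene_b == "C" &
                 res$cell_type == "T1", ]
  expect_equal(ab_t2$pvalue, 1)
})

test_that("association is 1 when the pair fires everywhere", {
  cells <- sprintf("c%02d", 1:12)
  meta <- data.frame(cell_id = cells, cell_type = rep(c("T1", "T2"), 6))
  ind <- ind_from_sets(c("A", "B"), cells, fire = list("A B" = cells))
  res <- celltype_association(ind, meta)
  expect_true(all(res$pvalue == 1))  # overlap |M| is the only outcome
})

test_that("conditional hypergeometric tail matches exhaustive enumeration", {
  expect_equal(conditional_hypergeom_pvalue(10, 4, 4, 3, 2, 1, 0), 1)
  # the documented instance: U=10, |M|=|E|=4, |O|=3, gamma=2, alpha=1
  for (lam in 1:3) {
    expect_equal(
      conditional_hypergeom_pvalue(10, 4, 4, 3, 2, 1, lam),
      oracle_cond_hyper(10, 4, 4, 3, 2, 1, lam),
      tolerance = 1e-12, info = paste("lambda =", lam))
  }
  # gamma = 0, alpha = 0 reduces to a plain hypergeometric on U \ E
  p <- conditional_hypergeom_pvalue(12, 4, 3, 4, 0, 0, 2)
  expect_equal(p, phyper(1, 4, 12 - 3 - 4, 4, lower.tail = FALSE))
  expect_equal(p, oracle_cond_hyper(12, 4, 3, 4, 0, 0, 2), tolerance = 1e-12)
  # property sweep over random consistent instances, |U| <= 12
  set.seed(19)
  worst <- 0
  for (rep in 1:25) {
    u <- sample(6:12, 1)
    m <- sample(2:(u - 2), 1)
    e <- m                       # |E| = |M| by construction
    gamma <- sample(0:min(m, e), 1)
    if (e - gamma + m > u) next  # sets must fit in U
    o <- sample(1:(u - 1), 1)
    # draw a feasible (alpha, lambda) by simulating one O'
    Op <- sample(u, o)
    E <- c(seq_len(gamma), if (e > gamma) (m + 1):(m + e - gamma))
    al <- length(intersect(Op, E))
    la <- length(intersect(Op, seq_len(m)))
    if (o - al > u - e) next
    got <- conditional_hypergeom_pvalue(u, m, e, o, gamma, al, la)
    want <- oracle_cond_hyper(u, m, e, o, gamma, al, la)
    if (!is.na(want)) worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-12)
  expect_error(conditional_hypergeom_pvalue(10, 4, 4, 3, 5, 1, 1),
               "gamma")
})

test_that("marker detection finds perfectly type-restricted genes", {
  set.seed(23)
  cells <- sprintf("c%02d", 1:30)
  type <- rep(c("T1", "T2"), each = 15)
  meta <- data.frame(cell_id = cells, cell_type = type)
  rows <- list()
  for (i in seq_along(cells)) {
    n_m <- if (type[i] == "T1") 20 else 0   # marker expressed only in T1
    rows[[i]] <- data.frame(
      cell = cells[i],
      gene = c(rep("MK", n_m), rep(c("u1", "u2", "u3"), times = rpois(3, 8))),
      x = 0, y = 0)
  }
  tab <- as_transcript_table(do.call(rbind, rows))
  mk <- find_markers(tab, meta, top_k = 1)
  expect_equal(mk$markers$T1, "MK")
  # the high-expression set has exactly |M| cells, ties broken by cell id
  E <- mk$expr_sets("MK", 15)
  expect_equal(sort(E), cells[1:15])
  expect_equal(length(mk$expr_sets("u1", 7)), 7)
})

test_that("pair categorization follows the decision flow", {
  set.seed(29)
  cells <- sprintf("c%02d", 1:40)
  type <- rep(c("T1", "T2"), each = 20)
  meta <- data.frame(cell_id = cells, cell_type = type)
  genes <- c("A", "B", "C", "D", "MK")
  # A-B fires strongly in T1 cells; C-D fires uniformly (no association)
  fire <- list("A B" = cells[1:12], "C D" = cells[c(1:3, 21:23)],
               "A MK" = cells[1:12])
  ind <- ind_from_sets(genes, cells, fire)
  # expression: all genes uniform except MK, a T1 marker
  rows <- lapply(seq_along(cells), function(i) data.frame(
    cell = cells[i],
    gene = c(rep(genes[1:4], times = 5 + rpois(4, 3)),
             rep("MK", if (type[i] == "T1") 25 else 0)),
    x = 0, y = 0))
  tab <- as_transcript_table(do.call(rbind, rows))
  map <- data.frame(gene_a = c("A", "C", "A"), gene_b = c("B", "D", "MK"),
                    stringsAsFactors = FALSE)
  cats <- categorize_pairs(map, ind, tab, meta, top_k_markers = 1)
  expect_equal(nrow(cats), 3)
  # C-D: no type association -> category 3
  expect_equal(cats$category[cats$gene_a == "C"], 3L)
  # A-B: associated with T1; neither gene T1-marker; both conditional tests
  # significant (expression is uniform, so conditioning explains nothing)
  ab <- cats[cats$gene_a == "A" & cats$gene_b == "B", ]
  expect_equal(ab$category, 2L)
  expect_equal(ab$cell_type, "T1")
  expect_true(all(c(ab$cond_p_a, ab$cond_p_b) < 0.05))
  # A-MK: associated with T1 but MK is a T1 marker -> category 1
  amk <- cats[cats$gene_b == "MK", ]
  expect_equal(amk$category, 1L)
  expect_true(amk$marker_b)
  # swapped labeling convention
  swapped <- categorize_pairs(map, ind, tab, meta, top_k_markers = 1,
                              legacy_labels = TRUE)
  expect_equal(swapped$category[swapped$gene_a == "A" &
                                  swapped$gene_b == "B"], 1L)
  expect_equal(swapped$category[swapped$gene_a == "C"], 3L)
  # every pair gets exactly one category
  expect_true(all(cats$category %in% 1:3))
})

test_that("neighbor graph matches a brute-force distance scan", {
  set.seed(37)
  meta <- data.frame(cell_id = sprintf("c%02d", 1:40),
                     centroid_x = runif(40, 0, 300),
                     centroid_y = runif(40, 0, 300))
  g <- build_neighbor_graph(meta, radius = 60)
  D <- as.matrix(dist(cbind(meta$centroid_x, meta$centroid_y)))
  for (i in 1:40) {
    expect_equal(g$neighbors[[i]],
                 sort(unname(which(D[i, ] <= 60 & seq_len(40) != i))))
  }
  # symmetry and no self-edges
  for (i in 1:40) for (j in g$neighbors[[i]]) {
    expect_true(i %in% g$neighbors[[j]])
    expect_false(i %in% g$neighbors[[i]])
  }
  g0 <- build_neighbor_graph(meta, radius = 0)
  expect_true(all(lengths(g0$neighbors) == 0))
  two <- data.frame(cell_id = c("a", "b"), centroid_x = c(0, 50),
                    centroid_y = 0)
  expect_equal(build_neighbor_graph(two, 100)$neighbors[[1]], 2L)
})

test_that("spatial LLR is zero for constant indicators and matches the grid oracle", {
  set.seed(41)
  meta <- data.frame(cell_id = sprintf("c%03d", 1:150),
                     centroid_x = runif(150, 0, 500),
                     centroid_y = runif(150, 0, 500))
  graph <- build_neighbor_graph(meta, radius = 80)
  expect_equal(spatial_modulation_llr(rep(0, 150), graph)$llr, 0)
  expect_equal(spatial_modulation_llr(rep(1, 150), graph)$llr, 0)
  # spatially shuffled labels: small llr, agreeing with the dense grid oracle
  worst <- 0
  for (rep in 1:5) {
    s <- sample(c(rep(1, 20), rep(0, 130)))
    fit <- spatial_modulation_llr(s, graph)
    oracle <- oracle_grid_llr(s, meta, radius = 80)
    worst <- max(worst, abs(fit$llr - oracle))
  }
  expect_lt(worst, 1e-6)
})

test_that("LLR is invariant to cell relabeling and rigid motion", {
  set.seed(43)
  meta <- data.frame(cell_id = sprintf("c%03d", 1:100),
                     centroid_x = runif(100, 0, 400),
                     centroid_y = runif(100, 0, 400))
  s <- rbinom(100, 1, 0.2)
  g1 <- build_neighbor_graph(meta, 70)
  base <- spatial_modulation_llr(s, g1)$llr
  # rigid motion: rotation + translation leaves the graph unchanged
  th <- 0.7
  rot <- data.frame(cell_id = meta$cell_id,
                    centroid_x = cos(th) * meta$centroid_x -
                      sin(th) * meta$centroid_y + 50,
                    centroid_y = sin(th) * meta$centroid_x +
                      cos(th) * meta$centroid_y - 20)
  expect_equal(spatial_modulation_llr(s, build_neighbor_graph(rot, 70))$llr,
               base, tolerance = 1e-8)
  # relabeling: permute cells and s together
  p <- sample(100)
  gp <- build_neighbor_graph(meta[p, ], 70)
  expect_equal(spatial_modulation_llr(s[p], gp)$llr, base, tolerance = 1e-8)
})

test_that("under iid Bernoulli labels the fitted weight concentrates near 0", {
  set.seed(47)
  meta <- data.frame(cell_id = sprintf("c%04d", 1:1000),
                     centroid_x = runif(1000, 0, 1500),
                     centroid_y = runif(1000, 0, 1500))
  graph <- build_neighbor_graph(meta, 100)
  ws <- vapply(1:11, function(i)
    spatial_modulation_llr(rbinom(1000, 1, 0.15), graph)$w, numeric(1))
  expect_lt(median(ws), 0.1)
})

test_that("the permutation scan flags a planted hotspot and nothing null", {
  set.seed(53)
  n <- 300
  meta <- data.frame(cell_id = sprintf("c%03d", 1:n),
                     centroid_x = runif(n, 0, 600),
                     centroid_y = runif(n, 0, 600))
  graph <- build_neighbor_graph(meta, 80)
  genes <- sprintf("g%02d", 1:6)
  inside <- (meta$centroid_x - 150)^2 + (meta$centroid_y - 150)^2 <= 120^2
  fire <- list()
  fire[["g01 g02"]] <- meta$cell_id[inside | runif(n) < 0.03]  # hotspot pair
  for (k in 2:5)
    fire[[paste(genes[k], genes[k + 1])]] <-
      meta$cell_id[runif(n) < 0.1]                             # null pairs
  ind <- ind_from_sets(genes, meta$cell_id, fire)
  map <- data.frame(gene_a = c("g01", sprintf("g%02d", 2:5)),
                    gene_b = c("g02", sprintf("g%02d", 3:6)),
                    stringsAsFactors = FALSE)
  scan <- spatial_modulation_scan(ind, map, graph, n_perm = 10, seed = 7)
  expect_true(scan$pairs$flagged[scan$pairs$gene_a == "g01"])
  expect_true(all(!scan$pairs$flagged[scan$pairs$gene_a != "g01"]))
  # determinism under a fixed seed
  scan2 <- spatial_modulation_scan(ind, map, graph, n_perm = 10, seed = 7)
  expect_identical(scan$pairs, scan2$pairs)
  expect_identical(scan$threshold, scan2$threshold)
})
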