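#' Simulation configuration
#'
#' Describes a synthetic single-molecule spatial transcriptomics dataset:
#' cells laid out on a 2D tissue extent, each a disc with a concentric
#' nucleus disc, heterogeneous per-cell transcript counts, optional z-planes
#' and blank probes, planted proximal gene pairs (with optional cell-type
#' restriction and tissue hotspots), and cell-type labels.
#'
#' Planted pair semantics: for a pair (a, b) with colocalization rate `rho`
#' and scale `sigma`, a fraction `rho` of the rarer gene's transcripts in a
#' cell is relocated next to a uniformly chosen partner transcript, at a
#' half-normal distance with scale `sigma` (micrometres) in a uniform
#' direction, in the partner's z-plane. Optional columns of `planted_pairs`:
#' `cell_type` (plant only in cells of that type), `hotspot_x, hotspot_y,
#' hotspot_r, rho_out` (inside the hotspot disc the rate is `rho`, outside
#' `rho_out`). Blanks are always background.
#'
#' @param n_cells,n_genes,n_blanks panel dimensions; blanks are named
#'   `Blank-1, ...` and appended to the `g001, ...` gene panel.
#' @param cell_radius_mean,cell_radius_sd cell disc radius distribution
#'   (micrometres; truncated normal, lower bound 2).
#' @param nucleus_frac nucleus radius as a fraction of the cell radius.
#' @param mean_transcripts mean whole-cell transcript count.
#' @param cell_size_sdlog log-normal spread of per-cell total counts.
#' @param abundance_sdlog log-normal spread of relative gene abundances.
#' @param blank_abundance blank probe abundance relative to the mean gene.
#' @param n_zplanes number of z-planes (transcripts split uniformly).
#' @param planted_pairs data.frame `gene_a, gene_b, rho, sigma` (+ optional
#'   columns above); `NULL` for a null dataset.
#' @param cell_types named numeric vector of type proportions (sums to 1).
#' @param cell_spacing grid spacing between cell centers (micrometres);
#'   default 2.5x the mean cell radius.
#' @param nuclear_genes genes whose background transcripts are placed inside
#'   the nucleus (region-biased expression).
#' @param abundance_mult named numeric vector of per-gene abundance
#'   multipliers (e.g. `c(g001 = 10)` inflates one gene tenfold); applied
#'   before normalization.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 200L, n_genes = 50L, n_blanks = 0L,
                       cell_radius_mean = 10, cell_radius_sd = 1.5,
                       nucleus_frac = 0.5, mean_transcripts = 400,
                       cell_size_sdlog = 0.3, abundance_sdlog = 1,
                       blank_abundance = 0.5, n_zplanes = 1L,
                       planted_pairs = NULL, cell_types = c(A = 1),
                       cell_spacing = NULL, nuclear_genes = character(0),
                       abundance_mult = NULL, seed = 1L) {
  stopifnot(n_cells >= 1, n_genes >= 2, nucleus_frac > 0, nucleus_frac < 1,
            abs(sum(cell_types) - 1) < 1e-8)
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("gene_a", "gene_b", "rho", "sigma") %in%
                    names(planted_pairs)),
              all(planted_pairs$rho >= 0), all(planted_pairs$rho <= 1),
              all(planted_pairs$sigma > 0))
  }
  structure(list(
    n_cells = n_cells, n_genes = n_genes, n_blanks = n_blanks,
    cell_radius_mean = cell_radius_mean, cell_radius_sd = cell_radius_sd,
    nucleus_frac = nucleus_frac, mean_transcripts = mean_transcripts,
    cell_size_sdlog = cell_size_sdlog, abundance_sdlog = abundance_sdlog,
    blank_abundance = blank_abundance, n_zplanes = n_zplanes,
    planted_pairs = planted_pairs, cell_types = cell_types,
    cell_spacing = cell_spacing %||% (2.5 * cell_radius_mean),
    nuclear_genes = nuclear_genes, abundance_mult = abundance_mult,
    seed = seed), class = "sim_config")
}

# uniform point in a disc
.runif_disc <- function(n, center, r) {
  rr <- r * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}

#' Simulate a spatial transcriptomics dataset with known ground truth
#'
#' @param cfg `sim_config`.
#' @return list: `transcripts` (transcript table), `geometry`
#'   (`cell_geometry_set` of discs), `meta` (cell metadata: type, centroid),
#'   `truth` (planted pairs, per-cell hotspot membership, seed). Fully
#'   reproducible for a fixed `cfg$seed`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  blanks <- if (cfg$n_blanks > 0) sprintf("Blank-%d", seq_len(cfg$n_blanks))
            else character(0)
  panel <- c(genes, blanks)

  # tissue layout: jittered grid of cell centers
  side <- ceiling(sqrt(cfg$n_cells))
  gx <- (seq_len(cfg$n_cells) - 1) %% side
  gy <- (seq_len(cfg$n_cells) - 1) %/% side
  centers <- cbind(gx * cfg$cell_spacing +
                     runif(cfg$n_cells, -0.15, 0.15) * cfg$cell_spacing,
                   gy * cfg$cell_spacing +
                     runif(cfg$n_cells, -0.15, 0.15) * cfg$cell_spacing)
  r_cell <- pmax(2, rnorm(cfg$n_cells, cfg$cell_radius_mean,
                          cfg$cell_radius_sd))
  r_nuc <- cfg$nucleus_frac * r_cell
  type <- sample(names(cfg$cell_types), cfg$n_cells, replace = TRUE,
                 prob = cfg$cell_types)
  cell_ids <- sprintf("c%04d", seq_len(cfg$n_cells))

  # relative abundances, normalized; blanks scaled down
  w <- rlnorm(length(panel), 0, cfg$abundance_sdlog)
  if (length(blanks))
    w[cfg$n_genes + seq_len(cfg$n_blanks)] <-
      cfg$blank_abundance * mean(w[seq_len(cfg$n_genes)])
  # planted-pair genes get the panel-mean abundance: a planted interaction
  # must be expressed to constitute ground truth (override via abundance_mult)
  if (!is.null(cfg$planted_pairs)) {
    pg <- match(unique(c(cfg$planted_pairs$gene_a, cfg$planted_pairs$gene_b)),
                panel)
    w[pg] <- mean(w[seq_len(cfg$n_genes)])
  }
  if (!is.null(cfg$abundance_mult)) {
    hit <- match(names(cfg$abundance_mult), panel)
    w[hit[!is.na(hit)]] <- w[hit[!is.na(hit)]] *
      cfg$abundance_mult[!is.na(hit)]
  }
  w <- w / sum(w)
  size_factor <- rlnorm(cfg$n_cells, 0, cfg$cell_size_sdlog)

  pp <- cfg$planted_pairs
  hotspot_cells <- list()
  if (!is.null(pp)) {
    for (q in seq_len(nrow(pp))) {
      if (!is.null(pp$hotspot_x) && !is.na(pp$hotspot_x[q])) {
        inside <- (centers[, 1] - pp$hotspot_x[q])^2 +
          (centers[, 2] - pp$hotspot_y[q])^2 <= pp$hotspot_r[q]^2
        hotspot_cells[[paste(pp$gene_a[q], pp$gene_b[q])]] <-
          cell_ids[inside]
      }
    }
  }

  tx_list <- vector("list", cfg$n_cells)
  for (c_i in seq_len(cfg$n_cells)) {
    lam <- cfg$mean_transcripts * size_factor[c_i] * w
    cnt <- stats::rpois(length(panel), lam)
    total <- sum(cnt)
    if (total == 0) { cnt[sample(length(panel), 1)] <- 1L; total <- 1L }
    gene_v <- rep(panel, cnt)
    xy <- .runif_disc(total, centers[c_i, ], r_cell[c_i])
    if (length(cfg$nuclear_genes)) {
      nucl <- gene_v %in% cfg$nuclear_genes
      if (any(nucl))
        xy[nucl, ] <- .runif_disc(sum(nucl), centers[c_i, ], r_nuc[c_i])
    }
    z <- if (cfg$n_zplanes > 1)
      sample.int(cfg$n_zplanes, total, replace = TRUE) - 1L else
      rep(0L, total)

    if (!is.null(pp)) {
      for (q in seq_len(nrow(pp))) {
        if (!is.null(pp$cell_type) && !is.na(pp$cell_type[q]) &&
            type[c_i] != pp$cell_type[q]) next
        rho <- pp$rho[q]
        hk <- paste(pp$gene_a[q], pp$gene_b[q])
        if (!is.null(hotspot_cells[[hk]])) {
          rho <- if (cell_ids[c_i] %in% hotspot_cells[[hk]]) pp$rho[q] else
            (pp$rho_out[q] %||% 0)
          if (is.na(rho)) rho <- 0
        }
        if (rho <= 0) next
        ia <- which(gene_v == pp$gene_a[q])
        ib <- which(gene_v == pp$gene_b[q])
        if (!length(ia) || !length(ib)) next
        if (length(ia) <= length(ib)) { mover <- ia; anchor <- ib }
        else { mover <- ib; anchor <- ia }
        nmove <- rbinom(1, length(mover), rho)
        if (nmove == 0) next
        mv <- sample(mover, nmove)
        an <- anchor[sample.int(length(anchor), nmove, replace = TRUE)]
        dist_r <- abs(rnorm(nmove, 0, pp$sigma[q]))
        ang <- runif(nmove, 0, 2 * pi)
        xy[mv, 1] <- xy[an, 1] + dist_r * cos(ang)
        xy[mv, 2] <- xy[an, 2] + dist_r * sin(ang)
        z[mv] <- z[an]
      }
    }
    tx_list[[c_i]] <- data.frame(cell = cell_ids[c_i], gene = gene_v,
                                 x = xy[, 1], y = xy[, 2], z = z,
                                 stringsAsFactors = FALSE)
  }
  transcripts <- as_transcript_table(do.call(rbind, tx_list))
  geometry <- cell_geometry_set(
    cell_ids,
    lapply(seq_len(cfg$n_cells), function(i)
      disc_boundary(centers[i, ], r_cell[i])),
    lapply(seq_len(cfg$n_cells), function(i)
      disc_boundary(centers[i, ], r_nuc[i])))
  meta <- data.frame(cell_id = cell_ids, cell_type = type,
                     centroid_x = centers[, 1], centroid_y = centers[, 2],
                     cell_radius = r_cell, nucleus_radius = r_nuc,
                     stringsAsFactors = FALSE)
  truth <- list(planted_pairs = pp, cell_types = setNames(type, cell_ids),
                hotspot_cells = hotspot_cells, genes = genes,
                blanks = blanks, seed = cfg$seed)
  list(transcripts = transcripts, geometry = geometry, meta = meta,
       truth = truth)
}

#' Power / false-positive-rate sweep over simulation configurations
#'
#' For each configuration: simulates a dataset, runs the PP + CPB pipeline at
#' the given thresholds, and reports the detection rate of planted pairs,
#' the permutation FPR and the blank-probe false-positive fraction.
#'
#' @param cfg_list list of `sim_config` objects.
#' @param d distance threshold for the PP test.
#' @param alpha_pp per-cell PP threshold.
#' @param alpha_cpb map-level CPB threshold.
#' @param mode `"2d"` or `"3d"`.
#' @return data.frame, one row per configuration: `n_cells, n_genes,
#'   n_planted, power, n_detected, fpr_perm, blank_fp_observed,
#'   blank_fp_expected` (`power` is `NA` for null configurations).
#' @export
sweep_power <- function(cfg_list, d, alpha_pp = 0.01, alpha_cpb = 1e-3,
                        mode = "2d") {
  rows <- lapply(cfg_list, function(cfg) {
    sim <- simulate_dataset(cfg)
    ind <- pp_test_dataset(sim$transcripts, d = d, mode = mode,
                           alpha_pp = alpha_pp)
    map <- cpb_test(ind)
    perm <- permute_gene_labels(sim$transcripts, seed = cfg$seed + 1L)
    map_p <- cpb_test(pp_test_dataset(perm, d = d, mode = mode,
                                      alpha_pp = alpha_pp))
    fpr <- estimate_fpr(map, map_p, thresholds = alpha_cpb)
    blanks <- sim$truth$blanks
    bl <- if (length(blanks)) blank_probe_fpr(map, blanks, alpha_cpb) else
      list(observed = NA_real_, expected = NA_real_)
    pp <- cfg$planted_pairs
    power <- NA_real_
    if (!is.null(pp) && nrow(pp)) {
      mk <- paste(pmin(map$gene_a, map$gene_b), pmax(map$gene_a, map$gene_b))
      tk <- paste(pmin(pp$gene_a, pp$gene_b), pmax(pp$gene_a, pp$gene_b))
      power <- mean(map$pvalue[match(tk, mk)] < alpha_cpb)
    }
    data.frame(n_cells = cfg$n_cells, n_genes = cfg$n_genes,
               n_planted = if (is.null(pp)) 0L else nrow(pp),
               power = power, n_detected = sum(map$pvalue < alpha_cpb),
               fpr_perm = fpr$fpr[1], blank_fp_observed = bl$observed,
               blank_fp_expected = bl$expected)
  })
  if (!length(rows))
    return(data.frame(n_cells = integer(0), n_genes = integer(0),
                      n_planted = integer(0), power = numeric(0),
                      n_detected = integer(0), fpr_perm = numeric(0),
                      blank_fp_observed = numeric(0),
                      blank_fp_expected = numeric(0)))
  do.call(rbind, rows)
}
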