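#' Run the full colocalization workflow
#'
#' Orchestrates simulate/load -> cell filtering -> region annotation -> PP
#' test -> CPB map (+ permutation FPR) -> cell-type categories -> spatial
#' modulation -> module mining from a single configuration, writing every
#' intermediate artifact plus a machine-readable run manifest to `out_dir`.
#' Re-running an identical configuration reproduces identical outputs.
#'
#' Configuration (list or YAML file): either `simulate:` (arguments for
#' [sim_config()]) or `input:` (`transcripts`, optional `geometry`, `meta`,
#' column mapping); `d` (required); optional `mode` ("2d"/"3d"), `alpha_pp`
#' (0.01), `alpha_cpb` (1e-3), `min_per_plane` (0), `pn_halfwidth` (2.5),
#' `cp_width` (4), `radius` (100), `n_perm` (10), `fsm_alpha` (0.05),
#' `fsm_min_nodes` (3), `fsm_min_support` (2), `gcc_n_clusters` (6),
#' `gcc_min_density` (0.7), `seed` (1).
#'
#' @param config named list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$d)) stop("config error: 'd' (distance threshold) missing")
  cfg <- config
  dflt <- list(mode = "2d", alpha_pp = 0.01, alpha_cpb = 1e-3,
               min_per_plane = 0L, pn_halfwidth = 2.5, cp_width = 4,
               radius = 100, n_perm = 10L, fsm_alpha = 0.05,
               fsm_min_nodes = 3L, fsm_min_support = 2L,
               gcc_n_clusters = 6L, gcc_min_density = 0.7, seed = 1L)
  for (nm in names(dflt)) cfg[[nm]] <- cfg[[nm]] %||% dflt[[nm]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = .dcoloc_version(), params = cfg, stages = list())
  artifacts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  record <- function(name, df, path) {
    write_dcoloc_tsv(df, file.path(out_dir, path),
                     params = list(stage = name, d = cfg$d, seed = cfg$seed))
    manifest$stages[[name]] <<- list(
      file = path,
      md5 = unname(tools::md5sum(file.path(out_dir, path))))
  }

  geometry <- meta <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, c(cfg$simulate,
                                  if (is.null(cfg$simulate$seed))
                                    list(seed = cfg$seed)))
      simulate_dataset(sc)
    })
    transcripts <- sim$transcripts
    geometry <- sim$geometry
    meta <- sim$meta
    record("simulate", transcripts, "transcripts.tsv")
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  } else if (!is.null(cfg$input)) {
    transcripts <- stage("load", do.call(load_transcripts, cfg$input["path"]))
    if (!is.null(cfg$input$geometry))
      geometry <- stage("load", load_geometry(cfg$input$geometry))
    if (!is.null(cfg$input$meta))
      meta <- stage("load", load_cell_meta(cfg$input$meta))
  } else stop("config error: neither 'simulate' nor 'input' given")

  if (cfg$min_per_plane > 0)
    transcripts <- stage("filter",
                         filter_cells(transcripts, cfg$min_per_plane))
  if (!is.null(geometry))
    transcripts <- stage("regions",
                         assign_regions(transcripts, geometry,
                                        cfg$pn_halfwidth, cfg$cp_width))

  ind <- stage("pp", pp_test_dataset(transcripts, d = cfg$d, mode = cfg$mode,
                                     alpha_pp = cfg$alpha_pp))
  record("pp", ind$results, "pp_results.tsv")
  record("indicators",
         data.frame(pair = rownames(ind$X), ind$X, check.names = FALSE),
         "indicators.tsv")

  map <- stage("cpb", cpb_test(ind))
  if (!is.null(geometry)) map <- stage("annotate", annotate_map(map, ind))
  record("cpb", map, "map.tsv")

  perm <- stage("fpr", {
    pt <- permute_gene_labels(transcripts, seed = cfg$seed + 1L)
    cpb_test(pp_test_dataset(pt, d = cfg$d, mode = cfg$mode,
                             alpha_pp = cfg$alpha_pp))
  })
  fpr <- estimate_fpr(map, perm, thresholds = c(1e-2, cfg$alpha_cpb))
  record("fpr", fpr, "fpr.tsv")

  sig <- map[map$pvalue < cfg$alpha_cpb, , drop = FALSE]
  if (!is.null(meta) && "cell_type" %in% names(meta) &&
      length(unique(meta$cell_type)) > 1 && nrow(sig) > 0) {
    cats <- stage("celltype",
                  categorize_pairs(sig, ind, transcripts, meta))
    record("celltype", cats, "categories.tsv")
  }
  if (!is.null(meta) && all(c("centroid_x", "centroid_y") %in% names(meta)) &&
      nrow(sig) > 0) {
    graph <- stage("spatial", {
      m2 <- meta[match(ind$cells, meta$cell_id), , drop = FALSE]
      build_neighbor_graph(m2, radius = cfg$radius)
    })
    scan <- stage("spatial",
                  spatial_modulation_scan(ind, sig, graph,
                                          n_perm = cfg$n_perm,
                                          seed = cfg$seed))
    record("spatial", scan$pairs, "spatial_modulation.tsv")
    manifest$stages$spatial$threshold <- scan$threshold
  }

  mods <- stage("gcc", gcc_cluster(map, n_clusters = cfg$gcc_n_clusters,
                                   min_density = cfg$gcc_min_density,
                                   alpha = cfg$alpha_cpb))
  record("gcc", mods, "gcc_modules.tsv")
  fsm <- stage("fsm", fsm_mine(cell_graphs(ind, alpha = cfg$fsm_alpha),
                               min_nodes = cfg$fsm_min_nodes,
                               min_support = cfg$fsm_min_support,
                               clique_only = TRUE))
  record("fsm", fsm, "fsm_modules.tsv")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(transcripts = transcripts, indicators = ind, map = map,
                 fpr = fpr, gcc = mods, fsm = fsm, manifest = manifest,
                 out_dir = out_dir))
}
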