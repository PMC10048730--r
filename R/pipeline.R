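#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with a
#' synthetic-study preset: a smooth environmental surface plus a DEM,
#' genotypes structured by a known true resistance transformation, and a
#' gravity stage on simulated site attributes. Any element can be
#' overridden via `...` (or by editing the returned list / a YAML file
#' with the same structure).
#'
#' @param ... named overrides of top-level elements.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    landscape = list(nrow = 30, ncol = 30, range = 5, cell_size = 100),
    sites = list(n = 10, per_site = 3, min_separation = 400),
    truth = list(family = "Monomolecular", shape = 3, maximum = 100,
                 beta = c(0, 1), sigma2_node = 0.2, sigma2_resid = 0.2),
    genotypes = list(n_loci = 10, n_alleles = 8, decay = 0.5,
                     missing_code = "0"),
    relatedness_threshold = 0.5,
    ga = list(pop_size = 12, max_generations = 12, stall_generations = 5,
              n_runs = 2),
    bootstrap = list(frac = 0.75, iters = 100),
    gravity = list(formulas = list(IBD = character(0))),
    current_map = TRUE
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a configuration list or path to a YAML file.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg)) stop("config must be a list or YAML path")
  need <- c("seed", "landscape", "sites", "truth", "genotypes",
            "ga", "bootstrap", "gravity")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(cfg$seed)) stop("config seed must be an integer")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full landscape-genetics pipeline on a synthetic study
#'
#' Executes the analysis chain end to end: simulate a landscape, sites and
#' genotypes from a known truth; estimate relatedness and filter related
#' dyads; compute Rousset's a-hat and Dps; optimize the resistance surface
#' by GA against the genetic distances; bootstrap model selection of the
#' optimized surface against a Euclidean-distance null; current-flow map;
#' and gravity models of Dps. All tables are written as CSV, rasters as
#' ASCII grids, and a JSON manifest records the resolved configuration and
#' seeds. A stage failure aborts with the stage name; partial artifacts
#' written before the failure are left in place for inspection.
#'
#' @param cfg a [pipeline_config()] list or YAML path.
#' @param out_dir output directory (created; existing files of a previous
#'   run are overwritten only by their own stage).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg, out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- as.integer(cfg$seed)

  land <- stage("landscape", {
    make_landscape("smooth", cfg$landscape$nrow, cfg$landscape$ncol,
                   seed = seed, range = cfg$landscape$range,
                   cell_size = cfg$landscape$cell_size)
  })
  write_ascii_grid(land, file.path(out_dir, "landscape.asc"))

  truth <- synthetic_truth(
    transform_spec(cfg$truth$family, cfg$truth$shape, cfg$truth$maximum),
    beta = cfg$truth$beta, sigma2_node = cfg$truth$sigma2_node,
    sigma2_resid = cfg$truth$sigma2_resid, seed = seed + 1L)

  sites <- stage("sites", {
    sample_locations(land, cfg$sites$n, seed = seed + 2L,
                     min_separation = cfg$sites$min_separation)
  })
  utils::write.csv(sites, file.path(out_dir, "sites.csv"),
                   row.names = FALSE)

  geno <- stage("genotypes", {
    simulate_genotypes(truth, land, sites,
                       n_per_site = cfg$sites$per_site,
                       n_loci = cfg$genotypes$n_loci,
                       n_alleles = cfg$genotypes$n_alleles,
                       decay = cfg$genotypes$decay, seed = seed + 3L)
  })
  write_genotypes(geno, file.path(out_dir, "genotypes.csv"),
                  missing_code = cfg$genotypes$missing_code)

  geno <- stage("relatedness_filter", {
    r <- estimate_relatedness(geno)
    write_pairwise_csv(r, file.path(out_dir, "relatedness.csv"))
    filter_related(geno, r, cfg$relatedness_threshold)
  })

  dists <- stage("genetic_distances", {
    ar <- rousset_ar(geno)
    dp <- dps(geno)
    write_pairwise_csv(ar, file.path(out_dir, "rousset_ar.csv"))
    write_pairwise_csv(dp, file.path(out_dir, "dps.csv"))
    list(ar = ar, dps = dp)
  })
  locs <- data.frame(id = geno$ids, x = geno$coords[, 1],
                     y = geno$coords[, 2])

  opt <- stage("optimize", {
    ga_cfg <- do.call(ga_control, cfg$ga)
    optimize_surface(land, dists$ar, locs, kind = "continuous",
                     cfg = ga_cfg, seed = seed + 4L)
  })
  spec <- opt$best_spec
  utils::write.csv(data.frame(
    surface = land$tag, logL = opt$objective, AICc = opt$best_fit$aicc,
    equation = spec$family, shape = spec$shape, maximum = spec$maximum,
    converged = opt$converged),
    file.path(out_dir, "optimized_models.csv"), row.names = FALSE)

  sel <- stage("selection", {
    best_surface <- apply_transform(rescale_surface(land), spec)
    gr <- conductance_graph(best_surface)
    cands <- list(
      optimized = commute_distance(gr, locs),
      Distance = euclidean_distances(locs))
    bootstrap_select(cands, dists$ar, frac = cfg$bootstrap$frac,
                     iters = cfg$bootstrap$iters, seed = seed + 5L)
  })
  utils::write.csv(as.data.frame(sel),
                   file.path(out_dir, "bootstrap_selection.csv"),
                   row.names = FALSE)

  if (isTRUE(cfg$current_map)) {
    stage("current_map", {
      best_surface <- apply_transform(rescale_surface(land), spec)
      gr <- conductance_graph(best_surface)
      nodes <- snap_nodes(gr, locs)
      un <- unique(nodes)
      pairs <- t(utils::combn(un, 2))
      cm <- current_map(gr, pairs)
      write_ascii_grid(cm, file.path(out_dir, "current_map.asc"))
    })
  }

  grav <- stage("gravity", {
    best_surface <- apply_transform(rescale_surface(land), spec)
    gr <- conductance_graph(best_surface)
    res_cd <- commute_distance(gr, locs)
    set.seed(seed + 6L)
    site_attrs <- data.frame(site = sites$id,
                             ivi = exp(stats::rnorm(nrow(sites), 0, 0.5)))
    net <- build_gravity_network(geno, site_attrs, dists$dps,
                                 resistances = list(resistance = res_cd))
    formulas <- cfg$gravity$formulas
    if (!"IBD" %in% names(formulas))
      formulas <- c(list(IBD = character(0)), formulas)
    if (length(formulas) < 2L)
      formulas$resistance <- "resistance"
    gravity_model_table(net, formulas)
  })
  utils::write.csv(grav, file.path(out_dir, "gravity_models.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "landres",
    seed = seed,
    stage_seeds = list(landscape = seed, truth = seed + 1L,
                       sites = seed + 2L, genotypes = seed + 3L,
                       optimize = seed + 4L, bootstrap = seed + 5L,
                       gravity = seed + 6L),
    config = unclass(cfg),
    artifacts = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genotypes = geno, distances = dists, optimization = opt,
                 selection = sel, gravity = grav, manifest = manifest))
}
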