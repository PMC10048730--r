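#' Genetic-algorithm settings
#'
#' Defaults sized for desk-scale landscapes: modest population, tournament
#' selection, uniform crossover, Gaussian mutation of log-shape and
#' log-maximum, and a stall rule that stops after `stall_generations`
#' generations without at least `stall_tol` log-likelihood units of
#' improvement.
#'
#' @param pop_size individuals per generation.
#' @param max_generations hard generation cap.
#' @param stall_generations,stall_tol stopping rule (see above).
#' @param tournament_size tournament selection size.
#' @param crossover_prob per-pair uniform crossover probability.
#' @param mutation_prob per-gene Gaussian mutation probability.
#' @param mutation_sd mutation standard deviation on the log scale.
#' @param family_mutation_prob probability of resampling the family gene.
#' @param elite individuals copied unchanged into the next generation.
#' @param n_runs independent optimization repeats (>= 2 recommended so
#'   convergence can be checked).
#' @param run_tol repeats whose best objectives differ by more than this
#'   many log-likelihood units are flagged as non-convergent.
#' @param shape_range search range for the shape parameter.
#' @param max_resistance upper bound for the maximum-resistance parameter
#'   (5000 for single surfaces; use 10000 within composites).
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 30, max_generations = 100,
                       stall_generations = 25, stall_tol = 0.1,
                       tournament_size = 3, crossover_prob = 0.8,
                       mutation_prob = 0.35, mutation_sd = 0.7,
                       family_mutation_prob = 0.15, elite = 2,
                       n_runs = 2, run_tol = 0.5,
                       shape_range = c(0.01, 100),
                       max_resistance = 5000) {
  structure(as.list(environment()), class = "ga_control")
}

# continuous-surface genome: family index + log(shape) + log(maximum - 1)
random_genome_continuous <- function(cfg, families) {
  list(fam = sample.int(length(families), 1L),
       ls = stats::runif(1, log(cfg$shape_range[1]), log(cfg$shape_range[2])),
       lm = stats::runif(1, log(0.01), log(cfg$max_resistance - 1)))
}

genome_to_spec <- function(gen, families) {
  fam <- families[gen$fam]
  if (fam == "Distance") transform_spec("Distance")
  else transform_spec(fam, shape = exp(gen$ls), maximum = 1 + exp(gen$lm))
}

mutate_continuous <- function(gen, cfg, families) {
  if (stats::runif(1) < cfg$family_mutation_prob)
    gen$fam <- sample.int(length(families), 1L)
  if (stats::runif(1) < cfg$mutation_prob)
    gen$ls <- clamp(gen$ls + stats::rnorm(1, 0, cfg$mutation_sd),
                    log(cfg$shape_range[1]), log(cfg$shape_range[2]))
  if (stats::runif(1) < cfg$mutation_prob)
    gen$lm <- clamp(gen$lm + stats::rnorm(1, 0, cfg$mutation_sd),
                    log(0.01), log(cfg$max_resistance - 1))
  gen
}

crossover_genes <- function(a, b, cfg) {
  if (stats::runif(1) >= cfg$crossover_prob) return(a)
  for (nm in names(a)) if (stats::runif(1) < 0.5) a[[nm]] <- b[[nm]]
  a
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# generic GA over list genomes; fitness maximized
run_ga <- function(init_fn, mutate_fn, fitness_fn, cfg) {
  pop <- replicate(cfg$pop_size, init_fn(), simplify = FALSE)
  fit <- vapply(pop, fitness_fn, numeric(1))
  best_hist <- max(fit)
  stall <- 0L
  for (gen in seq_len(cfg$max_generations - 1L)) {
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(cfg$elite)]]
    newfit <- fit[ord[seq_len(cfg$elite)]]
    while (length(newpop) < cfg$pop_size) {
      pick <- function() {
        cand <- sample.int(length(pop), cfg$tournament_size)
        cand[which.max(fit[cand])]
      }
      child <- crossover_genes(pop[[pick()]], pop[[pick()]], cfg)
      child <- mutate_fn(child)
      newpop[[length(newpop) + 1L]] <- child
      newfit <- c(newfit, fitness_fn(child))
    }
    pop <- newpop
    fit <- newfit
    prev <- best_hist[length(best_hist)]
    best_hist <- c(best_hist, max(prev, max(fit)))
    if (max(fit) > prev + cfg$stall_tol) stall <- 0L else stall <- stall + 1L
    if (stall >= cfg$stall_generations) break
  }
  ibest <- which.max(fit)
  list(best = pop[[ibest]], objective = fit[ibest], history = best_hist)
}

# objective evaluator shared by single and composite optimization: commute
# distances are cached by parameter signature so repeated genomes (elites,
# duplicates) cost nothing
make_objective <- function(raw_list, genetic, locs, cfg, families,
                           categorical = FALSE, ref_class = NULL,
                           levels_list = NULL) {
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_specs <- function(specs) {
    key <- paste(vapply(specs, function(s) {
      if (inherits(s, "transform_spec"))
        sprintf("%s|%.8g|%.8g", s$family, s$shape, s$maximum)
      else paste(sprintf("%.8g", s$values), collapse = ",")
    }, character(1)), collapse = ";")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    surfs <- mapply(function(raw, s) {
      if (inherits(s, "transform_spec")) apply_transform(raw, s)
      else apply_categorical(raw, s)
    }, raw_list, specs, SIMPLIFY = FALSE)
    comp <- if (length(surfs) == 1L) surfs[[1L]] else combine_surfaces(surfs)
    gr <- conductance_graph(comp, connectivity = 8)
    cd <- commute_distance(gr, locs)
    fit <- fit_mlpe(genetic, list(commute = cd), method = "ML")
    res <- list(logL = fit$logL, fit = fit)
    assign(key, res, envir = cache)
    n_eval <<- n_eval + 1L
    res
  }
  list(eval_specs = eval_specs, n_unique = function() n_eval)
}

#' Optimize a resistance surface against genetic distances
#'
#' Genetic-algorithm search for the resistance parameterization whose
#' commute distances best explain pairwise genetic distance under an MLPE
#' mixed model (maximum-likelihood objective). Continuous surfaces are
#' searched over the eight Monomolecular/Ricker transformation families
#' with shape and maximum (maximum bounded by `cfg$max_resistance`);
#' categorical surfaces are searched over per-class resistance values with
#' the reference class fixed at 1. The search runs `cfg$n_runs` independent
#' times; runs disagreeing by more than `cfg$run_tol` log-likelihood units
#' are flagged (not silently merged).
#'
#' @param raw a [raster_surface()]: a continuous environmental surface
#'   (rescaled internally) or a class-coded categorical surface.
#' @param genetic a [pairwise_matrix()] of genetic distances whose ids
#'   match `locs`.
#' @param locs data frame of `id, x, y` sampling coordinates (snapped to
#'   non-missing cells).
#' @param kind `"continuous"` or `"categorical"`.
#' @param cfg a [ga_control()].
#' @param seed integer seed; the full trajectory is reproducible.
#' @param ref_class reference class (categorical only; default the first
#'   class label).
#' @return An `optimization_result`: `best_spec`, `best_fit` (an
#'   [fit_mlpe()] result), `objective`, per-generation `history`, `runs`
#'   (per-run best spec and objective), and `converged`.
#' @export
optimize_surface <- function(raw, genetic, locs,
                             kind = c("continuous", "categorical"),
                             cfg = ga_control(), seed = 1L,
                             ref_class = NULL) {
  kind <- match.arg(kind)
  optimize_composite(stats::setNames(list(raw), raw$tag), genetic, locs,
                     kinds = kind, cfg = cfg, seed = seed,
                     ref_class = ref_class,
                     allow_distance_family = FALSE)
}

#' Optimize a composite of several resistance surfaces jointly
#'
#' Joint GA search over the transformation parameters of every component;
#' components are combined with [combine_surfaces()] before the commute /
#' MLPE objective is evaluated. Within a composite a continuous component
#' may also adopt the degenerate `"Distance"` family (a flat,
#' non-influential surface).
#'
#' @param raws named list of raw component [raster_surface()]s.
#' @param kinds `"continuous"`/`"categorical"`, recycled across components.
#' @param allow_distance_family include `"Distance"` in the family gene of
#'   continuous components (default `TRUE` for composites).
#' @inheritParams optimize_surface
#' @return An `optimization_result`; `best_spec` is a named list with one
#'   spec per component (a [transform_spec()] or
#'   [categorical_assignment()]).
#' @export
optimize_composite <- function(raws, genetic, locs, kinds = "continuous",
                               cfg = ga_control(), seed = 1L,
                               ref_class = NULL,
                               allow_distance_family = TRUE) {
  if (is.null(names(raws)))
    names(raws) <- vapply(raws, function(r) r$tag, character(1))
  kinds <- rep_len(kinds, length(raws))
  families <- transform_families()
  if (!allow_distance_family) families <- setdiff(families, "Distance")

  prep <- mapply(function(r, k) {
    if (k == "continuous") rescale_surface(r) else r
  }, raws, kinds, SIMPLIFY = FALSE)

  class_levels <- lapply(seq_along(raws), function(m) {
    if (kinds[m] != "categorical") return(NULL)
    lev <- attr(raws[[m]], "levels")
    if (is.null(lev))
      lev <- as.character(sort(unique(stats::na.omit(
        as.vector(raws[[m]]$values)))))
    lev
  })
  refs <- lapply(class_levels, function(lev) {
    if (is.null(lev)) NULL
    else if (!is.null(ref_class) && ref_class %in% lev) ref_class
    else lev[1L]
  })

  objective <- make_objective(prep, genetic, locs, cfg, families)

  init_component <- function(m) {
    if (kinds[m] == "continuous") random_genome_continuous(cfg, families)
    else {
      lev <- class_levels[[m]]
      free <- setdiff(lev, refs[[m]])
      list(vals = stats::setNames(
        stats::runif(length(free), log(0.01), log(cfg$max_resistance)),
        free))
    }
  }
  mutate_component <- function(gen, m) {
    if (kinds[m] == "continuous") mutate_continuous(gen, cfg, families)
    else {
      mut <- stats::runif(length(gen$vals)) < cfg$mutation_prob
      gen$vals[mut] <- clamp(gen$vals[mut] +
                               stats::rnorm(sum(mut), 0, cfg$mutation_sd),
                             log(1e-3), log(cfg$max_resistance))
      gen
    }
  }
  genome_to_specs <- function(genome) {
    lapply(seq_along(genome), function(m) {
      if (kinds[m] == "continuous") genome_to_spec(genome[[m]], families)
      else {
        vals <- c(1, exp(genome[[m]]$vals))
        names(vals) <- c(refs[[m]], names(genome[[m]]$vals))
        categorical_assignment(vals, bound = cfg$max_resistance)
      }
    }) |> stats::setNames(names(raws))
  }

  fitness <- function(g) objective$eval_specs(genome_to_specs(g))$logL

  # family signature of a genome (categorical components contribute a
  # constant token); used to shortlist family combinations for refinement
  signature_of <- function(genome) {
    paste(vapply(genome, function(gc) {
      if (!is.null(gc$fam)) families[gc$fam] else "categorical"
    }, character(1)), collapse = "+")
  }

  # flatten the continuous genes of a genome for local refinement with the
  # family genes held fixed
  pack <- function(genome) {
    unlist(lapply(genome, function(gc) {
      if (!is.null(gc$fam)) c(gc$ls, gc$lm) else as.numeric(gc$vals)
    }))
  }
  unpack <- function(genome, par) {
    k <- 0L
    for (m in seq_along(genome)) {
      if (!is.null(genome[[m]]$fam)) {
        genome[[m]]$ls <- clamp(par[k + 1L], log(cfg$shape_range[1]),
                                log(cfg$shape_range[2]))
        genome[[m]]$lm <- clamp(par[k + 2L], log(0.01),
                                log(cfg$max_resistance - 1))
        k <- k + 2L
      } else {
        nv <- length(genome[[m]]$vals)
        genome[[m]]$vals[] <- clamp(par[k + seq_len(nv)], log(1e-3),
                                    log(cfg$max_resistance))
        k <- k + nv
      }
    }
    genome
  }
  polish <- function(genome) {
    par0 <- pack(genome)
    o <- stats::optim(par0, function(p) fitness(unpack(genome, p)),
                      method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 150,
                                     reltol = 1e-8))
    list(genome = unpack(genome, o$par), objective = o$value)
  }

  one_run <- function(run_seed) {
    set.seed(run_seed)
    best_by_sig <- new.env(parent = emptyenv())
    tracked_fitness <- function(g) {
      v <- fitness(g)
      sig <- signature_of(g)
      prev <- get0(sig, envir = best_by_sig)
      if (is.null(prev) || v > prev$objective)
        assign(sig, list(genome = g, objective = v), envir = best_by_sig)
      v
    }
    res <- run_ga(
      init_fn = function() lapply(seq_along(raws), init_component),
      mutate_fn = function(g) lapply(seq_along(g), function(m)
        mutate_component(g[[m]], m)),
      fitness_fn = tracked_fitness,
      cfg = cfg)
    # refine the best genome of the top family combinations encountered
    cands <- mget(ls(best_by_sig), envir = best_by_sig)
    cands <- cands[order(-vapply(cands, `[[`, numeric(1), "objective"))]
    cands <- cands[seq_len(min(3L, length(cands)))]
    for (cd in cands) {
      ref <- polish(cd$genome)
      if (ref$objective > res$objective) {
        res$best <- ref$genome
        res$objective <- ref$objective
      }
    }
    res$history <- c(res$history, res$objective)
    res$specs <- genome_to_specs(res$best)
    res
  }

  run_seeds <- seed + seq_len(cfg$n_runs) - 1L
  runs <- lapply(run_seeds, one_run)
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  ibest <- which.max(objs)
  converged <- diff(range(objs)) <= cfg$run_tol
  if (!converged)
    warning(sprintf(
      "independent runs disagree by %.3f logL units (> run_tol = %.3f); %s",
      diff(range(objs)), cfg$run_tol, "treat the optimum as unconverged"))
  best_specs <- runs[[ibest]]$specs
  best_eval <- objective$eval_specs(best_specs)
  structure(list(
    best_spec = if (length(raws) == 1L) best_specs[[1L]] else best_specs,
    best_fit = best_eval$fit,
    objective = objs[ibest],
    history = runs[[ibest]]$history,
    runs = lapply(runs, function(r)
      list(spec = if (length(raws) == 1L) r$specs[[1L]] else r$specs,
           objective = r$objective, history = r$history)),
    converged = converged,
    n_evaluations = objective$n_unique(),
    seeds = run_seeds),
    class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>\n  best objective (ML logL):",
      sprintf("%.4f", x$objective), "\n")
  cat("  runs:", paste(sprintf("%.4f",
                               vapply(x$runs, `[[`, numeric(1),
                                      "objective")), collapse = ", "),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  if (inherits(x$best_spec, "transform_spec")) print(x$best_spec)
  else if (is.list(x$best_spec)) for (s in x$best_spec) print(s)
  invisible(x)
}

#' @export
print.categorical_assignment <- function(x, ...) {
  cat("<categorical_assignment> bound =", x$bound, "\n")
  print(round(x$values, 3))
  invisible(x)
}
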