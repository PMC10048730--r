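# Gaussian smoothing of a matrix by FFT convolution on the torus; sigma in
# cells. Used to give synthetic fields a controllable autocorrelation range.
gauss_smooth <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  K <- exp(-outer(dr^2, dc^2, `+`) / (2 * sigma^2))
  K <- K / sum(K)
  Re(stats::fft(stats::fft(m) * stats::fft(K), inverse = TRUE)) / (nr * nc)
}

#' Generate a synthetic landscape raster
#'
#' Emulates the statistical structure of the environmental layers the
#' pipeline consumes: `"smooth"` is a Gaussian-filtered white-noise field
#' with autocorrelation range set by `range` (cells), standardized to mean
#' 0 / sd 1; `"dem"` superposes a long-range field, ridged relief (the
#' absolute value of a medium-range field) and fine roughness, suitable for
#' deriving ruggedness and topographic position; `"categorical"` thresholds
#' a smooth field at quantiles into `n_classes` labeled classes.
#'
#' @param kind `"smooth"`, `"dem"` or `"categorical"`.
#' @param nrow,ncol grid size (at least 20 x 20).
#' @param seed RNG seed; the raster is a deterministic function of it.
#' @param range autocorrelation range in cells.
#' @param n_classes classes for `"categorical"`.
#' @param cell_size,origin grid geometry (meters).
#' @return A [raster_surface()]; categorical rasters carry a `levels`
#'   attribute with class labels.
#' @export
make_landscape <- function(kind = c("smooth", "dem", "categorical"),
                           nrow = 40, ncol = 40, seed = 1L, range = 6,
                           n_classes = 2, cell_size = 100,
                           origin = c(0, 0)) {
  kind <- match.arg(kind)
  if (nrow < 20 || ncol < 20) stop("landscape must be at least 20 x 20")
  set.seed(seed)
  std <- function(m) (m - mean(m)) / stats::sd(m)
  noise <- function() matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (kind == "smooth") {
    v <- std(gauss_smooth(noise(), range))
    return(raster_surface(v, cell_size, origin, tag = "smooth"))
  }
  if (kind == "dem") {
    broad <- std(gauss_smooth(noise(), max(range * 2, 8)))
    ridged <- abs(std(gauss_smooth(noise(), range)))
    fine <- std(gauss_smooth(noise(), max(range / 3, 1)))
    v <- 800 + 150 * broad + 120 * ridged + 15 * fine
    return(raster_surface(v, cell_size, origin, tag = "dem"))
  }
  v <- std(gauss_smooth(noise(), range))
  br <- stats::quantile(v, probs = seq(0, 1,
                                       length.out = n_classes + 1L))
  br[1] <- -Inf; br[length(br)] <- Inf
  cls <- matrix(as.integer(cut(v, breaks = br)), nrow, ncol)
  out <- raster_surface(cls, cell_size, origin, tag = "categorical")
  attr(out, "levels") <- paste0("class_", seq_len(n_classes))
  out
}

#' Place sampling locations on a landscape
#'
#' Draws `n` distinct non-missing cells, optionally enforcing a minimum
#' separation, and returns their cell-center coordinates.
#'
#' @param raster a [raster_surface()].
#' @param n number of locations.
#' @param seed RNG seed.
#' @param min_separation minimum pairwise distance in meters (greedy;
#'   default one cell).
#' @param ids labels (default `S1..Sn`).
#' @return Data frame `id, x, y`.
#' @export
sample_locations <- function(raster, n, seed = 1L, min_separation = NULL,
                             ids = NULL) {
  stopifnot_raster(raster)
  set.seed(seed)
  ok <- which(is.finite(raster$values))
  ctr <- cell_centers(raster, ok)
  if (is.null(min_separation)) min_separation <- raster$cell_size
  chosen <- integer(0)
  cand <- sample(seq_along(ok))
  for (c_i in cand) {
    if (length(chosen) == n) break
    if (!length(chosen) ||
        min(sqrt((ctr[chosen, 1] - ctr[c_i, 1])^2 +
                   (ctr[chosen, 2] - ctr[c_i, 2])^2)) >= min_separation)
      chosen <- c(chosen, c_i)
  }
  if (length(chosen) < n)
    stop("could not place ", n, " locations at the requested separation")
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  data.frame(id = ids, x = ctr[chosen, 1], y = ctr[chosen, 2],
             stringsAsFactors = FALSE)
}

#' Known-truth description of a synthetic study
#'
#' Bundles the generating resistance transformation, regression
#' coefficients and variance components used by the synthetic generators,
#' so recovery tests can close the loop against a recorded truth.
#'
#' @param spec a [transform_spec()] or [categorical_assignment()]
#'   describing the true resistance surface.
#' @param beta length-2 vector: intercept and slope on the standardized
#'   commute distance.
#' @param sigma2_node,sigma2_resid variance components of the MLPE
#'   generative model.
#' @param seed integer seed recorded for regeneration.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(spec, beta = c(0, 1), sigma2_node = 0.2,
                            sigma2_resid = 0.2, seed = 1L) {
  stopifnot(length(beta) == 2, sigma2_node >= 0, sigma2_resid >= 0)
  structure(list(spec = spec, beta = beta, sigma2_node = sigma2_node,
                 sigma2_resid = sigma2_resid, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Simulate genetic distances from the MLPE generative model
#'
#' Transforms the raw landscape with the true spec, computes commute
#' distances among the locations, standardizes them, and draws
#' `y_ij = b0 + b1 * commute_ij + u_i + u_j + e_ij` with the truth's
#' variance components. With both variances zero the output is an exact
#' affine function of commute distance.
#'
#' @param truth a [synthetic_truth()].
#' @param raster raw environmental [raster_surface()] (continuous).
#' @param locs data frame `id, x, y` of sampling locations.
#' @return A [pairwise_matrix()] tagged `"rousset_ar"` (a genetic
#'   dissimilarity).
#' @export
simulate_genetic_distances <- function(truth, raster, locs) {
  surf <- true_resistance(truth$spec, raster)
  gr <- conductance_graph(surf, connectivity = 8)
  cd <- commute_distance(gr, locs)
  set.seed(truth$seed)
  cz <- dyad_values(cd)
  z <- as.vector(scale(cz$value))
  n <- nrow(locs)
  u <- stats::rnorm(n, 0, sqrt(truth$sigma2_node))
  names(u) <- locs$id
  e <- stats::rnorm(length(z), 0, sqrt(truth$sigma2_resid))
  yv <- truth$beta[1] + truth$beta[2] * z + u[cz$id1] + u[cz$id2] + e
  m <- matrix(0, n, n, dimnames = list(locs$id, locs$id))
  m[cbind(match(cz$id1, locs$id), match(cz$id2, locs$id))] <- yv
  m <- m + t(m)
  pairwise_matrix(m, ids = locs$id, metric = "rousset_ar")
}

true_resistance <- function(spec, raster) {
  if (inherits(spec, "transform_spec")) {
    if (spec$family == "Distance") {
      flat <- raster
      flat$values[is.finite(flat$values)] <- 1
      flat
    } else apply_transform(rescale_surface(raster), spec)
  } else apply_categorical(raster, spec)
}

#' Simulate microsatellite genotypes structured by a resistance surface
#'
#' Site allele frequencies follow a logistic-normal model whose
#' between-site correlation decays exponentially with commute distance
#' through the true resistance surface
#' (`cor = exp(-commute_std / decay)`), so genetic differentiation
#' increases with resistance distance. Individuals are drawn as two
#' independent allele draws per locus from their site's frequencies.
#' Optional planted clone and parent-offspring dyads support relatedness
#' filtering tests.
#'
#' @param truth a [synthetic_truth()].
#' @param raster raw environmental [raster_surface()].
#' @param sites data frame `id, x, y` of site locations.
#' @param n_per_site individuals per site (recycled).
#' @param n_loci number of loci (>= 5).
#' @param n_alleles alleles per locus.
#' @param decay correlation-decay scale on the standardized commute
#'   distance; 0 disables structure (all sites share frequencies).
#' @param sd_site site-level logit standard deviation.
#' @param missing_rate per-genotype missing probability.
#' @param n_clone_pairs,n_po_pairs planted clone / parent-offspring dyads.
#' @param seed RNG seed.
#' @return A [genotype_table()] with locality set to the site id.
#' @export
simulate_genotypes <- function(truth, raster, sites, n_per_site = 4,
                               n_loci = 10, n_alleles = 8, decay = 0.5,
                               sd_site = 1, missing_rate = 0,
                               n_clone_pairs = 0, n_po_pairs = 0,
                               seed = 1L) {
  if (n_loci < 5) stop("need at least 5 loci")
  surf <- true_resistance(truth$spec, raster)
  gr <- conductance_graph(surf, connectivity = 8)
  cd <- commute_distance(gr, sites)
  S <- nrow(sites)
  cdm <- unclass(cd); diag(cdm) <- 0
  cdm <- cdm / stats::sd(cdm[upper.tri(cdm)])
  corr <- if (decay > 0) exp(-cdm / decay) else matrix(1, S, S)
  set.seed(seed)
  ch <- chol(corr + diag(1e-8, S))
  n_per_site <- rep_len(n_per_site, S)
  n <- sum(n_per_site)
  site_of <- rep(seq_len(S), n_per_site)
  arr <- array(NA_integer_, dim = c(n, n_loci, 2L),
               dimnames = list(NULL, paste0("L", seq_len(n_loci)), NULL))
  for (l in seq_len(n_loci)) {
    base <- stats::rnorm(n_alleles, 0, 1)
    dev <- t(ch) %*% matrix(stats::rnorm(S * n_alleles, 0, sd_site),
                            S, n_alleles)
    logits <- sweep(dev, 2, base, `+`)
    fr <- exp(logits)
    fr <- fr / rowSums(fr)
    for (s in seq_len(S)) {
      members <- which(site_of == s)
      draws <- sample.int(n_alleles, 2L * length(members), replace = TRUE,
                          prob = fr[s, ])
      arr[members, l, 1] <- draws[seq_along(members)]
      arr[members, l, 2] <- draws[length(members) + seq_along(members)]
    }
  }
  ids <- paste0(sites$id[site_of], "_", stats::ave(site_of, site_of,
                                                   FUN = seq_along))
  coords <- as.matrix(sites[site_of, c("x", "y")])
  locality <- sites$id[site_of]

  add_relative <- function(kind, idx) {
    donor <- sample.int(length(ids), 1L)
    newg <- arr[donor, , , drop = FALSE]
    if (kind == "po") {
      s <- site_of[donor]
      for (l in seq_len(n_loci)) {
        keep_copy <- sample(1:2, 1L)
        inherited <- arr[donor, l, keep_copy]
        other <- sample(arr[site_of == s, l, ], 1L)
        newg[1, l, ] <- c(inherited, other)
      }
    }
    arr <<- abind3(arr, newg)
    ids <<- c(ids, paste0(ids[donor],
                          if (kind == "clone") "_cl" else "_off", idx))
    coords <<- rbind(coords, coords[donor, ])
    locality <<- c(locality, locality[donor])
    site_of <<- c(site_of, site_of[donor])
  }
  for (k in seq_len(n_clone_pairs)) add_relative("clone", k)
  for (k in seq_len(n_po_pairs)) add_relative("po", k)

  if (missing_rate > 0) {
    drop <- matrix(stats::runif(nrow(arr) * n_loci) < missing_rate,
                   nrow(arr), n_loci)
    # keep at least one typed locus per individual
    full_rows <- rowSums(drop) >= n_loci
    drop[full_rows, 1] <- FALSE
    arr[, , 1][drop] <- NA_integer_
    arr[, , 2][drop] <- NA_integer_
  }
  genotype_table(ids, arr, locality = locality, coords = coords)
}

abind3 <- function(a, b) {
  out <- array(NA_integer_, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], 2L),
               dimnames = list(NULL, dimnames(a)[[2]], NULL))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Simulate a gravity network with known effects
#'
#' Generates sites with log-normal attributes, a saturated directed dyad
#' network among `n_sites * per_site` individuals, and a log response
#' `log(Dps) = b0 + b_dist * log(distance) + sum b_a * log(attr_dest) +
#' u_from + e` with normal origin effects and residuals. The response is
#' truncated at 1 (Dps is a proportion).
#'
#' @param n_sites,per_site network size.
#' @param true_beta named coefficients: `intercept`, `distance`, and any
#'   attribute names (attributes are generated for those names).
#' @param sigma2_origin,sigma2_resid variance components.
#' @param extent square landscape extent in meters.
#' @param seed RNG seed.
#' @return A `gravity_network` (see [build_gravity_network()]) with the
#'   truth stored in `attr(net, "truth")`.
#' @export
simulate_gravity_network <- function(n_sites = 15, per_site = 4,
                                     true_beta = c(intercept = -0.7,
                                                   distance = -0.03,
                                                   ivi = 0.09),
                                     sigma2_origin = 0.1,
                                     sigma2_resid = 0.05,
                                     extent = 30000, seed = 1L) {
  stopifnot(all(c("intercept", "distance") %in% names(true_beta)))
  set.seed(seed)
  attr_names <- setdiff(names(true_beta), c("intercept", "distance"))
  sites <- data.frame(site = paste0("S", seq_len(n_sites)),
                      x = stats::runif(n_sites, 0, extent),
                      y = stats::runif(n_sites, 0, extent))
  sa <- sites["site"]
  for (an in attr_names)
    sa[[an]] <- stats::rlnorm(n_sites, meanlog = 0, sdlog = 0.5)
  n <- n_sites * per_site
  nd <- data.frame(id = paste0("I", seq_len(n)),
                   site = rep(sites$site, each = per_site),
                   x = rep(sites$x, each = per_site) +
                     stats::runif(n, -200, 200),
                   y = rep(sites$y, each = per_site) +
                     stats::runif(n, -200, 200))
  u <- stats::rnorm(n, 0, sqrt(sigma2_origin))
  names(u) <- nd$id
  pairs <- expand.grid(to = seq_len(n), from = seq_len(n))[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, ]
  dist_ij <- sqrt((nd$x[pairs$from] - nd$x[pairs$to])^2 +
                    (nd$y[pairs$from] - nd$y[pairs$to])^2)
  lp <- true_beta[["intercept"]] +
    true_beta[["distance"]] * log(dist_ij)
  for (an in attr_names)
    lp <- lp + true_beta[[an]] * log(sa[[an]][match(nd$site[pairs$to],
                                                    sa$site)])
  ly <- lp + u[nd$id[pairs$from]] +
    stats::rnorm(length(lp), 0, sqrt(sigma2_resid))
  dps_v <- pmin(exp(ly), 1)
  # assemble as a symmetric-enough response: keep directed values in a
  # matrix-free network laid out like build_gravity_network()
  net <- data.frame(
    from = nd$id[pairs$from], to = nd$id[pairs$to],
    from_site = nd$site[pairs$from], to_site = nd$site[pairs$to],
    distance = dist_ij, dps = dps_v, stringsAsFactors = FALSE)
  dest_attr <- sa[match(net$to_site, sa$site), attr_names, drop = FALSE]
  rownames(dest_attr) <- NULL
  net <- cbind(net, dest_attr)
  out <- structure(net, class = c("gravity_network", "data.frame"),
                   attr_cols = attr_names, resistance_cols = character(0))
  attr(out, "truth") <- list(beta = true_beta,
                             sigma2_origin = sigma2_origin,
                             sigma2_resid = sigma2_resid, seed = seed,
                             sites = sa, nodes = nd)
  out
}
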