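test_that("landscapes are deterministic in the seed", {
  a <- make_landscape("smooth", 25, 25, seed = 5, range = 4)
  b <- make_landscape("smooth", 25, 25, seed = 5, range = 4)
  expect_identical(a, b)
  d1 <- make_landscape("dem", 25, 25, seed = 6)
  d2 <- make_landscape("dem", 25, 25, seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(a$values,
                         make_landscape("smooth", 25, 25, seed = 7,
                                        range = 4)$values))
})

test_that("longer smoothing ranges produce longer autocorrelation", {
  lag1_cor <- function(r) {
    v <- r$values
    stats::cor(as.vector(v[, -ncol(v)]), as.vector(v[, -1]))
  }
  short <- mean(sapply(1:4, function(s)
    lag1_cor(make_landscape("smooth", 40, 40, seed = s, range = 1))))
  long <- mean(sapply(1:4, function(s)
    lag1_cor(make_landscape("smooth", 40, 40, seed = s, range = 8))))
  expect_gt(long, short + 0.2)
})

test_that("categorical landscapes partition the grid into labeled classes", {
  r <- make_landscape("categorical", 30, 30, seed = 8, n_classes = 3)
  expect_setequal(unique(as.vector(r$values)), 1:3)
  expect_equal(attr(r, "levels"), paste0("class_", 1:3))
  # every cell belongs to exactly one class
  expect_false(anyNA(r$values))
})

test_that("zero-variance genetic distances are an exact affine function of commute", {
  land <- make_landscape("smooth", 25, 25, seed = 10, range = 5)
  locs <- sample_locations(land, 12, seed = 11, min_separation = 300)
  truth <- synthetic_truth(transform_spec("Monomolecular", 3, 100),
                           beta = c(0.5, 2), sigma2_node = 0,
                           sigma2_resid = 0, seed = 12)
  y <- simulate_genetic_distances(truth, land, locs)
  sf <- landres:::true_resistance(truth$spec, land)
  cd <- commute_distance(conductance_graph(sf), locs)
  yv <- dyad_values(y)$value
  cz <- as.vector(scale(dyad_values(cd)$value))
  expect_equal(yv, 0.5 + 2 * cz, tolerance = 1e-12)
  # and relabeling individuals permutes, never changes, the dyad values
  perm <- sample(locs$id)
  expect_equal(sort(dyad_values(pm_restrict(y, perm))$value), sort(yv),
               tolerance = 1e-12)
})

test_that("fitting the generative model recovers the planted slope", {
  land <- make_landscape("smooth", 25, 25, seed = 13, range = 5)
  locs <- sample_locations(land, 20, seed = 14, min_separation = 200)
  sf <- landres:::true_resistance(transform_spec("Monomolecular", 3, 100),
                                  land)
  cd <- commute_distance(conductance_graph(sf), locs)
  b1 <- sapply(1:25, function(r) {
    truth <- synthetic_truth(transform_spec("Monomolecular", 3, 100),
                             beta = c(0, 1), seed = 6000 + r)
    y <- simulate_genetic_distances(truth, land, locs)
    fit_mlpe(y, list(commute = cd))$beta[2]
  })
  expect_lt(abs(mean(b1) - 1), 3 * stats::sd(b1) / sqrt(length(b1)))
})

test_that("genotypes are seed-deterministic with the advertised block structure", {
  land <- make_landscape("smooth", 25, 25, seed = 15, range = 5)
  sites <- sample_locations(land, 8, seed = 16, min_separation = 300)
  truth <- synthetic_truth(transform_spec("Monomolecular", 3, 100),
                           seed = 17)
  g1 <- simulate_genotypes(truth, land, sites, n_per_site = 3, seed = 18)
  g2 <- simulate_genotypes(truth, land, sites, n_per_site = 3, seed = 18)
  expect_identical(g1$alleles, g2$alleles)
  expect_equal(n_individuals(g1), 24L)
  expect_equal(sort(unique(g1$locality)), sort(sites$id))

  # no-structure limit: between-site similarity matches within-site
  g0 <- simulate_genotypes(truth, land, sites, n_per_site = 4,
                           n_loci = 15, decay = 0, seed = 19)
  d0 <- dps(g0)
  same <- outer(g0$locality, g0$locality, "==")
  diag(same) <- NA
  gap <- mean(d0[same & !is.na(same)], na.rm = TRUE) -
    mean(d0[!same & !is.na(same)], na.rm = TRUE)
  expect_lt(abs(gap), 0.06)
})

test_that("structured genotypes show isolation by resistance via Mantel tests", {
  land <- make_landscape("smooth", 25, 25, seed = 20, range = 5)
  sites <- sample_locations(land, 10, seed = 21, min_separation = 300)
  truth <- synthetic_truth(transform_spec("Monomolecular", 3, 100),
                           seed = 22)
  sf <- landres:::true_resistance(truth$spec, land)
  positives <- 0L
  for (s in 1:5) {
    g <- simulate_genotypes(truth, land, sites, n_per_site = 4,
                            n_loci = 12, decay = 0.5, seed = 700 + s)
    ar <- rousset_ar(g)
    cd <- commute_distance(conductance_graph(sf),
                           data.frame(id = g$ids, x = g$coords[, 1],
                                      y = g$coords[, 2]))
    arm <- unclass(ar); diag(arm) <- 0
    cdm <- unclass(cd); diag(cdm) <- 0
    mt <- vegan::mantel(stats::as.dist(arm), stats::as.dist(cdm),
                        permutations = 199)
    if (mt$statistic > 0 && mt$signif < 0.05) positives <- positives + 1L
  }
  expect_gte(positives, 4L)
})

test_that("planted clones are detected and removed by the relatedness filter", {
  land <- make_landscape("smooth", 25, 25, seed = 23, range = 5)
  sites <- sample_locations(land, 8, seed = 24, min_separation = 300)
  truth <- synthetic_truth(transform_spec("Monomolecular", 3, 100),
                           seed = 25)
  g <- simulate_genotypes(truth, land, sites, n_per_site = 3, n_loci = 15,
                          n_clone_pairs = 2, seed = 26)
  r <- estimate_relatedness(g)
  clones <- grep("_cl", g$ids, value = TRUE)
  for (cl in clones) {
    donor <- sub("_cl[0-9]+$", "", cl)
    expect_gte(r[cl, donor], 0.95)
  }
  filt <- filter_related(g, r, 0.5)
  kept <- pm_restrict(r, filt$ids)
  expect_true(all(kept[upper.tri(kept)] <= 0.5))
  for (cl in clones) {
    donor <- sub("_cl[0-9]+$", "", cl)
    expect_equal(sum(c(cl, donor) %in% filt$ids), 1L)
  }
})

test_that("simulated gravity networks are reproducible with centered null effects", {
  n1 <- simulate_gravity_network(n_sites = 6, per_site = 2, seed = 30)
  n2 <- simulate_gravity_network(n_sites = 6, per_site = 2, seed = 30)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  # zero planted coefficients: fitted slopes near zero
  net0 <- simulate_gravity_network(
    n_sites = 10, per_site = 3,
    true_beta = c(intercept = -0.7, distance = 0, ivi = 0),
    sigma2_origin = 0.05, sigma2_resid = 0.05, seed = 31)
  f <- fit_gravity(net0, covariates = "ivi")
  cf <- f$coefficients
  for (tm in c("distance", "ivi"))
    expect_lt(abs(cf$beta[cf$term == tm]), 4 * cf$se[cf$term == tm])
})
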