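# Independent oracles and small fixture builders shared across tests.

# Build a genotype_table from a list of per-individual locus genotypes,
# e.g. toy_genotypes(A = list(c(1,1), c(1,2)), B = list(c(2,2), c(1,1)))
toy_genotypes <- function(..., coords = NULL, locality = NULL) {
  inds <- list(...)
  n <- length(inds)
  L <- length(inds[[1]])
  arr <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    gl <- inds[[i]][[l]]
    if (!is.null(gl)) arr[i, l, ] <- as.integer(gl)
  }
  genotype_table(names(inds), arr, coords = coords, locality = locality)
}

# Random genotype table: n individuals, L loci, K alleles per locus
random_genotypes <- function(n, L, K, seed, missing_rate = 0) {
  set.seed(seed)
  arr <- array(sample.int(K, n * L * 2, replace = TRUE), c(n, L, 2))
  if (missing_rate > 0) {
    drop <- matrix(runif(n * L) < missing_rate, n, L)
    drop[rowSums(drop) >= L, 1] <- FALSE
    arr[, , 1][drop] <- NA_integer_
    arr[, , 2][drop] <- NA_integer_
  }
  genotype_table(sprintf("I%02d", seq_len(n)), arr)
}

# Brute-force Rousset a-hat by direct enumeration of allele draws,
# written independently of the package implementation: Q_ij is the mean
# identity of the four cross-individual allele comparisons, Qw the mean
# homozygosity over individuals typed at the locus; multilocus values pool
# numerators and denominators before the ratio.
brute_force_rousset <- function(g) {
  n <- n_individuals(g)
  L <- n_loci(g)
  out <- matrix(NA_real_, n, n, dimnames = list(g$ids, g$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0; used <- FALSE
    for (l in seq_len(L)) {
      gi <- g$alleles[i, l, ]; gj <- g$alleles[j, l, ]
      if (anyNA(gi) || anyNA(gj)) next
      typed <- which(!is.na(g$alleles[, l, 1]))
      qw <- mean(sapply(typed, function(m)
        g$alleles[m, l, 1] == g$alleles[m, l, 2]))
      qij <- mean(c(gi[1] == gj[1], gi[1] == gj[2],
                    gi[2] == gj[1], gi[2] == gj[2]))
      num <- num + (qw - qij)
      den <- den + (1 - qw)
      used <- TRUE
    }
    if (used && den > 0) out[i, j] <- out[j, i] <- num / den
  }
  out
}

# Monte-Carlo commute-time oracle: average round-trip steps of a weighted
# random walk from node a to node b and back, on a conductance_graph.
random_walk_commute <- function(graph, a, b, walks = 2000, seed = 1) {
  set.seed(seed)
  n <- graph$n
  nbr <- vector("list", n)
  wt <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]; w <- graph$edges$w[k]
    nbr[[i]] <- c(nbr[[i]], j); wt[[i]] <- c(wt[[i]], w)
    nbr[[j]] <- c(nbr[[j]], i); wt[[j]] <- c(wt[[j]], w)
  }
  one <- function() {
    steps <- 0L
    cur <- a
    target <- b
    repeat {
      cur <- sample(nbr[[cur]], 1L, prob = wt[[cur]])
      steps <- steps + 1L
      if (cur == target) {
        if (target == a) return(steps)
        target <- a
      }
    }
  }
  vals <- replicate(walks, one())
  c(mean = mean(vals), se = sd(vals) / sqrt(walks))
}

# Random connected conductance graph (as a raster so the package path is
# exercised), for triangle-inequality style property checks.
random_resistance_raster <- function(nr, nc, seed, max_resistance = 20) {
  set.seed(seed)
  raster_surface(matrix(runif(nr * nc, 1, max_resistance), nr, nc))
}

# lme4 oracle for the MLPE model: lmer with the random-effects design
# replaced by the dyad incidence matrix (each dyad loads on both members).
lme4_mlpe <- function(yv, xv, id1, id2, ids, reml = FALSE) {
  p <- length(yv)
  n <- length(ids)
  d <- data.frame(y = yv, x = xv,
                  p1 = factor(rep(ids, length.out = p), levels = ids))
  ctl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                           check.nobs.vs.nRE = "ignore")
  Zt <- Matrix::sparseMatrix(i = c(match(id1, ids), match(id2, ids)),
                             j = rep(seq_len(p), 2), x = 1,
                             dims = c(n, p))
  lmod <- lme4::lFormula(y ~ x + (1 | p1), data = d, REML = reml,
                         control = ctl)
  lmod$reTrms$Zt <- Zt
  lmod$reTrms$Ztlist[[1]] <- Zt
  devfun <- do.call(lme4::mkLmerDevfun, lmod)
  opt <- lme4::optimizeLmer(devfun)
  lme4::mkMerMod(environment(devfun), opt, lmod$reTrms, fr = lmod$fr)
}

# Symmetric pairwise_matrix from a dyad-value vector in canonical
# (lower-triangle) order.
pm_from_dyads <- function(values, ids, metric = "rousset_ar") {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- values
  m <- m + t(m)
  diag(m) <- NA
  pairwise_matrix(m, ids = ids, metric = metric)
}

# Random symmetric dyadic predictor
random_pm <- function(n, seed, metric = "resistance") {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n))
  pm_from_dyads(rnorm(n * (n - 1) / 2), ids, metric = metric)
}
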