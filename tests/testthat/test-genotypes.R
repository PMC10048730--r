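test_that("genotype CSV round-trips preserve alleles in both dialects", {
  g <- random_genotypes(12, 5, 6, seed = 1, missing_rate = 0.1)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, f1, allele_sep = "/")
  g1 <- read_genotypes(f1, allele_sep = "/", quiet = TRUE)
  expect_identical(g1$alleles, g$alleles)
  expect_identical(g1$ids, g$ids)

  # two-columns-per-locus dialect
  f2 <- withr::local_tempfile(fileext = ".csv")
  wide <- data.frame(id = g$ids)
  for (l in seq_len(n_loci(g))) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    wide[[paste0("L", l, ".1")]] <- ifelse(is.na(a1), "0", a1)
    wide[[paste0("L", l, ".2")]] <- ifelse(is.na(a2), "0", a2)
  }
  utils::write.csv(wide, f2, row.names = FALSE)
  g2 <- read_genotypes(f2, quiet = TRUE)
  expect_identical(g2$alleles, g$alleles)
})

test_that("missing codes are flagged as missing, not parsed as allele 0", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,locA,locB",
               "A,101/103,0/0",
               "B,103/103,98/100",
               "C,0,98/98"), f)
  g <- read_genotypes(f, allele_sep = "/", quiet = TRUE)
  expect_true(all(is.na(g$alleles["A" == g$ids, 2, ])))
  expect_true(all(is.na(g$alleles["C" == g$ids, 1, ])))
  expect_false(any(stats::na.omit(c(g$alleles)) == 0))
})

test_that("malformed tokens and duplicate ids raise informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,locA", "A,10x/12", "B,10/12"), f)
  expect_error(read_genotypes(f, allele_sep = "/", quiet = TRUE),
               "row 1.*locA")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,locA", "A,10/12", "A,10/12"), f2)
  expect_error(read_genotypes(f2, allele_sep = "/", quiet = TRUE),
               "duplicate")
})

test_that("Dps matches hand counts and stays within [0, 1]", {
  g <- toy_genotypes(X = list(c(1, 2)), Y = list(c(1, 1)))
  expect_equal(dps(g)["X", "Y"], 0.5)
  # identical multilocus genotypes share everything
  gi <- toy_genotypes(A = list(c(1, 2), c(3, 3)), B = list(c(1, 2), c(3, 3)))
  expect_equal(dps(gi)["A", "B"], 1)
  # fully disjoint alleles share nothing
  gd <- toy_genotypes(A = list(c(1, 2), c(3, 4)), B = list(c(5, 6), c(7, 8)))
  expect_equal(dps(gd)["A", "B"], 0)
  # bounds and symmetry on random tables with missing data
  for (s in 1:5) {
    gr <- random_genotypes(10, 6, 4, seed = s, missing_rate = 0.15)
    d <- dps(gr)
    off <- d[upper.tri(d)]
    expect_true(all(off[is.finite(off)] >= 0 & off[is.finite(off)] <= 1))
    expect_equal(unclass(d), t(unclass(d)))
  }
})

test_that("Rousset's a-hat reproduces enumerated toy values", {
  g <- toy_genotypes(A = list(c(1, 1)), B = list(c(2, 2)), C = list(c(1, 2)))
  ar <- rousset_ar(g)
  expect_equal(ar["A", "B"], 2.0)
  expect_equal(ar["A", "C"], 0.5)
})

test_that("Rousset's a-hat agrees with brute-force enumeration on random toys", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:6, 1)
    L <- sample(1:3, 1)
    g <- random_genotypes(n, L, 3, seed = s + 100,
                          missing_rate = if (s %% 2) 0 else 0.2)
    ref <- try(brute_force_rousset(g), silent = TRUE)
    got <- try(rousset_ar(g), silent = TRUE)
    if (inherits(ref, "try-error") || inherits(got, "try-error")) next
    expect_equal(unclass(got), ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("Rousset's a-hat is invariant to allele relabeling", {
  g <- random_genotypes(8, 4, 4, seed = 3)
  perm <- c(3L, 1L, 4L, 2L)
  arr2 <- g$alleles
  arr2[] <- perm[arr2]
  g2 <- genotype_table(g$ids, arr2)
  expect_equal(unclass(rousset_ar(g)), unclass(rousset_ar(g2)),
               tolerance = 1e-12)
})

test_that("relatedness hits the clone limit and separates PO from unrelated", {
  # clones at many polymorphic loci
  set.seed(5)
  L <- 20; K <- 8
  arr <- array(sample.int(K, 25 * L * 2, replace = TRUE), c(25, L, 2))
  arr[2, , ] <- arr[1, , ]
  g <- genotype_table(sprintf("I%02d", 1:25), arr)
  r <- estimate_relatedness(g)
  expect_gte(r[1, 2], 0.99)
  expect_true(all(r[upper.tri(r)] >= 0 & r[upper.tri(r)] <= 1))

  # Mendelian oracle: parent-offspring dyads average r = 0.5, unrelated 0;
  # known equifrequent allele frequencies are supplied directly
  freqs <- rep(list(stats::setNames(rep(1 / K, K), as.character(1:K))), L)
  sim_dyad <- function(kind) {
    a <- array(NA_integer_, c(2, L, 2))
    for (l in seq_len(L)) {
      p1 <- sample.int(K, 2, replace = TRUE)
      p2 <- if (kind == "po") c(sample(p1, 1), sample.int(K, 1))
            else sample.int(K, 2, replace = TRUE)
      a[1, l, ] <- p1; a[2, l, ] <- p2
    }
    g <- genotype_table(c("P", "Q"), a)
    estimate_relatedness(g, freqs = freqs)[1, 2]
  }
  set.seed(11)
  po <- replicate(200, sim_dyad("po"))
  ur <- replicate(200, sim_dyad("ur"))
  expect_lt(abs(mean(po) - 0.5), 3 * sd(po) / sqrt(200) + 0.01)
  expect_lt(mean(ur), 0.05)
})

test_that("relatedness errors on fully monomorphic data", {
  arr <- array(1L, c(4, 5, 2))
  g <- genotype_table(c("A", "B", "C", "D"), arr)
  expect_error(estimate_relatedness(g), "monomorphic")
})

test_that("filter_related removes exactly the above-threshold structure", {
  g3 <- random_genotypes(3, 5, 4, seed = 9)
  ids <- g3$ids
  # single dyad above threshold: exactly one member goes
  r <- pm_from_dyads(c(0.6, 0.1, 0.1), ids, metric = "relatedness_r")
  out <- filter_related(g3, r, 0.5)
  expect_equal(n_individuals(out), 2L)
  expect_true(ids[3] %in% out$ids)
  expect_true(sum(ids[1:2] %in% out$ids) == 1L)

  # nothing above threshold, including a dyad exactly at it: unchanged
  r0 <- pm_from_dyads(c(0.5, 0.2, 0.3), ids, metric = "relatedness_r")
  expect_identical(filter_related(g3, r0, 0.5)$ids, ids)

  # property: output of random instances never contains an above-threshold
  # dyad (exhaustive scan), at several thresholds
  g8 <- random_genotypes(8, 5, 4, seed = 10)
  for (s in 1:10) {
    set.seed(s)
    rv <- runif(8 * 7 / 2)
    rr <- pm_from_dyads(rv, g8$ids, metric = "relatedness_r")
    thr <- runif(1)
    out <- filter_related(g8, rr, thr)
    sub <- pm_restrict(rr, out$ids)
    expect_true(all(sub[upper.tri(sub)] <= thr))
  }
})
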