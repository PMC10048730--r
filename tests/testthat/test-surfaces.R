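test_that("rescale_surface maps onto [0, 10] and rejects constants", {
  r <- raster_surface(matrix(c(0, 5, 10, 2, 7, 9), 2, 3))
  expect_equal(rescale_surface(r)$values, r$values)
  r2 <- raster_surface(matrix(c(100, 300, 100, 300), 2, 2))
  expect_equal(sort(unique(as.vector(rescale_surface(r2)$values))), c(0, 10))
  for (s in 1:5) {
    rr <- raster_surface(matrix(rnorm(64, s * 10, 3), 8, 8))
    v <- rescale_surface(rr)$values
    expect_equal(range(v), c(0, 10))
  }
  expect_error(rescale_surface(raster_surface(matrix(4, 5, 5))),
               "constant")
  # missing cells are preserved
  rm_ <- raster_surface(matrix(c(1, 2, NA, 4), 2, 2))
  expect_true(is.na(rescale_surface(rm_)$values[1, 2]))
})

test_that("every transformation family lands exactly on [1, maximum]", {
  r <- raster_surface(matrix(seq(0, 10, length.out = 144), 12, 12))
  for (fam in setdiff(transform_families(), "Distance")) {
    for (shape in c(0.5, 3, 20)) {
      s <- apply_transform(r, transform_spec(fam, shape, 250))
      expect_equal(min(s$values), 1)
      expect_equal(max(s$values), 250)
    }
  }
  d <- apply_transform(r, transform_spec("Distance"))
  expect_true(all(d$values == 1))
})

test_that("the Ricker curve peaks at x = shape", {
  x <- seq(0, 10, 0.0005)
  for (shape in c(1.5, 2.606, 5)) {
    g <- x * exp(-x / shape)
    expect_equal(x[which.max(g)], shape, tolerance = 1e-3)
  }
})

test_that("Inverse Ricker resistance is high at both extremes, low near the peak", {
  x <- seq(0, 10, length.out = 101)
  r <- raster_surface(matrix(x, 1, 101))
  s <- apply_transform(r, transform_spec("Inverse Ricker", 2.606, 3490.174))
  v <- s$values[1, ]
  peak_idx <- which.min(abs(x - 2.606))
  expect_equal(v[peak_idx], 1, tolerance = 1e-6)
  expect_equal(v[1], max(v))           # flattest terrain: highest resistance
  expect_gt(v[101], 0.5 * 3490.174)    # most rugged terrain: high again
  expect_gt(min(v[c(1, 101)]), max(v[(peak_idx - 2):(peak_idx + 2)]))
})

test_that("monotone families are monotone and reflections compose to identity", {
  x <- seq(0, 10, length.out = 50)
  r <- raster_surface(matrix(x, 1, 50))
  mono <- apply_transform(r, transform_spec("Monomolecular", 3, 100))$values[1, ]
  expect_true(all(diff(mono) > 0))
  rev_mono <- apply_transform(r, transform_spec("Reverse Monomolecular",
                                                3, 100))$values[1, ]
  expect_true(all(diff(rev_mono) < 0))
  # Reverse o Reverse on the [0,10] axis is the identity of the base curve
  expect_equal(rev_mono, rev(mono), tolerance = 1e-9)
  # Inverse o Inverse is the identity after the final rescale
  inv <- apply_transform(r, transform_spec("Inverse Monomolecular",
                                           3, 100))$values[1, ]
  inv_of_inv <- 1 + (100 - 1) * (max(inv) - inv) / (max(inv) - min(inv))
  expect_equal(inv_of_inv, mono, tolerance = 1e-9)
})

test_that("transform specs validate and round-trip through JSON", {
  expect_error(transform_spec("Monomolecular", -1, 10), "shape")
  expect_error(transform_spec("Monomolecular", 2, 0.5), "maximum")
  expect_error(transform_spec("NotAFamily", 2, 10))
  f <- withr::local_tempfile(fileext = ".json")
  sp <- transform_spec("Inverse Ricker", 2.606, 3490.174)
  write_transform_spec(sp, f)
  sp2 <- read_transform_spec(f)
  expect_equal(sp2, sp)
})

test_that("categorical assignment is a validated bijective lookup", {
  r <- raster_surface(matrix(c(1, 2, 1, 2, 1, 2), 2, 3))
  attr(r, "levels") <- c("Forest", "Matrix")
  a <- categorical_assignment(c(Forest = 1, Matrix = 12.740))
  s <- apply_categorical(r, a)
  expect_equal(s$values[r$values == 1], rep(1, 3))
  expect_equal(s$values[r$values == 2], rep(12.740, 3))
  # the matrix class is more resistant than forest, and the mapping is a
  # bijection on the classes present
  expect_gt(mean(s$values[r$values == 2]), mean(s$values[r$values == 1]))
  expect_equal(length(unique(as.vector(s$values))),
               length(unique(as.vector(r$values))))

  uni <- apply_categorical(r, categorical_assignment(c(Forest = 1,
                                                       Matrix = 1)))
  expect_true(all(uni$values == 1))

  expect_error(categorical_assignment(c(Forest = 2, Matrix = 3)),
               "reference")
  expect_error(categorical_assignment(c(Forest = 1, Matrix = 9999)),
               "bound")
  expect_error(apply_categorical(r, categorical_assignment(c(Forest = 1))),
               "Matrix")
})

test_that("composites sum cell-wise and re-anchor their minimum at 1", {
  r <- raster_surface(matrix(seq(0, 10, length.out = 100), 10, 10))
  s1 <- apply_transform(r, transform_spec("Monomolecular", 3, 50))
  expect_equal(combine_surfaces(list(s1))$values, s1$values)

  u <- raster_surface(matrix(1, 10, 10))
  expect_true(all(combine_surfaces(list(u, u))$values == 1))

  # a flat ("Distance") component leaves the composite ordering identical
  # to the other component alone
  flat <- apply_transform(r, transform_spec("Distance"))
  comp <- combine_surfaces(list(s1, flat))
  expect_equal(order(comp$values), order(s1$values))
  expect_equal(comp$values, s1$values)
})
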