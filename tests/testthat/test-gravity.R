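test_that("the saturated network enumerates ordered dyads with shared site conditions", {
  nodes <- data.frame(id = c("a", "b", "c"), site = c("S1", "S1", "S2"),
                      x = c(0, 10, 1000), y = c(0, 10, 0))
  attrs <- data.frame(site = c("S1", "S2"), ivi = c(2, 5), ndvi = c(0.8, 0.6))
  dmat <- pm_from_dyads(c(0.9, 0.5, 0.4), nodes$id, metric = "dps")
  net <- build_gravity_network(nodes, attrs, dmat)
  expect_equal(nrow(net), 3 * 2)
  # all dyads into the same destination site share its attributes
  expect_true(all(net$ivi[net$to_site == "S1"] == 2))
  expect_true(all(net$ivi[net$to_site == "S2"] == 5))
  # distance is symmetric across the two directions of a dyad
  ab <- net$distance[net$from == "a" & net$to == "b"]
  ba <- net$distance[net$from == "b" & net$to == "a"]
  expect_equal(ab, ba)
  expect_error(build_gravity_network(nodes,
                                     attrs[attrs$site == "S1", ], dmat),
               "S2")
})

test_that("gravity networks round-trip through CSV", {
  net <- simulate_gravity_network(n_sites = 4, per_site = 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(net), f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$dps, net$dps, tolerance = 1e-12)
  expect_identical(back$from, net$from)
  expect_identical(back$to, net$to)
})

test_that("the gravity AIC convention matches its closed form", {
  expect_equal(gravity_aic(722.129, 5), 2 * 5 - 2 * 722.129)
  net <- simulate_gravity_network(n_sites = 6, per_site = 2,
                                  true_beta = c(intercept = -0.7,
                                                distance = -0.03,
                                                ivi = 0.09), seed = 6)
  fibd <- fit_gravity(net)
  fivi <- fit_gravity(net, covariates = "ivi")
  # IBD: intercept + distance + 2 variance components
  expect_equal(fibd$k_eff, 4L)
  expect_equal(fivi$k_eff, 5L)
  expect_equal(fibd$aic, 2 * 4 - 2 * fibd$logL)
  expect_equal(fivi$aic, 2 * 5 - 2 * fivi$logL)
})

test_that("gravity fits recover planted effects with the right signs", {
  net <- simulate_gravity_network(
    n_sites = 12, per_site = 4,
    true_beta = c(intercept = -0.7, distance = -0.03, ivi = 0.09),
    sigma2_origin = 0.1, sigma2_resid = 0.05, seed = 7)
  f <- fit_gravity(net, covariates = "ivi")
  cf <- f$coefficients
  b_dist <- cf$beta[cf$term == "distance"]
  b_ivi <- cf$beta[cf$term == "ivi"]
  expect_lt(b_dist, 0)
  expect_gt(b_ivi, 0)
  expect_lt(abs(b_dist - (-0.03)),
            3 * cf$se[cf$term == "distance"] + 0.01)
  expect_lt(abs(b_ivi - 0.09), 3 * cf$se[cf$term == "ivi"] + 0.01)
  # zero planted effect: estimate centered near zero
  net0 <- simulate_gravity_network(
    n_sites = 12, per_site = 4,
    true_beta = c(intercept = -0.7, distance = -0.03, ivi = 0),
    sigma2_origin = 0.05, sigma2_resid = 0.05, seed = 8)
  f0 <- fit_gravity(net0, covariates = "ivi")
  cf0 <- f0$coefficients
  expect_lt(abs(cf0$beta[cf0$term == "ivi"]),
            4 * cf0$se[cf0$term == "ivi"])
})

test_that("without origin variance the mixed fit collapses to dyad regression", {
  net <- simulate_gravity_network(
    n_sites = 10, per_site = 3,
    true_beta = c(intercept = -0.7, distance = -0.03, ivi = 0.09),
    sigma2_origin = 0, sigma2_resid = 0.05, seed = 9)
  f <- suppressMessages(fit_gravity(net, covariates = "ivi"))
  v_origin <- as.numeric(lme4::VarCorr(f$model)$from)
  ols <- stats::lm(log(dps) ~ log(distance) + log(ivi),
                   data = as.data.frame(net))
  if (v_origin < 1e-10) {
    expect_equal(unname(f$coefficients$beta), unname(stats::coef(ols)),
                 tolerance = 1e-6)
  } else {
    expect_equal(unname(f$coefficients$beta), unname(stats::coef(ols)),
                 tolerance = 0.05)
  }
})

test_that("model tables rank resistance-aware models above the IBD null on planted truth", {
  # genetic structure driven by a resistance distance, not raw distance
  set.seed(20)
  n <- 30
  ids <- sprintf("I%02d", seq_len(n))
  nodes <- data.frame(id = ids, site = paste0("S", rep(1:10, each = 3)),
                      x = runif(n, 0, 2e4), y = runif(n, 0, 2e4))
  attrs <- data.frame(site = paste0("S", 1:10),
                      ivi = rlnorm(10, 0, 0.4))
  res <- random_pm(n, seed = 21)
  res_pos <- pm_from_dyads(exp(dyad_values(res)$value), ids,
                           metric = "resistance")
  lr <- dyad_values(res_pos)$value
  ly <- -0.6 - 0.25 * log(lr) + rnorm(length(lr), 0, 0.15)
  dmat <- pm_from_dyads(pmin(exp(ly), 1), ids, metric = "dps")
  net <- build_gravity_network(nodes, attrs, dmat,
                               resistances = list(res = res_pos))
  tab <- gravity_model_table(net, list(IBD = character(0), RES = "res"))
  expect_equal(tab$model[1], "RES")
  expect_gt(tab$logL[tab$model == "RES"], tab$logL[tab$model == "IBD"])
  # nested ML comparison respects the ordering too
  tab_ml <- gravity_model_table(net, list(IBD = character(0), RES = "res"),
                                ml = TRUE)
  expect_gte(tab_ml$logL[tab_ml$model == "RES"],
             tab_ml$logL[tab_ml$model == "IBD"])
})
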