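test_that("Dirichlet variance law matches closed form and simulation", {
  expect_equal(dirichlet_variance(0, 100), 0)
  expect_equal(dirichlet_variance(1, 100), 0)
  expect_equal(dirichlet_variance(0.5, 99), 0.0025)
  set.seed(12)
  draws <- pppmfa:::rdirichlet(1e6, 99 * c(0.5, 0.5))
  expect_equal(stats::var(draws[, 1]) / 0.0025, 1, tolerance = 0.05)
  # normalization induces negative pairwise correlation
  d3 <- pppmfa:::rdirichlet(1e4, 200 * c(0.5, 0.3, 0.2))
  cv <- stats::cov(d3)
  expect_true(all(cv[upper.tri(cv)] < 0))
})

test_that("Dirichlet log-likelihood peaks where predicted equals measured", {
  measured <- c(0.5, 0.3, 0.2)
  nc <- 200
  # grid search over the 3-simplex
  step <- 0.05
  grid <- expand.grid(p1 = seq(step, 1 - step, step),
                      p2 = seq(step, 1 - step, step))
  grid <- grid[grid$p1 + grid$p2 < 1 - step / 2, ]
  ll <- apply(grid, 1, function(g)
    mfa_loglik(measured, c(g[1], g[2], 1 - g[1] - g[2]), nc))
  best <- grid[which.max(ll), ]
  expect_equal(unname(unlist(best)), c(0.5, 0.3), tolerance = 1e-9)
  # concentration sharpens the self-likelihood
  lls <- vapply(c(10, 100, 1000, 10000), function(nc)
    mfa_loglik(measured, measured, nc), 0)
  expect_true(all(diff(lls) > 0))
  expect_error(mfa_loglik(measured, measured[1:2], nc), "equal length")
})

test_that("split-Rhat and ESS react to stationarity and autocorrelation", {
  set.seed(33)
  x <- stats::rnorm(600)
  expect_lt(pppmfa:::split_rhat(list(x, x + stats::rnorm(600, 0, 1e-3))),
            1.02)
  drifting <- list(stats::rnorm(600), stats::rnorm(600) + 4)
  expect_gt(pppmfa:::split_rhat(drifting), 1.5)
  iid <- replicate(2, stats::rnorm(500), simplify = FALSE)
  expect_gt(pppmfa:::ess_acf(iid), 500)
  ar <- replicate(2, as.numeric(stats::arima.sim(list(ar = 0.95), 500)),
                  simplify = FALSE)
  expect_lt(pppmfa:::ess_acf(ar), 300)
})

test_that("pairwise regions report correlation and flag degeneracy", {
  set.seed(44)
  fake <- structure(list(flux_draws = cbind(a = stats::rnorm(2000),
                                            b = stats::rnorm(2000))),
                    class = "mfa_fit")
  reg <- pairwise_region(fake, "a", "b")
  expect_lt(abs(reg$correlation), 0.1)
  expect_false(reg$degenerate)
  expect_equal(reg$axes[1] / reg$axes[2], 1, tolerance = 0.2)
  a <- stats::rnorm(500)
  fake2 <- structure(list(flux_draws = cbind(a = a, b = 2 * a)),
                     class = "mfa_fit")
  reg2 <- pairwise_region(fake2, "a", "b")
  expect_true(reg2$degenerate)
  expect_equal(reg2$correlation, 1, tolerance = 1e-9)
})

test_that("a triose-only fit is wide but reproducible with honest summaries", {
  truth <- fixture_truth()
  sc <- scenario_suite()[["i_3PG"]]
  data <- generate_scenario_data(truth, sc, seed = 101)
  cfg <- quick_config(warmup = 120, iter = 150, seed = 3)
  fit1 <- mfa_fit(data, ppp_network(), config = cfg)
  fit2 <- mfa_fit(data, ppp_network(), config = cfg)
  expect_equal(fit1$flux_draws, fit2$flux_draws)
  expect_lt(max(fit1$rhat, na.rm = TRUE), 1.1)
  s <- summary(fit1)
  # triose data alone leave the transaldolase flux poorly determined
  expect_gt(s$sd[s$flux == "dTAL"], 1)
  # summaries are computed on the draws, not transformed summaries
  z3 <- fit1$flux_draws[, "Z3"]
  expect_equal(s$mean[s$flux == "Z3"], mean(z3))
  expect_equal(s$ci2.5[s$flux == "Z3"],
               unname(stats::quantile(z3, 0.025, names = FALSE)))
  expect_equal(s$median[s$flux == "QR"],
               unname(stats::median(fit1$flux_draws[, "QR"])))
  # interval nesting
  expect_true(all(s$ci2.5 <= s$ci68_low & s$ci68_high <= s$ci97.5))
  # every stored draw is feasible and balanced
  S <- stoichiometric_matrix(ppp_network())
  expect_true(all(fit1$flux_draws[, c("Z3", "Q4", "Q11")] >= 0))
  res <- fit1$flux_draws[, colnames(S)] %*% t(S)
  expect_lt(max(abs(res)), 1e-9)
})

test_that("posterior intervals contract as measurement precision grows", {
  truth <- fixture_truth()
  frg <- mfa_fragments()
  ids <- vapply(seq_len(nrow(frg)), function(i) fragment_id(frg[i, ]), "")
  frg <- frg[ids %in% c("3PG C1-C3", "G6P C3-C6"), ]
  widths68 <- widths95 <- sds <- numeric(0)
  for (nc in c(500, 5000, 50000)) {
    data <- generate_measurements(truth, fragments = frg, nc = nc,
                                  seed = 202)
    fit <- suppressWarnings(
      mfa_fit(data, ppp_network(),
              config = quick_config(warmup = 80, iter = 110, seed = 5)))
    s <- summary(fit)
    r <- s[s$flux == "dTAL", ]
    widths68 <- c(widths68, r$ci68_high - r$ci68_low)
    widths95 <- c(widths95, r$ci97.5 - r$ci2.5)
    sds <- c(sds, r$sd)
  }
  expect_true(all(diff(widths68) < 0))
  expect_true(all(diff(widths95) < 0))
  # near-exact data sharpen the transaldolase flux at least five-fold
  expect_gt(sds[1] / sds[3], 5)
})

test_that("precision calibration recovers the generating NC", {
  truth <- fixture_truth()
  frg <- mfa_fragments()
  ids <- vapply(seq_len(nrow(frg)), function(i) fragment_id(frg[i, ]), "")
  frg <- frg[ids %in% c("3PG C1-C3", "DHAP C1-C3"), ]
  data <- generate_measurements(truth, fragments = frg, nc = 2000,
                                seed = 303)
  data$nc <- 400                       # deliberately misstated precision
  out <- suppressWarnings(
    calibrate_precision(data, ppp_network(),
                        config = quick_config(warmup = 250, iter = 300,
                                              seed = 8, sampler = "am"),
                        max_iter = 3))
  expect_true(all(out$nc > 1000 & out$nc < 4000))
  # exact data make the iteration diverge until it hits the cap and warns
  exact <- generate_measurements(truth, fragments = frg, nc = 1e9,
                                 seed = 304)
  exact$nc <- 5000
  expect_warning(
    calibrate_precision(exact, ppp_network(),
                        config = quick_config(warmup = 150, iter = 200,
                                              seed = 9, sampler = "am"),
                        max_iter = 4, nc_cap = 2e4),
    "cap")
})

test_that("68% intervals cover the generating transaldolase flux", {
  truth <- fixture_truth()
  frg <- mfa_fragments()
  ids <- vapply(seq_len(nrow(frg)), function(i) fragment_id(frg[i, ]), "")
  frg <- frg[ids %in% c("3PG C1-C3", "G6P C3-C6"), ]
  hits <- 0L
  n_rep <- 50L
  for (rep in seq_len(n_rep)) {
    data <- generate_measurements(truth, fragments = frg, nc = 5000,
                                  seed = 5000 + rep)
    fit <- suppressWarnings(
      mfa_fit(data, ppp_network(),
              config = quick_config(warmup = 45, iter = 65,
                                    seed = 600 + rep, init_tries = 30,
                                    init_optim = 40, walkers = 20)))
    s <- summary(fit)
    r <- s[s$flux == "dTAL", ]
    if (r$ci68_low <= 5 && 5 <= r$ci68_high) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.55)
  expect_lte(hits / n_rep, 0.80)
})
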