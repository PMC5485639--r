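test_that("distance-function design normalizes outputs correctly", {
  tab <- survey_table(
    data.frame(milk_yield = 1, milk = c(3, 2, 5, 4, 6, 3, 2, 4),
               land = c(2, 1, 3, 2, 5, 1, 2, 3),
               herd = c(4, 2, 6, 3, 2, 1, 5, 2)),
    outputs = "milk", inputs = c("land", "herd"))
  d <- frontier_design(tab, outputs = "milk", inputs = c("land", "herd"))
  expect_equal(ncol(d$X), 3L)  # intercept + two log inputs
  expect_equal(d$r, -log(tab$milk))
  expect_equal(unname(d$X[1, ]), c(1, log(2), log(4)))

  # hand-worked multi-output row: x = (2, 4), y = (3, 6), normalize y2
  tab2 <- survey_table(
    data.frame(milk_yield = 1, y1 = 3, y2 = 6, x1 = 2, x2 = 4)[rep(1, 8), ],
    outputs = c("y2", "y1"), inputs = c("x1", "x2"))
  d2 <- frontier_design(tab2, outputs = c("y2", "y1"),
                        inputs = c("x1", "x2"), normalize = "y2")
  expect_equal(d2$r[1], -log(6))
  expect_equal(unname(d2$X[1, ]), c(1, log(2), log(4), log(3 / 6)))

  # zero outputs are outside the log domain and dropped with a count
  tab3 <- survey_table(
    data.frame(milk_yield = 1, milk = c(0, 2:9), land = 1:9, herd = 2:10),
    outputs = "milk", inputs = c("land", "herd"))
  d3 <- frontier_design(tab3, "milk", c("land", "herd"))
  expect_equal(d3$dropped, 1L)
  expect_equal(length(d3$r), 8L)

  expect_error(
    frontier_design(tab2[1:4, ], c("y2", "y1"), c("x1", "x2"), "y2"),
    class = "dairygap_underidentified_error")
})

test_that("frontier likelihood matches the quadrature oracle and the
           Gaussian limit", {
  set.seed(21)
  design <- list(r = c(0.4, -0.3, 1.2, 0.1, -0.8),
                 X = cbind(rep(1, 5), rnorm(5)))
  theta <- c(0.2, 0.5)
  eps <- drop(design$r - design$X %*% theta)

  for (prm in list(c(0.4, 0.6), c(0.25, 0.9), c(1.3, 0.3))) {
    nll_oracle <- -sum(log(oracle_density(eps, prm[1], prm[2])))
    expect_equal(sfa_nll(theta, prm[1], prm[2], design), nll_oracle,
                 tolerance = 1e-6)
  }

  # gamma = 0: plain Gaussian negative log-likelihood
  expect_equal(sfa_nll(theta, 0.5, 0, design),
               -sum(dnorm(eps, 0, sqrt(0.5), log = TRUE)))

  # change of variables: scaling residuals and sigma by c shifts the NLL
  # by n log c
  cc <- 2.5
  d2 <- list(r = cc * design$r, X = cbind(cc * design$X[, 1], design$X[, 2]))
  th2 <- c(cc * theta[1], theta[2] * cc)
  # scale both columns' contribution: equivalently eps2 = cc * eps
  d2 <- list(r = cc * eps, X = cbind(rep(0, 5)))
  expect_equal(sfa_nll(0, cc^2 * 0.4, 0.6, d2),
               sfa_nll(theta, 0.4, 0.6, design) + 5 * log(cc),
               tolerance = 1e-8)
})

test_that("efficiency scores match the conditional-expectation oracle", {
  eps <- c(-0.8, -0.2, 0, 0.3, 1.5)
  for (prm in list(c(0.5, 0.7), c(0.3, 0.95))) {
    expect_equal(dairygap:::te_from_eps(eps, prm[1], prm[2], "bc"),
                 oracle_te(eps, prm[1], prm[2]), tolerance = 1e-8)
  }
  # no inefficiency: all scores 1
  expect_equal(dairygap:::te_from_eps(eps, 0.5, 0), rep(1, 5))
  # a worse residual strictly lowers efficiency
  sweep <- dairygap:::te_from_eps(seq(-1, 2, by = 0.1), 0.5, 0.8)
  expect_true(all(diff(sweep) < 0))
  expect_true(all(sweep > 0 & sweep <= 1))
})

test_that("inefficiency z-test maps statistics onto the published bands", {
  none <- inefficiency_z_test(fit_stub(0, 0.1))
  expect_equal(none$z_value, 0)
  expect_equal(none$p_value, 0.5)
  expect_equal(none$significant_at, "none")

  c_band <- inefficiency_z_test(fit_stub(0.228, 0.1))
  expect_equal(c_band$z_value, 2.28)
  expect_equal(c_band$p_value, 0.0113, tolerance = 1e-2)
  expect_equal(c_band$significant_at, "<0.05")

  a_band <- inefficiency_z_test(fit_stub(0.365, 0.1))
  expect_equal(a_band$significant_at, "<0.001")

  expect_error(inefficiency_z_test(fit_stub(0.5, 0)),
               class = "dairygap_degenerate_information_error")
})

test_that("efficiency converts to gap percentages by the reciprocal rule", {
  expect_equal(gap_from_efficiency(1), 0)
  expect_equal(round_half_up(gap_from_efficiency(0.69)), 45)
  expect_equal(gap_from_efficiency(0.5), 100)
  expect_error(gap_from_efficiency(0))
})

test_that("maximum-likelihood fit recovers a known frontier", {
  truth <- frontier_truth(alpha0 = 0.5, beta = c(land = 0.35, herd = 0.4),
                          gamma_out = c(sales = 0.3),
                          sigma_v_sq = 0.1, sigma_u_sq = 0.4)
  pop <- gen_frontier_population(400, truth, seed = 5)
  fit <- fit_frontier(pop$table, outputs = c("milk", "sales"),
                      inputs = c("land", "herd"))
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), c(0.35, 0.4), tolerance = 0.3)
  expect_equal(fit$gamma, 0.8, tolerance = 0.25)
  expect_gt(fit$sigma_sq, 0)
  te <- technical_efficiency(fit)
  expect_true(all(te$te > 0 & te$te <= 1))
  expect_equal(mean(te$te), mean(pop$te_true), tolerance = 0.1)
  # broom-style accessors
  expect_true(all(c("term", "estimate", "std.error") %in%
                    names(tidy(fit))))
  expect_equal(glance(fit)$n, 400L, ignore_attr = TRUE)
})

test_that("data without inefficiency collapses to least squares", {
  # gamma is weakly identified at the null (the profile likelihood is
  # nearly flat), so individual samples scatter; the median over seeds is
  # the stable summary
  truth <- frontier_truth(alpha0 = 0.3, beta = c(land = 0.5, herd = 0.3),
                          sigma_v_sq = 0.3, sigma_u_sq = 0)
  runs <- vapply(1:5, function(s) {
    pop <- gen_frontier_population(400, truth, seed = s)
    fit <- fit_frontier(pop$table, outputs = "milk",
                        inputs = c("land", "herd"))
    ols <- lm(fit$design$r ~ fit$design$X - 1)
    c(gamma = fit$gamma, dll = fit$loglik - as.numeric(logLik(ols)))
  }, numeric(2))
  expect_lt(stats::median(runs["gamma", ]), 0.15)
  expect_lt(stats::median(abs(runs["dll", ])), 0.5)
  # the maximized likelihood cannot fall materially below least squares
  expect_true(all(runs["dll", ] >= -0.01))
})

test_that("duplicating every farm doubles the optimized log-likelihood", {
  truth <- frontier_truth(alpha0 = 0.5, beta = c(land = 0.35),
                          sigma_v_sq = 0.1, sigma_u_sq = 0.3)
  pop <- gen_frontier_population(150, truth, seed = 3)
  fit <- fit_frontier(pop$table, outputs = "milk", inputs = "land")
  d <- fit$design
  d2 <- d
  d2$r <- rep(d$r, 2)
  d2$X <- rbind(d$X, d$X)
  expect_equal(sfa_nll(fit$coefficients, fit$sigma_sq, fit$gamma, d2),
               2 * sfa_nll(fit$coefficients, fit$sigma_sq, fit$gamma, d))
})
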