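# model families, likelihood fitting, information criteria, diagnostics

test_that("curve evaluation matches closed forms and analytic limits", {
  # logistic kernel is 1/2 at its location parameter
  f <- dr_curve("LL.2", c(b = -1, e = 7))
  expect_equal(predict(f, 7), 0.5)
  # LL.2 with b = -1, e = 10 is f(d) = d/(d + 10)
  f2 <- dr_curve("LL.2", c(b = -1, e = 10))
  expect_equal(predict(f2, 10 / 9), 0.1)
  expect_equal(predict(f2, c(10, 90)), c(0.5, 0.9))
  # weibull1 inner exponent is 0 at dose = e
  w <- dr_curve("W1.4", c(b = 2, c = 1, d = 5, e = 3))
  expect_equal(predict(w, 3), 1 + (5 - 1) * exp(-1))
  # dose 0 returns the analytic limit, not NaN from log(0)
  expect_equal(predict(f2, 0), 0)
  ln <- dr_curve("LN.4", c(b = 1.5, c = 0.1, d = 1, e = 40))
  expect_equal(predict(ln, 0), 0.1)
  expect_equal(ln$family$finf(ln$beta), 1)
  exd <- dr_curve("EXD.2", c(d = 3, e = 40), dist = "normal")
  expect_equal(predict(exd, 0), 3)
  expect_equal(predict(exd, 40), 3 * exp(-1))
  ms <- dr_curve("MS.2", c(c = 0.05, b1 = 0.1, b2 = 0.01))
  expect_equal(predict(ms, 0), 0.05)
  expect_equal(predict(ms, 2), 0.05 + 0.95 * (1 - exp(-(0.2 + 0.04))))
})

test_that("closed-form inverses agree with direct evaluation", {
  for (m in c("LL.4", "LN.4", "W1.4", "W2.4")) {
    f <- dr_curve(m, c(b = -1.3, c = 0.2, d = 4, e = 12))
    for (y in c(0.5, 1.1, 2.9, 3.8)) {
      d <- f$family$inverse(y, f$beta)
      expect_equal(predict(f, d), y, tolerance = 1e-10)
    }
  }
  exd <- dr_curve("EXD.3", c(c = 1, d = 5, e = 20), dist = "normal")
  d <- exd$family$inverse(2.5, exd$beta)
  expect_equal(predict(exd, d), 2.5, tolerance = 1e-10)
})

test_that("binomial likelihood recovers exactly interpolating parameters", {
  d <- exact_ll2_data()
  fit <- suppressWarnings(drfit(d, "LL.2"))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(-1, 10), tolerance = 1e-4)
  # plug-in likelihood comparison over a parameter grid: no grid point
  # beats the fitted optimum
  ll <- function(b, e) {
    p <- 1 / (1 + exp(b * (log(d$dose) - log(e))))
    sum(dbinom(d$events, d$trials, p, log = TRUE))
  }
  grid <- expand.grid(b = seq(-2, -0.3, by = 0.1), e = seq(4, 25, by = 0.5))
  best_grid <- max(mapply(ll, grid$b, grid$e))
  expect_gte(fit$loglik + 1e-6, best_grid)
})

test_that("continuous fits recover generating parameters within 3 SE", {
  scn <- validation_scenario(2, sd = 0.01, replicates = 50, seed = 42)
  d <- generate_scenario(scn)
  fit <- drfit(d, "LL.4")
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  truth <- scn$beta[fit$free]
  expect_true(all(abs(coef(fit) - truth) <= 3 * se + 1e-8))
  expect_equal(fit$sigma, 0.01, tolerance = 0.3)
})

test_that("restarting from the truth never beats the self-start solution", {
  d <- sim_ll4_continuous(seed = 9, sd = 0.1)
  f_self <- drfit(d, "LL.4")
  f_true <- drfit(d, "LL.4", start = c(b = -1.5, c = 2, d = 10, e = 1))
  expect_gte(f_self$loglik, f_true$loglik - 1e-6)
})

test_that("constant responses give a flat fitted curve", {
  d <- dose_response_data(dose = rep(c(0, 1, 10, 100), each = 3),
                          response = rep(5, 12), kind = "continuous")
  fit <- suppressWarnings(drfit(d, "LL.4"))
  pr <- predict(fit, c(0, 0.5, 5, 50, 100))
  expect_lt(diff(range(pr)), 1e-6)
  # BMD is undefined downstream: target outside the (degenerate) range
  expect_error(bmd(fit, bmr_spec(0.1, "relative")), "not reachable")
})

test_that("AIC/BIC follow their definitions, sigma and theta counted", {
  d <- sim_ll4_continuous(seed = 3)
  fit <- drfit(d, "LL.4")
  k <- 4 + 1  # four curve parameters plus sigma
  expect_equal(information_criteria(fit)[["aic"]], 2 * k - 2 * fit$loglik)
  expect_equal(information_criteria(fit)[["bic"]],
               log(nrow(d)) * k - 2 * fit$loglik)
  # nested fits with (almost) equal loglik differ by ~2 in AIC per parameter
  f3 <- drfit(d, "LL.4", fixed = c(c = 2))
  expect_equal(fit$k - f3$k, 1)
  # negbin on equidispersed Poisson data pays for theta
  scn <- scenario_spec("LL.3", c(b = 1, d = 20, e = 5),
                       doses = c(0, 1, 3, 10, 30), replicates = 20,
                       noise = list(kind = "poisson"), seed = 5)
  dp <- generate_scenario(scn)
  fp <- drfit(dp, "LL.3", dist = "poisson")
  fn <- drfit(dp, "LL.3", dist = "negbin")
  expect_gte(fn$aic, fp$aic - 2)
})

test_that("binomial predictions stay within [0, 1] across doses", {
  set.seed(71)
  for (i in 1:5) {
    d <- sim_ll2_binomial(seed = 100 + i)
    for (m in c("LL.2", "LN.2", "W1.2", "W2.2")) {
      fit <- drfit(d, m)
      p <- predict(fit, c(0, 10^seq(-3, 4, length.out = 40)))
      expect_true(all(p >= -1e-12 & p <= 1 + 1e-12))
    }
  }
})

test_that("doubling exposures with counts fixed halves fitted rates", {
  scn <- scenario_spec("EXD.2", c(d = 5, e = 30),
                       doses = c(0, 5, 15, 45), replicates = 8,
                       noise = list(kind = "poisson"), seed = 8)
  d1 <- generate_scenario(scn)
  d1$weight <- rep(2, nrow(d1))  # exposure, e.g. lifespan-days
  d2 <- d1
  d2$weight <- d1$weight * 2
  f1 <- drfit(d1, "EXD.2", offset_exposure = TRUE)
  f2 <- drfit(d2, "EXD.2", offset_exposure = TRUE)
  expect_equal(predict(f2, c(0, 10, 40)), predict(f1, c(0, 10, 40)) / 2,
               tolerance = 1e-5)
})

test_that("standardized residuals behave as pivots", {
  # perfect fit: all residuals zero
  d <- exact_ll2_data()
  fit <- suppressWarnings(drfit(d, "LL.2"))
  expect_equal(standardized_residuals(fit), rep(0, 3), tolerance = 1e-6)
  # large normal sample: mean ~ 0, SD ~ 1
  dn <- sim_ll4_continuous(seed = 21, sd = 0.5, replicates = 100)
  fn <- drfit(dn, "LL.4")
  r <- standardized_residuals(fn)
  expect_lt(abs(mean(r)), 0.1)
  expect_equal(sd(r), 1, tolerance = 0.1)
})

test_that("overdispersion ratio diagnoses Poisson vs negbin data", {
  # true Poisson noise: deviance/df near 1
  scn <- scenario_spec("LL.3", c(b = 1, d = 20, e = 5),
                       doses = c(0, 0.5, 1.5, 5, 15), replicates = 100,
                       noise = list(kind = "poisson"), seed = 31)
  dp <- generate_scenario(scn)
  fp <- drfit(dp, "LL.3", dist = "poisson")
  expect_gt(overdispersion_ratio(fp), 0.8)
  expect_lt(overdispersion_ratio(fp), 1.2)
  # negbin data (theta = 1) fit as Poisson: clear overdispersion
  scn2 <- scenario_spec("LL.3", c(b = 1, d = 20, e = 5),
                        doses = c(0, 0.5, 1.5, 5, 15), replicates = 100,
                        noise = list(kind = "negbin", theta = 1), seed = 32)
  dn <- generate_scenario(scn2)
  fo <- drfit(dn, "LL.3", dist = "poisson")
  expect_gt(overdispersion_ratio(fo), 1.5)
  # saturated grouped binomial fit: deviance ~ 0
  ds <- exact_ll2_data()
  fs <- suppressWarnings(drfit(ds, "LL.2"))
  expect_lt(fs$residual_deviance, 1e-4)
})

test_that("input validation names the offending rows", {
  expect_error(dose_response_data(dose = c(1, -2), response = c(1, 2)),
               "row\\(s\\) 2")
  expect_error(dose_response_data(dose = c(1, 2), events = c(5, 9),
                                  trials = c(10, 8)), "row\\(s\\) 2")
  expect_error(dose_response_data(dose = 1:3, response = c(1, 2.5, 3),
                                  kind = "count"), "row\\(s\\) 2")
  expect_error(drfit(dose_response_data(dose = c(0, 1), events = c(1, 5),
                                        trials = c(10, 10)), "LL.3"),
               "dose levels")
})
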