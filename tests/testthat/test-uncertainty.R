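# Wald/delta and inverse-regression BMDL, shrinkage, bootstrap schemes,
# sandwich covariance

test_that("Wald BMDL arithmetic, truncation, and log scale", {
  f <- dr_curve("LL.2", c(b = -1, e = 10))
  est <- bmd(f, bmr_spec(0.5, "point"), se = FALSE)  # BMD = 10
  est$se <- 2
  bl <- bmdl_delta(f, est, level = 0.95)
  expect_equal(bl$bmdl, 10 - qnorm(0.95) * 2, tolerance = 1e-6)
  expect_equal(round(bl$bmdl, 3), 6.710)
  # huge SE: natural scale truncates at 0, log scale stays positive
  est$se <- 50
  expect_identical(bmdl_delta(f, est)$bmdl, 0)
  expect_gt(bmdl_delta(f, est, scale = "log")$bmdl, 0)
  # zero SE collapses to the BMD with a warning
  est$se <- 0
  expect_warning(bl0 <- bmdl_delta(f, est), "zero standard error")
  expect_identical(bl0$bmdl, est$bmd)
  # strictly decreasing in the confidence level
  est$se <- 2
  lv <- c(0.8, 0.9, 0.95, 0.99)
  bmdls <- vapply(lv, function(l) bmdl_delta(f, est, level = l)$bmdl, 0)
  expect_true(all(diff(bmdls) < 0))
  # two-sided-style level input is rejected with a hint
  expect_error(bmdl_delta(f, est, level = 0.05), "one-sided")
})

test_that("inverse-regression BMDL sits on the confidence band", {
  d <- sim_ll2_binomial(seed = 77, trials = 500)
  fit <- drfit(d, "LL.2")
  sp <- bmr_spec(0.1, "excess")
  est <- bmd(fit, sp)
  inv <- bmdl_inverse_regression(fit, sp)
  expect_lt(inv$bmdl, est$bmd)  # band ordering
  # asymptotic agreement with the delta BMDL at large n
  del <- bmdl_delta(fit, est)
  expect_lt(abs(inv$bmdl - del$bmdl) / del$bmdl, 0.25)
  # degenerate zero covariance: band equals curve, BMDL = BMD
  f0 <- dr_curve("LL.2", c(b = -1, e = 10),
                 vcov = matrix(0, 2, 2, dimnames = list(c("b", "e"),
                                                        c("b", "e"))))
  inv0 <- bmdl_inverse_regression(f0, sp)
  expect_equal(inv0$bmdl, inv0$bmd, tolerance = 1e-6)
})

test_that("binomial shrinkage applies only to degenerate groups", {
  expect_equal(shrink_binomial(0, 40), 0.25 / 40.5)
  expect_equal(shrink_binomial(20, 20), 20.25 / 20.5)
  # the resampler leaves non-degenerate groups at their observed
  # proportion and shrinks all-0/all-1 groups
  d <- dose_response_data(dose = c(1, 2, 3), events = c(0, 10, 40),
                          trials = c(40, 40, 40))
  set.seed(1)
  draws <- replicate(4000, {
    r <- benchdose:::.resample_data(d, "nonparametric")
    r$events
  })
  expect_equal(mean(draws[2, ]) / 40, 0.25, tolerance = 0.02)
  expect_equal(mean(draws[1, ]) / 40, 0.25 / 40.5, tolerance = 0.25)
  expect_equal(mean(draws[3, ]) / 40, 40.25 / 40.5, tolerance = 0.01)
  # non-degenerate group matches Binom(N, Y/N) marginally (chi-square GOF)
  tab <- table(factor(draws[2, ], levels = 0:40))
  pexp <- dbinom(0:40, 40, 0.25)
  keep <- pexp > 5 / 4000
  chi <- sum((tab[keep] - 4000 * pexp[keep])^2 / (4000 * pexp[keep]))
  expect_lt(chi, qchisq(0.999, sum(keep) - 1))
})

test_that("bootstrap BMDL is reproducible and respects degeneracy", {
  d <- sim_ll2_binomial(seed = 12)
  sp <- bmr_spec(0.1, "excess")
  b1 <- bootstrap_bmd(d, "LL.2", sp, n_boot = 100, seed = 42)
  b2 <- bootstrap_bmd(d, "LL.2", sp, n_boot = 100, seed = 42)
  expect_identical(b1$bmdl, b2$bmdl)
  expect_identical(b1$samples, b2$samples)
  expect_equal(b1$bmdl, unname(quantile(b1$samples, 0.05, type = 7)))
  # zero-noise parametric continuous data: every replicate identical
  scn <- scenario_spec("EXD.2", c(d = 5, e = 30), doses = c(0, 10, 30, 90),
                       replicates = 5, noise = list(kind = "normal", sd = 0),
                       seed = 3)
  dz <- generate_scenario(scn)
  bz <- bootstrap_bmd(dz, "EXD.2", bmr_spec(0.1, "relative"),
                      kind = "parametric", n_boot = 60, seed = 5)
  expect_equal(bz$bmdl, bz$bmd, tolerance = 1e-6)
})

test_that("semiparametric bootstrap recentres residuals", {
  d <- sim_ll4_continuous(seed = 31, sd = 0.3)
  sp <- bmr_spec(0.05, "relative")
  bs <- bootstrap_bmd(d, "LL.4", sp, kind = "semiparametric",
                      n_boot = 100, seed = 9)
  expect_true(is.finite(bs$bmdl))
  expect_lt(bs$bmdl, bs$bmd)
  expect_error(
    bootstrap_bmd(sim_ll2_binomial(seed = 1), "LL.2",
                  bmr_spec(0.1, "excess"), kind = "semiparametric",
                  n_boot = 60, seed = 1),
    "continuous")
})

test_that("bootstrap BMDL approaches the delta BMDL as groups grow", {
  sp <- bmr_spec(0.1, "excess")
  gap <- vapply(c(50, 500), function(n) {
    d <- sim_ll2_binomial(seed = 202, trials = n)
    fit <- drfit(d, "LL.2")
    est <- bmd(fit, sp)
    del <- bmdl_delta(fit, est)$bmdl
    np <- bootstrap_bmd(d, "LL.2", sp, n_boot = 300, seed = 7)$bmdl
    abs(np - del) / del
  }, 0)
  expect_lt(gap[2], gap[1])
})

test_that("sandwich covariance: toy identity and glm cross-check", {
  # B = A recovers the model-based covariance exactly
  d <- sim_ll2_binomial(seed = 61)
  fit <- drfit(d, "LL.2")
  sw <- sandwich_vcov(fit)
  V_from_A <- solve(sw$A)
  expect_equal(V_from_A %*% sw$A %*% t(V_from_A), V_from_A,
               tolerance = 1e-6)
  expect_equal(sw$vcov, t(sw$vcov), tolerance = 1e-10)
  expect_true(all(eigen(sw$vcov, only.values = TRUE)$values > -1e-8))
  # zero residuals give a zero sandwich
  dz <- exact_ll2_data()
  fz <- suppressWarnings(drfit(dz, "LL.2"))
  swz <- sandwich_vcov(fz)
  expect_lt(max(abs(swz$B)), 1e-6)
  expect_lt(max(abs(swz$vcov)), 1e-6)
  # EXD.2 with Poisson counts is exactly loglinear: log mu = log d - dose/e;
  # compare against sandwich::vcovHC on the equivalent glm
  skip_if_not_installed("sandwich")
  scn <- scenario_spec("EXD.2", c(d = 20, e = 25),
                       doses = c(0, 5, 15, 40), replicates = 25,
                       noise = list(kind = "negbin", theta = 2), seed = 77)
  dp <- generate_scenario(scn)
  fp <- drfit(dp, "EXD.2", dist = "poisson")
  swp <- sandwich_vcov(fp)
  g <- glm(response ~ dose, family = poisson, data = as.data.frame(dp))
  Vg <- sandwich::vcovHC(g, type = "HC0")
  # map (log d0, -1/e) covariance to (d0, e): jacobian diag(d0, e^2)
  d0 <- fp$beta[["d"]]; e <- fp$beta[["e"]]
  J <- diag(c(d0, e^2))
  Vmapped <- J %*% Vg %*% t(J)
  expect_equal(unname(swp$vcov), unname(Vmapped), tolerance = 0.05)
})

test_that("model-based and sandwich SEs agree under a correct model", {
  scn <- scenario_spec("EXD.2", c(d = 20, e = 25),
                       doses = c(0, 5, 15, 40), replicates = 500,
                       noise = list(kind = "poisson"), seed = 88)
  dp <- generate_scenario(scn)
  fp <- drfit(dp, "EXD.2", dist = "poisson")
  sw <- sandwich_vcov(fp)
  ratio <- sqrt(diag(sw$vcov)) / sqrt(diag(fp$vcov))
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("cluster-robust sandwich sums scores within clusters", {
  d <- sim_ll2_binomial(seed = 93, trials = 30)
  d2 <- rbind(as.data.frame(d), as.data.frame(d))
  dd <- dose_response_data(d2$dose, events = d2$events, trials = d2$trials,
                           cluster = rep(c("a", "b"), each = nrow(d)))
  fit <- drfit(dd, "LL.2")
  sw_iid <- sandwich_vcov(fit)
  sw_cl <- sandwich_vcov(fit, cluster = TRUE)
  expect_equal(dim(sw_cl$vcov), dim(sw_iid$vcov))
  expect_false(isTRUE(all.equal(sw_cl$vcov, sw_iid$vcov)))
})
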