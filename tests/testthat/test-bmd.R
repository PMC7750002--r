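# background levels, target response, BMD solving, delta-method SE

test_that("background levels follow the definition formulas", {
  # estimated lower limit acts as the background mortality
  f <- dr_curve("LN.4", c(b = 1.5, c = 0.10, d = 1, e = 40))
  bg <- background_level(f, bmr_spec(0.05, "additional"))
  expect_equal(bg$p0, 0.10)
  # cut-off two control SDs above the control mean
  fc <- dr_curve("LL.4", c(b = -1.5, c = 2, d = 10, e = 1), sigma = 0.5,
                 dist = "normal")
  bg2 <- background_level(fc, bmr_spec(0.05, "hybridAdd", "hybridSD",
                                       k_sd = 2))
  expect_equal(bg2$p0, 1 - pnorm(2), tolerance = 1e-12)
  expect_equal(bg2$x0, 2 + 2 * 0.5)
  # specified background probability passes through
  bg3 <- background_level(f, bmr_spec(0.05, "excess", "hybridPercentile",
                                      p0 = 0))
  expect_equal(bg3$p0, 0)
  # hybrid on a binomial fit is refused
  expect_error(background_level(f, bmr_spec(0.05, "hybridAdd", "hybridSD",
                                            k_sd = 1)),
               "continuous")
})

test_that("target responses reproduce the risk arithmetic", {
  f <- dr_curve("LN.4", c(b = 1.5, c = 0.10, d = 1, e = 40))
  sp_add <- bmr_spec(0.05, "additional", "hybridPercentile", p0 = 0.10)
  sp_exc <- bmr_spec(0.05, "excess", "hybridPercentile", p0 = 0.10)
  expect_identical(target_response(f, sp_add), 0.10 + 0.05)
  expect_identical(target_response(f, sp_exc), 0.05 * (1 - 0.10) + 0.10)
  # relative change on a decreasing curve
  fd <- dr_curve("EXD.2", c(d = 8, e = 10), dist = "normal")
  expect_equal(target_response(fd, bmr_spec(0.1, "relative")), 7.2)
  # hybrid additional with k = 2: target mean f(0) + sigma (2 - qnorm(0.92725))
  fc <- dr_curve("LL.4", c(b = -1.5, c = 2, d = 10, e = 1), sigma = 0.5,
                 dist = "normal")
  sp_h <- bmr_spec(0.05, "hybridAdd", "hybridSD", k_sd = 2)
  expect_equal(target_response(fc, sp_h),
               2 + 0.5 * (2 - qnorm(1 - 0.05 - (1 - pnorm(2)))),
               tolerance = 1e-12)
})

test_that("BMD solving matches closed forms and a bisection oracle", {
  f <- dr_curve("LL.2", c(b = -1, e = 10))
  # f(d) = d/(d+10); excess 0.1 with p0 = 0 solves d/(d+10) = 0.1
  est <- bmd(f, bmr_spec(0.1, "excess"), se = FALSE)
  expect_equal(est$bmd, 10 / 9, tolerance = 1e-8)
  # point definition at 0.5 returns the location parameter
  expect_equal(bmd(f, bmr_spec(0.5, "point"), se = FALSE)$bmd, 10)
  # independent bisection oracle across definitions and families
  bisect <- function(fn, ystar, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if ((fn(mid) - ystar) * (fn(hi) - ystar) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  cases <- list(
    list(f = dr_curve("W2.4", c(b = -2, c = 0.05, d = 0.9, e = 15)),
         sp = bmr_spec(0.1, "excess")),
    list(f = dr_curve("LN.4", c(b = 1.5, c = 0.10, d = 1, e = 40)),
         sp = bmr_spec(0.05, "additional")),
    list(f = dr_curve("EXD.2", c(d = 8, e = 10), dist = "normal"),
         sp = bmr_spec(0.1, "relative")),
    list(f = dr_curve("MS.2", c(c = 0.02, b1 = 0.01, b2 = 0.002)),
         sp = bmr_spec(0.1, "extra")))
  for (cs in cases) {
    est <- bmd(cs$f, cs$sp, se = FALSE)
    oracle <- bisect(function(d) predict(cs$f, d), est$target_level,
                     1e-9, 1e4)
    expect_equal(est$bmd, oracle, tolerance = 1e-6)
    # definition consistency: curve at the BMD returns the target
    expect_equal(predict(cs$f, est$bmd), est$target_level,
                 tolerance = 1e-8)
  }
})

test_that("BMD is strictly increasing in BMR for monotone curves", {
  fits <- list(dr_curve("LL.2", c(b = -1, e = 10)),
               dr_curve("W1.3", c(b = -2, d = 1, e = 20)),
               dr_curve("LN.3", c(b = 1.2, d = 1, e = 5)))
  for (f in fits) {
    bmds <- vapply(seq(0.01, 0.2, by = 0.01), function(b)
      bmd(f, bmr_spec(b, "excess"), se = FALSE)$bmd, 0)
    expect_true(all(diff(bmds) > 0))
  }
})

test_that("additional and excess risk coincide when p0 = 0", {
  set.seed(404)
  for (i in 1:20) {
    b <- -runif(1, 0.5, 3); e <- runif(1, 2, 50)
    f <- dr_curve("LL.2", c(b = b, e = e))
    sp0 <- bmr_spec(0.08, "additional", "hybridPercentile", p0 = 0)
    sp1 <- bmr_spec(0.08, "excess", "hybridPercentile", p0 = 0)
    expect_equal(bmd(f, sp0, se = FALSE)$bmd, bmd(f, sp1, se = FALSE)$bmd,
                 tolerance = 1e-8)
  }
})

test_that("extra response equals excess risk when the limits are 0 and 1", {
  set.seed(405)
  for (i in 1:20) {
    b <- -runif(1, 0.5, 3); e <- runif(1, 2, 50)
    f <- dr_curve("LL.2", c(b = b, e = e))
    d_extra <- bmd(f, bmr_spec(0.07, "extra"), se = FALSE)$bmd
    d_exc <- bmd(f, bmr_spec(0.07, "excess"), se = FALSE)$bmd
    expect_equal(d_extra, d_exc, tolerance = 1e-8)
  }
})

test_that("unreachable targets raise errors naming the range", {
  f <- dr_curve("LL.3", c(b = -1, d = 0.4, e = 10))
  expect_error(bmd(f, bmr_spec(0.5, "additional"), se = FALSE),
               "not reachable")
})

test_that("delta-method SE matches a BMD-parameterized refit", {
  # oracle: reparameterize LL.2 so that the BMD (excess 0.1, p0 = 0) is
  # itself a parameter, fit by direct likelihood, and read its SE off the
  # inverse hessian
  d <- sim_ll2_binomial(seed = 55, doses = c(0.5, 2, 8, 32), trials = 200)
  fit <- drfit(d, "LL.2")
  sp <- bmr_spec(0.1, "excess")
  est <- bmd(fit, sp)
  bmr <- 0.1
  nll <- function(par) {
    b <- par[1]; bmd_p <- exp(par[2])
    # e implied by f(bmd) = bmr:  log e = log bmd - log(1/bmr - 1)/b
    loge <- log(bmd_p) - log(1 / bmr - 1) / b
    p <- 1 / (1 + exp(b * (log(d$dose) - loge)))
    -sum(dbinom(d$events, d$trials, pmin(pmax(p, 1e-12), 1 - 1e-12),
                log = TRUE))
  }
  o <- optim(c(coef(fit)[["b"]], log(est$bmd)), nll, hessian = TRUE)
  se_repar <- sqrt(solve(o$hessian)[2, 2]) * exp(o$par[2])  # delta to natural
  expect_equal(est$se, se_repar, tolerance = 0.1)
})

test_that("delta SE edge cases: zero covariance and solver tolerance", {
  f <- dr_curve("LL.2", c(b = -1, e = 10),
                vcov = matrix(0, 2, 2, dimnames = list(c("b", "e"),
                                                       c("b", "e"))))
  est <- bmd(f, bmr_spec(0.1, "excess"))
  expect_identical(est$se, 0)
  # stability: SE computed at the closed-form root equals SE at a
  # numerically re-solved root to high relative accuracy
  d <- sim_ll2_binomial(seed = 56)
  fit <- drfit(d, "LL.2")
  sp <- bmr_spec(0.1, "excess")
  est1 <- bmd(fit, sp)
  est2 <- est1
  est2$bmd <- est1$bmd * (1 + 1e-9)
  se2 <- bmd_se_delta(fit, est2)
  expect_equal(est1$se, se2, tolerance = 1e-4)
})
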