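# Maximum-likelihood fitting of dose-response models for binomial, count
# and continuous responses.
#
# Likelihoods:
#   normal   least squares with profiled sigma (single pooled sigma)
#   binomial grouped binomial likelihood per dose group
#   poisson  counts, optional log-exposure offset (weight column)
#   negbin   NB2 (variance mu + mu^2/theta), theta profiled on log scale
#
# Positive parameters (e, multistage b_m, theta) are optimized on the log
# scale; the optimizer is Nelder-Mead refined by BFGS with relative
# log-likelihood tolerance 1e-8.

.dist_for_kind <- function(kind) {
  switch(kind, binomial = "binomial", count = "poisson",
         continuous = "normal")
}

# --- parameter transforms --------------------------------------------------

.par_transform <- function(family, free) {
  pos <- intersect(family$positive, free)
  to_opt <- function(beta) {
    x <- beta[free]
    x[pos] <- log(x[pos])
    x
  }
  from_opt <- function(phi) {
    x <- phi
    names(x) <- free
    x[pos] <- exp(x[pos])
    x
  }
  list(to = to_opt, from = from_opt, positive = pos)
}

# --- log-likelihoods -------------------------------------------------------

# returns vector of per-row log-likelihood contributions (sigma/theta given),
# or total when total = TRUE; mu is the mean response at each row's dose
.loglik_rows <- function(dist, data, mu, sigma = NULL, theta = NULL,
                         exposure = NULL) {
  switch(dist,
    binomial = {
      p <- mu
      if (any(p < -1e-9 | p > 1 + 1e-9)) return(rep(-Inf, nrow(data)))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      stats::dbinom(data$events, data$trials, p, log = TRUE)
    },
    poisson = {
      lam <- if (is.null(exposure)) mu else exposure * mu
      if (any(lam <= 0)) return(rep(-Inf, nrow(data)))
      stats::dpois(data$response, lam, log = TRUE)
    },
    negbin = {
      lam <- if (is.null(exposure)) mu else exposure * mu
      if (any(lam <= 0) || theta <= 0) return(rep(-Inf, nrow(data)))
      stats::dnbinom(data$response, size = theta, mu = lam, log = TRUE)
    },
    normal = {
      w <- if (is.null(data$weight)) rep(1, nrow(data)) else data$weight
      -0.5 * (log(2 * pi * sigma^2) - log(w) +
                w * (data$response - mu)^2 / sigma^2)
    })
}

#' Fit a dose-response model by maximum likelihood
#'
#' Fits one of the parametric families of [dr_family()] to binomial,
#' count, or continuous dose-response data.  Continuous responses use a
#' normal likelihood with a single pooled residual standard deviation
#' (profiled out analytically); counts use a Poisson or NB2 negative
#' binomial likelihood, with the `weight` column used as an exposure
#' offset when `offset_exposure = TRUE`; binomial data use the grouped
#' binomial likelihood.  Starting values come from family-specific
#' self-starters (limits from extreme group means, slope and location
#' from a linearized regression of the transformed kernel on log dose)
#' unless supplied.
#'
#' @param data A [dose_response_data()] object (or data frame with the
#'   same columns).
#' @param model Model code, see [list_models()].
#' @param dist Distribution: `"normal"`, `"binomial"`, `"poisson"`, or
#'   `"negbin"`; default chosen from the response kind.
#' @param fixed Named numeric vector of parameters to hold fixed, e.g.
#'   `c(c = 0)`.
#' @param start Optional named starting values for the free parameters.
#' @param log_response Log-transform a continuous response before fitting.
#' @param offset_exposure Use the `weight` column as a Poisson/negbin
#'   exposure (rates are per unit of exposure).
#' @param compute_vcov Compute the observed-information covariance matrix
#'   (skip inside bootstrap loops for speed).
#' @return A `drfit` object with components `beta` (full named parameter
#'   vector), `coefficients` (free parameters), `vcov`, `loglik`, `aic`,
#'   `bic`, `sigma`, `theta`, `residual_deviance`, `df_residual`,
#'   `converged`, and `direction`.
#' @examples
#' d <- dose_response_data(dose = c(10/9, 10, 90), events = c(10, 50, 90),
#'                         trials = c(100, 100, 100))
#' fit <- drfit(d, "LL.2")
#' coef(fit)  # close to b = -1, e = 10
#' @export
drfit <- function(data, model, dist = NULL, fixed = NULL, start = NULL,
                  log_response = FALSE, offset_exposure = FALSE,
                  compute_vcov = TRUE) {
  if (!inherits(data, "dose_response_data")) {
    data <- if (!is.null(data$events))
      dose_response_data(data$dose, events = data$events, trials = data$trials,
                         weight = data$weight, cluster = data$cluster)
    else
      dose_response_data(data$dose, response = data$response,
                         weight = data$weight, cluster = data$cluster)
  }
  kind <- response_kind(data)
  if (is.null(dist)) dist <- .dist_for_kind(kind)
  dist <- match.arg(dist, c("normal", "binomial", "poisson", "negbin"))
  if (dist == "binomial" && kind != "binomial")
    stop("binomial distribution requires events/trials data")
  if (dist %in% c("poisson", "negbin") && kind != "count")
    stop(dist, " distribution requires count responses")
  if (log_response) {
    if (kind == "binomial") stop("log_response applies to continuous/count responses")
    if (any(data$response <= 0))
      stop("log_response requires strictly positive responses")
    data$response <- log(data$response)
    attr(data, "response_kind") <- kind <- "continuous"
    if (dist != "normal") dist <- "normal"
  }
  family <- dr_family(model)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), family$parnames)
    if (length(bad))
      stop("fixed parameter(s) not in family: ", paste(bad, collapse = ", "))
  }
  free <- setdiff(family$parnames, names(fixed))
  if (!length(free)) stop("no free parameters left after fixing")
  nlev <- length(unique(data$dose))
  if (nlev < length(free))
    stop("need at least ", length(free), " distinct dose levels, have ", nlev)
  if (nlev == length(free))
    warning("number of dose levels equals number of parameters; fit is saturated")
  if (nlev < 3)
    warning("fewer than 3 distinct dose levels; parametric fit is fragile")

  exposure <- if (offset_exposure) {
    if (is.null(data$weight)) stop("offset_exposure requires a weight column")
    data$weight
  } else NULL

  # two-parameter kernel families with binomial data are GLMs in log dose
  # (logit/probit/cloglog link); use IRLS via glm.fit when applicable
  if (dist == "binomial" && is.null(start) && is.null(fixed) &&
      family$n_par == 2L && family$kernel %in% c("ll", "ln", "w1", "w2") &&
      all(data$dose > 0)) {
    fast <- .fast_binomial2(data, family, model, compute_vcov)
    if (!is.null(fast)) return(fast)
  }

  full_beta <- function(bfree) {
    b <- c(bfree, fixed)
    b[family$parnames]
  }
  mu_fun <- function(bfree) family$fn(data$dose, full_beta(bfree))

  n <- nrow(data)
  est_theta <- dist == "negbin"
  tr <- .par_transform(family, free)

  # objective on the transformed scale; last element is log(theta) for negbin
  negll <- function(phi) {
    bfree <- tr$from(phi[seq_along(free)])
    theta <- if (est_theta) exp(phi[length(phi)]) else NULL
    mu <- mu_fun(bfree)
    if (any(!is.finite(mu))) return(1e10)
    ll <- if (dist == "normal") {
      w <- if (is.null(data$weight)) rep(1, n) else data$weight
      rss <- sum(w * (data$response - mu)^2)
      s2 <- rss / n
      if (s2 <= 0) s2 <- 1e-300
      -n / 2 * (log(2 * pi * s2) + 1) + sum(log(w)) / 2
    } else {
      sum(.loglik_rows(dist, data, mu, theta = theta, exposure = exposure))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (is.null(start)) {
    start <- .self_start(family, data, dist, fixed, exposure)
  } else {
    start <- start[free]
    if (anyNA(start)) stop("start must name every free parameter")
  }
  phi0 <- tr$to(start)
  if (est_theta) phi0 <- c(phi0, 0)  # theta starts at 1
  if (any(!is.finite(phi0)))
    stop("non-finite starting values; supply `start` explicitly")

  o1 <- stats::optim(phi0, negll, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-8))
  o2 <- tryCatch(
    stats::optim(o1$par, negll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) o1)
  opt <- if (o2$value <= o1$value) o2 else o1
  converged <- is.finite(opt$value) && opt$value < 1e9 &&
    (opt$convergence == 0 || abs(o2$value - o1$value) <=
       1e-8 * (abs(o1$value) + 1e-8))

  phi <- opt$par
  bfree <- tr$from(phi[seq_along(free)])
  theta <- if (est_theta) exp(phi[length(phi)]) else NULL
  beta <- full_beta(bfree)
  mu <- mu_fun(bfree)
  loglik <- -opt$value

  sigma <- NULL
  if (dist == "normal") {
    w <- if (is.null(data$weight)) rep(1, n) else data$weight
    sigma <- sqrt(sum(w * (data$response - mu)^2) / n)
  }

  k <- length(free) + (dist == "normal") + est_theta
  aic <- 2 * k - 2 * loglik
  bic <- log(n) * k - 2 * loglik

  # residual deviance against the saturated model
  gs <- .group_summary(data)
  if (dist == "binomial") {
    phat <- family$fn(gs$dose, beta)
    phat <- pmin(pmax(phat, 1e-12), 1 - 1e-12)
    ll_fit <- sum(stats::dbinom(gs$events, gs$trials, phat, log = TRUE))
    psat <- pmin(pmax(gs$mean, 1e-12), 1 - 1e-12)
    ll_sat <- sum(stats::dbinom(gs$events, gs$trials, psat, log = TRUE))
    residual_deviance <- 2 * (ll_sat - ll_fit)
    df_residual <- nrow(gs) - length(free)
  } else if (dist %in% c("poisson", "negbin")) {
    lam <- if (is.null(exposure)) mu else exposure * mu
    y <- data$response
    if (dist == "poisson") {
      dev_i <- 2 * (ifelse(y > 0, y * log(y / lam), 0) - (y - lam))
    } else {
      dev_i <- 2 * (ifelse(y > 0, y * log(y / lam), 0) -
                      (y + theta) * log((y + theta) / (lam + theta)))
    }
    residual_deviance <- sum(dev_i)
    df_residual <- n - length(free) - est_theta
  } else {
    w <- if (is.null(data$weight)) rep(1, n) else data$weight
    residual_deviance <- sum(w * (data$response - mu)^2)
    df_residual <- n - length(free)
  }

  f0 <- family$f0(beta)
  fmax <- family$fn(max(data$dose), beta)
  direction <- if (fmax >= f0) "increasing" else "decreasing"

  fit <- structure(list(
    family = family, model = model, dist = dist, fixed = fixed,
    free = free, beta = beta, coefficients = bfree,
    vcov = NULL, loglik = loglik, k = k, aic = aic, bic = bic,
    sigma = sigma, theta = theta,
    residual_deviance = residual_deviance, df_residual = df_residual,
    fitted = mu, data = data, n = n, exposure = exposure,
    offset_exposure = offset_exposure, log_response = log_response,
    converged = converged, direction = direction,
    optim_value = opt$value), class = "drfit")

  if (compute_vcov && converged) {
    fit$vcov <- tryCatch(.observed_info_vcov(fit), error = function(e) {
      warning("covariance computation failed: ", conditionMessage(e))
      NULL
    })
  }
  fit
}

# IRLS fit of a 2-parameter kernel family to grouped binomial data.
# With t = log dose - log e the kernels map to binomial GLMs in log dose:
# logistic -> logit on events (eta = -b t), log-normal -> probit,
# weibull2 -> cloglog, weibull1 -> cloglog on the non-events.
# Returns NULL when the GLM route fails (e.g. separation).
.fast_binomial2 <- function(data, family, model, compute_vcov) {
  type <- family$kernel
  x <- log(data$dose)
  succ <- if (type == "w1") data$trials - data$events else data$events
  fail <- data$trials - succ
  link <- switch(type, ll = "logit", ln = "probit", w1 = "cloglog",
                 w2 = "cloglog")
  g <- tryCatch(suppressWarnings(
    stats::glm.fit(cbind(1, x), cbind(succ, fail),
                   family = stats::binomial(link = link),
                   control = stats::glm.control(epsilon = 1e-10))),
    error = function(e) NULL)
  if (is.null(g) || !g$converged) return(NULL)
  a <- g$coefficients[1]; s <- g$coefficients[2]
  if (!all(is.finite(c(a, s))) || abs(s) < 1e-8 || abs(s) > 1e3 ||
      abs(a / s) > 500) return(NULL)
  b <- if (type == "ll") -s else s
  e <- exp(-a / s)
  beta <- c(b = unname(b), e = unname(e))
  p <- family$fn(data$dose, beta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loglik <- sum(stats::dbinom(data$events, data$trials, p, log = TRUE))
  gs <- .group_summary(data)
  phat <- pmin(pmax(family$fn(gs$dose, beta), 1e-12), 1 - 1e-12)
  psat <- pmin(pmax(gs$mean, 1e-12), 1 - 1e-12)
  residual_deviance <- 2 * (sum(stats::dbinom(gs$events, gs$trials, psat,
                                              log = TRUE)) -
                              sum(stats::dbinom(gs$events, gs$trials, phat,
                                                log = TRUE)))
  f0 <- family$f0(beta)
  direction <- if (family$fn(max(data$dose), beta) >= f0)
    "increasing" else "decreasing"
  fit <- structure(list(
    family = family, model = model, dist = "binomial", fixed = NULL,
    free = c("b", "e"), beta = beta, coefficients = beta,
    vcov = NULL, loglik = loglik, k = 2L, aic = 4 - 2 * loglik,
    bic = log(nrow(data)) * 2 - 2 * loglik, sigma = NULL, theta = NULL,
    residual_deviance = residual_deviance,
    df_residual = nrow(gs) - 2L,
    fitted = family$fn(data$dose, beta), data = data, n = nrow(data),
    exposure = NULL, offset_exposure = FALSE, log_response = FALSE,
    converged = TRUE, direction = direction,
    optim_value = -loglik), class = "drfit")
  if (compute_vcov) {
    fit$vcov <- tryCatch(.observed_info_vcov(fit), error = function(e) NULL)
  }
  fit
}

# observed-information covariance of the free curve parameters, on the
# natural scale, with sigma/theta held at their estimates
.observed_info_vcov <- function(fit) {
  free <- fit$free
  f <- function(bfree_vec) {
    names(bfree_vec) <- free
    -.loglik_beta(fit, bfree_vec)
  }
  H <- .num_hessian(f, unname(fit$coefficients[free]),
                    eps = 1e-5 * pmax(abs(fit$coefficients[free]), 1e-3))
  V <- solve(H)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(free, free)
  V
}

# total log-likelihood as a function of the free curve parameters,
# sigma/theta fixed at the fitted values
.loglik_beta <- function(fit, bfree) {
  beta <- c(bfree, fit$fixed)[fit$family$parnames]
  mu <- fit$family$fn(fit$data$dose, beta)
  sum(.loglik_rows(fit$dist, fit$data, mu, sigma = fit$sigma,
                   theta = fit$theta, exposure = fit$exposure))
}

# per-row log-likelihood contributions at given free parameters
.loglik_beta_rows <- function(fit, bfree) {
  beta <- c(bfree, fit$fixed)[fit$family$parnames]
  mu <- fit$family$fn(fit$data$dose, beta)
  .loglik_rows(fit$dist, fit$data, mu, sigma = fit$sigma,
               theta = fit$theta, exposure = fit$exposure)
}

# --- self-starters ---------------------------------------------------------

.self_start <- function(family, data, dist, fixed, exposure) {
  gs <- .group_summary(data)
  if (!is.null(exposure)) {
    # work on rates per unit exposure
    lev <- sort(unique(data$dose))
    gs$mean <- vapply(lev, function(d) {
      i <- data$dose == d
      sum(data$response[i]) / sum(exposure[i])
    }, 0)
  }
  gm <- gs$mean
  dose <- gs$dose
  increasing <- gm[which.max(dose)] >= gm[which.min(dose)]
  rng <- diff(range(gm))
  if (rng == 0) rng <- max(abs(gm), 1) * 1e-3

  code <- family$code
  type <- family$kernel

  if (type %in% c("ll", "ln", "w1", "w2")) {
    # limits
    cc <- if ("c" %in% names(fixed)) fixed[["c"]]
      else if (!("c" %in% family$parnames)) 0
      else min(gm) - 0.05 * rng
    dd <- if ("d" %in% names(fixed)) fixed[["d"]]
      else if (!("d" %in% family$parnames)) 1
      else max(gm) + 0.05 * rng
    if (dist == "binomial") {
      cc <- max(cc, 1e-4); dd <- min(dd, 1 - 1e-4)
      if ("c" %in% names(fixed)) cc <- fixed[["c"]]
      if ("d" %in% names(fixed)) dd <- fixed[["d"]]
    }
    k <- (gm - cc) / (dd - cc)
    k <- pmin(pmax(k, 0.02), 0.98)
    pos <- dose > 0
    u <- switch(type, ll = log(1 / k - 1), ln = stats::qnorm(k),
                w1 = log(-log(k)), w2 = log(-log(1 - k)))
    if (sum(pos) >= 2 && stats::var(log(dose[pos])) > 0) {
      x <- log(dose[pos]); uu <- u[pos]
      b <- stats::cov(x, uu) / stats::var(x)
      a <- mean(uu) - b * mean(x)
      if (!is.finite(b) || abs(b) < 1e-3)
        b <- if (xor(increasing, type == "ln")) -1 else 1
      e <- exp(-a / b)
      if (!is.finite(e) || e <= 0) e <- stats::median(dose[pos])
    } else {
      b <- if (xor(increasing, type == "ln")) -1 else 1
      e <- max(stats::median(dose[pos]), 1e-3)
    }
    st <- c(b = b, c = cc, d = dd, e = e)
    return(st[setdiff(family$parnames, names(fixed))])
  }

  if (type == "exd") {
    cc <- if ("c" %in% names(fixed)) fixed[["c"]]
      else if (!("c" %in% family$parnames)) 0
      else min(gm) - 0.05 * rng
    d0 <- gm[which.min(dose)]
    k <- (gm - cc) / (d0 - cc)
    k <- pmin(pmax(k, 0.02), 1)
    keep <- dose > 0 & k > 0 & k < 1
    e <- if (sum(keep) >= 1) {
      sl <- sum(dose[keep] * log(k[keep])) / sum(dose[keep]^2)
      if (is.finite(sl) && sl < 0) -1 / sl else max(dose) / 3
    } else max(dose) / 3
    st <- c(c = cc, d = d0, e = unname(e))
    return(st[setdiff(family$parnames, names(fixed))])
  }

  # multistage
  cc <- if ("c" %in% names(fixed)) fixed[["c"]] else max(gm[which.min(dose)], 1e-3)
  k <- (gm - cc) / (1 - cc)
  k <- pmin(pmax(k, 1e-3), 0.98)
  u <- -log(1 - k)
  deg <- family$degree
  X <- outer(dose, seq_len(deg), `^`)
  cf <- tryCatch(stats::.lm.fit(X, u)$coefficients, error = function(e) NULL)
  bm <- if (is.null(cf)) rep(0.1 / max(dose), deg) else pmax(cf, 1e-6)
  names(bm) <- paste0("b", seq_len(deg))
  st <- c(c = unname(cc), bm)
  st[setdiff(family$parnames, names(fixed))]
}

# --- methods ---------------------------------------------------------------

#' Predict mean response from a fitted dose-response model
#'
#' @param object A `drfit` object.
#' @param dose Non-negative doses; dose 0 returns the analytic limit
#'   of the curve as dose tends to 0 from above.
#' @param ... Unused.
#' @return Numeric vector of mean responses.
#' @export
predict.drfit <- function(object, dose, ...) {
  if (!isTRUE(object$converged))
    stop("model fit did not converge; predictions unavailable")
  if (any(!is.finite(object$beta)))
    stop("invalid fit: non-finite parameters")
  if (any(dose < 0)) stop("doses must be non-negative")
  object$family$fn(dose, object$beta)
}

#' @export
coef.drfit <- function(object, ...) object$coefficients

#' @export
vcov.drfit <- function(object, ...) object$vcov

#' @export
logLik.drfit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.drfit <- function(x, ...) {
  cat("Dose-response model ", x$model, " (", x$dist, ")\n", sep = "")
  cat("Parameters:\n")
  print(x$beta)
  if (!is.null(x$sigma)) cat("Residual SD:", format(x$sigma), "\n")
  if (!is.null(x$theta)) cat("NB dispersion theta:", format(x$theta), "\n")
  cat("logLik:", format(x$loglik), " AIC:", format(x$aic),
      " direction:", x$direction,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Information criteria of a fit
#'
#' AIC is \eqn{2k - 2\ell} with \eqn{k} the number of free parameters,
#' counting the residual standard deviation for continuous fits and the
#' negative-binomial dispersion when estimated; BIC replaces 2 by
#' \eqn{\log n}.
#'
#' @param fit A converged `drfit` object.
#' @return Named vector with elements `aic` and `bic`.
#' @export
information_criteria <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  c(aic = fit$aic, bic = fit$bic)
}

#' Standardized residuals of a dose-response fit
#'
#' Residuals \eqn{(y - \hat\mu)/s} with scale \eqn{s} equal to the residual
#' SD (normal), \eqn{\sqrt{\hat\mu}} (Poisson), \eqn{\sqrt{\hat\mu +
#' \hat\mu^2/\theta}} (negative binomial), or per dose group
#' \eqn{\sqrt{\hat p(1-\hat p)/n}} for binomial data (one residual per
#' group, on the proportion scale).
#'
#' @param fit A converged `drfit` object.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  data <- fit$data
  if (fit$dist == "binomial") {
    gs <- .group_summary(data)
    p <- fit$family$fn(gs$dose, fit$beta)
    v <- p * (1 - p) / gs$trials
    r <- gs$mean - p
  } else {
    mu <- fit$fitted
    lam <- if (is.null(fit$exposure)) mu else fit$exposure * mu
    v <- switch(fit$dist,
      normal = rep(fit$sigma^2, fit$n) /
        (if (is.null(data$weight)) 1 else data$weight),
      poisson = lam,
      negbin = lam + lam^2 / fit$theta)
    r <- data$response - lam
    if (fit$dist == "normal") r <- data$response - mu
  }
  zero <- v <= 0
  if (any(zero)) {
    warning("zero predicted variance; residual set to 0")
    v[zero] <- Inf
  }
  r / sqrt(v)
}

#' Overdispersion diagnostic
#'
#' Ratio of residual deviance to residual degrees of freedom for binomial
#' or Poisson fits; values clearly above 1 signal extra-model variation
#' (overdispersion).
#'
#' @param fit A converged binomial or Poisson `drfit`.
#' @return The deviance/df ratio.
#' @export
overdispersion_ratio <- function(fit) {
  if (!fit$dist %in% c("binomial", "poisson"))
    stop("overdispersion ratio applies to binomial or poisson fits")
  if (fit$df_residual <= 0)
    stop("no residual degrees of freedom; ratio undefined")
  fit$residual_deviance / fit$df_residual
}

#' Construct a dose-response curve object from known parameters
#'
#' Builds a `drfit`-compatible object directly from parameter values,
#' without data.  Useful for desk calculations, worked examples, and as
#' a container for externally estimated curves.
#'
#' @param model Model code, see [list_models()].
#' @param beta Named parameter vector covering the family's parameters
#'   (missing `c`/`d` limits default to 0/1 where the family fixes them).
#' @param sigma Optional residual SD (needed for hybrid definitions).
#' @param vcov Optional covariance matrix of `beta` (free parameters).
#' @param dist Distribution label, default `"binomial"`.
#' @return A `drfit` object with `converged = TRUE`.
#' @examples
#' f <- dr_curve("LL.2", c(b = -1, e = 10))
#' predict(f, 10/9)  # 0.1
#' @export
dr_curve <- function(model, beta, sigma = NULL, vcov = NULL,
                     dist = "binomial") {
  family <- dr_family(model)
  beta <- beta[family$parnames]
  if (anyNA(beta))
    stop("beta must name parameters: ", paste(family$parnames, collapse = ", "))
  free <- family$parnames
  f0 <- family$f0(beta)
  f1 <- family$finf(beta)
  structure(list(
    family = family, model = model, dist = dist, fixed = NULL,
    free = free, beta = beta, coefficients = beta,
    vcov = vcov, loglik = NA_real_, k = length(free), aic = NA_real_,
    bic = NA_real_, sigma = sigma, theta = NULL,
    residual_deviance = NA_real_, df_residual = NA_integer_,
    fitted = NULL, data = NULL, n = 0L, exposure = NULL,
    offset_exposure = FALSE, log_response = FALSE,
    converged = TRUE,
    direction = if (f1 >= f0) "increasing" else "decreasing"),
    class = "drfit")
}
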