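# BMDL estimation: Wald/delta intervals (natural and log scale), inverse
# regression on the one-sided confidence band, and bootstrap schemes.

.new_bmdl <- function(bmdl, method, level, bmd = NA_real_, n_boot = NA_integer_,
                      n_failed = NA_integer_, samples = NULL) {
  structure(list(bmdl = bmdl, method = method, level = level, bmd = bmd,
                 n_boot = n_boot, n_failed = n_failed, samples = samples),
            class = "bmdl_result")
}

#' @export
print.bmdl_result <- function(x, ...) {
  cat("BMDL (", x$method, ", one-sided ", format(100 * x$level), "%): ",
      format(x$bmdl), sep = "")
  if (is.finite(x$bmd)) cat("   BMD:", format(x$bmd))
  if (is.finite(x$n_failed) && x$n_failed > 0)
    cat("   [", x$n_failed, "failed replicates ]")
  cat("\n")
  invisible(x)
}

#' Wald-type (delta-method) BMDL
#'
#' One-sided lower confidence limit for the BMD from its delta-method
#' standard error: on the natural scale \eqn{\max(0, \mathrm{BMD} -
#' z_{level}\,\mathrm{se})} (negative limits are truncated at 0); on the
#' log scale \eqn{\exp(\log\mathrm{BMD} - z_{level}\,\mathrm{se}/
#' \mathrm{BMD})}, which is always positive.
#'
#' @param fit A converged `drfit`.
#' @param est A `bmd_estimate` with a finite `se`.
#' @param level One-sided confidence level (default 0.95).
#' @param scale `"natural"` or `"log"`.
#' @return A `bmdl_result`.
#' @examples
#' f <- dr_curve("LL.2", c(b = -1, e = 10))
#' est <- bmd(f, bmr_spec(0.1, "excess"), se = FALSE)
#' est$se <- 0.2
#' bmdl_delta(f, est)
#' @export
bmdl_delta <- function(fit, est, level = 0.95,
                       scale = c("natural", "log")) {
  scale <- match.arg(scale)
  .check_level(level)
  se <- est$se
  if (!is.finite(se)) stop("estimate carries no finite standard error")
  if (se == 0) {
    warning("zero standard error; BMDL equals BMD")
    return(.new_bmdl(est$bmd, paste0("delta_", scale), level, bmd = est$bmd))
  }
  z <- .z_level(level)
  bmdl <- if (scale == "natural") max(0, est$bmd - z * se)
          else exp(log(est$bmd) - z * se / est$bmd)
  .new_bmdl(bmdl, if (scale == "natural") "delta" else "delta_log",
            level, bmd = est$bmd)
}

.check_level <- function(level) {
  if (!is.numeric(level) || level <= 0.5 || level >= 1)
    stop("`level` is a one-sided confidence level in (0.5, 1); ",
         "for a two-sided 90% interval use level = 0.95")
}

#' Inverse-regression BMDL
#'
#' The BMDL is the smallest dose at which the one-sided pointwise
#' confidence limit of the predicted response (in the adverse direction)
#' reaches the target response level: the band \eqn{f(d) \pm
#' z_{level}\,\mathrm{se}(f(d))} is computed by the delta method on the
#' curve and root-solved at \eqn{y^\ast}.
#'
#' @param fit A converged `drfit` with a covariance matrix.
#' @param spec A [bmr_spec()].
#' @param level One-sided confidence level.
#' @param vcov Optional parameter covariance overriding the fit's.
#' @return A `bmdl_result`.
#' @export
bmdl_inverse_regression <- function(fit, spec, level = 0.95, vcov = NULL) {
  .check_level(level)
  V <- if (is.null(vcov)) fit$vcov else vcov
  if (is.null(V)) stop("no covariance matrix available")
  est <- bmd(fit, spec, se = FALSE)
  ystar <- est$target_level
  inc <- .adverse_increasing(fit, spec)
  z <- .z_level(level)
  free <- fit$free
  b0 <- fit$coefficients[free]
  band <- function(d) {
    g <- .num_grad(function(b) {
      fit$family$fn(d, c(stats::setNames(b, free), fit$fixed)[fit$family$parnames])
    }, unname(b0), eps = 1e-5 * pmax(abs(b0), 1e-3))
    sef <- sqrt(max(drop(t(g) %*% V[free, free, drop = FALSE] %*% g), 0))
    f <- fit$family$fn(d, fit$beta)
    if (inc) f + z * sef else f - z * sef
  }
  gfun <- function(ld) {
    b <- band(exp(ld))
    if (inc) b - ystar else ystar - b
  }
  lo <- 1e-10 * est$bmd
  g_hi <- gfun(log(est$bmd))
  if (g_hi < 0) g_hi <- 0  # zero-variance band: root at the BMD itself
  if (abs(g_hi) < 1e-12) return(.new_bmdl(est$bmd, "inv", level, bmd = est$bmd))
  g_lo <- gfun(log(lo))
  if (g_lo >= 0) {
    # band exceeds the target even as dose -> 0; no informative lower limit
    return(.new_bmdl(0, "inv", level, bmd = est$bmd))
  }
  r <- stats::uniroot(gfun, c(log(lo), log(est$bmd)), tol = 1e-10)
  .new_bmdl(exp(r$root), "inv", level, bmd = est$bmd)
}

#' Binomial shrinkage for degenerate dose groups
#'
#' For a dose group with only events or only non-events, resampling from
#' the observed proportion would reproduce the degenerate outcome in
#' every bootstrap replicate.  The shrunken proportion \eqn{(Y_i + 1/4) /
#' (N_i + 1/2)} is used instead.
#'
#' @param events,trials Group totals.
#' @return The shrunken proportion.
#' @examples
#' shrink_binomial(0, 40)   # 0.25/40.5
#' shrink_binomial(20, 20)  # 20.25/20.5
#' @export
shrink_binomial <- function(events, trials) {
  (events + 1 / 4) / (trials + 1 / 2)
}

# --- resampling ------------------------------------------------------------

# one bootstrap replicate of `data`; `fit` supplies fitted values/residuals
# for the semiparametric scheme and theta for negbin parametric sampling
.resample_data <- function(data, kind, fit = NULL,
                           sd_source = c("pooled", "control")) {
  sd_source <- match.arg(sd_source)
  rkind <- response_kind(data)
  gs <- .group_summary(data)
  if (rkind == "binomial") {
    # per-group binomial draw from the observed proportion, with shrinkage
    # for all-0 / all-1 groups (both nonparametric and parametric schemes)
    p <- gs$mean
    degen <- gs$events == 0 | gs$events == gs$trials
    p[degen] <- shrink_binomial(gs$events[degen], gs$trials[degen])
    ev <- stats::rbinom(nrow(gs), gs$trials, p)
    return(dose_response_data(gs$dose, events = ev, trials = gs$trials))
  }
  if (kind == "nonparametric") {
    idx <- unlist(lapply(sort(unique(data$dose)), function(d) {
      i <- which(data$dose == d)
      i[sample.int(length(i), length(i), replace = TRUE)]
    }))
    out <- data[idx, , drop = FALSE]
    attr(out, "response_kind") <- rkind
    class(out) <- class(data)
    rownames(out) <- NULL
    return(out)
  }
  if (kind == "semiparametric") {
    if (rkind != "continuous")
      stop("semiparametric bootstrap applies to continuous responses")
    if (is.null(fit)) stop("semiparametric bootstrap needs the original fit")
    res <- data$response - fit$fitted
    res <- res - mean(res)
    out <- data
    out$response <- fit$fitted + sample(res, length(res), replace = TRUE)
    return(out)
  }
  # parametric
  if (rkind == "continuous") {
    grp <- match(data$dose, gs$dose)
    s <- if (sd_source == "control") gs$sd[which.min(gs$dose)]
    else {
      df <- sum(gs$n) - nrow(gs)
      if (df <= 0) 0 else
        sqrt(sum((gs$n - 1) * gs$sd^2, na.rm = TRUE) / df)
    }
    out <- data
    out$response <- stats::rnorm(nrow(data), gs$mean[grp], s)
    return(out)
  }
  # counts: Poisson (or NB2 when the original fit was negbin) around the
  # group means, respecting exposure when present
  grp <- match(data$dose, gs$dose)
  mu <- gs$mean[grp]
  if (!is.null(fit) && isTRUE(fit$offset_exposure)) {
    lev <- gs$dose
    rate <- vapply(lev, function(d) {
      i <- data$dose == d
      sum(data$response[i]) / sum(data$weight[i])
    }, 0)
    mu <- rate[grp] * data$weight
  }
  y <- if (!is.null(fit) && fit$dist == "negbin")
    stats::rnbinom(nrow(data), size = fit$theta, mu = mu)
  else stats::rpois(nrow(data), mu)
  out <- data
  out$response <- y
  out
}

#' Bootstrap BMDL
#'
#' Resamples the data (`"nonparametric"`: with replacement within each
#' dose group, binomial groups drawn from their observed proportions
#' with shrinkage for degenerate groups; `"parametric"`: from the
#' normal/binomial/count distribution implied by the group summaries;
#' `"semiparametric"`: recentred residuals resampled onto the fitted
#' curve, continuous data only), refits the model and re-solves the BMD
#' in each replicate.  The BMDL is the empirical `1 - level` quantile
#' (type 7) of the converged replicate BMDs.
#'
#' @param data A [dose_response_data()] object.
#' @param model Model code for the refits.
#' @param spec A [bmr_spec()].
#' @param kind Resampling scheme, see above.
#' @param n_boot Number of replicates (>= 50; default 1000).
#' @param level One-sided confidence level.
#' @param seed Integer seed; replicates use derived sub-seeds so results
#'   are reproducible.
#' @param dist,fixed,log_response,offset_exposure Passed to [drfit()].
#' @param sd_source SD used by the parametric continuous sampler:
#'   pooled within-group SD (default) or the control group's SD.
#' @return A `bmdl_result` with the replicate BMDs in `$samples`.
#' @export
bootstrap_bmd <- function(data, model, spec,
                          kind = c("nonparametric", "parametric",
                                   "semiparametric"),
                          n_boot = 1000, level = 0.95, seed = 1,
                          dist = NULL, fixed = NULL, log_response = FALSE,
                          offset_exposure = FALSE,
                          sd_source = c("pooled", "control")) {
  kind <- match.arg(kind)
  sd_source <- match.arg(sd_source)
  .check_level(level)
  if (n_boot < 50) stop("n_boot must be at least 50")
  if (kind == "semiparametric" && response_kind(data) != "continuous" &&
      !log_response)
    stop("semiparametric bootstrap applies to continuous responses")
  if (log_response) {
    if (any(data$response <= 0))
      stop("log_response requires strictly positive responses")
    data$response <- log(data$response)
    attr(data, "response_kind") <- "continuous"
    log_response <- FALSE
  }
  fit0 <- drfit(data, model, dist = dist, fixed = fixed,
                offset_exposure = offset_exposure, compute_vcov = FALSE)
  est0 <- bmd(fit0, spec, se = FALSE)
  seeds <- .replicate_seeds(seed, n_boot)
  samples <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    set.seed(seeds[i])
    bi <- tryCatch(suppressWarnings({
      di <- .resample_data(data, kind, fit = fit0, sd_source = sd_source)
      fi <- drfit(di, model, dist = dist, fixed = fixed,
                  offset_exposure = offset_exposure, compute_vcov = FALSE)
      if (!fi$converged) NA_real_ else
        suppressMessages(bmd(fi, spec, se = FALSE)$bmd)
    }), error = function(e) NA_real_)
    samples[i] <- bi
  }
  ok <- is.finite(samples)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    stop("more than 20% of bootstrap replicates failed (", n_failed, "/",
         n_boot, "); review the model and data")
  bmdl <- unname(stats::quantile(samples[ok], 1 - level, type = 7))
  .new_bmdl(bmdl, paste0("boot_", kind), level, bmd = est0$bmd,
            n_boot = n_boot, n_failed = n_failed, samples = samples[ok])
}
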