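# BMD point estimation: root-solving the fitted curve at the target
# response, and delta-method standard errors via after-fitting.

# target response as a function of the free curve parameters (sigma fixed);
# used by the delta method
.target_of_beta <- function(fit, spec, bfree) {
  f2 <- fit
  f2$beta <- c(bfree, fit$fixed)[fit$family$parnames]
  f2$coefficients <- bfree
  target_response(f2, spec)
}

# solve f(d, beta) = ystar for d; closed form when available, else Brent
# bracketing on the log-dose scale over [1e-12 dmax, 100 dmax]
.solve_dose <- function(fit, ystar, dmax) {
  beta <- fit$beta
  fam <- fit$family
  d <- if (!is.null(fam$inverse)) fam$inverse(ystar, beta) else NA_real_
  if (is.finite(d) && d > 0) return(d)
  lo <- 1e-12 * dmax
  hi <- 100 * dmax
  h <- function(ld) fam$fn(exp(ld), beta) - ystar
  hlo <- h(log(lo)); hhi <- h(log(hi))
  if (!is.finite(hlo) || !is.finite(hhi) || hlo * hhi > 0)
    stop("BMR not reachable: target ", format(ystar),
         " not bracketed by the fitted curve on [", format(lo), ", ",
         format(hi), "]")
  r <- stats::uniroot(h, c(log(lo), log(hi)), tol = 1e-12)
  exp(r$root)
}

.dose_scale <- function(fit) {
  if (!is.null(fit$data) && nrow(fit$data) > 0) return(max(fit$data$dose))
  if ("e" %in% fit$family$parnames) return(abs(fit$beta[["e"]]))
  1
}

#' Benchmark dose from a fitted dose-response model
#'
#' Computes the BMD as the dose at which the fitted curve reaches the
#' target response level implied by the BMR specification, together with
#' a delta-method standard error obtained by after-fitting (the BMD is
#' derived from the fitted parameters in a subsequent step, so no
#' re-parameterization of the model is needed).
#'
#' @param fit A converged `drfit` object.
#' @param spec A [bmr_spec()].
#' @param vcov Optional covariance matrix for the free parameters
#'   (e.g. a sandwich estimate from [sandwich_vcov()]); defaults to the
#'   fit's model-based covariance.
#' @param se Compute the delta-method standard error (default TRUE).
#' @return A `bmd_estimate` object: `bmd`, `se`, `target_level`, `p0`,
#'   `definition`, `model_id`, and `extrapolated` (TRUE when the BMD
#'   exceeds the largest observed dose).
#' @examples
#' f <- dr_curve("LL.2", c(b = -1, e = 10))
#' bmd(f, bmr_spec(0.1, "excess"), se = FALSE)$bmd  # 10/9
#' @export
bmd <- function(fit, spec, vcov = NULL, se = TRUE) {
  if (!isTRUE(fit$converged)) stop("model fit did not converge")
  if (any(!is.finite(fit$beta))) stop("invalid fit: non-finite parameters")
  bg <- background_level(fit, spec)
  ystar <- target_response(fit, spec)
  f0 <- bg$f0
  fi <- fit$family$finf(fit$beta)
  # reachability: ystar strictly between the background and the asymptote
  if (is.finite(fi)) {
    lohi <- sort(c(f0, fi))
    if (ystar <= lohi[1] || ystar >= lohi[2])
      stop("BMR not reachable: target ", format(ystar),
           " outside the fitted curve's range (", format(lohi[1]), ", ",
           format(lohi[2]), ")")
  }
  dmax <- .dose_scale(fit)
  bmd_hat <- .solve_dose(fit, ystar, dmax)
  resp_scale <- max(abs(ystar), 1)
  if (abs(fit$family$fn(bmd_hat, fit$beta) - ystar) > 1e-8 * resp_scale)
    stop("BMD solver failed to reach the target response")
  extrapolated <- !is.null(fit$data) && nrow(fit$data) > 0 &&
    bmd_hat > max(fit$data$dose)
  if (extrapolated)
    message("BMD ", format(bmd_hat), " lies beyond the largest tested dose")
  est <- structure(list(bmd = bmd_hat, se = NA_real_, target_level = ystar,
                        p0 = bg$p0, definition = spec$def,
                        model_id = fit$model, spec = spec,
                        extrapolated = extrapolated),
                   class = "bmd_estimate")
  if (se) {
    V <- if (is.null(vcov)) fit$vcov else vcov
    if (!is.null(V)) est$se <- bmd_se_delta(fit, est, vcov = V)
  }
  est
}

#' @export
print.bmd_estimate <- function(x, ...) {
  cat("BMD (", x$definition, "): ", format(x$bmd), sep = "")
  if (is.finite(x$se)) cat("  SE:", format(x$se))
  cat("  target level:", format(x$target_level), "\n")
  invisible(x)
}

#' Delta-method standard error of a BMD
#'
#' Applies the implicit-function theorem to \eqn{h(d, \beta) = f(d,
#' \beta) - y^\ast(\beta)}: the gradient of the BMD with respect to the
#' parameters is \eqn{g = -(\partial h/\partial\beta)/(\partial
#' h/\partial d)} evaluated at the estimate, and \eqn{\mathrm{se} =
#' \sqrt{g^\top \Sigma g}} with \eqn{\Sigma} the parameter covariance.
#' Derivatives are central differences; the target level is recomputed
#' under each parameter perturbation so that model-based backgrounds
#' propagate into the standard error.
#'
#' @param fit A converged `drfit` object.
#' @param est A `bmd_estimate` from [bmd()].
#' @param vcov Covariance matrix of the free parameters; defaults to the
#'   fit's model-based covariance.
#' @return The standard error (0 for a zero covariance matrix).
#' @export
bmd_se_delta <- function(fit, est, vcov = NULL) {
  V <- if (is.null(vcov)) fit$vcov else vcov
  if (is.null(V)) stop("no covariance matrix available")
  if (any(!is.finite(V))) stop("non-finite covariance matrix")
  spec <- est$spec
  free <- fit$free
  b0 <- fit$coefficients[free]
  d0 <- est$bmd
  # dh/dd
  dd <- 1e-6 * max(abs(d0), 1e-6)
  dh_dd <- (fit$family$fn(d0 + dd, fit$beta) -
              fit$family$fn(max(d0 - dd, 0), fit$beta)) /
    (dd + min(dd, d0))
  if (abs(dh_dd) < 1e-12)
    stop("curve too flat for delta method at the BMD")
  # dh/dbeta_j with ystar recomputed at the perturbed parameters
  g <- numeric(length(free))
  for (j in seq_along(free)) {
    eps <- 1e-5 * max(abs(b0[j]), 1e-3)
    bp <- b0; bm <- b0
    bp[j] <- b0[j] + eps; bm[j] <- b0[j] - eps
    hp <- fit$family$fn(d0, c(bp, fit$fixed)[fit$family$parnames]) -
      .target_of_beta(fit, spec, bp)
    hm <- fit$family$fn(d0, c(bm, fit$fixed)[fit$family$parnames]) -
      .target_of_beta(fit, spec, bm)
    g[j] <- (hp - hm) / (2 * eps)
  }
  g <- -g / dh_dd
  se2 <- drop(t(g) %*% V[free, free, drop = FALSE] %*% g)
  sqrt(max(se2, 0))
}
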