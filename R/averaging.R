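# Model-averaged BMD and BMDL: information-criterion weights, estimate
# averaging, curve averaging, and bootstrap model-averaged BMDLs.

#' Model weights from information criteria
#'
#' The default weights are \eqn{w_k = \exp(-\Delta_k/2) / \sum_i
#' \exp(-\Delta_i/2)} with \eqn{\Delta_k} the criterion difference to
#' the best model.  `delta_scale = 1` selects the alternative
#' \eqn{\exp(-\Delta_k)} kernel.  User weights are renormalized.
#'
#' @param criteria Numeric vector of AIC or BIC values (ignored for
#'   `scheme = "user"`).
#' @param scheme `"aic"`, `"bic"`, or `"user"` (label only; the criteria
#'   supplied determine the weights for the first two).
#' @param user_weights Non-negative weights for `scheme = "user"`.
#' @param model_ids Optional model labels.
#' @param delta_scale Divisor of Delta in the exponent (2 = standard).
#' @return A `weight_set`: `model_ids`, `weights`, `deltas`, `criterion`,
#'   `K`.
#' @examples
#' compute_weights(c(100, 102))  # ~0.731 / 0.269
#' @export
compute_weights <- function(criteria = NULL, scheme = c("aic", "bic", "user"),
                            user_weights = NULL, model_ids = NULL,
                            delta_scale = 2) {
  scheme <- match.arg(scheme)
  if (scheme == "user") {
    if (is.null(user_weights) || any(user_weights < 0))
      stop("user scheme needs non-negative user_weights")
    w <- user_weights / sum(user_weights)
    K <- length(w)
    deltas <- rep(NA_real_, K)
  } else {
    if (is.null(criteria) || all(!is.finite(criteria)))
      stop("no finite criteria supplied")
    K <- length(criteria)
    deltas <- criteria - min(criteria, na.rm = TRUE)
    ew <- exp(-deltas / delta_scale)
    ew[!is.finite(criteria)] <- 0
    w <- ew / sum(ew)
  }
  if (is.null(model_ids)) model_ids <- paste0("model", seq_len(K))
  structure(list(model_ids = model_ids, weights = w, deltas = deltas,
                 criterion = scheme, K = K), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  print(stats::setNames(round(x$weights, 4), x$model_ids))
  invisible(x)
}

#' Model-averaged BMD by estimate averaging
#'
#' @param per_model_bmds Per-model BMD estimates.
#' @param ws A `weight_set` from [compute_weights()].
#' @return The weighted average \eqn{\sum_k w_k \mathrm{BMD}_k}.
#' @export
ma_bmd_estimates <- function(per_model_bmds, ws) {
  w <- ws$weights
  if (length(per_model_bmds) != length(w))
    stop("BMD vector and weights differ in length")
  if (any(!is.finite(per_model_bmds) & w > 0))
    stop("non-finite BMD with positive weight")
  sum(w * per_model_bmds, na.rm = FALSE)
}

#' Model-averaged BMDL via the Buckland variance inequality
#'
#' Bounds the MA variance by \eqn{(\sum_k w_k \sqrt{\mathrm{var}_k +
#' (\mathrm{BMD}_k - \mathrm{BMD}_{MA})^2})^2} and reports the one-sided
#' Wald lower limit truncated at 0.
#'
#' @param per_model_bmds Per-model BMDs.
#' @param per_model_vars Per-model delta-method variances (>= 0).
#' @param ws A `weight_set`.
#' @param level One-sided confidence level.
#' @return A `bmdl_result` with extra field `se_ma`.
#' @export
ma_bmdl_buckland <- function(per_model_bmds, per_model_vars, ws,
                             level = 0.95) {
  .check_level(level)
  if (any(per_model_vars < 0)) stop("negative variance input")
  bmd_ma <- ma_bmd_estimates(per_model_bmds, ws)
  se_ma <- sum(ws$weights *
                 sqrt(per_model_vars + (per_model_bmds - bmd_ma)^2))
  out <- .new_bmdl(max(0, bmd_ma - .z_level(level) * se_ma), "buckland",
                   level, bmd = bmd_ma)
  out$se_ma <- se_ma
  out
}

#' Model-averaged BMDL by weighting per-model BMDLs
#'
#' @param per_model_bmdls Per-model BMDL estimates.
#' @param ws A `weight_set`.
#' @return The weighted average \eqn{\sum_k w_k \mathrm{BMDL}_k}.
#' @export
ma_bmdl_weighted <- function(per_model_bmdls, ws) {
  w <- ws$weights
  if (length(per_model_bmdls) != length(w))
    stop("BMDL vector and weights differ in length")
  if (any(!is.finite(per_model_bmdls) & w > 0))
    stop("non-finite BMDL with positive weight")
  sum(w * per_model_bmdls)
}

#' Average entire dose-response curves
#'
#' Builds the mixture curve \eqn{f_{MA}(d) = \sum_k w_k f_k(d)} from a
#' list of fits.  The result behaves like a fit object: backgrounds and
#' BMD are computed from the averaged curve itself via [bmd()].
#'
#' @param fits List of converged `drfit` objects on the same data scale.
#' @param ws A `weight_set` with matching length.
#' @return A `drfit`-compatible `ma_curve` object.
#' @export
ma_curve <- function(fits, ws) {
  w <- ws$weights
  if (length(fits) != length(w)) stop("fits and weights differ in length")
  dirs <- vapply(fits, function(f) f$direction, "")
  if (length(unique(dirs[w > 1e-12])) > 1)
    stop("cannot average curves with mixed directions")
  fam <- structure(list(
    code = "MA", kernel = "ma", parnames = character(0),
    fn = function(dose, beta) {
      Reduce(`+`, Map(function(f, wk) wk * f$family$fn(dose, f$beta),
                      fits, w))
    },
    f0 = function(beta) sum(w * vapply(fits, function(f) f$family$f0(f$beta), 0)),
    finf = function(beta) sum(w * vapply(fits, function(f) f$family$finf(f$beta), 0)),
    inverse = NULL, positive = character(0)), class = "dr_family")
  sig <- vapply(fits, function(f) if (is.null(f$sigma)) NA_real_ else f$sigma, 0)
  data <- fits[[1]]$data
  structure(list(
    family = fam, model = "MA(curve)", dist = fits[[1]]$dist, fixed = NULL,
    free = character(0), beta = numeric(0), coefficients = numeric(0),
    vcov = NULL, loglik = NA_real_, k = NA_integer_, aic = NA_real_,
    bic = NA_real_,
    sigma = if (all(is.na(sig))) NULL else sum(w * sig),
    theta = NULL, residual_deviance = NA_real_, df_residual = NA_integer_,
    fitted = NULL, data = data, n = if (is.null(data)) 0L else nrow(data),
    exposure = NULL, offset_exposure = FALSE, log_response = FALSE,
    converged = TRUE, direction = dirs[which.max(w)],
    weights = w, fits = fits), class = c("ma_curve", "drfit"))
}

# normalize a candidate model specification
.as_spec <- function(m) {
  if (is.character(m)) list(model = m, dist = NULL, fixed = NULL)
  else {
    stopifnot(!is.null(m$model))
    list(model = m$model, dist = m$dist, fixed = m$fixed)
  }
}

#' Model-averaged BMD/BMDL with bootstrap uncertainty
#'
#' Fits all candidate models, computes information-criterion weights, and
#' derives the model-averaged BMD by estimate averaging or curve
#' averaging.  In every bootstrap replicate the data are resampled, all
#' candidates refitted, the weights recomputed from the replicate AICs
#' (propagating model-selection uncertainty), and the MA BMD re-derived;
#' the MA BMDL is the `1 - level` quantile of the replicate MA BMDs.
#' Candidates that fail on the original data are dropped with a warning;
#' replicates where a candidate fails are dropped and counted.
#'
#' @param data A [dose_response_data()] object.
#' @param models List of candidate model codes (or lists with `model`,
#'   `dist`, `fixed`).
#' @param spec A [bmr_spec()].
#' @param approach `"estimate_avg"` or `"curve_avg"`.
#' @param n_boot,level,seed Bootstrap settings as in [bootstrap_bmd()].
#' @param kind Resampling scheme.
#' @param criterion `"aic"` or `"bic"` weights.
#' @param delta_scale Passed to [compute_weights()].
#' @param sd_source Passed to the parametric sampler.
#' @return An `averaging_result`: `bmd_ma`, `bmdl_ma`, `weights`
#'   (`weight_set`), `per_model` table, `method_bmd`, `n_failed`,
#'   `samples`.
#' @export
ma_bootstrap_bmdl <- function(data, models, spec,
                              approach = c("estimate_avg", "curve_avg"),
                              n_boot = 1000, level = 0.95, seed = 1,
                              kind = c("nonparametric", "parametric",
                                       "semiparametric"),
                              criterion = c("aic", "bic"), delta_scale = 2,
                              sd_source = c("pooled", "control")) {
  approach <- match.arg(approach)
  kind <- match.arg(kind)
  criterion <- match.arg(criterion)
  sd_source <- match.arg(sd_source)
  .check_level(level)
  specs <- lapply(models, .as_spec)
  ids <- vapply(specs, function(s) s$model, "")

  fit_all <- function(d, compute_vcov = FALSE) {
    lapply(specs, function(s) {
      tryCatch(suppressWarnings(
        drfit(d, s$model, dist = s$dist, fixed = s$fixed,
              compute_vcov = compute_vcov)),
        error = function(e) NULL)
    })
  }
  ma_point <- function(fits_ok) {
    crit <- vapply(fits_ok, function(f)
      if (criterion == "aic") f$aic else f$bic, 0)
    ws <- compute_weights(crit, scheme = criterion, delta_scale = delta_scale,
                          model_ids = vapply(fits_ok, function(f) f$model, ""))
    bmd_ma <- if (approach == "estimate_avg") {
      bmds <- vapply(fits_ok, function(f)
        suppressMessages(bmd(f, spec, se = FALSE)$bmd), 0)
      ma_bmd_estimates(bmds, ws)
    } else {
      suppressMessages(bmd(ma_curve(fits_ok, ws), spec, se = FALSE)$bmd)
    }
    list(bmd = bmd_ma, ws = ws)
  }

  fits0 <- fit_all(data, compute_vcov = TRUE)
  ok0 <- !vapply(fits0, is.null, TRUE) &
    vapply(fits0, function(f) isTRUE(f$converged), TRUE)
  if (any(!ok0))
    warning("candidate model(s) failed on the original data and were dropped: ",
            paste(ids[!ok0], collapse = ", "))
  fits0 <- fits0[ok0]
  specs <- specs[ok0]
  ids <- ids[ok0]
  if (!length(fits0)) stop("no candidate model could be fitted")

  pt <- ma_point(fits0)
  per_model <- data.frame(
    model = ids,
    bmd = vapply(fits0, function(f)
      suppressMessages(bmd(f, spec, se = FALSE)$bmd), 0),
    weight = pt$ws$weights)

  fit_all_b <- function(d) {
    lapply(specs, function(s) {
      tryCatch(suppressWarnings(
        drfit(d, s$model, dist = s$dist, fixed = s$fixed,
              compute_vcov = FALSE)),
        error = function(e) NULL)
    })
  }

  seeds <- .replicate_seeds(seed, n_boot)
  samples <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    set.seed(seeds[i])
    samples[i] <- tryCatch(suppressWarnings({
      di <- .resample_data(data, kind, fit = fits0[[1]], sd_source = sd_source)
      fi <- fit_all_b(di)
      keep <- !vapply(fi, is.null, TRUE) &
        vapply(fi, function(f) isTRUE(f$converged), TRUE)
      if (!any(keep)) NA_real_ else ma_point(fi[keep])$bmd
    }), error = function(e) NA_real_)
  }
  okb <- is.finite(samples)
  n_failed <- sum(!okb)
  if (n_failed > 0.2 * n_boot)
    stop("more than 20% of bootstrap replicates failed (", n_failed, "/",
         n_boot, "); review the candidate set")
  bmdl_ma <- unname(stats::quantile(samples[okb], 1 - level, type = 7))

  structure(list(bmd_ma = pt$bmd, bmdl_ma = bmdl_ma,
                 method_bmd = approach, method_bmdl = "bootstrap",
                 weights = pt$ws, per_model = per_model, level = level,
                 n_boot = n_boot, n_failed = n_failed,
                 samples = samples[okb]),
            class = "averaging_result")
}

#' @export
print.averaging_result <- function(x, ...) {
  cat("Model-averaged BMD (", x$method_bmd, "): ", format(x$bmd_ma),
      "   BMDL (", x$method_bmdl, "): ", format(x$bmdl_ma), "\n", sep = "")
  print(x$per_model)
  invisible(x)
}
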