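# Nonparametric BMD: pool-adjacent-violators monotonization of the group
# means and linear interpolation between dose levels.

#' Weighted pool-adjacent-violators algorithm
#'
#' Weighted least-squares projection of a sequence onto the monotone
#' cone: adjacent blocks violating the required ordering are repeatedly
#' pooled and replaced by their weighted mean.
#'
#' @param means Numeric sequence (e.g. dose-group means).
#' @param weights Positive weights (e.g. group sizes); default 1.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return Monotone fitted sequence of the same length.
#' @examples
#' pava(c(3, 1, 2))                      # 2 2 2
#' pava(c(2, 1), weights = c(1, 9))      # 1.1 1.1
#' @export
pava <- function(means, weights = rep(1, length(means)),
                 direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  n <- length(means)
  if (n == 0) stop("empty input")
  if (length(weights) != n) stop("means and weights differ in length")
  if (any(weights <= 0)) stop("weights must be positive")
  y <- if (direction == "decreasing") -means else means
  # block representation: value, weight, size
  val <- y; w <- weights; size <- rep(1L, n)
  k <- 1L
  for (i in seq_len(n)) {
    if (i > 1) k <- k + 1L
    val[k] <- y[i]; w[k] <- weights[i]; size[k] <- 1L
    while (k > 1 && val[k - 1] > val[k]) {
      wm <- w[k - 1] + w[k]
      val[k - 1] <- (w[k - 1] * val[k - 1] + w[k] * val[k]) / wm
      w[k - 1] <- wm
      size[k - 1] <- size[k - 1] + size[k]
      k <- k - 1L
    }
  }
  out <- rep(val[seq_len(k)], times = size[seq_len(k)])
  if (direction == "decreasing") -out else out
}

# direction of the dose-response trend from the weighted Spearman
# correlation between dose and group mean
.iso_direction <- function(gs) {
  r <- stats::cor(rank(gs$dose), rank(gs$mean))
  if (!is.finite(r) || r == 0)
    stop("cannot infer trend direction (tied ranks); supply `direction`")
  if (r > 0) "increasing" else "decreasing"
}

#' Isotonic (nonparametric) benchmark dose
#'
#' Monotonizes the dose-group means with [pava()] (weights = group
#' sizes), computes the target response with the monotonized control
#' mean as background, and returns the BMD by linear interpolation
#' between the two flanking dose levels.  No standard error is produced;
#' use [bootstrap_bmd_isotonic()] for a BMDL.
#'
#' @param data A [dose_response_data()] object.
#' @param spec A [bmr_spec()] with a non-hybrid definition
#'   (`additional`, `excess`, `added`, `extra`, `relative`, `point`).
#' @param direction Trend direction; inferred from the weighted Spearman
#'   correlation when `"auto"`.
#' @param log_dose_interpolation Interpolate on the log-dose scale
#'   instead of the natural dose scale (control handled linearly).
#' @return A `bmd_estimate` (with `se = NA`) plus the `isotonic_fit`.
#' @export
bmd_isotonic <- function(data, spec,
                         direction = c("auto", "increasing", "decreasing"),
                         log_dose_interpolation = FALSE) {
  direction <- match.arg(direction)
  if (spec$def %in% c("hybrid_additional", "hybrid_excess"))
    stop("hybrid definitions are not supported by the isotonic procedure")
  gs <- .group_summary(data)
  if (direction == "auto") direction <- .iso_direction(gs)
  mono <- pava(gs$mean, gs$n, direction)
  iso <- structure(list(dose_levels = gs$dose, fitted_means = mono,
                        group_weights = gs$n, direction = direction),
                   class = "isotonic_fit")
  f0 <- mono[1]
  finf <- mono[length(mono)]
  inc_adverse <- if (spec$adverse == "auto") direction == "increasing"
    else spec$adverse == "increasing"
  bmr <- spec$bmr
  p0 <- if (spec$backg_type == "specified_p0" && !is.null(spec$p0))
    spec$p0 else f0
  ystar <- switch(spec$def,
    additional = if (inc_adverse) p0 + bmr else p0 - bmr,
    excess = if (inc_adverse) p0 + bmr * (1 - p0) else p0 * (1 - bmr),
    added = if (inc_adverse) f0 + bmr else f0 - bmr,
    extra = f0 + bmr * (finf - f0),
    relative = if (inc_adverse) f0 * (1 + bmr) else f0 * (1 - bmr),
    point = bmr)
  lo <- min(mono[1], mono[length(mono)])
  hi <- max(mono[1], mono[length(mono)])
  if (ystar < lo - 1e-12 || ystar > hi + 1e-12)
    stop("BMR not reachable: target ", format(ystar),
         " outside the monotonized response range [", format(lo), ", ",
         format(hi), "]")
  # first segment where the monotone step function crosses ystar
  reached <- if (direction == "increasing") mono >= ystar - 1e-12
             else mono <= ystar + 1e-12
  j <- which(reached)[1]
  bmd_hat <- if (j == 1) gs$dose[1] else {
    y1 <- mono[j - 1]; y2 <- mono[j]
    d1 <- gs$dose[j - 1]; d2 <- gs$dose[j]
    if (abs(y2 - y1) < 1e-15) d1
    else if (log_dose_interpolation && d1 > 0)
      exp(log(d1) + (ystar - y1) / (y2 - y1) * (log(d2) - log(d1)))
    else d1 + (ystar - y1) / (y2 - y1) * (d2 - d1)
  }
  structure(list(bmd = bmd_hat, se = NA_real_, target_level = ystar,
                 p0 = if (spec$def %in% c("additional", "excess")) p0 else NULL,
                 definition = spec$def, model_id = "isotonic", spec = spec,
                 extrapolated = FALSE, isotonic_fit = iso),
            class = "bmd_estimate")
}

#' Bootstrap BMDL for the isotonic BMD
#'
#' Shares the resampling machinery of [bootstrap_bmd()] but replaces the
#' parametric refit by monotonization + interpolation in each replicate.
#'
#' @inheritParams bootstrap_bmd
#' @inheritParams bmd_isotonic
#' @return A `bmdl_result`.
#' @export
bootstrap_bmd_isotonic <- function(data, spec, n_boot = 1000, level = 0.95,
                                   seed = 1,
                                   kind = c("nonparametric", "parametric"),
                                   direction = c("auto", "increasing",
                                                 "decreasing"),
                                   log_dose_interpolation = FALSE) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  .check_level(level)
  if (n_boot < 50) stop("n_boot must be at least 50")
  est0 <- bmd_isotonic(data, spec, direction, log_dose_interpolation)
  dir0 <- est0$isotonic_fit$direction  # freeze direction across replicates
  seeds <- .replicate_seeds(seed, n_boot)
  samples <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    set.seed(seeds[i])
    samples[i] <- tryCatch(suppressWarnings({
      di <- .resample_data(data, kind)
      bmd_isotonic(di, spec, dir0, log_dose_interpolation)$bmd
    }), error = function(e) NA_real_)
  }
  ok <- is.finite(samples)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    stop("more than 20% of isotonic bootstrap replicates failed (",
         n_failed, "/", n_boot, ")")
  bmdl <- unname(stats::quantile(samples[ok], 1 - level, type = 7))
  .new_bmdl(bmdl, paste0("iso_boot_", kind), level, bmd = est0$bmd,
            n_boot = n_boot, n_failed = n_failed, samples = samples[ok])
}
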