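# BMR specification: definition, benchmark response, and background type.

.def_codes <- c(additional = "additional", excess = "excess",
                hybridAdd = "hybrid_additional", hybridExc = "hybrid_excess",
                hybrid_additional = "hybrid_additional",
                hybrid_excess = "hybrid_excess",
                added = "added", extra = "extra", relative = "relative",
                point = "point")

.backg_codes <- c(modelBased = "model_based", model_based = "model_based",
                  absolute = "absolute_x0", absolute_x0 = "absolute_x0",
                  hybridSD = "hybrid_sd", hybrid_sd = "hybrid_sd",
                  hybridPercentile = "specified_p0",
                  specified_p0 = "specified_p0")

#' Specify a benchmark response
#'
#' Defines the benchmark response (BMR), the BMD definition, and how the
#' background response level is obtained.  Risk-type definitions
#' (`"additional"`, `"excess"`) interpret BMR as a change in the
#' probability of an adverse event; the hybrid definitions
#' (`"hybridAdd"`, `"hybridExc"`) do the same for a continuous endpoint
#' dichotomized at a cut-off `x0` (given directly, as `k_sd` control
#' standard deviations from the control mean, or implied by a specified
#' background probability `p0`); `"added"`, `"extra"`, and `"relative"`
#' interpret BMR as an absolute, range-normalized, or fold change in the
#' mean response, and `"point"` targets the response level BMR directly.
#'
#' @param bmr Benchmark response; a probability change in (0,1) for the
#'   risk/hybrid definitions, a positive change otherwise.
#' @param def Definition code: `"additional"`, `"excess"`, `"hybridAdd"`,
#'   `"hybridExc"`, `"added"`, `"extra"`, `"relative"`, or `"point"`.
#' @param backg_type Background type: `"modelBased"` (limit of the fitted
#'   curve at dose 0), `"absolute"` (cut-off `x0` on the response scale),
#'   `"hybridSD"` (cut-off `k_sd` SDs from the control mean), or
#'   `"hybridPercentile"` (background probability `p0` given directly).
#' @param p0,x0,k_sd Background parameters, see `backg_type`.
#' @param adverse Adverse direction: `"auto"` (from the fitted curve),
#'   `"increasing"`, or `"decreasing"`.
#' @param sigma_source For hybrid definitions, use the `"pooled"` residual
#'   SD of the fit (default) or the `"control"` group SD.
#' @return A `bmr_spec` object.
#' @examples
#' bmr_spec(0.05, "excess")                       # 5% excess risk
#' bmr_spec(0.1, "hybridAdd", "hybridSD", k_sd = 2)
#' @export
bmr_spec <- function(bmr, def = "excess", backg_type = "modelBased",
                     p0 = NULL, x0 = NULL, k_sd = NULL,
                     adverse = c("auto", "increasing", "decreasing"),
                     sigma_source = c("pooled", "control")) {
  if (!def %in% names(.def_codes))
    stop("unknown definition code: ", def)
  def <- unname(.def_codes[def])
  if (!backg_type %in% names(.backg_codes))
    stop("unknown background type: ", backg_type)
  backg_type <- unname(.backg_codes[backg_type])
  adverse <- match.arg(adverse)
  sigma_source <- match.arg(sigma_source)
  if (!is.numeric(bmr) || length(bmr) != 1 || !is.finite(bmr) || bmr <= 0)
    stop("bmr must be a single positive number")
  risk <- def %in% c("additional", "excess", "hybrid_additional", "hybrid_excess")
  if (risk && bmr >= 1)
    stop("risk-type definitions need bmr in (0, 1)")
  hybrid <- def %in% c("hybrid_additional", "hybrid_excess")
  if (hybrid && !backg_type %in% c("absolute_x0", "hybrid_sd", "specified_p0"))
    stop("hybrid definitions require backg_type 'absolute', 'hybridSD', or 'hybridPercentile'")
  if (backg_type == "specified_p0") {
    if (is.null(p0) || p0 < 0 || p0 >= 1)
      stop("backg_type 'hybridPercentile' requires p0 in [0, 1)")
  }
  if (backg_type == "absolute_x0" && is.null(x0))
    stop("backg_type 'absolute' requires x0")
  if (backg_type == "hybrid_sd" && (is.null(k_sd) || k_sd <= 0))
    stop("backg_type 'hybridSD' requires positive k_sd")
  structure(list(bmr = bmr, def = def, backg_type = backg_type,
                 p0 = p0, x0 = x0, k_sd = k_sd, adverse = adverse,
                 sigma_source = sigma_source),
            class = "bmr_spec")
}

#' @export
print.bmr_spec <- function(x, ...) {
  cat("BMR spec: bmr =", x$bmr, " definition =", x$def,
      " background =", x$backg_type, "\n")
  invisible(x)
}

# adverse direction is increasing?
.adverse_increasing <- function(fit, spec) {
  if (spec$adverse == "auto") fit$direction == "increasing"
  else spec$adverse == "increasing"
}

# sigma used for hybrid definitions
.hybrid_sigma <- function(fit, spec) {
  if (spec$sigma_source == "control" && !is.null(fit$data)) {
    d0 <- min(fit$data$dose)
    s <- stats::sd(fit$data$response[fit$data$dose == d0])
    if (is.finite(s) && s > 0) return(s)
    warning("control-group SD unavailable; falling back to pooled sigma")
  }
  if (is.null(fit$sigma) || !is.finite(fit$sigma))
    stop("hybrid definitions need a continuous fit with finite sigma")
  fit$sigma
}

#' Background response level
#'
#' Computes the background level used by a BMD definition: the background
#' probability of an adverse event `p0` for the risk and hybrid
#' definitions, and the background mean response `f0` for the others.
#' Model-based backgrounds use the analytic limit of the fitted curve at
#' dose 0.  For the hybrid definitions under a normal response model the
#' background probability is \eqn{p_0 = 1 - \Phi((x_0 - f(0))/\sigma)}
#' (adverse direction increasing; mirrored otherwise).
#'
#' @param fit A `drfit` object.
#' @param spec A [bmr_spec()].
#' @return List with `p0`, `f0`, `x0` (hybrid cut-off or NULL), and
#'   `sigma` (hybrid SD or NULL).
#' @export
background_level <- function(fit, spec) {
  f0 <- fit$family$f0(fit$beta)
  def <- spec$def
  hybrid <- def %in% c("hybrid_additional", "hybrid_excess")
  if (hybrid && fit$dist == "binomial")
    stop("hybrid definitions apply to continuous responses, not binomial fits")
  if (hybrid) {
    sig <- .hybrid_sigma(fit, spec)
    inc <- .adverse_increasing(fit, spec)
    if (spec$backg_type == "absolute_x0") {
      x0 <- spec$x0
      p0 <- if (inc) 1 - stats::pnorm((x0 - f0) / sig)
            else stats::pnorm((x0 - f0) / sig)
    } else if (spec$backg_type == "hybrid_sd") {
      x0 <- if (inc) f0 + spec$k_sd * sig else f0 - spec$k_sd * sig
      p0 <- 1 - stats::pnorm(spec$k_sd)
    } else {  # specified p0
      p0 <- spec$p0
      x0 <- if (inc) f0 + sig * stats::qnorm(1 - p0)
            else f0 - sig * stats::qnorm(1 - p0)
    }
    if (p0 < 0 || p0 >= 1)
      stop("background probability p0 = ", format(p0), " outside [0, 1)")
    return(list(p0 = p0, f0 = f0, x0 = x0, sigma = sig))
  }
  if (def %in% c("additional", "excess")) {
    p0 <- if (spec$backg_type == "specified_p0") spec$p0 else f0
    if (p0 < 0 || p0 >= 1)
      stop("background probability p0 = ", format(p0), " outside [0, 1)")
    return(list(p0 = p0, f0 = f0, x0 = NULL, sigma = NULL))
  }
  list(p0 = NULL, f0 = f0, x0 = NULL, sigma = NULL)
}

#' Target response level for a BMR specification
#'
#' Translates a BMR into the response level \eqn{y^\ast} that the fitted
#' curve must reach at the BMD: `additional` gives \eqn{p_0 +
#' \mathrm{BMR}}, `excess` \eqn{p_0 + \mathrm{BMR}(1 - p_0)}, the hybrid
#' definitions invert the normal tail probability at the cut-off, `added`
#' gives \eqn{f(0) + \mathrm{BMR}}, `extra` \eqn{f(0) +
#' \mathrm{BMR}(f(\infty) - f(0))}, `relative` \eqn{f(0)(1 +
#' \mathrm{BMR})}, and `point` returns BMR itself.  All signs flip for a
#' decreasing adverse direction.
#'
#' @inheritParams background_level
#' @return The target response level (probability or response units).
#' @examples
#' f <- dr_curve("LL.3", c(b = -1, d = 1, e = 20))
#' target_response(f, bmr_spec(0.05, "additional", "hybridPercentile", p0 = 0.10))
#' # 0.15
#' @export
target_response <- function(fit, spec) {
  bg <- background_level(fit, spec)
  inc <- .adverse_increasing(fit, spec)
  bmr <- spec$bmr
  ystar <- switch(spec$def,
    additional = if (inc) bg$p0 + bmr else bg$p0 - bmr,
    excess = if (inc) bg$p0 + bmr * (1 - bg$p0) else bg$p0 * (1 - bmr),
    hybrid_additional = {
      q <- if (inc) 1 - bmr - bg$p0 else bmr + bg$p0
      if (q <= 0 || q >= 1)
        stop("BMR not reachable: hybrid tail probability outside (0, 1)")
      bg$x0 - bg$sigma * stats::qnorm(q)
    },
    hybrid_excess = {
      q <- if (inc) 1 - bmr * (1 - bg$p0) - bg$p0 else bmr * (1 - bg$p0) + bg$p0
      if (q <= 0 || q >= 1)
        stop("BMR not reachable: hybrid tail probability outside (0, 1)")
      bg$x0 - bg$sigma * stats::qnorm(q)
    },
    added = if (inc) bg$f0 + bmr else bg$f0 - bmr,
    extra = {
      fi <- fit$family$finf(fit$beta)
      if (!is.finite(fi))
        stop("extra definition needs a finite asymptote f(Inf)")
      bg$f0 + bmr * (fi - bg$f0)
    },
    relative = if (inc) bg$f0 * (1 + bmr) else bg$f0 * (1 - bmr),
    point = bmr)
  ystar
}
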