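# Two-step meta-analytic BMD for hierarchical (nested) designs:
# per-cluster dose-response fits, then a DerSimonian-Laird random-effects
# combination of the cluster BMDs.

#' Per-cluster BMD estimates
#'
#' Fits the dose-response model separately to every cluster
#' (sub-experiment) and extracts the BMD and its delta-method standard
#' error from each fit.  Clusters that fail to converge, or whose BMD or
#' standard error cannot be computed, are excluded with a warning.
#'
#' @param data A [dose_response_data()] with a `cluster` column.
#' @param model Model code for the per-cluster fits.
#' @param spec A [bmr_spec()].
#' @param dist,fixed Passed to [drfit()].
#' @param log_scale Extract log-BMD and its SE (for combination on the
#'   log scale).
#' @return A `meta_input`: `estimates`, `ses`, `cluster_ids`.
#' @export
fit_per_cluster <- function(data, model, spec, dist = NULL, fixed = NULL,
                            log_scale = FALSE) {
  if (is.null(data$cluster)) stop("data carry no cluster column")
  ids <- unique(data$cluster)
  if (length(ids) < 2) stop("need at least 2 clusters")
  est <- se <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    rows <- data$cluster == ids[k]
    sub <- data[rows, , drop = FALSE]
    attr(sub, "response_kind") <- response_kind(data)
    class(sub) <- class(data)
    res <- tryCatch(suppressWarnings({
      f <- drfit(sub, model, dist = dist, fixed = fixed)
      b <- suppressMessages(bmd(f, spec))
      c(b$bmd, b$se)
    }), error = function(e) c(NA_real_, NA_real_))
    est[k] <- res[1]; se[k] <- res[2]
  }
  ok <- is.finite(est) & is.finite(se) & se > 0
  if (any(!ok))
    warning("cluster(s) excluded (fit or BMD failed): ",
            paste(ids[!ok], collapse = ", "))
  if (sum(ok) < 2) stop("fewer than 2 usable clusters")
  est <- est[ok]; se <- se[ok]; ids <- ids[ok]
  if (log_scale) {
    se <- se / est  # delta method on log BMD
    est <- log(est)
  }
  structure(list(estimates = est, ses = se, cluster_ids = as.character(ids),
                 log_scale = log_scale),
            class = "meta_input")
}

#' Random-effects combination of per-cluster BMDs
#'
#' DerSimonian-Laird random-effects meta-analysis: with fixed-effect
#' weights \eqn{w_i = 1/\mathrm{se}_i^2}, the heterogeneity statistic is
#' \eqn{Q = \sum w_i(\theta_i - \bar\theta_{FE})^2}, the between-cluster
#' variance \eqn{\tau^2 = \max(0, (Q - (K-1))/(\sum w - \sum w^2/\sum
#' w))}, and the combined estimate is the mean weighted by
#' \eqn{1/(\mathrm{se}_i^2 + \tau^2)}.  The BMDL is the one-sided normal
#' lower limit, truncated at 0 (exponentiated first when the input is on
#' the log scale).
#'
#' @param m A `meta_input` (or list with `estimates` and `ses`).
#' @param level One-sided confidence level.
#' @return A `meta_result`: `bmd_combined`, `se_combined`,
#'   `bmdl_combined`, `tau2`, `Q`, `K`.
#' @examples
#' meta_combine(list(estimates = c(1, 2), ses = c(0.5, 0.5)))
#' # tau2 = 0.25, combined = 1.5, se = 0.5
#' @export
meta_combine <- function(m, level = 0.95) {
  .check_level(level)
  th <- m$estimates; se <- m$ses
  if (length(th) != length(se)) stop("estimates and ses differ in length")
  if (any(!is.finite(th) | !is.finite(se) | se <= 0))
    stop("estimates must be finite with positive ses")
  K <- length(th)
  log_scale <- isTRUE(m$log_scale)
  if (K == 1) {
    warning("single cluster; returning it unchanged")
    comb <- th; sec <- se; tau2 <- 0; Q <- 0
  } else {
    w <- 1 / se^2
    theta_fe <- sum(w * th) / sum(w)
    Q <- sum(w * (th - theta_fe)^2)
    tau2 <- max(0, (Q - (K - 1)) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (se^2 + tau2)
    comb <- sum(wr * th) / sum(wr)
    sec <- sqrt(1 / sum(wr))
  }
  z <- .z_level(level)
  if (log_scale) {
    bmd_c <- exp(comb)
    bmdl_c <- exp(comb - z * sec)
  } else {
    bmd_c <- comb
    bmdl_c <- max(0, comb - z * sec)
  }
  structure(list(bmd_combined = bmd_c, se_combined = sec,
                 bmdl_combined = bmdl_c, tau2 = tau2, Q = Q, K = K,
                 log_scale = log_scale, level = level),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Random-effects combined BMD:", format(x$bmd_combined),
      " BMDL:", format(x$bmdl_combined), "\n")
  cat("tau^2:", format(x$tau2), " Q:", format(x$Q), " K:", x$K,
      if (x$log_scale) " (combined on log scale)" else "", "\n")
  invisible(x)
}
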