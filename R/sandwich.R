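# Sandwich (robust) covariance for dose-response fits.

#' Sandwich covariance of the fitted parameters
#'
#' Computes the robust covariance \eqn{\hat A^{-1}\hat B(\hat
#' A^{-1})^\top}, where \eqn{\hat A} is the observed information matrix
#' and \eqn{\hat B} the outer-product sum of per-observation score
#' vectors (numerically differentiated).  With `cluster` the scores are
#' summed within clusters before the outer product, giving
#' cluster-robust standard errors for hierarchical designs.  The
#' resulting matrix can be passed to [bmd()] or [bmdl_delta()] via their
#' `vcov` argument; point estimates are unchanged.
#'
#' @param fit A converged `drfit`.
#' @param cluster Optional cluster labels (defaults to the data's
#'   `cluster` column when `cluster = TRUE`).
#' @return A `sandwich_parts` object: `A`, `B`, and `vcov`.
#' @export
sandwich_vcov <- function(fit, cluster = NULL) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (is.null(fit$data)) stop("fit carries no data; cannot compute scores")
  free <- fit$free
  b0 <- unname(fit$coefficients[free])
  # observed information
  A <- .num_hessian(function(b) {
    -.loglik_beta(fit, stats::setNames(b, free))
  }, b0, eps = 1e-5 * pmax(abs(b0), 1e-3))
  dimnames(A) <- list(free, free)
  # per-observation scores by central differences
  n <- nrow(fit$data)
  S <- matrix(0, n, length(free))
  for (j in seq_along(free)) {
    eps <- 1e-6 * max(abs(b0[j]), 1e-3)
    bp <- b0; bm <- b0
    bp[j] <- b0[j] + eps; bm[j] <- b0[j] - eps
    S[, j] <- (.loglik_beta_rows(fit, stats::setNames(bp, free)) -
                 .loglik_beta_rows(fit, stats::setNames(bm, free))) / (2 * eps)
  }
  if (isTRUE(cluster)) cluster <- fit$data$cluster
  if (!is.null(cluster) && !isFALSE(cluster)) {
    if (length(cluster) != n) stop("cluster labels must match rows")
    S <- rowsum(S, group = as.character(cluster))
  }
  B <- crossprod(S)
  dimnames(B) <- list(free, free)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% t(Ainv)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(free, free)
  structure(list(A = A, B = B, vcov = V), class = "sandwich_parts")
}

#' @export
print.sandwich_parts <- function(x, ...) {
  cat("Sandwich covariance (A^-1 B A^-1):\n")
  print(x$vcov)
  invisible(x)
}
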