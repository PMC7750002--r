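# Dose-response model families, drc-style parameterizations.
#
# Each family is a list with:
#   code      string code ("LL.3", "W1.4", ...)
#   parnames  free parameter names after fixing
#   fn(dose, beta)       mean response, vectorized in dose, beta named
#   f0(beta), finf(beta) analytic limits at dose -> 0+ and dose -> Inf
#   inverse(y, beta)     closed-form dose solving fn(dose) = y, or NULL
#   selfstart(data)      crude starting values from the data
#
# Kernels (t = log dose - log e):
#   log-logistic  1 / (1 + exp(b t))
#   log-normal    Phi(b t)
#   weibull1      exp(-exp(b t))
#   weibull2      1 - exp(-exp(b t))
# plus exponential decay d0 * exp(-dose/e) and the multistage family
# c + (1 - c)(1 - exp(-sum b_m dose^m)) with b_m >= 0.

#' List available dose-response model codes
#'
#' @return Character vector of model codes accepted by [drfit()].
#' @export
list_models <- function() {
  c("LL.2", "LL.3", "LL.4", "LN.2", "LN.3", "LN.4",
    "W1.2", "W1.3", "W1.4", "W2.2", "W2.3", "W2.4",
    "EXD.2", "EXD.3", "MS.1", "MS.2", "MS.3")
}

# kernel helpers ------------------------------------------------------------

.kernel <- function(type, b, t) {
  switch(type,
    ll = 1 / (1 + exp(b * t)),
    ln = stats::pnorm(b * t),
    w1 = exp(-exp(b * t)),
    w2 = 1 - exp(-exp(b * t)))
}

# kernel value as t -> -Inf (dose -> 0) and t -> +Inf, given sign of b
.kernel_limit <- function(type, b, at = c("zero", "inf")) {
  at <- match.arg(at)
  s <- if (at == "zero") -sign(b) else sign(b)  # sign of b*t in the limit
  if (s == 0) return(.kernel(type, 0, 0))
  hi <- s > 0  # b*t -> +Inf
  switch(type,
    ll = if (hi) 0 else 1,
    ln = if (hi) 1 else 0,
    w1 = if (hi) 0 else 1,
    w2 = if (hi) 1 else 0)
}

# inverse of kernel: solve kernel(b*t) = k for t
.kernel_inv_t <- function(type, b, k) {
  u <- switch(type,
    ll = log(1 / k - 1),
    ln = stats::qnorm(k),
    w1 = log(-log(k)),
    w2 = log(-log(1 - k)))
  u / b
}

# four-parameter kernel family: f(d) = c + (dup - c) * kernel(b (log d - log e))
.make_kernel_family <- function(code, type, n_par) {
  parnames <- switch(as.character(n_par),
    "2" = c("b", "e"),
    "3" = c("b", "d", "e"),
    "4" = c("b", "c", "d", "e"))
  expand <- function(beta) {
    # full (b, c, dup, e) vector
    switch(as.character(n_par),
      "2" = c(beta[["b"]], 0, 1, beta[["e"]]),
      "3" = c(beta[["b"]], 0, beta[["d"]], beta[["e"]]),
      "4" = c(beta[["b"]], beta[["c"]], beta[["d"]], beta[["e"]]))
  }
  fn <- function(dose, beta) {
    p <- expand(beta)
    b <- p[1]; cc <- p[2]; dup <- p[3]; e <- p[4]
    out <- numeric(length(dose))
    pos <- dose > 0
    out[pos] <- cc + (dup - cc) * .kernel(type, b, log(dose[pos]) - log(e))
    if (any(!pos))
      out[!pos] <- cc + (dup - cc) * .kernel_limit(type, b, "zero")
    out
  }
  f0 <- function(beta) {
    p <- expand(beta)
    p[2] + (p[3] - p[2]) * .kernel_limit(type, p[1], "zero")
  }
  finf <- function(beta) {
    p <- expand(beta)
    p[2] + (p[3] - p[2]) * .kernel_limit(type, p[1], "inf")
  }
  inverse <- function(y, beta) {
    p <- expand(beta)
    k <- (y - p[2]) / (p[3] - p[2])
    if (!is.finite(k) || k <= 0 || k >= 1) return(NA_real_)
    t <- .kernel_inv_t(type, p[1], k)
    exp(t + log(p[4]))
  }
  structure(list(code = code, kernel = type, parnames = parnames,
                 n_par = n_par, fn = fn, f0 = f0, finf = finf,
                 inverse = inverse, positive = "e"),
            class = "dr_family")
}

.make_exd_family <- function(code, n_par) {
  parnames <- if (n_par == 2) c("d", "e") else c("c", "d", "e")
  expand <- function(beta) {
    if (n_par == 2) c(0, beta[["d"]], beta[["e"]])
    else c(beta[["c"]], beta[["d"]], beta[["e"]])
  }
  fn <- function(dose, beta) {
    p <- expand(beta)
    p[1] + (p[2] - p[1]) * exp(-dose / p[3])
  }
  f0 <- function(beta) expand(beta)[2]
  finf <- function(beta) expand(beta)[1]
  inverse <- function(y, beta) {
    p <- expand(beta)
    k <- (y - p[1]) / (p[2] - p[1])
    if (!is.finite(k) || k <= 0 || k > 1) return(NA_real_)
    -p[3] * log(k)
  }
  structure(list(code = code, kernel = "exd", parnames = parnames,
                 n_par = n_par, fn = fn, f0 = f0, finf = finf,
                 inverse = inverse, positive = "e"),
            class = "dr_family")
}

.make_ms_family <- function(code, degree) {
  parnames <- c("c", paste0("b", seq_len(degree)))
  fn <- function(dose, beta) {
    cc <- beta[["c"]]
    bm <- unname(beta[paste0("b", seq_len(degree))])
    s <- outer(dose, seq_len(degree), `^`) %*% bm
    cc + (1 - cc) * (1 - exp(-as.vector(s)))
  }
  f0 <- function(beta) beta[["c"]]
  finf <- function(beta) {
    bm <- unname(beta[paste0("b", seq_len(degree))])
    if (sum(bm) > 0) 1 else beta[["c"]]
  }
  inverse <- if (degree == 1L) {
    function(y, beta) {
      k <- (y - beta[["c"]]) / (1 - beta[["c"]])
      if (!is.finite(k) || k <= 0 || k >= 1) return(NA_real_)
      -log(1 - k) / beta[["b1"]]
    }
  } else NULL
  structure(list(code = code, kernel = "ms", parnames = parnames,
                 n_par = degree + 1L, fn = fn, f0 = f0, finf = finf,
                 inverse = inverse, positive = paste0("b", seq_len(degree)),
                 degree = degree),
            class = "dr_family")
}

#' Retrieve a dose-response family by code
#'
#' Families follow the drc convention: the log-logistic is
#' \eqn{f(d) = c + (d^\ast - c)/(1 + \exp(b(\log d - \log e)))}, the
#' log-normal replaces the logistic kernel by \eqn{\Phi(b(\log d - \log e))},
#' the Weibull type 1/2 kernels are \eqn{\exp(-\exp(\cdot))} and
#' \eqn{1 - \exp(-\exp(\cdot))}, exponential decay is
#' \eqn{f(d) = c + (d^\ast - c)\exp(-d/e)}, and the multistage family of
#' degree m is \eqn{c + (1 - c)(1 - \exp(-\sum_j b_j d^j))} with
#' \eqn{b_j \ge 0}.  The value at dose 0 is always the analytic limit.
#'
#' @param code Model code, one of [list_models()], e.g. `"LL.3"`.
#' @return A `dr_family` object (list of curve, limit and inverse functions).
#' @examples
#' fam <- dr_family("LL.2")
#' fam$fn(10, c(b = -1, e = 10))  # 0.5 at the location parameter
#' @export
dr_family <- function(code) {
  code <- match.arg(code, list_models())
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  n <- as.integer(parts[2])
  switch(parts[1],
    LL  = .make_kernel_family(code, "ll", n),
    LN  = .make_kernel_family(code, "ln", n),
    W1  = .make_kernel_family(code, "w1", n),
    W2  = .make_kernel_family(code, "w2", n),
    EXD = .make_exd_family(code, n),
    MS  = .make_ms_family(code, n))
}
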