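# numerical helpers shared across modules

# central-difference gradient of scalar function f at x
.num_grad <- function(f, x, eps = NULL) {
  p <- length(x)
  if (is.null(eps)) eps <- 1e-6 * pmax(abs(x), 1)
  g <- numeric(p)
  for (j in seq_len(p)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + eps[j]; xm[j] <- x[j] - eps[j]
    g[j] <- (f(xp) - f(xm)) / (2 * eps[j])
  }
  g
}

# central-difference Hessian of scalar function f at x (symmetric)
.num_hessian <- function(f, x, eps = NULL) {
  p <- length(x)
  if (is.null(eps)) eps <- 1e-4 * pmax(abs(x), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- x[i] + eps[i]; xm[i] <- x[i] - eps[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / eps[i]^2
      } else {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[i] <- x[i] + eps[i]; xpp[j] <- x[j] + eps[j]
        xpm[i] <- x[i] + eps[i]; xpm[j] <- x[j] - eps[j]
        xmp[i] <- x[i] - eps[i]; xmp[j] <- x[j] + eps[j]
        xmm[i] <- x[i] - eps[i]; xmm[j] <- x[j] - eps[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * eps[i] * eps[j])
      }
    }
  }
  (H + t(H)) / 2
}

# one-sided normal quantile for a confidence level
.z_level <- function(level) stats::qnorm(level)

# draw per-replicate RNG seeds below 2^31 from a master seed
.replicate_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
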