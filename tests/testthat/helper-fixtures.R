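# shared fixtures, all generated in code

# grouped binomial proportions lying exactly on LL.2(b = -1, e = 10)
exact_ll2_data <- function(n = 100) {
  dose_response_data(dose = c(10 / 9, 10, 90),
                     events = round(n * c(0.1, 0.5, 0.9)),
                     trials = rep(n, 3))
}

# binomial data simulated from LL.2(b = -1, e = 10)
sim_ll2_binomial <- function(seed, doses = c(0.5, 2, 8, 32), trials = 50) {
  generate_scenario(scenario_spec(
    "LL.2", c(b = -1, e = 10), doses = doses, replicates = 1,
    noise = list(kind = "binomial", trials = trials), seed = seed))
}

# continuous data from the validation design (LL.4, limits 2 and 10)
sim_ll4_continuous <- function(seed, sd = 0.1, replicates = 10, profile = 2) {
  generate_scenario(validation_scenario(profile, sd = sd,
                                        replicates = replicates, seed = seed))
}

# brute-force weighted monotone least squares: enumerate all partitions of
# 1..n into consecutive blocks, pool each block to its weighted mean, keep
# the feasible (monotone) candidate with smallest weighted SSE
brute_force_iso <- function(y, w = rep(1, length(y)),
                            direction = "increasing") {
  n <- length(y)
  if (direction == "decreasing") return(-Recall(-y, w, "increasing"))
  if (n == 1) return(y)
  best <- NULL; best_sse <- Inf
  # each subset of cut points between positions defines a partition
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- sum(w[idx] * y[idx]) / sum(w[idx])
    }
    if (is.unsorted(fit)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}
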