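# Seeded synthetic-data generators for all response kinds, including the
# validation design (four-parameter log-logistic curves with limits 2 and
# 10 observed at doses 0.1, 0.5, 1, 5, 10) and a hierarchical generator
# with between-cluster variation on the log-BMD scale.

#' Define a simulation scenario
#'
#' @param model Model code of the true curve.
#' @param beta Named true parameter vector (full family parameterization).
#' @param doses Dose levels (>= 0).
#' @param replicates Observations per dose level (binomial: groups of
#'   `trials` animals each).
#' @param noise List describing the response distribution: `list(kind =
#'   "normal", sd = )`, `list(kind = "binomial", trials = )`,
#'   `list(kind = "poisson")`, or `list(kind = "negbin", theta = )`.
#' @param n_clusters Optional number of clusters (hierarchical designs).
#' @param between_cluster_sd SD of the cluster-level shift of the
#'   log-location (equivalently of the log-BMD for the kernel families);
#'   0 means all clusters share the true curve.
#' @param seed Integer seed.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(model, beta, doses, replicates = 1,
                          noise = list(kind = "normal", sd = 1),
                          n_clusters = NULL, between_cluster_sd = 0,
                          seed = 1) {
  stopifnot(all(doses >= 0), replicates >= 1)
  fam <- dr_family(model)
  beta <- beta[fam$parnames]
  if (anyNA(beta))
    stop("beta must name parameters: ", paste(fam$parnames, collapse = ", "))
  if (noise$kind == "normal" && (is.null(noise$sd) || noise$sd < 0))
    stop("normal noise needs sd >= 0")
  if (noise$kind == "binomial" && (is.null(noise$trials) || noise$trials < 1))
    stop("binomial noise needs trials >= 1")
  if (noise$kind == "negbin" && (is.null(noise$theta) || noise$theta <= 0))
    stop("negbin noise needs theta > 0")
  structure(list(model = model, beta = beta, family = fam, doses = doses,
                 replicates = replicates, noise = noise,
                 n_clusters = n_clusters,
                 between_cluster_sd = between_cluster_sd, seed = seed),
            class = "scenario_spec")
}

# independent truth solver: plain bisection on the true curve, 1e-12
# relative tolerance, deliberately not sharing code with the BMD solver
.bisect_dose <- function(fn, ystar, lo, hi, increasing) {
  flo <- fn(lo) - ystar
  fhi <- fn(hi) - ystar
  if (flo * fhi > 0) stop("truth solver: target not bracketed")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- fn(mid) - ystar
    if (fm == 0 || (hi - lo) < 1e-12 * max(1, hi)) return(mid)
    if ((fm > 0) == (fhi > 0)) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' True benchmark dose of a scenario
#'
#' Computes the BMD implied by the scenario's true curve for a BMR
#' specification, by direct evaluation of the definition formulas and
#' bisection (tolerance 1e-12) on the true curve.  For hybrid
#' definitions the true residual SD is taken from the scenario's noise.
#'
#' @param scn A `scenario_spec`.
#' @param spec A [bmr_spec()].
#' @return The true BMD (dose units).
#' @export
true_bmd <- function(scn, spec) {
  fam <- scn$family
  beta <- scn$beta
  fn <- function(d) fam$fn(d, beta)
  f0 <- fam$f0(beta)
  fi <- fam$finf(beta)
  increasing <- fi >= f0
  inc_adverse <- if (spec$adverse == "auto") increasing
    else spec$adverse == "increasing"
  sig <- if (scn$noise$kind == "normal") scn$noise$sd else NULL
  bmr <- spec$bmr
  p0 <- NULL; x0 <- NULL
  if (spec$def %in% c("additional", "excess")) {
    p0 <- if (spec$backg_type == "specified_p0") spec$p0 else f0
  }
  if (spec$def %in% c("hybrid_additional", "hybrid_excess")) {
    if (is.null(sig)) stop("hybrid truth needs normal noise")
    if (spec$backg_type == "hybrid_sd") {
      x0 <- if (inc_adverse) f0 + spec$k_sd * sig else f0 - spec$k_sd * sig
      p0 <- 1 - stats::pnorm(spec$k_sd)
    } else if (spec$backg_type == "absolute_x0") {
      x0 <- spec$x0
      p0 <- if (inc_adverse) 1 - stats::pnorm((x0 - f0) / sig)
            else stats::pnorm((x0 - f0) / sig)
    } else {
      p0 <- spec$p0
      x0 <- if (inc_adverse) f0 + sig * stats::qnorm(1 - p0)
            else f0 - sig * stats::qnorm(1 - p0)
    }
  }
  ystar <- switch(spec$def,
    additional = if (inc_adverse) p0 + bmr else p0 - bmr,
    excess = if (inc_adverse) p0 + bmr * (1 - p0) else p0 * (1 - bmr),
    hybrid_additional = x0 - sig *
      stats::qnorm(if (inc_adverse) 1 - bmr - p0 else bmr + p0),
    hybrid_excess = x0 - sig *
      stats::qnorm(if (inc_adverse) 1 - bmr * (1 - p0) - p0
                   else bmr * (1 - p0) + p0),
    added = if (inc_adverse) f0 + bmr else f0 - bmr,
    extra = f0 + bmr * (fi - f0),
    relative = if (inc_adverse) f0 * (1 + bmr) else f0 * (1 - bmr),
    point = bmr)
  dmax <- max(scn$doses, 1)
  .bisect_dose(fn, ystar, 1e-12 * dmax, 1e4 * dmax, increasing)
}

#' Generate data from a scenario
#'
#' Draws a seeded data set from the scenario's true curve and noise
#' model.  Hierarchical scenarios draw one multiplicative log-normal
#' shift of the location parameter `e` per cluster (SD
#' `between_cluster_sd` on the log scale, which translates one-to-one to
#' the log-BMD for the kernel families) and stack the per-cluster data
#' with a `cluster` column.
#'
#' @param scn A `scenario_spec`.
#' @param seed Overrides the scenario's seed when given.
#' @return A [dose_response_data()] object; the scenario (with its truth
#'   functions) is attached as attribute `"scenario"`.
#' @export
generate_scenario <- function(scn, seed = NULL) {
  if (!is.null(seed)) scn$seed <- seed
  set.seed(scn$seed)
  fam <- scn$family
  draw_curve <- function(beta) {
    doses <- rep(scn$doses, each = scn$replicates)
    mu <- fam$fn(doses, beta)
    switch(scn$noise$kind,
      normal = dose_response_data(doses,
        response = stats::rnorm(length(doses), mu, scn$noise$sd),
        kind = "continuous"),
      binomial = {
        if (any(mu < -1e-12 | mu > 1 + 1e-12))
          stop("binomial mean outside [0, 1] at some dose")
        mu <- pmin(pmax(mu, 0), 1)
        dose_response_data(doses,
          events = stats::rbinom(length(doses), scn$noise$trials, mu),
          trials = rep(scn$noise$trials, length(doses)))
      },
      poisson = dose_response_data(doses,
        response = stats::rpois(length(doses), mu), kind = "count"),
      negbin = dose_response_data(doses,
        response = stats::rnbinom(length(doses), size = scn$noise$theta,
                                  mu = mu), kind = "count"))
  }
  if (is.null(scn$n_clusters)) {
    out <- draw_curve(scn$beta)
  } else {
    if (!"e" %in% fam$parnames)
      stop("hierarchical generator needs a family with location parameter e")
    shifts <- exp(stats::rnorm(scn$n_clusters, 0, scn$between_cluster_sd))
    parts <- lapply(seq_len(scn$n_clusters), function(k) {
      bk <- scn$beta
      bk[["e"]] <- bk[["e"]] * shifts[k]
      d <- draw_curve(bk)
      d$cluster <- paste0("exp", k)
      d
    })
    df <- do.call(rbind, lapply(parts, as.data.frame))
    kind <- response_kind(parts[[1]])
    out <- if (kind == "binomial")
      dose_response_data(df$dose, events = df$events, trials = df$trials,
                         cluster = df$cluster)
    else dose_response_data(df$dose, response = df$response,
                            cluster = df$cluster, kind = kind)
    attr(out, "cluster_shifts") <- shifts
  }
  attr(out, "scenario") <- scn
  out
}

#' Validation-design scenario for continuous data
#'
#' Four-parameter log-logistic truth with lower and upper limits 2 and
#' 10, observed at doses 0.1, 0.5, 1, 5, 10 under normal noise; three
#' profiles differ in location and steepness (shallow, medium, steep).
#'
#' @param profile 1 (shallow), 2 (medium), or 3 (steep).
#' @param sd Residual SD (1 or 0.1 in the validation design).
#' @param replicates Observations per dose (10 or 3).
#' @param seed Integer seed.
#' @return A `scenario_spec`.
#' @export
validation_scenario <- function(profile = 2, sd = 0.1, replicates = 10,
                                seed = 1) {
  pars <- switch(as.character(profile),
    "1" = c(b = -0.75, c = 2, d = 10, e = 2),
    "2" = c(b = -1.5, c = 2, d = 10, e = 1),
    "3" = c(b = -3, c = 2, d = 10, e = 1),
    stop("profile must be 1, 2, or 3"))
  scenario_spec("LL.4", pars, doses = c(0.1, 0.5, 1, 5, 10),
                replicates = replicates,
                noise = list(kind = "normal", sd = sd), seed = seed)
}

#' Canonical synthetic fixture suite
#'
#' Generates the named synthetic data sets used throughout the tests and
#' examples: an exact-interpolation binomial set lying on an LL.2 curve,
#' an earthworm-like binomial set with a 0.10 natural-mortality lower
#' limit, an overdispersed count set, a fish-like continuous set suited
#' to a four-model candidate set, and a 9-cluster hierarchical binomial
#' set.  All are reproducible from the seed; when `dir` is given, each
#' data set is written as CSV with a JSON truth sidecar.
#'
#' @param seed Master seed.
#' @param dir Optional output directory for CSV/JSON files.
#' @return Named list of data sets (each with attribute `"scenario"`
#'   where applicable).
#' @export
make_fixture_suite <- function(seed = 1, dir = NULL) {
  ss <- .replicate_seeds(seed, 8)
  out <- list()

  # binomial proportions lying exactly on LL.2(b = -1, e = 10)
  out$exact_binomial <- dose_response_data(
    dose = c(10 / 9, 10, 90), events = c(10, 50, 90),
    trials = c(100, 100, 100))

  # earthworm-like: 40 worms per concentration, natural mortality 0.10
  worm <- scenario_spec("LN.4", c(b = 1.5, c = 0.10, d = 1, e = 40),
                        doses = c(0, 5, 10, 20, 40, 80), replicates = 1,
                        noise = list(kind = "binomial", trials = 40),
                        seed = ss[1])
  out$earthworm <- generate_scenario(worm)

  # overdispersed shoot counts: decreasing LL.3, negbin theta = 1
  shoots <- scenario_spec("LL.3", c(b = 1, d = 8, e = 0.3),
                          doses = c(0, 0.01, 0.1, 1, 10, 100, 1000),
                          replicates = 6,
                          noise = list(kind = "negbin", theta = 1),
                          seed = ss[2])
  out$shoots_count <- generate_scenario(shoots)

  # fish-like continuous decay, 10 replicates per concentration
  fish <- scenario_spec("EXD.2", c(d = 3, e = 40),
                        doses = c(0, 6.25, 12.5, 25, 50, 100, 200),
                        replicates = 10,
                        noise = list(kind = "normal", sd = 0.35),
                        seed = ss[3])
  out$fish <- generate_scenario(fish)

  # 9 independent sub-experiments, 20 animals per concentration
  hier <- scenario_spec("LL.2", c(b = -2, e = 0.1),
                        doses = c(0.0125, 0.025, 0.05, 0.1, 0.2, 0.4),
                        replicates = 1,
                        noise = list(kind = "binomial", trials = 20),
                        n_clusters = 9, between_cluster_sd = 0.25,
                        seed = ss[4])
  out$hierarchical <- generate_scenario(hier)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.csv(as.data.frame(out[[nm]]),
                       file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
      scn <- attr(out[[nm]], "scenario")
      truth <- if (is.null(scn)) {
        list(note = "exact values on LL.2 curve with b = -1, e = 10")
      } else {
        list(model = scn$model, beta = as.list(scn$beta),
             noise = scn$noise, seed = scn$seed)
      }
      jsonlite::write_json(truth, file.path(dir, paste0(nm, "_truth.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
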