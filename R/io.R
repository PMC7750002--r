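# CSV input, configuration-driven analysis pipeline, and JSON/CSV output.

#' Read dose-response data from CSV
#'
#' Expects a header row.  Default column names are `dose` plus either
#' `response` (continuous/count) or `events` and `trials` (binomial),
#' with optional `weight` and `cluster`; the `mapping` argument renames
#' them.  Validation errors cite the offending row numbers.
#'
#' @param path CSV file path.
#' @param mapping Named list/vector mapping canonical names (`dose`,
#'   `response`, `events`, `trials`, `weight`, `cluster`) to the file's
#'   column names.
#' @param kind Optional response kind override for `response` columns.
#' @return A [dose_response_data()] object.
#' @export
read_dose_data <- function(path, mapping = NULL, kind = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(canon) {
    col <- if (!is.null(mapping) && canon %in% names(mapping))
      mapping[[canon]] else canon
    if (col %in% names(raw)) raw[[col]] else NULL
  }
  dose <- pick("dose")
  if (is.null(dose)) stop("no dose column found in ", path)
  nonnum <- which(is.na(suppressWarnings(as.numeric(dose))) & !is.na(dose))
  if (length(nonnum))
    stop("non-numeric dose on row(s) ", paste(nonnum, collapse = ", "))
  dose_response_data(as.numeric(dose),
                     response = pick("response"),
                     events = pick("events"), trials = pick("trials"),
                     weight = pick("weight"), cluster = pick("cluster"),
                     kind = kind)
}

#' Run a configured BMD analysis
#'
#' Executes the full pipeline from a configuration list (or JSON file):
#' read data, fit the requested model(s), derive BMD and BMDL by the
#' requested method(s), optionally model-average, and write a JSON
#' result bundle plus a CSV export of the fitted curve(s) with a
#' one-sided confidence band.  The configuration fully determines the
#' output given the seed.
#'
#' Configuration fields: `input` (CSV path) or `data`
#' (a [dose_response_data()] passed programmatically), `mapping`,
#' `models` (vector of model codes; one model = single-model analysis),
#' `fixed` (named list per model code, optional), `dist`, `bmr`, `def`,
#' `backg_type`, `p0`/`x0`/`k_sd`, `bmdl` (any of `"delta"`,
#' `"delta_log"`, `"inv"`, `"bootNP"`, `"bootPar"`, `"bootSemi"`),
#' `level`, `n_boot`, `seed`, `sandwich` (logical), `cluster` (column
#' flag for cluster-robust sandwich), `ma` (`"estimate"` or `"curve"`),
#' `ma_bmdl` (`"buckland"`, `"weighted"`, `"boot"`), `output_json`,
#' `output_curve`.
#'
#' @param cfg Configuration list or path to a JSON configuration file.
#' @return The result bundle, invisibly as a list (also written to
#'   `output_json` when set).
#' @export
run_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  get_or <- function(nm, default) if (is.null(cfg[[nm]])) default else cfg[[nm]]

  data <- if (!is.null(cfg$data)) cfg$data
    else read_dose_data(cfg$input, cfg$mapping)
  level <- get_or("level", 0.95)
  .check_level(level)
  seed <- get_or("seed", 1)
  n_boot <- get_or("n_boot", 1000)
  spec <- bmr_spec(get_or("bmr", 0.1), get_or("def", "excess"),
                   get_or("backg_type", "modelBased"),
                   p0 = cfg$p0, x0 = cfg$x0, k_sd = cfg$k_sd)
  models <- get_or("models", "LL.3")
  methods <- get_or("bmdl", "delta")
  log_resp <- isTRUE(cfg$log_response)
  offset_exp <- isTRUE(cfg$offset_exposure)

  boot_kind <- c(bootNP = "nonparametric", bootPar = "parametric",
                 bootSemi = "semiparametric")

  fit_one <- function(code) {
    fx <- if (!is.null(cfg$fixed)) unlist(cfg$fixed[[code]]) else NULL
    drfit(data, code, dist = cfg$dist, fixed = fx,
          log_response = log_resp, offset_exposure = offset_exp)
  }

  results <- list(config = cfg[setdiff(names(cfg),
                                       c("data", "output_json",
                                         "output_curve"))],
                  seed = seed,
                  version = as.character(utils::packageVersion("benchdose")),
                  models = list())
  log_msgs <- character(0)
  note <- function(...) log_msgs <<- c(log_msgs, paste0(...))

  fits <- list()
  for (code in models) {
    fit <- fit_one(code)
    fits[[code]] <- fit
    V <- fit$vcov
    used_sandwich <- FALSE
    if (isTRUE(cfg$sandwich)) {
      sw <- sandwich_vcov(fit, cluster = isTRUE(cfg$cluster))
      V <- sw$vcov
      used_sandwich <- TRUE
      note("model ", code, ": sandwich covariance",
           if (isTRUE(cfg$cluster)) " (cluster-robust)" else "")
    }
    est <- withCallingHandlers(
      bmd(fit, spec, vcov = V),
      message = function(m) {
        note("model ", code, ": ", conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    note("model ", code, ": direction ", fit$direction)
    bmdls <- list()
    for (m in methods) {
      bl <- switch(m,
        delta = bmdl_delta(fit, est, level, "natural"),
        delta_log = bmdl_delta(fit, est, level, "log"),
        inv = bmdl_inverse_regression(fit, spec, level, vcov = V),
        bootNP = , bootPar = , bootSemi =
          bootstrap_bmd(data, code, spec, kind = boot_kind[[m]],
                        n_boot = n_boot, level = level, seed = seed,
                        dist = cfg$dist,
                        fixed = if (!is.null(cfg$fixed))
                          unlist(cfg$fixed[[code]]) else NULL,
                        log_response = log_resp,
                        offset_exposure = offset_exp),
        stop("unknown bmdl method: ", m))
      if (is.finite(bl$n_failed) && bl$n_failed > 0)
        note("model ", code, " ", m, ": ", bl$n_failed,
             " bootstrap replicates dropped")
      bmdls[[m]] <- list(bmdl = bl$bmdl, method = m, level = level,
                         n_failed = if (is.finite(bl$n_failed))
                           bl$n_failed else NULL)
    }
    results$models[[code]] <- list(
      model = code, converged = fit$converged,
      beta = as.list(fit$beta), sigma = fit$sigma, theta = fit$theta,
      loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
      residual_deviance = fit$residual_deviance,
      df_residual = fit$df_residual,
      direction = fit$direction, sandwich = used_sandwich,
      bmd = est$bmd, se = if (is.finite(est$se)) est$se else NULL,
      target_level = est$target_level, p0 = est$p0,
      extrapolated = est$extrapolated, bmdl = bmdls)
  }

  if (length(models) > 1 && !is.null(cfg$ma)) {
    approach <- if (identical(cfg$ma, "curve")) "curve_avg" else "estimate_avg"
    crit <- vapply(fits, function(f) f$aic, 0)
    ws <- compute_weights(crit, "aic", model_ids = names(fits),
                          delta_scale = get_or("delta_scale", 2))
    bmds <- vapply(names(fits), function(code) results$models[[code]]$bmd, 0)
    ma <- list(weights = as.list(stats::setNames(ws$weights, names(fits))))
    ma$bmd_estimate_avg <- ma_bmd_estimates(bmds, ws)
    ma$bmd_curve_avg <- suppressMessages(
      bmd(ma_curve(fits, ws), spec, se = FALSE)$bmd)
    ma_methods <- get_or("ma_bmdl", "buckland")
    for (m in ma_methods) {
      if (m == "buckland") {
        vars <- vapply(names(fits), function(code) {
          s <- results$models[[code]]$se
          if (is.null(s)) NA_real_ else s^2
        }, 0)
        ma$bmdl_buckland <- ma_bmdl_buckland(bmds, vars, ws, level)$bmdl
      } else if (m == "weighted") {
        bl <- vapply(names(fits), function(code)
          results$models[[code]]$bmdl[[1]]$bmdl, 0)
        ma$bmdl_weighted <- ma_bmdl_weighted(bl, ws)
      } else if (m == "boot") {
        mb <- ma_bootstrap_bmdl(data, as.list(models), spec,
                                approach = approach, n_boot = n_boot,
                                level = level, seed = seed)
        ma$bmdl_bootstrap <- mb$bmdl_ma
        if (mb$n_failed > 0)
          note("model averaging: ", mb$n_failed,
               " bootstrap replicates dropped")
      }
    }
    results$ma <- ma
  }

  if (!is.null(data$cluster) && isTRUE(cfg$meta)) {
    mi <- fit_per_cluster(data, models[[1]], spec, dist = cfg$dist,
                          log_scale = isTRUE(cfg$meta_log_scale))
    mr <- meta_combine(mi, level)
    results$meta <- list(per_cluster = data.frame(cluster = mi$cluster_ids,
                                                  estimate = mi$estimates,
                                                  se = mi$ses),
                         bmd_combined = mr$bmd_combined,
                         se_combined = mr$se_combined,
                         bmdl_combined = mr$bmdl_combined,
                         tau2 = mr$tau2, Q = mr$Q, K = mr$K)
  }

  results$log <- log_msgs

  if (!is.null(cfg$output_curve)) {
    dmax <- max(data$dose)
    grid <- seq(0, dmax, length.out = get_or("curve_points", 101))
    curves <- data.frame(dose = grid)
    for (code in names(fits)) {
      fit <- fits[[code]]
      curves[[paste0(code, "_fitted")]] <- predict(fit, grid)
      if (!is.null(fit$vcov)) {
        z <- .z_level(level)
        sef <- vapply(grid, function(d) {
          b0 <- unname(fit$coefficients[fit$free])
          g <- .num_grad(function(b) {
            fit$family$fn(d, c(stats::setNames(b, fit$free),
                               fit$fixed)[fit$family$parnames])
          }, b0, eps = 1e-5 * pmax(abs(b0), 1e-3))
          sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
        }, 0)
        inc <- fit$direction == "increasing"
        curves[[paste0(code, "_band")]] <- if (inc)
          curves[[paste0(code, "_fitted")]] + z * sef
        else curves[[paste0(code, "_fitted")]] - z * sef
      }
    }
    utils::write.csv(curves, cfg$output_curve, row.names = FALSE)
  }
  if (!is.null(cfg$output_json)) {
    jsonlite::write_json(results, cfg$output_json, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(results)
}
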