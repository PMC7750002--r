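# Dose-response data container.

#' Construct a dose-response data set
#'
#' Validates and assembles unit-level dose-response data.  Exactly one
#' response encoding is allowed: `response` (continuous or count) or
#' `events` + `trials` (binomial, one row per dose group or per animal
#' batch).  Optional per-row `weight` (an observation weight or an exposure
#' measure such as lifespan-days, used as a rate offset for count models)
#' and `cluster` (sub-experiment label for hierarchical designs).
#'
#' @param dose Numeric vector of non-negative doses/concentrations.
#' @param response Numeric responses (continuous) or non-negative integer
#'   counts; mutually exclusive with `events`/`trials`.
#' @param events,trials Non-negative integer events out of positive trials.
#' @param weight Optional positive weights/exposures, recycled if length 1.
#' @param cluster Optional cluster labels.
#' @param kind One of `"binomial"`, `"count"`, `"continuous"`; inferred
#'   when omitted (events/trials present -> binomial; integer response ->
#'   count unless `kind` says otherwise).
#' @return A `dose_response_data` object (a data frame with attributes).
#' @examples
#' dose_response_data(dose = c(0, 1, 10), events = c(1, 5, 30),
#'                    trials = c(40, 40, 40))
#' @export
dose_response_data <- function(dose, response = NULL, events = NULL,
                               trials = NULL, weight = NULL, cluster = NULL,
                               kind = NULL) {
  dose <- as.numeric(dose)
  n <- length(dose)
  bad <- which(!is.finite(dose) | dose < 0)
  if (length(bad))
    stop("negative or non-finite dose on row(s) ", paste(bad, collapse = ", "))
  has_resp <- !is.null(response)
  has_bin <- !is.null(events) || !is.null(trials)
  if (has_resp == has_bin)
    stop("supply exactly one response encoding: `response`, or `events` + `trials`")
  if (has_bin) {
    if (is.null(events) || is.null(trials))
      stop("binomial data need both `events` and `trials`")
    events <- as.numeric(events); trials <- as.numeric(trials)
    if (length(events) != n || length(trials) != n)
      stop("events/trials length must match dose")
    bad <- which(!is.finite(events) | !is.finite(trials) | trials <= 0 |
                   events < 0 | events > trials |
                   events != round(events) | trials != round(trials))
    if (length(bad))
      stop("invalid events/trials (need integers, 0 <= events <= trials) on row(s) ",
           paste(bad, collapse = ", "))
    kind <- "binomial"
    df <- data.frame(dose = dose, events = events, trials = trials)
  } else {
    response <- as.numeric(response)
    if (length(response) != n) stop("response length must match dose")
    bad <- which(!is.finite(response))
    if (length(bad))
      stop("non-finite response on row(s) ", paste(bad, collapse = ", "))
    if (is.null(kind)) {
      kind <- if (all(response >= 0 & response == round(response)))
        "count" else "continuous"
    }
    kind <- match.arg(kind, c("count", "continuous"))
    if (kind == "count") {
      bad <- which(response < 0 | response != round(response))
      if (length(bad))
        stop("count responses must be non-negative integers; offending row(s) ",
             paste(bad, collapse = ", "))
    }
    df <- data.frame(dose = dose, response = response)
  }
  if (!is.null(weight)) {
    weight <- rep_len(as.numeric(weight), n)
    if (any(!is.finite(weight) | weight <= 0))
      stop("weights must be positive and finite")
    df$weight <- weight
  }
  if (!is.null(cluster)) df$cluster <- rep_len(as.character(cluster), n)
  structure(df, response_kind = kind,
            class = c("dose_response_data", "data.frame"))
}

#' @export
print.dose_response_data <- function(x, ...) {
  cat("Dose-response data (", attr(x, "response_kind"), "), ",
      nrow(x), " rows, ", length(unique(x$dose)), " dose levels\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Response kind of a data set
#' @param data A `dose_response_data` object.
#' @return `"binomial"`, `"count"`, or `"continuous"`.
#' @export
response_kind <- function(data) attr(data, "response_kind")

# group-level summary used by fitters, bootstrap and the isotonic module:
# one row per dose level with group mean, size and (binomial) events/trials
.group_summary <- function(data) {
  kind <- response_kind(data)
  lev <- sort(unique(data$dose))
  if (kind == "binomial") {
    ev <- vapply(lev, function(d) sum(data$events[data$dose == d]), 0)
    tr <- vapply(lev, function(d) sum(data$trials[data$dose == d]), 0)
    data.frame(dose = lev, events = ev, trials = tr, mean = ev / tr, n = tr)
  } else {
    m <- vapply(lev, function(d) mean(data$response[data$dose == d]), 0)
    s <- vapply(lev, function(d) stats::sd(data$response[data$dose == d]), 0)
    k <- vapply(lev, function(d) sum(data$dose == d), 0)
    data.frame(dose = lev, mean = m, sd = s, n = k)
  }
}
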