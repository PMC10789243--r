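# Behavioural endpoint formulas for preclinical phenotyping: discrimination
# index (D2), exploration-time inclusion rule, latency censoring, and
# per-group summary tables. Inferential statistics (ANOVA, post hoc tests)
# are deliberately not reimplemented: the tables emitted here feed any
# stats package.

#' Discrimination index (D2 score)
#'
#' `(t_novel - t_familiar) / (t_novel + t_familiar)`, the standard
#' recognition-memory readout. Positive values indicate preference for the
#' novel stimulus (object, location or conspecific); an animal with no
#' memory of the familiar stimulus scores near 0. Vectorized.
#'
#' @param t_novel,t_familiar Exploration times in seconds, non-negative;
#'   total exploration must be positive (enforce upstream with
#'   [apply_inclusion()]).
#' @return D2 score(s) in `[-1, 1]`.
#' @examples
#' d2_score(30, 10)  # 0.5
#' @export
d2_score <- function(t_novel, t_familiar) {
  if (any(t_novel < 0, na.rm = TRUE) || any(t_familiar < 0, na.rm = TRUE)) {
    stop("exploration times must be non-negative", call. = FALSE)
  }
  total <- t_novel + t_familiar
  if (any(total <= 0, na.rm = TRUE)) {
    stop("zero total exploration time: D2 undefined ",
         "(such trials should be excluded by the inclusion rule)",
         call. = FALSE)
  }
  (t_novel - t_familiar) / total
}

#' Apply the minimum-exploration inclusion rule
#'
#' Recognition-memory trials (NOR, OL, SR) require a minimum of total
#' object/stimulus exploration for the animal to enter the analysis;
#' animals below the threshold are excluded, which also guards the D2
#' denominator. The threshold applies to total (novel + familiar)
#' exploration and is inclusive at the boundary.
#'
#' @param trials Data frame with columns `animal_id`, `group_id`, `assay`,
#'   `t_novel`, `t_familiar`.
#' @param min_exploration Inclusion threshold in seconds (default 3).
#' @return Data frame of endpoint records: `animal_id`, `group_id`,
#'   `assay`, `endpoint_value` (D2; `NA` when excluded), `included`,
#'   `censored` (always `FALSE` for these assays).
#' @export
apply_inclusion <- function(trials, min_exploration = 3) {
  trials <- as.data.frame(trials)
  need <- c("animal_id", "group_id", "assay", "t_novel", "t_familiar")
  if (!all(need %in% names(trials))) {
    stop("trials needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(trials$t_novel < 0 | trials$t_familiar < 0, na.rm = TRUE)) {
    stop("exploration times must be non-negative", call. = FALSE)
  }
  total <- trials$t_novel + trials$t_familiar
  included <- !is.na(total) & total >= min_exploration
  value <- rep(NA_real_, nrow(trials))
  value[included] <- d2_score(trials$t_novel[included],
                              trials$t_familiar[included])
  data.frame(
    animal_id = trials$animal_id,
    group_id = trials$group_id,
    assay = trials$assay,
    endpoint_value = value,
    included = included,
    censored = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Cap a latency at the test duration
#'
#' Latency-to-event endpoints (e.g. latency to consume novel food in the
#' hyponeophagia test) are censored at the end of the test: an animal that
#' never shows the event receives the maximal latency score. A latency
#' recorded beyond the test duration is likewise capped. Whether a latency
#' landing exactly on the boundary counts as censored is an explicit
#' convention (`censor_at_limit`, default `FALSE`). Vectorized and
#' idempotent.
#'
#' @param latency Latency in seconds, or `NA` for no event observed.
#' @param event_observed Logical; `FALSE` forces the no-event branch even
#'   when a (partial) latency was recorded. Default `!is.na(latency)`.
#' @param test_duration Test length in seconds (default 300 = 5 min).
#' @param censor_at_limit Treat a latency exactly equal to `test_duration`
#'   as censored (default `FALSE`).
#' @return Data frame with columns `value` (capped latency) and `censored`.
#' @examples
#' cap_latency(NA)   # value 300, censored
#' cap_latency(120)  # value 120, not censored
#' @export
cap_latency <- function(latency, event_observed = !is.na(latency),
                        test_duration = 300, censor_at_limit = FALSE) {
  if (test_duration <= 0) stop("test_duration must be > 0", call. = FALSE)
  if (any(latency < 0, na.rm = TRUE)) {
    stop("latency must be non-negative", call. = FALSE)
  }
  n <- max(length(latency), length(event_observed))
  latency <- rep_len(latency, n)
  event_observed <- rep_len(event_observed, n)
  no_event <- !event_observed | is.na(latency)
  over <- !no_event &
    (latency > test_duration | (censor_at_limit & latency == test_duration))
  value <- ifelse(no_event | latency > test_duration, test_duration, latency)
  data.frame(value = value, censored = no_event | over)
}

#' Compute endpoint records for a trial table
#'
#' Dispatches per assay: recognition assays (NOR, OL, SR) go through the
#' inclusion rule and D2; `hyponeophagia` through latency capping; every
#' other assay passes `raw_value` through unchanged (distance travelled,
#' grooming time, mount count, percent freezing, ...).
#'
#' @param trials Data frame in the trial schema: `animal_id`, `group_id`,
#'   `assay`, and the assay-relevant subset of `t_novel`, `t_familiar`,
#'   `latency`, `event_observed`, `raw_value`.
#' @param min_exploration Seconds, see [apply_inclusion()].
#' @param test_duration Seconds, see [cap_latency()].
#' @param censor_at_limit See [cap_latency()].
#' @return Data frame of endpoint records (`animal_id`, `group_id`,
#'   `assay`, `endpoint_value`, `included`, `censored`).
#' @export
behaviour_endpoints <- function(trials, min_exploration = 3,
                                test_duration = 300,
                                censor_at_limit = FALSE) {
  trials <- as.data.frame(trials)
  if (!all(c("animal_id", "group_id", "assay") %in% names(trials))) {
    stop("trials needs columns animal_id, group_id, assay", call. = FALSE)
  }
  d2_assays <- c("NOR", "OL", "SR")
  out <- vector("list", 3L)
  is_d2 <- trials$assay %in% d2_assays
  if (any(is_d2)) {
    out[[1L]] <- apply_inclusion(trials[is_d2, , drop = FALSE],
                                 min_exploration)
  }
  is_lat <- trials$assay == "hyponeophagia"
  if (any(is_lat)) {
    tl <- trials[is_lat, , drop = FALSE]
    ev <- if ("event_observed" %in% names(tl)) {
      as.logical(tl$event_observed) & !is.na(tl$latency)
    } else {
      !is.na(tl$latency)
    }
    cl <- cap_latency(tl$latency, ev, test_duration, censor_at_limit)
    out[[2L]] <- data.frame(
      animal_id = tl$animal_id, group_id = tl$group_id, assay = tl$assay,
      endpoint_value = cl$value, included = TRUE, censored = cl$censored,
      stringsAsFactors = FALSE
    )
  }
  is_raw <- !is_d2 & !is_lat
  if (any(is_raw)) {
    tr <- trials[is_raw, , drop = FALSE]
    if (!"raw_value" %in% names(tr)) {
      stop("raw_value column required for assay(s): ",
           paste(unique(tr$assay), collapse = ", "), call. = FALSE)
    }
    out[[3L]] <- data.frame(
      animal_id = tr$animal_id, group_id = tr$group_id, assay = tr$assay,
      endpoint_value = tr$raw_value, included = !is.na(tr$raw_value),
      censored = FALSE, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  rownames(res) <- NULL
  res
}

#' Per-group endpoint summary (mean, SD, SEM)
#'
#' Summarizes included records per (group, assay) in stable first-seen
#' group order. SD uses the n-1 denominator and SEM = SD / sqrt(n), the
#' conventions of the usual graphing/statistics software. Excluded animals
#' are counted separately and never enter the statistics. Single-animal
#' groups have undefined SD/SEM (`NA`); a group with zero included records
#' gets a warning and an all-`NA` statistics row.
#'
#' @param records Endpoint records from [behaviour_endpoints()] or
#'   [apply_inclusion()].
#' @return Data frame with columns `group_id`, `assay`, `n_included`,
#'   `n_excluded`, `mean`, `sd`, `sem`.
#' @export
summarize_groups <- function(records) {
  records <- as.data.frame(records)
  need <- c("group_id", "assay", "endpoint_value", "included")
  if (!all(need %in% names(records))) {
    stop("records needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  key <- paste(records$group_id, records$assay, sep = "\r")
  keys <- unique(key)           # stable first-seen order
  rows <- lapply(keys, function(k) {
    r <- records[key == k, , drop = FALSE]
    inc <- r$endpoint_value[r$included]
    n <- length(inc)
    if (n == 0L) {
      warning("group '", r$group_id[1L], "' (", r$assay[1L],
              ") has no included records", call. = FALSE)
    }
    s <- if (n >= 2L) stats::sd(inc) else NA_real_
    data.frame(
      group_id = r$group_id[1L], assay = r$assay[1L],
      n_included = n, n_excluded = sum(!r$included),
      mean = if (n >= 1L) mean(inc) else NA_real_,
      sd = s, sem = s / sqrt(n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a behaviour trial table
#'
#' @param path TSV with header; columns `animal_id`, `group_id`, `assay`
#'   required, plus the assay-relevant measurement columns (`t_novel`,
#'   `t_familiar`, `latency`, `event_observed`, `raw_value`).
#' @return Data frame of trials.
#' @export
read_trials <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("animal_id", "group_id", "assay") %in% names(df))) {
    stop("expected columns animal_id, group_id, assay in ", path,
         call. = FALSE)
  }
  df
}
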