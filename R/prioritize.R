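# Merge CGEM and TargOpt rankings and attach annotation flags for expert
# triage. Flags inform a human decision; they never filter or reorder.

# Normalize a ranked pair table to (pair, rank). Accepts the column naming
# of either engine's output.
.pair_ranks <- function(df, what) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(pair = character(0), rank = integer(0)))
  }
  df <- as.data.frame(df)
  ab <- if (all(c("compound_a", "compound_b") %in% names(df))) {
    c("compound_a", "compound_b")
  } else if (all(c("drug_a", "drug_b") %in% names(df))) {
    c("drug_a", "drug_b")
  } else {
    stop(what, " table needs columns compound_a/compound_b or drug_a/drug_b",
         call. = FALSE)
  }
  if (!"rank" %in% names(df)) stop(what, " table needs a rank column", call. = FALSE)
  out <- data.frame(pair = pair_id(df[[ab[1L]]], df[[ab[2L]]]),
                    rank = as.numeric(df$rank), stringsAsFactors = FALSE)
  if (anyDuplicated(out$pair)) {
    stop("duplicate pair(s) in ", what, " table", call. = FALSE)
  }
  out
}

#' Aggregate CGEM and TargOpt rankings
#'
#' Pairs present in both lists receive the mean of their two ranks. A pair
#' surfaced by only one method is penalized with a worst-rank-plus-one
#' stand-in for the missing method (one past the length of the other list)
#' and flagged `single_method_only`, so convergent predictions sort ahead
#' of single-method ones without being the only candidates kept. Output is
#' sorted ascending by aggregate rank, ties by pair id.
#'
#' @param cgem Data frame from [cgem_rank_pairs()] (or any table with
#'   pair columns and `rank`). May be empty.
#' @param targopt Data frame from [targopt_rank_pairs()]. May be empty.
#' @param method Aggregation method; only `"mean_rank"` is implemented.
#' @return Data frame of class `combination_predictions` with columns
#'   `pair`, `drug_a`, `drug_b`, `cgem_rank`, `targopt_rank`,
#'   `aggregate_rank`, `flags` (semicolon-joined tokens, "" if none).
#' @export
aggregate_ranks <- function(cgem, targopt, method = c("mean_rank")) {
  method <- match.arg(method)
  rc <- .pair_ranks(cgem, "cgem")
  rt <- .pair_ranks(targopt, "targopt")
  if (nrow(rc) == 0L && nrow(rt) == 0L) {
    stop("both input rankings are empty", call. = FALSE)
  }
  pairs <- union(rc$pair, rt$pair)
  cg <- rc$rank[match(pairs, rc$pair)]
  tg <- rt$rank[match(pairs, rt$pair)]
  pen_cg <- nrow(rc) + 1            # stand-in rank for a missing method
  pen_tg <- nrow(rt) + 1
  agg <- rowMeans(cbind(ifelse(is.na(cg), pen_cg, cg),
                        ifelse(is.na(tg), pen_tg, tg)))
  flags <- ifelse(is.na(cg) | is.na(tg), "single_method_only", "")
  parts <- strsplit(pairs, "+", fixed = TRUE)
  out <- data.frame(
    pair = pairs,
    drug_a = vapply(parts, `[[`, character(1L), 1L),
    drug_b = vapply(parts, `[[`, character(1L), 2L),
    cgem_rank = cg,
    targopt_rank = tg,
    aggregate_rank = agg,
    flags = flags,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$aggregate_rank, out$pair, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("combination_predictions", "data.frame")
  out
}

.add_flag <- function(flags, add, where) {
  ifelse(where,
         ifelse(nzchar(flags), paste(flags, add, sep = ";"), add),
         flags)
}

#' Annotate predictions with interaction and mechanism flags
#'
#' Adds `ddi_alert` for pairs on a known drug-drug interaction blocklist
#' and `same_mechanism` for pairs whose drugs share a mechanism class.
#' Annotation never removes or reorders predictions: the flags assist a
#' human expert's triage, they do not auto-reject. Drugs without a
#' mechanism-class entry simply receive no `same_mechanism` flag.
#'
#' @param predictions Output of [aggregate_ranks()].
#' @param ddi_blocklist Unordered drug pairs with a known adverse
#'   interaction: a data frame with columns `drug_a`, `drug_b`, or a
#'   character vector of canonical pair ids (`"a+b"`). `NULL` for none.
#' @param mechanism_map Named character vector, drug id -> mechanism class.
#'   `NULL` for none.
#' @return `predictions` with updated `flags`; same rows, same order.
#' @export
annotate <- function(predictions, ddi_blocklist = NULL, mechanism_map = NULL) {
  stopifnot(is.data.frame(predictions))
  flags <- predictions$flags
  if (!is.null(ddi_blocklist)) {
    block <- if (is.data.frame(ddi_blocklist)) {
      pair_id(ddi_blocklist$drug_a, ddi_blocklist$drug_b)
    } else {
      as.character(ddi_blocklist)
    }
    flags <- .add_flag(flags, "ddi_alert", predictions$pair %in% block)
  }
  if (!is.null(mechanism_map) && length(mechanism_map) > 0L) {
    ma <- mechanism_map[predictions$drug_a]
    mb <- mechanism_map[predictions$drug_b]
    same <- !is.na(ma) & !is.na(mb) & ma == mb
    flags <- .add_flag(flags, "same_mechanism", same)
  }
  predictions$flags <- flags
  predictions
}
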