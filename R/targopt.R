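# TargOpt (Target Optimisation): score and rank drug pairs by on-target
# engagement of disease targets versus off-target burden.

#' Construct a target catalogue
#'
#' Couples a drug -> target map (with modulation direction) to the set of
#' disease-relevant targets and the direction in which therapy should push
#' each one. Directions are binary: `+1` activation/agonism, `-1`
#' inhibition/antagonism; no potency tiers are modelled.
#'
#' @param drug_targets Data frame with columns `drug_id`, `target_id`,
#'   `direction` (+1/-1). (drug, target, direction) rows must be unique per
#'   drug-target pair.
#' @param disease_targets Data frame with columns `target_id`,
#'   `desired_direction` (+1/-1); target ids unique.
#' @return An object of class `target_catalog`.
#' @export
target_catalog <- function(drug_targets, disease_targets) {
  drug_targets <- as.data.frame(drug_targets)
  disease_targets <- as.data.frame(disease_targets)
  need <- c("drug_id", "target_id", "direction")
  if (!all(need %in% names(drug_targets))) {
    stop("drug_targets needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("target_id", "desired_direction") %in% names(disease_targets))) {
    stop("disease_targets needs columns: target_id, desired_direction",
         call. = FALSE)
  }
  .check_direction(drug_targets$direction)
  .check_direction(disease_targets$desired_direction)
  key <- paste(drug_targets$drug_id, drug_targets$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (drug, target) row(s) in drug_targets", call. = FALSE)
  }
  if (anyDuplicated(disease_targets$target_id)) {
    stop("duplicate target ids in disease_targets", call. = FALSE)
  }
  structure(list(drug_targets = drug_targets,
                 disease_targets = disease_targets),
            class = "target_catalog")
}

.check_direction <- function(d) {
  if (!is.numeric(d) || !all(d %in% c(-1, 1))) {
    stop("directions must be +1 (activation) or -1 (inhibition); got: ",
         paste(utils::head(unique(d[!d %in% c(-1, 1)])), collapse = ", "),
         call. = FALSE)
  }
  invisible(d)
}

#' @export
print.target_catalog <- function(x, ...) {
  cat("<target_catalog> ", length(unique(x$drug_targets$drug_id)), " drugs, ",
      nrow(x$drug_targets), " drug-target links, ",
      nrow(x$disease_targets), " disease targets\n", sep = "")
  invisible(x)
}

#' Drug identifiers present in a catalogue
#' @param catalog A `target_catalog`.
#' @return Sorted character vector.
#' @export
catalog_drugs <- function(catalog) {
  stopifnot(inherits(catalog, "target_catalog"))
  sort(unique(catalog$drug_targets$drug_id))
}

#' TargOpt score of one drug pair
#'
#' Counts the disease targets that the pair engages in the desired
#' direction (each counted once, however many drugs hit it) and the
#' distinct targets carrying any liability engagement: a target outside
#' the disease set, or a disease target pushed in the wrong direction.
#' The scalar score is `alpha * on_count - beta * off_count`.
#'
#' @param targets_a,targets_b Data frames with columns `target_id`,
#'   `direction` (+1/-1): the engagement sets of the two drugs.
#' @param disease_targets Data frame with columns `target_id`,
#'   `desired_direction`.
#' @param alpha,beta Non-negative trade-off weights (defaults 1 and 0.5:
#'   one missed therapeutic target outweighs one liability).
#' @return An object of class `targopt_score`: list with `on_count`,
#'   `off_count`, `score`.
#' @export
targopt_score <- function(targets_a, targets_b, disease_targets,
                          alpha = 1, beta = 0.5) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  targets_a <- as.data.frame(targets_a)
  targets_b <- as.data.frame(targets_b)
  eng <- unique(rbind(targets_a[c("target_id", "direction")],
                      targets_b[c("target_id", "direction")]))
  if (nrow(eng) > 0L) .check_direction(eng$direction)
  desired <- stats::setNames(disease_targets$desired_direction,
                             disease_targets$target_id)
  want <- desired[eng$target_id]          # NA for non-disease targets
  is_on <- !is.na(want) & eng$direction == want
  on_count <- length(unique(eng$target_id[is_on]))
  off_count <- length(unique(eng$target_id[!is_on]))
  structure(list(on_count = on_count, off_count = off_count,
                 score = alpha * on_count - beta * off_count),
            class = "targopt_score")
}

#' @export
print.targopt_score <- function(x, ...) {
  cat(sprintf("<targopt_score> on=%d off=%d score=%.3f\n",
              x$on_count, x$off_count, x$score))
  invisible(x)
}

#' Rank all drug pairs by TargOpt score
#'
#' Exhaustively scores every unordered pair of the given drugs. Sorting is
#' by score descending, then higher on-target count, then lexicographic
#' pair id. A `pareto` column marks pairs on the (maximize on_count,
#' minimize off_count) Pareto front, so the ranking can be read under
#' either the scalarized or the bi-objective view.
#'
#' @param catalog A `target_catalog`.
#' @param drugs Drug ids to pair up; default all drugs in the catalogue.
#'   An id absent from the catalogue is an error.
#' @param alpha,beta Trade-off weights, see [targopt_score()].
#' @param top_k Number of top pairs to return; `NULL` returns all.
#' @return Data frame with columns `rank`, `drug_a`, `drug_b`, `on_count`,
#'   `off_count`, `score`, `pareto`.
#' @export
targopt_rank_pairs <- function(catalog, drugs = NULL, alpha = 1, beta = 0.5,
                               top_k = NULL) {
  stopifnot(inherits(catalog, "target_catalog"))
  present <- unique(catalog$drug_targets$drug_id)
  if (is.null(drugs)) drugs <- sort(present)
  missing <- setdiff(drugs, present)
  if (length(missing) > 0L) {
    stop("drug(s) absent from catalog: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- length(drugs)
  if (m < 2L) stop("need at least 2 drugs to form pairs", call. = FALSE)
  tsets <- lapply(drugs, function(d) {
    dt <- catalog$drug_targets
    dt[dt$drug_id == d, c("target_id", "direction")]
  })
  names(tsets) <- drugs
  combos <- utils::combn(m, 2L)
  n_pairs <- ncol(combos)
  on_count <- integer(n_pairs); off_count <- integer(n_pairs)
  score <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    s <- targopt_score(tsets[[combos[1L, k]]], tsets[[combos[2L, k]]],
                       catalog$disease_targets, alpha, beta)
    on_count[k] <- s$on_count; off_count[k] <- s$off_count
    score[k] <- s$score
  }
  da <- drugs[combos[1L, ]]; db <- drugs[combos[2L, ]]
  pid <- pair_id(da, db)
  pareto <- .pareto_front(on_count, off_count)
  ord <- order(-score, -on_count, pid, method = "radix")
  if (!is.null(top_k)) ord <- ord[seq_len(min(top_k, n_pairs))]
  data.frame(
    rank = seq_along(ord),
    drug_a = pmin(da, db)[ord],
    drug_b = pmax(da, db)[ord],
    on_count = on_count[ord],
    off_count = off_count[ord],
    score = score[ord],
    pareto = pareto[ord],
    stringsAsFactors = FALSE
  )
}

# TRUE for pairs not dominated under (max on, min off).
.pareto_front <- function(on, off) {
  n <- length(on)
  vapply(seq_len(n), function(i) {
    !any(on >= on[i] & off <= off[i] & (on > on[i] | off < off[i]))
  }, logical(1L))
}

#' Read a drug-target catalogue table
#'
#' @param path TSV with header columns `drug_id`, `target_id`, `direction`.
#' @return Data frame suitable for [target_catalog()].
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "target_id", "direction")
  if (!all(need %in% names(df))) {
    stop("expected columns ", paste(need, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  df
}

#' Read a disease-target wish list
#'
#' @param path TSV with header columns `target_id`, `desired_direction`.
#' @return Data frame suitable for [target_catalog()].
#' @export
read_disease_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("target_id", "desired_direction") %in% names(df))) {
    stop("expected columns target_id, desired_direction in ", path,
         call. = FALSE)
  }
  df
}
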