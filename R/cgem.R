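# CGEM (Combination Gene Expression Matching): build combination signatures
# for drug pairs and rank every unordered pair by reversal of the disease
# signature.

#' Canonical identifier for an unordered drug pair
#'
#' @param a,b Character vectors of drug identifiers (recycled pairwise).
#' @return `"<first>+<second>"` with the two ids in lexicographic order.
#' @export
pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "+")
}

#' Number of unordered pairs among m compounds
#'
#' The size of the exhaustive two-drug search space: `m * (m - 1) / 2`.
#' For the roughly 4000 drugs approved worldwide this is 7,998,000
#' candidate pair experiments, which is why the search is run in silico.
#'
#' @param m Number of compounds (>= 2).
#' @return Pair count as a double (exact for m well beyond any catalogue).
#' @export
pair_count <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != floor(m)) {
    stop("m must be a single integer >= 2", call. = FALSE)
  }
  m * (m - 1) / 2
}

#' Combine two signatures into a combination signature
#'
#' Models the transcriptional effect of co-administering two compounds as
#' the elementwise sum of their z-score profiles, then re-ranks. Additivity
#' is the minimal assumption for a two-drug effect; the choice is isolated
#' here so an alternative merge (e.g. max-magnitude) can be substituted.
#'
#' @param a,b `ranked_signature` objects over the same universe.
#' @return A `ranked_signature` with `compound_id` `"idA+idB"` (ids in
#'   lexicographic order).
#' @export
combine_signatures <- function(a, b) {
  stopifnot(inherits(a, "ranked_signature"), inherits(b, "ranked_signature"))
  if (!identical(a$genes, b$genes)) {
    stop("signatures are on different gene universes", call. = FALSE)
  }
  ranked_signature(pair_id(a$compound_id, b$compound_id), a$z + b$z, a$genes)
}

# Reversal of a raw combined z profile against pre-resolved set indices.
# Avoids building signature objects in the m(m-1)/2 inner loop.
.reversal_from_z <- function(zc, genes, up_idx, down_idx) {
  n <- length(zc)
  ord <- order(-zc, genes, method = "radix")
  r <- integer(n)
  r[ord] <- seq_len(n)
  es_up <- .ks_stat(sort(r[up_idx]), n)
  es_down <- .ks_stat(sort(r[down_idx]), n)
  if (sign(es_up) != sign(es_down)) -(es_up - es_down) / 2 else 0
}

#' CGEM reversal score of one drug pair
#'
#' Reversal achieved by the pair's combined signature against the disease
#' signature; symmetric in its two arguments.
#'
#' @param a,b `ranked_signature` objects over the same universe.
#' @param disease A `disease_signature` harmonized to that universe.
#' @return Reversal score in `[-1, 1]` (positive = the combination pushes
#'   disease up-genes down and down-genes up).
#' @export
cgem_score_pair <- function(a, b, disease) {
  connectivity_score(combine_signatures(a, b), disease)$reversal
}

#' Rank all drug pairs by CGEM reversal
#'
#' Exhaustively scores the `m(m-1)/2` unordered pairs of library compounds
#' and ranks them by reversal, descending. Ties are broken by lexicographic
#' pair id so reports are reproducible. Pairs are streamed one at a time;
#' memory is bounded by the library plus the score vector.
#'
#' @param lib A `compound_library` with at least two compounds.
#' @param disease A `disease_signature`; harmonized to the library universe
#'   automatically (genes outside the universe are dropped with a message).
#' @param top_k Number of top pairs to return; `NULL` (default) returns all.
#' @param quiet Suppress the pair-count message.
#' @return A data frame with columns `rank`, `compound_a`, `compound_b`,
#'   `reversal_score`, rows ordered by rank; attribute `n_pairs` holds the
#'   total number of pairs scored.
#' @export
cgem_rank_pairs <- function(lib, disease, top_k = NULL, quiet = FALSE) {
  stopifnot(inherits(lib, "compound_library"),
            inherits(disease, "disease_signature"))
  m <- ncol(lib$z)
  if (m < 2L) stop("need at least 2 compounds to form pairs", call. = FALSE)
  if (!is.null(top_k) && (!is.numeric(top_k) || top_k < 1)) {
    stop("top_k must be >= 1", call. = FALSE)
  }
  disease <- disease_signature(disease$name, disease$up, disease$down,
                               universe = lib$genes)
  up_idx <- match(disease$up, lib$genes)
  down_idx <- match(disease$down, lib$genes)
  ids <- colnames(lib$z)
  n_pairs <- as.integer(m * (m - 1L) / 2L)
  if (!quiet) message("CGEM: scoring ", n_pairs, " unordered pairs of ", m,
                      " compounds")
  ia <- integer(n_pairs); ib <- integer(n_pairs)
  k <- 0L
  for (i in seq_len(m - 1L)) {
    jj <- (i + 1L):m
    ia[k + seq_along(jj)] <- i
    ib[k + seq_along(jj)] <- jj
    k <- k + length(jj)
  }
  rev_score <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    zc <- lib$z[, ia[k]] + lib$z[, ib[k]]
    rev_score[k] <- .reversal_from_z(zc, lib$genes, up_idx, down_idx)
  }
  pid <- pair_id(ids[ia], ids[ib])
  ord <- order(-rev_score, pid, method = "radix")
  if (!is.null(top_k)) ord <- ord[seq_len(min(top_k, n_pairs))]
  out <- data.frame(
    rank = seq_along(ord),
    compound_a = pmin(ids[ia], ids[ib])[ord],
    compound_b = pmax(ids[ia], ids[ib])[ord],
    reversal_score = rev_score[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "n_pairs") <- n_pairs
  out
}
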