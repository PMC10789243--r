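# Kolmogorov-Smirnov enrichment and connectivity (reversal) scoring of a
# disease signature against a ranked perturbation signature.

# Core KS statistic on sorted rank positions p (1..n) of set members.
# a = max_j (j/t - p_j/n), b = max_j (p_j/n - (j-1)/t); returns a if a > b
# else -b. Positive: set concentrates at the top of the ranking.
.ks_stat <- function(p, n) {
  t <- length(p)
  j <- seq_len(t)
  a <- max(j / t - p / n)
  b <- max(p / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Kolmogorov-Smirnov enrichment score of a gene set in a ranked list
#'
#' Classic unweighted running-sum enrichment: the maximal deviation between
#' the cumulative fraction of set members encountered down the ranking and
#' the cumulative fraction of the list traversed. Scores lie in `[-1, 1]`;
#' positive when the set concentrates at the top (most up-regulated end) of
#' the ranking, negative when it concentrates at the bottom.
#'
#' @param ranks Integer permutation of `1..n` as produced by
#'   [rank_transform()], named by gene (names required unless `gene_set` is
#'   given as integer positions).
#' @param gene_set Character vector of member genes, or integer vector of
#'   positions into `ranks`. Must be non-empty and contained in the
#'   universe; harmonize upstream with [disease_signature()].
#' @return Enrichment score in `[-1, 1]`.
#' @examples
#' r <- stats::setNames(1:10, paste0("g", 1:10))
#' ks_enrichment(r, c("g1", "g2"))  # 0.8: set sits at the very top
#' @export
ks_enrichment <- function(ranks, gene_set) {
  n <- length(ranks)
  if (n == 0L) stop("ranks must be non-empty", call. = FALSE)
  if (length(gene_set) == 0L) stop("gene set is empty", call. = FALSE)
  if (is.character(gene_set)) {
    idx <- match(gene_set, names(ranks))
    if (anyNA(idx)) {
      stop("gene set member(s) not in universe: ",
           paste(gene_set[is.na(idx)], collapse = ", "),
           " (harmonize upstream)", call. = FALSE)
    }
  } else {
    idx <- as.integer(gene_set)
    if (any(idx < 1L | idx > n)) {
      stop("gene set positions out of range", call. = FALSE)
    }
  }
  .ks_stat(sort(ranks[idx]), n)
}

#' Connectivity and reversal score of a signature against a disease
#'
#' Scores both disease gene sets against the signature's ranking and
#' combines them with the sign-gated two-set rule used in connectivity
#' mapping: when the up- and down-set enrichment scores have opposite
#' signs, `connectivity = (es_up - es_down) / 2`; when they fall on the
#' same side of the ranking the result is uninformative and set to 0. A
#' positive connectivity means the perturbation mimics the disease; the
#' reversal score is its negation, positive when the perturbation pushes
#' disease up-genes down and down-genes up.
#'
#' @param sig A `ranked_signature`.
#' @param disease A `disease_signature` harmonized to the signature's
#'   universe.
#' @return An object of class `enrichment_result`: list with `es_up`,
#'   `es_down`, `connectivity`, `reversal`, all in `[-1, 1]`.
#' @export
connectivity_score <- function(sig, disease) {
  stopifnot(inherits(sig, "ranked_signature"),
            inherits(disease, "disease_signature"))
  es_up <- ks_enrichment(sig$rank, disease$up)
  es_down <- ks_enrichment(sig$rank, disease$down)
  conn <- if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
  structure(
    list(es_up = es_up, es_down = es_down, connectivity = conn,
         reversal = -conn),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> es_up=%.4f es_down=%.4f connectivity=%.4f reversal=%.4f\n",
              x$es_up, x$es_down, x$connectivity, x$reversal))
  invisible(x)
}
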