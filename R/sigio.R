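# Data model and file I/O: gene universes, ranked perturbation signatures,
# compound libraries (GCT 1.2 / headered TSV) and disease gene sets (GMT).

#' Validate a gene universe
#'
#' A gene universe is an ordered character vector of unique, non-empty gene
#' identifiers. Its order is canonical for every matrix that references it.
#' Identifiers are opaque strings: no species or ID-type assumption is made.
#'
#' @param genes Character vector of gene identifiers.
#' @return The validated character vector, invisibly unchanged.
#' @export
validate_universe <- function(genes) {
  if (!is.character(genes) || length(genes) == 0L) {
    stop("gene universe must be a non-empty character vector", call. = FALSE)
  }
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop("gene universe contains missing or empty identifiers", call. = FALSE)
  }
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop("duplicate gene identifiers in universe: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  genes
}

#' Rank-transform a z-score profile
#'
#' Converts per-gene scores into descending ranks 1..n, where rank 1 is the
#' most up-regulated gene. Ties are broken by ascending gene-identifier
#' lexicographic order (C locale), so the ranking is deterministic across
#' platforms.
#'
#' @param z Numeric vector of finite per-gene scores.
#' @param gene_ids Character vector of gene identifiers aligned with `z`;
#'   defaults to `names(z)`. Used only for tie-breaking; if absent, ties are
#'   broken by input position.
#' @return Integer vector of ranks (a permutation of `1:length(z)`) aligned
#'   with the input.
#' @examples
#' rank_transform(c(gA = 2, gB = -1, gC = 0.5))  # 1 3 2
#' @export
rank_transform <- function(z, gene_ids = names(z)) {
  if (!is.numeric(z) || length(z) == 0L) {
    stop("z must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- which(!is.finite(z))
  if (length(bad) > 0L) {
    stop("non-finite z-score at position ", bad[1L],
         if (!is.null(gene_ids)) paste0(" (", gene_ids[bad[1L]], ")"),
         call. = FALSE)
  }
  n <- length(z)
  ord <- if (is.null(gene_ids)) {
    order(-z, seq_len(n), method = "radix")
  } else {
    if (length(gene_ids) != n) {
      stop("gene_ids must have the same length as z", call. = FALSE)
    }
    order(-z, gene_ids, method = "radix")
  }
  r <- integer(n)
  r[ord] <- seq_len(n)
  r
}

#' Construct a ranked signature
#'
#' One compound's (or combination's) gene-level perturbation profile:
#' z-scores aligned to a gene universe plus the induced descending ranking.
#'
#' @param compound_id Single compound identifier.
#' @param z Numeric vector of finite z-scores, one per universe gene.
#' @param universe Gene universe (character vector, see
#'   [validate_universe()]).
#' @return An object of class `ranked_signature`: a list with elements
#'   `compound_id`, `genes`, `z` and `rank`.
#' @export
ranked_signature <- function(compound_id, z, universe) {
  universe <- validate_universe(universe)
  if (!is.character(compound_id) || length(compound_id) != 1L || !nzchar(compound_id)) {
    stop("compound_id must be a single non-empty string", call. = FALSE)
  }
  if (length(z) != length(universe)) {
    stop("signature length (", length(z), ") does not match universe size (",
         length(universe), ")", call. = FALSE)
  }
  z <- as.numeric(z)
  names(z) <- universe
  structure(
    list(compound_id = compound_id, genes = universe, z = z,
         rank = stats::setNames(rank_transform(z, universe), universe)),
    class = "ranked_signature"
  )
}

#' @export
print.ranked_signature <- function(x, ...) {
  cat("<ranked_signature> ", x$compound_id, ": ", length(x$genes),
      " genes, z in [", sprintf("%.3g", min(x$z)), ", ",
      sprintf("%.3g", max(x$z)), "]\n", sep = "")
  invisible(x)
}

#' Construct a compound library
#'
#' A gene x compound z-score matrix over a shared gene universe, with
#' per-column descending rankings and optional per-compound metadata.
#'
#' @param z Numeric matrix, rows = genes (rownames required), columns =
#'   compounds (colnames required, unique).
#' @param metadata Optional data frame of per-compound annotations with a
#'   `compound_id` column (approval status, mechanism class, free text).
#' @return An object of class `compound_library`: a list with `genes`,
#'   `z` (matrix), `rank` (integer matrix of per-column ranks) and
#'   `metadata`.
#' @export
compound_library <- function(z, metadata = NULL) {
  if (!is.matrix(z) || !is.numeric(z)) {
    stop("z must be a numeric matrix (genes x compounds)", call. = FALSE)
  }
  genes <- validate_universe(rownames(z))
  ids <- colnames(z)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("compound ids (column names) are required", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(z))) {
    stop("z matrix contains non-finite values", call. = FALSE)
  }
  rk <- apply(z, 2L, rank_transform, gene_ids = genes)
  dimnames(rk) <- dimnames(z)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"compound_id" %in% names(metadata)) {
      stop("metadata must have a compound_id column", call. = FALSE)
    }
  }
  structure(list(genes = genes, z = z, rank = rk, metadata = metadata),
            class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  cat("<compound_library> ", length(x$genes), " genes x ",
      ncol(x$z), " compounds\n", sep = "")
  invisible(x)
}

#' Number of compounds in a library
#' @param lib A `compound_library`.
#' @return Integer count.
#' @export
n_compounds <- function(lib) {
  stopifnot(inherits(lib, "compound_library"))
  ncol(lib$z)
}

#' Extract one signature from a library
#'
#' @param lib A `compound_library`.
#' @param compound_id Compound identifier present in the library.
#' @return A `ranked_signature`.
#' @export
get_signature <- function(lib, compound_id) {
  stopifnot(inherits(lib, "compound_library"))
  j <- match(compound_id, colnames(lib$z))
  if (is.na(j)) {
    stop("compound not in library: ", compound_id, call. = FALSE)
  }
  structure(
    list(compound_id = compound_id, genes = lib$genes,
         z = stats::setNames(lib$z[, j], lib$genes),
         rank = stats::setNames(lib$rank[, j], lib$genes)),
    class = "ranked_signature"
  )
}

#' Read a signature matrix (GCT 1.2 or headered TSV)
#'
#' Accepts either a GCT 1.2 file (a `#1.2` version line, a `n_genes<TAB>
#' n_compounds` dimension line, a header row starting with NAME and
#' Description, then one row per gene) or a plain gene x compound TSV whose
#' first column holds gene identifiers. Row order defines the gene universe;
#' ranks are computed with [rank_transform()].
#'
#' @param path Path to the file.
#' @return A `compound_library`.
#' @export
read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 2L) stop("file too short to be a signature matrix: ", path, call. = FALSE)
  is_gct <- startsWith(lines[1L], "#1.2")
  if (is_gct) {
    dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
    n_genes <- suppressWarnings(as.integer(dims[1L]))
    n_cmpds <- suppressWarnings(as.integer(dims[2L]))
    if (length(dims) < 2L || is.na(n_genes) || is.na(n_cmpds)) {
      stop("malformed GCT dimension line: ", lines[2L], call. = FALSE)
    }
    header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != n_genes) {
      stop("GCT dimension line declares ", n_genes, " genes but body has ",
           length(body), " rows", call. = FALSE)
    }
    ids <- header[-(1:2)]
    if (length(ids) != n_cmpds) {
      stop("GCT dimension line declares ", n_cmpds, " compounds but header has ",
           length(ids), call. = FALSE)
    }
    value_cols <- -(1:2)
  } else {
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    body <- lines[-1L]
    body <- body[nzchar(body)]
    ids <- header[-1L]
    if (length(ids) < 1L) stop("TSV has no compound columns: ", path, call. = FALSE)
    value_cols <- -1L
  }
  rows <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, character(1L), 1L)
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop("duplicate gene row: ", unique(dup)[1L], call. = FALSE)
  }
  z <- matrix(NA_real_, nrow = length(genes), ncol = length(ids),
              dimnames = list(genes, ids))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][value_cols]
    if (length(vals) != length(ids)) {
      stop("row ", i, " (", genes[i], ") has ", length(vals),
           " values; expected ", length(ids), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      j <- which(is.na(num))[1L]
      stop("non-numeric value '", vals[j], "' at gene ", genes[i],
           ", compound ", ids[j], call. = FALSE)
    }
    z[i, ] <- num
  }
  compound_library(z)
}

#' Write a compound library as GCT 1.2
#'
#' z-scores are written with 6 significant digits; a library already read
#' from disk round-trips exactly.
#'
#' @param lib A `compound_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(lib, path) {
  stopifnot(inherits(lib, "compound_library"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wline <- function(x) writeLines(x, con, sep = "\n", useBytes = TRUE)
  wline("#1.2")
  wline(paste(length(lib$genes), ncol(lib$z), sep = "\t"))
  wline(paste(c("NAME", "Description", colnames(lib$z)), collapse = "\t"))
  vals <- matrix(sprintf("%.6g", lib$z), nrow = nrow(lib$z))
  for (i in seq_along(lib$genes)) {
    wline(paste(c(lib$genes[i], "na", vals[i, ]), collapse = "\t"))
  }
  invisible(path)
}

#' Construct a disease signature
#'
#' Named sets of up- and down-regulated genes for a disease. If a universe
#' is supplied the sets are harmonized to it: genes absent from the universe
#' are dropped with a message stating the count (standard
#' connectivity-mapping practice, since only genes measured in the compound
#' resource can contribute to a score).
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene identifiers; must be disjoint
#'   and non-empty after harmonization.
#' @param universe Optional gene universe to harmonize against.
#' @return An object of class `disease_signature` with elements `name`,
#'   `up`, `down`.
#' @export
disease_signature <- function(name, up, down, universe = NULL) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both) > 0L) {
    stop("up and down sets are not disjoint; shared gene(s): ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  if (!is.null(universe)) {
    universe <- validate_universe(universe)
    drop_up <- setdiff(up, universe)
    drop_down <- setdiff(down, universe)
    n_drop <- length(drop_up) + length(drop_down)
    if (n_drop > 0L) {
      message("disease_signature '", name, "': dropped ", n_drop,
              " gene(s) absent from the compound universe")
    }
    up <- intersect(up, universe)
    down <- intersect(down, universe)
  }
  if (length(up) == 0L || length(down) == 0L) {
    stop("no scoreable genes: the ",
         if (length(up) == 0L) "up" else "down",
         " set is empty after harmonization", call. = FALSE)
  }
  structure(list(name = as.character(name), up = up, down = down),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("<disease_signature> ", x$name, ": ", length(x$up), " up / ",
      length(x$down), " down genes\n", sep = "")
  invisible(x)
}

#' Read a disease signature from a GMT file
#'
#' Expects two GMT lines named `<name>_UP` and `<name>_DOWN` (set name,
#' description, then member genes, tab separated). Genes absent from the
#' universe are dropped with a message.
#'
#' @param path Path to the GMT file.
#' @param universe Gene universe to harmonize against.
#' @param name Optional signature name; by default inferred as the common
#'   prefix of the first `*_UP` / `*_DOWN` line pair.
#' @return A `disease_signature`.
#' @export
read_gmt <- function(path, universe, name = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  set_names <- vapply(fields, `[[`, character(1L), 1L)
  if (is.null(name)) {
    up_names <- set_names[endsWith(set_names, "_UP")]
    if (length(up_names) == 0L) {
      stop("no *_UP gene-set line found in ", path, call. = FALSE)
    }
    name <- sub("_UP$", "", up_names[1L])
  }
  i_up <- match(paste0(name, "_UP"), set_names)
  i_down <- match(paste0(name, "_DOWN"), set_names)
  if (is.na(i_up)) stop("missing gene-set line ", name, "_UP in ", path, call. = FALSE)
  if (is.na(i_down)) stop("missing gene-set line ", name, "_DOWN in ", path, call. = FALSE)
  members <- function(f) {
    g <- f[-(1:2)]
    g[nzchar(g)]
  }
  disease_signature(name, up = members(fields[[i_up]]),
                    down = members(fields[[i_down]]), universe = universe)
}

#' Write a disease signature as GMT
#'
#' @param disease A `disease_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(disease, path) {
  stopifnot(inherits(disease, "disease_signature"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    paste(c(paste0(disease$name, "_UP"), "na", disease$up), collapse = "\t"),
    paste(c(paste0(disease$name, "_DOWN"), "na", disease$down), collapse = "\t")
  ), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
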