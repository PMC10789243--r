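# Shared fixtures and independent oracles, built in code at test time.

# Tiny gene x compound library from an explicit matrix.
make_lib <- function(z, genes = sprintf("g%02d", seq_len(nrow(z))),
                     ids = sprintf("c%02d", seq_len(ncol(z)))) {
  dimnames(z) <- list(genes, ids)
  compound_library(z)
}

# Write a plain headered TSV signature matrix.
write_tsv_matrix <- function(z, path) {
  lines <- c(
    paste(c("gene_id", colnames(z)), collapse = "\t"),
    vapply(seq_len(nrow(z)), function(i) {
      paste(c(rownames(z)[i], format(z[i, ], digits = 10)), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  path
}

# Write a two-line GMT file for a disease signature.
write_gmt_lines <- function(path, name, up, down) {
  writeLines(c(
    paste(c(paste0(name, "_UP"), "desc", up), collapse = "\t"),
    paste(c(paste0(name, "_DOWN"), "desc", down), collapse = "\t")
  ), path)
  path
}

# Independent KS oracle: scan every list position instead of only the
# sorted member positions. H(i) = members among the top i.
ks_oracle <- function(positions, n) {
  hit <- integer(n)
  hit[positions] <- 1L
  H <- cumsum(hit)
  t <- length(positions)
  i <- seq_len(n)
  a <- max(H[i] / t - i / n)
  b <- max(i / n - c(0L, H)[i] / t)
  if (a > b) a else -b
}

# Independent TargOpt oracle: literal set arithmetic over engagement pairs.
targopt_oracle <- function(ta, tb, disease, alpha = 1, beta = 0.5) {
  eng <- unique(rbind(ta, tb))
  on_targets <- character(0)
  off_targets <- character(0)
  for (k in seq_len(nrow(eng))) {
    tid <- eng$target_id[k]
    row <- disease[disease$target_id == tid, ]
    if (nrow(row) == 1L && row$desired_direction == eng$direction[k]) {
      on_targets <- union(on_targets, tid)
    } else {
      off_targets <- union(off_targets, tid)
    }
  }
  list(on = length(on_targets), off = length(off_targets),
       score = alpha * length(on_targets) - beta * length(off_targets))
}

drug_targets_of <- function(catalog, drug) {
  dt <- catalog$drug_targets
  dt[dt$drug_id == drug, c("target_id", "direction")]
}

# Path to the installed CLI wrapper.
cli_path <- function() {
  p <- system.file("cli", "combopredict.R", package = "combopredict")
  if (!nzchar(p)) {
    p <- file.path(testthat::test_path("..", ".."), "inst", "cli",
                   "combopredict.R")
  }
  normalizePath(p)
}

run_cli <- function(args) {
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c(shQuote(cli_path()), args),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("CLI failed: ", paste(out, collapse = "\n"))
  }
  invisible(out)
}
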