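# Seeded synthetic-data generators with planted ground truth: compound
# libraries with a planted reversing pair, target catalogues with a planted
# optimal pair, and behavioural cohorts with group-level effects. Every
# generator is a pure function of its arguments including the seed, so the
# whole pipeline is testable end to end with no external downloads.

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a synthetic compound library
#'
#' Draws i.i.d. standard-normal z-scores for `m` compounds over a shared
#' universe of `n` genes (`g0001`, `g0002`, ...). A standard-normal matrix
#' emulates the scale of moderated z-score perturbation profiles; it does
#' not emulate gene-gene correlation or batch structure of real resources.
#' Fully deterministic given `(m, n, seed)`.
#'
#' @param m Number of compounds (>= 2). Compound ids are `cmpd001`, ...
#' @param n Number of genes (>= 10).
#' @param seed Integer RNG seed.
#' @return A `compound_library`.
#' @export
generate_library <- function(m, n, seed) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != floor(m)) {
    stop("m must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 10 || n != floor(n)) {
    stop("n must be a single integer >= 10", call. = FALSE)
  }
  genes <- sprintf("g%04d", seq_len(n))
  ids <- sprintf("cmpd%03d", seq_len(m))
  z <- with_seed(seed, matrix(stats::rnorm(n * m), nrow = n,
                              dimnames = list(genes, ids)))
  compound_library(z)
}

#' Plant a maximally reversing pair in a library
#'
#' Reverse-engineers a disease signature from a chosen pair's combined
#' profile: the `n_up` genes with the most negative combined z become the
#' disease up-set and the `n_down` genes with the most positive combined z
#' the down-set, so the planted pair's combination is by construction the
#' extremal reverser of that signature. The whole library is then perturbed
#' with additive `N(0, sigma)` measurement noise; the disease sets are
#' frozen before the noise, so at `sigma = 0` recovery is guaranteed by
#' construction, at small `sigma` it is near-certain, and at `sigma` far
#' above the unit z-score scale the planted signal drowns and recovery
#' degrades toward chance.
#'
#' @param lib A `compound_library`.
#' @param pair Character vector of two distinct compound ids in `lib`.
#' @param n_up,n_down Disease set sizes; their sum must not exceed the
#'   number of genes.
#' @param sigma Standard deviation of the additive noise (>= 0).
#' @param seed Integer RNG seed for the noise.
#' @param name Disease signature name.
#' @return A list with elements `library` (the perturbed library),
#'   `disease` (the `disease_signature`) and `truth` (class
#'   `planted_truth`: `planted_pair`, `noise_sigma`, `seed`, `disease`).
#' @export
plant_reversal <- function(lib, pair, n_up = 50, n_down = 50, sigma = 0,
                           seed = 1, name = "synthetic_disease") {
  stopifnot(inherits(lib, "compound_library"))
  pair <- as.character(pair)
  if (length(pair) != 2L || pair[1L] == pair[2L]) {
    stop("pair must be two distinct compound ids", call. = FALSE)
  }
  jj <- match(pair, colnames(lib$z))
  if (anyNA(jj)) {
    stop("pair member(s) not in library: ",
         paste(pair[is.na(jj)], collapse = ", "), call. = FALSE)
  }
  n <- length(lib$genes)
  if (n_up < 1 || n_down < 1 || n_up + n_down > n) {
    stop("need n_up >= 1, n_down >= 1 and n_up + n_down <= ", n,
         call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  zc <- lib$z[, jj[1L]] + lib$z[, jj[2L]]
  ord <- order(zc, lib$genes, method = "radix")   # ascending combined z
  up <- lib$genes[ord[seq_len(n_up)]]                    # most negative
  down <- lib$genes[rev(ord)[seq_len(n_down)]]           # most positive
  disease <- disease_signature(name, up = up, down = down,
                               universe = lib$genes)
  z2 <- lib$z
  if (sigma > 0) {
    z2 <- z2 + with_seed(seed, matrix(stats::rnorm(length(z2), sd = sigma),
                                      nrow = n))
  }
  truth <- structure(
    list(planted_pair = sort(pair), noise_sigma = sigma, seed = seed,
         disease = disease),
    class = "planted_truth"
  )
  list(library = compound_library(z2, metadata = lib$metadata),
       disease = disease, truth = truth)
}

#' Generate a target catalogue with a planted optimal pair
#'
#' The planted pair jointly covers every disease target in the desired
#' direction, split between its two drugs, with zero off-targets; its
#' TargOpt score is therefore `alpha * n_disease_targets`, which strictly
#' dominates every other pair whenever `beta > 0`, because every decoy
#' drug covers at most `ceiling(n_disease_targets / 2)` disease targets
#' and carries at least one decoy off-target. Deterministic given the
#' seed.
#'
#' @param n_drugs Total drugs (>= 2), planted pair included. Decoys are
#'   `drug003`, ... when the planted pair is the default.
#' @param n_disease_targets Number of disease targets (>= 1), ids `T01`,
#'   ... with random desired directions.
#' @param n_decoy_targets Number of non-disease targets (>= 1), ids
#'   `decoy01`, ...
#' @param planted_pair Character vector of two drug ids (default
#'   `c("drug001", "drug002")`).
#' @param seed Integer RNG seed.
#' @return A list with elements `catalog` (a `target_catalog`) and `truth`
#'   (`planted_truth`-style list with `planted_pair` and `seed`).
#' @export
generate_target_catalog <- function(n_drugs, n_disease_targets,
                                    n_decoy_targets,
                                    planted_pair = c("drug001", "drug002"),
                                    seed = 1) {
  if (!is.numeric(n_drugs) || n_drugs < 2 || n_drugs != floor(n_drugs)) {
    stop("n_drugs must be an integer >= 2", call. = FALSE)
  }
  if (n_disease_targets < 1 || n_decoy_targets < 1) {
    stop("need at least one disease target and one decoy target",
         call. = FALSE)
  }
  planted_pair <- sort(as.character(planted_pair))
  if (length(planted_pair) != 2L || planted_pair[1L] == planted_pair[2L]) {
    stop("planted_pair must be two distinct drug ids", call. = FALSE)
  }
  dts <- sprintf("T%02d", seq_len(n_disease_targets))
  decoys <- sprintf("decoy%02d", seq_len(n_decoy_targets))
  n_others <- n_drugs - 2L
  other_ids <- if (n_others > 0L) {
    setdiff(sprintf("drug%03d", seq_len(n_drugs + 2L)), planted_pair)[seq_len(n_others)]
  } else {
    character(0)
  }
  with_seed(seed, {
    desired <- sample(c(-1, 1), n_disease_targets, replace = TRUE)
    # planted pair: split disease targets alternately, correct direction,
    # no off-targets
    split_a <- seq_len(n_disease_targets) %% 2L == 1L
    rows <- list(
      data.frame(drug_id = planted_pair[1L], target_id = dts[split_a],
                 direction = desired[split_a], stringsAsFactors = FALSE),
      data.frame(drug_id = planted_pair[2L], target_id = dts[!split_a],
                 direction = desired[!split_a], stringsAsFactors = FALSE)
    )
    max_cover <- ceiling(n_disease_targets / 2)
    for (d in other_ids) {
      k <- sample.int(max_cover + 1L, 1L) - 1L   # 0..max_cover on-targets
      on <- if (k > 0L) sample(seq_len(n_disease_targets), k) else integer(0)
      n_off <- sample.int(min(3L, n_decoy_targets), 1L)
      off <- sample(decoys, n_off)
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = d,
        target_id = c(dts[on], off),
        direction = c(desired[on], sample(c(-1, 1), n_off, replace = TRUE)),
        stringsAsFactors = FALSE
      )
    }
    catalog <- target_catalog(
      do.call(rbind, rows),
      data.frame(target_id = dts, desired_direction = desired,
                 stringsAsFactors = FALSE)
    )
    list(catalog = catalog,
         truth = list(planted_pair = planted_pair, seed = seed))
  })
}

#' Generate a synthetic behavioural cohort
#'
#' Draws per-animal measurements from seeded normal distributions clamped
#' at 0 (times and counts cannot be negative) according to a per-group,
#' per-assay specification, and emits a trial table in the behaviour
#' module's input schema. The default usage emulates a 10-animals-per-group
#' design.
#'
#' Specification columns: `group_id`, `assay`, `n`, `sd` plus the
#' assay-relevant means: `mean_novel`/`mean_familiar` for recognition
#' assays (NOR, OL, SR), `mean_latency` for `hyponeophagia`, `mean_raw`
#' otherwise.
#'
#' @param spec Data frame, one row per (group, assay), columns as above.
#' @param seed Integer RNG seed.
#' @return Data frame of trials: `animal_id`, `group_id`, `assay`,
#'   `t_novel`, `t_familiar`, `latency`, `event_observed`, `raw_value`.
#' @export
generate_behaviour_cohort <- function(spec, seed) {
  spec <- as.data.frame(spec)
  if (!all(c("group_id", "assay", "n", "sd") %in% names(spec))) {
    stop("spec needs columns group_id, assay, n, sd", call. = FALSE)
  }
  if (any(spec$n < 1 | spec$n != floor(spec$n))) {
    stop("spec: n must be integers >= 1", call. = FALSE)
  }
  if (any(spec$sd < 0)) stop("spec: sd must be >= 0", call. = FALSE)
  d2_assays <- c("NOR", "OL", "SR")
  draw <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      s <- spec[i, ]
      n <- s$n
      out <- data.frame(
        animal_id = sprintf("%s_%s_%02d", s$group_id, s$assay, seq_len(n)),
        group_id = s$group_id, assay = s$assay,
        t_novel = NA_real_, t_familiar = NA_real_,
        latency = NA_real_, event_observed = NA,
        raw_value = NA_real_, stringsAsFactors = FALSE
      )
      if (s$assay %in% d2_assays) {
        if (is.null(s$mean_novel) || is.na(s$mean_novel) ||
            is.null(s$mean_familiar) || is.na(s$mean_familiar)) {
          stop("spec row ", i, ": mean_novel and mean_familiar required for ",
               s$assay, call. = FALSE)
        }
        out$t_novel <- draw(n, s$mean_novel, s$sd)
        out$t_familiar <- draw(n, s$mean_familiar, s$sd)
      } else if (s$assay == "hyponeophagia") {
        if (is.null(s$mean_latency) || is.na(s$mean_latency)) {
          stop("spec row ", i, ": mean_latency required for hyponeophagia",
               call. = FALSE)
        }
        out$latency <- draw(n, s$mean_latency, s$sd)
        out$event_observed <- out$latency <= 300
      } else {
        if (is.null(s$mean_raw) || is.na(s$mean_raw)) {
          stop("spec row ", i, ": mean_raw required for ", s$assay,
               call. = FALSE)
        }
        out$raw_value <- draw(n, s$mean_raw, s$sd)
      }
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default behavioural cohort specification
#'
#' A compact stand-in for a 10-per-group chronic-dosing design: a healthy
#' control group, an untreated disease-model group with impaired
#' recognition memory and elevated anxiety latency, and a treated
#' disease-model group restored toward control levels, across the NOR and
#' hyponeophagia assays.
#'
#' @param n Animals per group (default 10).
#' @return Specification data frame for [generate_behaviour_cohort()].
#' @export
default_cohort_spec <- function(n = 10) {
  data.frame(
    group_id = rep(c("WT_vehicle", "KO_vehicle", "KO_treated"), each = 2L),
    assay = rep(c("NOR", "hyponeophagia"), 3L),
    n = n,
    mean_novel = c(30, NA, 20, NA, 28, NA),
    mean_familiar = c(10, NA, 20, NA, 11, NA),
    mean_latency = c(NA, 60, NA, 250, NA, 80),
    mean_raw = NA_real_,
    sd = c(4, 15, 4, 40, 4, 20),
    stringsAsFactors = FALSE
  )
}
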