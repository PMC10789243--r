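# TargOpt: on/off-target counting, pair ranking, Pareto annotation.

tg <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(target_id = m[, 1], direction = as.numeric(m[, 2]),
             stringsAsFactors = FALSE)
}

test_that("targopt_score counts forced cases correctly", {
  disease <- data.frame(target_id = c("T1", "T2"),
                        desired_direction = c(-1, -1))
  # complementary coverage, no liabilities
  s <- targopt_score(tg("T1", -1), tg("T2", -1), disease)
  expect_identical(s$on_count, 2L)
  expect_identical(s$off_count, 0L)
  expect_equal(s$score, 2.0)
  # wrong-direction engagement of a disease target is a liability
  s2 <- targopt_score(tg("T1", 1), tg("T1", 1)[0, ], disease)
  expect_identical(s2$on_count, 0L)
  expect_identical(s2$off_count, 1L)
  expect_equal(s2$score, -0.5)
  # both drugs hitting the same disease target counts once
  s3 <- targopt_score(tg("T1", -1), tg("T1", -1), disease)
  expect_identical(s3$on_count, 1L)
  expect_identical(s3$off_count, 0L)
  # malformed direction
  expect_error(targopt_score(tg("T1", 2), tg("T2", -1), disease),
               "directions must be")
  expect_error(targopt_score(tg("T1", -1), tg("T2", -1), disease,
                             alpha = -1), ">= 0")
})

test_that("targopt_score matches the set-arithmetic oracle on random catalogs", {
  set.seed(21)
  targets <- sprintf("T%02d", 1:8)
  for (rep in 1:100) {
    disease <- data.frame(
      target_id = sample(targets, 4),
      desired_direction = sample(c(-1, 1), 4, replace = TRUE)
    )
    rand_set <- function() {
      k <- sample.int(5, 1)
      data.frame(target_id = sample(targets, k),
                 direction = sample(c(-1, 1), k, replace = TRUE))
    }
    ta <- rand_set(); tb <- rand_set()
    got <- targopt_score(ta, tb, disease)
    want <- targopt_oracle(ta, tb, disease)
    expect_identical(got$on_count, want$on)
    expect_identical(got$off_count, want$off)
    expect_equal(got$score, want$score)
    # symmetry
    swapped <- targopt_score(tb, ta, disease)
    expect_equal(got$score, swapped$score)
  }
})

test_that("score is monotone in on-target gains and off-target burden", {
  set.seed(22)
  disease <- data.frame(target_id = c("T1", "T2", "T3"),
                        desired_direction = c(-1, 1, -1))
  for (rep in 1:50) {
    ta <- tg("T1", -1, "decoyA", sample(c(-1, 1), 1))
    tb <- tg("T2", sample(c(-1, 1), 1))
    base <- targopt_score(ta, tb, disease)
    # adding an off-target never increases the score (beta > 0)
    ta_off <- rbind(ta, data.frame(target_id = "decoyB", direction = 1))
    expect_lte(targopt_score(ta_off, tb, disease)$score, base$score)
    # adding a correctly-directed disease target never decreases it
    ta_on <- rbind(ta, data.frame(target_id = "T3", direction = -1))
    expect_gte(targopt_score(ta_on, tb, disease)$score, base$score)
  }
})

test_that("pair ranking equals exhaustive recomputation on toy catalogs", {
  set.seed(23)
  for (rep in 1:10) {
    n_drugs <- sample(3:6, 1)
    drugs <- sprintf("d%d", seq_len(n_drugs))
    targets <- sprintf("T%02d", 1:8)
    dt <- do.call(rbind, lapply(drugs, function(d) {
      k <- sample.int(4, 1)
      data.frame(drug_id = d, target_id = sample(targets, k),
                 direction = sample(c(-1, 1), k, replace = TRUE))
    }))
    disease <- data.frame(target_id = sample(targets, 3),
                          desired_direction = sample(c(-1, 1), 3, replace = TRUE))
    catalog <- target_catalog(dt, disease)
    res <- targopt_rank_pairs(catalog)
    expect_identical(nrow(res), as.integer(choose(n_drugs, 2)))
    # oracle: recompute every pair independently, re-sort with the same keys
    combos <- t(combn(sort(drugs), 2))
    oracle <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
      o <- targopt_oracle(drug_targets_of(catalog, combos[k, 1]),
                          drug_targets_of(catalog, combos[k, 2]), disease)
      data.frame(drug_a = combos[k, 1], drug_b = combos[k, 2],
                 on_count = o$on, off_count = o$off, score = o$score)
    }))
    oracle <- oracle[order(-oracle$score, -oracle$on_count,
                           pair_id(oracle$drug_a, oracle$drug_b),
                           method = "radix"), ]
    expect_equal(res[c("drug_a", "drug_b", "on_count", "off_count", "score")],
                 oracle, ignore_attr = TRUE)
  }
})

test_that("with beta = 0 the ranking depends only on on-target coverage", {
  set.seed(24)
  drugs <- sprintf("d%d", 1:5)
  dt <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(drug_id = d,
               target_id = c(sample(c("T1", "T2", "T3"), 2),
                             paste0("decoy_", d)),
               direction = -1)
  }))
  disease <- data.frame(target_id = c("T1", "T2", "T3"),
                        desired_direction = -1)
  catalog <- target_catalog(dt, disease)
  r0 <- targopt_rank_pairs(catalog, beta = 0)
  expect_equal(r0$score, r0$on_count)
  # permuting the off-target decoys changes nothing at beta = 0
  dt2 <- dt
  dt2$target_id <- sub("decoy_d1", "TMP", dt2$target_id)
  dt2$target_id <- sub("decoy_d2", "decoy_d1", dt2$target_id)
  dt2$target_id <- sub("TMP", "decoy_d2", dt2$target_id)
  r1 <- targopt_rank_pairs(target_catalog(dt2, disease), beta = 0)
  expect_equal(r0[c("rank", "drug_a", "drug_b", "on_count", "score")],
               r1[c("rank", "drug_a", "drug_b", "on_count", "score")])
})

test_that("the planted catalog pair ranks first with zero off-targets", {
  gen <- generate_target_catalog(n_drugs = 12, n_disease_targets = 6,
                                 n_decoy_targets = 8, seed = 3)
  res <- targopt_rank_pairs(gen$catalog, alpha = 1, beta = 0.5)
  expect_identical(c(res$drug_a[1], res$drug_b[1]), gen$truth$planted_pair)
  expect_identical(res$off_count[1], 0L)
  expect_equal(res$score[1], 6)
  expect_true(res$pareto[1])
})

test_that("unknown drugs and tiny inputs are rejected by name", {
  gen <- generate_target_catalog(4, 3, 4, seed = 1)
  expect_error(targopt_rank_pairs(gen$catalog, drugs = c("drug001", "ghost")),
               "absent from catalog: ghost")
  expect_error(targopt_rank_pairs(gen$catalog, drugs = "drug001"),
               "at least 2")
})

test_that("the Pareto front marks exactly the non-dominated pairs", {
  gen <- generate_target_catalog(8, 4, 6, seed = 5)
  res <- targopt_rank_pairs(gen$catalog)
  for (i in seq_len(nrow(res))) {
    dominated <- any(res$on_count >= res$on_count[i] &
                     res$off_count <= res$off_count[i] &
                     (res$on_count > res$on_count[i] |
                      res$off_count < res$off_count[i]))
    expect_identical(res$pareto[i], !dominated)
  }
})
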