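# Synthetic-data generators: determinism, distributional sanity, and the
# planted-truth constructions the pipeline tests rely on.

test_that("generate_library is deterministic and well scaled", {
  l1 <- generate_library(5, 100, seed = 1)
  l2 <- generate_library(5, 100, seed = 1)
  expect_identical(l1$z, l2$z)
  expect_false(identical(l1$z, generate_library(5, 100, seed = 2)$z))
  expect_identical(l1$genes[1], "g0001")
  # CLT bound on column means of standard normals
  expect_true(all(abs(colMeans(l1$z)) < 4 / sqrt(100)))
  expect_error(generate_library(1, 100, seed = 1), ">= 2")
  expect_error(generate_library(5, 5, seed = 1), ">= 10")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_library(3, 20, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("plant_reversal builds disjoint sets from the pair's extremes", {
  for (seed in 1:10) {
    lib <- generate_library(10, 60, seed = seed)
    pl <- plant_reversal(lib, c("cmpd001", "cmpd002"), n_up = 8, n_down = 8,
                         sigma = 0.1, seed = seed + 100)
    expect_length(intersect(pl$disease$up, pl$disease$down), 0)
    # sets are frozen from the pre-noise combined profile
    zc <- lib$z[, 1] + lib$z[, 2]
    expect_true(max(zc[pl$disease$up]) < min(zc[pl$disease$down]))
    # sigma = 0 leaves the library untouched
    pl0 <- plant_reversal(lib, c("cmpd001", "cmpd002"), n_up = 8,
                          n_down = 8, sigma = 0, seed = seed + 100)
    expect_identical(pl0$library$z, lib$z)
  }
  lib <- generate_library(5, 20, seed = 1)
  expect_error(plant_reversal(lib, c("cmpd001", "cmpd001")), "distinct")
  expect_error(plant_reversal(lib, c("cmpd001", "ghost")), "not in library")
  expect_error(plant_reversal(lib, c("cmpd001", "cmpd002"),
                              n_up = 15, n_down = 15), "n_up \\+ n_down")
})

test_that("overwhelming noise degrades planted-pair recovery", {
  hits <- vapply(1:6, function(seed) {
    lib <- generate_library(12, 60, seed = seed)
    pl <- plant_reversal(lib, c("cmpd001", "cmpd002"), n_up = 6, n_down = 6,
                         sigma = 10, seed = seed + 500)
    top <- cgem_rank_pairs(pl$library, pl$disease, top_k = 1, quiet = TRUE)
    identical(c(top$compound_a, top$compound_b), pl$truth$planted_pair)
  }, logical(1))
  expect_lt(sum(hits), 6)
})

test_that("generated target catalogs honour the planted construction", {
  for (seed in 1:10) {
    gen <- generate_target_catalog(n_drugs = 10, n_disease_targets = 5,
                                   n_decoy_targets = 6, seed = seed)
    cat <- gen$catalog
    pp <- gen$truth$planted_pair
    s <- targopt_score(drug_targets_of(cat, pp[1]),
                       drug_targets_of(cat, pp[2]),
                       cat$disease_targets)
    expect_identical(s$on_count, 5L)
    expect_identical(s$off_count, 0L)
    # every decoy drug covers at most ceiling(n/2) disease targets and
    # carries at least one decoy off-target
    for (d in setdiff(catalog_drugs(cat), pp)) {
      td <- drug_targets_of(cat, d)
      expect_lte(sum(td$target_id %in% cat$disease_targets$target_id), 3)
      expect_gte(sum(startsWith(td$target_id, "decoy")), 1)
    }
  }
  g1 <- generate_target_catalog(6, 4, 5, seed = 2)
  g2 <- generate_target_catalog(6, 4, 5, seed = 2)
  expect_identical(g1$catalog$drug_targets, g2$catalog$drug_targets)
  expect_error(generate_target_catalog(1, 4, 5, seed = 1), ">= 2")
  expect_error(generate_target_catalog(5, 0, 5, seed = 1), "at least one")
})

test_that("behaviour cohorts follow the group specification", {
  spec <- default_cohort_spec(n = 10)
  t1 <- generate_behaviour_cohort(spec, seed = 4)
  t2 <- generate_behaviour_cohort(spec, seed = 4)
  expect_identical(t1, t2)
  expect_identical(nrow(t1), as.integer(sum(spec$n)))
  expect_identical(as.integer(table(t1$group_id)[["KO_vehicle"]]), 20L)
  # sd = 0 collapses every animal onto the group mean
  spec0 <- data.frame(group_id = "G", assay = "NOR", n = 5,
                      mean_novel = 25, mean_familiar = 10, sd = 0)
  t0 <- generate_behaviour_cohort(spec0, seed = 1)
  expect_true(all(t0$t_novel == 25) && all(t0$t_familiar == 10))
  # draws are clamped at zero (times cannot be negative)
  specneg <- data.frame(group_id = "G", assay = "hyponeophagia", n = 200,
                        mean_latency = 1, sd = 50)
  tn <- generate_behaviour_cohort(specneg, seed = 2)
  expect_true(all(tn$latency >= 0))
  expect_error(generate_behaviour_cohort(
    data.frame(group_id = "G", assay = "NOR", n = 0, sd = 1), seed = 1),
    "n must be")
})

test_that("cohort tables flow through the behaviour module end to end", {
  trials <- generate_behaviour_cohort(default_cohort_spec(10), seed = 11)
  rec <- behaviour_endpoints(trials)
  s <- summarize_groups(rec)
  expect_identical(nrow(s), 6L)   # 3 groups x 2 assays
  # the planted group effect is visible: impaired group scores lower D2
  d2 <- s[s$assay == "NOR", ]
  expect_lt(d2$mean[d2$group_id == "KO_vehicle"],
            d2$mean[d2$group_id == "WT_vehicle"])
})
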