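test_that("identical spec and seed give identical cohorts; seeds differ otherwise", {
  spec <- cohort_spec(n_genes = 5, n_variants = 40,
                      planted_pathogenic_genes = 2, seed = 11)
  expect_identical(gen_cohort(spec), gen_cohort(spec))
  spec2 <- cohort_spec(n_genes = 5, n_variants = 40,
                       planted_pathogenic_genes = 2, seed = 12)
  expect_false(identical(gen_cohort(spec)$allele_frequency,
                         gen_cohort(spec2)$allele_frequency))
})

test_that("generation does not disturb the global random state", {
  withr::with_seed(99, {
    before <- .Random.seed
    gen_cohort(cohort_spec(n_genes = 3, n_variants = 10, seed = 5))
    expect_identical(.Random.seed, before)
  })
})

test_that("noise-free planted genes are recovered exactly; none without planting", {
  for (seed in 1:5) {
    cohort <- gen_cohort(cohort_spec(n_genes = 5, n_variants = 40,
                                     planted_pathogenic_genes = 2,
                                     noise_rate = 0, seed = seed))
    rec <- evaluate_recovery(cohort)
    expect_equal(rec$recovered, rec$planted, info = paste("seed", seed))
    expect_equal(rec$sensitivity, 1.0)
    expect_equal(rec$specificity, 1.0)
  }
  clean <- gen_cohort(cohort_spec(n_genes = 5, n_variants = 40,
                                  noise_rate = 0, seed = 1))
  expect_equal(evaluate_recovery(clean)$recovered, character())
})

test_that("planted variants always reach at least likely pathogenic at zero noise", {
  cohort <- gen_cohort(cohort_spec(n_genes = 8, n_variants = 120,
                                   planted_pathogenic_genes = 3,
                                   noise_rate = 0, seed = 3))
  planted_rank <- tier_rank(cohort$true_tier[cohort$planted])
  expect_true(all(planted_rank >= 4))
  other_rank <- tier_rank(cohort$true_tier[!cohort$planted])
  expect_true(all(other_rank <= 3))
})

test_that("specificity degrades (non-strictly) as noise rises", {
  mean_spec <- function(noise) {
    mean(vapply(1:8, function(seed) {
      cohort <- gen_cohort(cohort_spec(n_genes = 10, n_variants = 60,
                                       planted_pathogenic_genes = 2,
                                       noise_rate = noise, seed = seed))
      evaluate_recovery(cohort)$specificity
    }, numeric(1)))
  }
  curve <- c(mean_spec(0), mean_spec(0.2), mean_spec(0.5))
  expect_true(all(diff(curve) <= 0))
  expect_lt(curve[3], 1)
})

test_that("infeasible or invalid specs are rejected", {
  expect_error(cohort_spec(n_genes = 3, n_variants = 0,
                           planted_pathogenic_genes = 2), "infeasible")
  expect_error(cohort_spec(n_genes = 3, planted_pathogenic_genes = "ZZZ"),
               "subset")
  expect_error(cohort_spec(noise_rate = 1.5), "\\[0,1\\]")
})

test_that("random profiles honor count bounds and match the oracle", {
  profs <- gen_profiles(1000, code_probs = 0, seed = 1)
  expect_true(all(vapply(profs, function(p) length(p$codes) == 0, TRUE)))
  tiers <- vapply(profs[1:20], function(p) classify_profile(p)$tier, "")
  expect_true(all(tiers == "uncertain_significance"))

  ba_only <- gen_profiles(200, code_probs = c(BA1 = 1), seed = 2)
  expect_true(all(vapply(ba_only, function(p) classify_profile(p)$tier, "")
                  == "benign"))

  profs <- gen_profiles(2000, code_probs = 0.15, seed = 7)
  agree <- vapply(profs, function(p) {
    got <- classify_profile(p)
    want <- oracle_classify(as.list(p$counts))
    got$tier == want$tier && got$via_contradiction == want$via_contradiction
  }, TRUE)
  expect_equal(mean(agree), 1.0)
})

test_that("cohort specs survive a YAML/JSON round trip", {
  spec <- cohort_spec(n_genes = 6, n_variants = 30,
                      planted_pathogenic_genes = c("G02", "G05"),
                      noise_rate = 0.1, seed = 4)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cohort_spec(spec, path)
    expect_equal(read_cohort_spec(path), spec)
  }
})
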