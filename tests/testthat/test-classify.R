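test_that("published combination examples classify to their stated tier", {
  expect_equal(classify_profile(c("PVS1", "PS3"))$tier, "pathogenic")
  expect_equal(classify_profile(c("BA1"))$tier, "benign")
  expect_equal(classify_profile(c("PM1", "PM2", "PP1", "PP3"))$tier,
               "likely_pathogenic")
  expect_equal(classify_profile(c("BS1", "BP4"))$tier, "likely_benign")

  empty <- classify_profile(character())
  expect_equal(empty$tier, "uncertain_significance")
  expect_false(empty$via_contradiction)
  expect_length(empty$matched_rules, 0)

  both <- classify_profile(c("BA1", "PVS1", "PS1"))
  expect_equal(both$tier, "uncertain_significance")
  expect_true(both$via_contradiction)
})

test_that("a contradiction implies uncertain significance and non-VUS tiers carry matched rules", {
  grid <- enumerate_count_vectors()
  res <- classify_counts(grid)
  expect_true(all(res$tier[res$via_contradiction] == "uncertain_significance"))
  cls <- classify_profile(c("PVS1", "PM2"))
  expect_gt(length(cls$matched_rules), 0)
})

test_that("enumeration yields each admissible count vector exactly once", {
  grid <- enumerate_count_vectors()
  expect_equal(nrow(grid), 33600L)
  expect_equal(nrow(unique(grid)), 33600L)
  expect_true(any(rowSums(grid) == 0))       # all-zero vector present
  expect_true(all(grid$PVS <= 1))            # no vector beyond bounds
  expect_equal(sapply(grid, max),
               c(PVS = 1, PS = 4, PM = 6, PP = 5, BA = 1, BS = 4, BP = 7))
})

test_that("engine agrees with the brute-force oracle on sampled vectors in both dialects", {
  grid <- enumerate_count_vectors()
  idx <- withr::with_seed(42, sample(nrow(grid), 3000))
  sub <- grid[idx, ]
  for (dia in c("paper_verbatim", "acmg2015")) {
    got <- classify_counts(sub, rule_dialect(dia))
    want <- oracle_classify_all(sub, dia)
    expect_equal(got$tier, want$tier, info = dia)
    expect_equal(got$via_contradiction, want$via_contradiction, info = dia)
  }
})

test_that("classification depends only on the count vector, not code identity or order", {
  same_counts <- list(c("PS1", "PM2", "PP3", "PP5"),
                      c("PS4", "PM6", "PP1", "PP2"),
                      c("PP5", "PS2", "PP4", "PM1"))
  tiers <- vapply(same_counts, function(cs) classify_profile(cs)$tier, "")
  expect_equal(unique(tiers), "likely_pathogenic")
  shuffled <- withr::with_seed(1, sample(c("PVS1", "PM2", "BA1", "BP4")))
  expect_equal(classify_profile(shuffled),
               classify_profile(c("PVS1", "PM2", "BA1", "BP4")))
})

test_that("the two dialects disagree exactly on the vectors touched by their differing lines", {
  grid <- enumerate_count_vectors()
  verbatim <- classify_counts(grid, rule_dialect("paper_verbatim"))
  guideline <- classify_counts(grid, rule_dialect("acmg2015"))
  diff <- which(verbatim$tier != guideline$tier |
                  verbatim$via_contradiction != guideline$via_contradiction)
  expect_gt(length(diff), 0)
  # only vectors reachable by ">=3 PP" vs ">=3 PM" or "PVS1 + 1 PM + 1 PP"
  affected <- grid$PP >= 3 | grid$PM >= 3 |
    (grid$PVS >= 1 & grid$PM >= 1 & grid$PP >= 1)
  expect_true(all(affected[diff]))
})

test_that("explain reports every line, matched flags, and the tier deterministically", {
  rep1 <- explain_profile(c("PVS1", "PM2"))
  expect_equal(attr(rep1, "classification")$tier, "likely_pathogenic")
  matched_line <- grepl("1 PVS1 + 1 (PM1-PM6)", rep1, fixed = TRUE) &
    grepl("[x]", rep1, fixed = TRUE)
  expect_true(any(matched_line))
  expect_identical(unclass(rep1), unclass(explain_profile(c("PVS1", "PM2"))))

  rep2 <- explain_profile(character())
  expect_true(any(grepl("matched lines: 0", rep2, fixed = TRUE)))

  rep3 <- explain_profile(c("BA1", "PVS1", "PS1"))
  expect_true(any(grepl("contradictory", rep3)))
  expect_true(any(grepl("tier: uncertain_significance", rep3, fixed = TRUE)))
})

test_that("dialects serialize to YAML/JSON and load back unchanged", {
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_dialect(rule_dialect("acmg2015"), path)
    back <- read_dialect(path)
    expect_equal(back$name, "acmg2015")
    grid <- enumerate_count_vectors()[seq(1, 33600, by = 37), ]
    expect_equal(classify_counts(grid, back),
                 classify_counts(grid, rule_dialect("acmg2015")))
  }
})
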