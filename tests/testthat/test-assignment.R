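test_that("allele-frequency rules use strict boundaries on both thresholds", {
  af_codes <- function(af) {
    assign_codes(annotation_bundle(allele_frequency = af))$codes
  }
  expect_true("PM2" %in% af_codes(0.000999))
  expect_false("PM2" %in% af_codes(0.001))
  expect_false("BA1" %in% af_codes(0.005))
  expect_true("BA1" %in% af_codes(0.0051))
  expect_false("BA1" %in% af_codes(0.001))   # between the thresholds
  expect_true("PM2" %in% af_codes(NA))       # absent from databases
})

test_that("assignment reproduces the documented single-variant profiles", {
  expect_equal(
    assign_codes(annotation_bundle(allele_frequency = 0.0005,
                                   consequence = "missense"))$codes,
    "PM2")
  p <- assign_codes(annotation_bundle(allele_frequency = 0.02))$codes
  expect_equal(p, "BA1")
  p <- assign_codes(annotation_bundle(consequence = "frameshift",
                                      de_novo = "confirmed"),
                    gene_config = gene_rule_config(lof_mechanism = TRUE))
  expect_true(all(c("PVS1", "PS2", "PM2") %in% p$codes))
  expect_equal(
    assign_codes(annotation_bundle(allele_frequency = 0.5))$codes, "BA1")
})

test_that("PVS1 and PP2 are withheld without gene-level configuration", {
  null_bundle <- annotation_bundle(consequence = "nonsense")
  expect_false("PVS1" %in% assign_codes(null_bundle)$codes)
  expect_true("PVS1" %in% assign_codes(
    null_bundle, gene_rule_config(lof_mechanism = TRUE))$codes)
  mis <- annotation_bundle(consequence = "missense", allele_frequency = 0.002)
  expect_false("PP2" %in% assign_codes(mis)$codes)
  expect_true("PP2" %in% assign_codes(
    mis, gene_rule_config(missense_constrained = TRUE))$codes)
})

test_that("automatic rules never emit contradictory code pairs and respect count bounds", {
  bundles <- expand.grid(
    consequence = c("missense", "frameshift", "inframe_indel", "synonymous"),
    de_novo = c("confirmed", "unconfirmed", "no", "unknown"),
    segregates_in_family = c("yes", "no", "unknown"),
    functional_study = c("supports_pathogenic", "supports_benign", "none"),
    in_silico_verdict = c("deleterious", "benign_pred", "none"),
    af = c(NA, 1e-5, 0.002, 0.1),
    stringsAsFactors = FALSE
  )
  forbidden <- list(c("PS2", "PM6"), c("PP1", "BS4"), c("PS3", "BS3"),
                    c("PP3", "BP4"), c("PM2", "BA1"))
  for (i in seq_len(nrow(bundles))) {
    b <- bundles[i, ]
    prof <- assign_codes(annotation_bundle(
      allele_frequency = b$af, consequence = b$consequence,
      de_novo = b$de_novo, segregates_in_family = b$segregates_in_family,
      functional_study = b$functional_study,
      in_silico_verdict = b$in_silico_verdict,
      hotspot_or_domain = i %% 2 == 0),
      gene_config = gene_rule_config(lof_mechanism = i %% 3 == 0,
                                     missense_constrained = i %% 5 == 0))
    for (pair in forbidden) {
      expect_false(all(pair %in% prof$codes),
                   info = paste(pair, collapse = "+"))
    }
    expect_true(all(prof$counts <= c(PVS = 1, PS = 4, PM = 6, PP = 5,
                                     BA = 1, BS = 4, BP = 7)))
  }
})

test_that("assignment is deterministic and manual codes are additive without double counting", {
  b <- annotation_bundle(allele_frequency = 1e-5, consequence = "missense",
                         manual_codes = c("PP5", "PM2"))
  expect_identical(assign_codes(b), assign_codes(b))
  prof <- assign_codes(b)
  expect_equal(sum(prof$codes == "PM2"), 1L)   # manual PM2 not double counted
  expect_true("PP5" %in% prof$codes)
})

test_that("vocabulary violations and inverted thresholds are rejected", {
  expect_error(annotation_bundle(consequence = "stop_gained"),
               "unknown consequence")
  expect_error(acmg_thresholds(pm2_max_af = 0.01, ba1_min_af = 0.005),
               "inverted")
  expect_error(annotation_bundle(allele_frequency = 1.5), "\\[0,1\\]")
})

test_that("the composed variant classifier matches the documented end-to-end calls", {
  expect_equal(classify_variant(
    annotation_bundle(consequence = "frameshift",
                      functional_study = "supports_pathogenic"),
    gene_config = gene_rule_config(lof_mechanism = TRUE))$tier,
    "pathogenic")   # {PVS1, PM2, PS3}
  expect_equal(classify_variant(
    annotation_bundle(consequence = "synonymous",
                      allele_frequency = 0.3))$tier,
    "benign")
  expect_equal(classify_variant(
    annotation_bundle(consequence = "missense",
                      allele_frequency = 1e-4))$tier,
    "uncertain_significance")
})

test_that("splice descriptions map to canonical or other splice region by offset", {
  expect_equal(
    splice_consequence(c("c.1737+1G>T", "c.357-2A>G", "c.3963+2T>C",
                         "IVS9-3C>G", "c.-225-820T>C")),
    c("canonical_splice", "canonical_splice", "canonical_splice",
      "other_splice_region", "other_splice_region")
  )
})
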