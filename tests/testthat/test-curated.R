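curated <- load_curated()

test_that("the curated dataset carries the pinned record and gene counts", {
  expect_equal(nrow(curated), 99L)
  expect_equal(as.vector(table(curated$table_of_origin)[c("T3", "T4", "T5", "T6")]),
               c(73L, 16L, 1L, 9L))
  expect_equal(length(distinct_genes(curated)), 34L)
  t3 <- curated[curated$table_of_origin == "T3", ]
  expect_equal(length(distinct_genes(t3)), 28L)
  expect_equal(sum(t3$gene == "TRPM4"), 12L)
  expect_equal(distinct_genes(data.frame(gene = character())), character())
})

test_that("repeated reports stay separate records and symbols are normalized", {
  hcn4_dup <- curated[curated$chrom == "15" & !is.na(curated$pos) &
                        curated$pos == 73329719, ]
  expect_equal(nrow(hcn4_dup), 2L)           # two studies, same variant
  expect_equal(sum(curated$hgvs == "c.234delC", na.rm = TRUE), 2L)
  expect_false("NKX2.5" %in% curated$gene)
  expect_true("NKX2.5" %in% curated$printed_gene)
  expect_true("TGFB1" %in% curated$gene)
  expect_true("TGF beta 1" %in% curated$printed_gene)
})

test_that("every printed T3 verdict parses to a recognized tier", {
  t3 <- curated[curated$table_of_origin == "T3", ]
  expect_false(anyNA(t3$printed_classification))
  tiers <- parse_printed_classification(t3$printed_classification)
  expect_true(all(tiers %in% c("pathogenic", "likely_pathogenic",
                               "uncertain_significance", "likely_benign",
                               "benign")))
  expect_error(parse_printed_classification("Probably damaging"),
               "unrecognized")
})

test_that("TSV round trip reproduces the record list exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curated_tsv(curated, path)
  back <- read_curated_tsv(path)
  expect_identical(back, curated)
})

test_that("a corrupted fixture fails its checksum", {
  src <- system.file("extdata", "curated_variants.tsv", package = "bradyvar")
  tmpdir <- withr::local_tempdir()
  bad <- file.path(tmpdir, "curated_variants.tsv")
  txt <- readLines(src)
  txt[2] <- sub("Likely pathogenic", "Pathogenic", txt[2], fixed = TRUE)
  writeLines(txt, bad)
  file.copy(paste0(src, ".sha256"), paste0(bad, ".sha256"))
  expect_error(load_curated(bad, verify_checksum = TRUE), "checksum mismatch")
})

test_that("screening ledger arithmetic matches the stored counts", {
  expect_equal(included_count(screening_ledger()), 88L)
  expect_equal(included_count(list(enrolled = 0, excluded = 0)), 0L)
  expect_equal(included_count(list(enrolled = 10, excluded = 3)), 7L)
  expect_error(included_count(list(enrolled = 3, excluded = 10)),
               "inconsistent")
  expect_error(included_count(list(enrolled = 10, excluded = 3,
                                   included = 5)), "inconsistent")
})

test_that("VCF export writes exactly the coordinate-complete records as valid VCF 4.2", {
  path <- withr::local_tempfile(fileext = ".vcf")
  suppressMessages(out <- export_vcf(curated, path))
  expect_equal(attr(out, "n_written"), 73L)
  expect_equal(attr(out, "n_skipped"), 26L)
  txt <- readLines(path)
  expect_equal(txt[1], "##fileformat=VCFv4.2")
  expect_equal(sum(!startsWith(txt, "#")), 73L)

  # independent parse with vcfR, then round-trip the coordinates
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  expect_equal(nrow(fix), 73L)
  t3 <- curated[curated$variant_class == "snv", ]
  key <- function(chrom, pos, ref, alt) {
    sort(paste(sub("^chr", "", chrom), pos, ref, alt))
  }
  expect_equal(key(fix$CHROM, fix$POS, fix$REF, fix$ALT),
               key(t3$chrom, t3$pos, t3$ref, t3$alt))
})

test_that("an empty record list exports a header-only VCF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  export_vcf(curated[0, ], path)
  txt <- readLines(path)
  expect_true(all(startsWith(txt, "#")))
  expect_equal(txt[1], "##fileformat=VCFv4.2")
})
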