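ANNOTATION_COLUMNS <- c("allele_frequency", "consequence", "de_novo",
                        "segregates_in_family", "functional_study",
                        "in_silico_verdict", "hotspot_or_domain",
                        "observed_healthy_recessive", "manual_codes")

#' Read and write annotated variant tables (TSV dialect)
#'
#' The annotated-variant dialect is a TSV with one header row and one row
#' per variant: a `gene` column plus any of the annotation-bundle fields
#' (`allele_frequency`, `consequence`, `de_novo`, `segregates_in_family`,
#' `functional_study`, `in_silico_verdict`, `hotspot_or_domain`,
#' `observed_healthy_recessive`, `manual_codes` as a comma-separated
#' list). Missing columns and empty cells default to "no information".
#' Extra columns (identifiers, coordinates, ground-truth labels) pass
#' through untouched.
#'
#' @param path Input (or output) TSV path.
#' @return `read_annotated_tsv()` returns a data frame;
#'   `write_annotated_tsv()` returns `path` invisibly.
#' @export
read_annotated_tsv <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = c("", "NA"), quote = "",
                           stringsAsFactors = FALSE)
  if (!nrow(tbl) && !"gene" %in% names(tbl)) tbl$gene <- character()
  if (!"gene" %in% names(tbl)) stop("annotated table needs a 'gene' column")
  if ("allele_frequency" %in% names(tbl)) {
    tbl$allele_frequency <- as.numeric(tbl$allele_frequency)
  }
  for (col in c("hotspot_or_domain", "observed_healthy_recessive")) {
    if (col %in% names(tbl)) tbl[[col]] <- as.logical(tbl[[col]])
  }
  if ("manual_codes" %in% names(tbl)) {
    tbl$manual_codes <- ifelse(is.na(tbl$manual_codes), "",
                               tbl$manual_codes)
  }
  tbl
}

#' @rdname read_annotated_tsv
#' @param tbl Data frame to write.
#' @export
write_annotated_tsv <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read annotations from a minimal VCF
#'
#' Reads a VCF (4.x) and builds an annotated variant table from the INFO
#' keys `GENE`, `AF`, `CSQ_CLASS` (consequence label), `DENOVO`,
#' `SEGREGATION`, `FUNC` (functional-study verdict) and `INSILICO`;
#' absent keys default to "no information". Parsing is done with the
#' `vcfR` package.
#'
#' @param path VCF file path.
#' @return Data frame in the annotated-variant dialect, with `chrom`,
#'   `pos`, `ref`, `alt` and `variant_id` carried from the VCF columns.
#' @export
read_annotated_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info_key <- function(key) {
    if (!nrow(fix)) return(character())
    vals <- vcfR::extract.info(vcf, element = key)
    if (is.null(vals)) rep(NA_character_, nrow(fix)) else vals
  }
  or_default <- function(x, default) ifelse(is.na(x), default, x)
  data.frame(
    variant_id = or_default(fix$ID, paste0(fix$CHROM, ":", fix$POS)),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_key("GENE"),
    allele_frequency = suppressWarnings(as.numeric(info_key("AF"))),
    consequence = or_default(info_key("CSQ_CLASS"), "other"),
    de_novo = or_default(info_key("DENOVO"), "unknown"),
    segregates_in_family = or_default(info_key("SEGREGATION"), "unknown"),
    functional_study = or_default(info_key("FUNC"), "none"),
    in_silico_verdict = or_default(info_key("INSILICO"), "none"),
    hotspot_or_domain = FALSE,
    observed_healthy_recessive = FALSE,
    manual_codes = "",
    stringsAsFactors = FALSE
  )
}

#' Read or write a run configuration
#'
#' A run configuration bundles the tunables of a pipeline run: rule
#' dialect name, allele-frequency thresholds, verdict source for
#' prioritization, and seed. Defaults reproduce the curated analysis:
#' `paper_verbatim` dialect, PM2 below 0.001, BA1 above 0.005, printed
#' verdicts for the fixture.
#'
#' @param dialect Dialect name.
#' @param pm2_max_af,ba1_min_af Allele-frequency thresholds.
#' @param verdict_source `"printed"` or `"computed"`.
#' @param seed Integer seed for simulation commands.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dialect = "paper_verbatim", pm2_max_af = 0.001,
                       ba1_min_af = 0.005,
                       verdict_source = c("printed", "computed"), seed = 1) {
  verdict_source <- match.arg(verdict_source)
  acmg_thresholds(pm2_max_af, ba1_min_af)  # validates the pair
  structure(list(dialect = dialect, pm2_max_af = pm2_max_af,
                 ba1_min_af = ba1_min_af, verdict_source = verdict_source,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML or JSON file.
#' @export
read_run_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, doc)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  doc <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
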