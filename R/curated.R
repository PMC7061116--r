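CURATED_COLUMNS <- c("record_id", "table_of_origin", "chrom", "pos", "ref",
                     "alt", "hgvs", "dbsnp", "gene", "printed_gene",
                     "variant_class", "printed_classification", "gnomad_af",
                     "functional_study", "manifestations", "source")

curated_path <- function(file = "curated_variants.tsv") {
  system.file("extdata", file, package = "bradyvar", mustWork = TRUE)
}

#' Load the curated familial-bradycardia variant dataset
#'
#' The 99 literature-reported sequence variants transcribed from the
#' reclassification study: 73 SNVs with InterVar-derived five-tier verdicts
#' (table T3), 16 frameshift records (T4), 1 large deletion (T5) and 9
#' splicing records (T6). Each printed table row is one record, so the
#' same variant reported by two studies appears twice; gene symbols are
#' normalized (`NKX2.5` to `NKX2-5`, `TGF beta 1` to `TGFB1`) with the
#' printed form retained in `printed_gene`. Positions are 1-based GRCh38.
#' Irregular source rows (frameshift records lacking loci or verdicts) are
#' carried verbatim with absent fields.
#'
#' The shipped fixture is verified against its SHA-256 sidecar before use.
#'
#' @param path Fixture path; defaults to the file shipped with the package.
#' @param verify_checksum Verify the SHA-256 sidecar (default `TRUE` for
#'   the shipped fixture).
#' @return A data frame of variant records (one row each) with columns
#'   `record_id, table_of_origin, chrom, pos, ref, alt, hgvs, dbsnp, gene,
#'   printed_gene, variant_class, printed_classification, gnomad_af,
#'   functional_study, manifestations, source`. Absent fields are `NA`;
#'   `manifestations` and `source` are `"; "`-separated token lists.
#' @examples
#' vars <- load_curated()
#' nrow(vars)            # 99
#' table(vars$table_of_origin)
#' @export
load_curated <- function(path = curated_path(),
                         verify_checksum = missing(path)) {
  if (verify_checksum) {
    sidecar <- paste0(path, ".sha256")
    if (!file.exists(sidecar)) stop("checksum sidecar missing: ", sidecar)
    want <- trimws(strsplit(readLines(sidecar, warn = FALSE)[1], "\\s+")[[1]][1])
    got <- digest::digest(path, algo = "sha256", file = TRUE)
    if (!identical(got, want)) {
      stop("curated fixture checksum mismatch (transcription corrupted?): ",
           "expected ", want, ", got ", got)
    }
  }
  read_curated_tsv(path)
}

#' @rdname load_curated
#' @export
read_curated_tsv <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "",
                           quote = "", check.names = FALSE)
  missing_cols <- setdiff(CURATED_COLUMNS, names(tbl))
  if (length(missing_cols)) {
    stop("curated table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tbl <- tbl[CURATED_COLUMNS]
  tbl$pos <- as.integer(tbl$pos)
  tbl$gnomad_af <- as.numeric(tbl$gnomad_af)
  validate_curated(tbl)
  tbl
}

validate_curated <- function(tbl) {
  stopifnot(all(!is.na(tbl$gene)), all(!is.na(tbl$table_of_origin)))
  if (!all(tbl$table_of_origin %in% c("T3", "T4", "T5", "T6"))) {
    stop("unknown table_of_origin label")
  }
  snv <- tbl$variant_class == "snv"
  complete <- !is.na(tbl$chrom) & !is.na(tbl$pos) & !is.na(tbl$ref) &
    !is.na(tbl$alt)
  if (any(snv & !complete)) stop("snv record lacking chrom/pos/ref/alt")
  if (any(snv & tbl$ref == tbl$alt, na.rm = TRUE)) stop("snv with ref == alt")
  t3 <- tbl$table_of_origin == "T3"
  if (any(t3 & is.na(tbl$printed_classification))) {
    stop("T3 record without a printed classification")
  }
  invisible(tbl)
}

#' Write a curated variant table back to TSV
#'
#' Inverse of [read_curated_tsv()]; a write followed by a read reproduces
#' the record list exactly.
#'
#' @param records Curated variant data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curated_tsv <- function(records, path) {
  out <- records[CURATED_COLUMNS]
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Study-selection ledger
#'
#' Article counts from the study-selection flow of the literature review:
#' articles enrolled by the PubMed query, articles excluded by the
#' selection criteria, and articles included in the final analysis.
#'
#' @param path Ledger TSV; defaults to the shipped fixture
#'   (1015 enrolled, 927 excluded, 88 included).
#' @return A list with integer elements `enrolled`, `excluded`, `included`.
#' @export
screening_ledger <- function(path = curated_path("screening_ledger.tsv")) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE)
  ledger <- list(enrolled = as.integer(tbl$enrolled[1]),
                 excluded = as.integer(tbl$excluded[1]),
                 included = as.integer(tbl$included[1]))
  if (anyNA(unlist(ledger)) || any(unlist(ledger) < 0L)) {
    stop("screening ledger counts must be non-negative integers")
  }
  ledger
}

#' Included-article count from a screening ledger
#'
#' @param ledger A list with `enrolled`, `excluded` and (optionally)
#'   `included` counts.
#' @return `enrolled - excluded`; errors if negative or if a stored
#'   `included` field disagrees.
#' @examples
#' included_count(list(enrolled = 1015, excluded = 927))  # 88
#' @export
included_count <- function(ledger) {
  n <- as.integer(ledger$enrolled) - as.integer(ledger$excluded)
  if (is.na(n) || n < 0L) stop("inconsistent ledger: excluded > enrolled")
  if (!is.null(ledger$included) && !is.na(ledger$included) &&
      as.integer(ledger$included) != n) {
    stop("inconsistent ledger: stored included count (", ledger$included,
         ") != enrolled - excluded (", n, ")")
  }
  n
}

#' Distinct normalized gene symbols in a record set
#'
#' @param records Curated (or generated) variant data frame with a `gene`
#'   column.
#' @return Sorted character vector of distinct symbols.
#' @examples
#' length(distinct_genes(load_curated()))  # 34
#' @export
distinct_genes <- function(records) {
  sort(unique(records$gene[!is.na(records$gene)]))
}

#' Export coordinate-complete records as minimal VCF 4.2
#'
#' Writes one data line per record with complete `chrom/pos/ref/alt`
#' (GRCh38, 1-based); records lacking coordinates or alleles (the
#' frameshift/deletion/splice rows transcribed without loci) are skipped
#' and counted. The printed classification and source study are carried in
#' the INFO field (keys `GENE`, `CLASS`, `SRC`; spaces encoded as `_`).
#'
#' @param records Curated variant data frame.
#' @param path Output VCF path.
#' @return `path` invisibly, with attributes `n_written` and `n_skipped`.
#' @examples
#' \donttest{
#' path <- export_vcf(load_curated(), tempfile(fileext = ".vcf"))
#' attr(path, "n_written")  # 73
#' }
#' @export
export_vcf <- function(records, path) {
  exportable <- !is.na(records$chrom) & !is.na(records$pos) &
    !is.na(records$ref) & !is.na(records$alt)
  n_skip <- sum(!exportable)
  if (n_skip) {
    message(n_skip, " record(s) without complete chrom/pos/ref/alt skipped")
  }
  rec <- records[exportable, , drop = FALSE]
  rec <- rec[order(vcf_chrom_order(rec$chrom), rec$pos), , drop = FALSE]
  info_val <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "."
    gsub("[;=,[:space:]]+", "_", x)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh38",
    sprintf("##contig=<ID=%s>", unique(vcf_contig(rec$chrom))),
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="Printed five-tier classification">',
    '##INFO=<ID=SRC,Number=1,Type=String,Description="Source study">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- if (nrow(rec)) {
    paste(vcf_contig(rec$chrom), rec$pos,
          ifelse(is.na(rec$dbsnp), rec$record_id, rec$dbsnp),
          rec$ref, rec$alt, ".", ".",
          sprintf("GENE=%s;CLASS=%s;SRC=%s", info_val(rec$gene),
                  info_val(rec$printed_classification), info_val(rec$source)),
          sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  out <- path
  attr(out, "n_written") <- nrow(rec)
  attr(out, "n_skipped") <- n_skip
  invisible(out)
}

vcf_contig <- function(chrom) paste0("chr", sub("^chr", "", chrom))

vcf_chrom_order <- function(chrom) {
  key <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(key))
  num[key == "X"] <- 23L
  num[key == "Y"] <- 24L
  num[is.na(num)] <- 25L
  num
}
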