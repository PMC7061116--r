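PHENOTYPE_CATEGORIES <- c("conduction_disease", "other_arrhythmia",
                          "cardiomyopathy_or_myopathy", "nervous_system",
                          "other")

#' Phenotype-token to category map
#'
#' Maps the clinical-manifestation tokens of the curated records onto five
#' phenotype categories: bradycardia/conduction phenotypes (SSS, AVB,
#' PCCD, CCD), other arrhythmias (AF, AFL, VT, LQT, WPW, SCD), cardiomyopathy
#' or myopathy (DCM, HCM, LVNC, muscular dystrophy, Danon disease, ...),
#' nervous-system disease, and a residual `other` category. Tokens absent
#' from the map fall into `other` and are reported with a message.
#'
#' @return Named character vector: token to category.
#' @export
phenotype_map <- function() {
  c(
    "SSS" = "conduction_disease",
    "AVB" = "conduction_disease",
    "PCCD" = "conduction_disease",
    "CCD" = "conduction_disease",
    "AF" = "other_arrhythmia",
    "AFL" = "other_arrhythmia",
    "VT" = "other_arrhythmia",
    "LQT" = "other_arrhythmia",
    "WPW" = "other_arrhythmia",
    "SCD" = "other_arrhythmia",
    "Timothy syndrome 1 (TS1)" = "other_arrhythmia",
    "DCM" = "cardiomyopathy_or_myopathy",
    "HCM" = "cardiomyopathy_or_myopathy",
    "LVNC" = "cardiomyopathy_or_myopathy",
    "muscular dystrophy" = "cardiomyopathy_or_myopathy",
    "Danon disease" = "cardiomyopathy_or_myopathy",
    "cardiomyopathy" = "cardiomyopathy_or_myopathy",
    "Rett syndrome" = "nervous_system",
    "epilepsy" = "nervous_system",
    "HF" = "other",
    "ASD" = "other",
    "congenital cardiovascular diseases (CCVD)" = "other",
    "atrial dilatation (AD)" = "other",
    "focal segmental glomerulosclerosis (FSGS)" = "other"
  )
}

#' Map manifestation tokens to phenotype categories
#'
#' @param tokens Character vector of phenotype tokens.
#' @param phenomap Token-to-category map (default [phenotype_map()]).
#' @param warn Message unknown tokens (mapped to `"other"`)?
#' @return Character vector of categories, one per token.
#' @export
map_phenotypes <- function(tokens, phenomap = phenotype_map(), warn = TRUE) {
  tokens <- trimws(tokens)
  hit <- phenomap[tokens]
  unknown <- is.na(hit) & nzchar(tokens)
  if (warn && any(unknown)) {
    message("unmapped phenotype token(s) assigned to 'other': ",
            paste(unique(tokens[unknown]), collapse = ", "))
  }
  hit[is.na(hit)] <- "other"
  unname(hit)
}

# printed verdict labels -> canonical tier + rank.
# Slashed labels rank by their stronger side (P/LP ranks as pathogenic,
# B/LB as benign); "Conflicting interpretations" and absent verdicts rank
# as uncertain significance.
PRINTED_VERDICTS <- c(
  "Pathogenic" = "pathogenic",
  "Likely pathogenic" = "likely_pathogenic",
  "Pathogenic/likely pathogenic" = "pathogenic",
  "Uncertain significance" = "uncertain_significance",
  "Uncertain significant" = "uncertain_significance",
  "Conflicting interpretations of pathogenicity" = "uncertain_significance",
  "Likely benign" = "likely_benign",
  "Benign/likely benign" = "benign",
  "Benign" = "benign"
)

#' Canonical tier from a printed verdict label
#'
#' @param x Character vector of printed classification labels (possibly
#'   slashed pairs, `"Conflicting interpretations of pathogenicity"`, or
#'   `NA` for records published without a verdict).
#' @return Canonical tier labels (see [tier_rank()]); `NA` and conflicting
#'   labels map to `"uncertain_significance"`.
#' @export
parse_printed_classification <- function(x) {
  out <- PRINTED_VERDICTS[as.character(x)]
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("unrecognized printed classification: ",
         paste(unique(x[bad]), collapse = "; "))
  }
  out[is.na(out)] <- "uncertain_significance"
  unname(out)
}

#' Per-gene summary of classified variant records
#'
#' Aggregates variant records by gene: record count, the strongest
#' classification among the gene's records (on the order benign <
#' likely_benign < uncertain_significance < likely_pathogenic <
#' pathogenic), a high-priority flag (strongest tier at least likely
#' pathogenic), and the union of mapped phenotype categories.
#'
#' @param records Variant data frame with a `gene` column and, depending
#'   on `verdict_source`, either `printed_classification` (curated
#'   fixture) or a canonical `tier` column (output of
#'   [classify_cohort()]).
#' @param phenomap Token-to-category map for the `manifestations` column
#'   (ignored if the column is absent).
#' @param verdict_source `"printed"` to rank the printed verdict labels,
#'   `"computed"` to rank the `tier` column.
#' @return Data frame with one row per gene: `gene`, `n_records`,
#'   `best_classification`, `high_priority`, `phenotype_categories`
#'   (`;`-separated).
#' @examples
#' summaries <- summarize_by_gene(load_curated())
#' high_priority_genes(summaries)
#' @export
summarize_by_gene <- function(records, phenomap = phenotype_map(),
                              verdict_source = c("printed", "computed")) {
  verdict_source <- match.arg(verdict_source)
  if (!nrow(records)) {
    return(data.frame(gene = character(), n_records = integer(),
                      best_classification = character(),
                      high_priority = logical(),
                      phenotype_categories = character(),
                      stringsAsFactors = FALSE))
  }
  tier <- switch(verdict_source,
                 printed = parse_printed_classification(
                   records$printed_classification),
                 computed = {
                   if (is.null(records$tier)) {
                     stop("verdict_source = 'computed' needs a 'tier' column")
                   }
                   records$tier
                 })
  rank <- tier_rank(tier)
  cats <- if (!is.null(records$manifestations)) {
    lapply(strsplit(ifelse(is.na(records$manifestations), "",
                           records$manifestations), ";"),
           function(tok) unique(map_phenotypes(tok[nzchar(trimws(tok))],
                                               phenomap, warn = FALSE)))
  } else {
    rep(list(character()), nrow(records))
  }
  split_idx <- split(seq_len(nrow(records)), records$gene)
  out <- do.call(rbind, lapply(names(split_idx), function(g) {
    idx <- split_idx[[g]]
    best <- max(rank[idx])
    pc <- sort(unique(unlist(cats[idx])))
    data.frame(
      gene = g,
      n_records = length(idx),
      best_classification = names(which(c(
        benign = 1L, likely_benign = 2L, uncertain_significance = 3L,
        likely_pathogenic = 4L, pathogenic = 5L) == best)),
      high_priority = best >= 4L,
      phenotype_categories = paste(pc, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

#' High-priority genes from per-gene summaries
#'
#' A gene is high priority when at least one of its records is classified
#' pathogenic or likely pathogenic (slashed pathogenic/likely-pathogenic
#' verdicts qualify). On the full curated dataset this reproduces the 13
#' recommended conduction-disease panel genes.
#'
#' @param summaries Output of [summarize_by_gene()].
#' @return Alphabetically ordered character vector of gene symbols.
#' @examples
#' high_priority_genes(summarize_by_gene(load_curated()))
#' @export
high_priority_genes <- function(summaries) {
  if (!nrow(summaries)) return(character())
  sort(summaries$gene[summaries$high_priority])
}

#' Genes whose best classification is uncertain significance
#'
#' The genes published as pathogenic whose reevaluation under the
#' five-tier framework leaves no record above uncertain significance.
#'
#' @inheritParams high_priority_genes
#' @return Alphabetically ordered character vector of gene symbols.
#' @export
reclassified_to_vus <- function(summaries) {
  if (!nrow(summaries)) return(character())
  sort(summaries$gene[summaries$best_classification ==
                        "uncertain_significance"])
}

#' Write a per-gene report
#'
#' @param summaries Output of [summarize_by_gene()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_report <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
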