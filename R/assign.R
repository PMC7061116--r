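CONSEQUENCE_VOCAB <- c("missense", "nonsense", "frameshift", "inframe_indel",
                       "stoploss", "canonical_splice", "other_splice_region",
                       "synonymous", "large_deletion", "other")
NULL_CONSEQUENCES <- c("nonsense", "frameshift", "canonical_splice",
                       "large_deletion")
DENOVO_VOCAB <- c("confirmed", "unconfirmed", "no", "unknown")
SEGREGATION_VOCAB <- c("yes", "no", "unknown")
FUNCTIONAL_VOCAB <- c("supports_pathogenic", "supports_benign", "none")
INSILICO_VOCAB <- c("deleterious", "benign_pred", "conflicting", "none")

# codes that assign_codes() can emit on its own; everything else must come
# through manual_codes (it needs knowledge the annotation bundle cannot carry)
AUTO_CODES <- c("PVS1", "PS2", "PS3", "PM1", "PM2", "PM4", "PM6",
                "PP1", "PP2", "PP3", "BA1", "BS2", "BS3", "BS4", "BP4")

#' Allele-frequency thresholds for PM2 and BA1
#'
#' The rarity criterion PM2 fires for variants with population allele
#' frequency strictly under `pm2_max_af` (default 0.001, i.e. frequencies
#' "under 0.001" qualify) or absent from population databases; the
#' stand-alone benign criterion BA1 fires strictly above `ba1_min_af`
#' (default 0.005, i.e. "> 0.5%"). Both boundaries are exclusive.
#'
#' @param pm2_max_af Upper (exclusive) allele-frequency bound for PM2.
#' @param ba1_min_af Lower (exclusive) allele-frequency bound for BA1.
#' @return A named list of thresholds, validated so that
#'   `pm2_max_af < ba1_min_af`.
#' @export
acmg_thresholds <- function(pm2_max_af = 0.001, ba1_min_af = 0.005) {
  stopifnot(is.numeric(pm2_max_af), is.numeric(ba1_min_af),
            pm2_max_af >= 0, ba1_min_af <= 1)
  if (!(pm2_max_af < ba1_min_af)) {
    stop("thresholds inverted: pm2_max_af must be below ba1_min_af")
  }
  list(pm2_max_af = pm2_max_af, ba1_min_af = ba1_min_af)
}

#' Gene-level rule configuration
#'
#' PVS1 applies only in genes where loss of function is a known disease
#' mechanism, and PP2 only in genes constrained against benign missense
#' variation; both facts are gene-level knowledge supplied here. Defaults
#' are conservative (both `FALSE`), so PVS1/PP2 are withheld for
#' unconfigured genes.
#'
#' @param gene Gene symbol.
#' @param lof_mechanism Is loss of function a known disease mechanism?
#' @param missense_constrained Low rate of benign missense variation?
#' @return A named list of class `gene_rule_config`.
#' @export
gene_rule_config <- function(gene = NA_character_, lof_mechanism = FALSE,
                             missense_constrained = FALSE) {
  structure(list(gene = gene,
                 lof_mechanism = isTRUE(lof_mechanism),
                 missense_constrained = isTRUE(missense_constrained)),
            class = "gene_rule_config")
}

#' Per-variant annotation bundle
#'
#' The annotations the assignment layer consumes for one variant. Fields
#' left at their defaults mean "no information": absent allele frequency,
#' unknown de novo status and segregation, no functional study, no
#' computational verdict.
#'
#' @param allele_frequency Population allele frequency in `[0,1]`, or `NA`
#'   when the variant is absent from population databases.
#' @param consequence Consequence class; one of `r
#'   paste0('\x60"', CONSEQUENCE_VOCAB, '"\x60', collapse = ", ")`.
#' @param de_novo `"confirmed"` (parentage confirmed), `"unconfirmed"`,
#'   `"no"` or `"unknown"`.
#' @param segregates_in_family `"yes"`, `"no"` or `"unknown"`.
#' @param functional_study `"supports_pathogenic"`, `"supports_benign"` or
#'   `"none"`.
#' @param in_silico_verdict `"deleterious"`, `"benign_pred"`,
#'   `"conflicting"` or `"none"`.
#' @param hotspot_or_domain Variant in a mutational hot spot or known
#'   functional domain?
#' @param observed_healthy_recessive Observed in a healthy adult for a
#'   recessive condition?
#' @param manual_codes Character vector of curator-asserted evidence codes
#'   (for criteria needing external knowledge, e.g. PS1, PM3, PP5).
#' @return A named list of class `annotation_bundle`.
#' @export
annotation_bundle <- function(allele_frequency = NA_real_,
                              consequence = "other",
                              de_novo = "unknown",
                              segregates_in_family = "unknown",
                              functional_study = "none",
                              in_silico_verdict = "none",
                              hotspot_or_domain = FALSE,
                              observed_healthy_recessive = FALSE,
                              manual_codes = character()) {
  if (!consequence %in% CONSEQUENCE_VOCAB) {
    stop("unknown consequence label: ", consequence)
  }
  de_novo <- match.arg(de_novo, DENOVO_VOCAB)
  segregates_in_family <- match.arg(segregates_in_family, SEGREGATION_VOCAB)
  functional_study <- match.arg(functional_study, FUNCTIONAL_VOCAB)
  in_silico_verdict <- match.arg(in_silico_verdict, INSILICO_VOCAB)
  if (!is.na(allele_frequency) &&
      (allele_frequency < 0 || allele_frequency > 1)) {
    stop("allele_frequency must lie in [0,1]")
  }
  structure(list(allele_frequency = as.numeric(allele_frequency),
                 consequence = consequence,
                 de_novo = de_novo,
                 segregates_in_family = segregates_in_family,
                 functional_study = functional_study,
                 in_silico_verdict = in_silico_verdict,
                 hotspot_or_domain = isTRUE(hotspot_or_domain),
                 observed_healthy_recessive = isTRUE(observed_healthy_recessive),
                 manual_codes = as.character(manual_codes)),
            class = "annotation_bundle")
}

#' Map an annotation bundle to an evidence profile
#'
#' The automatic assignment rules:
#' \describe{
#'   \item{PVS1}{null consequence (nonsense, frameshift, canonical splice,
#'     large deletion) in a gene with `lof_mechanism = TRUE`}
#'   \item{PS2 / PM6}{de novo with confirmed / unconfirmed parentage}
#'   \item{PS3 / BS3}{functional study supporting a pathogenic / benign
#'     effect}
#'   \item{PM1}{hot spot or known functional domain}
#'   \item{PM2}{allele frequency absent or strictly under `pm2_max_af`}
#'   \item{PM4}{in-frame indel or stop-loss consequence}
#'   \item{PP1 / BS4}{segregation present / absent}
#'   \item{PP2}{missense in a missense-constrained gene}
#'   \item{PP3 / BP4}{computational verdict deleterious / benign}
#'   \item{BA1}{allele frequency strictly above `ba1_min_af`}
#'   \item{BS2}{observed in a healthy adult for a recessive condition}
#' }
#' Curator-asserted `manual_codes` are unioned in and never revoked;
#' a manual code that the automatic rules also produce is counted once.
#'
#' @param annotations An [annotation_bundle()] (or a list with its fields).
#' @param gene_config A [gene_rule_config()].
#' @param thresholds An [acmg_thresholds()] list.
#' @return An [evidence_profile()].
#' @examples
#' assign_codes(annotation_bundle(allele_frequency = 5e-4,
#'                                consequence = "missense"))
#' @export
assign_codes <- function(annotations,
                         gene_config = gene_rule_config(),
                         thresholds = acmg_thresholds()) {
  if (!inherits(annotations, "annotation_bundle")) {
    annotations <- do.call(annotation_bundle, annotations)
  }
  thresholds <- do.call(acmg_thresholds,
                        thresholds[c("pm2_max_af", "ba1_min_af")])
  a <- annotations
  af <- a$allele_frequency
  codes <- character()
  add <- function(codes, code, when) if (isTRUE(when)) c(codes, code) else codes

  codes <- add(codes, "PVS1", a$consequence %in% NULL_CONSEQUENCES &&
                 gene_config$lof_mechanism)
  codes <- add(codes, "PS2", a$de_novo == "confirmed")
  codes <- add(codes, "PM6", a$de_novo == "unconfirmed")
  codes <- add(codes, "PS3", a$functional_study == "supports_pathogenic")
  codes <- add(codes, "BS3", a$functional_study == "supports_benign")
  codes <- add(codes, "PM1", a$hotspot_or_domain)
  codes <- add(codes, "PM2", is.na(af) || af < thresholds$pm2_max_af)
  codes <- add(codes, "PM4", a$consequence %in% c("inframe_indel", "stoploss"))
  codes <- add(codes, "PP1", a$segregates_in_family == "yes")
  codes <- add(codes, "BS4", a$segregates_in_family == "no")
  codes <- add(codes, "PP2", a$consequence == "missense" &&
                 gene_config$missense_constrained)
  codes <- add(codes, "PP3", a$in_silico_verdict == "deleterious")
  codes <- add(codes, "BP4", a$in_silico_verdict == "benign_pred")
  codes <- add(codes, "BA1", !is.na(af) && af > thresholds$ba1_min_af)
  codes <- add(codes, "BS2", a$observed_healthy_recessive)

  evidence_profile(union(codes, a$manual_codes))
}

#' Classify one annotated variant end to end
#'
#' Composes [assign_codes()] and [classify_profile()]: the annotation
#' bundle is mapped to an evidence profile, which the combination engine
#' classifies.
#'
#' @inheritParams assign_codes
#' @inheritParams classify_profile
#' @return A `classification` (see [classify_profile()]).
#' @examples
#' classify_variant(annotation_bundle(consequence = "frameshift",
#'                                    functional_study = "supports_pathogenic"),
#'                  gene_config = gene_rule_config(lof_mechanism = TRUE))
#' @export
classify_variant <- function(annotations,
                             gene_config = gene_rule_config(),
                             thresholds = acmg_thresholds(),
                             dialect = rule_dialect()) {
  classify_profile(assign_codes(annotations, gene_config, thresholds), dialect)
}

#' Classify every row of an annotated variant table
#'
#' Table-level driver for user cohorts: each row is converted to an
#' [annotation_bundle()], assigned evidence codes, and classified. Rows
#' with a missing gene or a vocabulary violation are skipped with a
#' message and reported in the `n_skipped` attribute.
#'
#' @param tbl Data frame in the annotated-variant dialect (see
#'   [read_annotated_tsv()]); must carry a `gene` column.
#' @param gene_configs Optional data frame with columns `gene`,
#'   `lof_mechanism`, `missense_constrained` giving per-gene rule
#'   configuration; unlisted genes use the defaults.
#' @inheritParams classify_variant
#' @return The input table with appended columns `codes`
#'   (`+`-separated evidence codes), `matched_rules`, `tier` and
#'   `via_contradiction`; attribute `n_skipped` counts dropped rows.
#' @export
classify_cohort <- function(tbl, gene_configs = NULL,
                            thresholds = acmg_thresholds(),
                            dialect = rule_dialect()) {
  dialect <- rule_dialect(dialect)
  keep <- logical(nrow(tbl))
  codes <- matched <- tier <- character(nrow(tbl))
  contr <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, ]
    res <- tryCatch({
      if (is.null(row$gene) || is.na(row$gene) || !nzchar(row$gene)) {
        stop("missing gene symbol")
      }
      gc <- lookup_gene_config(row$gene, gene_configs)
      prof <- assign_codes(row_to_bundle(row), gc, thresholds)
      cls <- classify_profile(prof, dialect)
      list(prof = prof, cls = cls)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping row ", i, ": ", conditionMessage(res))
      next
    }
    keep[i] <- TRUE
    codes[i] <- paste(res$prof$codes, collapse = "+")
    matched[i] <- paste(res$cls$matched_rules, collapse = "+")
    tier[i] <- res$cls$tier
    contr[i] <- res$cls$via_contradiction
  }
  out <- tbl[keep, , drop = FALSE]
  out$codes <- codes[keep]
  out$matched_rules <- matched[keep]
  out$tier <- tier[keep]
  out$via_contradiction <- contr[keep]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!keep)
  out
}

lookup_gene_config <- function(gene, gene_configs) {
  if (is.null(gene_configs)) return(gene_rule_config(gene))
  hit <- which(gene_configs$gene == gene)
  if (!length(hit)) return(gene_rule_config(gene))
  gene_rule_config(gene,
                   lof_mechanism = isTRUE(gene_configs$lof_mechanism[hit[1]]),
                   missense_constrained =
                     isTRUE(gene_configs$missense_constrained[hit[1]]))
}

# one data-frame row (annotated-variant dialect) -> annotation_bundle
row_to_bundle <- function(row) {
  val <- function(field, default) {
    v <- row[[field]]
    if (is.null(v) || length(v) == 0 || is.na(v)) default else v
  }
  manual <- val("manual_codes", "")
  manual <- if (nzchar(manual)) strsplit(manual, "[,;+]")[[1]] else character()
  annotation_bundle(
    allele_frequency = as.numeric(val("allele_frequency", NA_real_)),
    consequence = val("consequence", "other"),
    de_novo = val("de_novo", "unknown"),
    segregates_in_family = val("segregates_in_family", "unknown"),
    functional_study = val("functional_study", "none"),
    in_silico_verdict = val("in_silico_verdict", "none"),
    hotspot_or_domain = as.logical(val("hotspot_or_domain", FALSE)),
    observed_healthy_recessive =
      as.logical(val("observed_healthy_recessive", FALSE)),
    manual_codes = trimws(manual)
  )
}

#' Splice-site consequence from an HGVS coding description
#'
#' Classifies an intronic HGVS string as `"canonical_splice"` when the
#' offset from the exon boundary is +/-1 or +/-2 (the splice donor/acceptor
#' dinucleotide), `"other_splice_region"` otherwise. Descriptions without a
#' parseable intronic offset (e.g. legacy IVS notation) are treated as
#' `"other_splice_region"`.
#'
#' @param hgvs Character vector of coding HGVS descriptions
#'   (e.g. `"c.1737+1G>T"`, `"c.357-2A>G"`).
#' @return Character vector of consequence labels.
#' @examples
#' splice_consequence(c("c.1737+1G>T", "IVS9-3C>G"))
#' @export
splice_consequence <- function(hgvs) {
  offset <- suppressWarnings(
    as.integer(sub("^c\\.-?[0-9*]+([+-][0-9]+).*$", "\\1", hgvs))
  )
  ifelse(!is.na(offset) & abs(offset) <= 2L,
         "canonical_splice", "other_splice_region")
}
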