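#' @importFrom stats setNames
NULL

# Category order used everywhere a count vector appears.
ACMG_CATEGORIES <- c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")

# Maximum number of distinct codes per category (1 PVS, 4 PS, 6 PM, 5 PP,
# 1 BA, 4 BS, 7 BP).
ACMG_CATEGORY_MAX <- c(PVS = 1L, PS = 4L, PM = 6L, PP = 5L, BA = 1L,
                       BS = 4L, BP = 7L)

ACMG_STRENGTH <- c(PVS = "very_strong_pathogenic",
                   PS  = "strong_pathogenic",
                   PM  = "moderate_pathogenic",
                   PP  = "supporting_pathogenic",
                   BA  = "stand_alone_benign",
                   BS  = "strong_benign",
                   BP  = "supporting_benign")

ACMG_DESCRIPTIONS <- c(
  PVS1 = "Null variant (nonsense, frameshift, canonical splice, large deletion) in a gene where loss of function is a known disease mechanism",
  PS1  = "Same amino acid change as an established pathogenic variant via a different nucleotide change",
  PS2  = "De novo, with maternity and paternity confirmed, in a patient with no family history",
  PS3  = "Well-established functional studies show a damaging effect",
  PS4  = "Variant prevalence in affected individuals significantly exceeds controls",
  PM1  = "Located in a mutational hot spot or well-characterized functional domain",
  PM2  = "Absent from (or at extremely low frequency in) large population studies",
  PM3  = "For recessive disorders, detected in trans with a pathogenic variant",
  PM4  = "Protein length change from in-frame indel in a non-repeat region or stop-loss",
  PM5  = "Novel missense change at a residue where a different pathogenic missense change is known",
  PM6  = "Assumed de novo, without confirmation of maternity and paternity",
  PP1  = "Cosegregation with disease in multiple affected family members",
  PP2  = "Missense variant in a gene with a low rate of benign missense variation where missense is a common mechanism",
  PP3  = "Multiple lines of computational evidence support a deleterious effect",
  PP4  = "Phenotype highly specific for a disease with a single genetic etiology",
  PP5  = "Reputable source reports the variant as pathogenic",
  BA1  = "Allele frequency above 0.5% in population databases (stand-alone)",
  BS1  = "Allele frequency greater than expected for the disorder",
  BS2  = "Observed in a healthy adult for a recessive (homozygous) condition",
  BS3  = "Well-established functional studies show no damaging effect",
  BS4  = "Lack of segregation in affected family members",
  BP1  = "Missense variant in a gene where only loss of function causes disease",
  BP2  = "Observed in trans with a pathogenic variant for a dominant disorder, or in cis with a pathogenic variant",
  BP3  = "In-frame indel in a repetitive region without known function",
  BP4  = "Multiple lines of computational evidence suggest no impact",
  BP5  = "Variant found in a case with an alternate molecular basis for disease",
  BP6  = "Reputable source reports the variant as benign",
  BP7  = "Synonymous/splice-region variant with no predicted splice impact"
)

#' Evidence-code taxonomy of the ACMG/AMP framework
#'
#' The 28 evidence codes of the 2015 ACMG/AMP sequence-variant
#' interpretation framework: one very-strong (PVS1), four strong (PS1-PS4),
#' six moderate (PM1-PM6) and five supporting (PP1-PP5) pathogenic codes,
#' plus one stand-alone (BA1), four strong (BS1-BS4) and seven supporting
#' (BP1-BP7) benign codes.
#'
#' @return A data frame with one row per code and columns `code`,
#'   `category` (the prefix, e.g. `"PM"`), `strength` (e.g.
#'   `"moderate_pathogenic"`) and `description`.
#' @examples
#' codes <- evidence_codes()
#' table(codes$category)
#' @export
evidence_codes <- function() {
  code <- names(ACMG_DESCRIPTIONS)
  category <- code_category(code)
  data.frame(
    code = code,
    category = category,
    strength = unname(ACMG_STRENGTH[category]),
    description = unname(ACMG_DESCRIPTIONS),
    stringsAsFactors = FALSE
  )
}

#' Category (prefix) and strength class of evidence codes
#'
#' The strength class of a code is a pure function of its prefix: PVS codes
#' are very-strong pathogenic, PS strong, PM moderate, PP supporting; BA is
#' stand-alone benign, BS strong benign, BP supporting benign.
#'
#' @param codes Character vector of code identifiers (e.g. `"PM2"`).
#' @return `code_category()` returns the prefix (`"PVS"`, `"PS"`, `"PM"`,
#'   `"PP"`, `"BA"`, `"BS"` or `"BP"`); `code_strength()` the strength
#'   class label.
#' @examples
#' code_category(c("PVS1", "BP7"))
#' code_strength("PM2")
#' @export
code_category <- function(codes) {
  bad <- !codes %in% names(ACMG_DESCRIPTIONS)
  if (any(bad)) {
    stop("unknown evidence code(s): ", paste(unique(codes[bad]), collapse = ", "))
  }
  sub("[0-9]+$", "", codes)
}

#' @rdname code_category
#' @export
code_strength <- function(codes) {
  unname(ACMG_STRENGTH[code_category(codes)])
}

#' Build an evidence profile from a set of codes
#'
#' An evidence profile is the set of ACMG/AMP codes asserted for one
#' variant, together with the derived per-category count vector
#' (n_PVS, n_PS, n_PM, n_PP, n_BA, n_BS, n_BP) that the combination engine
#' consumes. Duplicate codes are rejected: each criterion is asserted at
#' most once per variant.
#'
#' @param codes Character vector of evidence-code identifiers; may be empty.
#' @return An object of class `evidence_profile`: a list with elements
#'   `codes` (sorted character vector) and `counts` (named integer vector
#'   over the seven categories).
#' @examples
#' evidence_profile(c("PVS1", "PM2"))
#' @export
evidence_profile <- function(codes = character()) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) {
    stop("duplicate evidence codes in profile: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  counts <- count_codes(codes)
  structure(list(codes = sort(codes), counts = counts),
            class = "evidence_profile")
}

# Per-category counts from a code set; validates code identity.
count_codes <- function(codes) {
  cat <- if (length(codes)) code_category(codes) else character()
  counts <- setNames(integer(length(ACMG_CATEGORIES)), ACMG_CATEGORIES)
  tab <- table(factor(cat, levels = ACMG_CATEGORIES))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Validate an evidence count vector against category bounds
#'
#' @param counts Named integer vector (or coercible) over
#'   `c("PVS","PS","PM","PP","BA","BS","BP")`.
#' @return The validated integer vector, invisibly usable; errors on a
#'   malformed vector (wrong names, negative counts, or counts exceeding
#'   the number of codes in a category).
#' @keywords internal
validate_counts <- function(counts) {
  if (is.null(names(counts)) || !setequal(names(counts), ACMG_CATEGORIES)) {
    stop("count vector must be named over: ",
         paste(ACMG_CATEGORIES, collapse = ", "))
  }
  counts <- counts[ACMG_CATEGORIES]
  storage.mode(counts) <- "integer"
  if (anyNA(counts) || any(counts < 0L)) {
    stop("counts must be non-negative integers")
  }
  over <- counts > ACMG_CATEGORY_MAX
  if (any(over)) {
    stop("count bound exceeded for: ",
         paste(names(counts)[over], collapse = ", "))
  }
  counts
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat("<evidence_profile> ",
      if (length(x$codes)) paste(x$codes, collapse = " + ") else "(empty)",
      "\n", sep = "")
  nz <- x$counts[x$counts > 0L]
  if (length(nz)) {
    cat("  counts:", paste(names(nz), nz, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

as_profile <- function(x) {
  if (inherits(x, "evidence_profile")) x else evidence_profile(x)
}
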