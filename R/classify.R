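#' Classify an evidence profile into the five-tier system
#'
#' Applies the combination rules of a dialect to the per-category evidence
#' counts of a profile. The pathogenic side is evaluated as "any pathogenic
#' line, else any likely-pathogenic line"; the benign side as "any benign
#' line, else any likely-benign line". If both sides match, the pathogenic
#' and benign criteria are contradictory and the variant is reported as of
#' uncertain significance with `via_contradiction = TRUE`. If neither side
#' matches, the result is uncertain significance without contradiction.
#'
#' @param profile An [evidence_profile()], or a character vector of codes.
#' @param dialect A [rule_dialect()] or dialect name; default
#'   `"paper_verbatim"`.
#' @return An object of class `classification`: list with `tier` (one of
#'   `"pathogenic"`, `"likely_pathogenic"`, `"uncertain_significance"`,
#'   `"likely_benign"`, `"benign"`), `via_contradiction` (logical) and
#'   `matched_rules` (character vector of satisfied line ids).
#' @examples
#' classify_profile(c("PVS1", "PS3"))           # pathogenic
#' classify_profile(c("PM1", "PM2", "PP1", "PP3"))  # likely pathogenic
#' classify_profile(c("PS1", "BA1"))            # contradiction -> VUS
#' @export
classify_profile <- function(profile, dialect = rule_dialect()) {
  profile <- as_profile(profile)
  counts <- validate_counts(profile$counts)
  res <- classify_counts(matrix(counts, nrow = 1,
                                dimnames = list(NULL, names(counts))),
                         dialect)
  matched <- matched_lines(counts, rule_dialect(dialect))
  structure(list(tier = res$tier,
                 via_contradiction = res$via_contradiction,
                 matched_rules = matched$id),
            class = "classification")
}

# ids + labels of every satisfied combination line for one count vector
matched_lines <- function(counts, dialect) {
  lines <- dialect$lines
  mins <- as.matrix(lines[ACMG_CATEGORIES])
  ok <- apply(mins, 1L, function(m) all(counts[ACMG_CATEGORIES] >= m))
  lines[ok, c("id", "tier", "label")]
}

#' Vectorized tier assignment for count vectors
#'
#' The matrix form of [classify_profile()], used for exhaustive
#' enumeration: every row of `counts` is classified independently.
#'
#' @param counts Matrix or data frame with columns
#'   `PVS, PS, PM, PP, BA, BS, BP` (the `n_` count vector of a profile).
#' @param dialect A [rule_dialect()] or dialect name.
#' @param validate Check count bounds first (default `TRUE`).
#' @return A data frame with one row per input row: `tier` and
#'   `via_contradiction`.
#' @export
classify_counts <- function(counts, dialect = rule_dialect(), validate = TRUE) {
  dialect <- rule_dialect(dialect)
  counts <- as.matrix(as.data.frame(counts)[ACMG_CATEGORIES])
  storage.mode(counts) <- "integer"
  if (validate) {
    if (anyNA(counts) || any(counts < 0L)) {
      stop("counts must be non-negative integers")
    }
    over <- sweep(counts, 2L, ACMG_CATEGORY_MAX[colnames(counts)], ">")
    if (any(over)) stop("count bound exceeded in row(s): ",
                        paste(utils::head(which(rowSums(over) > 0L)),
                              collapse = ", "))
  }
  lines <- dialect$lines
  mins <- as.matrix(lines[ACMG_CATEGORIES])
  # n x L matrix: row i satisfies line l iff all category minima are met
  sat <- matrix(TRUE, nrow(counts), nrow(lines))
  for (j in seq_along(ACMG_CATEGORIES)) {
    needed <- mins[, j]
    use <- needed > 0
    if (any(use)) {
      sat[, use] <- sat[, use, drop = FALSE] &
        outer(counts[, j], needed[use], ">=")
    }
  }
  any_tier <- function(tier) {
    idx <- which(lines$tier == tier)
    if (!length(idx)) return(rep(FALSE, nrow(counts)))
    rowSums(sat[, idx, drop = FALSE]) > 0L
  }
  p  <- any_tier("pathogenic")
  lp <- any_tier("likely_pathogenic")
  b  <- any_tier("benign")
  lb <- any_tier("likely_benign")

  path_side <- p | lp
  ben_side  <- b | lb
  contradiction <- path_side & ben_side

  tier <- rep("uncertain_significance", nrow(counts))
  tier[path_side & !ben_side] <- ifelse(p[path_side & !ben_side],
                                        "pathogenic", "likely_pathogenic")
  tier[ben_side & !path_side] <- ifelse(b[ben_side & !path_side],
                                        "benign", "likely_benign")
  data.frame(tier = tier, via_contradiction = contradiction,
             stringsAsFactors = FALSE)
}

#' Enumerate all admissible evidence count vectors
#'
#' All combinations of per-category code counts within the taxonomy bounds
#' (0-1 PVS, 0-4 PS, 0-6 PM, 0-5 PP, 0-1 BA, 0-4 BS, 0-7 BP): 2 x 5 x 7 x
#' 6 x 2 x 5 x 8 = 33,600 vectors, each exactly once. Used to test the
#' combination engine exhaustively against an independent oracle.
#'
#' @return A data frame with 33,600 rows and columns
#'   `PVS, PS, PM, PP, BA, BS, BP`.
#' @examples
#' nrow(enumerate_count_vectors())  # 33600
#' @export
enumerate_count_vectors <- function() {
  grid <- expand.grid(PVS = 0:1, PS = 0:4, PM = 0:6, PP = 0:5,
                      BA = 0:1, BS = 0:4, BP = 0:7,
                      KEEP.OUT.ATTRS = FALSE)
  grid[ACMG_CATEGORIES]
}

#' Explain a classification line by line
#'
#' Produces a deterministic text report listing every combination line of
#' the dialect, whether the profile satisfies it, and the resulting tier
#' (flagging the contradiction pathway when both sides match).
#'
#' @inheritParams classify_profile
#' @return Character vector of report lines (classed `acmg_explanation`,
#'   printed one per line), invisibly also carrying the `classification`
#'   as an attribute.
#' @examples
#' explain_profile(c("PVS1", "PM2"))
#' @export
explain_profile <- function(profile, dialect = rule_dialect()) {
  profile <- as_profile(profile)
  dialect <- rule_dialect(dialect)
  cls <- classify_profile(profile, dialect)
  lines <- dialect$lines
  hit <- lines$id %in% cls$matched_rules
  out <- c(
    sprintf("evidence profile: %s",
            if (length(profile$codes)) paste(profile$codes, collapse = " + ")
            else "(empty)"),
    sprintf("dialect: %s", dialect$name),
    sprintf("counts: %s",
            paste(names(profile$counts), profile$counts, sep = "=",
                  collapse = " ")),
    "",
    sprintf("[%s] %-17s %s", ifelse(hit, "x", " "), lines$tier, lines$label),
    "",
    sprintf("matched lines: %d", sum(hit)),
    if (cls$via_contradiction)
      "pathogenic and benign criteria are contradictory",
    sprintf("tier: %s", cls$tier)
  )
  structure(out, class = "acmg_explanation", classification = cls)
}

#' @export
print.acmg_explanation <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification> ", x$tier,
      if (x$via_contradiction) " (contradictory evidence)", "\n", sep = "")
  if (length(x$matched_rules)) {
    cat("  matched rules:", paste(x$matched_rules, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ordering of the five tiers
#'
#' Ranks tiers on the pathogenicity scale benign (1) < likely_benign (2) <
#' uncertain_significance (3) < likely_pathogenic (4) < pathogenic (5).
#'
#' @param tier Character vector of canonical tier labels.
#' @return Integer ranks.
#' @export
tier_rank <- function(tier) {
  order <- c(benign = 1L, likely_benign = 2L, uncertain_significance = 3L,
             likely_pathogenic = 4L, pathogenic = 5L)
  bad <- !tier %in% names(order)
  if (any(bad)) stop("unknown tier label(s): ",
                     paste(unique(tier[bad]), collapse = ", "))
  unname(order[tier])
}
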