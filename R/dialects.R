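# A combination line is a conjunction of per-category minimum counts.
# Lines are stored one per row with a stable id, target tier, human-readable
# label, and the seven minima. Within a tier the lines are disjunctive, so
# their order never changes the resulting tier (first match is only used to
# head the explain() output).

dialect_line <- function(id, tier, label, PVS = 0, PS = 0, PM = 0, PP = 0,
                         BA = 0, BS = 0, BP = 0) {
  data.frame(id = id, tier = tier, label = label,
             PVS = PVS, PS = PS, PM = PM, PP = PP, BA = BA, BS = BS, BP = BP,
             stringsAsFactors = FALSE)
}

# Lines as printed in the source classification table: note the
# likely-pathogenic ">=3 (PP1-PP5)" line and the absence of the
# "1 PVS1 + 1 PM + 1 PP" pathogenic line.
paper_verbatim_lines <- function() {
  rbind(
    dialect_line("P1", "pathogenic", "1 PVS1 + >=1 (PS1-PS4)", PVS = 1, PS = 1),
    dialect_line("P2", "pathogenic", "1 PVS1 + >=2 (PM1-PM6)", PVS = 1, PM = 2),
    dialect_line("P3", "pathogenic", "1 PVS1 + 1 (PS1-PS4) + 1 (PM1-PM6)",
                 PVS = 1, PS = 1, PM = 1),
    dialect_line("P4", "pathogenic", "1 PVS1 + >=2 (PP1-PP5)", PVS = 1, PP = 2),
    dialect_line("P5", "pathogenic", ">=2 (PS1-PS4)", PS = 2),
    dialect_line("P6", "pathogenic", "1 (PS1-PS4) + >=3 (PM1-PM6)", PS = 1, PM = 3),
    dialect_line("P7", "pathogenic", "1 (PS1-PS4) + 2 (PM1-PM6) + >=2 (PP1-PP5)",
                 PS = 1, PM = 2, PP = 2),
    dialect_line("P8", "pathogenic", "1 (PS1-PS4) + 1 (PM1-PM6) + >=4 (PP1-PP5)",
                 PS = 1, PM = 1, PP = 4),
    dialect_line("LP1", "likely_pathogenic", "1 PVS1 + 1 (PM1-PM6)", PVS = 1, PM = 1),
    dialect_line("LP2", "likely_pathogenic", "1 (PS1-PS4) + 1-2 (PM1-PM6)",
                 PS = 1, PM = 1),
    dialect_line("LP3", "likely_pathogenic", "1 (PS1-PS4) + >=2 (PP1-PP5)",
                 PS = 1, PP = 2),
    dialect_line("LP4", "likely_pathogenic", ">=3 (PP1-PP5)", PP = 3),
    dialect_line("LP5", "likely_pathogenic", "2 (PM1-PM6) + >=2 (PP1-PP5)",
                 PM = 2, PP = 2),
    dialect_line("LP6", "likely_pathogenic", "1 (PM1-PM6) + >=4 (PP1-PP5)",
                 PM = 1, PP = 4),
    dialect_line("B1", "benign", "1 BA1", BA = 1),
    dialect_line("B2", "benign", ">=2 (BS1-BS4)", BS = 2),
    dialect_line("LB1", "likely_benign", "1 (BS1-BS4) + 1 (BP1-BP7)", BS = 1, BP = 1),
    dialect_line("LB2", "likely_benign", ">=2 (BP1-BP7)", BP = 2)
  )
}

# The 2015 guideline variant: the supporting-only likely-pathogenic line is
# replaced by ">=3 moderate" and the standard "PVS1 + 1 moderate +
# 1 supporting" pathogenic line is present.
acmg2015_lines <- function() {
  lines <- paper_verbatim_lines()
  lines[lines$id == "LP4", c("label", "PM", "PP")] <-
    list(">=3 (PM1-PM6)", 3, 0)
  rbind(
    lines[1:8, ],
    dialect_line("P9", "pathogenic", "1 PVS1 + 1 (PM1-PM6) + 1 (PP1-PP5)",
                 PVS = 1, PM = 1, PP = 1),
    lines[9:nrow(lines), ]
  )
}

#' Combination-rule dialects of the five-tier classifier
#'
#' A rule dialect is the ordered list of combination lines that map an
#' evidence count vector to a tier. Two built-in dialects are provided:
#'
#' * `"paper_verbatim"` (default): the combination table exactly as printed
#'   in the bradycardia reclassification study, including a
#'   likely-pathogenic line satisfied by three supporting pathogenic codes
#'   alone, and without the standard "PVS1 + 1 moderate + 1 supporting"
#'   pathogenic line.
#' * `"acmg2015"`: the 2015 ACMG/AMP guideline combinations, which replace
#'   that supporting-only line with ">=3 moderate" and include the
#'   "PVS1 + 1 moderate + 1 supporting" pathogenic line.
#'
#' Each line is a conjunction of per-category minimum counts; lines within
#' a tier are disjunctive.
#'
#' @param name `"paper_verbatim"` or `"acmg2015"`, or a path to a
#'   YAML/JSON dialect file written by [write_dialect()].
#' @return An object of class `rule_dialect`: a list with `name` and
#'   `lines` (a data frame of combination lines).
#' @seealso [classify_profile()], [write_dialect()]
#' @examples
#' rule_dialect("paper_verbatim")
#' @export
rule_dialect <- function(name = c("paper_verbatim", "acmg2015")) {
  if (inherits(name, "rule_dialect")) return(name)
  if (length(name) == 1 && file.exists(name)) return(read_dialect(name))
  name <- match.arg(name)
  lines <- switch(name,
                  paper_verbatim = paper_verbatim_lines(),
                  acmg2015 = acmg2015_lines())
  structure(list(name = name, lines = lines), class = "rule_dialect")
}

#' @export
print.rule_dialect <- function(x, ...) {
  cat("<rule_dialect> ", x$name, " (", nrow(x$lines), " combination lines)\n",
      sep = "")
  for (tier in unique(x$lines$tier)) {
    cat("  ", tier, ":\n", sep = "")
    for (lab in x$lines$label[x$lines$tier == tier]) {
      cat("    - ", lab, "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialize and read rule dialects
#'
#' Dialects are stored as a YAML or JSON document listing each combination
#' line as a count-threshold predicate, so that a modified rule set can be
#' audited and loaded by name.
#'
#' @param dialect A `rule_dialect`.
#' @param path Output (or input) file; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return `write_dialect()` returns `path` invisibly; `read_dialect()`
#'   returns a `rule_dialect`.
#' @export
write_dialect <- function(dialect, path) {
  dialect <- rule_dialect(dialect)
  doc <- list(
    name = dialect$name,
    lines = lapply(seq_len(nrow(dialect$lines)), function(i) {
      row <- dialect$lines[i, ]
      mins <- unlist(row[ACMG_CATEGORIES])
      c(list(id = row$id, tier = row$tier, label = row$label),
        as.list(mins[mins > 0]))
    })
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_dialect
#' @export
read_dialect <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  lines <- do.call(rbind, lapply(doc$lines, function(ln) {
    mins <- setNames(rep(0, length(ACMG_CATEGORIES)), ACMG_CATEGORIES)
    for (cat in intersect(names(ln), ACMG_CATEGORIES)) {
      mins[cat] <- as.numeric(ln[[cat]])
    }
    do.call(dialect_line,
            c(list(id = ln$id, tier = ln$tier, label = ln$label),
              as.list(mins)))
  }))
  structure(list(name = doc$name, lines = lines), class = "rule_dialect")
}
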