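#' Specification of a synthetic variant cohort
#'
#' Describes a cohort with a known answer: `n_variants` annotated variants
#' spread over `n_genes` genes, of which `planted_pathogenic_genes` carry
#' variants whose annotations are drawn so that evidence assignment plus
#' the combination engine yields at least likely pathogenic (a null
#' variant in a loss-of-function-mechanism gene, absent from population
#' databases). Non-planted variants draw benign or uninformative
#' annotations; with probability `noise_rate` a non-planted variant
#' instead receives pathogenic-leaning evidence (confirmed de novo plus a
#' supporting functional study), so recovery degrades as noise rises.
#'
#' Rare allele frequencies are drawn log-uniform on `[1e-6, 5e-4]` and
#' common ones uniform on `[0.01, 0.5]`, straddling both classification
#' thresholds with margin.
#'
#' @param n_genes Number of genes (symbols `G01`, `G02`, ...).
#' @param n_variants Number of variants; must be at least the number of
#'   planted genes (each planted gene receives at least one variant).
#' @param planted_pathogenic_genes Character vector of planted symbols, or
#'   a single integer k to plant the first k genes.
#' @param p_functional Probability a planted-gene variant carries a
#'   supporting functional study.
#' @param p_denovo Probability a planted-gene variant is confirmed de novo.
#' @param p_common Probability a non-planted, non-noise variant is a
#'   common (benign-tier) rather than rare (uncertain-tier) variant.
#' @param noise_rate Probability a non-planted variant receives
#'   pathogenic-leaning evidence.
#' @param seed Integer seed; identical spec and seed give identical
#'   cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 20, n_variants = 100,
                        planted_pathogenic_genes = character(),
                        p_functional = 0.5, p_denovo = 0.3, p_common = 0.5,
                        noise_rate = 0, seed = 1) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  if (is.numeric(planted_pathogenic_genes) &&
      length(planted_pathogenic_genes) == 1) {
    stopifnot(planted_pathogenic_genes <= n_genes)
    planted_pathogenic_genes <- genes[seq_len(planted_pathogenic_genes)]
  }
  probs <- c(p_functional, p_denovo, p_common, noise_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (!all(planted_pathogenic_genes %in% genes)) {
    stop("planted genes must be a subset of the generated genes")
  }
  if (length(planted_pathogenic_genes) > 0 && n_variants < 1) {
    stop("infeasible spec: planted genes but zero variants")
  }
  if (n_variants < length(planted_pathogenic_genes)) {
    stop("infeasible spec: fewer variants than planted genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_variants = as.integer(n_variants),
                 genes = genes,
                 planted_pathogenic_genes = planted_pathogenic_genes,
                 p_functional = p_functional, p_denovo = p_denovo,
                 p_common = p_common, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Read or write a cohort spec as YAML/JSON
#'
#' @param spec A [cohort_spec()].
#' @param path File path; format chosen by extension.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  doc <- unclass(spec)
  doc$genes <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  doc$planted_pathogenic_genes <-
    as.character(unlist(doc$planted_pathogenic_genes))
  do.call(cohort_spec, doc)
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Generate a synthetic annotated cohort
#'
#' Draws an annotated variant table in the same dialect the classification
#' pipeline reads (see [read_annotated_tsv()]), with ground-truth columns
#' `planted` and `true_tier` (the tier implied by the drawn annotations at
#' generation time). The gene configuration that makes planted genes
#' loss-of-function-mechanism genes is attached as the `gene_configs`
#' attribute (also available via [cohort_gene_configs()]).
#'
#' All randomness is scoped to the spec's seed: the global random state is
#' left untouched and identical specs give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `variant_id`, `gene`, the
#'   annotation-bundle fields, `planted` and `true_tier`.
#' @examples
#' cohort <- gen_cohort(cohort_spec(n_genes = 5, n_variants = 30,
#'                                  planted_pathogenic_genes = 2, seed = 1))
#' table(cohort$planted, cohort$true_tier)
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, gen_cohort_impl(spec))
}

gen_cohort_impl <- function(spec) {
  n <- spec$n_variants
  planted_genes <- spec$planted_pathogenic_genes
  # every planted gene gets at least one variant; the rest are uniform
  gene <- character(n)
  k <- length(planted_genes)
  if (k) gene[seq_len(k)] <- planted_genes
  if (n > k) gene[(k + 1):n] <- sample(spec$genes, n - k, replace = TRUE)
  planted <- gene %in% planted_genes

  af <- rep(NA_real_, n)
  consequence <- character(n)
  de_novo <- rep("unknown", n)
  segregates <- rep("unknown", n)
  functional <- rep("none", n)
  insilico <- rep("none", n)

  for (i in seq_len(n)) {
    if (planted[i]) {
      # null variant, absent from population databases -> PVS1 + PM2,
      # which alone already reaches likely pathogenic
      consequence[i] <- sample(c("frameshift", "nonsense",
                                 "canonical_splice"), 1)
      af[i] <- NA_real_
      if (stats::runif(1) < spec$p_functional) {
        functional[i] <- "supports_pathogenic"
      }
      if (stats::runif(1) < spec$p_denovo) de_novo[i] <- "confirmed"
      if (stats::runif(1) < 0.7) segregates[i] <- "yes"
      if (stats::runif(1) < 0.8) insilico[i] <- "deleterious"
    } else if (stats::runif(1) < spec$noise_rate) {
      # pathogenic-leaning noise: two strong codes force a false call
      consequence[i] <- "missense"
      af[i] <- runif_log(1, 1e-6, 5e-4)
      functional[i] <- "supports_pathogenic"
      de_novo[i] <- "confirmed"
      insilico[i] <- "deleterious"
    } else if (stats::runif(1) < spec$p_common) {
      # common variant: BA1 dominates
      consequence[i] <- sample(c("synonymous", "missense"), 1)
      af[i] <- stats::runif(1, 0.01, 0.5)
      if (stats::runif(1) < 0.5) insilico[i] <- "benign_pred"
    } else {
      # rare variant with no other evidence: PM2 only -> uncertain
      consequence[i] <- "missense"
      af[i] <- runif_log(1, 1e-6, 5e-4)
    }
  }

  cohort <- data.frame(
    variant_id = sprintf("V%04d", seq_len(n)),
    gene = gene,
    allele_frequency = af,
    consequence = consequence,
    de_novo = de_novo,
    segregates_in_family = segregates,
    functional_study = functional,
    in_silico_verdict = insilico,
    hotspot_or_domain = FALSE,
    observed_healthy_recessive = FALSE,
    manual_codes = "",
    planted = planted,
    stringsAsFactors = FALSE
  )
  configs <- cohort_gene_configs_for(spec)
  classified <- classify_cohort(cohort, gene_configs = configs)
  cohort$true_tier <- classified$tier
  attr(cohort, "gene_configs") <- configs
  attr(cohort, "spec") <- spec
  cohort
}

cohort_gene_configs_for <- function(spec) {
  data.frame(gene = spec$genes,
             lof_mechanism = spec$genes %in% spec$planted_pathogenic_genes,
             missense_constrained = FALSE,
             stringsAsFactors = FALSE)
}

#' Gene configuration attached to a generated cohort
#'
#' @param cohort Output of [gen_cohort()].
#' @return Data frame with columns `gene`, `lof_mechanism`,
#'   `missense_constrained`.
#' @export
cohort_gene_configs <- function(cohort) {
  cfg <- attr(cohort, "gene_configs")
  if (is.null(cfg)) stop("cohort carries no gene_configs attribute")
  cfg
}

#' Random evidence profiles for fuzzing the engine
#'
#' Draws `n` profiles by independent Bernoulli inclusion of each of the 28
#' evidence codes. Because each code can appear at most once, every drawn
#' profile satisfies the count bounds by construction.
#'
#' @param n Number of profiles.
#' @param code_probs Single inclusion probability, or a named vector of
#'   per-code probabilities (unnamed codes get 0).
#' @param seed Integer seed.
#' @return List of [evidence_profile()] objects.
#' @examples
#' profs <- gen_profiles(5, code_probs = 0.15, seed = 7)
#' @export
gen_profiles <- function(n, code_probs = 0.15, seed = 1) {
  all_codes <- evidence_codes()$code
  if (length(code_probs) == 1 && is.null(names(code_probs))) {
    p <- setNames(rep(code_probs, length(all_codes)), all_codes)
  } else {
    p <- setNames(rep(0, length(all_codes)), all_codes)
    bad <- setdiff(names(code_probs), all_codes)
    if (length(bad)) stop("unknown code(s) in code_probs: ",
                          paste(bad, collapse = ", "))
    p[names(code_probs)] <- code_probs
  }
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]")
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    evidence_profile(all_codes[stats::runif(length(all_codes)) < p])
  }))
}

#' Planted-gene recovery of the full pipeline
#'
#' Runs evidence assignment, classification and gene prioritization on a
#' generated cohort and compares the recovered high-priority genes with
#' the planted truth.
#'
#' @param cohort Output of [gen_cohort()].
#' @param dialect Rule dialect for classification.
#' @return List with `recovered` (gene symbols), `planted`, `sensitivity`
#'   and `specificity` (proportions over planted and non-planted genes
#'   that received at least one variant).
#' @export
evaluate_recovery <- function(cohort, dialect = rule_dialect()) {
  classified <- classify_cohort(cohort,
                                gene_configs = cohort_gene_configs(cohort),
                                dialect = dialect)
  summaries <- summarize_by_gene(classified, verdict_source = "computed")
  recovered <- high_priority_genes(summaries)
  spec <- attr(cohort, "spec")
  planted <- spec$planted_pathogenic_genes
  present <- unique(cohort$gene)
  neg <- setdiff(present, planted)
  sens <- if (length(planted)) {
    length(intersect(recovered, planted)) / length(planted)
  } else NA_real_
  spec_ <- if (length(neg)) {
    1 - length(intersect(recovered, neg)) / length(neg)
  } else NA_real_
  list(recovered = recovered, planted = sort(planted),
       sensitivity = sens, specificity = spec_)
}
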