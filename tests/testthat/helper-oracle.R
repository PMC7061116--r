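# Independent brute-force oracle for the five-tier combination rules.
# Each printed combination line is tested literally against one count
# vector; deliberately written as a scalar if-chain with no shared code
# with the package's engine.
oracle_classify <- function(v, dialect = "paper_verbatim") {
  PVS <- v[["PVS"]]; PS <- v[["PS"]]; PM <- v[["PM"]]; PP <- v[["PP"]]
  BA <- v[["BA"]]; BS <- v[["BS"]]; BP <- v[["BP"]]

  pathogenic <-
    (PVS >= 1 && PS >= 1) ||                 # 1 PVS1 + >=1 (PS1-PS4)
    (PVS >= 1 && PM >= 2) ||                 # 1 PVS1 + >=2 (PM1-PM6)
    (PVS >= 1 && PS >= 1 && PM >= 1) ||      # 1 PVS1 + 1 PS + 1 PM
    (PVS >= 1 && PP >= 2) ||                 # 1 PVS1 + >=2 (PP1-PP5)
    (PS >= 2) ||                             # >=2 (PS1-PS4)
    (PS >= 1 && PM >= 3) ||                  # 1 PS + >=3 PM
    (PS >= 1 && PM >= 2 && PP >= 2) ||       # 1 PS + 2 PM + >=2 PP
    (PS >= 1 && PM >= 1 && PP >= 4)          # 1 PS + 1 PM + >=4 PP
  if (dialect == "acmg2015") {
    pathogenic <- pathogenic ||
      (PVS >= 1 && PM >= 1 && PP >= 1)       # 1 PVS1 + 1 PM + 1 PP
  }

  likely_pathogenic <-
    (PVS >= 1 && PM >= 1) ||                 # 1 PVS1 + 1 (PM1-PM6)
    (PS >= 1 && PM >= 1) ||                  # 1 PS + 1-2 PM
    (PS >= 1 && PP >= 2) ||                  # 1 PS + >=2 PP
    (if (dialect == "acmg2015") PM >= 3 else PP >= 3) ||
    (PM >= 2 && PP >= 2) ||                  # 2 PM + >=2 PP
    (PM >= 1 && PP >= 4)                     # 1 PM + >=4 PP

  benign <- (BA >= 1) || (BS >= 2)           # 1 BA1 | >=2 (BS1-BS4)
  likely_benign <- (BS >= 1 && BP >= 1) ||   # 1 BS + 1 BP
    (BP >= 2)                                # >=2 (BP1-BP7)

  path_side <- pathogenic || likely_pathogenic
  ben_side <- benign || likely_benign
  if (path_side && ben_side) {
    return(list(tier = "uncertain_significance", via_contradiction = TRUE))
  }
  tier <- if (pathogenic) "pathogenic"
  else if (likely_pathogenic) "likely_pathogenic"
  else if (benign) "benign"
  else if (likely_benign) "likely_benign"
  else "uncertain_significance"
  list(tier = tier, via_contradiction = FALSE)
}

oracle_classify_all <- function(grid, dialect = "paper_verbatim") {
  tiers <- character(nrow(grid))
  contr <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- oracle_classify(as.list(grid[i, ]), dialect)
    tiers[i] <- res$tier
    contr[i] <- res$via_contradiction
  }
  data.frame(tier = tiers, via_contradiction = contr,
             stringsAsFactors = FALSE)
}
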