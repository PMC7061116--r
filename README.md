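# bradyvar

Five-tier ACMG/AMP sequence-variant classification for the genetics of
familial bradycardia.

Pedigree studies of inherited bradycardia — sick sinus syndrome (SSS),
atrioventricular block (AVB), progressive cardiac conduction disease
(PCCD) — have reported many candidate variants, but most were published
without a full evidence evaluation. `bradyvar` implements the ACMG/AMP
variant-interpretation framework as a tested pipeline and applies it to a
curated dataset of 99 literature-reported variants in 34 genes, reproducing
the prioritization of 13 high-priority conduction-disease genes. It is
aimed at clinical-genetics analysts and methodologists who want a rule
engine whose behaviour is checked exhaustively rather than by example.

## The classification model

Evidence for one variant is a set of codes from the 28-criterion ACMG/AMP
taxonomy: pathogenic evidence PVS1 (very strong), PS1–PS4 (strong),
PM1–PM6 (moderate), PP1–PP5 (supporting); benign evidence BA1
(stand-alone), BS1–BS4 (strong), BP1–BP7 (supporting). Classification
depends only on the per-category count vector
(n<sub>PVS</sub>, n<sub>PS</sub>, n<sub>PM</sub>, n<sub>PP</sub>,
n<sub>BA</sub>, n<sub>BS</sub>, n<sub>BP</sub>). Combination lines are
conjunctions of per-category minima, e.g.

* pathogenic: `1 PVS1 + ≥1 PS`, `≥2 PS`, `1 PS + ≥3 PM`, …
* likely pathogenic: `1 PVS1 + 1 PM`, `1 PS + ≥2 PP`, `2 PM + ≥2 PP`, …
* benign: `1 BA1`, `≥2 BS`; likely benign: `1 BS + 1 BP`, `≥2 BP`

The pathogenic and benign sides are evaluated independently; if both sides
match, the evidence is contradictory and the variant defaults to uncertain
significance (VUS). Two rule dialects are built in: `paper_verbatim` (the
combination table exactly as printed in the bradycardia reclassification
study, the default) and `acmg2015` (the 2015 guideline combinations); see
the methods vignette for where they differ.

The assignment layer maps per-variant annotations (population allele
frequency, consequence class, de novo status, segregation, functional
studies, computational predictions) to codes, with the study's thresholds:
PM2 for allele frequency strictly under 0.001 (or absent), BA1 strictly
above 0.005.

## Worked example

```r
library(bradyvar)

# a frameshift variant, absent from gnomAD, in a gene where loss of
# function is the known disease mechanism, with a supporting functional
# study
bundle <- annotation_bundle(consequence = "frameshift",
                            functional_study = "supports_pathogenic")
profile <- assign_codes(bundle, gene_rule_config(lof_mechanism = TRUE))
profile
#> <evidence_profile> PM2 + PS3 + PVS1
#>   counts: PVS=1 PS=1 PM=1

classify_profile(profile)
#> <classification> pathogenic
#>   matched rules: P1, P3, LP1, LP2
```

PVS1 + PS3 satisfies the pathogenic line `1 PVS1 + ≥1 (PS1-PS4)`; the
additional PM2 is consistent. Reproducing the curated analysis:

```r
cmd_reproduce()
#> Familial bradycardia reclassification: headline numbers
#>   included articles            88   (published: 88)
#>   variant records              99   (published: 99)
#>   distinct genes               34   (published: 34)
#>   high-priority genes          13   (published: 13)
#>     ABCC9, ACTN2, CACNA1C, DES, HCN4, KCNH2, KCNQ1, LAMP2, LMNA, MECP2,
#>     NPPA, SCN5A, TRPM4
```

The numbers mean: 1015 articles screened, 927 excluded, 88 analyzed; 99
variant records transcribed from the study's tables across 34 genes; 13
genes carry at least one variant classified pathogenic or likely
pathogenic and form the recommended evaluation panel for familial
conduction disease.

## Command line

A dispatcher ships in `exec/bradyvar`:

```sh
bradyvar classify  --input cohort.tsv --output-dir out/   # per-variant + per-gene reports
bradyvar reproduce                                        # headline numbers above
bradyvar simulate  --spec spec.yaml --output-dir sim/     # synthetic cohort with planted genes
bradyvar explain   --codes PVS1+PM2                       # line-by-line rule report
```

`classify` accepts the annotated TSV dialect (columns `gene`,
`allele_frequency`, `consequence`, `de_novo`, `segregates_in_family`,
`functional_study`, `in_silico_verdict`, `hotspot_or_domain`,
`observed_healthy_recessive`, `manual_codes`) or a VCF whose INFO field
carries `GENE`, `AF`, `CSQ_CLASS`, `DENOVO`, `SEGREGATION`, `FUNC`,
`INSILICO`.

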