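# splicedev

Tools for studying how alternative splicing changes across development and
across species, from junction-level read counts. The package is aimed at
comparative transcriptomics: given per-segment inclusion/exclusion counts
from bulk RNA-seq time courses in several species and organs, it
quantifies exon inclusion, finds developmentally dynamic splicing,
classifies its temporal shape, matches exons across species, screens
intronic flanks for regulatory hexamers and dates the evolutionary origin
of cassette exons. A synthetic data generator with known ground truth
makes the whole pipeline testable without any external data.

## What it computes

**Segments and PSI.** Genes are split at their splice sites into
*segments*; a segment included in some transcripts and excluded from
others is alternative, and its bounding splice-site kinds give the event
class (cassette exon CE, alternative acceptor AA, alternative donor AD,
retained intron RI). Inclusion is quantified as percent spliced-in,
correcting for the number of read placements supporting each read class:

    PSI = [i/(ls+lr-1)] / [i/(ls+lr-1) + e/(lr-1)]

with `i`/`e` inclusion/exclusion read counts and `ls`/`lr` the segment and
read lengths; PSI is undefined below 10 supporting reads.

**devAS.** Per species and organ, counts are modelled with a
quasi-binomial GLM, `cbind(i, e) ~ a + a² + a³`, where `a` is log days
from conception (postnatal ages offset by species gestation). Each
polynomial term gets a quasi-likelihood F-test; p-values are BH-adjusted.
A cubic spline of PSI on `a` (df = 4) gives the developmental amplitude
dPSI; segments with adjusted p < 0.05 and dPSI > 0.2 are developmentally
dynamic (devAS), and the signed step mass of the fitted trajectory
classifies them as up, down, up–down or down–up.

**Cross-species layers.** Exons lifted between genomes are grouped into
1:1 orthologs via intersect:union filtering (≥ 0.6) and graph components;
intronic 200-nt flanks are screened for all 4,096 hexamers with one-sided
Fisher tests, combined across species with the Irwin–Hall distribution
and annotated against PWM motifs; presence/absence of exons between
orthologous border exons, and cassette/constitutive status
(alternification), are dated on the species tree by single-event
parsimony.

## Worked example

```r
library(splicedev)

# a three-exon gene whose middle exon is skipped in one isoform
gm <- gene_model("g1", "chr1", "+",
                 list(t123 = cbind(c(0, 200, 400), c(100, 300, 500)),
                      t13  = cbind(c(0, 400), c(100, 500))))
subset(segment_gene(gm), status == "alternative")
#>   segment_id gene_id chrom start end strand start_kind end_kind      status as_class length
#> 3      g1.s3      g1  chr1   200 300      +   acceptor    donor alternative       CE    100

compute_psi(i = 20, e = 10, ls = 100, lr = 100)
#>       value defined
#> 1 0.4987406    TRUE

# developmental test on synthetic counts along a log-age axis
a   <- seq(log(10), log(1000), length.out = 15)
psi <- simulate_trajectory("up", 0.8, a)       # true amplitude 0.8
cnt <- simulate_counts(psi, depth = 200, rho = 0.05, seed = 7)
fit_devas_glm(cnt$i, cnt$e, a)$p
#>            a           a2           a3
#> 2.361077e-07 3.931038e-01 5.807810e-01

traj <- fit_psi_spline(compute_psi(cnt$i, cnt$e, 100, 100)$value, a)
c(dpsi = round(traj$dpsi, 3), pattern = classify_pattern(traj)$pattern)
#>    dpsi pattern
#> "0.867"    "up"

# date a presence pattern on the seven-species tree
pres <- c(human = TRUE, macaque = TRUE, mouse = TRUE, rat = TRUE,
          rabbit = TRUE, opossum = FALSE, chicken = FALSE)
parsimony_age(pres)[c("event", "age_class")]
#> $event
#> [1] "gain"
#> $age_class
#> [1] "eutherian"
```

The linear term carries the monotone trend (p = 2.4e-7; the sequential
quadratic and cubic tests add nothing, as expected for a logistic rise);
the fitted dPSI (0.867) recovers the planted amplitude 0.8 plus sampling
noise, and the trajectory is classified "up".

End to end on a synthetic seven-species, seven-organ dataset:

```r
run_pipeline(pipeline_config(seed = 1), "out/")   # ~1 min, deterministic
```

writes per-stage TSV tables (segments, counts, PSI matrix, devAS tests,
trajectories, ortholog groups, hexamer enrichment, evolutionary events,
MDS coordinates) plus `config.json` and `manifest.json`. The same verbs
are available from the command line via `inst/exec/splicedev`.

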