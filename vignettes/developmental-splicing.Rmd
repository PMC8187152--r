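---
title: "Methods: developmental alternative splicing across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental alternative splicing across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`splicedev`, the choices made where the design was genuinely open, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## Segments and PSI

A gene is split at every distinct splice site of its transcripts into
*segments*. A segment is alternative when at least one transcript
includes it (the segment lies inside an exon) and at least one excludes
it (an intron spans it). The bounding splice-site kinds, taken in
transcription orientation, give the event class: acceptor→donor is a
cassette exon (CE), donor→acceptor a retained intron (RI),
acceptor→acceptor and donor→donor alternative acceptor/donor (AA/AD)
segments. Coordinates are 0-based half-open internally so that length is
`end - start`; GTF input is converted at the boundary, and minus-strand
kinds are resolved by swapping the genomic edge roles.

Two open points were settled as follows. Terminal segments (before the
first or after the last splice site) have no splice-site kind on one
side; they are reported constitutive with class `NA`, and a segment that
transcript voting marks alternative but that touches a gene end is
demoted the same way — alternative first/last exons are a different
phenomenon (alternative promoters/polyadenylation) and are not analysed.
If a genomic position serves as donor in one transcript and acceptor in
another, the kind is ambiguous and the segment keeps class `NA`.

Inclusion is quantified as

$$\mathrm{PSI} = \frac{i/(l_s+l_r-1)}{i/(l_s+l_r-1) + e/(l_r-1)},$$

which weights the inclusion count $i$ and exclusion count $e$ by the
number of distinct read start positions that can support each ($l_s$,
$l_r$ = segment and read length). PSI is undefined below 10 supporting
reads. Note a consequence sometimes missed: at $l_s = l_r - 1$ the
inclusion normalizer is *twice* the exclusion normalizer, so equal counts
give PSI $= i/(i+2e) = 1/3$, not $1/2$; the formula only reduces to
$i/(i+e)$ as $l_s \to 0$. Inclusion counting requires a ≥1-nt overlap of
a uniquely mapped read with the segment; exclusion requires a junction
whose intron fully spans it. Paired mates are counted per alignment
record (one mate, one observation), recorded in output metadata.

## The devAS test

Per species and organ, counts follow a quasi-binomial GLM with logit
link,

$$(i, e) \sim a + a^2 + a^3, \qquad a = \log(\text{days from conception}),$$

postnatal ages being offset by the species gestation time (280, 165, 20,
21, 30, 15, 21 days for human, macaque, mouse, rat, rabbit, opossum,
chicken). The log base is irrelevant: the polynomial span is invariant
under linear rescaling of $a$, which the tests assert numerically.
Segments enter the test only when coverage $i+e>9$ holds in at least 60%
of the organ's samples and at least four samples have defined PSI in
$[0.1, 0.9]$; samples with zero coverage are dropped from the fit, and at
least six covered samples are required to identify four mean parameters
plus a dispersion.

**Term tests.** Terms are tested with sequential nested quasi-likelihood
F-tests — $a$ against the intercept model, $a^2$ against $a$, $a^3$
against $a+a^2$ — each F statistic being the quasi-deviance drop divided
by the Pearson dispersion $\hat\phi = \sum r_P^2/(n-4)$ of the full
model, referred to $F(1, n-4)$. This is what `anova.glm(test = "F")`
reports and, we argue, the only workable reading of a per-term
"quasi-likelihood ratio test" here: the raw polynomial basis is so
collinear on a log-age axis that deleting a single term from the full
model barely changes the fit even for a strong monotone trend (in a
planted-trend experiment at sequencing depth 200 with overdispersion,
single-term-deletion p-values were ≈ 0.9 where the sequential linear-term
test gave p ≈ 2×10⁻⁷). A method with near-zero power could not have
produced genome-wide devAS catalogues, so the sequential construction is
used. Under the null both constructions are calibrated, which the
acceptance suite verifies by simulation.

**Multiple testing.** All term p-values of all eligible segments within
one species–organ analysis are BH-adjusted together (the pooling scope is
not dictated by the model; one analysis unit is the most conservative
interpretable choice and is recorded in the output). A segment is devAS
when its minimum adjusted term p-value is < 0.05 *and* its developmental
amplitude dPSI is > 0.2 (both strict). A dPSI-only variant
(`call_devas_dpsi_only`, thresholds 0 or 0.5) supports analyses where
test power would confound a comparison.

## Trajectories, dPSI and patterns

PSI is regressed on a cubic B-spline basis of $a$ with four degrees of
freedom. The basis/knot layout is not dictated by "four degrees of
freedom" alone; we use one interior knot at the median age with boundary
knots at the age range, which is the quantile default, and expose the
knots as an argument. Predictions are clipped to $[0,1]$; dPSI is the
range of fitted values at the *sampled* ages (not the interpolation
grid). Fits require at least five defined PSI values over at least two
distinct ages.

For classification the fit is evaluated at 1,000 evenly spaced points on
the log-age domain — "evenly distributed age points" is interpreted on
the model's own axis. Step changes $\Delta_k$ are split into positive
mass `up` and negative mass `down`; `up_timing` and `down_timing` are
age-weighted means of each mass, the weight being the log age at each
step's right endpoint (weighting by raw days would let late postnatal
ages dominate; log age keeps the weights on the fitted axis).
`up/(up+down) < 0.3` classifies the exon as down, `> 0.7` as up;
otherwise `up_timing < down_timing` gives up–down and the reverse
down–up. Trajectories whose total step mass is below 1e-9 (numerically
flat, e.g. a constant fit) are reported as pattern `none`; they cannot be
devAS since their dPSI is 0. Telescoping (`up - down` equals the net
grid change) is asserted to 1e-10.

Two stage-level summaries complement the fits: `birth_timing` labels a
change before-birth when the earliest→newborn amplitude strictly exceeds
the newborn→last amplitude (ties fall to after-birth by the strict rule),
and `stage_change_counts` counts devAS exons whose stage-mean PSI moves
by strictly more than 0.2 between consecutive stages.

## Exon orthology

Cross-species coordinate mappings (chain liftover output) are an input,
not computed here. Exons are dropped unless, in every species, their
mapped interval reaches intersect:union ≥ 0.6 against the best-matching
native exon of that species — the reference for the filter is not fully
specified upstream, and the native-annotation reading is the one that
makes the filter meaningful for exons, so it is used and exposed as
`keep_threshold`. Edges connect surviving exons whose mapped intervals
exceed IoU 0.6 in *all* species (strict, as `edge_threshold`); the ≥ /
> asymmetry between the two steps is kept as stated and both thresholds
are configurable. Connected components with exactly one exon per species
become 1:1 ortholog groups; everything else is discarded. A naive
loop-based oracle re-derives the same grouping in the tests on random
instances.

## Motif enrichment

Analysis is restricted to cassette exons with canonical GU–AG splice
sites; 200-nt up- and downstream intronic flanks are screened for all
4,096 hexamers. The 2×2 Fisher table counts *presence/absence per flank
sequence*, not occurrences — the counting unit is ambiguous upstream, and
presence/absence is robust to flank length and tandem duplications. The
one-sided p-value is the hypergeometric tail (identical to Fisher's
one-sided test, but vectorisable across all hexamers). Per-species
p-values are combined with the Irwin–Hall CDF of their sum, computed by
the exact alternating-sum formula with the symmetry
$F_k(s) = 1 - F_k(k-s)$ used above $k/2$ for numerical stability, and
BH-adjusted across hexamers within one region × direction stratum.

Hexamer↔motif annotation uses the PWM generation probability
$p(\mathrm{hex}\mid\mathrm{motif}) = 1-\prod_o (1-p_o)$ over offsets $o$
from $1-l_m$ to 5 (that is $l_m+5$ offsets), with
$p_o = \prod_j f_{j-o}(nt_j)\,0.25^m$ for the $m$ non-overlapping
positions. Each motif annotates every hexamer whose probability is at
least half the motif's maximum. A resampling wrapper
(`resample_enrichment`) supports seed-controlled robustness checks.

## Exon gain, loss and alternification

Candidates are single exons interspaced between consecutive 1:1
orthologous border exons in a subset of species; pairs with more than one
interspaced exon in any species are excluded. Three filters apply: the
candidate (plus 4 flanking nt) must not align to the border exons or
inter-border sequence of any species lacking it; candidates observed in
several species must all align to each other; and only exons < 500 nt are
considered. Alignment is an in-repo seed-and-extend check (`seq_similar`:
exact 8-mer seeds, ungapped extension, match +1 / mismatch −2, x-drop 6,
accept at score ≥ 12) standing in for a permissive BLASTN run; the
threshold guarantees detection of any exact shared block ≥ 12 nt and is
configurable.

Events are dated by single-event parsimony on the rooted seven-species
tree: a gain on an edge predicts presence exactly in the clade below it,
a loss predicts absence there. Patterns matched by exactly one scenario
are dated; patterns matched by none, or by both a gain and a loss (the
root-split case, e.g. present in all mammals and absent in chicken), are
discarded rather than resolved by an unstated root prior. An exhaustive
enumeration oracle confirms the decision for all 126 non-constant
patterns. Alternification uses the same machinery on cassette status: an
exon is a cassette exon in a species when at least four organ–stage mean
PSI values fall strictly below 0.9; species without any defined PSI make
the record undatable and it is discarded.

## The synthetic world

The generator emulates the study design the pipeline consumes — it is a
stated world, not a tuning knob. Defaults: the seven species with their
gestation times; seven organs; seven stages per species (30/50/70/95% of
gestation, then 3/30/300 days postnatal: dense prenatal, sparse
postnatal) with two replicates; mean junction coverage 50 (Poisson);
beta-binomial overdispersion ρ = 0.05 (the implied quasi-dispersion is
≈ 1+(n−1)ρ ≈ 3.5 at coverage 50, in the range seen in real junction
data); read length 100; trajectory mixture 30% up, 30% down, 10%
up–down, 10% down–up, 20% flat with amplitudes U(0.3, 0.8) — monotone
shapes dominate, as they do in real organ development. Monotone shapes
are rescaled logistics, transient shapes rescaled Gaussian bumps, so the
sampled range equals the stated amplitude exactly.

Planted evolution scenarios draw a shared candidate-exon core for
presence species (with a couple of point mutations) and rejection-sample
absence-species border/inter-border sequences to share no 8-mer with the
core, making the birth filters noiseless by construction; root-child
clades are never planted because they are single-event ambiguous by
design. Planted motif datasets insert a hexamer into stated fractions of
target and background flanks of i.i.d. random sequence.

What a green test does *not* establish: the generator produces no read
mapping artifacts, no GC or length biases, no correlated replicates, no
paralogy or annotation error in the orthology input, and its flanks are
i.i.d. rather than real intronic sequence with composition structure.
Recovery rates on synthetic data are therefore upper bounds on real-data
performance.

One generator-adjacent arithmetic note: at coverage depth exactly 500 a
0.05 PSI error is only 2.3 binomial standard deviations, so "99% of
samples within 0.05" is unattainable there; the property holds from
depth ≈ 900 and is tested at depth 1000.

## Numerical choices and degenerate inputs

* `compute_psi` guards the 0/0 case at $i=0$ (PSI 0) and is exact
  elsewhere; undefined entries are `NA`, never 0.
* GLM non-convergence or inestimable dispersion yields `NA` p-values
  flagged `converged = FALSE`; iteration is capped at 100.
* Negative eigenvalues in classical MDS (possible for 1−r distances) are
  truncated at zero.
* Odds ratios are sample cross-product ratios; degenerate 2×2 margins
  report `NA` with p = 1. Perfect co-occurrence yields `Inf` as the
  sentinel.
* Confidence intervals are Clopper–Pearson from exact beta quantiles
  ("binomial-based" is ambiguous; the exact interval is the conservative
  choice and Wilson can be substituted upstream if needed).
* Pattern classification treats total step mass ≤ 1e-9 as flat to avoid
  classifying floating-point noise on constant fits.

## Limitations

* No replicate correlation or random effects in the GLM; replicates are
  treated as independent samples, as in the source analysis.
* The devAS F-tests are sequential, so the reported per-term p-values
  are order-dependent (linear before quadratic before cubic); the
  "at least one term" significance call is the intended consumer.
* `seq_similar` is not a full local aligner: gapped homology below the
  seed length, or diverged homology without an exact shared 8-mer, is
  missed — conservative for filter 1, anti-conservative for filter 2.
* The pipeline's statistical power at the default synthetic depth
  (coverage 50, n = 14 per organ) is moderate; with the sequential
  tests ≈ 80–90% of planted dynamic exons are recovered as devAS, and
  flat exons are called at ≈ the nominal false-positive rate.
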