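---
title: "Methods: models, generators and numerical choices in trem2quant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and numerical choices in trem2quant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trem2quant)
```

trem2quant re-implements the bespoke quantitative recipes of a multi-modal
mouse genotype study — field-potential feature extraction, first-order
interstitial-fluid clearance kinetics, histological morphometry,
internal-standard targeted proteomics, post-count RNA-seq analysis, and a
sample-size-driven statistical decision rule — together with synthetic-data
generators that plant known ground truth for every modality. This vignette
explains each model, the parameters that matter, what the generators do and
do not emulate, and the numerical decisions taken where the underlying
conventions are unstated.

## Field potentials

An evoked CA1 field trace contains, in order: a biphasic stimulus artifact,
a brief presynaptic fiber volley, and the fEPSP — a downward deflection
whose initial steepness indexes synaptic strength.

**The slope estimator.** The conventional measure is the slope over the
*first 1 ms of the descending domain*, the segment running from the local
maximum preceding the fEPSP trough down to the trough. Whether that slope
is a two-point difference or a regression is rarely stated; we use the
least-squares slope of all samples in the 1 ms window, which is equivalent
on noise-free data and markedly more stable against sample noise. The
window is located as the 1 ms window with the most negative least-squares
slope among windows ending at or before the trough. For the
difference-of-exponentials waveforms generated here (and for any waveform
whose descent decelerates monotonically) the steepest window is the one
anchored at the local maximum, so the two definitions coincide; the
steepest-window search is simply the noise-robust way of finding it.
Descent onset for validation is found on a 0.3 ms boxcar-smoothed copy of
the trace as the last pre-trough sample within 5% of the pre-trough
maximum; a descent shorter than 1 ms is an error, and a flat search window
is a typed "no response" error. The artifact is never modeled, only
excluded: the fEPSP search window (default 2–12 ms after the stimulus)
starts past it, and the fiber-volley window (default 0.5–2 ms) is
configurable because electrode geometry moves it in real recordings.

**Derived quantities.** The I/O curve is the least-squares line of |slope|
against fiber-volley amplitude. Test-stimulus selection returns the
smallest level whose amplitude falls within 50–60% of the maximum, or the
level closest to 55% (flagged) when none does. PPF is the ratio of second
to first |slope| at inter-pulse intervals 20, 40, …, 400 ms. LTP profiles
average |slope| per minute (3 sweeps/min at the 20 s stimulation interval,
minutes anchored at the theta-burst marker), normalize to the baseline-
minute grand mean — baseline minutes therefore average to exactly 100% —
and summarize the final five post-tetanus minutes. Slopes are stored
signed; every ratio and curve uses magnitudes, matching how these
quantities are conventionally plotted. The theta-burst tetanus itself is an
event marker only; nothing inside the tetanus is analyzed.

**The generator.** `gen_fepsp_sweep()` renders the synaptic component as a
difference of exponentials, `g(t) = exp(-t/τ_d) − exp(-t/τ_r)` with τ_r =
0.8 ms, τ_d = 4 ms (peak, and hence descent duration, at ~1.6 ms — longer
than the 1 ms analysis window). The kernel is scaled so that the
least-squares slope over the first 1 ms of descent, measured on a 1 µs
grid, equals the planted slope; on the default 0.05 ms recording grid the
analyzer recovers it to well within 2%. The fiber-volley triangle is
renormalized on the grid so its sampled peak equals the planted amplitude
exactly. Session generators plant slope sequences (a potentiation factor
after the TBS marker, a facilitation curve across PPF intervals) with
multiplicative per-sweep noise. Real recordings add artifact ringing,
drifting baselines and slow rundown, none of which are emulated — passing
recovery tests shows estimator correctness, not robustness to those
pathologies.

## Clearance kinetics

After a production inhibitor at t = 0, interstitial-fluid amyloid-β follows
first-order elimination. `fit_elimination()` regresses log10(concentration)
on time over the post-dose fractions and converts the slope *a* by
*Ke* = −*a*·ln 10 and T½ = ln 2/*Ke*. The classic pharmacokinetic shorthand
prints the rounded constants (*Ke* = −2.3 *a*, T½ = 0.693/*Ke*);
`paper_constants = TRUE` reproduces that arithmetic literally, and the
internal identity T½ × *Ke* = ln 2 (or 0.693) holds to 1e−12 under either
convention. The t = 0 fraction is excluded by default (the dose takes
effect during its collection; `include_t0` overrides). Fits are per-animal,
and group comparisons normalize per-animal half-lives to the reference
group's mean before dispatching through the decision rule — the alternative
(pooling fractions across animals) would hide between-animal variance.
Hourly fractions with a 10 h baseline and 4 post-dose hours give the usual
14-fraction series. The generator's noise is multiplicative log-normal with
stated CV and unit mean, keeping concentrations positive for the semi-log
fit; probe recovery, dead-volume lag and two-compartment kinetics are out
of scope.

## Histological morphometry

All geometry is reported in physical µm (pixel centers at (i − 0.5)·pixel
size, 0-based indices, origin top-left); objects are 8-connected components
of above-threshold pixels; the "diameter" of an irregular object is its
equivalent circular diameter 2·√(area/π). A unified per-stain threshold is
applied across a batch, as is standard; an Otsu-style pooled-histogram
helper is deliberately not the default because study thresholds are usually
fixed by eye once.

Plaque analysis keeps components with equivalent diameter strictly above
8 µm and reports counts, density per mm² of ROI (so density × ROI area
reproduces the count exactly), and mean size. Microglial somata are
particles inside a 3–15 µm equivalent-diameter gate at a threshold that
isolates the bright cell bodies from the dimmer processes.

**Skeletons.** Each cell is thinned to a medial-axis skeleton with a
Zhang–Suen-style iteration whose neighbor-count condition is tightened from
B ≥ 2 to B ≥ 3: the classic B = 2 rule progressively unravels oblique
stroke tips while wide regions elsewhere keep the iteration alive (the
Guo–Hall alternative was rejected because it deletes 2×2 blocks outright
and can disconnect somata). The skeleton is then treated as a graph:
8-neighbor edges weighted 1 or √2 pixels, with a diagonal edge dropped
whenever its two pixels share an orthogonal skeleton neighbor, so clean
paths have degree 2. Junctions are nodes of degree ≥ 3, clustered by
adjacency and merged across connector segments shorter than 5 px (thinning
splits an n-way crossing into nearby 3-way nodes); dead-end spurs of ≤ 4 px
hanging off a junction are pruned. Branches are the components left after
junction removal; branch length sums Euclidean chords of 4-pixel stride
along each ordered path — removing the staircase overestimate that
unit/√2 step sums suffer on oblique segments — plus the step joining each
branch to its junction. On rendered test cells this recovers planted branch
counts exactly and total lengths to within ~4%; residual error comes from
tip rounding (half a stroke width) and junction geometry.

Plaque-centered neighborhoods count somata whose centroid lies within 30 µm
of a plaque centroid — the automated surrogate for manual counting — and
report the plaque–microglia colocalized area inside the disk per counted
cell. Colocalization of two channels is the area above both thresholds,
with the fraction defined as intersection over union of the positive areas;
when thresholds are not supplied, a Costes-style scan walks the threshold
down channel A's range (channel B coupled through the A–B regression) and
stops at the highest threshold where the below-threshold pixels are
statistically uncorrelated (|r| ≤ 1.96/√n). A scan is used rather than
bisection because below the structure the correlation hovers around zero
and is not monotone.

The scene generator renders anti-aliased disks and thick polylines with
optional Poisson + Gaussian noise and records truth in µm. It does not
emulate microscope optics, uneven illumination, out-of-focus light or
stain bleed-through; morphometry accuracy on real images therefore depends
on acquisition quality in ways these tests cannot certify. Planted skeleton
truth is analytic only for cells whose arms are angularly well separated
(arms merging near the soma shorten the true medial axis below the planted
polyline sum), which the test fixtures enforce.

## Targeted proteomics and small assays

With a known spike of stable-isotope-labeled internal standard, the native
amount is `native_area / sil_area × spike_fmol` (default spike 5 fmol).
Peak areas are accepted as inputs: chromatogram integration and transition
selection happen upstream in dedicated software and are out of scope.
Per-sample summaries total soluble and full-length TREM2 across alleles and
form s/fl ratios globally and per allele (in heterozygotes); a zero
full-length denominator with measured soluble signal warns, while an absent
species pair is silently undefined. qPCR relative expression is 2^−ΔCT;
the C/N Ct ratio divides the C-terminal by the N-terminal Ct per sample and
normalizes to the reference group. All "normalized to WT" operations divide
by the arithmetic mean of the reference group (median was the alternative;
mean matches the usual reading of such normalizations), making the
reference group's mean exactly 1 and every such measure scale-free.

## RNA-seq after counting

Samples are dropped when their gene-count percentage falls below 50% or
their strandness score leaves [0.7, 1] (a score near 0.5 means a failed
strand-specific library); each exclusion carries a reason string. Genes
need ≥ 10 counts in ≥ 4 samples ("at least" is the boundary reading; both
cutoffs are arguments). TMM factors come from edgeR's calcNormFactors with
30%/5% trims, and the tests cross-check them against an independent
re-derivation of the published formula.

**The DE test.** The quasi-likelihood machinery used by the established
pipelines is approximated by a deliberately simple gene-wise test:
normalized counts (effective library sizes = library size × TMM factor),
method-of-moments dispersion from pooled within-group variability
(φ = (v − μ)/μ², floored at 0), log-scale shrinkage halfway toward a lowess
mean-dispersion trend, and a Wald statistic on the log2 ratio of
prior-augmented group means (prior count 2) with delta-method standard
errors referred to a t distribution with n − 2 degrees of freedom. The t
reference, rather than the normal, is what keeps the test calibrated at
n = 5/group, where moment dispersions are noisy. This stand-in is validated
by what it is used for here: null p-values are uniform (KS), null DEG
counts are near zero, and planted log2 fold-changes of 2 are recovered
within 0.2 — no claim of equivalence with the published packages is made,
and users analyzing real data should prefer those packages' inference.
DEGs require FDR < 0.05 (step-up Benjamini–Hochberg) and |log2FC| > 0.25,
strict inequalities; note 2^0.25 ≈ 1.19, consistent with the "1.2-fold"
rounding such thresholds are usually quoted with. Clustering standardizes
each feature to zero mean and unit variance before Euclidean distances with
average linkage — exactly the "standardized Euclidean" metric — and
expression is residualized against sex, strandness and exonic rate by
per-gene least squares before network construction.

**Co-expression modules.** The adjacency is signed-hybrid: cor^β for
positive correlations, zero otherwise, with β = 12 from the scale-free
criterion. Topological-overlap dissimilarity feeds an average-linkage tree.
Instead of the dynamic hybrid tree cut, a static cut is chosen from ~40
candidate heights to maximize total intramodular adjacency enrichment
(Σ size × (mean intra-adjacency − background)) subject to the minimum
module size of 40; candidate modules whose eigengene explains less than 30%
of member variance are dissolved — random 40-gene sets explain ~15–20% at
these sample sizes, so this guard is what keeps pure-noise matrices
module-free while planted modules (eigengene R² ≈ 50%+) pass. Modules whose
eigengenes correlate above 0.6 merge iteratively. The eigengene is the
first principal component of the scaled member profiles, unit-norm, sign
fixed so the average member correlation with it is positive; module
membership (MM) is the gene–eigengene correlation with a t-test p value,
and hubs are the ten members with smallest MM p. Genotype association codes
WT = 0, Hom = 1 and reports both the ME–trait correlation and a rank-sum
comparison of ME between genotypes.

**Preservation.** Zsummary for a reference module in test data averages two
permutation Z scores: density (mean intramodular adjacency in the test
data) and connectivity (Spearman correlation between the members'
intramodular connectivity in reference and test), each standardized against
random same-size gene sets drawn from the test data. This is a two-statistic
simplification of the published multi-statistic composite; the conventional
thresholds (> 2 moderate, > 10 strong preservation) are retained, and under
the null Zsummary behaves as a standard normal, so single null draws exceed
2 about 2% of the time — null assertions in the tests are therefore made at
the ≥ 90%-of-seeds level. Modules with fewer than three genes overlapping
the test universe are flagged undefined.

The count generator plants negative-binomial counts with log-normal
gene-wise dispersions, DE genes as mean shifts, and a module as a single
latent factor: f_j mixes the standardized group label with noise
(`module_trait_r2` controls the split) and member genes receive a log2-scale
shift of loading × f_j × 0.5. The 0.5 scale is the generator's definition
of one loading unit, chosen once so that a loading of 1.5 yields
within-module correlations around 0.6–0.7 — the regime real co-expression
modules occupy — against the NB sampling noise of typical expression
levels. It does not emulate GC/length biases, batch structure, or outlier
samples.

## The statistical decision rule

`choose_test()` reproduces the study-style dispatch: paired designs use the
matched-pairs signed-rank test; group sizes above 7 use rank tests
(Kruskal–Wallis with *uncorrected* Dunn pairwise z tests for 3+ groups —
uncorrected is the documented convention, Bonferroni is available — or the
rank-sum test for 2); sizes ≤ 7 use the unpaired t test, Welch-corrected
when an F-test rejects equal variances at α = 0.05 (the α is an assumption,
exposed as an argument). Small-sample signed-rank p values (n ≤ 12) are
enumerated exactly over all 2ⁿ sign patterns of the observed absolute
ranks, which stays valid under ties; larger samples use the normal
approximation with tie correction. Ties elsewhere use average ranks with
the standard variance correction. I/O-curve slopes are compared by one-way
ANCOVA — the F test of the group × x interaction in the two-line model —
with perfectly collinear degenerate inputs returning F = 0, p = 1 rather
than numerical noise. All tests hold their 5% size within [0.035, 0.065]
in 2000-replicate null calibrations at n = 10/group.

## Problem sizes and reproducibility

Every generator takes an explicit seed and restores the caller's RNG state,
so identical (seed, parameters) give byte-identical outputs; the demo
cohort writes bit-identical files on re-run. The test suite sizes its
simulations to what the checks need rather than to the study's scale:
100–200 seeds for slope/Ke/fmol recovery, 50 random scenes for counting, 30
planted cells for skeletons, 20 seeds × 300 genes × 20 samples for module
recovery and preservation (50–100 permutations), and 2000 null replicates
per calibration. `make_demo_cohort()` defaults to a shortened 5 + 10 min
LTP session purely to keep the demo light; the generators' own defaults are
the conventional 20 + 60 min design, 14 dialysate fractions, and a 5 fmol
spike.

## Known limitations

- The ephys module analyzes uniform-grid field traces only; vendor binary
  formats, spike sorting and whole-cell analyses are out of scope.
- The DE test is a calibrated approximation, not a replacement for the
  established count-model packages on real data.
- Image analysis is 2D; z-stacks must be projected upstream, and the
  colocalization threshold search assumes uncorrelated backgrounds.
- The module pipeline's static tree cut can split weakly attached members
  off a planted module (recovery is ~70–100% per seed, median ≥ 80%); the
  dynamic hybrid cut would likely recover more at the cost of determinism
  of this simple implementation.
- Normalization "to WT" uses the reference-group arithmetic mean throughout;
  per-protein vs wet-weight unit conventions for brain-tissue amounts vary
  between laboratories and are left to the caller via `total_protein`.
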