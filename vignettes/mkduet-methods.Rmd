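---
title: "Methods: deconvolving a concealed male-killing Wolbachia and mapping its suppressor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolving a concealed male-killing Wolbachia and mapping its suppressor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkduet)
library(dplyr)
```

mkduet implements the computational core of a detection problem that arises
when a *Wolbachia* strain causing male killing (MK) co-occurs, in the same
host individuals, with a second strain causing cytoplasmic incompatibility
(CI), and the MK phenotype is further masked by a dominant nuclear
suppressor in the host. None of the usual signatures — skewed sex ratios,
reduced egg hatch, strain-specific PCR — is individually decisive in such a
system, so the package combines four lines of inference: read-depth
deconvolution of the double infection, strain assignment of candidate loci,
sweep mapping of the suppressor, and a generative inheritance model. A
synthetic-data module generates inputs with the statistical structure each
analysis assumes, so the whole pipeline is testable end to end without
sequencing data.

## Two-strain deconvolution from read depth

When short reads from a doubly infected host are aligned to the assembly of
one strain (the "reference" strain), regions shared by both strains are
covered by reads from both, while regions private to the reference strain
draw reads only from it. With per-base coverage modelled as Poisson — the
classical uniform-coverage expectation, a sufficient summary once alignment
is done — the normalized depth (window mean divided by genome-wide mean) of
a private region estimates the reference strain's titer fraction $f$: at
$f = 0.7$, private windows sit near 0.7 while the shared backbone sits near
1. A copy-number change predicts different arithmetic: a $k \to k-1$ loss
leaves $k$ paired reference regions each at $(k-1)/k$ normalized depth
(0.5, 0.67, 0.75 for $k = 2, 3, 4$).

`windowed_normalized_depth()` uses 1,000 bp windows stepped by 500 bp from
position 1, a display cap of 5, and a genome mean computed from raw
per-base depth over all bases (trailing bases contribute to the mean but
form no partial window). Circularity of the reference is ignored for
windowing; end effects are negligible at megabase scale.

`segment_regions()` merges runs of at least 10 consecutive windows whose
capped depth falls in a band — (0.35, 0.90) for depressed, (1.15, Inf) for
elevated — tolerating at most 2 out-of-band interruptions per run. These
thresholds are tuned so that 50–100 kb regions at ~0.7 depth are always
recovered while isolated noisy windows (a few kb) are not called.

`classify_regions()` applies ordered rules. A depressed region is a
`cnv_loss` only if its depth is within `tol = 0.06` of a small-integer
ratio $(k-1)/k$ *and* the number of regions sharing that depth level is a
positive multiple of $k$ — each loss event leaves $k$ paired copies, so
counts come in multiples of $k$. Otherwise, regions sharing a common
depressed level inside the band are `strain_private`; independent evidence
of duplicated single-copy genes in the mixed assembly strengthens (and is
recorded in) the rationale string. This rule set reproduces the key
qualitative argument: two regions at 0.7 cannot be a 2→1 loss (wrong
level) nor a 3→2 loss (wrong count), leaving differential titer as the
parsimonious reading. Note the intrinsic confound: a strain at 50% titer
with exactly two private regions is indistinguishable from a 2→1 loss by
depth alone, and the rules deliberately prefer the copy-number reading
there.

`estimate_titer()` reports $\hat f$ as the mean raw normalized depth of
private member windows *divided by the mean over background windows*
(windows in no segmented region). The private regions themselves depress
the genome-wide mean, so the raw normalized private depth on a 1 Mb genome
with 150 kb private sequence is ~0.73 when the true titer is 0.70; the
ratio to the rest of the genome removes this bias. The confidence interval
is a seeded percentile bootstrap (default 1,000 replicates, 95%) over
member and background windows. The analysis cannot see regions private to
the *other* strain — they are absent from the reference.

## Strain assignment of candidate loci

The loci of interest (wmk homologs implicated in male killing, cifA/B pairs
causing CI, WO prophage serine recombinases) arrive as homolog hit tables;
running the similarity search itself is out of scope because the inference
lives in the assignment logic. `assign_hits()` applies ordered evidence
rules: a reference-assembly hit with at least half its span inside a region
private to the reference strain belongs to the CI strain (marginal 1–49%
overlaps are left unresolved rather than guessed); a mixed-assembly hit
identical to a reference hit is the CI strain's copy observed again; a
mixed-assembly hit with no identical reference counterpart is unique to the
MK strain; a non-private reference hit present identically in both
assemblies is merely shared evidence. "Identical" means equal sequence
when sequences are supplied, otherwise equal identity percentage (within
`identity_tol`, default exact) over the same query span.
`predict_collapsed_copies()` encodes the fragmented-assembly argument: if
the reference holds $k$ identical copies but the mixed assembly shows
$m < k$, the assembler has likely collapsed them and the predicted true
count is $k$. `percent_identity()` is ungapped positional identity at 0.1%
resolution (pre-aligned spans required), and `pseudogene_check()`
operationalizes "pseudogenized" as a premature stop before 90% of the
expected ORF length — the threshold is ours, chosen so a terminal or
near-terminal stop does not condemn a copy — reporting the next potential
start codon downstream.

## Mapping the suppressor from backcross SNPs

The suppressor is mapped from females derived by introgressing a suppressed
(MKS) line into an unsuppressed background and genotyping backcross-2
females grouped by whether their broods were female-only (MK) or mixed-sex
(MKS). `filter_sites()` retains SNPs called in ≥95% of individuals with
overall minor allele count ≥3. `heterozygosity_stats()` computes, per group
with complete cases only (any missing genotype in the group drops the
site), $H_O$ (mean fraction heterozygous), $H_E = 2p(1-p)$ and
$F_{IS} = 1 - H_O/H_E$, per contig and genome-wide; backcrossing produces
negative genome-wide $F_{IS}$, which the synthetic panels reproduce.

`contig_contrast()` nominates candidate suppressor contigs by a
*directional* signature: $H_O$ depressed below the mean of other contigs in
the MK group (the donor haplotype was swept out) while elevated above it in
the MKS group (the donor haplotype is retained at intermediate frequency),
both by at least `min_dev = 0.10` in relative terms. The direction matters:
with few contigs, the large suppressor-contig effect contaminates the
leave-one-out background and a sign-agnostic rule false-flags clean
contigs.

`detect_sweep()` then finds, per contig, maximal runs of ≥25 consecutive
SNPs whose MK-group MAF is below 0.1, tolerating ≤2 interrupting SNPs; the
interval spans the first to last member SNP and its length is the
*exclusive* difference `end - start`, matching the arithmetic of the
published interval (4,637,826 − 3,321,074 = 1,316,752; an alternative end
coordinate, 4,677,392, reported elsewhere for the same region, is noted
here but not used). Because backcross ancestry is autocorrelated along a contig, low-MAF
runs of this size arise by chance on unlinked contigs — with 24 lines the
background donor allele count is binomial with mean 6 and drifts slowly
along the chromosome — so the run statistic alone is not specific.
`map_suppressor_region()` therefore chains filter → heterozygosity →
directional contrast → run detection restricted to nominated contigs; on
synthetic panels this recovers the true locus in 20/20 seeds with no
background-contig calls, and random phenotype relabelling abolishes all
calls.

## The inheritance model

`model_params()` holds the generative model. Both symbiont strains are
strictly maternally transmitted: the CI strain with probability
`tau_ci = 1`, the MK strain with `tau_mk = 71/73` (occasional transmission
failure). CI acts at the egg stage: a cross of a CI-carrying male to a
female lacking the CI strain hatches at `h_ci = 0.0617` against a baseline
`h_0 = 0.76`; females carrying the CI strain are fully rescued, including
MK-line females, which carry both strains. A hook for CI loss in males
(`male_ci_loss`) exists but defaults to 0 — CI is strong despite low male
titer.

Male killing acts *late*, at the larval stage: it reduces egg-to-adult
viability, not hatch. Lethality is modelled as acting through the mother's
infection — an unsuppressed (`ss`) son of an MK-carrying mother dies with
probability `mu * (1 - leak)` (`mu = 1`, `leak = 0` by default; `leak`
captures partially expressing lines) — rather than through the son's own
cytotype. Two observations force this choice: the egg-to-adult viability of
MK-mother crosses equals $v_0(1 - (1-\text{leak})\mu/2)$ exactly (half the
control at full penetrance), with no transmission term, and observed
backcross reversion frequencies match the clean Mendelian 50% expectation,
which per-son escape at $1-\tau_{mk}$ would visibly erode. Suppression by
the nuclear allele `S` is fully dominant and fully penetrant by default
(`penetrance` is exposed for sensitivity analysis). MK confers no female
fitness benefit; no compensation term exists.

`expected_cross_outcome()` returns exact expectations (hatch, egg-to-adult
as $v_0 \cdot \text{hatch}/h_0 \cdot \Pr(\text{survives MK})$, percent
female among adults, and the full offspring genotype distribution);
`simulate_backcross_panel()` and `simulate_mixed_population()` are its
stochastic vial-level counterparts. Lines are scored with
`classify_line_phenotype()`: fewer than 15 offspring → excluded; no males →
MK; ≤70% female → MKS; otherwise ambiguous (MK can be leaky). Egg numbers
per female are Poisson with mean 60 at vial scale — several days of
oviposition at roughly 18–22 eggs per day, the per-day rate seen in
single-spoon scoring — because with spoon-scale broods (~18 eggs) an
all-female brood cannot reach the 15-offspring scoring minimum at baseline
viability 0.7 and every MK line would be excluded as too small.

The screening statistics are deliberately simple: `g_test()` is the
likelihood-ratio $G = 2\sum O\ln(O/E)$ on $k-1$ degrees of freedom,
`sex_ratio_chisq()` is $(n_f-n_m)^2/(n_f+n_m)$ against 50:50, and
`relative_density()` converts replicate qPCR crossing points to
$2^{\overline{Cp}_{host}-\overline{Cp}_{target}}$ with a quality flag when
a marker's replicate SD exceeds 2.5.

## What the synthetic data do and do not emulate

`make_strain_pair()`/`simulate_mixture_depth()` generate a shared backbone
with strain-private and CNV intervals and independent per-base Poisson
coverage at titer-weighted means. Real coverage has GC bias, mapping
artefacts, duplicated-read structure and over-dispersion; passing tests
show the windowing/segmentation/titer arithmetic is correct and well
calibrated under the model's assumptions, not that those nuisances are
handled. `simulate_backcross_genotypes()` draws Poisson-count crossovers at
uniform positions (default 1 crossover per contig per meiosis — a
placeholder of the right order for a Drosophila chromosome arm, not a map
estimate for this species) with a donor line fixed for alternate alleles;
real panels carry standing variation in both lines, crossover interference,
and genotyping error beyond uniform missingness. Vial simulations assume
single mating per female per generation and synchronous discrete
generations.

## Numerical and design choices

* Coordinates are 1-based with inclusive starts throughout; interval
  specifications use exclusive ends; exported BED converts to 0-based
  half-open.
* All stochastic operations take explicit seeds, default 42; the bootstrap
  is percentile-based with 1,000 replicates.
* The window-start example in the source protocol ("1 to 1,000, 500 to
  1,500") is internally inconsistent with a uniform 500 bp step from 1; we
  use the uniform step — at megabase scale the two give indistinguishable
  region calls.
* Genome-wide mean depth is computed from raw per-base depth before
  capping.
* Titer recovery assumes the private fraction of the genome is modest
  (~10–20%); above roughly 30% the depressed genome mean pushes shared
  windows over the elevated band and segmentation degenerates.
* Multi-allelic VCF sites are rejected rather than coerced; genotype codes
  are 0/1/2 copies of the alternate allele with `NA` missingness.
* Problem sizes used in the shipped checks: a 1 Mb depth fixture at 50×,
  backcross panels of 24 + 24 lines × 1,500 SNPs × 20 seeds, and vial
  simulations of 10 replicates × 5 generations — all chosen as the smallest
  scales at which the stochastic claims are testable with comfortable
  margins.

## Known limitations

Imperfect MK transmission compounds across generations: with
`tau_mk = 71/73`, an all-MK vial population is expected to be ~90% female
by generation 5 (non-carrier matrilines produce surviving sons), so
"remains above 90%" is a knife-edge claim under these defaults — long-term
line stability data suggest per-generation transmission in culture is
closer to 1. Titer estimation identifies only regions private to the
reference strain; the co-infecting strain's private content is invisible.
The classifier cannot distinguish a 50%-titer strain with an even number of
private regions from paired copy-number losses without sequence-level
evidence. The G-test uses the asymptotic chi-squared reference, not Monte
Carlo.

## A worked mini-example

```{r example}
pair <- make_strain_pair(
  strain_pair_spec(
    backbone_length = 2e5,
    private_regions_a = data.frame(start = 120001, end = 150001),
    titer_a = 0.7
  ),
  sequences = FALSE
)
depth <- simulate_mixture_depth(pair, cov = coverage_sim_spec(50, seed = 1))
wt <- windowed_normalized_depth(depth)
regions <- classify_regions(segment_regions(wt))
estimate_titer(regions, wt, seed = 1)
```
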