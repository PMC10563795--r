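---
title: "Models and methods behind ipmnevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ipmnevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmnevo)
```

# Scope

`ipmnevo` re-implements, as a tested and reusable pipeline, the integrative
analysis of multi-region sequencing of pancreatic cyst precursor lesions
(intraductal papillary mucinous neoplasms, IPMN): somatic variant
harmonization across three callers, allelic-imbalance-gated copy-number
calling with an arm-level aneuploidy score, clonal-trajectory
classification from SNVs and from arm-level copy states, transcriptomic
subtyping by nearest-template prediction, and the cohort-level association
statistics. The upstream tools that produce the raw evidence (aligners,
callers, segmenters, the published classifier packages) are *inputs* to
this package, not parts of it. Because the matching patient data are under
controlled access, the package carries a first-class synthetic cohort
generator with complete ground truth, and every end-to-end claim in the
test suite is a recovery statement against that truth.

# Variant harmonization

Per region, calls from up to three callers (tags `M2`, `SC`, `MU`) are
merged by exact variant identity `(chrom, pos, ref, alt)` — no position
fuzzing, which is conservative and testable. With three callers a variant
must be supported by at least two; when `MU` is unavailable (no matched
normal) the union of the other two is used. When callers disagree on
depths, the merged record takes fields by the fixed precedence
M2 > MU > SC, chosen once for determinism. Variants above 1% population
allele frequency are removed (absent annotations are kept); indels need at
least 5 supporting tumor reads and 0 normal reads, both bounds inclusive.

Targeted rescue recovers single-caller calls at predetermined sites under a
relaxed confidence threshold (emission log-odds 1.5): hotspot loci in 23
established PDAC driver genes (shipped as a toy-coordinate panel,
`driver_loci.toy.tsv`; coordinates are synthetic, gene names real), and
sites already detected by the stringent rule in another non-blood region of
the same patient. Rescued calls are flagged and site-disjoint from the
consensus set. Mutation burden divides the count of exonic/splicing
variants by the captured footprint in Mb; rescued calls are excluded from
burden by default (they are reported for driver auditing), since the
relaxed threshold would otherwise bias the genome-wide rate — the flag
makes either convention auditable.

A variant is *deleterious* iff it is exonic or splicing and either at
least two of the seven predictor verdicts (sift, polyphen, HVAR, LRT,
mutationTaster, fathmm, provean) call it deleterious or ClinVar labels it
pathogenic.

# Copy-number calling and the aneuploidy score

Copy-number events are emitted only where allelic imbalance (AI) is
observed: each AI segment is intersected with the log2 copy-ratio
segmentation and classified as gain (mean log2 >= +0.2), loss (<= -0.2) or
copy-neutral LOH otherwise; the thresholds are configurable and the
defaults are stated package choices. Balanced amplifications (both alleles
gained, no AI) are undetectable under this rule — a documented limitation,
mirrored in the simulator. Events under 3 Mb are *focal* (strict
inequality). The aneuploidy score (AS) of a region counts chromosome arms
whose length is at least 75% covered by the union of CNA bases; the union
rule (rather than single-event spans) is an explicit design choice and is
tested against a per-base coverage oracle. Copy-neutral LOH counts toward
AS by default (any-direction rule, configurable); the 1q amplification flag
uses the same 75% rule restricted to gains.

# Clonal trajectories

**From SNVs.** Variant allele fractions across a patient's neoplastic
regions are converted to cancer-cell fractions, CCF = min(1, 2·VAF/purity),
under a diploid approximation; sites inside called CNAs are excluded from
clustering by default. Variants are grouped into clones by complete-linkage
hierarchical clustering, with distances computed on the arcsine-sqrt VAF
scale. This variance-stabilizing transform is the load-bearing numerical
choice: binomial sampling noise on that scale has standard deviation about
1/(2·sqrt(depth)) regardless of VAF and purity, whereas on the CCF scale
noise grows as 1/purity and regions at the low end of the purity range
(0.2) shatter true clones into spurious clusters. The default cut height
0.2 is roughly eight noise standard deviations at 400x. A clone tree is
then built by CCF containment: the truncal cluster (present everywhere)
roots the tree, each cluster attaches to the smallest already-placed
cluster that dominates it in every region (tolerance 0.1), and pigeonhole
violations of the sum rule mark the tree unresolved — except under a
saturated parent (CCF ~ 1), where children may legitimately sum above the
parent because of spatial mixing and CCF clamping.

A patient is **linear** when every clone on the path from the root to the
dominant HG clone is present in the LG region (CCF >= 0.01, a threshold
chosen so that 2–3% precursor clones count as present) or is the dominant
HG clone itself, and the dominant LG clone lies on that path; **branched**
when the dominant HG clone sits on a branch carrying no LG-present clone
below the divergence node; otherwise **unclassifiable**. Dominance ties
break by fraction, then mutation-set size, then clone id. A minor-clone
expansion is a clone at fraction in (0, 0.05] in one region and >= 0.5 in a
higher-grade region (ND = AC < LG < HG < PDAC).

**From CNAs.** Region profiles are reduced to one integer copy state per
arm (events >= 5 Mb only), an all-neutral root leaf is added, every
unrooted binary topology over at most six regions is enumerated, and
internal states are solved by unit-cost small parsimony (dynamic
programming over states 0–4, cost = absolute state change). Full
copy-number mixture deconvolution and migration-history modeling are
deliberately out of scope: at 2–5 regions the exhaustive small-parsimony
tree suffices to reproduce the linear/branched/unclassifiable taxonomy and
is fully testable against brute-force enumeration. Classification reads
off the LG/HG divergence node of each minimum-cost topology: linear when
some optimal reconstruction places no event between the divergence node and
the LG leaf, branched when both sides carry events, unclassifiable when the
LG and HG profiles carry no discriminating event or co-optimal topologies
disagree.

# Transcriptomic subtyping

Counts are normalized by median-of-ratios scale factors plus a log2
transform with pseudocount 1. This deliberately replaces count-depth
regression normalization: template correlation needs relative profiles
only, and the deterministic scheme keeps the pipeline reproducible —
a documented divergence from the upstream choice. Nearest-template
prediction computes the correlation distance from a replicate's profile
(restricted to template genes; at least 20 must be present, else the
replicate is nonclassifiable for "low gene overlap", the FFPE-dropout
failure mode) to each class template; significance comes from gene-label
permutation, p = (1 + #{permuted distance <= observed}) / (n_perm + 1).
The permuted distance is itself the minimum over class templates, so the
null accounts for best-class selection: comparing permutations against only
the winning template inflates the false-call rate roughly by the number of
classes (measured at ~17% instead of ~5% on flat profiles with three
classes). Defaults are n_perm = 1000 and Benjamini–Hochberg FDR across
replicates
(threshold 0.05, a stated default). Region labels are majority votes over
classifiable replicates; ties are nonclassifiable. The published
Moffitt/Collisson/Bailey marker lists are user-supplied TSV inputs, not
vendored (license and version drift); the packaged default is a synthetic
three-class template set (classical / basal / exocrine) used by the
simulator and tests.

# Association statistics

`exact_2x2` computes the two-sided exact p by full hypergeometric
enumeration (all tables with point probability at most the observed, with a
1e-7 relative tolerance for floating-point ties), alongside uncorrected and
Yates-corrected chi-square p-values so that a chi-square-labelled published
result can be audited: on the subtype-by-1q table (18, 16, 3, 15) the exact
test reproduces the printed p = 0.017 while the uncorrected chi-square
gives 0.011. Grade comparisons use rank-based tests (unpaired rank-sum,
paired signed-rank with per-pair deltas); parametric alternatives were
considered and rejected because AS is a small count. All-zero deltas give
p = 1 by convention.

# The synthetic cohort: what it states and what it does not

Defaults state the simulated world: 400x mean depth; 2–5 regions per
patient, always one LG and one HG lesion, extras drawn from ND/AC/PDAC;
truncal KRAS G12D and GNAS R201C; 3–5 clones with 5–12 private SNVs each;
per-region neoplastic purity uniform in [0.2, 0.9] (purities are never
reported for the real assay; this range spans laser-microdissected FFPE
practice); three callers with distinct VAF-stratified sensitivities and
false-positive rates (stipulated, since no per-caller operating points are
published for this assay); a toy genome of 4 chromosomes / 400 Mb with a
50 Mb capture space; arm-scale CNAs covering 80% of an arm plus one 2 Mb
focal event, with the 1q gain preferentially assigned to the HG lineage;
and 2–5 expression replicates per region at log-scale noise sd 1 with 10%
dropout. Linear trees place the dominant HG clone as the direct child of
the dominant LG clone with a 2% presence in LG (the minor-clone expansion
pattern); branched trees split the trunk into an LG-dominant and an
HG-dominant branch with the HG branch absent from LG. A clone's CNAs
manifest in a region's segmentation when the clone's CCF reaches 0.5
(segment-level evidence needs clonal dominance). Indels are truncal only,
so that the >= 5-read depth filter never makes exact recovery ambiguous.

The generator emulates caller behaviour at the call level, not reads:
FFPE orientation artifacts appear only as caller false positives, germline
leak-through appears as high-population-AF calls shared by all callers, and
RNA replicates are template centroids plus noise. A green recovery test
therefore establishes that the integration logic is correct under the
stated noise model — it says nothing about alignment, barcode collapsing,
segmentation quality, or real FFPE artifact spectra. Subtype and 1q status
are simulated independently, so the cohort-level subtype-by-1q association
is not a recovery target; the association machinery is validated on the
published table instead.

# Numerical conventions

Coordinates are 1-based inclusive; BED-style output converts to 0-based
half-open. Continuous simulated values are rounded to 6 decimals at
generation so that text files round-trip bit-exactly. Every stochastic
function takes a seed, and child seeds are derived from the master seed
below 2^31. Noiseless mode (`sim_config(noiseless = TRUE)`) collapses all
stochastic layers (perfect sensitivity, deterministic depths and alt
counts, zero segment/expression noise) and is the regime in which the
pipeline must recover truth exactly.

# Known limitations

Balanced amplifications are invisible to the AI-gated overlay; CCFs use a
diploid approximation with a crude ploidy adjustment inside called CNAs;
cn-LOH does not discriminate lineages in the CNA tree (state 2); the
shared-site rescue uses the patient's other regions from the same run (no
panel-of-normals construction, which is an optional blocklist input); and
parental-haplotype phasing (distinguishing maternal from paternal arm
losses) is out of scope.
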