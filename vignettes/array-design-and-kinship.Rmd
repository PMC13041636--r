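---
title: "Marker selection, curation and kinship inference for grapevine SNP arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker selection, curation and kinship inference for grapevine SNP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vitisnp` implements the computational workflow around a mid-density SNP
genotyping array for grapevine-like panels: selecting markers from
resequencing-derived candidates, curating exported genotype calls,
inferring relationships from Mendelian incompatibilities, resolving
maternal lineages with plastid haplotypes, and validating trait-predictive
markers. This vignette explains the models behind each stage, the
parameters that matter, the numerical conventions, and what the synthetic
panels used in the tests do and do not establish about real data.

## The genotype-call model

All downstream analysis operates on a dense samples × markers table of
diploid biallelic calls in {`AA`, `AB`, `BB`, `NC`} — the shape of a
genotype export from an array analysis suite. Intensity-level information
(cluster positions, size/contrast variance) is deliberately out of scope:
the call-level statuses `PASS`, `MONO` and `LOW_CALL_RATE` produced by
`marker_qc()` are proxies for the intensity-based classes an array suite
assigns, adequate because the downstream analyses consume only the
polymorphic/monomorphic and pass/fail distinctions.

## Candidate filtering and quota selection

`apply_variant_filters()` applies the standard array-design chain:
site quality below 100 (a missing QUAL counts as failing, never as zero),
indels, multiallelic records, low depth, missingness above 20%, and A/T or
C/G transversions, which strand-symmetric probe chemistry cannot read with
a single probe. Two readings of the depth rule exist because per-site
"DP < 8" is ambiguous: the default fails a site when **any** called
sample's depth is below 8 (matching per-sample DP semantics in common
variant callers, and conservative for probe design); `dp_mode = "mean"`
aggregates instead.

`flag_proximal()` flags a variant when any other polymorphism lies within
35 nt on the same chromosome — inclusive at the boundary (|Δ| ≤ 35, the
plain-language reading; the window is a parameter). The flag is computed
against *all* input polymorphisms, including ones later rejected, because
probe interference does not depend on why a neighbour was dropped. A
single sorted pass suffices: a variant has a neighbour within the window
iff its nearest neighbour is. Proximity is an annotation, not a rejection:
`select_markers()` excludes flagged candidates by default but can be told
to tolerate them.

`select_markers()` fills per-(species, chromosome) cells: 130 markers per
chromosome for the cultivated pool, 40 for each wild species, and an extra
60 on chromosomes configured as resistance-locus carriers. The bonus is
attached to chromosomes, not species, so it is implemented as a
per-chromosome pool split round-robin across the wild species present
there — this honours the printed totals without inventing per-species
figures. Within a cell, candidates are ranked by recommendation score;
tied blocks straddling the cutoff are resolved by a greedy spacing rule
(maximise the minimum distance to already-selected markers), then by
position, then identifier, so selection is byte-identical across runs.
Shortfalls (cells with fewer candidates than quota) are reported, never
silently back-filled from other cells.

## Curation

`sample_qc()` computes call rate and observed heterozygosity over
non-missing calls; the default pass threshold of 0.85 (rather than a
stricter single-species default) accommodates multi-species panels in
which species-specific probe design inflates missingness. `marker_qc()`
computes MAF from allele counts — `p = (2·n_AA + n_AB)/(2·n_called)` —
with no-calls excluded from every denominator, and assigns status with
precedence `LOW_CALL_RATE > MONO > PASS`.

`filter_mendelian()` removes markers whose Mendelian error rate exceeds 3%
across confirmed relationships. A duo error is an opposing-homozygote
configuration (`AA` against `BB`), the only pair of genotypes impossible
under shared parentage; a trio error is any offspring genotype that cannot
be assembled from one allele of each parent. A transmission is evaluable
only when every member is called. The module is stateless; iteration lives
in `run_iterative_curation()`.

## Kinship from Mendelian incompatibilities

`compute_duo()` reports, per pair: compared markers, opposing homozygotes
(`duo_errors_perc`), and the directional heterozygous mismatch counters —
`het_mismatch_A1A2` counts markers where the first sample is `AB` and the
second homozygous, `het_mismatch_A2A1` the reverse. The directional
definition is this package's documented reading of the counters; the two
swap under pair reversal, all other fields are symmetric (a tested
contract). `all_duos()` computes the same table for every unordered pair
through indicator-matrix cross-products, so a 120-sample panel takes
milliseconds.

`infer_relationships()` starts from an initial duo threshold (default
0.5% of compared markers) and relaxes it to the maximum error observed
among pedigree-known parent-offspring pairs whenever they exceed it, so
that every expected true pair is captured; the final threshold is
reported. Trios are evaluated for each sample against every unordered pair
of its candidate partners plus all recorded parent pairs, and the trio
threshold (default 1%) is relaxed analogously against pedigree-known
trios. The trio relaxation is this package's extension of the duo rule:
real panels show known-trio errors near or above common defaults while
wrong-parent trios sit an order of magnitude higher, so relaxation costs
no specificity (it can be disabled with `relax_trios = FALSE`). Phasing is
deliberately absent: incompatibility counting needs none, and probabilistic
haplotype inference is unreliable on small heterogeneous panels.

`run_iterative_curation()` alternates inference with the 3% Mendelian
filter until no marker is removed (a fixed point, usually reached in two
iterations) or an iteration cap of 10 triggers a warning.

`classify_relationships()` fits a PCA on the four standardised duo
variables of pairs with pedigree-expected classes (PO, FS, GP, HS, UN);
pairs labelled "other" — unknown or heterogeneous relationships whose
large variance would otherwise dominate the axes — are projected onto the
fitted axes as supplementary individuals, using the stored centring,
scaling and rotation, without influencing the eigendecomposition. Variable
contributions per axis are squared loadings (summing to 100%); axis signs
are fixed so the dominant variable loads positively.

`pedigree_relationships()` classifies pairs structurally (parent-offspring,
full sibs, grandparent, half sibs, avuncular; precedence in that order)
and reports the numeric relationship coefficient from the additive
relationship matrix. Classification is structural rather than gated on a
coefficient threshold because grandparent and half-sib pairs sit exactly
at r = 0.25 in a non-inbred pedigree.

## Diversity and concordance

`genotype_pca()` codes genotypes as B-allele dosage, drops markers below a
0.05 MAF floor, mean-imputes no-calls per marker (keeping small panels
intact rather than dropping samples) and centres columns. Axis signs
follow the largest-loading convention, making ordinations reproducible.

`platform_concordance()` compares samples genotyped on two platforms over
shared markers, discarding markers missing on either side. The default
`zygosity` mode scores agreement on the heterozygous/homozygous class
only, because A/B allele assignment is platform-specific; `strict` mode
requires exact call identity, optionally after per-marker allele-swap
harmonisation (a marker is flipped when flipping increases matches across
samples — ties are not flipped).

## Chlorotypes and maternal lineage

Plastid loci are haploid and maternally inherited. `assign_chlorotypes()`
reads homozygous calls as haplotype letters; a heterozygous plastid call
is treated as a technical artifact — counted in `n_het_calls` and masked —
not as heteroplasmy. Markers monomorphic across the panel are reported as
non-discriminating, and typing requires complete calls only at
discriminating positions. Type labels are panel-relative, ordered by
descending frequency with lexicographic tie-breaks; mapping them onto any
published chlorotype nomenclature is a user-supplied table, never
inferred.

`maternal_lineage()` applies the parents-differ rule: confirmed when the
parents' types differ and the offspring matches the recorded mother;
inconclusive when the parents are identical; excluded when the recorded
mother's type mismatches the offspring's; unassessable when a required
type is missing.

## The trait-rule engine

Rules are data, not code: each candidate marker becomes a row binding a
predicate (dominant `allele_present`, recessive `homozygous_B`, their
complements, or a multi-marker `haplotype_match` vector over
{`AA`,`AB`,`BB`,`any`}) to a predicted phenotype class. Observed classes
pass through an explicit collapse map (e.g. OIV-225 berry-colour codes 5
and 6 to "colored", 1 and 2 to "non_colored") before comparison. Samples
missing the phenotype or a required call are excluded from `n_evaluable`;
a rule is `fully_predictive` when it is evaluable and makes no wrong call.
The flower-sex panel combines female-sterility markers (tagging the
dominant male-determining haplotype) and male-sterility markers (tagging
the recessive female-determining haplotype): male when only
female-sterility is indicated, female when only male-sterility is,
hermaphrodite when neither, and an explicit conflict flag — excluded from
accuracy — when both are. Duplicate clones are dropped before panel-level
counts.

## What the simulator emulates — and what it does not

`simulate_panel()` generates the reference study conditions used across
the tests: a 120-sample panel (a cultivated cluster of 24 founders, a
sylvestris-like cluster of 8, three wild clusters of 6, 48 F1 from 24
crosses, 4 wild×cultivated hybrids, 16 F2, and two somatic-duplicate
clones) at ~5,000 autosomal markers plus trait and plastid loci. Founder
frequencies follow a Balding-Nichols model (ancestral frequency uniform on
[0.1, 0.9], per-population divergence parameters 0.05 for the cultivated
cluster up to 0.35 for wild clusters) — the minimal standard model that
reproduces both the cultivated/wild separation on the first genotype PCA
axis and, through drift toward extreme frequencies, the lower observed
heterozygosity of wild species on markers ascertained in the cultivated
pool. Offspring receive one allele per parent at every marker
independently; genotyping error is a symmetric single-step perturbation
(hom→het; het→either hom) at 0.5% per call; planted failing probes
instead miscall to one of the other two genotype classes at 10% per call,
the plain reading of a 10% per-call error rate for a failed assay;
duplicates are cloned after error with exactly six discordant called
genotypes and before missingness (3% base, 6% for wild founders). Plastid
haplotypes are drawn per population, copied from the mother, and exempt
from error and missingness; trait loci are single Mendelian genes whose
marker readouts are deterministic in the carried haplotypes, with optional
recombination injected at chosen sex-panel markers. Random streams are
split per concern (founders, transmission, traits, plastid, failing-probe
choice, error, duplicates, missingness), so toggling one process does not
shift the others — the tests rely on this for paired comparisons.

The simulator deliberately omits: linkage and recombination maps (markers
are transmitted independently; none of the incompatibility statistics use
linkage), intensity-level artifacts (off-target variants, cluster
shifts), null alleles, ascertainment at the marker-discovery stage beyond
the divergence model, inbreeding loops, and heteroplasmy. Passing tests
therefore demonstrate the correctness of the counting, thresholding and
projection logic under a clean generative model — not robustness to the
full artifact spectrum of real array data.

Problem sizes in the test suite were chosen to keep the full run within a
few minutes on one core: unit tests use a 15-sample, ~300-marker panel;
the end-to-end checks use the full 120 × 5,000 reference panel, a
candidate pool of ~38,000 VCF records, an all-pairs proximity oracle at
10,000 variants and a duo symmetry sweep over 1,000 random pairs.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive throughout, as in VCF.
* Percentages are percentages of *compared* (both/all called) markers.
* A pair or trio with zero compared markers is flagged non-evaluable, with
  `NA` statistics, and can never be a candidate relationship.
* An empty confirmed-relationship set removes no markers and warns.
* Ordination on fewer than three labelled pairs, a zero-variance duo
  variable, or an empty post-MAF marker set is an error, not a silent
  degenerate fit.
* All outputs are sorted deterministically; re-running any stage on the
  same input is byte-identical, including PCA axis signs.

## Known limitations

* The Mendelian filter can only see failing probes through the pedigree:
  with roughly a quarter of the panel outside any confirmed duo or trio,
  a 10%-miscall probe expresses only ~5% of its errors as visible
  incompatibilities, and the per-marker count is overdispersed (one
  miscall in a well-connected parent yields several incompatibilities; a
  miscall in an unconnected founder yields none). A small fraction of
  failing probes therefore lands under the 3% removal threshold and
  survives curation; panels with denser pedigrees tighten this gap.
  Conversely, a real miscall in a heavily crossed parent can push an
  otherwise clean marker over the threshold — a property, not a defect, of
  pedigree-based filtering.
* Heterozygous-mismatch directionality (`A1A2` vs `A2A1`) is a documented
  package convention; other tools may define the direction oppositely.
* Call-level marker statuses approximate, but are not equivalent to,
  intensity-based array classes.
* The plastid typing cannot distinguish haplotypes that are identical at
  the assayed markers; the lineage verdict is accordingly "inconclusive",
  never a guess.
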