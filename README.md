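# vitisnp

Design, curation and exploitation of mid-density SNP genotyping arrays for
grapevine (*Vitis* spp.) and similar highly heterozygous, clonally
propagated crops.

Breeding programmes in grapevine work with panels that mix the cultivated
species, its wild relative, interspecific hybrids and divergent wild
species. A genotyping array serving such panels has to be designed from
heterogeneous candidate variants, and its exported genotype calls have to
be curated before they can answer the questions breeders actually ask: who
is a duplicate (somatic variant) of whom, which recorded pedigrees are
true, which parent was the maternal donor, and which candidate markers
really predict a trait. `vitisnp` implements that workflow end to end on
genotype-call tables, together with a synthetic-panel generator that plants
known truth so every stage can be validated.

## What it computes

* **Array design** — candidate-variant filtering (site quality `QUAL ≥ 100`,
  biallelic SNVs only, per-sample depth `DP ≥ 8`, missingness `≤ 20%`,
  removal of A/T and C/G transversions, flagging of variants within 35 nt
  of another polymorphism) and quota-based marker selection: 130 markers
  per chromosome for the cultivated pool, 40 per chromosome per wild
  species, plus a 60-marker per-chromosome bonus pool on chromosomes
  carrying resistance loci.
* **Curation** — per-sample call rate and observed heterozygosity
  (`Het_obs = n_AB / n_called`, pass at call rate ≥ 0.85), per-marker call
  rate, genotype-class counts and minor allele frequency
  (`MAF = min(p, 1−p)`, `p = (2·n_AA + n_AB)/(2·n_called)`), and removal of
  markers with more than 3% Mendelian segregation error across confirmed
  duos and trios.
* **Kinship** — duplicate detection by call discordance; duo statistics
  (opposing homozygotes `duo_errors_perc`, directional heterozygous
  mismatches `het_mismatch_A1A2`/`het_mismatch_A2A1`, `perc_mismatches`);
  trio incompatibility under gamete pairing; iterative
  inference-and-filtering with threshold relaxation to the maximum error
  observed among pedigree-known parent-offspring pairs; and a
  relationship-class PCA on the four duo variables in which unknown
  ("other") pairs are projected as supplementary individuals.
* **Diversity** — per-species heterozygosity summaries, genotype PCA on
  0/1/2 B-allele dosage (MAF floor 0.05, mean imputation), and per-sample
  heterozygous/homozygous concordance between two genotyping platforms.
* **Chlorotypes** — plastid haplotype assignment (haploid loci; heterozygous
  calls are counted as anomalies and masked), frequency-ranked type labels,
  and maternal-lineage verdicts: confirmed when the parents' chlorotypes
  differ and the offspring matches the recorded mother, inconclusive when
  the parents are identical, excluded when the recorded mother mismatches.
* **Traits** — a declarative rule engine mapping genotype predicates
  (dominant B allele, recessive homozygote, multi-marker haplotype match)
  to predicted phenotype classes, with class-collapse maps (e.g. OIV-225
  berry-colour codes to colored/non-colored) and a combined flower-sex
  call from female-sterility and male-sterility marker sets.
* **Simulation** — multi-population panels under a Balding-Nichols
  divergence model with Mendelian transmission through an explicit
  pedigree, per-call genotyping error, planted failing probes, somatic
  duplicates with an exact number of discordant calls, maternally
  inherited plastid haplotypes and fully penetrant trait loci; plus a
  candidate-VCF generator with labelled filter failures.

## Worked example

```r
library(vitisnp)

sim <- simulate_panel(simulation_config(seed = 42))
sim
#> <panel_sim> 120 samples x 5026 markers; 136 planted PO duos, 68 trios, 2 duplicate pair(s)

head(sample_qc(sim$genotypes), 3)
#> # A tibble: 3 x 5
#>   sample_id n_called call_rate observed_heterozygosity passes
#> 1 cv01          4877     0.970                   0.367 TRUE
#> 2 cv02          4854     0.966                   0.365 TRUE
#> 3 cv03          4874     0.970                   0.373 TRUE

find_duplicates(sim$genotypes)
#> # A tibble: 2 x 4
#>   sample_a sample_b   n_compared n_diff
#> 1 rp06     rp06_clone       4459      5
#> 2 cv23     cv23_clone       4744      6

cur <- run_iterative_curation(sim$genotypes, sim$truth$pedigree)
length(cur$removed)                  # markers over 3% Mendelian error: 170
nrow(cur$relationships$duos)         # candidate parent-offspring duos: 138

ct <- assign_chlorotypes(sim$genotypes, sim$truth$plastid_marker_ids)
attr(ct, "types")
#> # A tibble: 3 x 3
#>   type_label haplotype n_samples
#> 1 Type1      AAAA             53
#> 2 Type2      BBBA             48
#> 3 Type3      ABAB             19

table(maternal_lineage(ct, sim$truth$pedigree)$verdict)
#>    confirmed inconclusive
#>           52           16
```

The two reported duplicate pairs are the planted somatic variants (six
discordant calls each, partly hidden by missingness); the 138 candidate
duos are exactly the 136 planted parent-offspring pairs plus the two
clone-source pairs; every offspring carries its mother's chlorotype, so
maternal lineage is confirmed wherever the two parents differ and
inconclusive where they are identical.

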