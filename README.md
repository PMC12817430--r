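# seedtrace

Genomic detection of direct seeding and seed provenance in structured
plant populations.

## The problem

Revegetation programmes routinely sow wild-plant seed mixtures
(*direct seeding*), but the provenance of the seed is rarely recorded.
When a species is split into strongly diverged evolutionary
significant units (ESUs), sowing seed of a foreign ESU — or a commercial
mixture of several — can introduce maladapted genotypes, erode local
population structure, and trigger outbreeding depression. Conservation
agencies therefore need to answer, from genotype data alone: *which of
these populations were sown rather than naturally established, and
where did the seed come from?*

`seedtrace` implements that inference as a reusable, fully testable
pipeline for diploid biallelic SNP genotypes (VCF), aimed at
conservation geneticists running national monitoring programmes. Because
the original survey data live in sequence archives, the package ships a
calibrated simulator so every stage can be validated against known truth
without downloads.

## The model and decision rules

* **Ancestry.** Genotypes follow a binomial admixture model:
  `g_ij ~ Bin(2, f_ij)`, `f_ij = Σ_k q_ik p_kj`, with ancestry matrix
  `Q` (individuals × K) and ESU allele frequencies `P` (K × loci).
  `(Q, P)` are estimated by EM (provably monotone in the
  log-likelihood), `K` by masked ten-fold cross-validation, restarts
  aligned by exact assignment over cluster-label permutations.
* **Differentiation.** Pairwise multi-locus F_ST between ESUs
  (Weir–Cockerham 1984 ratio-of-averages by default; Hudson as
  alternative), computed on non-admixed individuals.
* **Diversity.** Per-individual observed heterozygosity `H_o` and
  inbreeding coefficient `F = (O − E)/(N − E)`, with `E` the expected
  homozygous-site count from ESU-specific allele frequencies
  (small-sample corrected by `n/(n−1)`).
* **Star clusters.** Populations sown from one homogeneous seed lot
  appear in identity-by-state neighbor-joining trees as star-shaped
  clusters that mix across populations. The package formalises this:
  a set of populations is flagged as sharing a seed source when all
  pairwise population F_ST < 0.02 and the mean nearest-neighbour
  mixing index ≥ 0.5.
* **Decision rules.** With an inclusive 10% admixture threshold and a
  100-km allochthony rule (an ESU observed > 100 km from its nearest
  natural, non-admixed reference population — or with no in-region
  reference at all — is allochthonous), populations are classified in
  priority order: single allochthonous source → `seeded_allochthonous`;
  admixed with an allochthonous component → `seeded_admixed`;
  star-cluster evidence with autochthonous sources →
  `seeded_autochthonous_homogeneous`; otherwise `natural` (admixture
  among autochthonous ESUs counts as natural gene flow).

The simulator draws ESU frequencies from the Balding–Nichols model
(`p_kj ~ Beta(p̄_j(1−F_k)/F_k, (1−p̄_j)(1−F_k)/F_k)`), so one drift
parameter per ESU maps onto its expected F_ST, and models commercial
seed lots as binomial founder bottlenecks of mixed ESU frequencies.

## Worked example

Classify the packaged 31-population survey evidence table:

```r
library(seedtrace)
fx  <- load_evidence_fixture()
res <- classify_populations(fx$evidence)
summarize_seeding(res, fx$evidence)
#> Seeding summary over 31 populations
#>   direct-seeded:                 15 (48.4%)
#>     allochthonous:               3 (9.7%)
#>     admixed seed sources:        5 (16.1%)
#>     homogeneous autochthonous:   7 (22.6%)
#>   natural:                       16 (51.6%)
#>   any allochthonous material:    8 (25.8%)
#>   collector-flagged:             11 (35.5%)
#>   habitat modification records:  9
#>     mean years since modification (start/end/midpoint): 12.9 / 9.8 / 11.3
#>   genomic - collector:           12.9%
```

Roughly half the surveyed populations were sown; a quarter carry some
foreign seed material; genomics detects 12.9 percentage points more
seeding than the collectors' field assessment did.

End to end on simulated data with known truth (three ESUs, two of them
autochthonous; three populations sown from one shared seed lot; one
foreign-sown and one admixed-sown population):

```r
out <- run_pipeline(pipeline_config(
  scenario = demo_scenario_config(rng_seed = 7),
  K_range = 3, rng_seed = 7))
round(out$fst, 3)            # ESU differentiation, non-admixed individuals
#>       ESU1  ESU2  ESU3
#> ESU1 0.000 0.259 0.223
#> ESU2 0.259 0.000 0.235
#> ESU3 0.223 0.235 0.000
out$source_report$table      # star-cluster detector
#>    esu             populations n_populations mean_mixing max_within_fst flagged
#> 1 ESU3 SEED_S2,SEED_S3,SEED_S1             3   0.7333333    0.002300369    TRUE
subset(out$classifications, direct_seeding)$pop_id
#> "NAT_A2" "SEED_S1" "SEED_S2" "SEED_S3" "SEED_L1" "SEED_M1"
```

The three seed-lot populations are flagged as one shared homogeneous
source (pairwise F_ST ≈ 0.002, mixing 0.73), the foreign and admixed
sowings are recovered, and `NAT_A2` illustrates the method's known
false-positive mode: a drifted natural population showing phantom
admixture just over the inclusive 10% threshold (see the methods
vignette). Across 20 replicate scenarios ≥ 95% of populations receive
their true category.

A command-line wrapper mirrors the pipeline stages
(`inst/cli/seedtrace.R`): `simulate`, `qc`, `errors`, `classify`,
`run-all`, each taking `--seed`/`--out`.

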