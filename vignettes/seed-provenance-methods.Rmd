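---
title: "Detecting direct seeding and seed provenance from SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting direct seeding and seed provenance from SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtrace)
```

## Scope and assumptions

`seedtrace` starts from called diploid genotypes at biallelic SNPs
(a VCF with `GT`, ideally per-genotype `DP` and caller annotations) and
a georeferenced population table, and ends with a per-population
classification: naturally established, or direct-seeded with a
homogeneous autochthonous source, an admixed source, or an
allochthonous source. Everything upstream of genotypes
(read mapping, variant calling) and everything phylogenetic beyond
distance-based trees (maximum-likelihood trees, ascertainment-bias
corrections, bootstrap support) is out of scope by design.

Three modelling assumptions run through the package:

1. **Binomial admixture.** Conditional on ancestry `q_i` and ESU
   frequencies `p_k`, genotypes are independent binomial draws —
   no linkage, Hardy–Weinberg within components. LD thinning (one SNP
   per 5 kb by default) is what makes this tolerable on real data.
2. **ESUs as frequency pools.** Evolutionary significant units are
   treated as exchangeable allele-frequency pools; within-ESU
   population structure exists (the simulator models it explicitly)
   but is nuisance, not signal, for provenance assignment.
3. **Missingness at random.** All statistics use pairwise deletion;
   genotype-depth filtering sets calls missing rather than dropping
   sites, after which missingness-based site filters apply.

## The synthetic world

Real surveys of this kind cannot ship with a package, so validation
rests on a generator with known truth. It emulates, in order:

* **Ancestral frequencies** i.i.d. uniform on [0.05, 0.95] —
  a flat SNP-panel-like ascertainment window that avoids rare-variant
  pathologies in small simulated samples.
* **ESU drift** via the Balding–Nichols Beta model. A two-ESU world at
  drift `F` yields pairwise F_ST ≈ `F` (checked to ±0.03 at 10⁴ loci),
  so drifts of 0.2–0.25 reproduce the low end of the differentiation
  reported between deeply diverged conspecific lineages (0.17–0.43).
* **Within-ESU population drift** (natural populations only, default
  0.05): without it, two natural populations of one ESU would be
  statistically identical and every ESU would look like one giant seed
  lot. 0.05 is deliberately well below the between-ESU drift. This
  field is an extension beyond the minimal population specification,
  as is `seed_lot`: populations sharing a lot label are sown from a
  single draw of lot frequencies, which is precisely what makes
  commercial multi-site seeding detectable.
* **Seed lots** as mixture-then-bottleneck: source ESU frequencies are
  mixed first, then resampled through `2 × founder_size` binomial
  allele copies (default 10 founders — illustrative; no empirical
  founder-size distribution is available). Mixing before the
  bottleneck mimics multi-origin commercial propagation, and the
  bottleneck depresses expected heterozygosity by ≈ `1/(2N_f)`,
  reproducing the diversity loss expected from seed multiplication.
* **Genotyping annotations** (negative-binomial depth, Beta
  allele balance, quality-per-depth, mapping-quality ratio) exist only
  so the QC cascade has something to act on; their defaults pass ~95%
  of sites. They model no particular caller.
* **Technical replicates** re-draw calls with a configurable
  per-genotype error probability and independent missingness, so
  replicate-concordance error rates are recoverable by construction.
* **Geography** is taken literally from the configuration; genotypes
  carry no spatial autocorrelation beyond ESU membership.

What a green test therefore establishes: the estimators recover the
parameters of *this* world at desk scale. What it does not establish:
robustness to linkage, ascertainment bias across sequencing platforms,
non-random missingness, or within-ESU isolation-by-distance — all
present in real data, all outside the model.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `tau` | 0.10 (inclusive) | admixture threshold on foreign ancestry |
| `threshold_km` | 100 km | allochthony range rule |
| `theta_fst` | 0.02 | max within-set population F_ST for a shared seed lot |
| `theta_mix` | 0.5 | min mean nearest-neighbour mixing index |
| `window_bp` | 5000 | LD-thinning window |
| filter cascade | see `filter_config()` | the survey's QC values |

The source survey writes both "≥ 10%" and "> 10%" for the admixture
threshold in different places; the inclusive reading is adopted
uniformly and is configurable. Exactly 100 km is autochthonous
("more than 100 km" is the exclusion). The star-cluster thresholds
`theta_fst`/`theta_mix` formalise what was originally a visual call on
a tree; they were calibrated once on the simulator (seed-lot sets sit
at F_ST ≲ 0.01 and mixing ≳ 0.7; distinct natural populations at
F_ST ≳ 0.1 and mixing ≈ 0) and are exposed in the configuration.

## Numerical and algorithmic choices

* **EM, not quasi-Newton.** The EM update for the binomial admixture
  likelihood is provably monotone (asserted in tests at 1e-8), keeps
  the simplex/box constraints by construction, and is fast enough at
  desk scale. `P` is clamped to `[1e-6, 1 − 1e-6]`; a zero EM
  denominator leaves the affected `p_kj` unchanged.
* **Short runs, then refine.** The likelihood is multimodal. Restarts
  (Dirichlet(1) rows for `Q`; observed frequency ± Uniform(−0.05, 0.05)
  jitter for `P`) run 100 iterations each; only the best continues to
  convergence (`|Δℓ| < 1e-6` or 2000 iterations by default). This
  deviates from running every restart to convergence: at equal budget
  it explores more modes, and a mode that leads after 100 iterations
  essentially always wins the refit race in this model family. Label
  switching across restarts is resolved by exact assignment
  (bitmask dynamic programme, exact for K ≤ 20).
* **Cross-validation** masks genotype *entries* (not individuals or
  loci), refits, and scores masked dosages by squared error against
  `2·f̂`; the elbow rule maximises the second difference of the error
  curve, the min rule breaks ties toward smaller K.
* **Neighbor joining** breaks Q-criterion ties toward the smallest row
  index and clamps negative branch lengths to zero, moving the deficit
  to the sibling edge so the joined pair's distance is preserved; it
  reconstructs additive matrices exactly.
* **Mixing-index ties** resolve to the smallest individual index.
  Consequence: at coarse IBS resolution (few hundred loci) ties are
  common and the index biases low — the package's validation worlds use
  ≥ 1000 loci so that tie-breaking is immaterial.
* **W&C vs Hudson.** The survey's F_ST tooling does not state its
  estimator; Weir–Cockerham 1984 is the default here (field standard),
  Hudson is provided, and on balanced two-group drift simulations they
  agree within ±0.02.
* **Inbreeding `F`** uses the per-site small-sample correction
  `1 − 2p(1−p)·n/(n−1)` for expected homozygosity; sites monomorphic
  within the group contribute 1 to `E` and are retained (a switch
  drops them). `F` is undefined when `N = E` (reported `NA`).
* **Homozygote allele balance.** The survey's wording ("< 0.01
  respectively > 0.9") is ambiguous about whether sites *inside*
  (0.01, 0.9) are kept; keep-if-outside is implemented, with
  `hom_ab_keep_outside = FALSE` flipping the reading.
* **Percentages** are printed to one decimal with
  round-half-away-from-zero, matching the survey's style.

## The evidence fixture

`inst/extdata/table2_evidence.tsv` transcribes the published summary of
genomic and non-genomic seeding evidence for 31 surveyed populations
(17 with at least one evidence line; the rest carry a single
autochthonous source and no flags). Two fields are synthetic and marked
as such in the file: coordinates (the published table prints none; the
classifier never reads them) and, for admixed populations, *which*
component ESU is the allochthonous one (the table flags allochthony
only at population level; the narrative identifies the plausible
components). Classification is a pure function of the genomic fields —
mutating the collector and habitat-history columns changes no category
(property-tested).

The decision rules give single-allochthonous-provenance priority over
the admixture rule; this is what places the one population that is both
foreign-sown and admixed in the allochthonous class and reproduces the
published partition {3 allochthonous, 5 admixed, 7 homogeneous,
16 natural}.

The habitat-modification records are year *ranges*; the published mean
of 11.5 years since modification is not recoverable under start-year
(12.9), end-year (9.8) or midpoint (11.3) conventions relative to the
2021 sampling campaign, so the summary reports all three rather than
targeting the printed value.

## Scaled-down validation worlds

Acceptance checks that need replication run at deliberately reduced
size, chosen once for statistical adequacy within a desk-scale budget:

* K selection: 20 replicates of 3 ESUs × 15 individuals, 600 loci,
  3 folds, K ∈ {1, 3, 5}.
* Seed-lot detection: 20 replicates of 5 populations × 8 individuals,
  1000 loci (IBS-resolution floor above).
* End-to-end: 20 replicates of the 8-population demo world at 1200
  simulated loci (≥ 1000 post-QC).

## Known limitations

* Phantom admixture: a natural population drifted within its ESU can
  place an individual just over the inclusive 10% threshold at ~10³
  loci, and if the phantom component is far from its references the
  population misclassifies as admixed-seeded (the demo world does this
  in ~3/20 replicates, always that failure mode; aggregate category
  accuracy stays ≥ 95%). More loci or an exclusive threshold both
  shrink the mode; the survey's own threshold is kept as stated.
* Cluster labels come from natural-status populations; an ESU whose
  natural populations were all lost cannot be told from an introduced
  one (it becomes allochthonous by definition — arguably the
  conservative behaviour).
* The star-cluster detector assumes seed lots were sown into at least
  two sampled populations; a lot sown once is undetectable by this
  route (it can still be caught by the allochthony or admixture rules).
* Error rates from technical replicates are concordance rates; they
  cannot separate the two replicates' error contributions, and
  class-conditional rates average over the two possible conditionings.
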