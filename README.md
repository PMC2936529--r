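# gcsel

Tests whether bacterial GC-content is maintained by mutation bias alone, or
whether selection (or a selection-like force such as biased gene conversion)
acts on it, using patterns of synonymous polymorphism in multi-strain gene
alignments.

## The problem and the statistic

Bacterial genomic GC-content spans roughly 15–75%. If base composition is at
a mutation-bias equilibrium, then among synonymous polymorphisms segregating
at third positions of 4-fold degenerate codons we expect **equal numbers of
GC→AT and AT→GC mutations**, regardless of how biased mutation is. The core
statistic is

> Z = U / (U + V)

where *U* and *V* count SNPs inferred (from allele frequencies — the minor
allele is taken to be the new mutation — or from Fitch parsimony on a
clock-rooted NJ tree) to be GC→AT and AT→GC respectively. A systematic
excess of GC→AT SNPs (Z > 0.5) in GC-rich species is the signature of
selection favouring GC, because mutation–selection–drift balance holds
deleterious GC→AT mutations at low frequencies, where the minor-allele rule
assigns them the GC→AT direction.

High mutation rates violate the infinite-sites assumption and bias Z away
from 0.5 even under neutrality. The package corrects for this with Wright's
stationary distribution for a biallelic site under reversible mutation
(scaled rates U = θ(1−f), V = θf, with f the equilibrium GC fraction) and
genic selection S = 2N<sub>e</sub>s:

> φ(x) ∝ e^{Sx} · x^{V−1} (1−x)^{U−1}

Binomial sampling of *n* strains gives a closed-form sample spectrum
P(i) ∝ C(n,i) B(V+i, U+n−i) ₁F₁(V+i; U+V+n; S), from which the package
computes the predicted Z (`z_pred`), the expected GC↔AT diversity, and a
per-species neutral prediction `Z_pred` obtained by calibrating θ to the
observed diversity at the observed GC4 (constant or exponentially
distributed per-site rates). Species whose observed Z exceeds Z_pred carry
a signal that mutation bias alone cannot explain.

Supporting machinery: degeneracy classification from the genetic code,
SNP extraction with tie/triallelic discard rules, four-gamete and maxchi
recombination screens (to exclude gene-conversion/HGT artifacts),
cohort-level regression of Z on GC4 with a bootstrapped crossing point,
sign tests, translational-selection contrasts, r/m correlations, and seeded
synthetic-data generators (stationary alignments, tree alignments with
known ancestral states, recombinant mosaics, whole cohorts) for validation
against known truth.

## Worked example

Simulate one GC-rich "species" (f = 0.8, θ = 0.19, no selection, 10
strains, 5000 fourfold sites), extract SNPs and compare observed Z with the
neutral prediction:

```r
library(gcsel)

p    <- theory_params(theta = 0.19, f = 0.8, S = 0, n = 10)
spec <- simulation_spec(p, n_4fold_sites = 5000, seed = 42)
aln   <- simulate_alignment(spec)
sites <- classify_sites(aln)
snps  <- extract_snps(aln, sites)
div   <- diversity_summary(aln, sites)
summarize_species(list(snps), list(div), species = "demo",
                  zpred_models = "constant")
```

```
  U4  V4         Z     GC4 pi_gc_at_4fold Z_pred_constant  GC4_pred passes_filters
 370 305 0.5481481 0.79262     0.05290222       0.5462548 0.7590722           TRUE
```

Even with no selection, this GC-rich, fairly diverse species shows Z = 0.548
(370 GC→AT vs 305 AT→GC; two-tail binomial p = 0.014) — an apparent GC→AT
excess created purely by the infinite-sites violation. The corrected neutral
prediction `Z_pred_constant` = 0.546 matches it almost exactly, so the
pipeline correctly reports nothing left for selection to explain; a real
selection signal shows up as Z substantially above Z_pred. `GC4_pred` = 0.76
is the GC4 to which the sequence would drift under the observed SNP fluxes.

For a directory of real alignments (`input_dir/<species>/<gene>.fasta`,
in-frame aligned FASTA), `run_pipeline()` performs the whole analysis —
per-gene SNP tables, direction inference, screens, species filters
(≥8 strains, ≥10 GC↔AT fourfold SNPs, π < 0.1), Z-vs-GC4 regression with a
bootstrap CI on the Z = 0.5 crossing, sign tests, and screen-filtered
re-analyses — and `write_report()` emits TSV/JSON.

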