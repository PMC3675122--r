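---
title: "Imputing HLA alleles and amino acids from MHC SNPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing HLA alleles and amino acids from MHC SNPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaimpute)
```

## The problem

The HLA genes in the MHC (chr6:29–34 Mb) are the most polymorphic loci in
the human genome and carry some of the largest known disease effects, but
direct high-resolution HLA typing does not scale to GWAS-sized cohorts.
Because linkage disequilibrium in the MHC extends over long distances,
SNP genotypes collected on ordinary arrays carry substantial information
about the classical alleles — and about the individual amino-acid
residues those alleles encode.  `hlaimpute` exploits this: it recodes
every form of HLA variation as binary presence/absence markers embedded
in a phased SNP reference panel, imputes those markers into
SNP-genotyped samples, and tests the imputed dosages for disease
association at the level of alleles, residues and multi-gene haplotypes.

## Binary encoding of multi-allelic variation

A classical 4-digit allele such as `DRB1*0401` is, for the purposes of a
haplotype model, just a label attached to a chromosome.  We create one
binary marker per distinct 2-digit and 4-digit allele observed in the
reference typings (`HLA_DRB1_04`, `HLA_DRB1_0401`, ...).  Each typed
allele is then mapped through its aligned protein sequence, and every
aligned position at which at least two distinct symbols occur among the
observed alleles becomes a set of residue markers — one marker per
residue, so a three-residue position yields exactly three markers.  Gap
(`-`) and termination (`*`) symbols are residues of their position for
this purpose, which preserves the central bookkeeping invariant: for a
fully typed individual the residue dosages at every position sum to 2,
exactly as the classical-allele dosages do within a gene.  Runs of gap
or termination symbols are additionally encoded as separate indel
markers keyed on the event (start, length), since a multi-residue
deletion is one biological event rather than several independent ones.

Two consequences of this design are tested as matrix identities: the
4-digit encoding is invertible (the allele multiset of every individual
can be recovered from the genotype table), and the amino-acid genotype
table is a linear image of the 4-digit table (residue dosage = sum of
the dosages of the alleles carrying that residue).

Markers need genomic coordinates so the haplotype model sees a total
order.  The paper-of-record for a marker's position would be its exact
exonic location; we instead anchor all of a gene's markers at a
configurable per-gene coordinate and give amino-acid markers a 3 bp
codon offset per alignment column.  This preserves ordering and
approximate genetic distances, which is all the copying model consumes.
Ambiguous typings contribute at the resolution they support: a
2-digit-only call counts toward 2-digit markers and leaves the gene's
4-digit markers missing for that individual (a `drop` policy is also
available).

## Reference-panel construction

SNPs entering the panel pass the conventional reference QC: minor
allele frequency ≥ 1%, missingness ≤ 5%, and an exact Hardy–Weinberg
test at p ≥ 1e-6.  The three filters are evaluated jointly on the input
so their order cannot matter.  Encoded markers are never subjected to
HWE (they are logically constrained, not independently sampled
genotypes); they are pruned only when the presence frequency over the
2N panel chromosomes falls below 0.01%.

Phasing uses the same haplotype-copying machinery as imputation.  For
modest conditioning sets (K ≤ 64 haplotypes) each individual is phased
exactly by Viterbi decoding over ordered pairs of reference haplotypes,
with heterozygous sites oriented by the decoded pair; for larger sets
an iterative conditional scheme is used in which each sweep re-orients
every heterozygous site toward the configuration favoured by the two
haplotypes' leave-one-out predictive probabilities.  After phasing,
each gene block is projected onto the configuration implied by the
individual's classical alleles, restoring the one-hot property exactly:
every haplotype carries exactly one 4-digit allele per typed gene and
one residue per amino-acid position.  Unrelated individuals are a
stated precondition; pedigree-aware phasing is out of scope.

## The imputation model

The engine is a Li–Stephens haplotype-copying hidden Markov model.  A
sample haplotype is modelled as an imperfect mosaic of the K reference
haplotypes: the copied haplotype switches between adjacent markers with
probability `1 − exp(−4·Ne·d/K)` (d the genetic distance under a
uniform 1 cM/Mb map, Ne = 15000 by default, both configurable), and the
observed allele differs from the copied one with probability θ, which
defaults to the usual Li–Stephens estimate
`θ̃/(2(K + θ̃))`, `θ̃ = 1/∑_{k<K} 1/k`.  These are standard
literature defaults rather than fitted quantities; both matter mainly
through their ratio, which sets how much evidence a mismatch provides
for a recombination switch.

Target samples are first harmonized: restricted to the MHC window,
filtered at 2.5% target MAF, matched to panel SNPs by position, and
strand-oriented (complement-matching labels are flipped; A/T and C/G
palindromic SNPs are oriented by frequency matching when the panel
frequency is at least 0.1 from 0.5, else dropped).  Each individual's
typed sites are then phased against the panel, and a haploid
forward–backward pass per phased haplotype along the full marker chain
(typed sites observed, untyped sites uninformative) yields the
posterior probability that the copied reference allele is 1 at every
marker.  The untyped-marker posterior is the exact interpolation of the
copying-state posterior between flanking typed sites.  Genotype
posteriors multiply the two haplotype posteriors, the reported dosage
is computed as `P1 + 2·P2` so the dosage/posterior identity holds to
the last bit, and best-guess calls take the posterior argmax with ties
broken toward the lower genotype count.  Classical alleles are called
per haplotype as the highest-posterior presence marker of each gene,
which is also the basis of the phased multi-gene haplotypes used in the
risk analysis.

On panels small enough to enumerate (K ≤ 6, M ≤ 8) the
forward–backward posteriors are checked against an independent oracle
that sums over every one of the K^M copying paths explicitly; the two
agree to 1e-8.  Because every reference haplotype carries exactly one
allele per gene, the imputed classical dosages of a gene sum to 2 per
individual by construction — deviations beyond ±0.1 indicate a damaged
panel and are flagged by `dosage_sanity_check()`.

Windowed processing (overlapping windows with centre splicing) is
available for very dense chips but the default runs the full region as
one chain, which is exact.

## Evaluation metrics

Four complementary views of imputation quality are implemented.
`hla_accuracy()` is the dosage-sum accuracy: over individuals typed at
the evaluation resolution, the imputed dosages of the true alleles are
summed (both alleles for heterozygotes, the single allele once for
homozygotes — the homozygote rule uses the truth typing, not the
imputation) and divided by the number of chromosomes, so partially
correct soft calls earn partial credit.  `dosage_r2()` is the squared
Pearson correlation between imputed and true dosages of one binary
marker; `multiallelic_r2()` extends it to a position's whole residue
vector using column-centred inner products, a form chosen so that it
reduces *exactly* to the biallelic r² at two-residue positions (the
uncentred variant is available behind a flag for sensitivity analysis).
`hla_concordance()` scores best-guess calls against the truth as
unordered pairs (0, ½ or 1 per individual), excluding individuals whose
truth is not typed at the evaluation resolution.  With hard calls the
dosage-sum accuracy coincides with allele concordance except in one
corner: calling a heterozygote as a homozygote of one of its true
alleles earns the full dosage 2 under the accuracy formula but only one
allele match under concordance.  The identity test therefore uses
fixtures free of that degeneracy.  `calibration_curve()` bins dosages
on [0, 2] and reports per-bin mean true dosage, the standard check that
posterior confidence tracks empirical accuracy.

## Association testing

All tests operate on dosages, not best-guess calls, since soft dosages
correlate better with the true genotypes.  `test_marker()` fits a
binomial GLM `status ~ dosage (+ covariates)` by IRLS (tolerance 1e-8,
up to 100 iterations) and reports both Wald and likelihood-ratio
p-values; suspected separation is flagged, in which case the LRT is the
one to trust.  `omnibus_position_test()` jointly tests all residues at
an amino-acid position: because residue dosages sum to 2, the design is
rank-deficient by one, so the most frequent residue is dropped as the
reference and the statistic is the deviance difference between the
null and the full-position model on `(residues − 1)` degrees of
freedom.  The statistic is numerically invariant to which residue is
dropped (tested), which is why the reference choice is a non-issue.
Raw p-values are reported without multiplicity correction by default.

`haplotype_odds_ratios()` estimates per-haplotype disease odds against
a designated reference haplotype from the phased best-guess output:
each individual contributes two haplotype observations to a logistic
model with haplotype indicators, haplotypes rarer than 0.5% are pooled,
confidence intervals are profile-likelihood based, and cells empty in
cases or controls fall back to a Haldane-corrected 2×2 estimate with an
explicit flag.  Covariates are supported throughout but default off.

## The synthetic-data generator

Every quantitative claim in the test suite is made on data with known
truth from `simulate_panel()`.  Haplotypes are recombinant mosaics of a
founder pool: each founder carries a random SNP haplotype and one
classical allele per gene drawn from a Dirichlet frequency spectrum;
mosaic haplotypes cross over as a Poisson process along the window and
acquire sparse SNP copy errors.  A haplotype's classical allele at a
gene is that of the founder segment covering the gene anchor, and its
amino-acid markers follow deterministically from the residue table, so
the encoded markers are exactly one-hot and the linear-image identity
holds by construction.  The target split is disjoint from the panel by
default, so imputation accuracy is not inflated by leakage.

Defaults define the study conditions used throughout: 40 founders,
K = 1000 reference haplotypes, n = 200 target individuals, 1600 SNPs
across chr6:29–34 Mb, five genes (A, B, C, DQB1, DRB1 — the classical
benchmark loci), 8 alleles per gene in 2-digit families of two,
Dirichlet concentration 1, 50 aligned residues per gene, crossover rate
4e-7/bp (about two switches per haplotype across the window, giving the
long-range LD blocks that make MHC imputation work), and SNP copy-error
rate 2e-4.  Two platform profiles mirror a sparse early GWAS array
(500 SNPs) and a dense immunochip-style array (up to 5000 SNPs; with
the default SNP count this is effectively all panel SNPs).  Larger
association designs (e.g. n = 2000 with a planted causal residue of
odds ratio 2) reuse the same machinery.

What the generator does *not* emulate is worth stating: real MHC allele
frequency spectra are far more skewed, real LD is shaped by selection
and gene conversion, typing error in reference panels is absent, and
population structure/admixture is absent.  Passing tests therefore
demonstrate that the algorithms are correct and well-calibrated under
the stated generative model, not that any particular accuracy level
will be attained on real cohorts — on real data, accuracy is known to
degrade for rare alleles and for targets whose ancestry the panel does
not represent.

## Numerical and design choices

* Forward–backward uses per-site rescaling (normalized forward
  variables, max-rescaled backward variables), so chains of thousands
  of markers are stable in double precision.
* The switch probability is floored at 1e-12 and capped at 1−1e-12 to
  keep logs finite on degenerate maps.
* Phasing: the exact pair-Viterbi decoder is used whenever K ≤ 64 (its
  O(M·K²) tables are cheap there); above that the iterative conditional
  scheme runs a default 10 sweeps with an early stop when no
  heterozygous site changes orientation.  Its random initialisation is
  drawn from the run seed, making every pipeline output reproducible
  bit-for-bit given `--seed`.
* Missing target genotypes at typed sites are treated as untyped for
  that individual at that site.
* Best-guess ties break toward the lower genotype count and are
  flagged rather than silently resolved.
* Degenerate inputs reject loudly: unparseable allele labels, mixed
  genes, misaligned sequences, duplicate marker ids, targets with no
  panel overlap, a reference haplotype absent from controls.

## Problem sizes used in the checks

The bundled checks run the full benchmark at the default conditions
(K = 1000, n = 200, dense profile) over five simulation seeds for the
headline concordance, with the sparse-platform and reduced-panel
(K = 100, K = 50) comparison arms imputing 100 of the 200 target
individuals each; association calibration uses 2000 permutation
replicates at n = 500, causal-residue recovery 20 phenotype seeds at
n = 2000, and haplotype-OR coverage 100 replicates at n = 800.  These
sizes were chosen so each property is measured with useful precision
(binomial standard errors of a percent or two) while the whole suite
stays comfortably runnable on a laptop.

## Known limitations

The engine is a faithful Li–Stephens model, not a re-implementation of
Beagle's haplotype-cluster graph; its parameter defaults are literature
conventions, not per-dataset fits.  Phasing at large K is a
coordinate-ascent heuristic and can in principle lodge in local optima
(the exact decoder guards the small-K regime).  Imputation quality for
alleles with very few panel copies is poor — as it is for every
LD-based method — and the rare-marker floor deliberately removes
markers that cannot be imputed meaningfully.  The tool assumes
unrelated individuals, a single genomic window on chr6, and binary
case/control phenotypes in the association layer.
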