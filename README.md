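# hlaimpute

Imputation and association testing of classical HLA alleles, amino-acid
polymorphisms and intragenic indels from SNP genotypes across the MHC
(chr6:29–34 Mb).

GWAS arrays do not type the HLA genes, but long-range linkage
disequilibrium in the MHC means ordinary SNPs carry most of the
information about which classical alleles — and which individual protein
residues — a chromosome carries. `hlaimpute` is a toolkit for exploiting
that:

* **Binary-marker encoding** — every 2-/4-digit classical allele, every
  residue at a polymorphic amino-acid position, and every
  insertion/deletion/truncation event becomes one presence/absence
  marker (`HLA_DRB1_0401`, `AA_DQB1_57_32628240_D`,
  `INDEL_B_9_31321673`, ...), so multi-allelic variation phases,
  imputes and tests with the same machinery as biallelic SNPs. A
  position with three residues yields exactly three markers; residue
  dosages at a position sum to 2 per individual.
* **Panel building** — reference SNP QC (MAF < 1%, missingness > 5%,
  exact Hardy–Weinberg p < 1e-6 removed), rare-marker pruning
  (presence frequency < 0.01%), genomic merge and phasing into
  reference haplotypes on which each gene is exactly one-hot.
* **Imputation** — a Li–Stephens haplotype-copying HMM: target
  haplotypes are modelled as mosaics of the K reference haplotypes with
  switch probability `1 − exp(−4·Ne·d/K)` per interval and copy-error
  rate θ. Forward–backward posteriors give allele dosages in [0, 2],
  genotype posterior triples (`dosage = P1 + 2·P2` exactly), best-guess
  calls and phased haplotypes.
* **Evaluation** — the standard HLA-imputation metrics: dosage-sum
  locus accuracy Acc(L) (heterozygotes contribute both true-allele
  dosages, homozygotes one, divided by 2n), per-marker Pearson
  r²_dosage, a multi-allelic vector R² that reduces exactly to r² at
  two-residue positions, best-guess genotype concordance at 2- and
  4-digit resolution, frequency correlation and calibration curves.
* **Association** — per-marker dosage logistic regression, omnibus
  amino-acid-position tests (deviance of the all-residues model versus
  the null, df = residues − 1), signal ranking, and per-haplotype odds
  ratios with profile CIs against a reference haplotype such as
  `DRB1*01-DQA1*0101-DQB1*0501`.
* **Synthetic data** — a founder-mosaic MHC simulator with known truth
  (recombinant haplotypes, Dirichlet allele spectra, residue tables,
  platform profiles, planted causal residues), so the whole pipeline is
  testable end to end without any external data.
* **I/O + CLI** — PLINK .bed/.bim/.fam (bit-exact), Beagle-style phased
  text, dosage tables and dosage VCF (DS/GP), plus an `hlaimpute`
  command with `simulate`, `build-panel`, `impute`, `evaluate` and
  `assoc` subcommands.

## Worked example

Simulate a reference panel of 1000 haplotypes and 200 SNP-typed target
individuals, impute, and score against the held-out truth:

```r
library(hlaimpute)

sim   <- simulate_panel(sim_config(seed = 11))   # K = 1000, n = 200
tgt   <- make_target(sim, "dense")               # immunochip-like SNP set
harm  <- harmonize(tgt$target, sim$panel)        # strand + MAF + window
res   <- impute(harm, sim$panel, hmm_params(seed = 3))

calls <- call_classical(res, resolution = 4)
hla_concordance(calls, tgt$truth, 4)
#>   gene concordance   n
#> 1    A       96.75 200
#> 2    C       94.75 200
#> 3    B       97.25 200
#> 4 DRB1       95.50 200
#> 5 DQB1       92.50 200
```

Each row is the fraction of best-guess 4-digit allele calls matching
the withheld gold-standard typings at that locus (percent over 200
individuals, both alleles scored). Classical-allele dosages sum to ~2
per gene per individual (`dosage_sanity_check(res)$pass` is `TRUE`),
and `hla_accuracy(res, tgt$truth, "B", 4)` gives the soft-dosage
accuracy, which credits partially correct posterior mass as well.

For association, plant a causal residue and scan:

```r
set.seed(99)
ph   <- simulate_phenotypes(sim, "DQB1", aa_pos = 4, residue = "Y",
                            beta = log(2))
scan <- rank_signals(assoc_scan(res, ph))
head(scan[, c("marker", "stat", "df", "p", "rank")])
#>                  marker stat df        p rank
#> 1          snp_33025173 11.7  1 0.000618    1
#> 2  AA_DQB1_4_32627250_W 10.4  1 0.001228    2
#> 3  AA_DQB1_4_32627250_Y 10.4  1 0.001228    3
#> 4          AApos_DQB1:4 10.4  1 0.001228    4
#> 5 AA_DQB1_47_32627379_N 10.4  1 0.001235    5
#> 6 AA_DQB1_47_32627379_P 10.4  1 0.001235    6
```

The omnibus rows (`AApos_<gene>:<position>`) jointly test all residues
of a position. At this sample size (n = 200) the planted DQB1 position
4 signal and its residue markers lead the HLA signals, with one SNP in
strong LD narrowly ahead; at GWAS-scale n = 2000 (the bundled power
checks) the planted position ranks first in essentially every seed.

The same pipeline is available from the shell:

```sh
hlaimpute simulate    --out run --seed 5 --k 1000 --n-target 200
hlaimpute impute      --panel run.panel --plink run.target --out imp --seed 3
hlaimpute evaluate    --dosage imp.dosage.tsv --markers run.panel.markers \
                      --truth run.target.typings --out eval.tsv
```

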