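make_snp_fixture <- function(n = 60, m = 100, seed = 31) {
  set.seed(seed)
  f <- runif(m, 0.1, 0.9)
  geno <- sapply(f, function(p) rbinom(n, 2, p))
  rownames(geno) <- sprintf("s%02d", seq_len(n))
  colnames(geno) <- sprintf("rs%03d", seq_len(m))
  pos <- sort(sample(seq(29.1e6, 33.9e6), m))
  snp_encoding(geno, pos, counted = rep("A", m), other = rep("G", m))
}

test_that("QC removes planted MAF, missingness and HWE failures exactly", {
  enc <- make_snp_fixture()
  g <- enc$geno
  n <- nrow(g)
  # plant 3 low-MAF, 2 high-missingness, 2 HWE failures
  low_maf <- c("rs001", "rs002", "rs003")
  g[, "rs001"] <- 0; g[seq_len(1), "rs001"] <- 1          # maf 1/120
  g[, "rs002"] <- 0                                        # monomorphic
  g[, "rs003"] <- 0; g[1, "rs003"] <- 1
  high_miss <- c("rs004", "rs005")
  g[seq_len(ceiling(0.2 * n)), "rs004"] <- NA
  g[seq_len(ceiling(0.5 * n)), "rs005"] <- NA
  hwe_bad <- c("rs006", "rs007")
  g[, "rs006"] <- rep(c(0, 2), length.out = n)             # no hets
  g[, "rs007"] <- 1                                        # all hets
  enc$geno <- g

  qc <- qc_filter_snps(enc)
  planted <- c(low_maf, high_miss, hwe_bad)
  expect_setequal(unique(qc$report$id), planted)
  expect_setequal(qc$report$id[qc$report$reason == "low_maf"], low_maf)
  expect_setequal(qc$report$id[qc$report$reason == "high_missing"],
                  high_miss)
  expect_setequal(qc$report$id[qc$report$reason == "hwe_fail"], hwe_bad)
  expect_equal(ncol(qc$snps$geno), 100 - 7)

  # a clean common SNP is retained
  expect_true("rs050" %in% qc$snps$markers$id)
})

test_that("exact HWE test matches the chi-square asymptotics on a large balanced fixture", {
  # 300 individuals at perfect HWE proportions, p = 0.5
  g <- c(rep(0, 75), rep(1, 150), rep(2, 75))
  p_exact <- hlaimpute:::hwe_exact_p(75, 150, 75)
  expect_gt(p_exact, 0.9)
  # gross het deficit is detected
  expect_lt(hlaimpute:::hwe_exact_p(150, 0, 150), 1e-20)
})

test_that("rare-marker pruning uses the chromosome-count frequency", {
  n <- 5225  # 10450 chromosomes
  geno <- matrix(0, n, 3,
                 dimnames = list(sprintf("i%04d", 1:n), c("a", "b", "c")))
  geno[1, "a"] <- 1             # 1/10450 < 0.01%
  geno[, "b"] <- 1              # freq 0.5
  # "c" all absent
  enc <- snp_encoding(geno, c(29.5e6, 29.6e6, 29.7e6),
                      c("A", "A", "A"), c("G", "G", "G"))
  pruned <- prune_rare_markers(enc)
  expect_setequal(pruned$markers$id, "b")
  expect_setequal(attr(pruned, "pruned"), c("a", "c"))
})

test_that("QC is order-independent", {
  enc <- make_snp_fixture(seed = 77)
  g <- enc$geno
  g[, "rs010"] <- 0; g[1, "rs010"] <- 1
  g[seq_len(20), "rs011"] <- NA
  enc$geno <- g
  full <- qc_filter_snps(enc)
  # apply single filters in both orders
  a <- qc_filter_snps(qc_filter_snps(enc, maf = 0, hwe_p = 0)$snps,
                      missing = 1, hwe_p = 0)
  b <- qc_filter_snps(qc_filter_snps(enc, missing = 1, hwe_p = 0)$snps,
                      maf = 0, hwe_p = 0)
  expect_setequal(a$snps$markers$id, b$snps$markers$id)
})

test_that("merge_and_order sorts by position and rejects duplicates", {
  typ <- tiny_typings()
  hla <- encode_classical_alleles(typ, 4)
  n <- nrow(hla$geno)
  geno <- matrix(rbinom(n * 4, 2, 0.5), n,
                 dimnames = list(rownames(hla$geno), sprintf("rs%d", 1:4)))
  snps <- snp_encoding(geno, c(33e6, 29.2e6, 31.4e6, 30e6),
                       rep("A", 4), rep("C", 4))
  merged <- merge_and_order(snps, hla)
  expect_false(is.unsorted(merged$markers$pos))
  expect_equal(colnames(merged$geno), merged$markers$id)

  dup <- snps
  dup$markers$id[2] <- "rs1"
  colnames(dup$geno)[2] <- "rs1"
  expect_error(merge_and_order(dup, hla), "duplicate")
})

test_that("homozygous individuals phase trivially", {
  typ <- hla_typing(c("h1", "h2"), "A",
                    c("A*0101", "A*0301"), c("A*0101", "A*0301"))
  enc <- encode_classical_alleles(typ, 4)
  n <- 2
  geno <- matrix(c(0, 2, 2, 0), n,
                 dimnames = list(c("h1", "h2"), c("rs1", "rs2")))
  snps <- snp_encoding(geno, c(29.5e6, 30.5e6), c("A", "A"), c("C", "C"))
  merged <- merge_and_order(snps, enc)
  panel <- phase_panel(merged, hmm_params(seed = 1))
  # phase of an everywhere-homozygous individual is the trivial duplication
  expect_equal(unname(panel$haps),
               unname(merged$geno[rep(1:2, each = 2), ] / 2))
})

test_that("phasing recovers known haplotypes without recombination", {
  # 4 founder haplotypes, individuals are founder pairs, no recombination
  set.seed(5)
  M <- 40
  founders <- matrix(rbinom(4 * M, 1, 0.5), 4, M)
  pairs <- rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4), c(1, 4), c(2, 3),
                 c(1, 2), c(3, 4))
  geno <- founders[pairs[, 1], ] + founders[pairs[, 2], ]
  rownames(geno) <- sprintf("d%d", seq_len(nrow(pairs)))
  colnames(geno) <- sprintf("rs%02d", seq_len(M))
  snps <- snp_encoding(geno, sort(sample(seq(29.1e6, 33.9e6), M)),
                       rep("A", M), rep("C", M))
  # the generative truth has no recombination, so phase under a
  # correspondingly flat map
  panel <- phase_panel(snps, hmm_params(seed = 3, iterations = 10,
                                        cm_per_mb = 0.01))
  # each recovered haplotype pair matches the truth up to a swap
  for (i in seq_len(nrow(pairs))) {
    got <- panel$haps[c(2 * i - 1, 2 * i), ]
    tru <- founders[pairs[i, ], ]
    direct <- all(got == tru)
    swapped <- all(got == tru[2:1, ])
    expect_true(direct || swapped)
  }
})

test_that("a phased panel is a fixed point of phasing", {
  sim <- small_sim(seed = 17, K = 40, n_target = 2, M = 60)
  expect_identical(phase_panel(sim$panel), sim$panel)
})

test_that("phased haplotypes are one-hot per gene and per AA position", {
  sim <- small_sim(seed = 19, K = 50, n_target = 2, M = 80)
  panel <- sim$panel
  mk <- panel$markers
  for (g in unique(mk$gene[mk$kind == "HLA4"])) {
    s4 <- rowSums(panel$haps[, mk$id[mk$kind == "HLA4" & mk$gene == g],
                             drop = FALSE])
    expect_true(all(s4 == 1))
  }
  aa <- mk[mk$kind == "AA", ]
  for (k in unique(paste(aa$gene, aa$aa_pos))) {
    cols <- aa$id[paste(aa$gene, aa$aa_pos) == k]
    expect_true(all(rowSums(panel$haps[, cols, drop = FALSE]) == 1))
  }

  # phasing an unphased genotype version restores one-hot exactly
  enc <- list(markers = mk, geno = sim$panel$haps[c(TRUE, FALSE), ] +
                sim$panel$haps[c(FALSE, TRUE), ])
  rownames(enc$geno) <- sim$panel$ids
  class(enc) <- "hla_encoding"
  rp <- phase_panel(enc, hmm_params(seed = 7, iterations = 3))
  for (g in unique(mk$gene[mk$kind == "HLA4"])) {
    s4 <- rowSums(rp$haps[, mk$id[mk$kind == "HLA4" & mk$gene == g],
                          drop = FALSE])
    expect_true(all(s4 == 1))
  }
})

test_that("individuals with excessive missingness are excluded", {
  enc <- make_snp_fixture(n = 8, m = 30, seed = 41)
  enc$geno[1, seq_len(20)] <- NA
  expect_warning(panel <- phase_panel(enc, hmm_params(seed = 2,
                                                      iterations = 2)),
                 "excluding")
  expect_equal(nrow(panel$haps), 14)
})
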