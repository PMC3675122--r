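test_that("classical-allele encoding counts alleles and conserves dosage", {
  typ <- tiny_typings()
  enc <- encode_classical_alleles(typ, resolution = 4)

  # individual typed A*0101/A*0301 has dosage 1 at each of the two markers
  expect_equal(unname(enc$geno["i01", "HLA_A_0101"]), 1)
  expect_equal(unname(enc$geno["i01", "HLA_A_0301"]), 1)
  expect_equal(unname(enc$geno["i02", "HLA_A_0101"]), 2)
  expect_equal(unname(enc$geno["i02", "HLA_A_0301"]), 0)

  # one marker per distinct allele observed
  expect_setequal(enc$markers$id[enc$markers$gene == "A"],
                  c("HLA_A_0101", "HLA_A_0301"))
  expect_setequal(enc$markers$id[enc$markers$gene == "B"],
                  c("HLA_B_0702", "HLA_B_0801", "HLA_B_4402"))

  # per-gene dosages sum to exactly 2 for every fully typed individual
  for (g in c("A", "B")) {
    sums <- rowSums(enc$geno[, enc$markers$id[enc$markers$gene == g],
                             drop = FALSE])
    expect_true(all(sums == 2))
  }

  # marker frequencies equal hand-tallied counts / 20 chromosomes
  counts_a0101 <- sum(c(typ$allele1[typ$gene == "A"],
                        typ$allele2[typ$gene == "A"]) == "A*0101")
  expect_equal(unname(enc$markers$freq[enc$markers$id == "HLA_A_0101"]),
               counts_a0101 / 20)
})

test_that("encoding is invertible at 4-digit resolution", {
  typ <- tiny_typings()
  enc <- encode_classical_alleles(typ, 4)
  for (g in c("A", "B")) {
    mk <- enc$markers[enc$markers$gene == g, ]
    labs <- vapply(mk$carriers, `[`, "", 1L)
    for (id in rownames(enc$geno)) {
      got <- sort(rep(labs, enc$geno[id, mk$id]))
      tr <- typ[typ$id == id & typ$gene == g, ]
      expect_equal(got, sort(c(tr$allele1, tr$allele2)))
    }
  }
})

test_that("label errors and gene mixing are rejected", {
  expect_error(parse_hla_allele("A-0101"), "unparseable")
  expect_error(hla_typing("x", "A", "B*0702", "A*0101"), "wrong gene")
  expect_error(parse_hla_allele("B*0702", gene = "A"), "do not match")
})

test_that("partial typings follow the missing/drop policies", {
  typ <- rbind(tiny_typings(),
               hla_typing("i11", "A", "A*01", "A*0301"))  # 2-digit call
  enc_m <- encode_classical_alleles(typ, 4, partial = "missing")
  expect_true(all(is.na(enc_m$geno["i11",
                                   enc_m$markers$id[enc_m$markers$gene == "A"]])))
  enc_d <- encode_classical_alleles(typ, 4, partial = "drop")
  expect_false("i11" %in% rownames(enc_d$geno))
  # the 2-digit call still contributes at 2-digit resolution
  enc2 <- encode_classical_alleles(typ, 2)
  expect_equal(unname(enc2$geno["i11", "HLA_A_01"]), 1)
})

test_that("resolution reduction keeps the first field and is idempotent", {
  expect_equal(as.character(reduce_resolution("B*0702")), "B*07")
  expect_equal(as.character(reduce_resolution("DRB1*0401")), "DRB1*04")
  batch <- sprintf("A*%02d%02d", rep(1:10, 5), rep(1:5, each = 10))
  once <- reduce_resolution(batch)
  expect_length(once, 50)
  twice <- reduce_resolution(as.character(once))
  expect_equal(as.character(twice), as.character(once))
  expect_true(all(attr(twice, "already_2digit")))
  expect_false(any(attr(reduce_resolution(batch), "already_2digit")))
})

test_that("amino-acid encoding emits one marker per residue at polymorphic positions", {
  seqs <- tiny_sequences()
  typ <- hla_typing(c("p1", "p2", "p3"), "A",
                    c("A*0101", "A*0102", "A*2501"),
                    c("A*0201", "A*0301", "A*2501"))
  enc <- encode_amino_acids(seqs, typ)
  mk <- enc$markers

  # position 3 has residues {D, A} -> 2 markers; an individual with one
  # D-allele and one A-allele has dosage (1, 1)
  m3 <- mk$id[mk$aa_pos == 3]
  expect_length(m3, 2)
  expect_equal(sort(unname(enc$geno["p1", m3])), c(1, 1))

  # position 7 has three residues among observed alleles -> 3 markers
  expect_length(mk$id[mk$aa_pos == 7], 3)

  # deletion columns make positions 12/13 polymorphic (residue + gap)
  expect_setequal(sub(".*_", "", mk$id[mk$aa_pos == 12]), c("A", "del"))

  # monomorphic positions emit nothing
  expect_false(any(mk$aa_pos %in% c(1, 2, 4, 5)))

  # per position, residue dosages sum to 2
  for (p in unique(mk$aa_pos)) {
    expect_true(all(rowSums(enc$geno[, mk$id[mk$aa_pos == p],
                                     drop = FALSE]) == 2))
  }
})

test_that("planted polymorphisms give exactly the expected AA marker count", {
  seqs <- tiny_sequences()
  # all five alleles observed -> pos 3 (2) + pos 7 (3) + pos 12 (2) +
  # pos 13 (2) = 9 markers
  typ <- hla_typing(sprintf("q%d", 1:5), "A",
                    c("A*0101", "A*0102", "A*0201", "A*0301", "A*2501"),
                    c("A*0101", "A*0102", "A*0201", "A*0301", "A*2501"))
  enc <- encode_amino_acids(seqs, typ)
  expect_equal(nrow(enc$markers), 9)
})

test_that("AA dosages are a linear image of the 4-digit allele dosages", {
  seqs <- tiny_sequences()
  typ <- hla_typing(sprintf("q%d", 1:6), "A",
                    c("A*0101", "A*0102", "A*0201", "A*0301", "A*2501",
                      "A*0101"),
                    c("A*0201", "A*0301", "A*2501", "A*0101", "A*0102",
                      "A*0101"))
  enc4 <- encode_classical_alleles(typ, 4)
  aa <- encode_amino_acids(seqs, typ)
  labs <- vapply(enc4$markers$carriers, `[`, "", 1L)
  L <- vapply(aa$markers$carriers, function(cc) as.numeric(labs %in% cc),
              numeric(length(labs)))
  expect_equal(unname(aa$geno), unname(enc4$geno %*% L))
})

test_that("sequence-table errors name the offending allele", {
  expect_error(hla_sequences("A", c("A*0101", "A*0201"), c("MGSH", "MGS")),
               "A\\*0201")
  expect_error(hla_sequences("A", "A*0101", "MG#H"), "alphabet")
  seqs <- tiny_sequences()
  typ <- hla_typing("z", "A", "A*9901", "A*0101")
  expect_error(encode_amino_acids(seqs, typ), "A\\*9901")
})

test_that("indel encoding keys on gap runs", {
  seqs <- tiny_sequences()
  typ5 <- hla_typing(sprintf("q%d", 1:5), "A",
                     c("A*0101", "A*0102", "A*0201", "A*0301", "A*2501"),
                     c("A*0101", "A*0102", "A*0201", "A*0301", "A*2501"))
  enc <- encode_indels(seqs, typ5)
  # one allele with one 2-residue deletion run -> exactly 1 INDEL marker
  expect_equal(nrow(enc$markers), 1)
  expect_equal(enc$markers$kind, "INDEL")
  expect_equal(enc$markers$aa_pos, 12)
  expect_equal(unname(enc$geno[, 1]), c(0, 0, 0, 0, 2))

  # gene without gaps -> 0 INDEL markers
  typ_nogap <- hla_typing("q1", "A", "A*0101", "A*0201")
  enc0 <- encode_indels(seqs, typ_nogap)
  expect_equal(nrow(enc0$markers), 0)
})

test_that("AA and INDEL marker classes are distinguished in summaries", {
  seqs <- tiny_sequences()
  typ <- hla_typing(sprintf("q%d", 1:5), "A",
                    c("A*0101", "A*0102", "A*0201", "A*0301", "A*2501"),
                    c("A*0101", "A*0102", "A*0201", "A*0301", "A*2501"))
  merged <- merge_and_order(encode_amino_acids(seqs, typ),
                            encode_indels(seqs, typ))
  expect_setequal(unique(merged$markers$kind), c("AA", "INDEL"))
  expect_equal(sum(merged$markers$kind == "INDEL"), 1)
})

test_that("typing and sequence files round-trip", {
  typ <- tiny_typings()
  tf <- tempfile(fileext = ".tsv")
  write_typings(typ, tf)
  back <- read_typing_file(tf)
  key <- function(x) x[order(x$gene, x$id), c("id", "gene", "allele1", "allele2")]
  expect_equal(key(as.data.frame(back)), key(as.data.frame(typ)),
               ignore_attr = TRUE)

  seqs <- tiny_sequences()
  sf <- tempfile(fileext = ".tsv")
  write_sequences(seqs, sf)
  back_s <- read_sequence_file(sf)
  expect_equal(back_s$seq, seqs$seq)
})
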