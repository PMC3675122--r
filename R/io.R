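## Readers and writers: PLINK bed/bim/fam, Beagle-style phased text,
## marker tables, dosage text and dosage VCF.

#' Read a PLINK binary genotype trio (.bed/.bim/.fam)
#'
#' Decodes the SNP-major binary format bit-exactly: after the magic
#' bytes 0x6c 0x1b and mode byte 0x01, each SNP occupies
#' `ceiling(N/4)` bytes, two bits per individual, little-endian within
#' the byte: 00 = homozygous A1, 01 = missing, 10 = heterozygous,
#' 11 = homozygous A2.  Genotypes are returned as counts of the A1
#' allele (PLINK's counted allele).
#'
#' @param prefix Path prefix, or explicit `bed`, `bim`, `fam` paths.
#' @param bed,bim,fam Optional explicit file paths.
#' @return List: `geno` (individuals x SNPs, counts of A1, NA missing),
#'   `markers` (data frame `id`, `chrom`, `pos`, `counted` = A1,
#'   `other` = A2), `fam` (data frame).
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
  }
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pat", "mat",
                                            "sex", "pheno"))
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos",
                                            "a1", "a2"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("bad magic bytes in ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed supported: ", bed)
  bps <- ceiling(n / 4)  # bytes per SNP block
  if (length(raw) - 3 != bps * m) {
    stop("truncated .bed block in ", bed, ": expected ", bps * m,
         " data bytes, found ", length(raw) - 3,
         " (at byte offset ", length(raw), ")")
  }
  body <- as.integer(raw[-(1:3)])
  ## expand each byte into 4 two-bit codes (little-endian)
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  dim(codes) <- c(4L * bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  ## 00->2 copies of A1, 10->1, 11->0, 01->missing
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  geno <- matrix(lut[codes + 1L], n, m,
                 dimnames = list(fam_df$iid, bim_df$id))
  list(geno = geno,
       markers = data.frame(id = bim_df$id, chrom = bim_df$chrom,
                            pos = bim_df$pos, counted = bim_df$a1,
                            other = bim_df$a2, stringsAsFactors = FALSE),
       fam = fam_df)
}

#' Write a PLINK binary genotype trio
#'
#' @param prefix Output path prefix.
#' @param geno Individuals x SNPs matrix of A1-allele counts (0/1/2/NA).
#' @param markers Data frame `id`, `pos`, `counted`, `other` (and
#'   optional `chrom`, default 6).
#' @param fam Optional fam data frame (`fid`, `iid`, `pat`, `mat`,
#'   `sex`, `pheno`); defaults built from row names.
#' @return Invisibly, the prefix.
#' @export
write_plink <- function(prefix, geno, markers, fam = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(fam)) {
    fam <- data.frame(fid = rownames(geno), iid = rownames(geno),
                      pat = 0, mat = 0, sex = 0, pheno = -9)
  }
  if (nrow(fam) != n) stop("fam/bed individual-count mismatch")
  chrom <- if ("chrom" %in% colnames(markers)) markers$chrom else 6
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom, markers$id, 0, markers$pos,
                    markers$counted, markers$other)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # NA -> 1
  bps <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    g <- geno[, j]
    cd <- ifelse(is.na(g), 1L, code_of[as.character(g)])
    cd <- c(cd, rep(0L, 4 * bps - n))
    byte <- cd[c(TRUE, FALSE, FALSE, FALSE)] +
      4L * cd[c(FALSE, TRUE, FALSE, FALSE)] +
      16L * cd[c(FALSE, FALSE, TRUE, FALSE)] +
      64L * cd[c(FALSE, FALSE, FALSE, TRUE)]
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Write phased haplotypes as Beagle-style phased text
#'
#' First line `I id` followed by each individual id twice; one line per
#' marker: `M <marker id>` followed by the two haplotype allele codes of
#' each individual (the presence/absence or ACGT labels).
#'
#' @param panel A [ref_panel()], or a list with `haps`, `markers`,
#'   `ids`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_phased <- function(panel, path) {
  mk <- panel$markers
  ids2 <- rep(panel$ids, each = 2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("I", "id", ids2), collapse = " "), con)
  code <- function(j) {
    ifelse(panel$haps[, j] == 1, mk$allele_present[j], mk$allele_absent[j])
  }
  lines <- vapply(seq_len(nrow(mk)), function(j) {
    paste(c("M", mk$id[j], code(j)), collapse = " ")
  }, "")
  writeLines(lines, con)
  invisible(path)
}

#' Write a marker metadata table (tab-separated)
#' @param markers Marker data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_markers <- function(markers, path) {
  mk <- markers
  mk$carriers <- vapply(mk$carriers, paste, "", collapse = ",")
  utils::write.table(mk, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a marker metadata table written by [write_markers()]
#' @param path File path.
#' @return Marker data frame with the `carriers` list column restored.
#' @export
read_markers <- function(path) {
  mk <- utils::read.delim(path, stringsAsFactors = FALSE)
  mk$carriers <- I(lapply(strsplit(as.character(mk$carriers), ","),
                          function(x) x[x != "" & !is.na(x)]))
  mk$gene[is.na(mk$gene)] <- ""
  mk
}

#' Read Beagle-style phased text back into a haplotype matrix
#'
#' @param path Phased text file (see [write_phased()]).
#' @param markers Marker table giving the allele codes per marker.
#' @return List: `haps` (2N x M binary matrix), `ids`.
#' @export
read_phased <- function(path, markers) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  ids <- unique(hdr[-(1:2)])
  body <- strsplit(lines[-1], " ")
  M <- length(body)
  haps <- matrix(0L, length(hdr) - 2, M)
  mids <- character(M)
  for (j in seq_len(M)) {
    f <- body[[j]]
    mids[j] <- f[2]
    k <- match(f[2], markers$id)
    if (is.na(k)) stop("marker not in table: ", f[2])
    haps[, j] <- as.integer(f[-(1:2)] == markers$allele_present[k])
  }
  colnames(haps) <- mids
  rownames(haps) <- paste0(rep(ids, each = 2), c(".1", ".2"))
  list(haps = haps, ids = ids)
}

#' Write a reference panel (phased text + marker table)
#' @param panel A [ref_panel()].
#' @param prefix Output prefix (`<prefix>.phased`, `<prefix>.markers`).
#' @return Invisibly, `prefix`.
#' @export
write_panel <- function(panel, prefix) {
  write_phased(panel, paste0(prefix, ".phased"))
  write_markers(panel$markers, paste0(prefix, ".markers"))
  writeLines(paste(panel$window, collapse = "\t"),
             paste0(prefix, ".window"))
  invisible(prefix)
}

#' Read a reference panel written by [write_panel()]
#' @param prefix Input prefix.
#' @return A [ref_panel()].
#' @export
read_panel <- function(prefix) {
  mk <- read_markers(paste0(prefix, ".markers"))
  ph <- read_phased(paste0(prefix, ".phased"), mk)
  window <- as.numeric(strsplit(readLines(paste0(prefix, ".window")),
                                "\t")[[1]])
  ref_panel(ph$haps, mk, ph$ids, window = window)
}

#' Write imputation results as a dosage VCF (DS and GP FORMAT fields)
#'
#' Encoded markers are emitted as biallelic records with symbolic
#' alleles (`P` presence / `A` absence) and the marker id in ID; `DS` is
#' the posterior dosage of the alternate (presence) allele and `GP` the
#' genotype posterior triple, so `DS = GP[2] + 2 GP[3]` in every record.
#'
#' @param result An `hla_dosage`.
#' @param path Output `.vcf` path (uncompressed).
#' @param chrom Chromosome label (default `"6"`).
#' @return Invisibly, `path`.
#' @export
write_dosage_vcf <- function(result, path, chrom = "6") {
  mk <- result$markers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hlaimpute",
    paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
           "Description=\"Best-guess genotype\">"),
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"estimated alternate allele dosage\">"),
    paste0("##FORMAT=<ID=GP,Number=3,Type=Float,",
           "Description=\"Genotype posterior probabilities\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", result$ids), collapse = "\t")), con)
  bg <- best_guess(result)$calls
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  fmt <- function(x) formatC(x, digits = 4, format = "f")
  for (j in seq_len(nrow(mk))) {
    is_snp <- mk$kind[j] == "SNP"
    ref <- if (is_snp) mk$allele_absent[j] else "A"
    alt <- if (is_snp) mk$allele_present[j] else "P"
    cells <- paste0(gt_of[as.character(bg[, j])], ":",
                    fmt(result$dosage[, j]), ":",
                    fmt(result$P0[, j]), ",", fmt(result$P1[, j]), ",",
                    fmt(result$P2[, j]))
    writeLines(paste(c(chrom, mk$pos[j], mk$id[j], ref, alt, ".", "PASS",
                       ".", "GT:DS:GP", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a tab-separated dosage table
#'
#' Columns: marker id, presence and absence allele labels, then one
#' dosage column per individual.
#'
#' @param result An `hla_dosage`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dosage <- function(result, path) {
  mk <- result$markers
  tab <- data.frame(marker = mk$id, alleleP = mk$allele_present,
                    alleleA = mk$allele_absent,
                    t(result$dosage), check.names = FALSE)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}
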