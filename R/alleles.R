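#' @useDynLib hlaimpute, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

#' HLA genes handled by the toolkit
#'
#' Class I (A, B, C) and class II (DPA1, DPB1, DQA1, DQB1, DRB1) loci.
#' @export
HLA_GENES <- c("A", "B", "C", "DPA1", "DPB1", "DQA1", "DQB1", "DRB1")

#' Default genomic anchor coordinates (bp, chr6) for the HLA genes
#'
#' Encoded markers of a gene are placed at the gene anchor; amino-acid
#' markers add a 3 bp-per-residue codon offset so that the haplotype model
#' sees a total genomic order.  Coordinates are treated as pure positions
#' within the configured MHC window; the genome build is metadata only.
#'
#' @return Named integer vector of base-pair positions.
#' @export
hla_gene_coords <- function() {
  c(A = 29910247L, C = 31236526L, B = 31321649L,
    DRB1 = 32546547L, DQA1 = 32605183L, DQB1 = 32627241L,
    DPA1 = 33036427L, DPB1 = 33043703L)
}

#' Parse classical HLA allele labels
#'
#' Labels follow the `GENE*digits` convention, e.g. `"A*0101"` (4-digit)
#' or `"A*01"` (2-digit).
#'
#' @param allele Character vector of allele labels (NA allowed).
#' @param gene Optional expected gene; labels from a different gene raise
#'   an error.
#' @return Data frame with columns `gene`, `digits`, `resolution`
#'   (2 or 4, NA for missing calls).
#' @export
parse_hla_allele <- function(allele, gene = NULL) {
  allele <- as.character(allele)
  ok <- is.na(allele) | grepl("^[A-Z][A-Z0-9]*\\*[0-9]{2}([0-9]{2})?$", allele)
  if (any(!ok)) {
    stop("unparseable HLA allele label(s): ",
         paste(unique(allele[!ok]), collapse = ", "))
  }
  g <- sub("\\*.*$", "", allele)
  d <- sub("^.*\\*", "", allele)
  g[is.na(allele)] <- NA_character_
  d[is.na(allele)] <- NA_character_
  if (!is.null(gene)) {
    bad <- !is.na(g) & g != gene
    if (any(bad)) {
      stop("allele label(s) do not match gene ", gene, ": ",
           paste(unique(allele[bad]), collapse = ", "))
    }
  }
  data.frame(gene = g, digits = d,
             resolution = ifelse(is.na(d), NA_integer_, nchar(d)),
             stringsAsFactors = FALSE)
}

#' Reduce a 4-digit classical allele label to 2-digit resolution
#'
#' The first allele field (the allele family) is retained; labels already
#' at 2-digit resolution are returned unchanged.  Deterministic and
#' idempotent.
#'
#' @param allele Character vector of allele labels.
#' @return Character vector of 2-digit labels with a logical attribute
#'   `already_2digit` flagging inputs that were not reduced.
#' @export
reduce_resolution <- function(allele) {
  p <- parse_hla_allele(allele)
  out <- ifelse(is.na(p$digits), NA_character_,
                paste0(p$gene, "*", substr(p$digits, 1L, 2L)))
  attr(out, "already_2digit") <- !is.na(p$resolution) & p$resolution == 2L
  out
}

#' Construct a table of classical HLA typings
#'
#' One row per individual per gene, with the two classical allele calls at
#' 2- or 4-digit resolution.  Missing calls are `NA`.
#'
#' @param id Individual identifiers.
#' @param gene HLA gene of each row (one of [HLA_GENES]).
#' @param allele1,allele2 Classical allele labels (e.g. `"A*0101"`) or NA.
#' @return Data frame of class `hla_typing` with per-allele resolution
#'   columns `res1`, `res2`.
#' @export
hla_typing <- function(id, gene, allele1, allele2) {
  gene <- as.character(gene)
  if (!all(gene %in% HLA_GENES)) {
    stop("unknown HLA gene(s): ",
         paste(setdiff(unique(gene), HLA_GENES), collapse = ", "))
  }
  p1 <- parse_hla_allele(allele1)
  p2 <- parse_hla_allele(allele2)
  for (p in list(p1, p2)) {
    bad <- !is.na(p$gene) & p$gene != gene
    if (any(bad)) {
      stop("allele label(s) under the wrong gene: ",
           paste(unique(paste0(p$gene[bad], " vs ", gene[bad])), collapse = ", "))
    }
  }
  out <- data.frame(id = as.character(id), gene = gene,
                    allele1 = as.character(allele1),
                    allele2 = as.character(allele2),
                    res1 = p1$resolution, res2 = p2$resolution,
                    stringsAsFactors = FALSE)
  class(out) <- c("hla_typing", "data.frame")
  out
}

#' Read a tab-separated classical typing file
#'
#' Expected layout: one row per individual, first column the individual
#' id, then two columns per gene named `<gene>.1` and `<gene>.2` (a
#' ped-like layout).  Missing calls may be `NA`, `0`, `-` or empty.
#'
#' @param path Path to the file.
#' @return An [hla_typing] table.
#' @export
read_typing_file <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- colnames(tab)
  genes <- unique(sub("\\.[12]$", "", cn[grepl("\\.[12]$", cn)]))
  genes <- intersect(HLA_GENES, genes)
  if (!length(genes)) stop("no <gene>.1/<gene>.2 columns found in ", path)
  rows <- lapply(genes, function(g) {
    a1 <- as.character(tab[[paste0(g, ".1")]])
    a2 <- as.character(tab[[paste0(g, ".2")]])
    a1[a1 %in% c("", "0", "-", "NA")] <- NA
    a2[a2 %in% c("", "0", "-", "NA")] <- NA
    hla_typing(tab[[1L]], g, a1, a2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hla_typing", "data.frame")
  out
}

#' Read a tab-separated allele-sequence table
#'
#' Columns: `gene`, `allele` (4-digit label), `seq` (aligned residue
#' string over the amino-acid alphabet, gap `-`, termination `*`).
#'
#' @param path Path to the file.
#' @param aa_start Named integer vector giving, per gene, the
#'   mature-protein position of the first alignment column (may be
#'   negative for the leader peptide; position 0 does not exist).
#' @return Data frame of class `hla_sequences`.
#' @export
read_sequence_file <- function(path, aa_start = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "allele", "seq") %in% colnames(tab)))
  hla_sequences(tab$gene, tab$allele, tab$seq, aa_start = aa_start)
}

#' Construct an aligned allele-sequence table
#'
#' @param gene,allele,seq Vectors: HLA gene, 4-digit allele label, aligned
#'   residue string (one shared alignment frame per gene).
#' @inheritParams read_sequence_file
#' @return Data frame of class `hla_sequences` with attribute `aa_start`.
#' @export
hla_sequences <- function(gene, allele, seq, aa_start = NULL) {
  p <- parse_hla_allele(allele, gene = NULL)
  if (any(p$gene != gene, na.rm = TRUE)) {
    stop("sequence table allele labels do not match their gene column")
  }
  seq <- toupper(as.character(seq))
  bad <- grepl(sprintf("[^%s*-]", "ACDEFGHIKLMNPQRSTVWYX"), seq)
  if (any(bad)) {
    stop("residue symbol outside alphabet in allele(s): ",
         paste(allele[bad], collapse = ", "))
  }
  out <- data.frame(gene = as.character(gene), allele = as.character(allele),
                    seq = seq, stringsAsFactors = FALSE)
  for (g in unique(out$gene)) {
    len <- unique(nchar(out$seq[out$gene == g]))
    if (length(len) != 1L) {
      off <- out[out$gene == g, ]
      ref_len <- nchar(off$seq[1L])
      bad_a <- off$allele[nchar(off$seq) != ref_len]
      stop("aligned sequence length mismatch within gene ", g,
           " for allele(s): ", paste(bad_a, collapse = ", "))
    }
  }
  if (is.null(aa_start)) aa_start <- setNames(rep(1L, length(unique(out$gene))),
                                              unique(out$gene))
  attr(out, "aa_start") <- aa_start
  class(out) <- c("hla_sequences", "data.frame")
  out
}

#' Map alignment columns to mature-protein amino-acid positions
#'
#' Positions run from `start` (which may be negative for leader-peptide
#' residues) and skip 0, following standard protein numbering.
#'
#' @param start Position of the first alignment column.
#' @param len Number of alignment columns.
#' @return Integer vector of length `len`.
#' @export
aa_positions <- function(start, len) {
  pos <- seq(from = start, length.out = len + (start <= 0L))
  pos <- pos[pos != 0L]
  pos[seq_len(len)]
}
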