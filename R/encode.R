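## Binary-marker encoding of classical HLA alleles, amino acid residues
## and intragenic indels.  Every encoded variant becomes one
## presence/absence marker so that multi-allelic variation can be phased,
## imputed and tested with the same machinery as biallelic SNPs.

marker_frame <- function(id, kind, gene, pos, present = "P", absent = "A",
                         freq = NA_real_, carriers = NULL) {
  if (!length(id)) {
    kind <- gene <- present <- absent <- character(0)
    pos <- integer(0); freq <- numeric(0)
  }
  df <- data.frame(id = id, kind = kind, gene = gene, pos = as.integer(pos),
                   allele_present = present, allele_absent = absent,
                   freq = freq, stringsAsFactors = FALSE)
  if (is.null(carriers)) carriers <- replicate(nrow(df), character(0), simplify = FALSE)
  df$carriers <- I(carriers)
  df
}

presence_freq <- function(geno) {
  colSums(geno, na.rm = TRUE) / (2 * colSums(!is.na(geno)))
}

new_encoding <- function(markers, geno) {
  stopifnot(identical(markers$id,
                      if (is.null(colnames(geno))) character(0)
                      else colnames(geno)))
  markers$freq <- unname(presence_freq(geno))
  out <- list(markers = markers, geno = geno)
  class(out) <- "hla_encoding"
  out
}

#' @export
print.hla_encoding <- function(x, ...) {
  cat("hla_encoding:", nrow(x$markers), "binary markers x",
      nrow(x$geno), "individuals\n")
  print(table(x$markers$kind))
  invisible(x)
}

#' Encode classical HLA alleles as binary presence/absence markers
#'
#' One marker per distinct allele label observed at the requested
#' resolution; an individual's genotype at a marker is the count (0/1/2)
#' of that allele among their two calls.  Within each gene the counts of
#' a fully typed individual sum to exactly 2.
#'
#' @param typings An [hla_typing] table.
#' @param resolution 2 or 4 (digit resolution of the markers).
#' @param partial How to handle individuals whose typing cannot be fully
#'   resolved at `resolution` (e.g. a 2-digit-only call when building
#'   4-digit markers): `"missing"` sets all of that gene's markers to NA
#'   for the individual, `"drop"` removes the individual from the table.
#' @param coords Named vector of per-gene anchor positions
#'   (default [hla_gene_coords()]).
#' @return An object of class `hla_encoding`: a list with `markers`
#'   (marker metadata, ids `HLA_<gene>_<digits>`) and `geno`
#'   (individual x marker dosage matrix).
#' @export
encode_classical_alleles <- function(typings, resolution = 4,
                                     partial = c("missing", "drop"),
                                     coords = hla_gene_coords()) {
  stopifnot(inherits(typings, "hla_typing"), nrow(typings) > 0,
            resolution %in% c(2, 4))
  partial <- match.arg(partial)
  ids <- unique(typings$id)
  genes <- intersect(HLA_GENES, unique(typings$gene))

  all_markers <- list(); geno_cols <- list()
  unresolved <- character(0)
  for (g in genes) {
    tg <- typings[typings$gene == g, , drop = FALSE]
    conv <- function(a, res) {
      if (resolution == 2) reduce_resolution(a)
      else ifelse(!is.na(res) & res == 4L, a, NA_character_)
    }
    a1 <- conv(tg$allele1, tg$res1)
    a2 <- conv(tg$allele2, tg$res2)
    partial_row <- (is.na(a1) & !is.na(tg$allele1)) |
                   (is.na(a2) & !is.na(tg$allele2))
    unresolved <- c(unresolved, tg$id[partial_row])
    labs <- sort(unique(stats::na.omit(c(a1, a2))))
    if (!length(labs)) next
    digs <- sub("^.*\\*", "", labs)
    mk <- marker_frame(id = paste0("HLA_", g, "_", digs),
                       kind = if (resolution == 4) "HLA4" else "HLA2",
                       gene = g, pos = coords[[g]],
                       carriers = as.list(labs))
    gm <- matrix(NA_real_, length(ids), length(labs),
                 dimnames = list(ids, mk$id))
    ridx <- match(tg$id, ids)
    for (j in seq_along(labs)) {
      cnt <- (!is.na(a1) & a1 == labs[j]) + (!is.na(a2) & a2 == labs[j])
      ## a half-typed individual still has unknown counts everywhere in
      ## the gene, handled below
      gm[ridx, j] <- cnt
    }
    bad <- ridx[partial_row | (is.na(a1) & is.na(a2))]
    if (length(bad)) gm[bad, ] <- NA_real_
    all_markers[[g]] <- mk
    geno_cols[[g]] <- gm
  }
  if (!length(all_markers)) stop("no callable alleles at the requested resolution")
  markers <- do.call(rbind, all_markers)
  rownames(markers) <- NULL
  geno <- do.call(cbind, geno_cols)
  if (partial == "drop" && length(unresolved)) {
    geno <- geno[!(rownames(geno) %in% unresolved), , drop = FALSE]
  }
  enc <- new_encoding(markers, geno)
  enc$unresolved <- unique(unresolved)
  enc
}

## residue symbol -> id-safe token
residue_token <- function(r) {
  r <- ifelse(r == "-", "del", ifelse(r == "*", "ter", r))
  r
}

aligned_residue_matrix <- function(sequences, gene, alleles) {
  sq <- sequences[sequences$gene == gene, , drop = FALSE]
  miss <- setdiff(alleles, sq$allele)
  if (length(miss)) {
    stop("no aligned sequence for typed allele(s): ",
         paste(miss, collapse = ", "))
  }
  sq <- sq[match(alleles, sq$allele), , drop = FALSE]
  do.call(rbind, strsplit(sq$seq, ""))
}

#' Encode polymorphic amino-acid positions as binary residue markers
#'
#' For every aligned position at which the observed alleles carry at
#' least two distinct symbols, one marker is emitted per symbol (a
#' position with three residues yields exactly three markers); gap and
#' termination symbols count as residues of the position so that an
#' individual's residue dosages at a position always sum to 2.
#' Monomorphic positions emit nothing.  An individual's dosage at a
#' residue marker is the number of their two classical alleles whose
#' sequence carries that residue.
#'
#' @param sequences An [hla_sequences] table covering every typed
#'   4-digit allele.
#' @param typings An [hla_typing] table (4-digit calls are used).
#' @inheritParams encode_classical_alleles
#' @return An `hla_encoding` with marker ids
#'   `AA_<gene>_<position>_<bp>_<residue>`; marker positions are the gene
#'   anchor plus 3 bp per alignment column (codon map).
#' @export
encode_amino_acids <- function(sequences, typings,
                               partial = c("missing", "drop"),
                               coords = hla_gene_coords()) {
  enc4 <- encode_classical_alleles(typings, resolution = 4, partial = partial,
                                   coords = coords)
  aa_start <- attr(sequences, "aa_start")
  genes <- intersect(unique(enc4$markers$gene), unique(sequences$gene))
  all_markers <- list(); geno_cols <- list()
  for (g in genes) {
    mk4 <- enc4$markers[enc4$markers$gene == g, , drop = FALSE]
    alleles <- vapply(mk4$carriers, `[`, "", 1L)
    res <- aligned_residue_matrix(sequences, g, alleles)  # alleles x columns
    start <- if (!is.null(aa_start) && g %in% names(aa_start)) aa_start[[g]] else 1L
    pos <- aa_positions(start, ncol(res))
    g4 <- enc4$geno[, mk4$id, drop = FALSE]
    for (j in seq_len(ncol(res))) {
      syms <- sort(unique(res[, j]))
      if (length(syms) < 2L) next
      bp <- coords[[g]] + 3L * (j - 1L)
      for (s in syms) {
        carry <- alleles[res[, j] == s]
        dos <- rowSums(g4[, mk4$id[res[, j] == s], drop = FALSE])
        mid <- paste0("AA_", g, "_", pos[j], "_", bp, "_", residue_token(s))
        all_markers[[mid]] <- marker_frame(mid, "AA", g, bp,
                                           carriers = list(carry))
        all_markers[[mid]]$aa_pos <- pos[j]
        geno_cols[[mid]] <- dos
      }
    }
  }
  if (!length(all_markers)) {
    markers <- marker_frame(character(0), character(0), character(0), integer(0))
    markers$aa_pos <- integer(0)
    return(new_encoding(markers, matrix(0, nrow(enc4$geno), 0,
                                        dimnames = list(rownames(enc4$geno), character(0)))))
  }
  markers <- do.call(rbind, all_markers)
  rownames(markers) <- NULL
  geno <- do.call(cbind, geno_cols)
  rownames(geno) <- rownames(enc4$geno)
  new_encoding(markers, geno)
}

#' Encode insertion/deletion/truncation events as binary markers
#'
#' Each distinct maximal run of gap (`-`) symbols, and each distinct
#' truncation (a termination `*` followed only by further alignment
#' columns), observed among the typed alleles of a gene is one binary
#' marker; an individual's dosage is the number of their two classical
#' alleles carrying that event.  Genes without gap or termination symbols
#' emit nothing.
#'
#' @inheritParams encode_amino_acids
#' @return An `hla_encoding` with marker ids `INDEL_<gene>_<position>_<bp>`
#'   (a length suffix disambiguates distinct events starting at the same
#'   position).
#' @export
encode_indels <- function(sequences, typings,
                          partial = c("missing", "drop"),
                          coords = hla_gene_coords()) {
  enc4 <- encode_classical_alleles(typings, resolution = 4, partial = partial,
                                   coords = coords)
  aa_start <- attr(sequences, "aa_start")
  genes <- intersect(unique(enc4$markers$gene), unique(sequences$gene))
  all_markers <- list(); geno_cols <- list()
  for (g in genes) {
    mk4 <- enc4$markers[enc4$markers$gene == g, , drop = FALSE]
    alleles <- vapply(mk4$carriers, `[`, "", 1L)
    res <- aligned_residue_matrix(sequences, g, alleles)
    start <- if (!is.null(aa_start) && g %in% names(aa_start)) aa_start[[g]] else 1L
    pos <- aa_positions(start, ncol(res))
    g4 <- enc4$geno[, mk4$id, drop = FALSE]
    ## event table: one row per (allele, start column, length, type)
    events <- list()
    for (i in seq_along(alleles)) {
      r <- rle(res[i, ] %in% c("-", "*"))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        type <- if (res[i, starts[k]] == "*") "ter" else "del"
        key <- paste(starts[k], r$lengths[k], type, sep = ":")
        events[[key]] <- c(events[[key]], alleles[i])
      }
    }
    if (!length(events)) next
    keys <- names(events)
    parts <- do.call(rbind, strsplit(keys, ":"))
    starts <- as.integer(parts[, 1L]); lens <- as.integer(parts[, 2L])
    ord <- order(starts, lens)
    for (k in ord) {
      j <- starts[k]
      bp <- coords[[g]] + 3L * (j - 1L)
      mid <- paste0("INDEL_", g, "_", pos[j], "_", bp)
      if (sum(starts == j) > 1L) mid <- paste0(mid, "_L", lens[k])
      carry <- events[[keys[k]]]
      dos <- rowSums(g4[, mk4$id[alleles %in% carry], drop = FALSE])
      all_markers[[mid]] <- marker_frame(mid, "INDEL", g, bp,
                                         carriers = list(carry))
      all_markers[[mid]]$aa_pos <- pos[j]
      geno_cols[[mid]] <- dos
    }
  }
  if (!length(all_markers)) {
    markers <- marker_frame(character(0), character(0), character(0), integer(0))
    markers$aa_pos <- integer(0)
    return(new_encoding(markers, matrix(0, nrow(enc4$geno), 0,
                                        dimnames = list(rownames(enc4$geno), character(0)))))
  }
  markers <- do.call(rbind, all_markers)
  rownames(markers) <- NULL
  geno <- do.call(cbind, geno_cols)
  rownames(geno) <- rownames(enc4$geno)
  new_encoding(markers, geno)
}
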