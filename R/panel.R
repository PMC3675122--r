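## Reference-panel construction: SNP QC, rare-marker pruning, merging of
## SNPs with encoded HLA/amino-acid/indel markers, and phasing into
## reference haplotypes.

#' Wrap a SNP genotype matrix as an encoding object
#'
#' @param geno Individuals x SNPs matrix of counted-allele dosages
#'   (0/1/2/NA); column names are marker ids.
#' @param pos Base-pair positions.
#' @param counted,other Allele labels: `counted` is the allele whose
#'   copies the genotype counts (the "presence" allele of the binary
#'   marker), `other` the opposite allele.
#' @param gene Optional gene label per SNP (empty for plain SNPs).
#' @return An `hla_encoding` with marker kind `"SNP"`.
#' @export
snp_encoding <- function(geno, pos, counted, other, gene = "") {
  stopifnot(is.matrix(geno), length(pos) == ncol(geno))
  mk <- marker_frame(colnames(geno), "SNP", gene, pos,
                     present = counted, absent = other)
  new_encoding(mk, geno)
}

## Exact Hardy-Weinberg test (two-sided, mid-p off), conditioning on the
## observed allele counts; standard exact-distribution enumeration over
## heterozygote counts.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  het_obs <- n_ab
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  sum(p[p <= p[match(het_obs, hets)] * (1 + 1e-10)])
}

#' Quality-control filter for reference-panel SNPs
#'
#' Removes SNPs with minor allele frequency below `maf`, missing-genotype
#' proportion above `missing`, or exact Hardy-Weinberg equilibrium
#' p-value below `hwe_p`.  The three filters are evaluated on the input
#' table, so their application order cannot change the retained set.
#'
#' @param snps An `hla_encoding` of SNP genotypes ([snp_encoding()]).
#' @param maf MAF floor (default 0.01).
#' @param missing Missingness ceiling (default 0.05).
#' @param hwe_p HWE p-value floor (default 1e-6).
#' @return List with `snps` (filtered encoding) and `report` (data frame
#'   of removed marker ids with machine-readable reason codes
#'   `low_maf` / `high_missing` / `hwe_fail`).
#' @export
qc_filter_snps <- function(snps, maf = 0.01, missing = 0.05, hwe_p = 1e-6) {
  g <- snps$geno
  miss_rate <- colMeans(is.na(g))
  f <- presence_freq(g)
  maf_obs <- pmin(f, 1 - f)
  hwe <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]; x <- x[!is.na(x)]
    hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  }, 0)
  fail <- list(low_maf = maf_obs < maf,
               high_missing = miss_rate > missing,
               hwe_fail = hwe < hwe_p)
  report <- do.call(rbind, lapply(names(fail), function(r) {
    idx <- which(fail[[r]])
    if (!length(idx)) return(NULL)
    data.frame(id = colnames(g)[idx], reason = r, stringsAsFactors = FALSE)
  }))
  if (is.null(report)) report <- data.frame(id = character(0),
                                            reason = character(0))
  drop <- Reduce(`|`, fail)
  if (all(drop)) stop("no informative SNPs remain after QC")
  keep <- which(!drop)
  out <- new_encoding(snps$markers[keep, , drop = FALSE],
                      g[, keep, drop = FALSE])
  list(snps = out, report = report)
}

#' Prune encoded markers with very low presence frequency
#'
#' Presence frequency is computed over the 2N chromosomes; markers below
#' `floor` (default 0.01%) are dropped.
#'
#' @param enc An `hla_encoding`.
#' @param floor Frequency floor (default 1e-4).
#' @return The pruned encoding, with attribute `pruned` listing removals.
#' @export
prune_rare_markers <- function(enc, floor = 1e-4) {
  f <- presence_freq(enc$geno)
  keep <- which(!is.na(f) & f >= floor)
  out <- new_encoding(enc$markers[keep, , drop = FALSE],
                      enc$geno[, keep, drop = FALSE])
  attr(out, "pruned") <- colnames(enc$geno)[setdiff(seq_len(ncol(enc$geno)),
                                                    keep)]
  out
}

rbind_markers <- function(mklist) {
  cols <- unique(unlist(lapply(mklist, colnames)))
  mklist <- lapply(mklist, function(m) {
    for (cc in setdiff(cols, colnames(m))) m[[cc]] <- NA
    m[, cols, drop = FALSE]
  })
  do.call(rbind, mklist)
}

#' Merge SNPs with encoded markers into one genomically ordered table
#'
#' @param ... `hla_encoding` objects over the same individuals.
#' @return A single `hla_encoding`, markers sorted by position (ties
#'   broken by marker id).  Duplicate marker ids are rejected.
#' @export
merge_and_order <- function(...) {
  encs <- Filter(function(e) nrow(e$markers) > 0, list(...))
  stopifnot(length(encs) >= 1)
  ids0 <- rownames(encs[[1]]$geno)
  for (e in encs) {
    if (!identical(sort(rownames(e$geno)), sort(ids0))) {
      stop("encodings cover different individuals")
    }
  }
  markers <- rbind_markers(lapply(encs, `[[`, "markers"))
  if (anyDuplicated(markers$id)) {
    stop("duplicate marker id(s): ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  }
  geno <- do.call(cbind, lapply(encs, function(e) e$geno[ids0, , drop = FALSE]))
  ord <- order(markers$pos, markers$id)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  new_encoding(markers, geno[, markers$id, drop = FALSE])
}

#' Construct a phased reference panel object
#'
#' @param haps 2N x M binary haplotype matrix (two rows per individual,
#'   in order); row names `<id>.1`, `<id>.2`.
#' @param markers Marker metadata (position-sorted).
#' @param ids Source individual ids (length N).
#' @param window MHC window bounds in bp, `c(start, end)`.
#' @return Object of class `ref_panel`.
#' @export
ref_panel <- function(haps, markers, ids,
                      window = c(29e6, 34e6)) {
  stopifnot(nrow(haps) == 2 * length(ids), ncol(haps) == nrow(markers),
            !is.unsorted(markers$pos), !anyNA(haps))
  rownames(haps) <- paste0(rep(ids, each = 2), c(".1", ".2"))
  colnames(haps) <- markers$id
  markers$freq <- unname(colMeans(haps))
  out <- list(haps = haps, markers = markers, ids = ids,
              window = window)
  class(out) <- "ref_panel"
  out
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("ref_panel:", nrow(x$haps), "haplotypes x", ncol(x$haps), "markers\n")
  print(table(x$markers$kind))
  invisible(x)
}

## Project each gene block of a haplotype pair onto the configuration
## implied by the individual's classical alleles (one allele per
## haplotype), choosing the orientation that agrees best with the phased
## values.  Restores the per-gene one-hot property exactly.
repair_one_hot <- function(h1, h2, markers, geno_row) {
  for (g in unique(markers$gene[markers$kind == "HLA4"])) {
    block <- which(markers$gene == g &
                   markers$kind %in% c("HLA4", "HLA2", "AA", "INDEL"))
    m4 <- which(markers$gene == g & markers$kind == "HLA4")
    dos <- geno_row[m4]
    if (anyNA(dos) || sum(dos) != 2) next
    alle <- vapply(markers$carriers[m4], `[`, "", 1L)
    pair <- rep(alle, dos)  # the individual's two 4-digit alleles
    implied <- function(a) {
      vapply(block, function(j) {
        carr <- markers$carriers[[j]]
        hit <- switch(markers$kind[j],
                      HLA4 = a %in% carr,
                      HLA2 = reduce_resolution(a)[1L] %in% carr,
                      a %in% carr)
        as.integer(hit)
      }, 0L)
    }
    ia <- implied(pair[1]); ib <- implied(pair[2])
    score_ab <- sum(h1[block] == ia) + sum(h2[block] == ib)
    score_ba <- sum(h1[block] == ib) + sum(h2[block] == ia)
    if (score_ab >= score_ba) {
      h1[block] <- ia; h2[block] <- ib
    } else {
      h1[block] <- ib; h2[block] <- ia
    }
  }
  list(h1 = h1, h2 = h2)
}

#' Phase a merged genotype panel into reference haplotypes
#'
#' Iterative conditional phasing: each individual's haplotype pair is
#' re-estimated against the current haplotypes of all other individuals
#' with the haplotype-copying HMM, sweeping until convergence (at most
#' `params$iterations` sweeps).  Unrelated individuals are assumed.
#' After phasing, encoded-marker blocks are projected per gene onto the
#' configuration implied by the individual's classical alleles, so each
#' haplotype carries exactly one 4-digit allele per typed gene and one
#' residue per amino-acid position.  An already phased `ref_panel` input
#' is a fixed point and is returned unchanged.
#'
#' @param panel Merged `hla_encoding` (e.g. from [merge_and_order()]),
#'   or a `ref_panel` (returned as is).
#' @param params [hmm_params()]; `seed` controls initial phase draws.
#' @param window MHC window bounds.
#' @return A [ref_panel()].  Individuals with more than 50% missing
#'   markers are excluded with a warning.
#' @export
phase_panel <- function(panel, params = hmm_params(), window = c(29e6, 34e6)) {
  if (inherits(panel, "ref_panel")) return(panel)
  g <- panel$geno
  miss <- rowMeans(is.na(g))
  if (any(miss > 0.5)) {
    warning("excluding individual(s) with >50% missing markers: ",
            paste(rownames(g)[miss > 0.5], collapse = ", "))
    g <- g[miss <= 0.5, , drop = FALSE]
  }
  n <- nrow(g); M <- ncol(g)
  ids <- rownames(g)
  K_cond <- 2 * (n - 1)
  theta <- resolve_theta(params, max(K_cond, 2))
  rho <- switch_rates(panel$markers$pos, max(K_cond, 2),
                      params$ne, params$cm_per_mb)

  set.seed(params$seed)
  haps <- matrix(0L, 2 * n, M)
  for (i in seq_len(n)) {
    gi <- g[i, ]
    h1 <- ifelse(is.na(gi), NA_integer_, as.integer(gi >= 1))
    h2 <- ifelse(is.na(gi), NA_integer_, as.integer(gi == 2))
    het <- which(!is.na(gi) & gi == 1)
    flip <- het[stats::runif(length(het)) < 0.5]
    h1[flip] <- 0L; h2[flip] <- 1L
    ## initial fill of missing by frequency draw
    na_idx <- which(is.na(gi))
    if (length(na_idx)) {
      f <- presence_freq(g)[na_idx]
      h1[na_idx] <- as.integer(stats::runif(length(na_idx)) < f)
      h2[na_idx] <- as.integer(stats::runif(length(na_idx)) < f)
    }
    haps[2 * i - 1, ] <- h1
    haps[2 * i, ] <- h2
  }
  if (n > 1) {
    for (sweep in seq_len(params$iterations)) {
      changed <- FALSE
      for (i in seq_len(n)) {
        others <- setdiff(seq_len(2 * n), c(2 * i - 1, 2 * i))
        ref <- t(haps[others, , drop = FALSE])  # M x K
        gi <- g[i, ]
        gi_int <- as.integer(ifelse(is.na(gi), -1L, gi))
        init1 <- haps[2 * i - 1, ]
        res <- .ls_phase_cpp(gi_int, ref, rho, theta, 2L, init1)
        new1 <- res$h1; new2 <- res$h2
        if (!identical(new1, haps[2 * i - 1, ]) ||
            !identical(new2, haps[2 * i, ])) changed <- TRUE
        haps[2 * i - 1, ] <- new1
        haps[2 * i, ] <- new2
      }
      if (!changed) break
    }
  }
  ## one-hot projection for encoded gene blocks
  for (i in seq_len(n)) {
    rep_ <- repair_one_hot(haps[2 * i - 1, ], haps[2 * i, ],
                           panel$markers, g[i, ])
    haps[2 * i - 1, ] <- rep_$h1
    haps[2 * i, ] <- rep_$h2
  }
  ref_panel(haps, panel$markers, ids, window = window)
}
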