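## Imputation-quality metrics: dosage-based locus accuracy, Pearson r2
## for biallelic markers, the multi-allelic vector R2, genotype
## concordance of best-guess calls, frequency correlation and a
## calibration curve.

truth_at_resolution <- function(truth, gene, resolution) {
  tg <- truth[truth$gene == gene, , drop = FALSE]
  if (resolution == 2) {
    a1 <- reduce_resolution(tg$allele1)
    a2 <- reduce_resolution(tg$allele2)
  } else {
    a1 <- ifelse(!is.na(tg$res1) & tg$res1 == 4L, tg$allele1, NA)
    a2 <- ifelse(!is.na(tg$res2) & tg$res2 == 4L, tg$allele2, NA)
  }
  data.frame(id = tg$id, a1 = a1, a2 = a2, stringsAsFactors = FALSE)
}

#' Dosage-based imputation accuracy at an HLA locus
#'
#' `Acc(L)` sums, over individuals typed at the evaluation resolution,
#' the imputed dosage of each of the individual's true alleles
#' (heterozygotes contribute both allele terms; homozygotes contribute
#' the single allele term once) and divides by the number of chromosomes
#' `2n`.  Uncertain but partially correct imputations therefore receive
#' partial credit.  Individuals with either allele untyped at the
#' requested resolution are excluded.
#'
#' @param result An `hla_dosage`, or a plain individual x marker dosage
#'   matrix whose columns follow the `HLA_<gene>_<digits>` convention.
#' @param truth An [hla_typing] table of gold-standard calls.
#' @param gene HLA locus to score.
#' @param resolution 2 or 4.
#' @return List: `acc` (percent), `n` (individuals counted),
#'   `missing_alleles` (truth alleles with no panel marker, scored as
#'   dosage 0).
#' @export
hla_accuracy <- function(result, truth, gene, resolution = 4) {
  dosage <- if (inherits(result, "hla_dosage")) result$dosage else result
  tr <- truth_at_resolution(truth, gene, resolution)
  tr <- tr[!is.na(tr$a1) & !is.na(tr$a2) & tr$id %in% rownames(dosage), ,
           drop = FALSE]
  n <- nrow(tr)
  if (n == 0) return(list(acc = NA_real_, n = 0L,
                          missing_alleles = character(0)))
  marker_of <- function(a) paste0("HLA_", gene, "_", sub("^.*\\*", "", a))
  missing_alleles <- character(0)
  dose_of <- function(id, a) {
    m <- marker_of(a)
    if (!m %in% colnames(dosage)) {
      missing_alleles <<- union(missing_alleles, a)
      return(0)
    }
    dosage[id, m]
  }
  total <- 0
  for (i in seq_len(n)) {
    if (tr$a1[i] == tr$a2[i]) {
      total <- total + dose_of(tr$id[i], tr$a1[i])
    } else {
      total <- total + dose_of(tr$id[i], tr$a1[i]) +
        dose_of(tr$id[i], tr$a2[i])
    }
  }
  list(acc = 100 * total / (2 * n), n = n, missing_alleles = missing_alleles)
}

#' Squared Pearson correlation between imputed and true dosages
#'
#' @param x Imputed dosages over individuals.
#' @param y True dosages over the same individuals.
#' @return r^2 in `[0, 1]`, or NA (with attribute `reason`) when either
#'   vector is constant.
#' @export
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "constant vector"
    return(out)
  }
  stats::cor(x, y)^2
}

#' Multi-allelic dosage correlation at an amino-acid position
#'
#' Generalises the Pearson r^2 to positions with more than two residues:
#' each individual contributes a vector of per-residue dosages, and
#' `R^2 = (sum_i <Xc_i, Yc_i>)^2 / (sum_i |Xc_i|^2 sum_i |Yc_i|^2)` with
#' the residue columns centred at their means (Xc = X - colMeans(X)).
#' For a two-residue position this reduces exactly to the biallelic
#' [dosage_r2()] of either residue marker.
#'
#' @param X Imputed dosage matrix, individuals x residues.
#' @param Y True dosage matrix, same shape.
#' @param centered Use the centred form (default TRUE); the uncentred
#'   variant is available for sensitivity analysis.
#' @return R^2 in `[0, 1]`, NA (with `reason`) if either matrix is
#'   constant.
#' @export
multiallelic_r2 <- function(X, Y, centered = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(identical(dim(X), dim(Y)))
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  if (centered) {
    X <- sweep(X, 2, colMeans(X))
    Y <- sweep(Y, 2, colMeans(Y))
  }
  sxx <- sum(X * X); syy <- sum(Y * Y)
  if (sxx == 0 || syy == 0) {
    out <- NA_real_
    attr(out, "reason") <- "constant vector"
    return(out)
  }
  sum(X * Y)^2 / (sxx * syy)
}

#' Genotype concordance of best-guess classical calls
#'
#' Per individual and gene the two called alleles are compared with the
#' truth as unordered multisets, contributing 0, 1/2 or 1; the per-gene
#' concordance is the average over individuals typed at the evaluation
#' resolution (individuals typed at another resolution are excluded from
#' the denominator).
#'
#' @param calls Data frame `id`, `gene`, `allele1`, `allele2`
#'   (see [call_classical()]).
#' @param truth An [hla_typing] table.
#' @param resolution 2 or 4.
#' @param allele_freq Optional named vector of panel allele frequencies;
#'   with `min_freq`, truth alleles at or below the floor are excluded
#'   from scoring (rare alleles are known to impute worse and can be
#'   reported separately).
#' @param min_freq Frequency floor used with `allele_freq` (default 0).
#' @return Data frame `gene`, `concordance` (percent), `n`.
#' @export
hla_concordance <- function(calls, truth, resolution = 4,
                            allele_freq = NULL, min_freq = 0) {
  out <- lapply(unique(calls$gene), function(g) {
    cg <- calls[calls$gene == g, , drop = FALSE]
    tr <- truth_at_resolution(truth, g, resolution)
    tr <- tr[!is.na(tr$a1) & !is.na(tr$a2), , drop = FALSE]
    m <- match(tr$id, cg$id)
    tr <- tr[!is.na(m), , drop = FALSE]; cg <- cg[m[!is.na(m)], , drop = FALSE]
    if (!nrow(tr)) return(data.frame(gene = g, concordance = NA_real_, n = 0L))
    score <- vapply(seq_len(nrow(tr)), function(i) {
      called <- c(cg$allele1[i], cg$allele2[i])
      if (resolution == 2) called <- reduce_resolution(called)
      truth2 <- c(tr$a1[i], tr$a2[i])
      if (!is.null(allele_freq)) {
        keep <- !is.na(allele_freq[truth2]) & allele_freq[truth2] > min_freq
        if (!any(keep)) return(NA_real_)
        ## score only the common truth alleles; matches among them
        s <- 0
        for (a in unique(truth2[keep])) {
          s <- s + min(sum(truth2[keep] == a), sum(called == a, na.rm = TRUE))
        }
        return(s / sum(keep))
      }
      ## order-free multiset match
      s <- 0
      for (a in unique(truth2)) {
        s <- s + min(sum(truth2 == a), sum(called == a, na.rm = TRUE))
      }
      s / 2
    }, 0)
    data.frame(gene = g, concordance = 100 * mean(score, na.rm = TRUE),
               n = sum(!is.na(score)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between imputed and typed allele frequencies
#'
#' @param f_imputed,f_typed Frequency vectors across markers (same
#'   order).
#' @return Squared Pearson correlation.
#' @export
freq_correlation <- function(f_imputed, f_typed) {
  dosage_r2(f_imputed, f_typed)
}

#' Calibration curve of imputed dosages against true genotypes
#'
#' Dosages are binned on `[0, 2]`; each bin reports its observation
#' count and the mean true dosage, so that a well-calibrated imputation
#' places the bin means on the diagonal.
#'
#' @param result An `hla_dosage` or dosage matrix.
#' @param truth_geno Matrix of true hard genotypes (0/1/2), same
#'   dimnames.
#' @param bins Number of bins (default 20).
#' @return Data frame `bin`, `lower`, `upper`, `mid`, `n`, `mean_true`
#'   (NA for empty bins).
#' @export
calibration_curve <- function(result, truth_geno, bins = 20) {
  dosage <- if (inherits(result, "hla_dosage")) result$dosage else result
  common_c <- intersect(colnames(dosage), colnames(truth_geno))
  common_r <- intersect(rownames(dosage), rownames(truth_geno))
  d <- as.vector(dosage[common_r, common_c, drop = FALSE])
  y <- as.vector(truth_geno[common_r, common_c, drop = FALSE])
  ok <- !is.na(d) & !is.na(y)
  d <- d[ok]; y <- y[ok]
  br <- seq(0, 2, length.out = bins + 1)
  idx <- findInterval(d, br, rightmost.closed = TRUE, all.inside = TRUE)
  out <- data.frame(bin = seq_len(bins),
                    lower = br[-length(br)], upper = br[-1],
                    mid = (br[-length(br)] + br[-1]) / 2)
  out$n <- vapply(seq_len(bins), function(b) sum(idx == b), 0L)
  out$mean_true <- vapply(seq_len(bins), function(b)
    if (any(idx == b)) mean(y[idx == b]) else NA_real_, 0)
  out
}
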