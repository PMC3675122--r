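## Case/control association testing of imputed dosages: per-marker
## logistic regression, omnibus amino-acid-position deviance tests,
## signal ranking and haplotype odds ratios against a reference
## haplotype.

#' Construct a phenotype table
#'
#' @param id Individual ids (must match the dosage table).
#' @param status 1/0, TRUE/FALSE, or "case"/"control".
#' @param covariates Optional data frame of real-valued covariates.
#' @return Data frame of class `hla_pheno`.
#' @export
hla_pheno <- function(id, status, covariates = NULL) {
  if (is.character(status)) status <- as.integer(status == "case")
  status <- as.integer(status)
  stopifnot(all(status %in% c(0L, 1L)))
  if (!all(c(0L, 1L) %in% status)) stop("both cases and controls required")
  out <- data.frame(id = as.character(id), status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  class(out) <- c("hla_pheno", "data.frame")
  out
}

glm_ctl <- function() stats::glm.control(epsilon = 1e-8, maxit = 100)

#' Logistic-regression test of one imputed marker
#'
#' Fits `status ~ dosage (+ covariates)` by iteratively reweighted least
#' squares and reports the allelic log-odds ratio with both Wald and
#' likelihood-ratio p-values.  Quasi-complete separation (diverging
#' estimates) is flagged, and the LRT p-value should be used then.
#'
#' @param dosage Numeric dosage vector for one marker.
#' @param pheno An [hla_pheno] table aligned with `dosage` (by `id` when
#'   `dosage` is named, else by position).
#' @param covariates Character vector of covariate column names in
#'   `pheno` (default none).
#' @param marker Marker id carried into the result.
#' @return One-row data frame of class `assoc_result`: `marker`, `beta`
#'   (log-OR), `se`, `or`, `stat` (LRT deviance), `df`, `p` (LRT),
#'   `p_wald`, `separation`.
#' @export
test_marker <- function(dosage, pheno, covariates = character(0),
                        marker = "marker") {
  d <- align_pheno(dosage, pheno)
  if (stats::sd(d$dosage) == 0) stop("constant dosage vector for ", marker)
  fm0 <- if (length(covariates)) {
    stats::reformulate(covariates, response = "status")
  } else status ~ 1
  fm1 <- stats::update(fm0, . ~ . + dosage)
  f0 <- suppressWarnings(stats::glm(fm0, data = d,
                                    family = stats::binomial(),
                                    control = glm_ctl()))
  f1 <- suppressWarnings(stats::glm(fm1, data = d,
                                    family = stats::binomial(),
                                    control = glm_ctl()))
  sm <- summary(f1)$coefficients
  beta <- sm["dosage", "Estimate"]
  se <- sm["dosage", "Std. Error"]
  stat <- f0$deviance - f1$deviance
  separation <- !f1$converged || abs(beta) > 15
  out <- data.frame(marker = marker, beta = beta, se = se, or = exp(beta),
                    stat = max(stat, 0), df = 1L,
                    p = stats::pchisq(max(stat, 0), 1, lower.tail = FALSE),
                    p_wald = 2 * stats::pnorm(-abs(beta / se)),
                    separation = separation, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

align_pheno <- function(dosage, pheno, mat = FALSE) {
  if (mat) {
    ids <- rownames(dosage)
  } else {
    ids <- names(dosage)
  }
  if (!is.null(ids)) {
    m <- match(pheno$id, ids)
    keep <- !is.na(m)
    dosage <- if (mat) dosage[m[keep], , drop = FALSE] else dosage[m[keep]]
    pheno <- pheno[keep, , drop = FALSE]
  }
  if (mat) {
    cbind(data.frame(status = pheno$status), as.data.frame(dosage),
          pheno[, setdiff(colnames(pheno), c("id", "status")), drop = FALSE])
  } else {
    cbind(data.frame(status = pheno$status, dosage = as.numeric(dosage)),
          pheno[, setdiff(colnames(pheno), c("id", "status")), drop = FALSE])
  }
}

#' Omnibus deviance test of one amino-acid position
#'
#' Jointly tests all residues at a position: the alternative model fits
#' an individual dosage effect for every residue except a reference
#' residue (the most frequent, dropped to break the dosages-sum-to-2
#' collinearity); the statistic is the deviance difference
#' `deviance(null) - deviance(alt)`, referred to a chi-square with
#' `(number of residues - 1)` degrees of freedom.  The statistic is
#' invariant to which residue is dropped.
#'
#' @param dosages Individuals x residues dosage matrix for one position
#'   (row names are individual ids).
#' @param pheno An [hla_pheno].
#' @param covariates Covariate column names in `pheno`.
#' @param position Position label carried into the result.
#' @return One-row `assoc_result` data frame with `stat`, `df`, `p` and
#'   `dropped` (residues removed for zero variance).
#' @export
omnibus_position_test <- function(dosages, pheno,
                                  covariates = character(0),
                                  position = "position") {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) < 2) stop("omnibus test needs a position with >= 2 residues")
  d <- align_pheno(dosages, pheno, mat = TRUE)
  res_cols <- colnames(dosages)
  v <- apply(d[, res_cols, drop = FALSE], 2, stats::sd)
  dropped <- res_cols[v == 0]
  res_cols <- res_cols[v > 0]
  if (length(res_cols) < 2) stop("position is monomorphic after dropping ",
                                 "zero-variance residues")
  ## reference residue = most frequent (largest mean dosage)
  mu <- colMeans(d[, res_cols, drop = FALSE])
  ref <- res_cols[which.max(mu)]
  keep <- setdiff(res_cols, ref)
  y <- d$status
  X0 <- cbind(`(Intercept)` = 1, as.matrix(d[, covariates, drop = FALSE]))
  X1 <- cbind(X0, as.matrix(d[, keep, drop = FALSE]))
  f0 <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial(),
                                        control = glm_ctl()))
  f1 <- suppressWarnings(stats::glm.fit(X1, y, family = stats::binomial(),
                                        control = glm_ctl()))
  stat <- max(f0$deviance - f1$deviance, 0)
  df <- length(keep)
  out <- data.frame(marker = position, beta = NA_real_, se = NA_real_,
                    or = NA_real_, stat = stat, df = df,
                    p = stats::pchisq(stat, df, lower.tail = FALSE),
                    p_wald = NA_real_, separation = !f1$converged,
                    stringsAsFactors = FALSE)
  out$dropped <- I(list(dropped))
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Scan all markers and amino-acid positions for association
#'
#' Runs [test_marker()] on every non-constant marker dosage and
#' [omnibus_position_test()] on every amino-acid position with at least
#' two residue markers.
#'
#' @param result An `hla_dosage` (or dosage matrix plus `markers`).
#' @param pheno An [hla_pheno].
#' @param covariates Covariate column names.
#' @param kinds Marker kinds to include in per-marker tests.
#' @return `assoc_result` data frame, one row per marker/position.
#' @export
assoc_scan <- function(result, pheno, covariates = character(0),
                       kinds = c("SNP", "HLA2", "HLA4", "AA", "INDEL")) {
  dosage <- result$dosage
  mk <- result$markers
  rows <- list()
  for (j in which(mk$kind %in% kinds)) {
    dj <- dosage[, mk$id[j]]
    if (stats::sd(dj, na.rm = TRUE) == 0) next
    rows[[length(rows) + 1L]] <-
      test_marker(dj, pheno, covariates, marker = mk$id[j])
  }
  aa <- mk[mk$kind == "AA", , drop = FALSE]
  if (nrow(aa)) {
    key <- paste(aa$gene, aa$aa_pos, sep = ":")
    for (k in unique(key)) {
      cols <- aa$id[key == k]
      if (length(cols) < 2) next
      D <- dosage[, cols, drop = FALSE]
      if (all(apply(D, 2, stats::sd, na.rm = TRUE) == 0)) next
      rows[[length(rows) + 1L]] <- tryCatch(
        omnibus_position_test(D, pheno, covariates,
                              position = paste0("AApos_", k)),
        error = function(e) NULL)
    }
  }
  rows <- Filter(Negate(is.null), rows)
  rows <- lapply(rows, function(r) {
    if (is.null(r$dropped)) r$dropped <- I(list(character(0)))
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Rank association signals by p-value
#'
#' @param results An `assoc_result` table.
#' @return The table sorted by increasing p (stable; ties broken by id),
#'   with a `rank` column.
#' @export
rank_signals <- function(results) {
  if (!nrow(results)) {
    results$rank <- integer(0)
    return(results)
  }
  ord <- order(results$p, results$marker)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Haplotype odds ratios against a reference haplotype
#'
#' Builds multi-gene haplotype labels from the phased best-guess calls
#' (e.g. `DRB1*01-DQA1*0101-DQB1*0501`), pools haplotypes rarer than
#' `floor` into `"rare"`, and fits a logistic model on haplotype
#' observations (each individual contributes two) with the reference
#' haplotype as baseline.  Profile-likelihood 95% CIs are reported; a
#' haplotype absent from cases or controls is flagged and its OR is
#' computed from Haldane-corrected counts.
#'
#' @param haplotypes Data frame with `id` and one column per gene
#'   holding the allele carried by each haplotype (two rows per
#'   individual), e.g. from [phased_classical_haplotypes()].
#' @param pheno An [hla_pheno].
#' @param reference Reference haplotype label (alleles joined by `-`).
#' @param genes Gene columns to span (default: all non-id columns).
#' @param floor Frequency floor below which haplotypes are pooled
#'   (default 0.005).
#' @return Data frame: `haplotype`, `n_case`, `n_control`, `or`,
#'   `ci_lower`, `ci_upper`, `p`, `degenerate`.
#' @export
haplotype_odds_ratios <- function(haplotypes, pheno, reference,
                                  genes = NULL, floor = 0.005) {
  if (is.null(genes)) genes <- setdiff(colnames(haplotypes), "id")
  lab <- apply(haplotypes[, genes, drop = FALSE], 1, paste, collapse = "-")
  st <- pheno$status[match(haplotypes$id, pheno$id)]
  ok <- !is.na(st) & !is.na(lab)
  lab <- lab[ok]; st <- st[ok]
  freq <- table(lab) / length(lab)
  lab[lab != reference & freq[lab] < floor] <- "rare"
  if (!reference %in% lab) stop("reference haplotype absent: ", reference)
  if (!any(lab == reference & st == 0)) {
    stop("reference haplotype absent from controls: ", reference)
  }
  lev <- c(reference, sort(setdiff(unique(lab), reference)))
  f <- factor(lab, levels = lev)
  fit <- suppressWarnings(stats::glm(st ~ f, family = stats::binomial()))
  cf <- stats::coef(fit)
  requireNamespace("MASS", quietly = TRUE)  # registers profile CIs for glm
  ci <- suppressWarnings(suppressMessages(
    tryCatch(stats::confint(fit, level = 0.95), error = function(e) NULL)))
  rows <- lapply(lev, function(h) {
    n_case <- sum(lab == h & st == 1); n_ctl <- sum(lab == h & st == 0)
    if (h == reference) {
      return(data.frame(haplotype = h, n_case = n_case, n_control = n_ctl,
                        or = 1, ci_lower = NA_real_, ci_upper = NA_real_,
                        p = NA_real_, degenerate = FALSE,
                        stringsAsFactors = FALSE))
    }
    cn <- paste0("f", h)
    degenerate <- n_case == 0 || n_ctl == 0
    if (degenerate) {
      ## Haldane-Anscombe correction on the 2x2 vs the reference
      rc <- sum(lab == reference & st == 1)
      rn <- sum(lab == reference & st == 0)
      or <- ((n_case + 0.5) / (n_ctl + 0.5)) / ((rc + 0.5) / (rn + 0.5))
      return(data.frame(haplotype = h, n_case = n_case, n_control = n_ctl,
                        or = or, ci_lower = NA_real_, ci_upper = NA_real_,
                        p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    b <- cf[[cn]]
    z <- summary(fit)$coefficients[cn, ]
    lo <- if (!is.null(ci)) exp(ci[cn, 1]) else NA_real_
    hi <- if (!is.null(ci)) exp(ci[cn, 2]) else NA_real_
    data.frame(haplotype = h, n_case = n_case, n_control = n_ctl,
               or = exp(b), ci_lower = lo, ci_upper = hi,
               p = z[["Pr(>|z|)"]], degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classical-allele haplotypes from imputed phased output
#'
#' @param result An `hla_dosage`.
#' @param genes Genes to span, in output order.
#' @param resolution Per-gene resolution: a single value (2 or 4)
#'   recycled, or a vector matching `genes` (the classical risk-haplotype
#'   nomenclature mixes 2-digit DRB1 with 4-digit DQA1/DQB1).
#' @return Data frame with `id` and one column per gene; two rows per
#'   individual (haplotypes 1 and 2).
#' @export
phased_classical_haplotypes <- function(result, genes, resolution = 4) {
  resolution <- rep(resolution, length.out = length(genes))
  per_gene <- lapply(seq_along(genes), function(k) {
    cc <- call_classical(result, gene = genes[k], resolution = resolution[k])
    cc[match(result$ids, cc$id), c("allele1", "allele2")]
  })
  n <- length(result$ids)
  out <- data.frame(id = rep(result$ids, each = 2),
                    stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    a <- per_gene[[k]]
    v <- character(2 * n)
    v[seq(1, 2 * n, by = 2)] <- a$allele1
    v[seq(2, 2 * n, by = 2)] <- a$allele2
    out[[genes[k]]] <- v
  }
  out
}

#' Check that classical-allele dosages sum to ~2 per gene
#'
#' @param result An `hla_dosage`.
#' @param tol Allowed deviation of the per-individual per-gene sum of
#'   4-digit allele dosages from 2 (default 0.1).
#' @return List: `pass` (logical), `sums` (individual x gene matrix),
#'   `failures` (data frame id/gene/sum).
#' @export
dosage_sanity_check <- function(result, tol = 0.1) {
  mk <- result$markers
  genes <- unique(mk$gene[mk$kind == "HLA4"])
  sums <- sapply(genes, function(g) {
    rowSums(result$dosage[, mk$id[mk$gene == g & mk$kind == "HLA4"],
                          drop = FALSE])
  })
  sums <- matrix(sums, nrow = length(result$ids),
                 dimnames = list(result$ids, genes))
  bad <- which(abs(sums - 2) > tol, arr.ind = TRUE)
  failures <- data.frame(id = rownames(sums)[bad[, 1]],
                         gene = colnames(sums)[bad[, 2]],
                         sum = sums[bad], stringsAsFactors = FALSE)
  list(pass = nrow(failures) == 0, sums = sums, failures = failures)
}
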