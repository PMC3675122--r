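## Target harmonization and imputation of untyped markers from the
## phased reference panel.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize target SNP genotypes with a reference panel
#'
#' Restricts the target to the panel's MHC window, drops SNPs with
#' target minor allele frequency below `maf` (default 2.5%), matches
#' target SNPs to panel markers by position, and orients every SNP onto
#' the panel strand: when the target allele pair equals the complement
#' of the panel pair the SNP is strand-flipped; when the counted allele
#' is the panel's absence allele the genotype is inverted.  A/T and C/G
#' palindromic SNPs cannot be strand-resolved by labels and are oriented
#' by frequency matching when the panel presence frequency is away from
#' 0.5 (|freq - 0.5| > 0.1), otherwise dropped.  Unresolvable SNPs are
#' dropped and reported.
#'
#' @param target List with `geno` (individuals x SNPs matrix of counted
#'   allele dosages 0/1/2/NA), `markers` (data frame: `id`, `pos`,
#'   `counted`, `other`), or the output of [make_target()].
#' @param panel A [ref_panel()].
#' @param maf Target MAF floor (default 0.025).
#' @return Object of class `hla_target`: `geno` (oriented to count the
#'   panel presence allele), `markers` (the matching panel marker rows),
#'   and `report` (data frame of id / action with actions `kept`,
#'   `flipped_strand`, `swapped`, `low_maf`, `outside_window`,
#'   `ambiguous_dropped`, `unmatched`).  Errors if no marker overlaps.
#' @export
harmonize <- function(target, panel, maf = 0.025) {
  tm <- target$markers
  g <- target$geno
  stopifnot(ncol(g) == nrow(tm))
  action <- setNames(rep("kept", nrow(tm)), tm$id)

  inside <- tm$pos >= panel$window[1] & tm$pos <= panel$window[2]
  action[!inside] <- "outside_window"

  f <- presence_freq(g)
  maf_obs <- pmin(f, 1 - f, na.rm = TRUE)
  action[inside & maf_obs < maf] <- "low_maf"

  pm <- panel$markers
  pidx <- match(tm$pos, pm$pos)
  ## only SNP-kind panel markers are matchable by position
  pidx[!is.na(pidx) & pm$kind[pidx] != "SNP"] <- NA
  action[action == "kept" & is.na(pidx)] <- "unmatched"

  keep <- which(action == "kept")
  geno_out <- list(); rows <- integer(0)
  for (j in keep) {
    pj <- pidx[j]
    tp <- c(tm$counted[j], tm$other[j])
    pp <- c(pm$allele_present[pj], pm$allele_absent[pj])
    flip <- FALSE
    if (!setequal(tp, pp)) {
      tpc <- unname(COMPLEMENT[tp])
      if (!anyNA(tpc) && setequal(tpc, pp)) {
        tp <- tpc; flip <- TRUE
      } else {
        action[j] <- "unmatched"; next
      }
    }
    ambiguous <- setequal(pp, c("A", "T")) || setequal(pp, c("C", "G"))
    gj <- g[, j]
    if (ambiguous) {
      pf <- pm$freq[pj]
      if (abs(pf - 0.5) <= 0.1) { action[j] <- "ambiguous_dropped"; next }
      ## orient so the counted-allele frequency matches the panel side
      tf <- f[j]
      if (abs(tf - pf) > abs((1 - tf) - pf)) gj <- 2 - gj
      action[j] <- "kept"
    } else {
      if (tp[1] == pp[2]) { gj <- 2 - gj; action[j] <- "swapped" }
      if (flip) action[j] <- if (action[j] == "swapped") "swapped" else
        "flipped_strand"
    }
    geno_out[[length(geno_out) + 1L]] <- gj
    rows <- c(rows, pj)
  }
  if (!length(rows)) stop("no overlap with panel after harmonization")
  geno <- do.call(cbind, geno_out)
  ord <- order(pm$pos[rows], pm$id[rows])
  geno <- geno[, ord, drop = FALSE]
  rows <- rows[ord]
  colnames(geno) <- pm$id[rows]
  rownames(geno) <- rownames(g)
  out <- list(geno = geno, markers = pm[rows, , drop = FALSE],
              ids = rownames(g),
              report = data.frame(id = tm$id, action = unname(action),
                                  stringsAsFactors = FALSE))
  class(out) <- "hla_target"
  out
}

#' Impute untyped markers in target samples from a phased panel
#'
#' For each individual the typed sites are phased by iterative
#' conditional haplotype-copying (sweeps re-orienting heterozygous sites
#' towards the jointly likelier configuration), then a haploid
#' forward-backward pass per haplotype along the full panel marker chain
#' yields the posterior copied allele at every marker.  Genotype
#' posteriors combine the two haplotype posteriors; the dosage is
#' `P1 + 2 P2`.  Deterministic given `params$seed`.
#'
#' @param target An `hla_target` (see [harmonize()]); its markers must
#'   be a subset of the panel markers.
#' @param panel A [ref_panel()].
#' @param params [hmm_params()].
#' @return Object of class `hla_dosage`: matrices `dosage`, `P0`, `P1`,
#'   `P2` (individual x marker), binary phased haplotype matrices `hap1`,
#'   `hap2`, the panel `markers`, `ids`, and `low_confidence` flags for
#'   individuals typed at fewer than 10 markers.
#' @export
impute <- function(target, panel, params = hmm_params()) {
  pm <- panel$markers
  typed_idx <- match(colnames(target$geno), pm$id)
  if (anyNA(typed_idx)) stop("target contains markers absent from the panel")
  K <- nrow(panel$haps); M <- nrow(pm)
  theta <- resolve_theta(params, K)
  rho <- switch_rates(pm$pos, K, params$ne, params$cm_per_mb)
  ref <- t(panel$haps)  # M x K
  storage.mode(ref) <- "integer"
  n <- nrow(target$geno)
  ids <- rownames(target$geno)

  dosage <- P0 <- P1 <- P2 <- matrix(NA_real_, n, M,
                                     dimnames = list(ids, pm$id))
  hap1 <- hap2 <- matrix(NA_real_, n, M, dimnames = list(ids, pm$id))
  hap1_post <- hap2_post <- matrix(NA_real_, n, M,
                                   dimnames = list(ids, pm$id))
  low_conf <- setNames(logical(n), ids)

  win <- params$window
  blocks <- if (win > 0 && M > win) impute_windows(M, win) else
    list(list(idx = seq_len(M), core = seq_len(M)))

  set.seed(params$seed)
  init_all <- matrix(as.integer(stats::runif(n * length(typed_idx)) < 0.5),
                     n, length(typed_idx))
  for (i in seq_len(n)) {
    gi <- as.integer(target$geno[i, ])
    gi[is.na(gi)] <- -1L
    n_typed <- sum(gi >= 0)
    low_conf[i] <- n_typed < 10
    p1 <- numeric(M); p2 <- numeric(M)
    for (b in blocks) {
      sel <- b$idx
      t_in <- which(typed_idx %in% sel)
      if (!length(t_in)) {
        p1[b$core] <- p2[b$core] <- pm$freq[b$core]
        next
      }
      loc_idx <- match(typed_idx[t_in], sel) - 1L
      res <- .ls_impute_cpp(gi[t_in], as.integer(loc_idx),
                            ref[sel, , drop = FALSE],
                            rho[sel[-length(sel)]], theta,
                            params$iterations, init_all[i, t_in])
      p1[b$core] <- res$p1[match(b$core, sel)]
      p2[b$core] <- res$p2[match(b$core, sel)]
      hap1[i, sel[loc_idx + 1L][res$h1 >= 0]] <- res$h1[res$h1 >= 0]
      hap2[i, sel[loc_idx + 1L][res$h2 >= 0]] <- res$h2[res$h2 >= 0]
    }
    hap1_post[i, ] <- p1
    hap2_post[i, ] <- p2
    P2[i, ] <- p1 * p2
    P1[i, ] <- p1 * (1 - p2) + p2 * (1 - p1)
    P0[i, ] <- (1 - p1) * (1 - p2)
    dosage[i, ] <- P1[i, ] + 2 * P2[i, ]
    hap1[i, ] <- ifelse(is.na(hap1[i, ]), as.numeric(p1 > 0.5), hap1[i, ])
    hap2[i, ] <- ifelse(is.na(hap2[i, ]), as.numeric(p2 > 0.5), hap2[i, ])
  }
  out <- list(dosage = dosage, P0 = P0, P1 = P1, P2 = P2,
              hap1 = hap1, hap2 = hap2,
              hap1_post = hap1_post, hap2_post = hap2_post,
              markers = pm, ids = ids,
              low_confidence = low_conf, theta = theta)
  class(out) <- "hla_dosage"
  out
}

## Overlapping windows with centre splicing: each window contributes its
## central block of markers to the output.
impute_windows <- function(M, win) {
  step <- max(win %/% 2, 1L)
  starts <- seq(1L, max(M - win + 1L, 1L), by = step)
  if (starts[length(starts)] + win - 1L < M) starts <- c(starts, M - win + 1L)
  blocks <- list()
  prev_end <- 0L
  for (s in starts) {
    e <- min(s + win - 1L, M)
    core_start <- prev_end + 1L
    core_end <- if (e == M) M else e - step %/% 2
    blocks[[length(blocks) + 1L]] <-
      list(idx = s:e, core = core_start:core_end)
    prev_end <- core_end
  }
  blocks
}

#' @export
print.hla_dosage <- function(x, ...) {
  cat("hla_dosage:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "markers\n")
  invisible(x)
}

#' Best-guess genotypes from posterior triples
#'
#' Argmax of (P0, P1, P2) per individual and marker; exact ties are
#' broken toward the lower genotype count and flagged.
#'
#' @param result An `hla_dosage`.
#' @return List with `calls` (individual x marker matrix of 0/1/2) and
#'   `ties` (logical matrix flagging broken ties).
#' @export
best_guess <- function(result) {
  n <- nrow(result$P0); M <- ncol(result$P0)
  pmax_ <- pmax(result$P0, result$P1, result$P2)
  calls <- matrix(0L, n, M, dimnames = dimnames(result$P0))
  ## lower genotype wins ties: assign from highest genotype downwards
  calls[result$P2 == pmax_] <- 2L
  calls[result$P1 == pmax_] <- 1L
  calls[result$P0 == pmax_] <- 0L
  ties <- (result$P0 == pmax_) + (result$P1 == pmax_) +
    (result$P2 == pmax_) > 1
  list(calls = calls, ties = ties)
}

#' Call classical HLA alleles from imputed phased haplotypes
#'
#' For each individual and gene, each phased haplotype is assigned the
#' classical allele whose presence marker has the highest posterior
#' copied-allele probability on that haplotype (flat posteriors fall
#' back to the lowest marker id and are flagged ambiguous).
#'
#' @param result An `hla_dosage` holding per-haplotype allele posteriors.
#' @param gene HLA gene to call (default: all genes with HLA4 markers).
#' @param resolution 4 (native) or 2 (calls reduced with
#'   [reduce_resolution()]).
#' @return Data frame `id`, `gene`, `allele1`, `allele2`, `ambiguous`.
#' @export
call_classical <- function(result, gene = NULL, resolution = 4) {
  mk <- result$markers
  genes <- if (is.null(gene)) unique(mk$gene[mk$kind == "HLA4"]) else gene
  rows <- list()
  for (g in genes) {
    m4 <- which(mk$gene == g & mk$kind == "HLA4")
    if (!length(m4)) next
    alle <- vapply(mk$carriers[m4], `[`, "", 1L)
    ## haplotype-level posterior: use stored per-hap probabilities
    h1 <- result$hap1_post[, m4, drop = FALSE]
    h2 <- result$hap2_post[, m4, drop = FALSE]
    pick <- function(p) {
      j <- which(p == max(p))
      c(alle[min(j)], length(j) > 1)
    }
    for (i in seq_along(result$ids)) {
      c1 <- pick(h1[i, ]); c2 <- pick(h2[i, ])
      a1 <- c1[1]; a2 <- c2[1]
      if (resolution == 2) {
        a1 <- reduce_resolution(a1)[1L]; a2 <- reduce_resolution(a2)[1L]
      }
      rows[[length(rows) + 1L]] <-
        data.frame(id = result$ids[i], gene = g, allele1 = a1, allele2 = a2,
                   ambiguous = as.logical(c1[2]) || as.logical(c2[2]),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
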