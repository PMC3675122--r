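## Synthetic MHC data with known truth: founder haplotypes carrying
## classical alleles, recombinant mosaic haplotypes with long-range LD,
## per-allele amino-acid sequences, SNP-chip-like target samples and a
## phenotype generator with a planted causal residue.

#' Configuration of the synthetic MHC simulator
#'
#' Haplotypes are recombinant mosaics of a modest pool of founder
#' lineages, which reproduces the long-range linkage disequilibrium
#' between MHC SNPs and HLA alleles that imputation exploits.  Classical
#' allele frequencies follow a Dirichlet spectrum; every 4-digit allele
#' maps deterministically to an aligned amino-acid sequence so residue
#' markers are an exact linear image of the classical dosages.
#'
#' @param founders Number of founder haplotype lineages (default 40).
#' @param K Reference haplotypes to generate (default 1000).
#' @param n_target Target individuals, drawn from a disjoint haplotype
#'   split (default 200).
#' @param M SNP count across the window (default 1600).
#' @param window MHC window in bp (default chr6:29-34 Mb).
#' @param genes HLA genes to simulate (default A, B, C, DQB1, DRB1, the
#'   classical benchmark loci).
#' @param alleles_per_gene Distinct 4-digit alleles per gene (default 8,
#'   grouped into 2-digit families of two).
#' @param dirichlet Concentration of the allele-frequency Dirichlet
#'   (default 1).
#' @param aa_len Aligned amino-acid positions per gene (default 50).
#' @param aa_mut Expected residue substitutions per allele relative to
#'   the gene consensus (default 6).
#' @param recomb Crossover rate per bp per haplotype mosaic
#'   (default 4e-7, about two switches across the 5 Mb window).
#' @param mut SNP copy-error rate per site per haplotype (default 2e-4).
#' @param indel_prob Probability that a gene carries one allele with a
#'   short deletion run (default 0.5).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(founders = 40L, K = 1000L, n_target = 200L,
                       M = 1600L, window = c(29e6, 34e6),
                       genes = c("A", "B", "C", "DQB1", "DRB1"),
                       alleles_per_gene = 8L, dirichlet = 1,
                       aa_len = 50L, aa_mut = 6, recomb = 4e-7,
                       mut = 2e-4, indel_prob = 0.5, seed = 1L) {
  stopifnot(founders >= 2, K >= 2, n_target >= 1, M >= 10,
            alleles_per_gene >= 2, all(genes %in% HLA_GENES),
            recomb >= 0, mut >= 0, dirichlet > 0)
  out <- as.list(environment())
  class(out) <- "sim_config"
  out
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

sim_sequences <- function(cfg) {
  rows <- list()
  for (g in cfg$genes) {
    consensus <- sample(AA20, cfg$aa_len, replace = TRUE)
    fams <- ceiling(cfg$alleles_per_gene / 2)
    for (a in seq_len(cfg$alleles_per_gene)) {
      fam <- ceiling(a / 2)
      lab <- sprintf("%s*%02d%02d", g, fam, ((a - 1) %% 2) + 1)
      s <- consensus
      ## family-shared substitutions then allele-private ones, so
      ## 2-digit families share part of their sequence signature
      set_mut <- function(s, n, offset) {
        idx <- 1 + ((offset + seq_len(n) * 7) %% cfg$aa_len)
        for (j in idx) s[j] <- AA20[1 + (match(s[j], AA20) %% 20)]
        s
      }
      s <- set_mut(s, max(1, round(cfg$aa_mut / 2)), fam * 13)
      s <- set_mut(s, max(1, round(cfg$aa_mut / 2)), a * 29 + 3)
      if (stats::runif(1) < cfg$indel_prob && a == cfg$alleles_per_gene) {
        del_at <- sample(5:(cfg$aa_len - 5), 1)
        del_len <- sample(1:3, 1)
        s[del_at:(del_at + del_len - 1)] <- "-"
      }
      rows[[lab]] <- data.frame(gene = g, allele = lab,
                                seq = paste(s, collapse = ""),
                                stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  hla_sequences(tab$gene, tab$allele, tab$seq)
}

#' Simulate a phased MHC reference panel with known truth
#'
#' Founder lineages receive random SNP haplotypes and, per gene, a
#' classical allele drawn from the Dirichlet frequency spectrum.
#' Reference and target haplotypes are independent recombinant mosaics
#' of the founders (crossovers Poisson along the window) with sparse SNP
#' copy errors; the classical allele of a haplotype at a gene is the
#' allele of the founder segment covering the gene anchor.  The encoded
#' HLA/AA/indel markers are built with the package encoders from the
#' recorded truth, so every haplotype is exactly one-hot per gene and
#' per amino-acid position.
#'
#' @param cfg A [sim_config()].
#' @return List of class `hla_sim`: `panel` (a [ref_panel()]), `truth`
#'   (panel typings), `sequences`, `target_truth`, hidden target
#'   haplotypes, and the simulated platform SNP sets.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  sequences <- sim_sequences(cfg)
  coords <- hla_gene_coords()[cfg$genes]
  pos <- sort(sample(seq(cfg$window[1], cfg$window[2]), cfg$M))
  ## founder pool
  fa_freq <- lapply(cfg$genes, function(g) {
    w <- stats::rgamma(cfg$alleles_per_gene, cfg$dirichlet)
    w / sum(w)
  })
  names(fa_freq) <- cfg$genes
  f_snp <- matrix(as.integer(stats::runif(cfg$founders * cfg$M) < 0.5),
                  cfg$founders, cfg$M)
  f_allele <- sapply(cfg$genes, function(g) {
    labs <- sequences$allele[sequences$gene == g]
    sample(labs, cfg$founders, replace = TRUE, prob = fa_freq[[g]])
  })
  f_allele <- matrix(f_allele, nrow = cfg$founders,
                     dimnames = list(NULL, cfg$genes))

  n_hap <- cfg$K + 2 * cfg$n_target
  span <- diff(cfg$window)
  hap_snp <- matrix(0L, n_hap, cfg$M)
  hap_allele <- matrix("", n_hap, length(cfg$genes),
                       dimnames = list(NULL, cfg$genes))
  for (h in seq_len(n_hap)) {
    n_x <- stats::rpois(1, cfg$recomb * span)
    bk <- sort(stats::runif(n_x, cfg$window[1], cfg$window[2]))
    founder_seq <- sample.int(cfg$founders, n_x + 1, replace = TRUE)
    seg_of <- function(p) founder_seq[findInterval(p, bk) + 1L]
    hap_snp[h, ] <- f_snp[cbind(seg_of(pos), seq_len(cfg$M))]
    hap_allele[h, ] <- f_allele[cbind(seg_of(coords), seq_along(cfg$genes))]
    flip <- stats::runif(cfg$M) < cfg$mut
    hap_snp[h, flip] <- 1L - hap_snp[h, flip]
  }

  panel_rows <- seq_len(cfg$K)
  target_rows <- cfg$K + seq_len(2 * cfg$n_target)
  panel_ids <- sprintf("ref%04d", seq_len(cfg$K %/% 2))
  target_ids <- sprintf("tgt%04d", seq_len(cfg$n_target))

  truth <- sim_typings(hap_allele[panel_rows, , drop = FALSE], panel_ids,
                       cfg$genes)
  target_truth <- sim_typings(hap_allele[target_rows, , drop = FALSE],
                              target_ids, cfg$genes)

  panel <- build_sim_panel(hap_snp[panel_rows, , drop = FALSE],
                           hap_allele[panel_rows, , drop = FALSE],
                           pos, truth, sequences, cfg, panel_ids)
  ## platform SNP subsets: evenly spaced across the panel's SNP markers
  snp_ids <- panel$markers$id[panel$markers$kind == "SNP"]
  platform <- list(
    dense = snp_ids[unique(round(seq(1, length(snp_ids),
                                     length.out = min(5000, length(snp_ids)))))],
    sparse = snp_ids[unique(round(seq(1, length(snp_ids),
                                      length.out = min(500, length(snp_ids)))))])
  out <- list(panel = panel, truth = truth, sequences = sequences,
              target_truth = target_truth,
              target_hap_snp = hap_snp[target_rows, , drop = FALSE],
              target_hap_allele = hap_allele[target_rows, , drop = FALSE],
              snp_pos = pos, platform = platform, config = cfg,
              founder_alleles = f_allele, allele_freq_target = fa_freq,
              panel_hap_allele = hap_allele[panel_rows, , drop = FALSE])
  class(out) <- "hla_sim"
  out
}

sim_typings <- function(hap_allele, ids, genes) {
  rows <- list()
  for (g in genes) {
    a <- hap_allele[, g]
    rows[[g]] <- hla_typing(ids, g, a[c(TRUE, FALSE)], a[c(FALSE, TRUE)])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hla_typing", "data.frame")
  out
}

## build the merged phased panel from simulated haplotypes: SNP columns
## directly, encoded columns one-hot from the per-haplotype allele
build_sim_panel <- function(hap_snp, hap_allele, pos, truth, sequences,
                            cfg, ids) {
  K <- nrow(hap_snp)
  snp_ids <- sprintf("snp_%d", pos)
  geno_snp <- hap_snp[c(TRUE, FALSE), , drop = FALSE] +
    hap_snp[c(FALSE, TRUE), , drop = FALSE]
  dimnames(geno_snp) <- list(ids, snp_ids)
  a12 <- replicate(length(pos), sample(names(COMPLEMENT), 2))
  snps <- snp_encoding(geno_snp, pos, counted = a12[1, ], other = a12[2, ])
  hla4 <- encode_classical_alleles(truth, 4)
  hla2 <- encode_classical_alleles(truth, 2)
  aa <- encode_amino_acids(sequences, truth)
  ind <- encode_indels(sequences, truth)
  merged <- merge_and_order(snps, hla4, hla2, aa, ind)
  merged <- prune_rare_markers(merged)

  ## haplotype matrix: SNPs copied, encoded markers one-hot by carrier set
  mk <- merged$markers
  haps <- matrix(0L, K, nrow(mk))
  is_snp <- mk$kind == "SNP"
  haps[, is_snp] <- hap_snp[, match(mk$id[is_snp], snp_ids)]
  enc_idx <- which(!is_snp)
  for (j in enc_idx) {
    carr <- mk$carriers[[j]]
    a <- hap_allele[, mk$gene[j]]
    hit <- if (mk$kind[j] == "HLA2") reduce_resolution(a) %in% carr else
      a %in% carr
    haps[, j] <- as.integer(hit)
  }
  ref_panel(haps, mk, ids, window = cfg$window)
}

#' Build a SNP-genotyped target sample from a simulation
#'
#' Individuals are formed from the simulation's held-out haplotype split
#' (disjoint from the reference panel, so no target haplotype is a panel
#' haplotype unless recombination is switched off).  Only the platform's
#' SNP subset is exposed; all encoded markers are masked and the gold
#' standard is returned separately.
#'
#' @param sim An `hla_sim` from [simulate_panel()].
#' @param profile `"dense"` (up to 5000 SNPs) or `"sparse"` (about 500
#'   SNPs), emulating a high-density immunochip versus an early GWAS
#'   array.
#' @param n Number of target individuals (default: all simulated).
#' @param flip_fraction Fraction of exposed SNPs reported on the
#'   opposite strand (exercises harmonization; default 0).
#' @param seed Optional seed for the strand-flip draw.
#' @return List: `target` (raw genotypes + marker table for
#'   [harmonize()]), `truth` (gold-standard typings), `truth_geno`
#'   (true dosage matrix over all panel markers).
#' @export
make_target <- function(sim, profile = c("dense", "sparse"), n = NULL,
                        flip_fraction = 0, seed = NULL) {
  profile <- match.arg(profile)
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim$config
  if (is.null(n)) n <- cfg$n_target
  stopifnot(n <= cfg$n_target)
  ids <- sprintf("tgt%04d", seq_len(n))
  keep_ids <- sim$platform[[profile]]
  pm <- sim$panel$markers
  sel <- match(keep_ids, pm$id)
  hap_rows <- seq_len(2 * n)
  h <- sim$target_hap_snp[hap_rows, , drop = FALSE]
  snp_ids_all <- sprintf("snp_%d", sim$snp_pos)
  cols <- match(keep_ids, snp_ids_all)
  geno <- h[c(TRUE, FALSE), cols, drop = FALSE] +
    h[c(FALSE, TRUE), cols, drop = FALSE]
  rownames(geno) <- ids
  colnames(geno) <- keep_ids
  markers <- data.frame(id = keep_ids, pos = pm$pos[sel],
                        counted = pm$allele_present[sel],
                        other = pm$allele_absent[sel],
                        stringsAsFactors = FALSE)
  if (flip_fraction > 0) {
    fl <- stats::runif(nrow(markers)) < flip_fraction
    markers$counted[fl] <- unname(COMPLEMENT[markers$counted[fl]])
    markers$other[fl] <- unname(COMPLEMENT[markers$other[fl]])
    attr(markers, "flipped") <- markers$id[fl]
  }
  truth <- sim$target_truth[sim$target_truth$id %in% ids, , drop = FALSE]
  class(truth) <- c("hla_typing", "data.frame")
  truth_geno <- true_dosages(sim, ids)
  list(target = list(geno = geno, markers = markers),
       truth = truth, truth_geno = truth_geno)
}

#' True dosages of all panel markers for target individuals
#'
#' @param sim An `hla_sim`.
#' @param ids Target individual ids.
#' @return Individuals x panel-marker matrix of true dosages.
#' @export
true_dosages <- function(sim, ids = NULL) {
  cfg <- sim$config
  if (is.null(ids)) ids <- sprintf("tgt%04d", seq_len(cfg$n_target))
  idx <- as.integer(sub("^tgt", "", ids))
  mk <- sim$panel$markers
  n <- length(ids)
  out <- matrix(0, n, nrow(mk), dimnames = list(ids, mk$id))
  snp_ids_all <- sprintf("snp_%d", sim$snp_pos)
  is_snp <- mk$kind == "SNP"
  cols <- match(mk$id[is_snp], snp_ids_all)
  h1 <- sim$target_hap_snp[2 * idx - 1, cols, drop = FALSE]
  h2 <- sim$target_hap_snp[2 * idx, cols, drop = FALSE]
  out[, is_snp] <- h1 + h2
  for (j in which(!is_snp)) {
    carr <- mk$carriers[[j]]
    a1 <- sim$target_hap_allele[2 * idx - 1, mk$gene[j]]
    a2 <- sim$target_hap_allele[2 * idx, mk$gene[j]]
    if (mk$kind[j] == "HLA2") {
      a1 <- reduce_resolution(a1); a2 <- reduce_resolution(a2)
    }
    out[, j] <- (a1 %in% carr) + (a2 %in% carr)
  }
  out
}

#' Simulate case/control phenotypes with a planted causal residue
#'
#' Disease status follows `logit P(case) = alpha + beta * dose` where
#' `dose` is the individual's true count (0-2) of the causal amino-acid
#' residue, and `alpha = qlogis(prevalence)`.
#'
#' @param sim An `hla_sim`.
#' @param gene,aa_pos,residue The causal residue: gene, amino-acid
#'   position and residue symbol (must be polymorphic in the panel).
#' @param beta Causal log-odds ratio (0 = null).
#' @param prevalence Baseline probability of being a case at dose 0
#'   (default 0.5, a balanced design).
#' @param ids Individuals to phenotype (default all targets).
#' @return An [hla_pheno] with attribute `causal` recording the spec.
#' @export
simulate_phenotypes <- function(sim, gene, aa_pos, residue, beta,
                                prevalence = 0.5, ids = NULL) {
  mk <- sim$panel$markers
  j <- which(mk$kind == "AA" & mk$gene == gene & mk$aa_pos == aa_pos &
             endsWith(mk$id, paste0("_", residue)))
  if (length(j) != 1) stop("causal residue not found: ", gene, " pos ",
                           aa_pos, " ", residue)
  if (is.null(ids)) ids <- sprintf("tgt%04d", seq_len(sim$config$n_target))
  dose <- true_dosages(sim, ids)[, mk$id[j]]
  p <- stats::plogis(stats::qlogis(prevalence) + beta * dose)
  status <- as.integer(stats::runif(length(ids)) < p)
  ## guarantee both classes (resample degenerate draws are vanishingly
  ## rare at the default sizes; fail loudly instead of looping)
  out <- hla_pheno(ids, status)
  attr(out, "causal") <- list(gene = gene, aa_pos = aa_pos,
                              residue = residue, beta = beta,
                              marker = mk$id[j])
  out
}
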