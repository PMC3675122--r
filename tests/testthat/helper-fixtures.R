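# Shared fixtures: tiny hand-built typings/sequences and an exhaustive
# path-enumeration oracle for the haplotype-copying HMM.

# Ten individuals at genes A and B with known allele counts.
tiny_typings <- function() {
  rbind(
    hla_typing(sprintf("i%02d", 1:10), "A",
               c("A*0101", "A*0101", "A*0301", "A*0101", "A*0301",
                 "A*0101", "A*0301", "A*0301", "A*0101", "A*0101"),
               c("A*0301", "A*0101", "A*0301", "A*0101", "A*0101",
                 "A*0301", "A*0301", "A*0101", "A*0101", "A*0301")),
    hla_typing(sprintf("i%02d", 1:10), "B",
               rep(c("B*0702", "B*0801"), 5),
               rep(c("B*0702", "B*4402", "B*0801"), length.out = 10))
  )
}

# 5 alleles x 20 aligned positions for gene A with planted polymorphisms:
#  pos 3: residues {D, A}; pos 7: {K, R, T}; pos 12: one allele deleted
#  (2-residue run covers 12-13); all other positions monomorphic.
tiny_sequences <- function() {
  base <- strsplit("MGSHSMRYFDTAVSRPGRGE", "")[[1]]
  stopifnot(length(base) == 20)
  mk <- function(sub) {
    s <- base
    for (nm in names(sub)) s[as.integer(nm)] <- sub[[nm]]
    paste(s, collapse = "")
  }
  hla_sequences(
    gene = rep("A", 5),
    allele = c("A*0101", "A*0102", "A*0201", "A*0301", "A*2501"),
    seq = c(mk(list(`3` = "D", `7` = "K")),
            mk(list(`3` = "D", `7` = "R")),
            mk(list(`3` = "A", `7` = "K")),
            mk(list(`3` = "A", `7` = "T")),
            mk(list(`3` = "D", `7` = "K", `12` = "-", `13` = "-"))))
}

# Exhaustive Li-Stephens oracle: enumerate every copying path z in
# {1..K}^M, weight by uniform start, mixing transitions
# (P(k->k) = 1-rho+rho/K, P(k->j) = rho/K) and copy-error emissions,
# and average the copied allele per site.  Independent of the
# forward-backward code path.
oracle_pallele <- function(obs, ref, rho, theta) {
  M <- nrow(ref); K <- ncol(ref)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  logw <- rep(-log(K), nrow(paths))
  for (m in seq_len(M)) {
    if (m > 1) {
      same <- paths[, m] == paths[, m - 1]
      logw <- logw + log(ifelse(same, 1 - rho[m - 1] + rho[m - 1] / K,
                                rho[m - 1] / K))
    }
    if (!is.na(obs[m])) {
      a <- ref[cbind(m, paths[, m])]
      logw <- logw + log(ifelse(a == obs[m], 1 - theta, theta))
    }
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  vapply(seq_len(M), function(m) sum(w * ref[cbind(m, paths[, m])]), 0)
}

# deterministic small reference haplotype set
tiny_ref <- function(K, M, seed = 42) {
  set.seed(seed)
  matrix(rbinom(M * K, 1, 0.5), M, K)
}

small_sim <- function(seed = 5, K = 120, n_target = 25, M = 260) {
  simulate_panel(sim_config(K = K, n_target = n_target, M = M,
                            genes = c("A", "B", "DRB1"),
                            alleles_per_gene = 6, seed = seed))
}
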