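sim_marker_data <- function(n, beta, seed, maf = 0.3) {
  set.seed(seed)
  dose <- rbinom(n, 2, maf)
  p <- plogis(-0.2 + beta * dose)
  status <- rbinom(n, 1, p)
  list(dose = setNames(as.numeric(dose), sprintf("i%04d", seq_len(n))),
       pheno = hla_pheno(sprintf("i%04d", seq_len(n)), status))
}

test_that("per-marker logistic test recovers a planted effect", {
  # null: OR ~ 1
  d0 <- sim_marker_data(2000, 0, seed = 1)
  r0 <- test_marker(d0$dose, d0$pheno)
  expect_lt(abs(r0$beta), 0.2)
  expect_equal(r0$df, 1L)

  # planted log-OR 0.7 at n = 2000, averaged over seeds
  betas <- vapply(1:6, function(s) {
    d <- sim_marker_data(2000, 0.7, seed = 100 + s)
    test_marker(d$dose, d$pheno)$beta
  }, 0)
  expect_lt(abs(mean(betas) - 0.7), 0.15)

  # constant dosage is rejected
  expect_error(test_marker(rep(1, 100), d0$pheno[1:100, ]), "constant")
})

test_that("Wald and LRT p-values agree for well-behaved markers", {
  d <- sim_marker_data(1500, 0.4, seed = 7)
  r <- test_marker(d$dose, d$pheno)
  expect_false(r$separation)
  expect_equal(log10(r$p), log10(r$p_wald), tolerance = 0.1)
})

test_that("omnibus test equals the single-marker LRT at 2-residue positions", {
  d <- sim_marker_data(800, 0.5, seed = 3)
  D <- cbind(r1 = d$dose, r2 = 2 - d$dose)
  rownames(D) <- names(d$dose)
  om <- omnibus_position_test(D, d$pheno)
  single <- test_marker(d$dose, d$pheno)
  expect_equal(om$df, 1L)
  expect_equal(om$stat, single$stat, tolerance = 1e-6)
  expect_equal(om$p, single$p, tolerance = 1e-6)
})

test_that("omnibus statistic is invariant to the reference residue", {
  # 3-residue position; force different reference choices by reordering
  set.seed(21)
  n <- 600
  a <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  b <- vapply(a, function(x) sample(0:(2 - x), 1), 0L)
  D <- cbind(r1 = a, r2 = b, r3 = 2 - a - b)
  rownames(D) <- sprintf("i%04d", seq_len(n))
  ph <- hla_pheno(rownames(D), rbinom(n, 1, plogis(0.4 * a - 0.2)))
  stats <- vapply(list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)), function(o) {
    omnibus_position_test(D[, o], ph)$stat
  }, 0)
  expect_lt(max(stats) - min(stats), 1e-6)
  expect_equal(omnibus_position_test(D, ph)$df, 2L)
})

test_that("zero-variance residues are dropped with adjusted df", {
  set.seed(5)
  n <- 300
  a <- rbinom(n, 2, 0.4)
  D <- cbind(r1 = a, r2 = 2 - a, r3 = rep(0, n))
  rownames(D) <- sprintf("i%03d", seq_len(n))
  ph <- hla_pheno(rownames(D), rbinom(n, 1, 0.5))
  om <- omnibus_position_test(D, ph)
  expect_equal(om$df, 1L)
  expect_equal(om$dropped[[1]], "r3")
})

test_that("null p-values are uniform under permutation", {
  # fixed dosages, permuted phenotypes; marker and omnibus tests
  set.seed(77)
  n <- 400
  dose <- rbinom(n, 2, 0.3)
  names(dose) <- sprintf("i%04d", seq_len(n))
  b <- vapply(2 - dose, function(x) if (x > 0) sample(0:x, 1) else 0L, 0L)
  D <- cbind(r1 = dose, r2 = b, r3 = 2 - dose - b)
  rownames(D) <- names(dose)
  status0 <- rbinom(n, 1, 0.5)
  nrep <- 400
  pm <- numeric(nrep); po <- numeric(nrep)
  for (r in seq_len(nrep)) {
    ph <- hla_pheno(names(dose), sample(status0))
    pm[r] <- test_marker(dose, ph)$p
    po[r] <- omnibus_position_test(D, ph)$p
  }
  expect_gt(suppressWarnings(stats::ks.test(pm, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(po, "punif"))$p.value, 0.01)
})

test_that("signal ranking is stable and p-ordered", {
  res <- rbind(
    data.frame(marker = "m2", beta = 1, se = 1, or = 1, stat = 9, df = 1,
               p = 0.01, p_wald = 0.01, separation = FALSE),
    data.frame(marker = "m1", beta = 1, se = 1, or = 1, stat = 1, df = 1,
               p = 0.5, p_wald = 0.5, separation = FALSE),
    data.frame(marker = "m0", beta = 1, se = 1, or = 1, stat = 9, df = 1,
               p = 0.01, p_wald = 0.01, separation = FALSE))
  rk <- rank_signals(res)
  expect_equal(rk$marker, c("m0", "m2", "m1"))  # ties broken by id
  expect_equal(rk$rank, 1:3)
  empty <- res[0, ]
  expect_equal(nrow(rank_signals(empty)), 0)
})

test_that("a planted causal residue tops the omnibus scan", {
  sim <- simulate_panel(sim_config(K = 300, n_target = 600, M = 300,
                                   genes = c("A", "B", "DQB1", "DRB1"),
                                   seed = 61))
  mk <- sim$panel$markers
  aa <- mk[mk$kind == "AA" & mk$gene == "DQB1", ]
  # pick a reasonably common residue as causal
  cand <- aa[aa$freq > 0.2 & aa$freq < 0.8, ]
  residue <- sub(".*_", "", cand$id[1])
  ph <- simulate_phenotypes(sim, "DQB1", cand$aa_pos[1], residue,
                            beta = log(2))
  truth_d <- true_dosages(sim)
  res <- list(dosage = truth_d, markers = mk, ids = rownames(truth_d))
  scan <- rank_signals(assoc_scan(res, ph, kinds = character(0)))
  top <- scan$marker[1]
  expect_equal(top, paste0("AApos_DQB1:", cand$aa_pos[1]))
})

test_that("haplotype odds ratios are anchored at the reference", {
  set.seed(41)
  n <- 800
  hap_pool <- c("DRB1*01-DQA1*0101-DQB1*0501",
                "DRB1*03-DQA1*0501-DQB1*0201",
                "DRB1*04-DQA1*0301-DQB1*0302",
                "DRB1*15-DQA1*0102-DQB1*0602")
  freqs <- c(0.35, 0.25, 0.2, 0.2)
  risk <- c(0, log(3), log(0.5), 0)  # per-copy log-OR vs reference
  h1 <- sample(hap_pool, n, TRUE, freqs)
  h2 <- sample(hap_pool, n, TRUE, freqs)
  eta <- -0.5 + risk[match(h1, hap_pool)] + risk[match(h2, hap_pool)]
  status <- rbinom(n, 1, plogis(eta))
  ids <- sprintf("i%04d", seq_len(n))
  haps <- data.frame(id = rep(ids, each = 2),
                     DRB1 = sub("-.*", "", as.vector(rbind(h1, h2))),
                     DQA1 = sub(".*-(DQA1[^-]*)-.*", "\\1",
                                as.vector(rbind(h1, h2))),
                     DQB1 = sub(".*-", "", as.vector(rbind(h1, h2))),
                     stringsAsFactors = FALSE)
  ph <- hla_pheno(ids, status)
  out <- haplotype_odds_ratios(haps, ph, reference = hap_pool[1])
  expect_equal(out$or[out$haplotype == hap_pool[1]], 1)
  expect_true(is.na(out$ci_lower[out$haplotype == hap_pool[1]]))
  r3 <- out[out$haplotype == hap_pool[2], ]
  expect_gt(r3$or, 1.8)
  expect_true(r3$ci_lower < 3 && r3$ci_upper > 3 * 0.7)
  # haplotype observations are conserved: 2n
  expect_equal(sum(out$n_case + out$n_control), 2 * n)
  # individual order invariance
  perm <- sample(n)
  haps2 <- haps[as.vector(rbind(2 * perm - 1, 2 * perm)), ]
  out2 <- haplotype_odds_ratios(haps2, ph, reference = hap_pool[1])
  expect_equal(out2[order(out2$haplotype), "or"],
               out[order(out$haplotype), "or"], tolerance = 1e-10)
  # missing reference is rejected by name
  expect_error(haplotype_odds_ratios(haps, ph, reference = "DRB1*99-X-Y"),
               "DRB1\\*99")
})

test_that("degenerate haplotype cells get continuity handling and a flag", {
  set.seed(13)
  n <- 200
  ids <- sprintf("i%03d", seq_len(n))
  lab <- rep(c("ref", "common", "ctl_only"), times = c(200, 180, 20))
  lab <- sample(lab)[seq_len(2 * n)]
  status <- rbinom(n, 1, 0.5)
  # force ctl_only absent from cases
  carrier <- unique(ceiling(which(lab == "ctl_only") / 2))
  status[carrier] <- 0
  haps <- data.frame(id = rep(ids, each = 2), H = lab,
                     stringsAsFactors = FALSE)
  ph <- hla_pheno(ids, status)
  out <- haplotype_odds_ratios(haps, ph, reference = "ref", floor = 0)
  row <- out[out$haplotype == "ctl_only", ]
  expect_true(row$degenerate)
  expect_true(is.finite(row$or))
})

test_that("dosage sanity check flags corrupted rows", {
  sim <- small_sim(seed = 27, K = 50, n_target = 8, M = 100)
  tgt <- make_target(sim, "dense")
  h <- harmonize(tgt$target, sim$panel)
  res <- impute(h, sim$panel, hmm_params(seed = 2, iterations = 3))
  chk <- dosage_sanity_check(res)
  expect_true(chk$pass)
  # corrupt one individual's A-gene dosages
  mk <- res$markers
  cols <- mk$id[mk$kind == "HLA4" & mk$gene == "A"]
  res$dosage[2, cols] <- res$dosage[2, cols] * 0.6
  chk2 <- dosage_sanity_check(res)
  expect_false(chk2$pass)
  expect_true(all(chk2$failures$id == res$ids[2]))
  # tol = 0 flags soft dosages
  chk3 <- dosage_sanity_check(res, tol = 0)
  expect_false(chk3$pass)
})
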