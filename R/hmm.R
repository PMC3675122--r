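#' Parameters of the haplotype-copying imputation HMM
#'
#' The sample haplotype is modelled as a mosaic of the K reference
#' haplotypes.  Between adjacent markers the copied haplotype switches
#' with probability `1 - exp(-4 Ne d / K)` where `d` is the genetic
#' distance in Morgans (`cm_per_mb` centimorgans per megabase); at each
#' site the observed allele differs from the copied allele with
#' probability `theta` (copy error).  The default `theta` is the
#' population-genetic mutation estimate
#' `tilde(theta) / (2 (K + tilde(theta)))` with
#' `tilde(theta) = 1 / sum_{k=1}^{K-1} 1/k`.
#'
#' @param ne Effective population size scaling the switch rate
#'   (default 15000).
#' @param cm_per_mb Recombination map density, centimorgans per megabase
#'   (default 1, a uniform map).
#' @param theta Copy-error probability per site; `NULL` (default) uses
#'   the Li-Stephens estimate, which depends on the panel size K.
#' @param iterations Phasing sweeps for target individuals (default 10).
#' @param window Markers per processing window; 0 (default) runs the full
#'   region as one chain.  Positive values process overlapping windows of
#'   this many markers and splice their centres, for very dense chips.
#' @param seed Integer seed controlling phasing initialisation.
#' @return List of class `hmm_params`.
#' @export
hmm_params <- function(ne = 15000, cm_per_mb = 1.0, theta = NULL,
                       iterations = 10L, window = 0L, seed = 1L) {
  stopifnot(ne > 0, cm_per_mb > 0, iterations >= 1, window >= 0)
  if (!is.null(theta)) stopifnot(theta > 0, theta < 1)
  out <- list(ne = ne, cm_per_mb = cm_per_mb, theta = theta,
              iterations = as.integer(iterations),
              window = as.integer(window), seed = as.integer(seed))
  class(out) <- "hmm_params"
  out
}

#' Li-Stephens default copy-error rate for a panel of K haplotypes
#' @param K Number of reference haplotypes.
#' @return Mismatch probability in (0, 1).
#' @export
ls_theta <- function(K) {
  stopifnot(K >= 2)
  tt <- 1 / sum(1 / seq_len(K - 1))
  tt / (2 * (K + tt))
}

resolve_theta <- function(params, K) {
  if (!is.null(params$theta)) params$theta else ls_theta(K)
}

#' Per-interval switch probabilities from marker positions
#' @param pos Base-pair positions (sorted).
#' @param K Reference haplotype count.
#' @param ne,cm_per_mb See [hmm_params()].
#' @return Numeric vector of length `length(pos) - 1`.
#' @export
switch_rates <- function(pos, K, ne = 15000, cm_per_mb = 1.0) {
  d_morgans <- diff(pos) * cm_per_mb * 1e-8
  r <- 1 - exp(-4 * ne * d_morgans / K)
  pmin(pmax(r, 1e-12), 1 - 1e-12)
}

#' Haploid forward-backward pass of the copying HMM
#'
#' Low-level access to the engine: given one haplotype's observed alleles
#' (0/1, `NA` = unobserved) and the reference haplotypes, returns the
#' posterior probability that the copied reference allele is 1 at every
#' marker, the leave-one-out predictive probability of observing allele 1
#' at each site, and the log-likelihood.
#'
#' @param obs Integer vector (0/1/NA) along the marker chain.
#' @param ref K reference haplotypes as a markers x K matrix (0/1).
#' @param rho Switch probabilities per interval (length M-1).
#' @param theta Copy-error probability.
#' @return List with `pallele`, `loo`, `loglik`.
#' @export
ls_forward_backward <- function(obs, ref, rho, theta) {
  obs <- as.integer(obs)
  obs[is.na(obs)] <- -1L
  .ls_fb_cpp(obs, ref, as.numeric(rho), theta)
}
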