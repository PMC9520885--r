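# Shared fixture builders (all generated in code, fixed seeds set by the
# calling tests).

# panel whose sites are exactly the five tag sites: chromosomes drawn
# from named haplotype frequencies
tag_only_panel <- function(hap_freq, n_ind) {
  haps <- names(hap_freq)
  L <- nchar(haps[1L])
  draws <- sample(haps, 2L * n_ind, replace = TRUE, prob = hap_freq)
  alleles <- do.call(rbind, lapply(strsplit(draws, ""), as.integer))
  haplotype_panel(alleles, positions = seq_len(L) * 1000,
                  distances = rep(1e-4, L - 1L),
                  sample_id = rep(sprintf("I%04d", seq_len(n_ind)), each = 2),
                  tag_sites = seq_len(L))
}

# case-control cohort drawn from haplotype frequencies with an additive
# log-OR on the target haplotype; returns unphased genotypes + outcome
sim_case_control <- function(n, hap_freq, target, log_or, alpha = qlogis(0.3)) {
  panel <- tag_only_panel(hap_freq, n)
  dos <- haplotype_dosages(panel)
  d_t <- if (target %in% colnames(dos)) dos[, target] else rep(0L, n)
  y <- rbinom(n, 1L, plogis(alpha + log_or * d_t))
  list(genotypes = panel_genotypes(panel), y = y, dose_target = d_t,
       panel = panel)
}

# random small painting instance for HMM oracle comparisons
random_hmm_instance <- function(D, L) {
  list(target = rbinom(L, 1L, 0.5),
       donors = matrix(rbinom(D * L, 1L, 0.5), D, L),
       distances = runif(L - 1L, 0.001, 0.05),
       rho = runif(1, 0.5, 5), theta = runif(1, 0.05, 0.3))
}
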