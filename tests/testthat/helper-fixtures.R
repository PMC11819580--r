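# Shared builders for small, fully in-code fixtures.

# a minimal three-member genotype table around explicit per-site calls;
# `calls` is a list of lists with fields gt = c(father, mother, child) and
# optional overrides for dp/gq/ad/strand/concordance
tiny_trio_table <- function(calls, contig = "chr1",
                            samples = c("fa", "mo", "ch")) {
  n <- length(calls)
  take <- function(field, default) {
    t(vapply(calls, function(cl) {
      v <- cl[[field]]
      if (is.null(v)) rep(default, 3) else rep_len(v, 3)
    }, numeric(3)))
  }
  gt <- t(vapply(calls, function(cl) cl$gt, numeric(3)))
  dp <- take("dp", 40)
  gq <- take("gq", 80)
  ad_alt <- take("ad_alt", NA)
  miss <- is.na(ad_alt)
  ad_alt[miss] <- (dp * (gt / 2))[miss]  # AB from genotype when not forced
  ad_ref <- take("ad_ref", NA)
  ad_ref[is.na(ad_ref)] <- (dp - ad_alt)[is.na(ad_ref)]
  fwd <- take("fwd_alt", NA); fwd[is.na(fwd)] <- floor(ad_alt / 2)[is.na(fwd)]
  rev <- take("rev_alt", NA); rev[is.na(rev)] <- (ad_alt - fwd)[is.na(rev)]
  conc <- take("concordant", 1) == 1
  sites <- data.frame(contig = contig, pos = seq_len(n) * 1000L,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  colnames(gt) <- samples
  genotype_table(sites, gt, dp, gq, ad_ref, ad_alt, fwd, rev, conc,
                 samples = samples)
}

tiny_trio <- function(samples = c("fa", "mo", "ch")) {
  data.frame(child_id = samples[3], father_id = samples[1],
             mother_id = samples[2], paternal_age = 10, maternal_age = 10,
             stringsAsFactors = FALSE)
}

# small but fully exercised simulated cohort used across tests
small_sim <- function(seed = 11, n_trios = 4, het_rate = 1e-3,
                      grandchildren = 0, ...) {
  cf <- sim_config(
    n_trios = n_trios,
    genome = data.frame(contig = c("c1", "c2", "c3"),
                        length = rep(1e6, 3), is_X = FALSE),
    het_rate = het_rate, beta0 = 2, betaP = 3e-7, betaM = 1.2e-6,
    grandchildren = grandchildren, ...)
  simulate_cohort(cf, seed = seed)
}

# clean-evidence config: no caller noise, no error reads, tight GQ, so
# every injected DNM satisfies all filters
clean_sim <- function(seed = 11, n_trios = 4, het_rate = 1e-3,
                      grandchildren = 0) {
  cf <- sim_config(
    n_trios = n_trios,
    genome = data.frame(contig = c("c1", "c2", "c3"),
                        length = rep(1e6, 3), is_X = FALSE),
    het_rate = het_rate, beta0 = 2, betaP = 3e-7, betaM = 1.2e-6,
    gq_mean = 95, gq_sd = 1, ab_sd = 0.01,
    caller_discordance_rate = 0, error_alt_rate = 0,
    depth_mean = 40, grandchildren = grandchildren,
    exact_evidence = TRUE)
  simulate_cohort(cf, seed = seed)
}

# brute-force two-sided exact binomial (minimum-likelihood convention)
binom_two_sided_oracle <- function(k, n, p = 0.5) {
  probs <- stats::dbinom(0:n, n, p)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# hypergeometric enumeration oracle for the two-sided Fisher p-value
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}
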