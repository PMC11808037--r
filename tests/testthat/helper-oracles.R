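# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the logistic oracle is a dense grid search over
# the Bernoulli log-likelihood, the domain oracle a literal scan over the
# 15 ranges.

# maximize sum(y * lp - log1p(exp(lp))) for lp = b0 + b1 * x by iteratively
# refined grid search over (b0, b1)
grid_logit_oracle <- function(y, x, span = 10, n_grid = 101, rounds = 5) {
  center <- c(0, 0)
  loglik <- function(b0, b1) {
    lp <- b0 + b1 * x
    sum(y * lp - log1p(exp(lp)))
  }
  for (r in seq_len(rounds)) {
    b0s <- seq(center[1] - span, center[1] + span, length.out = n_grid)
    b1s <- seq(center[2] - span, center[2] + span, length.out = n_grid)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    center <- c(b0s[best[1]], b1s[best[2]])
    span <- 4 * (b0s[2] - b0s[1])
  }
  c(intercept = center[1], beta = center[2])
}

# brute-force domain lookup: loop over ranges, first (unique) hit wins
scan_domain_oracle <- function(aa) {
  starts <- c(28, 91, 155, 219, 291, 361, 431, 490, 561, 626, 701, 768,
              843, 910, 987)
  ends <- c(66, 153, 216, 285, 352, 423, 489, 551, 622, 688, 757, 830,
            905, 971, 1048)
  vapply(aa, function(a) {
    for (d in 1:15) if (a >= starts[d] && a <= ends[d]) return(d)
    NA_integer_
  }, integer(1))
}

# a small valid cohort data frame for io tests
make_cohort_df <- function(n = 4) {
  base <- tibble::tibble(
    patient_id = paste0("P", seq_len(n)),
    source = "test",
    age_years = seq_len(n),
    allele1_cdna = rep(c("c.153delT", "c.1887+1G>A"), length.out = n),
    allele2_cdna = rep(c("c.153delT", "c.995delT"), length.out = n),
    died_in_infancy = "NA"
  )
  for (p in phenotype_names()) base[[p]] <- "+"
  base
}
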