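# independent arithmetic for the single-variant log ABF, written as the
# ratio of a marginal likelihood to the null likelihood
labf_reference <- function(beta, se, sd0) {
  log(stats::dnorm(beta, 0, sqrt(se^2 + sd0^2)) / stats::dnorm(beta, 0, se))
}

# brute-force posterior over every causal-configuration assignment for m
# variants: configurations are (none), (i, trait1 only), (j, trait2 only),
# (i != j, both), (i, shared)
enumerate_coloc <- function(b1, s1, b2, s2, p1, p2, p12, sd1, sd2) {
  m <- length(b1)
  l1 <- vapply(seq_len(m), function(i) labf_reference(b1[i], s1[i], sd1),
               numeric(1))
  l2 <- vapply(seq_len(m), function(i) labf_reference(b2[i], s2[i], sd2),
               numeric(1))
  w <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(m)) {
    w["H1"] <- w["H1"] + p1 * exp(l1[i])
    w["H2"] <- w["H2"] + p2 * exp(l2[i])
    w["H4"] <- w["H4"] + p12 * exp(l1[i] + l2[i])
    for (j in seq_len(m)) {
      if (i != j) w["H3"] <- w["H3"] + p1 * p2 * exp(l1[i] + l2[j])
    }
  }
  w / sum(w)
}
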