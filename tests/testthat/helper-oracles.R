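# Independent brute-force oracles, kept deliberately naive: they enumerate
# outcomes directly and share no code with the implementations they check.

# Two-sided binomial p-value by explicit enumeration of all 2^n
# success/failure sequences (feasible for n <= ~14): accumulate the exact
# point probability of each success count, then sum the probabilities of
# all counts whose point probability does not exceed that of the observed
# count (up to the same relative tolerance the test definition uses).
binom_enum_oracle <- function(x, n, p0) {
  seqs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  k <- rowSums(seqs)
  pr <- p0^k * (1 - p0)^(n - k)
  dk <- as.numeric(tapply(pr, factor(k, levels = 0:n), sum))
  dk[is.na(dk)] <- 0
  sum(dk[dk <= dk[x + 1] * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p-value by complete enumeration of all
# choose(n_a + n_b, n_a) group labelings of the pooled sample.
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  us <- apply(utils::combn(length(pooled), m), 2,
              function(idx) sum(r[idx]) - m * (m + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(lower, upper)))
}
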