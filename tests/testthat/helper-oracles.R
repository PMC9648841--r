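# Independent enumeration of the signal-duration distribution: sum over
# onset slots of the per-step offset process, with the forced offset before
# the decision step.
duration_pmf_oracle <- function(l, params) {
  N <- params$N; N1 <- params$N1; q <- params$q
  total <- 0
  for (s in (params$N0 + 1):(N - 1)) {
    last <- s + l - 1
    if (last < N - 1) total <- total + q * (1 - q)^(l - 1) / N1
    if (last == N - 1) total <- total + (1 - q)^(l - 1) / N1
  }
  total
}
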