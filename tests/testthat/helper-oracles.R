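# Independent enumeration oracles for the rank tests.

# enumeration oracle: exact two-sided Mann-Whitney p by listing all
# C(n1+n2, n1) group assignments of the pooled values
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- combn(length(pooled), n1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# sign-enumeration oracle for the signed-rank test
wsr_exact_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
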