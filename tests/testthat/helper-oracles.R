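# Exhaustive two-sided Mann-Whitney p by full enumeration of group
# assignments (no ties assumed).
enumerate_mwu <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(idx, 2, u_of)
  mu <- n1 * (length(b)) / 2
  if (u_obs <= mu) p <- 2 * mean(us <= u_obs) else p <- 2 * mean(us >= u_obs)
  list(u = u_obs, p = min(p, 1))
}
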