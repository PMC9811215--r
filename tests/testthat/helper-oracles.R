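# Independent statistical oracles, deliberately kept free of the package's
# code paths: exhaustive enumeration of the Mann-Whitney statistic over all
# group assignments, and the Kruskal-Wallis H from the rank-sum formula.

perm_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(length(pooled), n1)
  u_all <- apply(assignments, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  center <- n1 * length(y) / 2
  mean(abs(u_all - center) >= abs(u_obs - center))
}

kw_h_formula <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
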