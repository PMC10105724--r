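# shared fixtures, built in code

# canonical 3-pool parameter set with well-separated rates
fx_params3 <- function() pool_kinetics(c(0.1, 0.3, 0.6), c(0.05, 2e-3, 5e-5))

fx_params2 <- function() pool_kinetics(c(0.2, 0.8), c(0.05, 0.005))

# regular 60-point grid over a year
fx_times60 <- function() seq(365 / 60, 365, length.out = 60)

# minimal valid compiled-table data.frame (before validation)
fx_table_df <- function(n = 6) {
  data.frame(
    record_id = sprintf("R%02d", seq_len(n)),
    source_id = "S01",
    latitude = seq(-40, 60, length.out = n),
    longitude = seq(-120, 120, length.out = n),
    model_type = rep(c("M2", "M3"), length.out = n),
    f1 = 0.2, f2 = ifelse(rep(c(FALSE, TRUE), length.out = n), 0.3, NA),
    f3 = NA,
    k1 = 0.1, k2 = 1e-3,
    k3 = ifelse(rep(c(FALSE, TRUE), length.out = n), 1e-5, NA),
    sand = 40, silt = 35, clay = 25, ph = 6.5
  )
}

# brute-force Spearman: average ranks then Pearson
fx_spearman_oracle <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# exhaustive permutation p-value for the two-group Kruskal-Wallis H
fx_kw_perm_p <- function(g1, g2) {
  x <- c(g1, g2)
  n1 <- length(g1)
  idx <- utils::combn(length(x), n1)
  h_of <- function(a) kruskal_wallis(list(x[a], x[-a]))$H
  h_obs <- h_of(seq_len(n1))
  hs <- apply(idx, 2, h_of)
  mean(hs >= h_obs - 1e-12)
}
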