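# small shared fixtures, generated in code

# a modest simulated study reused across test files
small_sim_config <- function(seed = 101, ...) {
  simulation_config(
    n_probes = 1200,
    n_effect_probes = c(scenario1 = 0, scenario2 = 0, scenario3 = 25),
    n_cellmix_probes = 60,
    n_covariate_probes = 30,
    repeat_track_spec = list(
      Alu = list(n_intervals = 15, length = 300, n_probes = 40, n_effect = 0),
      LINE1 = list(n_intervals = 10, length = 1000, n_probes = 40, n_effect = 0)),
    seed = seed, ...)
}

# noiseless, bias-free configuration: planted means pass through exactly
exact_sim_config <- function(seed = 7, ...) {
  simulation_config(
    n_probes = 300,
    n_effect_probes = c(scenario1 = 0, scenario2 = 0, scenario3 = 10),
    n_cellmix_probes = 0, n_covariate_probes = 0,
    noise_sd_m = 0, subject_sd_m = 0,
    frac_typeII = 0.5, typeII_compression = 1,
    frac_detection_fail = 0, frac_missing = 0,
    repeat_track_spec = list(
      Alu = list(n_intervals = 5, length = 300, n_probes = 10, n_effect = 0),
      LINE1 = list(n_intervals = 5, length = 1000, n_probes = 10, n_effect = 0)),
    mirna_spec = list(loci = c("miR-21", "miR-30e", "miR-215", "miR-144"),
                      n_probes = 7, effect_delta = NULL),
    seed = seed, ...)
}

# independent sort-and-average oracle for quantile normalization
qn_oracle <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) {
    out <- numeric(length(col))
    r <- rank(col, ties.method = "average")
    # average the target values of tied ranks
    out <- vapply(r, function(ri) {
      lo <- floor(ri); hi <- ceiling(ri)
      mean(target[c(lo, hi)])
    }, 0)
    out
  })
}

# full-enumeration oracle for the two-sided exact rank-sum p-value
wilcox_enum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  v <- c(x, y)
  idx <- utils::combn(n, n1)
  u_all <- apply(idx, 2, function(ii) {
    sum(rank(v)[ii]) - n1 * (n1 + 1) / 2
  })
  u_obs <- sum(rank(v)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  eu <- mean(u_all)
  mean(abs(u_all - eu) >= abs(u_obs - eu) - 1e-9)
}

# independent Benjamini-Hochberg step-up implementation
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
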