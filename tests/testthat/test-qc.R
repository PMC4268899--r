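toy_annotation <- function(ids, on_xy = FALSE, ch = FALSE, poly = FALSE) {
  n <- length(ids)
  data.frame(probe_id = ids, chr = "chr1", pos = seq(1000, by = 1000,
                                                     length.out = n),
             probe_type = "II", channel = "Both", gene = "G",
             on_xy = rep_len(on_xy, n), cross_hybridizing = rep_len(ch, n),
             polymorphic = rep_len(poly, n), stringsAsFactors = FALSE)
}

test_that("filtering removes probes stage by stage in fixed order", {
  ids <- paste0("p", 1:5)
  beta <- matrix(0.5, 5, 3, dimnames = list(ids, paste0("s", 1:3)))
  detp <- matrix(0, 5, 3, dimnames = dimnames(beta))
  detp["p1", 2] <- 0.02                    # stage 1: detection
  beta["p2", 3] <- NA                      # stage 1: missing
  anno <- toy_annotation(ids)
  anno$on_xy[3] <- TRUE                    # stage 2
  anno$polymorphic[4] <- TRUE              # stage 3
  res <- filter_probes(beta, anno, detp)
  expect_equal(res$kept, "p5")
  expect_equal(unname(res$report$removed), c(2L, 1L, 1L))
  # stage counts sum to input - output
  expect_equal(sum(res$report$removed),
               res$report$n_input - res$report$n_kept)
})

test_that("stage order matters: an X/Y probe failing detection counts at stage 1", {
  ids <- paste0("p", 1:3)
  beta <- matrix(0.5, 3, 2, dimnames = list(ids, c("a", "b")))
  detp <- matrix(0, 3, 2, dimnames = dimnames(beta))
  detp["p1", 1] <- 0.5
  anno <- toy_annotation(ids)
  anno$on_xy[1] <- TRUE                    # also flagged, but caught earlier
  res <- filter_probes(beta, anno, detp)
  expect_equal(unname(res$report$removed), c(1L, 0L, 0L))
})

test_that("clean input passes unfiltered and empty survival errors", {
  ids <- paste0("p", 1:4)
  beta <- matrix(runif(8), 4, 2, dimnames = list(ids, c("a", "b")))
  anno <- toy_annotation(ids)
  res <- filter_probes(beta, anno, detp = matrix(0, 4, 2,
                                                 dimnames = dimnames(beta)))
  expect_equal(res$kept, ids)
  anno2 <- toy_annotation(ids, poly = TRUE)
  expect_error(filter_probes(beta, anno2), "no probes survive")
})

test_that("quantile normalization matches the sort-and-average oracle", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 6, 8))
  got <- quantile_normalize(x)
  expect_equal(unname(got[, 1]), c(2.5, 4, 5.5))
  expect_equal(unname(got[, 2]), c(2.5, 4, 5.5))
  set.seed(8)
  y <- matrix(rlnorm(600), 100, 6)
  expect_equal(unname(quantile_normalize(y)), unname(qn_oracle(y)),
               tolerance = 1e-10)
})

test_that("quantile normalization is idempotent, rank-preserving, and a fixed point on equal columns", {
  set.seed(9)
  y <- matrix(rnorm(500), 100, 5)
  q1 <- quantile_normalize(y)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  for (j in 1:5) expect_equal(rank(q1[, j]), rank(y[, j]))
  # identical columns are unchanged
  z <- matrix(rep(sort(rnorm(50)), 3), 50, 3)
  expect_equal(quantile_normalize(z), z, ignore_attr = TRUE)
  # column-wise sorted vectors are equal across columns
  s <- apply(q1, 2, sort)
  expect_true(all(abs(s - s[, 1]) < 1e-12))
})

test_that("colour-bias correction aligns the red channel onto green", {
  set.seed(10)
  n <- 2000
  channel <- rep(c("Grn", "Red"), each = n / 2)
  g <- rlnorm(n / 2, 7, 0.5)
  # constant offset removed
  x1 <- matrix(c(g, g + 500), ncol = 1)
  c1 <- color_bias_correct(x1, channel)
  expect_lt(abs(median(c1[channel == "Red", 1]) -
                  median(c1[channel == "Grn", 1])), 20)
  # identically distributed channels: map close to identity
  x2 <- matrix(c(g, rlnorm(n / 2, 7, 0.5)), ncol = 1)
  c2 <- color_bias_correct(x2, channel)
  expect_lt(median(abs(c2[channel == "Red", 1] - x2[channel == "Red", 1])) /
              median(g), 0.1)
  # red = 2 x green: post-correction quantiles agree within 1%
  x3 <- matrix(c(g, 2 * rlnorm(n / 2, 7, 0.5)), ncol = 1)
  c3 <- color_bias_correct(x3, channel)
  qs <- seq(0.05, 0.95, by = 0.05)
  qr <- quantile(c3[channel == "Red", 1], qs)
  qg <- quantile(c3[channel == "Grn", 1], qs)
  expect_true(all(abs(qr - qg) / qg < 0.01))
})

test_that("colour-bias correction skips tiny channels with a warning", {
  x <- matrix(rlnorm(20), ncol = 1)
  channel <- c(rep("Grn", 15), rep("Red", 5))
  expect_warning(out <- color_bias_correct(x, channel), "skipped")
  expect_identical(out, x)
})

test_that("peak correction recovers a known type II compression", {
  for (comp in c(0.7, 0.85)) {
    sim <- generate_dataset(simulation_config(seed = 61,
                                              typeII_compression = comp))
    pc <- peak_correct(beta_to_m(sim$beta), sim$annotation)
    expect_false(is.null(pc$map))
    expect_lt(abs(pc$map$slope - 1 / comp) / (1 / comp), 0.05)
  }
})

test_that("peak correction is near-identity without compression and passes through degenerate input", {
  sim <- generate_dataset(simulation_config(seed = 71, typeII_compression = 1))
  pc <- peak_correct(beta_to_m(sim$beta), sim$annotation)
  expect_lt(abs(pc$map$slope - 1), 0.05)
  expect_lt(abs(pc$map$intercept), 0.3)
  # unimodal M values: no two peaks, pass-through with warning
  ids <- paste0("p", 1:200)
  m1 <- matrix(rnorm(200 * 4, mean = 3, sd = 0.2), 200, 4,
               dimnames = list(ids, paste0("s", 1:4)))
  anno <- toy_annotation(ids)
  anno$probe_type <- rep(c("I", "II"), 100)
  expect_warning(out <- peak_correct(m1, anno), "skipped")
  expect_identical(out$m, m1)
})

test_that("beta from intensities and back behaves", {
  meth <- matrix(c(900, 100), 2, 1)
  unmeth <- matrix(c(0, 900), 2, 1)
  b <- intensities_to_beta(meth, unmeth)
  expect_equal(b[1, 1], 900 / 1000)         # offset 100 in the denominator
  expect_equal(b[2, 1], 100 / 1100)
})
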