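test_that("generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 5)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$detp, b$detp)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(small_sim_config(seed = 6))
  expect_false(identical(a$beta, c$beta))
})

test_that("design structure: 96 samples, counterbalanced order, complete blocks", {
  sim <- generate_dataset(small_sim_config())
  sh <- sim$sheet
  expect_equal(ncol(sim$beta), 96)          # 16 subjects x 2 arms x 3 times
  expect_equal(nrow(sh), 96)
  expect_equal(unname(table(sh$arm)), c(48L, 48L), ignore_attr = TRUE)
  per_subject <- table(sh$subject)
  expect_true(all(per_subject == 6))
  ord <- unique(sh[, c("subject", "order")])
  expect_equal(sum(ord$order == "DE_first"), 8)
  # subject-level covariates constant within subject
  for (v in c("age", "bmi", "sex", "gstp1", "order"))
    expect_true(all(tapply(sh[[v]], sh$subject,
                           function(x) length(unique(x))) == 1))
})

test_that("no-signal configuration yields constant probes and zero delta", {
  cfg <- exact_sim_config(seed = 3)
  cfg$n_effect_probes[] <- 0L
  sim <- generate_dataset(cfg)
  expect_true(all(apply(sim$beta, 1, function(x) diff(range(x)) == 0)))
  expect_true(all(sim$truth$planted_delta_beta == 0))
  db <- delta_beta(sim$beta, sim$sheet)
  expect_equal(db$delta_beta_DE, rep(0, nrow(sim$beta)))
  expect_equal(db$delta_beta_FA, rep(0, nrow(sim$beta)))
})

test_that("planted scenario-3 shift is recovered by direct averaging", {
  # noise-free: exact recovery of the signed planted shift
  sim0 <- generate_dataset(exact_sim_config(seed = 9))
  mask <- sim0$sheet$arm == "DE" & sim0$sheet$timepoint != 0
  planted <- sim0$truth$probe_id[sim0$truth$label == "scenario3"]
  got <- rowMeans(sim0$beta[planted, mask]) -
    rowMeans(sim0$beta[planted, !mask])
  expect_equal(unname(got),
               sim0$truth[planted, "planted_delta_beta"], tolerance = 1e-9)
  # with noise: recovery within 3 standard errors
  cfg <- small_sim_config(seed = 13, typeII_compression = 1)
  sim <- generate_dataset(cfg)
  mask <- sim$sheet$arm == "DE" & sim$sheet$timepoint != 0
  planted <- sim$truth$probe_id[sim$truth$label == "scenario3"]
  for (p in planted) {
    d <- mean(sim$beta[p, mask]) - mean(sim$beta[p, !mask])
    se <- sqrt(var(sim$beta[p, mask]) / sum(mask) +
                 var(sim$beta[p, !mask]) / sum(!mask))
    expect_lt(abs(d - sim$truth[p, "planted_delta_beta"]),
              3 * se + 0.005)  # small allowance for logit-noise attenuation
  }
})

test_that("cell-mixture slopes are recovered by per-probe OLS", {
  cfg <- small_sim_config(seed = 23, noise_sd_m = 0.05, subject_sd_m = 0,
                          typeII_compression = 1)
  sim <- generate_dataset(cfg)
  cm <- sim$truth$probe_id[sim$truth$label == "cellmix"]
  sl <- sim$config$cellmix_slopes
  sign_p <- sim$truth[cm, "cellmix_sign"]
  fits <- t(vapply(cm, function(p) {
    f <- lm(sim$beta[p, ] ~ sim$sheet$lymphocytes + sim$sheet$monocytes)
    cf <- summary(f)$coefficients
    c(cf[2, 1], cf[2, 2], cf[3, 1], cf[3, 2])
  }, numeric(4)))
  expect_true(mean(abs(fits[, 1] - sign_p * sl[["lymphocytes"]]) <
                     3 * fits[, 2] + 0.005) > 0.9)
  expect_true(mean(abs(fits[, 3] - sign_p * sl[["monocytes"]]) <
                     3 * fits[, 4] + 0.01) > 0.9)
})

test_that("covariate probes track the assigned demographic", {
  cfg <- small_sim_config(seed = 31, noise_sd_m = 0.05, subject_sd_m = 0,
                          typeII_compression = 1)
  sim <- generate_dataset(cfg)
  idx <- which(sim$truth$label == "covariate" & sim$truth$covariate == "age")
  p <- sim$truth$probe_id[idx[1]]
  f <- lm(sim$beta[p, ] ~ sim$sheet$age)
  expect_lt(abs(coef(f)[2] - sim$config$covariate_slopes[["age"]]), 0.0005)
})

test_that("repeat track respects spec and planted boundary overlaps", {
  spec <- list(Alu = list(n_intervals = 10, length = 300),
               LINE1 = list(n_intervals = 4, length = 1000))
  tr <- generate_repeat_track(spec, seed = 2)
  expect_equal(sum(tr$class == "Alu"), 10)
  expect_equal(sum(tr$class == "LINE1"), 4)
  expect_true(all(tr$end > tr$start))
  # chromosome-sorted
  expect_false(is.unsorted(order(tr$chrom, tr$start)))

  sim <- generate_dataset(small_sim_config(seed = 41))
  bnd <- sim$truth[sim$truth$alu_overlap_bp %in% c(14, 15, 16) &
                     sim$truth$label == "null", ]
  expect_setequal(c(14L, 15L, 16L), unique(bnd$alu_overlap_bp))
  expect_true(all(bnd$in_alu[bnd$alu_overlap_bp >= 15]))
  expect_false(any(bnd$in_alu[bnd$alu_overlap_bp == 14]))
})

test_that("detection failures and missingness land where configured", {
  sim <- generate_dataset(small_sim_config(seed = 51))
  fail <- sim$truth$detection_fail
  expect_equal(sum(fail), round(0.01 * nrow(sim$beta)))
  expect_true(all(apply(sim$detp[fail, , drop = FALSE], 1,
                        function(x) any(x > 0.01))))
  expect_true(all(apply(sim$detp[!fail, , drop = FALSE], 1,
                        function(x) all(x <= 0.01))))
  miss <- sim$truth$has_missing
  expect_true(all(apply(sim$beta[miss, , drop = FALSE], 1, anyNA)))
  expect_false(anyNA(sim$beta[!miss, ]))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_probes = 100), "exceed")
  expect_error(simulation_config(frac_typeII = 1.5), "fractions")
  expect_error(simulation_config(typeII_compression = 0), "compression")
  expect_error(simulation_config(n_subjects = 15), "even")
})
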