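sim_lme <- generate_dataset(small_sim_config(seed = 113))
m_lme <- beta_to_m(sim_lme$beta)

test_that("mixed-model fixed effects equal OLS when subjects carry no intercepts", {
  cfg <- small_sim_config(seed = 121, subject_sd_m = 0)
  sim <- generate_dataset(cfg)
  m <- beta_to_m(sim$beta)
  probes <- sim$truth$probe_id[sim$truth$label == "scenario3"][1:5]
  fit <- fit_lme(m, sim$sheet, probes)
  d <- data.frame(exposure = factor(sim$sheet$arm, c("FA", "DE")),
                  time = factor(ifelse(sim$sheet$timepoint == 0, "pre",
                                       "post"), c("pre", "post")))
  for (p in probes) {
    ols <- coef(lm(m[p, ] ~ exposure * time, data = d))
    got <- unlist(fit[fit$probe_id == p,
                      c("b0", "b_exposure", "b_time", "b_interaction")])
    expect_equal(unname(got), unname(ols), tolerance = 1e-6)
  }
})

test_that("the DE-arm contrast recovers a planted M-scale shift with known subject intercepts", {
  set.seed(20)
  sheet <- sim_lme$sheet
  delta <- 0.8
  de_post <- sheet$arm == "DE" & sheet$timepoint != 0
  u <- rnorm(16, 0, 0.4)
  names(u) <- unique(sheet$subject)
  reps <- t(replicate(40, {
    y <- u[sheet$subject] + delta * de_post + rnorm(96, 0, 0.3)
    m1 <- matrix(y, 1, 96, dimnames = list("probe", sheet$sample_id))
    fit <- fit_lme(m1, sheet)
    c(est = fit$b_time + fit$b_interaction, se = fit$se_de)
  }))
  expect_true(mean(abs(reps[, "est"] - delta) < 3 * reps[, "se"]) > 0.9)
  # and the subject random-intercept SD is estimated near its truth
  y <- u[sheet$subject] + rnorm(96, 0, 0.3)
  m1 <- matrix(y, 1, 96, dimnames = list("probe", sheet$sample_id))
  fit <- fit_lme(m1, sheet)
  expect_lt(abs(fit$sd_subject - 0.4), 0.3)
})

test_that("time-flat probes give near-zero effect estimates; constants are flagged", {
  set.seed(22)
  sheet <- sim_lme$sheet
  u <- rnorm(16, 0, 0.5)
  names(u) <- unique(sheet$subject)
  y <- 2 + u[sheet$subject]                 # subject structure, no time effect
  m1 <- matrix(y + rnorm(96, 0, 1e-6), 1, 96,
               dimnames = list("probe", sheet$sample_id))
  fit <- fit_lme(m1, sheet)
  expect_lt(abs(fit$b_time), 1e-5)
  expect_lt(abs(fit$b_interaction), 1e-5)
  # an exactly constant probe cannot be fit: flagged and excluded downstream
  m0 <- matrix(2, 1, 96, dimnames = list("flat", sheet$sample_id))
  f0 <- suppressMessages(fit_lme(m0, sheet))
  expect_false(f0$converged)
  expect_true(is.na(f0$p_DE))
})

test_that("subjects with missing visits are dropped with a warning", {
  sheet <- sim_lme$sheet
  keep <- !(sheet$subject == "S01" & sheet$timepoint == 30 &
              sheet$arm == "DE")
  m <- m_lme[1:3, keep]
  expect_warning(fit <- fit_lme(m, sheet[keep, ]), "missing visits")
  expect_equal(nrow(fit), 3)
})

test_that("DMP calling applies the two-family FDR rule and the cell filter", {
  mk_fit <- function(p_de, p_fa) {
    n <- length(p_de)
    structure(data.frame(probe_id = sprintf("p%03d", seq_len(n)),
                         p_DE = p_de, p_FA = p_fa, converged = TRUE,
                         stringsAsFactors = FALSE),
              class = c("lme_fit", "data.frame"))
  }
  delta <- data.frame(probe_id = sprintf("p%03d", 1:40),
                      delta_beta_FA = 0,
                      delta_beta_DE = rep(c(0.06, -0.02), 20))
  # all p_DE = 1: nothing called
  r0 <- suppressWarnings(call_dmps(mk_fit(rep(1, 40), runif(40)), delta))
  expect_equal(sum(r0$dmp), 0)
  # strong DE signal, null FA: everything called, direction from delta
  set.seed(23)
  r1 <- suppressWarnings(
    call_dmps(mk_fit(rep(1e-8, 40), seq(0.3, 0.99, length.out = 40)), delta))
  expect_equal(sum(r1$dmp), 40)
  expect_equal(sum(r1$direction == "increase", na.rm = TRUE), 20)
  expect_equal(sum(r1$large_effect), 20)     # |0.06| > 0.05, |-0.02| is not
  # cell-associated probes are vetoed
  r2 <- suppressWarnings(
    call_dmps(mk_fit(rep(1e-8, 40), seq(0.3, 0.99, length.out = 40)), delta,
              cell_result = sprintf("p%03d", 1:10)))
  expect_equal(sum(r2$dmp), 30)
  expect_equal(attr(r2, "counts")[["cell_removed"]], 10)
  # FA-significant probes are vetoed too
  r3 <- suppressWarnings(
    call_dmps(mk_fit(rep(1e-8, 40), rep(1e-8, 40)), delta))
  expect_equal(sum(r3$dmp), 0)
})

test_that("delta beta summarizes constructed shifts exactly", {
  sheet <- sim_lme$sheet
  b <- matrix(0.4, 2, 96, dimnames = list(c("shifted", "flat"),
                                          sheet$sample_id))
  post_de <- sheet$arm == "DE" & sheet$timepoint != 0
  b["shifted", post_de] <- 0.45
  db <- delta_beta(b, sheet)
  expect_equal(db$delta_beta_DE[db$probe_id == "shifted"], 0.05)
  expect_equal(db$delta_beta_FA[db$probe_id == "shifted"], 0)
  expect_equal(db$delta_beta_DE[db$probe_id == "flat"], 0)
})

test_that("carryover test flags planted carryover and stays null otherwise", {
  sheet <- sim_lme$sheet
  probes <- sprintf("c%02d", 1:8)
  report <- structure(data.frame(probe_id = probes, dmp = TRUE,
                                 direction = rep(c("increase", "decrease"),
                                                 each = 4)),
                      class = c("dmp_report", "data.frame"))
  de_first <- sheet$order == "DE_first"
  fa <- sheet$arm == "FA"
  set.seed(24)
  mk_beta <- function(carry) {
    b <- matrix(0.5 + rnorm(8 * 96, 0, 0.01), 8, 96,
                dimnames = list(probes, sheet$sample_id))
    if (carry) b[1:4, fa & de_first] <- b[1:4, fa & de_first] + 0.05
    b
  }
  planted <- carryover_test(mk_beta(TRUE), sheet, report)
  expect_lt(planted$p_increase, 0.05)
  null_p <- replicate(200, carryover_test(mk_beta(FALSE), sheet,
                                          report)$p_increase)
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)
  # empty direction group
  rep2 <- report; rep2$direction <- "increase"
  expect_warning(res <- carryover_test(mk_beta(FALSE), sheet, rep2),
                 "empty DMP direction")
  expect_true(is.na(res$p_decrease))
})

test_that("genotype-stratified test detects a planted baseline offset", {
  sheet <- sim_lme$sheet
  subj <- unique(sheet$subject)
  geno <- sheet$gstp1[match(subj, sheet$subject)]
  set.seed(25)
  detect <- replicate(50, {
    b <- matrix(0.5 + rnorm(96, 0, 0.03), 1, 96,
                dimnames = list("p1", sheet$sample_id))
    g_subj <- sheet$gstp1 == "G"
    b[1, g_subj] <- b[1, g_subj] + 0.1
    genotype_stratified_test(b, sheet, "p1")$baseline_p
  })
  expect_gt(mean(detect < 0.01), 0.9)
  # null baseline p-values are uniform
  null_p <- replicate(200, {
    b <- matrix(0.5 + rnorm(96, 0, 0.03), 1, 96,
                dimnames = list("p1", sheet$sample_id))
    genotype_stratified_test(b, sheet, "p1")$baseline_p
  })
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)
  # identical groups: p = 1
  b1 <- matrix(0.5, 1, 96, dimnames = list("p1", sheet$sample_id))
  res <- genotype_stratified_test(b1, sheet, "p1")
  expect_equal(res$baseline_p, 1)
  expect_equal(unname(res$prepost_p), c(1, 1))
})
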