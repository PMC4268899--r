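sim_sc <- generate_dataset(small_sim_config(seed = 103))

test_that("scenario masks split the design as expected", {
  sh <- sim_sc$sheet
  expect_equal(sum(scenario_mask(sh, "scenario1")), 16)
  expect_equal(sum(scenario_mask(sh, "scenario2")), 16)
  expect_equal(sum(scenario_mask(sh, "scenario3")), 32)
  m3 <- scenario_mask(sh, "scenario3")
  expect_true(all(sh$arm[m3] == "DE" & sh$timepoint[m3] %in% c(6, 30)))
  expect_error(scenario_mask(sh, "scenario9"), "unknown scenario")
  fa_only <- sh[sh$arm == "FA", ]
  expect_error(scenario_mask(fa_only, "scenario3"), "both FA and DE")
})

test_that("the planted scenario-3 component is found and free of confounds", {
  sim_sc <- generate_dataset(simulation_config(seed = 103))
  m <- beta_to_m(sim_sc$beta)
  m <- m[!apply(is.na(m), 1, any), ]
  pca <- methyl_pca(m)
  assoc <- suppressWarnings(
    associate_components(pca, add_scenario_columns(sim_sc$sheet)))
  scen <- find_scenario_component(pca, confound_table = assoc,
                                  sheet = sim_sc$sheet)
  expect_gt(nrow(scen), 0)
  best <- scen[which.min(scen$q), ]
  expect_equal(best$scenario, "scenario3")
  # the component's top loadings are dominated by planted probes
  hits <- loading_hits(pca, best$component, 3)
  planted <- sim_sc$truth$probe_id[sim_sc$truth$label == "scenario3"]
  expect_gte(mean(intersect(planted, rownames(m)) %in% hits), 0.8)
  # and the score separation is strong in the expected direction pattern
  mask <- scenario_mask(sim_sc$sheet, "scenario3")
  sep <- score_separation(pca, best$component, mask)
  expect_lt(sep$t_p, 1e-4)
  expect_true(sign(sep$mean_in) != sign(sep$mean_out))
})

test_that("a component equal to the mask indicator gives a minimal rank-sum p", {
  sh <- sim_sc$sheet
  mask <- scenario_mask(sh, "scenario3")
  scores <- matrix(as.numeric(mask), ncol = 1,
                   dimnames = list(NULL, "PC1"))
  fake <- structure(list(scores = scores, loadings = matrix(0, 5, 1),
                         d = 1, variance_fraction = 1),
                    class = "methyl_pca")
  confound <- data.frame(component = "PC1", variable = "age",
                         test = "spearman", statistic = 0, p = 0.9,
                         q = 0.9, significant = FALSE)
  scen <- suppressWarnings(
    find_scenario_component(fake, confound_table = confound, sheet = sh))
  row <- scen[scen$scenario == "scenario3", ]
  expect_equal(row$component, "PC1")
  expect_lt(row$p, 1e-10)
})

test_that("confound-dominated components are excluded from the scenario result", {
  sh <- sim_sc$sheet
  mask <- scenario_mask(sh, "scenario3")
  scores <- matrix(as.numeric(mask), ncol = 1,
                   dimnames = list(NULL, "PC1"))
  fake <- structure(list(scores = scores, loadings = matrix(0, 5, 1),
                         d = 1, variance_fraction = 1),
                    class = "methyl_pca")
  # a confound explaining the component more decisively than the
  # scenario itself: excluded under both rules
  strong <- data.frame(component = "PC1", variable = "lymphocytes",
                       test = "spearman", statistic = 0.99, p = 1e-30,
                       q = 1e-28, significant = TRUE)
  scen <- suppressWarnings(
    find_scenario_component(fake, confound_table = strong, sheet = sh))
  expect_equal(nrow(scen), 0)
  expect_equal(nrow(suppressWarnings(
    find_scenario_component(fake, confound_table = strong, sheet = sh,
                            confound_rule = "strict"))), 0)
  # a weak (but formally significant) confound association: the
  # exposure-dominated component survives the default rule, not strict
  weak <- data.frame(component = "PC1", variable = "age",
                     test = "spearman", statistic = 0.4, p = 1e-3,
                     q = 0.04, significant = TRUE)
  kept <- suppressWarnings(
    find_scenario_component(fake, confound_table = weak, sheet = sh))
  expect_gt(nrow(kept), 0)
  expect_equal(nrow(suppressWarnings(
    find_scenario_component(fake, confound_table = weak, sheet = sh,
                            confound_rule = "strict"))), 0)
})

test_that("score separation handles degenerate and shifted groups", {
  scores <- matrix(c(rep(1, 48), rep(1, 48)), ncol = 1,
                   dimnames = list(NULL, "PC1"))
  fake <- structure(list(scores = scores, loadings = matrix(0, 5, 1),
                         d = 1, variance_fraction = 1),
                    class = "methyl_pca")
  mask <- rep(c(TRUE, FALSE), each = 48)
  sep <- score_separation(fake, "PC1", mask)
  expect_equal(sep$mean_in, sep$mean_out)
  expect_equal(sep$t_p, 1)
  # planted 1 SD shift is recovered
  set.seed(19)
  reps <- replicate(200, {
    s <- rnorm(96)
    s[mask] <- s[mask] + 1
    fake$scores[, 1] <- s
    sep <- score_separation(fake, "PC1", mask)
    sep$mean_in - sep$mean_out
  })
  expect_lt(abs(mean(reps) - 1), 3 * sd(reps) / sqrt(length(reps)))
  # degenerate group
  expect_warning(s0 <- score_separation(fake, "PC1",
                                        c(TRUE, rep(FALSE, 95))))
  expect_true(is.na(s0$t_p))
})
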