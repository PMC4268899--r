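# Per-probe linear mixed-effects modelling -------------------------------
#
# The exposure model for a crossover design with repeated draws:
#
#   Y = b0 + u_subject + b1*Exposure + b2*Time + b3*Exposure:Time + e
#
# on the M scale, with a random intercept per subject (REML). Time is
# dichotomized pre (baseline draw) vs post (pooled later draws). The
# time effect under the control arm is b2; the time effect under the
# exposure arm is the contrast b2 + b3. Both are tested per probe with
# Wald z statistics, and the two p-value families are FDR-controlled
# separately: a differentially methylated position (DMP) must move under
# exposure (q_DE <= fdr) but not under control (q_FA > fdr), and must
# not be a cell-composition probe.

# design frame shared by every probe of one fit
lme_design <- function(sheet, timepoints = sort(unique(sheet$timepoint))) {
  pre <- timepoints[1L]
  data.frame(subject = factor(sheet$subject),
             exposure = factor(sheet$arm, levels = c("FA", "DE")),
             time = factor(ifelse(sheet$timepoint == pre, "pre", "post"),
                           levels = c("pre", "post")))
}

#' Fit the random-intercept exposure model probe by probe
#'
#' Fits `Y ~ exposure * time` with a per-subject random intercept by
#' restricted maximum likelihood ([nlme::lme()]) to each requested probe
#' of an M-value matrix. Subjects without all `2 x length(timepoints)`
#' observations are dropped with a warning. Per probe the fit records
#' the four fixed effects, the random-intercept and residual SDs, the
#' Wald z p-value for the control-arm time effect (`p_FA`, testing
#' \eqn{\beta_2 = 0}) and for the exposure-arm time effect (`p_DE`,
#' testing \eqn{\beta_2 + \beta_3 = 0}). Probes whose fit does not
#' converge are flagged and excluded from downstream q-value families.
#'
#' @param m probes x samples M-value matrix.
#' @param sheet sample sheet with `subject`, `arm`, `timepoint`.
#' @param probes probe ids to fit (default: all rows of `m`).
#' @return object of class `"lme_fit"`: a data.frame with one row per
#'   probe (`probe_id`, `b0`, `b_exposure`, `b_time`, `b_interaction`,
#'   `se_time`, `se_de`, `sd_subject`, `sd_resid`, `p_FA`, `p_DE`,
#'   `converged`).
#' @examples
#' sim <- generate_dataset(simulation_config(n_probes = 60, seed = 11))
#' fit <- fit_lme(beta_to_m(sim$beta), sim$sheet,
#'                probes = rownames(sim$beta)[1:5])
#' fit[, c("probe_id", "p_FA", "p_DE")]
#' @export
fit_lme <- function(m, sheet, probes = rownames(m)) {
  tps <- sort(unique(sheet$timepoint))
  per_subject <- table(sheet$subject)
  complete <- names(per_subject)[per_subject == 2L * length(tps)]
  if (length(complete) < length(per_subject)) {
    warning(length(per_subject) - length(complete),
            " subject(s) with missing visits dropped from the LME fit")
    keep <- sheet$subject %in% complete
    sheet <- sheet[keep, , drop = FALSE]
    m <- m[, sheet$sample_id, drop = FALSE]
  }
  d <- lme_design(sheet, tps)
  probes <- intersect(probes, rownames(m))
  if (!length(probes)) stop("no probes to fit")
  contrast_de <- c(0, 0, 1, 1)
  one <- function(y) {
    d$y <- y
    fit <- tryCatch(
      nlme::lme(y ~ exposure * time, random = ~ 1 | subject, data = d,
                method = "REML"),
      error = function(e) NULL)
    if (is.null(fit)) return(rep(NA_real_, 10L))
    b <- nlme::fixef(fit)
    V <- stats::vcov(fit)
    se_time <- sqrt(V["timepost", "timepost"])
    est_de <- sum(contrast_de * b)
    se_de <- sqrt(drop(t(contrast_de) %*% V %*% contrast_de))
    vc <- nlme::VarCorr(fit)
    c(b, se_time, se_de,
      as.numeric(vc["(Intercept)", "StdDev"]), fit$sigma,
      p_fa = if (se_time > 0) 2 * stats::pnorm(-abs(b[["timepost"]] / se_time)) else 1,
      p_de = if (se_de > 0) 2 * stats::pnorm(-abs(est_de / se_de)) else 1)
  }
  res <- t(vapply(probes, function(p) one(m[p, ]), numeric(10L)))
  out <- data.frame(probe_id = probes,
                    b0 = res[, 1L], b_exposure = res[, 2L],
                    b_time = res[, 3L], b_interaction = res[, 4L],
                    se_time = res[, 5L], se_de = res[, 6L],
                    sd_subject = res[, 7L], sd_resid = res[, 8L],
                    p_FA = res[, 9L], p_DE = res[, 10L],
                    converged = !is.na(res[, 1L]),
                    stringsAsFactors = FALSE, row.names = NULL)
  n_fail <- sum(!out$converged)
  if (n_fail) message(n_fail, " probe fit(s) did not converge")
  class(out) <- c("lme_fit", "data.frame")
  out
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("Per-probe random-intercept exposure model:", nrow(x), "probes (",
      sum(x$converged), "converged )\n")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 3)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
coef.lme_fit <- function(object, ...) {
  out <- as.matrix(object[, c("b0", "b_exposure", "b_time", "b_interaction")])
  rownames(out) <- object$probe_id
  out
}

#' Average beta change post- vs pre-exposure, per arm
#'
#' For each probe and arm, the effect size on the interpretable beta
#' scale: the mean over subjects of (mean beta at the post-exposure
#' draws) minus (beta at the baseline draw).
#'
#' @param beta probes x samples beta matrix.
#' @param sheet sample sheet.
#' @param probes probe ids (default all).
#' @return data.frame with `probe_id`, `delta_beta_FA`, `delta_beta_DE`.
#' @export
delta_beta <- function(beta, sheet, probes = rownames(beta)) {
  tps <- sort(unique(sheet$timepoint))
  pre <- tps[1L]
  post <- tps[-1L]
  probes <- intersect(probes, rownames(beta))
  b <- beta[probes, , drop = FALSE]
  out <- data.frame(probe_id = probes, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (arm in c("FA", "DE")) {
    sel_arm <- sheet$arm == arm
    subjects <- unique(sheet$subject[sel_arm])
    w <- matrix(0, nrow = ncol(b), ncol = length(subjects),
                dimnames = list(colnames(b), subjects))
    for (s in subjects) {
      ip <- which(sel_arm & sheet$subject == s & sheet$timepoint == pre)
      io <- which(sel_arm & sheet$subject == s & sheet$timepoint %in% post)
      w[ip, s] <- -1
      w[io, s] <- 1 / length(io)
    }
    out[[paste0("delta_beta_", arm)]] <- rowMeans(b %*% w)
  }
  out
}

#' Call differentially methylated positions
#'
#' Computes Storey q-values separately over the `p_DE` and `p_FA`
#' families of converged probes and flags a probe as a DMP when
#' `q_DE <= fdr`, `q_FA > fdr`, and the probe is not in the significant
#' cell-composition set. Direction is the sign of the exposure-arm beta
#' change; probes with `|delta_beta_DE| > 0.05` (a change above five
#' percentage points of methylation) are counted separately.
#'
#' @param fit an `"lme_fit"` object.
#' @param delta the [delta_beta()] table for the same probes.
#' @param cell_result a `"cell_assoc"` table, a character vector of
#'   cell-associated probe ids, or `NULL`.
#' @param fdr FDR level for both families (default 0.10).
#' @return object of class `"dmp_report"`: a data.frame with per-probe
#'   statistics, q-values, beta changes, direction and flags.
#' @export
call_dmps <- function(fit, delta, cell_result = NULL, fdr = 0.10) {
  stopifnot(inherits(fit, "lme_fit"))
  out <- merge(as.data.frame(fit), delta, by = "probe_id", sort = FALSE)
  out$q_DE <- out$q_FA <- NA_real_
  conv <- out$converged
  out$q_DE[conv] <- suppressWarnings(storey_qvalue(out$p_DE[conv]))$q
  out$q_FA[conv] <- suppressWarnings(storey_qvalue(out$p_FA[conv]))$q
  cell_sig <- if (is.null(cell_result)) character(0)
              else if (is.character(cell_result)) cell_result
              else cell_result$probe_id[cell_result$significant]
  out$cell_associated <- out$probe_id %in% cell_sig
  out$dmp <- conv & !is.na(out$q_DE) & out$q_DE <= fdr &
    out$q_FA > fdr & !out$cell_associated
  out$direction <- ifelse(out$delta_beta_DE >= 0, "increase", "decrease")
  out$direction[!out$dmp] <- NA
  out$large_effect <- out$dmp & abs(out$delta_beta_DE) > 0.05
  attr(out, "fdr") <- fdr
  attr(out, "counts") <- c(
    tested = sum(conv), dmp = sum(out$dmp),
    increase = sum(out$dmp & out$direction == "increase", na.rm = TRUE),
    decrease = sum(out$dmp & out$direction == "decrease", na.rm = TRUE),
    large_effect = sum(out$large_effect),
    cell_removed = sum(out$cell_associated & conv & !is.na(out$q_DE) &
                         out$q_DE <= fdr & out$q_FA > fdr))
  class(out) <- c("dmp_report", "data.frame")
  out
}

#' @export
print.dmp_report <- function(x, ...) {
  ct <- attr(x, "counts")
  if (is.null(ct))   # subsetted report: recompute from the columns
    ct <- c(tested = sum(x$converged),
            dmp = sum(x$dmp),
            increase = sum(x$dmp & x$direction == "increase", na.rm = TRUE),
            decrease = sum(x$dmp & x$direction == "decrease", na.rm = TRUE),
            large_effect = sum(x$large_effect),
            cell_removed = NA)
  fdr <- attr(x, "fdr")
  cat("DMP report:", ct[["tested"]], "probes tested",
      if (!is.null(fdr)) paste("at FDR", fdr) else "", "\n")
  cat("  DMPs:", ct[["dmp"]], "(", ct[["increase"]], "increase /",
      ct[["decrease"]], "decrease;", ct[["large_effect"]],
      "with |delta beta| > 0.05 )\n")
  if (!is.na(ct[["cell_removed"]]))
    cat("  would-be DMPs removed as cell-associated:",
        ct[["cell_removed"]], "\n")
  invisible(x)
}

#' Carryover test for the crossover design
#'
#' If an exposure effect carried over into the other arm, subjects
#' exposed to DE first would show shifted control-arm (FA) methylation
#' at the affected probes. For each DMP direction group the test
#' compares the per-subject mean FA beta (averaged over the group's
#' probes and all FA draws) between DE-first and FA-first subjects with
#' Welch's two-sample t-test.
#'
#' @param beta probes x samples beta matrix.
#' @param sheet sample sheet with an `order` column (`"DE_first"` /
#'   `"FA_first"`).
#' @param report a `"dmp_report"`.
#' @return list with `p_increase` and `p_decrease` (NA, with a warning,
#'   when a direction group is empty or an order group has fewer than
#'   two subjects).
#' @export
carryover_test <- function(beta, sheet, report) {
  fa <- sheet$arm == "FA"
  subj <- unique(sheet$subject)
  ord <- sheet$order[match(subj, sheet$subject)]
  one_group <- function(probes) {
    if (!length(probes)) {
      warning("empty DMP direction group in carryover test")
      return(NA_real_)
    }
    pm <- vapply(subj, function(s)
      mean(beta[probes, fa & sheet$subject == s, drop = FALSE]), 0)
    g1 <- pm[ord == "DE_first"]
    g2 <- pm[ord == "FA_first"]
    if (length(g1) < 2L || length(g2) < 2L) {
      warning("fewer than two subjects in an exposure-order group")
      return(NA_real_)
    }
    welch_t(g1, g2)$p
  }
  list(
    p_increase = one_group(report$probe_id[report$dmp &
                                             report$direction == "increase"]),
    p_decrease = one_group(report$probe_id[report$dmp &
                                             report$direction == "decrease"]))
}

#' Genotype-stratified methylation test at one probe
#'
#' Two questions at a single CpG: (1) do the genotype groups differ at
#' baseline (Welch t-test of the control-arm baseline betas, one value
#' per subject)? (2) within each genotype group, does methylation change
#' pre vs post exposure (paired t-test of the DE baseline draw against
#' the mean of the DE post draws, paired by subject)? Strata with fewer
#' than two subjects return `NA`.
#'
#' @param beta probes x samples beta matrix.
#' @param sheet sample sheet.
#' @param probe probe id.
#' @param genotype_variable sheet column holding the genotype (default
#'   `"gstp1"`).
#' @return list with `baseline_p` and `prepost_p` (named per genotype
#'   level).
#' @export
genotype_stratified_test <- function(beta, sheet, probe,
                                     genotype_variable = "gstp1") {
  tps <- sort(unique(sheet$timepoint))
  pre <- tps[1L]
  subj <- unique(sheet$subject)
  geno <- sheet[[genotype_variable]][match(subj, sheet$subject)]
  base <- vapply(subj, function(s)
    beta[probe, sheet$subject == s & sheet$arm == "FA" &
                 sheet$timepoint == pre], 0)
  de_pre <- vapply(subj, function(s)
    beta[probe, sheet$subject == s & sheet$arm == "DE" &
                 sheet$timepoint == pre], 0)
  de_post <- vapply(subj, function(s)
    mean(beta[probe, sheet$subject == s & sheet$arm == "DE" &
                     sheet$timepoint != pre]), 0)
  lev <- sort(unique(geno))
  baseline_p <- if (min(table(geno)) < 2L || length(lev) != 2L) {
    warning("singleton or missing genotype stratum; baseline test NA")
    NA_real_
  } else {
    welch_t(base[geno == lev[1L]], base[geno == lev[2L]])$p
  }
  prepost_p <- vapply(lev, function(g) {
    sel <- geno == g
    if (sum(sel) < 2L) return(NA_real_)
    suppressWarnings(paired_t(de_pre[sel], de_post[sel])$p)
  }, 0)
  list(baseline_p = baseline_p, prepost_p = prepost_p)
}
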