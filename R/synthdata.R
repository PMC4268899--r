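# Synthetic crossover methylation data -----------------------------------
#
# The generator emulates the statistical structure the downstream pipeline
# assumes: a two-arm (filtered air vs diesel exhaust) crossover design with
# three blood draws per arm, a bimodal baseline beta distribution, planted
# exposure effects under three temporal scenarios, probes tracking blood
# cell composition or demographics, the type I/II probe dichotomy with
# compressed type II peaks, detection failures and missing values, and a
# repeat-element track with boundary-overlap probes for interval testing.

#' Configuration for the synthetic crossover methylation dataset
#'
#' Collects and validates every knob of the generator. Defaults describe
#' the emulated study: 16 subjects crossing over between filtered air (FA)
#' and diesel exhaust (DE) with samples at 0, 6 and 30 h per arm (96
#' samples), 5000 probes of which 50 carry a scenario-3 exposure effect of
#' 0.05 on the beta scale, 200 track lymphocyte/monocyte counts and 100
#' track age or BMI.
#'
#' Scenario labels encode when the exposure effect is present: scenario 1
#' only at DE 6 h, scenario 2 only at DE 30 h, scenario 3 at both DE 6 h
#' and DE 30 h. Planted shifts point away from the nearer beta boundary
#' (hypomethylated probes shift up, hypermethylated probes shift down) so
#' the shifted mean stays inside (0, 1).
#'
#' @param n_subjects number of subjects; half are exposed to DE first.
#' @param timepoints sampling times in hours; the first is the
#'   pre-exposure baseline.
#' @param n_probes total number of probes.
#' @param n_effect_probes named vector: probes planted per scenario.
#' @param effect_size_beta magnitude of the planted shift on the beta scale.
#' @param n_cellmix_probes probes linear in blood cell counts.
#' @param cellmix_slopes beta change per K/uL for `lymphocytes` and
#'   `monocytes`.
#' @param n_covariate_probes probes linear in a demographic covariate
#'   (split evenly between age and BMI).
#' @param covariate_slopes beta change per unit for `age` (years) and
#'   `bmi` (kg/m^2).
#' @param noise_sd_m residual noise SD on the M scale.
#' @param subject_sd_m SD of the per-probe subject random intercept on the
#'   M scale (the between-subject variance the mixed model estimates).
#' @param frac_typeII fraction of probes with type II chemistry.
#' @param typeII_compression multiplicative M-scale compression of type II
#'   probes, in (0, 1]; 1 disables the probe-type bias.
#' @param frac_detection_fail fraction of probes given a failing detection
#'   p-value (> 0.01) in at least one sample.
#' @param frac_missing fraction of probes given at least one missing beta.
#' @param frac_on_xy,frac_crosshyb,frac_polymorphic fractions of probes
#'   placed on chrX/chrY or flagged as cross-hybridizing / polymorphic.
#' @param repeat_track_spec per-class list (`Alu`, `LINE1`) with
#'   `n_intervals`, `length` (bp), `n_probes` placed fully inside
#'   intervals, and `n_effect` of those carrying the scenario-3 shift.
#' @param boundary_overlaps exact probe-vs-Alu overlaps (bp) to plant for
#'   boundary testing of the overlap rule.
#' @param mirna_spec list with `loci` (names), `n_probes` overlapping
#'   them, and `effect_delta` (signed beta shift, scenario-3 pattern)
#'   planted on the first locus' first probe (`NULL` for none).
#' @param seed integer seed; the same seed reproduces the dataset
#'   bit-identically.
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_subjects = 16L,
                              timepoints = c(0L, 6L, 30L),
                              n_probes = 5000L,
                              n_effect_probes = c(scenario1 = 0L,
                                                  scenario2 = 0L,
                                                  scenario3 = 50L),
                              effect_size_beta = 0.05,
                              n_cellmix_probes = 200L,
                              cellmix_slopes = c(lymphocytes = 0.06,
                                                 monocytes = 0.25),
                              n_covariate_probes = 100L,
                              covariate_slopes = c(age = 0.002, bmi = 0.003),
                              noise_sd_m = 0.15,
                              subject_sd_m = 0.05,
                              frac_typeII = 0.7,
                              typeII_compression = 0.8,
                              frac_detection_fail = 0.01,
                              frac_missing = 0.005,
                              frac_on_xy = 0.02,
                              frac_crosshyb = 0.02,
                              frac_polymorphic = 0.01,
                              repeat_track_spec = list(
                                Alu = list(n_intervals = 40L, length = 300L,
                                           n_probes = 150L, n_effect = 5L),
                                LINE1 = list(n_intervals = 30L, length = 1000L,
                                             n_probes = 150L, n_effect = 5L)),
                              boundary_overlaps = c(14L, 15L, 16L),
                              mirna_spec = list(
                                loci = c("miR-21", "miR-30e", "miR-215", "miR-144"),
                                n_probes = 7L,
                                effect_delta = -0.039),
                              seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              arms = c("FA", "DE"),
              timepoints = as.integer(timepoints),
              n_probes = as.integer(n_probes),
              n_effect_probes = n_effect_probes,
              effect_size_beta = effect_size_beta,
              n_cellmix_probes = as.integer(n_cellmix_probes),
              cellmix_slopes = cellmix_slopes,
              n_covariate_probes = as.integer(n_covariate_probes),
              covariate_slopes = covariate_slopes,
              noise_sd_m = noise_sd_m, subject_sd_m = subject_sd_m,
              frac_typeII = frac_typeII,
              typeII_compression = typeII_compression,
              frac_detection_fail = frac_detection_fail,
              frac_missing = frac_missing,
              frac_on_xy = frac_on_xy, frac_crosshyb = frac_crosshyb,
              frac_polymorphic = frac_polymorphic,
              repeat_track_spec = repeat_track_spec,
              boundary_overlaps = as.integer(boundary_overlaps),
              mirna_spec = mirna_spec,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  fr <- c(cfg$frac_typeII, cfg$frac_detection_fail, cfg$frac_missing,
          cfg$frac_on_xy, cfg$frac_crosshyb, cfg$frac_polymorphic)
  if (any(fr < 0 | fr > 1)) stop("configuration error: fractions must lie in [0, 1]")
  if (cfg$typeII_compression <= 0 || cfg$typeII_compression > 1)
    stop("configuration error: typeII_compression must be in (0, 1]")
  if (cfg$n_subjects < 2L || cfg$n_subjects %% 2L != 0L)
    stop("configuration error: n_subjects must be even (counterbalanced order) and >= 2")
  if (length(cfg$timepoints) < 2L)
    stop("configuration error: need a baseline and at least one post timepoint")
  counts <- c(cfg$n_effect_probes, cfg$n_cellmix_probes, cfg$n_covariate_probes)
  if (any(counts < 0)) stop("configuration error: probe counts must be non-negative")
  if (!all(c("scenario1", "scenario2", "scenario3") %in% names(cfg$n_effect_probes)))
    stop("configuration error: n_effect_probes needs scenario1..scenario3 entries")
  n_special <- sum(cfg$n_effect_probes) + cfg$n_cellmix_probes +
    cfg$n_covariate_probes +
    sum(vapply(cfg$repeat_track_spec, function(s) s$n_probes, 0)) +
    length(cfg$boundary_overlaps) + cfg$mirna_spec$n_probes
  if (n_special > cfg$n_probes)
    stop("configuration error: planted probe counts exceed n_probes")
  for (s in cfg$repeat_track_spec) {
    if (s$length < 60L) stop("configuration error: repeat intervals must be >= 60 bp to host probes")
    if (s$n_effect > s$n_probes) stop("configuration error: n_effect exceeds n_probes in repeat spec")
  }
  if (cfg$noise_sd_m < 0 || cfg$subject_sd_m < 0)
    stop("configuration error: noise SDs must be non-negative")
  invisible(cfg)
}

# moment-matched lognormal draws
rlnorm_match <- function(n, mean, sd) {
  sdlog <- sqrt(log1p((sd / mean)^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# truncated normal via inverse CDF (keeps the RNG stream deterministic)
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic repeat-element track
#'
#' Places non-overlapping-by-construction Alu and LINE1 intervals
#' (0-based, half-open, chromosome-sorted) in a coordinate band disjoint
#' from the generator's regular probe grid.
#'
#' @param spec per-class list as in [simulation_config()]
#'   (`repeat_track_spec`); only `n_intervals` and `length` are used here.
#' @param seed optional seed; omit to draw from the current RNG stream.
#' @return data.frame with columns `chrom`, `start`, `end`, `class`.
#' @export
generate_repeat_track <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- paste0("chr", 1:22)
  rows <- lapply(names(spec), function(cls) {
    s <- spec[[cls]]
    if (s$length < 1L) stop("interval lengths must be >= 1")
    chrom <- sample(chroms, s$n_intervals, replace = TRUE)
    start <- sample(5e6:9e6, s$n_intervals, replace = TRUE)
    data.frame(chrom = chrom, start = start, end = start + s$length,
               class = cls, stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, rows)
  track[order(track$chrom, track$start), , drop = FALSE]
}

# max overlap (bp) of each probe footprint with intervals of one class;
# plain arithmetic sweep, independent of the package's interval engine
overlap_bp_by_class <- function(anno, track, probe_length = 50L) {
  p_start <- anno$pos - probe_length + 1L   # 1-based inclusive
  p_end <- anno$pos
  out <- matrix(0L, nrow(anno), length(unique(track$class)),
                dimnames = list(anno$probe_id, sort(unique(track$class))))
  for (cls in colnames(out)) {
    tr <- track[track$class == cls, , drop = FALSE]
    for (ch in unique(tr$chrom)) {
      iv <- tr[tr$chrom == ch, , drop = FALSE]
      idx <- which(anno$chr == ch)
      if (!length(idx) || !nrow(iv)) next
      # interval in 1-based inclusive coordinates: [start + 1, end]
      lo <- outer(p_start[idx], iv$start + 1L, pmax)
      hi <- outer(p_end[idx], iv$end, pmin)
      ov <- pmax(hi - lo + 1L, 0L)
      out[idx, cls] <- pmax(out[idx, cls], apply(ov, 1L, max))
    }
  }
  out
}

#' Generate a synthetic crossover methylation dataset
#'
#' Draws a complete dataset under the crossover design described in
#' [simulation_config()]: beta/M matrices, detection p-values, a sample
#' sheet with demographics, blood counts and genotype, a probe annotation
#' table, a repeat-element track, a microRNA locus table, and the ground
#' truth of every planted signal.
#'
#' Baseline betas come from a two-component Beta mixture with modes near
#' 0.1 and 0.85 (the canonical bimodal array profile). Signals are added
#' to the mean beta, transformed to the M scale, given a subject random
#' intercept and Gaussian noise, compressed for type II probes, and mapped
#' back to beta; betas therefore stay inside (0, 1) by construction.
#'
#' @param config a [simulation_config()] object.
#' @return object of class `"crossmeth_sim"`: list with elements `beta`,
#'   `m`, `detp` (probes x samples matrices), `sheet`, `annotation`,
#'   `repeats`, `mirna_loci`, `truth`, and `config`.
#' @examples
#' sim <- generate_dataset(simulation_config(n_probes = 300, seed = 7))
#' dim(sim$beta)           # 300 x 96
#' table(sim$truth$label)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  validate_simulation_config(config)
  set.seed(config$seed)
  ns <- config$n_subjects
  tps <- config$timepoints
  subjects <- sprintf("S%02d", seq_len(ns))

  ## ---- sample sheet -----------------------------------------------------
  sheet <- expand.grid(timepoint = tps, arm = config$arms, subject = subjects,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- sheet[, c("subject", "arm", "timepoint")]
  n_samples <- nrow(sheet)
  de_first <- sample(subjects, ns / 2L)
  ord <- ifelse(subjects %in% de_first, "DE_first", "FA_first")
  names(ord) <- subjects
  age <- rtnorm(ns, 28.7, 6.7, 19, 47)
  bmi <- rtnorm(ns, 24.8, 3.9, 18, 35)
  sex <- sample(rep(c("M", "F"), length.out = ns))
  eth <- sample(rep(c("Caucasian", "Asian", "MiddleEastern", "SouthAsian"),
                    times = pmax(1L, round(ns * c(12, 2, 1, 1) / 16))),
                ns, replace = FALSE)
  gstp1 <- sample(rep(c("A", "G"), times = c(round(ns * 5 / 16),
                                             ns - round(ns * 5 / 16))))
  # subject-level counts: lymphocytes and monocytes share hematopoietic
  # and inflammatory drivers, so their baselines correlate (r ~ 0.5)
  z1 <- stats::rnorm(ns)
  z2 <- 0.5 * z1 + sqrt(1 - 0.5^2) * stats::rnorm(ns)
  lnpar <- function(mean, sd) {
    sdlog <- sqrt(log1p((sd / mean)^2))
    c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  pl <- lnpar(1.9, 0.5)
  pm <- lnpar(0.43, 0.13)
  lym0 <- exp(pl[["meanlog"]] + pl[["sdlog"]] * z1)
  mon0 <- exp(pm[["meanlog"]] + pm[["sdlog"]] * z2)
  bas0 <- rlnorm_match(ns, 0.04, 0.03)
  si <- match(sheet$subject, subjects)
  sheet$order <- ord[si]
  sheet$age <- age[si]
  sheet$bmi <- bmi[si]
  sheet$sex <- sex[si]
  sheet$ethnicity <- eth[si]
  sheet$gstp1 <- gstp1[si]
  chip_of_subject <- sample(rep(1:2, length.out = ns))
  sheet$chip <- chip_of_subject[si]
  sheet$position <- sample(rep(1:12, length.out = n_samples))
  # per-visit complete blood counts: subject level times visit-level jitter
  sheet$lymphocytes <- lym0[si] * exp(stats::rnorm(n_samples, 0, 0.1))
  sheet$monocytes <- mon0[si] * exp(stats::rnorm(n_samples, 0, 0.1))
  sheet$basophils <- bas0[si] * exp(stats::rnorm(n_samples, 0, 0.15))
  sheet$sample_id <- sprintf("%s_%s_%02dh", sheet$subject, sheet$arm,
                             sheet$timepoint)
  rownames(sheet) <- sheet$sample_id
  sheet <- sheet[, c("sample_id", setdiff(names(sheet), "sample_id"))]

  ## ---- probe roles ------------------------------------------------------
  np <- config$n_probes
  probe_id <- sprintf("cg%08d", seq_len(np))
  pool <- sample(np)                      # random disjoint role assignment
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  idx_sc <- lapply(config$n_effect_probes, take)
  idx_cell <- take(config$n_cellmix_probes)
  idx_cov <- take(config$n_covariate_probes)
  idx_rep <- lapply(config$repeat_track_spec, function(s) take(s$n_probes))
  idx_bnd <- take(length(config$boundary_overlaps))
  idx_mir <- take(config$mirna_spec$n_probes)

  label <- rep("null", np)
  for (sc in names(idx_sc)) label[idx_sc[[sc]]] <- sc
  label[idx_cell] <- "cellmix"
  label[idx_cov] <- "covariate"
  # repeat-hosted and microRNA effect probes carry a scenario-3 pattern
  idx_rep_eff <- lapply(names(config$repeat_track_spec), function(cls) {
    n_eff <- config$repeat_track_spec[[cls]]$n_effect
    idx_rep[[cls]][seq_len(n_eff)]
  })
  names(idx_rep_eff) <- names(config$repeat_track_spec)
  for (v in idx_rep_eff) label[v] <- "scenario3"
  mir_eff <- integer(0)
  if (!is.null(config$mirna_spec$effect_delta) && length(idx_mir))
    mir_eff <- idx_mir[1L]
  if (length(mir_eff)) label[mir_eff] <- "scenario3"

  ## ---- annotation and tracks -------------------------------------------
  track <- generate_repeat_track(config$repeat_track_spec)
  chroms <- paste0("chr", 1:22)
  chr <- rep_len(chroms, np)
  pos <- 10000L + (seq_len(np) %/% 22L) * 1000L +
    sample(0:400, np, replace = TRUE)
  # repeat-hosted probes: footprint [pos-49, pos] fully inside an interval
  for (cls in names(idx_rep)) {
    iv <- track[track$class == cls, , drop = FALSE]
    pick <- rep_len(seq_len(nrow(iv)), length(idx_rep[[cls]]))
    chr[idx_rep[[cls]]] <- iv$chrom[pick]
    pos[idx_rep[[cls]]] <- iv$start[pick] + 50L +
      vapply(iv$end[pick] - iv$start[pick] - 50L,
             function(m) sample.int(m, 1L), 1L)
  }
  # boundary probes: exact k-bp overlap with the left edge of an Alu interval
  alu <- track[track$class == "Alu", , drop = FALSE]
  bnd_iv <- rep_len(seq_len(nrow(alu)), length(idx_bnd))
  chr[idx_bnd] <- alu$chrom[bnd_iv]
  pos[idx_bnd] <- alu$start[bnd_iv] + config$boundary_overlaps
  # microRNA loci (80 bp) in their own band, probes inside them
  mir <- data.frame(chrom = sample(chroms, length(config$mirna_spec$loci),
                                   replace = TRUE),
                    start = sample(3e6:4e6, length(config$mirna_spec$loci),
                                   replace = TRUE),
                    stringsAsFactors = FALSE)
  mir$end <- mir$start + 80L
  mir$name <- config$mirna_spec$loci
  mir_of_probe <- rep_len(seq_len(nrow(mir)), length(idx_mir))
  mir_of_probe <- sort(mir_of_probe)      # first probe sits in the first locus
  chr[idx_mir] <- mir$chrom[mir_of_probe]
  pos[idx_mir] <- mir$start[mir_of_probe] + 40L
  # X/Y and blacklist flags live on plain null probes
  on_xy <- cross_hyb <- polymorphic <- rep(FALSE, np)
  nxy <- round(config$frac_on_xy * np)
  xy <- utils::head(pool, nxy); pool <- utils::tail(pool, -nxy)
  on_xy[xy] <- TRUE
  chr[xy] <- sample(c("chrX", "chrY"), length(xy), replace = TRUE,
                    prob = c(0.85, 0.15))
  nch <- round(config$frac_crosshyb * np)
  ch_idx <- utils::head(pool, nch); pool <- utils::tail(pool, -nch)
  cross_hyb[ch_idx] <- TRUE
  npm <- round(config$frac_polymorphic * np)
  pm <- utils::head(pool, npm); pool <- utils::tail(pool, -npm)
  polymorphic[pm] <- TRUE

  probe_type <- ifelse(stats::runif(np) < config$frac_typeII, "II", "I")
  channel <- ifelse(probe_type == "II", "Both",
                    sample(c("Grn", "Red"), np, replace = TRUE))
  anno <- data.frame(probe_id = probe_id, chr = chr, pos = pos,
                     probe_type = probe_type, channel = channel,
                     gene = sprintf("GENE%04d", ((seq_len(np) - 1L) %/% 4L) + 1L),
                     on_xy = on_xy, cross_hybridizing = cross_hyb,
                     polymorphic = polymorphic, stringsAsFactors = FALSE)
  rownames(anno) <- probe_id

  ## ---- mean beta surface ------------------------------------------------
  comp <- stats::runif(np) < 0.5
  base_beta <- ifelse(comp, stats::rbeta(np, 3, 19), stats::rbeta(np, 18, 4))
  # cell-composition-sensitive probes sit at intermediate methylation: their
  # bulk beta is a cell-type mixture of differing extremes
  if (length(idx_cell))
    base_beta[idx_cell] <- stats::rbeta(length(idx_cell), 8, 8)
  mu <- matrix(base_beta, np, n_samples)
  sign_p <- ifelse(base_beta < 0.5, 1, -1)
  delta <- numeric(np)
  masks <- list(scenario1 = sheet$arm == "DE" & sheet$timepoint == tps[2L],
                scenario2 = sheet$arm == "DE" & sheet$timepoint == tps[3L],
                scenario3 = sheet$arm == "DE" & sheet$timepoint != tps[1L])
  for (sc in names(idx_sc)) {
    ii <- idx_sc[[sc]]
    if (!length(ii)) next
    delta[ii] <- sign_p[ii] * config$effect_size_beta
    mu[ii, masks[[sc]]] <- mu[ii, masks[[sc]]] + delta[ii]
  }
  for (cls in names(idx_rep_eff)) {
    ii <- idx_rep_eff[[cls]]
    if (!length(ii)) next
    delta[ii] <- sign_p[ii] * config$effect_size_beta
    mu[ii, masks$scenario3] <- mu[ii, masks$scenario3] + delta[ii]
  }
  if (length(mir_eff)) {
    delta[mir_eff] <- config$mirna_spec$effect_delta
    mu[mir_eff, masks$scenario3] <- mu[mir_eff, masks$scenario3] + delta[mir_eff]
  }
  cell_sign <- rep(0L, np)
  if (length(idx_cell)) {
    dl <- sheet$lymphocytes - 1.9
    dm <- sheet$monocytes - 0.43
    shift <- config$cellmix_slopes[["lymphocytes"]] * dl +
      config$cellmix_slopes[["monocytes"]] * dm
    # sign varies per probe: some CpGs are methylated high in lymphoid,
    # others in myeloid cells, so composition moves them in opposite
    # directions (and the panel stays mean-balanced across probes)
    cell_sign[idx_cell] <- rep_len(c(1L, -1L), length(idx_cell))
    mu[idx_cell, ] <- mu[idx_cell, ] +
      cell_sign[idx_cell] * rep(shift, each = length(idx_cell))
  }
  cov_of <- rep(NA_character_, np)
  if (length(idx_cov)) {
    cov_of[idx_cov] <- rep_len(names(config$covariate_slopes), length(idx_cov))
    centers <- c(age = 28.7, bmi = 24.8)
    for (v in names(config$covariate_slopes)) {
      ii <- idx_cov[cov_of[idx_cov] == v]
      if (!length(ii)) next
      shift <- config$covariate_slopes[[v]] * (sheet[[v]] - centers[[v]])
      mu[ii, ] <- mu[ii, ] + rep(shift, each = length(ii))
    }
  }
  mu <- pmin(pmax(mu, 0.005), 0.995)

  ## ---- noise, probe-type bias, assembly --------------------------------
  m <- beta_to_m(mu)
  if (config$subject_sd_m > 0) {
    u <- matrix(stats::rnorm(np * ns, 0, config$subject_sd_m), np, ns)
    m <- m + u[, si, drop = FALSE]
  }
  if (config$noise_sd_m > 0)
    m <- m + matrix(stats::rnorm(np * n_samples, 0, config$noise_sd_m),
                    np, n_samples)
  ii_type2 <- anno$probe_type == "II"
  m[ii_type2, ] <- m[ii_type2, ] * config$typeII_compression
  beta <- m_to_beta(m)
  dimnames(beta) <- dimnames(m) <- list(probe_id, sheet$sample_id)

  detp <- matrix(stats::runif(np * n_samples, 0, 0.005), np, n_samples,
                 dimnames = dimnames(beta))
  ndf <- round(config$frac_detection_fail * np)
  if (ndf > 0) {
    df_idx <- utils::head(pool, ndf)
    pool <- utils::tail(pool, -length(df_idx))
    for (i in df_idx)
      detp[i, sample.int(n_samples, sample(1:3, 1L))] <-
        stats::runif(1, 0.02, 0.8)
  } else df_idx <- integer(0)
  nmiss <- round(config$frac_missing * np)
  if (nmiss > 0) {
    ms_idx <- utils::head(pool, nmiss)
    for (i in ms_idx) beta[i, sample.int(n_samples, 1L)] <- NA
    m[is.na(beta)] <- NA
  } else ms_idx <- integer(0)

  ## ---- ground truth -----------------------------------------------------
  ovl <- overlap_bp_by_class(anno, track)
  truth <- data.frame(probe_id = probe_id, label = label,
                      planted_delta_beta = delta,
                      covariate = cov_of,
                      cellmix_sign = cell_sign,
                      alu_overlap_bp = ovl[, "Alu"],
                      line1_overlap_bp = ovl[, "LINE1"],
                      in_alu = ovl[, "Alu"] >= 15L,
                      in_line1 = ovl[, "LINE1"] >= 15L,
                      mirna = NA_character_,
                      detection_fail = seq_len(np) %in% df_idx,
                      has_missing = seq_len(np) %in% ms_idx,
                      stringsAsFactors = FALSE)
  truth$mirna[idx_mir] <- mir$name[mir_of_probe]
  rownames(truth) <- probe_id

  structure(list(beta = beta, m = m, detp = detp, sheet = sheet,
                 annotation = anno, repeats = track, mirna_loci = mir,
                 truth = truth, config = config),
            class = "crossmeth_sim")
}

#' @export
print.crossmeth_sim <- function(x, ...) {
  cat("Synthetic crossover methylation dataset\n")
  cat("  probes:", nrow(x$beta), "  samples:", ncol(x$beta),
      sprintf("(%d subjects x %d arms x %d timepoints)\n",
              x$config$n_subjects, length(x$config$arms),
              length(x$config$timepoints)))
  tab <- table(x$truth$label)
  cat("  planted labels:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
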