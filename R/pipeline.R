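# End-to-end analysis orchestration --------------------------------------
#
# Fixed stage order: quality control and normalization -> PCA and
# covariate screen -> cell-composition filter -> scenario association ->
# loading hits on the scenario component -> per-probe mixed models and
# DMP calls -> repeat/microRNA region analyses. Each stage's summary
# counts go into a manifest so a silent change anywhere is visible.

#' Pipeline configuration
#'
#' @param detection_alpha detection p-value threshold for probe
#'   filtering (default 0.01).
#' @param sd_multiplier loading cutoff in SD units (default 3).
#' @param fdr FDR level used by every q-value family (default 0.10).
#' @param min_overlap_bp minimum probe/repeat overlap in bp (default 15).
#' @param clip_eps beta clipping margin for the M transform.
#' @param peak_bw kernel bandwidth for peak-based correction
#'   (`"nrd0"` = Silverman's rule).
#' @param stages stages to run, a subset of `"qc"`, `"pca"`,
#'   `"cellmix"`, `"scenario"`, `"dmp"`, `"regions"`; the fixed order is
#'   enforced and later stages require their prerequisites.
#' @param variables optional named class vector for the association
#'   screen; defaults to [default_variable_classes()] of the scenario-
#'   augmented sheet.
#' @param epigenome_wide when `TRUE` the mixed model runs on every
#'   surviving probe instead of the scenario-component loading hits
#'   (sensitivity analysis; much slower).
#' @param out_dir optional directory: stage tables and a JSON manifest
#'   are written there.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(detection_alpha = 0.01, sd_multiplier = 3,
                            fdr = 0.10, min_overlap_bp = 15L,
                            clip_eps = 1e-6, peak_bw = "nrd0",
                            stages = c("qc", "pca", "cellmix", "scenario",
                                       "dmp", "regions"),
                            variables = NULL,
                            epigenome_wide = FALSE,
                            out_dir = NULL) {
  stopifnot(detection_alpha > 0, detection_alpha < 1,
            sd_multiplier >= 0, fdr > 0, fdr < 1, min_overlap_bp >= 1)
  all_stages <- c("qc", "pca", "cellmix", "scenario", "dmp", "regions")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- list(pca = "qc", cellmix = c("qc", "pca"),
               scenario = c("qc", "pca"),
               dmp = c("qc", "pca", "scenario"),
               regions = "qc")
  for (s in intersect(names(need), stages))
    if (!all(need[[s]] %in% stages))
      stop("stage '", s, "' requires: ",
           paste(setdiff(need[[s]], stages), collapse = ", "))
  structure(list(detection_alpha = detection_alpha,
                 sd_multiplier = sd_multiplier, fdr = fdr,
                 min_overlap_bp = as.integer(min_overlap_bp),
                 clip_eps = clip_eps, peak_bw = peak_bw,
                 stages = stages, variables = variables,
                 epigenome_wide = epigenome_wide, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full crossover methylation analysis
#'
#' Executes the enabled stages in fixed order on a dataset bundle: the
#' output of [generate_dataset()], of [read_fixture()], or a fixture
#' directory path. A stage failure aborts with the stage name; results
#' of completed stages are preserved in the error's `partial` attribute.
#'
#' @param data dataset bundle (`beta`, `detp`, `sheet`, `annotation`,
#'   `repeats`, `mirna_loci`) or a fixture directory path.
#' @param config a [pipeline_config()].
#' @return object of class `"crossmeth_result"`: list with the per-stage
#'   results (`qc`, `matrix` (`m`, `beta`), `pca`, `associations`,
#'   `cellmix`, `scenario`, `hits`, `dmp`, `carryover`, `regions`) and a
#'   `manifest` of counts and thresholds.
#' @examples
#' \donttest{
#' sim <- generate_dataset(simulation_config(n_probes = 800, seed = 4))
#' res <- run_pipeline(sim, pipeline_config(stages = c("qc", "pca")))
#' res$manifest$qc
#' }
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  if (is.character(data) && length(data) == 1L) data <- read_fixture(data)
  stopifnot(is.list(data), !is.null(data$beta), !is.null(data$sheet),
            !is.null(data$annotation))
  res <- list(config = config)
  manifest <- list(thresholds = list(
    detection_alpha = config$detection_alpha,
    sd_multiplier = config$sd_multiplier, fdr = config$fdr,
    min_overlap_bp = config$min_overlap_bp))
  stage <- "qc"
  run_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("pipeline stage '", stage, "' failed: ",
                                conditionMessage(e)))
      attr(err, "partial") <- res
      stop(err)
    })
  }

  ## qc ---------------------------------------------------------------
  sheet <- data$sheet
  res$qc <- run_guard("qc", {
    filter_probes(data$beta, data$annotation, data$detp,
                  config$detection_alpha)
  })
  manifest$qc <- c(list(n_input = res$qc$report$n_input,
                        n_kept = res$qc$report$n_kept),
                   as.list(res$qc$report$removed))
  res$matrix <- run_guard("qc", {
    b <- data$beta[res$qc$kept, , drop = FALSE]
    b <- quantile_normalize(b)
    m <- beta_to_m(b, eps = config$clip_eps)
    pc <- peak_correct(m, data$annotation, bw = config$peak_bw)
    list(m = pc$m, beta = pc$beta, peak_map = pc$map)
  })
  anno_kept <- data$annotation[match(res$qc$kept, data$annotation$probe_id), ,
                               drop = FALSE]

  ## pca ---------------------------------------------------------------
  if ("pca" %in% config$stages) {
    res$pca <- run_guard("pca", methyl_pca(res$matrix$m))
    sheet_sc <- run_guard("pca", add_scenario_columns(sheet))
    vars <- config$variables
    if (is.null(vars)) vars <- default_variable_classes(sheet_sc)
    res$associations <- run_guard("pca",
      associate_components(res$pca, sheet_sc, vars, fdr = config$fdr))
    manifest$pca <- list(
      n_components = length(res$pca$d),
      n_significant_associations = sum(res$associations$significant))
  }

  ## cellmix -----------------------------------------------------------
  cell_result <- NULL
  if ("cellmix" %in% config$stages) {
    res$cellmix <- run_guard("cellmix", {
      comps <- cell_components(res$associations, fdr = config$fdr)
      cand <- candidate_cell_probes(res$pca, comps, config$sd_multiplier)
      list(components = comps, candidates = cand,
           result = if (length(cand))
             regress_cell_counts(res$matrix$m, sheet, cand, config$fdr)
           else NULL)
    })
    cell_result <- res$cellmix$result
    manifest$cellmix <- list(
      n_components = length(res$cellmix$components),
      n_candidates = length(res$cellmix$candidates),
      n_significant = if (is.null(cell_result)) 0L
                      else sum(cell_result$significant))
  }

  ## scenario ----------------------------------------------------------
  if ("scenario" %in% config$stages) {
    res$scenario <- run_guard("scenario", {
      scen <- find_scenario_component(res$pca, confound_table = res$associations,
                                      sheet = sheet, fdr = config$fdr)
      sep <- NULL
      if (nrow(scen)) {
        best <- scen[which.min(scen$q), ]
        mask <- scenario_mask(sheet, best$scenario)
        sep <- score_separation(res$pca, best$component, mask)
      }
      list(table = scen, separation = sep)
    })
    best_row <- if (nrow(res$scenario$table))
      res$scenario$table[which.min(res$scenario$table$q), ] else NULL
    manifest$scenario <- list(
      n_found = nrow(res$scenario$table),
      component = if (is.null(best_row)) NA else best_row$component,
      scenario = if (is.null(best_row)) NA else best_row$scenario)
  }

  ## dmp ----------------------------------------------------------------
  if ("dmp" %in% config$stages) {
    res <- run_guard("dmp", {
      hits <- character(0)
      if (config$epigenome_wide) {
        hits <- rownames(res$matrix$m)
      } else if (nrow(res$scenario$table)) {
        best <- res$scenario$table[which.min(res$scenario$table$q), ]
        hits <- loading_hits(res$pca, best$component, config$sd_multiplier)
      }
      res$hits <- hits
      if (length(hits)) {
        fit <- fit_lme(res$matrix$m, sheet, hits)
        db <- delta_beta(res$matrix$beta, sheet, hits)
        res$dmp <- call_dmps(fit, db, cell_result, config$fdr)
        res$carryover <- suppressWarnings(
          carryover_test(res$matrix$beta, sheet, res$dmp))
      } else {
        message("no scenario component found; DMP stage has no hit set")
      }
      res
    })
    manifest$dmp <- if (!is.null(res$dmp)) {
      c(list(n_hits = length(res$hits)),
        as.list(attr(res$dmp, "counts")))
    } else list(n_hits = length(res$hits))
  }

  ## regions -------------------------------------------------------------
  if ("regions" %in% config$stages) {
    res$regions <- run_guard("regions", {
      pr <- probe_intervals(anno_kept)
      sets <- probes_in_repeats(pr, data$repeats, config$min_overlap_bp)
      mir <- if (!is.null(data$mirna_loci))
        probes_in_mirna(pr, data$mirna_loci) else NULL
      if (!is.null(mir) && nrow(mir)) sets$miRNA <- unique(mir$probe_id)
      reports <- suppressWarnings(
        region_dmp_analysis(res$matrix$m, res$matrix$beta, sheet, sets,
                            cell_result, config$fdr))
      list(sets = sets, mirna_membership = mir, reports = reports)
    })
    manifest$regions <- lapply(res$regions$reports, function(r)
      as.list(attr(r, "counts")))
    manifest$regions$set_sizes <- lapply(res$regions$sets, length)
  }

  res$manifest <- manifest
  class(res) <- "crossmeth_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

# write stage tables and the manifest under out_dir
write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  write_filter_report(res$qc$report, file.path(dir, "filter_report.json"))
  if (!is.null(res$associations))
    write_result_tsv(res$associations, file.path(dir, "associations.tsv"))
  if (!is.null(res$cellmix$result))
    write_result_tsv(res$cellmix$result, file.path(dir, "cell_assoc.tsv"))
  if (!is.null(res$scenario) && nrow(res$scenario$table))
    write_result_tsv(res$scenario$table, file.path(dir, "scenario.tsv"))
  if (!is.null(res$dmp))
    write_result_tsv(res$dmp, file.path(dir, "dmp_report.tsv"))
  if (!is.null(res$regions)) {
    for (cls in names(res$regions$reports))
      write_result_tsv(res$regions$reports[[cls]],
                       file.path(dir, paste0("dmp_", cls, ".tsv")))
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.crossmeth_result <- function(x, ...) {
  cat("Crossover methylation pipeline result\n")
  m <- x$manifest
  cat("  QC:", m$qc$n_input, "probes in,", m$qc$n_kept, "kept\n")
  if (!is.null(m$pca))
    cat("  PCA:", m$pca$n_components, "components,",
        m$pca$n_significant_associations, "significant covariate associations\n")
  if (!is.null(m$cellmix))
    cat("  Cell filter:", m$cellmix$n_candidates, "candidates,",
        m$cellmix$n_significant, "confirmed\n")
  if (!is.null(m$scenario))
    cat("  Scenario:", m$scenario$n_found, "component(s); best:",
        m$scenario$component, "for", m$scenario$scenario, "\n")
  if (!is.null(m$dmp))
    cat("  DMPs:", if (!is.null(m$dmp$dmp)) m$dmp$dmp else 0, "from",
        m$dmp$n_hits, "hits\n")
  if (!is.null(x$regions))
    for (cls in names(x$regions$reports))
      cat("  Region ", cls, ": ",
          attr(x$regions$reports[[cls]], "counts")[["dmp"]], " DMPs of ",
          length(x$regions$sets[[cls]]), " probes\n", sep = "")
  invisible(x)
}

#' @export
summary.crossmeth_result <- function(object, ...) object$manifest
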