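# Temporal exposure scenarios --------------------------------------------
#
# Three dichotomous codings of when a diesel-exhaust effect would be
# visible, each splitting the samples into an "exposed" group and a
# pooled baseline (all FA samples plus DE pre-exposure): scenario 1 at
# 6 h only, scenario 2 at 30 h only, scenario 3 at both 6 h and 30 h.

#' Dichotomous sample mask for a temporal exposure scenario
#'
#' @param sheet sample sheet with `arm` and `timepoint` columns covering
#'   both arms and all timepoints.
#' @param label `"scenario1"`, `"scenario2"` or `"scenario3"`.
#' @param timepoints the design's timepoints in hours; the first is the
#'   baseline, the second and third are the post-exposure draws.
#' @return logical vector, `TRUE` for samples in the exposed group.
#' @examples
#' sim <- generate_dataset(simulation_config(n_probes = 100, seed = 2))
#' sum(scenario_mask(sim$sheet, "scenario3"))  # 32 = 16 subjects x 2 draws
#' @export
scenario_mask <- function(sheet, label,
                          timepoints = sort(unique(sheet$timepoint))) {
  if (!all(c("FA", "DE") %in% sheet$arm))
    stop("sheet must contain both FA and DE samples")
  if (length(timepoints) < 3L)
    stop("need a baseline and two post-exposure timepoints")
  de <- sheet$arm == "DE"
  mask <- switch(label,
    scenario1 = de & sheet$timepoint == timepoints[2L],
    scenario2 = de & sheet$timepoint == timepoints[3L],
    scenario3 = de & sheet$timepoint %in% timepoints[2:3],
    stop("unknown scenario label: ", label))
  if (!any(mask) || all(mask))
    stop("scenario mask does not split the samples into two groups")
  mask
}

#' Add scenario indicator columns to a sample sheet
#'
#' @param sheet sample sheet.
#' @return `sheet` with logical columns `scenario1`, `scenario2`,
#'   `scenario3` appended, for use in the component association screen.
#' @export
add_scenario_columns <- function(sheet) {
  for (sc in c("scenario1", "scenario2", "scenario3"))
    sheet[[sc]] <- scenario_mask(sheet, sc)
  sheet
}

#' Find exposure-scenario-associated, confound-free components
#'
#' Tests every retained component's scores against each scenario mask
#' with the Wilcoxon rank-sum test and returns the components that are
#' significant at `fdr` and NOT significantly associated with any
#' confound variable in `confound_table`. An empty result is a valid
#' outcome (no exposure-associated variation detected).
#'
#' The scenario codings are screened as part of the same covariate
#' association screen as everything else, so when `confound_table`
#' already contains rows for the scenario variables their q-values
#' (computed over the full component-by-variable family) are reused;
#' otherwise Storey q-values are computed over the (component x
#' scenario) table alone.
#'
#' @param pca a [methyl_pca()] object.
#' @param masks named list of logical scenario masks (default: all three
#'   scenarios derived from `sheet`).
#' @param confound_table an `"association_table"` covering demographics,
#'   batch and cell counts.
#' @param sheet sample sheet (used only when `masks` is not given).
#' @param confound_vars variables regarded as confounds; defaults to
#'   every variable in `confound_table` except the scenario codings and
#'   exposure-design variables (`arm`, `order`, `timepoint`, `subject`).
#' @param fdr q-value cutoff (default 0.1).
#' @param confound_rule how a confound association disqualifies a
#'   component. `"dominant"` (default): the component is excluded only
#'   when some confound is associated at least as decisively as the
#'   scenario itself (confound q no larger than the scenario q), i.e.
#'   the component cannot be attributed primarily to exposure.
#'   `"strict"`: any confound association significant at `fdr` excludes
#'   the component, regardless of how overwhelmingly the scenario
#'   explains it. The strict rule is fragile for components dominated by
#'   within-subject exposure signal: their subject-mean scores are
#'   vanishingly small, so even a trace of subject-level admixture can
#'   produce a formally significant (but negligible) covariate
#'   correlation.
#' @return data.frame of class `"scenario_assoc"` with one row per
#'   (scenario, component) pair that passed, columns `scenario`,
#'   `component`, `p`, `q`; the full test table is in
#'   `attr(, "all_tests")`.
#' @export
find_scenario_component <- function(pca, masks = NULL, confound_table,
                                    sheet = NULL,
                                    confound_vars = NULL, fdr = 0.1,
                                    confound_rule = c("dominant", "strict")) {
  confound_rule <- match.arg(confound_rule)
  stopifnot(inherits(pca, "methyl_pca"))
  if (is.null(masks)) {
    if (is.null(sheet)) stop("provide masks or a sheet to derive them from")
    masks <- lapply(stats::setNames(nm = paste0("scenario", 1:3)),
                    function(sc) scenario_mask(sheet, sc))
  }
  comps <- colnames(pca$scores)
  screened <- !is.null(confound_table) &&
    all(names(masks) %in% confound_table$variable)
  if (screened) {
    sel <- confound_table$variable %in% names(masks)
    tab <- data.frame(scenario = confound_table$variable[sel],
                      component = confound_table$component[sel],
                      p = confound_table$p[sel],
                      q = confound_table$q[sel],
                      stringsAsFactors = FALSE)
  } else {
    tab <- expand.grid(scenario = names(masks), component = comps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab$p <- mapply(function(sc, comp) {
      s <- pca$scores[, comp]
      mk <- masks[[sc]]
      wilcoxon_ranksum(s[mk], s[!mk])$p
    }, tab$scenario, tab$component)
    tab$q <- suppressWarnings(storey_qvalue(tab$p))$q
  }
  if (is.null(confound_vars))
    confound_vars <- setdiff(unique(confound_table$variable),
                             c(names(masks), "arm", "order", "timepoint",
                               "subject"))
  conf <- confound_table[confound_table$variable %in% confound_vars &
                           confound_table$significant, , drop = FALSE]
  if (confound_rule == "strict") {
    confounded <- unique(conf$component)
    keep <- tab$q <= fdr & !(tab$component %in% confounded)
  } else {
    min_conf_q <- tapply(conf$q, conf$component, min)
    comp_conf_q <- unname(min_conf_q[tab$component])
    comp_conf_q[is.na(comp_conf_q)] <- Inf
    keep <- tab$q <= fdr & comp_conf_q > tab$q
    confounded <- unique(tab$component[tab$q <= fdr & comp_conf_q <= tab$q])
  }
  out <- tab[keep, , drop = FALSE]
  out <- out[order(out$scenario, out$q), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_tests") <- tab
  attr(out, "confounded_components") <- confounded
  class(out) <- c("scenario_assoc", "data.frame")
  out
}

#' Score separation of a component between mask groups
#'
#' Group means of the component's sample scores inside and outside the
#' mask, with Welch's two-sample t-test of the difference. The reported
#' means follow the decomposition's sign convention; both are returned
#' so the direction can be read either way.
#'
#' @param pca a [methyl_pca()] object.
#' @param component component name or index.
#' @param mask logical sample mask.
#' @return list with `mean_in`, `mean_out`, `t_p`.
#' @export
score_separation <- function(pca, component, mask) {
  s <- pca$scores[, component]
  if (sum(mask) < 2L || sum(!mask) < 2L) {
    warning("degenerate group in score_separation")
    return(list(mean_in = NA_real_, mean_out = NA_real_, t_p = NA_real_))
  }
  tt <- welch_t(s[mask], s[!mask])
  list(mean_in = mean(s[mask]), mean_out = mean(s[!mask]), t_p = tt$p)
}
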