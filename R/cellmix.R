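# Blood cell-composition confound filtering ------------------------------
#
# PBMC methylation is measured on a cell mixture, so probes whose signal
# tracks lymphocyte or monocyte counts reflect composition shifts rather
# than within-cell change. The filter finds components associated with
# counts, collects high-loading probes on them, confirms the association
# per probe by regression, and removes confirmed probes from exposure
# hits.

#' Components associated with blood cell counts
#'
#' Convenience accessor: the components whose scores are significantly
#' associated (q at or below `fdr`) with any of the given count variables
#' in an association table.
#'
#' @param assoc an `"association_table"` from [associate_components()].
#' @param count_vars count variable names (default lymphocytes and
#'   monocytes; basophils are screened but, matching the regression
#'   model, not used to build the candidate set).
#' @param fdr q-value cutoff (default 0.1).
#' @return character vector of component names.
#' @export
cell_components <- function(assoc, count_vars = c("lymphocytes", "monocytes"),
                            fdr = 0.1) {
  sel <- assoc$variable %in% count_vars & !is.na(assoc$q) & assoc$q <= fdr
  unique(assoc$component[sel])
}

#' Candidate cell-composition probes from component loadings
#'
#' Union of [loading_hits()] over the cell-count-associated components at
#' the given SD cutoff. Duplicated component names contribute once (union
#' semantics). An empty component list yields an empty set with a
#' message.
#'
#' @param pca a [methyl_pca()] object.
#' @param components component names associated with cell counts (e.g.
#'   from [cell_components()]).
#' @param sd_multiplier loading cutoff in SD units (default 3).
#' @return character vector of candidate probe ids.
#' @export
candidate_cell_probes <- function(pca, components, sd_multiplier = 3) {
  components <- unique(components)
  if (!length(components)) {
    message("no cell-count-associated components; empty candidate set")
    return(character(0))
  }
  unique(unlist(lapply(components, function(k)
    loading_hits(pca, k, sd_multiplier))))
}

#' Per-probe regression on blood cell counts
#'
#' Fits, for every candidate probe, the linear model
#' \eqn{Y = \beta_0 + \beta_1 \mathrm{Lymphocyte} + \beta_2 \mathrm{Monocyte} + \varepsilon}
#' on M values across all samples, and summarizes the association with
#' the joint F-test of \eqn{(\beta_1, \beta_2) = 0}. Storey q-values are
#' computed over the candidate family and probes are flagged significant
#' at `fdr`. Zero-variance probes get `NA` p-values and are excluded from
#' the family.
#'
#' @param m probes x samples M-value matrix.
#' @param sheet sample sheet with `lymphocytes` and `monocytes` columns
#'   (per-sample counts).
#' @param candidates candidate probe ids (non-empty).
#' @param fdr q-value cutoff (default 0.1).
#' @return data.frame of class `"cell_assoc"` with columns `probe_id`,
#'   `beta_lymph`, `beta_mono`, `statistic`, `p`, `q`, `significant`.
#' @export
regress_cell_counts <- function(m, sheet, candidates, fdr = 0.1) {
  if (!length(candidates)) stop("candidate set is empty")
  candidates <- intersect(candidates, rownames(m))
  y <- t(m[candidates, , drop = FALSE])          # samples x probes
  x <- cbind(1, lymph = sheet$lymphocytes, mono = sheet$monocytes)
  if (anyNA(x)) stop("cell counts must be complete")
  kappa_x <- kappa(crossprod(x))
  if (kappa_x > 1e10)
    warning("cell-count design is near-collinear (condition number ",
            format(kappa_x, digits = 3), "); fit proceeds")
  qr_x <- qr(x)
  coefs <- qr.coef(qr_x, y)                      # 3 x probes
  fit <- qr.fitted(qr_x, y)
  rss1 <- colSums((y - fit)^2)
  rss0 <- colSums(scale(y, scale = FALSE)^2)
  df2 <- nrow(y) - 3L
  fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
  p <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  zero_var <- rss0 <= .Machine$double.eps * nrow(y)
  p[zero_var] <- NA
  fstat[zero_var] <- NA
  q <- suppressWarnings(storey_qvalue(p))$q
  out <- data.frame(probe_id = candidates,
                    beta_lymph = coefs["lymph", ],
                    beta_mono = coefs["mono", ],
                    statistic = fstat, p = p, q = q,
                    significant = !is.na(q) & q <= fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("cell_assoc", "data.frame")
  out
}

#' Remove cell-composition probes from a hit set
#'
#' Pure set difference: exposure hits minus the probes confirmed to track
#' blood cell counts.
#'
#' @param hits character vector of exposure-associated probe ids.
#' @param cell_result a `"cell_assoc"` data.frame (or a character vector
#'   of probe ids to remove).
#' @return the surviving probe ids; the number removed is reported via
#'   `message()`.
#' @export
exclude_cell_probes <- function(hits, cell_result) {
  sig <- if (is.character(cell_result)) cell_result
         else cell_result$probe_id[cell_result$significant]
  out <- setdiff(hits, sig)
  message(length(hits) - length(out), " of ", length(hits),
          " hits removed as cell-composition-associated; ",
          length(out), " remain")
  out
}
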