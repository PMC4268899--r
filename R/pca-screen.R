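# PCA decomposition, covariate association screen, loading selection ------

#' Principal component decomposition of a methylation matrix
#'
#' Centres each probe across samples (which removes the global-intensity
#' offset component by construction) and applies the singular value
#' decomposition. Probe loadings are the left singular vectors (unit norm
#' per component), sample scores the right singular vectors (unit norm),
#' and the centred matrix is reconstructed as
#' `loadings %*% diag(sdev * sqrt(n - 1)) %*% t(scores)`. Components are
#' ordered by decreasing explained variance and at most
#' `min(samples - 1, probes)` are retained; a sign convention (the
#' largest-magnitude loading of each component is positive) removes the
#' SVD sign ambiguity so reports are reproducible.
#'
#' @param m probes x samples numeric matrix of M values, no missing
#'   values, at least two samples.
#' @return object of class `"methyl_pca"`: list with `scores` (samples x
#'   components), `loadings` (probes x components), `d` (singular
#'   values), `variance_fraction`, and `center` (per-probe means).
#' @examples
#' sim <- generate_dataset(simulation_config(n_probes = 300, seed = 5))
#' pca <- methyl_pca(beta_to_m(sim$beta))
#' head(pca$variance_fraction)
#' @export
methyl_pca <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  if (anyNA(m)) stop("PCA requires a complete matrix; run QC first")
  ctr <- rowMeans(m)
  x <- m - ctr
  k <- min(ncol(m) - 1L, nrow(m))
  sv <- svd(x, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  pos <- d > max(d[1L], .Machine$double.eps) * 1e-10
  if (!all(pos)) {
    k <- sum(pos)
    message("rank-deficient input: retaining ", k, " components")
  }
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  scores <- sv$v[, seq_len(k), drop = FALSE]
  d <- d[seq_len(k)]
  # orient each component so its largest-|loading| entry is positive
  flip <- vapply(seq_len(k), function(j) {
    sign(loadings[which.max(abs(loadings[, j])), j])
  }, 0)
  loadings <- sweep(loadings, 2L, flip, `*`)
  scores <- sweep(scores, 2L, flip, `*`)
  cn <- paste0("PC", seq_len(k))
  dimnames(loadings) <- list(rownames(m), cn)
  dimnames(scores) <- list(colnames(m), cn)
  structure(list(scores = scores, loadings = loadings, d = d,
                 variance_fraction = d^2 / sum(sv$d^2),
                 center = ctr),
            class = "methyl_pca")
}

#' @export
print.methyl_pca <- function(x, ...) {
  k <- length(x$d)
  cat("Methylation PCA:", nrow(x$loadings), "probes,", nrow(x$scores),
      "samples,", k, "components\n")
  vf <- utils::head(round(100 * x$variance_fraction, 2), 5)
  cat("  top variance fractions (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.methyl_pca <- function(object, ...) {
  data.frame(component = colnames(object$scores),
             sd = object$d / sqrt(nrow(object$scores) - 1),
             variance_fraction = object$variance_fraction)
}

#' Default variable class declarations for the association screen
#'
#' Maps the sample-sheet columns the generator emits (and the analogous
#' columns of a real study sheet) to test families: nominal variables get
#' one-way ANOVA, continuous variables Spearman correlation, dichotomous
#' variables the Wilcoxon rank-sum test. Only variables present in
#' `sheet` are returned.
#'
#' @param sheet sample sheet data.frame.
#' @return named character vector (`variable -> class`).
#' @export
default_variable_classes <- function(sheet) {
  cls <- c(subject = "nominal", timepoint = "nominal",
           ethnicity = "nominal", chip = "nominal", position = "nominal",
           age = "continuous", bmi = "continuous",
           lymphocytes = "continuous", monocytes = "continuous",
           basophils = "continuous",
           arm = "dichotomous", sex = "dichotomous",
           order = "dichotomous", gstp1 = "dichotomous",
           scenario1 = "dichotomous", scenario2 = "dichotomous",
           scenario3 = "dichotomous")
  cls[names(cls) %in% names(sheet)]
}

#' Associate principal components with sample covariates
#'
#' For every (component, variable) pair applies the declared test to the
#' component's sample scores: one-way ANOVA for nominal variables,
#' Spearman correlation for continuous variables, Wilcoxon rank-sum for
#' dichotomous variables. Storey q-values are computed over the whole
#' table (one family) and significance is flagged at `fdr`. Constant or
#' otherwise degenerate variables yield `NA` rows.
#'
#' The design is nested: each subject contributes several samples. A
#' covariate that is constant within subject (age, sex, genotype, chip,
#' ...) carries only as many independent observations as there are
#' subjects, so testing it against per-sample scores would treat
#' replicate draws as evidence and inflate significance. Such variables
#' are therefore tested against the subject-mean scores. The same logic
#' applies to continuous covariates dominated by between-subject
#' variance (blood cell counts vary a little from visit to visit but
#' mostly between people): when the subject explains more than
#' `icc_threshold` of a continuous variable's variance it is aggregated
#' to subject means as well. Variables that genuinely vary within
#' subject (timepoint, exposure arm, scenario codings, chip position)
#' are tested per sample.
#'
#' @param pca a [methyl_pca()] object.
#' @param sheet sample sheet aligned with the score rows.
#' @param variables named character vector mapping sheet columns to
#'   `"nominal"`, `"continuous"` or `"dichotomous"`; defaults to
#'   [default_variable_classes()].
#' @param fdr significance cutoff on the q-value (default 0.1).
#' @param subject_col sheet column identifying the subject (`NULL` to
#'   disable subject-level aggregation).
#' @param icc_threshold fraction of a continuous variable's variance
#'   that the subject must explain for the variable to be tested at the
#'   subject level (default 0.5).
#' @return data.frame of class `"association_table"` with columns
#'   `component`, `variable`, `test`, `statistic`, `p`, `q`,
#'   `significant`, `unit` (`"sample"` or `"subject"`).
#' @export
associate_components <- function(pca, sheet,
                                 variables = default_variable_classes(sheet),
                                 fdr = 0.1, subject_col = "subject",
                                 icc_threshold = 0.5) {
  stopifnot(inherits(pca, "methyl_pca"))
  if (nrow(pca$scores) != nrow(sheet))
    stop("sheet and scores are not aligned")
  if (!all(names(variables) %in% names(sheet)))
    stop("undeclared sheet columns: ",
         paste(setdiff(names(variables), names(sheet)), collapse = ", "))
  subj <- if (!is.null(subject_col) && subject_col %in% names(sheet))
    sheet[[subject_col]] else NULL
  is_subject_level <- function(v, cls) {
    if (is.null(subj)) return(FALSE)
    if (all(tapply(as.character(v), subj,
                   function(x) length(unique(x[!is.na(x)])) <= 1L)))
      return(TRUE)
    if (cls == "continuous") {
      vn <- as.numeric(v)
      if (stats::var(vn, na.rm = TRUE) == 0) return(FALSE)
      r2 <- summary(stats::lm(vn ~ factor(subj)))$r.squared
      return(r2 >= icc_threshold)
    }
    FALSE
  }
  comps <- colnames(pca$scores)
  grid <- expand.grid(component = comps, variable = names(variables),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  subject_level <- vapply(names(variables), function(v)
    is_subject_level(sheet[[v]], variables[[v]]), TRUE)
  res <- mapply(function(comp, var) {
    s <- pca$scores[, comp]
    v <- sheet[[var]]
    if (subject_level[[var]]) {
      s <- as.numeric(tapply(s, subj, mean))
      v <- if (variables[[var]] == "continuous")
        as.numeric(tapply(as.numeric(v), subj, mean, na.rm = TRUE))
      else vapply(split(as.character(v), subj),
                  function(x) x[!is.na(x)][1L], "")
    }
    cls <- variables[[var]]
    if (length(unique(v[!is.na(v)])) < 2L)
      return(c(NA_real_, NA_real_))
    ans <- switch(cls,
      nominal = {
        a <- suppressWarnings(oneway_anova(s, v))
        c(a$statistic, a$p)
      },
      continuous = {
        a <- suppressWarnings(spearman_cor(as.numeric(v), s))
        c(a$rho, a$p)
      },
      dichotomous = {
        lv <- sort(unique(as.character(v)))
        if (length(lv) != 2L) return(c(NA_real_, NA_real_))
        a <- wilcoxon_ranksum(s[as.character(v) == lv[1L]],
                              s[as.character(v) == lv[2L]])
        c(a$statistic, a$p)
      },
      stop("unknown variable class: ", cls))
    ans
  }, grid$component, grid$variable)
  grid$test <- unname(c(nominal = "anova", continuous = "spearman",
                        dichotomous = "wilcoxon")[variables[grid$variable]])
  grid$unit <- ifelse(subject_level[grid$variable], "subject", "sample")
  grid$statistic <- res[1L, ]
  grid$p <- res[2L, ]
  qv <- suppressWarnings(storey_qvalue(grid$p))
  grid$q <- qv$q
  grid$significant <- !is.na(grid$q) & grid$q <= fdr
  attr(grid, "pi0") <- qv$pi0
  attr(grid, "fdr") <- fdr
  class(grid) <- c("association_table", "data.frame")
  grid
}

#' Select probes by loading magnitude on one component
#'
#' Returns the probes whose loading on `component` deviates from the mean
#' loading by more than `sd_multiplier` standard deviations (mean and SD
#' taken over that component's probe loadings). The selection is
#' invariant to a global sign flip of the component.
#'
#' @param pca a [methyl_pca()] object.
#' @param component component name (`"PC22"`) or index.
#' @param sd_multiplier cutoff in SD units (default 3).
#' @return character vector of probe ids.
#' @export
loading_hits <- function(pca, component, sd_multiplier = 3) {
  stopifnot(inherits(pca, "methyl_pca"), sd_multiplier >= 0)
  l <- pca$loadings[, component]
  dev <- abs(l - mean(l))
  rownames(pca$loadings)[dev > sd_multiplier * stats::sd(l)]
}

#' Write an association table (or any result table) as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
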