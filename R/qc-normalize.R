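# Probe filtering and normalization --------------------------------------

#' Probe quality filtering
#'
#' Removes probes in a fixed three-stage order: (1) probes with a
#' detection p-value above `detection_alpha` in at least one sample, or
#' with at least one missing beta; (2) probes on the X or Y chromosome
#' (sex-derived differences); (3) probes flagged as cross-hybridizing or
#' polymorphic. Stage counts are conditional on the previous stage, so
#' they sum to the number of probes removed overall.
#'
#' @param beta probes x samples beta matrix (may contain `NA`).
#' @param annotation probe annotation data.frame with columns `probe_id`,
#'   `on_xy`, `cross_hybridizing`, `polymorphic`, covering every probe in
#'   `beta`.
#' @param detp optional probes x samples matrix of detection p-values,
#'   aligned with `beta`; omit to skip the detection part of stage 1.
#' @param detection_alpha detection p-value threshold (default 0.01).
#' @return list with `kept` (character vector of surviving probe ids) and
#'   `report`, a `"filter_report"` object with per-stage removal counts.
#' @examples
#' sim <- generate_dataset(simulation_config(n_probes = 200, seed = 3))
#' fr <- filter_probes(sim$beta, sim$annotation, sim$detp)
#' fr$report
#' @export
filter_probes <- function(beta, annotation, detp = NULL,
                          detection_alpha = 0.01) {
  stopifnot(is.matrix(beta), detection_alpha > 0, detection_alpha < 1)
  ids <- rownames(beta)
  if (is.null(ids)) stop("beta matrix must have probe-id rownames")
  if (!all(ids %in% annotation$probe_id))
    stop("every probe in the matrix must be annotated")
  anno <- annotation[match(ids, annotation$probe_id), , drop = FALSE]
  if (!is.null(detp)) {
    stopifnot(identical(dim(detp), dim(beta)))
    bad_det <- apply(detp > detection_alpha, 1L, any)
  } else {
    bad_det <- rep(FALSE, length(ids))
  }
  bad_na <- apply(is.na(beta), 1L, any)
  s1 <- bad_det | bad_na
  keep <- !s1
  s2 <- keep & anno$on_xy
  keep <- keep & !s2
  s3 <- keep & (anno$cross_hybridizing | anno$polymorphic)
  keep <- keep & !s3
  report <- structure(list(
    n_input = length(ids),
    removed = c(detection_or_missing = sum(s1),
                xy_chromosome = sum(s2),
                blacklist = sum(s3)),
    n_kept = sum(keep),
    detection_alpha = detection_alpha), class = "filter_report")
  if (report$n_kept == 0L)
    stop("no probes survive filtering (removed ",
         paste(names(report$removed), report$removed,
               sep = "=", collapse = ", "), ")")
  list(kept = ids[keep], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe filtering:", x$n_input, "probes in\n")
  cat("  stage 1 (detection p >", x$detection_alpha, "or missing):",
      x$removed[["detection_or_missing"]], "removed\n")
  cat("  stage 2 (X/Y chromosome):", x$removed[["xy_chromosome"]],
      "removed\n")
  cat("  stage 3 (cross-hybridizing / polymorphic):",
      x$removed[["blacklist"]], "removed\n")
  cat("  kept:", x$n_kept, "\n")
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a `"filter_report"` object from [filter_probes()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(list(n_input = report$n_input,
                            removed = as.list(report$removed),
                            n_kept = report$n_kept,
                            detection_alpha = report$detection_alpha),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Quantile normalization across samples
#'
#' Forces every sample column onto the identical empirical distribution,
#' the mean of the per-rank sorted values across columns, while preserving
#' the rank order within each column. Ties receive the average of their
#' tied ranks' target values. Delegates to
#' [limma::normalizeQuantiles()], the standard implementation for array
#' data.
#'
#' @param x numeric matrix (no missing values).
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("quantile_normalize requires a complete matrix")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Colour-channel bias correction
#'
#' For each sample, quantile-maps the red-channel probe intensities onto
#' the green-channel intensity distribution (a smooth monotone map built
#' from the green empirical quantiles), so that after correction the two
#' channels share the same distribution and in particular the same
#' median. Type II probes (channel `"Both"`) are left untouched. With
#' fewer than `min_probes` probes in either channel the correction is
#' skipped with a warning.
#'
#' @param intensity probes x samples matrix of (non-negative) intensities.
#' @param channel character vector per probe: `"Grn"`, `"Red"` or
#'   `"Both"`.
#' @param min_probes minimum probes per channel for the map to be fit.
#' @return corrected intensity matrix.
#' @export
color_bias_correct <- function(intensity, channel, min_probes = 10L) {
  stopifnot(is.matrix(intensity), length(channel) == nrow(intensity))
  red <- channel == "Red"
  grn <- channel == "Grn"
  if (sum(red) < min_probes || sum(grn) < min_probes) {
    warning("fewer than ", min_probes,
            " probes in a colour channel; correction skipped")
    return(intensity)
  }
  out <- intensity
  probs <- seq(0, 1, length.out = 512)
  for (s in seq_len(ncol(intensity))) {
    rv <- intensity[red, s]
    gq <- stats::quantile(intensity[grn, s], probs = probs, names = FALSE)
    rq <- stats::quantile(rv, probs = probs, names = FALSE)
    # monotone map red-quantiles -> green-quantiles, linear interpolation
    out[red, s] <- stats::approx(rq, gq, xout = rv, rule = 2, ties = mean)$y
  }
  out
}

#' Beta values from methylated/unmethylated intensities
#'
#' @param meth,unmeth probes x samples intensity matrices.
#' @param offset regularizing constant added to the denominator (the
#'   conventional 100).
#' @return beta matrix.
#' @export
intensities_to_beta <- function(meth, unmeth, offset = 100) {
  stopifnot(identical(dim(meth), dim(unmeth)))
  meth / (meth + unmeth + offset)
}

# kernel-density modes of an M-value vector: the density maxima below and
# above zero (unmethylated and methylated peaks). Returns NULL when either
# peak is missing or negligible, i.e. the distribution is not bimodal.
find_m_modes <- function(m, bw = "nrd0", min_height = 0.1) {
  m <- m[is.finite(m)]
  if (length(m) < 50L) return(NULL)
  d <- stats::density(m, bw = bw)
  lo <- d$x < 0
  hi <- d$x > 0
  if (!any(lo) || !any(hi)) return(NULL)
  peak <- function(sel) {
    i <- which(sel)[which.max(d$y[sel])]
    c(x = d$x[i], y = d$y[i])
  }
  p_lo <- peak(lo)
  p_hi <- peak(hi)
  if (min(p_lo["y"], p_hi["y"]) < min_height * max(d$y)) return(NULL)
  c(unmeth = unname(p_lo["x"]), meth = unname(p_hi["x"]))
}

#' Peak-based probe-type correction
#'
#' The two Infinium chemistries have different dynamic ranges: type II
#' probes show unmethylated/methylated density peaks compressed towards
#' M = 0 relative to type I. This correction estimates the two peaks of
#' each probe type by kernel density on the pooled M values (bandwidth:
#' Silverman's rule by default), then rescales the type II values with the
#' linear map that sends the type II peaks onto the type I peaks. Type I
#' values are unchanged. If fewer than two peaks are detectable for either
#' type, the matrix is passed through with a warning.
#'
#' @param m probes x samples M-value matrix.
#' @param annotation annotation data.frame with `probe_id` and
#'   `probe_type` (`"I"`/`"II"`) covering all probes of `m`.
#' @param bw kernel bandwidth passed to [stats::density()].
#' @return list with `m` (corrected matrix), `beta` (consistent betas),
#'   and `map` (`NULL` if skipped, else the slope/intercept applied and
#'   the peak locations).
#' @export
peak_correct <- function(m, annotation, bw = "nrd0") {
  stopifnot(is.matrix(m))
  anno <- annotation[match(rownames(m), annotation$probe_id), , drop = FALSE]
  t1 <- anno$probe_type == "I"
  t2 <- anno$probe_type == "II"
  modes1 <- find_m_modes(m[t1, , drop = FALSE], bw = bw)
  modes2 <- find_m_modes(m[t2, , drop = FALSE], bw = bw)
  if (is.null(modes1) || is.null(modes2)) {
    warning("fewer than two density modes detected for a probe type; ",
            "peak correction skipped")
    return(list(m = m, beta = m_to_beta(m), map = NULL))
  }
  slope <- (modes1[["meth"]] - modes1[["unmeth"]]) /
    (modes2[["meth"]] - modes2[["unmeth"]])
  intercept <- modes1[["unmeth"]] - slope * modes2[["unmeth"]]
  out <- m
  out[t2, ] <- intercept + slope * m[t2, ]
  list(m = out, beta = m_to_beta(out),
       map = list(slope = slope, intercept = intercept,
                  typeI_modes = modes1, typeII_modes = modes2))
}
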