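#' Convert methylation beta values to M values
#'
#' The beta value of a CpG probe is the fraction-methylated signal in
#' \[0, 1\]; the M value is its log2-odds transform,
#' \eqn{M = \log_2(\beta / (1 - \beta))}. M values are approximately
#' homoscedastic and are the scale on which all modelling in this package
#' is performed; betas are retained for effect-size reporting because they
#' read as percent methylation.
#'
#' Betas are clipped to \[`eps`, 1 - `eps`\] before the transform so that
#' fully (un)methylated probes map to finite M values. On the clipped
#' domain the transform is a strictly increasing bijection and
#' `m_to_beta(beta_to_m(b))` returns `b` exactly.
#'
#' @param beta numeric vector or matrix of beta values in \[0, 1\].
#' @param eps clipping margin; betas are forced into \[`eps`, 1 - `eps`\].
#' @return numeric object of the same shape on the M scale.
#' @examples
#' beta_to_m(0.5)  # 0
#' beta_to_m(0.8)  # 2
#' m_to_beta(beta_to_m(0.3))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(is.numeric(beta), eps > 0, eps < 0.5)
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m numeric vector or matrix of M values.
#' @export
m_to_beta <- function(m) {
  stopifnot(is.numeric(m))
  1 / (1 + 2^(-m))
}
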