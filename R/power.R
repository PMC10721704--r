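#' Power of the carrier symptomatic/asymptomatic design
#'
#' Two-sided Wald power for detecting an odds ratio `or` for symptoms given
#' carrier status, in a cohort of `n_total` with a fraction `carrier_freq`
#' of carriers and baseline symptomatic prevalence `1 - asymptomatic_fraction`
#' among non-carriers. The log-OR variance uses expected 2x2 cell counts
#' (carrier status x symptom status).
#'
#' @param n_total cohort size.
#' @param carrier_freq fraction of individuals carrying the variant.
#' @param asymptomatic_fraction non-carrier probability of being asymptomatic.
#' @param or odds ratio (>= 1).
#' @param alpha two-sided significance level.
#' @return power in [0, 1]; `NA` with a warning if any expected cell < 1.
#' @export
power_carrier_design <- function(n_total, carrier_freq, asymptomatic_fraction,
                                 or, alpha = 0.05) {
  stopifnot(n_total > 0, carrier_freq > 0, carrier_freq < 1,
            asymptomatic_fraction > 0, asymptomatic_fraction < 1,
            or >= 1, alpha > 0, alpha < 1)
  p0 <- 1 - asymptomatic_fraction
  p1 <- plogis(qlogis(p0) + log(or))
  n_c <- n_total * carrier_freq
  n_n <- n_total * (1 - carrier_freq)
  cells <- c(n_c * p1, n_c * (1 - p1), n_n * p0, n_n * (1 - p0))
  if (any(cells < 1)) {
    warning("expected cell count below 1; design degenerate")
    return(NA_real_)
  }
  wald_power(log(or), sqrt(sum(1 / cells)), alpha)
}

#' Power of a per-allele case-control association test
#'
#' Two-sided Wald power of the allelic log-OR test at a variant with control
#' minor allele frequency `maf`, with the genome-wide default
#' `alpha = 5e-8`.
#'
#' @param n_case,n_control group sizes (individuals).
#' @param maf control-group minor allele frequency.
#' @param or per-allele odds ratio (>= 1).
#' @param alpha two-sided significance level.
#' @return power in [0, 1]; `NA` with a warning if any expected allele
#'   count < 1.
#' @export
power_gwas <- function(n_case, n_control, maf, or, alpha = 5e-8) {
  stopifnot(n_case > 0, n_control > 0, maf > 0, maf < 0.5 + 1e-12,
            or >= 1, alpha > 0, alpha < 1)
  p0 <- maf
  p1 <- plogis(qlogis(p0) + log(or))
  cells <- c(2 * n_case * p1, 2 * n_case * (1 - p1),
             2 * n_control * p0, 2 * n_control * (1 - p0))
  if (any(cells < 1)) {
    warning("expected allele count below 1; design degenerate")
    return(NA_real_)
  }
  wald_power(log(or), sqrt(sum(1 / cells)), alpha)
}

wald_power <- function(effect, se, alpha) {
  z <- qnorm(1 - alpha / 2)
  pnorm(abs(effect) / se - z) + pnorm(-abs(effect) / se - z)
}
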