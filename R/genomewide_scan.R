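# Fast logistic fit for a scan: design = [base covariate matrix, g].
scan_logistic <- function(Xbase, g, y) {
  X <- cbind(Xbase, exposure = g)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- fit$coefficients
  vc <- tryCatch(solve(crossprod(X * sqrt(fit$weights))),
                 error = function(e) NULL)
  flagged <- !fit$converged || is.null(vc) || any(abs(beta) > 15)
  k <- length(beta)
  se <- if (is.null(vc)) NA_real_ else sqrt(vc[k, k])
  z <- beta[k] / se
  list(beta = unname(beta[k]), se = unname(se),
       p = if (flagged) NA_real_ else 2 * pnorm(-abs(z)), flagged = flagged)
}

#' Genome-wide logistic scan on the unrelated subset
#'
#' Per-variant additive logistic model
#' logit(outcome) ~ age + sex + PC1 + dosage, with outcome 1 = asymptomatic
#' carrier, 0 = asymptomatic non-carrier, run on an unrelated subset (see
#' [select_unrelated()]). Variants are filtered before testing: MAF >
#' `maf_case_min` within cases (asymptomatic carriers), MAF >
#' `maf_control_min` within controls, and INFO > `info_min`; skipped
#' variants keep a reason code. Separated fits are flagged with missing p.
#'
#' @param gm a [genotype_matrix()].
#' @param outcome 0/1 vector aligned with rows of `gm$dosage`.
#' @param covariates data.frame (age, sex, PC1) aligned likewise.
#' @param maf_case_min,maf_control_min,info_min filters (defaults 0.1,
#'   0.05, 0.4).
#' @param founder_dosage optional founder-variant dosage vector; when given,
#'   per-variant LD r^2 with the founder variant is reported.
#' @return data.frame (one row per variant): id, chrom, pos, tested, reason,
#'   beta, se, p, or, maf_case, maf_control, info, r2_founder, flagged.
#' @export
gwas_scan <- function(gm, outcome, covariates,
                      maf_case_min = 0.1, maf_control_min = 0.05,
                      info_min = 0.4, founder_dosage = NULL) {
  stopifnot(length(outcome) == nrow(gm$dosage))
  if (sum(outcome == 1) < 2) stop("fewer than 2 cases; aborting scan")
  covariates <- as.data.frame(covariates)
  Xbase <- model.matrix(~., data = covariates)
  cc <- complete.cases(outcome, Xbase)
  y <- outcome[cc]; Xbase <- Xbase[cc, , drop = FALSE]
  D <- gm$dosage[cc, , drop = FALSE]
  maf_case <- allele_frequency(D, subset = y == 1)
  maf_ctrl <- allele_frequency(D, subset = y == 0)
  res <- data.frame(id = gm$variants$id, chrom = gm$variants$chrom,
                    pos = gm$variants$pos, tested = FALSE,
                    reason = NA_character_, beta = NA_real_, se = NA_real_,
                    p = NA_real_, or = NA_real_,
                    maf_case = maf_case, maf_control = maf_ctrl,
                    info = gm$variants$info, r2_founder = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  if (!is.null(founder_dosage))
    res$r2_founder <- ld_r2(D, founder_dosage[cc])
  skip <- ifelse(is.na(maf_case) | maf_case <= maf_case_min, "carrier-MAF",
          ifelse(is.na(maf_ctrl) | maf_ctrl <= maf_control_min, "control-MAF",
          ifelse(gm$variants$info <= info_min, "INFO", NA_character_)))
  res$reason <- skip
  for (j in which(is.na(skip))) {
    f <- scan_logistic(Xbase, D[, j], y)
    res$tested[j] <- TRUE
    res$beta[j] <- f$beta; res$se[j] <- f$se; res$p[j] <- f$p
    res$or[j] <- exp(f$beta); res$flagged[j] <- f$flagged
  }
  res
}

#' Genomic inflation factor
#'
#' Median-based lambda of a vector of p-values.
#'
#' @param p p-values.
#' @return lambda (median chi-square over its null median).
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Founder-LD confound screen for scan hits
#'
#' Association strength at variants linked to the founder haplotype tracks
#' their LD with the founder variant. For variants with p <= `p_max`, the
#' screen regresses -log10(p) on r^2 with the founder variant; variants
#' off that line (externally studentized residual > `resid_max`) that are
#' also essentially unlinked (r^2 < `r2_max`) are flagged
#' `"independent_suggestive"`; all others are `"founder_LD"`. This is a
#' deterministic operationalization of an otherwise visual judgement.
#'
#' @param scan a [gwas_scan()] result with `r2_founder` filled.
#' @param p_max inclusion threshold (default 5e-4).
#' @param resid_max studentized-residual cutoff (default 3).
#' @param r2_max maximal founder LD for an independent signal (default 0.1).
#' @return the qualifying subset of `scan` with columns `residual` and
#'   `flag` added.
#' @export
ld_confound_screen <- function(scan, p_max = 5e-4, resid_max = 3,
                               r2_max = 0.1) {
  sub <- scan[!is.na(scan$p) & scan$p <= p_max, , drop = FALSE]
  if (nrow(sub) == 0) {
    sub$residual <- numeric(0)
    sub$flag <- character(0)
    return(sub)
  }
  if (nrow(sub) < 10) {
    warning("fewer than 10 variants at p <= ", p_max,
            "; LD trend not estimable, flags set missing")
    sub$residual <- NA_real_
    sub$flag <- NA_character_
    return(sub)
  }
  if (all(sub$r2_founder == 0, na.rm = TRUE)) {
    warning("all r^2 with the founder variant are zero; ",
            "flagging every variant independent")
    sub$residual <- NA_real_
    sub$flag <- "independent_suggestive"
    return(sub)
  }
  fit <- lm(-log10(p) ~ r2_founder, data = sub)
  # externally studentized residuals
  h <- stats::hatvalues(fit)
  r <- residuals(fit)
  n <- nrow(sub); k <- 2
  s2 <- sum(r^2) / (n - k)
  s2_i <- (s2 * (n - k) - r^2 / (1 - h)) / (n - k - 1)
  sub$residual <- r / sqrt(pmax(s2_i, 1e-300) * (1 - h))
  sub$flag <- ifelse(sub$residual > resid_max & sub$r2_founder < r2_max,
                     "independent_suggestive", "founder_LD")
  sub
}

#' Precompute a permutation pool for burden calibration
#'
#' Fits the covariate-only logistic null model on `B` random shuffles of the
#' outcome labels (covariates stay attached to participants). The pool of
#' fitted probabilities is shared across regions, so calibrating many
#' regions costs one covariate-model fit per permutation in total.
#'
#' @param outcome 0/1 vector.
#' @param covariates data.frame aligned with `outcome`.
#' @param B number of permutations.
#' @param seed RNG seed.
#' @return object of class `burden_perm_pool`.
#' @export
make_perm_pool <- function(outcome, covariates, B = 200L, seed = 1L) {
  covariates <- as.data.frame(covariates)
  X <- model.matrix(~., data = covariates)
  cc <- complete.cases(outcome, X)
  y <- outcome[cc]; X <- X[cc, , drop = FALSE]
  n <- length(y)
  set.seed(seed)
  Yp <- matrix(0L, n, B)
  MU <- matrix(0, n, B)
  for (b in seq_len(B)) {
    yp <- y[sample.int(n)]
    fit <- suppressWarnings(glm.fit(X, yp, family = binomial()))
    Yp[, b] <- yp
    MU[, b] <- fit$fitted.values
  }
  structure(list(X = X, y = y, Yp = Yp, MU = MU, keep = cc, B = B,
                 seed = seed), class = "burden_perm_pool")
}

# Covariate-adjusted score statistic of a burden vector g against outcome
# y with null fitted probabilities mu: U^2 / V with
# V = g'Wg - g'WX (X'WX)^-1 X'Wg.
burden_score_stat <- function(g, y, mu, X) {
  w <- mu * (1 - mu)
  U <- sum(g * (y - mu))
  XtWX <- crossprod(X * sqrt(w))
  XtWg <- crossprod(X, w * g)
  V <- sum(w * g^2) - drop(crossprod(XtWg, solve(XtWX, XtWg)))
  if (V <= 0) return(0)
  U^2 / V
}

#' Rare-variant burden test with permutation calibration
#'
#' Collapses qualifying variants of a region (MAF <= `maf_max`, INFO >
#' `info_min`) into a per-participant minor-allele count and tests it with
#' the scan's logistic model. Because the case-control ratio is extreme,
#' the reported p-value is calibrated by `n_perm` outcome-label
#' permutations of a covariate-adjusted score statistic (asymptotic Wald
#' results are returned alongside). When the permutation p meets
#' `split_p_max`, the region is split into ten equal-bp subregions, each
#' retested.
#'
#' @param gm a [genotype_matrix()].
#' @param outcome 0/1 vector aligned with `gm$dosage` rows.
#' @param covariates data.frame (age, sex, PC1).
#' @param region list/vector with chrom, start, end (1-based, closed).
#' @param maf_max variant-inclusion MAF tier (0.05 low-frequency, 0.01 rare).
#' @param info_min INFO filter (default 0.8).
#' @param n_perm label permutations (ignored when `perm_pool` given).
#' @param perm_pool optional [make_perm_pool()] result to share across
#'   regions.
#' @param seed RNG seed for a locally built pool.
#' @param split_p_max significance threshold that triggers subregion
#'   analysis (default 2.5e-6; set `NA` to disable).
#' @return object of class `region_result`: region, maf tier, n_variants,
#'   burden beta/se/wald p, permutation p, and `subregions` (10-row
#'   data.frame) when triggered.
#' @export
burden_test <- function(gm, outcome, covariates, region, maf_max = 0.01,
                        info_min = 0.8, n_perm = 200L, perm_pool = NULL,
                        seed = 1L, split_p_max = 2.5e-6) {
  region <- as.list(region)
  if (is.null(perm_pool))
    perm_pool <- make_perm_pool(outcome, covariates, B = n_perm, seed = seed)
  sel_var <- which(gm$variants$chrom == region$chrom &
                     gm$variants$pos >= region$start &
                     gm$variants$pos <= region$end)
  out <- list(region = region, maf_max = maf_max, n_variants = 0L,
              beta = NA_real_, se = NA_real_, p_wald = NA_real_,
              p_perm = NA_real_, n_perm = perm_pool$B, subregions = NULL)
  class(out) <- "region_result"
  if (!length(sel_var)) return(out)
  D <- gm$dosage[perm_pool$keep, sel_var, drop = FALSE]
  maf <- allele_frequency(D)
  qual <- !is.na(maf) & maf > 0 & maf <= maf_max &
    gm$variants$info[sel_var] > info_min
  out$n_variants <- sum(qual)
  if (!any(qual)) return(out)
  qcols <- which(qual)
  # minor-allele orientation per variant
  af <- colSums(D[, qcols, drop = FALSE], na.rm = TRUE) /
    (2 * colSums(!is.na(D[, qcols, drop = FALSE])))
  Dq <- D[, qcols, drop = FALSE]
  flip <- which(af > 0.5)
  if (length(flip)) Dq[, flip] <- 2 - Dq[, flip]
  Dq[is.na(Dq)] <- 0
  burden <- rowSums(Dq)
  y <- perm_pool$y; X <- perm_pool$X
  f <- scan_logistic(X, burden, y)
  out$beta <- f$beta; out$se <- f$se; out$p_wald <- f$p
  mu0 <- suppressWarnings(glm.fit(X, y, family = binomial()))$fitted.values
  s_obs <- burden_score_stat(burden, y, mu0, X)
  s_perm <- vapply(seq_len(perm_pool$B), function(b)
    burden_score_stat(burden, perm_pool$Yp[, b], perm_pool$MU[, b], X),
    numeric(1))
  out$p_perm <- (1 + sum(s_perm >= s_obs)) / (perm_pool$B + 1)
  if (!is.na(split_p_max) && out$p_perm < split_p_max) {
    segs <- tile_region(region, 10L)
    out$subregions <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
      r <- burden_test(gm, outcome, covariates,
                       list(chrom = region$chrom, start = segs$start[i],
                            end = segs$end[i]),
                       maf_max = maf_max, info_min = info_min,
                       perm_pool = perm_pool, split_p_max = NA)
      data.frame(segment = i, start = segs$start[i], end = segs$end[i],
                 n_variants = r$n_variants, beta = r$beta, p_wald = r$p_wald,
                 p_perm = r$p_perm)
    }))
  }
  out
}

#' @export
print.region_result <- function(x, ...) {
  cat(sprintf(
    "<region_result> %s:%s-%s MAF<=%g: %d variant(s), beta = %.3g, p_perm = %.3g\n",
    x$region$chrom, format(x$region$start, big.mark = ","),
    format(x$region$end, big.mark = ","), x$maf_max, x$n_variants,
    x$beta, x$p_perm))
  invisible(x)
}

#' Tile a region into equal-bp segments
#'
#' Segments tile the region exactly (union = region, pairwise disjoint,
#' 1-based closed coordinates); any bp remainder goes to the last segment.
#'
#' @param region list/vector with start, end.
#' @param n number of segments (default 10).
#' @return data.frame with segment, start, end.
#' @export
tile_region <- function(region, n = 10L) {
  region <- as.list(region)
  width <- region$end - region$start + 1
  base <- width %/% n
  starts <- region$start + base * (seq_len(n) - 1)
  ends <- c(starts[-1] - 1, region$end)
  data.frame(segment = seq_len(n), start = starts, end = ends)
}

#' Gene regions with flanks
#'
#' Builds BED-style test regions (gene +/- `flank_bp`) from a gene table.
#'
#' @param genes data.frame with gene, chrom, start, end.
#' @param flank_bp flank on each side (default 50 kb).
#' @return data.frame with gene, chrom, start, end (floored at 1).
#' @export
gene_regions <- function(genes, flank_bp = 50000) {
  data.frame(gene = genes$gene, chrom = genes$chrom,
             start = pmax(1, genes$start - flank_bp),
             end = genes$end + flank_bp)
}
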