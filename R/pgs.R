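#' Polygenic scores from per-variant weights
#'
#' Raw score = sum over matched weight variants of weight x effect-allele
#' dosage. Variants are matched on (chrom, pos) with exact allele match
#' (effect = alt) or swapped match (effect = ref, dosage reversed);
#' strand-ambiguous palindromic variants (A/T, C/G) and allele mismatches
#' are dropped, as are variants on `exclude_chroms` (used to rebuild scores
#' without the founder-variant chromosome). Missing dosages are imputed at
#' the variant mean. Scores are standardized within the cohort and
#' percentiles assigned by average rank; extreme codes mark the top and
#' bottom quintile.
#'
#' @param gm a [genotype_matrix()].
#' @param weights data.frame as from [read_weight_table()].
#' @param exclude_chroms chromosomes to leave out.
#' @return data.frame (one row per participant): participant_id, raw, std,
#'   percentile, high20, low20; attribute `match_report`.
#' @export
score_pgs <- function(gm, weights, exclude_chroms = character()) {
  v <- gm$variants
  wkey <- paste(weights$chrom, weights$pos)
  gkey <- paste(v$chrom, v$pos)
  hit <- match(wkey, gkey)
  status <- rep("matched", nrow(weights))
  status[is.na(hit)] <- "absent"
  pal <- function(a, b) paste0(pmin(a, b), pmax(a, b)) %in% c("AT", "CG")
  ok <- !is.na(hit)
  flip <- rep(FALSE, nrow(weights))
  for (i in which(ok)) {
    j <- hit[i]
    if (weights$chrom[i] %in% exclude_chroms) {
      status[i] <- "excluded_chrom"
    } else if (pal(weights$effect_allele[i], weights$other_allele[i])) {
      status[i] <- "palindromic"
    } else if (weights$effect_allele[i] == v$alt[j] &&
               weights$other_allele[i] == v$ref[j]) {
      status[i] <- "matched"
    } else if (weights$effect_allele[i] == v$ref[j] &&
               weights$other_allele[i] == v$alt[j]) {
      status[i] <- "matched"; flip[i] <- TRUE
    } else {
      status[i] <- "allele_mismatch"
    }
  }
  use <- which(status == "matched")
  report <- table(status)
  if (!length(use))
    stop("no weight variants matched the genotypes: ",
         paste(sprintf("%s=%d", names(report), report), collapse = ", "))
  D <- gm$dosage[, hit[use], drop = FALSE]
  cm <- colMeans(D, na.rm = TRUE)
  na <- which(is.na(D), arr.ind = TRUE)
  if (nrow(na)) D[na] <- cm[na[, 2]]
  if (any(flip[use])) D[, flip[use]] <- 2 - D[, flip[use], drop = FALSE]
  raw <- drop(D %*% weights$weight[use])
  s <- sd(raw)
  std <- if (s > 0) (raw - mean(raw)) / s else rep(0, length(raw))
  r <- rank(std, ties.method = "average")
  pct <- 100 * (r - 0.5) / length(r)
  out <- data.frame(participant_id = rownames(gm$dosage), raw = raw,
                    std = std, percentile = pct,
                    high20 = as.integer(pct > 80),
                    low20 = as.integer(pct < 20),
                    stringsAsFactors = FALSE)
  attr(out, "match_report") <- report
  out
}

#' Group association of polygenic scores
#'
#' The score-level analogue of the trait screen: for each score the linear
#' model PGS ~ age + sex + outcome is fitted on the two asymptomatic
#' groups, with the PGS entered as continuous percentile of the
#' standardized score (`mode = "percentile"`) or recoded as an extreme
#' indicator (top/bottom quintile). With `B > 0`, empirical q-values are
#' attached by permuting the score values across participants (covariates
#' and outcome stay attached), pooled over all scores.
#'
#' @param scores matrix of raw scores (participants x scores, rownames =
#'   participant IDs) or a single [score_pgs()] result.
#' @param cohort a [cohort()].
#' @param groups an [assign_groups()] table.
#' @param mode PGS coding.
#' @param B permutations for q-values (0 = none).
#' @param seed RNG seed.
#' @param method q estimator, see [empirical_q()].
#' @return data.frame: score, beta, se, statistic, p (outcome coefficient),
#'   and q when `B > 0`.
#' @export
pgs_group_assoc <- function(scores, cohort, groups,
                            mode = c("percentile", "high20", "low20"),
                            B = 0L, seed = 1L,
                            method = c("storey", "pooled_p")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (is.data.frame(scores)) {
    scores <- matrix(scores$raw, ncol = 1,
                     dimnames = list(scores$participant_id, "PGS"))
  }
  keep <- apply(scores, 2, function(x) sd(x, na.rm = TRUE) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant score(s) skipped")
    scores <- scores[, keep, drop = FALSE]
  }
  code <- apply(scores, 2, function(x) {
    pct <- 100 * (rank(x, ties.method = "average") - 0.5) / length(x)
    switch(mode, percentile = pct,
           high20 = as.numeric(pct > 80), low20 = as.numeric(pct < 20))
  })
  rownames(code) <- rownames(scores)
  ctx <- contrast_subset(cohort, groups, "asymptomatic_carrier",
                         "asymptomatic_noncarrier")
  ids <- cohort$participant_id[ctx$rows]
  Y <- code[match(ids, rownames(code)), , drop = FALSE]
  X <- model.matrix(~ age + sex, data = ctx$covariates)
  X <- cbind(X, outcome = ctx$outcome)
  p <- ncol(X)
  XtXi <- solve(crossprod(X))
  M <- XtXi %*% t(X)
  ols_stats <- function(Ym) {
    coefs <- M %*% Ym
    rss <- colSums((Ym - X %*% coefs)^2)
    df <- nrow(X) - p
    se <- sqrt(XtXi[p, p] * rss / df)
    tt <- coefs[p, ] / se
    list(beta = coefs[p, ], se = se, t = tt, p = 2 * pt(-abs(tt), df))
  }
  obs <- ols_stats(Y)
  res <- data.frame(score = colnames(scores), beta = obs$beta, se = obs$se,
                    statistic = obs$t, p = obs$p, row.names = NULL)
  if (B > 0) {
    set.seed(seed)
    n <- nrow(Y)
    perm_p <- matrix(NA_real_, B, ncol(Y))
    P <- matrix(0L, n, B)
    for (b in seq_len(B)) P[, b] <- sample.int(n)
    for (s in seq_len(ncol(Y))) {
      Yp <- matrix(Y[, s][P], n, B)
      perm_p[, s] <- ols_stats(Yp)$p
    }
    res$q <- empirical_q(res$p, perm_p, method = method)
  }
  res
}

#' Interaction of a polygenic score with group assignment on its trait
#'
#' Fits trait ~ age + sex + group + PGS + PGS:group with the
#' asymptomatic-non-carrier group as reference, reporting the Wald test of
#' each PGS-by-group interaction (does the score predict the measurement
#' more strongly in some carrier-by-symptom group?), per-group partial
#' correlations of score and trait residualized on age and sex, and a
#' rank-normalized sensitivity refit. Groups with fewer than `min_n`
#' complete observations are reported untestable.
#'
#' @param trait numeric trait vector.
#' @param pgs numeric score vector (standardized internally).
#' @param groups factor/character of the four group labels.
#' @param age,sex covariate vectors (`sex` as "male"/"female").
#' @param min_n minimal complete observations per non-reference group.
#' @return list: `model` (full coefficient table), `interaction` (per group:
#'   beta, se, p, untestable), `partial_cor` (per group: r, n),
#'   `rank_normal` (interaction table after inverse-normal transform).
#' @export
pgs_trait_interaction <- function(trait, pgs, groups, age, sex, min_n = 3L) {
  groups <- factor(as.character(groups), levels = group_levels)
  dat <- data.frame(trait = trait, pgs = as.numeric(scale(pgs)),
                    group = groups, age = age,
                    sex = factor(sex, levels = c("female", "male")))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n_by_g <- table(dat$group)
  testable <- names(n_by_g)[n_by_g >= min_n]
  fit_dat <- dat[dat$group %in% testable, , drop = FALSE]
  fit_dat$group <- droplevels(fit_dat$group)
  fit_one <- function(d) {
    m <- lm(trait ~ age + sex + group + pgs + pgs:group, data = d)
    sm <- summary(m)$coefficients
    data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
               statistic = sm[, 3], p = sm[, 4], row.names = NULL)
  }
  tab <- fit_one(fit_dat)
  inter_tab <- function(tab) {
    out <- data.frame(group = setdiff(group_levels, group_levels[1]),
                      beta = NA_real_, se = NA_real_, p = NA_real_,
                      untestable = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(out))) {
      tn <- paste0("group", out$group[i], ":pgs")
      tn2 <- paste0("pgs:group", out$group[i])
      row <- tab[tab$term %in% c(tn, tn2), , drop = FALSE]
      if (!out$group[i] %in% testable || nrow(row) == 0) {
        out$untestable[i] <- TRUE
      } else {
        out$beta[i] <- row$beta[1]; out$se[i] <- row$se[1]
        out$p[i] <- row$p[1]
      }
    }
    out
  }
  partial <- do.call(rbind, lapply(group_levels, function(g) {
    d <- dat[dat$group == g, , drop = FALSE]
    if (nrow(d) < min_n + 2)
      return(data.frame(group = g, r = NA_real_, n = nrow(d)))
    rt <- residuals(lm(trait ~ age + sex, data = d))
    rp <- residuals(lm(pgs ~ age + sex, data = d))
    data.frame(group = g, r = cor(rt, rp), n = nrow(d))
  }))
  rn_dat <- fit_dat
  rn_dat$trait <- rank_normalize(rn_dat$trait)
  rn_tab <- fit_one(rn_dat)
  list(model = tab, interaction = inter_tab(tab), partial_cor = partial,
       rank_normal = inter_tab(rn_tab))
}

#' Ordinal severity trend of a score among symptomatic carriers
#'
#' Linear trend of the number of distinct positive signs/symptoms on the
#' (standardized) score, restricted to symptomatic carriers.
#'
#' @param pgs numeric score vector.
#' @param n_signs integer count of positive flags per participant.
#' @return list: beta, se, p, n.
#' @export
pgs_severity_trend <- function(pgs, n_signs) {
  cc <- complete.cases(pgs, n_signs)
  if (sum(cc) < 4) return(list(beta = NA_real_, se = NA_real_,
                               p = NA_real_, n = sum(cc)))
  m <- summary(lm(n_signs[cc] ~ scale(pgs[cc])))$coefficients
  list(beta = m[2, 1], se = m[2, 2], p = m[2, 4], n = sum(cc))
}
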