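#' Eigendecomposition of the additive-relatedness matrix
#'
#' One-time decomposition of 2*Phi used by the mixed-model fitter. The
#' matrix is block-diagonal over connected pedigree components, so the
#' decomposition is performed block-by-block (singletons are scalars) and
#' the eigenvector matrix is assembled sparse.
#'
#' @param kinship a [kinship_matrix()].
#' @param idx optional row subset (indices into `kinship$ids`) to decompose.
#' @return object of class `kinship_eigen`: sparse eigenvectors `U`,
#'   eigenvalues `d` (of 2*Phi), and `ids`.
#' @export
kinship_eigen <- function(kinship, idx = NULL) {
  phi <- kinship$phi
  ids <- kinship$ids
  if (!is.null(idx)) {
    phi <- phi[idx, idx, drop = FALSE]
    ids <- ids[idx]
  }
  K <- 2 * phi
  n <- nrow(K)
  Tm <- methods::as(K, "TsparseMatrix")
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ei <- Tm@i + 1L; ej <- Tm@j + 1L
  for (e in which(ei < ej)) {
    a <- find(ei[e]); b <- find(ej[e])
    if (a != b) parent[a] <- b
  }
  root <- vapply(seq_len(n), find, 1L)
  blocks <- split(seq_len(n), root)
  d <- numeric(n)
  ui <- vector("list", length(blocks))
  uj <- vector("list", length(blocks))
  ux <- vector("list", length(blocks))
  pos <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    k <- length(b)
    cols <- pos + seq_len(k)
    if (k == 1L) {
      d[cols] <- K[b, b]
      ui[[bi]] <- b; uj[[bi]] <- cols; ux[[bi]] <- 1
    } else {
      eg <- eigen(as.matrix(K[b, b, drop = FALSE]), symmetric = TRUE)
      if (min(eg$values) < -1e-8)
        stop("2*kinship is not positive semi-definite; ",
             "consider adding a small diagonal jitter")
      d[cols] <- pmax(eg$values, 0)
      ui[[bi]] <- rep(b, times = k)
      uj[[bi]] <- rep(cols, each = k)
      ux[[bi]] <- as.vector(eg$vectors)
    }
    pos <- pos + k
  }
  U <- Matrix::sparseMatrix(i = unlist(ui), j = unlist(uj), x = unlist(ux),
                            dims = c(n, n))
  structure(list(U = U, d = d, ids = ids, n = n), class = "kinship_eigen")
}

# Profile-REML fit in the rotated (eigen) basis. Xt = U'X, yt = U'y,
# d = eigenvalues of 2*Phi. The variance ratio lambda = sigma2_g / sigma2_e
# is profiled on a log10 grid with Brent refinement.
reml_profile <- function(Xt, yt, d, grid = 10^seq(-10, 10, by = 0.5),
                         tol = 1e-8) {
  n <- length(yt); p <- ncol(Xt)
  nll <- function(loglam) {
    w <- 1 / (10^loglam * d + 1)
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    rss <- sum(w * (yt - Xt %*% beta)^2)
    (n - p) * log(rss) - sum(log(w)) + 2 * sum(log(diag(ch)))
  }
  lg <- log10(grid)
  vals <- vapply(lg, nll, numeric(1))
  if (all(!is.finite(vals)))
    stop("mixed model did not converge: REML objective non-finite over the ",
         "whole variance-ratio bracket [", min(lg), ", ", max(lg), "] (log10)")
  i0 <- which.min(vals)
  lo <- lg[max(1L, i0 - 1L)]; hi <- lg[min(length(lg), i0 + 1L)]
  opt <- optimize(nll, c(lo, hi), tol = tol)
  # keep the boundary if the grid end beats the interior optimum
  loglam <- if (opt$objective <= vals[i0]) opt$minimum else lg[i0]
  lambda <- 10^loglam
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xt, Xt * w)
  XtWXi <- solve(XtWX)
  beta <- drop(XtWXi %*% crossprod(Xt, yt * w))
  rss <- sum(w * (yt - Xt %*% beta)^2)
  sigma2_e <- rss / (n - p)
  se <- sqrt(pmax(diag(XtWXi), 0) * sigma2_e)
  list(lambda = lambda, beta = beta, se = se, sigma2_e = sigma2_e,
       sigma2_g = lambda * sigma2_e, df = n - p, w = w, XtWXi = XtWXi,
       grid_nll = vals, grid_log10 = lg, nll = min(opt$objective, vals[i0]))
}

#' Kinship-aware linear mixed model
#'
#' REML fit of `y = X beta + u + e` with `Var(u) = 2 Phi sigma2_g` and
#' `Var(e) = sigma2_e I`, via a one-time eigendecomposition of 2*Phi and 1-D
#' profile optimization of the variance ratio. The design matrix is
#' intercept + covariates + `outcome` (the group indicator, entered last);
#' the outcome coefficient carries the screen's effect estimate and Wald
#' test. This is the trait model of the step-1/step-2 screens
#' (trait ~ age + age^2 + sex + PC1..PC4 + outcome + (1|ID)).
#'
#' @param y numeric response, aligned with `kinship$ids`.
#' @param covariates data.frame or matrix of covariates (factors allowed).
#' @param outcome 0/1 group indicator.
#' @param kinship a [kinship_matrix()] (or `NULL` with `eigenK` supplied).
#' @param eigenK optional precomputed [kinship_eigen()] for the complete-case
#'   subset (advanced use; must match the complete-case rows exactly).
#' @return object of class `trait_model_fit`: coefficient table (term, beta,
#'   se, statistic, p), variance components, `lambda`, `n`, and the REML
#'   profile grid for diagnostics.
#' @export
fit_lmm <- function(y, covariates, outcome, kinship, eigenK = NULL) {
  covariates <- as.data.frame(covariates)
  X <- model.matrix(~., data = covariates)
  X <- cbind(X, outcome = outcome)
  cc <- complete.cases(y, X)
  n <- sum(cc)
  if (n < ncol(X) + 2)
    stop("need at least ", ncol(X) + 2, " complete-case rows, have ", n)
  if (is.null(eigenK)) {
    eigenK <- kinship_eigen(kinship, idx = which(cc))
  } else if (eigenK$n != n) {
    stop("supplied eigenK does not match the complete-case subset")
  }
  Xc <- X[cc, , drop = FALSE]
  Xt <- as.matrix(Matrix::crossprod(eigenK$U, Xc))
  yt <- as.numeric(Matrix::crossprod(eigenK$U, y[cc]))
  fit <- reml_profile(Xt, yt, eigenK$d)
  stat <- fit$beta / fit$se
  coefs <- data.frame(term = colnames(X), beta = fit$beta, se = fit$se,
                      statistic = stat,
                      p = 2 * pt(-abs(stat), df = fit$df),
                      row.names = NULL)
  structure(list(coefficients = coefs, sigma2_g = fit$sigma2_g,
                 sigma2_e = fit$sigma2_e, lambda = fit$lambda, n = n,
                 df = fit$df, grid_nll = fit$grid_nll,
                 grid_log10 = fit$grid_log10,
                 covariate_spec = colnames(X)),
            class = "trait_model_fit")
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf("<trait_model_fit> n = %d, sigma2_g = %.4g, sigma2_e = %.4g\n",
              x$n, x$sigma2_g, x$sigma2_e))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Extract the outcome-coefficient row of a mixed-model fit
#' @param fit a `trait_model_fit`.
#' @return one-row data.frame (beta, se, statistic, p).
#' @export
outcome_coef <- function(fit) {
  fit$coefficients[fit$coefficients$term == "outcome",
                   c("beta", "se", "statistic", "p")]
}

#' Logistic regression with separation flagging
#'
#' Maximum-likelihood logistic fit of a binary outcome on covariates plus a
#' single exposure (the genome-scan model
#' logit(outcome) ~ age + sex + PC1 + SNP_dosage). Wald statistics are
#' reported; when the fit shows signs of separation (non-convergence or a
#' diverging coefficient) the record is flagged and the p-value set missing.
#'
#' @param outcome 0/1 vector (both classes must be present).
#' @param covariates data.frame or matrix of covariates.
#' @param exposure numeric exposure vector (e.g. allele dosage).
#' @return list: beta, se, p, or (= exp(beta)) for the exposure; full
#'   coefficient table; `flagged`; `n`.
#' @export
fit_logistic <- function(outcome, covariates, exposure) {
  covariates <- as.data.frame(covariates)
  X <- model.matrix(~., data = covariates)
  X <- cbind(X, exposure = exposure)
  cc <- complete.cases(outcome, X)
  y <- outcome[cc]; Xc <- X[cc, , drop = FALSE]
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  fit <- suppressWarnings(glm.fit(Xc, y, family = binomial()))
  beta <- fit$coefficients
  W <- fit$weights
  XtWX <- crossprod(Xc * sqrt(W))
  vc <- tryCatch(solve(XtWX), error = function(e) NULL)
  flagged <- !fit$converged || is.null(vc) || any(abs(beta) > 15)
  se <- if (is.null(vc)) rep(NA_real_, length(beta)) else sqrt(diag(vc))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  coefs <- data.frame(term = colnames(Xc), beta = beta, se = se,
                      statistic = z, p = p, row.names = NULL)
  k <- nrow(coefs)
  list(beta = beta[[k]], se = se[[k]],
       p = if (flagged) NA_real_ else p[[k]],
       or = exp(beta[[k]]), coefficients = coefs, flagged = flagged,
       n = length(y))
}
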