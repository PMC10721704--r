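#' Kinship matrix
#'
#' Symmetric matrix of pairwise kinship coefficients phi (probability that
#' two randomly sampled alleles are identical by descent; self-kinship 0.5
#' for non-inbred individuals). Twice this matrix, 2*Phi, is the
#' additive-relatedness covariance used as the random-effect structure in
#' the mixed models. Stored sparse: unrelated families contribute nothing
#' off the diagonal.
#'
#' @param phi symmetric (sparse) matrix of kinship coefficients.
#' @param ids participant IDs in matrix order.
#' @param provenance "pedigree" or "genotype".
#' @return object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(phi, ids, provenance = c("pedigree", "genotype")) {
  provenance <- match.arg(provenance)
  phi <- methods::as(methods::as(phi, "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(phi) == length(ids), ncol(phi) == length(ids))
  dimnames(phi) <- list(ids, ids)
  structure(list(phi = phi, ids = ids, provenance = provenance),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d participants (%s), %d related pairs\n",
              length(x$ids), x$provenance,
              (Matrix::nnzero(x$phi) - length(x$ids)) / 2))
  invisible(x)
}

#' Pedigree kinship coefficients
#'
#' Standard recursive kinship on an acyclic pedigree: founders are unrelated
#' and non-inbred; for individual i with parents (f, m),
#' phi(i,i) = 1/2 + phi(f,m)/2 and phi(i,j) = (phi(f,j) + phi(m,j))/2 for
#' any j that is not a descendant of i. Computed family-by-family (the FAM
#' family ID), so the result is block-sparse.
#'
#' @param fam data.frame as from [read_fam()].
#' @return a [kinship_matrix()] in the FAM row order.
#' @export
pedigree_kinship <- function(fam) {
  n <- nrow(fam)
  ids <- fam$participant_id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (f in unique(fam$family_id)) {
    rows <- which(fam$family_id == f)
    sub <- fam[rows, , drop = FALSE]
    k <- nrow(sub)
    fa <- match(sub$father_id, sub$participant_id)
    mo <- match(sub$mother_id, sub$participant_id)
    ord <- pedigree_order(sub$participant_id, fa, mo)
    phi <- matrix(0, k, k)
    for (s in seq_along(ord)) {
      i <- ord[s]
      pf <- fa[i]; pm <- mo[i]
      done <- ord[seq_len(s - 1L)]
      if (length(done)) {
        v <- numeric(length(done))
        if (!is.na(pf)) v <- v + phi[pf, done]
        if (!is.na(pm)) v <- v + phi[pm, done]
        phi[i, done] <- phi[done, i] <- v / 2
      }
      phi[i, i] <- 0.5 +
        if (!is.na(pf) && !is.na(pm)) phi[pf, pm] / 2 else 0
    }
    nz <- which(phi != 0, arr.ind = TRUE)
    ii <- c(ii, rows[nz[, 1]]); jj <- c(jj, rows[nz[, 2]])
    xx <- c(xx, phi[nz])
  }
  kinship_matrix(Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)),
                 ids, "pedigree")
}

# Topological order (parents before children) for one family; errors on
# pedigree loops (an individual that is its own ancestor).
pedigree_order <- function(ids, fa, mo) {
  k <- length(ids)
  placed <- logical(k)
  ord <- integer(0)
  repeat {
    ready <- which(!placed)
    ready <- ready[vapply(ready, function(i) {
      (is.na(fa[i]) || placed[fa[i]]) && (is.na(mo[i]) || placed[mo[i]])
    }, logical(1))]
    if (!length(ready)) {
      if (all(placed)) break
      stop("pedigree loop: individual(s) ",
           paste(ids[!placed], collapse = ", "), " are their own ancestors")
    }
    placed[ready] <- TRUE
    ord <- c(ord, ready)
    if (all(placed)) break
  }
  ord
}

#' Genotype-based kinship (standardized GRM / 2)
#'
#' Kinship estimated from genome-wide dosages as half the standardized
#' genetic relationship matrix: Z = centered and variance-standardized
#' dosages, phi = Z Z' / (2 m). Used when no pedigree is available; the
#' thresholding semantics in [select_unrelated()] are identical.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min variants below this MAF are excluded (default 0.01).
#' @return a [kinship_matrix()] with provenance "genotype".
#' @export
genotype_kinship <- function(gm, maf_min = 0.01) {
  maf <- allele_frequency(gm$dosage)
  keep <- which(!is.na(maf) & maf >= maf_min)
  if (!length(keep)) stop("no variants pass the MAF filter")
  Z <- scale(gm$dosage[, keep, drop = FALSE])
  Z[is.na(Z)] <- 0
  phi <- tcrossprod(Z) / (2 * length(keep))
  kinship_matrix(Matrix::Matrix(phi, sparse = TRUE), rownames(gm$dosage),
                 "genotype")
}

#' Leading genotype principal components
#'
#' PCA of the centered, variance-standardized dosage matrix after a
#' MAF > `maf_min` filter; constant columns are dropped with a warning.
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, so results do not depend on the SVD implementation.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components.
#' @param maf_min MAF filter (default 0.01).
#' @return matrix of scores (participants x k), columns PC1..PCk.
#' @export
genotype_pcs <- function(gm, k, maf_min = 0.01) {
  if (k == 0)
    return(matrix(numeric(0), nrow = nrow(gm$dosage), ncol = 0,
                  dimnames = list(rownames(gm$dosage), NULL)))
  maf <- allele_frequency(gm$dosage)
  keep <- !is.na(maf) & maf > maf_min
  X <- gm$dosage[, keep, drop = FALSE]
  v <- apply(X, 2, var, na.rm = TRUE)
  if (any(v == 0 | is.na(v))) {
    warning(sum(v == 0 | is.na(v)), " constant variant column(s) dropped")
    X <- X[, v > 0 & !is.na(v), drop = FALSE]
  }
  if (ncol(X) < k) stop("fewer than k variants after filtering")
  Z <- scale(X)
  Z[is.na(Z)] <- 0
  pc <- prcomp(Z, center = FALSE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(gm$dosage)
  scores
}

#' Select an unrelated analysis subset
#'
#' Greedy, deterministic pruning used before the genome-wide scan:
#' (1) within each group, while any kept pair has kinship above `threshold`,
#' the younger member of the (lexicographically first) violating pair is
#' removed (age tie: the lexicographically later ID is removed);
#' (2) kept controls related to any kept case above `threshold` are removed.
#' The result is invariant to input row order when ages are distinct.
#'
#' @param kinship a [kinship_matrix()].
#' @param ages numeric vector aligned with `kinship$ids`.
#' @param groups factor/character aligned with `kinship$ids`; individuals
#'   with `NA` group are ignored (removed).
#' @param threshold kinship threshold (default 0.125, i.e. closer than
#'   second degree).
#' @param case_level group level treated as cases for the cross-group rule
#'   (default: the least frequent level present).
#' @return character vector of kept participant IDs.
#' @export
select_unrelated <- function(kinship, ages, groups, threshold = 0.125,
                             case_level = NULL) {
  ids <- kinship$ids
  stopifnot(length(ages) == length(ids), length(groups) == length(ids))
  if (any(is.na(ages))) stop("ages must be known for all individuals")
  groups <- as.character(groups)
  if (is.null(case_level)) {
    tab <- sort(table(groups))
    case_level <- names(tab)[1]
  }
  keep <- !is.na(groups)
  tri <- Matrix::which(kinship$phi > threshold, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  if (nrow(tri)) {
    a <- ids[tri[, 1]]; b <- ids[tri[, 2]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    o <- order(lo, hi)
    tri <- tri[o, , drop = FALSE]
  }
  within <- tri[groups[tri[, 1]] == groups[tri[, 2]] &
                  !is.na(groups[tri[, 1]]) & !is.na(groups[tri[, 2]]), ,
                drop = FALSE]
  repeat {
    live <- which(keep[within[, 1]] & keep[within[, 2]])
    if (!length(live)) break
    pr <- within[live[1], ]
    i <- pr[1]; j <- pr[2]
    drop_idx <- if (ages[i] < ages[j]) i
    else if (ages[j] < ages[i]) j
    else if (ids[i] > ids[j]) i else j
    keep[drop_idx] <- FALSE
  }
  cross <- tri[xor(groups[tri[, 1]] == case_level,
                   groups[tri[, 2]] == case_level) &
                 !is.na(groups[tri[, 1]]) & !is.na(groups[tri[, 2]]), ,
               drop = FALSE]
  if (nrow(cross)) {
    live <- keep[cross[, 1]] & keep[cross[, 2]]
    ctrl <- ifelse(groups[cross[, 1]] == case_level, cross[, 2], cross[, 1])
    keep[unique(ctrl[live])] <- FALSE
  }
  ids[keep]
}
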