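#' Extract carrier deletion-phase haplotypes from a phased region
#'
#' Given a phased region [genotype_matrix()] containing the founder variant,
#' returns one haplotype per carrier: the phased chromosome copy that
#' carries the deletion allele. Variant metadata gains `maf` (population
#' MAF over all participants' dosages) and `mac` (minor allele count among
#' the carrier haplotypes), the two filter inputs of the expansion
#' profiles.
#'
#' @param region a phased [genotype_matrix()].
#' @param index_id variant ID of the founder variant.
#' @return object of class `phased_haplotypes`: `variants` (with maf/mac),
#'   `hap` (carriers x variants 0/1 matrix, rownames carrier IDs),
#'   `index` (column of the founder variant).
#' @export
carrier_haplotypes <- function(region, index_id = "founder_del") {
  j <- match(index_id, region$variants$id)
  if (is.na(j)) stop("index variant ", index_id, " not found")
  if (is.null(region$haplotypes)) stop("region is not phased")
  h1 <- region$haplotypes$h1; h2 <- region$haplotypes$h2
  on1 <- h1[, j] == 1L; on2 <- h2[, j] == 1L
  car <- which(on1 | on2)
  if (!length(car)) stop("no carriers of ", index_id)
  hap <- matrix(0L, length(car), ncol(h1),
                dimnames = list(rownames(h1)[car], region$variants$id))
  hap[on1[car], ] <- h1[car[on1[car]], , drop = FALSE]
  hap[!on1[car], ] <- h2[car[!on1[car]], , drop = FALSE]
  variants <- region$variants
  variants$maf <- allele_frequency(region$dosage)
  mac <- colSums(hap)
  variants$mac <- pmin(mac, nrow(hap) - mac)
  variants$mac[j] <- nrow(hap)  # every carrier haplotype carries the deletion
  structure(list(variants = variants, hap = hap, index = j),
            class = "phased_haplotypes")
}

#' @export
print.phased_haplotypes <- function(x, ...) {
  cat(sprintf("<phased_haplotypes> %d carrier haplotypes x %d variants\n",
              nrow(x$hap), ncol(x$hap)))
  invisible(x)
}

#' Expand the shared founder haplotype window
#'
#' Starting from the founder variant, flanking variants are added one at a
#' time, strictly alternating left/right (left first). Adding a variant
#' partitions carriers into haplotype-allele groups over the current
#' window; when an addition shrinks the modal (most frequent) group by more
#' than `split_threshold` carriers, that side freezes and the offending
#' variant is excluded from the window. Variant eligibility follows one of
#' two profiles: `"common"` keeps variants with population MAF >=
#' `maf_min` (0.01) and threshold 3 — the longest-shared-haplotype scan —
#' while `"rare"` keeps variants with carrier-haplotype minor allele count
#' >= `mac_min` (4) and threshold 10, admitting rare variants that can
#' separate haplotype groups.
#'
#' @param phased a [carrier_haplotypes()] object.
#' @param profile `"common"`, `"rare"`, or `NULL` to give filters directly.
#' @param maf_min,mac_min explicit eligibility filters (one of the two).
#' @param split_threshold maximal tolerated drop of the modal group size.
#' @param gene_interval optional c(start, end) bp of the focal gene, for
#'   reporting the window relative to the gene.
#' @return object of class `haplotype_window`: window variant indices and
#'   bp bounds, span (bp), haplotype groups (member IDs, modal first),
#'   per-side stop reasons, and gene-relative offsets when requested.
#' @export
expand_shared_haplotype <- function(phased, profile = c("common", "rare"),
                                    maf_min = NULL, mac_min = NULL,
                                    split_threshold = NULL,
                                    gene_interval = NULL) {
  if (is.null(maf_min) && is.null(mac_min)) {
    profile <- match.arg(profile)
    if (profile == "common") {
      maf_min <- 0.01
      split_threshold <- split_threshold %||% 3
    } else {
      mac_min <- 4
      split_threshold <- split_threshold %||% 10
    }
  }
  split_threshold <- split_threshold %||% 3
  v <- phased$variants
  j0 <- phased$index
  elig <- if (!is.null(maf_min)) which(!is.na(v$maf) & v$maf >= maf_min)
  else which(v$mac >= mac_min)
  elig <- sort(union(elig, j0))
  at <- match(j0, elig)
  if (length(elig) < 2) stop("no eligible flanking variants")
  hap <- phased$hap
  n_car <- nrow(hap)
  key <- rep("", n_car)
  modal <- n_car
  lp <- at; rp <- at                  # pointers into elig (current bounds)
  frozen <- c(left = FALSE, right = FALSE)
  reason <- c(left = NA_character_, right = NA_character_)
  side <- "left"
  repeat {
    if (all(frozen)) break
    if (frozen[side]) side <- setdiff(c("left", "right"), side)
    nxt <- if (side == "left") lp - 1L else rp + 1L
    if (nxt < 1L || nxt > length(elig)) {
      frozen[side] <- TRUE
      reason[side] <- "end_of_region"
    } else {
      jv <- elig[nxt]
      tkey <- paste0(key, ".", hap[, jv])
      new_modal <- max(table(tkey))
      if (modal - new_modal > split_threshold) {
        frozen[side] <- TRUE
        reason[side] <- "split"
      } else {
        key <- tkey
        modal <- new_modal
        if (side == "left") lp <- nxt else rp <- nxt
      }
    }
    side <- setdiff(c("left", "right"), side)
  }
  li <- elig[lp]; ri <- elig[rp]
  groups <- split(rownames(hap), key)
  groups <- groups[order(-lengths(groups))]
  names(groups) <- paste0("H", seq_along(groups))
  out <- list(left_index = li, right_index = ri,
              left_pos = v$pos[li], right_pos = v$pos[ri],
              span_bp = v$pos[ri] - v$pos[li] + 1L,
              index_pos = v$pos[j0],
              groups = groups, modal_size = modal,
              stop_reason = reason, split_threshold = split_threshold,
              eligible = elig)
  if (!is.null(gene_interval)) {
    out$gene_offsets <- c(left_of_gene_bp = gene_interval[1] - out$left_pos,
                          right_of_gene_bp = out$right_pos - gene_interval[2])
  }
  structure(out, class = "haplotype_window")
}

#' @export
print.haplotype_window <- function(x, ...) {
  cat(sprintf(
    "<haplotype_window> %s-%s (%.2f Mb), %d group(s), modal %d, stops: L=%s R=%s\n",
    format(x$left_pos, big.mark = ","), format(x$right_pos, big.mark = ","),
    x$span_bp / 1e6, length(x$groups), x$modal_size,
    x$stop_reason["left"], x$stop_reason["right"]))
  invisible(x)
}

#' Chi-square test of haplotype groups against symptom status
#'
#' 2 x k chi-square (no continuity correction) of membership in the main
#' haplotype groups (size >= `min_size`) against symptomatic status. When
#' any expected cell falls below 1, a Monte-Carlo permutation p-value
#' replaces the asymptotic one, with a warning.
#'
#' @param groups list of member-ID vectors (e.g. `window$groups`) or a
#'   group-label vector named by carrier ID.
#' @param status named logical/0-1 vector: symptomatic status per carrier.
#' @param min_size minimal group size entering the test (default 3).
#' @param mc_reps Monte-Carlo replicates for the fallback.
#' @return list: statistic, df, p, table, method.
#' @export
haplotype_group_test <- function(groups, status, min_size = 3L,
                                 mc_reps = 2000L) {
  if (is.list(groups)) {
    lab <- rep(names(groups), lengths(groups))
    names(lab) <- unlist(groups)
  } else lab <- groups
  keep <- names(which(table(lab) >= min_size))
  if (length(keep) < 2)
    stop("need at least two haplotype groups of size >= ", min_size)
  lab <- lab[lab %in% keep]
  st <- status[names(lab)]
  if (anyNA(st)) stop("status missing for some carriers")
  tab <- table(symptomatic = as.logical(st), group = lab)
  exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cells < 1)) {
    warning("expected cell below 1; using Monte-Carlo permutation p-value")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE,
                                      simulate.p.value = TRUE, B = mc_reps))
    method <- "chi-square (Monte-Carlo p)"
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    method <- "chi-square"
  }
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, method = method)
}
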