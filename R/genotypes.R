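#' Genotype dosage matrix
#'
#' Container for imputed or genotyped variants: a variant table (chrom,
#' 1-based pos, id, ref, alt, imputation INFO score in [0,1]) and a
#' participants x variants dosage matrix with values in [0,2] (alt-allele
#' dose). Optionally phased haplotype matrices (see [read_region_vcf()]).
#'
#' @param variants data.frame with columns chrom, pos, id, ref, alt, info.
#' @param dosage numeric matrix, participants x variants; rownames are
#'   participant IDs, colnames variant IDs.
#' @param haplotypes optional list(h1, h2) of phased allele matrices
#'   (participants x variants, values 0/1).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, dosage, haplotypes = NULL) {
  stopifnot(is.data.frame(variants), is.matrix(dosage),
            ncol(dosage) == nrow(variants))
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  colnames(dosage) <- variants$id
  structure(list(variants = variants, dosage = dosage, haplotypes = haplotypes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d participants x %d variants%s\n",
              nrow(x$dosage), nrow(x$variants),
              if (!is.null(x$haplotypes)) " (phased)" else ""))
  invisible(x)
}

#' Hard-call genotypes from dosages
#'
#' Rounds each allele dosage to the nearest integer genotype, or sets it
#' missing when the dosage lies more than 0.3 from that integer.
#'
#' @param dosage numeric vector/matrix of dosages in [0, 2].
#' @param band half-width of the calling band around each integer (0.3).
#' @return integer genotypes in {0, 1, 2} with `NA` outside the band.
#' @export
dosage_to_genotype <- function(dosage, band = 0.3) {
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosage outside [0, 2]")
  g <- round(dosage)
  g[!is.na(dosage) & abs(dosage - g) > band + 1e-9] <- NA
  storage.mode(g) <- "integer"
  g
}

#' Minor allele frequency from dosages
#'
#' MAF per variant from the dosage sum over 2N non-missing participants,
#' folded to [0, 0.5]. All-missing columns give `NA`.
#'
#' @param dosage numeric matrix (participants x variants) or vector.
#' @param subset optional row indices / logical mask / participant IDs.
#' @return numeric vector of MAFs.
#' @export
allele_frequency <- function(dosage, subset = NULL) {
  if (is.vector(dosage)) dosage <- matrix(dosage, ncol = 1)
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- match(subset, rownames(dosage))
    dosage <- dosage[subset, , drop = FALSE]
  }
  if (nrow(dosage) == 0) stop("empty participant subset")
  n_obs <- colSums(!is.na(dosage))
  af <- colSums(dosage, na.rm = TRUE) / (2 * n_obs)
  af[n_obs == 0] <- NA_real_
  pmin(af, 1 - af)
}

#' Read a (possibly phased) VCF with dosages
#'
#' Reads genotypes via vcfR. Alt-allele dosage is taken from the FORMAT `DS`
#' field when present, otherwise from hard genotypes. The INFO score is read
#' from `INFO/R2` (1.0 when absent). When all GT fields are phased ("|"),
#' haplotype matrices are extracted as well.
#'
#' @param path VCF path (.vcf or .vcf.gz).
#' @return a [genotype_matrix()].
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info_r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "R2")))
  info_r2[is.na(info_r2)] <- 1.0
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], info = info_r2,
    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, "GT")
  ds <- suppressWarnings(vcfR::extract.gt(v, "DS", as.numeric = TRUE))
  haplotypes <- NULL
  if (all(grepl("|", gt, fixed = TRUE), na.rm = TRUE) && !all(is.na(gt))) {
    a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
    haplotypes <- list(h1 = t(matrix(as.integer(a1), nrow = nrow(gt),
                                     dimnames = dimnames(gt))),
                       h2 = t(matrix(as.integer(a2), nrow = nrow(gt),
                                     dimnames = dimnames(gt))))
  }
  if (is.null(ds) || all(is.na(ds))) {
    alleles <- gsub("[|/]", "", gt)
    ds <- matrix(vapply(strsplit(alleles, ""), function(a)
      sum(as.integer(a)), numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  genotype_matrix(variants, t(ds), haplotypes = haplotypes)
}

#' Write a genotype matrix to VCF
#'
#' Emits GT:DS records (phased GT when haplotypes are present, otherwise
#' hard-called unphased GT) and INFO/R2 scores; the file is gzip-compressed
#' by vcfR, so use a `.vcf.gz` path.
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf_dosage <- function(x, path) {
  vn <- nrow(x$variants); n <- nrow(x$dosage)
  fix <- cbind(CHROM = as.character(x$variants$chrom),
               POS = as.character(x$variants$pos),
               ID = x$variants$id, REF = x$variants$ref, ALT = x$variants$alt,
               QUAL = ".", FILTER = "PASS",
               INFO = sprintf("R2=%g", x$variants$info))
  ds <- format(round(t(x$dosage), 4), trim = TRUE, scientific = FALSE)
  if (!is.null(x$haplotypes)) {
    gt_str <- matrix(paste0(t(x$haplotypes$h1), "|", t(x$haplotypes$h2)),
                     nrow = vn)
  } else {
    hard <- dosage_to_genotype(t(x$dosage), band = 0.5)
    gt_str <- matrix(c("0/0", "0/1", "1/1")[hard + 1L], nrow = vn)
    gt_str[is.na(hard)] <- "./."
  }
  gt <- cbind(FORMAT = "GT:DS", matrix(paste0(gt_str, ":", ds), nrow = vn,
                                       dimnames = list(NULL, rownames(x$dosage))))
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation INFO score\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">")
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Squared allelic correlation with a focal variant
#'
#' LD r^2 between each variant's dosage and a focal dosage vector
#' (e.g. the founder deletion), computed on shared non-missing participants.
#'
#' @param dosage participants x variants dosage matrix.
#' @param focal focal dosage vector (same participant order).
#' @return numeric vector of r^2, `NA` for monomorphic columns.
#' @export
ld_r2 <- function(dosage, focal) {
  stopifnot(nrow(dosage) == length(focal))
  r <- suppressWarnings(cor(dosage, focal, use = "pairwise.complete.obs"))
  as.numeric(r^2)
}
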