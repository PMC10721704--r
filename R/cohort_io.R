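#' Read a cohort from phenotype, flag and pedigree files
#'
#' Phenotype and flag tables are tab-separated with a `participant_id` column;
#' missing values are empty fields or `"NA"`. The pedigree is a PLINK-style
#' 6-column FAM file (family, individual, father, mother, sex 1/2/0,
#' phenotype). Trait and flag columns are visit-wise (`<name>_v1`,
#' `<name>_v2`); the flag table may carry a `cause_of_death` column.
#'
#' @param phenotype_path path to the phenotype TSV (participant_id, age, sex,
#'   carrier, trait columns).
#' @param flags_path path to the symptom/sign flag TSV.
#' @param fam_path path to the FAM file.
#' @param traits,symptoms,signs optional base-name vectors; when `NULL` they
#'   are inferred from column names (`_v1`/`_v2` suffixes stripped; flag
#'   columns are those in the flags file).
#' @return a [cohort()].
#' @export
read_cohort <- function(phenotype_path, flags_path, fam_path,
                        traits = NULL, symptoms = NULL, signs = NULL) {
  for (p in c(phenotype_path, flags_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  phe <- read.table(phenotype_path, header = TRUE, sep = "\t",
                    na.strings = c("NA", ""), stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = c(participant_id = "character"))
  flg <- read.table(flags_path, header = TRUE, sep = "\t",
                    na.strings = c("NA", ""), stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = c(participant_id = "character"))
  fam <- read_fam(fam_path)

  unmatched <- setdiff(flg$participant_id, phe$participant_id)
  if (length(unmatched))
    stop("flag table IDs absent from phenotype table: ",
         paste(unmatched, collapse = ", "))

  flag_cols <- setdiff(names(flg), c("participant_id", "cause_of_death"))
  for (cc in flag_cols) flg[[cc]] <- as.logical(flg[[cc]])
  dat <- merge(phe, flg, by = "participant_id", all.x = TRUE, sort = FALSE)
  dat <- merge(dat, fam[, c("participant_id", "family_id", "father_id", "mother_id")],
               by = "participant_id", all.x = TRUE, sort = FALSE)
  dat <- dat[match(phe$participant_id, dat$participant_id), , drop = FALSE]
  rownames(dat) <- NULL

  strip <- function(cols) unique(sub("_v[12]$", "", cols))
  trait_cols <- setdiff(names(phe), c("participant_id", "age", "sex", "carrier"))
  if (is.null(traits)) traits <- strip(grep("_v[12]$", trait_cols, value = TRUE))
  flag_base <- strip(grep("_v[12]$", flag_cols, value = TRUE))
  if (is.null(symptoms)) symptoms <- intersect(default_symptom_config()$symptoms, flag_base)
  if (is.null(signs)) signs <- setdiff(flag_base, symptoms)
  visits <- sort(unique(as.integer(sub("^.*_v", "",
                                       grep("_v[12]$", names(dat), value = TRUE)))))
  if (!length(visits)) visits <- 1L
  cohort(dat, traits = traits, symptoms = symptoms, signs = signs, visits = visits)
}

#' Write a cohort back to phenotype, flag and FAM files
#'
#' Inverse of [read_cohort()]; missing values are written as `"NA"`.
#'
#' @param x a [cohort()].
#' @param phenotype_path,flags_path,fam_path output paths.
#' @return invisibly, the three paths.
#' @export
write_cohort <- function(x, phenotype_path, flags_path, fam_path) {
  validate_cohort(x)
  tcols <- unlist(lapply(cohort_visits(x),
                         function(v) trait_col(cohort_traits(x), v)))
  tcols <- intersect(tcols, names(x))
  phe <- as.data.frame(x)[, c("participant_id", "age", "sex", "carrier", tcols)]
  fcols <- unlist(lapply(cohort_visits(x),
                         function(v) trait_col(c(cohort_symptoms(x), cohort_signs(x)), v)))
  fcols <- intersect(fcols, names(x))
  flg <- as.data.frame(x)[, c("participant_id", fcols,
                              intersect("cause_of_death", names(x)))]
  for (cc in fcols) flg[[cc]] <- as.integer(flg[[cc]])
  write.table(phe, phenotype_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write.table(flg, flags_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  sexcode <- ifelse(is.na(x$sex), 0L, ifelse(x$sex == "male", 1L, 2L))
  fam <- data.frame(family_id = x$family_id, participant_id = x$participant_id,
                    father_id = ifelse(is.na(x$father_id), "0", x$father_id),
                    mother_id = ifelse(is.na(x$mother_id), "0", x$mother_id),
                    sex = sexcode, phenotype = -9L)
  write.table(fam, fam_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(phenotype_path, flags_path, fam_path))
}

#' Read a PLINK 6-column FAM file
#'
#' Sex is coded 1 = male, 2 = female, 0 = unknown. Parent code "0" means
#' unknown and is stored as `NA`.
#'
#' @param path FAM path.
#' @return data.frame with family_id, participant_id, father_id, mother_id,
#'   sex, phenotype.
#' @export
read_fam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- vapply(parts, length, 1L)
  if (any(nf != 6L))
    stop("malformed FAM line ", which(nf != 6L)[1], ": expected 6 fields, got ",
         nf[nf != 6L][1])
  m <- do.call(rbind, parts)
  data.frame(
    family_id = m[, 1], participant_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = c("0" = NA, "1" = "male", "2" = "female")[m[, 5]],
    phenotype = suppressWarnings(as.numeric(m[, 6])),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Quality-control filters for quantitative traits
#'
#' Values above per-trait upper bounds are set missing (never whole rows);
#' traits observed in fewer than `min_asymptomatic_carriers` members of the
#' asymptomatic-carrier group are removed from the trait list. Bounds are
#' strict (value > bound is removed). Defaults reproduce the cardiac-trait
#' cleanup used in the screen: HR > 200 bpm, QRS > 200 ms, QTC > 600 ms,
#' PQ > 320 ms, and a minimum of 25 asymptomatic carriers per trait.
#'
#' @param cohort a [cohort()].
#' @param rules list with elements `bounds` (named numeric vector of upper
#'   bounds per trait base name) and `min_asymptomatic_carriers` (integer).
#' @param groups optional [assign_groups()] table; required for the
#'   minimum-count rule (skipped with a message if absent).
#' @return list with `cohort` (filtered) and `report` (data.frame of removals
#'   plus dropped traits).
#' @export
apply_trait_qc <- function(cohort, rules = qc_rules(), groups = NULL) {
  validate_cohort(cohort)
  bounds <- rules$bounds
  unknown <- setdiff(names(bounds), cohort_traits(cohort))
  if (length(unknown))
    stop("unknown trait(s) in QC rules: ", paste(unknown, collapse = ", "))
  removed <- data.frame(trait = character(), visit = integer(),
                        n_removed = integer())
  for (tr in names(bounds)) {
    for (v in cohort_visits(cohort)) {
      cc <- trait_col(tr, v)
      if (!cc %in% names(cohort)) next
      bad <- !is.na(cohort[[cc]]) & cohort[[cc]] > bounds[[tr]]
      if (any(bad)) cohort[[cc]][bad] <- NA_real_
      removed <- rbind(removed, data.frame(trait = tr, visit = v,
                                           n_removed = sum(bad)))
    }
  }
  dropped <- character()
  min_n <- rules$min_asymptomatic_carriers %||% 25L
  if (!is.null(groups)) {
    ac <- groups$participant_id[groups$group == "asymptomatic_carrier"]
    idx <- cohort$participant_id %in% ac
    for (tr in cohort_traits(cohort)) {
      cc <- trait_col(tr, 1L)
      if (!cc %in% names(cohort)) next
      if (sum(!is.na(cohort[[cc]][idx])) < min_n) dropped <- c(dropped, tr)
    }
    attr(cohort, "traits") <- setdiff(cohort_traits(cohort), dropped)
  } else if (min_n > 0) {
    message("no group assignment supplied; minimum asymptomatic-carrier ",
            "count rule not applied")
  }
  list(cohort = cohort,
       report = list(values_removed = removed, traits_dropped = dropped))
}

#' @rdname apply_trait_qc
#' @param bounds named numeric vector of strict upper bounds.
#' @param min_asymptomatic_carriers minimum non-missing asymptomatic carriers
#'   for a trait to be kept.
#' @export
qc_rules <- function(bounds = c(HR = 200, QRS = 200, QTC = 600, PQ = 320),
                     min_asymptomatic_carriers = 25L) {
  list(bounds = bounds,
       min_asymptomatic_carriers = as.integer(min_asymptomatic_carriers))
}

#' Read a PGS weight table
#'
#' Tab-separated columns: chrom, pos, effect_allele, other_allele, weight.
#'
#' @param path weight table path.
#' @return data.frame of per-allele weights with unique variant keys.
#' @export
read_weight_table <- function(path) {
  w <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "effect_allele", "other_allele", "weight")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop("weight table missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(w$chrom, w$pos, w$effect_allele, w$other_allele)
  if (anyDuplicated(key)) stop("duplicated variant keys in weight table")
  if (any(w$effect_allele == w$other_allele))
    stop("effect_allele equals other_allele for some variants")
  w
}

#' Read a YAML analysis configuration
#'
#' Used for symptom/sign column lists, QC rules and screen settings.
#'
#' @param path YAML path.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
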