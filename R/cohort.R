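#' Cohort container
#'
#' A cohort is a participant-level data frame with a small amount of
#' metadata describing which columns hold quantitative traits and which hold
#' symptom/sign flags. Trait and flag columns are visit-wise and named
#' `<name>_v<visit>` (e.g. `QRS_v1`, `HF_v2`). Core columns are
#' `participant_id`, `family_id`, `father_id`, `mother_id`, `age` (years),
#' `sex` (`"male"`/`"female"`), `carrier` (0/1) and optionally
#' `cause_of_death`.
#'
#' @param participants data.frame with the columns described above.
#' @param traits character vector of trait base names.
#' @param symptoms character vector of self-reported symptom flag base names.
#' @param signs character vector of ECG sign flag base names.
#' @param visits integer vector of visit indices present (subset of 1:2).
#'
#' @return An object of class `cohort` (a data.frame subclass).
#' @export
cohort <- function(participants, traits = character(), symptoms = character(),
                   signs = character(), visits = 1L) {
  stopifnot(is.data.frame(participants))
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  obj <- structure(participants,
                   traits = traits, symptoms = symptoms, signs = signs,
                   visits = as.integer(visits),
                   class = c("cohort", "data.frame"))
  validate_cohort(obj)
}

#' @rdname cohort
#' @param x object to validate.
#' @export
validate_cohort <- function(x) {
  need <- c("participant_id", "age", "sex", "carrier")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$participant_id))
    stop("duplicated participant_id: ",
         paste(unique(x$participant_id[duplicated(x$participant_id)]), collapse = ", "))
  if (any(x$age < 0, na.rm = TRUE)) stop("negative ages in cohort")
  if (!all(x$carrier %in% c(0L, 1L)))
    stop("carrier must be coded 0/1")
  if (!all(attr(x, "visits") %in% 1:2))
    stop("visit index must be in {1, 2}")
  bad_sex <- setdiff(unique(x$sex[!is.na(x$sex)]), c("male", "female"))
  if (length(bad_sex)) stop("sex must be 'male'/'female', found: ",
                            paste(bad_sex, collapse = ", "))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d carriers, %d traits, visits %s\n",
              nrow(x), sum(x$carrier), length(attr(x, "traits")),
              paste(attr(x, "visits"), collapse = ",")))
  invisible(x)
}

cohort_traits   <- function(x) attr(x, "traits")
cohort_symptoms <- function(x) attr(x, "symptoms")
cohort_signs    <- function(x) attr(x, "signs")
cohort_visits   <- function(x) attr(x, "visits")

#' Trait column name for a visit
#' @param trait trait base name.
#' @param visit visit index.
#' @return column name string.
#' @export
trait_col <- function(trait, visit = 1L) paste0(trait, "_v", visit)
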