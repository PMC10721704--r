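#' Default symptom/sign configuration
#'
#' Self-reported symptoms (heart failure, heart attack, infarct, treated for
#' arrhythmia) and cardiologist-reviewed ECG signs (low voltages, negative T,
#' ventricular tachycardia, ventricular extrasystole, atrial fibrillation)
#' scanned at both visits. `cardiac_death_values` are `cause_of_death`
#' entries that mark a carrier as symptomatic.
#'
#' @param symptoms,signs flag base-name vectors.
#' @param visits visits to scan.
#' @param cardiac_death_values character values of `cause_of_death` treated
#'   as cardiac.
#' @return named list usable as `symptom_config`.
#' @export
default_symptom_config <- function(
    symptoms = c("HF", "heart_attack", "infarct", "treated_arrhythmia"),
    signs = c("low_voltage", "negative_T", "ventricular_tachycardia",
              "ventricular_extrasystole", "atrial_fibrillation"),
    visits = 1:2,
    cardiac_death_values = "cardiac") {
  list(symptoms = symptoms, signs = signs, visits = visits,
       cardiac_death_values = cardiac_death_values)
}

group_levels <- c("asymptomatic_noncarrier", "symptomatic_noncarrier",
                  "asymptomatic_carrier", "symptomatic_carrier")

#' Assign participants to the four carrier-by-symptom groups
#'
#' A participant is symptomatic if at least one configured symptom or sign
#' flag is `TRUE` at any scanned visit or, for carriers only, if
#' `cause_of_death` matches a configured cardiac value; otherwise
#' asymptomatic. Missing flags count as "not reported" (`FALSE`) and are
#' tallied in the report; carriers with no non-missing flag at any scanned
#' visit are listed rather than guessed about.
#'
#' @param cohort a [cohort()].
#' @param symptom_config list as from [default_symptom_config()] (or a YAML
#'   profile read with [read_config()]).
#' @return data.frame with participant_id, group (factor over the four
#'   levels), triggering_flags (list column); attributes `missing_flag_count`
#'   and `unobserved_carriers`.
#' @export
assign_groups <- function(cohort, symptom_config = default_symptom_config()) {
  validate_cohort(cohort)
  cols <- unlist(lapply(symptom_config$visits, function(v)
    trait_col(c(symptom_config$symptoms, symptom_config$signs), v)))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("flag column(s) missing from cohort: ",
         paste(missing_cols, collapse = ", "))
  flags <- as.matrix(as.data.frame(cohort)[, cols, drop = FALSE])
  n_missing <- sum(is.na(flags))
  trig <- apply(flags, 1, function(r) cols[which(!is.na(r) & r)],
                simplify = FALSE)
  symptomatic <- lengths(trig) > 0
  if ("cause_of_death" %in% names(cohort)) {
    cardiac <- cohort$carrier == 1 & !is.na(cohort$cause_of_death) &
      cohort$cause_of_death %in% symptom_config$cardiac_death_values
    trig[cardiac] <- lapply(trig[cardiac], c, "cause_of_death")
    symptomatic <- symptomatic | cardiac
  }
  grp <- ifelse(cohort$carrier == 1,
                ifelse(symptomatic, "symptomatic_carrier", "asymptomatic_carrier"),
                ifelse(symptomatic, "symptomatic_noncarrier", "asymptomatic_noncarrier"))
  unobserved <- cohort$participant_id[cohort$carrier == 1 &
                                        rowSums(!is.na(flags)) == 0]
  out <- data.frame(participant_id = cohort$participant_id,
                    group = factor(grp, levels = group_levels))
  out$triggering_flags <- trig
  attr(out, "missing_flag_count") <- n_missing
  attr(out, "unobserved_carriers") <- unobserved
  out
}

#' Crude odds ratio for symptoms given carrier status
#'
#' OR = (symptomatic carriers / asymptomatic carriers) /
#' (symptomatic non-carriers / asymptomatic non-carriers), with a Wald
#' confidence interval and p-value on the log scale. A zero cell triggers
#' the Haldane-Anscombe continuity correction (0.5 added to every cell)
#' with a warning.
#'
#' @param groups an [assign_groups()] table, or a named numeric vector of the
#'   four cell counts (`symptomatic_carrier`, `asymptomatic_carrier`,
#'   `symptomatic_noncarrier`, `asymptomatic_noncarrier`).
#' @param conf_level confidence level (default 0.95).
#' @return list with or, ci (length-2), p, counts.
#' @export
crude_or <- function(groups, conf_level = 0.95) {
  if (is.data.frame(groups)) {
    counts <- table(factor(groups$group, levels = group_levels))
    cells <- c(sc = counts[["symptomatic_carrier"]],
               ac = counts[["asymptomatic_carrier"]],
               sn = counts[["symptomatic_noncarrier"]],
               an = counts[["asymptomatic_noncarrier"]])
  } else {
    cells <- c(sc = groups[["symptomatic_carrier"]],
               ac = groups[["asymptomatic_carrier"]],
               sn = groups[["symptomatic_noncarrier"]],
               an = groups[["asymptomatic_noncarrier"]])
  }
  work <- cells
  if (any(cells == 0)) {
    warning("zero cell; applying continuity correction (0.5 per cell)")
    work <- cells + 0.5
  }
  or <- (work[["sc"]] / work[["ac"]]) / (work[["sn"]] / work[["an"]])
  se <- sqrt(sum(1 / work))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- 2 * pnorm(-abs(log(or) / se))
  list(or = unname(or), ci = unname(ci), p = unname(p), counts = cells)
}
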