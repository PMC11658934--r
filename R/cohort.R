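## Selection-report helpers ---------------------------------------------

new_selection_report <- function(unit) {
  rep <- data.frame(step = integer(0), name = character(0),
                    criterion = character(0), n_before = integer(0),
                    n_removed = integer(0), n_after = integer(0),
                    stringsAsFactors = FALSE)
  attr(rep, "unit") <- unit
  class(rep) <- c("selection_report", "data.frame")
  rep
}

add_step <- function(report, name, criterion, n_before, n_after) {
  row <- data.frame(step = nrow(report) + 1L, name = name,
                    criterion = criterion, n_before = as.integer(n_before),
                    n_removed = as.integer(n_before - n_after),
                    n_after = as.integer(n_after), stringsAsFactors = FALSE)
  out <- rbind(report, row)
  attr(out, "unit") <- attr(report, "unit")
  class(out) <- c("selection_report", "data.frame")
  out
}

#' Minimum guaranteed age at questionnaire time
#'
#' From calendar years alone the respondent is guaranteed to have reached
#' `fill_year - birth_year - 1` (the birthday in the fill year may not have
#' passed yet).
#'
#' @param birth_year,fill_year integer years.
#' @return integer minimum age.
#' @export
min_guaranteed_age <- function(birth_year, fill_year) {
  fill_year - birth_year - 1L
}

#' Completed-reproduction rule
#'
#' A respondent is treated as having final reproductive success when either
#' (a) they are surely at least 45 (women) / 55 (men) years old and did not
#' answer "yes" to wanting more children, or (b) they are up to 10 years
#' younger than that threshold, claim a stable partnership for the next 10
#' years, and explicitly answered "no" to wanting more children.
#'
#' @param r one-row respondent record (data frame or list) with
#'   `birth_year`, `fill_year`, `sex`, `wants_more`, `stable_partner_10y`.
#' @return logical. Missing `birth_year`/`fill_year` yields `FALSE` with a
#'   warning (conservative exclusion).
#' @export
is_completed_reproduction <- function(r) {
  if (is.na(r$birth_year) || is.na(r$fill_year)) {
    warning("missing birth_year/fill_year; treating reproduction as ",
            "incomplete", call. = FALSE)
    return(FALSE)
  }
  thr <- if (r$sex == "F") 45L else 55L
  age <- min_guaranteed_age(r$birth_year, r$fill_year)
  wm <- r$wants_more
  over <- age >= thr && (is.na(wm) || wm != "yes")
  window <- age >= thr - 10L && age < thr &&
    !is.na(r$stable_partner_10y) && r$stable_partner_10y == "yes" &&
    !is.na(wm) && wm == "no"
  over || window
}

## Vectorised form used by the cohort builder.
completed_reproduction_vec <- function(df) {
  thr <- ifelse(df$sex == "F", 45L, 55L)
  age <- min_guaranteed_age(df$birth_year, df$fill_year)
  wm <- df$wants_more
  over <- age >= thr & (is.na(wm) | wm != "yes")
  window <- age >= thr - 10L & age < thr &
    !is.na(df$stable_partner_10y) & df$stable_partner_10y == "yes" &
    !is.na(wm) & wm == "no"
  out <- over | window
  out[is.na(df$birth_year) | is.na(df$fill_year)] <- FALSE
  out
}

#' Child-count consistency check
#'
#' The reported total number of children must equal the sum of sons,
#' daughters and foetuses of unknown sex.
#'
#' @param r one-row respondent record with `n_children`, `n_sons`,
#'   `n_daughters`, `n_foetus_unknown`.
#' @return logical.
#' @export
check_child_count_consistency <- function(r) {
  cnt <- c(r$n_children, r$n_sons, r$n_daughters, r$n_foetus_unknown)
  if (any(is.na(cnt))) return(FALSE)
  if (any(cnt < 0)) stop("negative children count", call. = FALSE)
  r$n_children == r$n_sons + r$n_daughters + r$n_foetus_unknown
}

#' Choose one representative respondent per family
#'
#' Preference order: abortion-free males, then abortion-free females, then
#' everyone else (males are preferred because they are underrepresented
#' among survey respondents; abortion-free reproduction dominates sex).
#' Ties within the winning class are broken uniformly at random with the
#' current RNG stream.
#'
#' @param members data frame of the family's respondents with columns
#'   `respondent_id`, `sex`, `abortion_free`.
#' @return the chosen `respondent_id`.
#' @export
select_representative <- function(members) {
  stopifnot(nrow(members) >= 1)
  if (nrow(members) == 1) return(members$respondent_id[1])
  af <- !is.na(members$abortion_free) & members$abortion_free
  cls <- ifelse(af & members$sex == "M", 1L,
                ifelse(af & members$sex == "F", 2L, 3L))
  pool <- which(cls == min(cls))
  pick <- if (length(pool) == 1) pool else pool[sample.int(length(pool), 1L)]
  members$respondent_id[pick]
}

## shared by both cohort builders
check_region <- function(region) {
  if (!region %in% c("whole_country", "budapest"))
    stop("unknown region '", region,
         "' (use whole_country or budapest)", call. = FALSE)
}

#' Build the reproductive-success analysis cohort
#'
#' Applies the staged exclusion cascade, in order: born in Hungary;
#' childhood residence known; current residence in Hungary and known;
#' completed reproduction; child-count consistency; one respondent per
#' family (pseudoreplication removal via [select_representative()]);
#' reproduction unaffected by induced abortion; for the Budapest region,
#' born and living in Budapest; finally, removal of respondents with more
#' than `max_children` children.
#'
#' @param respondents,rosters questionnaire tables.
#' @param assignment a `family_assignment` covering all respondents.
#' @param region `"whole_country"` or `"budapest"`.
#' @param max_children largest number of children retained (default 12:
#'   larger counts are treated as outliers).
#' @param seed optional integer seed for representative tie-breaks.
#' @return list `cohort` (surviving respondent rows with added
#'   `family_id` and `n_siblings` columns) and `report` (a
#'   `selection_report`).
#' @export
build_precondition_cohort <- function(respondents, rosters, assignment,
                                      region = "whole_country",
                                      max_children = 12, seed = NULL) {
  check_region(region)
  if (!is.null(seed)) set.seed(seed)
  asg <- assignment$assignment
  if (!all(respondents$respondent_id %in% asg$respondent_id))
    stop("assignment does not cover all respondents", call. = FALSE)
  df <- respondents
  df$family_id <- asg$family_id[match(df$respondent_id, asg$respondent_id)]
  roster_sizes <- table(rosters$respondent_id)
  df$n_siblings <- as.integer(roster_sizes[df$respondent_id]) - 1L

  report <- new_selection_report("respondents")
  keep_step <- function(df, name, criterion, keep) {
    keep[is.na(keep)] <- FALSE
    report <<- add_step(report, name, criterion, nrow(df), sum(keep))
    df[keep, , drop = FALSE]
  }

  df <- keep_step(df, "born_in_hungary", "born in Hungary",
                  df$country_of_birth == "hungary")
  df <- keep_step(df, "childhood_residence_known",
                  "childhood settlement type known",
                  !is.na(df$childhood_settlement))
  df <- keep_step(df, "current_residence_in_hungary",
                  "currently living in Hungary, residence known",
                  !is.na(df$current_country) &
                    df$current_country == "hungary" &
                    !is.na(df$current_settlement))
  df <- keep_step(df, "completed_reproduction",
                  "final reproductive success observable (45/55-year rule)",
                  completed_reproduction_vec(df))
  cons <- !is.na(df$n_children) & !is.na(df$n_sons) &
    !is.na(df$n_daughters) & !is.na(df$n_foetus_unknown) &
    df$n_children == df$n_sons + df$n_daughters + df$n_foetus_unknown
  df <- keep_step(df, "child_count_consistency",
                  "children total equals sons + daughters + foetuses", cons)
  if (nrow(df)) {
    reps <- vapply(split(df[, c("respondent_id", "sex", "abortion_free")],
                         df$family_id),
                   select_representative, character(1))
    keep <- df$respondent_id %in% reps
  } else keep <- logical(0)
  df <- keep_step(df, "one_per_family",
                  "one respondent per family (pseudoreplication)", keep)
  df <- keep_step(df, "abortion_free",
                  "reproduction certainly unaffected by induced abortion",
                  !is.na(df$abortion_free) & df$abortion_free)
  if (region == "budapest") {
    df <- keep_step(df, "budapest_only", "born and living in Budapest",
                    df$childhood_settlement == "budapest" &
                      df$current_settlement == "budapest")
  }
  df <- keep_step(df, "children_outliers",
                  sprintf("no more than %d children", max_children),
                  df$n_children <= max_children)
  list(cohort = df, report = report)
}

#' Build the sex-ratio analysis cohort (family level)
#'
#' One record per family, represented by the respondent chosen by
#' [select_representative()]. Families are excluded when any sibling was
#' born abroad, when siblings' childhood settlement types differ or are
#' missing, or when the family contains identical twins. For the Budapest
#' region only families in which every sibling was born in Budapest are
#' retained. A final step drops families whose representative did not
#' report childhood SES.
#'
#' @inheritParams build_precondition_cohort
#' @return list `families` (one row per family: `family_id`,
#'   `respondent_id`, `sex`, `childhood_ses`, `settlement`, `n_siblings`)
#'   and `report` (family-level `selection_report`).
#' @export
build_prediction_cohort <- function(respondents, rosters, assignment,
                                    region = "whole_country", seed = NULL) {
  check_region(region)
  if (!is.null(seed)) set.seed(seed)
  asg <- assignment$assignment
  if (!all(respondents$respondent_id %in% asg$respondent_id))
    stop("assignment does not cover all respondents", call. = FALSE)
  df <- respondents
  df$family_id <- asg$family_id[match(df$respondent_id, asg$respondent_id)]

  reps <- vapply(split(df[, c("respondent_id", "sex", "abortion_free")],
                       df$family_id), select_representative, character(1))
  fam <- df[df$respondent_id %in% reps, , drop = FALSE]

  ## per-representative roster summaries
  rost <- rosters[rosters$respondent_id %in% fam$respondent_id, ,
                  drop = FALSE]
  rsplit <- split(rost, rost$respondent_id)
  summarise1 <- function(ro) {
    list(all_born_hu = all(ro$born_in_hungary == 1L),
         settlement_ok = all(!is.na(ro$childhood_settlement)) &&
           length(unique(ro$childhood_settlement)) == 1,
         has_twins = any(ro$is_identical_twin == 1L),
         all_budapest = all(!is.na(ro$childhood_settlement) &
                              ro$childhood_settlement == "budapest" &
                              ro$born_in_hungary == 1L),
         n_sibs = nrow(ro) - 1L)
  }
  sm <- lapply(rsplit[fam$respondent_id], summarise1)
  fam$all_born_hu <- vapply(sm, `[[`, logical(1), "all_born_hu")
  fam$settlement_ok <- vapply(sm, `[[`, logical(1), "settlement_ok")
  fam$has_twins <- vapply(sm, `[[`, logical(1), "has_twins")
  fam$all_budapest <- vapply(sm, `[[`, logical(1), "all_budapest")
  fam$n_siblings <- vapply(sm, `[[`, integer(1), "n_sibs")

  report <- new_selection_report("families")
  keep_step <- function(fam, name, criterion, keep) {
    keep[is.na(keep)] <- FALSE
    report <<- add_step(report, name, criterion, nrow(fam), sum(keep))
    fam[keep, , drop = FALSE]
  }
  fam <- keep_step(fam, "all_siblings_born_in_hungary",
                   "no sibling born abroad",
                   fam$all_born_hu & fam$country_of_birth == "hungary")
  fam <- keep_step(fam, "settlement_homogeneous",
                   "siblings share a known childhood settlement type",
                   fam$settlement_ok)
  fam <- keep_step(fam, "no_identical_twins",
                   "no identical twins among the siblings",
                   !fam$has_twins)
  if (region == "budapest") {
    fam <- keep_step(fam, "budapest_only",
                     "every sibling born in Budapest", fam$all_budapest)
  }
  fam <- keep_step(fam, "ses_known", "childhood SES reported",
                   !is.na(fam$childhood_ses))
  families <- data.frame(family_id = fam$family_id,
                         respondent_id = fam$respondent_id,
                         sex = fam$sex,
                         childhood_ses = fam$childhood_ses,
                         settlement = fam$childhood_settlement,
                         n_siblings = fam$n_siblings,
                         stringsAsFactors = FALSE)
  list(families = families, report = report)
}
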