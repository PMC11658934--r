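## The two headline analyses.
##
## Precondition: does childhood socioeconomic status relate to completed
## reproductive success differently in men and women? Quasi-Poisson GLM of
## the number of children on SES (forward-Helmert), sex (sum), their
## interaction, number of siblings, and (whole-country only) settlement
## type.
##
## Prediction: does childhood SES predict the proportion of males among
## the siblings? Binomial-logit GLM of sons on SES (and settlement for the
## whole country), with the sibling count as binomial denominator, run on
## 100 balanced subsets that equalise male- and female-respondent
## families; medians of the per-replicate statistics are reported.

## Merge the two highest status levels ("lived better than average",
## "lived very well") into one analysis level; the top category is too
## sparse to estimate on its own.
merge_top_ses <- function(ses) {
  stopifnot(all(ses %in% 1:5))
  SES_LEVELS4[pmin(ses, 4L)]
}

precondition_terms <- function(region) {
  terms <- list(
    design_term("ses", "ordinal_factor", "forward_helmert", SES_LEVELS4),
    design_term("sex", "factor", "sum", c("F", "M")),
    design_term("n_siblings", "numeric", "none"))
  if (region == "whole_country")
    terms <- c(terms, list(design_term("settlement", "factor", "sum",
                                       SETTLEMENT_LEVELS)))
  terms
}

#' Run the reproductive-success (precondition) analysis
#'
#' Fits the quasi-Poisson model of the number of children and reports
#' type-3 Wald tests for every term, the Pearson dispersion, estimated
#' marginal means for the SES-by-sex cells, and (whole-country region)
#' FDR-adjusted pairwise settlement contrasts.
#'
#' @param cohort result cohort of [build_precondition_cohort()]; must
#'   carry `childhood_ses` (1..5), `sex`, `n_children`, `n_siblings`,
#'   `childhood_settlement`.
#' @param region `"whole_country"` (settlement covariate included) or
#'   `"budapest"`.
#' @return object of class `precondition_result`: `region`, `n`, `fit`,
#'   `dispersion`, `wald` (type-3 table), `marginal_means` (SES x sex),
#'   `settlement_contrasts` (or `NULL`).
#' @export
run_precondition <- function(cohort, region = "whole_country") {
  check_region(region)
  if (any(is.na(cohort$childhood_ses)))
    stop("cohort has missing childhood SES", call. = FALSE)
  d <- data.frame(ses = merge_top_ses(cohort$childhood_ses),
                  sex = cohort$sex,
                  n_siblings = as.numeric(cohort$n_siblings),
                  settlement = cohort$childhood_settlement,
                  y = cohort$n_children,
                  stringsAsFactors = FALSE)
  empty <- setdiff(SES_LEVELS4, unique(d$ses))
  if (length(empty))
    stop("SES level(s) empty after merging: ",
         paste(empty, collapse = ", "), call. = FALSE)
  design <- build_design(d, precondition_terms(region),
                         interactions = list(c("ses", "sex")))
  fit <- fit_glm(design, d$y, "poisson_log")
  phi <- pearson_dispersion(fit)
  out <- list(region = region,
              n = nrow(d),
              fit = fit,
              dispersion = phi,
              wald = type3_wald(fit, phi),
              marginal_means = estimate_marginal_means(fit, c("ses", "sex"),
                                                       phi),
              settlement_contrasts = if (region == "whole_country")
                pairwise_contrasts(fit, "settlement", phi) else NULL)
  class(out) <- "precondition_result"
  out
}

#' @export
print.precondition_result <- function(x, ...) {
  cat(sprintf("reproductive-success model (%s), n = %d, dispersion = %.3f\n",
              x$region, x$n, x$dispersion))
  print(x$wald, row.names = FALSE)
  invisible(x)
}

#' Balanced subsample of families
#'
#' Keeps every family with a male representative and a uniform random
#' sample (without replacement) of female-representative families of equal
#' count, correcting the female-biased response rate. If there are fewer
#' female families than male ones, everything is returned with a warning.
#'
#' @param families family table with a `sex` column (representative's sex).
#' @return row subset of `families`.
#' @export
balance_subsample <- function(families) {
  male <- which(families$sex == "M")
  female <- which(families$sex == "F")
  if (!length(male))
    stop("no families with male representatives; balanced analysis ",
         "undefined", call. = FALSE)
  if (length(female) < length(male)) {
    warning("fewer female- than male-representative families; ",
            "returning all", call. = FALSE)
    return(families)
  }
  keep <- c(male, sample(female, length(male)))
  families[sort(keep), , drop = FALSE]
}

## Per-family response (males, total) at the requested level.
family_responses <- function(families, rosters, level) {
  rost <- rosters[rosters$respondent_id %in% families$respondent_id, ,
                  drop = FALSE]
  rsplit <- split(rost, rost$respondent_id)
  res <- lapply(families$respondent_id, function(id) {
    ro <- rsplit[[id]]
    ro <- ro[order(ro$position), , drop = FALSE]
    if (level == "family") {
      sr <- family_sex_ratio(ro)
    } else {
      sr <- select_analysis_subunit(extract_subunits(ro, quiet = TRUE))
    }
    c(n_males = sr$n_males, n_total = sr$n_total)
  })
  res <- do.call(rbind, res)
  families$n_males <- res[, "n_males"]
  families$n_total <- res[, "n_total"]
  families
}

prediction_terms <- function(region) {
  terms <- list(
    design_term("ses", "ordinal_factor", "forward_helmert", SES_LEVELS4))
  if (region == "whole_country")
    terms <- c(terms, list(design_term("settlement", "factor", "sum",
                                       SETTLEMENT_LEVELS)))
  terms
}

#' Run the sex-ratio (prediction) analysis with balanced resampling
#'
#' For each of `n_reps` replicates (each with a seed derived from the base
#' seed, so any replicate is reproducible in isolation) a balanced subset
#' is drawn with [balance_subsample()] -- the male-family set is fixed,
#' only the female sample varies -- and a binomial-logit GLM of the number
#' of sons on childhood SES (forward-Helmert, top two levels merged) and,
#' for the whole country, settlement type (sum coding) is fitted, with the
#' sibling count as binomial denominator. Per replicate, the omnibus SES
#' type-3 Wald p-value, the 'worse' - 'better' contrast estimate and
#' p-value, and the predicted sex ratio per SES level are recorded.
#' Replicates whose GLM fails are recorded as failed and excluded from the
#' aggregates.
#'
#' @param families family table from [build_prediction_cohort()].
#' @param rosters rosters table covering the representatives.
#' @param level `"family"` or `"subunit"` (the binomial denominator is the
#'   number of offspring in the family or in the analysis subunit).
#' @param region `"whole_country"` or `"budapest"`.
#' @param n_reps number of balanced replicates (default 100).
#' @param seed base seed.
#' @return object of class `resampling_summary`: `level`, `region`,
#'   `n_reps`, `n_failed`, `per_rep` (data frame with one row per
#'   successful replicate: `rep`, `seed`, `n`, `p_omnibus`,
#'   `contrast_estimate`, `contrast_p`, and `sr_<level>` predicted sex
#'   ratios), `median_p_omnibus`, `median_contrast_p`,
#'   `median_contrast_estimate`, `frac_contrast_significant`,
#'   `median_predicted_sr` (per SES level), `mean_subset_sr` (average over
#'   replicates of the per-subset mean family sex ratio).
#' @export
run_prediction <- function(families, rosters, level = c("family", "subunit"),
                           region = "whole_country", n_reps = 100,
                           seed = 1) {
  level <- match.arg(level)
  check_region(region)
  if (any(is.na(families$childhood_ses)))
    stop("families table has missing childhood SES", call. = FALSE)
  fam <- families
  fam$ses <- merge_top_ses(fam$childhood_ses)
  fam <- family_responses(fam, rosters, level)
  terms <- prediction_terms(region)

  one_rep <- function(r) {
    rep_seed <- derive_seed(seed, r)
    set.seed(rep_seed)
    sub <- balance_subsample(fam)
    fit <- fit_glm(build_design(sub, terms), sub$n_males,
                   "binomial_logit", denominators = sub$n_total)
    phi <- pearson_dispersion(fit)
    wald <- type3_wald(fit, phi)
    ctr <- pairwise_contrasts(fit, "ses", phi)
    wb <- ctr[ctr$label == "worse - better", , drop = FALSE]
    mm <- estimate_marginal_means(fit, "ses", phi)
    srs <- stats::setNames(mm$response, paste0("sr_", mm$ses))
    c(rep = r, seed = rep_seed, n = nrow(sub),
      p_omnibus = wald$p[wald$term == "ses"],
      contrast_estimate = wb$estimate, contrast_p = wb$p_raw,
      mean_family_sr = mean(sub$n_males / sub$n_total),
      srs)
  }

  per_rep <- vector("list", n_reps)
  failed <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch(one_rep(r), error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else per_rep[[r]] <- res
  }
  per_rep <- as.data.frame(do.call(rbind, per_rep))
  if (!nrow(per_rep))
    stop("all replicates failed", call. = FALSE)
  med_sr <- vapply(paste0("sr_", SES_LEVELS4),
                   function(cn) stats::median(per_rep[[cn]]), numeric(1))
  out <- list(level = level, region = region, n_reps = n_reps,
              n_failed = failed, per_rep = per_rep,
              median_p_omnibus = stats::median(per_rep$p_omnibus),
              median_contrast_p = stats::median(per_rep$contrast_p),
              median_contrast_estimate =
                stats::median(per_rep$contrast_estimate),
              frac_contrast_significant = mean(per_rep$contrast_p < 0.05),
              median_predicted_sr = med_sr,
              mean_subset_sr = mean(per_rep$mean_family_sr),
              seed = seed)
  class(out) <- "resampling_summary"
  out
}

#' @export
print.resampling_summary <- function(x, ...) {
  cat(sprintf(
    "sex-ratio resampling (%s, %s): %d replicates (%d failed)\n",
    x$region, x$level, x$n_reps, x$n_failed))
  cat(sprintf("  median omnibus SES p: %.3f\n", x$median_p_omnibus))
  cat(sprintf("  median 'worse'-'better' contrast: %.3f (median p %.3f, %d%% significant)\n",
              x$median_contrast_estimate, x$median_contrast_p,
              round(100 * x$frac_contrast_significant)))
  cat("  median predicted sex ratio by SES:\n")
  print(round(x$median_predicted_sr, 3))
  invisible(x)
}

#' Render a selection report as a fixed-width flow chart
#'
#' One row per exclusion step plus a conservation footer (total removed =
#' first `n_before` minus last `n_after`).
#'
#' @param report a `selection_report`.
#' @return character scalar of fixed-width text.
#' @export
render_flowchart <- function(report) {
  unit <- attr(report, "unit")
  if (is.null(unit)) unit <- "records"
  header <- sprintf("%-4s %-34s %9s %9s %9s", "step", "criterion",
                    "n_before", "removed", "n_after")
  lines <- c(header, strrep("-", nchar(header)))
  for (i in seq_len(nrow(report))) {
    lines <- c(lines, sprintf("%-4d %-34s %9d %9d %9d", report$step[i],
                              substr(report$name[i], 1, 34),
                              report$n_before[i], report$n_removed[i],
                              report$n_after[i]))
  }
  total <- if (nrow(report))
    report$n_before[1] - report$n_after[nrow(report)] else 0L
  lines <- c(lines, strrep("-", nchar(header)),
             sprintf("total %s removed: %d", unit, total))
  paste(lines, collapse = "\n")
}

#' Parse a rendered flow chart back into a selection report
#'
#' Inverse of [render_flowchart()] for the numeric fields and step names.
#'
#' @param text output of [render_flowchart()].
#' @return `selection_report` (criterion text truncated to the rendered
#'   width).
#' @export
parse_flowchart <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  unit <- sub("^total (\\w+) removed.*$", "\\1", lines[length(lines)])
  body <- lines[grepl("^\\d+ ", lines)]
  rep <- new_selection_report(unit)
  for (ln in body) {
    ## fixed-width fields of "%-4d %-34s %9d %9d %9d"
    nb <- as.integer(substr(ln, 41, 49))
    na_ <- as.integer(substr(ln, 61, 69))
    name <- trimws(substr(ln, 6, 39))
    rep <- add_step(rep, name, name, nb, na_)
  }
  rep
}
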