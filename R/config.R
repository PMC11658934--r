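#' @keywords internal
"_PACKAGE"

## Settlement categories used throughout (Hungarian census-style classes).
SETTLEMENT_LEVELS <- c("village", "small_town", "medium_town", "large_town",
                       "budapest")

## Analysis labels for the four merged childhood-status levels.
SES_LEVELS4 <- c("worst", "worse", "average", "better")

#' Generator configuration for synthetic questionnaire populations
#'
#' Builds and validates the parameter set governing [generate_population()].
#' Defaults describe a population resembling the sampling frame of a
#' retrospective online family survey: small full-sibling families (mostly
#' 2-3 children), a 1-5 ordinal childhood living-standard scale with few
#' families at the extremes, a strongly female-biased response process, and
#' no socioeconomic effect on offspring sex (the null world).
#'
#' @param n_families number of families to emit. A family is emitted only
#'   when at least one of its siblings responds to the survey, so the
#'   generator draws candidate families until `n_families` have at least one
#'   respondent.
#' @param family_size_probs probability vector over family sizes 2..6
#'   (number of full siblings including the respondent).
#' @param ses_probs probability vector over initial childhood
#'   socioeconomic-status (SES) levels 1..5.
#' @param sex_alpha log-odds intercept of a male birth.
#' @param sex_beta_ses log-odds slope of a male birth per SES unit, SES
#'   centred at level 3. `sex_alpha = 0, sex_beta_ses = 0` gives unbiased
#'   coin-flip sexes.
#' @param birth_gap_probs probability vector over between-birth gaps 1..8
#'   years.
#' @param p_financial_change_per_interval probability that the family's
#'   financial situation changes substantially between two consecutive
#'   births.
#' @param ses_shift_on_change integer in -2..2: SES shift applied at a
#'   financial-change event, clamped to the 1..5 scale.
#' @param children_coefs named list `b0`, `b_sex_male`, `b_ses_linear`,
#'   `b_interaction`, `b_nsibs`, `settlement_effects` (length 5) on the log
#'   scale of the Poisson mean number of children.
#' @param p_respond_female,p_respond_male per-sibling response
#'   probabilities by sex; the female excess emulates the usual online
#'   survey pattern.
#' @param p_code_shared probability that all respondents of a family share
#'   the explicit family code.
#' @param p_code_error per-respondent probability that a shared code is
#'   corrupted into another family's code.
#' @param p_foreign_born probability that a family is a migrant family
#'   with a foreign episode: an arrival index is drawn uniformly and all
#'   earlier-born siblings were born abroad.
#' @param p_missing_residence probability mass governing missing residence
#'   answers.
#' @param p_identical_twin_family probability that a family contains one
#'   identical (same-sex, same birth year) twin pair.
#' @param abortion list `p_abortion_base` (log-odds that a respondent's
#'   reproduction was affected by induced abortion at SES 3) and
#'   `abortion_ses_slope` (log-odds per SES unit).
#' @param first_birth_year_range integer interval for the first sibling's
#'   birth year.
#' @param fill_year calendar year the questionnaire is filled out.
#' @param settlement_probs probability vector over the five settlement
#'   types.
#' @param p_settlement_mismatch per-sibling probability that the recorded
#'   childhood settlement differs from (or is missing relative to) the
#'   family's, emulating reporting inconsistencies.
#' @param p_foetus probability that a respondent reports a foetus of
#'   unknown sex.
#' @param seed integer seed; all randomness flows from it via per-family
#'   substreams.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_families = 500,
                             family_size_probs = c(0.55, 0.30, 0.10, 0.04, 0.01),
                             ses_probs = c(0.07, 0.25, 0.47, 0.19, 0.02),
                             sex_alpha = 0,
                             sex_beta_ses = 0,
                             birth_gap_probs = c(0.10, 0.25, 0.25, 0.15,
                                                 0.10, 0.07, 0.05, 0.03),
                             p_financial_change_per_interval = 0.15,
                             ses_shift_on_change = 1L,
                             children_coefs = list(
                               b0 = log(2.1), b_sex_male = 0,
                               b_ses_linear = 0.03, b_interaction = 0,
                               b_nsibs = 0.03,
                               settlement_effects = c(-0.05, 0, 0, 0, 0.05)),
                             p_respond_female = 0.15,
                             p_respond_male = 0.035,
                             p_code_shared = 0.15,
                             p_code_error = 0.01,
                             p_foreign_born = 0.045,
                             p_missing_residence = 0.03,
                             p_identical_twin_family = 0.009,
                             abortion = list(p_abortion_base = -0.75,
                                             abortion_ses_slope = 0),
                             first_birth_year_range = c(1940L, 1975L),
                             fill_year = 2020L,
                             settlement_probs = rep(0.2, 5),
                             p_settlement_mismatch = 0.04,
                             p_foetus = 0.003,
                             seed = 1L) {
  cfg <- list(n_families = n_families,
              family_size_probs = family_size_probs,
              ses_probs = ses_probs,
              sex_alpha = sex_alpha,
              sex_beta_ses = sex_beta_ses,
              birth_gap_probs = birth_gap_probs,
              p_financial_change_per_interval = p_financial_change_per_interval,
              ses_shift_on_change = as.integer(ses_shift_on_change),
              children_coefs = children_coefs,
              p_respond_female = p_respond_female,
              p_respond_male = p_respond_male,
              p_code_shared = p_code_shared,
              p_code_error = p_code_error,
              p_foreign_born = p_foreign_born,
              p_missing_residence = p_missing_residence,
              p_identical_twin_family = p_identical_twin_family,
              abortion = abortion,
              first_birth_year_range = as.integer(first_birth_year_range),
              fill_year = as.integer(fill_year),
              settlement_probs = settlement_probs,
              p_settlement_mismatch = p_settlement_mismatch,
              p_foetus = p_foetus,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_generator_config <- function(cfg) {
  chk_probvec <- function(field, len) {
    p <- cfg[[field]]
    if (!is.numeric(p) || length(p) != len)
      config_error(field, sprintf("must be a numeric vector of length %d", len))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      config_error(field, "must be nonnegative and sum to 1 (tol 1e-12)")
  }
  chk_prob <- function(field, value = cfg[[field]]) {
    if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
        value < 0 || value > 1)
      config_error(field, "must be a probability in [0, 1]")
  }
  if (!is.numeric(cfg$n_families) || length(cfg$n_families) != 1 ||
      is.na(cfg$n_families) || cfg$n_families < 1)
    config_error("n_families", "must be a positive integer")
  chk_probvec("family_size_probs", 5)
  chk_probvec("ses_probs", 5)
  chk_probvec("birth_gap_probs", 8)
  chk_probvec("settlement_probs", 5)
  for (f in c("p_financial_change_per_interval", "p_respond_female",
              "p_respond_male", "p_code_shared", "p_code_error",
              "p_foreign_born", "p_missing_residence",
              "p_identical_twin_family", "p_settlement_mismatch", "p_foetus"))
    chk_prob(f)
  if (!cfg$ses_shift_on_change %in% -2:2)
    config_error("ses_shift_on_change", "must be an integer in -2..2")
  cc <- cfg$children_coefs
  need <- c("b0", "b_sex_male", "b_ses_linear", "b_interaction", "b_nsibs",
            "settlement_effects")
  if (!is.list(cc) || !all(need %in% names(cc)))
    config_error("children_coefs",
                 paste("must contain", paste(need, collapse = ", ")))
  if (length(cc$settlement_effects) != 5 ||
      any(!is.finite(cc$settlement_effects)))
    config_error("children_coefs",
                 "settlement_effects must be 5 finite numbers")
  if (!all(vapply(cc[setdiff(need, "settlement_effects")],
                  function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    config_error("children_coefs", "entries must be finite scalars")
  ab <- cfg$abortion
  if (!is.list(ab) || !all(c("p_abortion_base", "abortion_ses_slope")
                           %in% names(ab)))
    config_error("abortion",
                 "must contain p_abortion_base and abortion_ses_slope")
  if (length(cfg$first_birth_year_range) != 2 ||
      diff(cfg$first_birth_year_range) < 0)
    config_error("first_birth_year_range",
                 "must be a nondecreasing integer interval")
  if (!is.finite(cfg$sex_alpha) || !is.finite(cfg$sex_beta_ses))
    config_error("sex_alpha/sex_beta_ses", "must be finite")
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' Top-level YAML keys are passed straight to [generator_config()]; absent
#' keys keep their defaults.
#'
#' @param path YAML file path.
#' @return `generator_config` object.
#' @export
generator_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    config_error(unknown[1], "is not a recognised configuration field")
  do.call(generator_config, raw)
}

## Deterministic 31-bit substream seed for unit `k` under base seed `base`.
derive_seed <- function(base, k) {
  as.integer((abs(as.numeric(base)) %% 100000) * 20011 +
               as.numeric(k) * 7919 + 1) %% 2147483647L
}
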