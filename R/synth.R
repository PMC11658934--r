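#' Sample offspring sex under a logistic status model
#'
#' Returns `"M"` with probability `plogis(alpha + beta * (ses_level - 3))`,
#' i.e. the status effect is centred at the middle of the 1-5 scale.
#'
#' @param ses_level integer vector with values in 1..5.
#' @param alpha log-odds intercept of a male birth.
#' @param beta log-odds slope per SES unit.
#' @return character vector of `"M"`/`"F"`, one draw per element of
#'   `ses_level`, drawn from the current RNG stream.
#' @export
sample_offspring_sex <- function(ses_level, alpha = 0, beta = 0) {
  if (any(is.na(ses_level)) || any(ses_level != round(ses_level)) ||
      any(ses_level < 1) || any(ses_level > 5))
    stop("ses_level must be an integer in 1..5", call. = FALSE)
  p <- stats::plogis(alpha + beta * (ses_level - 3))
  ifelse(stats::runif(length(ses_level)) < p, "M", "F")
}

#' Sample a number of children from a log-linear Poisson model
#'
#' The Poisson mean is `exp(b0 + b_sex_male*[male] + b_ses_linear*(ses-3) +
#' b_interaction*[male]*(ses-3) + b_nsibs*n_sibs + settlement_effect)`.
#' All arguments are recycled to a common length.
#'
#' @param sex character `"M"`/`"F"`.
#' @param ses_level integer 1..5.
#' @param n_sibs number of siblings (family size minus one).
#' @param settlement settlement category, one of
#'   `village, small_town, medium_town, large_town, budapest`.
#' @param coefs coefficient list as in [generator_config()]'s
#'   `children_coefs`.
#' @return integer vector of children counts.
#' @export
sample_children_count <- function(sex, ses_level, n_sibs, settlement, coefs) {
  sidx <- match(settlement, SETTLEMENT_LEVELS)
  if (any(is.na(sidx))) stop("unknown settlement category", call. = FALSE)
  male <- as.numeric(sex == "M")
  lp <- coefs$b0 + coefs$b_sex_male * male +
    coefs$b_ses_linear * (ses_level - 3) +
    coefs$b_interaction * male * (ses_level - 3) +
    coefs$b_nsibs * n_sibs +
    coefs$settlement_effects[sidx]
  if (any(!is.finite(lp)))
    stop("non-finite linear predictor in children-count model", call. = FALSE)
  stats::rpois(length(lp), exp(lp))
}

#' Generate a synthetic questionnaire population
#'
#' Simulates families of full siblings with birth years, sexes, an ordinal
#' childhood living-standard (SES) trajectory that may shift at
#' financial-change events between births, per-sibling children counts, and
#' a sex-biased survey response process. Only families with at least one
#' respondent are emitted (families nobody responded from are never
#' observed by a survey), and candidate families are drawn until
#' `config$n_families` such families exist. Every respondent contributes a
#' full roster of their family; respondents of the same family may share an
#' explicit family code, occasionally corrupted.
#'
#' Randomness is fully determined by `config$seed`: candidate family `k`
#' uses the substream seed `derive_seed(seed, k)`, so the same
#' configuration always yields byte-identical tables.
#'
#' @param config a [generator_config()] object.
#' @return list with elements `respondents` (one row per respondent),
#'   `rosters` (one row per sibling per respondent) and `truth` (a
#'   `truth_table`: respondent-to-family map, per-family parameters, and
#'   the configuration echo).
#' @export
generate_population <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, unclass(config))
  validate_generator_config(config)
  n_target <- as.integer(config$n_families)
  cc <- config$children_coefs

  resp_acc <- vector("list", n_target)
  rost_acc <- vector("list", n_target)
  fam_acc <- vector("list", n_target)
  emitted <- 0L
  rid <- 0L
  k <- 0L
  max_attempts <- 200L * n_target + 1000L

  while (emitted < n_target) {
    k <- k + 1L
    if (k > max_attempts)
      stop("generate_population: response probabilities too low to emit ",
           n_target, " families", call. = FALSE)
    set.seed(derive_seed(config$seed, k))

    size <- sample.int(5L, 1L, prob = config$family_size_probs) + 1L
    ses0 <- sample.int(5L, 1L, prob = config$ses_probs)
    settlement <- SETTLEMENT_LEVELS[sample.int(5L, 1L,
                                               prob = config$settlement_probs)]
    by1 <- sample(config$first_birth_year_range[1]:
                    config$first_birth_year_range[2], 1L)
    gaps <- sample.int(8L, size - 1L, replace = TRUE,
                       prob = config$birth_gap_probs)
    fin_change <- stats::rbinom(size - 1L, 1L,
                                config$p_financial_change_per_interval)

    twin_pos <- 0L
    if (stats::runif(1) < config$p_identical_twin_family) {
      twin_pos <- sample.int(size - 1L, 1L)  # twins at positions twin_pos,+1
      gaps[twin_pos] <- 0L
      fin_change[twin_pos] <- 0L
    }

    birth_years <- by1 + c(0L, cumsum(gaps))
    ses_traj <- ses0
    for (j in seq_len(size - 1L)) {
      nxt <- ses_traj[j]
      if (fin_change[j] == 1L)
        nxt <- min(5L, max(1L, nxt + config$ses_shift_on_change))
      ses_traj <- c(ses_traj, nxt)
    }

    sexes <- sample_offspring_sex(ses_traj, config$sex_alpha,
                                  config$sex_beta_ses)
    if (twin_pos > 0L) sexes[twin_pos + 1L] <- sexes[twin_pos]
    ## foreign birth is a family episode: a migrant family arrives before
    ## the birth of sibling a+1, so siblings 1..a were born abroad
    born_hu <- rep(1L, size)
    if (stats::runif(1) < config$p_foreign_born) {
      arrival <- sample.int(size, 1L)
      born_hu[seq_len(arrival)] <- 0L
    }

    sib_settlement <- rep(settlement, size)
    mis <- stats::runif(size) < config$p_settlement_mismatch
    if (any(mis)) {
      for (j in which(mis)) {
        sib_settlement[j] <- if (stats::runif(1) < 0.5) NA_character_ else
          SETTLEMENT_LEVELS[sample.int(5L, 1L)]
      }
    }

    n_child <- sample_children_count(sexes, ses_traj, size - 1L,
                                     rep(settlement, size), cc)

    p_resp <- ifelse(sexes == "M", config$p_respond_male,
                     config$p_respond_female)
    responds <- stats::runif(size) < p_resp
    if (!any(responds)) next
    emitted <- emitted + 1L
    fam_id <- sprintf("FAM%06d", k)
    has_code <- stats::runif(1) < config$p_code_shared
    code <- if (has_code) sprintf("F%06d", k) else NA_character_

    ridx <- which(responds)
    nresp <- length(ridx)
    r_ids <- sprintf("R%06d", rid + seq_len(nresp))
    rid <- rid + nresp

    ## respondent-level answers
    ses_child <- ses_traj[ridx]
    n_foetus <- stats::rbinom(nresp, 1L, config$p_foetus)
    n_live <- n_child[ridx]
    n_sons <- stats::rbinom(nresp, n_live, 0.5)
    p_affected <- stats::plogis(config$abortion$p_abortion_base +
                                  config$abortion$abortion_ses_slope *
                                  (ses_child - 3))
    abortion_free <- ifelse(stats::runif(nresp) < 0.04, NA,
                            stats::runif(nresp) >= p_affected)
    wants_more <- sample(c("yes", "no", NA_character_), nresp, replace = TRUE,
                         prob = c(0.05, 0.90, 0.05))
    stable <- sample(c("yes", "no", NA_character_), nresp, replace = TRUE,
                     prob = c(0.70, 0.20, 0.10))
    u_cc <- stats::runif(nresp)
    current_country <- ifelse(u_cc < config$p_missing_residence / 2,
                              NA_character_,
                              ifelse(u_cc < config$p_missing_residence / 2 +
                                       0.02, "other", "hungary"))
    cur_set <- sib_settlement[ridx]
    move <- stats::runif(nresp) < 0.3
    cur_set[move] <- SETTLEMENT_LEVELS[sample.int(5L, sum(move),
                                                  replace = TRUE)]
    cur_set[stats::runif(nresp) < config$p_missing_residence / 2] <-
      NA_character_

    codes <- rep(code, nresp)
    if (has_code && config$p_code_error > 0) {
      bad <- stats::runif(nresp) < config$p_code_error
      if (any(bad)) {
        wrong <- k + sample(c(-(1:50), 1:50), sum(bad), replace = TRUE)
        codes[bad] <- sprintf("F%06d", pmax(1L, wrong))
      }
    }

    resp_acc[[emitted]] <- list(
      respondent_id = r_ids,
      family_code = codes,
      sex = sexes[ridx],
      birth_year = birth_years[ridx],
      fill_year = rep(config$fill_year, nresp),
      country_of_birth = ifelse(born_hu[ridx] == 1L, "hungary", "other"),
      childhood_settlement = sib_settlement[ridx],
      current_country = current_country,
      current_settlement = cur_set,
      childhood_ses = ses_child,
      n_children = n_live + n_foetus,
      n_sons = n_sons,
      n_daughters = n_live - n_sons,
      n_foetus_unknown = n_foetus,
      wants_more = wants_more,
      stable_partner_10y = stable,
      abortion_free = abortion_free)

    twin_flag <- integer(size)
    if (twin_pos > 0L) twin_flag[c(twin_pos, twin_pos + 1L)] <- 1L
    fc_before <- c(NA_integer_, fin_change)
    rost_acc[[emitted]] <- list(
      respondent_id = rep(r_ids, each = size),
      position = rep(seq_len(size), nresp),
      sex = rep(sexes, nresp),
      birth_year = rep(birth_years, nresp),
      is_respondent = as.integer(rep(seq_len(size), nresp) ==
                                   rep(ridx, each = size)),
      is_identical_twin = rep(twin_flag, nresp),
      born_in_hungary = rep(born_hu, nresp),
      childhood_settlement = rep(sib_settlement, nresp),
      financial_change_before = rep(fc_before, nresp),
      n_children = rep(n_child, nresp))

    fam_acc[[emitted]] <- list(
      family_id = fam_id, size = size,
      ses_trajectory = paste(ses_traj, collapse = ","),
      settlement = settlement,
      respondent_ids = list(r_ids))
  }

  respondents <- as.data.frame(data.table::rbindlist(resp_acc))
  rosters <- as.data.frame(data.table::rbindlist(rost_acc))
  fam_sizes <- vapply(fam_acc, function(f) length(f$respondent_ids[[1]]),
                      integer(1))
  truth <- list(
    respondent_to_family = data.frame(
      respondent_id = respondents$respondent_id,
      family_id = rep(vapply(fam_acc, `[[`, character(1), "family_id"),
                      fam_sizes),
      stringsAsFactors = FALSE),
    families = data.frame(
      family_id = vapply(fam_acc, `[[`, character(1), "family_id"),
      size = vapply(fam_acc, `[[`, integer(1), "size"),
      ses_trajectory = vapply(fam_acc, `[[`, character(1), "ses_trajectory"),
      settlement = vapply(fam_acc, `[[`, character(1), "settlement"),
      stringsAsFactors = FALSE),
    config = config)
  class(truth) <- "truth_table"

  stopifnot(!anyDuplicated(truth$respondent_to_family$respondent_id))
  list(respondents = respondents, rosters = rosters, truth = truth)
}

#' Perturb reported fields with random noise
#'
#' Emulates the reporting inconsistencies of real survey data that degrade
#' exact-key record linkage. Each targeted field of each row is perturbed
#' independently with probability `noise_rate_per_field`:
#' \describe{
#'   \item{birth_year}{shifted by plus or minus one year (roster entries and
#'     respondent records).}
#'   \item{n_children}{shifted by plus or minus one, truncated at zero.}
#'   \item{birthplace}{childhood settlement resampled uniformly.}
#'   \item{family_size}{one random non-respondent entry dropped from the
#'     respondent's roster.}
#' }
#' Inputs are not modified; new tables are returned.
#'
#' @param tables list with `respondents` and `rosters` tables.
#' @param noise_rate_per_field probability in `[0, 1]`.
#' @param fields subset of `c("birth_year", "n_children", "family_size",
#'   "birthplace")`.
#' @param seed optional integer; if given, a local seed is used.
#' @return list with perturbed `respondents` and `rosters`.
#' @export
inject_reporting_noise <- function(tables, noise_rate_per_field,
                                   fields = c("birth_year", "n_children",
                                              "family_size", "birthplace"),
                                   seed = NULL) {
  allowed <- c("birth_year", "n_children", "family_size", "birthplace")
  bad <- setdiff(fields, allowed)
  if (length(bad))
    stop("unknown noise field: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.numeric(noise_rate_per_field) || noise_rate_per_field < 0 ||
      noise_rate_per_field > 1)
    stop("noise_rate_per_field must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rate <- noise_rate_per_field
  resp <- tables$respondents
  rost <- tables$rosters
  flip <- function(n) stats::runif(n) < rate
  pm1 <- function(n) ifelse(stats::runif(n) < 0.5, -1L, 1L)

  if ("birth_year" %in% fields) {
    hit <- flip(nrow(rost))
    rost$birth_year[hit] <- rost$birth_year[hit] + pm1(sum(hit))
    hit <- flip(nrow(resp))
    resp$birth_year[hit] <- resp$birth_year[hit] + pm1(sum(hit))
  }
  if ("n_children" %in% fields) {
    hit <- flip(nrow(rost))
    rost$n_children[hit] <- pmax(0L, rost$n_children[hit] + pm1(sum(hit)))
    hit <- flip(nrow(resp))
    resp$n_children[hit] <- pmax(0L, resp$n_children[hit] + pm1(sum(hit)))
  }
  if ("birthplace" %in% fields) {
    hit <- flip(nrow(rost))
    rost$childhood_settlement[hit] <-
      SETTLEMENT_LEVELS[sample.int(5L, sum(hit), replace = TRUE)]
    hit <- flip(nrow(resp))
    resp$childhood_settlement[hit] <-
      SETTLEMENT_LEVELS[sample.int(5L, sum(hit), replace = TRUE)]
  }
  if ("family_size" %in% fields) {
    ids <- unique(rost$respondent_id)
    hit_ids <- ids[flip(length(ids))]
    if (length(hit_ids)) {
      drop_idx <- integer(0)
      for (id in hit_ids) {
        rows <- which(rost$respondent_id == id & rost$is_respondent == 0L)
        if (length(rows))
          drop_idx <- c(drop_idx, rows[sample.int(length(rows), 1L)])
      }
      if (length(drop_idx)) rost <- rost[-drop_idx, , drop = FALSE]
    }
  }
  list(respondents = resp, rosters = rost)
}

#' Write a generated population to disk
#'
#' Writes `respondents.csv`, `rosters.csv` and `truth.json` under `dir`.
#'
#' @param population result of [generate_population()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(population$respondents,
                   file.path(dir, "respondents.csv"), row.names = FALSE)
  utils::write.csv(population$rosters,
                   file.path(dir, "rosters.csv"), row.names = FALSE)
  tt <- population$truth
  jsonlite::write_json(
    list(respondent_to_family = tt$respondent_to_family,
         families = tt$families,
         config = unclass(tt$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read a truth table written by [write_population()]
#'
#' @param path path to `truth.json`.
#' @return `truth_table` object.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- list(respondent_to_family = raw$respondent_to_family,
                families = raw$families,
                config = raw$config)
  class(truth) <- "truth_table"
  truth
}
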