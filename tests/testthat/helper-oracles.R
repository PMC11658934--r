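## Independent oracles used to derive expected values.  These deliberately
## avoid the package's own code paths.

## Newton-Raphson maximization of the Poisson log-likelihood with log link.
oracle_newton_poisson <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta))
    grad <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * mu)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

## Newton-Raphson for the binomial logit log-likelihood (y successes of m).
oracle_newton_binomial <- function(X, y, m, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- plogis(drop(X %*% beta))
    grad <- drop(t(X) %*% (y - m * p))
    H <- t(X) %*% (X * (m * p * (1 - p)))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

## Exhaustive subunit oracle: enumerate every contiguous run that is valid
## (all internal boundaries have gap <= max_gap, an explicit 0 change flag)
## and keep the maximal ones.  Returns a list of integer index vectors.
oracle_subunits <- function(birth_years, change_flags, max_gap = 5) {
  n <- length(birth_years)
  boundary_ok <- function(t) {  # boundary between t-1 and t (t >= 2)
    !is.na(change_flags[t]) && change_flags[t] == 0 &&
      (birth_years[t] - birth_years[t - 1]) <= max_gap
  }
  valid <- function(i, j) {
    if (i == j) return(TRUE)
    all(vapply((i + 1):j, boundary_ok, logical(1)))
  }
  runs <- list()
  for (i in 1:n) for (j in i:n) if (valid(i, j)) {
    runs <- c(runs, list(i:j))
  }
  is_maximal <- vapply(seq_along(runs), function(a) {
    ra <- runs[[a]]
    !any(vapply(seq_along(runs), function(b) {
      b != a && all(ra %in% runs[[b]])
    }, logical(1)))
  }, logical(1))
  runs[is_maximal]
}

## Small deterministic roster builder for sexratio/cohort tests.
make_roster <- function(birth_years, sexes = NULL, changes = NULL,
                        respondent_pos = 1L, id = "R1",
                        settlement = "budapest", twins = NULL) {
  n <- length(birth_years)
  if (is.null(sexes)) sexes <- rep("F", n)
  if (is.null(changes)) changes <- c(NA, rep(0L, n - 1))
  tw <- integer(n)
  if (!is.null(twins)) tw[twins] <- 1L
  data.frame(respondent_id = id, position = seq_len(n), sex = sexes,
             birth_year = birth_years,
             is_respondent = as.integer(seq_len(n) == respondent_pos),
             is_identical_twin = tw, born_in_hungary = 1L,
             childhood_settlement = settlement,
             financial_change_before = changes,
             n_children = rep(2L, n), stringsAsFactors = FALSE)
}

## A minimal respondent row compatible with the cohort builders.
make_respondent <- function(id, sex = "F", birth_year = 1960,
                            fill_year = 2020, code = NA_character_,
                            country = "hungary", settlement = "budapest",
                            cur_country = "hungary",
                            cur_settlement = "budapest", ses = 3L,
                            n_children = 2L, n_sons = 1L, n_daughters = 1L,
                            n_foetus = 0L, wants_more = "no",
                            stable = "yes", abortion_free = TRUE) {
  data.frame(respondent_id = id, family_code = code, sex = sex,
             birth_year = birth_year, fill_year = fill_year,
             country_of_birth = country, childhood_settlement = settlement,
             current_country = cur_country,
             current_settlement = cur_settlement, childhood_ses = ses,
             n_children = n_children, n_sons = n_sons,
             n_daughters = n_daughters, n_foetus_unknown = n_foetus,
             wants_more = wants_more, stable_partner_10y = stable,
             abortion_free = abortion_free, stringsAsFactors = FALSE)
}

## Two-respondent family fixture (reciprocal rosters, all keys equal).
make_family_pair <- function(id1 = "A", id2 = "B", code = NA_character_,
                             birth_years = c(1960, 1963),
                             sexes = c("F", "M"), settlement = "budapest",
                             children = c(2L, 1L)) {
  r1 <- make_respondent(id1, sex = sexes[1], birth_year = birth_years[1],
                        settlement = settlement,
                        n_children = children[1],
                        n_sons = children[1], n_daughters = 0L, code = code)
  r2 <- make_respondent(id2, sex = sexes[2], birth_year = birth_years[2],
                        settlement = settlement,
                        n_children = children[2],
                        n_sons = children[2], n_daughters = 0L, code = code)
  ro1 <- make_roster(birth_years, sexes, respondent_pos = 1L, id = id1,
                     settlement = settlement)
  ro2 <- make_roster(birth_years, sexes, respondent_pos = 2L, id = id2,
                     settlement = settlement)
  ro1$n_children <- children
  ro2$n_children <- children
  list(respondents = rbind(r1, r2), rosters = rbind(ro1, ro2))
}

## Clean-key generator configuration (within-family heterogeneity off),
## the world in which exact-key linkage is exact.
clean_config <- function(n_families, seed, ...) {
  generator_config(n_families = n_families, seed = seed,
                   p_foreign_born = 0, p_settlement_mismatch = 0, ...)
}
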