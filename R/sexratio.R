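#' Family sex ratio
#'
#' Number of male siblings divided by the number of all siblings in the
#' family; the respondent's own entry counts.
#'
#' @param roster one respondent's roster (all full siblings including the
#'   respondent), with columns `sex` and `birth_year`.
#' @return list `n_males`, `n_total`, `sex_ratio`.
#' @export
family_sex_ratio <- function(roster) {
  if (nrow(roster) < 1) stop("empty roster", call. = FALSE)
  if (!all(roster$sex %in% c("M", "F")))
    stop("unknown sex code in roster", call. = FALSE)
  n_males <- sum(roster$sex == "M")
  list(n_males = n_males, n_total = nrow(roster),
       sex_ratio = n_males / nrow(roster))
}

#' Extract family subunits
#'
#' A family subunit is a maximal run of birth-ordered siblings in which the
#' age gap between successive siblings is at most 5 years and the family's
#' financial situation did not change substantially between their births.
#' The birth-ordered roster is split at every boundary where the gap to the
#' previous sibling exceeds 5 years or a financial change was reported
#' before that birth; a missing change flag (positions 2 and later) is
#' treated as a split, conservatively.
#'
#' @param roster one respondent's roster, sorted by birth order, with
#'   columns `sex`, `birth_year`, `is_respondent`,
#'   `financial_change_before`.
#' @param max_gap largest between-birth gap (years) kept within a subunit;
#'   a gap of exactly `max_gap` does not split.
#' @param quiet suppress the message emitted when missing change flags
#'   force splits.
#' @return list of subunits, each a list with `member_positions` (row
#'   indices into the birth-ordered roster), `n_males`, `n_total`,
#'   `contains_respondent`, `sex_ratio`.
#' @export
extract_subunits <- function(roster, max_gap = 5, quiet = FALSE) {
  n <- nrow(roster)
  if (n < 1) stop("empty roster", call. = FALSE)
  if (is.unsorted(roster$birth_year))
    stop("roster must be sorted by birth year", call. = FALSE)
  split_before <- logical(n)  # split between sibling j-1 and j
  if (n > 1) {
    gaps <- diff(roster$birth_year)
    fc <- roster$financial_change_before[-1]
    na_fc <- is.na(fc)
    if (any(na_fc) && !quiet)
      message("extract_subunits: ", sum(na_fc),
              " missing financial-change flag(s) treated as splits")
    split_before[-1] <- gaps > max_gap | na_fc | fc == 1
  }
  run_id <- cumsum(split_before) + 1L
  lapply(split(seq_len(n), run_id), function(idx) {
    list(member_positions = idx,
         n_males = sum(roster$sex[idx] == "M"),
         n_total = length(idx),
         contains_respondent = any(roster$is_respondent[idx] == 1L),
         sex_ratio = sum(roster$sex[idx] == "M") / length(idx))
  })
}

#' Select the analysis subunit
#'
#' Among the subunits containing a respondent, returns the largest; size
#' ties are broken uniformly at random with the current RNG stream.
#'
#' @param subunits result of [extract_subunits()].
#' @return a single subunit.
#' @export
select_analysis_subunit <- function(subunits) {
  with_resp <- Filter(function(s) isTRUE(s$contains_respondent), subunits)
  if (!length(with_resp))
    stop("no subunit contains a respondent", call. = FALSE)
  sizes <- vapply(with_resp, `[[`, numeric(1), "n_total")
  best <- which(sizes == max(sizes))
  pick <- if (length(best) == 1) best else
    best[sample.int(length(best), 1L)]
  with_resp[[pick]]
}
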