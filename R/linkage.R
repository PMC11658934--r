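## Per-respondent matching keys, precomputed once.
## A key bundle holds: family size, the sorted (birth_year, sex) multiset,
## the birthplace (country + settlement), the respondent's own (birth_year,
## sex), the live-children count they report for themselves, and the full
## roster needed for cross children checks.
linkage_keys <- function(respondents, rosters) {
  ids <- respondents$respondent_id
  if (anyDuplicated(ids))
    stop("duplicate respondent_id in respondents table", call. = FALSE)
  rost_split <- split(rosters[, c("sex", "birth_year", "n_children")],
                      rosters$respondent_id)
  missing <- setdiff(ids, names(rost_split))
  if (length(missing))
    stop("missing roster for respondent(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  keys <- vector("list", length(ids))
  names(keys) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    ro <- rost_split[[id]]
    ord <- order(ro$birth_year, ro$sex, ro$n_children)
    ro <- ro[ord, , drop = FALSE]
    keys[[i]] <- list(
      size = nrow(ro),
      bysex = paste(ro$birth_year, ro$sex, sep = "/", collapse = ";"),
      birthplace = paste(respondents$country_of_birth[i],
                         respondents$childhood_settlement[i], sep = "|"),
      birthplace_known = !is.na(respondents$childhood_settlement[i]) &&
        !is.na(respondents$country_of_birth[i]),
      own_by = respondents$birth_year[i],
      own_sex = respondents$sex[i],
      own_live_children = respondents$n_children[i] -
        respondents$n_foetus_unknown[i],
      roster = ro)
  }
  keys
}

## TRUE iff respondent `a`'s own (birth_year, sex) appears in roster `b_ro`
## and the children count recorded there matches a's own live-children
## report (any matching slot may satisfy it).
cross_children_ok <- function(a, b_ro) {
  slots <- which(b_ro$birth_year == a$own_by & b_ro$sex == a$own_sex)
  length(slots) > 0 && a$own_live_children %in% b_ro$n_children[slots]
}

## Full Stage-2 pairwise key correspondence.
pair_matches <- function(a, b) {
  a$size == b$size &&
    a$bysex == b$bysex &&
    a$birthplace_known && b$birthplace_known &&
    a$birthplace == b$birthplace &&
    cross_children_ok(a, b$roster) &&
    cross_children_ok(b, a$roster)
}

## Stage-1 consistency of a code group: equal sizes, each member's own
## (birth_year, sex) present in every other member's roster, birthplaces
## agree.
code_group_consistent <- function(members, keys) {
  ks <- keys[members]
  sizes <- vapply(ks, `[[`, numeric(1), "size")
  if (length(unique(sizes)) > 1) return(FALSE)
  bps <- vapply(ks, `[[`, character(1), "birthplace")
  if (any(!vapply(ks, `[[`, logical(1), "birthplace_known"))) return(FALSE)
  if (length(unique(bps)) > 1) return(FALSE)
  for (a in seq_along(ks)) for (b in seq_along(ks)) {
    if (a == b) next
    ka <- ks[[a]]
    ro <- ks[[b]]$roster
    if (!any(ro$birth_year == ka$own_by & ro$sex == ka$own_sex))
      return(FALSE)
  }
  TRUE
}

#' Reconstruct families from questionnaire tables
#'
#' Two-stage family reconstruction. Stage 1 groups respondents sharing an
#' explicit family code, provided their reports are mutually consistent
#' (same family size, each member's own birth year and sex present in every
#' other member's roster, equal birthplaces); inconsistent code groups are
#' split, their members counted as code errors and passed on. Stage 2 links
#' the remaining respondents pairwise when all keys correspond: equal
#' number of siblings, identical (birth year, sex) roster multisets, equal
#' childhood birthplace (country and settlement type), and each one's
#' reported number of children (excluding foetuses of unknown sex) equal to
#' the children count the other's roster records for the matching sibling.
#' Links are transitive; a linked component is accepted only if every pair
#' in it matches (ambiguous, non-clique components are conservatively left
#' as singletons).
#'
#' @param respondents respondents table as produced by
#'   [generate_population()].
#' @param rosters rosters table.
#' @return object of class `family_assignment`: data frame `assignment`
#'   with columns `respondent_id`, `family_id`, `provenance` (one of
#'   `explicit_code`, `matched`, `singleton`), plus `n_code_errors`.
#' @export
assign_families <- function(respondents, rosters) {
  keys <- linkage_keys(respondents, rosters)
  ids <- respondents$respondent_id
  fam_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  prov <- stats::setNames(rep("singleton", length(ids)), ids)
  n_code_errors <- 0L
  next_fam <- 0L
  new_fam <- function() {
    next_fam <<- next_fam + 1L
    sprintf("L%05d", next_fam)
  }

  ## Stage 1: explicit codes
  coded <- ids[!is.na(respondents$family_code)]
  code_of <- stats::setNames(respondents$family_code, ids)
  stage2_pool <- ids[is.na(respondents$family_code)]
  for (code in unique(code_of[coded])) {
    members <- coded[code_of[coded] == code]
    if (length(members) < 2) {
      stage2_pool <- c(stage2_pool, members)
      next
    }
    if (code_group_consistent(members, keys)) {
      fid <- new_fam()
      fam_of[members] <- fid
      prov[members] <- "explicit_code"
    } else {
      n_code_errors <- n_code_errors + length(members)
      stage2_pool <- c(stage2_pool, members)
    }
  }

  ## Stage 2: attribute matching among the remaining respondents.
  ## Cheap blocking on (size, bysex multiset, birthplace) before the full
  ## pairwise check.
  pool <- stage2_pool
  if (length(pool) > 1) {
    block_key <- vapply(keys[pool], function(k)
      paste(k$size, k$bysex, k$birthplace, sep = "#"), character(1))
    blocks <- split(pool, block_key)
    for (blk in blocks) {
      if (length(blk) < 2) next
      m <- length(blk)
      adj <- matrix(FALSE, m, m)
      for (a in seq_len(m - 1)) for (b in (a + 1):m) {
        adj[a, b] <- adj[b, a] <- pair_matches(keys[[blk[a]]],
                                               keys[[blk[b]]])
      }
      ## connected components by BFS
      comp <- rep(0L, m)
      cid <- 0L
      for (s in seq_len(m)) {
        if (comp[s] > 0L || !any(adj[s, ])) next
        cid <- cid + 1L
        queue <- s
        comp[s] <- cid
        while (length(queue)) {
          v <- queue[1]
          queue <- queue[-1]
          nb <- which(adj[v, ] & comp == 0L)
          comp[nb] <- cid
          queue <- c(queue, nb)
        }
      }
      for (ci in seq_len(cid)) {
        mem <- which(comp == ci)
        if (length(mem) < 2) next
        is_clique <- all(adj[mem, mem][upper.tri(diag(length(mem)))])
        if (is_clique && length(mem) <= keys[[blk[mem[1]]]]$size) {
          fid <- new_fam()
          fam_of[blk[mem]] <- fid
          prov[blk[mem]] <- "matched"
        }
        ## non-clique (ambiguous): left unlinked
      }
    }
  }

  singles <- is.na(fam_of)
  fam_of[singles] <- vapply(seq_len(sum(singles)), function(i) new_fam(),
                            character(1))
  out <- list(assignment = data.frame(respondent_id = ids,
                                      family_id = unname(fam_of[ids]),
                                      provenance = unname(prov[ids]),
                                      stringsAsFactors = FALSE),
              n_code_errors = n_code_errors)
  class(out) <- "family_assignment"
  out
}

#' Treat the ground-truth family map as an assignment
#'
#' Useful for running downstream cohort construction directly on generator
#' output without the linkage step.
#'
#' @param truth a `truth_table`.
#' @return `family_assignment` with provenance `explicit_code`.
#' @export
truth_assignment <- function(truth) {
  map <- truth$respondent_to_family
  out <- list(assignment = data.frame(respondent_id = map$respondent_id,
                                      family_id = map$family_id,
                                      provenance = "explicit_code",
                                      stringsAsFactors = FALSE),
              n_code_errors = 0L)
  class(out) <- "family_assignment"
  out
}

#' Score a family assignment against ground truth
#'
#' Only multi-respondent families count: recall is the fraction of true
#' multi-respondent families whose member set is exactly reproduced by some
#' predicted family; precision is the fraction of predicted
#' multi-respondent families whose member set exactly matches a true
#' family. With no multi-respondent predictions, precision is `NA`.
#'
#' @param assignment a `family_assignment`.
#' @param truth a `truth_table` covering all assigned respondents.
#' @return list of class `linkage_metrics`: `recall`, `precision`,
#'   `n_true`, `n_predicted`, `n_correct`.
#' @export
evaluate_linkage <- function(assignment, truth) {
  asg <- assignment$assignment
  map <- truth$respondent_to_family
  if (!all(asg$respondent_id %in% map$respondent_id))
    stop("assignment contains respondents absent from truth", call. = FALSE)
  canon <- function(ids) paste(sort(ids), collapse = ",")
  true_sets <- tapply(map$respondent_id, map$family_id, canon)
  true_multi <- true_sets[vapply(strsplit(true_sets, ","), length,
                                 integer(1)) >= 2]
  pred_sets <- tapply(asg$respondent_id, asg$family_id, canon)
  pred_multi <- pred_sets[vapply(strsplit(pred_sets, ","), length,
                                 integer(1)) >= 2]
  n_correct <- sum(pred_multi %in% true_multi)
  out <- list(recall = if (length(true_multi)) n_correct / length(true_multi)
              else NA_real_,
              precision = if (length(pred_multi))
                n_correct / length(pred_multi) else NA_real_,
              n_true = length(true_multi),
              n_predicted = length(pred_multi),
              n_correct = n_correct)
  class(out) <- "linkage_metrics"
  out
}

#' @export
print.linkage_metrics <- function(x, ...) {
  cat(sprintf(
    "family linkage: recall %.3f, precision %s (%d/%d true, %d predicted)\n",
    x$recall,
    if (is.na(x$precision)) "NA" else sprintf("%.3f", x$precision),
    x$n_correct, x$n_true, x$n_predicted))
  invisible(x)
}

#' Enforce the unique-key property on a generated population
#'
#' Validation fixtures for the matching algorithm presuppose that the
#' matching-key combinations identify families uniquely; at realistic key
#' granularity (birth years, sexes, settlement type, children counts) two
#' unrelated families can by chance carry identical keys, in which case no
#' key-based algorithm could tell them apart. This helper removes, using
#' the ground truth only, every family involved in a cross-family key
#' collision (a pair of respondents from different true families whose
#' full key bundles correspond), so the remaining population has unique
#' keys by construction.
#'
#' @param population result of [generate_population()].
#' @return population of the same shape with colliding families removed
#'   (count recorded in attribute `n_collision_families`).
#' @export
enforce_unique_keys <- function(population) {
  resp <- population$respondents
  keys <- linkage_keys(resp, population$rosters)
  truth_map <- population$truth$respondent_to_family
  fam_of <- stats::setNames(truth_map$family_id, truth_map$respondent_id)
  ids <- resp$respondent_id
  block_key <- vapply(keys[ids], function(k)
    paste(k$size, k$bysex, k$birthplace, sep = "#"), character(1))
  drop_fams <- character(0)
  for (blk in split(ids, block_key)) {
    if (length(blk) < 2) next
    for (a in seq_len(length(blk) - 1)) for (b in (a + 1):length(blk)) {
      if (fam_of[blk[a]] != fam_of[blk[b]] &&
          pair_matches(keys[[blk[a]]], keys[[blk[b]]]))
        drop_fams <- c(drop_fams, fam_of[blk[a]], fam_of[blk[b]])
    }
  }
  drop_fams <- unique(drop_fams)
  if (length(drop_fams)) {
    keep_ids <- truth_map$respondent_id[!truth_map$family_id %in% drop_fams]
    population$respondents <-
      resp[resp$respondent_id %in% keep_ids, , drop = FALSE]
    population$rosters <- population$rosters[
      population$rosters$respondent_id %in% keep_ids, , drop = FALSE]
    population$truth$respondent_to_family <-
      truth_map[truth_map$family_id %in% setdiff(truth_map$family_id,
                                                 drop_fams), , drop = FALSE]
    population$truth$families <- population$truth$families[
      !population$truth$families$family_id %in% drop_fams, , drop = FALSE]
  }
  attr(population, "n_collision_families") <- length(drop_fams)
  population
}
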