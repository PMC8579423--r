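#' Fellegi-Sunter agreement weights
#'
#' For every identifier field and agreement level, the probability of that
#' level among true matches (m) and among non-matches (u); the log2
#' likelihood ratio w = log2(m/u) is the field's score contribution.
#' Missing-level weights are carried for completeness but contribute 0 to
#' scores. Per-field m and u probabilities must each sum to 1.
#'
#' @param table data.frame with columns `field`, `level`, `m`, `u`.
#' @return data.frame of class `match_weights` with a `w` column.
#' @export
match_weights <- function(table) {
  stopifnot(all(c("field", "level", "m", "u") %in% names(table)))
  stopifnot(all(table$m > 0 & table$m < 1), all(table$u > 0 & table$u < 1))
  sums <- aggregate(cbind(m, u) ~ field, table, sum)
  if (any(abs(sums$m - 1) > 1e-6) || any(abs(sums$u - 1) > 1e-6))
    stop("per-field m and u probabilities must each sum to 1")
  table$w <- log2(table$m / table$u)
  class(table) <- c("match_weights", "data.frame")
  table
}

#' @rdname match_weights
#' @details `default_match_weights()` carries defaults aligned with the
#'   synthetic error model (m from the corruption rates) and the synthetic
#'   identifier universe (u from name-pool, calendar and postcode-universe
#'   collision frequencies). They are configuration, not estimates: no EM
#'   fitting is performed.
#' @export
default_match_weights <- function() {
  match_weights(data.frame(
    field = c(rep("surname", 4), rep("forename", 4), rep("dob", 4),
              rep("postcode", 5)),
    level = c("exact", "partial", "disagree", "missing",
              "exact", "partial", "disagree", "missing",
              "exact", "partial", "disagree", "missing",
              "exact", "partial", "neighbouring_authority", "disagree",
              "missing"),
    m = c(0.92, 0.04, 0.03, 0.01,
          0.93, 0.03, 0.03, 0.01,
          0.960, 0.030, 0.005, 0.005,
          0.82, 0.05, 0.08, 0.04, 0.01),
    u = c(0.012, 0.020, 0.958, 0.010,
          0.012, 0.020, 0.958, 0.010,
          0.0005, 0.0050, 0.9895, 0.0050,
          0.001, 0.020, 0.040, 0.929, 0.010),
    stringsAsFactors = FALSE))
}

# normalised edit-distance similarity for unique string pairs
string_similarity <- function(a, b) {
  out <- rep(NA_real_, length(a))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(out)
  key <- paste(a[ok], b[ok], sep = "\r")
  uk <- !duplicated(key)
  ua <- a[ok][uk]; ub <- b[ok][uk]
  d <- mapply(function(x, y) utils::adist(x, y)[1, 1], ua, ub,
              USE.NAMES = FALSE)
  sim <- 1 - d / pmax(nchar(ua), nchar(ub))
  out[ok] <- sim[match(key, key[uk])]
  out
}

name_level <- function(a, b, partial_threshold = 0.8) {
  lev <- rep("disagree", length(a))
  lev[is.na(a) | is.na(b)] <- "missing"
  eq <- !is.na(a) & !is.na(b) & a == b
  lev[eq] <- "exact"
  near <- which(lev == "disagree")
  if (length(near)) {
    sim <- string_similarity(a[near], b[near])
    lev[near[sim >= partial_threshold]] <- "partial"
  }
  lev
}

dob_level <- function(a, b) {
  lev <- rep("disagree", length(a))
  lev[is.na(a) | is.na(b)] <- "missing"
  ok <- !is.na(a) & !is.na(b)
  eq <- ok & a == b
  lev[eq] <- "exact"
  part <- ok & !eq
  if (any(part)) {
    da <- as.POSIXlt(a[part]); db <- as.POSIXlt(b[part])
    ndiff <- (da$mday != db$mday) + (da$mon != db$mon) +
      (da$year != db$year)
    lev[part][ndiff == 1] <- "partial"
  }
  lev
}

postcode_level <- function(pc_a, auth_a, pc_b, auth_b, lookup) {
  lev <- rep("disagree", length(pc_a))
  lev[is.na(pc_a) | is.na(pc_b)] <- "missing"
  ok <- !is.na(pc_a) & !is.na(pc_b)
  lev[ok & pc_a == pc_b] <- "exact"
  rest <- which(lev == "disagree")
  if (length(rest)) {
    same_auth <- !is.na(auth_a[rest]) & !is.na(auth_b[rest]) &
      auth_a[rest] == auth_b[rest]
    lev[rest[same_auth]] <- "partial"
    rest2 <- rest[!same_auth]
    if (length(rest2)) {
      nb <- mapply(function(x, y) {
        !is.na(x) && !is.na(y) && y %in% lookup$neighbours[[x]]
      }, auth_a[rest2], auth_b[rest2], USE.NAMES = FALSE)
      lev[rest2[nb]] <- "neighbouring_authority"
    }
  }
  lev
}

level_rank <- function(lev) {
  # higher is stronger agreement; used to pick each field's best level
  match(lev, c("missing", "disagree", "neighbouring_authority", "partial",
               "exact"))
}

register_entry_table <- function(register) {
  ids <- register$identifiers
  data.frame(pupil_id = ids$pupil_id,
             surname = canonical_string(ids$surname),
             forename = canonical_string(ids$forename),
             dob = as.Date(ids$dob),
             postcode = ids$postcode,
             outward = sub(" .*", "", ids$postcode),
             authority = ids$authority,
             stringsAsFactors = FALSE)
}

block_pairs <- function(tkey, rkey, tid, rid) {
  ok_t <- !is.na(tkey); ok_r <- !is.na(rkey)
  sp <- split(rid[ok_r], rkey[ok_r])
  hit <- sp[tkey[ok_t]]
  n <- lengths(hit)
  data.frame(participant_id = rep(tid[ok_t], n),
             pupil_id = unlist(hit, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Generate up to four candidate register matches per participant
#'
#' Candidate pairs are the union of three deterministic blocking passes over
#' the identifier chronology and the register identity table: (1) exact date
#' of birth; (2) canonical surname + postcode outward code; (3) birth year +
#' forename initial + local authority. For each candidate pair every field is
#' compared across all chronology/register entry combinations and the best
#' agreement level per field is kept (exact, partial, neighbouring authority
#' for postcodes, disagree, or missing). Pairs are then truncated to
#' `max_candidates` per participant by provisional agreement count
#' (2 per exact + 1 per partial/neighbouring level, ties to the lowest pupil
#' id). Participants with zero candidates pass through absent from the table.
#'
#' @param chronology an [build_identifier_chronology()] table for the trial
#'   side.
#' @param register a `pupil_register`.
#' @param max_candidates cap per participant.
#' @param partial_threshold normalised edit-distance similarity at or above
#'   which a name pair counts as partial agreement.
#' @return data.frame of class `candidate_links`: participant_id, pupil_id,
#'   per-field levels, `n_exact`, `n_partial`.
#' @export
generate_candidates <- function(chronology, register, max_candidates = 4,
                                partial_threshold = 0.8) {
  tr <- as.data.frame(chronology)
  re <- register_entry_table(register)
  p1 <- block_pairs(as.character(tr$dob), as.character(re$dob),
                    tr$participant_id, re$pupil_id)
  k2t <- ifelse(is.na(tr$surname) | is.na(tr$outward), NA,
                paste(tr$surname, tr$outward))
  k2r <- ifelse(is.na(re$surname) | is.na(re$outward), NA,
                paste(re$surname, re$outward))
  p2 <- block_pairs(k2t, k2r, tr$participant_id, re$pupil_id)
  k3t <- ifelse(is.na(tr$dob) | is.na(tr$forename) | is.na(tr$authority),
                NA, paste(format(tr$dob, "%Y"), substr(tr$forename, 1, 1),
                          tr$authority))
  k3r <- ifelse(is.na(re$dob) | is.na(re$forename) | is.na(re$authority),
                NA, paste(format(re$dob, "%Y"), substr(re$forename, 1, 1),
                          re$authority))
  p3 <- block_pairs(k3t, k3r, tr$participant_id, re$pupil_id)
  pairs <- unique(rbind(p1, p2, p3))
  if (!nrow(pairs)) {
    return(structure(data.frame(participant_id = character(0),
                                pupil_id = character(0)),
                     class = c("candidate_links", "data.frame")))
  }

  # expand to entry-level comparisons, then take the per-field best level
  t_by <- split(seq_len(nrow(tr)), tr$participant_id)
  r_by <- split(seq_len(nrow(re)), re$pupil_id)
  ti <- t_by[pairs$participant_id]
  ri <- r_by[pairs$pupil_id]
  reps <- lengths(ti) * lengths(ri)
  pair_id <- rep(seq_len(nrow(pairs)), reps)
  ii <- unlist(mapply(function(a, b) rep(a, each = length(b)), ti, ri,
                      SIMPLIFY = FALSE), use.names = FALSE)
  jj <- unlist(mapply(function(a, b) rep(b, times = length(a)), ti, ri,
                      SIMPLIFY = FALSE), use.names = FALSE)

  lev <- data.frame(
    pair = pair_id,
    surname = name_level(tr$surname[ii], re$surname[jj], partial_threshold),
    forename = name_level(tr$forename[ii], re$forename[jj],
                          partial_threshold),
    dob = dob_level(tr$dob[ii], re$dob[jj]),
    postcode = postcode_level(tr$postcode[ii], tr$authority[ii],
                              re$postcode[jj], re$authority[jj],
                              register$lookup),
    stringsAsFactors = FALSE)
  best <- function(l) {
    r <- level_rank(l)
    m <- tapply(r, pair_id, max)
    c("missing", "disagree", "neighbouring_authority", "partial",
      "exact")[m[as.character(seq_len(nrow(pairs)))]]
  }
  pairs$surname <- best(lev$surname)
  pairs$forename <- best(lev$forename)
  pairs$dob <- best(lev$dob)
  pairs$postcode <- best(lev$postcode)

  lv <- as.matrix(pairs[, c("surname", "forename", "dob", "postcode")])
  pairs$n_exact <- rowSums(lv == "exact")
  pairs$n_partial <- rowSums(lv == "partial" |
                               lv == "neighbouring_authority")
  prov <- 2 * pairs$n_exact + pairs$n_partial
  o <- order(pairs$participant_id, -prov, pairs$pupil_id)
  pairs <- pairs[o, ]
  keep <- stats::ave(seq_len(nrow(pairs)), pairs$participant_id,
                     FUN = seq_along) <= max_candidates
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("candidate_links", "data.frame")
  pairs
}

#' Score candidate links by summed log2 agreement weights
#'
#' The score of a candidate is the sum over the four identifier fields of
#' the weight for its observed agreement level; missing fields contribute 0.
#' Candidates are ranked per participant by descending score.
#'
#' @param candidates a [generate_candidates()] table.
#' @param weights a [match_weights()] table.
#' @return the candidate table with `score` and `rank` columns.
#' @export
score_candidates <- function(candidates, weights = default_match_weights()) {
  w <- weights$w
  names(w) <- paste(weights$field, weights$level)
  sc <- rep(0, nrow(candidates))
  for (f in c("surname", "forename", "dob", "postcode")) {
    lev <- candidates[[f]]
    contrib <- ifelse(lev == "missing", 0, w[paste(f, lev)])
    if (anyNA(contrib))
      stop("agreement level absent from weight table for field ", f)
    sc <- sc + contrib
  }
  candidates$score <- sc
  o <- order(candidates$participant_id, -sc, -candidates$n_exact,
             candidates$pupil_id)
  candidates <- candidates[o, ]
  candidates$rank <- stats::ave(seq_len(nrow(candidates)),
                                candidates$participant_id, FUN = seq_along)
  rownames(candidates) <- NULL
  candidates
}

#' Select at most one best link per participant
#'
#' Greedy one-to-one assignment by descending score with deterministic tie
#' breaks (more exact-level fields first, then lowest pupil id). Participants
#' who died before school entry are excluded up front and never linked.
#' Within a twin group, a candidate whose forename disagrees is ceded to the
#' co-twin when the co-twin holds a forename-exact candidate for the same
#' pupil, so twins sharing surname, date of birth and postcode are not
#' cross-assigned. Scores below `threshold` stay unlinked; `margin` records
#' each linked participant's score gap to their runner-up candidate.
#'
#' @param candidates scored candidates (see [score_candidates()]).
#' @param participants the cohort participant table (for death, twin group,
#'   trial and arm labels).
#' @param threshold minimum score for a link; the default 0 links exactly
#'   when a match is likelier than a non-match under the weights.
#' @param tie_margin minimum required margin over the runner-up; 0 disables.
#' @return data.frame of class `link_decisions`: one row per participant
#'   with `pupil_id` (NA when unlinked), `status`
#'   (linked/unlinked/excluded_death), `score`, `margin`.
#' @export
select_best_links <- function(candidates, participants, threshold = 0,
                              tie_margin = 0) {
  cand <- candidates[candidates$participant_id %in%
                       participants$participant_id, , drop = FALSE]
  dead <- participants$participant_id[participants$death]
  cand <- cand[!cand$participant_id %in% dead, , drop = FALSE]

  # twin ceding
  tg <- participants$twin_group[match(cand$participant_id,
                                      participants$participant_id)]
  if (any(!is.na(tg))) {
    key <- paste(tg, cand$pupil_id)
    exact_for_pupil <- unique(key[!is.na(tg) & cand$forename == "exact"])
    cede <- !is.na(tg) & cand$forename == "disagree" &
      key %in% exact_for_pupil
    cand <- cand[!cede, , drop = FALSE]
  }

  cand <- cand[cand$score >= threshold, , drop = FALSE]
  o <- order(-cand$score, -cand$n_exact, cand$pupil_id,
             cand$participant_id)
  cand <- cand[o, , drop = FALSE]
  runner_up <- function(p, chosen_pupil) {
    s <- cand$score[cand$participant_id == p & cand$pupil_id != chosen_pupil]
    if (length(s)) max(s) else NA_real_
  }
  linked_p <- character(0); linked_pupil <- character(0)
  score_v <- numeric(0); margin_v <- numeric(0)
  p_used <- new.env(); u_used <- new.env()
  for (i in seq_len(nrow(cand))) {
    p <- cand$participant_id[i]; q <- cand$pupil_id[i]
    if (!is.null(p_used[[p]]) || !is.null(u_used[[q]])) next
    mar <- cand$score[i] - runner_up(p, q)
    if (!is.na(mar) && mar < tie_margin) next
    p_used[[p]] <- TRUE; u_used[[q]] <- TRUE
    linked_p <- c(linked_p, p); linked_pupil <- c(linked_pupil, q)
    score_v <- c(score_v, cand$score[i]); margin_v <- c(margin_v, mar)
  }
  stopifnot(!anyDuplicated(linked_pupil))   # one-to-one by construction

  dec <- data.frame(participant_id = participants$participant_id,
                    trial_id = participants$trial_id,
                    arm = participants$arm,
                    pupil_id = NA_character_,
                    status = "unlinked", score = NA_real_,
                    margin = NA_real_, stringsAsFactors = FALSE)
  dec$status[dec$participant_id %in% dead] <- "excluded_death"
  m <- match(linked_p, dec$participant_id)
  dec$pupil_id[m] <- linked_pupil
  dec$status[m] <- "linked"
  dec$score[m] <- score_v
  dec$margin[m] <- margin_v
  class(dec) <- c("link_decisions", "data.frame")
  dec
}

#' Evaluate link decisions against the ground truth
#'
#' Standard definitions: precision is the fraction of made links that agree
#' with the truth table; recall is the fraction of truly register-present
#' participants that were correctly linked; the link rate is linked over
#' randomised, overall and per trial (and per arm). With zero links made,
#' precision is reported as 1.0 and flagged.
#'
#' @param decisions a [select_best_links()] table.
#' @param truth data.frame participant_id, pupil_id (NA = no register
#'   record).
#' @return list with `precision`, `recall`, `link_rate`, `per_trial`,
#'   `zero_links` flag.
#' @export
evaluate_linkage <- function(decisions, truth) {
  m <- match(decisions$participant_id, truth$participant_id)
  if (anyNA(m)) stop("truth table is missing participant ids")
  true_pupil <- truth$pupil_id[m]
  linked <- decisions$status == "linked"
  correct <- linked & !is.na(true_pupil) & decisions$pupil_id == true_pupil
  zero_links <- !any(linked)
  precision <- if (zero_links) 1.0 else sum(correct) / sum(linked)
  linkable <- sum(!is.na(true_pupil))
  recall <- if (linkable == 0) NA_real_ else sum(correct) / linkable
  per <- do.call(rbind, lapply(split(seq_along(linked), list(
    decisions$trial_id, decisions$arm), drop = TRUE), function(i) {
      data.frame(trial_id = decisions$trial_id[i][1],
                 arm = decisions$arm[i][1],
                 randomised = length(i), linked = sum(linked[i]),
                 link_rate = mean(linked[i]), stringsAsFactors = FALSE)
    }))
  per <- per[order(per$trial_id, per$arm), ]
  rownames(per) <- NULL
  list(precision = precision, recall = recall,
       link_rate = mean(linked), per_trial = per, zero_links = zero_links)
}
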