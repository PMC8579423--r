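two_level_weights <- function(m_exact, u_exact) {
  match_weights(data.frame(
    field = rep(c("surname", "forename", "dob", "postcode"), each = 2),
    level = rep(c("exact", "disagree"), 4),
    m = rep(c(m_exact, 1 - m_exact), 4),
    u = rep(c(u_exact, 1 - u_exact), 4)))
}

cand_row <- function(participant = "T1", pupil = "P1", surname = "exact",
                     forename = "exact", dob = "exact",
                     postcode = "exact") {
  d <- data.frame(participant_id = participant, pupil_id = pupil,
                  surname = surname, forename = forename, dob = dob,
                  postcode = postcode, stringsAsFactors = FALSE)
  lv <- as.matrix(d[, c("surname", "forename", "dob", "postcode")])
  d$n_exact <- rowSums(lv == "exact")
  d$n_partial <- rowSums(lv == "partial" | lv == "neighbouring_authority")
  d
}

test_that("candidate scores follow the closed-form log2 likelihood ratios", {
  w_all_exact <- two_level_weights(0.95, 0.05)
  sc <- score_candidates(cand_row(), w_all_exact)
  expect_equal(sc$score, 4 * log2(19), tolerance = 1e-10)

  w_disagree <- match_weights(data.frame(
    field = rep(c("surname", "forename", "dob", "postcode"), each = 2),
    level = rep(c("exact", "disagree"), 4),
    m = rep(c(0.99, 0.01), 4), u = rep(c(0.10, 0.90), 4)))
  sc <- score_candidates(cand_row(surname = "disagree",
                                  forename = "disagree", dob = "disagree",
                                  postcode = "disagree"), w_disagree)
  expect_equal(sc$score, 4 * log2(1 / 90), tolerance = 1e-10)

  # m = u makes a field uninformative; missing fields contribute nothing
  w_flat <- two_level_weights(0.5, 0.5)
  expect_equal(score_candidates(cand_row(), w_flat)$score, 0)
  sc <- score_candidates(cand_row(postcode = "missing"), w_all_exact)
  expect_equal(sc$score, 3 * log2(19), tolerance = 1e-10)
})

test_that("scores decompose as the sum of per-field weights", {
  sim <- iront_sim()
  cand <- sim$cand
  w <- default_match_weights()
  wl <- stats::setNames(w$w, paste(w$field, w$level))
  pick <- cand[sample(seq_len(nrow(cand)), 50), ]
  manual <- rowSums(vapply(
    c("surname", "forename", "dob", "postcode"),
    function(f) ifelse(pick[[f]] == "missing", 0,
                       wl[paste(f, pick[[f]])]),
    numeric(nrow(pick))))
  expect_equal(unname(manual), pick$score, tolerance = 1e-10)
})

test_that("invalid weight tables are rejected", {
  bad <- data.frame(field = rep("dob", 2), level = c("exact", "disagree"),
                    m = c(0.9, 0.2), u = c(0.1, 0.9))
  expect_error(match_weights(bad), "sum to 1")
  expect_error(score_candidates(cand_row(dob = "partial"),
                                two_level_weights(0.9, 0.1)),
               "absent from weight table")
})

test_that("at most four candidates are kept, lowest pupil ids on ties", {
  reg <- simulate_register(50, error_model = zero_error_model(), seed = 51)
  # six clones of pupil 1: identical identifiers, same dob
  for (f in c("forename", "surname", "sex", "postcode", "authority",
              "reg_postcode", "reg_authority")) {
    reg$pupils[[f]][2:6] <- reg$pupils[[f]][1]
  }
  reg$pupils$dob[2:6] <- reg$pupils$dob[1]
  reg$identifiers <- dormantlink:::register_identifiers(reg$pupils)
  contacts <- data.frame(participant_id = "T1",
                         contact_date = as.Date("1994-01-01"),
                         forename = reg$pupils$forename[1],
                         surname = reg$pupils$surname[1],
                         dob = reg$pupils$dob[1],
                         postcode = reg$pupils$postcode[1])
  chron <- build_identifier_chronology(contacts, reg$lookup)
  cand <- generate_candidates(chron, reg)
  expect_equal(nrow(cand), 4L)
  expect_equal(sort(cand$pupil_id), sort(reg$pupils$pupil_id[1:4]))
})

test_that("perfect identifiers give perfect candidate recall and linkage", {
  sim <- full_sim(zero_error_model())
  truth <- sim$cohort$truth
  linkable <- truth[!is.na(truth$pupil_id), ]
  key <- paste(sim$cand$participant_id, sim$cand$pupil_id)
  expect_true(all(paste(linkable$participant_id, linkable$pupil_id) %in% key))
  ev <- sim$eval
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 1.0)
})

test_that("register-absent participants can only attract false candidates", {
  reg <- simulate_register(2500, error_model = zero_error_model(),
                           seed = 61, birth_from = "1992-08-01",
                           birth_to = "1995-07-31")
  clean <- simulate_trials(iront_spec(), reg, seed = 62)
  original <- clean$truth
  co <- corrupt_identifiers(clean,
                            error_model(0, 0, 0, 0, 0,
                                        p_register_absent = 1), seed = 63)
  expect_true(all(is.na(co$truth$pupil_id)))
  chron <- build_identifier_chronology(co$contacts, co$register$lookup)
  cand <- generate_candidates(chron, co$register)
  # the true records are gone, so every remaining candidate is false
  truth_key <- paste(original$participant_id, original$pupil_id)
  expect_false(any(paste(cand$participant_id, cand$pupil_id) %in% truth_key))
  dec <- select_best_links(score_candidates(cand), co$participants)
  ev <- evaluate_linkage(dec, co$truth)
  expect_equal(sum(dec$status == "linked" &
                     dec$pupil_id %in% original$pupil_id), 0)
  expect_equal(ev$recall, NA_real_)
})

test_that("death excludes a participant from linkage regardless of score", {
  cand <- score_candidates(cand_row("T1", "P1"), default_match_weights())
  parts <- data.frame(participant_id = "T1", trial_id = "IRONT",
                      arm = "modified", death = TRUE,
                      twin_group = NA_character_, stringsAsFactors = FALSE)
  dec <- select_best_links(cand, parts)
  expect_equal(dec$status, "excluded_death")
  expect_true(is.na(dec$pupil_id))
})

test_that("twins are not cross-assigned when forenames distinguish them", {
  cand <- rbind(cand_row("T1", "P1"), cand_row("T1", "P2", forename = "disagree"),
                cand_row("T2", "P2"), cand_row("T2", "P1", forename = "disagree"))
  cand <- score_candidates(cand, default_match_weights())
  parts <- data.frame(participant_id = c("T1", "T2"), trial_id = "IRONT",
                      arm = c("modified", "standard"), death = FALSE,
                      twin_group = "G1", stringsAsFactors = FALSE)
  dec <- select_best_links(cand, parts)
  expect_equal(dec$pupil_id[dec$participant_id == "T1"], "P1")
  expect_equal(dec$pupil_id[dec$participant_id == "T2"], "P2")

  # and across the simulated twin pairs under perfect identifiers
  sim <- full_sim(zero_error_model())
  p <- sim$cohort$participants
  tw <- p$participant_id[!is.na(p$twin_group) & !p$death]
  d <- sim$dec[sim$dec$participant_id %in% tw, ]
  tr <- sim$cohort$truth
  expect_equal(
    sum(d$pupil_id != tr$pupil_id[match(d$participant_id,
                                        tr$participant_id)],
        na.rm = TRUE), 0)
})

test_that("link decisions are one-to-one over pupils", {
  sim <- full_sim(error_model())
  linked <- sim$dec$pupil_id[sim$dec$status == "linked"]
  expect_equal(anyDuplicated(linked), 0L)
})

test_that("evaluation conventions: zero links give flagged precision 1, recall 0", {
  dec <- data.frame(participant_id = c("A", "B"), trial_id = "IRONT",
                    arm = c("modified", "standard"),
                    pupil_id = NA_character_, status = "unlinked",
                    score = NA_real_, margin = NA_real_,
                    stringsAsFactors = FALSE)
  truth <- data.frame(participant_id = c("A", "B"),
                      pupil_id = c("P1", "P2"), stringsAsFactors = FALSE)
  ev <- evaluate_linkage(dec, truth)
  expect_true(ev$zero_links)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 0.0)
  expect_error(evaluate_linkage(dec,
                                truth[truth$participant_id != "A", ]),
               "missing participant ids")
})

test_that("raising field corruption does not raise recall", {
  base <- full_sim(error_model())$eval$recall
  reg <- simulate_register(6000, error_model = error_model(
    p_dob_error = 0.5), seed = 101)
  co <- corrupt_identifiers(simulate_trials(trial_specs(), reg, seed = 102),
                            error_model(p_dob_error = 0.5), seed = 103)
  chron <- build_identifier_chronology(co$contacts, co$register$lookup)
  dec <- select_best_links(
    score_candidates(generate_candidates(chron, co$register)),
    co$participants)
  worse <- evaluate_linkage(dec, co$truth)$recall
  expect_lte(worse, base + 0.02)   # Monte-Carlo slack
})
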