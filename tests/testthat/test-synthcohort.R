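test_that("register simulation is deterministic in the seed", {
  a <- simulate_register(300, seed = 5)
  b <- simulate_register(300, seed = 5)
  c <- simulate_register(300, seed = 6)
  expect_identical(a$pupils, b$pupils)
  expect_identical(a$gcse, b$gcse)
  expect_identical(a$identifiers, b$identifiers)
  expect_false(identical(a$pupils, c$pupils))
})

test_that("register grade marginals match the configured national scale", {
  reg <- simulate_register(10000, seed = 11)
  maths <- reg$gcse[reg$gcse$subject == "maths", ]
  yr <- reg$pupils$gcse_year[match(maths$pupil_id, reg$pupils$pupil_id)]
  z <- standardise_external(maths$points, yr, reg$national_scale)
  expect_lt(abs(mean(z)), 0.05)
  for (y in unique(yr)) {
    if (sum(yr == y) >= 500) expect_lt(abs(mean(z[yr == y])), 0.2)
  }
})

test_that("zero error model leaves trial and register identifiers identical", {
  reg <- simulate_register(2500, error_model = zero_error_model(),
                           seed = 21, birth_from = "1992-08-01",
                           birth_to = "1995-07-31")
  co <- corrupt_identifiers(
    simulate_trials(iront_spec(), reg, seed = 22),
    zero_error_model(), seed = 23)
  alive <- co$participants[!co$participants$death, ]
  idx <- match(alive$true_pupil_id, co$register$identifiers$pupil_id)
  rows <- match(alive$participant_id, co$contacts$participant_id)
  expect_true(all(is.na(alive$true_pupil_id) |
    (co$contacts$surname[rows] == co$register$identifiers$surname[idx] &
     co$contacts$forename[rows] == co$register$identifiers$forename[idx] &
     co$contacts$dob[rows] == co$register$identifiers$dob[idx] &
     co$contacts$postcode[rows] == co$register$identifiers$postcode[idx])))
  expect_equal(sum(is.na(alive$true_pupil_id)), 0)
})

test_that("default specs reproduce the published randomised totals", {
  sim <- full_sim(error_model())
  totals <- table(sim$cohort$participants$trial_id)
  expect_equal(totals[["NEP"]], 229)
  expect_equal(totals[["NETSGA"]], 299)
  expect_equal(totals[["LCPUFAP"]], 196)
  expect_equal(totals[["LCPUFAT"]], 309)
  expect_equal(totals[["IRONT"]], 327)
  expect_equal(totals[["PALMT"]], 203)
  expect_equal(totals[["NUCLEOT"]], 200)
  arm_tab <- table(sim$cohort$participants$trial_id,
                   sim$cohort$participants$arm)
  expect_equal(arm_tab["IRONT", "modified"], 162)
  expect_equal(arm_tab["IRONT", "standard"], 165)
})

test_that("block length 2 forces alternating pairs with prefix imbalance <= 1", {
  for (s in 1:5) {
    set.seed(s)
    arms <- dormantlink:::permuted_block_sequence(40, 2L)
    x <- cumsum(arms == "modified") - cumsum(arms == "standard")
    expect_true(all(abs(x) <= 1))
    expect_true(all(x[seq(2, 40, 2)] == 0))
  }
})

test_that("corruption counts obey the binomial bound and forced corruption hits everyone", {
  reg <- simulate_register(2500, error_model = zero_error_model(),
                           seed = 31, birth_from = "1992-08-01",
                           birth_to = "1995-07-31")
  co <- simulate_trials(iront_spec(), reg, seed = 32)
  n <- nrow(co$participants)

  name_changed <- function(cohort, clean) {
    key <- function(cc) paste(cc$contacts$surname, cc$contacts$forename)
    changed <- key(cohort) != key(clean)
    unique(cohort$contacts$participant_id[changed])
  }
  em <- error_model(p_name_typo = 0.05, p_name_change = 0,
                    p_dob_error = 0, p_unrecorded_move = 0,
                    p_missing_field = 0, p_register_absent = 0)
  corr <- corrupt_identifiers(co, em, seed = 33)
  hit <- length(name_changed(corr, co))
  expect_lt(abs(hit - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95) + 1)

  all_typo <- corrupt_identifiers(co, error_model(
    p_name_typo = 1, p_name_change = 0, p_dob_error = 0,
    p_unrecorded_move = 0, p_missing_field = 0,
    p_register_absent = 0), seed = 34)
  expect_equal(length(name_changed(all_typo, co)), n)
})

test_that("twin groups share date of birth, surname and postcode", {
  sim <- full_sim(error_model())
  p <- sim$cohort$participants
  tw <- p[!is.na(p$twin_group), ]
  expect_gt(nrow(tw), 0)
  by_group <- split(tw, tw$twin_group)
  for (g in by_group) {
    expect_equal(length(unique(g$dob)), 1L)
  }
})

test_that("population deficits order mean raw scores as preterm < term", {
  sim <- full_sim(error_model())
  reg <- sim$cohort$register
  maths <- reg$gcse[reg$gcse$subject == "maths", ]
  truth <- sim$cohort$truth
  pts <- maths$points[match(truth$pupil_id, maths$pupil_id)]
  pop <- sim$cohort$participants$population[
    match(truth$participant_id, sim$cohort$participants$participant_id)]
  mean_by <- tapply(pts, pop, mean, na.rm = TRUE)
  expect_lt(mean_by[["preterm"]], mean_by[["term"]])
  expect_lt(mean_by[["term_sga"]], mean_by[["term"]])
})

test_that("a null generator leaves arms balanced on latent ability", {
  sim <- iront_sim()
  p <- sim$cohort$participants
  d <- tapply(p$latent_ability, p$arm, mean)
  se <- sqrt(sum(tapply(p$latent_ability, p$arm, var) /
                   table(p$arm)))
  expect_lt(abs(d[["modified"]] - d[["standard"]]), 3 * se)
})

test_that("deceased participants leave no register record or exam outcomes", {
  sim <- full_sim(error_model())
  p <- sim$cohort$participants
  dead <- p$participant_id[p$death]
  expect_true(all(is.na(sim$cohort$truth$pupil_id[
    sim$cohort$truth$participant_id %in% dead])))
  ds <- build_analysis_dataset(sim$cohort, sim$dec)
  expect_true(all(is.na(ds$points_maths16[ds$participant_id %in% dead])))
})

test_that("exhausting the register raises an informative error", {
  reg <- simulate_register(100, seed = 41, birth_from = "1992-08-01",
                           birth_to = "1995-07-31")
  expect_error(simulate_trials(iront_spec(), reg, seed = 42),
               "register exhausted")
})
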