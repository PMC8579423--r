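grade_levels <- function() c("A*", "A", "B", "C", "D", "E", "F", "G", "U")

#' GCSE letter-grade to points map (8-point pre-2017 scale)
#'
#' A* = 8 down to G = 1; U (unclassified) scores 0. The study cohorts sat
#' letter-graded GCSEs, so the numeric scale is fixed to this map.
#' @return named numeric vector.
#' @export
gcse_points_map <- function() {
  stats::setNames(c(8, 7, 6, 5, 4, 3, 2, 1, 0), grade_levels())
}

default_grade_dist <- function() {
  stats::setNames(c(0.05, 0.10, 0.15, 0.25, 0.15, 0.10, 0.08, 0.06, 0.06),
                  grade_levels())
}

.forenames <- c(
  "JACK", "THOMAS", "JAMES", "DANIEL", "JOSHUA", "MATTHEW", "RYAN", "LUKE",
  "SAMUEL", "JORDAN", "ADAM", "MICHAEL", "ALEXANDER", "CHRISTOPHER", "BENJAMIN",
  "CONNOR", "JOSEPH", "LIAM", "NATHAN", "GEORGE", "CALLUM", "KIERAN", "HARRY",
  "AARON", "ROBERT", "DAVID", "JAKE", "LEWIS", "OLIVER", "BRANDON", "WILLIAM",
  "CHARLIE", "REECE", "ANDREW", "JOHN", "EDWARD", "PETER", "PATRICK", "TOBY",
  "CAMERON", "SOPHIE", "CHLOE", "JESSICA", "EMILY", "LAUREN", "REBECCA",
  "CHARLOTTE", "HANNAH", "AMY", "MEGAN", "KATIE", "EMMA", "LUCY", "BETHANY",
  "OLIVIA", "RACHEL", "GEORGIA", "SARAH", "DANIELLE", "HOLLY", "ABIGAIL",
  "JADE", "STEPHANIE", "VICTORIA", "NATASHA", "ELEANOR", "PAIGE", "NICOLE",
  "ELIZABETH", "SHANNON", "GRACE", "ANNA", "MOLLY", "LEAH", "JASMINE", "ALICE",
  "KIRSTY", "ZOE", "COURTNEY", "GEMMA")

.surnames <- c(
  "SMITH", "JONES", "TAYLOR", "BROWN", "WILLIAMS", "WILSON", "JOHNSON",
  "DAVIES", "ROBINSON", "WRIGHT", "THOMPSON", "EVANS", "WALKER", "WHITE",
  "ROBERTS", "GREEN", "HALL", "WOOD", "JACKSON", "CLARKE", "PATEL", "KHAN",
  "LEWIS", "JAMES", "PHILLIPS", "MASON", "MITCHELL", "ROSE", "DAVIS",
  "RODGERS", "HARRIS", "COOPER", "KING", "LEE", "BAKER", "EDWARDS", "TURNER",
  "MORRIS", "HUGHES", "PARKER", "MOORE", "ALLEN", "YOUNG", "BELL", "HILL",
  "CARTER", "SCOTT", "ADAMS", "SINGH", "MURPHY", "KELLY", "OBRIEN", "RYAN",
  "SHAW", "WALSH", "BENNETT", "GRAY", "HARRISON", "GIBSON", "HOLMES", "REID",
  "WEBB", "SIMPSON", "MARSHALL", "COLLINS", "STEWART", "MURRAY", "GRANT",
  "FOSTER", "BUTLER", "PEARSON", "BARKER", "FLETCHER", "DIXON", "HUNT",
  "KNIGHT", "LLOYD", "OWEN", "PERRY", "REYNOLDS")

#' Generative model for school outcomes
#'
#' A single standard-normal latent ability per child drives every outcome:
#' subject grades at 16 (latent ability plus subject noise, cut at year-
#' specific thresholds), age-11 test scores, and special-educational-needs
#' status. Trial participants' ability additionally receives linear covariate
#' effects (in SD units), a non-negative population deficit for preterm and
#' term-SGA cohorts, and the injected arm effect.
#'
#' @param arm_effect true treatment effect in SD units of the observed exam
#'   score, the scale of the primary analysis (internally converted to the
#'   latent-ability scale); scalar or named vector by trial id. 0 gives a
#'   null generator.
#' @param deficit named SD-unit penalties by population.
#' @param resid_sd residual SD of participant latent ability.
#' @param subject_noise_sd per-subject measurement noise SD.
#' @param b_male,b_smoking,b_degree,b_bw,b_ga covariate effects (SD units;
#'   weight/gestation per within-trial SD).
#' @param grade_dist national grade distribution (A* to U probabilities).
#' @param inflation per-year downward drift of grade thresholds, emulating
#'   grade inflation; the per-year national scale corrects for it.
#' @param p_missing_gcse,p_missing_ks2 probability an in-register pupil has
#'   no exam record at that stage.
#' @param sen_intercept,sen_slope logistic model of ever receiving special
#'   educational needs support given ability.
#' @return list of class `outcome_model`.
#' @export
outcome_model <- function(arm_effect = 0,
                          deficit = c(preterm = 0.8, term_sga = 0.45, term = 0),
                          resid_sd = 0.95, subject_noise_sd = 0.5,
                          b_male = -0.15, b_smoking = -0.2, b_degree = 0.5,
                          b_bw = 0.1, b_ga = 0.1,
                          grade_dist = default_grade_dist(),
                          inflation = 0.03,
                          p_missing_gcse = 0.04, p_missing_ks2 = 0.04,
                          sen_intercept = -2.2, sen_slope = -1.2) {
  stopifnot(all(deficit >= 0), abs(sum(grade_dist) - 1) < 1e-8)
  structure(list(arm_effect = arm_effect, deficit = deficit,
                 resid_sd = resid_sd, subject_noise_sd = subject_noise_sd,
                 b_male = b_male, b_smoking = b_smoking, b_degree = b_degree,
                 b_bw = b_bw, b_ga = b_ga, grade_dist = grade_dist,
                 inflation = inflation, p_missing_gcse = p_missing_gcse,
                 p_missing_ks2 = p_missing_ks2, sen_intercept = sen_intercept,
                 sen_slope = sen_slope),
            class = "outcome_model")
}

#' Identifier error model
#'
#' Field-level corruption probabilities applied when trial paper records and
#' register identifiers diverge, plus the probability a participant never
#' appears in the state register (private schooling, emigration). The zero
#' model is the identity: identifiers then agree exactly across sources.
#'
#' @param p_name_typo probability a participant has a transcription typo in
#'   one recorded contact's name.
#' @param p_name_change probability the register surname changed after trial
#'   follow-up ended (so the trial holds a former surname).
#' @param p_dob_error probability the date of birth was transcribed with a
#'   digit error (systematic across the trial's contacts).
#' @param p_unrecorded_move probability the family moved after the last trial
#'   contact, so the register postcode is never the trial one.
#' @param p_missing_field per-contact probability the postcode was not
#'   recorded (and half that for the forename).
#' @param p_register_absent probability a participant is absent from the
#'   register entirely.
#' @return list of class `error_model`.
#' @export
error_model <- function(p_name_typo = 0.05, p_name_change = 0.03,
                        p_dob_error = 0.02, p_unrecorded_move = 0.10,
                        p_missing_field = 0.02, p_register_absent = 0.05) {
  p <- c(p_name_typo, p_name_change, p_dob_error, p_unrecorded_move,
         p_missing_field, p_register_absent)
  stopifnot(all(p >= 0 & p <= 1))
  structure(list(p_name_typo = p_name_typo, p_name_change = p_name_change,
                 p_dob_error = p_dob_error,
                 p_unrecorded_move = p_unrecorded_move,
                 p_missing_field = p_missing_field,
                 p_register_absent = p_register_absent),
            class = "error_model")
}

#' @rdname error_model
#' @export
zero_error_model <- function() {
  error_model(0, 0, 0, 0, 0, 0)
}

# year-specific grade thresholds on the latent subject score
gcse_thresholds <- function(year, model) {
  s_tot <- sqrt(1 + model$subject_noise_sd^2)
  cum <- cumsum(model$grade_dist)[-length(model$grade_dist)]
  base <- stats::qnorm(1 - cum, sd = s_tot)    # descending: A* cut first
  base - model$inflation * (year - 2010)
}

# analytic national mean/SD of GCSE points for a given exam year
national_scale_for_years <- function(years, model) {
  pts <- gcse_points_map()
  out <- lapply(years, function(y) {
    thr <- gcse_thresholds(y, model)
    s_tot <- sqrt(1 + model$subject_noise_sd^2)
    cum <- c(0, 1 - stats::pnorm(thr, sd = s_tot), 1)
    p <- diff(cum)
    m <- sum(p * pts)
    data.frame(year = y, mean = m, sd = sqrt(sum(p * pts^2) - m^2))
  })
  do.call(rbind, out)
}

draw_grades <- function(ability, year, model) {
  # one subject draw: latent = ability + noise, cut at the year's thresholds
  lat <- ability + stats::rnorm(length(ability), 0, model$subject_noise_sd)
  thr <- matrix(NA_real_, length(ability), 8)
  for (y in unique(year)) thr[year == y, ] <-
      matrix(gcse_thresholds(y, model), sum(year == y), 8, byrow = TRUE)
  idx <- 9L - rowSums(lat >= thr)    # 1 = A* ... 9 = U
  grade_levels()[idx]
}

gcse_subjects <- function() {
  c("maths", "english", "science", "history", "geography", "french", "art",
    "design")
}

# regenerate the exam and SEN records implied by a vector of abilities
outcomes_for <- function(pupil_id, ability, gcse_year, model, last_exam_year) {
  n <- length(ability)
  has_gcse <- gcse_year <= last_exam_year &
    stats::runif(n) >= model$p_missing_gcse
  subs <- gcse_subjects()
  idx <- which(has_gcse)
  gcse <- if (length(idx)) {
    g <- data.frame(
      pupil_id = rep(pupil_id[idx], length(subs)),
      subject = rep(subs, each = length(idx)),
      grade = unlist(lapply(subs, function(s)
        draw_grades(ability[idx], gcse_year[idx], model))),
      stringsAsFactors = FALSE)
    g$points <- unname(gcse_points_map()[g$grade])
    g
  } else {
    data.frame(pupil_id = character(0), subject = character(0),
               grade = character(0), points = numeric(0))
  }
  has_ks2 <- stats::runif(n) >= model$p_missing_ks2
  ks2_maths <- ifelse(has_ks2, pmin(100, pmax(0, round(
    50 + 10 * (ability + stats::rnorm(n, 0, model$subject_noise_sd))))), NA)
  ks2_english <- ifelse(has_ks2, pmin(100, pmax(0, round(
    50 + 10 * (ability + stats::rnorm(n, 0, model$subject_noise_sd))))), NA)
  sen <- stats::rbinom(n, 1, stats::plogis(
    model$sen_intercept + model$sen_slope * ability))
  list(gcse = gcse, ks2_maths = ks2_maths, ks2_english = ks2_english,
       sen_ever = sen)
}

#' Simulate a national pupil register
#'
#' Generates `population_size` pupils with identities (name, date of birth,
#' postcode with local authority), a standard-normal latent ability, exam
#' records at ages 11 and 16 drawn from the configured national grade
#' distribution with per-year threshold drift, and special-educational-needs
#' status. Identifier histories carry the postcode observed at school
#' censuses; with probability `error_model$p_unrecorded_move` the family
#' moved between birth and school entry, so the census postcode differs from
#' the birth postcode that trial records would hold.
#'
#' @param population_size number of pupils.
#' @param outcome_model an [outcome_model()].
#' @param error_model an [error_model()].
#' @param seed integer seed; output is a pure function of the arguments.
#' @param lookup optional [make_postcode_lookup()]; generated if NULL.
#' @param birth_from,birth_to date-of-birth window.
#' @param last_exam_year last summer exam year observable at linkage; pupils
#'   reaching age 16 later have no GCSE record (the nucleotide-trial cohort).
#' @return object of class `pupil_register`: list of data.frames `pupils`,
#'   `identifiers`, `gcse`, the per-year `national_scale`, and the `lookup`.
#' @export
simulate_register <- function(population_size, outcome_model = NULL,
                              error_model = NULL, seed = 1, lookup = NULL,
                              birth_from = "1992-06-01",
                              birth_to = "2002-06-30",
                              last_exam_year = 2016) {
  model <- outcome_model %||% dormantlink::outcome_model()
  err <- error_model %||% dormantlink::error_model()
  stopifnot(population_size >= 1)
  if (is.null(lookup)) lookup <- make_postcode_lookup(seed = seed)
  set.seed(seed)
  n <- population_size
  pupil_id <- sprintf("P%06d", seq_len(n))
  forename <- sample(.forenames, n, TRUE)
  surname <- sample(.surnames, n, TRUE)
  sex <- sample(c("male", "female"), n, TRUE)
  dob <- random_dates(n, birth_from, birth_to)
  pci <- sample(nrow(lookup$table), n, TRUE)
  postcode <- lookup$table$postcode[pci]
  authority <- lookup$table$authority[pci]
  ability <- stats::rnorm(n)
  gcse_year <- academic_year_turning(dob, 16L)
  in_state <- stats::runif(n) >= 0.01

  # census-view postcode: unrecorded movers show a different address,
  # usually within the same or a neighbouring authority
  moved <- stats::runif(n) < err$p_unrecorded_move
  reg_postcode <- postcode
  reg_authority <- authority
  if (any(moved)) {
    idx <- which(moved)
    local_move <- stats::runif(length(idx)) < 0.7
    new_pc <- integer(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (local_move[k]) {
        pool <- which(lookup$table$authority %in%
                        c(authority[i], lookup$neighbours[[authority[i]]]) &
                        lookup$table$postcode != postcode[i])
      } else {
        pool <- which(lookup$table$postcode != postcode[i])
      }
      new_pc[k] <- if (length(pool)) pool[sample.int(length(pool), 1)] else pci[i]
    }
    reg_postcode[idx] <- lookup$table$postcode[new_pc]
    reg_authority[idx] <- lookup$table$authority[new_pc]
  }

  out <- outcomes_for(pupil_id, ability, gcse_year, model, last_exam_year)
  pupils <- data.frame(pupil_id = pupil_id, forename = forename,
                       surname = surname, sex = sex, dob = dob,
                       postcode = postcode, authority = authority,
                       reg_postcode = reg_postcode,
                       reg_authority = reg_authority,
                       ability = ability, in_state_census = in_state,
                       sen_ever = out$sen_ever, ks2_maths = out$ks2_maths,
                       ks2_english = out$ks2_english,
                       ks2_year = academic_year_turning(dob, 11L),
                       gcse_year = gcse_year, stringsAsFactors = FALSE)
  reg <- structure(list(pupils = pupils,
                        identifiers = register_identifiers(pupils),
                        gcse = out$gcse,
                        national_scale = national_scale_for_years(
                          sort(unique(gcse_year)), model),
                        lookup = lookup,
                        params = list(model = model, error_model = err,
                                      last_exam_year = last_exam_year,
                                      seed = seed)),
                   class = "pupil_register")
  reg
}

register_identifiers <- function(pupils) {
  data.frame(pupil_id = pupils$pupil_id,
             census_year = academic_year_turning(pupils$dob, 5L),
             forename = pupils$forename, surname = pupils$surname,
             dob = pupils$dob, postcode = pupils$reg_postcode,
             authority = pupils$reg_authority, stringsAsFactors = FALSE)
}

#' @export
print.pupil_register <- function(x, ...) {
  cat("<pupil_register> ", nrow(x$pupils), " pupils, ",
      nrow(x$gcse), " GCSE subject records, exam years ",
      min(x$national_scale$year), "-", max(x$national_scale$year), "\n",
      sep = "")
  invisible(x)
}

# permuted blocks of randomly chosen (even) length; exact target totals are
# restored, if needed, by flipping allocations drawn from the final block
permuted_block_sequence <- function(n, block_lengths) {
  out <- character(0)
  while (length(out) < n) {
    bl <- block_lengths[sample.int(length(block_lengths), 1)]
    out <- c(out, sample(rep(c("modified", "standard"), bl / 2)))
  }
  out[seq_len(n)]
}

allocate_arms <- function(n_by_stratum, n_modified, n_standard,
                          block_lengths) {
  seqs <- lapply(n_by_stratum, permuted_block_sequence,
                 block_lengths = block_lengths)
  arms <- unlist(seqs, use.names = FALSE)
  excess <- sum(arms == "modified") - n_modified
  if (excess != 0) {
    from <- if (excess > 0) "modified" else "standard"
    to <- if (excess > 0) "standard" else "modified"
    # flip within the trailing (possibly incomplete) blocks only
    tail_idx <- unlist(mapply(function(s, off) off + which(
      s == from & seq_along(s) > length(s) - max(block_lengths)),
      seqs, cumsum(c(0, utils::head(lengths(seqs), -1))),
      SIMPLIFY = FALSE))
    flip <- sample(tail_idx, min(abs(excess), length(tail_idx)))
    arms[flip] <- to
    # any residual imbalance (tiny strata): flip anywhere
    excess <- sum(arms == "modified") - n_modified
    if (excess != 0) {
      from <- if (excess > 0) "modified" else "standard"
      to <- if (excess > 0) "standard" else "modified"
      arms[sample(which(arms == from), abs(excess))] <- to
    }
  }
  arms
}

#' Simulate the seven trial cohorts from a register
#'
#' Draws each trial's participants from register pupils born in the trial's
#' recruitment window (stratified to the trial's sex ratio), assigns arms by
#' permuted blocks of randomly chosen length within centre strata (trimmed to
#' reproduce the published per-arm totals), samples baseline covariates from
#' the published parametric summaries, creates twin pairs sharing date of
#' birth, surname and postcode, marks infant deaths (removed from the
#' register: they never enter school), recomputes participant ability under
#' the outcome model (covariate effects + population deficit + arm effect)
#' and regenerates those pupils' register exam records accordingly, and
#' writes the trial-side identifier contact history.
#'
#' @param specs a [trial_specs()] table (possibly subset).
#' @param register a [simulate_register()] object; returned updated.
#' @param outcome_model an [outcome_model()]; NULL uses the register's.
#' @param seed integer seed.
#' @param twin_frac fraction of participants in a twin pair, by population
#'   class (preterm trials carry more multiple births).
#' @param death_prob probability of infant death, by population class.
#' @return object of class `trial_cohort`: list with `participants`,
#'   `contacts`, `truth` (participant_id, pupil_id; NA when the child has no
#'   register record) and the updated `register`.
#' @export
simulate_trials <- function(specs = trial_specs(), register,
                            outcome_model = NULL, seed = 1,
                            twin_frac = c(preterm = 0.05, term_sga = 0.01,
                                          term = 0.01),
                            death_prob = c(preterm = 0.03, term_sga = 0.01,
                                           term = 0.005)) {
  model <- outcome_model %||% register$params$model
  set.seed(seed)
  pupils <- register$pupils
  taken <- logical(nrow(pupils))
  parts <- list(); contacts <- list()
  for (t in seq_len(nrow(specs))) {
    sp <- specs[t, ]
    n_mf <- sp$n_modified; n_sf <- sp$n_standard; n <- n_mf + n_sf
    dob_lo <- sp$period_start - sp$rand_age_days - 45
    dob_hi <- sp$period_end - sp$rand_age_days + 45
    elig <- !taken & pupils$dob >= dob_lo & pupils$dob <= dob_hi
    n_male <- stats::rbinom(1, n, sp$p_male)
    pool_m <- which(elig & pupils$sex == "male")
    pool_f <- which(elig & pupils$sex == "female")
    if (length(pool_m) < n_male || length(pool_f) < n - n_male)
      stop("register exhausted for trial ", sp$trial_id,
           ": need ", n, " pupils born ", dob_lo, " to ", dob_hi)
    pick <- c(pool_m[sample.int(length(pool_m), n_male)],
              pool_f[sample.int(length(pool_f), n - n_male)])
    pick <- sample(pick)   # shuffle so randomisation order is not sex-sorted
    taken[pick] <- TRUE
    pp <- pupils[pick, ]
    rand_date <- pmin(pmax(pp$dob + round(stats::rnorm(
      n, sp$rand_age_days, 2 + 0.1 * sp$rand_age_days)), sp$period_start),
      sp$period_end)
    centre <- sample(sp$centres[[1]], n, TRUE)
    ord <- order(centre, rand_date)
    pp <- pp[ord, ]; rand_date <- rand_date[ord]; centre <- centre[ord]
    arm <- allocate_arms(as.integer(table(centre)), n_mf, n_sf,
                         sp$block_lengths[[1]])

    bw <- round(rtruncnorm1(n, sp$bw_mean, sp$bw_sd, sp$bw_min, sp$bw_max))
    ga <- round(rtruncnorm1(n, sp$ga_mean, sp$ga_sd, sp$ga_min, sp$ga_max), 1)
    mage <- round(rtruncnorm1(n, sp$mage_mean, sp$mage_sd, sp$mage_min,
                              sp$mage_max))
    smoking <- stats::rbinom(n, 1, sp$p_smoking)
    degree <- stats::rbinom(n, 1, sp$p_degree)
    smoking[stats::runif(n) < sp$miss_smoking] <- NA
    degree[stats::runif(n) < sp$miss_degree] <- NA

    df <- data.frame(
      participant_id = sprintf("%s-%04d", sp$trial_id, seq_len(n)),
      trial_id = sp$trial_id, arm = arm, sex = pp$sex,
      birth_weight = bw, gestational_age = ga, maternal_age = mage,
      maternal_smoking = smoking, maternal_degree = degree,
      centre = centre, rand_date = rand_date, dob = pp$dob,
      death = FALSE, death_date = as.Date(NA),
      twin_group = NA_character_, true_pupil_id = pp$pupil_id,
      population = sp$population, stringsAsFactors = FALSE)

    # twin pairs: consecutive participants within a centre share dob,
    # surname and postcode; forenames stay distinct
    tf <- twin_frac[[sp$population]] %||% 0.01
    n_pairs <- floor(n * tf / 2)
    if (n_pairs > 0) {
      cand <- order(centre)   # pair within centre
      for (k in seq_len(n_pairs)) {
        i <- cand[2 * k - 1]; j <- cand[2 * k]
        if (df$centre[i] != df$centre[j]) next
        gid <- sprintf("%s-TW%02d", sp$trial_id, k)
        df$twin_group[c(i, j)] <- gid
        df$dob[j] <- df$dob[i]
        df$gestational_age[j] <- df$gestational_age[i]
        df$maternal_age[j] <- df$maternal_age[i]
        df$maternal_smoking[j] <- df$maternal_smoking[i]
        df$maternal_degree[j] <- df$maternal_degree[i]
        # mirror onto the register identity of the co-twin's pupil
        pi <- match(df$true_pupil_id[i], pupils$pupil_id)
        pj <- match(df$true_pupil_id[j], pupils$pupil_id)
        pupils$dob[pj] <- pupils$dob[pi]
        pupils$surname[pj] <- pupils$surname[pi]
        pupils$postcode[pj] <- pupils$postcode[pi]
        pupils$authority[pj] <- pupils$authority[pi]
        pupils$reg_postcode[pj] <- pupils$reg_postcode[pi]
        pupils$reg_authority[pj] <- pupils$reg_authority[pi]
        if (pupils$forename[pj] == pupils$forename[pi]) {
          alt <- setdiff(.forenames, pupils$forename[pi])
          pupils$forename[pj] <- alt[sample.int(length(alt), 1)]
        }
        pupils$gcse_year[pj] <- academic_year_turning(pupils$dob[pj], 16L)
        pupils$ks2_year[pj] <- academic_year_turning(pupils$dob[pj], 11L)
        df$dob[j] <- pupils$dob[pj]
      }
    }

    dp <- death_prob[[sp$population]] %||% 0.005
    died <- stats::runif(n) < dp
    df$death <- died
    df$death_date[died] <- df$dob[died] + sample(30:700, sum(died), TRUE)

    parts[[t]] <- df

    # trial-side contact history: identifiers as held by the trial
    n_contacts <- pmax(1L, round(stats::rnorm(n, sp$mean_contacts,
                                              sp$sd_contacts)))
    rows <- rep(seq_len(n), n_contacts)
    offset <- unlist(lapply(n_contacts, function(k)
      sort(c(0, sample(7:400, k - 1, TRUE)))))
    pidx <- match(df$true_pupil_id, pupils$pupil_id)
    contacts[[t]] <- data.frame(
      participant_id = df$participant_id[rows],
      contact_date = df$rand_date[rows] + offset,
      forename = pupils$forename[pidx][rows],
      surname = pupils$surname[pidx][rows],
      dob = df$dob[rows],
      postcode = pupils$postcode[pidx][rows],  # birth address
      stringsAsFactors = FALSE)
  }

  participants <- do.call(rbind, parts)
  contacts <- do.call(rbind, contacts)
  register$pupils <- pupils

  # recompute participant ability under the trial outcome model and refresh
  # those pupils' register outcome records
  eff <- model$arm_effect
  arm_eff <- if (length(eff) > 1 || !is.null(names(eff))) {
    unname(ifelse(is.na(eff[participants$trial_id]), 0,
                  eff[participants$trial_id]))
  } else rep(eff, nrow(participants))
  z <- function(x) {
    out <- stats::ave(x, participants$trial_id,
                      FUN = function(v) (v - mean(v)) / max(stats::sd(v), 1e-9))
    out
  }
  base_ability <- -unname(model$deficit[participants$population]) +
    model$b_male * (participants$sex == "male") +
    model$b_smoking * ifelse(is.na(participants$maternal_smoking), 0,
                             participants$maternal_smoking) +
    model$b_degree * ifelse(is.na(participants$maternal_degree), 0,
                            participants$maternal_degree) +
    model$b_bw * z(participants$birth_weight) +
    model$b_ga * z(participants$gestational_age) +
    stats::rnorm(nrow(participants), 0, model$resid_sd)
  # arm_effect is contracted in SD units of the observed exam score, which
  # carries subject measurement noise on top of ability: convert it to the
  # ability scale with the realised within-trial outcome SD so the analysis
  # recovers the injected value without attenuation
  outcome_sd <- sqrt(stats::ave(base_ability, participants$trial_id,
                                FUN = stats::var) +
                       model$subject_noise_sd^2)
  ability <- base_ability +
    arm_eff * outcome_sd * (participants$arm == "modified")
  participants$latent_ability <- ability

  pidx <- match(participants$true_pupil_id, register$pupils$pupil_id)
  register$pupils$ability[pidx] <- ability
  new_out <- outcomes_for(participants$true_pupil_id, ability,
                          register$pupils$gcse_year[pidx], model,
                          register$params$last_exam_year)
  register$gcse <- rbind(
    register$gcse[!register$gcse$pupil_id %in% participants$true_pupil_id, ],
    new_out$gcse)
  register$pupils$ks2_maths[pidx] <- new_out$ks2_maths
  register$pupils$ks2_english[pidx] <- new_out$ks2_english
  register$pupils$sen_ever[pidx] <- new_out$sen_ever

  # infant deaths never enter the school system
  dead_pupils <- participants$true_pupil_id[participants$death]
  register <- drop_pupils(register, dead_pupils)
  participants$true_pupil_id[participants$death] <- NA_character_

  register$identifiers <- register_identifiers(register$pupils)
  truth <- data.frame(participant_id = participants$participant_id,
                      trial_id = participants$trial_id,
                      pupil_id = participants$true_pupil_id,
                      stringsAsFactors = FALSE)
  structure(list(participants = participants, contacts = contacts,
                 truth = truth, register = register),
            class = "trial_cohort")
}

drop_pupils <- function(register, ids) {
  if (!length(ids)) return(register)
  register$pupils <- register$pupils[!register$pupils$pupil_id %in% ids, ]
  register$gcse <- register$gcse[!register$gcse$pupil_id %in% ids, ]
  register
}

#' @export
print.trial_cohort <- function(x, ...) {
  tab <- table(x$participants$trial_id, x$participants$arm)
  cat("<trial_cohort> ", nrow(x$participants), " participants in ",
      nrow(tab), " trials; ", sum(x$participants$death), " deaths; ",
      sum(is.na(x$truth$pupil_id)), " without register record\n", sep = "")
  print(tab)
  invisible(x)
}

mutate_string <- function(x) {
  # one random character substitution, guaranteed to change the string
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) == 0) return(s)
    pos <- sample.int(nchar(s), 1)
    repl <- sample(setdiff(LETTERS, toupper(substr(s, pos, pos))), 1)
    substr(s, pos, pos) <- repl
    s
  }, "", USE.NAMES = FALSE)
}

#' Corrupt trial-side identifiers and finalise the ground-truth link table
#'
#' Applies the error model to the simulated cohort: name typos in single
#' contacts, register-side surname changes after follow-up, systematic
#' date-of-birth transcription errors, per-contact missing fields, and
#' register absence (participants whose pupil record is deleted and whose
#' true link becomes NA). The zero model is the identity.
#'
#' @param cohort a [simulate_trials()] object.
#' @param error_model an [error_model()]; NULL uses the register's.
#' @param seed integer seed.
#' @return the updated `trial_cohort` (contacts, truth and register amended).
#' @export
corrupt_identifiers <- function(cohort, error_model = NULL, seed = 1) {
  err <- error_model %||% cohort$register$params$error_model
  set.seed(seed)
  contacts <- cohort$contacts
  parts <- cohort$participants
  reg <- cohort$register
  pid <- unique(contacts$participant_id)

  # name typo: one contact per affected participant gets a character edit
  hit <- pid[stats::runif(length(pid)) < err$p_name_typo]
  if (length(hit)) {
    rows <- vapply(hit, function(p) {
      w <- which(contacts$participant_id == p)
      w[sample.int(length(w), 1)]
    }, integer(1))
    to_sur <- stats::runif(length(rows)) < 0.5
    contacts$surname[rows[to_sur]] <- mutate_string(contacts$surname[rows[to_sur]])
    contacts$forename[rows[!to_sur]] <- mutate_string(contacts$forename[rows[!to_sur]])
  }

  # register surname change after trial follow-up: register rows get a new
  # surname, the trial keeps the old one
  hit <- pid[stats::runif(length(pid)) < err$p_name_change]
  hit_pupil <- parts$true_pupil_id[match(hit, parts$participant_id)]
  hit_pupil <- hit_pupil[!is.na(hit_pupil)]
  if (length(hit_pupil)) {
    i <- match(hit_pupil, reg$pupils$pupil_id)
    reg$pupils$surname[i] <- sample(.surnames, length(i), TRUE)
  }

  # systematic dob transcription error across all of a participant's contacts
  hit <- pid[stats::runif(length(pid)) < err$p_dob_error]
  if (length(hit)) {
    shift <- sample(c(-3:-1, 1:3), length(hit), TRUE)
    m <- match(contacts$participant_id, hit)
    sel <- !is.na(m)
    contacts$dob[sel] <- as.Date(contacts$dob[sel]) + shift[m[sel]]
  }

  # per-contact missing fields
  n <- nrow(contacts)
  contacts$postcode[stats::runif(n) < err$p_missing_field] <- NA
  contacts$forename[stats::runif(n) < err$p_missing_field / 2] <- NA

  # register absence: the child never appears in the state system
  alive <- parts$participant_id[!parts$death]
  hit <- alive[stats::runif(length(alive)) < err$p_register_absent]
  gone <- parts$true_pupil_id[match(hit, parts$participant_id)]
  reg <- drop_pupils(reg, gone[!is.na(gone)])
  parts$true_pupil_id[parts$participant_id %in% hit] <- NA_character_

  reg$identifiers <- register_identifiers(reg$pupils)
  cohort$contacts <- contacts
  cohort$participants <- parts
  cohort$truth <- data.frame(participant_id = parts$participant_id,
                             trial_id = parts$trial_id,
                             pupil_id = parts$true_pupil_id,
                             stringsAsFactors = FALSE)
  cohort$register <- reg
  cohort
}
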