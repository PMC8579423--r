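# shared simulation fixtures, built once per test run and cached

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, build(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

iront_spec <- function() {
  s <- trial_specs()
  s[s$trial_id == "IRONT", ]
}

# single-trial cohort at the iron-trial scale with the default error model,
# taken through the whole linkage, fully deterministic
iront_sim <- function() cached("iront", function() {
  reg <- simulate_register(2500, seed = 42, birth_from = "1992-08-01",
                           birth_to = "1995-07-31")
  co <- corrupt_identifiers(simulate_trials(iront_spec(), reg, seed = 43),
                            seed = 44)
  chron <- build_identifier_chronology(co$contacts, co$register$lookup)
  cand <- score_candidates(generate_candidates(chron, co$register))
  dec <- select_best_links(cand, co$participants)
  list(cohort = co, chron = chron, cand = cand, dec = dec,
       dataset = build_analysis_dataset(co, dec))
})

# all seven trials; `err` switches the corruption regime
full_sim <- function(err) {
  name <- paste0("full_", if (identical(err, zero_error_model())) "zero"
                 else "default")
  cached(name, function() {
    reg <- simulate_register(6000, error_model = err, seed = 101)
    co <- corrupt_identifiers(simulate_trials(trial_specs(), reg,
                                              seed = 102), err, seed = 103)
    chron <- build_identifier_chronology(co$contacts, co$register$lookup)
    cand <- score_candidates(generate_candidates(chron, co$register))
    dec <- select_best_links(cand, co$participants)
    list(cohort = co, cand = cand, dec = dec,
         eval = evaluate_linkage(dec, co$truth))
  })
}

# one full single-trial pipeline replicate (simulate -> corrupt -> link ->
# derive -> impute -> estimate) for the Monte Carlo calibration checks;
# imputes the covariates with missingness plus the primary outcome
pipeline_rep <- function(seed, arm_effect = 0) {
  m <- outcome_model(arm_effect = arm_effect)
  reg <- simulate_register(1000, m, seed = seed,
                           birth_from = "1992-08-01",
                           birth_to = "1995-07-31")
  co <- corrupt_identifiers(simulate_trials(iront_spec(), reg, m,
                                            seed = seed + 1),
                            seed = seed + 2)
  chron <- build_identifier_chronology(co$contacts, co$register$lookup)
  dec <- select_best_links(
    score_candidates(generate_candidates(chron, co$register)),
    co$participants)
  rows <- build_analysis_dataset(co, dec)
  rows <- rows[!rows$death, ]
  mi <- impute_chained(rows, imputation_config(
    m = 15, iterations = 10, seed = seed + 3,
    vars = c("maternal_smoking", "maternal_degree", "sd_maths16")))
  pool_fit(mi, "sd_maths16", "mean_difference", TRUE)
}
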