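#' Default pipeline configuration
#'
#' A fully serialisable list (YAML-ready) from which a run is reproducible
#' given only the seed: register size and observation window, outcome and
#' error model parameters, linkage settings, imputation settings and the
#' analysis grid. Model objects are constructed from these entries inside
#' [run_pipeline()].
#'
#' @param seed integer run seed.
#' @param population_size register size.
#' @return named list.
#' @export
default_config <- function(seed = 20211111, population_size = 12000) {
  list(seed = seed,
       population_size = population_size,
       trials = NULL,   # NULL = all seven
       register = list(birth_from = "1992-06-01", birth_to = "2002-06-30",
                       last_exam_year = 2016),
       outcome_model = list(arm_effect = 0),
       error_model = list(),
       linkage = list(threshold = 0, tie_margin = 0, max_candidates = 4,
                      partial_threshold = 0.8),
       imputation = list(m = 15, iterations = 10),
       outcomes = c("sd_maths16", "sd_english16", "sd_maths11",
                    "sd_english11"),
       binary_outcomes = c("five_plus_gcse_c", "sen_ever"),
       min_observed = 0.3,
       robustness_margin = 0.2)
}

#' Read / write a pipeline configuration as YAML
#' @param path file path.
#' @return for `read_config`, the config list merged over defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg[names(user)] <- user
  cfg
}

#' @rdname read_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

wcsv <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  nrow(x)
}

#' Estimate odds ratios for the binary attainment outcomes
#'
#' Per trial, the multiply-imputed covariate-adjusted logistic estimate with
#' robust variance, pooled by Rubin's rules, on the log-odds scale. Trials
#' whose outcome is observed for too few surviving participants, or with a
#' single observed class, are reported non-estimable (suppressed-cell
#' behaviour).
#'
#' @param dataset an [build_analysis_dataset()] table.
#' @param outcomes binary outcome columns.
#' @param config an [imputation_config()].
#' @param min_observed minimum observed fraction to attempt a fit.
#' @return data.frame like [run_sensitivity_matrix()] with `scale =
#'   "log_or"`.
#' @export
estimate_odds_ratios <- function(dataset,
                                 outcomes = c("five_plus_gcse_c",
                                              "sen_ever"),
                                 config = imputation_config(),
                                 min_observed = 0.3) {
  out <- list()
  for (trial in unique(dataset$trial_id)) {
    rows <- dataset[dataset$trial_id == trial & !dataset$death, ]
    cfg <- config
    cfg$seed <- config$seed + 100 + match(trial, unique(dataset$trial_id))
    cfg$vars <- intersect(
      c("maternal_smoking", "maternal_degree", "birth_weight",
        "gestational_age", "sd_maths16", "sd_english16", "sd_maths11",
        "sd_english11", outcomes), names(rows))
    cfg$vars <- cfg$vars[vapply(cfg$vars, function(v)
      !all(is.na(rows[[v]])), TRUE)]
    mi <- NULL
    for (oc in outcomes) {
      obs <- rows[[oc]][!is.na(rows[[oc]])]
      est <- if (mean(!is.na(rows[[oc]])) < min_observed ||
                 length(unique(obs)) < 2) {
        data.frame(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, W = NA_real_, B = NA_real_,
                   m = cfg$m, note = "insufficient_data",
                   stringsAsFactors = FALSE)
      } else {
        if (is.null(mi)) mi <- impute_chained(rows, cfg)
        pool_fit(mi, oc, "odds_ratio", TRUE)
      }
      out[[paste(trial, oc)]] <- cbind(
        data.frame(trial_id = trial, outcome = oc,
                   analysis = "MI_adjusted", stringsAsFactors = FALSE),
        est, divergent = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

flow_table <- function(participants, decisions, dataset) {
  m <- match(participants$participant_id, decisions$participant_id)
  a <- match(participants$participant_id, dataset$participant_id)
  key <- split(seq_len(nrow(participants)),
               list(participants$trial_id, participants$arm), drop = TRUE)
  out <- do.call(rbind, lapply(key, function(i) {
    st <- decisions$status[m[i]]
    data.frame(trial_id = participants$trial_id[i][1],
               arm = participants$arm[i][1],
               randomised = length(i),
               excluded_death = sum(st == "excluded_death"),
               linked = sum(st == "linked"),
               unlinked = sum(st == "unlinked"),
               gcse_maths_available = sum(!is.na(
                 dataset$points_maths16[a[i]])),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$trial_id, out$arm), ]
  rownames(out) <- NULL
  out
}

#' Run the full reactivation pipeline
#'
#' One call covers simulate, standardise, link, derive, impute, estimate and
#' report: generates the synthetic register and trial cohorts, corrupts
#' identifiers, canonicalises both sources, generates and scores candidate
#' links, selects best links under death/twin constraints, assembles the
#' intention-to-treat dataset, runs the sensitivity-analysis matrix and the
#' binary-outcome models, and writes every stage artefact (plain CSV/JSON)
#' plus a human-readable report into `out_dir`. Reruns with the same config
#' and seed produce byte-identical outputs.
#'
#' @param config a [default_config()]-shaped list.
#' @param out_dir output directory (created).
#' @param quiet suppress per-stage logging?
#' @return invisibly, a list with the main in-memory objects.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile(),
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  say <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] seed=%d %s", stage, seed,
                    paste0(..., collapse = "")))
  write_config(config, file.path(out_dir, "config.yaml"))

  specs <- trial_specs()
  if (!is.null(config$trials))
    specs <- specs[specs$trial_id %in% config$trials, ]
  model <- do.call(outcome_model, config$outcome_model %||% list())
  err <- do.call(error_model, config$error_model %||% list())

  lookup <- make_postcode_lookup(seed = child_seed(seed, "register"))
  register <- simulate_register(
    config$population_size, model, err,
    seed = child_seed(seed, "register"), lookup = lookup,
    birth_from = config$register$birth_from,
    birth_to = config$register$birth_to,
    last_exam_year = config$register$last_exam_year)
  say("simulate", "register: ", nrow(register$pupils), " pupils")

  cohort <- simulate_trials(specs, register, model,
                            seed = child_seed(seed, "trials"))
  cohort <- corrupt_identifiers(cohort, err,
                                seed = child_seed(seed, "corrupt"))
  say("simulate", "cohort: ", nrow(cohort$participants), " participants")

  nb <- vapply(cohort$register$lookup$neighbours, paste, "",
               collapse = "|")
  wcsv(cbind(cohort$register$lookup$table,
             neighbours = nb[cohort$register$lookup$table$authority]),
       out_dir, "postcode_lookup.csv")
  wcsv(cohort$participants, out_dir, "trial_register.csv")
  wcsv(cohort$contacts, out_dir, "trial_contacts.csv")
  wcsv(cohort$register$pupils, out_dir, "pupil_register.csv")
  wcsv(cohort$register$identifiers, out_dir, "pupil_identifiers.csv")
  wcsv(cohort$register$gcse, out_dir, "pupil_gcse.csv")
  wcsv(cohort$truth[, c("participant_id", "pupil_id")], out_dir,
       "truth_links.csv")

  chron <- build_identifier_chronology(cohort$contacts,
                                       cohort$register$lookup)
  wcsv(as.data.frame(chron), out_dir, "trial_canonical.csv")
  say("standardise", nrow(chron), " chronology entries")

  weights <- if (is.null(config$weights)) default_match_weights()
  else match_weights(as.data.frame(config$weights))
  cand <- generate_candidates(
    chron, cohort$register,
    max_candidates = config$linkage$max_candidates %||% 4,
    partial_threshold = config$linkage$partial_threshold %||% 0.8)
  cand <- score_candidates(cand, weights)
  decisions <- select_best_links(cand, cohort$participants,
                                 threshold = config$linkage$threshold %||% 0,
                                 tie_margin = config$linkage$tie_margin %||% 0)
  linkrep <- evaluate_linkage(decisions, cohort$truth)
  wcsv(as.data.frame(cand), out_dir, "candidates.csv")
  wcsv(as.data.frame(decisions), out_dir, "links.csv")
  jsonlite::write_json(
    list(precision = linkrep$precision, recall = linkrep$recall,
         link_rate = linkrep$link_rate, per_trial = linkrep$per_trial),
    file.path(out_dir, "linkage_report.json"), auto_unbox = TRUE,
    digits = NA)
  say("link", sum(decisions$status == "linked"), " linked of ",
      nrow(decisions))

  dataset <- build_analysis_dataset(cohort, decisions)
  wcsv(as.data.frame(dataset), out_dir, "analysis_dataset.csv")
  say("derive", nrow(dataset), " analysis rows")

  icfg <- imputation_config(m = config$imputation$m %||% 15,
                            iterations = config$imputation$iterations %||% 10,
                            seed = child_seed(seed, "impute"))
  est_cont <- run_sensitivity_matrix(
    dataset, outcomes = config$outcomes, config = icfg,
    min_observed = config$min_observed %||% 0.3,
    robustness_margin = config$robustness_margin %||% 0.2)
  est_cont$scale <- "sd"
  est_bin <- estimate_odds_ratios(
    dataset, outcomes = config$binary_outcomes, config = icfg,
    min_observed = config$min_observed %||% 0.3)
  if (!is.null(est_bin)) est_bin$scale <- "log_or"
  estimates <- rbind(est_cont, est_bin)
  wcsv(estimates, out_dir, "estimates.csv")
  say("estimate", nrow(estimates), " estimate rows")

  flow <- flow_table(cohort$participants, decisions, dataset)
  wcsv(flow, out_dir, "flow.csv")

  linked_arm <- flow[, c("trial_id", "arm")]
  linked_arm$linked <- flow$gcse_maths_available
  power <- do.call(rbind, lapply(split(linked_arm, linked_arm$trial_id),
    function(x) {
      n1 <- x$linked[x$arm == "modified"]
      n2 <- x$linked[x$arm == "standard"]
      data.frame(trial_id = x$trial_id[1], n1 = n1, n2 = n2,
                 mdes = if (n1 >= 2 && n2 >= 2) mdes(n1, n2) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  power <- power[match(specs$trial_id, power$trial_id), ]
  wcsv(power, out_dir, "power.csv")

  make_report(out_dir)
  invisible(list(cohort = cohort, decisions = decisions,
                 linkage = linkrep, dataset = dataset,
                 estimates = estimates, flow = flow, power = power,
                 out_dir = out_dir))
}

#' Render the human-readable run report
#'
#' Regenerates `report.txt` from the stage artefacts in a completed run
#' directory: the participant flow accounting, linkage quality, the
#' forest-style estimate listing across the five sensitivity analyses with
#' a no-evidence-of-benefit label wherever the confidence interval crosses
#' the null, and the minimum-detectable-effect table. Pure function of the
#' directory contents.
#'
#' @param run_dir a completed [run_pipeline()] directory.
#' @return invisibly, the report lines.
#' @export
make_report <- function(run_dir) {
  need <- c("flow.csv", "linkage_report.json", "estimates.csv", "power.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("missing stage outputs: ", paste(missing, collapse = ", "))
  flow <- utils::read.csv(file.path(run_dir, "flow.csv"))
  linkrep <- jsonlite::read_json(file.path(run_dir, "linkage_report.json"))
  est <- utils::read.csv(file.path(run_dir, "estimates.csv"))
  power <- utils::read.csv(file.path(run_dir, "power.csv"))

  L <- c("Dormant-trial reactivation run report",
         "=====================================", "")
  L <- c(L, sprintf("Randomised: %d   Linked: %d (%.1f%%)",
                    sum(flow$randomised), sum(flow$linked),
                    100 * sum(flow$linked) / sum(flow$randomised)),
         sprintf("Linkage precision %.3f, recall %.3f",
                 linkrep$precision, linkrep$recall), "")
  L <- c(L, "Participant flow (per trial-arm):",
         utils::capture.output(print(flow, row.names = FALSE)), "")
  L <- c(L, "Effect estimates:")
  for (i in seq_len(nrow(est))) {
    e <- est[i, ]
    if (!is.na(e$estimate) && e$scale == "log_or") {
      lab <- if (e$ci_low <= 0 && e$ci_high >= 0) "no evidence of benefit"
      else if (e$ci_low > 0) "higher odds" else "lower odds"
      L <- c(L, sprintf(
        "  %-8s %-18s %-22s OR %5.2f (%4.2f to %4.2f)  %s",
        e$trial_id, e$outcome, e$analysis, exp(e$estimate),
        exp(e$ci_low), exp(e$ci_high), lab))
    } else if (!is.na(e$estimate)) {
      lab <- if (e$ci_low <= 0 && e$ci_high >= 0) "no evidence of benefit"
      else if (e$ci_low > 0) "benefit" else "harm"
      L <- c(L, sprintf(
        "  %-8s %-18s %-22s %6.2f (%5.2f to %5.2f)  %s",
        e$trial_id, e$outcome, e$analysis, e$estimate, e$ci_low,
        e$ci_high, lab))
    } else {
      L <- c(L, sprintf("  %-8s %-18s %-22s not estimable (%s)",
                        e$trial_id, e$outcome, e$analysis, e$note))
    }
  }
  L <- c(L, "", "Minimum detectable differences (SD units, 80% power):",
         utils::capture.output(print(power, row.names = FALSE)))
  writeLines(L, file.path(run_dir, "report.txt"))
  invisible(L)
}
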