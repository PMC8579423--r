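#' Standardise scores internally, within trial
#'
#' z = (x - mean) / sd using the sample SD (n-1 denominator) over the
#' non-missing values of each trial, both arms pooled. This is the reference
#' distribution of the primary analysis: each trial is its own yardstick.
#'
#' @param points numeric scores (NA allowed).
#' @param trial_id grouping vector, recycled to `length(points)`.
#' @return numeric z-scores, NA where input was missing.
#' @export
standardise_internal <- function(points, trial_id) {
  trial_id <- rep_len(trial_id, length(points))
  unsplit(lapply(split(points, trial_id), function(x) {
    obs <- x[!is.na(x)]
    if (length(obs) < 2) return(rep(NA_real_, length(x)))
    s <- stats::sd(obs)
    if (s < .Machine$double.eps^0.5)
      stop("degenerate scale: constant scores within a trial")
    (x - mean(obs)) / s
  }), trial_id)
}

#' Standardise scores externally, against a per-year national reference
#'
#' z = (x - national mean of the exam year) / national SD of that year. Used
#' by the sensitivity analysis that replaces the within-trial reference with
#' the national grade distribution (which also absorbs grade inflation,
#' since the reference moves with the year).
#'
#' @param points numeric scores.
#' @param year exam year per score.
#' @param scale data.frame with `year`, `mean`, `sd` (the register's
#'   `national_scale`).
#' @return numeric z-scores.
#' @export
standardise_external <- function(points, year, scale) {
  i <- match(year, scale$year)
  if (any(is.na(i) & !is.na(points)))
    stop("exam year absent from national scale: ",
         paste(unique(year[is.na(i) & !is.na(points)]), collapse = ", "))
  (points - scale$mean[i]) / scale$sd[i]
}

#' Derive binary attainment outcomes for one pupil
#'
#' `five_plus_gcse_c` is 1 when at least five GCSE subjects were graded C or
#' above AND both mathematics and English are among those at C or above;
#' `sen_ever` is 1 when any census year ever flagged special-educational-
#' needs support. Absent grades give a missing attainment outcome.
#'
#' @param gcse_grades named character vector, subject to letter grade, or a
#'   data.frame with `subject` and `grade`.
#' @param sen_history 0/1 vector of per-year support flags (may be empty).
#' @return list with `five_plus_gcse_c` and `sen_ever` (NA when underived).
#' @export
derive_binary_outcomes <- function(gcse_grades, sen_history = integer(0)) {
  if (is.data.frame(gcse_grades))
    gcse_grades <- stats::setNames(gcse_grades$grade, gcse_grades$subject)
  pts <- gcse_points_map()
  five <- if (length(gcse_grades) == 0 || all(is.na(gcse_grades))) {
    NA_integer_
  } else {
    p <- unname(pts[gcse_grades])
    at_c <- !is.na(p) & p >= pts[["C"]]
    as.integer(sum(at_c) >= 5 &&
                 isTRUE(at_c[match("maths", names(gcse_grades))]) &&
                 isTRUE(at_c[match("english", names(gcse_grades))]))
  }
  sen <- if (length(sen_history) == 0 || all(is.na(sen_history))) NA_integer_
  else as.integer(any(sen_history == 1, na.rm = TRUE))
  list(five_plus_gcse_c = five, sen_ever = sen)
}

#' Assemble the intention-to-treat analysis dataset
#'
#' One row per randomised participant, in the allocated arm, regardless of
#' linkage: unlinked participants keep their baseline covariates with
#' missing outcomes; participants who died are retained with a death flag
#' (they are excluded from imputation and analysis downstream). Linked
#' participants receive their pupil's GCSE mathematics/English points, the
#' age-11 scores, the binary attainment outcomes, and standardised scores:
#' internal (within trial, pooled arms, computed on linked non-deceased
#' complete cases before any imputation) and external (per-year national
#' reference).
#'
#' @param cohort a `trial_cohort`.
#' @param decisions a [select_best_links()] table.
#' @return data.frame of class `analysis_dataset`.
#' @export
build_analysis_dataset <- function(cohort, decisions) {
  parts <- cohort$participants
  reg <- cohort$register
  d <- decisions[match(parts$participant_id, decisions$participant_id), ]
  df <- parts[, c("participant_id", "trial_id", "arm", "sex",
                  "birth_weight", "gestational_age", "maternal_age",
                  "maternal_smoking", "maternal_degree", "centre",
                  "death", "twin_group")]
  df$linked <- d$status == "linked"
  df$pupil_id <- d$pupil_id

  g <- reg$gcse
  key <- function(subj) {
    s <- g[g$subject == subj, ]
    s$points[match(df$pupil_id, s$pupil_id)]
  }
  df$points_maths16 <- key("maths")
  df$points_english16 <- key("english")
  pidx <- match(df$pupil_id, reg$pupils$pupil_id)
  df$ks2_maths <- reg$pupils$ks2_maths[pidx]
  df$ks2_english <- reg$pupils$ks2_english[pidx]
  df$gcse_year <- reg$pupils$gcse_year[pidx]

  # binary outcomes, vectorised over linked pupils with any GCSE record
  at_c <- g$points >= gcse_points_map()[["C"]]
  n_at_c <- tapply(at_c, g$pupil_id, sum)
  core <- g$subject %in% c("maths", "english") & at_c
  core_ok <- tapply(core, g$pupil_id, sum)
  fp <- as.integer(n_at_c[df$pupil_id] >= 5 & core_ok[df$pupil_id] == 2)
  df$five_plus_gcse_c <- ifelse(is.na(df$points_maths16) &
                                  is.na(df$points_english16), NA, fp)
  df$five_plus_gcse_c[is.na(df$five_plus_gcse_c) & !is.na(df$pupil_id) &
                        df$pupil_id %in% g$pupil_id] <- 0L
  df$sen_ever <- reg$pupils$sen_ever[pidx]

  df$sd_maths16 <- standardise_internal(df$points_maths16, df$trial_id)
  df$sd_english16 <- standardise_internal(df$points_english16, df$trial_id)
  df$sd_maths11 <- standardise_internal(df$ks2_maths, df$trial_id)
  df$sd_english11 <- standardise_internal(df$ks2_english, df$trial_id)
  df$sd_maths16_ext <- standardise_external(df$points_maths16, df$gcse_year,
                                            reg$national_scale)
  class(df) <- c("analysis_dataset", "data.frame")
  df
}
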