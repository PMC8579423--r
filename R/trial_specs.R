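#' Default specifications of the seven infant formula trials
#'
#' One row per trial, carrying the design quantities used by the simulator:
#' per-arm randomised sizes, infant population (preterm, term small for
#' gestational age, or term), recruitment centres, randomisation period,
#' mean and SD of identifier contacts per participant, the approximate age
#' at randomisation (days after birth; the iron follow-on trial randomised
#' at nine months), and parametric summaries of the baseline covariates
#' (normal means/SDs truncated to the published ranges for birth weight,
#' gestational age and maternal age; proportions for sex, maternal smoking
#' and maternal degree; per-trial covariate missingness fractions).
#'
#' @return data.frame of class `trial_specs`.
#' @export
trial_specs <- function() {
  s <- data.frame(
    trial_id   = c("NEP", "NETSGA", "LCPUFAP", "LCPUFAT", "IRONT", "PALMT", "NUCLEOT"),
    population = c("preterm", "term_sga", "preterm", "term", "term", "term", "term"),
    n_modified = c(113L, 152L, 96L, 155L, 162L, 103L, 100L),
    n_standard = c(116L, 147L, 100L, 154L, 165L, 100L, 100L),
    period_start = as.Date(c("1993-10-07", "1993-09-21", "1993-08-11",
                             "1993-11-02", "1993-10-26", "1995-05-15",
                             "2000-02-11")),
    period_end   = as.Date(c("1996-11-19", "1996-01-11", "1996-05-11",
                             "1995-06-30", "1995-05-21", "1996-11-26",
                             "2001-10-29")),
    centres = I(list(c("NT", "L", "C", "I"), c("NT", "L", "C"), c("NT", "L"),
                     c("NT", "L"), c("NT", "L", "NW"), "C", c("NT", "L"))),
    mean_contacts = c(5.0, 4.8, 1.7, 4.1, 5.5, 3.1, 2.7),
    sd_contacts   = c(1.5, 1.9, 0.8, 1.8, 1.0, 0.8, 0.9),
    rand_age_days = c(60, 3, 3, 3, 274, 3, 3),
    ga_min = c(25, 37, 25, 37, 35, 37, 37),
    ga_max = c(36, 42, 36, 42, 43, 42, 42),
    ga_mean = c(30.8, 39.25, 30.3, 40.05, 39.8, 40.0, 39.35),
    ga_sd = c(2.5, 1.2, 2.5, 1.2, 1.3, 1.2, 1.2),
    bw_min = c(630, 1400, 640, 2680, 2466, 2460, 2170),
    bw_max = c(2160, 3160, 1850, 4930, 5046, 5400, 5360),
    bw_mean = c(1378, 2568, 1348, 3593, 3476, 3530, 3468),
    bw_sd = c(320, 340, 280, 430, 430, 460, 490),
    mage_min = c(16, 15, 16, 17, 15, 15, 16),
    mage_max = c(44, 42, 39, 44, 40, 42, 40),
    mage_mean = c(28.2, 26.8, 26.4, 27.4, 27.7, 27.5, 27.0),
    mage_sd = c(5.5, 5.5, 5.0, 5.5, 5.0, 5.5, 5.0),
    p_male = c(0.48, 0.49, 0.49, 0.535, 0.51, 0.565, 0.58),
    p_smoking = c(0.35, 0.47, 0.41, 0.245, 0.28, 0.31, 0.335),
    p_degree = c(0.09, 0.045, 0.08, 0.06, 0.10, 0.08, 0.08),
    miss_smoking = c(9, 22, 0, 7, 4, 0, 2) / c(229, 299, 196, 309, 327, 203, 200),
    miss_degree  = c(5, 1, 70, 4, 3, 144, 2) / c(229, 299, 196, 309, 327, 203, 200),
    block_lengths = I(rep(list(c(2L, 4L, 6L)), 7)),
    stringsAsFactors = FALSE
  )
  class(s) <- c("trial_specs", "data.frame")
  s
}

#' Published per-arm linked and randomised counts
#'
#' The participant accounting of the original study: for every trial and arm,
#' the number of participants linked to a pupil record over the number
#' randomised. These printed counts are inputs to the accounting and power
#' calculations; they are not produced by the simulator.
#'
#' @return data.frame with `trial_id`, `arm`, `linked`, `randomised`.
#' @export
linked_counts <- function() {
  data.frame(
    trial_id = rep(c("NEP", "NETSGA", "LCPUFAP", "LCPUFAT", "IRONT", "PALMT",
                     "NUCLEOT"), each = 2),
    arm = rep(c("modified", "standard"), 7),
    linked     = c(108L, 114L, 135L, 134L, 82L, 89L, 137L, 143L, 149L, 150L,
                   98L, 92L, 90L, 86L),
    randomised = c(113L, 116L, 152L, 147L, 96L, 100L, 155L, 154L, 162L, 165L,
                   103L, 100L, 100L, 100L),
    stringsAsFactors = FALSE
  )
}

#' Participant accounting from per-arm linked/randomised counts
#'
#' Sums a per-arm count table into per-trial and overall totals and the
#' overall linkage percentage.
#'
#' @param counts a data.frame as returned by [linked_counts()].
#' @return list with `per_trial` (data.frame), `randomised_total`,
#'   `linked_total`, `link_pct` (percentage, one decimal scale).
#' @export
trial_accounting <- function(counts = linked_counts()) {
  per_trial <- aggregate(cbind(linked, randomised) ~ trial_id, counts, sum)
  per_trial <- per_trial[match(unique(counts$trial_id), per_trial$trial_id), ]
  rownames(per_trial) <- NULL
  linked_total <- sum(counts$linked)
  randomised_total <- sum(counts$randomised)
  list(per_trial = per_trial,
       randomised_total = randomised_total,
       linked_total = linked_total,
       link_pct = 100 * linked_total / randomised_total)
}
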