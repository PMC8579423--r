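`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage child seed from a single run seed
#'
#' All randomness in the package fans out from one integer seed. Each pipeline
#' stage draws its own child seed so that, for example, regenerating the trial
#' cohorts does not perturb the register. The splitting rule is a fixed affine
#' map of the run seed and the stage's position in the declared stage list;
#' results stay within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer run seed.
#' @param stage character; one of the declared pipeline stages.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stages <- c("register", "trials", "corrupt", "linkage", "impute", "analysis")
  k <- match(stage, stages)
  if (is.na(k)) stop("unknown stage: ", stage)
  as.integer((as.double(seed) * 7L + k * 999983) %% 2147483629)
}

random_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + floor(stats::runif(n) * (as.numeric(to - from) + 1))
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF truncated normal; exact and vectorised
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

academic_year_turning <- function(dob, age) {
  # academic year (labelled by its summer exam year) in which a child born on
  # `dob` reaches `age`: September-August cohorts sit exams in the summer of
  # birth_year + age (+1 for autumn-born children)
  y <- as.integer(format(dob, "%Y"))
  m <- as.integer(format(dob, "%m"))
  y + age + ifelse(m >= 9, 1L, 0L)
}
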