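#' Minimum detectable effect size for a two-arm comparison
#'
#' The standardised difference detectable with two-sided level `alpha` and
#' the given power for analysable group sizes n1, n2 (unit outcome SD):
#' (z_{1-alpha/2} + z_{power}) * sqrt(1/n1 + 1/n2). Strictly decreasing in
#' both group sizes.
#'
#' @param n1,n2 per-arm analysable counts (>= 2).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return minimum detectable difference in SD units.
#' @export
mdes <- function(n1, n2, alpha = 0.05, power = 0.80) {
  if (any(n1 < 2) || any(n2 < 2)) stop("group sizes must be at least 2")
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) * sqrt(1 / n1 + 1 / n2)
}

#' Minimum detectable effects from per-arm linked counts
#'
#' Applies [mdes()] to a per-arm linked-count table (by default the
#' published accounting), giving the detectable standardised difference per
#' trial at the sizes actually linked.
#'
#' @param counts per-arm count table, see [linked_counts()].
#' @param alpha,power passed to [mdes()].
#' @return data.frame trial_id, n1, n2, mdes.
#' @export
mdes_table <- function(counts = linked_counts(), alpha = 0.05,
                       power = 0.80) {
  wide <- do.call(rbind, lapply(split(counts, counts$trial_id), function(x) {
    data.frame(trial_id = x$trial_id[1],
               n1 = x$linked[x$arm == "modified"],
               n2 = x$linked[x$arm == "standard"],
               stringsAsFactors = FALSE)
  }))
  wide <- wide[match(unique(counts$trial_id), wide$trial_id), ]
  wide$mdes <- mdes(wide$n1, wide$n2, alpha, power)
  rownames(wide) <- NULL
  wide
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Pooled estimate = mean of the m estimates; total variance
#' T = W + (1 + 1/m) B with W the mean within-imputation variance and B the
#' between-imputation variance (n-1 denominator). Intervals use the normal
#' reference, matching the 1.96-style confidence intervals reported for
#' large m and n.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances matching squared standard errors.
#' @return list: estimate, W, B, total_var, se, ci_low, ci_high, m.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 1, length(variances) == m)
  W <- mean(variances)
  B <- if (m > 1) stats::var(estimates) else 0
  total <- W + (1 + 1 / m) * B
  se <- sqrt(total)
  est <- mean(estimates)
  z <- stats::qnorm(0.975)
  list(estimate = est, W = W, B = B, total_var = total, se = se,
       ci_low = est - z * se, ci_high = est + z * se, m = m)
}

default_covariates <- function() {
  c("maternal_smoking", "maternal_degree", "sex", "birth_weight",
    "gestational_age", "centre")
}

# numeric design matrix for one trial's data; factors expanded, constant
# columns dropped (e.g. a single-centre trial's centre dummy)
build_design <- function(data, covariates) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)),
               arm = as.numeric(data$arm == "modified"))
  for (v in covariates) {
    if (!v %in% names(data)) next
    x <- data[[v]]
    if (is.character(x) || is.factor(x)) {
      levs <- sort(unique(x[!is.na(x)]))
      if (length(levs) < 2) next
      for (l in levs[-1]) {
        d <- as.numeric(x == l)
        d[is.na(x)] <- NA
        cols[[paste0(v, l)]] <- d
      }
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  keep <- apply(X, 2, function(col) {
    obs <- col[!is.na(col)]
    length(obs) > 0 && stats::sd(obs) > 0
  })
  keep[1] <- TRUE
  X[, keep, drop = FALSE]
}

drop_aliased <- function(X, y) {
  q <- qr(X[!is.na(y), , drop = FALSE])
  if (q$rank < ncol(X)) {
    keep <- q$pivot[seq_len(q$rank)]
    message("dropping collinear columns: ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X
}

hc1_vcov <- function(X, resid, n, k) {
  bread <- solve(crossprod(X))
  meat <- crossprod(X * resid)
  n / (n - k) * bread %*% meat %*% bread
}

#' Mean difference between arms by covariate-adjusted linear regression
#'
#' Ordinary least squares of the (standardised) outcome on the arm
#' indicator, optionally with the pre-specified baseline covariates
#' (maternal smoking, maternal education, infant sex, birth weight,
#' gestational age, study centre). The variance is the HC1
#' heteroscedasticity-robust sandwich,
#' (X'X)^-1 X' diag(e^2) X (X'X)^-1 scaled by n/(n-k), at the individual
#' level. Rows with missing model variables are dropped, which is exactly
#' the complete-case analysis when the input has not been imputed.
#' Collinear columns are dropped with a message.
#'
#' @param data one trial's analysis rows (deceased excluded).
#' @param outcome outcome column name.
#' @param adjusted include the baseline covariates?
#' @param covariates covariate column names used when adjusted.
#' @return list: estimate (SD units), se, ci_low, ci_high, n.
#' @export
fit_mean_difference <- function(data, outcome, adjusted = TRUE,
                                covariates = default_covariates()) {
  X <- build_design(data, if (adjusted) covariates else character(0))
  y <- data[[outcome]]
  ok <- !is.na(y) & stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(y) < ncol(X) + 1) stop("too few complete cases for the model")
  X <- drop_aliased(X, y)
  fit <- stats::lm.fit(X, y)
  n <- length(y); k <- ncol(X)
  V <- hc1_vcov(X, fit$residuals, n, k)
  est <- fit$coefficients[["arm"]]
  se <- sqrt(V["arm", "arm"])
  z <- stats::qnorm(0.975)
  list(estimate = est, se = se, ci_low = est - z * se,
       ci_high = est + z * se, n = n)
}

#' Odds ratio between arms by logistic regression with robust variance
#'
#' Maximum-likelihood logistic fit of a binary outcome on the arm indicator
#' (plus covariates when adjusted), with the HC1 sandwich variance on the
#' log-odds scale. A degenerate outcome (a single observed class) is an
#' error; separation is flagged and returned non-estimable by default.
#'
#' @inheritParams fit_mean_difference
#' @param on_separation "na" returns a flagged empty estimate, "error"
#'   raises.
#' @return list: estimate (log odds ratio), se, ci_low, ci_high, or,
#'   or_ci_low, or_ci_high, n, flag.
#' @export
fit_odds_ratio <- function(data, outcome, adjusted = TRUE,
                           covariates = default_covariates(),
                           on_separation = c("na", "error")) {
  on_separation <- match.arg(on_separation)
  X <- build_design(data, if (adjusted) covariates else character(0))
  y <- data[[outcome]]
  ok <- !is.na(y) & stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(unique(y)) < 2)
    stop("degenerate binary outcome: a single class observed")
  X <- drop_aliased(X, y)
  fit <- suppressWarnings(stats::glm.fit(X, y,
                                         family = stats::binomial()))
  sep <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (sep) {
    if (on_separation == "error") stop("separation in logistic model")
    return(list(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, or = NA_real_, or_ci_low = NA_real_,
                or_ci_high = NA_real_, n = length(y),
                flag = "separation"))
  }
  n <- length(y); k <- ncol(X)
  mu <- fit$fitted.values
  Xw <- X * (mu * (1 - mu))
  bread <- solve(crossprod(X, Xw))
  meat <- crossprod(X * (y - mu))
  V <- n / (n - k) * bread %*% meat %*% bread
  est <- fit$coefficients[["arm"]]
  se <- sqrt(V["arm", "arm"])
  z <- stats::qnorm(0.975)
  list(estimate = est, se = se, ci_low = est - z * se,
       ci_high = est + z * se, or = exp(est),
       or_ci_low = exp(est - z * se), or_ci_high = exp(est + z * se),
       n = n, flag = "")
}

#' Configuration for chained multiple imputation
#'
#' @param m number of imputations.
#' @param iterations Gibbs sweeps per chain after initialisation.
#' @param seed integer seed.
#' @param vars variables to impute; NULL selects the standard outcome and
#'   covariate set present in the data.
#' @return list of class `imputation_config`.
#' @export
imputation_config <- function(m = 15, iterations = 10, seed = 1,
                              vars = NULL) {
  stopifnot(m >= 1, iterations >= 1)
  structure(list(m = m, iterations = iterations, seed = seed, vars = vars),
            class = "imputation_config")
}

draw_continuous <- function(X_obs, y_obs, X_mis) {
  q <- qr(X_obs)
  keep <- q$pivot[seq_len(q$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]; X_mis <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(X_obs, y_obs)
  n <- length(y_obs); p <- ncol(X_obs)
  rss <- sum(fit$residuals^2)
  df <- max(n - p, 1)
  sigma2 <- rss / stats::rchisq(1, df)
  XtXinv <- chol2inv(chol(crossprod(X_obs)))
  beta <- fit$coefficients +
    t(chol(sigma2 * XtXinv)) %*% stats::rnorm(p)
  drop(X_mis %*% beta) + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

# bare-bones logistic IRLS; much faster than glm.fit in the imputation loop
fast_logit <- function(X, y, maxit = 20, tol = 1e-7) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    new <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(new)) return(NULL)
    done <- max(abs(new - beta)) < tol
    beta <- drop(new)
    if (done) return(list(coef = beta, converged = TRUE,
                          fitted = stats::plogis(drop(X %*% beta))))
  }
  list(coef = beta, converged = FALSE, fitted = stats::plogis(drop(X %*% beta)))
}

draw_binary <- function(X_obs, y_obs, X_mis) {
  q <- qr(X_obs)
  keep <- q$pivot[seq_len(q$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]; X_mis <- X_mis[, keep, drop = FALSE]
  fit <- fast_logit(X_obs, y_obs)
  if (is.null(fit) || !fit$converged || any(abs(fit$coef) > 15)) {
    # separation or failure: fall back to observed-prevalence draws
    p <- mean(y_obs)
    return(stats::rbinom(nrow(X_mis), 1, p))
  }
  W <- pmax(fit$fitted * (1 - fit$fitted), 1e-10)
  V <- chol2inv(chol(crossprod(X_obs * sqrt(W))))
  beta <- fit$coef + t(chol(V)) %*% stats::rnorm(ncol(X_obs))
  stats::rbinom(nrow(X_mis), 1, stats::plogis(drop(X_mis %*% beta)))
}

#' Multiple imputation by chained equations
#'
#' Imputes missing outcomes and covariates with m independent chains of
#' iterated conditional draws: continuous variables by Bayesian linear
#' regression (posterior draws of coefficients and residual variance, then
#' predictive draws), binary variables by logistic regression with
#' approximate posterior coefficient draws and Bernoulli predictive draws.
#' Variables are visited in ascending missingness order (covariates
#' typically first, outcomes last); chains initialise from random draws of
#' the observed values. Deceased participants must be excluded before
#' imputation and never appear in any completed dataset. With no
#' missingness among the modelled variables the m completed datasets are
#' identical copies of the input.
#'
#' @param data one trial's analysis rows (deceased excluded beforehand).
#' @param config an [imputation_config()].
#' @return object of class `mi_set`: list with `datasets` (m completed
#'   data.frames), `m`, `config`, `imputed_vars`.
#' @export
impute_chained <- function(data, config = imputation_config()) {
  if (any(data$death %||% FALSE))
    stop("deceased participants must be excluded before imputation")
  vars <- config$vars %||% intersect(
    c("maternal_smoking", "maternal_degree", "birth_weight",
      "gestational_age", "sd_maths16", "sd_english16", "sd_maths11",
      "sd_english11", "five_plus_gcse_c", "sen_ever"),
    names(data))
  n_mis <- vapply(vars, function(v) sum(is.na(data[[v]])), 0L)
  if (any(n_mis == nrow(data)))
    stop("variable(s) 100% missing: ",
         paste(vars[n_mis == nrow(data)], collapse = ", "))
  to_impute <- names(n_mis)[n_mis > 0]   # all vars stay as predictors
  if (!length(to_impute)) {
    return(structure(list(datasets = rep(list(data), config$m),
                          m = config$m, config = config,
                          imputed_vars = character(0)),
                     class = "mi_set"))
  }
  set.seed(config$seed)
  to_impute <- to_impute[order(n_mis[to_impute])]
  is_binary <- vapply(to_impute, function(v) {
    obs <- data[[v]][!is.na(data[[v]])]
    all(obs %in% c(0, 1))
  }, TRUE)
  fixed <- build_design(data, intersect(c("sex", "centre"), names(data)))
  datasets <- vector("list", config$m)
  for (imp in seq_len(config$m)) {
    cur <- data
    for (v in to_impute) {
      mis <- is.na(cur[[v]])
      cur[[v]][mis] <- sample(cur[[v]][!mis], sum(mis), TRUE)
    }
    for (it in seq_len(config$iterations)) {
      for (v in to_impute) {
        mis <- is.na(data[[v]])
        others <- setdiff(vars, v)
        X <- cbind(fixed,
                   as.matrix(as.data.frame(cur[others],
                                           check.names = FALSE)))
        X_obs <- X[!mis, , drop = FALSE]
        X_mis <- X[mis, , drop = FALSE]
        cur[[v]][mis] <- if (is_binary[[v]]) {
          draw_binary(X_obs, data[[v]][!mis], X_mis)
        } else {
          draw_continuous(X_obs, data[[v]][!mis], X_mis)
        }
      }
    }
    datasets[[imp]] <- cur
  }
  structure(list(datasets = datasets, m = config$m, config = config,
                 imputed_vars = to_impute),
            class = "mi_set")
}

#' @export
print.mi_set <- function(x, ...) {
  cat("<mi_set> m = ", x$m, ", imputed: ",
      if (length(x$imputed_vars)) paste(x$imputed_vars, collapse = ", ")
      else "(nothing missing)", "\n", sep = "")
  invisible(x)
}

#' Fit an effect model in every completed dataset and pool
#'
#' @param imputations an [impute_chained()] object (or a bare data.frame,
#'   treated as m = 1 complete data).
#' @param outcome outcome column name.
#' @param type mean difference (linear) or odds ratio (logistic).
#' @param adjusted include baseline covariates?
#' @param ... passed to the fitter.
#' @return one-row data.frame: estimate, se, ci_low, ci_high, W, B, m, note.
#' @export
pool_fit <- function(imputations, outcome,
                     type = c("mean_difference", "odds_ratio"),
                     adjusted = TRUE, ...) {
  type <- match.arg(type)
  dats <- if (inherits(imputations, "mi_set")) imputations$datasets
  else list(imputations)
  fitter <- if (type == "mean_difference") fit_mean_difference
  else fit_odds_ratio
  fits <- lapply(dats, function(d) fitter(d, outcome, adjusted, ...))
  est <- vapply(fits, `[[`, 0, "estimate")
  if (anyNA(est)) {
    return(data.frame(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, W = NA_real_, B = NA_real_,
                      m = length(dats), note = "non_estimable",
                      stringsAsFactors = FALSE))
  }
  pooled <- pool_rubin(est, vapply(fits, `[[`, 0, "se")^2)
  data.frame(estimate = pooled$estimate, se = pooled$se,
             ci_low = pooled$ci_low, ci_high = pooled$ci_high,
             W = pooled$W, B = pooled$B, m = pooled$m, note = "",
             stringsAsFactors = FALSE)
}

#' Run the sensitivity-analysis matrix for one or more trials
#'
#' For every trial and continuous outcome, five labelled analyses: the
#' primary multiply-imputed adjusted analysis, unadjusted multiple
#' imputation, adjusted and unadjusted complete-case analyses, and the
#' externally standardised (national reference) adjusted analysis. Cells
#' whose outcome is observed for less than `min_observed` of surviving
#' participants are reported non-estimable (the nucleotide-trial GCSE
#' situation). Any pair of estimable cells differing by more than
#' `robustness_margin` SD flags the trial-outcome as divergent.
#'
#' @param dataset an [build_analysis_dataset()] table.
#' @param outcomes continuous outcome columns to analyse.
#' @param config an [imputation_config()].
#' @param min_observed minimum observed outcome fraction to attempt a fit.
#' @param robustness_margin SD-unit margin for the divergence flag.
#' @return data.frame: trial_id, outcome, analysis, estimate, se, ci_low,
#'   ci_high, W, B, m, note, divergent.
#' @export
run_sensitivity_matrix <- function(dataset, outcomes = "sd_maths16",
                                   config = imputation_config(),
                                   min_observed = 0.3,
                                   robustness_margin = 0.2) {
  labels <- c("MI_adjusted", "MI_unadjusted", "CC_adjusted",
              "CC_unadjusted", "external_standardised")
  out <- list()
  for (trial in unique(dataset$trial_id)) {
    rows <- dataset[dataset$trial_id == trial & !dataset$death, ]
    cfg <- config
    cfg$seed <- config$seed + match(trial, unique(dataset$trial_id))
    cfg$vars <- cfg$vars %||% intersect(
      c("maternal_smoking", "maternal_degree", "birth_weight",
        "gestational_age", outcomes, paste0(outcomes, "_ext"),
        "five_plus_gcse_c", "sen_ever"),
      names(rows))
    cfg$vars <- cfg$vars[vapply(cfg$vars, function(v)
      !all(is.na(rows[[v]])), TRUE)]
    mi <- NULL
    for (oc in outcomes) {
      frac <- mean(!is.na(rows[[oc]]))
      ext_oc <- paste0(oc, "_ext")
      cells <- lapply(labels, function(lab) {
        if (frac < min_observed) {
          return(data.frame(estimate = NA_real_, se = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            W = NA_real_, B = NA_real_, m = cfg$m,
                            note = "insufficient_data",
                            stringsAsFactors = FALSE))
        }
        if (lab %in% c("MI_adjusted", "MI_unadjusted",
                       "external_standardised") && is.null(mi)) {
          mi <<- impute_chained(rows, cfg)
        }
        switch(lab,
          MI_adjusted = pool_fit(mi, oc, "mean_difference", TRUE),
          MI_unadjusted = pool_fit(mi, oc, "mean_difference", FALSE),
          CC_adjusted = pool_fit(rows, oc, "mean_difference", TRUE),
          CC_unadjusted = pool_fit(rows, oc, "mean_difference", FALSE),
          external_standardised = if (ext_oc %in% names(rows)) {
            pool_fit(mi, ext_oc, "mean_difference", TRUE)
          } else {
            data.frame(estimate = NA_real_, se = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_, W = NA_real_,
                       B = NA_real_, m = cfg$m, note = "no_external_scale",
                       stringsAsFactors = FALSE)
          })
      })
      cell_df <- do.call(rbind, cells)
      cell_df <- cbind(data.frame(trial_id = trial, outcome = oc,
                                  analysis = labels,
                                  stringsAsFactors = FALSE), cell_df)
      est <- cell_df$estimate[cell_df$note == ""]
      cell_df$divergent <- length(est) > 1 &&
        (max(est) - min(est)) > robustness_margin
      out[[paste(trial, oc)]] <- cell_df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
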