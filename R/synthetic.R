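#' Configuration for one synthetic cohort
#'
#' Builds and validates the parameter set from which [generate_cohort()]
#' simulates a person-level cohort: sample size, moments of the baseline
#' covariates, their correlation structure, follow-up distribution, true
#' per-SD log hazard ratios, and baseline log hazards for fracture and death.
#'
#' Continuous covariates (age, BMI, muscle cross-sectional area, muscle
#' density, femoral-neck BMD T-score, and the latent log-FRAX variables) are
#' drawn from a correlated multivariate normal; FRAX 10-year probabilities
#' are log-normal (moment-matched to the configured mean/SD) clipped to
#' (0, 100]. Events are simulated in discrete time on the same 1-month grid
#' the estimator uses, so generator and fitted model share one probability
#' space: in each month the fracture hazard is
#' \deqn{\lambda = \exp(\beta_0 + \beta_t t + \beta_a \,\mathrm{age}(t) +
#'   \sum_x \beta_x x_{std})}
#' and an event occurs with probability \eqn{1 - \exp(-\lambda\,\Delta t)}.
#' Death competes with fracture through its own log-linear hazard in current
#' age; within a month, fracture is evaluated before death, so a subject who
#' fractures and dies in the same month contributes the fracture.
#'
#' @param name cohort label.
#' @param n number of subjects (>= 1).
#' @param age_mean,age_sd baseline age, years.
#' @param bmi_mean,bmi_sd body mass index, kg/m^2.
#' @param csa_mean,csa_sd calf muscle cross-sectional area, cm^2.
#' @param density_mean,density_sd calf muscle density, mg/cm^3.
#' @param tscore_mean,tscore_sd femoral-neck BMD T-score, SD units.
#' @param frax_mof_wo_mean,frax_mof_wo_sd FRAX major-osteoporotic-fracture
#'   10-year probability without BMD, percent.
#' @param frax_mof_w_mean,frax_mof_w_sd FRAX probability with BMD, percent.
#' @param frax_missing_prob probability that a subject's FRAX values (both)
#'   are missing, emulating the complete-case FRAX subset.
#' @param prior_fall_prob probability of a self-reported fall in the year
#'   before baseline.
#' @param fu_mean,fu_sd potential follow-up, years (clipped to
#'   \code{[1/12, max_followup]}).
#' @param max_followup administrative censoring horizon, years.
#' @param corr 7x7 correlation matrix over
#'   (age, bmi, csa, density, tscore, lfrax_wo, lfrax_w); must be positive
#'   semi-definite with unit diagonal.
#' @param true_log_hr named numeric vector of true log hazard ratios per
#'   configured SD of the named covariate (names among
#'   \code{c("age","bmi","csa","density","tscore")}; \code{"prior_fall"} is
#'   accepted and applied to the 0/1 indicator).
#' @param baseline_log_hazard fracture-process intercept \eqn{\beta_0}
#'   (log hazard per person-year at age 0, covariates at their means).
#' @param time_coef,age_coef fracture log-hazard slopes per year of time
#'   since baseline and of current age.
#' @param death_log_hazard,death_age_coef mortality intercept and age slope.
#' @param site_probs named probability vector over fracture site codes (see
#'   [site_vocabulary()]) from which each simulated fracture's site is drawn.
#' @param seed integer seed; [generate_cohort()] is byte-reproducible given
#'   the config and seed.
#' @return an object of class \code{cohort_config} (a validated list).
#' @seealso [mros_cohort_configs()] for the three calibrated default cohorts.
#' @export
cohort_config <- function(name, n,
                          age_mean = 75, age_sd = 5,
                          bmi_mean = 26, bmi_sd = 3.5,
                          csa_mean = 50, csa_sd = 9,
                          density_mean = 72, density_sd = 4,
                          tscore_mean = -1, tscore_sd = 1,
                          frax_mof_wo_mean = 10, frax_mof_wo_sd = 5,
                          frax_mof_w_mean = 9, frax_mof_w_sd = 4.5,
                          frax_missing_prob = 0,
                          prior_fall_prob = 0.2,
                          fu_mean = 7, fu_sd = 2,
                          max_followup = 15,
                          corr = default_covariate_corr(),
                          true_log_hr = c(density = log(0.82), tscore = log(0.72)),
                          baseline_log_hazard = log(0.015) - 0.07 * 75,
                          time_coef = 0,
                          age_coef = 0.07,
                          death_log_hazard = log(0.04) - 0.09 * 75,
                          death_age_coef = 0.09,
                          site_probs = c(hip = 0.28, vertebra = 0.14,
                                         wrist = 0.12, shoulder = 0.05,
                                         ribs = 0.08, pelvis = 0.05,
                                         tibia = 0.06, foot = 0.08,
                                         hand = 0.07, skull_face = 0.07),
                          seed = 1L) {
  cfg <- list(name = as.character(name), n = as.integer(n),
              age_mean = age_mean, age_sd = age_sd,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              csa_mean = csa_mean, csa_sd = csa_sd,
              density_mean = density_mean, density_sd = density_sd,
              tscore_mean = tscore_mean, tscore_sd = tscore_sd,
              frax_mof_wo_mean = frax_mof_wo_mean, frax_mof_wo_sd = frax_mof_wo_sd,
              frax_mof_w_mean = frax_mof_w_mean, frax_mof_w_sd = frax_mof_w_sd,
              frax_missing_prob = frax_missing_prob,
              prior_fall_prob = prior_fall_prob,
              fu_mean = fu_mean, fu_sd = fu_sd, max_followup = max_followup,
              corr = corr, true_log_hr = true_log_hr,
              baseline_log_hazard = baseline_log_hazard,
              time_coef = time_coef, age_coef = age_coef,
              death_log_hazard = death_log_hazard,
              death_age_coef = death_age_coef,
              site_probs = site_probs, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n < 1L) stop("cohort_config: n must be >= 1")
  sds <- c(cfg$age_sd, cfg$bmi_sd, cfg$csa_sd, cfg$density_sd, cfg$tscore_sd,
           cfg$frax_mof_wo_sd, cfg$frax_mof_w_sd, cfg$fu_sd)
  if (any(sds <= 0)) stop("cohort_config: all SDs must be > 0")
  if (cfg$prior_fall_prob < 0 || cfg$prior_fall_prob > 1)
    stop("cohort_config: prior_fall_prob must lie in [0, 1]")
  if (cfg$frax_missing_prob < 0 || cfg$frax_missing_prob > 1)
    stop("cohort_config: frax_missing_prob must lie in [0, 1]")
  if (cfg$max_followup <= 0) stop("cohort_config: max_followup must be > 0")
  cr <- cfg$corr
  if (!is.matrix(cr) || nrow(cr) != 7L || ncol(cr) != 7L ||
      max(abs(diag(cr) - 1)) > 1e-12 || max(abs(cr - t(cr))) > 1e-12)
    stop("cohort_config: corr must be a symmetric 7x7 matrix with unit diagonal")
  ev <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("cohort_config: corr is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  allowed <- c("age", "bmi", "csa", "density", "tscore", "prior_fall")
  if (length(cfg$true_log_hr) &&
      !all(names(cfg$true_log_hr) %in% allowed))
    stop("cohort_config: true_log_hr names must be among ",
         paste(allowed, collapse = ", "))
  if (abs(sum(cfg$site_probs) - 1) > 1e-8 || any(cfg$site_probs < 0))
    stop("cohort_config: site_probs must be non-negative and sum to 1")
  invisible(cfg)
}

#' Default correlation matrix of the baseline covariates
#'
#' Correlations among (age, bmi, csa, density, tscore, lfrax_wo, lfrax_w),
#' where the last two are the latent normal variables behind the log-normal
#' FRAX probabilities. The published cohort tables report only means and SDs,
#' so these correlations are modelling assumptions: muscle size tracks body
#' size and bone density; muscle density falls with adiposity and age; FRAX
#' probability rises with age and (for the with-BMD variant) falls steeply
#' with T-score. Override via the \code{corr} argument of [cohort_config()].
#'
#' @return a 7x7 correlation matrix with dimnames.
#' @export
default_covariate_corr <- function() {
  v <- c("age", "bmi", "csa", "density", "tscore", "lfrax_wo", "lfrax_w")
  m <- diag(7)
  dimnames(m) <- list(v, v)
  set <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set("age", "bmi", -0.10); set("age", "csa", -0.25)
  set("age", "density", -0.20); set("age", "tscore", -0.15)
  set("age", "lfrax_wo", 0.45); set("age", "lfrax_w", 0.40)
  set("bmi", "csa", 0.45); set("bmi", "density", -0.25)
  set("bmi", "tscore", 0.25); set("bmi", "lfrax_wo", -0.10)
  set("bmi", "lfrax_w", -0.15)
  set("csa", "density", 0.05); set("csa", "tscore", 0.45)
  set("csa", "lfrax_wo", -0.10); set("csa", "lfrax_w", -0.20)
  set("density", "tscore", -0.10); set("density", "lfrax_wo", -0.05)
  set("density", "lfrax_w", -0.10)
  set("tscore", "lfrax_wo", -0.15); set("tscore", "lfrax_w", -0.55)
  set("lfrax_wo", "lfrax_w", 0.80)
  m
}

# run `expr` under a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one person-level cohort
#'
#' Draws baseline covariates from the configured correlated distribution and
#' simulates fracture and death month-by-month under the log-linear hazards
#' described in [cohort_config()]. All fractures (not just the first) are
#' recorded with a site code drawn from \code{site_probs}, so that nested
#' outcome definitions can be applied downstream; death ends observation;
#' administrative censoring occurs at each subject's potential follow-up.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer overriding \code{config$seed}.
#' @return a data frame with one row per subject and columns
#'   \code{subject_id}, \code{cohort}, \code{age0}, \code{followup},
#'   \code{bmi}, \code{csa}, \code{density}, \code{tscore},
#'   \code{frax_mof_wo}, \code{frax_mof_w}, \code{prior_fall},
#'   \code{fracture_events} (semicolon-delimited \code{site:time} pairs,
#'   empty if none), \code{death_time} and \code{loss_time} (\code{NA} when
#'   absent). Event times are in years from baseline and lie on the monthly
#'   grid (interval ends).
#' @examples
#' cfg <- cohort_config("demo", n = 200, seed = 42)
#' dat <- generate_cohort(cfg)
#' head(dat$fracture_events[nzchar(dat$fracture_events)])
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_local_seed(if (is.null(seed)) config$seed else as.integer(seed),
                  generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n
  z <- MASS::mvrnorm(n, mu = rep(0, 7), Sigma = cfg$corr)
  if (n == 1L) z <- matrix(z, nrow = 1)
  age0    <- cfg$age_mean + cfg$age_sd * z[, 1]
  bmi     <- cfg$bmi_mean + cfg$bmi_sd * z[, 2]
  csa     <- cfg$csa_mean + cfg$csa_sd * z[, 3]
  density <- cfg$density_mean + cfg$density_sd * z[, 4]
  tscore  <- cfg$tscore_mean + cfg$tscore_sd * z[, 5]
  lnorm_from <- function(m, s, zz) {
    sigma2 <- log(1 + s^2 / m^2)
    pmin(exp(log(m) - sigma2 / 2 + sqrt(sigma2) * zz), 100)
  }
  frax_wo <- lnorm_from(cfg$frax_mof_wo_mean, cfg$frax_mof_wo_sd, z[, 6])
  frax_w  <- lnorm_from(cfg$frax_mof_w_mean, cfg$frax_mof_w_sd, z[, 7])
  if (cfg$frax_missing_prob > 0) {
    miss <- stats::runif(n) < cfg$frax_missing_prob
    frax_wo[miss] <- NA_real_
    frax_w[miss] <- NA_real_
  }
  prior_fall <- as.integer(stats::runif(n) < cfg$prior_fall_prob)
  fu <- pmin(pmax(stats::rnorm(n, cfg$fu_mean, cfg$fu_sd), 1 / 12),
             cfg$max_followup)

  # subject-level part of the fracture linear predictor (effects per
  # configured SD, so the generator's truth matches the per-SD estimand)
  std <- list(age = (age0 - cfg$age_mean) / cfg$age_sd,
              bmi = (bmi - cfg$bmi_mean) / cfg$bmi_sd,
              csa = (csa - cfg$csa_mean) / cfg$csa_sd,
              density = (density - cfg$density_mean) / cfg$density_sd,
              tscore = (tscore - cfg$tscore_mean) / cfg$tscore_sd,
              prior_fall = prior_fall)
  lp <- rep(cfg$baseline_log_hazard, n)
  for (v in names(cfg$true_log_hr)) lp <- lp + cfg$true_log_hr[[v]] * std[[v]]

  n_months <- as.integer(ceiling(round(fu * 12, 9)))
  alive <- rep(TRUE, n)
  death_time <- rep(NA_real_, n)
  ev_row <- vector("list", 0L); ev_site <- vector("list", 0L)
  ev_time <- vector("list", 0L)
  site_names <- names(cfg$site_probs)
  for (m in seq_len(max(n_months))) {
    at_risk <- alive & (m <= n_months)
    if (!any(at_risk)) break
    idx <- which(at_risk)
    t0 <- (m - 1) / 12
    end_t <- pmin(m / 12, fu[idx])
    delta <- end_t - t0
    lam_f <- exp(lp[idx] + cfg$time_coef * t0 +
                   cfg$age_coef * (age0[idx] + t0))
    hit <- stats::runif(length(idx)) < 1 - exp(-lam_f * delta)
    if (any(hit)) {
      k <- sum(hit)
      ev_row[[length(ev_row) + 1L]] <- idx[hit]
      ev_site[[length(ev_site) + 1L]] <-
        site_names[sample.int(length(site_names), k, replace = TRUE,
                              prob = cfg$site_probs)]
      ev_time[[length(ev_time) + 1L]] <- end_t[hit]
    }
    lam_d <- exp(cfg$death_log_hazard +
                   cfg$death_age_coef * (age0[idx] + t0))
    die <- stats::runif(length(idx)) < 1 - exp(-lam_d * delta)
    if (any(die)) {
      death_time[idx[die]] <- end_t[die]
      alive[idx[die]] <- FALSE
    }
  }

  events <- rep("", n)
  if (length(ev_row)) {
    er <- unlist(ev_row); es <- unlist(ev_site); et <- unlist(ev_time)
    o <- order(er, et)
    er <- er[o]; es <- es[o]; et <- et[o]
    # %.17g round-trips doubles exactly: event times must compare exactly
    # against death/censoring times after CSV serialization
    pair <- sprintf("%s:%.17g", es, et)
    events[unique(er)] <- vapply(split(pair, er), paste, character(1),
                                 collapse = ";")
  }

  data.frame(
    subject_id = sprintf("%s-%05d", cfg$name, seq_len(n)),
    cohort = cfg$name,
    age0 = age0, followup = fu,
    bmi = bmi, csa = csa, density = density, tscore = tscore,
    frax_mof_wo = frax_wo, frax_mof_w = frax_w,
    prior_fall = prior_fall,
    fracture_events = events,
    death_time = death_time,
    loss_time = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Calibrated three-cohort study configuration
#'
#' Returns configurations for three cohorts of older men ("hk", "sweden",
#' "us") with covariate means/SDs, follow-up distributions, FRAX-complete
#' fractions, fall prevalences and fracture/mortality rates calibrated to the
#' published baseline tables of the MrOS pQCT cohorts. The effect structure
#' shared by all three cohorts encodes the hypothesis the package is built to
#' examine: muscle density and femoral-neck T-score carry direct protective
#' effects on fracture, while muscle cross-sectional area has no direct
#' effect and is associated with fracture only through its correlation with
#' T-score — so its unadjusted gradient of risk is below 1 and attenuates to
#' the null once T-score enters the model.
#'
#' @param n optional vector (length 1 or 3) overriding the per-cohort sample
#'   sizes (defaults 1662, 1521, 991).
#' @param true_log_hr optional named vector replacing each cohort's true
#'   per-SD log hazard ratios.
#' @param seed master seed; each cohort uses \code{seed + cohort index - 1}
#'   as its sub-stream.
#' @return named list of three [cohort_config()] objects.
#' @export
mros_cohort_configs <- function(n = NULL, true_log_hr = NULL, seed = 1L) {
  base <- list(
    hk = list(n = 1662L, age_mean = 73.9, age_sd = 4.9,
              bmi_mean = 23.4, bmi_sd = 3.1, csa_mean = 35.4, csa_sd = 7.0,
              density_mean = 77.0, density_sd = 3.6,
              tscore_mean = -1.41, tscore_sd = 0.91,
              frax_mof_wo_mean = 7.9, frax_mof_wo_sd = 3.4,
              frax_mof_w_mean = 7.2, frax_mof_w_sd = 3.7,
              frax_missing_prob = 1 - 1382 / 1662,
              prior_fall_prob = 0.173,
              fu_mean = 8.1, fu_sd = 2.3,
              any_rate = 161 / 13541.8, death_rate = 0.03,
              site_probs = c(hip = 0.29, vertebra = 0.13, wrist = 0.11,
                             shoulder = 0.05, ribs = 0.08, pelvis = 0.05,
                             tibia = 0.07, foot = 0.08, hand = 0.07,
                             skull_face = 0.07)),
    sweden = list(n = 1521L, age_mean = 79.5, age_sd = 3.4,
                  bmi_mean = 26.2, bmi_sd = 3.3, csa_mean = 38.9, csa_sd = 7.4,
                  density_mean = 69.6, density_sd = 3.7,
                  tscore_mean = -0.92, tscore_sd = 1.02,
                  frax_mof_wo_mean = 15.7, frax_mof_wo_sd = 6.7,
                  frax_mof_w_mean = 11.8, frax_mof_w_sd = 6.7,
                  frax_missing_prob = 1 - 976 / 1521,
                  prior_fall_prob = 0.132,
                  fu_mean = 5.3, fu_sd = 2.0,
                  any_rate = 238 / 8057.5, death_rate = 0.05,
                  site_probs = c(hip = 0.33, vertebra = 0.20, wrist = 0.17,
                                 shoulder = 0.06, ribs = 0.05, pelvis = 0.03,
                                 tibia = 0.03, foot = 0.05, hand = 0.04,
                                 skull_face = 0.04)),
    us = list(n = 991L, age_mean = 77.0, age_sd = 5.1,
              bmi_mean = 27.8, bmi_sd = 3.7, csa_mean = 75.5, csa_sd = 11.8,
              density_mean = 70.5, density_sd = 4.6,
              tscore_mean = -0.53, tscore_sd = 1.06,
              frax_mof_wo_mean = 10.6, frax_mof_wo_sd = 5.0,
              frax_mof_w_mean = 8.2, frax_mof_w_sd = 4.3,
              frax_missing_prob = 1 - 478 / 991,
              prior_fall_prob = 0.232,
              fu_mean = 7.8, fu_sd = 2.2,
              any_rate = 137 / 7777.5, death_rate = 0.04,
              site_probs = c(hip = 0.23, vertebra = 0.13, wrist = 0.10,
                             shoulder = 0.04, ribs = 0.10, pelvis = 0.07,
                             tibia = 0.08, foot = 0.09, hand = 0.08,
                             skull_face = 0.08))
  )
  if (!is.null(n)) {
    n <- as.integer(rep_len(n, 3L))
    for (i in 1:3) base[[i]]$n <- n[i]
  }
  out <- vector("list", 3L)
  names(out) <- names(base)
  for (i in seq_along(base)) {
    b <- base[[i]]
    thr <- if (is.null(true_log_hr)) c(density = log(0.82), tscore = log(0.72))
           else true_log_hr
    out[[i]] <- cohort_config(
      name = names(base)[i], n = b$n,
      age_mean = b$age_mean, age_sd = b$age_sd,
      bmi_mean = b$bmi_mean, bmi_sd = b$bmi_sd,
      csa_mean = b$csa_mean, csa_sd = b$csa_sd,
      density_mean = b$density_mean, density_sd = b$density_sd,
      tscore_mean = b$tscore_mean, tscore_sd = b$tscore_sd,
      frax_mof_wo_mean = b$frax_mof_wo_mean, frax_mof_wo_sd = b$frax_mof_wo_sd,
      frax_mof_w_mean = b$frax_mof_w_mean, frax_mof_w_sd = b$frax_mof_w_sd,
      frax_missing_prob = b$frax_missing_prob,
      prior_fall_prob = b$prior_fall_prob,
      fu_mean = b$fu_mean, fu_sd = b$fu_sd, max_followup = 15,
      true_log_hr = thr,
      baseline_log_hazard = log(b$any_rate) - 0.07 * b$age_mean,
      time_coef = 0, age_coef = 0.07,
      death_log_hazard = log(b$death_rate) - 0.09 * b$age_mean,
      death_age_coef = 0.09,
      site_probs = b$site_probs,
      seed = seed + i - 1L
    )
  }
  out
}

#' Simulate several cohorts into one person-level table
#'
#' @param configs list of [cohort_config()] objects (e.g.
#'   [mros_cohort_configs()]).
#' @param seed optional master seed; cohort i uses \code{seed + i - 1},
#'   overriding each config's own seed.
#' @return row-bound data frame of [generate_cohort()] outputs.
#' @export
generate_cohorts <- function(configs, seed = NULL) {
  stopifnot(length(configs) >= 1L)
  pieces <- lapply(seq_along(configs), function(i) {
    s <- if (is.null(seed)) NULL else as.integer(seed) + i - 1L
    generate_cohort(configs[[i]], seed = s)
  })
  do.call(rbind, pieces)
}

#' Descriptive baseline table by cohort
#'
#' Summarizes a person-level table the way multi-cohort fracture studies
#' present their first table: sample size, total person-years (time to end of
#' observation: minimum of death, loss and potential follow-up), covariate
#' means and SDs, prior-fall prevalence, observed follow-up, and counts and
#' percentages of subjects with at least one qualifying fracture per outcome.
#'
#' @param subjects person-level data frame (see [generate_cohort()]).
#' @param site_map optional replacement site map.
#' @return an object of class \code{fracgr_table_one}: a named list of
#'   per-cohort numeric summaries with a print method that renders the
#'   familiar rows-by-cohorts layout.
#' @export
table_one <- function(subjects, site_map = NULL) {
  if (is.null(subjects) || nrow(subjects) == 0L)
    stop("table_one: empty input")
  cohorts <- split(subjects, subjects$cohort)
  if (any(vapply(cohorts, nrow, 1L) == 0L)) stop("table_one: empty cohort")
  res <- lapply(cohorts, function(d) {
    end_obs <- pmin(d$followup,
                    ifelse(is.na(d$death_time), Inf, d$death_time),
                    ifelse(is.na(d$loss_time), Inf, d$loss_time))
    ev <- sapply(outcome_names(), function(oc) {
      ft <- first_event_time(d, oc, site_map)
      sum(!is.na(ft) & ft <= end_obs)
    })
    msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                         sd = stats::sd(x, na.rm = TRUE),
                         n = sum(!is.na(x)))
    list(n = nrow(d),
         person_years = sum(end_obs),
         age = msd(d$age0), bmi = msd(d$bmi), csa = msd(d$csa),
         density = msd(d$density), tscore = msd(d$tscore),
         frax_mof_wo = msd(d$frax_mof_wo), frax_mof_w = msd(d$frax_mof_w),
         followup = msd(end_obs),
         prior_fall_pct = 100 * mean(d$prior_fall),
         events = ev,
         events_pct = 100 * ev / nrow(d))
  })
  class(res) <- "fracgr_table_one"
  res
}

#' @export
print.fracgr_table_one <- function(x, digits = 1, ...) {
  fmt_msd <- function(s) sprintf("%.*f ± %.*f", digits, s["mean"],
                                 digits, s["sd"])
  rows <- c("n", "Person-years (total)", "Age (years)", "BMI",
            "Muscle CSA (cm2)", "Muscle density (mg/cm3)",
            "FN BMD T-score", "FRAX MOF wo BMD", "FRAX MOF w BMD",
            "Prior fall (%)", "FU (years)",
            paste0(c("Any", "Osteoporotic", "MOF", "Hip"), " fx, n (%)"))
  cols <- lapply(x, function(s) {
    c(sprintf("%d", s$n),
      sprintf("%.1f", s$person_years),
      fmt_msd(s$age), fmt_msd(s$bmi), fmt_msd(s$csa), fmt_msd(s$density),
      sprintf("%.2f ± %.2f", s$tscore["mean"], s$tscore["sd"]),
      fmt_msd(s$frax_mof_wo), fmt_msd(s$frax_mof_w),
      sprintf("%.1f", s$prior_fall_pct), fmt_msd(s$followup),
      sprintf("%d (%.1f)", s$events, s$events_pct))
  })
  out <- data.frame(Characteristic = rows, cols, check.names = FALSE)
  names(out) <- c("Characteristic", names(x))
  print(out, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Read and write person-level cohort CSV files
#'
#' The on-disk schema has one header row, one row per subject, columns as in
#' [generate_cohort()], fracture events serialized as semicolon-delimited
#' \code{site:time} pairs, and missing values as empty fields.
#'
#' @param subjects person-level data frame.
#' @param path file path.
#' @return [read_cohort_csv()] returns the person-level data frame.
#' @export
write_cohort_csv <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(fracture_events = "character"))
  d$fracture_events[is.na(d$fracture_events)] <- ""
  for (col in c("death_time", "loss_time", "frax_mof_wo", "frax_mof_w"))
    if (col %in% names(d)) d[[col]] <- as.numeric(d[[col]])
  d
}
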