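# shared fixtures, built in code

# a minimal one-row (or vectorized) person-level table
make_subjects <- function(n = 1, age0 = 75, followup = 5,
                          fracture_events = "", death_time = NA_real_,
                          loss_time = NA_real_, cohort = "t",
                          csa = 40, density = 72, tscore = -1, bmi = 26,
                          frax_mof_wo = 10, frax_mof_w = 9, prior_fall = 0L) {
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             cohort = cohort, age0 = age0, followup = followup,
             bmi = bmi, csa = csa, density = density, tscore = tscore,
             frax_mof_wo = frax_mof_wo, frax_mof_w = frax_mof_w,
             prior_fall = prior_fall,
             fracture_events = fracture_events,
             death_time = death_time, loss_time = loss_time,
             stringsAsFactors = FALSE)
}

# small cohort config with simple hazards; covariate effects off by default.
# `rate` and `death_rate` are hazards at the mean age (75), so a nonzero
# age_coef tilts the hazard without changing its overall level
quick_config <- function(n = 500, rate = 0.03, death_rate = 0,
                         true_log_hr = c(), fu_mean = 5, fu_sd = 1,
                         age_coef = 0, seed = 7L, ...) {
  cohort_config(
    "t", n = n,
    baseline_log_hazard = if (rate > 0) log(rate) - age_coef * 75 else -Inf,
    age_coef = age_coef, time_coef = 0,
    death_log_hazard = if (death_rate > 0) log(death_rate) else -Inf,
    death_age_coef = 0,
    true_log_hr = true_log_hr,
    fu_mean = fu_mean, fu_sd = fu_sd,
    seed = seed, ...
  )
}

# the independent log-likelihood used by oracle checks (no shared code with
# the fitter beyond the model definition)
pm_loglik <- function(beta, X, y, dt) {
  eta <- drop(X %*% beta)
  sum(y * eta - exp(eta) * dt)
}
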