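# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Mean of a normal truncated to [lo, hi].
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter such that the truncated normal has the requested mean:
# truncating at [lo, hi] shifts the mean, so the generator solves for the
# location that restores the configured target exactly.
truncnorm_location <- function(target_mean, sd, lo, hi) {
  stats::uniroot(
    function(mu) truncnorm_mean(mu, sd, lo, hi) - target_mean,
    lower = target_mean - 3 * sd, upper = target_mean + 3 * sd
  )$root
}

rtruncnorm <- function(n, mu, sd, lo, hi) {
  out <- stats::rnorm(n, mu, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mu, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# Snap a disability value to the valid EDSS grid: 0 or 0.5-multiples in
# [1, 10].  The non-existent value 0.5 rounds up to 1 at or above 0.5 and
# down to 0 below.
snap_edss <- function(x) {
  r <- round(pmin(pmax(x, 0), 10) * 2) / 2
  r[abs(r - 0.5) < 1e-9] <- ifelse(x[abs(r - 0.5) < 1e-9] >= 0.5, 1, 0)
  r
}

#' Configuration of the synthetic registry-cohort simulator
#'
#' Defaults calibrate the generator to the marginal structure of a large
#' national MS registry: 71.4% female; symptom-onset age normal with mean
#' 32.4 and SD 10.2 years (truncated to 5-70 years, with the location
#' re-solved so the truncated mean equals the target); follow-up (disease
#' duration at the latest visit) log-normal with median 14 years; a latent
#' time from onset to SP transition log-normal with median 25 years; annual
#' visits; a relapse process active during the RR phase only; and an EDSS
#' trajectory that mean-reverts on the 0.5-grid during the RR phase and
#' drifts upward after the SP transition.
#'
#' @param n_patients Number of patients.
#' @param female_fraction Probability a patient is female (default 0.714).
#' @param onset_age_mean,onset_age_sd Onset-age distribution in years
#'   (defaults 32.4, 10.2), truncated to `onset_age_range`.
#' @param onset_age_range Truncation bounds (default `c(5, 70)`).
#' @param duration_median_years Median disease duration at the latest visit
#'   (default 14).
#' @param duration_sdlog Log-scale SD of the duration distribution
#'   (default 0.6).
#' @param duration_range Truncation bounds for duration (default `c(1, 50)`).
#' @param visit_interval_mean_years Mean gap between visits (default 1).
#' @param relapse_rate Relapse rate at onset, events/year during the RR
#'   phase (default 0.35), decaying exponentially with disease duration.
#' @param relapse_decay_years e-folding time of the relapse-rate decay
#'   (default 8).
#' @param sp_median_years Median latent time from onset to SP transition
#'   (default 25; `Inf` disables transitions).
#' @param sp_sdlog Log-scale SD of the transition-time distribution
#'   (default 0.7).
#' @param entry_frac_max Registry entry (start of the observed visit record)
#'   is uniform on `[0, entry_frac_max]` of the disease duration, emulating
#'   the left truncation of registry records: patients are often enrolled
#'   years after onset, so their early history is unobserved (default 0.75).
#' @param edss_start_mean Mean initial disability after onset (default 1.5).
#' @param rr_attractor Baseline level toward which the RR-phase walk reverts
#'   (default 1.75); residual relapse disability shifts it upward.
#' @param rr_attractor_sdlog Between-patient severity heterogeneity: each
#'   patient's attractor is multiplied by a log-normal factor with this
#'   log-scale SD (default 0.55).  This yields a small stratum of stable
#'   high-disability RR patients, as seen in registries.
#' @param rr_reversion Mean-reversion rate per year (default 0.25).
#' @param edss_noise_sd Diffusion coefficient of the RR-phase
#'   Ornstein-Uhlenbeck disability walk, points per sqrt-year
#'   (default 0.2).
#' @param sp_drift Upward EDSS drift after SP transition, points/year
#'   (default 0.35).
#' @param relapse_bump Transient EDSS elevation at visits within 30 days
#'   after a relapse (default 1.0).
#' @param relapse_residual_mean Mean permanent disability left by each
#'   relapse (exponential; default 0.15 points).  This produces the heavy
#'   right tail of the RR EDSS distribution seen in registries: a minority
#'   of RR patients carry substantial relapse-related disability.
#' @param label_noise Probability that a patient's clinical label is flipped
#'   (default 0).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       female_fraction = 0.714,
                       onset_age_mean = 32.4,
                       onset_age_sd = 10.2,
                       onset_age_range = c(5, 70),
                       duration_median_years = 14,
                       duration_sdlog = 0.6,
                       duration_range = c(1, 50),
                       visit_interval_mean_years = 1,
                       relapse_rate = 0.35,
                       relapse_decay_years = 8,
                       sp_median_years = 25,
                       sp_sdlog = 0.7,
                       entry_frac_max = 0.75,
                       edss_start_mean = 1.5,
                       rr_attractor = 1.75,
                       rr_attractor_sdlog = 0.55,
                       rr_reversion = 0.25,
                       edss_noise_sd = 0.2,
                       sp_drift = 0.35,
                       relapse_bump = 1.0,
                       relapse_residual_mean = 0.15,
                       label_noise = 0,
                       seed = 1L) {
  if (n_patients < 1 || onset_age_sd < 0 || duration_sdlog < 0 ||
      female_fraction < 0 || female_fraction > 1 ||
      label_noise < 0 || label_noise > 1 ||
      entry_frac_max < 0 || entry_frac_max >= 1 ||
      relapse_rate < 0 || sp_drift < 0 || visit_interval_mean_years <= 0) {
    abort("sim_config(): infeasible configuration.",
          class = "msclassify_config_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic registry cohort
#'
#' Draws demographics, a visit schedule, relapse onsets, a latent SP
#' transition time and an EDSS trajectory for each patient, then assembles
#' and validates the result with [cohort()].  The neurologist-style
#' ("clinical") labels are the generated `assigned_phenotype` and `sp_date`:
#' a patient is SP exactly when the latent transition falls before their
#' last visit.  Fully deterministic given the configured seed.
#'
#' @param config A [sim_config()]; or pass arguments through `...`.
#' @param ... Arguments forwarded to [sim_config()] when `config` is `NULL`.
#' @return An `ms_cohort`.
#' @examples
#' cohort_sim <- simulate_cohort(n_patients = 50, seed = 7)
#' cohort_sim
#' @export
simulate_cohort <- function(config = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  extraction_date <- as.Date("2019-02-01") # fixed reference date

  sex <- ifelse(stats::runif(n) < cfg$female_fraction, "female", "male")
  mu_adj <- truncnorm_location(cfg$onset_age_mean, cfg$onset_age_sd,
                               cfg$onset_age_range[1], cfg$onset_age_range[2])
  onset_age <- rtruncnorm(n, mu_adj, cfg$onset_age_sd,
                          cfg$onset_age_range[1], cfg$onset_age_range[2])
  duration <- stats::rlnorm(n, log(cfg$duration_median_years), cfg$duration_sdlog)
  duration <- pmin(pmax(duration, cfg$duration_range[1]), cfg$duration_range[2])
  t_sp <- if (is.finite(cfg$sp_median_years)) {
    stats::rlnorm(n, log(cfg$sp_median_years), cfg$sp_sdlog)
  } else {
    rep(Inf, n)
  }

  onset_date <- extraction_date - round(duration * 365.25)
  birth_date <- onset_date - round(onset_age * 365.25)

  pid <- sprintf("P%05d", seq_len(n))
  visits_list <- vector("list", n)
  relapses_list <- vector("list", n)

  entry <- stats::runif(n, 0, cfg$entry_frac_max) * duration

  for (i in seq_len(n)) {
    # observed visit record starts at registry entry (left truncation) and
    # ends at the latest follow-up; exponential gaps floored at ~1 month
    tv <- entry[i]
    repeat {
      g <- max(stats::rexp(1, 1 / cfg$visit_interval_mean_years), 1 / 12)
      if (tv[length(tv)] + g >= duration[i]) break
      tv <- c(tv, tv[length(tv)] + g)
    }
    if (duration[i] - tv[length(tv)] > 1 / 24) {
      tv <- c(tv, duration[i])
    } else {
      tv[length(tv)] <- duration[i]
    }

    # relapses: thinned inhomogeneous Poisson during the RR phase, with
    # rate decaying over disease duration
    rr_end <- min(t_sp[i], duration[i])
    lam0 <- cfg$relapse_rate
    t_rel <- numeric(0)
    if (lam0 > 0 && rr_end > 0) {
      t_cur <- 0
      while (TRUE) {
        t_cur <- t_cur + stats::rexp(1, lam0)
        if (t_cur > rr_end) break
        if (stats::runif(1) < exp(-t_cur / cfg$relapse_decay_years)) {
          t_rel <- c(t_rel, t_cur)
        }
      }
    }
    residual <- if (length(t_rel) && cfg$relapse_residual_mean > 0) {
      stats::rexp(length(t_rel), 1 / cfg$relapse_residual_mean)
    } else {
      rep(0, length(t_rel))
    }

    # latent disability path from onset, advanced event-by-event over the
    # sorted union of relapse times, the SP transition and visit times.
    # RR phase: Ornstein-Uhlenbeck reversion (exact discretisation) toward
    # an attractor raised by accumulated relapse residuals.  SP phase:
    # linear upward drift with a soft ratchet.
    kappa <- cfg$rr_reversion
    sigma <- cfg$edss_noise_sd
    ou_sd <- function(dt) {
      if (kappa > 0) sigma * sqrt((1 - exp(-2 * kappa * dt)) / (2 * kappa))
      else sigma * sqrt(dt)
    }
    events <- rbind(
      data.frame(t = tv, type = "visit", jump = 0),
      if (length(t_rel)) data.frame(t = t_rel, type = "relapse", jump = residual),
      if (is.finite(t_sp[i]) && t_sp[i] < duration[i]) {
        data.frame(t = t_sp[i], type = "sp", jump = 0)
      }
    )
    events <- events[order(events$t, events$type != "relapse"), ]

    severity <- stats::rlnorm(1, 0, cfg$rr_attractor_sdlog)
    attractor <- cfg$rr_attractor * severity
    d_cur <- max(stats::rnorm(1, cfg$edss_start_mean * severity, 0.75), 0)
    t_cur <- 0
    in_sp <- FALSE
    d_at_visit <- numeric(length(tv))
    vk <- 0L
    for (e in seq_len(nrow(events))) {
      dt <- events$t[e] - t_cur
      if (dt > 0) {
        if (in_sp) {
          step <- cfg$sp_drift * dt + stats::rnorm(1, 0, 0.3 * sqrt(dt))
          d_cur <- max(d_cur + step, d_cur - 0.25)
        } else {
          d_cur <- attractor + (d_cur - attractor) * exp(-kappa * dt) +
            stats::rnorm(1, 0, ou_sd(dt))
        }
        d_cur <- min(max(d_cur, 0), 10)
        t_cur <- events$t[e]
      }
      if (events$type[e] == "relapse") {
        attractor <- attractor + events$jump[e]
        d_cur <- min(d_cur + events$jump[e], 10)
      } else if (events$type[e] == "sp") {
        in_sp <- TRUE
      } else {
        vk <- vk + 1L
        d_at_visit[vk] <- d_cur
      }
    }

    # transient relapse-related elevation at visits shortly after a relapse
    observed <- d_at_visit
    if (length(t_rel) && cfg$relapse_bump > 0) {
      for (k in seq_along(tv)) {
        since <- tv[k] - t_rel
        if (any(since >= 0 & since <= 30 / 365.25)) {
          observed[k] <- min(observed[k] + cfg$relapse_bump, 10)
        }
      }
    }
    edss <- snap_edss(observed)

    vd <- onset_date[i] + round(tv * 365.25)
    keep <- !duplicated(vd)
    visits_list[[i]] <- tibble::tibble(
      patient_id = pid[i], visit_date = vd[keep], edss = edss[keep]
    )
    # only relapses during the observed record are in the registry
    t_rel_obs <- t_rel[t_rel >= entry[i]]
    if (length(t_rel_obs)) {
      relapses_list[[i]] <- tibble::tibble(
        patient_id = pid[i],
        relapse_date = onset_date[i] + round(t_rel_obs * 365.25)
      )
    }
  }

  is_sp <- t_sp <= duration
  sp_date <- as.Date(ifelse(is_sp,
                            onset_date + round(t_sp * 365.25),
                            NA_real_),
                     origin = "1970-01-01")

  if (cfg$label_noise > 0) {
    flip <- stats::runif(n) < cfg$label_noise
    # a flipped RR patient gets an SP date at the midpoint of follow-up;
    # a flipped SP patient loses the date
    new_sp <- flip & !is_sp
    lost_sp <- flip & is_sp
    sp_date[new_sp] <- onset_date[new_sp] + round(duration[new_sp] / 2 * 365.25)
    sp_date[lost_sp] <- NA
    is_sp <- xor(is_sp, flip)
  }

  patients <- tibble::tibble(
    patient_id = pid,
    sex = sex,
    birth_date = birth_date,
    onset_date = onset_date,
    assigned_phenotype = ifelse(is_sp, "SP", "RR"),
    sp_date = sp_date
  )
  relapses <- dplyr::bind_rows(relapses_list)
  cohort(
    patients,
    dplyr::bind_rows(visits_list),
    if (nrow(relapses) > 0) relapses
  )
}

#' Cohort characteristics by phenotype
#'
#' Registry-style summary stratified by assigned phenotype plus an overall
#' column set: age at the latest visit (mean, SD), percent female, onset age
#' (mean, SD), disease duration at the latest visit (median, IQR), and the
#' latest EDSS score (median, IQR).
#'
#' @param x An `ms_cohort`.
#' @return A tibble with one row per stratum (`RR`, `SP`, `all`); strata
#'   with no patients are omitted.
#' @export
summarize_cohort <- function(x) {
  stopifnot(inherits(x, "ms_cohort"))
  if (nrow(x$patients) == 0) {
    abort("summarize_cohort(): empty cohort.",
          class = "msclassify_domain_error")
  }
  latest <- latest_assessments(x)
  df <- x$patients %>%
    dplyr::left_join(dplyr::select(latest, "patient_id", "visit_date",
                                   "edss", "age"),
                     by = "patient_id") %>%
    dplyr::mutate(
      onset_age = age_at(.data$birth_date, .data$onset_date),
      duration = as.numeric(.data$visit_date - .data$onset_date) / 365.25
    )
  one <- function(d, label) {
    tibble::tibble(
      stratum = label,
      n = nrow(d),
      age_last_mean = mean(d$age, na.rm = TRUE),
      age_last_sd = stats::sd(d$age, na.rm = TRUE),
      female_pct = 100 * mean(d$sex == "female"),
      onset_age_mean = mean(d$onset_age),
      onset_age_sd = stats::sd(d$onset_age),
      duration_median = stats::median(d$duration, na.rm = TRUE),
      duration_q1 = unname(stats::quantile(d$duration, 0.25, na.rm = TRUE)),
      duration_q3 = unname(stats::quantile(d$duration, 0.75, na.rm = TRUE)),
      edss_median = stats::median(d$edss, na.rm = TRUE),
      edss_q1 = unname(stats::quantile(d$edss, 0.25, na.rm = TRUE)),
      edss_q3 = unname(stats::quantile(d$edss, 0.75, na.rm = TRUE))
    )
  }
  out <- list()
  for (ph in c("RR", "SP")) {
    d <- dplyr::filter(df, .data$assigned_phenotype == ph)
    if (nrow(d) > 0) out[[ph]] <- one(d, ph)
  }
  out$all <- one(df, "all")
  dplyr::bind_rows(out)
}
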