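#' Configuration for the synthetic ICU cohort simulator
#'
#' Each stay carries two latent dimensions that the feature panel reads out:
#' an infection-severity process \eqn{s_{t+1} = \rho s_t + \epsilon_t}
#' (AR(1) decay towards recovery) that drives the antibiotic course, and a
#' static frailty score \eqn{f} (comorbidity / organ-failure burden) that
#' mainly drives how long the patient needs intensive care after the
#' infection resolves. Antibiotics run from day 1 until either the observed
#' severity (latent severity plus daily clinician decision noise) falls
#' below `policy_threshold`, a per-stay protocol course cap (guideline
#' durations such as 3, 5 or 7 days) is reached, or the patient leaves the
#' ICU. Mortality log-odds depend on both latents.
#'
#' LOS follows \eqn{LOS_i = b_i + e \cdot L_i} with \eqn{L_i} the realised
#' in-ICU treatment days and recovery time
#' \eqn{b_i = d_i (1 + c \cdot z_i)}, where
#' \eqn{d_i = floor + \min(cap, a\,e^{\beta_s s_{i,1} + \beta_f f_i})} and
#' \eqn{z_i} is standard normal clamped to \eqn{\pm}`los_noise_clamp`. This
#' puts the strong right skew of ICU length-of-stay into the
#' feature-observable component (so an outcome model can learn it) while
#' keeping the residual strictly symmetric and the support positive —
#' the statistical structure the downstream estimator assumes.
#' `cessation_effect_los` is \eqn{e}, the true causal LOS change per
#' treatment day, the parameter the estimation pipeline is asked to recover.
#'
#' The numeric defaults are calibrated against the headline statistics of
#' the ICU population the method targets: mean LOS about 5.6 days (SD about
#' 4.5), treatment-length SD about 3.2, Spearman correlation between LOS
#' and treatment length about 0.77, and a stay-level mortality rate of
#' 18.6%.
#'
#' @param n_stays number of ICU stays to simulate.
#' @param n_features number of dynamic features emitted (default 43).
#' @param severity_init_mean,severity_init_sd admission severity distribution.
#' @param severity_decay per-day AR(1) decay of latent severity in (0, 1).
#' @param severity_noise_sd innovation SD of the severity process.
#' @param missing_rate per feature-day probability of a missing observation.
#' @param informative_missing if `TRUE`, missingness probability increases
#'   with current severity (logit-linear, slope `missing_severity_coef`).
#' @param missing_severity_coef slope of the informative-missingness mode.
#' @param policy_threshold observed-severity threshold below which
#'   antibiotics are stopped.
#' @param policy_sd SD of the daily decision noise added to latent severity
#'   before comparing with `policy_threshold` (clinician variability; this
#'   creates the overlap between stopping and continuing patients that any
#'   synthetic-control estimator requires).
#' @param course_caps,course_cap_probs support and probabilities of the
#'   per-stay protocol course cap in days (guideline-driven fixed durations;
#'   a cap of `max_treatment_days` means no protocol limit).
#' @param min_treatment_days,max_treatment_days course-length clamps (1, 21).
#' @param cessation_effect_los true causal LOS change (days) per day of
#'   antibiotic treatment received.
#' @param los_recovery_floor,los_recovery_scale,los_recovery_exp,frailty_exp,los_recovery_cap
#'   recovery-time location model (see above): floor, scale \eqn{a},
#'   severity exponent \eqn{\beta_s}, frailty exponent \eqn{\beta_f}, cap.
#' @param los_noise_cv,los_noise_clamp multiplicative residual noise:
#'   coefficient of variation and symmetric clamp of the standard-normal
#'   draw. `cv * clamp < 1` is required so recovery time stays positive.
#' @param mortality_base_rate marginal (cohort-level) mortality probability.
#' @param mortality_severity_coef,mortality_frailty_coef log-odds slopes of
#'   mortality in admission severity and frailty.
#' @param discharge_margin minimum days a stay extends past an in-ICU
#'   cessation day (0 disables).
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @param feature_seed RNG seed of the feature measurement model (loadings,
#'   intercepts, noise scales). Kept separate from `seed` so that replicate
#'   cohorts share one fixed "instrument", as hospitals measuring different
#'   patients with the same devices and assays would.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_stays = 1000L,
                       n_features = 43L,
                       severity_init_mean = 2.0,
                       severity_init_sd = 1.1,
                       severity_decay = 0.93,
                       severity_noise_sd = 0.25,
                       missing_rate = 0.30,
                       informative_missing = FALSE,
                       missing_severity_coef = 0.5,
                       policy_threshold = 1.0,
                       policy_sd = 0.6,
                       course_caps = c(2L, 3L, 5L, 8L, 21L),
                       course_cap_probs = c(0.15, 0.15, 0.2, 0.2, 0.3),
                       min_treatment_days = 1L,
                       max_treatment_days = 21L,
                       cessation_effect_los = 0.8,
                       los_recovery_floor = 0.55,
                       los_recovery_scale = 0.34,
                       los_recovery_exp = 0.55,
                       frailty_exp = 1.35,
                       los_recovery_cap = 10,
                       los_noise_cv = 0.45,
                       los_noise_clamp = 1.5,
                       mortality_base_rate = 0.186,
                       mortality_severity_coef = 0.6,
                       mortality_frailty_coef = 0.4,
                       discharge_margin = 0,
                       seed = 1L,
                       feature_seed = 761L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid sim_config field '", field, "': ", what,
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$n_stays) && cfg$n_stays >= 1, "n_stays", "must be >= 1")
  chk(num1(cfg$n_features) && cfg$n_features >= 1, "n_features", "must be >= 1")
  chk(num1(cfg$missing_rate) && cfg$missing_rate >= 0 && cfg$missing_rate < 1,
      "missing_rate", "must be in [0, 1)")
  for (f in c("mortality_base_rate")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f,
        "must be a probability in [0, 1]")
  }
  chk(num1(cfg$severity_decay) && cfg$severity_decay > 0 &&
        cfg$severity_decay < 1, "severity_decay", "must be in (0, 1)")
  for (f in c("severity_init_sd", "severity_noise_sd", "policy_sd",
              "los_recovery_floor", "los_recovery_cap", "los_noise_cv",
              "los_recovery_exp", "frailty_exp", "discharge_margin")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, f, "must be non-negative")
  }
  chk(num1(cfg$los_recovery_scale) && cfg$los_recovery_scale > 0,
      "los_recovery_scale", "must be positive")
  chk(num1(cfg$los_noise_clamp) && cfg$los_noise_clamp > 0 &&
        cfg$los_noise_cv * cfg$los_noise_clamp < 1,
      "los_noise_clamp", "requires cv * clamp < 1 (positive recovery time)")
  chk(is.numeric(cfg$course_caps) && length(cfg$course_caps) >= 1 &&
        all(cfg$course_caps >= 1),
      "course_caps", "must be course lengths >= 1")
  chk(is.numeric(cfg$course_cap_probs) &&
        length(cfg$course_cap_probs) == length(cfg$course_caps) &&
        all(cfg$course_cap_probs >= 0) &&
        abs(sum(cfg$course_cap_probs) - 1) < 1e-8,
      "course_cap_probs", "must be probabilities summing to 1")
  chk(num1(cfg$min_treatment_days) && cfg$min_treatment_days >= 1,
      "min_treatment_days", "must be >= 1")
  chk(num1(cfg$max_treatment_days) &&
        cfg$max_treatment_days >= cfg$min_treatment_days,
      "max_treatment_days", "must be >= min_treatment_days")
  chk(num1(cfg$cessation_effect_los), "cessation_effect_los",
      "must be a finite number")
  chk(num1(cfg$seed), "seed", "must be a finite number")
  invisible(cfg)
}

#' Simulate a synthetic ICU cohort with known counterfactual ground truth
#'
#' Generates long-format daily feature events, a daily antibiotic
#' administration table, stay-level outcome labels, and a ground-truth object
#' holding the latent severity trajectories and the true counterfactual LOS
#' for every antibiotic day under both the stop and the continue scenario.
#' The ground truth is never an input to the estimation pipeline; it exists
#' to validate it.
#'
#' Scenario convention (matching the donor-pool taxonomy used throughout the
#' package): "stop at day t" means day `t` is the first antibiotic-free day,
#' i.e. treatment was received on days `1..t-1`; "continue at day t" means
#' treatment is received on day `t` and the factual policy is followed
#' thereafter. Consequently, for a stay factually treated `L` days, the true
#' counterfactual LOS of stopping at treatment day `t <= L` is
#' `LOS - e * (L - t + 1)` (floored at `t - 1`, presence up to the queried
#' day), and both scenarios equal the realised LOS on the factually-taken
#' action.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   `events` (`stay_id, day, variable, value`; absent rows are missing
#'   observations), `abx` (`stay_id, day, on_antibiotics`),
#'   `labels` (`stay_id, los_days, mortality`), and `ground_truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- as.integer(cfg$n_stays)
  maxd <- as.integer(cfg$max_treatment_days)
  e <- cfg$cessation_effect_los

  # latent severity over the policy horizon; static frailty
  s1 <- pmax(0.05, rnorm(n, cfg$severity_init_mean, cfg$severity_init_sd))
  frailty <- rnorm(n)
  S <- matrix(0, n, maxd)
  S[, 1] <- s1
  for (t in seq_len(maxd - 1L)) {
    S[, t + 1L] <- pmax(0, cfg$severity_decay * S[, t] +
                           rnorm(n, 0, cfg$severity_noise_sd))
  }

  # stopping policy on observed severity; treatment is daily from day 1;
  # per-stay protocol cap on the course length
  obs <- S + matrix(rnorm(n * maxd, 0, cfg$policy_sd), n, maxd)
  below <- obs < cfg$policy_threshold
  below[, seq_len(min(cfg$min_treatment_days, maxd))] <- FALSE
  first_below <- apply(below, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })
  L_policy <- ifelse(is.na(first_below), maxd, first_below - 1L)
  cap_i <- if (length(cfg$course_caps) == 1L) {
    rep(as.integer(cfg$course_caps), n)
  } else {
    sample(as.integer(cfg$course_caps), n, replace = TRUE,
           prob = cfg$course_cap_probs)
  }
  L_policy <- pmin(L_policy, cap_i)
  L_policy <- pmax(cfg$min_treatment_days, pmin(maxd, L_policy))

  # recovery time: skew in the learnable location term, symmetric clamped
  # multiplicative residual (support stays positive, no censoring)
  det <- cfg$los_recovery_floor +
    pmin(cfg$los_recovery_cap,
         cfg$los_recovery_scale *
           exp(cfg$los_recovery_exp * s1 + cfg$frailty_exp * frailty))
  zres <- pmax(-cfg$los_noise_clamp, pmin(cfg$los_noise_clamp, rnorm(n)))
  base <- det * (1 + cfg$los_noise_cv * zres)

  # LOS linear in realised treatment days; fixed point for stays discharged
  # while still on antibiotics (treated every ICU day)
  treated <- L_policy
  for (it in 1:30) {
    los <- base + e * treated
    treated_new <- pmin(L_policy, pmax(1L, ceiling(los)))
    if (all(treated_new == treated)) break
    treated <- treated_new
  }
  los <- base + e * treated
  stopped <- L_policy < ceiling(los)  # cessation day observed in-ICU
  if (cfg$discharge_margin > 0) {
    los <- ifelse(stopped, pmax(los, treated + cfg$discharge_margin), los)
  }
  T_i <- pmax(1L, as.integer(ceiling(los)))
  treated <- pmin(L_policy, T_i)
  stopped <- treated < T_i

  # intercept solved so the configured rate is the *marginal* mortality rate
  lin <- cfg$mortality_severity_coef * (s1 - cfg$severity_init_mean) +
    cfg$mortality_frailty_coef * frailty
  p0 <- cfg$mortality_base_rate
  if (p0 <= 0 || p0 >= 1) {
    p_mort <- rep(p0, n)
  } else {
    delta <- stats::uniroot(function(d) mean(plogis(qlogis(p0) + d + lin)) - p0,
                            c(-10, 10))$root
    p_mort <- plogis(qlogis(p0) + delta + lin)
  }
  mortality <- rbinom(n, 1L, p_mort)

  # extend severity to the full stay grid
  Tmax <- max(T_i)
  if (Tmax > maxd) {
    S2 <- matrix(0, n, Tmax)
    S2[, seq_len(maxd)] <- S
    for (t in maxd:(Tmax - 1L)) {
      S2[, t + 1L] <- pmax(0, cfg$severity_decay * S2[, t] +
                              rnorm(n, 0, cfg$severity_noise_sd))
    }
    S <- S2
  }

  stay_ids <- sprintf("stay_%05d", seq_len(n))
  age <- pmin(95, pmax(18, round(rnorm(n, 65, 15))))

  # feature measurement model: each feature reads a mix of the current
  # severity and the static frailty score; drawn under its own seed so the
  # instrument is shared across replicate cohorts
  D <- as.integer(cfg$n_features)
  inst <- with_seed(cfg$feature_seed, list(
    load = runif(D, 0.6, 1.4) * sample(c(-1, 1), D, replace = TRUE),
    frail = runif(D, 0.1, 0.9) * sample(c(-1, 1), D, replace = TRUE),
    sat = runif(D, 0, 1),
    int = rnorm(D, 0, 1),
    sd = runif(D, 0.25, 0.6)))
  f_load <- inst$load; f_frail <- inst$frail; f_sat <- inst$sat
  f_int <- inst$int; f_sd <- inst$sd
  feat_names <- sprintf("feat_%02d", seq_len(D))

  # long-format day grid
  day_dt <- data.table::data.table(
    stay_idx = rep(seq_len(n), T_i),
    day = unlist(lapply(T_i, seq_len), use.names = FALSE)
  )
  sev <- S[cbind(day_dt$stay_idx, day_dt$day)]
  nd <- nrow(day_dt)

  ev <- data.table::data.table(
    stay_idx = rep(day_dt$stay_idx, times = D),
    day = rep(day_dt$day, times = D),
    fidx = rep(seq_len(D), each = nd),
    sev = rep(sev, times = D)
  )
  ev[, value := f_int[fidx] + f_load[fidx] *
       ((1 - f_sat[fidx]) * sev + f_sat[fidx] * 2 * tanh(sev / 2)) +
       f_frail[fidx] * frailty[stay_idx] +
       rnorm(.N, 0, f_sd[fidx])]
  if (cfg$missing_rate > 0) {
    if (isTRUE(cfg$informative_missing)) {
      pmis <- plogis(qlogis(cfg$missing_rate) +
                       cfg$missing_severity_coef *
                         (ev$sev - cfg$severity_init_mean))
    } else {
      pmis <- cfg$missing_rate
    }
    keep <- runif(nrow(ev)) >= pmis
    ev <- ev[keep]
  }
  events <- ev[, .(stay_id = stay_ids[stay_idx], day,
                   variable = feat_names[fidx], value)]
  # static variables, always observed on day 1: age and the planned course
  # duration documented at order entry (the protocol cap)
  events <- rbind(events,
                  data.table::data.table(stay_id = stay_ids, day = 1L,
                                         variable = "age",
                                         value = as.numeric(age)),
                  data.table::data.table(stay_id = stay_ids, day = 1L,
                                         variable = "planned_course_days",
                                         value = as.numeric(cap_i)))
  data.table::setorder(events, stay_id, day, variable)

  abx <- day_dt[, .(stay_id = stay_ids[stay_idx], day,
                    on_antibiotics = as.integer(day <= treated[stay_idx]))]
  data.table::setorder(abx, stay_id, day)

  labels <- data.table::data.table(stay_id = stay_ids, los_days = los,
                                   mortality = mortality)

  # ground truth: counterfactual LOS for every antibiotic day
  n_abx <- treated + as.integer(stopped)
  gt_dt <- data.table::data.table(
    stay_idx = rep(seq_len(n), n_abx),
    day = unlist(lapply(n_abx, seq_len), use.names = FALSE)
  )
  gt_dt[, `:=`(
    stay_id = stay_ids[stay_idx],
    los = los[stay_idx],
    trt = treated[stay_idx]
  )]
  gt_dt[, is_cessation := day > trt]
  gt_dt[, cf_stop := ifelse(is_cessation, los,
                            pmax(day - 1, los - e * (trt - day + 1)))]
  gt_dt[, cf_continue := ifelse(is_cessation, pmax(day - 1, los + e), los)]
  gt <- list(
    stay_id = stay_ids,
    severity = S,
    frailty = frailty,
    course_cap = cap_i,
    n_days = T_i,
    policy_length = L_policy,
    treatment_length = treated,
    stopped_in_icu = stopped,
    cessation_day = ifelse(stopped, treated + 1L, NA_integer_),
    los_days = los,
    mortality = mortality,
    counterfactuals = gt_dt[, .(stay_id, day, cf_stop, cf_continue)],
    effect = e
  )
  class(gt) <- "abx_ground_truth"

  list(events = events[], abx = abx[], labels = labels[], ground_truth = gt)
}

#' Query the simulator's true counterfactual LOS
#'
#' Returns the causal LOS outcome for taking `scenario` on `day` of `stay`,
#' per the simulator's outcome model. Only defined on the stay's antibiotic
#' days (treatment days plus the in-ICU cessation day, when one exists).
#'
#' @param gt the `ground_truth` element returned by [simulate_cohort()].
#' @param stay a stay identifier.
#' @param day a day index (1-based).
#' @param scenario `"stop"` or `"continue"`.
#' @return the true counterfactual LOS in days.
#' @export
true_counterfactual <- function(gt, stay, day, scenario = c("stop", "continue")) {
  stopifnot(inherits(gt, "abx_ground_truth"))
  scenario <- match.arg(scenario)
  cf <- gt$counterfactuals
  q_stay <- stay; q_day <- day
  row <- cf[cf$stay_id == q_stay & cf$day == q_day, ]
  if (nrow(row) == 0L) {
    stop("(", stay, ", day ", day, ") is not an antibiotic day of this stay",
         call. = FALSE)
  }
  if (scenario == "stop") row$cf_stop else row$cf_continue
}
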