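#' Configuration for the synthetic surgical-cohort generator
#'
#' Builds the parameter set that [generate_cohort()] uses to emulate an
#' intraoperative dataset: one clinical row per surgical case, long-format
#' biosignal traces for 14 channels, and arterial blood-gas (ABGA) events with
#' a hidden true draw time, a delayed recorded timestamp, and a PaCO2 target
#' generated as ETCO2 plus a covariate-dependent arterial-to-end-tidal
#' gradient.
#'
#' Defaults encode the study conditions the package is designed around:
#' roughly 11.4% of blood draws leave no detectable arterial-pressure surge;
#' timestamp entry delays are log-normal with median 34 s and interquartile
#' range close to 22-54 s; and the gradient model is calibrated so the cohort
#' mean PaCO2 - ETCO2 difference is about 7.6 mm Hg, rising with age and
#' falling with body temperature, SpO2/FiO2 ratio, and respiratory-system
#' compliance.
#'
#' @param n_cases Number of surgical cases.
#' @param seed Integer seed; identical `(config, seed)` gives bitwise-identical
#'   cohorts.
#' @param case_duration_s Range (s) from which each case's duration is drawn.
#' @param sample_interval_s Sampling interval for all channels (s).
#' @param abga_per_case Integer range of ABGA events per case (capped by what
#'   the case duration accommodates at `min_draw_gap_s` spacing).
#' @param min_draw_gap_s Minimum separation between consecutive draws in a
#'   case. The default exceeds the 20-minute detector lookback so that one
#'   event's pressure surge can never fall inside another event's lookback
#'   window.
#' @param surge_amplitude Range (mm Hg) of the transient MAP surge height.
#' @param surge_duration_s Range (s) of the surge width. The bump is centred
#'   on the true draw time.
#' @param no_surge_fraction Fraction of draws that produce no MAP surge.
#' @param entry_delay_meanlog,entry_delay_sdlog Log-normal parameters of the
#'   recorded-timestamp entry delay (s).
#' @param gradient Named list with intercept `g0` and slopes `g_age`, `g_bt`,
#'   `g_sf`, `g_crs` (see [sample_gradient()]) plus noise SD `sd`.
#' @param distractor_rate_per_h Rate of off-draw MAP artifacts (bumps per
#'   hour); they are never placed inside a surge-free event's lookback window
#'   so that surge-free ground truth stays well defined.
#' @param distractor_guard_s Half-width bookkeeping margin used when placing
#'   distractors away from protected intervals.
#' @param channels Named list of per-channel mean-reverting noise parameters
#'   (`mean`, `sd`, `tau_s`); see [generator_config()] defaults.
#' @param map_bounded Keep MAP physiologic noise bounded (uniform marginal of
#'   the same SD, capped at sqrt(3) SDs) so that detector-grade excursions come
#'   only from injected artifacts and surge-free ground truth is well defined.
#'
#' @return A list of class `co2gap_generator_config`.
#' @seealso [generate_cohort()], [sample_gradient()], [inject_surge()]
#' @export
generator_config <- function(n_cases = 300,
                             seed = 42,
                             case_duration_s = c(4200, 7200),
                             sample_interval_s = 1,
                             abga_per_case = c(2, 4),
                             min_draw_gap_s = 1400,
                             surge_amplitude = c(20, 40),
                             surge_duration_s = c(10, 24),
                             no_surge_fraction = 0.114,
                             entry_delay_meanlog = log(34),
                             entry_delay_sdlog = 0.665,
                             gradient = list(g0 = 5.29, g_age = 1, g_bt = 2,
                                             g_sf = 1, g_crs = 1, sd = 2),
                             distractor_rate_per_h = 0.2,
                             distractor_guard_s = 1300,
                             channels = NULL,
                             map_bounded = TRUE) {
  if (!is_number(n_cases) || n_cases < 1) stop_config("`n_cases` must be >= 1")
  if (!is_number(seed)) stop_config("`seed` must be a single number")
  if (!is_number(sample_interval_s) || sample_interval_s <= 0) {
    stop_config("`sample_interval_s` must be > 0")
  }
  if (!is_number(no_surge_fraction) || no_surge_fraction < 0 || no_surge_fraction >= 1) {
    stop_config("`no_surge_fraction` must be in [0, 1)")
  }
  gradient <- utils::modifyList(
    list(g0 = 5.29, g_age = 1, g_bt = 2, g_sf = 1, g_crs = 1, sd = 2),
    gradient %||% list()
  )
  if (!is_number(gradient$sd) || gradient$sd < 0) stop_config("gradient `sd` must be >= 0")

  default_channels <- list(
    # MAP: fast bounded wander plus slow baseline drift. The short fast
    # timescale keeps every 20-min window's empirical SD close to the marginal
    # SD, so bounded (max sqrt(3) SD) physiologic noise stays below the z = 3
    # detector threshold and surge-free ground truth is well defined.
    MAP   = list(mean = 75,   sd = 4,    tau_s = 10,
                 slow_sd = 1.5, slow_tau_s = 3600),
    HR    = list(mean = 70,   sd = 6,    tau_s = 120),
    SPO2  = list(mean = 98,   sd = 0.6,  tau_s = 120),
    BT    = list(mean = 36.3, sd = 0.25, tau_s = 600),
    ETCO2 = list(mean = 35,   sd = 2,    tau_s = 300),
    CO    = list(mean = 5,    sd = 0.7,  tau_s = 300),
    vent_noise = list(sd = 0.4, tau_s = 60)
  )
  channels <- utils::modifyList(default_channels, channels %||% list())

  cfg <- list(
    n_cases = as.integer(n_cases),
    seed = as.integer(seed),
    case_duration_s = check_pair(case_duration_s, "case_duration_s", lo = 1500),
    sample_interval_s = sample_interval_s,
    abga_per_case = as.integer(check_pair(abga_per_case, "abga_per_case", lo = 1)),
    min_draw_gap_s = min_draw_gap_s,
    surge_amplitude = check_pair(surge_amplitude, "surge_amplitude", lo = 0),
    surge_duration_s = check_pair(surge_duration_s, "surge_duration_s", lo = 1),
    no_surge_fraction = no_surge_fraction,
    entry_delay_meanlog = entry_delay_meanlog,
    entry_delay_sdlog = entry_delay_sdlog,
    gradient = gradient,
    distractor_rate_per_h = distractor_rate_per_h,
    distractor_guard_s = distractor_guard_s,
    channels = channels,
    map_bounded = isTRUE(map_bounded)
  )
  class(cfg) <- "co2gap_generator_config"
  cfg
}

#' @export
print.co2gap_generator_config <- function(x, ...) {
  cat("<co2gap generator config>\n")
  cat("  cases:", x$n_cases, " seed:", x$seed, "\n")
  cat("  duration:", x$case_duration_s[1], "-", x$case_duration_s[2], "s at",
      x$sample_interval_s, "Hz^-1\n")
  cat("  draws/case:", x$abga_per_case[1], "-", x$abga_per_case[2],
      " surge-free fraction:", x$no_surge_fraction, "\n")
  g <- x$gradient
  cat(sprintf("  gradient: %.2f + %.2f*age' - %.2f*BT' - %.2f*SF' - %.2f*CRS' + N(0, %.2f)\n",
              g$g0, g$g_age, g$g_bt, g$g_sf, g$g_crs, g$sd))
  invisible(x)
}

# discretised Ornstein-Uhlenbeck (AR(1)) series around `mean`.
# bounded = TRUE maps the Gaussian marginal onto a uniform one of the same SD
# (probability-integral transform), keeping the autocorrelation but bounding
# deviations at sqrt(3)*sd: physiologic wander stays strictly below detector
# thresholds, so detector-grade excursions come only from injected artifacts.
ou_series <- function(n, mean, sd, tau_s, dt, bounded = FALSE) {
  a <- exp(-dt / tau_s)
  innov <- stats::rnorm(n, 0, sqrt(1 - a^2))
  dev <- as.numeric(stats::filter(innov, a, method = "recursive",
                                  init = stats::rnorm(1)))
  if (bounded) {
    dev <- sqrt(3) * (2 * stats::pnorm(dev) - 1)
  }
  mean + sd * dev
}

# piecewise-constant ventilator setting: base value with `n_steps` changes
piecewise_setting <- function(times, base, draw_value, n_steps) {
  out <- rep(base, length(times))
  if (n_steps > 0) {
    at <- sort(stats::runif(n_steps, min(times), max(times)))
    for (t0 in at) out[times >= t0] <- draw_value()
  }
  out
}

#' Sample timestamp entry delays
#'
#' Draws the delay between the true arterial blood draw and the moment its
#' result is recorded, from the generator's log-normal model (default median
#' 34 s, quartiles close to 22 and 54 s).
#'
#' @param n Number of delays.
#' @param config A [generator_config()].
#' @return Numeric vector of positive delays (s).
#' @export
sample_entry_delay <- function(n, config = generator_config()) {
  stats::rlnorm(n, config$entry_delay_meanlog, config$entry_delay_sdlog)
}

#' Arterial-to-end-tidal CO2 gradient model
#'
#' The synthetic PaCO2 target is ETCO2 plus a gradient that is linear in
#' engineered covariates:
#' `g0 + g_age*(age-50)/10 - g_bt*(BT-36.5) - g_sf*(SF-400)/100 - g_crs*(CRS-50)/10 + N(0, sd)`
#' where `SF = SpO2/FiO2` and `CRS = TV/(PPLAT - PEEP)`. Signs follow the
#' physiological pattern the package is built to recover: the gradient widens
#' with higher age and with lower body temperature, oxygenation ratio, and
#' respiratory-system compliance.
#'
#' @param case One-row data frame (or list) with at least `age`.
#' @param window_state Named list/one-row frame with window medians `bt`,
#'   `spo2`, `fio2`, `tv`, `pplat`, `peep`.
#' @param config A [generator_config()].
#' @return Gradient in mm Hg (length matching `window_state` rows).
#' @export
sample_gradient <- function(case, window_state, config = generator_config()) {
  g <- config$gradient
  ws <- as.list(window_state)
  sf <- ws$spo2 / ws$fio2
  crs <- ws$tv / (ws$pplat - ws$peep)
  n <- length(sf)
  g$g0 +
    g$g_age * (case$age - 50) / 10 -
    g$g_bt * (ws$bt - 36.5) -
    g$g_sf * (sf - 400) / 100 -
    g$g_crs * (crs - 50) / 10 +
    stats::rnorm(n, 0, g$sd)
}

#' Inject a transient pressure surge into a trace
#'
#' Adds a unimodal (raised-cosine) bump of height `amplitude` supported on
#' `[time_s, time_s + duration_s]` to a single-channel trace; samples outside
#' the bump are unchanged. This is the artifact model for the transient mean
#' arterial pressure rise that accompanies an arterial blood draw.
#'
#' @param trace Data frame with columns `time_s`, `value`.
#' @param time_s Bump onset (s); must lie inside the trace span.
#' @param amplitude Bump height (mm Hg); 0 returns the input unchanged.
#' @param duration_s Bump width (s).
#' @return The trace with the bump added, as a tibble.
#' @export
inject_surge <- function(trace, time_s, amplitude, duration_s) {
  if (!all(c("time_s", "value") %in% names(trace))) {
    stop_config("`trace` needs columns time_s and value")
  }
  if (time_s < min(trace$time_s) || time_s > max(trace$time_s)) {
    stop_config("surge time ", time_s, " lies outside the trace span")
  }
  if (amplitude < 0) stop_config("`amplitude` must be >= 0")
  out <- tibble::as_tibble(trace)
  out$value <- out$value + surge_bump(out$time_s, time_s, amplitude, duration_s)
  out
}

# additive raised-cosine bump on [t0, t0 + dur]
surge_bump <- function(times, t0, amplitude, dur) {
  u <- (times - t0) / dur
  inside <- u >= 0 & u <= 1
  bump <- numeric(length(times))
  bump[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * u[inside]))
  bump
}

# clinical covariates for n cases
sample_clinical <- function(n, start_index = 1L) {
  sex <- sample(c("male", "female"), n, replace = TRUE)
  height <- round(ifelse(sex == "male", stats::rnorm(n, 172, 6), stats::rnorm(n, 159, 6)), 1)
  bmi <- pmin(pmax(stats::rnorm(n, 24, 3), 16), 40)
  tibble::tibble(
    case_id = sprintf("case_%04d", seq.int(start_index, length.out = n)),
    age = round(stats::runif(n, 18, 80), 1),
    sex = sex,
    height = height,
    weight = round(bmi * (height / 100)^2, 1),
    asa_class = sample(1:4, n, replace = TRUE, prob = c(0.20, 0.45, 0.30, 0.05)),
    surgery_type = sample(c("general", "thoracic", "urologic", "gynecologic", "orthopedic"),
                          n, replace = TRUE, prob = c(0.35, 0.15, 0.15, 0.15, 0.20)),
    surgical_approach = sample(c("open", "laparoscopic", "robotic"),
                               n, replace = TRUE, prob = c(0.45, 0.40, 0.15)),
    fev1_fvc_ratio = round(pmin(pmax(stats::rnorm(n, 0.78, 0.07), 0.40), 0.95), 3),
    fvc_pct_predicted = round(pmin(pmax(stats::rnorm(n, 95, 15), 40), 140), 1)
  )
}

# draw times with a minimum gap, uniform over the feasible region
sample_draw_times <- function(n, t_min, t_max, gap) {
  slack <- (t_max - t_min) - (n - 1) * gap
  x <- sort(stats::runif(n, 0, slack))
  round(t_min + x + gap * (seq_len(n) - 1))
}

#' Generate a synthetic surgical cohort
#'
#' Produces the three tables the estimation pipeline consumes, plus a
#' synthetic-only truth table used to score alignment and calibration:
#' \describe{
#'   \item{clinical}{one row per case (demographics, ASA class, surgery
#'     descriptors, pulmonary-function values).}
#'   \item{signals}{long-format traces `(case_id, channel, time_s, value)` for
#'     MAP, HR, SPO2, BT, ETCO2, RR, TV, MV, PEEP, PIP, PPLAT, MAWP, FIO2, CO,
#'     sampled at 1 Hz by default. MAP carries a transient surge centred on
#'     each (surge-bearing) draw plus occasional off-draw artifacts.}
#'   \item{abga}{one row per PaCO2 measurement with the delayed
#'     `recorded_time_s`, the hidden `true_draw_time_s`, and `surge_present`.}
#'   \item{truth}{per-event generating quantities (entry delay, window ETCO2
#'     median, sampled gradient) for diagnostics and tests only.}
#' }
#'
#' @param config A [generator_config()].
#' @return A list of class `co2gap_cohort` with elements `clinical`,
#'   `signals`, `abga`, `truth`, and the `config` used.
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "co2gap_generator_config")) {
    stop_config("`config` must come from generator_config()")
  }
  set.seed(config$seed)
  ch <- config$channels
  dt <- config$sample_interval_s

  clinical <- sample_clinical(config$n_cases)
  durations <- round(runif_pair(config$n_cases, config$case_duration_s))

  signal_parts <- vector("list", config$n_cases)
  abga_parts <- vector("list", config$n_cases)
  truth_parts <- vector("list", config$n_cases)

  for (i in seq_len(config$n_cases)) {
    case <- clinical[i, ]
    dur <- durations[i]
    times <- seq(0, dur, by = dt)
    n <- length(times)

    # ventilator settings: piecewise-constant per case
    ibw <- ideal_body_weight(case$height, case$sex)
    peep <- piecewise_setting(times, sample1(c(4, 5, 6, 8)),
                              function() sample1(c(4, 5, 6, 8)),
                              stats::rbinom(1, 1, 0.25))
    fio2 <- piecewise_setting(times, sample1(seq(0.40, 0.60, by = 0.05)),
                              function() sample1(seq(0.40, 0.60, by = 0.05)),
                              stats::rbinom(1, 1, 0.25))
    rr <- piecewise_setting(times, sample1(10:16), function() sample1(10:16),
                            stats::rbinom(1, 1, 0.25))
    tv <- rep(round(stats::runif(1, 6, 10) * ibw), n)
    crs_case <- pmin(pmax(stats::rnorm(1, 50, 10), 25), 90)
    dp_insp <- stats::runif(1, 3, 6)

    vn <- function() ou_series(n, 0, ch$vent_noise$sd, ch$vent_noise$tau_s, dt)
    pplat <- peep + tv / crs_case + vn()
    pip <- pplat + dp_insp + vn()
    mawp <- peep + 0.4 * (pip - peep) + vn()
    mv <- rr * tv / 1000 + ou_series(n, 0, 0.2, 60, dt)

    map <- ou_series(n, ch$MAP$mean, ch$MAP$sd, ch$MAP$tau_s, dt,
                     bounded = config$map_bounded) +
      ou_series(n, 0, ch$MAP$slow_sd, ch$MAP$slow_tau_s, dt,
                bounded = config$map_bounded)
    hr <- ou_series(n, ch$HR$mean, ch$HR$sd, ch$HR$tau_s, dt)
    spo2 <- pmin(ou_series(n, ch$SPO2$mean, ch$SPO2$sd, ch$SPO2$tau_s, dt), 100)
    bt <- ou_series(n, ch$BT$mean, ch$BT$sd, ch$BT$tau_s, dt)
    etco2 <- ou_series(n, ch$ETCO2$mean, ch$ETCO2$sd, ch$ETCO2$tau_s, dt)
    co <- ou_series(n, ch$CO$mean, ch$CO$sd, ch$CO$tau_s, dt)

    # ABGA events: well-separated draws, centred surges, delayed timestamps
    n_max <- max(1L, floor((dur - 660) / config$min_draw_gap_s) + 1L)
    n_ev <- min(sample1(seq(config$abga_per_case[1], config$abga_per_case[2])), n_max)
    draws <- sample_draw_times(n_ev, 600, dur - 60, config$min_draw_gap_s)
    surge_present <- stats::runif(n_ev) >= config$no_surge_fraction
    delays <- sample_entry_delay(n_ev, config)
    recorded <- draws + round(delays, 2)
    amp <- runif_pair(n_ev, config$surge_amplitude)
    sdur <- runif_pair(n_ev, config$surge_duration_s)

    for (j in seq_len(n_ev)) {
      if (surge_present[j]) {
        map <- map + surge_bump(times, draws[j] - sdur[j] / 2, amp[j], sdur[j])
      }
    }

    # off-draw distractor artifacts, kept out of protected lookback windows
    n_d <- stats::rpois(1, config$distractor_rate_per_h * dur / 3600)
    if (n_d > 0) {
      cand <- stats::runif(n_d, 0, dur)
      protected <- cbind(
        lo = ifelse(surge_present, draws - 30, recorded - config$distractor_guard_s),
        hi = recorded + 30
      )
      keep <- vapply(cand, function(t0) {
        all(t0 + 30 < protected[, "lo"] | t0 - 30 > protected[, "hi"])
      }, logical(1))
      for (t0 in cand[keep]) {
        map <- map + surge_bump(times, t0,
                                runif_pair(1, config$surge_amplitude),
                                runif_pair(1, config$surge_duration_s))
      }
    }

    # PaCO2 target from the true (hidden) observation window [draw-120, draw-60)
    win_med <- function(x, d) {
      idx <- times >= d - 120 & times < d - 60
      stats::median(x[idx])
    }
    etco2_med <- vapply(draws, function(d) win_med(etco2, d), numeric(1))
    ws <- tibble::tibble(
      bt = vapply(draws, function(d) win_med(bt, d), numeric(1)),
      spo2 = vapply(draws, function(d) win_med(spo2, d), numeric(1)),
      fio2 = vapply(draws, function(d) win_med(fio2, d), numeric(1)),
      tv = vapply(draws, function(d) win_med(tv, d), numeric(1)),
      pplat = vapply(draws, function(d) win_med(pplat, d), numeric(1)),
      peep = vapply(draws, function(d) win_med(peep, d), numeric(1))
    )
    grad <- sample_gradient(case, ws, config)
    paco2 <- etco2_med + grad

    signal_parts[[i]] <- tibble::tibble(
      case_id = case$case_id,
      channel = rep(c("MAP", "HR", "SPO2", "BT", "ETCO2", "RR", "TV", "MV",
                      "PEEP", "PIP", "PPLAT", "MAWP", "FIO2", "CO"),
                    each = n),
      time_s = rep(times, 14L),
      value = c(map, hr, spo2, bt, etco2, rr, tv, mv, peep, pip, pplat, mawp,
                fio2, co)
    )
    abga_parts[[i]] <- tibble::tibble(
      case_id = case$case_id,
      event_id = sprintf("%s_ev%02d", case$case_id, seq_len(n_ev)),
      recorded_time_s = recorded,
      paco2 = paco2,
      true_draw_time_s = draws,
      surge_present = surge_present
    )
    truth_parts[[i]] <- tibble::tibble(
      event_id = abga_parts[[i]]$event_id,
      entry_delay_s = delays,
      etco2_window_median = etco2_med,
      gradient = grad
    )
  }

  out <- list(
    clinical = clinical,
    signals = dplyr::bind_rows(signal_parts),
    abga = dplyr::bind_rows(abga_parts),
    truth = dplyr::bind_rows(truth_parts),
    config = config
  )
  class(out) <- "co2gap_cohort"
  out
}

#' @export
print.co2gap_cohort <- function(x, ...) {
  cat("<co2gap synthetic cohort>\n")
  cat("  cases:", nrow(x$clinical),
      " events:", nrow(x$abga),
      " signal samples:", nrow(x$signals), "\n")
  cat(sprintf("  surge-free events: %d (%.1f%%)\n",
              sum(!x$abga$surge_present),
              100 * mean(!x$abga$surge_present)))
  invisible(x)
}

#' Channel units for the synthetic biosignal traces
#'
#' @return A tibble with one row per channel and its unit string.
#' @export
channel_units <- function() {
  tibble::tibble(
    channel = c("MAP", "HR", "SPO2", "BT", "ETCO2", "RR", "TV", "MV",
                "PEEP", "PIP", "PPLAT", "MAWP", "FIO2", "CO"),
    unit = c("mm Hg", "beats/min", "%", "degC", "mm Hg", "breaths/min", "mL",
             "L/min", "cmH2O", "cmH2O", "cmH2O", "cmH2O", "fraction", "L/min")
  )
}
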