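#' Simulation configuration for a synthetic joint-acoustic-emission cohort
#'
#' Defines the acquisition geometry and the statistical structure of a
#' synthetic vibroarthrography cohort: seated, unloaded flexion-extension
#' cycles recorded by two skin-mounted accelerometers (medial and lateral of
#' the patellar tendon), with class-dependent transient "click" statistics
#' and subject- and leg-level random effects.
#'
#' The default cohort mirrors the study protocol being emulated: 86 JIA
#' subjects and 30 healthy controls, two knees each, 43 of the 172 JIA knees
#' clinically active, ten 4-second cycles per knee, and a sensor noise floor
#' of 0.0007 g-rms. The default sampling rate is 25 kHz — a desk-scale rate
#' that keeps the full 100 Hz - 12 kHz analysis band below Nyquist; the
#' instrument rate of 100 kHz is supported by setting \code{fs}.
#'
#' Class separation is controlled by \code{effect_size}: per unit effect,
#' active-knee click rate, click amplitude and click centre frequency are
#' multiplied by \code{rate_mult}, \code{amp_mult} and \code{f0_mult};
#' inactive JIA knees receive the fraction \code{inactive_fraction} of the
#' active shift (on the log scale). \code{effect_size = 0} collapses all
#' classes onto the healthy baseline.
#'
#' @param n_jia_subjects number of JIA subjects (two knees each).
#' @param n_control_subjects number of healthy control subjects.
#' @param fraction_active_knees fraction of JIA knees labeled active.
#' @param fs sampling rate in Hz.
#' @param n_cycles flexion-extension cycles per recording.
#' @param cycle_period seconds per cycle.
#' @param effect_size dimensionless class-separation scale (>= 0).
#' @param inactive_fraction fraction of the active shift applied to
#'   inactive JIA knees (default 0.5).
#' @param subject_sd,leg_sd standard deviations (log scale) of the
#'   multiplicative log-normal subject and leg random effects.
#' @param noise_rms sensor noise floor in g-rms.
#' @param rate_mult,amp_mult,f0_mult per-unit-effect multipliers for click
#'   rate, click amplitude and click centre frequency.
#' @param base_rate,base_amp,base_f0,base_decay healthy-baseline click rate
#'   (clicks/cycle), peak amplitude (g), centre frequency (Hz) and damping
#'   time constant (s).
#' @param phase_concentration concentration of click timing around
#'   mid-cycle (larger = tighter clustering).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration including this seed.
#' @return object of class \code{jae_sim_config}.
#' @export
sim_config <- function(n_jia_subjects = 86L, n_control_subjects = 30L,
                       fraction_active_knees = 43 / 172,
                       fs = 25000, n_cycles = 10L, cycle_period = 4.0,
                       effect_size = 1, inactive_fraction = 0.5,
                       subject_sd = 0.2, leg_sd = 0.1,
                       noise_rms = 7e-4,
                       rate_mult = 1.5, amp_mult = 1.5, f0_mult = 1.25,
                       base_rate = 8, base_amp = 0.02, base_f0 = 2000,
                       base_decay = 2e-3, phase_concentration = 4,
                       seed = 1L) {
  cfg <- list(n_jia_subjects = as.integer(n_jia_subjects),
              n_control_subjects = as.integer(n_control_subjects),
              fraction_active_knees = fraction_active_knees,
              fs = fs, n_cycles = as.integer(n_cycles),
              cycle_period = cycle_period,
              effect_size = effect_size,
              inactive_fraction = inactive_fraction,
              subject_sd = subject_sd, leg_sd = leg_sd,
              noise_rms = noise_rms,
              rate_mult = rate_mult, amp_mult = amp_mult, f0_mult = f0_mult,
              base_rate = base_rate, base_amp = base_amp, base_f0 = base_f0,
              base_decay = base_decay,
              phase_concentration = phase_concentration,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "jae_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$subject_sd < 0 || cfg$leg_sd < 0) stop("random-effect SDs must be >= 0")
  if (cfg$n_cycles < 1L) stop("n_cycles must be >= 1")
  if (cfg$fraction_active_knees < 0 || cfg$fraction_active_knees > 1)
    stop("fraction_active_knees must lie in [0, 1]")
  # the highest class-shifted f0 must stay below Nyquist
  fmax <- cfg$base_f0 * cfg$f0_mult^cfg$effect_size
  if (cfg$fs <= 2 * fmax)
    stop("fs must exceed twice the highest click centre frequency")
  invisible(cfg)
}

#' @export
print.jae_sim_config <- function(x, ...) {
  cat("Synthetic JAE cohort configuration\n")
  cat(sprintf("  subjects: %d JIA + %d control (%.0f%% of JIA knees active)\n",
              x$n_jia_subjects, x$n_control_subjects,
              100 * x$fraction_active_knees))
  cat(sprintf("  acquisition: %d cycles x %.1f s at %g Hz, noise %.2g g-rms\n",
              x$n_cycles, x$cycle_period, x$fs, x$noise_rms))
  cat(sprintf("  effect size: %g (inactive fraction %g), seed %d\n",
              x$effect_size, x$inactive_fraction, x$seed))
  invisible(x)
}

#' Draw per-knee click parameters
#'
#' Samples the phenomenological transient parameters of one knee: expected
#' clicks per cycle, mean peak amplitude, mean centre frequency, damping
#' time constant, phase concentration, and the medial/lateral channel gain
#' ratio. Group shifts are multiplicative (\code{mult^effect_size} for
#' active knees, \code{mult^(effect_size * inactive_fraction)} for inactive
#' JIA knees); log-normal subject and leg effects multiply rate and
#' amplitude. A draw whose centre frequency lands outside the sensor band
#' (10 kHz) or at/above 0.45 fs is resampled, up to 100 times.
#'
#' @param group \code{"jia"} or \code{"control"}.
#' @param activity \code{"active"}, \code{"inactive"} or \code{"none"}.
#' @param subject_effect log-scale subject random effect (one draw per
#'   subject, shared by both knees).
#' @param config a [sim_config()].
#' @return list of class \code{jae_knee_params}.
#' @export
sample_knee_params <- function(group, activity, subject_effect, config) {
  group <- match.arg(group, c("jia", "control"))
  activity <- match.arg(activity, c("active", "inactive", "none"))
  if ((activity == "none") != (group == "control"))
    stop("activity must be 'none' iff group is 'control'")
  shift <- switch(activity,
                  active = config$effect_size,
                  inactive = config$effect_size * config$inactive_fraction,
                  none = 0)
  f_cap <- min(10000, 0.45 * config$fs)
  for (attempt in seq_len(100L)) {
    leg_effect <- stats::rnorm(1L, 0, config$leg_sd)
    re <- exp(subject_effect + leg_effect)
    p <- list(
      click_rate = config$base_rate * config$rate_mult^shift * re,
      click_amp = config$base_amp * config$amp_mult^shift *
        exp(subject_effect + stats::rnorm(1L, 0, config$leg_sd)),
      click_f0 = config$base_f0 * config$f0_mult^shift *
        exp(stats::rnorm(1L, 0, 0.1)),
      click_decay = config$base_decay * exp(stats::rnorm(1L, 0, 0.1)),
      phase_concentration = config$phase_concentration,
      channel_gain_ratio = exp(stats::rnorm(1L, 0, 0.15)))
    ok <- all(unlist(p) > 0) && p$click_f0 <= f_cap
    if (ok) return(structure(p, class = "jae_knee_params"))
  }
  stop("sample_knee_params: no valid parameter draw in 100 attempts")
}

#' Synthesize one joint-sound transient
#'
#' A damped sinusoid \eqn{a e^{-t/\tau} \sin(2\pi f_0 t)} truncated at
#' \eqn{5\tau}; the amplitude is rescaled so the peak absolute sample equals
#' \code{amp} (within discretisation of the first quarter-period).
#'
#' @param amp peak amplitude (g).
#' @param f0 centre frequency (Hz); must be below \code{fs/2}.
#' @param decay damping time constant tau (s).
#' @param fs sampling rate (Hz).
#' @return numeric waveform of \code{ceiling(5 * decay * fs)} samples.
#' @export
synthesize_click <- function(amp, f0, decay, fs) {
  if (f0 >= fs / 2) stop("synthesize_click: f0 at or above Nyquist")
  n <- ceiling(5 * decay * fs)
  t <- (seq_len(n) - 1L) / fs
  w <- exp(-t / decay) * sin(2 * pi * f0 * t)
  pk <- max(abs(w))
  if (pk > 0) w <- w / pk
  amp * w
}

#' Simulate one two-channel knee recording
#'
#' Per cycle, a Poisson(\code{click_rate}) number of clicks occurs; click
#' phases follow a wrapped-normal distribution centred at mid-cycle with
#' standard deviation \code{1 / (2 sqrt(phase_concentration))} (cycle
#' fraction). Each click lands on both channels with the knee's
#' medial/lateral gain ratio, a small independent inter-channel timing
#' jitter (50 us RMS), and per-click log-normal amplitude and frequency
#' variation. Independent Gaussian sensor noise at \code{noise_rms} is
#' added per channel.
#'
#' @param params a \code{jae_knee_params} object.
#' @param config a [sim_config()].
#' @param subject_id,knee_side,group,activity identity metadata.
#' @return object of class \code{jae_recording}: list with \code{channels}
#'   (2-column matrix, acceleration in g), \code{fs}, metadata fields and a
#'   \code{click_times} attribute (per-cycle click counts are diagnostic).
#' @export
simulate_recording <- function(params, config, subject_id = "S1",
                               knee_side = "left", group = "control",
                               activity = "none") {
  fs <- config$fs
  n <- round(config$n_cycles * config$cycle_period * fs)
  ch <- matrix(0, nrow = n, ncol = 2L)
  phase_sd <- 1 / (2 * sqrt(params$phase_concentration))
  g1 <- sqrt(params$channel_gain_ratio)
  g2 <- 1 / g1
  click_times <- numeric(0)
  for (cyc in seq_len(config$n_cycles)) {
    k <- stats::rpois(1L, params$click_rate)
    if (k == 0L) next
    phase <- (0.5 + stats::rnorm(k, 0, phase_sd)) %% 1
    t0 <- (cyc - 1L + phase) * config$cycle_period
    click_times <- c(click_times, t0)
    for (j in seq_len(k)) {
      a <- params$click_amp * stats::rlnorm(1L, 0, 0.3)
      f0 <- params$click_f0 * stats::rlnorm(1L, 0, 0.1)
      f0 <- min(f0, 0.45 * fs)
      w <- synthesize_click(a, f0, params$click_decay, fs)
      jit <- stats::rnorm(1L, 0, 5e-5)
      for (chan in 1:2) {
        i <- round((t0[j] + if (chan == 2L) jit else 0) * fs) + 1L
        g <- if (chan == 1L) g1 else g2
        if (i > n) next
        wseg <- if (i < 1L) w[(2L - i):length(w)] else w
        if (i < 1L) i <- 1L
        jend <- min(n, i + length(wseg) - 1L)
        idx <- i:jend
        ch[idx, chan] <- ch[idx, chan] + g * wseg[seq_along(idx)]
      }
    }
  }
  if (config$noise_rms > 0) {
    ch[, 1L] <- ch[, 1L] + stats::rnorm(n, 0, config$noise_rms)
    ch[, 2L] <- ch[, 2L] + stats::rnorm(n, 0, config$noise_rms)
  }
  structure(list(subject_id = subject_id, knee_side = knee_side,
                 group = group, activity = activity,
                 channels = ch, fs = fs),
            class = "jae_recording",
            click_times = click_times)
}

#' @export
print.jae_recording <- function(x, ...) {
  cat(sprintf("JAE recording %s/%s [%s/%s]: 2 x %d samples at %g Hz (%.1f s)\n",
              x$subject_id, x$knee_side, x$group, x$activity,
              nrow(x$channels), x$fs, nrow(x$channels) / x$fs))
  invisible(x)
}

#' Simulate a full synthetic cohort
#'
#' Generates two knees for every subject. Active knees are assigned at
#' random among JIA knees to match \code{fraction_active_knees} (count
#' rounded to the nearest knee). The whole cohort, waveforms included, is a
#' deterministic function of the configuration.
#'
#' @param config a [sim_config()].
#' @return object of class \code{jae_cohort}: list with \code{recordings}
#'   (list of \code{jae_recording}) and \code{metadata} (data.frame with
#'   subject_id, knee_side, group, activity, knee_id).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(config$seed)

  n_jia <- config$n_jia_subjects
  n_ctl <- config$n_control_subjects
  subjects <- data.frame(
    subject_id = c(sprintf("JIA%03d", seq_len(n_jia)),
                   sprintf("CTL%03d", seq_len(n_ctl))),
    group = rep(c("jia", "control"), c(n_jia, n_ctl)),
    stringsAsFactors = FALSE)

  n_jia_knees <- 2L * n_jia
  n_active <- round(config$fraction_active_knees * n_jia_knees)
  jia_knee_idx <- seq_len(n_jia_knees)
  active_idx <- if (n_active > 0L) sample(jia_knee_idx, n_active) else integer(0)

  recordings <- vector("list", 2L * nrow(subjects))
  meta <- vector("list", length(recordings))
  knee_counter <- 0L
  jia_knee_counter <- 0L
  for (s in seq_len(nrow(subjects))) {
    grp <- subjects$group[s]
    subject_effect <- stats::rnorm(1L, 0, config$subject_sd)
    for (side in c("left", "right")) {
      knee_counter <- knee_counter + 1L
      if (grp == "jia") {
        jia_knee_counter <- jia_knee_counter + 1L
        act <- if (jia_knee_counter %in% active_idx) "active" else "inactive"
      } else act <- "none"
      params <- sample_knee_params(grp, act, subject_effect, config)
      rec <- simulate_recording(params, config,
                                subject_id = subjects$subject_id[s],
                                knee_side = side, group = grp, activity = act)
      recordings[[knee_counter]] <- rec
      meta[[knee_counter]] <- data.frame(
        subject_id = subjects$subject_id[s], knee_side = side,
        group = grp, activity = act,
        knee_id = paste(subjects$subject_id[s], side, sep = "_"),
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  structure(list(recordings = recordings, metadata = metadata,
                 config = config),
            class = "jae_cohort")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.jae_cohort <- function(x, ...) {
  tb <- table(x$metadata$activity)
  cat(sprintf("Synthetic JAE cohort: %d knees (%s)\n",
              nrow(x$metadata),
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}
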