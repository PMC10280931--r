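# Shared fixtures, built in code and memoised for the duration of the run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# small desk-scale config for unit tests (keeps the analysis band sensible
# at a low sampling rate by using a low click frequency)
tiny_sim_config <- function(...) {
  defaults <- list(n_jia_subjects = 2L, n_control_subjects = 2L,
                   fraction_active_knees = 0.5, fs = 4000, n_cycles = 2L,
                   cycle_period = 4.0, effect_size = 1, base_f0 = 400,
                   seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# deterministic healthy knee parameters for waveform-level tests
fixed_knee_params <- function(click_rate = 8, click_amp = 0.02,
                              click_f0 = 400, click_decay = 2e-3,
                              phase_concentration = 4,
                              channel_gain_ratio = 1) {
  structure(list(click_rate = click_rate, click_amp = click_amp,
                 click_f0 = click_f0, click_decay = click_decay,
                 phase_concentration = phase_concentration,
                 channel_gain_ratio = channel_gain_ratio),
            class = "jae_knee_params")
}

# two-cluster toy feature set that is trivially separable
toy_separable <- function(n_per_class = 10L, p = 8L, gap = 6, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class, p),
             matrix(rnorm(n_per_class * p, mean = gap), n_per_class, p))
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- sprintf("knee%02d", seq_len(2L * n_per_class))
  list(x = x, y = rep(c("control", "jia"), each = n_per_class))
}

# 60-knee training cohort (all-active JIA + controls) featurized at desk
# scale; memoised per effect size for the acceptance properties
acc_train_features <- function(effect_size) {
  fixture(paste0("acc_train_", effect_size), {
    sc <- sim_config(n_jia_subjects = 15L, n_control_subjects = 15L,
                     fraction_active_knees = 1, fs = 25000, n_cycles = 3L,
                     effect_size = effect_size, seed = 777L)
    cfg <- run_config(sim = sc, seed = 777L)
    cohort <- simulate_cohort(sc)
    fm <- suppressWarnings(featurize_cohort(cohort, cfg))  # band-edge clip at 25 kHz
    list(x = fm$x,
         y = ifelse(fm$meta$group == "jia", "jia", "control"),
         meta = fm$meta)
  })
}
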