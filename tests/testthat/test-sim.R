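test_that("synthesized clicks have the stated shape, length and spectrum", {
  expect_equal(synthesize_click(0, 500, 2e-3, 8000),
               numeric(ceiling(5 * 2e-3 * 8000)))
  w <- synthesize_click(0.5, 400, 3e-3, 8000)
  expect_length(w, ceiling(5 * 3e-3 * 8000))
  expect_lt(abs(max(abs(w)) - 0.5) / 0.5, 0.05)
  expect_error(synthesize_click(1, 4000, 1e-3, 8000), "Nyquist")

  # spectral peak at f0 within one FFT bin (1 kHz click at 100 kHz)
  w <- synthesize_click(1, 1000, 2e-3, 1e5)
  nfft <- 2^14
  spec <- Mod(stats::fft(c(w, numeric(nfft - length(w)))))[1:(nfft / 2)]
  f_peak <- (which.max(spec) - 1) * 1e5 / nfft
  expect_lt(abs(f_peak - 1000), 1e5 / nfft + 1e-9)
})

test_that("zero effect size collapses the class parameter distributions", {
  cfg <- tiny_sim_config(effect_size = 0, subject_sd = 0, leg_sd = 0)
  set.seed(1)
  a <- sample_knee_params("jia", "active", 0, cfg)
  set.seed(1)
  h <- sample_knee_params("control", "none", 0, cfg)
  expect_equal(a$click_rate, h$click_rate)
  expect_equal(a$click_amp, h$click_amp)
  expect_equal(a$click_f0, h$click_f0)

  # with all randomness off, every knee is identical
  b <- sample_knee_params("jia", "inactive", 0, cfg)
  # frequency/decay/gain jitter remains; rate and amp are deterministic
  expect_equal(b$click_rate, cfg$base_rate)
  expect_equal(b$click_amp, cfg$base_amp)
})

test_that("group mean click rate follows the configured multiplier", {
  cfg <- tiny_sim_config(effect_size = 2)
  set.seed(42)
  n <- 1e4
  active <- replicate(n, sample_knee_params("jia", "active",
                                            rnorm(1, 0, cfg$subject_sd),
                                            cfg)$click_rate)
  healthy <- replicate(n, sample_knee_params("control", "none",
                                             rnorm(1, 0, cfg$subject_sd),
                                             cfg)$click_rate)
  ratio <- mean(active) / mean(healthy)
  expect_lt(abs(ratio - cfg$rate_mult^2) / cfg$rate_mult^2, 0.03)
})

test_that("recordings have the protocol geometry and noise floor", {
  cfg <- tiny_sim_config(noise_rms = 0)
  p <- fixed_knee_params(click_rate = 1e-9)
  set.seed(3)
  rec <- simulate_recording(p, cfg)
  expect_equal(nrow(rec$channels), round(cfg$n_cycles * cfg$cycle_period * cfg$fs))
  expect_identical(ncol(rec$channels), 2L)
  expect_true(all(rec$channels == 0))  # silent when no clicks and no noise

  cfg2 <- tiny_sim_config(noise_rms = 7e-4, n_cycles = 4L)
  set.seed(4)
  rec2 <- simulate_recording(fixed_knee_params(click_rate = 1e-9), cfg2)
  for (ch in 1:2) {
    rms <- sqrt(mean(rec2$channels[, ch]^2))
    expect_lt(abs(rms - 7e-4) / 7e-4, 0.05)
  }
})

test_that("instrument-scale recording length is cycles x period x rate", {
  cfg <- sim_config(fs = 1e5, n_cycles = 10L, cycle_period = 4.0,
                    effect_size = 0, seed = 2L)
  set.seed(2)
  rec <- simulate_recording(fixed_knee_params(click_f0 = 2000), cfg)
  expect_identical(nrow(rec$channels), 4000000L)
})

test_that("click counts are Poisson with the configured rate", {
  cfg <- tiny_sim_config(fs = 2000, n_cycles = 10000L, cycle_period = 0.05,
                         noise_rms = 0)
  p <- fixed_knee_params(click_rate = 20, click_f0 = 300, click_decay = 2e-3)
  set.seed(8)
  rec <- simulate_recording(p, cfg)
  mean_clicks <- length(attr(rec, "click_times")) / cfg$n_cycles
  expect_lt(abs(mean_clicks - 20) / 20, 0.02)
})

test_that("cohorts have the study structure and are deterministic", {
  cfg <- tiny_sim_config(n_jia_subjects = 86L, n_control_subjects = 30L,
                         fraction_active_knees = 43 / 172,
                         fs = 500, n_cycles = 1L, cycle_period = 1.0,
                         base_f0 = 100)
  co <- simulate_cohort(cfg)
  expect_length(co$recordings, 232L)
  expect_identical(nrow(co$metadata), 232L)
  expect_identical(sum(co$metadata$activity == "active"), 43L)
  expect_identical(sum(co$metadata$group == "control"), 60L)
  expect_true(all((co$metadata$activity == "none") ==
                    (co$metadata$group == "control")))

  co2 <- simulate_cohort(cfg)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$recordings[[5]]$channels, co2$recordings[[5]]$channels)

  expect_error(simulate_cohort(tiny_sim_config(fraction_active_knees = 1.2)),
               "fraction_active_knees")
})

test_that("class separation is monotone in effect size", {
  cfg0 <- tiny_sim_config()
  grid <- c(0, 0.5, 1, 2)
  set.seed(99)
  mean_rate <- mean_amp <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cfg <- tiny_sim_config(effect_size = grid[i])
    draws <- replicate(1000, {
      p <- sample_knee_params("jia", "active", rnorm(1, 0, cfg$subject_sd), cfg)
      c(p$click_rate, p$click_amp)
    })
    mean_rate[i] <- mean(draws[1, ])
    mean_amp[i] <- mean(draws[2, ])
  }
  expect_true(all(diff(mean_rate) > 0))
  expect_true(all(diff(mean_amp) > 0))
})

test_that("parameter distributions are indistinguishable at zero effect", {
  cfg <- tiny_sim_config(effect_size = 0)
  set.seed(123)
  draw <- function(group, activity) replicate(500, {
    p <- sample_knee_params(group, activity, rnorm(1, 0, cfg$subject_sd), cfg)
    unlist(p[c("click_rate", "click_amp", "click_f0", "click_decay")])
  })
  a <- draw("jia", "active")
  h <- draw("control", "none")
  for (f in seq_len(nrow(a))) {
    p <- suppressWarnings(stats::ks.test(a[f, ], h[f, ]))$p.value
    expect_gt(p, 0.01)
  }
})
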