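test_that("the VEP waveform is a Gaussian-windowed downward chirp", {
  N <- 768
  v <- vep_waveform(N, fs = 256)
  n <- seq_len(N)
  sigma <- sqrt(0.125 * N)
  env <- (1 / sqrt(2 * pi)) * exp(-((n - 0.5 * N) / sigma)^2 / 2)
  gam <- (N - 0.5 * n) / N
  expect_equal(as.numeric(v), env * sin(2 * pi * 10 * (n / N) * gam),
               tolerance = 1e-12)
  # gamma endpoints: 1 at n = 0, 0.5 at n = N
  expect_equal((N - 0) / N, 1)
  expect_equal(gam[N], 0.5)
  # envelope peak at mid-epoch, i.e. 1.5 s at 256 Hz
  expect_equal(which.max(env), 384L)
  # instantaneous frequency at the peak falls in the 1.6 Hz band
  expect_equal(attr(v, "inst_freq_hz")[384], 256 * 10 * (1 - 384 / 768) / 768,
               tolerance = 1e-12)
  expect_equal(attr(v, "inst_freq_hz")[384], 5 / 3, tolerance = 1e-9)
  expect_error(vep_waveform(0))
})

test_that("source generation honors kinds, seeds and trajectories", {
  specs <- list(
    source_spec("harmonic", amplitude = 1, frequency = 3, initial_phase = 0),
    source_spec("white", amplitude = 1),
    source_spec("colored", amplitude = 1)
  )
  a <- generate_sources(specs, N = 512, fs = 256, seed = 11)
  b <- generate_sources(specs, N = 512, fs = 256, seed = 11)
  expect_identical(a$waves, b$waves)
  c2 <- generate_sources(specs, N = 512, fs = 256, seed = 12)
  expect_false(identical(a$waves[2, ], c2$waves[2, ]))
  expect_identical(a$waves[1, ], c2$waves[1, ])  # harmonic is deterministic
  expect_equal(a$waves[1, 1], 0)                 # sin(0) at t = 0
  expect_error(generate_sources(list(), 10, 256))
})

test_that("colored noise has a 1/f^alpha averaged periodogram", {
  N <- 4096
  acc <- 0
  set.seed(1)
  for (i in 1:100) acc <- acc + Mod(fft(colored_noise(N, alpha = 1)))[2:(N / 2)]^2
  f <- seq_len(N / 2 - 1)
  fit <- stats::lm(log(acc) ~ log(f))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.05)
})

test_that("records are the linear instantaneous mixture of their sources", {
  vep <- list(source_spec("vep", amplitude = 2,
                          trajectory = trajectory_fixed(0, -0.8, 0.1)))
  harm <- list(source_spec("harmonic", amplitude = 1, frequency = 5,
                           trajectory = trajectory_fixed(0.3, 0.3, 0.5)))
  ra <- simulate_record(m8, vep, n_epochs = 2, epoch_seconds = 1, seed = 3)
  rb <- simulate_record(m8, harm, n_epochs = 2, epoch_seconds = 1, seed = 3)
  rab <- simulate_record(m8, c(vep, harm), n_epochs = 2, epoch_seconds = 1, seed = 3)
  expect_equal(rab$data, ra$data + rb$data, tolerance = 1e-12)

  # single source: every channel a scaled copy (rank-1 record)
  sv <- svd(ra$data)$d
  expect_lt(sv[2] / sv[1], 1e-10)

  # epoch bookkeeping: 30 epochs x 3 s x 256 Hz
  expect_equal(30 * 3 * 256, 23040)
  r30 <- simulate_record(m8, vep, n_epochs = 30, epoch_seconds = 3, seed = 1)
  expect_equal(ncol(r30$data), 23040)

  # VEP identical across epochs and peaking at the same within-epoch sample
  L <- r30$epoch_length
  e1 <- r30$data[, 1:L]
  e2 <- r30$data[, (L + 1):(2 * L)]
  expect_equal(e1, e2, tolerance = 1e-12)
  peaks <- apply(abs(e1), 1, which.max)
  expect_true(all(peaks == peaks[1]))
})

test_that("same seed reproduces a record; VEP contribution is seed-invariant", {
  specs <- seeg_default_sources()
  a <- simulate_record(m19, specs, n_epochs = 2, epoch_seconds = 1, seed = 5)
  b <- simulate_record(m19, specs, n_epochs = 2, epoch_seconds = 1, seed = 5)
  expect_identical(a$data, b$data)
  c2 <- simulate_record(m19, specs, n_epochs = 2, epoch_seconds = 1, seed = 6)
  expect_false(identical(a$data, c2$data))
  expect_equal(a$ground_truth$contributions[[1]],
               c2$ground_truth$contributions[[1]], tolerance = 1e-12)
})

test_that("trajectories move sources and stay inside the head", {
  tr <- trajectory_linear(c(0, 0, 0), c(0.1, 0, 0))
  pos <- tr(c(0, 1, 2))
  expect_equal(pos[, 1], c(0, 0.1, 0.2))
  expect_error(tr(c(0, 20)))  # leaves the unit sphere
  rot <- trajectory_rotational(c(0, 0, 0), 0.5, pi)
  p <- rot(c(0, 1))
  expect_equal(p[1, ], c(0.5, 0, 0))
  expect_equal(p[2, ], c(-0.5, 0, 0), tolerance = 1e-12)
  # a moving source changes its mixing over time
  spec <- list(source_spec("harmonic", amplitude = 1, frequency = 2,
                           trajectory = trajectory_linear(c(-0.4, 0, 0.2),
                                                          c(0.2, 0, 0))))
  rec <- simulate_record(m8, spec, n_epochs = 2, epoch_seconds = 1, seed = 1)
  ratio <- abs(rec$data["P3", 10] / rec$data["P4", 10]) -
    abs(rec$data["P3", 400] / rec$data["P4", 400])
  expect_gt(abs(ratio), 1e-6)
})

test_that("speller schedules have the row/column ERP structure", {
  s <- speller_schedule(5, 10, isi_ms = 125, fs = 256)
  expect_equal(sum(s$condition == "ERP"), 100L)
  expect_equal(sum(s$condition == "noERP"), 500L)
  expect_equal(unique(diff(s$onset_sample)), 32L)
  expect_equal(nrow(speller_schedule(1, 1)), 12L)
  # 1:5 ratio regardless of counts
  for (cfg in list(c(2, 3), c(7, 1), c(3, 8))) {
    sc <- speller_schedule(cfg[1], cfg[2])
    expect_equal(sum(sc$condition == "noERP") / sum(sc$condition == "ERP"), 5)
  }
  expect_error(speller_schedule(0, 1))
})

test_that("SNR follows the power definition", {
  vep <- source_spec("vep", amplitude = 1, trajectory = trajectory_fixed(0, -0.8, 0.1))
  wn <- source_spec("white", amplitude = 0.05, trajectory = trajectory_fixed(0, 0.5, 0.3))
  r1 <- simulate_record(m8, list(vep, wn), n_epochs = 2, epoch_seconds = 1, seed = 9)
  wn2 <- wn; wn2$amplitude <- 0.1
  r2 <- simulate_record(m8, list(vep, wn2), n_epochs = 2, epoch_seconds = 1, seed = 9)
  expect_equal(snr_db(r1) - snr_db(r2), 20 * log10(2), tolerance = 1e-9)
  r0 <- simulate_record(m8, list(vep), n_epochs = 1, epoch_seconds = 1, seed = 9)
  expect_identical(snr_db(r0), Inf)
  # restricting to the evoked window raises the measured SNR
  expect_gt(snr_db(r1, epoch_window = c(98, 158)), snr_db(r1))
})
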