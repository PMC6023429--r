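test_that("excitation pulse is an odd differentiated Gaussian peaking at 6 GHz", {
  p <- mw_pulse()
  expect_equal(pulse_waveform(0, p), 0)
  t <- seq(-0.5, 0.5, by = 1 / 600)
  w <- pulse_waveform(t, p)
  expect_equal(w, -rev(w), tolerance = 1e-12)          # odd about centre
  expect_lt(abs(sum(w) / 600), 1e-12)                  # zero integral
  expect_equal(max(abs(w)), p$amplitude, tolerance = 1e-4)

  ## discrete spectrum of the sampled waveform peaks within 10% of 6 GHz
  n <- 8192
  x <- pulse_waveform((0:(n - 1)) / 600 - 3, p)
  f <- (0:(n - 1)) * 600 / n
  fpk <- f[which.max(Mod(fft(x))[1:(n / 2)])]
  expect_lt(abs(fpk - 6) / 6, 0.1)
})

test_that("reference signals reflect ring symmetry and immersion delay", {
  arr <- ring_array(12, radius = 70)
  b <- breast_spec()
  p <- mw_pulse()
  ch <- enumerate_channels(arr)

  ## monostatic: self-coupling at zero delay (energy at the record head)
  r0 <- simulate_reference(ch[1, ], arr, b, p, n_samples = 2048)
  expect_gt(max(abs(r0[1:50])), 0.5)

  ## equal channel angle -> identical reference
  i1 <- which(ch$tx == 0 & ch$rx == 3)
  i2 <- which(ch$tx == 5 & ch$rx == 8)
  expect_equal(simulate_reference(ch[i1, ], arr, b, p, n_samples = 2048),
               simulate_reference(ch[i2, ], arr, b, p, n_samples = 2048))

  ## delay of the diametric channel: locate the waveform centre as the
  ## zero-crossing between the two extrema and compare to the closed form
  i3 <- which(ch$tx == 0 & ch$rx == 6)
  r <- simulate_reference(ch[i3, ], arr, b, p, n_samples = 4096)
  expected <- 140 * sqrt(b$eps_immersion) / 299.792458
  ipk <- which.max(abs(r))
  ctr <- mean(c(which.max(r), which.min(r))) - 1
  expect_lt(abs(ctr / 600 - expected), 1 / 600 * (1 + 1e-9))
  expect_gt(ipk, 1)
})

test_that("a clean channel signal is exactly one scaled, delayed pulse copy", {
  arr <- ring_array(12, radius = 70)
  b <- breast_spec(glandular_fraction = 0)
  p <- mw_pulse()
  ch <- enumerate_channels(arr)[3, ]   # channel (0, 2)
  tum <- tumour_spec(10, 0, c(10, -5))

  x <- simulate_channel_signal(b, tum, ch, arr, p, n_samples = 4096,
                               noise_sigma = 0, skin_ratio = 0)
  ref <- simulate_reference(ch, arr, b, p, n_samples = 4096)
  resid <- remove_artifact(x, ref)

  d <- roundtrip_delay(c(10, -5), ch, arr, as_media_model(b))
  pos <- arr$positions
  path <- sqrt(sum((pos[1, ] - c(10, -5))^2)) + sqrt(sum((pos[3, ] - c(10, -5))^2))
  t <- (0:4095) / 600
  expected <- (1 / (1 + path)) * pulse_waveform(t - d, p)
  expect_equal(resid, expected, tolerance = 1e-12)

  ## principal echo delay matches the ray oracle within one sample
  ipk <- which.max(resid); ineg <- which.min(resid)
  ctr <- (mean(c(ipk, ineg)) - 1) / 600
  d_oracle <- oracle_delay_one_way(pos[1, ], c(10, -5), as_media_model(b)) +
    oracle_delay_one_way(pos[3, ], c(10, -5), as_media_model(b))
  expect_lt(abs(ctr - d_oracle), 1 / 600 * (1 + 1e-9))
})

test_that("skin echo dominates the tumour echo by the configured ratio", {
  arr <- ring_array(12, radius = 70)
  b <- breast_spec(glandular_fraction = 0)
  p <- mw_pulse()
  ch <- enumerate_channels(arr)[1, ]
  tum <- tumour_spec(10, 0, c(0, 0))
  x <- simulate_channel_signal(b, tum, ch, arr, p, n_samples = 4096,
                               noise_sigma = 0, skin_ratio = 15,
                               include_reference = FALSE)
  m <- as_media_model(b)
  d_t <- roundtrip_delay(c(0, 0), ch, arr, m)
  d_s <- 2 * (70 - 50) * sqrt(b$eps_immersion) / 299.792458
  amp_at <- function(d) max(abs(x[round(d * 600) + seq(-30, 30)]))
  expect_gte(amp_at(d_s) / amp_at(d_t), 10)
})

test_that("spiculation increases the peak count of windowed signatures", {
  arr <- ring_array(12, radius = 70)
  b <- breast_spec(glandular_fraction = 0)
  p <- mw_pulse()
  ch <- enumerate_channels(arr)[20, ]
  m <- as_media_model(b)
  pos <- c(12, 8)
  d <- roundtrip_delay(pos, ch, arr, m)

  count_peaks <- function(s) {
    x <- simulate_channel_signal(b, tumour_spec(10, s, pos, label = "benign"),
                                 ch, arr, p, n_samples = 4096,
                                 noise_sigma = 0.02, skin_ratio = 15)
    ref <- simulate_reference(ch, arr, b, p, n_samples = 4096)
    w <- window_tumour(remove_artifact(x, ref), d, p, 600)
    sig <- align_and_downsample(w)$samples
    nrow(detect_peaks(sig, "positive")) + nrow(detect_peaks(sig, "negative"))
  }
  withr::with_seed(5, {
    smooth <- replicate(100, count_peaks(0))
    spiky <- replicate(100, count_peaks(0.9))
  })
  expect_gt(mean(spiky), mean(smooth))
})

test_that("sampled tumours respect the class spiculation bands", {
  withr::with_seed(3, {
    sb <- replicate(1000, sample_tumour("benign")$spiculation)
    sm <- replicate(1000, sample_tumour("malignant")$spiculation)
  })
  expect_true(all(sb >= 0 & sb <= 0.25))
  expect_true(all(sm >= 0.50 & sm <= 0.90))
  expect_false(any(c(sb, sm) > 0.25 & c(sb, sm) < 0.50))
  expect_error(tumour_spec(10, 0.4, c(0, 0)), "band")
})

test_that("dataset generation follows the factorial design deterministically", {
  design <- list(n_breasts = 2, n_tumours = 4, n_positions = 3)
  s1 <- generate_dataset(design, glandular_fractions = c(0.01, 0.27),
                         n_samples = 256, seed = 9)
  expect_equal(nrow(s1), 2 * 4 * 3)
  expect_equal(sum(sapply(s1$signals, nrow)), 24 * 78)
  expect_true(all(sapply(s1$signals, function(m) all(is.finite(m)))))
  expect_equal(sum(s1$label == "benign"), sum(s1$label == "malignant"))

  s2 <- generate_dataset(design, glandular_fractions = c(0.01, 0.27),
                         n_samples = 256, seed = 9)
  expect_identical(s1$signals, s2$signals)
  s3 <- generate_dataset(design, glandular_fractions = c(0.01, 0.27),
                         n_samples = 256, seed = 10)
  expect_false(identical(s1$signals, s3$signals))

  expect_error(
    generate_dataset(list(n_breasts = 1, n_tumours = 3, n_positions = 1),
                     glandular_fractions = 0.05, n_samples = 64),
    "even"
  )
})
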