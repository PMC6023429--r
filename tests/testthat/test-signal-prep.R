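test_that("artefact removal is exact pointwise subtraction", {
  x <- sin(1:100)
  expect_equal(remove_artifact(x, x), rep(0, 100))
  a <- rnorm(100); r <- rnorm(100)
  expect_equal(remove_artifact(a + r, r), a)
  expect_error(remove_artifact(1:5, 1:4), "length")
})

test_that("round-trip delay follows the three-media ray model", {
  arr <- ring_array(12, radius = 70)
  ch <- enumerate_channels(arr)

  ## homogeneous media: closed form (|Tx-p| + |p-Rx|) sqrt(eps) / c
  m_h <- media_model(4, 4, 4, skin_thickness = 2, breast_radius = 50)
  p <- c(10, 15)
  d <- roundtrip_delay(p, ch, arr, m_h)
  pos <- arr$positions
  paths <- sapply(seq_len(nrow(ch)), function(i) {
    sqrt(sum((pos[ch$tx[i] + 1, ] - p)^2)) + sqrt(sum((pos[ch$rx[i] + 1, ] - p)^2))
  })
  expect_equal(d, paths * 2 / 299.792458, tolerance = 1e-12)

  ## monostatic channel: both legs identical
  m <- media_model(9, 36, 12)
  mono <- ch[ch$tx == ch$rx, ]
  d_mono <- roundtrip_delay(p, mono, arr, m)
  one <- sapply(seq_len(nrow(mono)), function(i) {
    oracle_delay_one_way(pos[mono$tx[i] + 1, ], p, m)
  })
  expect_equal(d_mono, 2 * one, tolerance = 1e-3)

  ## layered case vs fine-stepped slowness integral, within 0.1%
  d_all <- roundtrip_delay(p, ch[1:10, ], arr, m)
  oracle <- sapply(1:10, function(i) {
    oracle_delay_one_way(pos[ch$tx[i] + 1, ], p, m) +
      oracle_delay_one_way(pos[ch$rx[i] + 1, ], p, m)
  })
  expect_equal(d_all, oracle, tolerance = 1e-3)

  ## monotone in each permittivity
  d0 <- roundtrip_delay(p, ch[5, ], arr, media_model(9, 36, 12))
  expect_gt(roundtrip_delay(p, ch[5, ], arr, media_model(12, 36, 12)), d0)
  expect_gt(roundtrip_delay(p, ch[5, ], arr, media_model(9, 45, 12)), d0)
  expect_gt(roundtrip_delay(p, ch[5, ], arr, media_model(9, 36, 16)), d0)

  expect_error(roundtrip_delay(c(49.5, 0), ch[1, ], arr, m), "interior")
})

test_that("tumour window spans 2.5 pulse widths around the arrival", {
  p <- mw_pulse()          # 0.8 ns width
  sig <- numeric(4096)
  w <- window_tumour(sig, 2, p, 600)
  expect_length(w, 1200)
  expect_true(all(w == 0))

  ## pure pulse at t = 0 with delay 0: full energy captured (zero-padded head)
  t <- (0:4095) / 600
  x <- pulse_waveform(t - 0.05, p)
  expect_warning(w0 <- window_tumour(x, 0.05, p, 600), "zero-padding")
  expect_gt(sum(w0^2) / sum(x^2), 0.999)

  expect_error(window_tumour(numeric(100), 5, p, 600), "beyond")
})

test_that("aligned signatures have 60 samples with the peak at the alignment index", {
  p <- mw_pulse()
  t <- (0:4095) / 600
  ## asymmetric echo (principal + trailing sub-echo) so the energy peak is
  ## unique; a lone differentiated Gaussian has two equal-magnitude extrema
  echo <- function(d) pulse_waveform(t - d, p) + 0.4 * pulse_waveform(t - d - 0.15, p)
  x <- echo(2)
  w <- window_tumour(x, 2, p, 600)
  ts <- align_and_downsample(w)
  expect_length(ts$samples, 60)
  expect_equal(which.max(abs(ts$samples)), 34)
  expect_equal(ts$alignment_index, 34L)
  expect_false(ts$low_quality)

  ## idempotence: aligning an already-aligned signature changes nothing
  again <- align_and_downsample(ts$samples, fs_in = 30, fs_out = 30)
  expect_equal(again$samples, ts$samples)

  ## identical echoes at different (sample-aligned) delays on different
  ## channels give identical signatures after alignment
  d2 <- 2 + 300 / 600
  x2 <- echo(d2)
  ts2 <- align_and_downsample(window_tumour(x2, d2, p, 600))
  expect_equal(ts2$samples, ts$samples, tolerance = 1e-9)

  ## all-zero window: flagged low quality
  z <- align_and_downsample(numeric(1200))
  expect_true(z$low_quality)
  expect_true(all(z$samples == 0))
})

test_that("anti-aliased decimation tracks the ideal-filter oracle", {
  ## band-limited input well inside the 15 GHz output Nyquist band
  t <- (0:1199) / 600
  x <- sin(2 * pi * 4 * t) + 0.5 * cos(2 * pi * 9 * t + 1)
  b <- mwdiagnosis:::anti_alias_fir(600, 30)
  filt <- as.numeric(signal::filtfilt(b, 1, x))
  got <- filt[seq(1, by = 20, length.out = 60)]
  want <- oracle_downsample(x, 600, 30)[1:60]
  ## compare away from the window edges (FIR vs circular-FFT edge handling)
  i <- 6:55
  expect_lt(sqrt(sum((got[i] - want[i])^2)) / sqrt(sum(want[i]^2)), 0.01)
})

test_that("prepare_signatures yields finite 60-sample rows for every channel", {
  scans <- generate_dataset(list(n_breasts = 1, n_tumours = 2, n_positions = 2),
                            glandular_fractions = 0.05, n_samples = 4096,
                            seed = 21)
  sigs <- prepare_signatures(scans, angles = c(0, 30))
  expect_equal(nrow(sigs), 4 * 24)
  expect_true(all(vapply(sigs$signature, length, integer(1)) == 60L))
  expect_true(all(vapply(sigs$signature, function(s) all(is.finite(s)), logical(1))))
  expect_true(all(vapply(sigs$signature,
                         function(s) which.max(abs(s)) == 34L, logical(1))))

  ## time-alignment contract: the same tumour seen on different channels
  ## (noise/clutter-free) gives near-identical aligned signatures
  clean <- generate_dataset(list(n_breasts = 1, n_tumours = 2, n_positions = 1),
                            glandular_fractions = 0, n_samples = 4096,
                            noise_sigma = 0, seed = 22,
                            benign_s = c(0, 0), malignant_s = c(0.5, 0.9))
  cs <- prepare_signatures(clean, angles = 0)
  ben <- cs[cs$label == "benign", ]
  ## normalise away path-loss amplitude differences
  norm1 <- ben$signature[[1]] / max(abs(ben$signature[[1]]))
  for (j in 2:nrow(ben)) {
    nj <- ben$signature[[j]] / max(abs(ben$signature[[j]]))
    expect_gt(sum(norm1 * nj) / sqrt(sum(norm1^2) * sum(nj^2)), 0.99)
  }

  st <- signature_table(cs)
  expect_equal(length(grep("^t[0-9]{2}$", names(st))), 60)
})
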