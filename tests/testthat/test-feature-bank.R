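test_that("peak detection matches the exhaustive scan oracle", {
  expect_equal(nrow(detect_peaks(numeric(10))), 0)
  expect_error(detect_peaks(c(1, 2)), "3 samples")

  ## sampled Gaussian: one peak, FWHM ~ 2.355 sigma
  x <- exp(-((1:60) - 30)^2 / (2 * 5^2))
  pk <- detect_peaks(x, "positive")
  expect_equal(nrow(pk), 1)
  expect_equal(pk$location, 30L)
  expect_lt(abs(pk$fwhm - 2.3548 * 5) / (2.3548 * 5), 0.02)

  withr::with_seed(17, {
    for (rep in 1:30) {
      x <- random_signature(60)
      for (pol in c("positive", "negative")) {
        got <- detect_peaks(x, pol)
        want <- oracle_peaks(x, pol)
        expect_equal(got$location, want$location)
        expect_equal(got$amplitude, want$amplitude)
        expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
        expect_equal(got$fwhm, want$fwhm, tolerance = 1e-12)
      }
    }
  })
})

test_that("time-domain features follow their definitions", {
  z <- time_features(numeric(60))
  expect_equal(unname(z[c("f05", "f07", "f08", "f15", "f16", "f17")]),
               rep(0, 6))

  ## single positive half-cycle: all area positive
  half <- pmax(sin(2 * pi * (0:59) / 60), 0)
  tf <- time_features(half)
  expect_equal(unname(tf["f18"]), 100)
  expect_equal(unname(tf["f19"]), 0)

  withr::with_seed(23, {
    x <- random_signature(60)
    got <- time_features(x)
    want <- oracle_features(x)[1:19]
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  })
})

test_that("autocorrelation features match the definitional lag sums", {
  x <- random_signature(60)
  r <- autocorr_sequence(x)
  expect_equal(r[1], 1)
  expect_equal(r, oracle_autocorr(x), tolerance = 1e-10)

  ## sinusoid of period P: autocorrelation peaks separated by ~P
  P <- 12
  s <- sin(2 * pi * (0:59) / P)
  af <- autocorr_features(s)
  expect_lt(abs(af[["f24"]] - P), 0.5)

  expect_equal(unname(autocorr_features(numeric(60))), rep(0, 5))
})

test_that("PSD features match definitional Welch/periodogram estimates", {
  expect_equal(unname(psd_features(numeric(60))), rep(0, 6))

  withr::with_seed(29, {
    x <- random_signature(60)
    expect_equal(periodogram_psd(x, 30), oracle_periodogram(x, 30),
                 tolerance = 1e-8)
    expect_equal(welch_psd(x, 30), oracle_welch(x, 30), tolerance = 1e-8)
  })

  ## Parseval: integrated periodogram equals the mean signal power, so the
  ## mean periodogram of white noise tracks its variance
  withr::with_seed(31, {
    ratio <- replicate(1000, {
      x <- rnorm(60)
      sum(periodogram_psd(x, 30)) * (30 / 60) / mean(x^2)
    })
  })
  expect_lt(abs(mean(ratio) - 1), 0.05)

  ## single tone at an exact bin: exactly one periodogram peak
  tone <- sin(2 * pi * 6 * (0:59) / 60)
  expect_equal(unname(psd_features(tone)["f27"]), 1)
})

test_that("the 30-feature vector matches the brute-force oracle on seeded signatures", {
  withr::with_seed(37, {
    for (rep in 1:100) {
      x <- random_signature(60)
      got <- extract_features(x)
      want <- oracle_features(x)
      expect_equal(got, want, tolerance = 1e-8)
    }
  })
  expect_length(extract_features(numeric(60)), 30)
  expect_true(all(is.finite(extract_features(numeric(60)))))
  x <- random_signature(60)
  expect_identical(extract_features(x), extract_features(x))
})

test_that("features scale and shift the way their definitions imply", {
  withr::with_seed(41, {
    x <- random_signature(60)
    f1 <- extract_features(x)
    a <- 3.7
    fa <- extract_features(a * x)
    lin <- c("f01", "f03", "f09", "f10", "f16", "f17")
    expect_equal(unname(fa[lin]), unname(a * f1[lin]), tolerance = 1e-9)
    expect_equal(fa[["f05"]], a^2 * f1[["f05"]], tolerance = 1e-9)
    inv <- c("f02", "f04", "f07", "f08", "f15", "f18", "f19",
             sprintf("f%02d", 20:24))
    expect_equal(unname(fa[inv]), unname(f1[inv]), tolerance = 1e-9)

    ## autocorrelation/PSD features are invariant under circular shift of a
    ## periodic signal
    per <- sin(2 * pi * 3 * (0:59) / 60) + 0.4 * sin(2 * pi * 7 * (0:59) / 60)
    f_per <- extract_features(per)
    sh <- c(per[21:60], per[1:20])
    f_sh <- extract_features(sh)
    ## periodogram and autocorrelation peak structure are shift-insensitive;
    ## f23/f25 (linear-autocorrelation FWHM, Welch mean) only up to edge
    ## effects of the finite record
    spec <- c("f20", "f21", "f22", "f24", sprintf("f%02d", 26:30))
    expect_equal(unname(f_sh[spec]), unname(f_per[spec]), tolerance = 1e-6)
    expect_equal(f_sh[["f23"]], f_per[["f23"]], tolerance = 0.1)
    expect_equal(f_sh[["f25"]], f_per[["f25"]], tolerance = 0.2)
  })
})

test_that("feature tables carry 30 finite columns per signal", {
  scans <- generate_dataset(list(n_breasts = 1, n_tumours = 2, n_positions = 1),
                            glandular_fractions = 0.05, n_samples = 4096,
                            seed = 43)
  sigs <- prepare_signatures(scans, angles = 0)
  ft <- extract_feature_table(sigs)
  fcols <- grep("^f[0-9]{2}$", names(ft), value = TRUE)
  expect_length(fcols, 30)
  expect_true(all(vapply(ft[fcols], function(c) all(is.finite(c)), logical(1))))
  expect_equal(nrow(ft), nrow(sigs))
})
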