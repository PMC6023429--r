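# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive every quantity from its definition with
# different code (double loops, direct DFT sums, pairwise comparisons).

# strict local maxima with positive value, exhaustive neighbour scan
oracle_local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1] && y[i] > 0) out <- c(out, i)
  }
  out
}

# topographic prominence by exhaustive search for higher ground
oracle_prominence <- function(y, i) {
  n <- length(y)
  higher_left <- which(y[seq_len(i - 1)] >= y[i])
  lo <- if (length(higher_left)) max(higher_left) + 1L else 1L
  base_left <- min(y[lo:i])
  higher_right <- which(y[seq(i + 1, n)] >= y[i])
  hi <- if (length(higher_right)) i + min(higher_right) - 1L else n
  base_right <- min(y[i:hi])
  y[i] - max(base_left, base_right)
}

oracle_fwhm <- function(y, i, prom) {
  n <- length(y)
  ref <- y[i] - prom / 2
  below_left <- which(y[seq_len(i - 1)] <= ref)
  xl <- if (length(below_left)) {
    j <- max(below_left)
    j + (ref - y[j]) / (y[j + 1] - y[j])
  } else 1
  below_right <- which(y[seq(i + 1, n)] <= ref)
  xr <- if (length(below_right)) {
    j <- i + min(below_right)
    j - (ref - y[j]) / (y[j - 1] - y[j])
  } else n
  xr - xl
}

# full peak set matching the documented definition, independent code path
oracle_peaks <- function(x, polarity = "positive", min_prominence = NULL) {
  if (is.null(min_prominence)) min_prominence <- 0.05 * max(abs(x))
  y <- if (polarity == "positive") x else -x
  locs <- oracle_local_maxima(y)
  proms <- vapply(locs, function(i) oracle_prominence(y, i), numeric(1))
  keep <- proms >= min_prominence & proms > 0
  locs <- locs[keep]; proms <- proms[keep]
  data.frame(
    location = locs,
    amplitude = x[locs],
    prominence = proms,
    fwhm = vapply(seq_along(locs),
                  function(k) oracle_fwhm(y, locs[k], proms[k]), numeric(1))
  )
}

# autocorrelation by O(n^2) definitional lag sums, normalised to lag 0
oracle_autocorr <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (k in 0:(n - 1)) {
    acc <- 0
    for (t in 1:(n - k)) acc <- acc + x[t] * x[t + k]
    r[k + 1] <- acc
  }
  r / r[1]
}

# one-sided PSD via direct DFT double sum
oracle_psd_windowed <- function(x, w, fs) {
  n <- length(x)
  xw <- x * w
  nb <- n %/% 2 + 1
  p <- numeric(nb)
  for (k in 0:(nb - 1)) {
    re <- sum(xw * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xw * sin(-2 * pi * k * (0:(n - 1)) / n))
    p[k + 1] <- (re^2 + im^2) / (fs * sum(w^2))
  }
  sc <- rep(2, nb); sc[1] <- 1
  if (n %% 2 == 0) sc[nb] <- 1
  p * sc
}

oracle_periodogram <- function(x, fs) {
  oracle_psd_windowed(x, rep(1, length(x)), fs)
}

oracle_welch <- function(x, fs, segment = 30) {
  n <- length(x)
  hop <- segment %/% 2
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(segment - 1)) / (segment - 1))
  starts <- seq(1, n - segment + 1, by = hop)
  psds <- sapply(starts, function(s) {
    oracle_psd_windowed(x[s:(s + segment - 1)], w, fs)
  })
  rowMeans(psds)
}

# all 30 features from their definitions, using only oracle components
oracle_features <- function(x, fs = 30) {
  dt <- 1 / fs
  pos <- oracle_peaks(x, "positive")
  neg <- oracle_peaks(x, "negative")
  m0 <- function(v) if (length(v) == 0) 0 else mean(v)
  s0 <- function(l) if (length(l) < 2) 0 else mean(diff(l))
  tot <- sum(abs(x))
  tf <- c(
    if (nrow(pos)) max(pos$amplitude) else 0,
    if (nrow(pos)) pos$location[which.max(pos$amplitude)] else 0,
    if (nrow(neg)) min(neg$amplitude) else 0,
    if (nrow(neg)) neg$location[which.min(neg$amplitude)] else 0,
    sum((x - mean(x))^2) / (length(x) - 1),
    sqrt(sum(x^2) / length(x)),
    nrow(pos), nrow(neg),
    m0(pos$amplitude), m0(neg$amplitude),
    m0(pos$fwhm), m0(neg$fwhm),
    s0(pos$location), s0(neg$location),
    sum(x[-length(x)] * x[-1] < 0),
    sum(x) * dt, sum(abs(x)) * dt,
    if (tot > 0) 100 * sum(x[x > 0]) / tot else 0,
    if (tot > 0) -100 * sum(x[x < 0]) / tot else 0
  )
  r <- oracle_autocorr(x)
  pk <- oracle_peaks(r, "positive")
  af <- c(mean(r), nrow(pk), m0(pk$amplitude), m0(pk$fwhm), s0(pk$location))
  pg <- oracle_periodogram(x, fs)
  pp <- oracle_peaks(pg, "positive")
  pf <- c(mean(oracle_welch(x, fs)), mean(pg), nrow(pp), m0(pp$amplitude),
          m0(pp$fwhm), s0(pp$location))
  setNames(c(tf, af, pf), sprintf("f%02d", 1:30))
}

# AUC by exhaustive pairwise comparison (Mann-Whitney identity, ties 1/2)
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == "malignant"]
  sn <- scores[labels == "benign"]
  acc <- 0
  for (a in sp) for (b in sn) {
    acc <- acc + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  acc / (length(sp) * length(sn))
}

# ideal-filter downsampling: FFT brick wall at the output Nyquist + decimate
oracle_downsample <- function(x, fs_in, fs_out) {
  n <- length(x)
  X <- fft(x)
  f <- (0:(n - 1)) / n * fs_in
  f <- ifelse(f > fs_in / 2, f - fs_in, f)
  X[abs(f) > fs_out / 2] <- 0
  xf <- Re(fft(X, inverse = TRUE)) / n
  xf[seq(1, by = round(fs_in / fs_out), length.out = floor(n / round(fs_in / fs_out)))]
}

# three-media delay by a fine-stepped line integral of slowness
oracle_delay_one_way <- function(a, p, media, n_steps = 20000) {
  c0 <- media$breast_centre
  ts <- (seq_len(n_steps) - 0.5) / n_steps
  pts <- cbind(a[1] + ts * (p[1] - a[1]), a[2] + ts * (p[2] - a[2]))
  rr <- sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2)
  eps <- ifelse(rr > media$breast_radius, media$eps_immersion,
                ifelse(rr > media$breast_radius - media$skin_thickness,
                       media$eps_skin, media$eps_interior))
  L <- sqrt(sum((p - a)^2))
  sum(sqrt(eps)) * (L / n_steps) / 299.792458
}

# random smooth-ish test signatures with occasional sign structure
random_signature <- function(n = 60) {
  raw <- rnorm(n + 8)
  x <- stats::filter(raw, rep(1 / 3, 3), sides = 2)
  x <- x[!is.na(x)][1:n]
  as.numeric(x)
}

# well-separated two-class Gaussian feature data for forest tests
gaussian_classes <- function(n_per_class = 100, p = 30, sep = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_per_class * p, 0), n_per_class, p),
      matrix(rnorm(n_per_class * p, sep), n_per_class, p)
    )
    colnames(x) <- sprintf("f%02d", seq_len(p))
    list(features = as.data.frame(x),
         labels = rep(c("benign", "malignant"), each = n_per_class))
  })
}
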