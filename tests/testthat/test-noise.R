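test_that("EMG corruption at level none is the identity and never mutates input", {
  ref <- fixture_ref()
  e <- ref$excitations
  e0 <- e + 0
  spec <- noise_spec("none", "none", seed = 5)
  expect_identical(corrupt_emg(e, spec, rate = 50), e)
  noisy <- corrupt_emg(e, noise_spec("mid", "none", seed = 5), rate = 50)
  expect_identical(e, e0)                  # input untouched
  expect_false(identical(noisy, e))
  expect_true(all(noisy >= 0 & noisy <= 1))
})

test_that("the Fourier transform round-trip is exact to numerical precision", {
  set.seed(21)
  x <- runif(256)
  expect_lt(max(abs(Re(fft(fft(x), inverse = TRUE)) / 256 - x)), 1e-12)
})

test_that("added EMG noise is confined below the cutoff frequency", {
  # mid-range envelopes (no clipping): essentially all added power is in band
  rate <- 50
  Tn <- 200
  e <- matrix(0.5, 4, Tn)
  freq <- pmin(0:(Tn - 1), Tn - 0:(Tn - 1)) * rate / Tn
  above <- freq > 2.125
  leak <- function(emat, lv) {
    worst <- 0
    for (seed in 1:30) {
      noisy <- corrupt_emg(emat, noise_spec(lv, "none", seed = seed),
                           rate = rate)
      d <- noisy - emat
      for (ch in seq_len(nrow(d))) {
        p <- Mod(fft(d[ch, ]))^2
        if (sum(p) > 0) worst <- max(worst, sum(p[above]) / sum(p))
      }
    }
    worst
  }
  expect_lt(leak(e, "mid"), 0.01)
  # real envelopes ride near zero, so clipping folds some noise out of band;
  # the added power still stays predominantly low-frequency
  ref <- fixture_ref()
  expect_lt(leak(ref$excitations, "mid"), 0.3)
})

test_that("EMG noise magnitude increases strictly with the level", {
  ref <- fixture_ref()
  e <- ref$excitations
  mse <- sapply(c("low", "mid", "high"), function(lv) {
    mean(sapply(1:30, function(seed) {
      noisy <- corrupt_emg(e, noise_spec(lv, "none", seed = seed),
                           rate = 1 / ref$dt)
      mean((noisy - e)^2)
    }))
  })
  expect_true(all(diff(mse) > 0))
})

test_that("marker placement noise matches the 3-D Gaussian norm law", {
  m <- fixture_model()
  spec <- noise_spec(marker_level = "high")
  sigma <- spec$marker_sd[["high"]]
  norms <- unlist(lapply(1:250, function(seed) {
    s <- corrupt_marker_placement(m, "high", seed = seed)
    sqrt(colSums(attr(s, "placement_offsets")^2))
  }))
  expect_length(norms, 1000)
  expect_lt(abs(mean(norms) - chi3_mean(sigma / sqrt(3))) /
              chi3_mean(sigma / sqrt(3)), 0.1)
})

test_that("placement error displaces locally, constant over time, level none is identity", {
  m <- fixture_model()
  s0 <- corrupt_marker_placement(m, "none", seed = 3)
  expect_equal(compile_model(s0)$marker_loc, compile_model(m)$marker_loc)
  s <- corrupt_marker_placement(m, "mid", seed = 3)
  off <- attr(s, "placement_offsets")
  # muscles and segments untouched
  expect_identical(s$muscles, m$muscles)
  expect_identical(s$segments, m$segments)
  # rigid-transform isometry: per-frame displacement of a marker is bounded
  # by (and for a rotation-only chain equals) its local offset norm
  ref <- fixture_ref()
  noisy <- resimulate_markers(s, ref$states[1:2, ])
  clean <- ref$markers
  for (k in seq_len(compile_model(m)$nmark)) {
    rows <- (k - 1) * 3 + 1:3
    d <- sqrt(colSums((noisy[rows, ] - clean[rows, ])^2))
    expect_lt(max(abs(d - sqrt(sum(off[, k]^2)))), 1e-12)
  }
  expect_equal(dim(noisy), c(3 * 4, length(ref$time)))
})

test_that("re-simulating with the original model reproduces the reference markers", {
  ref <- fixture_ref()
  again <- resimulate_markers(ref$model, ref$states[1:2, ])
  expect_equal(again, ref$markers, tolerance = 1e-14)
})

test_that("corruption is reproducible from the seed", {
  ref <- fixture_ref()
  spec <- noise_spec("mid", "mid", seed = 77)
  s1 <- corrupt_reference(ref, spec)
  s2 <- corrupt_reference(ref, spec)
  expect_identical(s1$emg, s2$emg)
  expect_identical(s1$markers, s2$markers)
  s3 <- corrupt_reference(ref, noise_spec("mid", "mid", seed = 78))
  expect_false(identical(s1$emg, s3$emg))
})
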