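test_that("MODWT preserves energy and length", {
  set.seed(4)
  x <- rnorm(256)
  tr <- modwt(x, 5, "db4")
  expect_length(tr$W, 5L)
  expect_true(all(vapply(tr$W, nrow, 0L) == 256L))
  energy <- sum(vapply(tr$W, function(w) sum(w^2), 0)) + sum(tr$V^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-10)
  expect_error(modwt(rnorm(16), 5), "too short")
  expect_error(modwt(x, 3, "sym9"), "unsupported wavelet")
})

test_that("band spec validates geometry and resolves packets", {
  sp <- default_band_spec(0.735)
  expect_equal(sp$depth, 6L)
  expect_length(sp$packets, 3L)
  expect_error(band_spec(list(c(0.05, 0.9)), sampling_interval = 0.735),
               "Nyquist")
  expect_error(band_spec(list(c(0.05, 0.1), c(0.08, 0.2)),
                         sampling_interval = 0.2), "overlap")
  expect_error(band_spec(list(c(0.1, 0.05)), sampling_interval = 0.735),
               "low < high")
})

test_that("a pure tone concentrates in its target band (FFT-placed oracle)", {
  dt <- 0.735
  sp <- default_band_spec(dt)
  # tones well inside each band land >= 70% of the across-band energy
  # in that band; 0.04 Hz sits at a dyadic scale boundary, the packet
  # design keeps it in-band
  for (case in list(c(0.02, 3), c(0.04, 2), c(0.07, 1))) {
    x <- matrix(sin(2 * pi * case[1] * (0:4095) * dt), ncol = 1)
    en <- vapply(decompose_bands(x, sp), function(w) sum(w^2), 0)
    expect_gt(en[case[2]] / sum(en), 0.70)
  }
})

test_that("degenerate series and short inputs are handled explicitly", {
  sp <- default_band_spec(0.735)
  # constant series: zero oscillatory energy in every band
  co <- decompose_bands(matrix(1, 256, 2), sp)
  for (b in 1:3) expect_lt(max(abs(co[[b]])), 1e-12)
  # unresolvable depth names the offending band
  expect_error(decompose_bands(matrix(rnorm(8 * 2), 8, 2), sp),
               "band 3 .* unresolvable")
  expect_error(decompose_bands(matrix(c(NA, rnorm(255)), ncol = 1), sp),
               "missing")
})

test_that("band correlation has exact structure and flags zero variance", {
  set.seed(9)
  x <- matrix(rnorm(512 * 3), 512, 3)
  x[, 2] <- x[, 1]          # identical parcels
  x[, 3] <- -x[, 1]         # sign-flipped parcel
  wcon <- timeseries_to_connectome(x, default_band_spec(0.735))
  for (b in 1:3) {
    expect_equal(wcon$matrix[b, 1, 2], 1)
    expect_equal(wcon$matrix[b, 1, 3], -1)
    expect_true(isSymmetric(wcon$matrix[b, , ]))
    expect_equal(diag(wcon$matrix[b, , ]), rep(1, 3))
  }
  co <- decompose_bands(matrix(rnorm(512 * 2), 512, 2),
                        default_band_spec(0.735))
  co[[2]][, 2] <- 0
  expect_error(band_correlation(co), "parcel\\(s\\) 2 in band 2")
})

test_that("independent parcels decorrelate as T grows (ESS null bound)", {
  # wavelet coefficients are band-limited, so the null sd of r is
  # ~sqrt(2^J / T), not 1/sqrt(T); 4-sigma of the effective-sample-size
  # bound should contain (essentially) every edge
  dt <- 0.735
  sp <- default_band_spec(dt)
  set.seed(10)
  x <- matrix(rnorm(4096 * 8), 4096, 8)
  wcon <- timeseries_to_connectome(x, sp)
  bound <- 4 * sqrt(2^sp$depth / 4096)
  off <- upper.tri(wcon$matrix[1, , ])
  for (b in 1:3) expect_lt(max(abs(wcon$matrix[b, , ][off])), bound)
  # and the bound shrinks with T: longer series give smaller max |r|
  x2 <- matrix(rnorm(1024 * 8), 1024, 8)
  w2 <- timeseries_to_connectome(x2, sp)
  expect_gt(mean(abs(w2$matrix[1, , ][off])),
            mean(abs(wcon$matrix[1, , ][off])))
})

test_that("correlations are invariant to positive parcel rescaling", {
  set.seed(12)
  x <- matrix(rnorm(512 * 4), 512, 4)
  sp <- default_band_spec(0.735)
  w1 <- timeseries_to_connectome(x, sp)
  w2 <- timeseries_to_connectome(sweep(x, 2, c(1, 17.3, 0.01, 250), "*"), sp)
  expect_equal(w1$matrix, w2$matrix, tolerance = 1e-10)
})

test_that("planted band structure survives decompose -> correlate", {
  # build series whose band-2 component is shared between parcels 1-2
  # with independent content in the other bands; the wavelet pipeline
  # must recover the planted band and leave the others near zero
  dt <- 0.735
  cc <- diag(3); cc[1, 2] <- cc[2, 1] <- 0.95
  x <- generate_timeseries(2048, dt, n_parcels = 3,
                           band_corr = list(diag(3), cc, diag(3)),
                           noise_sd = 0.3, seed = 14)
  wcon <- timeseries_to_connectome(x, default_band_spec(dt))
  expect_gt(wcon$matrix[2, 1, 2], 0.6)
  expect_lt(abs(wcon$matrix[1, 1, 2]), 0.35)
  expect_lt(abs(wcon$matrix[3, 1, 2]), 0.35)
})
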