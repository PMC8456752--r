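test_that("phenotype generation honours the class-conditional models", {
  ph <- confounded_cohort(n = 2000, seed = 7)
  expect_equal(nrow(ph), 2000L)
  expect_setequal(names(ph), c("subject_id", "sex", "condition", "age",
                               "icv", "mfd", "dvars", "spike_pct"))
  # male ICV strictly above female under the defaults
  expect_gt(mean(ph$icv[ph$sex == 1]), mean(ph$icv[ph$sex == 0]))
  # condition-dependent motion
  expect_gt(mean(ph$mfd[ph$condition == "rest"]),
            mean(ph$mfd[ph$condition == "task"]))
  # ICV difference within 3 standard errors of the generating 2e5
  cm <- default_covariate_models()
  diff <- mean(ph$icv[ph$sex == 1]) - mean(ph$icv[ph$sex == 0])
  se <- 1e5 * sqrt(1 / sum(ph$sex == 1) + 1 / sum(ph$sex == 0))
  expect_lt(abs(diff - 2e5), 3 * se)
})

test_that("identical class distributions give null covariate tests", {
  spec <- cohort_spec(600, covariate_models = flat_covariate_models(),
                      seed = 3)
  ph <- generate_phenotypes(spec)
  for (cv in c("age", "icv", "mfd", "dvars")) {
    p <- wilcox.test(ph[[cv]][ph$sex == 1], ph[[cv]][ph$sex == 0],
                     exact = FALSE)$p.value
    expect_gt(p, 0.001)  # no planted effect: tiny p would be a 1/1000 event
  }
})

test_that("empty and invalid cohort specs behave", {
  expect_equal(nrow(generate_phenotypes(cohort_spec(0))), 0L)
  expect_error(cohort_spec(10, sex_ratio = 1), "sex_ratio")
  expect_error(cohort_spec(10, rest_fraction = 0), "rest_fraction")
  expect_error(cohort_spec(-1), "n_subjects")
  expect_error(effect_entry(0:9, "sometimes", 1), "condition")
  expect_error(cohort_spec(10, effect_plan = list(effect_entry(c(0, 200), "rest", 1))),
               "node indices")
})

test_that("connectomes are symmetric correlation-like stacks, reproducibly", {
  spec <- cohort_spec(6, seed = 11)
  ph <- generate_phenotypes(spec)
  wc <- generate_connectomes(ph, spec)
  expect_s3_class(wc, "wavelet_cohort")
  expect_equal(dim(wc$edges), c(6, 6670, 3))
  expect_true(all(abs(wc$edges) < 1))
  m <- connectome_matrix(wc, ph$subject_id[3])
  for (b in 1:3) {
    expect_true(isSymmetric(m[b, , ]))
    expect_equal(diag(m[b, , ]), rep(1, 116))
  }
  # bit-identical under the same seed
  wc2 <- generate_connectomes(ph, spec)
  expect_identical(wc$edges, wc2$edges)
  # different under another seed
  spec2 <- cohort_spec(6, seed = 12)
  wc3 <- generate_connectomes(generate_phenotypes(spec2), spec2)
  expect_false(identical(wc$edges, wc3$edges))
})

test_that("planted effects land on the right edges, condition and size", {
  nets <- load_networks()
  sal_in <- inner_edges(nets$SAL) + 1L
  cp <- planted_cohort(1000, nets$SAL, condition = "rest", d = 1.0, seed = 21)
  ph <- cp$phenotypes; wc <- cp$cohort
  pooled_d <- function(rows, cols) {
    x <- wc$edges[rows & ph$sex == 1, cols, 1]
    y <- wc$edges[rows & ph$sex == 0, cols, 1]
    (mean(x) - mean(y)) / sqrt((var(as.vector(x)) + var(as.vector(y))) / 2)
  }
  d_rest <- mean(vapply(sal_in, function(e)
    pooled_d(ph$condition == "rest", e), 0))
  d_task <- mean(vapply(sal_in, function(e)
    pooled_d(ph$condition == "task", e), 0))
  expect_lt(abs(d_rest - 1.0), 0.15)   # recovers the planted size
  expect_lt(abs(d_task), 0.15)         # absent in the other condition
  # non-planted edges separate at chance level
  off <- setdiff(seq_len(500), sal_in)[1:50]
  d_off <- mean(vapply(off, function(e) pooled_d(ph$condition == "rest", e), 0))
  expect_lt(abs(d_off), 0.15)
})

test_that("a zero-size effect entry is a no-op", {
  nets <- load_networks()
  spec0 <- cohort_spec(8, seed = 5)
  spec_d0 <- cohort_spec(8, seed = 5,
                         effect_plan = list(effect_entry(nets$SAL$nodes,
                                                         "rest", d = 0)))
  ph <- generate_phenotypes(spec0)
  expect_identical(generate_connectomes(ph, spec0)$edges,
                   generate_connectomes(ph, spec_d0)$edges)
})

test_that("time-series generation enforces its sampling preconditions", {
  expect_error(generate_timeseries(256, dt = 0), "positive")
  expect_error(generate_timeseries(32, dt = 0.5), ">= 64")
  expect_error(generate_timeseries(128, dt = 0.5), "too short")
  expect_error(generate_timeseries(4096, dt = 20), "Nyquist")
  x <- generate_timeseries(512, dt = 0.735, n_parcels = 4, seed = 2)
  expect_equal(dim(x), c(512L, 4L))
  expect_true(all(is.finite(x)))
})

test_that("band-limited components drive band-specific correlations", {
  # two parcels share one band-2 target correlation of ~1; empirical
  # band correlations follow (oracle: direct FFT bandpass construction)
  cc <- diag(4)
  cc[1, 2] <- cc[2, 1] <- 0.99
  x <- generate_timeseries(4096, dt = 0.735, n_parcels = 4,
                           band_corr = list(diag(4), cc, diag(4)),
                           noise_sd = 0.5, seed = 8)
  wcon <- timeseries_to_connectome(x, default_band_spec(0.735))
  expect_gt(wcon$matrix[2, 1, 2], 0.85)       # planted band
  expect_lt(abs(wcon$matrix[1, 1, 2]), 0.35)  # other bands near zero
  expect_lt(abs(wcon$matrix[3, 1, 2]), 0.35)
  expect_lt(abs(wcon$matrix[2, 3, 4]), 0.35)  # untouched pair
})
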