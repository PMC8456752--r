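test_that("equal-width discretization matches hand-computed bins", {
  tb <- data.frame(subject_id = letters[1:4], x = c(0, 1, 2, 3))
  sch <- binning_scheme(tb, c(x = 2L))
  bins <- discretize(tb, sch)
  expect_equal(as.integer(bins), c(1L, 1L, 2L, 2L))     # split at 1.5
  # degenerate constant covariate: single bin with a warning
  tb2 <- data.frame(subject_id = letters[1:3], x = c(10, 10, 10))
  expect_warning(sch2 <- binning_scheme(tb2, c(x = 4L)), "constant")
  expect_length(unique(discretize(tb2, sch2)), 1L)
  # multivariate bins are the product of the per-covariate bins
  tb3 <- data.frame(subject_id = letters[1:6],
                    x = c(0, 1, 2, 3, 4, 5), y = c(0, 0, 1, 1, 2, 2))
  sch3 <- binning_scheme(tb3, c(x = 2L, y = 3L))
  expect_length(levels(discretize(tb3, sch3)), 6L)
})

test_that("within-bin matching follows the hand-run of the rule", {
  # class A ICV {10,10,20}, class B {10,20,20}, 2 bins -> 1A+1B per bin
  tb <- data.frame(subject_id = paste0("s", 1:6),
                   sex = c(0, 0, 0, 1, 1, 1),
                   icv = c(10, 10, 20, 10, 20, 20))
  sch <- binning_scheme(tb, c(icv = 2L))
  kept <- match_within_bins(tb, discretize(tb, sch), "sex",
                            force_ratio = c(1, 1), seed = 4)
  sub <- tb[tb$subject_id %in% kept, ]
  expect_equal(nrow(sub), 4L)
  expect_equal(sum(sub$sex == 0), 2L)
  expect_equal(sum(sub$sex == 1), 2L)
  expect_equal(sort(sub$icv[sub$sex == 0]), c(10, 20))
  expect_equal(sort(sub$icv[sub$sex == 1]), c(10, 20))
  # identical multisets: everything retained
  tb2 <- data.frame(subject_id = paste0("t", 1:8), sex = rep(c(0, 1), 4),
                    icv = rep(c(1, 2, 3, 4), each = 2))
  sch2 <- binning_scheme(tb2, c(icv = 4L))
  expect_length(match_within_bins(tb2, discretize(tb2, sch2), "sex",
                                  c(1, 1), seed = 1), 8L)
  # disjoint supports: nothing survives
  tb3 <- data.frame(subject_id = paste0("u", 1:6), sex = rep(c(0, 1), 3),
                    icv = c(1, 100, 2, 101, 3, 102))
  sch3 <- binning_scheme(tb3, c(icv = 2L))
  expect_length(match_within_bins(tb3, discretize(tb3, sch3), "sex",
                                  c(1, 1), seed = 1), 0L)
})

test_that("balancing a confounded cohort certifies p > 0.10 at exact 1:1", {
  ph <- confounded_cohort(n = 2000, seed = 7)
  res <- balance(ph, balance_config(seed = 3))
  cert <- res$certificate
  expect_equal(cert$status, "success")
  expect_true(all(cert$p_values > 0.10))
  expect_equal(as.integer(cert$counts[1]), as.integer(cert$counts[2]))
  # certificate p-values recomputed independently (rank-sum by hand,
  # normal approximation with tie correction)
  sub <- ph[ph$subject_id %in% res$retained, ]
  for (cv in names(cert$p_values)) {
    x <- sub[[cv]][sub$sex == 0]; y <- sub[[cv]][sub$sex == 1]
    r <- rank(c(x, y))
    nx <- length(x); ny <- length(y)
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    ties <- table(c(x, y))
    s2 <- nx * ny / 12 * ((nx + ny + 1) -
                            sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    z <- (abs(U - nx * ny / 2) - 0.5) / sqrt(s2)
    p_manual <- 2 * pnorm(-z)
    expect_equal(unname(cert$p_values[cv]), p_manual, tolerance = 1e-8)
  }
})

test_that("identical class distributions pass at one bin per covariate", {
  # classes with literally identical covariate multisets: the rank test
  # cannot distinguish them, so the first (1-bin) configuration passes
  ph <- confounded_cohort(n = 200, seed = 19)
  half <- ph[seq_len(100), c("age", "icv", "mfd", "dvars", "spike_pct")]
  mirrored <- cbind(subject_id = ph$subject_id,
                    sex = rep(c(0L, 1L), each = 100),
                    condition = ph$condition,
                    rbind(half, half))
  res <- balance(mirrored, balance_config(seed = 2))
  expect_equal(res$certificate$status, "success")
  expect_true(all(res$certificate$n_bins == 1L))
  expect_true(all(res$certificate$p_values > 0.9))
  expect_length(res$retained, 200L)
})

test_that("degenerate classes yield failure certificates", {
  ph <- confounded_cohort(n = 60, seed = 1)
  ph$sex <- 0L  # one class empty
  res <- balance(ph, balance_config(seed = 1))
  expect_equal(res$certificate$status, "failure")
  expect_length(res$retained, 0L)
  # unattainable threshold exhausts the bin budget and names covariates
  ph2 <- confounded_cohort(n = 200, seed = 2)
  res2 <- balance(ph2, balance_config(p_threshold = 0.999,
                                      max_bins_per_covariate = 2L, seed = 1))
  expect_equal(res2$certificate$status, "failure")
  expect_true(any(res2$certificate$p_values <= 0.999))
})

test_that("retained sets are subsets without duplication, 1:1 for any seed", {
  ph <- confounded_cohort(n = 600, seed = 5)
  for (s in c(1, 2, 3)) {
    res <- balance(ph, balance_config(seed = s))
    expect_true(all(res$retained %in% ph$subject_id))
    expect_false(anyDuplicated(res$retained) > 0)
    sub <- ph[ph$subject_id %in% res$retained, ]
    expect_equal(sum(sub$sex == 0), sum(sub$sex == 1))
  }
})

test_that("finer binning never widens the within-bin covariate span", {
  ph <- confounded_cohort(n = 400, seed = 8)
  span <- function(nb) {
    sch <- binning_scheme(ph, c(icv = nb))
    max(diff(sch$breaks$icv))
  }
  spans <- vapply(c(1L, 2L, 4L, 8L, 16L), span, 0)
  expect_true(all(diff(spans) < 0))
})

test_that("two-factor balancing yields four matched divisions", {
  # on a cohort with identical class-conditional distributions both
  # stages pass and every covariate test clears the threshold twice
  spec <- cohort_spec(800, covariate_models = flat_covariate_models(),
                      seed = 23)
  ph <- generate_phenotypes(spec)
  res <- balance_two_factor(ph, balance_config(seed = 4))
  expect_equal(res$sex_certificate$status, "success")
  expect_equal(res$condition_certificate$status, "success")
  expect_true(all(res$sex_certificate$p_values > 0.10))
  expect_true(all(res$condition_certificate$p_values > 0.10))
  expect_gt(length(res$retained), 0.8 * nrow(ph))  # pre-balanced: keeps most
  # condition stage does not force a ratio: original rest/task mix kept
  sub <- ph[ph$subject_id %in% res$retained, ]
  in_ratio <- mean(ph$condition == "rest")
  out_ratio <- mean(sub$condition == "rest")
  expect_lt(abs(in_ratio - out_ratio), 0.08)
})

test_that("config validation rejects malformed input", {
  expect_error(balance_config(p_threshold = 1.5), "p_threshold")
  expect_error(balance_config(covariates = character(0)))
  expect_error(balance_config(force_ratio = c(2, 1)), "force_ratio")
  ph <- confounded_cohort(100, seed = 3)
  expect_error(balance(ph[, -4], balance_config()), "lacks column")
})
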