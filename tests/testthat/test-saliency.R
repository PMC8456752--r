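test_that("a zero-weight head yields an identically zero CAM", {
  cp <- planted_cohort(120, network_definition("w", 0:19), "both", d = 2,
                       seed = 91)
  m <- train_member(cp$cohort$edges, cp$phenotypes$sex, tiny_member_config())
  m$params$W_out[] <- 0
  m$params$b_out[] <- 0
  sal <- member_cam(m, cp$cohort$edges, m$test_idx[1:3], target_class = 1L)
  expect_true(all(sal == 0))
})

test_that("saliency of an effectively linear scorer matches |weight x input| scaling", {
  # identity-like member: no conv, one pass-through architecture is not
  # available, so check the analytic property on the guided gradient of
  # a network clamped to a linear regime (all-positive weights and
  # inputs keep every gate open; see test-nn for the gradient identity)
  cfg <- member_config(n_filters = 2L, dense_units = c(3L, 3L, 3L),
                       dropout = 0, epochs = 1L, grid_rows = 5L,
                       grid_cols = 4L, n_bands = 1L, seed = 3L)
  init <- connectoscramble:::nn_init(cfg)
  p <- lapply(init$params, abs)
  x <- array(abs(rnorm(2 * 5 * 4)) + 0.5, c(2, 5, 4))
  gr <- connectoscramble:::nn_input_gradient(p, init$run, x, cfg, 2L,
                                             guided = TRUE)
  # in the open-gate regime the map is linear, so the gradient is
  # constant in x: doubling the input leaves it unchanged
  gr2 <- connectoscramble:::nn_input_gradient(p, init$run, x * 2, cfg, 2L,
                                              guided = TRUE)
  expect_equal(gr$input_grad, gr2$input_grad, tolerance = 1e-10)
})

test_that("permuting edges together with the codec permutes the CAM", {
  # relabel the input edges by a permutation p and compose the codec so
  # the scrambled grids are bit-identical; the edge-space CAM must then
  # be exactly the p-relabelling of the original
  cp <- planted_cohort(120, network_definition("w", 0:19), "both", d = 2,
                       seed = 101)
  m1 <- train_member(cp$cohort$edges, cp$phenotypes$sex,
                     tiny_member_config(seed = 5))
  p <- with_seed(42, sample.int(6670L))
  pinv <- integer(6670L)
  pinv[p] <- seq_len(6670L)
  edges2 <- cp$cohort$edges[, p, , drop = FALSE]
  m2 <- m1
  m2$codec$perm <- pinv[m1$codec$perm]
  subj <- m1$test_idx[1:4]
  g1 <- connectoscramble:::build_grids(cp$cohort$edges, subj, m1$codec)
  g2 <- connectoscramble:::build_grids(edges2, subj, m2$codec)
  expect_identical(g1, g2)
  s1 <- member_cam(m1, cp$cohort$edges, subj, 1L)
  s2 <- member_cam(m2, edges2, subj, 1L)
  expect_equal(s2, s1[, p, , drop = FALSE])
})

test_that("aggregate CAMs are symmetric, non-negative and order-invariant", {
  cp <- planted_cohort(150, network_definition("w", 0:19), "both", d = 2,
                       seed = 111)
  cfg <- tiny_member_config()
  ens <- run_ensemble(cp$cohort$edges, cp$phenotypes, k = 3, cfg, seed = 5)
  cams <- suppressWarnings(aggregate_cams(ens$members, cp$cohort$edges))
  expect_true(all(cams$cam >= 0))
  cm <- subject_cam_matrix(cams, cams$subject[1])
  expect_true(isSymmetric(cm))
  expect_equal(diag(cm), rep(0, 116))
  cams_rev <- suppressWarnings(aggregate_cams(rev(ens$members),
                                              cp$cohort$edges))
  expect_equal(cams$cam, cams_rev$cam)
  expect_identical(cams$subject, cams_rev$subject)
  # a single member aggregates to its own class-averaged band mean
  cams1 <- suppressWarnings(aggregate_cams(ens$members[1], cp$cohort$edges))
  m <- ens$members[[1]]
  sal <- (member_cam(m, cp$cohort$edges, m$test_idx, 0L) +
            member_cam(m, cp$cohort$edges, m$test_idx, 1L)) / 2
  expect_equal(cams1$cam[match(m$test_idx, cams1$subject), ],
               apply(sal, c(1, 2), mean), ignore_attr = TRUE)
  # duplicated identical members change nothing (idempotent mean)
  cams2 <- suppressWarnings(aggregate_cams(list(m, m), cp$cohort$edges))
  expect_equal(cams2$cam, cams1$cam)
})

test_that("Cohen's d matches direct computation and handles degeneracy", {
  set.seed(5)
  x <- rnorm(5000, mean = 1); y <- rnorm(5000, mean = 0)
  expect_lt(abs(cohens_d(x, y) - 1), 0.1)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_message(d0 <- cohens_d(rep(1, 5), rep(1, 5)), "zero pooled")
  expect_true(is.na(d0))
  expect_error(cohens_d(1, c(1, 2)), ">= 2 values")
})

test_that("effect-size report has the full network x mode x stratum grid", {
  cp <- planted_cohort(150, network_definition("w", 0:19), "both", d = 2,
                       seed = 121)
  ens <- run_ensemble(cp$cohort$edges, cp$phenotypes, k = 2,
                      tiny_member_config(), seed = 6)
  cams <- suppressWarnings(aggregate_cams(ens$members, cp$cohort$edges))
  nets <- load_networks()
  eff <- network_effect_sizes(cams, nets, cp$phenotypes$condition)
  expect_equal(nrow(eff), 3 * 2 * 2)
  expect_setequal(unique(eff$network), c("DMN", "CEN", "SAL"))
  expect_true(all(is.finite(eff$d)))
  expect_true(all(eff$n_in > 0 & eff$n_out > 0))
})
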