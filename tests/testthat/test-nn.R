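# the network core is hand-rolled, so its gradients are verified against
# central finite differences on a tiny architecture

tiny_cfg <- function(use_conv = TRUE) {
  member_config(n_filters = 4L, dense_units = c(5L, 5L, 5L), dropout = 0,
                epochs = 1L, grid_rows = 6L, grid_cols = 4L, n_bands = 2L,
                use_conv = use_conv, seed = 9L)
}

test_that("softmax probabilities are a distribution for any input", {
  cfg <- tiny_cfg()
  init <- connectoscramble:::nn_init(cfg)
  set.seed(2)
  x <- array(rnorm(7 * 6 * 8, sd = 10), c(7, 6, 8))
  out <- connectoscramble:::nn_forward_eval(init$params, init$run, x, cfg)
  expect_equal(rowSums(out$probs), rep(1, 7))
  expect_true(all(out$probs >= 0))
})

test_that("weight initialisation is seed-determined and architecture-stable", {
  cfg <- tiny_cfg()
  p1 <- connectoscramble:::nn_init(cfg)$params
  p2 <- connectoscramble:::nn_init(cfg)$params
  expect_identical(p1, p2)
  cfg2 <- cfg; cfg2$seed <- 10L
  p3 <- connectoscramble:::nn_init(cfg2)$params
  expect_false(identical(p1$conv_W, p3$conv_W))
  # parameter count identical across members with the same config
  expect_equal(n_parameters(cfg), n_parameters(cfg2))
  expect_gt(n_parameters(cfg), 0)
  # and matches the closed-form count for the reference architecture
  ref <- member_config()
  expect_equal(n_parameters(ref),
               (58 * 3) * 256 + 256 + 2 * 256 +          # conv + bn
                 (115 * 256) * 64 + 64 + 2 * 64 +        # dense 1 + bn
                 64 * 64 + 64 + 2 * 64 +                 # dense 2 + bn
                 64 * 64 + 64 + 2 * 64 +                 # dense 3 + bn
                 64 * 2 + 2)                             # softmax head
})

test_that("analytic gradients match finite differences", {
  for (use_conv in c(TRUE, FALSE)) {
    cfg <- tiny_cfg(use_conv)
    init <- connectoscramble:::nn_init(cfg)
    p <- init$params
    set.seed(3)
    n <- 5
    x <- array(rnorm(n * 6 * 8), c(n, 6, 8))
    y <- cbind(c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 0))
    masks <- vector("list", 3)
    loss <- function(p) {
      fwd <- connectoscramble:::nn_forward_train(p, x, cfg, masks)
      -mean(log(pmax(rowSums(fwd$probs * y), 1e-12)))
    }
    fwd <- connectoscramble:::nn_forward_train(p, x, cfg, masks)
    g <- connectoscramble:::nn_backward(p, y, fwd, cfg)
    eps <- 1e-5
    for (nm in names(g)) {
      if (nm %in% c("conv_b", "b1", "b2", "b3")) next # absorbed by batch norm
      w <- p[[nm]]
      for (k in sample(length(w), min(4, length(w)))) {
        p_hi <- p; p_hi[[nm]][k] <- p_hi[[nm]][k] + eps
        p_lo <- p; p_lo[[nm]][k] <- p_lo[[nm]][k] - eps
        num <- (loss(p_hi) - loss(p_lo)) / (2 * eps)
        expect_equal(g[[nm]][k], num, tolerance = 1e-4,
                     label = paste("grad", nm, k))
      }
    }
  }
})

test_that("input gradients match finite differences (plain backward)", {
  cfg <- tiny_cfg()
  init <- connectoscramble:::nn_init(cfg)
  set.seed(5)
  x <- array(rnorm(3 * 6 * 8), c(3, 6, 8))
  gr <- connectoscramble:::nn_input_gradient(init$params, init$run, x, cfg,
                                             class_idx = 2L, guided = FALSE)
  f <- function(x) sum(connectoscramble:::nn_forward_eval(init$params,
                                                          init$run, x,
                                                          cfg)$logits[, 2])
  eps <- 1e-5
  for (k in sample(length(x), 12)) {
    x_hi <- x; x_hi[k] <- x_hi[k] + eps
    x_lo <- x; x_lo[k] <- x_lo[k] - eps
    expect_equal(gr$input_grad[k], (f(x_hi) - f(x_lo)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("guided backprop equals the plain gradient on all-positive paths", {
  # with non-negative weights and inputs no ReLU or guidance gate closes,
  # so the guided and plain input gradients coincide (closed-form check
  # of the guidance rule)
  cfg <- tiny_cfg()
  init <- connectoscramble:::nn_init(cfg)
  p <- lapply(init$params, abs)
  run <- init$run
  set.seed(6)
  x <- array(abs(rnorm(3 * 6 * 8)) + 0.1, c(3, 6, 8))
  gG <- connectoscramble:::nn_input_gradient(p, run, x, cfg, 2L, guided = TRUE)
  gP <- connectoscramble:::nn_input_gradient(p, run, x, cfg, 2L, guided = FALSE)
  expect_equal(gG$input_grad, gP$input_grad, tolerance = 1e-12)
})

test_that("grid stacking round-trips", {
  set.seed(7)
  x <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  xs <- connectoscramble:::.stack_rows(x)
  expect_equal(connectoscramble:::.unstack_rows(xs, 3, 4), x)
  a <- matrix(rnorm(12 * 5), 12, 5)
  fl <- connectoscramble:::.flatten_conv(a, 3, 4)
  expect_equal(connectoscramble:::.unflatten_conv(fl, 3, 4), a)
})
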