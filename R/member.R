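# One ensemble member: permutation codec + scrambled-grid classifier
#
# Each member draws its own random bijection over the unique edges (the
# codec), lays the permuted edge values of every band onto a 115 x 58
# grid (115 x 29 in half-edge occlusion mode) with the SAME permutation
# in all three bands, and trains the small convolutional classifier on
# its own balanced subsample with a 4:1:1 subject-level split. Test-set
# probabilities are recorded for the ensemble vote; test data are never
# touched during training.

#' Permutation codec over unique edges
#'
#' A seeded bijection on the edge ids `0..n-1`, shared across all wavelet
#' bands, together with the grid shape the permuted values are reshaped
#' into (row-major).
#'
#' @param n_values number of values to scramble: the full unique-edge
#'   count (6670) or the occlusion half (3335).
#' @param seed codec seed.
#' @param n_nodes parcellation size (sets the grid row count `V - 1`).
#' @return object of class `permutation_codec` with fields `perm` (1-based
#'   permutation: grid slot k holds input value `perm[k]`), `n_values`,
#'   `rows`, `cols`.
#' @export
make_codec <- function(n_values = 6670L, seed = 1L, n_nodes = 116L) {
  rows <- n_nodes - 1L
  if (n_values %% rows != 0L)
    stop2("cannot arrange ", n_values, " values on a ", rows, "-row grid")
  perm <- with_seed(substream_seed(seed, "codec"),
                    sample.int(n_values))
  structure(list(perm = perm, n_values = as.integer(n_values),
                 rows = rows, cols = as.integer(n_values / rows)),
            class = "permutation_codec")
}

#' @export
print.permutation_codec <- function(x, ...) {
  cat("<permutation_codec>", x$n_values, "values on a", x$rows, "x", x$cols,
      "grid\n")
  invisible(x)
}

# edge-value matrix (E x n_bands) from the accepted connectome inputs
.edge_values <- function(connectome) {
  if (inherits(connectome, "wavelet_connectome")) {
    nb <- dim(connectome$matrix)[1]
    return(vapply(seq_len(nb), function(b)
      matrix_to_edges(connectome$matrix[b, , ]),
      numeric(n_edges(dim(connectome$matrix)[2]))))
  }
  if (is.matrix(connectome)) return(connectome)
  stop2("connectome must be a wavelet_connectome or an edge-value matrix")
}

#' Scramble a connectome onto the member grid
#'
#' Permutes the unique edge values of every band by the codec and
#' reshapes them row-major onto the grid; bands stack as the third array
#' dimension. With an occlusion `mask` (half of the edges), only the
#' masked edges enter the (narrower) grid and the codec must have been
#' built for the mask size.
#'
#' @param connectome a `wavelet_connectome` or an `E x n_bands` edge-value
#'   matrix (edge-id order).
#' @param codec a [make_codec()].
#' @param mask optional sorted 0-based edge ids (occlusion mode); its
#'   length must be the codec size and equal `floor(E/2)` or `E`.
#' @return array `rows x cols x n_bands`.
#' @export
scramble <- function(connectome, codec, mask = NULL) {
  ev <- .edge_values(connectome)
  E <- nrow(ev)
  if (!is.null(mask)) {
    if (length(mask) != floor(E / 2) && length(mask) != E)
      stop2("mask must cover half (", floor(E / 2), ") or all (", E,
            ") edges, not ", length(mask))
    ev <- ev[mask + 1L, , drop = FALSE]
  }
  if (nrow(ev) != codec$n_values)
    stop2("codec built for ", codec$n_values, " values, got ", nrow(ev))
  out <- array(NA_real_, c(codec$rows, codec$cols, ncol(ev)))
  for (b in seq_len(ncol(ev)))
    out[, , b] <- matrix(ev[codec$perm, b], codec$rows, codec$cols,
                         byrow = TRUE)
  out
}

#' Invert the scramble
#'
#' @param grid array from [scramble()].
#' @param codec the same codec.
#' @return matrix `n_values x n_bands` in edge-id order (masked-edge order
#'   when the codec is a mask codec).
#' @export
unscramble <- function(grid, codec) {
  stopifnot(dim(grid)[1] == codec$rows, dim(grid)[2] == codec$cols)
  nb <- dim(grid)[3]
  out <- matrix(NA_real_, codec$n_values, nb)
  for (b in seq_len(nb)) {
    rowmajor <- as.vector(t(grid[, , b]))
    out[codec$perm, b] <- rowmajor
  }
  out
}

# subject-level stratified split with proportions cfg$split (default
# 4:1:1): floor for validation/test per class, remainder to train
split_subjects <- function(labels, split = c(4, 1, 1), seed = 1L) {
  idx <- with_seed(substream_seed(seed, "split"), {
    parts <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cl in sort(unique(labels))) {
      w <- which(labels == cl)
      w <- w[sample.int(length(w))]
      n_val <- floor(length(w) * split[2] / sum(split))
      n_test <- floor(length(w) * split[3] / sum(split))
      parts$val <- c(parts$val, w[seq_len(n_val)])
      parts$test <- c(parts$test, w[n_val + seq_len(n_test)])
      parts$train <- c(parts$train, w[-seq_len(n_val + n_test)])
    }
    parts
  })
  for (nm in names(idx)) {
    cls <- unique(labels[idx[[nm]]])
    if (length(cls) < 2L)
      stop2("split '", nm, "' lost a class: too few subjects to split ",
            paste(split, collapse = ":"), " with both classes present")
  }
  idx
}

# grids for a set of subjects: (n, rows, cols*n_bands) ready for the net
build_grids <- function(edge_array, subjects, codec, mask = NULL) {
  rows <- codec$rows
  rowlen <- codec$cols * dim(edge_array)[3]
  out <- array(NA_real_, c(length(subjects), rows, rowlen))
  for (k in seq_along(subjects)) {
    g <- scramble(edge_array[subjects[k], , ], codec, mask)
    out[k, , ] <- matrix(g, rows, rowlen)
  }
  out
}

#' Train one ensemble member
#'
#' Splits the supplied subjects 4:1:1 at subject level (stratified by
#' class), trains the scrambled classifier for `config$epochs` epochs,
#' restores the weights of the epoch with the highest validation
#' accuracy (earliest epoch on ties), and records the held-out test-set
#' class probabilities. Test data are never evaluated during training.
#'
#' @param edge_array `n x E x n_bands` edge-value array (e.g.
#'   `wavelet_cohort$edges`).
#' @param labels 0/1 class labels, length n.
#' @param config a [member_config()].
#' @param subjects integer indices of the subjects available to this
#'   member (its balanced subsample); default all.
#' @param mask optional 0-based occlusion edge mask (half of the edges).
#' @param subject_ids optional ids carried through to the result.
#' @return object of class `trained_member`: parameters, running
#'   statistics, codec, mask, split indices, per-epoch training log,
#'   `best_epoch`, test ids/labels/probabilities and test AUROC.
#' @export
train_member <- function(edge_array, labels, config,
                         subjects = seq_along(labels), mask = NULL,
                         subject_ids = NULL) {
  stopifnot(inherits(config, "member_config"),
            length(dim(edge_array)) == 3L)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop2("labels must be 0/1")
  n_vals <- if (is.null(mask)) dim(edge_array)[2] else length(mask)
  codec <- make_codec(n_vals, seed = config$seed,
                      n_nodes = as.integer((1 + sqrt(1 + 8 * dim(edge_array)[2])) / 2))
  if (codec$cols != config$grid_cols || codec$rows != config$grid_rows)
    stop2("config grid ", config$grid_rows, "x", config$grid_cols,
          " incompatible with codec grid ", codec$rows, "x", codec$cols)
  lab <- labels[subjects]
  sp <- split_subjects(lab, config$split, seed = config$seed)
  x_train <- build_grids(edge_array, subjects[sp$train], codec, mask)
  x_val <- build_grids(edge_array, subjects[sp$val], codec, mask)
  y_train <- lab[sp$train]
  y_val <- lab[sp$val]
  y_onehot <- cbind(y_train == 0L, y_train == 1L) * 1
  init <- nn_init(config)
  p <- init$params
  run <- init$run
  opt <- adam_init(p)
  n_tr <- length(y_train)
  best <- list(acc = -Inf, epoch = NA_integer_, params = p, run = run)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_accuracy = numeric(0))
  with_seed(substream_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0
      for (start in seq(1, n_tr, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        if (length(bi) < 2L) next  # batch statistics need >= 2 samples
        xb <- x_train[bi, , , drop = FALSE]
        yb <- y_onehot[bi, , drop = FALSE]
        masks <- lapply(seq_along(config$dense_units), function(i) {
          if (config$dropout <= 0) return(NULL)
          u <- config$dense_units[i]
          matrix(stats::rbinom(length(bi) * u, 1L, 1 - config$dropout) /
                   (1 - config$dropout), length(bi), u)
        })
        fwd <- nn_forward_train(p, xb, config, masks)
        ep_loss <- ep_loss - sum(log(pmax(
          rowSums(fwd$probs * yb), 1e-12))) / n_tr
        # running statistics update (momentum as in common frameworks)
        if (config$use_conv) {
          run$mean0 <- .bn_momentum * run$mean0 +
            (1 - .bn_momentum) * fwd$cache$bn0$mu
          run$var0 <- .bn_momentum * run$var0 +
            (1 - .bn_momentum) * fwd$cache$bn0$v
        }
        for (i in seq_along(config$dense_units)) {
          bn <- fwd$cache[[paste0("bn", i)]]
          run[[paste0("mean", i)]] <- .bn_momentum * run[[paste0("mean", i)]] +
            (1 - .bn_momentum) * bn$mu
          run[[paste0("var", i)]] <- .bn_momentum * run[[paste0("var", i)]] +
            (1 - .bn_momentum) * bn$v
        }
        grad <- nn_backward(p, yb, fwd, config)
        upd <- adam_step(p, grad, opt, config$learning_rate)
        p <- upd$params
        opt <- upd$state
      }
      val_pred <- nn_forward_eval(p, run, x_val, config)$probs
      val_acc <- mean((val_pred[, 2] > 0.5) == (y_val == 1L))
      log[nrow(log) + 1L, ] <- list(ep, ep_loss, val_acc)
      if (val_acc > best$acc) {  # strict: earliest epoch wins ties
        best <- list(acc = val_acc, epoch = ep, params = p, run = run)
      }
    }
  })
  x_test <- build_grids(edge_array, subjects[sp$test], codec, mask)
  test_probs <- nn_forward_eval(best$params, best$run, x_test, config)$probs
  y_test <- lab[sp$test]
  structure(list(
    params = best$params, run = best$run, config = config, codec = codec,
    mask = mask, best_epoch = best$epoch, log = log,
    train_idx = subjects[sp$train], val_idx = subjects[sp$val],
    test_idx = subjects[sp$test],
    test_ids = if (is.null(subject_ids)) subjects[sp$test]
               else subject_ids[subjects[sp$test]],
    test_labels = y_test, test_probs = test_probs,
    test_auroc = auroc(test_probs[, 2], y_test)),
    class = "trained_member")
}

#' @export
print.trained_member <- function(x, ...) {
  cat("<trained_member> best epoch", x$best_epoch, "| test AUROC",
      round(x$test_auroc, 4), "on", length(x$test_idx), "subjects\n")
  invisible(x)
}

#' Class probabilities from a trained member
#'
#' @param member a `trained_member`.
#' @param edge_array `n x E x n_bands` edge values.
#' @param subjects indices to score (default all).
#' @return matrix `length(subjects) x 2` of class probabilities
#'   (columns: female, male).
#' @export
predict_member <- function(member, edge_array, subjects = NULL) {
  subjects <- subjects %||% seq_len(dim(edge_array)[1])
  x <- build_grids(edge_array, subjects, member$codec, member$mask)
  nn_forward_eval(member$params, member$run, x, member$config)$probs
}

#' Parameter count of a member architecture
#'
#' @param config a [member_config()].
#' @return total number of trainable parameters.
#' @export
n_parameters <- function(config) {
  p <- nn_init(config)$params
  sum(vapply(p, length, 0L))
}
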