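# Guided Grad-CAM saliency in edge space
#
# For each member and subject, Grad-CAM channel weights (spatially
# averaged gradients of the target-class score at the convolutional
# feature maps, ReLU-ed weighted combination) give one importance value
# per grid row; these are broadcast over the row and multiplied by the
# guided-backpropagation input gradient, then mapped back through the
# member's inverse codec to (edge, band) space. Per-subject maps are
# averaged over members, both target classes and the three bands into a
# single symmetric 116 x 116 class activation map. Network comparisons
# use Cohen's d of in-set versus out-of-set CAM values rather than
# significance tests (the value counts are enormous, so any difference
# is "significant").

#' Guided Grad-CAM edge saliency for one member
#'
#' @param member a `trained_member`.
#' @param edge_array `n x E x n_bands` edge values.
#' @param subjects subject indices to map.
#' @param target_class 0 (female) or 1 (male).
#' @return array `length(subjects) x n_values x n_bands` of non-negative
#'   saliencies in the member's edge space (masked-edge order for
#'   occlusion members).
#' @export
member_cam <- function(member, edge_array, subjects, target_class = 1L) {
  stopifnot(inherits(member, "trained_member"), target_class %in% c(0L, 1L))
  cfg <- member$config
  x <- build_grids(edge_array, subjects, member$codec, member$mask)
  gr <- nn_input_gradient(member$params, member$run, x, cfg,
                          class_idx = target_class + 1L, guided = TRUE)
  n <- length(subjects)
  rows <- cfg$grid_rows
  if (cfg$use_conv) {
    # Grad-CAM at the conv feature maps with PLAIN (unguided) gradients:
    # alpha_f = row-mean of the class gradient, cam_row =
    # ReLU(sum_f alpha_f A[row, f]) per subject
    grp <- nn_input_gradient(member$params, member$run, x, cfg,
                             class_idx = target_class + 1L, guided = FALSE)
    act <- array(gr$conv_act, c(rows, n, cfg$n_filters))
    gcam <- array(grp$conv_grad, c(rows, n, cfg$n_filters))
    cam_rows <- matrix(0, n, rows)
    for (s in seq_len(n)) {
      alpha <- colMeans(gcam[, s, , drop = TRUE])
      cam_rows[s, ] <- pmax(act[, s, ] %*% alpha, 0)
    }
  } else {
    cam_rows <- matrix(1, n, rows)  # no conv layer: guidance alone
  }
  # the ReLU-layer guidance leaves the very first (input) layer signed:
  # class-0 evidence on male-shifted edges is a negative input gradient,
  # so the magnitude is taken at the input layer only, keeping the map
  # non-negative and class-symmetric
  sal_grid <- abs(gr$input_grad) * array(rep(cam_rows, dim(x)[3]), dim(x))
  out <- array(NA_real_, c(n, member$codec$n_values, cfg$n_bands))
  for (s in seq_len(n)) {
    g3 <- array(sal_grid[s, , ], c(rows, cfg$grid_cols, cfg$n_bands))
    out[s, , ] <- unscramble(g3, member$codec)
  }
  out
}

#' Aggregate member CAMs into per-subject maps
#'
#' For every subject, saliency maps are computed with respect to both
#' classes in every member in whose held-out test set the subject
#' appeared, then averaged with equal weight over members, classes and
#' bands into one edge-space map.
#'
#' @param members list of `trained_member` objects.
#' @param edge_array `n x E x n_bands` edge values.
#' @return object of class `subject_cams`: `cam` (matrix
#'   `n_covered x E`, non-negative), `subject` (cohort indices),
#'   `n_members` (members averaged per subject), `n_nodes`. Subjects in
#'   no member's test set are excluded with a warning.
#' @export
aggregate_cams <- function(members, edge_array) {
  stopifnot(length(members) >= 1L)
  n_total <- dim(edge_array)[1]
  E <- dim(edge_array)[2]
  acc <- matrix(0, n_total, E)
  cnt <- integer(n_total)
  for (m in members) {
    subj <- m$test_idx
    sal <- (member_cam(m, edge_array, subj, target_class = 0L) +
              member_cam(m, edge_array, subj, target_class = 1L)) / 2
    band_mean <- apply(sal, c(1, 2), mean)
    cols <- if (is.null(m$mask)) seq_len(E) else m$mask + 1L
    acc[subj, cols] <- acc[subj, cols] + band_mean
    cnt[subj] <- cnt[subj] + 1L
  }
  covered <- which(cnt > 0L)
  if (length(covered) < n_total)
    warning(n_total - length(covered),
            " subject(s) in no member's test set; excluded from CAMs",
            call. = FALSE)
  structure(list(cam = acc[covered, , drop = FALSE] / cnt[covered],
                 subject = covered, n_members = cnt[covered],
                 n_nodes = as.integer((1 + sqrt(1 + 8 * E)) / 2)),
            class = "subject_cams")
}

#' @export
print.subject_cams <- function(x, ...) {
  cat("<subject_cams>", nrow(x$cam), "subjects x", ncol(x$cam), "edges\n")
  invisible(x)
}

#' One subject's CAM as a symmetric matrix
#'
#' @param cams a `subject_cams` object.
#' @param subject cohort index of the subject.
#' @return symmetric `V x V` matrix with zero diagonal.
#' @export
subject_cam_matrix <- function(cams, subject) {
  k <- match(subject, cams$subject)
  if (is.na(k)) stop2("subject ", subject, " has no aggregated CAM")
  edges_to_matrix(cams$cam[k, ], cams$n_nodes, diag = 0)
}

#' Cohen's d (pooled standard deviation)
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param na_zero_sd return `NA` (with a message) when the pooled sd is
#'   zero, instead of erroring.
#' @return standardized mean difference, positive when `x` is larger.
#' @export
cohens_d <- function(x, y, na_zero_sd = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop2("Cohen's d needs >= 2 values per group")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) {
    if (!na_zero_sd) stop2("pooled standard deviation is zero")
    message("Cohen's d undefined: zero pooled standard deviation")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Network effect sizes of CAM values
#'
#' For every network, edge mode (inner/connecting) and stratum
#' (rest/task), Cohen's d of the CAM values on the network's edge set
#' against the CAM values of all remaining edges, pooled over the
#' stratum's subjects.
#'
#' @param cams a `subject_cams` object.
#' @param networks named list of [network_definition()] objects.
#' @param strata character vector aligned with the cohort (e.g. the
#'   phenotype `condition` column); use a constant vector for a single
#'   stratum.
#' @param modes subset of `c("inner", "connecting")`.
#' @return data.frame: `network`, `edge_set`, `stratum`, `d`, `n_in`,
#'   `n_out`.
#' @export
network_effect_sizes <- function(cams, networks, strata,
                                 modes = c("inner", "connecting")) {
  stopifnot(inherits(cams, "subject_cams"))
  strata_cov <- strata[cams$subject]
  out <- list()
  for (nm in names(networks)) {
    for (mode in modes) {
      set <- if (mode == "inner") inner_edges(networks[[nm]])
             else connecting_edges(networks[[nm]])
      for (st in sort(unique(strata_cov))) {
        rows <- which(strata_cov == st)
        inside <- as.vector(cams$cam[rows, set + 1L, drop = FALSE])
        outside <- as.vector(cams$cam[rows, -(set + 1L), drop = FALSE])
        out[[length(out) + 1L]] <- data.frame(
          network = nm, edge_set = mode, stratum = st,
          d = cohens_d(inside, outside),
          n_in = length(inside), n_out = length(outside))
      }
    }
  }
  do.call(rbind, out)
}
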