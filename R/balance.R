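# Multivariate confound balancing
#
# Curates a subset of a cohort in which every named covariate is
# distributionally indistinguishable between two classes: covariates are
# discretized into equal-width bins, subjects are matched within
# multivariate bin cells, and the bin counts are refined (worst covariate
# first) until a two-sided Mann-Whitney U test on the retained subset
# exceeds the p threshold for every covariate. With a forced 1:1 ratio
# the retained classes have exactly equal size for any seed.

#' Balancing configuration
#'
#' @param covariates covariate column names (default: the five balancing
#'   covariates age, MFD, ICV, DVARS, spike percentage).
#' @param p_threshold every covariate's two-sided Mann-Whitney p between
#'   the retained classes must exceed this (default 0.10).
#' @param force_ratio `c(1, 1)` to force exactly equal class counts, or
#'   `NULL` to preserve the input class ratio (no forced ratio).
#' @param max_bins_per_covariate refinement cap per covariate.
#' @param seed seed for the within-bin random draws.
#' @return object of class `balance_config`.
#' @export
balance_config <- function(covariates = c("age", "mfd", "icv", "dvars",
                                          "spike_pct"),
                           p_threshold = 0.10,
                           force_ratio = c(1, 1),
                           max_bins_per_covariate = 32L,
                           seed = 1L) {
  stopifnot(length(covariates) >= 1L, is.character(covariates))
  if (!(p_threshold > 0 && p_threshold < 1))
    stop2("p_threshold must lie in (0,1)")
  if (!is.null(force_ratio) &&
      !(length(force_ratio) == 2L && all(force_ratio == c(1, 1))))
    stop2("force_ratio must be NULL or c(1, 1)")
  structure(list(covariates = covariates, p_threshold = p_threshold,
                 force_ratio = force_ratio,
                 max_bins_per_covariate = as.integer(max_bins_per_covariate),
                 seed = as.integer(seed)),
            class = "balance_config")
}

#' Equal-width binning scheme
#'
#' Bin edges cover `[min, max]` of each covariate over the full table in
#' equal spans. A constant covariate collapses to a single bin with a
#' warning.
#'
#' @param table data.frame holding the covariates.
#' @param n_bins named integer vector, bins per covariate.
#' @return object of class `binning_scheme` (per-covariate breaks).
#' @export
binning_scheme <- function(table, n_bins) {
  stopifnot(all(names(n_bins) %in% names(table)), all(n_bins >= 1))
  breaks <- lapply(stats::setNames(names(n_bins), names(n_bins)), function(cv) {
    x <- table[[cv]]
    if (anyNA(x) || !all(is.finite(x)))
      stop2("covariate '", cv, "' has missing or non-finite values")
    r <- range(x)
    if (r[1] == r[2]) {
      warning("covariate '", cv, "' is constant; using a single bin",
              call. = FALSE)
      return(c(r[1] - 0.5, r[1] + 0.5))
    }
    seq(r[1], r[2], length.out = n_bins[[cv]] + 1L)
  })
  structure(list(n_bins = n_bins, breaks = breaks), class = "binning_scheme")
}

#' Multivariate bin index per subject
#'
#' Assigns every subject the tuple of equal-width bin indices of its
#' covariates (encoded as a single factor of the interacted bins; every
#' subject falls in exactly one multivariate bin).
#'
#' @param table data.frame of subjects.
#' @param scheme a [binning_scheme()].
#' @return factor of length `nrow(table)`; levels are multivariate bins.
#' @export
discretize <- function(table, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  parts <- lapply(names(scheme$breaks), function(cv) {
    br <- scheme$breaks[[cv]]
    cut(table[[cv]], breaks = br, include.lowest = TRUE, labels = FALSE)
  })
  interaction(as.data.frame(parts), drop = FALSE, sep = "|")
}

# per-bin retained counts honouring the ratio rule
.bin_quota <- function(nA, nB, ratio) {
  if (is.null(ratio)) return(c(A = nA, B = nB))  # caller rescales
  k <- min(nA, nB)
  c(A = k, B = k)
}

#' Match subjects within multivariate bins
#'
#' Within each multivariate bin, subjects are drawn at random (seeded)
#' from each class: with `force_ratio = c(1, 1)`, `min(nA, nB)` per class,
#' which makes the retained classes exactly equal in size; with
#' `force_ratio = NULL` the draw preserves the overall input class ratio
#' per bin (`kB = min(nB, floor(nA / r))`, `kA = min(nA, round(kB r))`
#' with `r =` total A / total B).
#'
#' @param table data.frame with a `subject_id` column and the class column.
#' @param bins factor from [discretize()].
#' @param class_col name of the binary class column.
#' @param force_ratio `c(1, 1)` or `NULL` (see [balance_config()]).
#' @param seed draw seed.
#' @return character vector of retained subject ids (no duplicates,
#'   subset of the input).
#' @export
match_within_bins <- function(table, bins, class_col = "sex",
                              force_ratio = c(1, 1), seed = 1L) {
  cls <- table[[class_col]]
  lv <- sort(unique(cls))
  if (length(lv) != 2L)
    stop2("class column '", class_col, "' must have exactly two classes (has ",
          length(lv), ")")
  r_global <- sum(cls == lv[1]) / sum(cls == lv[2])
  with_seed(seed, {
    keep <- lapply(levels(bins)[tabulate(bins) > 0], function(bn) {
      inA <- which(bins == bn & cls == lv[1])
      inB <- which(bins == bn & cls == lv[2])
      if (!is.null(force_ratio)) {
        k <- min(length(inA), length(inB))
        kA <- k; kB <- k
      } else {
        kB <- min(length(inB), floor(length(inA) / r_global))
        kA <- min(length(inA), round(kB * r_global))
      }
      c(inA[sample.int(length(inA), kA)], inB[sample.int(length(inB), kB)])
    })
  })
  table$subject_id[sort(unlist(keep))]
}

# two-sided Mann-Whitney U p-value (normal approximation with tie
# correction, the large-sample form)
mann_whitney_p <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) return(NA_real_)
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE,
                                      alternative = "two.sided")$p.value)
}

#' Balance a cohort on one class factor
#'
#' Iterative equal-width-bin matching: starting from one bin per
#' covariate, subjects are matched within multivariate bins, the
#' two-sided Mann-Whitney U test is computed per covariate between the
#' retained classes, and while any p is at or below the threshold the bin
#' count of the covariate with the smallest p is incremented and matching
#' re-run from scratch. The first (minimum total bins) passing
#' configuration is returned.
#'
#' @param table data.frame with `subject_id`, the class column and all
#'   covariates.
#' @param config a [balance_config()].
#' @param class_col binary class column name (default `"sex"`).
#' @return list with `retained` (subject ids) and `certificate`: a
#'   `balance_certificate` holding status, per-covariate p-values on the
#'   retained subset, per-class retained counts and final bin counts.
#' @export
balance <- function(table, config, class_col = "sex") {
  stopifnot(inherits(config, "balance_config"))
  miss <- setdiff(c("subject_id", class_col, config$covariates), names(table))
  if (length(miss)) stop2("table lacks column(s): ", paste(miss, collapse = ", "))
  cls_all <- table[[class_col]]
  lv <- sort(unique(cls_all))
  fail_cert <- function(pvals, n_bins, counts) {
    structure(list(status = "failure", p_values = pvals, counts = counts,
                   n_bins = n_bins, p_threshold = config$p_threshold,
                   class_col = class_col),
              class = "balance_certificate")
  }
  if (length(lv) != 2L) {
    return(list(retained = character(0),
                certificate = fail_cert(
                  stats::setNames(rep(NA_real_, length(config$covariates)),
                                  config$covariates),
                  stats::setNames(rep(1L, length(config$covariates)),
                                  config$covariates),
                  table(factor(cls_all)))))
  }
  n_bins <- stats::setNames(rep(1L, length(config$covariates)),
                            config$covariates)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    scheme <- binning_scheme(table, n_bins)
    ids <- match_within_bins(table, discretize(table, scheme), class_col,
                             config$force_ratio,
                             seed = substream_seed(config$seed, "match", iter))
    sub <- table[table$subject_id %in% ids, , drop = FALSE]
    cls <- sub[[class_col]]
    pvals <- vapply(config$covariates, function(cv)
      mann_whitney_p(sub[[cv]][cls == lv[1]], sub[[cv]][cls == lv[2]]),
      0)
    counts <- table(factor(cls, levels = lv))
    if (all(!is.na(pvals)) && all(pvals > config$p_threshold)) {
      cert <- structure(list(status = "success", p_values = pvals,
                             counts = counts, n_bins = n_bins,
                             p_threshold = config$p_threshold,
                             class_col = class_col),
                        class = "balance_certificate")
      return(list(retained = sub$subject_id, certificate = cert))
    }
    worst <- names(pvals)[which.min(pvals)]
    if (length(worst) == 0L || all(is.na(pvals)) ||
        n_bins[[worst]] >= config$max_bins_per_covariate) {
      return(list(retained = character(0),
                  certificate = fail_cert(pvals, n_bins, counts)))
    }
    n_bins[[worst]] <- n_bins[[worst]] + 1L
  }
}

#' @export
print.balance_certificate <- function(x, ...) {
  cat("<balance_certificate>", x$status, "on", x$class_col,
      "| threshold", x$p_threshold, "\n  counts:",
      paste(names(x$counts), as.integer(x$counts), sep = "=", collapse = " "),
      "\n  bins:  ",
      paste(names(x$n_bins), x$n_bins, sep = "=", collapse = " "),
      "\n  p:     ",
      paste(names(x$p_values), signif(x$p_values, 3), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Two-factor balancing: sex then condition
#'
#' Sequential application of [balance()]: first by sex with a forced 1:1
#' ratio, then (on the retained subset) by rest/task condition with no
#' forced ratio, yielding four divisions of the data with matched
#' covariate distributions.
#'
#' @param table phenotype table with `sex` and `condition` columns.
#' @param config a [balance_config()]; its `force_ratio` applies to the
#'   sex stage, the condition stage never forces a ratio.
#' @return list with `retained`, `sex_certificate`, `condition_certificate`.
#' @export
balance_two_factor <- function(table, config) {
  s1 <- balance(table, config, class_col = "sex")
  if (s1$certificate$status != "success")
    return(list(retained = character(0), sex_certificate = s1$certificate,
                condition_certificate = NULL))
  sub <- table[table$subject_id %in% s1$retained, , drop = FALSE]
  cfg2 <- config
  cfg2$force_ratio <- NULL
  cfg2$seed <- substream_seed(config$seed, "stage2")
  s2 <- balance(sub, cfg2, class_col = "condition")
  list(retained = s2$retained, sex_certificate = s1$certificate,
       condition_certificate = s2$certificate)
}
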