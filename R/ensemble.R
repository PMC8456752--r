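# Ensemble training and vote aggregation
#
# K members are trained on independently drawn class- and
# covariate-balanced subsamples (fixed bins from the cohort-level
# balancing stage, fresh seeded draw per member), each with its own
# codec and 4:1:1 split. A subject's ensemble vote is the mean class-1
# probability over the members in whose held-out test set it appeared;
# since members never evaluate test data during training, no vote mixes
# train and test information, and no subject is counted twice in any
# AUROC.

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half (the rank-sum / Mann-Whitney
#' form).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop2("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate member votes into per-subject ensemble predictions
#'
#' @param members list of `trained_member` objects.
#' @param n_subjects cohort size.
#' @return data.frame with one row per covered subject: `subject`,
#'   `n_models` (members whose test set contained it), `vote` (mean
#'   class-1 probability), `label`.
#' @export
ensemble_votes <- function(members, n_subjects) {
  acc <- numeric(n_subjects)
  cnt <- integer(n_subjects)
  lab <- rep(NA_integer_, n_subjects)
  for (m in members) {
    acc[m$test_idx] <- acc[m$test_idx] + m$test_probs[, 2]
    cnt[m$test_idx] <- cnt[m$test_idx] + 1L
    lab[m$test_idx] <- m$test_labels
  }
  covered <- which(cnt > 0L)
  data.frame(subject = covered, n_models = cnt[covered],
             vote = acc[covered] / cnt[covered], label = lab[covered])
}

#' Train an ensemble of scrambled-CNN members
#'
#' Runs the cohort-level two-factor balancing once to fix the binning,
#' then trains `k` members, each on a fresh seeded matching draw within
#' those bins, and aggregates overlapping test-set votes.
#'
#' @param edge_array `n x E x n_bands` edge values (e.g.
#'   `wavelet_cohort$edges`).
#' @param phenotypes phenotype table aligned with `edge_array` rows
#'   (columns `subject_id`, `sex`, `condition`, covariates).
#' @param k number of members.
#' @param member_cfg a [member_config()]; each member gets a derived seed.
#' @param balance_cfg a [balance_config()] for the per-member subsample
#'   draw; `NULL` trains every member on the full cohort.
#' @param mask optional occlusion edge mask applied to every member.
#' @param seed ensemble master seed.
#' @param progress print one line per trained member.
#' @return object of class `ensemble_result`: `members`, `votes`,
#'   `member_aurocs`, `ensemble_auroc`, per-stratum ensemble AUROCs
#'   (`rest`, `task`), `coverage`, and the cumulative ensemble-size
#'   `curve` (members in training order).
#' @export
run_ensemble <- function(edge_array, phenotypes, k, member_cfg,
                         balance_cfg = NULL, mask = NULL, seed = 1L,
                         progress = FALSE) {
  stopifnot(nrow(phenotypes) == dim(edge_array)[1], k >= 1)
  labels <- as.integer(phenotypes$sex)
  members <- vector("list", k)
  for (j in seq_len(k)) {
    subjects <- seq_len(nrow(phenotypes))
    if (!is.null(balance_cfg)) {
      cfg_j <- balance_cfg
      cfg_j$seed <- substream_seed(seed, "member-draw", j)
      bal <- balance(phenotypes, cfg_j, class_col = "sex")
      if (bal$certificate$status != "success")
        stop2("member ", j, ": balanced subsample draw failed")
      subjects <- which(phenotypes$subject_id %in% bal$retained)
    }
    cfg_m <- member_cfg
    cfg_m$seed <- substream_seed(seed, "member", j)
    members[[j]] <- tryCatch(
      train_member(edge_array, labels, cfg_m, subjects = subjects,
                   mask = mask, subject_ids = phenotypes$subject_id),
      error = function(e) stop2("member ", j, " failed: ", conditionMessage(e)))
    if (progress)
      message(sprintf("member %d/%d: test AUROC %.4f (best epoch %d)",
                      j, k, members[[j]]$test_auroc, members[[j]]$best_epoch))
  }
  votes <- ensemble_votes(members, nrow(phenotypes))
  strat <- phenotypes$condition[votes$subject]
  stratum_auc <- function(keep) {
    if (length(unique(votes$label[keep])) < 2L) return(NA_real_)
    auroc(votes$vote[keep], votes$label[keep])
  }
  curve <- vapply(seq_len(k), function(j) {
    v <- ensemble_votes(members[seq_len(j)], nrow(phenotypes))
    auroc(v$vote, v$label)
  }, 0)
  structure(list(
    members = members, votes = votes,
    member_aurocs = vapply(members, `[[`, 0, "test_auroc"),
    ensemble_auroc = auroc(votes$vote, votes$label),
    rest_auroc = stratum_auc(strat == "rest"),
    task_auroc = stratum_auc(strat == "task"),
    coverage = nrow(votes) / nrow(phenotypes),
    curve = data.frame(size = seq_len(k), auroc = curve)),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result>", length(x$members), "members\n",
      sprintf(" member AUROC %.4f +/- %.4f | ensemble %.4f (rest %.4f, task %.4f)\n",
              mean(x$member_aurocs), stats::sd(x$member_aurocs),
              x$ensemble_auroc, x$rest_auroc, x$task_auroc),
      sprintf(" coverage %.3f\n", x$coverage))
  invisible(x)
}

#' Logistic-growth projection of the ensemble accuracy ceiling
#'
#' Least-squares fit of `y = a / (1 + b exp(-k x))` (k constrained
#' positive) to AUROC versus ensemble size, whose asymptote `a` estimates
#' the ceiling of vote averaging; 95% confidence bounds on `a` come from
#' the asymptotic covariance of the nonlinear fit.
#'
#' @param sizes strictly increasing ensemble sizes (>= 4 points).
#' @param aurocs AUROC at each size.
#' @return object of class `logistic_fit`: `a`, `b`, `k`, `a_lower`,
#'   `a_upper`, `converged`, and `flags` (degeneracy notes, e.g. a flat
#'   or decreasing series).
#' @export
fit_growth_curve <- function(sizes, aurocs) {
  stopifnot(length(sizes) == length(aurocs))
  if (length(sizes) < 4L) stop2("need at least 4 points to fit the curve")
  if (any(diff(sizes) <= 0)) stop2("sizes must be strictly increasing")
  flags <- character(0)
  if (stats::sd(aurocs) < 1e-12) {
    # flat series: a equals the constant level, k unidentifiable
    return(structure(list(a = aurocs[1], b = 0, k = NA_real_,
                          a_lower = aurocs[1], a_upper = aurocs[1],
                          converged = TRUE, flags = "flat series: k unidentifiable"),
                     class = "logistic_fit"))
  }
  if (stats::cor(sizes, aurocs) < 0) {
    flags <- c(flags, "decreasing series: asymptote below initial values")
    warning("AUROC series decreases with ensemble size; fit may be degenerate",
            call. = FALSE)
  }
  d <- data.frame(x = sizes, y = aurocs)
  starts <- expand.grid(b = c(0.05, 0.5, 2), k = c(2 / max(sizes), 0.2, 0.02))
  fit <- NULL
  last_err <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (1 + b * exp(-k * x)), data = d,
                        start = list(a = max(aurocs), b = starts$b[s],
                                     k = starts$k[s]),
                        lower = c(a = 1e-6, b = 1e-9, k = 1e-9),
                        upper = c(a = 1, b = Inf, k = Inf),  # AUROC ceiling
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    if (length(flags)) {
      # degenerate (e.g. decreasing) series: report the level fit
      return(structure(list(a = mean(aurocs), b = 0, k = NA_real_,
                            a_lower = NA_real_, a_upper = NA_real_,
                            converged = FALSE,
                            flags = c(flags, "level fallback fit")),
                       class = "logistic_fit"))
    }
    stop2("growth-curve fit failed to converge: ",
          conditionMessage(last_err))
  }
  co <- stats::coef(fit)
  se_a <- tryCatch(sqrt(stats::vcov(fit)["a", "a"]), error = function(e) NA_real_)
  structure(list(a = unname(co["a"]), b = unname(co["b"]), k = unname(co["k"]),
                 a_lower = unname(co["a"] - 1.96 * se_a),
                 a_upper = unname(co["a"] + 1.96 * se_a),
                 converged = TRUE, flags = flags),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> a = %.4f [%.4f, %.4f], b = %.3g, k = %.3g\n",
              x$a, x$a_lower, x$a_upper, x$b, x$k))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
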