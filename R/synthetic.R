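# Synthetic cohorts
#
# The generator emulates the structure the pipeline assumes from a large
# population-imaging cohort: class-conditional covariate distributions
# (males with larger intracranial volume; head-motion summaries that differ
# between resting-state and task acquisitions), three-band symmetric
# wavelet-correlation matrices from a low-rank latent-factor population
# model, and class effects planted on configurable node sets with separate
# effect sizes per condition and band. It exists so that every downstream
# stage (balancing, ensemble training, saliency, occlusion) is testable
# with known ground truth.

#' Default class-conditional covariate models
#'
#' Means/sds per sex x condition cell for the five balancing covariates.
#' Values are chosen once as realistic for an adult population-imaging
#' cohort: intracranial volume (mm^3) larger in males; motion summaries
#' (mean framewise displacement, DVARS, spike percentage) larger at rest
#' than during the task and slightly larger in males; age identical across
#' cells.
#'
#' @return named list; each element has `mean` and `sd`, 2 x 2 matrices
#'   with rows `female`, `male` and columns `rest`, `task`.
#' @export
default_covariate_models <- function() {
  cell <- function(fr, ft, mr, mt) {
    matrix(c(fr, mr, ft, mt), 2, 2,
           dimnames = list(c("female", "male"), c("rest", "task")))
  }
  list(
    age       = list(mean = cell(62, 62, 62, 62),       sd = cell(7.5, 7.5, 7.5, 7.5)),
    icv       = list(mean = cell(1.4e6, 1.4e6, 1.6e6, 1.6e6),
                     sd   = cell(1e5, 1e5, 1e5, 1e5)),
    mfd       = list(mean = cell(0.16, 0.12, 0.17, 0.13), sd = cell(0.05, 0.04, 0.05, 0.04)),
    dvars     = list(mean = cell(1.25, 1.10, 1.28, 1.13), sd = cell(0.20, 0.18, 0.20, 0.18)),
    spike_pct = list(mean = cell(2.5, 2.0, 2.6, 2.1),     sd = cell(1.0, 0.9, 1.0, 0.9))
  )
}

#' Planted class-effect entry
#'
#' Describes one standardized sex effect planted on the inner edges of a
#' node set, restricted to a condition and a subset of the three wavelet
#' bands. Effects are planted additively on Fisher-z transformed edge
#' weights (males shifted by +d/2, females by -d/2 standardized units) and
#' back-transformed, so generated values stay inside (-1, 1).
#'
#' @param nodes 0-based node indices; the effect lives on their inner edges.
#' @param condition `"rest"`, `"task"` or `"both"`.
#' @param d standardized effect size (Cohen's d) of the male-female edge
#'   difference.
#' @param bands bands carrying the effect (subset of 1:3).
#' @return list of class `effect_entry`.
#' @export
effect_entry <- function(nodes, condition = "both", d = 1, bands = 1:3) {
  stopifnot(is.finite(d), condition %in% c("rest", "task", "both"),
            all(bands %in% 1:3))
  structure(list(nodes = as.integer(nodes), condition = condition,
                 d = d, bands = as.integer(bands)),
            class = "effect_entry")
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of acquisitions to generate.
#' @param sex_ratio fraction of males, in (0, 1).
#' @param rest_fraction fraction of resting-state acquisitions, in (0, 1).
#' @param covariate_models per-covariate class-conditional parameters; see
#'   [default_covariate_models()].
#' @param effect_plan list of [effect_entry()] objects (possibly empty).
#' @param seed master seed; covariates, time series and connectomes are
#'   drawn from independent substreams derived from it.
#' @param n_nodes parcellation size (default 116).
#' @param n_bands number of wavelet bands (default 3).
#' @param base_model parameters of the latent-factor population connectome
#'   model: `rank` (factors per band), `loading_sd` (sd of factor
#'   loadings), `edge_noise_sd` (between-subject edge sd on the Fisher-z
#'   scale). Exposed because no public characterisation of the target
#'   population's edge-weight distribution exists; the defaults give
#'   correlation-like matrices with moderate dependence.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        sex_ratio = 0.5,
                        rest_fraction = 0.5,
                        covariate_models = default_covariate_models(),
                        effect_plan = list(),
                        seed = 1L,
                        n_nodes = 116L,
                        n_bands = 3L,
                        base_model = list(rank = 4L, loading_sd = 0.35,
                                          edge_noise_sd = 0.10)) {
  if (!is_count(n_subjects)) stop2("n_subjects must be a non-negative integer")
  if (!(sex_ratio > 0 && sex_ratio < 1)) stop2("sex_ratio must lie in (0,1)")
  if (!(rest_fraction > 0 && rest_fraction < 1))
    stop2("rest_fraction must lie in (0,1)")
  for (e in effect_plan) {
    if (!inherits(e, "effect_entry")) stop2("effect_plan entries must be effect_entry objects")
    if (any(e$nodes < 0 | e$nodes >= n_nodes))
      stop2("effect_plan node indices must lie in [0, ", n_nodes, ")")
  }
  stopifnot(is.list(covariate_models), length(covariate_models) >= 1L)
  structure(list(n_subjects = as.integer(n_subjects), sex_ratio = sex_ratio,
                 rest_fraction = rest_fraction,
                 covariate_models = covariate_models,
                 effect_plan = effect_plan, seed = as.integer(seed),
                 n_nodes = as.integer(n_nodes), n_bands = as.integer(n_bands),
                 base_model = base_model),
            class = "cohort_spec")
}

#' Generate a phenotype table
#'
#' Draws sex and condition labels at the specified fractions (counts fixed
#' by rounding, order shuffled) and the five balancing covariates from the
#' class-conditional normal models; spike percentage is truncated at zero.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `subject_id`, `sex` (0 = female,
#'   1 = male), `condition` (`"rest"`/`"task"`), and one column per
#'   covariate.
#' @export
generate_phenotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (n == 0L) {
    out <- data.frame(subject_id = character(0), sex = integer(0),
                      condition = character(0))
    for (cv in names(spec$covariate_models)) out[[cv]] <- numeric(0)
    return(out)
  }
  with_seed(substream_seed(spec$seed, "phenotypes"), {
    n_male <- round(n * spec$sex_ratio)
    sex <- sample(rep(c(1L, 0L), c(n_male, n - n_male)))
    n_rest <- round(n * spec$rest_fraction)
    condition <- sample(rep(c("rest", "task"), c(n_rest, n - n_rest)))
    out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                      sex = sex, condition = condition,
                      stringsAsFactors = FALSE)
    srow <- ifelse(sex == 1L, "male", "female")
    for (cv in names(spec$covariate_models)) {
      m <- spec$covariate_models[[cv]]
      mu <- m$mean[cbind(srow, condition)]
      sd <- m$sd[cbind(srow, condition)]
      x <- stats::rnorm(n, mu, sd)
      if (cv == "spike_pct") x <- pmax(x, 0)
      out[[cv]] <- x
    }
    out
  })
}

# per-band population structure: factor loadings L (V x r) give a base
# Fisher-z matrix z0 = L L^T (off-diagonal); each subject adds i.i.d.
# symmetric edge noise on the z scale
base_z_matrices <- function(spec) {
  with_seed(substream_seed(spec$seed, "population"), {
    lapply(seq_len(spec$n_bands), function(b) {
      L <- matrix(stats::rnorm(spec$n_nodes * spec$base_model$rank,
                               sd = spec$base_model$loading_sd),
                  spec$n_nodes, spec$base_model$rank)
      z0 <- tcrossprod(L)
      diag(z0) <- 0
      z0
    })
  })
}

effect_applies <- function(entry, condition) {
  entry$condition == "both" || entry$condition == condition
}

#' Generate per-subject wavelet connectomes
#'
#' Draws, for every row of `phenotypes`, a 3-band stack of symmetric
#' correlation matrices from the cohort's latent-factor population model,
#' with the spec's planted effects applied on the Fisher-z scale. Values
#' are stored edge-wise (see [edge_index()]); use [connectome_matrix()] to
#' recover full `n_bands x V x V` stacks.
#'
#' @param phenotypes table from [generate_phenotypes()] (or any table with
#'   `subject_id`, `sex`, `condition`).
#' @param spec the [cohort_spec()] that produced it.
#' @return object of class `wavelet_cohort`: list with `edges` (array
#'   `n_subjects x n_edges x n_bands`), `subject_id`, `n_nodes`, `bands`.
#' @export
generate_connectomes <- function(phenotypes, spec) {
  stopifnot(inherits(spec, "cohort_spec"),
            all(c("subject_id", "sex", "condition") %in% names(phenotypes)))
  n <- nrow(phenotypes)
  V <- spec$n_nodes
  E <- n_edges(V)
  z0 <- lapply(base_z_matrices(spec), matrix_to_edges)
  sdn <- spec$base_model$edge_noise_sd
  edges <- array(NA_real_, c(n, E, spec$n_bands))
  # standardized shift per (entry): males +d/2 sd, females -d/2 sd in z-space
  plan <- lapply(spec$effect_plan, function(e) {
    if (e$d == 0) return(NULL)
    list(edges = inner_edges(network_definition("planted", e$nodes,
                                                n_nodes = V)) + 1L,
         condition = e$condition, shift = e$d * sdn / 2, bands = e$bands)
  })
  plan <- Filter(Negate(is.null), plan)
  with_seed(substream_seed(spec$seed, "connectomes"), {
    for (s in seq_len(n)) {
      sgn <- if (phenotypes$sex[s] == 1L) 1 else -1
      for (b in seq_len(spec$n_bands)) {
        z <- z0[[b]] + stats::rnorm(E, sd = sdn)
        for (p in plan) {
          if (b %in% p$bands && effect_applies(p, phenotypes$condition[s]))
            z[p$edges] <- z[p$edges] + sgn * p$shift
        }
        edges[s, , b] <- tanh(z)
      }
    }
  })
  if (any(abs(edges) >= 1)) {
    edges <- pmin(pmax(edges, -1 + 1e-12), 1 - 1e-12)
    warning("planted effects drove edge weights to +/-1; values clipped",
            call. = FALSE)
  }
  structure(list(edges = edges, subject_id = phenotypes$subject_id,
                 n_nodes = V, bands = seq_len(spec$n_bands)),
            class = "wavelet_cohort")
}

#' @export
print.wavelet_cohort <- function(x, ...) {
  cat("<wavelet_cohort>", length(x$subject_id), "subjects,",
      dim(x$edges)[2], "edges x", dim(x$edges)[3], "bands\n")
  invisible(x)
}

#' Full connectivity stack for one subject
#'
#' @param cohort a `wavelet_cohort`.
#' @param subject_id one id present in the cohort.
#' @return array `n_bands x V x V`, symmetric with unit diagonal per band.
#' @export
connectome_matrix <- function(cohort, subject_id) {
  s <- match(subject_id, cohort$subject_id)
  if (is.na(s)) stop2("unknown subject_id: ", subject_id)
  V <- cohort$n_nodes
  nb <- dim(cohort$edges)[3]
  out <- array(NA_real_, c(nb, V, V))
  for (b in seq_len(nb))
    out[b, , ] <- edges_to_matrix(cohort$edges[s, , b], V, diag = 1)
  out
}

# ---- parcel time series ------------------------------------------------

# Gaussian noise band-limited to [low, high] Hz by FFT synthesis: unit
# variance, zero mean, exactly zero power outside the passband
band_limited_noise <- function(n_t, dt, low, high, n_series) {
  freqs <- (seq_len(n_t) - 1) / (n_t * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  if (!any(keep)) stop2("no FFT bins in band [", low, ", ", high, "] Hz")
  out <- matrix(0, n_t, n_series)
  for (k in seq_len(n_series)) {
    spec <- complex(real = stats::rnorm(n_t), imaginary = stats::rnorm(n_t))
    spec[!keep] <- 0
    x <- Re(stats::fft(spec, inverse = TRUE))
    out[, k] <- x / stats::sd(x)
  }
  out
}

#' Generate parcel BOLD-like time series
#'
#' Each parcel series is the sum of three band-limited Gaussian components
#' (passbands 0.01-0.03, 0.03-0.05 and 0.05-0.1 Hz) plus white measurement
#' noise. Cross-parcel correlation within each band follows `band_corr`
#' (a list of one target correlation matrix per band; identity when
#' omitted), imposed through its Cholesky factor.
#'
#' @param n_t number of samples T (>= 64 and long enough for two cycles of
#'   the slowest band).
#' @param dt sampling interval in seconds (> 0).
#' @param n_parcels number of parcels (default 116).
#' @param band_corr optional list of 3 positive-definite correlation
#'   matrices (`n_parcels` square), one per band, slowest band last to
#'   match [default_band_spec()] ordering: bands are 0.05-0.1, 0.03-0.05,
#'   0.01-0.03 Hz.
#' @param noise_sd sd of the added white noise relative to the unit-variance
#'   band components (default 0.5).
#' @param seed RNG seed.
#' @return matrix `n_t x n_parcels`.
#' @export
generate_timeseries <- function(n_t, dt, n_parcels = 116L, band_corr = NULL,
                                noise_sd = 0.5, seed = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop2("dt must be a positive number of seconds")
  if (!is_count(n_t) || n_t < 64) stop2("n_t must be an integer >= 64")
  bands <- list(c(0.05, 0.10), c(0.03, 0.05), c(0.01, 0.03))
  slowest <- bands[[3]][1]
  if (n_t * dt < 2 / slowest)
    stop2("series too short: need at least ", ceiling(2 / slowest / dt),
          " samples at dt = ", dt, " s to resolve the ", slowest, " Hz band")
  if (1 / (2 * dt) < bands[[1]][2])
    stop2("Nyquist frequency ", 1 / (2 * dt), " Hz below the fastest band")
  if (!is.null(band_corr)) stopifnot(length(band_corr) == 3L)
  with_seed(seed, {
    x <- matrix(0, n_t, n_parcels)
    for (b in 1:3) {
      w <- band_limited_noise(n_t, dt, bands[[b]][1], bands[[b]][2], n_parcels)
      if (!is.null(band_corr)) {
        cc <- band_corr[[b]]
        stopifnot(nrow(cc) == n_parcels)
        w <- w %*% chol(cc)
      }
      x <- x + w
    }
    x + matrix(stats::rnorm(n_t * n_parcels, sd = noise_sd), n_t, n_parcels)
  })
}

#' Per-band target correlation structure implied by a cohort spec
#'
#' Builds, for one subject, the band-wise cross-parcel correlation targets
#' used by [generate_timeseries()]: the latent-factor population structure
#' plus any planted effect applicable to the subject's sex/condition,
#' expressed as a positive-definite correlation matrix per band.
#'
#' @param spec a [cohort_spec()].
#' @param sex 0/1 label.
#' @param condition `"rest"` or `"task"`.
#' @return list of `n_bands` correlation matrices.
#' @export
subject_band_corr <- function(spec, sex, condition) {
  V <- spec$n_nodes
  psi <- 1.5  # idiosyncratic variance keeping correlations moderate
  z0 <- base_z_matrices(spec)
  lapply(seq_len(spec$n_bands), function(b) {
    # rebuild a PSD covariance from the population loadings
    S <- z0[[b]]
    diag(S) <- 0
    cov <- S + diag(psi, V)
    for (e in spec$effect_plan) {
      if (b %in% e$bands && effect_applies(e, condition) && e$d != 0) {
        load <- numeric(V)
        # shared component over the node set, stronger for the favoured sex
        amp <- sqrt(abs(e$d) * 0.1) * (1 + 0.5 * (if (sex == 1L) 1 else -1) *
                                         sign(e$d))
        load[e$nodes + 1L] <- amp
        cov <- cov + tcrossprod(load)
      }
    }
    stats::cov2cor(cov)
  })
}
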