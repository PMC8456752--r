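# Wavelet-band connectomes
#
# Parcel time series are decomposed with a maximal-overlap discrete
# wavelet packet transform (MODWPT, Percival-Walden pyramid with periodic
# boundary, non-decimated) and the inter-parcel Pearson correlations of
# the coefficients in three frequency bands (0.05-0.1, 0.03-0.05 and
# 0.01-0.03 Hz) form the edge weights of one symmetric 116 x 116 matrix
# per band. Packets are used rather than plain dyadic scales because the
# target Hz bands do not align with dyadic scale boundaries at typical
# sampling rates (e.g. at TR = 0.735 s a 0.04 Hz oscillation falls on the
# scale-4/5 boundary); depth-J packets of width Nyquist/2^J track the
# band edges closely, so in-band energy capture stays high.

# standard Daubechies decomposition filters (scaling g), ascending-index
# ordering; the wavelet filter follows by the QMF relation
# h_l = (-1)^l g_{L-1-l}
.modwt_filters <- list(
  haar = list(g = c(0.7071067811865476, 0.7071067811865476)),
  db2  = list(g = c(0.4829629131445341, 0.8365163037378079,
                    0.2241438680420134, -0.1294095225512604)),
  db4  = list(g = c(0.2303778133088965, 0.7148465705529157,
                    0.6308807679298589, -0.0279837694168599,
                    -0.1870348117190931, 0.0308413818355607,
                    0.0328830116668852, -0.0105974017850690)),
  db8  = list(g = c(0.0544158422431040, 0.3128715909142999,
                    0.6756307362972898, 0.5853546836542067,
                    -0.0158291052563493, -0.2840155429615469,
                    0.0004724845739133, 0.1287474266204785,
                    -0.0173693010018075, -0.0440882539307948,
                    0.0139810279173983, 0.0087460940474058,
                    -0.0048703529934516, -0.0003917403733769,
                    0.0006754494064506, -0.0001174767841248))
)

wavelet_filter <- function(name) {
  f <- .modwt_filters[[name]]
  if (is.null(f)) stop2("unsupported wavelet '", name, "'; available: ",
                        paste(names(.modwt_filters), collapse = ", "))
  g <- f$g
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1) * rev(g)
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)  # MODWT rescaling
}

# circularly shift rows of a matrix down by s (periodic extension):
# out[t, ] = m[(t - s - 1) mod n + 1, ]
.circshift_rows <- function(m, s) {
  n <- nrow(m)
  idx <- ((seq_len(n) - 1 - s) %% n) + 1L
  m[idx, , drop = FALSE]
}

# one MODWT/MODWPT filtering step at level j: y[t] = sum_l f_l x[t - l*2^(j-1)]
.modwt_step <- function(x, filt, level) {
  step <- 2^(level - 1)
  acc <- matrix(0, nrow(x), ncol(x))
  for (l in seq_along(filt) - 1L)
    acc <- acc + filt[l + 1L] * .circshift_rows(x, l * step)
  acc
}

#' Maximal-overlap discrete wavelet transform
#'
#' Pyramid MODWT of one or more series with periodic boundary handling.
#' All levels retain the input length (no decimation); total energy is
#' preserved exactly across levels.
#'
#' @param x numeric vector or `T x P` matrix (columns are series).
#' @param n_levels decomposition depth J.
#' @param wavelet filter name: `"haar"`, `"db2"`, `"db4"` or `"db8"`.
#' @return list with `W` (list of J `T x P` wavelet-coefficient matrices)
#'   and `V` (level-J scaling coefficients, `T x P`).
#' @export
modwt <- function(x, n_levels, wavelet = "db4") {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  stopifnot(is.matrix(x), all(is.finite(x)), is_count(n_levels), n_levels >= 1)
  if (nrow(x) < 2^n_levels)
    stop2("series length ", nrow(x), " too short for MODWT level ", n_levels,
          " (need >= ", 2^n_levels, ")")
  f <- wavelet_filter(wavelet)
  V <- x
  W <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    W[[j]] <- .modwt_step(V, f$h, j)
    V <- .modwt_step(V, f$g, j)
  }
  list(W = W, V = V)
}

# natural -> frequency (sequency) packet ordering at depth J:
# returns a vector o with o[k] = natural index (0-based) of the k-th
# lowest-frequency packet (Gray-code permutation)
.packet_freq_order <- function(depth) {
  ord <- 0L
  for (l in seq_len(depth)) {
    nxt <- integer(2 * length(ord))
    for (k in seq_along(ord)) {
      ch <- if (k %% 2 == 1L) c(2L * ord[k], 2L * ord[k] + 1L)
            else c(2L * ord[k] + 1L, 2L * ord[k])
      nxt[(2 * k - 1):(2 * k)] <- ch
    }
    ord <- nxt
  }
  ord
}

# compute the depth-J MODWPT coefficient matrices for the requested
# natural-order leaves only (pruned pyramid)
.modwpt_leaves <- function(x, depth, wavelet, leaves_nat) {
  f <- wavelet_filter(wavelet)
  cur <- list("0" = x)
  for (l in seq_len(depth)) {
    need <- sort(unique(leaves_nat %/% (2L^(depth - l))))
    nxt <- vector("list", length(need))
    names(nxt) <- as.character(need)
    for (n in need) {
      par <- cur[[as.character(n %/% 2L)]]
      filt <- if (n %% 2L == 1L) f$h else f$g
      nxt[[as.character(n)]] <- .modwt_step(par, filt, l)
    }
    cur <- nxt
  }
  cur
}

#' Nominal passband of a MODWT scale
#'
#' Scale j covers `[1/(2^(j+1) dt), 1/(2^j dt)]` Hz at sampling interval
#' `dt`; depth-J packets subdivide `[0, Nyquist]` into `2^J` equal spans.
#'
#' @param j scale (level) index, >= 1.
#' @param dt sampling interval in seconds.
#' @return numeric length-2 vector `(low, high)` in Hz.
#' @export
scale_passband <- function(j, dt) {
  c(1 / (2^(j + 1) * dt), 1 / (2^j * dt))
}

#' Band specification for wavelet connectomes
#'
#' Resolves the target Hz bands into wavelet packet selections: the depth
#' J is the smallest for which the packet width `Nyquist/2^J` is at most
#' about half the narrowest target band, and each band receives every
#' depth-J packet whose nominal span overlaps it by at least half the
#' packet width (or the single best-overlapping packet if none does).
#'
#' @param bands ordered list of `(low, high)` Hz pairs; the default is the
#'   three-band scheme 0.05-0.1, 0.03-0.05, 0.01-0.03 Hz.
#' @param sampling_interval sampling interval (TR) in seconds.
#' @param wavelet wavelet family (default `"db4"`, the 8-tap Daubechies
#'   filter).
#' @return object of class `band_spec` with fields `bands`,
#'   `sampling_interval`, `wavelet`, `depth` and `packets` (per band, the
#'   0-based frequency-ordered packet indices at that depth).
#' @export
band_spec <- function(bands = list(c(0.05, 0.10), c(0.03, 0.05), c(0.01, 0.03)),
                      sampling_interval = 0.735,
                      wavelet = "db4") {
  dt <- sampling_interval
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  nyq <- 1 / (2 * dt)
  for (b in bands) {
    if (!(b[1] > 0 && b[1] < b[2])) stop2("each band needs 0 < low < high")
    if (b[2] > nyq)
      stop2("band [", b[1], ", ", b[2], "] Hz exceeds the Nyquist frequency ",
            signif(nyq, 4), " Hz at dt = ", dt, " s")
  }
  ord <- order(vapply(bands, `[`, 0, 1))
  for (k in seq_along(ord)[-1])
    if (bands[[ord[k]]][1] < bands[[ord[k - 1]]][2])
      stop2("bands must not overlap")
  wavelet_filter(wavelet)  # validate name early
  min_width <- min(vapply(bands, function(b) b[2] - b[1], 0))
  depth <- max(2L, ceiling(log2(nyq / (0.55 * min_width))))
  width <- nyq / 2^depth
  packets <- lapply(seq_along(bands), function(k) {
    b <- bands[[k]]
    plo <- (0:(2^depth - 1)) * width
    phi <- plo + width
    ov <- pmax(0, pmin(phi, b[2]) - pmax(plo, b[1]))
    sel <- which(ov / width >= 0.5) - 1L
    if (length(sel)) return(sel)
    if (max(ov) <= 0)
      stop2("band ", k, " [", b[1], ", ", b[2],
            "] Hz matches no wavelet packet at dt = ", dt, " s")
    which.max(ov) - 1L
  })
  structure(list(bands = bands, sampling_interval = dt, wavelet = wavelet,
                 depth = depth, packets = packets), class = "band_spec")
}

#' Default three-band specification
#' @param sampling_interval TR in seconds.
#' @param wavelet wavelet family.
#' @return a [band_spec()].
#' @export
default_band_spec <- function(sampling_interval = 0.735, wavelet = "db4") {
  band_spec(sampling_interval = sampling_interval, wavelet = wavelet)
}

#' @export
print.band_spec <- function(x, ...) {
  width <- 1 / (2 * x$sampling_interval) / 2^x$depth
  cat("<band_spec> dt =", x$sampling_interval, "s, wavelet =", x$wavelet,
      ", packet depth", x$depth, "\n")
  for (k in seq_along(x$bands))
    cat(sprintf("  band %d: %.3f-%.3f Hz -> packets [%s] (%.4f-%.4f Hz)\n", k,
                x$bands[[k]][1], x$bands[[k]][2],
                paste(x$packets[[k]], collapse = ","),
                min(x$packets[[k]]) * width, (max(x$packets[[k]]) + 1) * width))
  invisible(x)
}

#' Decompose parcel time series into wavelet frequency bands
#'
#' Applies the pruned MODWPT per parcel and assembles, for each target
#' band, the coefficient series of its assigned packets (concatenated in
#' time when a band spans several packets; each packet series keeps the
#' input length T). The first `(2^J - 1)(L - 1) + 1` coefficients of each
#' packet are affected by the periodic boundary; they are retained and
#' their total count per band is reported in the `n_boundary` attribute.
#'
#' @param series `T x P` matrix of parcel time series (no missing values).
#' @param spec a [band_spec()].
#' @return list of class `band_coefficients`: one `T_b x P` matrix per
#'   band, with `spec` attached as attribute `band_spec`.
#' @export
decompose_bands <- function(series, spec) {
  stopifnot(inherits(spec, "band_spec"), is.matrix(series))
  if (anyNA(series) || !all(is.finite(series)))
    stop2("time series contain missing or non-finite values")
  n <- nrow(series)
  if (n < 2^spec$depth) {
    narrowest <- which.min(vapply(spec$bands, function(b) b[2] - b[1], 0))
    stop2("band ", narrowest, " [", spec$bands[[narrowest]][1], ", ",
          spec$bands[[narrowest]][2], "] Hz requires packet depth ",
          spec$depth, ", unresolvable with T = ", n,
          " samples (need >= ", 2^spec$depth, ")")
  }
  freq2nat <- .packet_freq_order(spec$depth)
  leaves_nat <- sort(unique(unlist(lapply(spec$packets, function(p)
    freq2nat[p + 1L]))))
  leaves <- .modwpt_leaves(series, spec$depth, spec$wavelet, leaves_nat)
  L <- wavelet_filter(spec$wavelet)$L
  out <- lapply(spec$packets, function(p) {
    do.call(rbind, lapply(freq2nat[p + 1L], function(nat)
      leaves[[as.character(nat)]]))
  })
  attr(out, "band_spec") <- spec
  attr(out, "n_boundary") <- vapply(spec$packets, function(p)
    length(p) * min((2^spec$depth - 1) * (L - 1) + 1, n), 0)
  class(out) <- "band_coefficients"
  out
}

#' Band-wise inter-parcel correlation matrices
#'
#' Pearson correlation of the wavelet coefficient series between all
#' parcel pairs, per band: the edge weights of the wavelet connectome.
#'
#' @param coefficients a `band_coefficients` object from
#'   [decompose_bands()].
#' @param subject_id optional id carried on the result.
#' @return object of class `wavelet_connectome`: list with `subject_id`,
#'   `matrix` (array `n_bands x P x P`, symmetric, unit diagonal) and
#'   `band_spec`.
#' @export
band_correlation <- function(coefficients, subject_id = "") {
  stopifnot(inherits(coefficients, "band_coefficients"))
  nb <- length(coefficients)
  P <- ncol(coefficients[[1]])
  out <- array(NA_real_, c(nb, P, P))
  for (b in seq_len(nb)) {
    w <- coefficients[[b]]
    v <- apply(w, 2, stats::var)
    if (any(v <= 0 | !is.finite(v)))
      stop2("zero-variance wavelet coefficients for parcel(s) ",
            paste(which(v <= 0 | !is.finite(v)), collapse = ", "),
            " in band ", b)
    cc <- stats::cor(w)
    cc <- (cc + t(cc)) / 2
    diag(cc) <- 1
    out[b, , ] <- cc
  }
  structure(list(subject_id = subject_id, matrix = out,
                 band_spec = attr(coefficients, "band_spec")),
            class = "wavelet_connectome")
}

#' @export
print.wavelet_connectome <- function(x, ...) {
  d <- dim(x$matrix)
  cat("<wavelet_connectome>", x$subject_id, ":", d[1], "bands x", d[2], "x",
      d[3], "\n")
  invisible(x)
}

#' Time series to wavelet connectome in one step
#'
#' @param series `T x P` matrix.
#' @param spec a [band_spec()].
#' @param subject_id optional id.
#' @return a `wavelet_connectome` (see [band_correlation()]).
#' @export
timeseries_to_connectome <- function(series, spec = default_band_spec(),
                                     subject_id = "") {
  band_correlation(decompose_bands(series, spec), subject_id = subject_id)
}
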