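#' Daubechies analysis filters
#'
#' Decomposition low/high-pass filter pairs for the orthogonal Daubechies
#' family, in the convention used by the periodized wavelet-packet
#' transform of this package (coefficients listed h\[0\]..h\[L-1\]).
#'
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"`, `"db8"`, `"db16"`,
#'   `"db20"`. Higher orders have sharper band edges (less cross-band
#'   leakage at deep packet levels) at the cost of longer filters.
#' @return A list with numeric vectors `lo` and `hi`.
#' @keywords internal
wt_filters <- function(wavelet = c("db4", "db2", "haar", "db8", "db16", "db20")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079, 0.48296291314453416),
    db4 = c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.23037781330889648),
    db8 = c(-0.00011747678412476953, 0.00067544940645056933, -0.00039174037337694705,
            -0.0048703529934515741, 0.0087460940474057766, 0.013981027917398282,
            -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
            0.00047248457391328279, -0.28401554296154691, -0.015829105256349306,
            0.58535468365420673, 0.67563073629728976, 0.31287159091429995,
            0.054415842243104008),
    db16 = c(-2.1093396301007431e-08, 2.3087840868575457e-07, -7.3636567854512051e-07,
             -1.0435713423116066e-06, 1.1336608661276258e-05, -1.3945668988208893e-05,
             -6.103596621410936e-05, 0.00017478724522533817, 0.00011424152003872239,
             -0.00094102174935956756, 0.00040789698084971285, 0.003128023381206269,
             -0.0036442796214983899, -0.0069900145634139163, 0.013993768859828731,
             0.01029765964095597, -0.036888397691730142, -0.0075889743688577378,
             0.075924236044276311, -0.006239722752474872, -0.1323883055638104,
             0.027340263752716042, 0.2111906939471043, -0.027918208133028276,
             -0.32706331052791771, -0.089751089402489645, 0.44029025688635692,
             0.63735633208378895, 0.4303127228460038, 0.16506428348885313,
             0.034907714323673344, 0.0031892209253477381),
    db20 = c(-2.9988364896193194e-10, 4.0561270555518328e-09, -1.814843248299696e-08,
             2.0143220235505126e-10, 2.6339242262700013e-07, -6.8470795970005574e-07,
             -1.0119940100188862e-06, 7.2412482876736205e-06, -4.3761438621839971e-06,
             -3.7105861833947128e-05, 6.7742808283777301e-05, 0.00010153288973670291,
             -0.00038510474869921763, -5.3497598439976948e-05, 0.0013925596193231364,
             -0.00083156217282255693, -0.0035814942596096226, 0.0044205423870457908,
             0.006721627302259457, -0.01381052613715192, -0.0087893249239015606,
             0.03229429953076958, 0.0058746818118118266, -0.061722899624680458,
             0.0056322468573074356, 0.10229171917444256, -0.024716827338613585,
             -0.15545875070726795, 0.039850246457771202, 0.22829105081991632,
             -0.016727088309077008, -0.32678680043403496, -0.13921208801148388,
             0.36150229873933104, 0.61049323893859386, 0.47269618531090168,
             0.21994211355139703, 0.063423780459081522, 0.010549394624950399,
             0.00077995361366684629)
  )
  L <- length(lo)
  # quadrature mirror: g[k] = (-1)^(k+1) h[L-1-k] (pywt sign convention)
  hi <- rev(lo) * (-1)^seq_len(L)
  list(lo = lo, hi = hi)
}

# One analysis step of the periodized transform on the columns of X.
# X: n x m (n even). Returns (n/2) x m. Circular convolution then dyadic
# downsampling, matching the 'periodization' boundary mode:
#   y[k] = sum_j f[j] * x[(2k + L/2 - j) mod n]   (0-based)
.wpt_step <- function(X, filt) {
  n <- nrow(X)
  L <- length(filt)
  half <- n / 2L
  out <- matrix(0, half, ncol(X))
  base <- 2L * (seq_len(half) - 1L) + L / 2L
  for (j in seq_len(L)) {
    idx <- (base - (j - 1L)) %% n + 1L
    out <- out + filt[j] * X[idx, , drop = FALSE]
  }
  out
}

#' Periodized wavelet-packet decomposition (frequency-ordered)
#'
#' Decomposes each column of `x` down to `level`, returning the terminal
#' packet coefficients with nodes sorted by their passband centre
#' frequency (sequency order), so node `i` of `2^level` covers
#' approximately `[(i-1), i] * fs / 2^(level+1)` Hz.
#'
#' The transform is orthonormal on dyadic lengths: total energy of the
#' coefficients equals the energy of the input exactly.
#'
#' @param x Numeric vector or matrix (columns are independent signals).
#'   Length (rows) must be a power of two; use [wpt_band_energy()] for
#'   automatic zero-padding.
#' @param level Decomposition depth; `2^level` terminal nodes.
#' @param wavelet Mother wavelet, see [wt_filters()].
#' @return A 3-d array `[node, coefficient, signal]` with
#'   `2^level` frequency-ordered nodes.
#' @export
wpt_decompose <- function(x, level, wavelet = "db4") {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2 || bitwAnd(n, n - 1L) != 0)
    stop("signal length must be a power of two; got ", n)
  if (level < 1 || 2^level > n)
    stop("decomposition level ", level, " too deep for signal length ", n)
  filt <- wt_filters(wavelet)
  # recursion carrying the frequency-orientation flag: a high-pass split
  # mirrors the band, so the flipped child lists its high-pass branch first
  rec <- function(X, lev, flip) {
    if (lev == 0L) return(list(X))
    A <- .wpt_step(X, filt$lo)
    D <- .wpt_step(X, filt$hi)
    lo_part <- rec(A, lev - 1L, flip)
    hi_part <- rec(D, lev - 1L, !flip)
    if (flip) c(hi_part, lo_part) else c(lo_part, hi_part)
  }
  nodes <- rec(x, as.integer(level), FALSE)
  ncoef <- n / 2^level
  out <- array(0, dim = c(2^level, ncoef, ncol(x)))
  for (i in seq_along(nodes)) out[i, , ] <- nodes[[i]]
  out
}

# next power of two >= n
.next_pow2 <- function(n) 2^ceiling(log2(n))

#' Band energies from the wavelet-packet transform
#'
#' Sums squared terminal-node coefficients over the nodes whose centre
#' frequency falls inside each requested band. Signals are zero-padded to
#' the next power of two (padding adds no energy); the effective level is
#' `min(maxlevel, log2(padded length))`, giving a node bandwidth of
#' `fs / 2^(level+1)` Hz (0.39 Hz for 1 s at 200 Hz, level 8).
#'
#' @param x Numeric vector or matrix (columns are independent signals).
#' @param fs Sampling rate in Hz.
#' @param bands Named list of `c(lo, hi)` frequency bands in Hz, e.g.
#'   `list(theta = c(4, 8), beta = c(13, 30))`. Bands are half-open
#'   `[lo, hi)` on node centres.
#' @param wavelet,maxlevel Wavelet-packet parameters (defaults `"db4"`,
#'   level 8).
#' @return A matrix `bands x signals` of band energies (sum of squared
#'   coefficients).
#' @export
wpt_band_energy <- function(x, fs, bands, wavelet = "db4", maxlevel = 8) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(fs > 0, length(bands) >= 1)
  spec <- wpt_node_power(x, fs, wavelet = wavelet, maxlevel = maxlevel)
  out <- matrix(0, length(bands), ncol(x),
                dimnames = list(names(bands), colnames(x)))
  for (b in seq_along(bands)) {
    rng <- bands[[b]]
    if (rng[1] >= rng[2]) stop("band must satisfy lo < hi")
    if (rng[1] >= fs / 2) stop("band outside Nyquist range")
    sel <- spec$freq >= rng[1] & spec$freq < rng[2]
    out[b, ] <- colSums(spec$power[sel, , drop = FALSE])
  }
  out
}

#' Wavelet-packet node power spectrum
#'
#' Energy per frequency-ordered terminal node, with node centre
#' frequencies. The workhorse behind [wpt_band_energy()] and
#' [trial_spectrogram()].
#'
#' @inheritParams wpt_band_energy
#' @return List with `freq` (node centres, Hz) and `power`
#'   (nodes x signals energy matrix).
#' @export
wpt_node_power <- function(x, fs, wavelet = "db4", maxlevel = 8) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2) stop("signal too short for wavelet-packet analysis")
  npad <- .next_pow2(n)
  if (npad > n) x <- rbind(x, matrix(0, npad - n, ncol(x)))
  level <- min(as.integer(maxlevel), as.integer(log2(npad)))
  coefs <- wpt_decompose(x, level, wavelet)
  nnode <- dim(coefs)[1]
  # energy per node: sum of squared packet coefficients
  pw <- apply(coefs^2, c(1, 3), sum)
  if (is.null(dim(pw))) pw <- matrix(pw, nrow = nnode)
  width <- fs / 2 / nnode
  list(freq = (seq_len(nnode) - 0.5) * width, power = pw, width = width,
       level = level)
}
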