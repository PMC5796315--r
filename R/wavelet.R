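# Periodized orthogonal discrete wavelet transform.
#
# No wavelet package ships with the dependency set used here, so the
# multilevel DWT/IDWT is implemented directly. The transform is the
# classical periodized pyramid: one analysis step maps x (even length N) to
#   a[k] = sum_l g[l] x[(2k+1-l) mod N],   d[k] = sum_l h[l] x[(2k+1-l) mod N]
# for k = 0..N/2-1, with orthonormal scaling/wavelet filters (g, h); the
# synthesis step is the adjoint, which for an orthonormal filter pair is the
# exact inverse. Odd lengths are handled by repeating the final sample
# before a step and dropping it on inversion, so reconstruction is exact for
# every input length.

# Daubechies-6 (12-tap) orthonormal scaling filter; the wavelet filter is
# its quadrature mirror. Standard published coefficients.
DB6_LO <- c(
  -0.00107730108530848, 0.00477725751094551, 0.000553842201161496,
  -0.0315820393174860, 0.0275228655303057, 0.0975016055873230,
  -0.129766867567262, -0.226264693965440, 0.315250351709198,
  0.751133908021095, 0.494623890398453, 0.111540743350109)

DB6_HI <- rev(DB6_LO) * rep_len(c(-1, 1), length(DB6_LO))

waveletFilters <- function(name = "db6") {
  name <- tolower(gsub("[^a-z0-9]", "", name))
  if (!name %in% c("db6", "db06", "daubechies6"))
    stop("unsupported wavelet '", name, "' (available: db06)")
  list(lo = DB6_LO, hi = DB6_HI)
}

# One periodized analysis step. x must have even length.
dwtStep <- function(x, filt) {
  n <- length(x)
  half <- n / 2L
  k <- seq_len(half) - 1L
  a <- numeric(half)
  d <- numeric(half)
  L <- length(filt$lo)
  for (l in seq_len(L) - 1L) {
    idx <- ((2L * k + 1L - l) %% n) + 1L
    xv <- x[idx]
    a <- a + filt$lo[l + 1L] * xv
    d <- d + filt$hi[l + 1L] * xv
  }
  list(a = a, d = d)
}

# One periodized synthesis step (adjoint of dwtStep); returns even length 2m.
idwtStep <- function(a, d, filt) {
  m <- length(a)
  n <- 2L * m
  k <- seq_len(m) - 1L
  x <- numeric(n)
  L <- length(filt$lo)
  for (l in seq_len(L) - 1L) {
    idx <- ((2L * k + 1L - l) %% n) + 1L
    x[idx] <- x[idx] + filt$lo[l + 1L] * a + filt$hi[l + 1L] * d
  }
  x
}

#' Multilevel periodized discrete wavelet transform
#'
#' Decomposes a signal into `level` detail bands plus a final approximation
#' using an orthonormal Daubechies-6 filter pair with periodic boundary
#' handling. [idwt()] inverts the decomposition exactly.
#'
#' @param x numeric signal.
#' @param level number of decomposition levels (>= 1).
#' @param wavelet wavelet name; only `"db06"` (Daubechies-6) is provided.
#' @return A list with elements `approx` (final approximation coefficients),
#'   `details` (list of detail coefficient vectors, level 1 first),
#'   `lengths` (original length entering each step, needed for inversion),
#'   `wavelet` and `level`.
#' @seealso [idwt()], [waveletDetrend()], [waveletDenoise()]
#' @export
dwt <- function(x, level, wavelet = "db06") {
  x <- as.numeric(x)
  level <- as.integer(level)
  if (level < 1L) stop("'level' must be >= 1")
  filt <- waveletFilters(wavelet)
  if (length(x) < 2^level)
    stop("signal of length ", length(x),
         " is too short for ", level, " decomposition levels")
  details <- vector("list", level)
  lengths <- integer(level)
  cur <- x
  for (j in seq_len(level)) {
    lengths[j] <- length(cur)
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    st <- dwtStep(cur, filt)
    details[[j]] <- st$d
    cur <- st$a
  }
  list(approx = cur, details = details, lengths = lengths,
       wavelet = wavelet, level = level)
}

#' Inverse multilevel periodized discrete wavelet transform
#'
#' @param dec a decomposition as returned by [dwt()] (its `approx` or
#'   `details` may have been modified, e.g. zeroed or thresholded).
#' @return The reconstructed numeric signal, with the original length.
#' @export
idwt <- function(dec) {
  filt <- waveletFilters(dec$wavelet)
  cur <- dec$approx
  for (j in rev(seq_len(dec$level))) {
    cur <- idwtStep(cur, dec$details[[j]], filt)
    cur <- cur[seq_len(dec$lengths[j])]
  }
  cur
}

# Deepest level at which the periodized pyramid still has more samples than
# filter taps (the usual max-level rule for a 12-tap filter).
maxDwtLevel <- function(n, taps = length(DB6_LO)) {
  max(1L, floor(log2(n / (taps - 1))))
}
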