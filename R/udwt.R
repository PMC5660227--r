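# Undecimated (stationary, shift-invariant) discrete wavelet transform,
# implemented as an a-trous filter bank in the Fourier domain.
#
# For an orthonormal quadrature-mirror pair (h, g) the frequency responses
# satisfy |H(w)|^2 + |G(w)|^2 = 2 at every w, so the synthesis rule
#   A_{j-1} = (conj(H_j) A_j + conj(G_j) D_j) / 2
# reconstructs perfectly (exactly, in exact arithmetic) under circular
# boundary handling. Signals whose length is a large prime would make the
# FFT quadratic, so inputs are reflection-padded to the next 2-3-5-smooth
# length and truncated after reconstruction.

# Daubechies extremal-phase 8-tap scaling filter, normalized to sum sqrt(2)
daub8_h <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
             -0.027983769416984, -0.187034811718881, 0.030841381835987,
             0.032883011666983, -0.010597401784997)

wavelet_filters <- function(wavelet_name = "d8") {
  h <- switch(wavelet_name,
              d8 = , db4 = , daub8 = daub8_h,
              haar = , d2 = c(1, 1) / sqrt(2),
              stop("unknown wavelet '", wavelet_name,
                   "'; available: d8, haar", call. = FALSE))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)  # quadrature mirror
  list(h = h, g = g)
}

# FFTs of the level-j upsampled filters (taps spaced 2^(j-1) apart), cached
# per (n, levels, wavelet) since the pipeline reuses one grid many times.
.udwt_cache <- new.env(parent = emptyenv())

udwt_filter_ffts <- function(n, levels, wavelet_name) {
  key <- paste(n, levels, wavelet_name, sep = "|")
  if (!is.null(.udwt_cache[[key]])) return(.udwt_cache[[key]])
  flt <- wavelet_filters(wavelet_name)
  L <- length(flt$h)
  out <- vector("list", levels)
  for (j in seq_len(levels)) {
    spread <- 2L^(j - 1L)
    if (spread * (L - 1L) + 1L > n)
      stop("spectrum too short for ", levels, " decomposition levels",
           call. = FALSE)
    hj <- gj <- numeric(n)
    pos <- 1L + (seq_len(L) - 1L) * spread
    hj[pos] <- flt$h
    gj[pos] <- flt$g
    out[[j]] <- list(H = stats::fft(hj), G = stats::fft(gj))
  }
  .udwt_cache[[key]] <- out
  out
}

# Forward transform: returns detail coefficients per level (time domain)
# and the coarsest approximation, all of length n.
udwt_forward <- function(x, levels, wavelet_name = "d8") {
  n <- length(x)
  filts <- udwt_filter_ffts(n, levels, wavelet_name)
  A <- stats::fft(x)
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    D <- A * filts[[j]]$G
    details[[j]] <- Re(stats::fft(D, inverse = TRUE)) / n
    A <- A * filts[[j]]$H
  }
  list(details = details,
       approx = Re(stats::fft(A, inverse = TRUE)) / n,
       levels = levels, wavelet = wavelet_name)
}

udwt_inverse <- function(w) {
  n <- length(w$approx)
  filts <- udwt_filter_ffts(n, w$levels, w$wavelet)
  A <- stats::fft(w$approx)
  for (j in rev(seq_len(w$levels))) {
    D <- stats::fft(w$details[[j]])
    A <- (A * Conj(filts[[j]]$H) + D * Conj(filts[[j]]$G)) / 2
  }
  Re(stats::fft(A, inverse = TRUE)) / n
}

# Reflection-pad x at the end to the next 2-3-5-smooth length >= n + pad_min
reflect_pad <- function(x, pad_min = 0L) {
  n <- length(x)
  target <- stats::nextn(n + pad_min, c(2, 3, 5))
  extra <- target - n
  if (extra == 0L) return(x)
  refl <- rev(x)
  pad <- rep_len(c(refl, x), extra)  # alternating reflections, seamless
  c(x, pad)
}

soft_threshold <- function(d, lambda) sign(d) * pmax(abs(d) - lambda, 0)
hard_threshold <- function(d, lambda) d * (abs(d) > lambda)
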