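# Empirical mode decomposition with cubic-spline envelopes and mirrored
# boundary extrema. Written for the cleaning use case here: modest numbers
# of IMFs, Cauchy-type sifting stop, exact reconstruction by construction
# (each IMF is subtracted from the running residual, so the sum identity
# holds to floating-point).

# indices of strict local maxima/minima, with plateaus collapsed to their
# midpoint
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  # collapse exact plateaus by nudging with position (stable, tiny)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  s_comp <- s[nz]
  turns <- which(diff(s_comp) != 0)
  pos <- integer(0); kind <- integer(0)
  for (t in turns) {
    i <- nz[t]; j <- nz[t + 1]      # d changes sign between i and j
    p <- as.integer(ceiling((i + 1 + j) / 2))  # midpoint of plateau
    pos <- c(pos, p)
    kind <- c(kind, if (s_comp[t] > 0) 1L else -1L)
  }
  list(max = pos[kind == 1L], min = pos[kind == -1L])
}

# spline envelope through extrema, with the two outermost extrema mirrored
# beyond each end to tame boundary swings
envelope <- function(pos, val, n) {
  k <- length(pos)
  lp <- 2 - rev(pos[seq_len(min(2, k))]);  lv <- rev(val[seq_len(min(2, k))])
  rp <- 2 * n - rev(pos)[seq_len(min(2, k))]; rv <- rev(val)[seq_len(min(2, k))]
  ord <- order(c(lp, pos, rp))
  xs <- c(lp, pos, rp)[ord]; ys <- c(lv, val, rv)[ord]
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition of a 1-D signal
#'
#' Decomposes a signal into intrinsic mode functions (IMFs, highest
#' frequency first) plus a residual trend by iterative sifting: at each
#' step the mean of the upper and lower cubic-spline extrema envelopes is
#' subtracted until a Cauchy-type criterion is met. Sifting of a component
#' stops when the relative squared change drops below `tol` or after
#' `max_sift` iterations; decomposition stops when the residual has fewer
#' than two maxima or two minima, or after `max_imf` IMFs.
#'
#' The components reconstruct the input exactly:
#' `rowSums(cbind(imfs)) + residual == x` to floating-point precision.
#'
#' @param x Numeric vector (finite, length >= 8 for a meaningful result).
#' @param max_imf Maximum number of IMFs.
#' @param max_sift Maximum sifting iterations per IMF.
#' @param tol Cauchy stop tolerance on the relative squared change.
#' @return List with `imfs` (matrix, one row per IMF; zero rows if the
#'   input has no oscillation) and `residual`.
#' @examples
#' t <- seq(0, 1, by = 1 / 250)
#' x <- sin(2 * pi * 30 * t) + sin(2 * pi * 2 * t)
#' dec <- emd_decompose(x)
#' nrow(dec$imfs)
#' @export
emd_decompose <- function(x, max_imf = 10, max_sift = 10, tol = 0.05) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  imfs <- list()
  resid <- x
  while (length(imfs) < max_imf) {
    ext <- local_extrema(resid)
    if (length(ext$max) < 2 || length(ext$min) < 2) break
    h <- resid
    for (it in seq_len(max_sift)) {
      e <- local_extrema(h)
      if (length(e$max) < 2 || length(e$min) < 2) break
      upper <- envelope(e$max, h[e$max], n)
      lower <- envelope(e$min, h[e$min], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (crit < tol) break
    }
    imfs[[length(imfs) + 1L]] <- h
    resid <- resid - h
  }
  list(imfs = if (length(imfs)) do.call(rbind, imfs) else
         matrix(numeric(0), nrow = 0, ncol = n),
       residual = resid)
}

#' Amplitude-thresholded EMD cleaning of an epoch
#'
#' Decomposes each channel of an epoch into IMFs plus residual, discards
#' every component whose maximum absolute amplitude exceeds the threshold
#' (borderline components equal to the threshold are kept; the residual
#' trend is subject to the same rule), and reconstructs the channel from the
#' surviving components. Large slow transients such as eye blinks
#' concentrate in high-amplitude low-frequency components and are removed,
#' while sub-threshold brain activity passes through.
#'
#' @param epoch Channels x samples numeric matrix (microvolts).
#' @param threshold_uv Rejection threshold in microvolts.
#' @return Matrix of the same shape as `epoch`.
#' @export
emd_clean <- function(epoch, threshold_uv = 100) {
  stopifnot(is.matrix(epoch), all(is.finite(epoch)))
  out <- epoch
  for (ch in seq_len(nrow(epoch))) {
    x <- epoch[ch, ]
    if (length(x) == 0) next
    dec <- emd_decompose(x)
    comps <- rbind(dec$imfs, dec$residual)
    keep <- apply(abs(comps), 1, max) <= threshold_uv
    out[ch, ] <- if (any(keep)) colSums(comps[keep, , drop = FALSE]) else 0
  }
  out
}
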