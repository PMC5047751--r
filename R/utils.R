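# Internal helpers shared across modules: angle wrapping, interval algebra,
# Gaussian kernel smoothing, and seed derivation for per-component RNG streams.

#' Wrap angles into [-180, 180)
#' @param x angles in degrees.
#' @return wrapped angles in degrees.
#' @keywords internal
wrap_deg <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Unwrap a head-direction trace
#'
#' Removes 360-degree jumps so that cumulative rotation is continuous.
#' @param hd_deg head direction samples in degrees.
#' @return unwrapped trace in degrees.
#' @keywords internal
unwrap_deg <- function(hd_deg) {
  d <- diff(hd_deg)
  d <- d - 360 * round(d / 360)
  c(hd_deg[1], hd_deg[1] + cumsum(d))
}

# intervals are data.frames with columns start_s, end_s; half-open [start, end)
empty_intervals <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0))
}

interval_duration <- function(iv) {
  if (nrow(iv) == 0) return(0)
  sum(iv$end_s - iv$start_s)
}

#' Test membership of time points in a set of half-open intervals
#' @keywords internal
in_intervals <- function(t, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) {
    out <- out | (t >= iv$start_s[i] & t < iv$end_s[i])
  }
  out
}

# set difference a \ b on half-open intervals; both data.frames(start_s, end_s)
subtract_intervals <- function(a, b) {
  if (is.null(a) || nrow(a) == 0) return(empty_intervals())
  if (is.null(b) || nrow(b) == 0) return(a[, c("start_s", "end_s")])
  res <- list()
  b <- b[order(b$start_s), , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    segs <- data.frame(start_s = a$start_s[i], end_s = a$end_s[i])
    for (j in seq_len(nrow(b))) {
      keep <- list()
      for (k in seq_len(nrow(segs))) {
        s <- segs$start_s[k]; e <- segs$end_s[k]
        bs <- max(s, b$start_s[j]); be <- min(e, b$end_s[j])
        if (bs >= be) {          # no overlap
          keep[[length(keep) + 1]] <- c(s, e)
        } else {
          if (s < bs) keep[[length(keep) + 1]] <- c(s, bs)
          if (be < e) keep[[length(keep) + 1]] <- c(be, e)
        }
      }
      segs <- if (length(keep)) {
        m <- do.call(rbind, keep)
        data.frame(start_s = m[, 1], end_s = m[, 2])
      } else empty_intervals()
      if (nrow(segs) == 0) break
    }
    res[[i]] <- segs
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) return(empty_intervals())
  out[out$end_s > out$start_s, , drop = FALSE]
}

#' Gaussian kernel smoothing of a binned series
#'
#' Kernel truncated at +/- 3 sigma. Linear smoothing renormalises the kernel
#' at the edges; circular smoothing wraps around.
#' @param x numeric vector of bin values (NA allowed; NAs are excluded from
#'   the kernel mass and the kernel renormalised over observed bins).
#' @param sigma_bins kernel standard deviation in bins.
#' @param circular wrap around the ends?
#' @return smoothed vector, same length.
#' @keywords internal
smooth_gaussian <- function(x, sigma_bins, circular = FALSE) {
  n <- length(x)
  if (n == 0 || sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  out <- numeric(n)
  ok <- !is.na(x)
  xf <- ifelse(ok, x, 0)
  for (i in seq_len(n)) {
    idx <- i + seq(-half, half)
    if (circular) {
      idx <- ((idx - 1) %% n) + 1
      w <- k
    } else {
      sel <- idx >= 1 & idx <= n
      idx <- idx[sel]
      w <- k[sel]
    }
    w <- w * ok[idx]
    sw <- sum(w)
    out[i] <- if (sw > 0) sum(w * xf[idx]) / sw else NA_real_
  }
  out
}

#' Derive a child seed from a master seed
#'
#' All stochastic operations take an explicit seed; one master seed is
#' expanded into independent per-component streams with fixed offsets.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 2654435761) %% 2147483629) + 1L
}

# restore RNG state on exit so library code does not clobber the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
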