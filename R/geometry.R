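#' Arc length and radius of curvature of a sampled path
#'
#' Computes per-sample cumulative arc length and radius of curvature for a
#' sampled 2-D path. Arc length is the running sum of chord lengths.
#' Curvature uses the parameterization-invariant cross-product formula
#' `R = |v|^3 / |v x a|`, where `v` and `a` are first and second derivatives
#' of position with respect to sample index, taken by five-point centred
#' differences after a light moving-average smoothing of the coordinates.
#' For closed paths differencing wraps around periodically. `R` is capped
#' at `R_max` (straight segments and inflection samples report the cap).
#'
#' @param traj A trajectory tibble with columns `x`, `y` (m), e.g. from
#'   [simulate_steady_cycle()]. If the first and last samples coincide (a
#'   closed cycle stored with its duplicate endpoint) the duplicate is
#'   detected and handled internally.
#' @param closed Treat the path as closed (wrap-around differencing).
#' @param smooth_window Width (samples, odd) of the moving-average smoother
#'   applied to the coordinates before differentiation.
#' @param R_max Cap on the radius of curvature (m).
#' @return A tibble with columns `s` (m, `s[1] = 0`, nondecreasing) and `R`
#'   (m, in `(0, R_max]`), one row per input sample. Attributes:
#'   `total_length` (m, including the closing chord for closed paths) and
#'   `closed`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 1001)[-1001]
#' circ <- tibble::tibble(x = 0.1 * cos(th), y = 0.1 * sin(th))
#' g <- path_geometry(circ)
#' attr(g, "total_length") # ~ 2 * pi * 0.1
#' @export
path_geometry <- function(traj, closed = TRUE, smooth_window = 9,
                          R_max = 10) {
  xy <- cbind(traj$x, traj$y)
  n <- nrow(xy)
  if (n < 8) stop("path_geometry() needs at least 8 samples")
  dup <- closed && has_closing_duplicate(xy)
  m <- if (dup) n - 1L else n
  P <- xy[seq_len(m), , drop = FALSE]

  chords <- sqrt(rowSums((P[c(seq(2, m), 1), , drop = FALSE] - P)^2))
  if (all(chords == 0)) stop("zero-length path")
  s_unique <- c(0, cumsum(chords[-m]))
  total <- if (closed) sum(chords) else sum(chords[-m])

  R <- curvature_radius(P, closed = closed,
                        smooth_window = smooth_window, R_max = R_max)

  s <- if (dup) c(s_unique, total) else s_unique
  Rout <- if (dup) c(R, R[1]) else R
  structure(
    tibble::tibble(s = s, R = Rout),
    total_length = total, closed = closed,
    class = class(tibble::tibble())
  )
}

has_closing_duplicate <- function(xy) {
  n <- nrow(xy)
  chord <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-n, , drop = FALSE])^2))
  gap <- sqrt(sum((xy[n, ] - xy[1, ])^2))
  gap <= max(1e-4, 0.5 * mean(chord))
}

curvature_radius <- function(P, closed, smooth_window, R_max) {
  m <- nrow(P)
  xs <- smooth_ma(P[, 1], smooth_window, closed)
  ys <- smooth_ma(P[, 2], smooth_window, closed)
  d1 <- function(f) stencil5(f, c(1, -8, 0, 8, -1) / 12, closed)
  d2 <- function(f) stencil5(f, c(-1, 16, -30, 16, -1) / 12, closed)
  xd <- d1(xs); yd <- d1(ys)
  xdd <- d2(xs); ydd <- d2(ys)
  num <- (xd^2 + yd^2)^1.5
  den <- abs(xd * ydd - yd * xdd)
  R <- ifelse(den < num / R_max, R_max, num / den)
  pmin(pmax(R, .Machine$double.eps), R_max)
}

# moving average; circular wrap for closed paths, edge replication otherwise
smooth_ma <- function(f, window, closed) {
  if (window <= 1) return(f)
  if (window %% 2 == 0) window <- window + 1
  k <- (window - 1) / 2
  m <- length(f)
  ext <- if (closed) {
    c(f[(m - k + 1):m], f, f[1:k])
  } else {
    c(rep(f[1], k), f, rep(f[m], k))
  }
  as.numeric(stats::filter(ext, rep(1 / window, window), sides = 2))[(k + 1):(k + m)]
}

# five-point stencil with respect to sample index
stencil5 <- function(f, w, closed) {
  m <- length(f)
  sh <- function(o) {
    if (closed) f[((seq_len(m) - 1 + o) %% m) + 1]
    else f[pmin(pmax(seq_len(m) + o, 1), m)]
  }
  w[1] * sh(-2) + w[2] * sh(-1) + w[3] * sh(0) + w[4] * sh(1) + w[5] * sh(2)
}
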