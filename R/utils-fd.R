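# Second-order finite differences on a (possibly nonuniform) periodic time
# grid. `y` and `tt` hold one period without the closing duplicate sample;
# `period` is the full cycle duration so the wrap steps are well defined.
fd1_periodic <- function(y, tt, period) {
  m <- length(y)
  ym <- y[c(m, seq_len(m - 1))]
  yp <- y[c(seq(2, m), 1)]
  h1 <- tt - c(tt[m] - period, tt[-m])
  h2 <- c(tt[-1], tt[1] + period) - tt
  if (any(h1 <= 0) || any(h2 <= 0)) {
    stop("time grid must be strictly increasing over the cycle")
  }
  (-h2 / (h1 * (h1 + h2))) * ym +
    ((h2 - h1) / (h1 * h2)) * y +
    (h1 / (h2 * (h1 + h2))) * yp
}

# non-periodic first derivative: central in the interior, one-sided edges
fd1_open <- function(y, tt) {
  m <- length(y)
  d <- numeric(m)
  h1 <- tt[2:(m - 1)] - tt[1:(m - 2)]
  h2 <- tt[3:m] - tt[2:(m - 1)]
  d[2:(m - 1)] <- (-h2 / (h1 * (h1 + h2))) * y[1:(m - 2)] +
    ((h2 - h1) / (h1 * h2)) * y[2:(m - 1)] +
    (h1 / (h2 * (h1 + h2))) * y[3:m]
  d[1] <- (y[2] - y[1]) / (tt[2] - tt[1])
  d[m] <- (y[m] - y[m - 1]) / (tt[m] - tt[m - 1])
  d
}

# trapezoidal weights of a periodic grid (sum to `period`)
periodic_weights <- function(tt, period) {
  m <- length(tt)
  h1 <- tt - c(tt[m] - period, tt[-m])
  h2 <- c(tt[-1], tt[1] + period) - tt
  (h1 + h2) / 2
}

`%||%` <- function(x, y) if (is.null(x)) y else x
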