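# Independent oracles used across the suite.

# Brute-force weighted-average moments over the discrete points: explicit
# loops, no shared code with the package's segment-sum implementation.
brute_moments <- function(times, conc) {
  n <- length(times)
  dt <- numeric(n)
  for (i in seq_len(n)) {
    dt[i] <- if (i == 1L) times[2L] - times[1L] else times[i] - times[i - 1L]
  }
  w <- conc * dt
  den <- 0
  m1 <- 0
  m2 <- 0
  for (i in seq_len(n)) {
    den <- den + w[i]
    m1 <- m1 + times[i] * w[i]
    m2 <- m2 + times[i]^2 * w[i]
  }
  list(mrt = m1 / den, variance = m2 / den - (m1 / den)^2)
}

# Central finite differences of the training loss w.r.t. a flat parameter
# vector.
fd_gradient <- function(net, X, y, eps = 1e-6) {
  v0 <- extrurtd:::flatten_params(net)
  loss_at <- function(v) {
    cand <- extrurtd:::unflatten_params(net, v)
    mean((forward(cand, X) - y)^2)
  }
  vapply(seq_along(v0), function(j) {
    vp <- v0
    vm <- v0
    vp[j] <- vp[j] + eps
    vm[j] <- vm[j] - eps
    (loss_at(vp) - loss_at(vm)) / (2 * eps)
  }, numeric(1))
}

# sRGB -> CIELAB reference values (D65) for the primaries, secondaries,
# white and black, frozen from an independent implementation of the CIE
# closed form.
lab_reference <- function() {
  cols <- rbind(white = c(1, 1, 1), black = c(0, 0, 0),
                red = c(1, 0, 0), green = c(0, 1, 0), blue = c(0, 0, 1),
                yellow = c(1, 1, 0), cyan = c(0, 1, 1),
                magenta = c(1, 0, 1))
  lab <- rbind(
    c(100.000000, -0.002455, 0.004653),
    c(0.000000, 0.000000, 0.000000),
    c(53.240588, 80.092308, 67.202751),
    c(87.735099, -86.183030, 83.179703),
    c(32.295673, 79.185591, -107.857300),
    c(97.139507, -21.554681, 94.478122),
    c(91.113301, -48.090596, -14.126330),
    c(60.323507, 98.233054, -60.821015))
  rownames(lab) <- rownames(cols)
  list(rgb = cols, lab = lab)
}

# Random small tracer series for property loops.
random_series <- function(n = 10L) {
  t <- cumsum(stats::runif(n, 1, 15))
  conc <- stats::runif(n, 0, 0.4)
  conc[sample.int(n, 1L)] <- stats::runif(1, 0.1, 0.4)  # ensure > 0
  tracer_series(t, conc)
}
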