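# Brute-force oracles kept deliberately naive and independent of the
# package's vectorized implementations.

make_track <- function(x, y, id = 1L) {
  tibble::tibble(track_id = id, frame = seq_along(x) - 1L, x = x, y = y)
}

random_track <- function(n, seed, id = 1L) {
  set.seed(seed)
  make_track(cumsum(rnorm(n)), cumsum(rnorm(n)), id = id)
}

collinear_track <- function(n = 10, angle = 0.7) {
  s <- seq_len(n)
  make_track(s * cos(angle), s * sin(angle))
}

square_track <- function() {
  make_track(c(0, 1, 1, 0), c(0, 0, 1, 1))
}

# time-averaged MSD by an explicit double loop over all frame pairs
naive_msd <- function(x, y, max_steps, dt = 1) {
  n <- length(x)
  out <- data.frame(lag = numeric(0), msd = numeric(0), n_pairs = integer(0))
  for (k in seq_len(max_steps)) {
    acc <- 0
    cnt <- 0L
    for (i in seq_len(n - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
      cnt <- cnt + 1L
    }
    out <- rbind(out, data.frame(lag = k * dt, msd = acc / cnt, n_pairs = cnt))
  }
  out
}

# gyration tensor by an explicit covariance double loop
naive_gyration <- function(x, y) {
  n <- length(x)
  xs <- cbind(x, y)
  mu <- c(sum(x) / n, sum(y) / n)
  t_mat <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      s <- 0
      for (k in seq_len(n)) s <- s + xs[k, i] * xs[k, j]
      t_mat[i, j] <- s / n - mu[i] * mu[j]
    }
  }
  t_mat
}

rotate_track <- function(tr, theta, dx = 0, dy = 0) {
  out <- tr
  out$x <- tr$x * cos(theta) - tr$y * sin(theta) + dx
  out$y <- tr$x * sin(theta) + tr$y * cos(theta) + dy
  out
}
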