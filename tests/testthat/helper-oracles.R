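# Independent oracles used across tests. These deliberately re-derive results
# with the most naive method available (double loops, scalar arithmetic) so
# they share no code with the implementation they check.

# Brute-force GLCM pair counter: loop over every pixel, look up the neighbor.
brute_glcm_counts <- function(img, levels, d, angle, symmetric = FALSE) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  P <- matrix(0L, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (cc in seq_len(ncol(img))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        i <- img[r, cc] + 1L; j <- img[r2, c2] + 1L
        P[i, j] <- P[i, j] + 1L
      }
    }
  }
  if (symmetric) P <- P + t(P)
  P
}

# Scalar-loop LSTM cell: every gate entry computed with explicit sums.
scalar_lstm_cell <- function(x, h, c, p) {
  hs <- length(h)
  sig <- function(z) 1 / (1 + exp(-z))
  f <- i <- o <- g <- numeric(hs)
  for (k in seq_len(hs)) {
    af <- ai <- ao <- ag <- 0
    for (m in seq_along(x)) {
      af <- af + p$W_f[k, m] * x[m]; ai <- ai + p$W_i[k, m] * x[m]
      ao <- ao + p$W_o[k, m] * x[m]; ag <- ag + p$W_c[k, m] * x[m]
    }
    for (m in seq_len(hs)) {
      af <- af + p$U_f[k, m] * h[m]; ai <- ai + p$U_i[k, m] * h[m]
      ao <- ao + p$U_o[k, m] * h[m]; ag <- ag + p$U_c[k, m] * h[m]
    }
    f[k] <- sig(af + p$b_f[k]); i[k] <- sig(ai + p$b_i[k])
    o[k] <- sig(ao + p$b_o[k]); g[k] <- tanh(ag + p$b_c[k])
  }
  c2 <- f * c + i * g
  list(h = o * tanh(c2), c = c2)
}

# Random LSTM parameters for oracle tests (plain list, same field names).
random_lstm_params <- function(input_size, hidden_size) {
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.5), nr, nc)
  list(W_f = mk(hidden_size, input_size), U_f = mk(hidden_size, hidden_size),
       b_f = stats::rnorm(hidden_size, sd = 0.5),
       W_i = mk(hidden_size, input_size), U_i = mk(hidden_size, hidden_size),
       b_i = stats::rnorm(hidden_size, sd = 0.5),
       W_o = mk(hidden_size, input_size), U_o = mk(hidden_size, hidden_size),
       b_o = stats::rnorm(hidden_size, sd = 0.5),
       W_c = mk(hidden_size, input_size), U_c = mk(hidden_size, hidden_size),
       b_c = stats::rnorm(hidden_size, sd = 0.5),
       hidden_size = as.integer(hidden_size),
       input_size = as.integer(input_size))
}

# All-zero LSTM parameters of the given dimensions.
zero_lstm_params <- function(input_size, hidden_size) {
  z <- function(nr, nc) matrix(0, nr, nc)
  list(W_f = z(hidden_size, input_size), U_f = z(hidden_size, hidden_size),
       b_f = numeric(hidden_size),
       W_i = z(hidden_size, input_size), U_i = z(hidden_size, hidden_size),
       b_i = numeric(hidden_size),
       W_o = z(hidden_size, input_size), U_o = z(hidden_size, hidden_size),
       b_o = numeric(hidden_size),
       W_c = z(hidden_size, input_size), U_c = z(hidden_size, hidden_size),
       b_c = numeric(hidden_size),
       hidden_size = as.integer(hidden_size),
       input_size = as.integer(input_size))
}

# Linearly separable two-feature fixture (standardized).
separable_fixture <- function(n = 200, gap = 2, seed = 3) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(stats::rnorm(n) + ifelse(y == 1, gap, -gap),
             stats::rnorm(n) + ifelse(y == 1, -gap, gap))
  list(x = scale(x), y = y)
}

# The two texture classes used for end-to-end image fixtures: coarse
# (blob_scale 2) vs smooth (blob_scale 16) texture, same mean level.
fixture_specs <- function() {
  list(texture_class_spec(0, 16, 2, 1),
       texture_class_spec(1, 16, 16, 1))
}
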