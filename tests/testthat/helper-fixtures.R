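# Shared fixtures and numerical oracles for the test suite.

# central finite-difference gradient of a scalar-valued function of one
# parameter array (the independent oracle for all backward passes)
fd_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_tensor <- function(h, w, n, c, sd = 1) {
  array(stats::rnorm(h * w * n * c, sd = sd), dim = c(h, w, n, c))
}

# brute-force direct convolution ("same" padding), the independent oracle
# for the im2col path; weight w is an array (kh, kw, cin, cout)
naive_conv <- function(x, w, stride = 1L) {
  d <- dim(x); kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  ho <- ceiling(d[1] / stride); wo <- ceiling(d[2] / stride)
  pt <- max((ho - 1) * stride + kh - d[1], 0); pl <- max((wo - 1) * stride + kw - d[2], 0)
  py <- pt %/% 2; px <- pl %/% 2
  y <- array(0, dim = c(ho, wo, d[3], cout))
  for (n in seq_len(d[3])) for (o in seq_len(cout))
    for (oy in seq_len(ho)) for (ox in seq_len(wo)) {
      acc <- 0
      for (dy in seq_len(kh)) for (dx in seq_len(kw)) {
        iy <- (oy - 1) * stride + dy - py
        ix <- (ox - 1) * stride + dx - px
        if (iy >= 1 && iy <= d[1] && ix >= 1 && ix <= d[2])
          acc <- acc + sum(x[iy, ix, n, ] * w[dy, dx, , o])
      }
      y[oy, ox, n, o] <- acc
    }
  y
}

# in-memory synthetic split used by several training tests
toy_split <- function(n_train = 48L, n_val = 32L, image_size = 32L, seed = 7L,
                      noise_sd = 0.02) {
  tr <- generate_dataset_array(synth_config(n = n_train, image_size = image_size,
                                            noise_sd = noise_sd, seed = seed))
  va <- generate_dataset_array(synth_config(n = n_val, image_size = image_size,
                                            noise_sd = noise_sd, seed = seed + 1L))
  list(train = tr, val = va)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
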