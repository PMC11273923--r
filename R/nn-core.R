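# Compact reverse-mode layer library.
#
# Feature maps are numeric arrays with dim c(H, W, N, C): spatial dims first,
# batch third, channels last.  Channels-last keeps every per-channel operation
# (batch norm, depthwise taps, channel masks) a plain column operation on the
# (H*W*N) x C matrix view, and im2col patch matrices feed straight into BLAS.
#
# A module is an environment with fields:
#   fwd(self, x, train)  -> output (caches what backward needs on self)
#   bwd(self, dy)        -> gradient w.r.t. the module input
#   params               -> named list of nn_param environments
#   children             -> list of sub-modules
# Gradients accumulate into param$g; nn_zero_grad() clears them.

nn_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  class(e) <- "nn_param"
  e
}

new_module <- function(.kind, params = list(), children = list(), fwd, bwd, ...) {
  self <- new.env(parent = emptyenv())
  self$kind <- .kind
  self$params <- params
  self$children <- children
  self$fwd <- fwd
  self$bwd <- bwd
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = self)
  class(self) <- "nn_module"
  self
}

nn_forward <- function(mod, x, train = TRUE) mod$fwd(mod, x, train)
nn_backward <- function(mod, dy) mod$bwd(mod, dy)

#' @keywords internal
nn_params <- function(mod) {
  out <- mod$params
  for (ch in mod$children) out <- c(out, nn_params(ch))
  out
}

nn_zero_grad <- function(mod) {
  for (p in nn_params(mod)) p$g <- NULL
  invisible(mod)
}

acc_grad <- function(p, g) {
  p$g <- if (is.null(p$g)) g else p$g + g
  invisible(p)
}

tensor_dims <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  list(h = d[1L], w = d[2L], n = d[3L], c = d[4L])
}

# "same" padding amounts for kernel k, stride s on extent n (output ceil(n/s))
pad_amounts <- function(n, k, s) {
  out <- ceiling(n / s)
  total <- max((out - 1L) * s + k - n, 0L)
  lo <- total %/% 2L
  c(lo = lo, hi = total - lo, out = out)
}

pad_hw <- function(x, ph, pw) {
  if (ph[1] == 0 && ph[2] == 0 && pw[1] == 0 && pw[2] == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + ph[1] + ph[2], d[2] + pw[1] + pw[2], d[3], d[4]))
  xp[ph[1] + seq_len(d[1]), pw[1] + seq_len(d[2]), , ] <- x
  xp
}

unpad_hw <- function(xp, ph, pw, h, w) {
  xp[ph[1] + seq_len(h), pw[1] + seq_len(w), , , drop = FALSE]
}

# Row/col index grids for one kernel tap on the padded array
tap_index <- function(off, out, stride) off + seq_len(out) * stride - stride + 1L

# im2col: (H*W*N) x (kh*kw*C) patch matrix; tap-major, channels within a tap.
im2col <- function(xp, kh, kw, stride, ho, wo) {
  d <- dim(xp)
  n <- d[3]; c <- d[4]
  ncolP <- kh * kw * c
  P <- matrix(0, nrow = ho * wo * n, ncol = ncolP)
  t <- 0L
  for (dx in seq_len(kw)) {
    cols <- tap_index(dx - 1L, wo, stride)
    for (dy in seq_len(kh)) {
      rows <- tap_index(dy - 1L, ho, stride)
      t <- t + 1L
      slab <- xp[rows, cols, , , drop = FALSE]
      P[, ((t - 1L) * c + 1L):(t * c)] <- slab
      # dim(slab) = (ho, wo, n, c); matrix fill is column-major, consistent
    }
    # order over (dy, dx) must match col2im and weight packing below
  }
  P
}

# Transpose of im2col: scatter patch-matrix gradients back onto the padded grid
col2im <- function(dP, dim_xp, kh, kw, stride, ho, wo) {
  n <- dim_xp[3]; c <- dim_xp[4]
  dxp <- array(0, dim = dim_xp)
  t <- 0L
  for (dx in seq_len(kw)) {
    cols <- tap_index(dx - 1L, wo, stride)
    for (dy in seq_len(kh)) {
      rows <- tap_index(dy - 1L, ho, stride)
      t <- t + 1L
      slab <- array(dP[, ((t - 1L) * c + 1L):(t * c)], dim = c(ho, wo, n, c))
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + slab
    }
  }
  dxp
}

init_conv_weight <- function(kh, kw, cin_g, cout) {
  fan_in <- kh * kw * cin_g
  matrix(stats::rnorm(kh * kw * cin_g * cout, sd = sqrt(2 / fan_in)),
         nrow = kh * kw * cin_g, ncol = cout)
}

# General (optionally grouped) convolution, "same" padding, no bias.
# Weight: one (kh*kw*cin/groups) x (cout/groups) matrix per group.
nn_conv2d <- function(cin, cout, kh, kw = kh, stride = 1L, groups = 1L) {
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("channels not divisible by groups", call. = FALSE)
  cin_g <- cin %/% groups
  cout_g <- cout %/% groups
  W <- lapply(seq_len(groups), function(g) nn_param(init_conv_weight(kh, kw, cin_g, cout_g)))
  names(W) <- paste0("w", seq_len(groups))
  new_module(
    "conv2d", params = W,
    cin = cin, cout = cout, kh = kh, kw = kw, stride = as.integer(stride), groups = groups,
    fwd = function(self, x, train) {
      d <- tensor_dims(x)
      stopifnot(d$c == self$cin)
      ph <- pad_amounts(d$h, self$kh, self$stride)
      pw <- pad_amounts(d$w, self$kw, self$stride)
      ho <- ph[["out"]]; wo <- pw[["out"]]
      cin_g <- self$cin %/% self$groups
      cout_g <- self$cout %/% self$groups
      y <- array(0, dim = c(ho, wo, d$n, self$cout))
      self$cache <- list(dim_x = dim(x), ph = ph, pw = pw, ho = ho, wo = wo, P = vector("list", self$groups))
      for (g in seq_len(self$groups)) {
        xg <- x[, , , ((g - 1L) * cin_g + 1L):(g * cin_g), drop = FALSE]
        xp <- pad_hw(xg, ph[1:2], pw[1:2])
        P <- im2col(xp, self$kh, self$kw, self$stride, ho, wo)
        self$cache$P[[g]] <- P
        self$cache$dim_xp <- dim(xp)
        y[, , , ((g - 1L) * cout_g + 1L):(g * cout_g)] <- P %*% self$params[[g]]$v
      }
      y
    },
    bwd = function(self, dy) {
      cc <- self$cache
      d <- cc$dim_x
      cin_g <- self$cin %/% self$groups
      cout_g <- self$cout %/% self$groups
      dY <- matrix(dy, nrow = cc$ho * cc$wo * d[3])
      dx <- array(0, dim = d)
      for (g in seq_len(self$groups)) {
        dYg <- dY[, ((g - 1L) * cout_g + 1L):(g * cout_g), drop = FALSE]
        acc_grad(self$params[[g]], crossprod(cc$P[[g]], dYg))
        dP <- tcrossprod(dYg, self$params[[g]]$v)
        dxp <- col2im(dP, cc$dim_xp, self$kh, self$kw, self$stride, cc$ho, cc$wo)
        dx[, , , ((g - 1L) * cin_g + 1L):(g * cin_g)] <-
          unpad_hw(dxp, cc$ph[1:2], cc$pw[1:2], d[1], d[2])
      }
      dx
    })
}

# Depthwise convolution (channel multiplier 1) via shift-accumulate:
# cheaper than per-channel im2col for the small kernels used here.
nn_depthwise <- function(channels, kh, kw = kh, stride = 1L) {
  W <- nn_param(matrix(stats::rnorm(kh * kw * channels, sd = sqrt(2 / (kh * kw))),
                       nrow = kh * kw, ncol = channels))
  new_module(
    "depthwise", params = list(w = W),
    channels = channels, kh = kh, kw = kw, stride = as.integer(stride),
    fwd = function(self, x, train) {
      d <- tensor_dims(x)
      stopifnot(d$c == self$channels)
      ph <- pad_amounts(d$h, self$kh, self$stride)
      pw <- pad_amounts(d$w, self$kw, self$stride)
      ho <- ph[["out"]]; wo <- pw[["out"]]
      xp <- pad_hw(x, ph[1:2], pw[1:2])
      m <- ho * wo * d$n
      Y <- matrix(0, nrow = m, ncol = d$c)
      S <- vector("list", self$kh * self$kw)
      t <- 0L
      for (dx_ in seq_len(self$kw)) {
        cols <- tap_index(dx_ - 1L, wo, self$stride)
        for (dy_ in seq_len(self$kh)) {
          rows <- tap_index(dy_ - 1L, ho, self$stride)
          t <- t + 1L
          St <- matrix(xp[rows, cols, , , drop = FALSE], nrow = m)
          S[[t]] <- St
          Y <- Y + St * rep(self$params$w$v[t, ], each = m)
        }
      }
      self$cache <- list(dim_x = dim(x), dim_xp = dim(xp), ph = ph, pw = pw,
                         ho = ho, wo = wo, S = S)
      array(Y, dim = c(ho, wo, d$n, d$c))
    },
    bwd = function(self, dy) {
      cc <- self$cache
      d <- cc$dim_x
      m <- cc$ho * cc$wo * d[3]
      dY <- matrix(dy, nrow = m)
      dW <- matrix(0, nrow = self$kh * self$kw, ncol = d[4])
      dxp <- array(0, dim = cc$dim_xp)
      t <- 0L
      for (dx_ in seq_len(self$kw)) {
        cols <- tap_index(dx_ - 1L, cc$wo, self$stride)
        for (dy_ in seq_len(self$kh)) {
          rows <- tap_index(dy_ - 1L, cc$ho, self$stride)
          t <- t + 1L
          dW[t, ] <- colSums(cc$S[[t]] * dY)
          dSt <- dY * rep(self$params$w$v[t, ], each = m)
          dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] +
            array(dSt, dim = c(cc$ho, cc$wo, d[3], d[4]))
        }
      }
      acc_grad(self$params$w, dW)
      unpad_hw(dxp, cc$ph[1:2], cc$pw[1:2], d[1], d[2])
    })
}

# Batch normalization over (H, W, N) per channel with affine terms.
nn_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_module(
    "batchnorm",
    params = list(gamma = nn_param(rep(1, channels)), beta = nn_param(rep(0, channels))),
    channels = channels, eps = eps, momentum = momentum,
    run_mean = rep(0, channels), run_var = rep(1, channels),
    fwd = function(self, x, train) {
      d <- tensor_dims(x)
      m <- d$h * d$w * d$n
      X <- matrix(x, nrow = m)
      if (train) {
        mu <- colMeans(X)
        xc <- X - rep(mu, each = m)
        v <- colMeans(xc * xc)
        self$run_mean <- (1 - self$momentum) * self$run_mean + self$momentum * mu
        self$run_var <- (1 - self$momentum) * self$run_var + self$momentum * v
      } else {
        mu <- self$run_mean
        v <- self$run_var
        xc <- X - rep(mu, each = m)
      }
      istd <- 1 / sqrt(v + self$eps)
      xhat <- xc * rep(istd, each = m)
      Y <- xhat * rep(self$params$gamma$v, each = m) + rep(self$params$beta$v, each = m)
      self$cache <- list(xhat = xhat, istd = istd, m = m, dim_x = dim(x), train = train)
      array(Y, dim = dim(x))
    },
    bwd = function(self, dy) {
      cc <- self$cache
      m <- cc$m
      dY <- matrix(dy, nrow = m)
      acc_grad(self$params$gamma, colSums(dY * cc$xhat))
      acc_grad(self$params$beta, colSums(dY))
      g <- rep(self$params$gamma$v, each = m)
      dxhat <- dY * g
      if (cc$train) {
        # full batch-statistics backward
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cc$xhat)
        dX <- (dxhat - rep(s1 / m, each = m) - cc$xhat * rep(s2 / m, each = m)) *
          rep(cc$istd, each = m)
      } else {
        dX <- dxhat * rep(cc$istd, each = m)
      }
      array(dX, dim = cc$dim_x)
    })
}

nn_activation <- function(type = c("relu6", "relu", "sigmoid")) {
  type <- match.arg(type)
  new_module(
    paste0("act_", type), type = type,
    fwd = function(self, x, train) {
      y <- switch(self$type,
        relu6 = pmin(pmax(x, 0), 6),
        relu = pmax(x, 0),
        sigmoid = 1 / (1 + exp(-x)))
      self$cache <- switch(self$type, sigmoid = y, x)
      if (is.null(dim(y)) || !identical(dim(y), dim(x))) dim(y) <- dim(x)
      y
    },
    bwd = function(self, dy) {
      switch(self$type,
        relu6 = dy * (self$cache > 0 & self$cache < 6),
        relu = dy * (self$cache > 0),
        sigmoid = dy * self$cache * (1 - self$cache))
    })
}

# 3x3 pooling with "same" padding; average pooling excludes padded cells
# from the divisor (the DARTS convention).
nn_pool <- function(type = c("max", "avg"), k = 3L, stride = 1L) {
  type <- match.arg(type)
  new_module(
    paste0(type, "pool"), type = type, k = as.integer(k), stride = as.integer(stride),
    fwd = function(self, x, train) {
      d <- tensor_dims(x)
      ph <- pad_amounts(d$h, self$k, self$stride)
      pw <- pad_amounts(d$w, self$k, self$stride)
      ho <- ph[["out"]]; wo <- pw[["out"]]
      xp <- pad_hw(x, ph[1:2], pw[1:2])
      # validity mask marks non-padded cells for the avg divisor
      vp <- pad_hw(array(1, dim = c(d$h, d$w, 1, 1)), ph[1:2], pw[1:2])
      m <- ho * wo * d$n
      nt <- self$k * self$k
      S <- vector("list", nt)
      cnt <- matrix(0, nrow = ho * wo, ncol = 1)
      t <- 0L
      for (dx_ in seq_len(self$k)) {
        cols <- tap_index(dx_ - 1L, wo, self$stride)
        for (dy_ in seq_len(self$k)) {
          rows <- tap_index(dy_ - 1L, ho, self$stride)
          t <- t + 1L
          S[[t]] <- matrix(xp[rows, cols, , , drop = FALSE], nrow = m)
          cnt <- cnt + matrix(vp[rows, cols, 1, 1], ncol = 1)
        }
      }
      if (self$type == "avg") {
        Y <- Reduce(`+`, S) / as.vector(cnt)  # cnt recycles over batch*channel cols
        self$cache <- list(dim_x = dim(x), dim_xp = dim(xp), ph = ph, pw = pw,
                           ho = ho, wo = wo, cnt = as.vector(cnt), m = m)
      } else {
        Y <- S[[1]]
        which_t <- matrix(1L, nrow = m, ncol = d$c)
        for (t in 2:nt) {
          upd <- S[[t]] > Y
          Y[upd] <- S[[t]][upd]
          which_t[upd] <- t
        }
        self$cache <- list(dim_x = dim(x), dim_xp = dim(xp), ph = ph, pw = pw,
                           ho = ho, wo = wo, which_t = which_t, m = m)
      }
      array(Y, dim = c(ho, wo, d$n, d$c))
    },
    bwd = function(self, dy) {
      cc <- self$cache
      d <- cc$dim_x
      m <- cc$m
      dY <- matrix(dy, nrow = m)
      dxp <- array(0, dim = cc$dim_xp)
      t <- 0L
      for (dx_ in seq_len(self$k)) {
        cols <- tap_index(dx_ - 1L, cc$wo, self$stride)
        for (dy_ in seq_len(self$k)) {
          rows <- tap_index(dy_ - 1L, cc$ho, self$stride)
          t <- t + 1L
          dSt <- if (self$type == "avg") dY / cc$cnt else dY * (cc$which_t == t)
          dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] +
            array(dSt, dim = c(cc$ho, cc$wo, d[3], d[4]))
        }
      }
      unpad_hw(dxp, cc$ph[1:2], cc$pw[1:2], d[1], d[2])
    })
}

# Global average pooling: (H, W, N, C) -> (N, C)
nn_global_pool <- function() {
  new_module(
    "global_pool",
    fwd = function(self, x, train) {
      d <- tensor_dims(x)
      self$cache <- d
      X <- matrix(aperm(x, c(1, 2, 4, 3)), nrow = d$h * d$w)  # (HW) x (C*N)
      t(matrix(colMeans(X), nrow = d$c))                       # N x C
    },
    bwd = function(self, dy) {
      d <- self$cache
      g <- array(rep(t(dy) / (d$h * d$w), each = d$h * d$w),
                 dim = c(d$h, d$w, d$c, d$n))
      aperm(g, c(1, 2, 4, 3))
    })
}

nn_linear <- function(cin, cout, bias = TRUE) {
  params <- list(w = nn_param(matrix(stats::rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout)))
  if (bias) params$b <- nn_param(rep(0, cout))
  new_module(
    "linear", params = params, bias = bias,
    fwd = function(self, x, train) {
      self$cache <- x
      y <- x %*% self$params$w$v
      if (self$bias) y <- y + rep(self$params$b$v, each = nrow(x))
      y
    },
    bwd = function(self, dy) {
      acc_grad(self$params$w, crossprod(self$cache, dy))
      if (self$bias) acc_grad(self$params$b, colSums(dy))
      dy %*% t(self$params$w$v)
    })
}

nn_sequential <- function(...) {
  mods <- Filter(Negate(is.null), list(...))
  new_module(
    "sequential", children = mods,
    fwd = function(self, x, train) {
      for (ch in self$children) x <- nn_forward(ch, x, train)
      x
    },
    bwd = function(self, dy) {
      for (ch in rev(self$children)) dy <- nn_backward(ch, dy)
      dy
    })
}

# --- loss -------------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy of softmax(logits) against target distributions (rows sum to 1).
# Returns list(loss, probs, dlogits); gradient already averaged over the batch.
softmax_xent <- function(logits, targets) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -sum(targets * log(pmax(p, 1e-12))) / n
  list(loss = loss, probs = p, dlogits = (p - targets) / n)
}

# --- optimizers -------------------------------------------------------------

opt_sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0) {
  for (p in params) {
    if (is.null(p$g)) next
    g <- p$g + weight_decay * p$v
    if (momentum > 0) {
      if (is.null(p$mom)) p$mom <- g * 0
      p$mom <- momentum * p$mom + g
      g <- p$mom
    }
    p$v <- p$v - lr * g
  }
  invisible(NULL)
}

opt_adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          weight_decay = 0) {
  for (p in params) {
    if (is.null(p$g)) next
    g <- p$g + weight_decay * p$v
    if (is.null(p$adam_m)) {
      p$adam_m <- g * 0
      p$adam_v <- g * 0
      p$adam_t <- 0L
    }
    p$adam_t <- p$adam_t + 1L
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * g
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * g * g
    mhat <- p$adam_m / (1 - beta1^p$adam_t)
    vhat <- p$adam_v / (1 - beta2^p$adam_t)
    p$v <- p$v - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}
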