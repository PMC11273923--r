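# Candidate operators and building blocks shared by both search spaces.
#
# Two representations coexist:
#   * declarative specs (plain lists with stable field names, JSON-friendly),
#     consumed by the analytic complexity counter;
#   * runtime modules (nn-core objects with forward/backward), consumed by the
#     search engines and trainers.
# Both are produced from the same constructors so counting and execution can
# never drift apart.

#' Operator specification
#'
#' Describes one candidate operation of the differentiable search space:
#' its kernel geometry, grouping and kind. Cell operators are
#' channel-preserving at stride 1.
#'
#' @param name Stable string identifier.
#' @param kernel Integer pair `(kh, kw)`.
#' @param groups Positive integer group count.
#' @param kind One of `"standard_conv"`, `"separable_conv"`, `"group_conv"`,
#'   `"asym_group_conv"`, `"max_pool"`, `"avg_pool"`, `"identity"`, `"zero"`.
#' @param stride Positive integer stride (cells instantiate 1 or 2).
#' @return An object of class `operator_spec`.
#' @export
operator_spec <- function(name, kernel, groups = 1L, kind, stride = 1L) {
  kinds <- c("standard_conv", "separable_conv", "group_conv", "asym_group_conv",
             "max_pool", "avg_pool", "identity", "zero")
  stopifnot(is.character(name), length(kernel) == 2L, groups >= 1L, kind %in% kinds)
  structure(list(name = name, kernel = as.integer(kernel), groups = as.integer(groups),
                 kind = kind, stride = as.integer(stride)),
            class = "operator_spec")
}

#' The 11-operator registry of the differentiable search space
#'
#' Returns the candidate operator set searched over by the cell-based engine,
#' in its canonical order: a 3x3 standard convolution; 3x3 and 5x5 separable
#' convolutions (each applied twice); 3x3 and 5x5 group convolutions with 9
#' groups; two-stage asymmetric group convolutions (1xk then kx1, k = 3 and 7,
#' 9 groups); 3x3 max and average pooling; identity; and the zero
#' (no-connection) operator. Every group convolution is followed by a
#' pointwise convolution.
#'
#' @return A list of 11 [operator_spec()] objects.
#' @export
#' @examples
#' length(list_search_operators())
list_search_operators <- function() {
  list(
    operator_spec("conv_3x3",          c(3L, 3L), 1L, "standard_conv"),
    operator_spec("sep_conv_3x3",      c(3L, 3L), 1L, "separable_conv"),
    operator_spec("sep_conv_5x5",      c(5L, 5L), 1L, "separable_conv"),
    operator_spec("group_conv_3x3",    c(3L, 3L), 9L, "group_conv"),
    operator_spec("group_conv_5x5",    c(5L, 5L), 9L, "group_conv"),
    operator_spec("asym_group_conv_3", c(1L, 3L), 9L, "asym_group_conv"),
    operator_spec("asym_group_conv_7", c(1L, 7L), 9L, "asym_group_conv"),
    operator_spec("max_pool_3x3",      c(3L, 3L), 1L, "max_pool"),
    operator_spec("avg_pool_3x3",      c(3L, 3L), 1L, "avg_pool"),
    operator_spec("identity",          c(1L, 1L), 1L, "identity"),
    operator_spec("zero",              c(1L, 1L), 1L, "zero")
  )
}

search_operator_names <- function() {
  vapply(list_search_operators(), `[[`, character(1), "name")
}

op_spec_by_name <- function(name) {
  reg <- list_search_operators()
  i <- match(name, vapply(reg, `[[`, character(1), "name"))
  if (is.na(i)) stop("unknown operator: ", name, call. = FALSE)
  reg[[i]]
}

# Zero operator: emits an all-zero map of the stride-reduced output shape.
nn_zero_op <- function(stride = 1L) {
  new_module(
    "zero", stride = as.integer(stride),
    fwd = function(self, x, train) {
      d <- tensor_dims(x)
      self$cache <- dim(x)
      array(0, dim = c(ceiling(d$h / self$stride), ceiling(d$w / self$stride), d$n, d$c))
    },
    bwd = function(self, dy) array(0, dim = self$cache))
}

nn_identity_op <- function() {
  new_module("identity_op",
    fwd = function(self, x, train) x,
    bwd = function(self, dy) dy)
}

#' Instantiate a search-space operator as a runnable feature transform
#'
#' Builds the runtime module for an [operator_spec()]: a transform mapping a
#' feature map of `channels` channels to the same channel count with spatial
#' dims divided by `stride` (ceiling, "same" padding). Convolutional
#' operators are followed by batch normalization and ReLU6; pooling operators
#' carry no weights and are followed by batch normalization; identity at
#' stride > 1 is realized as a strided pointwise convolution.
#'
#' @param spec An [operator_spec()].
#' @param channels Channel count (must be divisible by `spec$groups`).
#' @param stride Stride at which the operator is instantiated.
#' @return An internal network module with forward/backward methods.
#' @export
make_operator <- function(spec, channels, stride = 1L) {
  stopifnot(inherits(spec, "operator_spec"))
  if (channels %% spec$groups != 0L)
    stop("channels (", channels, ") not divisible by groups (", spec$groups, ")",
         call. = FALSE)
  k <- spec$kernel
  switch(spec$kind,
    standard_conv = nn_sequential(
      nn_conv2d(channels, channels, k[1], k[2], stride = stride),
      nn_batchnorm(channels), nn_activation("relu6")),
    separable_conv = {
      # applied twice; the stride lives in the first repeat
      rep1 <- nn_sequential(
        nn_depthwise(channels, k[1], k[2], stride = stride),
        nn_conv2d(channels, channels, 1, 1),
        nn_batchnorm(channels), nn_activation("relu6"))
      rep2 <- nn_sequential(
        nn_depthwise(channels, k[1], k[2], stride = 1L),
        nn_conv2d(channels, channels, 1, 1),
        nn_batchnorm(channels), nn_activation("relu6"))
      nn_sequential(rep1, rep2)
    },
    group_conv = nn_sequential(
      nn_conv2d(channels, channels, k[1], k[2], stride = stride, groups = spec$groups),
      nn_conv2d(channels, channels, 1, 1),
      nn_batchnorm(channels), nn_activation("relu6")),
    asym_group_conv = nn_sequential(
      nn_conv2d(channels, channels, k[1], k[2], stride = stride, groups = spec$groups),
      nn_conv2d(channels, channels, k[2], k[1], stride = 1L, groups = spec$groups),
      nn_conv2d(channels, channels, 1, 1),
      nn_batchnorm(channels), nn_activation("relu6")),
    max_pool = nn_sequential(nn_pool("max", 3L, stride), nn_batchnorm(channels)),
    avg_pool = nn_sequential(nn_pool("avg", 3L, stride), nn_batchnorm(channels)),
    identity = if (stride == 1L) nn_identity_op() else nn_sequential(
      nn_conv2d(channels, channels, 1, 1, stride = stride), nn_batchnorm(channels)),
    zero = nn_zero_op(stride),
    stop("unhandled operator kind: ", spec$kind, call. = FALSE))
}

#' Block specification for the one-shot search space
#'
#' Declarative description of one building block: either a MobileNetV2
#' inverted residual (`mbconv`) or the parallel asymmetric convolution block
#' (`parallel_asym`), whose depthwise stage splits the expanded channels into
#' two equal halves processed by 1x7 and 7x1 depthwise convolutions in
#' parallel (7 taps per expanded channel). A residual connection is present
#' iff `stride == 1` and `cin == cout`. Both kinds have a depth of three
#' weighted stages.
#'
#' @param kind `"mbconv"` or `"parallel_asym"`.
#' @param cin,cout Input/output channel counts.
#' @param stride 1 or 2.
#' @param expand Channel expansion ratio of the block.
#' @param kernel Depthwise kernel size for `mbconv` (3 or 5); ignored for
#'   `parallel_asym`, whose effective tap count is 7.
#' @param use_se Include a Squeeze-Excitation module after the depthwise
#'   stage.
#' @param se_reduction Bottleneck reduction of the SE module.
#' @param force_expand Keep the expansion convolution even when
#'   `expand == 1` (preserves the three-stage depth; the one-shot space does
#'   this, the reference MobileNetV2 does not).
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(kind = c("mbconv", "parallel_asym"), cin, cout, stride = 1L,
                       expand = 6, kernel = 3L, use_se = FALSE, se_reduction = 4L,
                       force_expand = TRUE) {
  kind <- match.arg(kind)
  stopifnot(cin >= 1, cout >= 1, stride %in% c(1L, 2L), expand > 0)
  cexp <- expanded_channels(cin, expand)
  if (kind == "parallel_asym" && cexp %% 2L != 0L)
    stop("parallel_asym requires an even expanded channel count (expand * cin)",
         call. = FALSE)
  if (kind == "mbconv" && !kernel %in% c(3L, 5L))
    stop("mbconv kernel must be 3 or 5", call. = FALSE)
  structure(list(kind = kind, cin = as.integer(cin), cout = as.integer(cout),
                 stride = as.integer(stride), expand = expand, kernel = as.integer(kernel),
                 use_se = isTRUE(use_se), se_reduction = as.integer(se_reduction),
                 force_expand = isTRUE(force_expand)),
            class = "block_spec")
}

expanded_channels <- function(cin, expand) as.integer(round(cin * expand))

block_has_residual <- function(spec) spec$stride == 1L && spec$cin == spec$cout

block_has_expand_conv <- function(spec) spec$expand != 1 || spec$force_expand

#' Squeeze-Excitation configuration
#'
#' @param channels Channel count the module reweights.
#' @param reduction Bottleneck reduction factor (`channels / reduction >= 1`).
#' @return An object of class `se_config`.
#' @export
se_config <- function(channels, reduction = 4L) {
  stopifnot(channels >= 1, reduction >= 1, channels / reduction >= 1)
  structure(list(channels = as.integer(channels), reduction = as.integer(reduction)),
            class = "se_config")
}

se_bottleneck_width <- function(cfg) max(1L, cfg$channels %/% cfg$reduction)

#' Build a Squeeze-Excitation channel-reweighting module
#'
#' Global average pool, a two-layer bottleneck (width `channels/reduction`,
#' with biases), a sigmoid gate in (0, 1) per channel, and a channel-wise
#' multiply. Output shape equals input shape.
#'
#' @param cfg A [se_config()].
#' @return A runtime network module.
#' @export
make_se_module <- function(cfg) {
  stopifnot(inherits(cfg, "se_config"))
  hidden <- se_bottleneck_width(cfg)
  fc1 <- nn_linear(cfg$channels, hidden, bias = TRUE)
  act <- nn_activation("relu")
  fc2 <- nn_linear(hidden, cfg$channels, bias = TRUE)
  gate <- nn_activation("sigmoid")
  pool <- nn_global_pool()
  new_module(
    "se", children = list(pool = pool, fc1 = fc1, act = act, fc2 = fc2, gate = gate),
    fwd = function(self, x, train) {
      ch <- self$children
      s <- nn_forward(ch$pool, x, train)                      # N x C
      g <- nn_forward(ch$gate,
             nn_forward(ch$fc2, nn_forward(ch$act, nn_forward(ch$fc1, s, train), train),
                        train), train)                         # N x C in (0,1)
      d <- tensor_dims(x)
      gmap <- aperm(array(rep(t(g), each = d$h * d$w), dim = c(d$h, d$w, d$c, d$n)),
                    c(1, 2, 4, 3))
      self$cache <- list(x = x, g = g, gmap = gmap, d = d)
      x * gmap
    },
    bwd = function(self, dy) {
      cc <- self$cache
      ch <- self$children
      dx_direct <- dy * cc$gmap
      # gradient into the gate: sum over spatial positions of dy * x
      prod <- dy * cc$x
      X <- matrix(aperm(prod, c(1, 2, 4, 3)), nrow = cc$d$h * cc$d$w)
      dg <- t(matrix(colSums(X), nrow = cc$d$c))               # N x C
      ds <- nn_backward(ch$fc1, nn_backward(ch$act,
              nn_backward(ch$fc2, nn_backward(ch$gate, dg))))
      dx_direct + nn_backward(ch$pool, ds)
    })
}

# Shared tail of both block kinds: optional SE, projection conv, final BN,
# optional residual.  `inner` maps input -> post-depthwise activation.
make_block_module <- function(spec, inner, cexp) {
  se <- if (spec$use_se) make_se_module(se_config(cexp, spec$se_reduction)) else NULL
  proj <- nn_sequential(nn_conv2d(cexp, spec$cout, 1, 1), nn_batchnorm(spec$cout))
  residual <- block_has_residual(spec)
  new_module(
    paste0("block_", spec$kind),
    children = c(list(inner = inner), if (!is.null(se)) list(se = se), list(proj = proj)),
    spec = spec, residual = residual,
    fwd = function(self, x, train) {
      ch <- self$children
      h <- nn_forward(ch$inner, x, train)
      if (!is.null(ch$se)) h <- nn_forward(ch$se, h, train)
      y <- nn_forward(ch$proj, h, train)
      if (self$residual) y + x else y
    },
    bwd = function(self, dy) {
      ch <- self$children
      dh <- nn_backward(ch$proj, dy)
      if (!is.null(ch$se)) dh <- nn_backward(ch$se, dh)
      dx <- nn_backward(ch$inner, dh)
      if (self$residual) dx + dy else dx
    })
}

#' Build a MobileNetV2 inverted-residual block
#'
#' Expansion 1x1 convolution, depthwise kxk convolution (stride applied
#' here), and linear 1x1 projection, with batch normalization throughout and
#' ReLU6 after the first two stages. Convolutions are bias-free. A residual
#' connection is added iff `stride == 1` and `cin == cout`.
#'
#' @param spec A [block_spec()] with `kind = "mbconv"`.
#' @return A runtime network module.
#' @export
make_mbconv_block <- function(spec) {
  stopifnot(inherits(spec, "block_spec"), spec$kind == "mbconv")
  cexp <- expanded_channels(spec$cin, spec$expand)
  expand_stage <- if (block_has_expand_conv(spec)) nn_sequential(
    nn_conv2d(spec$cin, cexp, 1, 1), nn_batchnorm(cexp), nn_activation("relu6"))
  inner <- nn_sequential(
    expand_stage,
    nn_depthwise(cexp, spec$kernel, spec$kernel, stride = spec$stride),
    nn_batchnorm(cexp), nn_activation("relu6"))
  make_block_module(spec, inner, cexp)
}

#' Build a parallel asymmetric convolution block
#'
#' Expansion 1x1 convolution, then the expanded channels are split into two
#' equal halves processed in parallel by a 1x7 and a 7x1 depthwise
#' convolution (stride applied in this stage), concatenated, normalized and
#' activated, and linearly projected by a 1x1 convolution. The depthwise
#' stage costs 7 multiply-accumulate taps per expanded channel, and the block
#' has the same three-stage depth as an mbconv block.
#'
#' @param spec A [block_spec()] with `kind = "parallel_asym"`.
#' @return A runtime network module.
#' @export
make_parallel_asym_block <- function(spec) {
  stopifnot(inherits(spec, "block_spec"), spec$kind == "parallel_asym")
  cexp <- expanded_channels(spec$cin, spec$expand)
  if (cexp %% 2L != 0L) stop("odd expanded channel count", call. = FALSE)
  half <- cexp %/% 2L
  expand_stage <- if (block_has_expand_conv(spec)) nn_sequential(
    nn_conv2d(spec$cin, cexp, 1, 1), nn_batchnorm(cexp), nn_activation("relu6"))
  dw_a <- nn_depthwise(half, 1L, 7L, stride = spec$stride)
  dw_b <- nn_depthwise(half, 7L, 1L, stride = spec$stride)
  post <- nn_sequential(nn_batchnorm(cexp), nn_activation("relu6"))
  inner <- new_module(
    "parallel_asym_inner",
    children = c(if (!is.null(expand_stage)) list(expand = expand_stage),
                 list(dw_a = dw_a, dw_b = dw_b, post = post)),
    half = half,
    fwd = function(self, x, train) {
      ch <- self$children
      h <- if (!is.null(ch$expand)) nn_forward(ch$expand, x, train) else x
      ya <- nn_forward(ch$dw_a, h[, , , seq_len(self$half), drop = FALSE], train)
      yb <- nn_forward(ch$dw_b, h[, , , self$half + seq_len(self$half), drop = FALSE], train)
      d <- dim(ya)
      y <- array(0, dim = c(d[1], d[2], d[3], 2L * self$half))
      y[, , , seq_len(self$half)] <- ya
      y[, , , self$half + seq_len(self$half)] <- yb
      nn_forward(ch$post, y, train)
    },
    bwd = function(self, dy) {
      ch <- self$children
      dcat <- nn_backward(ch$post, dy)
      da <- nn_backward(ch$dw_a, dcat[, , , seq_len(self$half), drop = FALSE])
      db <- nn_backward(ch$dw_b, dcat[, , , self$half + seq_len(self$half), drop = FALSE])
      d <- dim(da)
      dh <- array(0, dim = c(d[1], d[2], d[3], 2L * self$half))
      dh[, , , seq_len(self$half)] <- da
      dh[, , , self$half + seq_len(self$half)] <- db
      if (!is.null(ch$expand)) nn_backward(ch$expand, dh) else dh
    })
  make_block_module(spec, inner, cexp)
}

#' Build a runtime block from its specification
#'
#' @param spec A [block_spec()].
#' @return A runtime network module.
#' @export
make_block <- function(spec) {
  switch(spec$kind,
    mbconv = make_mbconv_block(spec),
    parallel_asym = make_parallel_asym_block(spec))
}
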