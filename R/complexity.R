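# Analytic complexity accounting.
#
# Every architecture specification is first lowered to a flat table of
# primitive layers (convolutions, fully connected layers, normalizations,
# activations, poolings) with their resolved shapes; counting is then a
# column sum.  The same lowering backs both the reported totals and the
# closed-form oracle tests, so the closed forms are checked against an
# enumeration, not against themselves.

#' Block cost query for the closed-form FLOPs expressions
#'
#' @param cin,cout Input and output channel counts of the block.
#' @param k Depthwise kernel size (mbconv form only).
#' @param exp Channel expansion ratio.
#' @param h,w Output spatial dimensions.
#' @return An object of class `block_cost_query`.
#' @export
block_cost_query <- function(cin, cout, k = 3L, exp = 6, h, w) {
  stopifnot(cin >= 1, cout >= 1, k >= 1, exp > 0, h >= 1, w >= 1)
  structure(list(cin = cin, cout = cout, k = k, exp = exp, h = h, w = w),
            class = "block_cost_query")
}

#' Closed-form multiply-accumulate count of an inverted-residual block
#'
#' `EXP2 * (Cin^2 + Cin*Cout + Cin*k^2) * h * w`: the expansion, projection
#' and depthwise convolution costs of a three-stage inverted-residual block
#' whose layers all emit `h x w` maps.
#'
#' @param q A [block_cost_query()].
#' @return The multiply-accumulate count (a single number).
#' @export
#' @examples
#' mbconv_flops_closed_form(block_cost_query(16, 16, k = 3, exp = 6, h = 8, w = 8))
mbconv_flops_closed_form <- function(q) {
  stopifnot(inherits(q, "block_cost_query"))
  q$exp * (q$cin^2 + q$cin * q$cout + q$cin * q$k^2) * q$h * q$w
}

#' Closed-form multiply-accumulate count of the parallel asymmetric block
#'
#' `EXP2 * (Cin^2 + Cin*Cout + Cin*7) * h * w`: the depthwise stage costs 7
#' taps per expanded channel (two parallel halves of 1x7 and 7x1 depthwise
#' convolutions), so the block is cheaper than an mbconv block whenever
#' `k^2 > 7`, i.e. for k = 3 or 5 the cost ratio is
#' `(Cin + Cout + 7) / (Cin + Cout + k^2) < 1`.
#'
#' @param q A [block_cost_query()] (`k` is ignored).
#' @return The multiply-accumulate count.
#' @export
parallel_asym_flops_closed_form <- function(q) {
  stopifnot(inherits(q, "block_cost_query"))
  q$exp * (q$cin^2 + q$cin * q$cout + q$cin * 7) * q$h * q$w
}

#' FLOPs ratio of the parallel asymmetric block to the mbconv block
#'
#' @param cin,cout Channel counts.
#' @param k mbconv depthwise kernel size.
#' @return `(cin + cout + 7) / (cin + cout + k^2)`.
#' @export
parallel_asym_flops_ratio <- function(cin, cout, k = 3L) {
  (cin + cout + 7) / (cin + cout + k^2)
}

# --- lowering ---------------------------------------------------------------

prim <- function(type, cin = 0, cout = 0, kh = 1, kw = 1, groups = 1,
                 h = 1, w = 1, bias = FALSE, stage = NA_character_) {
  macs <- params <- extra <- 0
  if (type == "conv") {
    macs <- kh * kw * (cin / groups) * cout * h * w
    params <- kh * kw * (cin / groups) * cout + if (bias) cout else 0
  } else if (type == "fc") {
    macs <- cin * cout
    params <- cin * cout + if (bias) cout else 0
  } else if (type == "bn") {
    params <- 2 * cout
    extra <- 2 * cout * h * w
  } else if (type == "act") {
    extra <- cout * h * w
  } else if (type %in% c("pool", "global_pool")) {
    extra <- cout * h * w
  } else stop("unknown primitive: ", type)
  data.frame(type = type, cin = cin, cout = cout, kh = kh, kw = kw,
             groups = groups, h = h, w = w, macs = macs, params = params,
             extra_ops = extra, stage = stage, stringsAsFactors = FALSE)
}

conv_bn_act <- function(cin, cout, kh, kw, groups, h, w, act = TRUE, stage = NA) {
  rows <- list(prim("conv", cin, cout, kh, kw, groups, h, w, stage = stage),
               prim("bn", cout = cout, h = h, w = w, stage = stage))
  if (act) rows <- c(rows, list(prim("act", cout = cout, h = h, w = w, stage = stage)))
  rows
}

out_hw <- function(hw, stride) ceiling(hw / stride)

lower_block <- function(spec, h, w, stage = NA) {
  cexp <- expanded_channels(spec$cin, spec$expand)
  rows <- list()
  if (block_has_expand_conv(spec))
    rows <- c(rows, conv_bn_act(spec$cin, cexp, 1, 1, 1, h, w, stage = stage))
  ho <- out_hw(h, spec$stride); wo <- out_hw(w, spec$stride)
  if (spec$kind == "mbconv") {
    rows <- c(rows, conv_bn_act(cexp, cexp, spec$kernel, spec$kernel, cexp, ho, wo,
                                stage = stage))
  } else {
    half <- cexp %/% 2L
    rows <- c(rows,
              list(prim("conv", half, half, 1, 7, half, ho, wo, stage = stage),
                   prim("conv", half, half, 7, 1, half, ho, wo, stage = stage),
                   prim("bn", cout = cexp, h = ho, w = wo, stage = stage),
                   prim("act", cout = cexp, h = ho, w = wo, stage = stage)))
  }
  if (spec$use_se) {
    hidden <- se_bottleneck_width(se_config(cexp, spec$se_reduction))
    rows <- c(rows, list(
      prim("global_pool", cout = cexp, h = 1, w = 1, stage = stage),
      prim("fc", cexp, hidden, bias = TRUE, stage = stage),
      prim("act", cout = hidden, stage = stage),
      prim("fc", hidden, cexp, bias = TRUE, stage = stage),
      prim("act", cout = cexp, stage = stage)))
  }
  rows <- c(rows, conv_bn_act(cexp, spec$cout, 1, 1, 1, ho, wo, act = FALSE,
                              stage = stage))
  list(rows = rows, h = ho, w = wo, cout = spec$cout)
}

# one search-cell operator, for genotype-based (cell) architectures
lower_cell_op <- function(name, channels, stride, h, w, stage = NA) {
  spec <- op_spec_by_name(name)
  k <- spec$kernel
  ho <- out_hw(h, stride); wo <- out_hw(w, stride)
  rows <- switch(spec$kind,
    standard_conv = conv_bn_act(channels, channels, k[1], k[2], 1, ho, wo, stage = stage),
    separable_conv = c(
      list(prim("conv", channels, channels, k[1], k[2], channels, ho, wo, stage = stage)),
      conv_bn_act(channels, channels, 1, 1, 1, ho, wo, stage = stage),
      list(prim("conv", channels, channels, k[1], k[2], channels, ho, wo, stage = stage)),
      conv_bn_act(channels, channels, 1, 1, 1, ho, wo, stage = stage)),
    group_conv = c(
      list(prim("conv", channels, channels, k[1], k[2], spec$groups, ho, wo, stage = stage)),
      conv_bn_act(channels, channels, 1, 1, 1, ho, wo, stage = stage)),
    asym_group_conv = c(
      list(prim("conv", channels, channels, k[1], k[2], spec$groups, ho, wo, stage = stage),
           prim("conv", channels, channels, k[2], k[1], spec$groups, ho, wo, stage = stage)),
      conv_bn_act(channels, channels, 1, 1, 1, ho, wo, stage = stage)),
    max_pool = list(prim("pool", cout = channels, h = ho, w = wo, stage = stage),
                    prim("bn", cout = channels, h = ho, w = wo, stage = stage)),
    avg_pool = list(prim("pool", cout = channels, h = ho, w = wo, stage = stage),
                    prim("bn", cout = channels, h = ho, w = wo, stage = stage)),
    identity = if (stride == 1L) list() else
      conv_bn_act(channels, channels, 1, 1, 1, ho, wo, act = FALSE, stage = stage),
    zero = list())
  list(rows = rows, h = ho, w = wo)
}

lower_cells <- function(arch, h, w) {
  cfg <- arch$cells
  geno <- cfg$genotype
  C <- cfg$init_channels
  rows <- list()
  # channel counts carried by the two cell inputs (concat of nodes = nodes*C)
  c_prev_prev <- arch$stem$cout
  c_prev <- arch$stem$cout
  for (pos in seq_len(cfg$num_cells)) {
    reduction <- pos %in% cfg$reduction_positions
    if (reduction) C <- 2L * C
    conns <- if (reduction) geno$reduce else geno$normal
    stage <- sprintf("cell%d%s", pos, if (reduction) "R" else "")
    # preprocessing convs bring both inputs to C channels at the input grid
    rows <- c(rows,
              conv_bn_act(c_prev_prev, C, 1, 1, 1, h, w, act = FALSE, stage = stage),
              conv_bn_act(c_prev, C, 1, 1, 1, h, w, act = FALSE, stage = stage))
    ho <- if (reduction) out_hw(h, 2L) else h
    wo <- if (reduction) out_hw(w, 2L) else w
    for (conn in conns) {
      stride <- if (reduction && conn[[2]] < 2) 2L else 1L
      lo <- lower_cell_op(conn[[1]], C, stride,
                          if (stride == 2L) h else ho,
                          if (stride == 2L) w else wo, stage = stage)
      rows <- c(rows, lo$rows)
    }
    h <- ho; w <- wo
    c_prev_prev <- c_prev
    c_prev <- cfg$num_nodes * C
  }
  list(rows = rows, h = h, w = w, cout = c_prev)
}

#' Count multiply-accumulates and parameters of a declared network
#'
#' Lowers an architecture specification (stem, blocks or cells, head) to
#' primitive layers at the given input size and sums their costs. Two
#' conventions are available: `"profiler"` (the default) counts convolution
#' and fully connected multiply-accumulates plus normalization, activation
#' and pooling element operations, matching the convention of common network
#' profilers; `"macs_only"` counts convolution and fully connected
#' multiply-accumulates alone (depthwise and grouped convolutions divided by
#' their group count). Parameters always include normalization affine terms.
#'
#' @param arch An architecture specification (see [arch_spec()]).
#' @param input_hw Input spatial size, a single number or `(h, w)` pair.
#' @param convention `"profiler"` or `"macs_only"`.
#' @return A `complexity_report`: list with `flops`, `params`, `depth`,
#'   scaled `flops_g` and `params_m`, and the lowered `layers` table.
#' @export
#' @examples
#' arch <- build_age_spos(agespos_published_path(), width_mult = 1)
#' count_network(arch, 384)
count_network <- function(arch, input_hw, convention = c("profiler", "macs_only")) {
  convention <- match.arg(convention)
  stopifnot(inherits(arch, "arch_spec"))
  if (length(input_hw) == 1L) input_hw <- c(input_hw, input_hw)
  h <- input_hw[1]; w <- input_hw[2]
  rows <- list()
  cin <- arch$input_channels
  if (!is.null(arch$stem)) {
    h <- out_hw(h, arch$stem$stride); w <- out_hw(w, arch$stem$stride)
    rows <- c(rows, conv_bn_act(cin, arch$stem$cout, arch$stem$kernel,
                                arch$stem$kernel, 1, h, w, stage = "stem"))
    cin <- arch$stem$cout
  }
  if (!is.null(arch$blocks)) {
    for (i in seq_along(arch$blocks)) {
      lo <- lower_block(arch$blocks[[i]], h, w, stage = sprintf("block%02d", i))
      rows <- c(rows, lo$rows)
      h <- lo$h; w <- lo$w; cin <- lo$cout
    }
  }
  if (!is.null(arch$cells)) {
    lo <- lower_cells(arch, h, w)
    rows <- c(rows, lo$rows)
    h <- lo$h; w <- lo$w; cin <- lo$cout
  }
  head <- arch$head
  if (!is.null(head$conv_width)) {
    rows <- c(rows, conv_bn_act(cin, head$conv_width, 1, 1, 1, h, w, stage = "head"))
    cin <- head$conv_width
  }
  rows <- c(rows, list(prim("global_pool", cout = cin, h = 1, w = 1, stage = "head"),
                       prim("fc", cin, head$num_classes, bias = TRUE, stage = "head")))
  layers <- do.call(rbind, rows)
  macs <- sum(layers$macs)
  flops <- if (convention == "profiler") macs + sum(layers$extra_ops) else macs
  params <- sum(layers$params)
  report <- list(flops = flops, params = params, depth = count_depth(arch),
                 macs = macs, flops_g = flops / 1e9, params_m = params / 1e6,
                 input_hw = input_hw, convention = convention, layers = layers)
  class(report) <- "complexity_report"
  report
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("complexity report (%s, input %dx%d)\n", x$convention,
              x$input_hw[1], x$input_hw[2]))
  cat(sprintf("  FLOPs : %.3f x 10^9\n", x$flops_g))
  cat(sprintf("  params: %.3f x 10^6\n", x$params_m))
  cat(sprintf("  depth : %d weighted stages\n", x$depth))
  invisible(x)
}

#' Weighted-stage depth of an architecture
#'
#' Counts the stem convolution (1), three weighted stages per block, and the
#' classification head (1; an optional feature-mixing 1x1 convolution plus
#' the pooled linear classifier form one classification stage). The 16-block
#' one-shot family therefore has depth 1 + 48 + 1 = 50. Blocks that omit the
#' expansion convolution contribute two stages. For cell-based
#' architectures, each cell counts as one stage.
#'
#' @param arch An architecture specification.
#' @return Integer depth.
#' @export
count_depth <- function(arch) {
  d <- 0L
  if (!is.null(arch$stem)) d <- d + 1L
  if (!is.null(arch$blocks))
    d <- d + sum(vapply(arch$blocks, function(b)
      if (block_has_expand_conv(b)) 3L else 2L, integer(1)))
  if (!is.null(arch$cells)) d <- d + arch$cells$num_cells
  d + 1L
}

#' Architecture specification container
#'
#' @param name Human-readable model name.
#' @param stem List with `cout`, `kernel`, `stride` of the stem convolution.
#' @param blocks List of [block_spec()] objects (block-based networks).
#' @param cells Cell configuration (cell-based networks): list with
#'   `genotype`, `init_channels`, `num_cells`, `reduction_positions`,
#'   `num_nodes`.
#' @param head List with optional `conv_width` (feature-mixing 1x1
#'   convolution before pooling) and `num_classes`.
#' @param input_channels Image channels expected (1 for grayscale).
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(name, stem, blocks = NULL, cells = NULL,
                      head = list(conv_width = NULL, num_classes = 76L),
                      input_channels = 1L) {
  if (is.null(blocks) && is.null(cells))
    stop("under-specified architecture: needs blocks or cells", call. = FALSE)
  structure(list(name = name, input_channels = as.integer(input_channels),
                 stem = stem, blocks = blocks, cells = cells, head = head),
            class = "arch_spec")
}

# round to the nearest multiple of `divisor`, never below it
make_divisible <- function(x, divisor = 4L) {
  as.integer(max(divisor, round(x / divisor) * divisor))
}

#' Reference MobileNetV2 architecture specification
#'
#' The standard MobileNetV2 inverted-residual schedule (expansion 6 except
#' the first stage, 17 blocks, 1280-wide head convolution) with a
#' classification head of `num_classes` outputs, used as the complexity
#' reference baseline.
#'
#' @param width_mult Global channel width multiplier.
#' @param num_classes Classifier width (76 age bins by default).
#' @param input_channels Image channels (3 for the RGB-trained reference).
#' @return An `arch_spec`.
#' @export
build_mobilenet_v2 <- function(width_mult = 1, num_classes = 76L, input_channels = 3L) {
  schedule <- list(  # t (expand), c (cout), n (repeats), s (first stride)
    c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
    c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  stem_c <- make_divisible(32 * width_mult, 8L)
  blocks <- list()
  cin <- stem_c
  for (st in schedule) {
    cout <- make_divisible(st[2] * width_mult, 8L)
    for (i in seq_len(st[3])) {
      blocks[[length(blocks) + 1L]] <- block_spec(
        "mbconv", cin = cin, cout = cout, stride = if (i == 1L) st[4] else 1L,
        expand = st[1], kernel = 3L, force_expand = FALSE)
      cin <- cout
    }
  }
  head_c <- if (width_mult > 1) make_divisible(1280 * width_mult, 8L) else 1280L
  arch_spec(sprintf("MobileNetV2 (%.1fx)", width_mult),
            stem = list(cout = stem_c, kernel = 3L, stride = 2L),
            blocks = blocks,
            head = list(conv_width = head_c, num_classes = as.integer(num_classes)),
            input_channels = input_channels)
}
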