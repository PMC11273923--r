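# Single-path one-shot supernet engine.
#
# The search space stacks 16 choice layers, each holding three candidate
# blocks: mbconv with a 3x3 depthwise kernel (choice 0), mbconv with 5x5
# (choice 1), and the parallel asymmetric convolution block (choice 2).
# Training activates one uniformly sampled path per mini-batch; the discrete
# search stage is an evolutionary algorithm over path codes under a FLOPs
# budget.

PATH_CHOICES <- c("mbconv_k3", "mbconv_k5", "parallel_asym")

#' Path code through the one-shot search space
#'
#' @param choices Integer vector with entries in {0, 1, 2}: 0 = mbconv 3x3,
#'   1 = mbconv 5x5, 2 = parallel asymmetric block.
#' @param num_layers Expected length (16 for the full space).
#' @return An object of class `path_code`.
#' @export
path_code <- function(choices, num_layers = 16L) {
  choices <- as.integer(choices)
  if (length(choices) != num_layers)
    stop("path code must have length ", num_layers, call. = FALSE)
  if (!all(choices %in% 0:2))
    stop("path code entries must be in {0, 1, 2}", call. = FALSE)
  structure(list(choices = choices), class = "path_code")
}

#' The packaged AGE-SPOS path code
#'
#' The searched 16-block architecture places parallel asymmetric convolution
#' blocks in half of the 16 slots (the textual finding of the search); the
#' exact slot order is a synthetic transcription -- the asymmetric blocks
#' occupy the even slots and the mbconv blocks alternate between 3x3 and 5x5
#' kernels -- because the original layout is published only as a figure.
#'
#' @return A [path_code()] of length 16 with eight parallel-asym entries.
#' @export
agespos_published_path <- function() {
  path_code(rep(c(0L, 2L, 1L, 2L), 4L))
}

#' Supernet stage plan
#'
#' Per-layer channel/stride/expansion schedule of the one-shot space: a
#' MobileNetV2-style schedule trimmed to exactly 16 blocks (the 96-channel
#' stage carries two blocks instead of three), a width-scaled stem, a fixed
#' 1152-wide head convolution (the head width is not scaled by the
#' multiplier; its value is reconstructed from the published complexity of
#' the three width variants, which agree on it to within a few channels)
#' and a 76-way classifier. Channel counts scale
#' with `width_mult` and round to multiples of 4 so the half- and
#' 1.5-width variants scale exactly. Realized depth is 50 weighted stages:
#' stem (1) + 16 blocks x 3 + classification head (1).
#'
#' @param width_mult Width multiplier (0.5, 1.0 and 1.5 are the published
#'   variants).
#' @param num_classes Classifier width.
#' @param use_se Build blocks with Squeeze-Excitation modules.
#' @param input_channels Image channels.
#' @return An object of class `supernet_plan`.
#' @export
supernet_plan <- function(width_mult = 1, num_classes = 76L, use_se = FALSE,
                          input_channels = 3L) {
  schedule <- list(  # t (expand), c (cout), n (repeats), s (first stride)
    c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
    c(6, 96, 2, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  stem_c <- make_divisible(32 * width_mult, 4L)
  layers <- list()
  cin <- stem_c
  for (st in schedule) {
    cout <- make_divisible(st[2] * width_mult, 4L)
    for (i in seq_len(st[3])) {
      layers[[length(layers) + 1L]] <- list(
        cin = cin, cout = cout, stride = if (i == 1L) as.integer(st[4]) else 1L,
        expand = st[1])
      cin <- cout
    }
  }
  stopifnot(length(layers) == 16L)
  structure(list(width_mult = width_mult, stem = list(cout = stem_c, kernel = 3L,
                                                      stride = 2L),
                 layers = layers, head_conv = 1152L,
                 num_classes = as.integer(num_classes), use_se = isTRUE(use_se),
                 input_channels = as.integer(input_channels)),
            class = "supernet_plan")
}

#' Reduced stage plan for desk-scale experiments
#'
#' A small plan with an arbitrary number of choice layers, used for tests
#' and toy searches; the canonical 16-layer space is [supernet_plan()].
#'
#' @param couts Per-layer output channels.
#' @param strides Per-layer strides.
#' @param expands Per-layer expansion ratios.
#' @param stem_c Stem width.
#' @param head_conv Head convolution width.
#' @param num_classes Classifier width.
#' @param use_se Build blocks with SE modules.
#' @param input_channels Image channels.
#' @return A `supernet_plan` with `length(couts)` layers.
#' @export
toy_supernet_plan <- function(couts, strides = rep(1L, length(couts)),
                              expands = rep(2, length(couts)), stem_c = 8L,
                              head_conv = 32L, num_classes = 76L, use_se = FALSE,
                              input_channels = 1L) {
  cin <- stem_c
  layers <- list()
  for (i in seq_along(couts)) {
    layers[[i]] <- list(cin = cin, cout = as.integer(couts[i]),
                        stride = as.integer(strides[i]), expand = expands[i])
    cin <- as.integer(couts[i])
  }
  structure(list(width_mult = 1, stem = list(cout = as.integer(stem_c), kernel = 3L,
                                             stride = 1L),
                 layers = layers, head_conv = as.integer(head_conv),
                 num_classes = as.integer(num_classes), use_se = isTRUE(use_se),
                 input_channels = as.integer(input_channels)),
            class = "supernet_plan")
}

plan_block_spec <- function(plan, layer_index, choice) {
  ly <- plan$layers[[layer_index]]
  kind <- PATH_CHOICES[choice + 1L]
  if (kind == "parallel_asym")
    block_spec("parallel_asym", ly$cin, ly$cout, ly$stride, ly$expand,
               use_se = plan$use_se, force_expand = TRUE)
  else
    block_spec("mbconv", ly$cin, ly$cout, ly$stride, ly$expand,
               kernel = if (kind == "mbconv_k5") 5L else 3L,
               use_se = plan$use_se, force_expand = TRUE)
}

#' Realize a path through a plan as an architecture specification
#'
#' @param plan A [supernet_plan()].
#' @param path A [path_code()] of matching length.
#' @param name Model name recorded in the spec.
#' @return An [arch_spec()] consumable by [count_network()] and the trainer.
#' @export
realize_path_arch <- function(plan, path, name = "AGE-SPOS") {
  stopifnot(inherits(plan, "supernet_plan"), inherits(path, "path_code"),
            length(path$choices) == length(plan$layers))
  blocks <- lapply(seq_along(plan$layers), function(i)
    plan_block_spec(plan, i, path$choices[i]))
  arch_spec(name, stem = plan$stem, blocks = blocks,
            head = list(conv_width = plan$head_conv, num_classes = plan$num_classes),
            input_channels = plan$input_channels)
}

#' Build the searched AGE-SPOS architecture
#'
#' @param path A [path_code()]; defaults to the packaged searched path.
#' @param width_mult Width multiplier (0.5, 1.0, 1.5 published).
#' @param num_classes Classifier width.
#' @param use_se Include SE modules.
#' @param input_channels Image channels.
#' @return An [arch_spec()].
#' @export
#' @examples
#' count_network(build_age_spos(width_mult = 1), 384)
build_age_spos <- function(path = agespos_published_path(), width_mult = 1,
                           num_classes = 76L, use_se = FALSE, input_channels = 3L) {
  plan <- supernet_plan(width_mult, num_classes, use_se, input_channels)
  realize_path_arch(plan, path, sprintf("AGE-SPOS (%.1fx)", width_mult))
}

# --- runtime supernet -------------------------------------------------------

make_stem_module <- function(stem, input_channels) {
  nn_sequential(nn_conv2d(input_channels, stem$cout, stem$kernel, stem$kernel,
                          stride = stem$stride),
                nn_batchnorm(stem$cout), nn_activation("relu6"))
}

make_head_module <- function(cin, head_conv, num_classes) {
  new_module(
    "head",
    children = c(
      if (!is.null(head_conv)) list(conv = nn_sequential(
        nn_conv2d(cin, head_conv, 1, 1), nn_batchnorm(head_conv),
        nn_activation("relu6"))),
      list(pool = nn_global_pool(),
           fc = nn_linear(if (is.null(head_conv)) cin else head_conv, num_classes,
                          bias = TRUE))),
    fwd = function(self, x, train) {
      ch <- self$children
      if (!is.null(ch$conv)) x <- nn_forward(ch$conv, x, train)
      nn_forward(ch$fc, nn_forward(ch$pool, x, train), train)
    },
    bwd = function(self, dy) {
      ch <- self$children
      dx <- nn_backward(ch$pool, nn_backward(ch$fc, dy))
      if (!is.null(ch$conv)) dx <- nn_backward(ch$conv, dx)
      dx
    })
}

#' Build the weight-sharing supernet
#'
#' Each choice layer holds three independently parameterized candidate
#' blocks; the stem and head are shared. Any path code induces a valid
#' forward pass through one block per layer.
#'
#' @param plan A [supernet_plan()].
#' @return A `supernet` object.
#' @export
build_supernet <- function(plan) {
  stopifnot(inherits(plan, "supernet_plan"))
  stem <- make_stem_module(plan$stem, plan$input_channels)
  layers <- lapply(seq_along(plan$layers), function(i)
    lapply(0:2, function(ch) make_block(plan_block_spec(plan, i, ch))))
  last_c <- plan$layers[[length(plan$layers)]]$cout
  head <- make_head_module(last_c, plan$head_conv, plan$num_classes)
  structure(list(plan = plan, stem = stem, layers = layers, head = head),
            class = "supernet")
}

#' Forward pass of the supernet along one path
#'
#' @param sup A `supernet`.
#' @param x Input batch, array `(H, W, N, C)`.
#' @param path A [path_code()].
#' @param train Use batch statistics and cache for backward.
#' @return Logits matrix `N x num_classes`.
#' @export
supernet_forward <- function(sup, x, path, train = TRUE) {
  h <- nn_forward(sup$stem, x, train)
  for (i in seq_along(sup$layers))
    h <- nn_forward(sup$layers[[i]][[path$choices[i] + 1L]], h, train)
  nn_forward(sup$head, h, train)
}

supernet_backward <- function(sup, path, dlogits) {
  dh <- nn_backward(sup$head, dlogits)
  for (i in rev(seq_along(sup$layers)))
    dh <- nn_backward(sup$layers[[i]][[path$choices[i] + 1L]], dh)
  nn_backward(sup$stem, dh)
}

supernet_path_params <- function(sup, path) {
  ps <- c(nn_params(sup$stem), nn_params(sup$head))
  for (i in seq_along(sup$layers))
    ps <- c(ps, nn_params(sup$layers[[i]][[path$choices[i] + 1L]]))
  ps
}

supernet_all_params <- function(sup) {
  ps <- c(nn_params(sup$stem), nn_params(sup$head))
  for (layer in sup$layers) for (b in layer) ps <- c(ps, nn_params(b))
  ps
}

#' Sample a uniform random path
#'
#' Draws each layer's choice i.i.d. uniformly over the three candidates,
#' using R's global random number stream (seed with [set.seed()]).
#'
#' @param num_layers Number of choice layers.
#' @return A [path_code()].
#' @export
sample_path <- function(num_layers = 16L) {
  path_code(sample(0:2, num_layers, replace = TRUE), num_layers)
}

#' Train the one-shot supernet with uniform path sampling
#'
#' Per mini-batch, one uniformly sampled path is activated and only its
#' parameters (plus the shared stem and head) receive gradient updates.
#' The objective is cross-entropy of the label-smoothed age distribution
#' (momentum SGD).
#'
#' @param sup A supernet from [build_supernet()].
#' @param data List with `x` (array `(H, W, N, C)`) and `age` (integer
#'   vector).
#' @param num_batches Number of mini-batches (20,000 at full scale).
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate (cosine-annealed to 0).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty.
#' @param label_eps Label-smoothing mass.
#' @param seed Seed governing path sampling and batch order.
#' @return The supernet (updated in place) with a `loss_log` attribute.
#' @export
train_supernet <- function(sup, data, num_batches = 200L, batch_size = 16L,
                           lr = 0.1, momentum = 0.9, weight_decay = 4e-5,
                           label_eps = 0.1, seed = 1L) {
  set.seed(seed)
  n <- dim(data$x)[3]
  k <- sup$plan$num_classes
  losses <- numeric(num_batches)
  for (b in seq_len(num_batches)) {
    idx <- sample.int(n, min(batch_size, n))
    xb <- data$x[, , idx, , drop = FALSE]
    targets <- t(vapply(data$age[idx], function(a)
      label_smoothing_target(a, k, label_eps)$probs, numeric(k)))
    path <- sample_path(length(sup$layers))
    logits <- supernet_forward(sup, xb, path, train = TRUE)
    ls <- softmax_xent(logits, targets)
    losses[b] <- ls$loss
    ps <- supernet_path_params(sup, path)
    for (p in ps) p$g <- NULL
    supernet_backward(sup, path, ls$dlogits)
    lr_b <- lr * 0.5 * (1 + cos(pi * (b - 1) / num_batches))
    opt_sgd_step(ps, lr_b, momentum, weight_decay)
  }
  attr(sup, "loss_log") <- losses
  sup
}

# deep copy of parameter values from one module tree into another of
# identical structure
copy_weights <- function(dst, src) {
  pd <- nn_params(dst)
  psrc <- nn_params(src)
  stopifnot(length(pd) == length(psrc))
  for (i in seq_along(pd)) pd[[i]]$v <- psrc[[i]]$v
  copy_bn_stats(dst, src)
  invisible(dst)
}

copy_bn_stats <- function(dst, src) {
  if (identical(dst$kind, "batchnorm")) {
    dst$run_mean <- src$run_mean
    dst$run_var <- src$run_var
  }
  stopifnot(length(dst$children) == length(src$children))
  for (i in seq_along(dst$children)) copy_bn_stats(dst$children[[i]], src$children[[i]])
  invisible(dst)
}

#' Extract a standalone network for one path of a trained supernet
#'
#' Builds the standalone network of the path and copies the supernet's
#' weights (stem, the chosen block of every layer, head) into it; the
#' standalone forward pass reproduces the supernet forward pass exactly.
#'
#' @param sup A supernet.
#' @param path A [path_code()].
#' @return A runtime network (see [build_network_from_spec()]).
#' @export
extract_path_network <- function(sup, path) {
  plan <- sup$plan
  net <- build_network_from_plan(plan, path)
  copy_weights(net$stem, sup$stem)
  for (i in seq_along(sup$layers))
    copy_weights(net$blocks[[i]], sup$layers[[i]][[path$choices[i] + 1L]])
  copy_weights(net$head, sup$head)
  net
}

build_network_from_plan <- function(plan, path) {
  stem <- make_stem_module(plan$stem, plan$input_channels)
  blocks <- lapply(seq_along(plan$layers), function(i)
    make_block(plan_block_spec(plan, i, path$choices[i])))
  last_c <- plan$layers[[length(plan$layers)]]$cout
  head <- make_head_module(last_c, plan$head_conv, plan$num_classes)
  structure(list(stem = stem, blocks = blocks, head = head,
                 num_classes = plan$num_classes, input_channels = plan$input_channels),
            class = "age_network")
}

#' Evolution configuration for the discrete search stage
#'
#' @param population Population size.
#' @param generations Number of generations.
#' @param mutation_prob Per-locus mutation probability.
#' @param crossover_prob Probability an offspring is produced by single-point
#'   crossover (otherwise a mutated elite).
#' @param flops_budget Upper bound on multiply-accumulate count of a
#'   candidate (profiler convention, raw operations).
#' @param topk Number of elites retained and returned.
#' @return An object of class `evo_config`.
#' @export
evo_config <- function(population = 50L, generations = 20L, mutation_prob = 0.1,
                       crossover_prob = 0.5, flops_budget = Inf, topk = 10L) {
  stopifnot(population >= topk, topk >= 1L)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_prob = mutation_prob, crossover_prob = crossover_prob,
                 flops_budget = flops_budget, topk = as.integer(topk)),
            class = "evo_config")
}

path_flops <- function(plan, path, input_hw) {
  count_network(realize_path_arch(plan, path), input_hw)$flops
}

#' Evolutionary search over path codes of a trained supernet
#'
#' Ranks paths by validation mean absolute error of the DEX age prediction
#' under the shared supernet weights, among candidates whose realized
#' network satisfies the FLOPs budget. Offspring arise by single-point
#' crossover and per-locus mutation; elites are retained across
#' generations. Deterministic given `seed`.
#'
#' @param sup A trained supernet.
#' @param val_data List with `x` and `age` as in [train_supernet()].
#' @param evo An [evo_config()].
#' @param input_hw Input size used for the FLOPs constraint.
#' @param seed Random seed.
#' @return List of `list(path, mae, flops)` of length `evo$topk`, best
#'   first.
#' @export
evolutionary_search <- function(sup, val_data, evo, input_hw = dim(val_data$x)[1],
                                seed = 1L) {
  set.seed(seed)
  plan <- sup$plan
  nl <- length(plan$layers)
  feasible <- function(p) path_flops(plan, p, input_hw) <= evo$flops_budget
  eval_path <- function(p) {
    preds <- dex_expected_age_batch(
      softmax_rows(supernet_forward(sup, val_data$x, p, train = FALSE)))
    mae(preds, val_data$age)
  }
  draw_feasible <- function() {
    for (i in 1:1000) {
      p <- sample_path(nl)
      if (feasible(p)) return(p)
    }
    stop("infeasible FLOPs budget: no sampled path satisfies it", call. = FALSE)
  }
  pop <- replicate(evo$population, draw_feasible(), simplify = FALSE)
  seen <- new.env(parent = emptyenv())
  score <- function(p) {
    key <- paste(p$choices, collapse = "")
    if (is.null(seen[[key]])) seen[[key]] <- eval_path(p)
    seen[[key]]
  }
  elites <- list()
  for (g in seq_len(evo$generations)) {
    scored <- lapply(pop, function(p) list(path = p, mae = score(p)))
    all_sc <- c(elites, scored)
    ord <- order(vapply(all_sc, `[[`, numeric(1), "mae"))
    keys <- vapply(all_sc, function(s) paste(s$path$choices, collapse = ""), character(1))
    keep <- ord[!duplicated(keys[ord])]
    elites <- all_sc[keep[seq_len(min(evo$topk, length(keep)))]]
    offspring <- list()
    while (length(offspring) < evo$population) {
      if (stats::runif(1) < evo$crossover_prob && length(elites) >= 2L) {
        pr <- sample.int(length(elites), 2L)
        cut <- sample.int(nl - 1L, 1L)
        ch <- c(elites[[pr[1]]]$path$choices[seq_len(cut)],
                elites[[pr[2]]]$path$choices[(cut + 1L):nl])
      } else {
        ch <- elites[[sample.int(length(elites), 1L)]]$path$choices
      }
      mut <- stats::runif(nl) < evo$mutation_prob
      if (any(mut)) ch[mut] <- sample(0:2, sum(mut), replace = TRUE)
      cand <- path_code(ch, nl)
      if (feasible(cand)) offspring[[length(offspring) + 1L]] <- cand
    }
    pop <- offspring
  }
  lapply(elites, function(e)
    list(path = e$path, mae = e$mae, flops = path_flops(plan, e$path, input_hw)))
}
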