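# Differentiable cell-based search with partial channel connections.
#
# The search network stacks cells; each cell is a DAG whose edges carry a
# softmax-weighted mixture of candidate operators (architecture weights
# alpha), with only a sampled fraction of channels routed through the
# mixture (channel mask S) and the remainder bypassed unchanged; incoming
# edges of a node are combined with a second softmax over edge-normalization
# weights beta.  Network weights and architecture weights are optimized
# alternately on disjoint data splits.

#' Softmax-weighted mixture of candidate operators on one edge
#'
#' Computes `sum_o softmax(alpha)_o * o(x)`.
#'
#' @param x Input feature map, array `(H, W, N, C)`.
#' @param alpha_edge Real vector, one entry per operator.
#' @param ops List of runtime operator modules (see [make_operator()]), all
#'   channel-compatible with `x` and sharing an output shape.
#' @param train Forward in training mode.
#' @return The mixed feature map.
#' @export
mixed_edge_forward <- function(x, alpha_edge, ops, train = TRUE) {
  stopifnot(length(alpha_edge) == length(ops), length(ops) >= 1L)
  w <- softmax_vec(alpha_edge)
  out <- NULL
  for (k in seq_along(ops)) {
    yk <- nn_forward(ops[[k]], x, train)
    out <- if (is.null(out)) w[k] * yk else {
      if (!identical(dim(out), dim(yk)))
        stop("operator output shapes disagree on the edge", call. = FALSE)
      out + w[k] * yk
    }
  }
  out
}

softmax_vec <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

#' Partial-channel mixed edge
#'
#' Channels selected by the binary mask go through the operator mixture of
#' [mixed_edge_forward()]; masked-out channels pass through unchanged, and
#' the channels are recombined in their original order. With an all-ones
#' mask this reduces exactly to the full mixture; with an all-zeros mask the
#' input is returned unchanged.
#'
#' @param x Input feature map `(H, W, N, C)`.
#' @param alpha_edge Operator weight vector.
#' @param mask Binary vector of length `C`.
#' @param ops Operator modules built for `sum(mask)` channels (stride 1).
#' @param train Forward in training mode.
#' @return Feature map of the same shape as `x`.
#' @export
partial_mixed_edge_forward <- function(x, alpha_edge, mask, ops, train = TRUE) {
  d <- tensor_dims(x)
  stopifnot(length(mask) == d$c, all(mask %in% c(0, 1)))
  sel <- which(mask == 1)
  if (length(sel) == 0L) return(x)
  mixed <- mixed_edge_forward(x[, , , sel, drop = FALSE], alpha_edge, ops, train)
  out <- x
  out[, , , sel] <- mixed
  out
}

#' Edge-normalized node aggregation
#'
#' `x_j = sum_i softmax(beta)_i * f_i`, the combination of a node's incoming
#' edge outputs weighted by the softmax of the edge-normalization weights.
#'
#' @param edge_outputs List of feature maps with identical shapes.
#' @param beta Real vector, one entry per incoming edge.
#' @return The aggregated feature map.
#' @export
node_aggregate <- function(edge_outputs, beta) {
  if (length(edge_outputs) == 0L)
    stop("node has no incoming edges", call. = FALSE)
  stopifnot(length(beta) == length(edge_outputs))
  w <- softmax_vec(beta)
  out <- w[1] * edge_outputs[[1]]
  for (i in seq_along(edge_outputs)[-1]) out <- out + w[i] * edge_outputs[[i]]
  out
}

#' Search network configuration
#'
#' @param num_cells Number of stacked cells (8 at full scale).
#' @param reduction_positions 1-indexed cell slots that are reduction cells
#'   (`c(1, 3, 6)` at full scale); reduction cells double the channel count
#'   and halve the resolution.
#' @param init_channels Base channel count.
#' @param num_nodes Intermediate nodes per cell.
#' @param operators Character vector of operator names from
#'   [list_search_operators()].
#' @param sample_ratio Fraction of channels routed through the operator
#'   mixture on each edge.
#' @param num_classes Classifier width.
#' @param input_channels Image channels.
#' @return An object of class `search_network_config`.
#' @export
search_network_config <- function(num_cells = 8L, reduction_positions = c(1L, 3L, 6L),
                                  init_channels = 16L, num_nodes = 4L,
                                  operators = search_operator_names(),
                                  sample_ratio = 0.25, num_classes = 76L,
                                  input_channels = 1L) {
  stopifnot(all(reduction_positions %in% seq_len(num_cells)),
            all(operators %in% search_operator_names()),
            sample_ratio > 0, sample_ratio <= 1)
  structure(list(num_cells = as.integer(num_cells),
                 reduction_positions = as.integer(reduction_positions),
                 init_channels = as.integer(init_channels),
                 num_nodes = as.integer(num_nodes), operators = operators,
                 sample_ratio = sample_ratio, num_classes = as.integer(num_classes),
                 input_channels = as.integer(input_channels)),
            class = "search_network_config")
}

# edges of a cell with n intermediate nodes: (i, j) for every j = 2..n+1
# (node ids 0,1 are the two cell inputs) and every i < j
cell_edges <- function(num_nodes) {
  out <- list()
  for (j in seq_len(num_nodes) + 1L)
    for (i in 0:(j - 1L))
      out[[length(out) + 1L]] <- c(i = i, j = j)
  out
}

edge_key <- function(i, j) sprintf("%d_%d", i, j)

#' Initialize architecture parameters
#'
#' One alpha vector (over the operator set) and one beta scalar per DAG
#' edge, for the normal-cell table and, if reduction cells exist, a second
#' table shared by the reduction cells. Alphas start near zero so the
#' initial mixture is near-uniform.
#'
#' @param cfg A [search_network_config()].
#' @param seed Seed for the small symmetry-breaking noise.
#' @return An object of class `arch_params`.
#' @export
init_arch_params <- function(cfg, seed = 1L) {
  set.seed(seed)
  mk_table <- function() {
    edges <- cell_edges(cfg$num_nodes)
    alpha <- lapply(edges, function(e)
      nn_param(stats::rnorm(length(cfg$operators), sd = 1e-3)))
    beta <- lapply(edges, function(e) nn_param(stats::rnorm(1, sd = 1e-3)))
    names(alpha) <- names(beta) <- vapply(edges, function(e) edge_key(e[1], e[2]),
                                          character(1))
    list(alpha = alpha, beta = beta, edges = edges)
  }
  tabs <- list(normal = mk_table())
  if (length(cfg$reduction_positions) > 0L) tabs$reduce <- mk_table()
  structure(c(tabs, list(sample_ratio = cfg$sample_ratio, operators = cfg$operators)),
            class = "arch_params")
}

arch_param_list <- function(params) {
  out <- list()
  for (tab in intersect(c("normal", "reduce"), names(params)))
    out <- c(out, params[[tab]]$alpha, params[[tab]]$beta)
  out
}

#' Softmax operator weights of every edge
#'
#' @param params An `arch_params` object.
#' @param table `"normal"` or `"reduce"`.
#' @return Named list of softmax weight vectors (one per edge, operators in
#'   registry order).
#' @export
arch_softmax_weights <- function(params, table = "normal") {
  lapply(params[[table]]$alpha, function(a) {
    w <- softmax_vec(a$v)
    names(w) <- params$operators
    w
  })
}

# --- search cell runtime ----------------------------------------------------

# Per-edge partial mixed operator: ops instantiated at the masked channel
# count; a fresh channel permutation is drawn each forward pass.
make_partial_mixed_op <- function(channels, mc, op_names, stride) {
  ops <- lapply(op_names, function(nm) make_operator(op_spec_by_name(nm), mc, stride))
  bypass_pool <- if (stride > 1L) nn_pool("avg", 2L, stride)
  new_module(
    "partial_mixed", children = c(ops, if (!is.null(bypass_pool)) list(bypass_pool)),
    channels = channels, mc = mc, stride = stride, n_ops = length(ops),
    fwd = function(self, x, train) {
      ch <- self$children
      perm <- sample.int(self$channels)
      sel <- perm[seq_len(self$mc)]
      rest <- perm[-seq_len(self$mc)]
      xa <- x[, , , sel, drop = FALSE]
      op_outs <- lapply(seq_len(self$n_ops), function(k)
        nn_forward(ch[[k]], xa, train))
      mix <- self$w[1] * op_outs[[1]]
      if (self$n_ops > 1L)
        for (k in 2:self$n_ops) mix <- mix + self$w[k] * op_outs[[k]]
      dm <- dim(mix)
      out <- array(0, dim = c(dm[1], dm[2], dm[3], self$channels))
      out[, , , sel] <- mix
      if (length(rest) > 0L) {
        xb <- x[, , , rest, drop = FALSE]
        if (self$stride > 1L) xb <- nn_forward(ch[[self$n_ops + 1L]], xb, train)
        out[, , , rest] <- xb
      }
      self$cache <- list(sel = sel, rest = rest, op_outs = op_outs, dim_x = dim(x))
      out
    },
    bwd = function(self, dy) {
      cc <- self$cache
      ch <- self$children
      dmix <- dy[, , , cc$sel, drop = FALSE]
      # gradient w.r.t. the mixture weights, harvested by the engine
      self$dw <- vapply(cc$op_outs, function(o) sum(o * dmix), numeric(1))
      dxa <- NULL
      for (k in seq_len(self$n_ops)) {
        g <- nn_backward(ch[[k]], self$w[k] * dmix)
        dxa <- if (is.null(dxa)) g else dxa + g
      }
      dx <- array(0, dim = cc$dim_x)
      dx[, , , cc$sel] <- dxa
      if (length(cc$rest) > 0L) {
        db <- dy[, , , cc$rest, drop = FALSE]
        if (self$stride > 1L) db <- nn_backward(ch[[self$n_ops + 1L]], db)
        dx[, , , cc$rest] <- db
      }
      dx
    })
}

# preprocessing of a cell input: 1x1 conv (stride 2 when the source grid is
# larger than the cell's working grid) + batch norm
make_preprocess <- function(cin, cout, stride = 1L) {
  nn_sequential(nn_conv2d(cin, cout, 1, 1, stride = stride), nn_batchnorm(cout))
}

make_search_cell <- function(cfg, c_prev_prev, c_prev, C, reduction, prev_reduction) {
  edges <- cell_edges(cfg$num_nodes)
  mc <- max(1L, as.integer(round(C * cfg$sample_ratio)))
  pre0 <- make_preprocess(c_prev_prev, C, stride = if (prev_reduction) 2L else 1L)
  pre1 <- make_preprocess(c_prev, C)
  mops <- lapply(edges, function(e) {
    stride <- if (reduction && e[1] < 2L) 2L else 1L
    make_partial_mixed_op(C, mc, cfg$operators, stride)
  })
  names(mops) <- vapply(edges, function(e) edge_key(e[1], e[2]), character(1))
  new_module(
    "search_cell", children = c(list(pre0 = pre0, pre1 = pre1), mops),
    cfg = cfg, edges = edges, C = C, reduction = reduction,
    fwd = function(self, inputs, train) {
      ch <- self$children
      states <- list(nn_forward(ch$pre0, inputs[[1]], train),
                     nn_forward(ch$pre1, inputs[[2]], train))
      edge_outs <- list()
      for (j in seq_len(self$cfg$num_nodes) + 1L) {
        outs <- list()
        for (i in 0:(j - 1L)) {
          key <- edge_key(i, j)
          outs[[length(outs) + 1L]] <- nn_forward(ch[[key]], states[[i + 1L]], train)
          edge_outs[[key]] <- outs[[length(outs)]]
        }
        bw <- self$beta_w[[as.character(j)]]
        node <- bw[1] * outs[[1]]
        for (i in seq_along(outs)[-1]) node <- node + bw[i] * outs[[i]]
        states[[j + 1L]] <- node
      }
      self$cache <- list(edge_outs = edge_outs, n_states = length(states))
      d <- dim(states[[3]])
      out <- array(0, dim = c(d[1], d[2], d[3], self$C * self$cfg$num_nodes))
      for (n in seq_len(self$cfg$num_nodes))
        out[, , , (n - 1L) * self$C + seq_len(self$C)] <- states[[n + 2L]]
      out
    },
    bwd = function(self, dy) {
      ch <- self$children
      nn_ <- self$cfg$num_nodes
      dstates <- vector("list", self$cache$n_states)
      d <- dim(dy)
      for (n in seq_len(nn_))
        dstates[[n + 2L]] <- dy[, , , (n - 1L) * self$C + seq_len(self$C), drop = FALSE]
      self$dbeta <- list()
      for (j in rev(seq_len(nn_) + 1L)) {
        dnode <- dstates[[j + 1L]]
        bw <- self$beta_w[[as.character(j)]]
        dbw <- numeric(j)
        for (i in (j - 1L):0) {
          key <- edge_key(i, j)
          dbw[i + 1L] <- sum(dnode * self$cache$edge_outs[[key]])
          dedge <- nn_backward(ch[[key]], bw[i + 1L] * dnode)
          dstates[[i + 1L]] <- if (is.null(dstates[[i + 1L]])) dedge else
            dstates[[i + 1L]] + dedge
        }
        self$dbeta[[as.character(j)]] <- dbw
      }
      list(nn_backward(ch$pre0, dstates[[1L]]),
           nn_backward(ch$pre1, dstates[[2L]]))
    })
}

build_search_network <- function(cfg) {
  stem_c <- cfg$init_channels
  stem <- nn_sequential(nn_conv2d(cfg$input_channels, stem_c, 3, 3, stride = 2L),
                        nn_batchnorm(stem_c))
  cells <- list()
  C <- cfg$init_channels
  c_prev_prev <- stem_c
  c_prev <- stem_c
  prev_reduction <- FALSE
  for (pos in seq_len(cfg$num_cells)) {
    reduction <- pos %in% cfg$reduction_positions
    if (reduction) C <- 2L * C
    cell <- make_search_cell(cfg, c_prev_prev, c_prev, C, reduction, prev_reduction)
    cells[[pos]] <- cell
    c_prev_prev <- c_prev
    c_prev <- cfg$num_nodes * C
    prev_reduction <- reduction
  }
  head <- make_head_module(c_prev, NULL, cfg$num_classes)
  structure(list(cfg = cfg, stem = stem, cells = cells, head = head),
            class = "search_network")
}

# push current softmax(alpha)/softmax(beta) values into the cell modules
refresh_arch_weights <- function(net, params) {
  for (pos in seq_along(net$cells)) {
    cell <- net$cells[[pos]]
    tab <- if (cell$reduction && !is.null(params$reduce)) "reduce" else "normal"
    beta_by_node <- split_beta(params, tab, net$cfg$num_nodes)
    cell$beta_w <- lapply(beta_by_node, softmax_vec)
    for (e in cell$edges) {
      key <- edge_key(e[1], e[2])
      cell$children[[key]]$w <- softmax_vec(params[[tab]]$alpha[[key]]$v)
    }
  }
  invisible(net)
}

# beta scalars grouped by target node (softmax runs over incoming edges)
split_beta <- function(params, tab, num_nodes) {
  out <- list()
  for (j in seq_len(num_nodes) + 1L)
    out[[as.character(j)]] <- vapply(0:(j - 1L), function(i)
      params[[tab]]$beta[[edge_key(i, j)]]$v, numeric(1))
  out
}

# harvest mixture-weight gradients from the cells into alpha/beta grads
# (chain through the softmax Jacobian: da = w * (dw - sum(dw * w)))
softmax_grad <- function(w, dw) w * (dw - sum(dw * w))

collect_arch_grads <- function(net, params) {
  for (pos in seq_along(net$cells)) {
    cell <- net$cells[[pos]]
    tab <- if (cell$reduction && !is.null(params$reduce)) "reduce" else "normal"
    for (e in cell$edges) {
      key <- edge_key(e[1], e[2])
      mop <- cell$children[[key]]
      acc_grad(params[[tab]]$alpha[[key]], softmax_grad(mop$w, mop$dw))
    }
    for (j in seq_len(net$cfg$num_nodes) + 1L) {
      bw <- cell$beta_w[[as.character(j)]]
      dbw <- cell$dbeta[[as.character(j)]]
      db <- softmax_grad(bw, dbw)
      for (i in 0:(j - 1L))
        acc_grad(params[[tab]]$beta[[edge_key(i, j)]], db[i + 1L])
    }
  }
  invisible(params)
}

search_net_forward <- function(net, x, train = TRUE) {
  s <- nn_forward(net$stem, x, train)
  s0 <- s; s1 <- s
  for (cell in net$cells) {
    out <- nn_forward(cell, list(s0, s1), train)
    s0 <- s1; s1 <- out
  }
  nn_forward(net$head, s1, train)
}

search_net_backward <- function(net, dlogits) {
  ds1 <- nn_backward(net$head, dlogits)
  ds0 <- NULL
  for (cell in rev(net$cells)) {
    din <- nn_backward(cell, ds1)
    ds1 <- din[[2]]
    if (!is.null(ds0)) ds1 <- ds1 + ds0
    ds0 <- din[[1]]
  }
  dstem <- ds1
  if (!is.null(ds0)) dstem <- dstem + ds0
  nn_backward(net$stem, dstem)
}

search_net_weight_params <- function(net) {
  ps <- c(nn_params(net$stem), nn_params(net$head))
  for (cell in net$cells) ps <- c(ps, nn_params(cell))
  ps
}

#' Alternating bilevel architecture search
#'
#' Alternates momentum-SGD steps on the network weights (training split)
#' with adaptive-moment steps on the architecture weights alpha and beta
#' (validation split), both against the label-smoothed cross-entropy of the
#' age head. The channel mask of every edge is resampled each forward pass.
#' Deterministic given `seed`.
#'
#' @param train_data,val_data Lists with `x` (array `(H, W, N, C)`) and
#'   `age` (integer vector); the two splits of the search data (60/40 at
#'   full scale).
#' @param cfg A [search_network_config()].
#' @param steps Number of alternation steps.
#' @param batch_size Mini-batch size.
#' @param lr_w Network-weight learning rate (momentum SGD).
#' @param wd_w Network weight decay.
#' @param lr_arch Architecture learning rate (Adam).
#' @param wd_arch Architecture weight decay.
#' @param label_eps Label-smoothing mass.
#' @param seed Random seed.
#' @return List with `params` (final `arch_params`), `net` (the search
#'   network), `loss_log` (per-step train/val losses), and
#'   `alpha_trajectory` (per-step snapshots of the normal-cell softmax
#'   weights).
#' @export
bilevel_search <- function(train_data, val_data, cfg, steps = 50L, batch_size = 16L,
                           lr_w = 0.1, wd_w = 1e-4, lr_arch = 6e-4, wd_arch = 1e-3,
                           label_eps = 0.1, seed = 1L) {
  if (dim(train_data$x)[3] == 0L || dim(val_data$x)[3] == 0L)
    stop("empty data split", call. = FALSE)
  set.seed(seed)
  params <- init_arch_params(cfg, seed = seed)
  net <- build_search_network(cfg)
  wps <- search_net_weight_params(net)
  aps <- arch_param_list(params)
  k <- cfg$num_classes
  make_targets <- function(ages) t(vapply(ages, function(a)
    label_smoothing_target(a, k, label_eps)$probs, numeric(k)))
  one_batch <- function(data) {
    idx <- sample.int(dim(data$x)[3], min(batch_size, dim(data$x)[3]))
    list(x = data$x[, , idx, , drop = FALSE], t = make_targets(data$age[idx]))
  }
  log_rows <- data.frame(step = integer(), train_loss = numeric(),
                         val_loss = numeric())
  traj <- vector("list", steps)
  for (s in seq_len(steps)) {
    # (1) architecture step on the validation split
    refresh_arch_weights(net, params)
    b <- one_batch(val_data)
    logits <- search_net_forward(net, b$x, train = TRUE)
    lv <- softmax_xent(logits, b$t)
    for (p in c(wps, aps)) p$g <- NULL
    search_net_backward(net, lv$dlogits)
    collect_arch_grads(net, params)
    opt_adam_step(aps, lr_arch, weight_decay = wd_arch)
    # (2) weight step on the training split
    refresh_arch_weights(net, params)
    b <- one_batch(train_data)
    logits <- search_net_forward(net, b$x, train = TRUE)
    lt <- softmax_xent(logits, b$t)
    for (p in c(wps, aps)) p$g <- NULL
    search_net_backward(net, lt$dlogits)
    opt_sgd_step(wps, lr_w, momentum = 0.9, weight_decay = wd_w)
    log_rows <- rbind(log_rows, data.frame(step = s, train_loss = lt$loss,
                                           val_loss = lv$loss))
    traj[[s]] <- arch_softmax_weights(params, "normal")
  }
  list(params = params, net = net, loss_log = log_rows, alpha_trajectory = traj)
}

#' Discrete cell genotype
#'
#' @param normal List of `(op_name, source_node)` pairs, two per
#'   intermediate node, for normal cells.
#' @param reduce Same structure for reduction cells (may equal `normal`).
#' @param nodes Number of intermediate nodes.
#' @return An object of class `cell_genotype`.
#' @export
cell_genotype <- function(normal, reduce = normal, nodes = 4L) {
  check_conns <- function(conns) {
    stopifnot(length(conns) == 2L * nodes)
    for (idx in seq_along(conns)) {
      cn <- conns[[idx]]
      node <- (idx + 1L) %/% 2L + 1L  # target node id (2-based intermediate)
      stopifnot(cn[[1]] %in% setdiff(search_operator_names(), "zero"),
                cn[[2]] >= 0L, cn[[2]] < node)
    }
  }
  check_conns(normal); check_conns(reduce)
  structure(list(normal = normal, reduce = reduce, nodes = as.integer(nodes)),
            class = "cell_genotype")
}

#' Derive the discrete genotype from searched architecture parameters
#'
#' Per edge, the strongest non-zero operator (by softmax weight) is
#' selected; per intermediate node, the two incoming edges with the largest
#' `softmax(beta)_edge * max-operator-weight` score are kept, ties broken
#' toward the lower source index. The zero operator never appears in the
#' genotype.
#'
#' @param params An `arch_params` object (from [bilevel_search()]).
#' @param cfg The matching [search_network_config()].
#' @return A [cell_genotype()].
#' @export
derive_genotype <- function(params, cfg) {
  derive_table <- function(tab) {
    conns <- list()
    alpha_w <- arch_softmax_weights(params, tab)
    nz <- setdiff(cfg$operators, "zero")
    for (j in seq_len(cfg$num_nodes) + 1L) {
      bw <- softmax_vec(vapply(0:(j - 1L), function(i)
        params[[tab]]$beta[[edge_key(i, j)]]$v, numeric(1)))
      score <- op_best <- numeric(j)
      best_name <- character(j)
      for (i in 0:(j - 1L)) {
        w <- alpha_w[[edge_key(i, j)]][nz]
        op_best[i + 1L] <- max(w)
        best_name[i + 1L] <- nz[which.max(w)]
        score[i + 1L] <- bw[i + 1L] * op_best[i + 1L]
      }
      keep <- order(-score, 0:(j - 1L))[seq_len(min(2L, j))]
      for (i in sort(keep))
        conns[[length(conns) + 1L]] <- list(best_name[i], i - 1L)
    }
    conns
  }
  normal <- derive_table("normal")
  reduce <- if (!is.null(params$reduce)) derive_table("reduce") else normal
  cell_genotype(normal, reduce, cfg$num_nodes)
}

#' Build the AGENet architecture from a cell genotype
#'
#' Stacks eight cells (reduction cells at slots 1, 3 and 6 double the
#' channels and halve the resolution) on a stride-2 stem, with a pooled
#' 76-way DEX classification head. `init_channels = 36` gives AGENet-Small,
#' `54` AGENet-Large.
#'
#' @param genotype A [cell_genotype()].
#' @param init_channels Base channel count.
#' @param num_cells Number of cells.
#' @param reduction_positions Reduction slots (1-indexed).
#' @param num_classes Classifier width.
#' @param input_channels Image channels.
#' @return An [arch_spec()] consumable by [count_network()] and
#'   [build_network_from_spec()].
#' @export
build_agenet <- function(genotype, init_channels = 36L, num_cells = 8L,
                         reduction_positions = c(1L, 3L, 6L), num_classes = 76L,
                         input_channels = 3L) {
  stopifnot(inherits(genotype, "cell_genotype"))
  arch_spec(sprintf("AGENet (C=%d)", init_channels),
            stem = list(cout = as.integer(init_channels), kernel = 3L, stride = 2L),
            cells = list(genotype = genotype, init_channels = as.integer(init_channels),
                         num_cells = as.integer(num_cells),
                         reduction_positions = as.integer(reduction_positions),
                         num_nodes = genotype$nodes),
            head = list(conv_width = NULL, num_classes = as.integer(num_classes)),
            input_channels = as.integer(input_channels))
}

# --- discrete cell network runtime ------------------------------------------

make_discrete_cell <- function(genotype, C, reduction, c_prev_prev, c_prev,
                               prev_reduction) {
  conns <- if (reduction) genotype$reduce else genotype$normal
  pre0 <- make_preprocess(c_prev_prev, C, stride = if (prev_reduction) 2L else 1L)
  pre1 <- make_preprocess(c_prev, C)
  ops <- lapply(seq_along(conns), function(idx) {
    cn <- conns[[idx]]
    stride <- if (reduction && cn[[2]] < 2L) 2L else 1L
    make_operator(op_spec_by_name(cn[[1]]), C, stride)
  })
  new_module(
    "discrete_cell", children = c(list(pre0 = pre0, pre1 = pre1), ops),
    genotype = genotype, conns = conns, C = C, reduction = reduction,
    nodes = genotype$nodes,
    fwd = function(self, inputs, train) {
      ch <- self$children
      states <- list(nn_forward(ch$pre0, inputs[[1]], train),
                     nn_forward(ch$pre1, inputs[[2]], train))
      for (nd in seq_len(self$nodes)) {
        o1 <- nn_forward(ch[[2L + 2L * nd - 1L]], states[[self$conns[[2L * nd - 1L]][[2]] + 1L]], train)
        o2 <- nn_forward(ch[[2L + 2L * nd]], states[[self$conns[[2L * nd]][[2]] + 1L]], train)
        states[[nd + 2L]] <- o1 + o2
      }
      self$cache <- length(states)
      d <- dim(states[[3]])
      out <- array(0, dim = c(d[1], d[2], d[3], self$C * self$nodes))
      for (nd in seq_len(self$nodes))
        out[, , , (nd - 1L) * self$C + seq_len(self$C)] <- states[[nd + 2L]]
      out
    },
    bwd = function(self, dy) {
      ch <- self$children
      dstates <- vector("list", self$cache)
      for (nd in seq_len(self$nodes))
        dstates[[nd + 2L]] <- dy[, , , (nd - 1L) * self$C + seq_len(self$C), drop = FALSE]
      for (nd in rev(seq_len(self$nodes))) {
        dnode <- dstates[[nd + 2L]]
        for (ei in c(2L * nd, 2L * nd - 1L)) {
          src <- self$conns[[ei]][[2]] + 1L
          g <- nn_backward(ch[[2L + ei]], dnode)
          dstates[[src]] <- if (is.null(dstates[[src]])) g else dstates[[src]] + g
        }
      }
      list(nn_backward(ch$pre0, dstates[[1]]),
           nn_backward(ch$pre1, dstates[[2]]))
    })
}

build_cell_network_from_spec <- function(arch) {
  cfg <- arch$cells
  stem <- make_stem_module(arch$stem, arch$input_channels)
  cells <- list()
  C <- cfg$init_channels
  c_prev_prev <- arch$stem$cout
  c_prev <- arch$stem$cout
  prev_reduction <- FALSE
  for (pos in seq_len(cfg$num_cells)) {
    reduction <- pos %in% cfg$reduction_positions
    if (reduction) C <- 2L * C
    cells[[pos]] <- make_discrete_cell(cfg$genotype, C, reduction, c_prev_prev,
                                       c_prev, prev_reduction)
    c_prev_prev <- c_prev
    c_prev <- cfg$num_nodes * C
    prev_reduction <- reduction
  }
  head <- make_head_module(c_prev, arch$head$conv_width, arch$head$num_classes)
  structure(list(stem = stem, cells = cells, head = head,
                 num_classes = arch$head$num_classes,
                 input_channels = arch$input_channels),
            class = "cell_network")
}

#' @export
net_forward.cell_network <- function(net, x, train = TRUE) {
  s <- nn_forward(net$stem, x, train)
  s0 <- s; s1 <- s
  for (cell in net$cells) {
    out <- nn_forward(cell, list(s0, s1), train)
    s0 <- s1; s1 <- out
  }
  nn_forward(net$head, s1, train)
}

#' @export
net_backward.cell_network <- function(net, dlogits) {
  ds1 <- nn_backward(net$head, dlogits)
  ds0 <- NULL
  for (cell in rev(net$cells)) {
    din <- nn_backward(cell, ds1)
    ds1 <- din[[2]]
    if (!is.null(ds0)) ds1 <- ds1 + ds0
    ds0 <- din[[1]]
  }
  dstem <- ds1
  if (!is.null(ds0)) dstem <- dstem + ds0
  nn_backward(net$stem, dstem)
}

#' @export
net_params.cell_network <- function(net) {
  ps <- c(nn_params(net$stem), nn_params(net$head))
  for (cell in net$cells) ps <- c(ps, nn_params(cell))
  ps
}
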