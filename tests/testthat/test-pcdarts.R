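# Differentiable search: mixed-edge algebra, partial channel connections,
# edge normalization, architecture gradients, genotype derivation and the
# AGENet builder.

id_op <- function(ch) make_operator(agenas:::op_spec_by_name("identity"), ch, 1)
zero_op <- function(ch) make_operator(agenas:::op_spec_by_name("zero"), ch, 1)

test_that("mixed edge weights are the softmax of alpha", {
  set.seed(41)
  x <- rand_tensor(5, 5, 1, 3)
  # singleton: exactly that operator's output
  expect_identical(mixed_edge_forward(x, 0.7, list(id_op(3))), x)
  # identity + zero at equal alpha: half the input
  expect_equal(mixed_edge_forward(x, c(0, 0), list(id_op(3), zero_op(3))), 0.5 * x)
  # softmax(1,2,3) = (0.0900, 0.2447, 0.6652)
  y <- mixed_edge_forward(x, c(1, 2, 3), list(id_op(3), id_op(3), zero_op(3)))
  expect_equal(y, (0.0900 + 0.2447) * x, tolerance = 1e-3)
  w <- agenas:::softmax_vec(c(1, 2, 3))
  expect_equal(w, c(0.0900, 0.2447, 0.6652), tolerance = 1e-3)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("partial mixed edge reduces to the full mixture under an all-ones mask", {
  set.seed(42)
  x <- rand_tensor(6, 6, 2, 4)
  ops_full <- list(id_op(4), zero_op(4))
  alpha <- c(0.3, -0.2)
  full <- mixed_edge_forward(x, alpha, ops_full)
  expect_identical(partial_mixed_edge_forward(x, alpha, rep(1, 4), ops_full), full)
  # all-zeros mask: pure identity path
  expect_identical(partial_mixed_edge_forward(x, alpha, rep(0, 4), list()), x)
  # identity-only ops: unchanged under any mask
  mask <- c(1, 0, 1, 0)
  expect_identical(partial_mixed_edge_forward(x, c(0.5), mask, list(id_op(2))), x)
})

test_that("node aggregation uses the softmax of beta over incoming edges", {
  set.seed(43)
  a <- rand_tensor(4, 4, 1, 2)
  b <- rand_tensor(4, 4, 1, 2)
  expect_identical(node_aggregate(list(a), 1.3), a)
  expect_equal(node_aggregate(list(a, b), c(0, 0)), (a + b) / 2)
  expect_equal(node_aggregate(list(a, b), c(log(1), log(3))), 0.25 * a + 0.75 * b)
  expect_error(node_aggregate(list(), numeric(0)), "no incoming")
})

test_that("masked-out channels carry the pure bypass gradient", {
  set.seed(44)
  mop <- agenas:::make_partial_mixed_op(4, 2, c("sep_conv_3x3", "zero"), 1)
  mop$w <- agenas:::softmax_vec(c(0.2, -0.1))
  x <- rand_tensor(5, 5, 1, 4, sd = 0.5)
  set.seed(7)
  y <- agenas:::nn_forward(mop, x)
  sel <- mop$cache$sel
  rest <- mop$cache$rest
  dy <- array(stats::rnorm(length(y)), dim = dim(y))
  dx <- agenas:::nn_backward(mop, dy)
  expect_identical(dx[, , , rest], dy[, , , rest])  # identity path, exact
  expect_false(isTRUE(all.equal(dx[, , , sel], dy[, , , sel])))
})

test_that("architecture parameter invariants hold after initialization", {
  cfg <- search_network_config(num_cells = 2L, reduction_positions = 1L,
                               init_channels = 8L, num_nodes = 2L,
                               operators = c("sep_conv_3x3", "identity", "zero"),
                               sample_ratio = 0.25)
  params <- init_arch_params(cfg, seed = 5L)
  for (tab in c("normal", "reduce")) {
    ws <- arch_softmax_weights(params, tab)
    expect_length(ws, 5L)  # edges of a 2-node cell: 2 + 3
    for (w in ws) expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  # mask size: round(C * ratio) channels pass through the mixture
  mop <- agenas:::make_partial_mixed_op(8, 2, cfg$operators, 1)
  x <- rand_tensor(4, 4, 1, 8)
  mop$w <- rep(1 / 3, 3)
  agenas:::nn_forward(mop, x)
  expect_length(mop$cache$sel, 2L)
})

test_that("alpha and beta gradients match finite differences through a cell", {
  set.seed(45)
  cfg <- search_network_config(num_cells = 1L, reduction_positions = integer(0),
                               init_channels = 4L, num_nodes = 2L,
                               operators = c("sep_conv_3x3", "identity", "zero"),
                               sample_ratio = 0.5, num_classes = 4L)
  params <- init_arch_params(cfg, seed = 9L)
  net <- agenas:::build_search_network(cfg)
  x <- rand_tensor(8, 8, 2, 1, sd = 0.5)
  targets <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE)
  loss_at <- function() {
    agenas:::refresh_arch_weights(net, params)
    set.seed(123)  # fixes the per-forward channel permutations
    agenas:::softmax_xent(agenas:::search_net_forward(net, x, train = TRUE),
                          targets)$loss
  }
  # analytic gradients
  agenas:::refresh_arch_weights(net, params)
  set.seed(123)
  ls <- agenas:::softmax_xent(agenas:::search_net_forward(net, x, train = TRUE),
                              targets)
  aps <- agenas:::arch_param_list(params)
  for (p in aps) p$g <- NULL
  agenas:::search_net_backward(net, ls$dlogits)
  agenas:::collect_arch_grads(net, params)
  for (key in names(params$normal$alpha)) {
    for (slot in c("alpha", "beta")) {
      p <- params$normal[[slot]][[key]]
      pv <- p$v
      fd <- fd_grad(function(v) {
        p$v <- v
        out <- loss_at()
        p$v <- pv
        out
      }, pv, eps = 1e-4)
      expect_equal(as.vector(p$g), as.vector(fd), tolerance = 1e-3,
                   label = sprintf("%s grad, edge %s", slot, key))
    }
  }
})

test_that("the architecture gradient favours the zero-loss operator on a 2-op edge", {
  # op A (identity) reproduces the regression target exactly, op B (zero)
  # incurs a constant loss; one gradient step on alpha must move softmax
  # mass toward A
  set.seed(46)
  x <- rand_tensor(6, 6, 2, 4, sd = 0.8)
  mop <- agenas:::make_partial_mixed_op(4, 4, c("identity", "zero"), 1)
  alpha <- c(0, 0)
  mop$w <- agenas:::softmax_vec(alpha)
  y <- agenas:::nn_forward(mop, x)
  # L = mean((y - x)^2); identity alone would give zero loss
  dy <- 2 * (y - x) / length(y)
  agenas:::nn_backward(mop, dy)
  dalpha <- agenas:::softmax_grad(mop$w, mop$dw)
  expect_lt(dalpha[1], 0)  # descending alpha_A's gradient raises its weight
  expect_gt(dalpha[2], 0)
  # finite-difference confirmation of the sign
  loss_at <- function(a) {
    mop$w <- agenas:::softmax_vec(a)
    yy <- agenas:::nn_forward(mop, x)
    mean((yy - x)^2)
  }
  expect_lt(loss_at(c(0.1, -0.1)), loss_at(c(0, 0)))
})

test_that("bilevel search is deterministic and numerically stable", {
  cfg <- search_network_config(num_cells = 1L, reduction_positions = integer(0),
                               init_channels = 4L, num_nodes = 2L,
                               operators = c("sep_conv_3x3", "identity", "zero"),
                               sample_ratio = 0.5, num_classes = 76L)
  split <- toy_split(n_train = 16L, n_val = 16L, image_size = 32L, seed = 4L)
  r1 <- bilevel_search(split$train, split$val, cfg, steps = 5L, batch_size = 8L,
                       seed = 11L)
  r2 <- bilevel_search(split$train, split$val, cfg, steps = 5L, batch_size = 8L,
                       seed = 11L)
  a1 <- lapply(r1$params$normal$alpha, function(p) p$v)
  a2 <- lapply(r2$params$normal$alpha, function(p) p$v)
  expect_identical(a1, a2)
  expect_true(all(vapply(a1, function(v) all(is.finite(v)), logical(1))))
})

test_that("the informative operator wins the search in at least 8 of 10 seeds", {
  # young/old discrimination task: identity preserves the age signal, zero
  # removes it, so the search should concentrate mass on identity
  two_age_split <- function(seed) {
    a <- generate_dataset_array(synth_config(n = 16L, image_size = 32L,
                                             age_min = 0L, age_max = 0L,
                                             noise_sd = 0.02, seed = seed))
    b <- generate_dataset_array(synth_config(n = 16L, image_size = 32L,
                                             age_min = 75L, age_max = 75L,
                                             noise_sd = 0.02, seed = seed + 100L))
    list(x = array(c(a$x, b$x), dim = c(32, 32, 32, 1)), age = c(a$age, b$age))
  }
  cfg <- search_network_config(num_cells = 1L, reduction_positions = integer(0),
                               init_channels = 6L, num_nodes = 2L,
                               operators = c("identity", "zero"),
                               sample_ratio = 1, num_classes = 76L)
  tr <- two_age_split(1L)
  va <- two_age_split(3L)
  wins <- 0L
  for (seed in 1:10) {
    res <- bilevel_search(tr, va, cfg, steps = 40L, batch_size = 16L,
                          lr_arch = 0.01, seed = seed)
    ws <- arch_softmax_weights(res$params, "normal")
    m <- rowMeans(vapply(ws, identity, numeric(2)))
    wins <- wins + (m["identity"] > m["zero"])
  }
  expect_gte(wins, 8L)
})

test_that("genotype derivation matches a brute-force selection oracle", {
  cfg <- search_network_config(num_cells = 1L, reduction_positions = integer(0),
                               init_channels = 4L, num_nodes = 2L,
                               operators = c("sep_conv_3x3", "identity", "zero"),
                               sample_ratio = 0.5)
  params <- init_arch_params(cfg, seed = 21L)
  set.seed(22)
  for (k in names(params$normal$alpha)) {
    params$normal$alpha[[k]]$v <- stats::rnorm(3)
    params$normal$beta[[k]]$v <- stats::rnorm(1)
  }
  geno <- derive_genotype(params, cfg)
  # oracle: enumerate every edge/op choice directly
  nz <- c("sep_conv_3x3", "identity")
  for (j in 2:3) {
    incoming <- 0:(j - 1)
    bw <- agenas:::softmax_vec(vapply(incoming, function(i)
      params$normal$beta[[agenas:::edge_key(i, j)]]$v, numeric(1)))
    scores <- vapply(seq_along(incoming), function(ii) {
      w <- agenas:::softmax_vec(params$normal$alpha[[agenas:::edge_key(incoming[ii], j)]]$v)
      names(w) <- cfg$operators
      bw[ii] * max(w[nz])
    }, numeric(1))
    keep <- sort(incoming[order(-scores)[1:2]])
    got <- geno$normal[(2 * (j - 1) - 1):(2 * (j - 1))]
    expect_identical(sort(vapply(got, function(cn) cn[[2]], numeric(1))),
                     as.numeric(keep))
    for (cn in got) {
      w <- agenas:::softmax_vec(params$normal$alpha[[
        agenas:::edge_key(cn[[2]], j)]]$v)
      names(w) <- cfg$operators
      expect_identical(cn[[1]], nz[which.max(w[nz])])
    }
  }
  # zero never appears
  expect_false("zero" %in% vapply(geno$normal, `[[`, character(1), 1))
})

test_that("AGENet builder stacks 5 normal and 3 reduction cells with the DEX head", {
  geno <- cell_genotype(
    normal = list(list("sep_conv_3x3", 0L), list("identity", 1L),
                  list("sep_conv_5x5", 0L), list("max_pool_3x3", 2L),
                  list("identity", 1L), list("conv_3x3", 3L),
                  list("avg_pool_3x3", 2L), list("sep_conv_3x3", 4L)),
    nodes = 4L)
  arch <- build_agenet(geno, init_channels = 36L)
  expect_identical(arch$cells$num_cells, 8L)
  expect_identical(arch$cells$reduction_positions, c(1L, 3L, 6L))
  expect_identical(arch$head$num_classes, 76L)
  expect_identical(length(arch$cells$reduction_positions), 3L)
  # spatial contract: stem stride 2 plus 3 reductions divide 384 by 16
  rep384 <- count_network(arch, 384)
  last_conv <- rep384$layers[rep384$layers$type == "conv", ]
  expect_identical(max(last_conv$h[nrow(last_conv)]), 384 / 2^4)
  # channel doubling: 36 -> 72 -> 144 -> 288 across the reduction cells
  small <- count_network(build_agenet(geno, 36L), 64)
  large <- count_network(build_agenet(geno, 54L), 64)
  expect_gt(large$params / small$params, 2)
  expect_lt(large$params / small$params, 2.4)
})

test_that("a small discrete cell network trains end to end", {
  set.seed(47)
  geno <- cell_genotype(
    normal = list(list("sep_conv_3x3", 0L), list("identity", 1L),
                  list("identity", 0L), list("sep_conv_3x3", 2L)),
    nodes = 2L)
  arch <- build_agenet(geno, init_channels = 6L, num_cells = 2L,
                       reduction_positions = 2L, input_channels = 1L)
  net <- build_network_from_spec(arch)
  split <- toy_split(n_train = 32L, n_val = 1L, image_size = 32L, seed = 6L)
  fit <- train_age_model(net, split$train, epochs = 2L, batch_size = 8L,
                         lr = 1e-3, augment = FALSE, seed = 1L)
  expect_lt(fit$log$loss[2], fit$log$loss[1])
})
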