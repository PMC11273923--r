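# One-shot supernet engine: plan structure, uniform sampling, weight-sharing
# consistency, training locality and the evolutionary search stage.

test_that("the canonical plan has 16 choice layers and a depth-50 realization", {
  plan <- supernet_plan(1)
  expect_length(plan$layers, 16L)
  strides <- vapply(plan$layers, `[[`, integer(1), "stride")
  expect_true(all(strides %in% c(1L, 2L)))
  # stem (2) times block strides reduce 384 to a 12x12 final grid
  expect_equal(384 / (plan$stem$stride * prod(strides)), 12)
  arch <- realize_path_arch(plan, agespos_published_path())
  expect_identical(count_depth(arch), 50L)
})

test_that("the packaged path places 8 parallel-asym blocks among 16", {
  p <- agespos_published_path()
  expect_length(p$choices, 16L)
  expect_identical(sum(p$choices == 2L), 8L)
  arch <- build_age_spos(p, width_mult = 1)
  kinds <- vapply(arch$blocks, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "parallel_asym"), 8L)
})

test_that("every supernet candidate block contains a depthwise convolution", {
  plan <- supernet_plan(1)
  for (i in seq_along(plan$layers)) for (choice in 0:2) {
    sp <- agenas:::plan_block_spec(plan, i, choice)
    tab <- do.call(rbind, agenas:::lower_block(sp, 12, 12)$rows)
    dw <- tab$type == "conv" & tab$groups > 1
    expect_true(any(dw))
  }
})

test_that("path codes validate and sample uniformly", {
  expect_error(path_code(c(0, 1, 2), num_layers = 16), "length")
  expect_error(path_code(rep(3, 16)), "entries")
  set.seed(31)
  p1 <- sample_path(16)
  set.seed(31)
  p2 <- sample_path(16)
  expect_identical(p1, p2)
  expect_true(all(p1$choices %in% 0:2))
  # per-layer frequencies within 3 sigma of 1/3 at n = 30,000
  set.seed(32)
  n <- 30000L
  counts <- matrix(0L, nrow = 16, ncol = 3)
  for (i in seq_len(n)) {
    ch <- sample_path(16)$choices
    for (l in 1:16) counts[l, ch[l] + 1L] <- counts[l, ch[l] + 1L] + 1L
  }
  sigma <- sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n / 3) <= 3 * sigma))
})

test_that("supernet forward under a path equals the extracted standalone network", {
  set.seed(33)
  plan <- toy_supernet_plan(couts = c(8L, 8L, 12L), strides = c(1L, 2L, 1L),
                            expands = c(2, 2, 2), stem_c = 6L, head_conv = 16L,
                            num_classes = 10L)
  sup <- build_supernet(plan)
  x <- rand_tensor(12, 12, 2, 1, sd = 0.4)
  for (rep in 1:5) {
    p <- sample_path(3)
    y_sup <- supernet_forward(sup, x, p, train = FALSE)
    net <- extract_path_network(sup, p)
    y_net <- net_forward(net, x, train = FALSE)
    expect_identical(y_sup, y_net)
  }
})

test_that("a supernet step updates only the sampled path's blocks", {
  set.seed(34)
  plan <- toy_supernet_plan(couts = c(6L, 6L), strides = c(1L, 1L),
                            expands = c(2, 2), stem_c = 6L, head_conv = 12L,
                            num_classes = 6L)
  sup <- build_supernet(plan)
  snapshot <- function(mod) lapply(agenas:::nn_params(mod), function(p) p$v)
  before <- lapply(sup$layers, function(layer) lapply(layer, snapshot))
  data <- list(x = rand_tensor(8, 8, 6, 1, sd = 0.3), age = c(0L, 1L, 2L, 3L, 4L, 5L))
  # one mini-batch; seed fixes the sampled path
  set.seed(99)
  sup <- train_supernet(sup, data, num_batches = 1L, batch_size = 6L, lr = 0.5,
                        label_eps = 0.1, seed = 99L)
  set.seed(99)
  sample.int(6L, 6L)  # consume the batch draw the trainer made
  taken <- sample_path(2L)$choices
  after <- lapply(sup$layers, function(layer) lapply(layer, snapshot))
  for (l in 1:2) for (c in 1:3) {
    changed <- !isTRUE(all.equal(before[[l]][[c]], after[[l]][[c]],
                                 tolerance = 1e-12))
    expect_identical(changed, c == taken[l] + 1L,
                     label = sprintf("layer %d choice %d", l, c - 1L))
  }
})

test_that("toy supernet training reduces the running loss", {
  set.seed(35)
  split <- toy_split(n_train = 60L, image_size = 32L)
  plan <- toy_supernet_plan(couts = c(8L, 12L), strides = c(2L, 2L),
                            expands = c(2, 2), stem_c = 8L, head_conv = 24L)
  sup <- build_supernet(plan)
  sup <- train_supernet(sup, split$train, num_batches = 100L, batch_size = 16L,
                        lr = 0.05, seed = 35L)
  losses <- attr(sup, "loss_log")
  expect_lt(mean(tail(losses, 10)), mean(head(losses, 10)))
  expect_true(all(is.finite(losses)))
})

test_that("evolutionary search recovers the exhaustive optimum on a toy space", {
  set.seed(36)
  plan <- toy_supernet_plan(couts = c(6L, 8L), strides = c(2L, 1L),
                            expands = c(2, 2), stem_c = 6L, head_conv = 12L)
  sup <- build_supernet(plan)
  split <- toy_split(n_train = 40L, n_val = 24L, image_size = 32L, seed = 11L)
  sup <- train_supernet(sup, split$train, num_batches = 30L, batch_size = 8L,
                        lr = 0.05, seed = 36L)
  # exhaustive oracle over all 9 paths
  grid <- expand.grid(a = 0:2, b = 0:2)
  oracle <- apply(grid, 1, function(g) {
    p <- path_code(c(g[1], g[2]), 2L)
    preds <- agenas:::dex_expected_age_batch(agenas:::softmax_rows(
      supernet_forward(sup, split$val$x, p, train = FALSE)))
    mae(preds, split$val$age)
  })
  best <- as.integer(grid[which.min(oracle), ])
  ranked <- evolutionary_search(sup, split$val,
                                evo_config(population = 9L, generations = 6L,
                                           topk = 3L), seed = 1L)
  expect_identical(ranked[[1]]$path$choices, best)
  expect_equal(ranked[[1]]$mae, min(oracle), tolerance = 1e-12)
  # determinism of the ranking
  ranked2 <- evolutionary_search(sup, split$val,
                                 evo_config(population = 9L, generations = 6L,
                                            topk = 3L), seed = 1L)
  expect_identical(lapply(ranked, `[[`, "path"), lapply(ranked2, `[[`, "path"))
})

test_that("the FLOPs budget constrains every returned path", {
  set.seed(37)
  plan <- toy_supernet_plan(couts = c(6L, 8L), strides = c(2L, 1L),
                            expands = c(2, 2), stem_c = 6L, head_conv = 12L)
  sup <- build_supernet(plan)
  split <- toy_split(n_train = 20L, n_val = 16L, image_size = 32L, seed = 12L)
  sup <- train_supernet(sup, split$train, num_batches = 10L, batch_size = 8L,
                        seed = 37L)
  all_flops <- apply(expand.grid(a = 0:2, b = 0:2), 1, function(g)
    agenas:::path_flops(plan, path_code(c(g[1], g[2]), 2L), 16))
  budget <- stats::median(all_flops)
  ranked <- evolutionary_search(sup, split$val,
                                evo_config(population = 6L, generations = 4L,
                                           flops_budget = budget, topk = 2L),
                                input_hw = 16, seed = 2L)
  for (r in ranked) expect_lte(r$flops, budget)
  # an impossible budget raises the infeasibility error
  expect_error(evolutionary_search(sup, split$val,
                                   evo_config(population = 4L, generations = 2L,
                                              flops_budget = 1, topk = 1L),
                                   input_hw = 16, seed = 3L),
               "infeasible")
})
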