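# Operator registry and block construction contracts.

test_that("the search registry holds the 11 operators in canonical order", {
  reg <- list_search_operators()
  expect_length(reg, 11L)
  nms <- vapply(reg, `[[`, character(1), "name")
  expect_identical(nms, c("conv_3x3", "sep_conv_3x3", "sep_conv_5x5",
                          "group_conv_3x3", "group_conv_5x5",
                          "asym_group_conv_3", "asym_group_conv_7",
                          "max_pool_3x3", "avg_pool_3x3", "identity", "zero"))
  expect_identical(nms[length(nms)], "zero")
  kinds <- vapply(reg, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "asym_group_conv"), 2L)
  # asymmetric group convs: two-stage 1xk then kx1 with k in {3, 7}, 9 groups
  asym <- reg[kinds == "asym_group_conv"]
  expect_setequal(vapply(asym, function(s) s$kernel[2], integer(1)), c(3L, 7L))
  expect_true(all(vapply(asym, `[[`, integer(1), "groups") == 9L))
  # round trip through the name lookup preserves the specs
  for (s in reg) expect_identical(agenas:::op_spec_by_name(s$name), s)
})

test_that("every operator preserves channels and obeys the ceil(n/s) shape contract", {
  set.seed(11)
  for (s in list_search_operators()) {
    for (stride in c(1L, 2L)) {
      for (hw in c(7L, 8L)) {
        ch <- 9L  # divisible by the grouped operators' 9 groups
        x <- rand_tensor(hw, hw, 1, ch, sd = 0.3)
        op <- make_operator(s, ch, stride)
        y <- agenas:::nn_forward(op, x)
        expect_identical(dim(y), c(ceiling(hw / stride), ceiling(hw / stride),
                                   1, ch) |> as.integer(),
                         label = sprintf("%s stride %d hw %d", s$name, stride, hw))
      }
    }
  }
})

test_that("identity and zero operators behave literally", {
  set.seed(12)
  x <- rand_tensor(6, 6, 2, 3)
  idop <- make_operator(agenas:::op_spec_by_name("identity"), 3, 1)
  expect_identical(agenas:::nn_forward(idop, x), x)
  z <- agenas:::nn_forward(make_operator(agenas:::op_spec_by_name("zero"), 3, 1), x)
  expect_true(all(z == 0))
  expect_identical(dim(z), dim(x))
})

test_that("channels not divisible by groups is a configuration error", {
  expect_error(make_operator(agenas:::op_spec_by_name("group_conv_3x3"), 8, 1),
               "divisible")
})

test_that("3x3 average pooling preserves a constant map in the interior", {
  x <- array(3.7, dim = c(5, 5, 1, 1))
  pool <- agenas:::nn_pool("avg", 3, 1)
  y <- agenas:::nn_forward(pool, x)
  expect_equal(y[2:4, 2:4, 1, 1], matrix(3.7, 3, 3))
})

test_that("mbconv residual condition and output shapes are honoured", {
  set.seed(13)
  x <- rand_tensor(8, 8, 1, 16, sd = 0.2)
  b <- make_mbconv_block(block_spec("mbconv", 16, 16, stride = 1, expand = 2))
  y <- agenas:::nn_forward(b, x)
  expect_identical(dim(y), dim(x))
  # residual: zeroing the projection conv weight must give back exactly x
  proj_conv <- b$children$proj$children[[1]]
  proj_conv$params$w1$v[] <- 0
  expect_equal(agenas:::nn_forward(b, x), x)
  # stride-2 block without residual changes channels and halves resolution
  b2 <- make_mbconv_block(block_spec("mbconv", 16, 24, stride = 2, expand = 6))
  x2 <- rand_tensor(32, 32, 1, 16, sd = 0.2)
  expect_identical(dim(agenas:::nn_forward(b2, x2)), c(16L, 16L, 1L, 24L))
})

test_that("parallel asym block propagates zeros and matches mbconv depth", {
  x <- array(0, dim = c(8, 8, 1, 32))
  b <- make_parallel_asym_block(block_spec("parallel_asym", 32, 32, stride = 1,
                                           expand = 2))
  # bias-free convolutions: zero input stays zero through the branch, and
  # the residual returns the (zero) input
  expect_true(all(agenas:::nn_forward(b, x, train = FALSE) == 0))
  # both block kinds lower to three weighted conv stages
  for (kind in c("mbconv", "parallel_asym")) {
    sp <- block_spec(kind, 16, 24, stride = 1, expand = 2)
    lowered <- agenas:::lower_block(sp, 8, 8)$rows
    tab <- do.call(rbind, lowered)
    expect_identical(sum(tab$type == "conv") - (kind == "parallel_asym"), 3L)
  }
  arch1 <- arch_spec("one-block", stem = list(cout = 16, kernel = 3, stride = 1),
                     blocks = list(block_spec("mbconv", 16, 16)),
                     head = list(conv_width = NULL, num_classes = 5L))
  arch2 <- arch_spec("one-block-asym", stem = list(cout = 16, kernel = 3, stride = 1),
                     blocks = list(block_spec("parallel_asym", 16, 16)),
                     head = list(conv_width = NULL, num_classes = 5L))
  expect_identical(count_depth(arch1), count_depth(arch2))
  expect_identical(count_depth(arch1), 5L)
})

test_that("odd expanded channel count is rejected for the parallel asym block", {
  expect_error(block_spec("parallel_asym", 9, 9, expand = 1), "even")
})

test_that("SE module gates channels and adds 2*C^2/r (+bias) parameters", {
  set.seed(14)
  x <- rand_tensor(6, 6, 2, 8, sd = 0.5)
  se <- make_se_module(se_config(8L, 4L))
  y <- agenas:::nn_forward(se, x)
  expect_identical(dim(y), dim(x))
  # gate forced to one: zero the second fc and shift its bias far positive
  se$children$fc2$params$w$v[] <- 0
  se$children$fc2$params$b$v[] <- 1e3
  expect_equal(agenas:::nn_forward(se, x), x, tolerance = 1e-12)
  # SE parameter increment in the counter: 2*C^2/r weights + C + C/r biases
  sp_on <- block_spec("mbconv", 8, 8, expand = 2, use_se = TRUE, se_reduction = 4)
  sp_off <- block_spec("mbconv", 8, 8, expand = 2, use_se = FALSE)
  p_on <- sum(do.call(rbind, agenas:::lower_block(sp_on, 8, 8)$rows)$params)
  p_off <- sum(do.call(rbind, agenas:::lower_block(sp_off, 8, 8)$rows)$params)
  cexp <- 16
  expect_identical(p_on - p_off, 2 * cexp^2 / 4 + cexp + cexp / 4)
  # runtime parameter count agrees with the analytic increment
  n_par <- function(b) sum(vapply(agenas:::nn_params(b), function(p)
    length(p$v), numeric(1)))
  expect_identical(n_par(make_mbconv_block(sp_on)) - n_par(make_mbconv_block(sp_off)),
                   2 * cexp^2 / 4 + cexp + cexp / 4)
})

test_that("block backward passes match finite differences", {
  set.seed(15)
  x <- rand_tensor(6, 6, 1, 4, sd = 0.3)
  for (kind in c("mbconv", "parallel_asym")) {
    b <- make_block(block_spec(kind, 4, 4, stride = 1, expand = 2, kernel = 3,
                               use_se = (kind == "mbconv")))
    y0 <- agenas:::nn_forward(b, x)
    v <- array(stats::rnorm(length(y0)), dim = dim(y0))
    agenas:::nn_forward(b, x)
    dx <- agenas:::nn_backward(b, v)
    fx <- function(xx) sum(agenas:::nn_forward(b, array(xx, dim = dim(x))) * v)
    expect_equal(as.vector(dx), as.vector(fd_grad(fx, x)), tolerance = 1e-4,
                 label = paste("block grad", kind))
  }
})
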