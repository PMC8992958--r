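test_that("canonical graph has 19 conv layers and 1,962,337 parameters", {
  g <- build_layer_graph(unet_config())
  expect_equal(count_conv_layers(g), 19)
  expect_equal(count_trainable_params(g), 1962337)
  # independent per-layer oracle: recompute the sum from the layer table
  df <- as.data.frame(g)
  expect_equal(sum(df$n_params), 1962337)
  expect_equal(sum(df$kind %in% c("conv", "output-conv")), 19)
})

test_that("toy depth-2 graph matches the hand summation", {
  g <- tiny_unet(size = 8, depth = 2, filters = 1)
  # enc 10+10, bottleneck 20+38, dec 28+10, head 2
  expect_equal(count_trainable_params(g), 118)
  expect_equal(count_conv_layers(g), 7)
  df <- as.data.frame(g)
  expect_equal(df$n_params[df$kind %in% c("conv", "output-conv")],
               c(10, 10, 20, 38, 28, 10, 2))
})

test_that("degenerate graphs and configs are handled", {
  empty <- structure(list(layers = list()), class = "layer_graph")
  expect_equal(count_conv_layers(empty), 0)
  expect_equal(count_trainable_params(empty), 0)
  expect_equal(mrisynth:::conv_params(1, 1, 1, 1), 2)  # one weight + one bias
  expect_error(unet_config(input_shape = c(100, 100, 1)), "divisible")
  expect_error(unet_config(depth = 1), "depth")
  expect_error(unet_config(dropout_schedule = c(0.1, 0.2)), "per level")
})

test_that("layer shapes chain consistently and the output matches the input", {
  g <- build_layer_graph(unet_config())
  for (l in g$layers) {
    for (j in l$input) {
      if (j == 0) next
      prod_shape <- g$layers[[j]]$output_shape
      if (l$kind == "concat") {
        expect_equal(prod_shape[1:2], l$output_shape[1:2])
      } else {
        expect_equal(prod_shape, l$input_shape)
      }
    }
  }
  last <- g$layers[[length(g$layers)]]
  expect_equal(last$output_shape[1:2], g$config$input_shape[1:2])
  # encoder level k spatial size input / 2^(k-1): check the pool outputs
  pools <- Filter(function(l) l$kind == "maxpool", g$layers)
  expect_equal(vapply(pools, function(l) l$output_shape[1], numeric(1)),
               224 / 2^(1:4))
})

test_that("doubling base_filters scales parameters by ~4", {
  p16 <- count_trainable_params(build_layer_graph(unet_config()))
  p32 <- count_trainable_params(build_layer_graph(
    unet_config(base_filters = 32)))
  expect_gt(p32 / p16, 3.9)
  expect_lt(p32 / p16, 4.1)
})

test_that("instantiated parameter count equals the analytic count", {
  for (g in list(build_layer_graph(unet_config()),
                 tiny_unet(8, 2, 1))) {
    net <- instantiate_network(g, seed = 1)
    expect_equal(network_n_params(net), count_trainable_params(g))
  }
})

test_that("He-uniform initialisation is seeded and correctly bounded", {
  g <- tiny_unet(16, 3, 4)
  a <- instantiate_network(g, seed = 42)
  b <- instantiate_network(g, seed = 42)
  expect_identical(a$params, b$params)
  c <- instantiate_network(g, seed = 43)
  expect_false(identical(a$params, c$params))
  for (i in seq_along(a$params)) {
    p <- a$params[[i]]
    if (is.null(p)) next
    fan_in <- nrow(p$w)
    expect_lte(max(abs(p$w)), sqrt(6 / fan_in))
    expect_true(all(p$b == 0))
  }
})

test_that("forward pass honours shapes and stays finite", {
  g <- tiny_unet(16, 3, 2)
  net <- instantiate_network(g, seed = 1)
  x <- array(0, dim = c(16, 16, 1, 3))
  y <- mrisynth:::network_forward(net, x)
  expect_equal(dim(y), c(16, 16, 1, 3))
  expect_true(all(is.finite(y)))
  x2 <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  y2 <- mrisynth:::network_forward(net, x2)
  expect_true(all(y2 > -1 & y2 < 1))   # tanh range
})

test_that("backpropagation matches a central-difference numerical gradient", {
  set.seed(42)
  g <- build_layer_graph(unet_config(input_shape = c(8, 8, 1), depth = 2,
                                     base_filters = 2,
                                     dropout_schedule = c(0, 0)))
  net <- instantiate_network(g, seed = 3)
  x <- array(runif(8 * 8 * 2), dim = c(8, 8, 1, 2))
  tg <- array(runif(8 * 8 * 2), dim = c(8, 8, 1, 2))
  loss <- function(n) mean((mrisynth:::network_forward(n, x) - tg)^2)
  f <- mrisynth:::network_forward(net, x, training = TRUE)
  pg <- mrisynth:::network_backward(net, x, f, 2 * (f$out - tg) / length(tg))
  eps <- 1e-6
  for (i in seq_along(net$params)) {
    if (is.null(net$params[[i]])) next
    for (k in c("w", "b")) {
      for (j in sample(length(net$params[[i]][[k]]),
                       min(4, length(net$params[[i]][[k]])))) {
        up <- net; up$params[[i]][[k]][j] <- up$params[[i]][[k]][j] + eps
        dn <- net; dn$params[[i]][[k]][j] <- dn$params[[i]][[k]][j] - eps
        num <- (loss(up) - loss(dn)) / (2 * eps)
        ana <- pg[[i]][[k]][j]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-5)
      }
    }
  }
})

test_that("convolution kernel agrees with a direct-loop oracle", {
  set.seed(7)
  H <- 5; W <- 6; Cin <- 2; Cout <- 3
  x <- array(rnorm(H * W * Cin), dim = c(H, W, Cin, 1))
  wm <- matrix(rnorm(9 * Cin * Cout), 9 * Cin, Cout)
  b <- rnorm(Cout)
  y <- mrisynth:::conv2d_fw(x, dim(x), wm, b, 3L, 3L)
  # brute-force zero-padded 3x3 convolution
  xp <- array(0, dim = c(H + 2, W + 2, Cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x[, , , 1]
  for (o in 1:Cout) for (i in 1:H) for (j in 1:W) {
    acc <- b[o]
    for (c in 1:Cin) for (ki in 1:3) for (kj in 1:3)
      acc <- acc + xp[i + ki - 1, j + kj - 1, c] *
        wm[ki + 3 * (kj - 1) + 9 * (c - 1), o]
    expect_equal(y[i, j, o, 1], acc, tolerance = 1e-12)
  }
})

test_that("layer graph serialises to a summary table and JSON", {
  g <- tiny_unet(8, 2, 1)
  df <- as.data.frame(g)
  expect_equal(nrow(df), length(g$layers))
  expect_true(all(c("kind", "input_shape", "output_shape", "n_params")
                  %in% names(df)))
  js <- layer_graph_json(g)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$total_params, 118)
  expect_equal(parsed$n_conv_layers, 7)
})
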