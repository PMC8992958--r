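#' Instantiate a trainable network from a layer graph
#'
#' Allocates He-uniform weights (uniform on `[-sqrt(6/fan_in),
#' sqrt(6/fan_in)]` with `fan_in = kh*kw*c_in`, the initialisation suited
#' to ReLU networks) and zero biases for every convolutional layer, under
#' a fixed seed. The network's trainable-parameter count equals
#' [count_trainable_params()] of the graph exactly.
#'
#' @param graph a `layer_graph` from [build_layer_graph()].
#' @param seed integer seed for the weight draw.
#' @return object of class `unet_network`: the graph plus a `params` list
#'   (per conv layer: weight matrix `w` of shape `(kh*kw*c_in) x c_out`
#'   and bias vector `b`).
#' @export
instantiate_network <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "layer_graph"))
  params <- vector("list", length(graph$layers))
  with_seed(seed, {
    for (i in seq_along(graph$layers)) {
      l <- graph$layers[[i]]
      if (!l$kind %in% c("conv", "output-conv")) next
      kh <- l$kernel[1]; kw <- l$kernel[2]
      c_in <- l$input_shape[3]; c_out <- l$output_shape[3]
      fan_in <- kh * kw * c_in
      lim <- sqrt(6 / fan_in)
      params[[i]] <- list(
        w = matrix(runif(fan_in * c_out, -lim, lim), fan_in, c_out),
        b = numeric(c_out))
    }
  })
  structure(list(graph = graph, params = params, seed = as.integer(seed)),
            class = "unet_network")
}

#' Total trainable parameters held by an instantiated network
#' @param net a `unet_network`.
#' @return integer count of weights plus biases.
#' @export
network_n_params <- function(net) {
  stopifnot(inherits(net, "unet_network"))
  sum(vapply(net$params, function(p)
    if (is.null(p)) 0 else length(p$w) + length(p$b), numeric(1)))
}

#' @export
print.unet_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("U-Net network: input %s, %d conv layers, %s parameters (seed %d)\n",
              paste(g$config$input_shape, collapse = "x"), g$n_conv_layers,
              format(network_n_params(x), big.mark = ","), x$seed))
  invisible(x)
}

# Forward pass. x: (H, W, C, N). When training = TRUE, dropout is active
# (inverted dropout, using the current RNG stream) and every intermediate
# activation is cached for the backward pass.
network_forward <- function(net, x, training = FALSE) {
  layers <- net$graph$layers
  nL <- length(layers)
  outs <- vector("list", nL)
  caches <- vector("list", nL)
  get_in <- function(j) if (j == 0L) x else outs[[j]]
  for (i in seq_len(nL)) {
    l <- layers[[i]]
    xin <- get_in(l$input[1])
    y <- switch(l$kind,
      "conv" = ,
      "output-conv" = conv2d_fw(xin, dim(xin), net$params[[i]]$w,
                                net$params[[i]]$b, l$kernel[1], l$kernel[2]),
      "activation" = if (l$activation == "relu") {
        caches[[i]] <- xin > 0
        xin * (xin > 0)
      } else {
        yt <- tanh(xin); caches[[i]] <- yt; yt
      },
      "dropout" = if (training && l$rate > 0) {
        mask <- (array(runif(length(xin)), dim(xin)) >= l$rate) / (1 - l$rate)
        caches[[i]] <- mask
        xin * mask
      } else xin,
      "maxpool" = {
        r <- maxpool_fw(xin, dim(xin))
        caches[[i]] <- list(idx = r$idx, xdim = dim(xin))
        r$y
      },
      "upsample" = upsample_fw(xin, dim(xin)),
      "concat" = {
        xb <- get_in(l$input[2])
        d1 <- dim(xin); d2 <- dim(xb)
        y <- array(0, dim = c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
        y[, , seq_len(d1[3]), ] <- xin
        y[, , d1[3] + seq_len(d2[3]), ] <- xb
        y
      },
      stop("unknown layer kind: ", l$kind))
    outs[[i]] <- y
  }
  if (training) list(out = outs[[nL]], outs = outs, caches = caches)
  else outs[[nL]]
}

# Backward pass: given d(loss)/d(output), returns per-conv-layer parameter
# gradients. fw is the cached forward result from network_forward(training
# = TRUE).
network_backward <- function(net, x, fw, dout) {
  layers <- net$graph$layers
  nL <- length(layers)
  grads <- vector("list", nL)       # d loss / d layer-output
  pgrads <- vector("list", nL)      # conv weight gradients
  grads[[nL]] <- dout
  get_in <- function(j) if (j == 0L) x else fw$outs[[j]]
  prop <- function(j, d) {
    if (j == 0L) return(invisible(NULL))
    grads[[j]] <<- if (is.null(grads[[j]])) d else grads[[j]] + d
    invisible(NULL)
  }
  for (i in rev(seq_len(nL))) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]
    switch(l$kind,
      "conv" = ,
      "output-conv" = {
        xin <- get_in(l$input[1])
        bw <- conv2d_bw(xin, dim(xin), net$params[[i]]$w, g,
                        l$kernel[1], l$kernel[2])
        pgrads[[i]] <- list(w = bw$dw, b = as.numeric(bw$db))
        prop(l$input[1], bw$dx)
      },
      "activation" = prop(l$input[1], if (l$activation == "relu")
        g * fw$caches[[i]] else g * (1 - fw$caches[[i]]^2)),
      "dropout" = prop(l$input[1],
                       if (is.null(fw$caches[[i]])) g
                       else g * fw$caches[[i]]),
      "maxpool" = prop(l$input[1],
                       maxpool_bw(g, fw$caches[[i]]$idx,
                                  fw$caches[[i]]$xdim)),
      "upsample" = prop(l$input[1], upsample_bw(g, dim(g))),
      "concat" = {
        c1 <- l$split[1]; c2 <- l$split[2]
        prop(l$input[1], g[, , seq_len(c1), , drop = FALSE])
        prop(l$input[2], g[, , c1 + seq_len(c2), , drop = FALSE])
      })
    grads[[i]] <- NULL   # free as we go
  }
  pgrads
}

#' Run inference on a stack of slices
#'
#' Forward pass in evaluation mode (dropout off); tanh outputs are clipped
#' to `[0,1]` to match the scale of the normalised targets.
#'
#' @param net a `unet_network`.
#' @param slices 3D array `(H, W, n)` or a single matrix.
#' @param batch_size slices per forward pass.
#' @param clip clip range applied to the raw tanh outputs; NULL disables.
#' @return 3D array `(H, W, n)` of synthesised slices.
#' @export
network_infer <- function(net, slices, batch_size = 32L, clip = c(0, 1)) {
  if (is.matrix(slices)) slices <- array(slices, dim = c(dim(slices), 1L))
  d <- dim(slices)
  out <- array(0, dim = d)
  for (at in seq(1L, d[3], by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, d[3])
    xb <- array(slices[, , idx], dim = c(d[1], d[2], 1L, length(idx)))
    yb <- network_forward(net, xb, training = FALSE)
    if (!is.null(clip)) yb <- pmin(pmax(yb, clip[1]), clip[2])
    out[, , idx] <- yb[, , 1L, ]
  }
  out
}
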