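#' Configuration of the 2D U-Net architecture
#'
#' The canonical configuration mirrors a compact U-Net for image-to-image
#' regression: five resolution levels, 16 base filters doubling to 256, two
#' 3x3 zero-padded stride-1 convolutions per level, ReLU activations,
#' dropout rising linearly from 10% to 30% with depth, 2x2 max pooling,
#' nearest-neighbour upsampling in the decoder with skip concatenations,
#' and a 1x1 convolution with tanh activation as the output head. Batch
#' normalisation is deliberately absent.
#'
#' @param input_shape `(H, W, channels)`; H and W must be divisible by
#'   `2^(depth-1)`.
#' @param depth number of resolution levels (>= 2).
#' @param base_filters filters at the first level; doubled at each level.
#' @param kernel convolution kernel shape, default 3x3.
#' @param dropout_schedule dropout rate per level, default linear from 0.10
#'   to 0.30 across `depth` levels; values in `[0, 1)`.
#' @param decoder_dropout logical: mirror the encoder dropout schedule in
#'   the decoder (parameter counts are unaffected either way).
#' @return object of class `unet_config`.
#' @export
unet_config <- function(input_shape = c(224L, 224L, 1L),
                        depth = 5L,
                        base_filters = 16L,
                        kernel = c(3L, 3L),
                        dropout_schedule = NULL,
                        decoder_dropout = TRUE) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be at least 2")
  if (base_filters < 1L) stop("base_filters must be at least 1")
  if (is.null(dropout_schedule))
    dropout_schedule <- seq(0.10, 0.30, length.out = depth)
  if (length(dropout_schedule) != depth ||
      any(dropout_schedule < 0 | dropout_schedule >= 1))
    stop("dropout_schedule must give one rate in [0,1) per level")
  fac <- 2^(depth - 1L)
  if (any(input_shape[1:2] %% fac != 0))
    stop("input spatial size must be divisible by 2^(depth-1) = ", fac)
  structure(list(input_shape = as.integer(input_shape),
                 depth = depth,
                 base_filters = as.integer(base_filters),
                 filters = as.integer(base_filters * 2^(0:(depth - 1L))),
                 kernel = as.integer(kernel),
                 conv_stride = 1L,
                 padding = "same",
                 dropout_schedule = dropout_schedule,
                 decoder_dropout = isTRUE(decoder_dropout),
                 pool = c(2L, 2L),
                 upsample = "nearest",
                 hidden_activation = "relu",
                 output_activation = "tanh",
                 weight_init = "he_uniform"),
            class = "unet_config")
}

conv_params <- function(kh, kw, c_in, c_out) (kh * kw * c_in + 1L) * c_out

#' Build the framework-independent layer graph of the U-Net
#'
#' Produces an ordered list of layer descriptors (kind, shapes, kernel,
#' stride, parameter count, and the indices of the layers feeding each
#' layer), from which both the analytic parameter count and the executable
#' network are derived. Topology: encoder levels each run
#' conv-ReLU-dropout, conv-ReLU, maxpool; the bottleneck runs
#' conv-ReLU-dropout, conv-ReLU; decoder levels run upsample, concat with
#' the mirrored encoder features, conv-ReLU(-dropout), conv-ReLU; the head
#' is a 1x1 convolution with tanh. With the canonical configuration this
#' gives 19 convolutional layers and 1,962,337 trainable parameters.
#'
#' Note on the two-convolution bottleneck: with a single-convolution final
#' block the same schedule would count 18 convolutional layers and about
#' 1.37 M parameters; only the two-convolution reading reproduces both the
#' 19-layer and the ~2.0 M-parameter figures, so it is the one built here.
#'
#' @param config a [unet_config()].
#' @return object of class `layer_graph`: list with `layers`,
#'   `total_params`, `n_conv_layers`, and the originating `config`.
#' @export
build_layer_graph <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  H <- config$input_shape[1]; W <- config$input_shape[2]
  C <- config$input_shape[3]
  kh <- config$kernel[1]; kw <- config$kernel[2]
  layers <- list()
  add <- function(kind, input, in_shape, out_shape, kernel = NA,
                  n_params = 0L, extra = list()) {
    layers[[length(layers) + 1L]] <<- c(list(
      kind = kind, input = input, input_shape = in_shape,
      output_shape = out_shape, kernel = kernel,
      stride = if (kind == "maxpool") 2L else 1L,
      n_params = as.integer(n_params)), extra)
    length(layers)
  }
  conv_block <- function(input, h, w, c_in, c_out, rate, with_dropout) {
    i <- add("conv", input, c(h, w, c_in), c(h, w, c_out), c(kh, kw),
             conv_params(kh, kw, c_in, c_out))
    i <- add("activation", i, c(h, w, c_out), c(h, w, c_out),
             extra = list(activation = "relu"))
    if (with_dropout)
      i <- add("dropout", i, c(h, w, c_out), c(h, w, c_out),
               extra = list(rate = rate))
    i
  }
  cur <- 0L   # 0 denotes the network input
  h <- H; w <- W; c_prev <- C
  skips <- integer(config$depth - 1L)
  for (l in seq_len(config$depth - 1L)) {
    f <- config$filters[l]
    cur <- conv_block(cur, h, w, c_prev, f, config$dropout_schedule[l], TRUE)
    cur <- conv_block(cur, h, w, f, f, NA, FALSE)
    skips[l] <- cur
    cur <- add("maxpool", cur, c(h, w, f), c(h / 2, w / 2, f))
    h <- h / 2; w <- w / 2; c_prev <- f
  }
  f <- config$filters[config$depth]
  cur <- conv_block(cur, h, w, c_prev, f,
                    config$dropout_schedule[config$depth], TRUE)
  cur <- conv_block(cur, h, w, f, f, NA, FALSE)
  c_prev <- f
  for (l in rev(seq_len(config$depth - 1L))) {
    f <- config$filters[l]
    cur <- add("upsample", cur, c(h, w, c_prev), c(2 * h, 2 * w, c_prev))
    h <- 2 * h; w <- 2 * w
    cur <- add("concat", c(cur, skips[l]), c(h, w, c_prev),
               c(h, w, c_prev + f),
               extra = list(split = c(c_prev, f)))
    cur <- conv_block(cur, h, w, c_prev + f, f, config$dropout_schedule[l],
                      config$decoder_dropout)
    cur <- conv_block(cur, h, w, f, f, NA, FALSE)
    c_prev <- f
  }
  cur <- add("output-conv", cur, c(h, w, c_prev), c(h, w, 1L), c(1L, 1L),
             conv_params(1L, 1L, c_prev, 1L))
  add("activation", cur, c(h, w, 1L), c(h, w, 1L),
      extra = list(activation = "tanh"))
  g <- structure(list(layers = layers, config = config), class = "layer_graph")
  g$n_conv_layers <- count_conv_layers(g)
  g$total_params <- count_trainable_params(g)
  g
}

#' Count convolutional layers in a layer graph
#'
#' Counts layers of kind `conv` or `output-conv` (the 1x1 head counts).
#'
#' @param graph a `layer_graph`.
#' @return integer count.
#' @export
count_conv_layers <- function(graph) {
  stopifnot(inherits(graph, "layer_graph"))
  sum(vapply(graph$layers, function(l)
    l$kind %in% c("conv", "output-conv"), logical(1)))
}

#' Analytic count of trainable parameters
#'
#' Sums `(kh*kw*c_in + 1) * c_out` over every convolutional layer; all
#' other layer kinds carry no parameters. The instantiated network's
#' parameter count equals this sum exactly.
#'
#' @param graph a `layer_graph`.
#' @return integer total.
#' @export
count_trainable_params <- function(graph) {
  stopifnot(inherits(graph, "layer_graph"))
  sum(vapply(graph$layers, function(l) as.numeric(l$n_params), numeric(1)))
}

#' @export
as.data.frame.layer_graph <- function(x, ...) {
  shp <- function(s) paste(s, collapse = "x")
  data.frame(
    index = seq_along(x$layers),
    kind = vapply(x$layers, `[[`, character(1), "kind"),
    input_shape = vapply(x$layers, function(l) shp(l$input_shape),
                         character(1)),
    output_shape = vapply(x$layers, function(l) shp(l$output_shape),
                          character(1)),
    kernel = vapply(x$layers, function(l)
      if (all(is.na(l$kernel))) "" else shp(l$kernel), character(1)),
    n_params = vapply(x$layers, function(l) as.integer(l$n_params),
                      integer(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("U-Net layer graph: %d layers (%d convolutional), %s trainable parameters\n",
              length(x$layers), x$n_conv_layers,
              format(x$total_params, big.mark = ",")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Serialise a layer graph to JSON
#'
#' @param graph a `layer_graph`.
#' @param path optional file to write to.
#' @return the JSON string, invisibly if `path` is given.
#' @export
layer_graph_json <- function(graph, path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("layer_graph_json requires the jsonlite package")
  js <- jsonlite::toJSON(list(
    total_params = graph$total_params,
    n_conv_layers = graph$n_conv_layers,
    layers = as.data.frame(graph)), pretty = TRUE, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
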