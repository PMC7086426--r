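# Convolutional topology as data: layer chain plus valid-convolution shape
# algebra. Shapes are (h, w, l) = (channel axis, time axis, filter depth).

#' Output shape of a valid convolution
#'
#' Shape propagation for an unpadded (valid) convolution with a square
#' `f x f` filter and stride `s`:
#' `h' = floor((h - f + s)/s)`, `w' = floor((w - f + s)/s)`, depth
#' `n_filters`. The floor is required for the stride-2 pooling layers
#' (e.g. height 43 with f = s = 2 gives 21).
#'
#' @param shape Input shape: numeric vector `c(h, w, l)`.
#' @param f Filter size (>= 1).
#' @param s Stride (>= 1).
#' @param n_filters Number of filters, the output depth.
#' @return Integer vector `c(h, w, l)` of the output feature map.
#' @export
conv_output_shape <- function(shape, f, s, n_filters) {
  stopifnot(length(shape) >= 2, f >= 1, s >= 1, n_filters >= 1)
  h <- shape[[1]]; w <- shape[[2]]
  if (h < f || w < f) {
    stop(sprintf("shape error: input %d x %d smaller than %d x %d filter",
                 h, w, f, f), call. = FALSE)
  }
  c(h = as.integer((h - f + s) %/% s),
    w = as.integer((w - f + s) %/% s),
    l = as.integer(n_filters))
}

#' Output shape of a pooling layer
#'
#' Same floor formula as [conv_output_shape()] with the pooling window as
#' the filter; the depth is preserved.
#'
#' @inheritParams conv_output_shape
#' @return Integer vector `c(h, w, l)`.
#' @export
pool_output_shape <- function(shape, f, s) {
  out <- conv_output_shape(shape, f, s, n_filters = shape[[3]])
  out
}

layer_spec <- function(kind, f = NA_integer_, s = NA_integer_,
                       n_filters = NA_integer_,
                       post_ops = character(0), activation = "none") {
  kind <- match.arg(kind, c("convolution", "average_pool", "fully_connected"))
  structure(list(kind = kind, f = f, s = s, n_filters = n_filters,
                 post_ops = post_ops, activation = activation),
            class = "cnn_layer_spec")
}

conv_layer <- function(f = 5, s = 1, n_filters = 6) {
  layer_spec("convolution", f, s, n_filters, post_ops = c("batch_norm", "relu"))
}

pool_layer <- function(f = 2, s = 2) layer_spec("average_pool", f, s)

fc_layer <- function() layer_spec("fully_connected", activation = "softmax")

#' Define a CNN topology
#'
#' A topology is data: the input shape, an ordered layer chain and the class
#' count. The shape trace is validated on construction, so an architecture
#' whose feature maps collapse to non-positive dimensions is rejected with
#' the offending layer index.
#'
#' @param input_h,input_w Input height (channels) and width (samples).
#' @param layers List of layer specs (see [build_reference_topology()] for the
#'   reference chain).
#' @param n_classes Number of output classes (default 2).
#' @return An object of class `cnn_topology`.
#' @export
topology <- function(input_h, input_w, layers, n_classes = 2) {
  stopifnot(input_h >= 1, input_w >= 1, n_classes >= 2)
  last <- layers[[length(layers)]]
  if (last$kind != "fully_connected") {
    stop("final layer must be fully_connected", call. = FALSE)
  }
  topo <- structure(
    list(input_shape = c(h = as.integer(input_h), w = as.integer(input_w),
                         l = 1L),
         layers = layers, n_classes = as.integer(n_classes)),
    class = "cnn_topology")
  trace_shapes(topo)  # validates
  topo
}

#' The nine-layer reference topology
#'
#' The fixed architecture for 63 x 1000 one-second EEG matrices: five
#' convolution layers (5 x 5, stride 1, 6 filters, each followed by batch
#' normalization and ReLU), average pooling (2 x 2, stride 2), a sixth
#' convolution, a second average pooling, and a softmax fully connected
#' layer mapping the flattened 8 x 243 x 6 = 11664 activations to the two
#' class logits. Nine layers in total.
#'
#' @return A `cnn_topology`.
#' @export
build_reference_topology <- function() {
  topology(63, 1000,
           c(replicate(5, conv_layer(), simplify = FALSE),
             list(pool_layer()),
             list(conv_layer()),
             list(pool_layer()),
             list(fc_layer())),
           n_classes = 2)
}

#' Build a topology from a compact layout string
#'
#' Convenience constructor for reduced architectures on smaller inputs
#' (e.g. downsampled synthetic cohorts): `layout` is a vector of
#' `"conv"`/`"pool"` tokens; a softmax fully connected layer is appended.
#'
#' @param input_h,input_w Input dimensions.
#' @param layout Character vector of `"conv"` and `"pool"` tokens.
#' @param conv_f,n_filters Convolution filter size and count.
#' @param pool_f Pooling window (stride equals the window).
#' @param n_classes Number of classes.
#' @return A `cnn_topology`.
#' @export
make_topology <- function(input_h, input_w,
                          layout = c("conv", "conv", "pool", "conv", "pool"),
                          conv_f = 3, n_filters = 6, pool_f = 2,
                          n_classes = 2) {
  layers <- lapply(layout, function(tok) {
    switch(match.arg(tok, c("conv", "pool")),
           conv = conv_layer(f = conv_f, n_filters = n_filters),
           pool = pool_layer(f = pool_f, s = pool_f))
  })
  topology(input_h, input_w, c(layers, list(fc_layer())), n_classes)
}

#' Largest reduced topology that fits an input
#'
#' Greedily applies the conv/conv/pool/conv/pool pattern with 3 x 3
#' kernels, skipping any layer the input is too small for, and appends the
#' softmax fully connected layer. Used when a pipeline must pick an
#' architecture for segments smaller than the 63 x 1000 reference input.
#'
#' @param input_h,input_w Input dimensions.
#' @param conv_f Convolution kernel size (default 3).
#' @param n_filters Filters per convolution (default 6).
#' @param n_classes Number of classes.
#' @return A `cnn_topology`.
#' @export
default_small_topology <- function(input_h, input_w, conv_f = 3,
                                   n_filters = 6, n_classes = 2) {
  cur <- c(h = input_h, w = input_w, l = 1)
  layout <- character(0)
  for (tok in c("conv", "conv", "pool", "conv", "pool")) {
    nxt <- tryCatch(
      if (tok == "conv") conv_output_shape(cur, conv_f, 1, n_filters)
      else pool_output_shape(cur, 2, 2),
      error = function(e) NULL)
    if (!is.null(nxt) && all(nxt >= 1)) {
      layout <- c(layout, tok)
      cur <- nxt
    }
  }
  if (!any(layout == "conv")) {
    stop(sprintf("shape error: input %d x %d too small for any %d x %d convolution",
                 input_h, input_w, conv_f, conv_f), call. = FALSE)
  }
  make_topology(input_h, input_w, layout, conv_f = conv_f,
                n_filters = n_filters, n_classes = n_classes)
}

#' Layer-by-layer shape trace
#'
#' Folds the shape algebra over the layer chain and returns one row per
#' layer. For the reference topology the trace reproduces the eight
#' feature-map triples 59x996x6, 55x992x6, 51x988x6, 47x984x6, 43x980x6,
#' 21x490x6, 17x486x6 and 8x243x6, followed by the 2-logit output. The
#' fully connected row reports `h = n_classes, w = 1, l = 1`.
#'
#' @param topo A `cnn_topology`.
#' @return A data.frame with columns `layer`, `kind`, `h`, `w`, `l`.
#' @export
trace_shapes <- function(topo) {
  stopifnot(inherits(topo, "cnn_topology"))
  shape <- topo$input_shape
  rows <- vector("list", length(topo$layers))
  for (i in seq_along(topo$layers)) {
    ly <- topo$layers[[i]]
    shape <- tryCatch(
      switch(ly$kind,
             convolution = conv_output_shape(shape, ly$f, ly$s, ly$n_filters),
             average_pool = pool_output_shape(shape, ly$f, ly$s),
             fully_connected = c(h = topo$n_classes, w = 1L, l = 1L)),
      error = function(e) {
        stop(sprintf("shape error at layer %d (%s): %s", i, ly$kind,
                     conditionMessage(e)), call. = FALSE)
      })
    if (any(shape < 1)) {
      stop(sprintf("shape error at layer %d (%s): non-positive dimension",
                   i, ly$kind), call. = FALSE)
    }
    rows[[i]] <- data.frame(layer = i, kind = ly$kind, h = shape[["h"]],
                            w = shape[["w"]], l = shape[["l"]])
  }
  do.call(rbind, rows)
}

#' Learnable parameter count of a topology
#'
#' Convolution: `f*f*l_in*l_out` weights + `l_out` biases + `2*l_out` batch
#' norm scale/shift when present; fully connected: `n_flat*n_classes + n_classes`.
#'
#' @param topo A `cnn_topology`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(topo) {
  tr <- trace_shapes(topo)
  shape <- topo$input_shape
  total <- 0L
  for (i in seq_along(topo$layers)) {
    ly <- topo$layers[[i]]
    if (ly$kind == "convolution") {
      total <- total + ly$f * ly$f * shape[["l"]] * ly$n_filters +
        ly$n_filters + if ("batch_norm" %in% ly$post_ops) 2L * ly$n_filters else 0L
    } else if (ly$kind == "fully_connected") {
      total <- total + prod(shape) * topo$n_classes + topo$n_classes
    }
    shape <- c(h = tr$h[i], w = tr$w[i], l = tr$l[i])
  }
  as.integer(total)
}

#' @export
#' @method print cnn_topology
print.cnn_topology <- function(x, ...) {
  tr <- trace_shapes(x)
  cat(sprintf("CNN topology: input %d x %d, %d layers, %d classes, %d parameters\n",
              x$input_shape[["h"]], x$input_shape[["w"]], length(x$layers),
              x$n_classes, n_parameters(x)))
  for (i in seq_len(nrow(tr))) {
    ly <- x$layers[[i]]
    desc <- switch(ly$kind,
                   convolution = sprintf("convolution %dx%d/%d, %d filters%s",
                                         ly$f, ly$f, ly$s, ly$n_filters,
                                         if (length(ly$post_ops))
                                           paste0(" + ", paste(ly$post_ops, collapse = "+"))
                                         else ""),
                   average_pool = sprintf("average pool %dx%d/%d", ly$f, ly$f, ly$s),
                   fully_connected = "fully connected + softmax")
    out <- if (ly$kind == "fully_connected") sprintf("%d logits", x$n_classes)
           else sprintf("%d x %d x %d", tr$h[i], tr$w[i], tr$l[i])
    cat(sprintf("  %d. %-40s -> %s\n", i, desc, out))
  }
  invisible(x)
}

#' Serialize / deserialize a topology
#'
#' The architecture is data: a YAML document with the input shape, class
#' count and layer list (kind, filter size, stride, filter count, post-ops).
#'
#' @param topo A `cnn_topology`.
#' @param path File path.
#' @return `write_topology` returns `path` invisibly; `read_topology`
#'   returns the `cnn_topology`.
#' @export
write_topology <- function(topo, path) {
  obj <- list(
    input_h = unname(topo$input_shape[["h"]]),
    input_w = unname(topo$input_shape[["w"]]),
    n_classes = topo$n_classes,
    layers = lapply(topo$layers, function(ly) {
      keep <- list(kind = ly$kind)
      if (!is.na(ly$f)) { keep$f <- ly$f; keep$s <- ly$s }
      if (!is.na(ly$n_filters)) keep$n_filters <- ly$n_filters
      if (length(ly$post_ops)) keep$post_ops <- as.list(ly$post_ops)
      if (ly$activation != "none") keep$activation <- ly$activation
      keep
    }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- yaml::read_yaml(path)
  layers <- lapply(obj$layers, function(ly) {
    layer_spec(ly$kind,
               f = ly$f %||% NA_integer_, s = ly$s %||% NA_integer_,
               n_filters = ly$n_filters %||% NA_integer_,
               post_ops = unlist(ly$post_ops) %||% character(0),
               activation = ly$activation %||% "none")
  })
  topology(obj$input_h, obj$input_w, layers, obj$n_classes)
}
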