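# Network builders: the CycleGAN generator/discriminator pair used for
# HE -> Ki-67 stain translation, the label-channel conditioning operation,
# and the small CNN backbone used by the MIL patch classifiers.

#' Build the stain-translation generator
#'
#' Eight-block fully convolutional encoder-decoder: a 7x7 stem, two stride-2
#' downsampling convolutions, two 3x3 bottleneck convolutions at the lowest
#' resolution (the second normalised but not activated), two stride-2
#' transposed convolutions back to full resolution, and a 7x7 projection to
#' RGB through `tanh`. Instance normalisation follows every convolution except
#' the output projection. Spatial size is preserved for inputs whose sides are
#' divisible by 4, and outputs always lie in \[-1, 1\].
#'
#' @param conditioned logical; if `TRUE` (the pipeline default) the first
#'   convolution takes 4 input channels — RGB plus a constant class-label
#'   plane (see [condition_patch()]). If `FALSE` the classic 3-channel
#'   unconditioned variant is built (kept for ablation).
#' @param width_multiplier scales all internal channel widths (64/128/256 at
#'   1.0). Reduced widths (e.g. 0.25) give desk-scale models with identical
#'   topology; input/output channel counts are unaffected.
#' @param residual logical; if `TRUE` the two bottleneck convolutions form a
#'   residual block (skip connection around them). Default `FALSE`: the plain
#'   printed sequence.
#' @return an object of class `sc_generator`.
#' @export
build_generator <- function(conditioned = TRUE, width_multiplier = 1.0,
                            residual = FALSE) {
  ch <- function(c) max(1L, as.integer(round(c * width_multiplier)))
  cin <- if (conditioned) 4L else 3L
  layers <- list(
    layer_conv(cin, ch(64), k = 7, s = 1, p = 3), layer_inorm(ch(64)), layer_relu(),
    layer_conv(ch(64), ch(128), k = 3, s = 2, p = 1), layer_inorm(ch(128)), layer_relu(),
    layer_conv(ch(128), ch(256), k = 3, s = 2, p = 1), layer_inorm(ch(256)), layer_relu(),
    layer_conv(ch(256), ch(256), k = 3, s = 1, p = 1), layer_inorm(ch(256)), layer_relu(),
    layer_conv(ch(256), ch(256), k = 3, s = 1, p = 1), layer_inorm(ch(256)),
    layer_convt(ch(256), ch(128), k = 3, s = 2, p = 1, op = 1), layer_inorm(ch(128)), layer_relu(),
    layer_convt(ch(128), ch(64), k = 3, s = 2, p = 1, op = 1), layer_inorm(ch(64)), layer_relu(),
    layer_conv(ch(64), 3L, k = 7, s = 1, p = 3), layer_tanh()
  )
  net <- new_net(layers)
  structure(list(net = net, conditioned = conditioned,
                 width_multiplier = width_multiplier, residual = residual,
                 # bottleneck residual join: output of layer 14 += input of layer 10
                 res_from = 10L, res_to = 14L),
            class = "sc_generator")
}

#' Build the PatchGAN-style discriminator
#'
#' 7x7 stem with LeakyReLU(0.2), three stride-2 convolutions with instance
#' normalisation and LeakyReLU(0.2) reaching 512 channels, a 4x4 convolution
#' to a single-channel score map, and global average pooling to one scalar
#' per image. At 224x224 input the pre-pool map is 27x27.
#'
#' @inheritParams build_generator
#' @param in_channels input channels: 3 for plain images (default), 4 when
#'   the discriminator is conditioned on the class-label plane.
#' @return an object of class `sc_discriminator`.
#' @export
build_discriminator <- function(width_multiplier = 1.0, in_channels = 3L) {
  ch <- function(c) max(1L, as.integer(round(c * width_multiplier)))
  layers <- list(
    layer_conv(as.integer(in_channels), ch(64), k = 7, s = 1, p = 3), layer_lrelu(0.2),
    layer_conv(ch(64), ch(128), k = 3, s = 2, p = 1), layer_inorm(ch(128)), layer_lrelu(0.2),
    layer_conv(ch(128), ch(256), k = 3, s = 2, p = 1), layer_inorm(ch(256)), layer_lrelu(0.2),
    layer_conv(ch(256), ch(512), k = 3, s = 2, p = 1), layer_inorm(ch(512)), layer_lrelu(0.2),
    layer_conv(ch(512), 1L, k = 4, s = 1, p = 1),
    layer_gap()
  )
  structure(list(net = new_net(layers), width_multiplier = width_multiplier,
                 in_channels = as.integer(in_channels)),
            class = "sc_discriminator")
}

generator_forward <- function(gen, x, cache = TRUE) {
  if (!gen$residual) return(net_forward(gen$net, x, cache = cache))
  # residual variant: run sequentially but add the bottleneck input back in
  stop_at <- gen$res_from - 1L
  pre <- new_net(gen$net$layers[seq_len(stop_at)])
  mid <- new_net(gen$net$layers[gen$res_from:gen$res_to])
  post <- new_net(gen$net$layers[(gen$res_to + 1L):length(gen$net$layers)])
  f1 <- net_forward(pre, x, cache)
  f2 <- net_forward(mid, f1$out, cache)
  f3 <- net_forward(post, f2$out + f1$out, cache)
  list(out = f3$out, cache = list(pre = f1$cache, mid = f2$cache, post = f3$cache))
}

generator_backward <- function(gen, cache, dout) {
  if (!gen$residual) return(net_backward(gen$net, cache, dout))
  stop_at <- gen$res_from - 1L
  pre <- new_net(gen$net$layers[seq_len(stop_at)])
  mid <- new_net(gen$net$layers[gen$res_from:gen$res_to])
  post <- new_net(gen$net$layers[(gen$res_to + 1L):length(gen$net$layers)])
  b3 <- net_backward(post, cache$post, dout)
  b2 <- net_backward(mid, cache$mid, b3$dx)
  b1 <- net_backward(pre, cache$pre, b2$dx + b3$dx)  # skip adds gradient
  list(grads = c(b1$grads, b2$grads, b3$grads), dx = b1$dx)
}

#' Append a constant class-label channel to a normalised patch batch
#'
#' The class produced by the MIL patch classifier enters the generator as a
#' fourth input plane: TUMOR is encoded +1, NORMAL -1, matching the \[-1, 1\]
#' scale of tanh-normalised pixels. Channel order is (R, G, B, label).
#'
#' @param x normalised patch array, dim (H, W, 3) or (H, W, 3, N), values in
#'   \[-1, 1\].
#' @param label character vector of `"TUMOR"`/`"NORMAL"`, length 1 or N.
#' @return array with dim (H, W, 4, N).
#' @export
condition_patch <- function(x, label) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[3] != 3L) stop("condition_patch: expected 3-channel input")
  bad <- setdiff(unique(label), c("TUMOR", "NORMAL"))
  if (length(bad)) stop("condition_patch: unknown label: ", bad[1])
  label <- rep_len(label, d[4])
  enc <- ifelse(label == "TUMOR", 1, -1)
  out <- array(0, c(d[1], d[2], 4L, d[4]))
  out[, , 1:3, ] <- x
  out[, , 4, ] <- rep(enc, each = d[1] * d[2])
  out
}

#' Remove the label channel from a conditioned patch batch
#' @param x array dim (H, W, 4, N).
#' @return array dim (H, W, 3, N).
#' @export
strip_label_channel <- function(x) {
  d <- dim(x)
  stopifnot(d[3] == 4L)
  x[, , 1:3, , drop = FALSE]
}

#' Normalise 8-bit pixels to the \[-1, 1\] scale used by the networks
#' @param x array of pixel values in \[0, 255\].
#' @export
normalize_pixels <- function(x) x / 127.5 - 1

#' Map network outputs in \[-1, 1\] back to 8-bit pixel values
#' @param x array of values in \[-1, 1\].
#' @export
denormalize_pixels <- function(x) pmin(pmax((x + 1) * 127.5, 0), 255)

# Small CNN backbone for the MIL patch classifier: three stride-2 conv+ReLU
# blocks, global average pooling, and a linear head to the two classes
# (NORMAL = 1, TUMOR = 2 in R's 1-based indexing). No normalisation layers:
# absolute stain darkness is itself a class cue and per-patch normalisation
# would remove it.
build_small_cnn <- function(input_size = 32L) {
  he <- function(k, cin) sqrt(2 / (k * k * cin))
  layers <- list(
    layer_conv(3L, 8L, k = 3, s = 2, p = 1, init_sd = he(3, 3)), layer_relu(),
    layer_conv(8L, 16L, k = 3, s = 2, p = 1, init_sd = he(3, 8)), layer_relu(),
    layer_conv(16L, 32L, k = 3, s = 2, p = 1, init_sd = he(3, 16)), layer_relu(),
    layer_gap(),
    layer_linear(32L, 2L)
  )
  structure(list(net = new_net(layers), backbone = "SMALL_CNN",
                 input_size = as.integer(input_size),
                 classes = c(NORMAL = 0L, TUMOR = 1L)),
            class = "patch_classifier")
}

#' Count of learnable parameters in a generator, discriminator or classifier
#' @param x a network-bearing object.
#' @export
parameter_count <- function(x) {
  net <- if (inherits(x, "sc_net")) x else x$net
  n_params(net)
}
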