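# Module surface: CNN encoder, morphological channel attention, pooling.

#' Run the convolutional encoder
#'
#' Applies the configured conv/ReLU stages to a batch of images and returns
#' the final feature map. For the `"b0"` profile the output has C = 1280
#' channels at 1/32 of the input resolution; for `"tiny"`, C = 32 at 1/8.
#'
#' @param images Array `H x W x 3` (single image) or `H x W x 3 x B` in
#'   `[0,1]`.
#' @param net A `cytoxai_net` (from [init_net()]) or fitted [cytoxai()]
#'   model.
#' @return Feature map array `H' x W' x C x B`.
#' @export
cnn_forward <- function(images, net) {
  net <- as_net(net)
  x <- as_image_batch(images)
  cfg <- net$config
  if (dim(x)[1] %% cfg$stride_prod != 0L ||
      dim(x)[2] %% cfg$stride_prod != 0L)
    stop(sprintf("spatial size %dx%d is not divisible by the stride product %d",
                 dim(x)[1], dim(x)[2], cfg$stride_prod))
  h <- x
  for (i in seq_along(net$params$cnn)) {
    s <- cfg$stages[[i]]
    co <- conv2d_fwd(h, net$params$cnn[[i]]$W, net$params$cnn[[i]]$b,
                     s$k, s$k, s$s, s$p)$out
    h <- pmax(bn_eval(co, net$params$cnn[[i]]$g, net$params$cnn[[i]]$beta,
                      net$buffers$cnn[[i]]$rm, net$buffers$cnn[[i]]$rv), 0)
  }
  h
}

#' Morphological channel attention
#'
#' Computes the channel gate from globally pooled features and applies it:
#' `z` is the spatial mean per channel, `w = sigmoid(W2 relu(W1 z))`, and
#' the feature map is multiplied channel-wise by `w`. The gate is bias-free,
#' so with zero weights `w = 0.5` exactly and the feature map is halved.
#'
#' @param F_map Feature map array `H' x W' x C x B`.
#' @param params List with matrices `W1` (hidden x C) and `W2` (C x hidden).
#' @return List with `F_att` (gated feature map, same shape), `w` (gate,
#'   `B x C`, entries strictly in (0,1)) and `z` (pooled means, `B x C`).
#' @export
morph_attention <- function(F_map, params) {
  d <- dim(F_map)
  if (length(d) == 3L) { dim(F_map) <- c(d, 1L); d <- dim(F_map) }
  stopifnot(length(d) == 4L)
  HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  if (ncol(params$W1) != C || nrow(params$W2) != C)
    stop("gate parameter shapes do not match the channel count")
  Fmat <- matrix(F_map, HW, C * B)
  z <- matrix(colMeans(Fmat), C, B)
  h1 <- pmax(params$W1 %*% z, 0)
  w <- 1 / (1 + exp(-(params$W2 %*% h1)))
  F_att <- array(sweep(Fmat, 2, as.vector(w), "*"), dim = d)
  list(F_att = F_att, w = t(w), z = t(z))
}

#' Global average pooling of a feature map
#'
#' @param F_att Feature map array `H' x W' x C x B` (or `H' x W' x C`).
#' @return Matrix `B x C` of spatial means.
#' @export
pool_cnn <- function(F_att) {
  d <- dim(F_att)
  if (length(d) == 3L) { dim(F_att) <- c(d, 1L); d <- dim(F_att) }
  t(matrix(colMeans(matrix(F_att, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

as_image_batch <- function(images) {
  d <- dim(images)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("images must be an H x W x 3 (x B) array")
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  images
}

as_net <- function(x) {
  if (inherits(x, "cytoxai")) return(x$net)
  if (inherits(x, "cytoxai_net")) return(x)
  stop("expected a 'cytoxai_net' or fitted 'cytoxai' model")
}
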