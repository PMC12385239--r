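# Attribution methods: Grad-CAM, Integrated Gradients, exact and
# gradient-sampled Shapley values, LIME; plus explanation-quality metrics
# and per-sample method selection.
#
# All methods run against a small model interface (logit forward pass,
# input gradients, last-conv activations/gradients) so they can be tested
# on closed-form toy models as well as on fitted networks.

# ---- model interface ---------------------------------------------------

#' Class logits of a model on an image batch
#'
#' Generic used by the attribution methods; implemented for `cytoxai_net`
#' and fitted `cytoxai` models, and implementable for any toy model that
#' exposes logits.
#'
#' @param model The model object.
#' @param images Array `H x W x 3` or `H x W x 3 x B`.
#' @return Matrix `B x K` of logits.
#' @export
predict_scores <- function(model, images) UseMethod("predict_scores")

#' @export
predict_scores.cytoxai_net <- function(model, images) {
  forward_batched(model, as_image_batch(images))$logits
}

#' @export
predict_scores.cytoxai <- function(model, images)
  predict_scores(model$net, images)

#' Gradient of a class logit with respect to the input
#'
#' @param model The model object.
#' @param images Array `H x W x 3` or `H x W x 3 x B`.
#' @param class_index 0-based class whose logit is differentiated (scalar,
#'   recycled over the batch).
#' @return Array shaped like `images`.
#' @export
input_gradient <- function(model, images, class_index)
  UseMethod("input_gradient")

#' @export
input_gradient.cytoxai_net <- function(model, images, class_index) {
  single <- length(dim(images)) == 3L
  x <- as_image_batch(images)
  B <- dim(x)[4]
  fw <- net_forward(model, x)
  dlogits <- matrix(0, B, model$config$n_classes)
  dlogits[cbind(seq_len(B), rep_len(class_index + 1L, B))] <- 1
  g <- net_backward(model, fw$cache, dlogits, wrt_input = TRUE)$dinput
  if (single) g <- array(g, dim = dim(g)[1:3])
  g
}

#' @export
input_gradient.cytoxai <- function(model, images, class_index)
  input_gradient(model$net, images, class_index)

#' Last-convolution activations of a model
#'
#' @param model The model object.
#' @param image Array `H x W x 3`.
#' @return Array `H' x W' x C` of post-ReLU activations.
#' @export
conv_features <- function(model, image) UseMethod("conv_features")

#' @export
conv_features.cytoxai_net <- function(model, image) {
  fm <- net_forward(model, as_image_batch(image),
                    keep_cache = FALSE)$feature_map
  array(fm, dim = dim(fm)[1:3])
}

#' @export
conv_features.cytoxai <- function(model, image)
  conv_features(model$net, image)

#' Gradient of a class logit with respect to the last-conv activations
#'
#' @param model The model object.
#' @param image Array `H x W x 3`.
#' @param class_index 0-based class.
#' @return Array `H' x W' x C`.
#' @export
feature_gradient <- function(model, image, class_index)
  UseMethod("feature_gradient")

#' @export
feature_gradient.cytoxai_net <- function(model, image, class_index) {
  x <- as_image_batch(image)
  fw <- net_forward(model, x)
  dlogits <- matrix(0, 1L, model$config$n_classes)
  dlogits[1L, class_index + 1L] <- 1
  g <- net_backward(model, fw$cache, dlogits)$dFcnn
  array(g, dim = dim(g)[1:3])
}

#' @export
feature_gradient.cytoxai <- function(model, image, class_index)
  feature_gradient(model$net, image, class_index)

#' Wrap arbitrary score/gradient functions as an explainable model
#'
#' Adapter for the attribution methods: any model that can produce class
#' logits (and, for the gradient-based methods, input gradients or
#' last-conv activations) can be explained by wrapping the corresponding
#' functions. Used heavily by the test suite's closed-form toy models.
#'
#' @param score_fn `function(images) -> B x K` logit matrix (images come
#'   as `H x W x 3 x B`).
#' @param gradient_fn Optional `function(images, class_index) ->` array
#'   shaped like `images`, the gradient of the class logit.
#' @param features_fn Optional `function(image) -> H' x W' x C` last-conv
#'   activations.
#' @param feature_gradient_fn Optional
#'   `function(image, class_index) -> H' x W' x C` gradient at those
#'   activations.
#' @return An object of class `cytoxai_manual` usable with [grad_cam()],
#'   [integrated_gradients()], [shap_gradient()], [lime_explain()].
#' @export
manual_model <- function(score_fn, gradient_fn = NULL, features_fn = NULL,
                         feature_gradient_fn = NULL) {
  stopifnot(is.function(score_fn))
  structure(list(score_fn = score_fn, gradient_fn = gradient_fn,
                 features_fn = features_fn,
                 feature_gradient_fn = feature_gradient_fn),
            class = "cytoxai_manual")
}

#' @export
predict_scores.cytoxai_manual <- function(model, images)
  model$score_fn(as_image_batch(images))

#' @export
input_gradient.cytoxai_manual <- function(model, images, class_index) {
  if (is.null(model$gradient_fn))
    stop("this model was wrapped without a gradient function")
  single <- length(dim(images)) == 3L
  g <- model$gradient_fn(as_image_batch(images), class_index)
  if (single) g <- array(g, dim = dim(g)[1:3])
  g
}

#' @export
conv_features.cytoxai_manual <- function(model, image) {
  if (is.null(model$features_fn))
    stop("this model was wrapped without a feature function")
  model$features_fn(image)
}

#' @export
feature_gradient.cytoxai_manual <- function(model, image, class_index) {
  if (is.null(model$feature_gradient_fn))
    stop("this model was wrapped without a feature-gradient function")
  model$feature_gradient_fn(image, class_index)
}

predicted_class <- function(model, image)
  which.max(predict_scores(model, image)[1L, ]) - 1L

class_prob <- function(model, images, class_index) {
  softmax_rows(predict_scores(model, images))[, class_index + 1L]
}

# ---- attribution container --------------------------------------------

new_attribution <- function(values, method, explained_class, ...) {
  structure(c(list(values = values, method = method,
                   explained_class = as.integer(explained_class)),
              list(...)),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  d <- dim(x$values) %||% length(x$values)
  cat(sprintf("Attribution map: method '%s', class %d, shape %s\n",
              x$method, x$explained_class, paste(d, collapse = "x")))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  if (!is.null(x$completeness_gap))
    cat(sprintf("  completeness gap %.4g\n", x$completeness_gap))
  invisible(x)
}

# Collapse an attribution to a single non-negative H x W saliency plane.
attribution_plane <- function(att) {
  v <- att$values
  if (att$method == "lime") {
    seg <- att$segments
    v <- matrix(pmax(v[as.vector(seg) + 1L], 0), nrow(seg), ncol(seg))
    return(v)
  }
  if (!is.null(dim(v)) && length(dim(v)) == 3L)
    v <- apply(abs(v), c(1, 2), sum)
  else v <- abs(v)
  v
}

# ---- Grad-CAM ----------------------------------------------------------

#' Grad-CAM saliency map
#'
#' Pools the spatial gradient of the explained-class logit over each
#' channel of the last convolutional block (`kappa_m`), forms the
#' kappa-weighted sum of the activation channels and rectifies it. The map
#' is non-negative by construction and is bilinearly upsampled to the
#' input resolution (upsampling is presentation-level; quality metrics use
#' the same values either way).
#'
#' @param model Model implementing [conv_features()] and
#'   [feature_gradient()].
#' @param image Array `H x W x 3`.
#' @param class_index 0-based explained class; default the predicted one.
#' @param upsample Upsample the map to the image size (default TRUE).
#' @return An `attribution_map` (`values` = `H x W` map, >= 0; the channel
#'   weights are kept in `$kappa`).
#' @export
grad_cam <- function(model, image, class_index = NULL, upsample = TRUE) {
  cls <- class_index %||% predicted_class(model, image)
  T_act <- conv_features(model, image)
  if (length(dim(T_act)) != 3L)
    stop("the chosen layer has no spatial extent")
  dT <- feature_gradient(model, image, cls)
  C <- dim(T_act)[3]
  kappa <- vapply(seq_len(C), function(m) mean(dT[, , m]), numeric(1))
  map <- matrix(0, dim(T_act)[1], dim(T_act)[2])
  for (m in seq_len(C)) map <- map + kappa[m] * T_act[, , m]
  map <- pmax(map, 0)
  if (upsample) map <- bilinear_resize(map, dim(image)[1], dim(image)[2])
  new_attribution(map, "grad_cam", cls, kappa = kappa)
}

# ---- Integrated Gradients ---------------------------------------------

#' Integrated Gradients attribution
#'
#' Accumulates input gradients of the explained-class logit along the
#' straight path from a baseline (default: the black image) to the input,
#' using a midpoint Riemann approximation with `steps` points, and scales
#' by `(input - baseline)`. The completeness gap
#' `|sum(attribution) - (F(input) - F(baseline))|` is reported alongside
#' and shrinks as `steps` grows.
#'
#' @param model Model implementing [input_gradient()].
#' @param image Array `H x W x 3`.
#' @param baseline Same-shape baseline (default all zeros).
#' @param steps Number of path points (>= 1, default 64).
#' @param class_index 0-based explained class; default predicted.
#' @param batch_size Gradient batch size (default 32).
#' @return An `attribution_map` with `values` `H x W x 3`,
#'   `$completeness_gap` and `$delta_logit`.
#' @export
integrated_gradients <- function(model, image, baseline = NULL, steps = 64L,
                                 class_index = NULL, batch_size = 32L) {
  steps <- check_count(steps, "steps", min = 1L)
  cls <- class_index %||% predicted_class(model, image)
  baseline <- baseline %||% array(0, dim = dim(image))
  if (!identical(dim(baseline), dim(image)))
    stop("baseline and image shapes differ")
  diff <- image - baseline
  taus <- (seq_len(steps) - 0.5) / steps
  avg <- array(0, dim = dim(image))
  for (s in seq(1L, steps, by = batch_size)) {
    e <- min(s + batch_size - 1L, steps)
    nb <- e - s + 1L
    batch <- array(0, dim = c(dim(image), nb))
    for (j in seq_len(nb))
      batch[, , , j] <- baseline + taus[s + j - 1L] * diff
    g <- input_gradient(model, batch, cls)
    avg <- avg + apply(g, 1:3, sum)
  }
  gamma <- diff * (avg / steps)
  f1 <- predict_scores(model, image)[1L, cls + 1L]
  f0 <- predict_scores(model, baseline)[1L, cls + 1L]
  new_attribution(gamma, "integrated_gradients", cls,
                  completeness_gap = abs(sum(gamma) - (f1 - f0)),
                  delta_logit = f1 - f0, baseline_ref = "supplied")
}

# ---- LIME --------------------------------------------------------------

#' Regular grid superpixel segmentation
#'
#' @param h,w Image height and width.
#' @param grid Segments per side (default 4, so 16 superpixels).
#' @return Integer matrix `h x w` of segment ids `0..grid^2-1`, a
#'   partition of the image.
#' @export
grid_segments <- function(h, w = h, grid = 4L) {
  gy <- pmin(floor((seq_len(h) - 1L) / (h / grid)), grid - 1L)
  gx <- pmin(floor((seq_len(w) - 1L) / (w / grid)), grid - 1L)
  matrix(as.integer(outer(gy, gx * grid, "+")), h, w)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Weighted L1-penalized least squares by coordinate descent with an
# unpenalized intercept; objective sum_j w_j (y_j - v0 - v'z_j)^2 +
# lambda * sum |v_k|.
weighted_lasso <- function(Z, y, w, lambda, max_iter = 1000L, tol = 1e-10) {
  S <- ncol(Z)
  v <- numeric(S)
  v0 <- sum(w * y) / sum(w)
  a <- colSums(w * Z * Z)
  if (all(a == 0)) stop("degenerate perturbation design: no variation")
  for (it in seq_len(max_iter)) {
    v_old <- v; v0_old <- v0
    r <- y - v0 - as.vector(Z %*% v)
    v0 <- v0 + sum(w * r) / sum(w)
    r <- y - v0 - as.vector(Z %*% v)
    for (k in seq_len(S)) {
      if (a[k] == 0) next
      rho <- sum(w * Z[, k] * r) + a[k] * v[k]
      vk_new <- soft_threshold(rho, lambda / 2) / a[k]
      if (vk_new != v[k]) {
        r <- r - Z[, k] * (vk_new - v[k])
        v[k] <- vk_new
      }
    }
    if (max(abs(c(v - v_old, v0 - v0_old))) < tol) break
  }
  list(weights = v, intercept = v0, iterations = it)
}

#' LIME superpixel explanation
#'
#' Fits a locally weighted sparse linear surrogate to the model's
#' explained-class probability on superpixel-masked perturbations of the
#' image. Perturbations set masked segments to a fill colour (default: the
#' image's per-channel mean); the proximity kernel is
#' `exp(-d^2 / kernel_width^2)` with `d` the fraction of masked segments;
#' the surrogate is solved by coordinate descent (tolerance 1e-8) on the
#' weighted L1-penalized least squares.
#'
#' @param model Model implementing [predict_scores()].
#' @param image Array `H x W x 3`.
#' @param segments Integer `H x W` segment-id matrix (default a 4x4
#'   [grid_segments()]).
#' @param n_samples Number of perturbations (recommended >= S + 1; the
#'   first sample is always the unperturbed image).
#' @param lambda_l1 Sparsity penalty (default 0.01; 0 gives weighted least
#'   squares).
#' @param kernel_width Proximity kernel width (default 0.25).
#' @param seed Integer seed for the perturbation draws.
#' @param class_index 0-based explained class; default predicted.
#' @param fill Length-3 fill colour for masked segments (default image
#'   mean).
#' @param output Surrogate target: the explained-class `"prob"` (default)
#'   or raw `"logit"`.
#' @return An `attribution_map` with `values` = per-segment weights
#'   (length S), `$intercept`, and `$segments`.
#' @export
lime_explain <- function(model, image, segments = NULL, n_samples = 64L,
                         lambda_l1 = 0.01, kernel_width = 0.25, seed = 1L,
                         class_index = NULL, fill = NULL,
                         output = c("prob", "logit")) {
  output <- match.arg(output)
  d <- dim(image)
  segments <- segments %||% grid_segments(d[1], d[2])
  if (!identical(dim(segments), d[1:2]))
    stop("segments must match the image's spatial size")
  S <- as.integer(max(segments)) + 1L
  ids <- sort(unique(as.integer(segments)))
  if (!identical(ids, 0:(S - 1L)))
    stop("segment ids must be a contiguous partition 0..S-1")
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  cls <- class_index %||% predicted_class(model, image)
  fill <- fill %||% vapply(1:3, function(c) mean(image[, , c]), numeric(1))
  Z <- with_seed(seed, {
    Z <- matrix(rbinom((n_samples - 1L) * S, 1L, 0.5), n_samples - 1L, S)
    rbind(rep(1L, S), Z)
  })
  if (nrow(unique(Z)) < 2L)
    stop("degenerate perturbation design: all samples identical")
  y <- numeric(n_samples)
  for (j in seq_len(n_samples)) {
    pert <- image
    off <- Z[j, as.vector(segments) + 1L] == 0L
    if (any(off)) for (c in 1:3) {
      plane <- pert[, , c]
      plane[matrix(off, d[1], d[2])] <- fill[c]
      pert[, , c] <- plane
    }
    y[j] <- if (output == "prob") class_prob(model, pert, cls)
    else predict_scores(model, pert)[1L, cls + 1L]
  }
  dist <- 1 - rowMeans(Z)
  w <- exp(-dist^2 / kernel_width^2)
  fit <- weighted_lasso(Z, y, w, lambda_l1)
  new_attribution(fit$weights, "lime", cls, intercept = fit$intercept,
                  segments = segments, kernel_weights = w)
}

# ---- Shapley values ----------------------------------------------------

#' Exact Shapley values by subset enumeration
#'
#' Computes the Shapley value of every player of a cooperative game by
#' enumerating all `2^theta` coalitions with the exact combinatorial
#' weights `|B|! (theta-|B|-1)! / theta!`. Guarded to `theta <= 12`
#' features. Satisfies efficiency, symmetry, additivity and the dummy
#' axiom by construction (property-tested).
#'
#' @param value_fn Function taking an integer vector of 1-based member
#'   indices (possibly empty) and returning the coalition's value.
#' @param n_features Number of players `theta` (<= 12).
#' @return Numeric vector of `theta` Shapley values.
#' @examples
#' shap_exact(function(s) length(s), 3)  # each player contributes 1
#' @export
shap_exact <- function(value_fn, n_features) {
  theta <- check_count(n_features, "n_features", min = 1L)
  if (theta > 12L)
    stop("n_features > 12: exact enumeration would need ", 2^theta,
         " evaluations")
  n_sub <- bitwShiftL(1L, theta)
  vals <- numeric(n_sub)
  for (mask in 0:(n_sub - 1L)) {
    members <- which(bitwAnd(bitwShiftR(mask, 0:(theta - 1L)), 1L) == 1L)
    vals[mask + 1L] <- value_fn(members)
  }
  fact <- factorial(0:theta)
  phi <- numeric(theta)
  for (i in seq_len(theta)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(n_sub - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      sz <- sum(bitwAnd(bitwShiftR(mask, 0:(theta - 1L)), 1L))
      wgt <- fact[sz + 1L] * fact[theta - sz] / fact[theta + 1L]
      phi[i] <- phi[i] + wgt * (vals[bitwOr(mask, bit) + 1L] -
                                  vals[mask + 1L])
    }
  }
  phi
}

#' Gradient-sampled Shapley attribution (expected gradients)
#'
#' Estimates per-pixel Shapley-style attributions by the expected-gradients
#' sampler: each draw picks a background image and an interpolation point
#' `tau ~ U(0,1)`, evaluates the input gradient at
#' `b + tau * (x - b)`, and weights it by `(x - b)`. For a linear model
#' this is exact in expectation, and segment sums converge to the exact
#' Shapley values of the induced coalition game.
#'
#' @param model Model implementing [input_gradient()].
#' @param image Array `H x W x 3`.
#' @param background Background distribution: one image, an
#'   `H x W x 3 x M` array, or a list of images. Must be non-empty.
#' @param n_samples Number of draws (default 200).
#' @param seed Integer seed.
#' @param class_index 0-based explained class; default predicted.
#' @param batch_size Gradient batch size (default 32).
#' @return An `attribution_map` with `values` `H x W x 3`.
#' @export
shap_gradient <- function(model, image, background, n_samples = 200L,
                          seed = 1L, class_index = NULL, batch_size = 32L) {
  d <- dim(image)
  bgs <- if (is.list(background)) background
  else if (length(dim(background)) == 4L)
    lapply(seq_len(dim(background)[4]), function(m) background[, , , m])
  else list(background)
  if (length(bgs) == 0L) stop("background must be non-empty")
  for (b in bgs) if (!identical(dim(b), d))
    stop("background images must match the image's shape")
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  cls <- class_index %||% predicted_class(model, image)
  draws <- with_seed(seed, list(bg = sample.int(length(bgs), n_samples,
                                                replace = TRUE),
                                tau = runif(n_samples)))
  acc <- array(0, dim = d)
  for (s in seq(1L, n_samples, by = batch_size)) {
    e <- min(s + batch_size - 1L, n_samples)
    nb <- e - s + 1L
    batch <- array(0, dim = c(d, nb))
    for (j in seq_len(nb)) {
      b <- bgs[[draws$bg[s + j - 1L]]]
      batch[, , , j] <- b + draws$tau[s + j - 1L] * (image - b)
    }
    g <- input_gradient(model, batch, cls)
    for (j in seq_len(nb)) {
      b <- bgs[[draws$bg[s + j - 1L]]]
      acc <- acc + g[, , , j] * (image - b)
    }
  }
  new_attribution(acc / n_samples, "shap", cls,
                  n_samples = n_samples, baseline_ref = "background set")
}

# ---- quality and selection --------------------------------------------

#' Explanation quality: mask IoU or deletion fidelity
#'
#' With a ground-truth mask, binarizes the attribution at its top-`q`
#' quantile (`q` = the mask's area fraction) and returns the intersection
#' over union with the mask. Without a mask, returns the normalized drop
#' in the explained-class probability after deleting (zeroing) the top 20%
#' attributed pixels; a constant predictor scores 0.
#'
#' @param att An `attribution_map`.
#' @param mask Optional binary `H x W` matrix (nucleus ground truth).
#' @param model,image Required for fidelity mode.
#' @param top_frac Deleted fraction in fidelity mode (default 0.2).
#' @return A score in `[0, 1]`.
#' @export
explanation_quality <- function(att, mask = NULL, model = NULL,
                                image = NULL, top_frac = 0.2) {
  stopifnot(inherits(att, "attribution_map"))
  plane <- attribution_plane(att)
  if (!is.null(mask)) {
    mask <- mask > 0
    if (!any(mask)) stop("empty mask")
    if (!identical(dim(plane), dim(mask)))
      plane <- bilinear_resize(plane, nrow(mask), ncol(mask))
    q <- mean(mask)
    thr <- stats::quantile(plane, 1 - q, names = FALSE)
    bin <- plane >= thr & plane > 0
    inter <- sum(bin & mask); uni <- sum(bin | mask)
    return(if (uni == 0L) 0 else inter / uni)
  }
  if (is.null(model) || is.null(image))
    stop("fidelity mode needs 'model' and 'image'")
  if (!identical(dim(plane), dim(image)[1:2]))
    plane <- bilinear_resize(plane, dim(image)[1], dim(image)[2])
  p0 <- class_prob(model, image, att$explained_class)
  thr <- stats::quantile(plane, 1 - top_frac, names = FALSE)
  kill <- plane >= thr
  masked <- image
  for (c in 1:3) {
    pl <- masked[, , c]; pl[kill] <- 0; masked[, , c] <- pl
  }
  p1 <- class_prob(model, masked, att$explained_class)
  if (p0 <= 0) return(0)
  clip01((p0 - p1) / p0)
}

#' Select the attribution method per sample from a policy
#'
#' Argmax over the policy rows with lowest-index tie-breaking (the method
#' order is fixed; see [xai_methods()]).
#'
#' @param policy Matrix `B x 4` of method weights (rows on the simplex) or
#'   a length-4 vector.
#' @return Data frame with `method` (factor in [xai_methods()] order) and
#'   `weight` (the winning weight).
#' @export
select_explanation <- function(policy) {
  policy <- rbind(policy)
  if (ncol(policy) != 4L) stop("a policy has 4 method weights per row")
  if (any(abs(rowSums(policy) - 1) > 1e-6) || any(policy < -1e-9))
    stop("policy rows must lie on the probability simplex")
  idx <- max.col(policy, ties.method = "first")
  data.frame(method = factor(xai_methods()[idx], levels = xai_methods()),
             weight = policy[cbind(seq_len(nrow(policy)), idx)])
}

#' Explain one image with the policy-selected (or a chosen) method
#'
#' Convenience front-end: runs the model, picks the attribution method
#' from the fitted policy head (`method = "auto"`) or uses the requested
#' one, and computes the attribution for the predicted class.
#'
#' @param model A fitted [cytoxai()] model (or `cytoxai_net`).
#' @param image Array `H x W x 3`.
#' @param method `"auto"` or one of [xai_methods()].
#' @param seed Seed for the sampled methods (default 1).
#' @param ... Passed to the chosen attribution function.
#' @return An `attribution_map` (with `$policy` attached when auto-selected).
#' @export
explain <- function(model, image, method = "auto", seed = 1L, ...) {
  net <- as_net(model)
  pol <- NULL
  if (identical(method, "auto")) {
    fw <- net_forward(net, as_image_batch(image), keep_cache = FALSE)
    if (is.null(fw$policy))
      stop("this configuration has no policy head; pick a method explicitly")
    pol <- fw$policy
    method <- as.character(select_explanation(pol)$method[1L])
  }
  method <- match.arg(method, xai_methods())
  att <- switch(method,
                grad_cam = grad_cam(net, image, ...),
                integrated_gradients = integrated_gradients(net, image, ...),
                shap = shap_gradient(net, image,
                                     background = array(0, dim = dim(image)),
                                     seed = seed, ...),
                lime = lime_explain(net, image, seed = seed, ...))
  if (!is.null(pol)) att$policy <- pol
  att
}
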