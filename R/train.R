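# Training harness: splits, the fitting front-end, cross-validation and
# model profiling.

#' Stratified fixed train/validation split
#'
#' Splits a manifest into disjoint train and validation parts, preserving
#' class proportions (per-class validation fraction within one row of
#' `frac`). Deterministic for a given seed.
#'
#' @param manifest Manifest data frame; every class needs at least 2 rows.
#' @param frac Validation fraction (default 0.2).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default TRUE).
#' @return List with `train` and `val` manifests.
#' @export
fixed_split <- function(manifest, frac = 0.2, seed = 1L, stratified = TRUE) {
  manifest <- as_manifest(manifest)
  check_range(frac, "frac", 0, 1, lo_open = TRUE, hi_open = TRUE)
  counts <- class_counts(manifest)
  if (any(counts < 2L))
    stop("every class needs at least 2 rows to split")
  val_idx <- integer(0)
  if (stratified) {
    for (cl in sort(names(counts))) {
      rows <- which(manifest$label == cl)
      n_val <- max(1L, min(length(rows) - 1L, round(length(rows) * frac)))
      pick <- with_seed(derive_seed(seed, match(cl, sort(names(counts)))),
                        sample(rows, n_val))
      val_idx <- c(val_idx, pick)
    }
  } else {
    n_val <- max(1L, min(nrow(manifest) - 1L, round(nrow(manifest) * frac)))
    val_idx <- with_seed(seed, sample(nrow(manifest), n_val))
  }
  list(train = as_manifest(manifest[-val_idx, , drop = FALSE]),
       val = as_manifest(manifest[sort(val_idx), , drop = FALSE]))
}

#' Stratified k-fold split
#'
#' Partitions a manifest into `k` non-overlapping folds (stratified by
#' class by default): fold `i`'s validation set is the i-th part and its
#' training set is the union of the rest. A fixed seed drives all
#' shuffling, so fold assignment is reproducible.
#'
#' @param manifest Manifest data frame with at least `k` rows.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param stratified Stratify folds by class (default TRUE).
#' @return List of `k` elements, each a list with `train` and `val`.
#' @export
kfold_split <- function(manifest, k = 5L, seed = 1L, stratified = TRUE) {
  manifest <- as_manifest(manifest)
  k <- check_count(k, "k", min = 2L)
  if (nrow(manifest) < k)
    stop(sprintf("need at least %d rows for %d folds", k, k))
  fold_of <- integer(nrow(manifest))
  if (stratified) {
    classes <- sort(unique(manifest$label))
    for (cl in classes) {
      rows <- which(manifest$label == cl)
      ord <- with_seed(derive_seed(seed, match(cl, classes)),
                       sample(rows))
      fold_of[ord] <- rep_len(seq_len(k), length(ord))
    }
  } else {
    ord <- with_seed(seed, sample(nrow(manifest)))
    fold_of[ord] <- rep_len(seq_len(k), nrow(manifest))
  }
  lapply(seq_len(k), function(i)
    list(train = as_manifest(manifest[fold_of != i, , drop = FALSE]),
         val = as_manifest(manifest[fold_of == i, , drop = FALSE])))
}

# Batched forward pass without caches; returns user-facing outputs.
forward_batched <- function(net, images, batch_size = 32L) {
  B <- dim(images)[4]
  K <- net$config$n_classes
  logits <- matrix(0, B, K)
  policy <- if (has_policy(net$config))
    matrix(0, B, net$config$n_methods) else NULL
  starts <- seq(1L, B, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, B)
    fw <- net_forward(net, images[, , , s:e, drop = FALSE],
                      keep_cache = FALSE)
    logits[s:e, ] <- fw$logits
    if (!is.null(policy)) policy[s:e, ] <- fw$policy
  }
  probs <- softmax_rows(logits)
  list(logits = logits, probs = probs, policy = policy)
}

# Precise batch-norm recalibration: replace the exponentially decayed
# running statistics by the exact average of batch statistics over the
# training set, so evaluation reflects the current parameters rather than
# a lagged mixture from earlier optimizer steps.
recalibrate_bn <- function(net, images, batch_size) {
  B <- dim(images)[4]
  for (l in seq_along(net$buffers$cnn)) {
    net$buffers$cnn[[l]]$rm[] <- 0
    net$buffers$cnn[[l]]$rv[] <- 0
  }
  k <- 0L
  for (s in seq(1L, B, by = batch_size)) {
    e <- min(s + batch_size - 1L, B)
    k <- k + 1L
    fw <- net_forward(net, images[, , , s:e, drop = FALSE],
                      keep_cache = FALSE, train = TRUE, bn_momentum = 1 / k)
    net$buffers <- fw$buffers
  }
  net$buffers
}

# Per-method explanation quality on a handful of images: IoU against the
# nucleus mask when one exists, deletion fidelity otherwise.
epoch_quality <- function(net, images, masks, seed) {
  n <- dim(images)[4]
  q <- matrix(NA_real_, n, 4L)
  seg <- NULL
  for (i in seq_len(n)) {
    img <- images[, , , i]
    mask <- masks[[i]]
    fw <- net_forward(net, array(img, dim = c(dim(img), 1L)),
                      keep_cache = FALSE)
    cls <- which.max(fw$logits[1L, ]) - 1L
    atts <- list(
      grad_cam(net, img, class_index = cls),
      shap_gradient(net, img, background = array(0, dim = dim(img)),
                    n_samples = 8L, seed = derive_seed(seed, i),
                    class_index = cls),
      integrated_gradients(net, img, steps = 8L, class_index = cls),
      lime_explain(net, img, n_samples = 20L,
                   seed = derive_seed(seed, 1000L + i), class_index = cls))
    for (k in 1:4)
      q[i, k] <- explanation_quality(atts[[k]], mask = mask, model = net,
                                     image = img)
  }
  colMeans(q)
}

#' Fit the hybrid blood-smear classifier
#'
#' The fitting front-end: encodes labels, initializes the network from the
#' seed, and trains for `epochs` epochs of mini-batch gradient descent on
#' the composite loss (cross-entropy plus, when the policy head is present
#' and `lambda_x > 0`, the explanation-quality auxiliary term). Per-epoch
#' accuracy and loss on both the training and validation sets are recorded
#' in `$history`. The model is re-initialized from `seed` at the start of
#' every call, so repeated calls are bitwise reproducible.
#'
#' The per-method explanation-quality signal is recomputed once per epoch
#' on `quality_n` training images (mask IoU when the manifest carries
#' nucleus masks, deletion fidelity otherwise) and held fixed within the
#' epoch; `quality_mode = "none"` (or `lambda_x = 0`) trains on plain
#' cross-entropy.
#'
#' @param manifest Training manifest (see [as_manifest()]).
#' @param val Validation manifest, or `NULL` to carve a stratified
#'   `val_frac` split out of `manifest`.
#' @param config A [model_config()] (default tiny profile sized to the
#'   manifest's classes).
#' @param optimizer An [optimizer_spec()] (default SGD preset).
#' @param epochs Training epochs (>= 1, default 10).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed controlling initialization, shuffling and the
#'   quality subsample.
#' @param val_frac Validation fraction when `val` is NULL (default 0.2).
#' @param lambda_x Weight of the explanation-quality auxiliary loss
#'   (default 0.1; ignored when the configuration has no policy head).
#' @param quality_n Images per epoch used for the quality signal
#'   (default 4).
#' @param quality_mode `"per_epoch"` (default) or `"none"`.
#' @param ema_decay Polyak-Ruppert iterate averaging. A fixed-rate
#'   momentum optimizer ends in a limit cycle around the minimum, so the
#'   raw final iterate is a lottery over that cycle; the averaged iterate
#'   sits at the cycle's centre. `"epoch"` (default) reports, and finally
#'   returns, the uniform average of the iterates within each epoch;
#'   `"tail"` averages uniformly over the whole second half of training;
#'   a number in (0,1) uses an exponential moving average with that
#'   per-step decay instead; `NULL` disables averaging.
#' @param clip_norm Global gradient-norm ceiling (default `Inf`, off);
#'   when finite, gradients are rescaled so their overall norm never
#'   exceeds it.
#' @param agc_lambda Adaptive gradient clipping factor (default 0.5):
#'   each parameter array's gradient is rescaled so the implied update is
#'   at most `agc_lambda` times the array's own norm. This keeps the
#'   momentum-heavy presets from throwing small-scale layers (the
#'   transformer projections) into saturation while letting large layers
#'   move freely. `Inf` disables.
#' @param checkpoint Optional path; the fitted model is `saveRDS()`d there
#'   after the final epoch.
#' @param verbose Print per-epoch progress (default FALSE).
#' @return An object of class `cytoxai` with elements `net`, `encoder`,
#'   `history`, `config`, `optimizer`, `seed`.
#' @seealso [evaluate()], [cross_validate()], [predict.cytoxai()]
#' @export
cytoxai <- function(manifest, val = NULL, config = NULL, optimizer = NULL,
                    epochs = 10L, batch_size = 32L, seed = 1L,
                    val_frac = 0.2, lambda_x = 0.1, quality_n = 4L,
                    quality_mode = c("per_epoch", "none"),
                    ema_decay = "epoch", clip_norm = Inf, agc_lambda = 0.5,
                    checkpoint = NULL, verbose = FALSE) {
  quality_mode <- match.arg(quality_mode)
  epochs <- check_count(epochs, "epochs", min = 1L)
  batch_size <- check_count(batch_size, "batch_size", min = 1L)
  manifest <- as_manifest(manifest)
  if (nrow(manifest) == 0L) stop("empty training manifest")
  if (is.null(val)) {
    sp <- fixed_split(manifest, frac = val_frac, seed = seed)
    manifest <- sp$train; val <- sp$val
  } else val <- as_manifest(val)
  encoder <- label_encoder(c(manifest$label, val$label))
  K <- length(encoder$vocabulary)
  config <- config %||% model_config("tiny", n_classes = K)
  if (config$n_classes != K)
    stop(sprintf("config has %d classes but the data has %d",
                 config$n_classes, K))
  optimizer <- optimizer %||% optimizer_spec("sgd")
  y_tr <- encode_labels(manifest$label, encoder)$codes
  y_va <- encode_labels(val$label, encoder)$codes
  x_tr <- load_manifest_images(manifest, config$side)
  x_va <- load_manifest_images(val, config$side)

  net <- init_net(config, seed = seed)
  opt <- make_optimizer(optimizer, net$params)
  avg_mode <- if (is.null(ema_decay)) "none" else
    if (identical(ema_decay, "epoch")) "epoch" else
    if (identical(ema_decay, "tail")) "tail" else "ema"
  tail_start <- epochs %/% 2L + 1L
  use_ema <- avg_mode != "none"
  avg_params <- if (use_ema) net$params else NULL
  n <- length(y_tr)
  use_aux <- has_policy(config) && lambda_x > 0 &&
    quality_mode == "per_epoch"
  qual_idx <- if (use_aux)
    with_seed(derive_seed(seed, 777L),
              sample(n, min(quality_n, n))) else integer(0)
  qual_masks <- lapply(qual_idx, function(i) {
    mp <- manifest$mask_path[i]
    if (is.na(mp) || !file.exists(mp)) NULL else {
      m <- load_image(mp, side = NULL)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      round(m)
    }
  })
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        train_acc = NA_real_, val_loss = NA_real_,
                        val_acc = NA_real_)
  quality <- rep(NA_real_, 4L)
  k_avg <- 0L
  for (ep in seq_len(epochs)) {
    if (avg_mode == "epoch" || (avg_mode == "tail" && ep == tail_start)) {
      k_avg <- 0L; avg_params <- net$params
    }
    if (use_aux)
      quality <- epoch_quality(net, x_tr[, , , qual_idx, drop = FALSE],
                               qual_masks, seed = derive_seed(seed, ep))
    ord <- with_seed(derive_seed(seed, 10000L + ep), sample(n))
    for (s in seq(1L, n, by = batch_size)) {
      e <- min(s + batch_size - 1L, n)
      bi <- ord[s:e]
      nb <- length(bi)
      fw <- net_forward(net, x_tr[, , , bi, drop = FALSE], train = TRUE)
      net$buffers <- fw$buffers
      onehot <- matrix(0, nb, K)
      onehot[cbind(seq_len(nb), y_tr[bi] + 1L)] <- 1
      dlogits <- (fw$probs - onehot) / nb
      dpolicy <- NULL
      if (use_aux && !anyNA(quality))
        dpolicy <- matrix(rep(-lambda_x * quality / nb, each = nb), nb, 4L)
      bw <- net_backward(net, fw$cache, dlogits, dpolicy)
      if (is.finite(agc_lambda))
        bw$grads <- nn_map2(function(w, g) {
          gn <- sqrt(sum(g * g))
          cap <- agc_lambda * max(sqrt(sum(w * w)), 1e-3)
          if (gn > cap) g * (cap / gn) else g
        }, net$params, bw$grads)
      gnorm <- nn_global_norm(bw$grads)
      if (is.finite(clip_norm) && gnorm > clip_norm)
        bw$grads <- nn_map(function(g) g * (clip_norm / gnorm), bw$grads)
      net$params <- opt$step(net$params, bw$grads)
      if (avg_mode == "ema")
        avg_params <- nn_map2(function(a, p)
          ema_decay * a + (1 - ema_decay) * p, avg_params, net$params)
      else if (avg_mode == "epoch" ||
               (avg_mode == "tail" && ep >= tail_start)) {
        k_avg <- k_avg + 1L
        avg_params <- nn_map2(function(a, p) a + (p - a) / k_avg,
                              avg_params, net$params)
      }
    }
    eval_net <- net
    if (use_ema && (avg_mode != "tail" || ep >= tail_start))
      eval_net$params <- avg_params
    eval_net$buffers <- recalibrate_bn(eval_net, x_tr, batch_size)
    net$buffers <- eval_net$buffers
    tr <- forward_batched(eval_net, x_tr, batch_size)
    va <- forward_batched(eval_net, x_va, batch_size)
    aux_term <- if (use_aux && !anyNA(quality) && !is.null(tr$policy))
      lambda_x * (1 - mean(tr$policy %*% quality)) else 0
    history$train_loss[ep] <- cross_entropy(tr$probs, y_tr) + aux_term
    history$train_acc[ep] <- mean(max.col(tr$probs, "first") - 1L == y_tr)
    history$val_loss[ep] <- cross_entropy(va$probs, y_va)
    history$val_acc[ep] <- mean(max.col(va$probs, "first") - 1L == y_va)
    if (verbose)
      message(sprintf(
        "epoch %2d/%d  train loss %.4f acc %.4f | val loss %.4f acc %.4f",
        ep, epochs, history$train_loss[ep], history$train_acc[ep],
        history$val_loss[ep], history$val_acc[ep]))
  }
  if (use_ema) {
    net$params <- avg_params
    net$buffers <- recalibrate_bn(net, x_tr, batch_size)
  }
  fit <- structure(list(net = net, encoder = encoder, history = history,
                        config = config, optimizer = optimizer,
                        seed = as.integer(seed), lambda_x = lambda_x,
                        quality = quality,
                        n_train = n, n_val = length(y_va),
                        call = match.call()),
                   class = "cytoxai")
  if (!is.null(checkpoint)) saveRDS(fit, checkpoint)
  fit
}

#' @export
print.cytoxai <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("cytoxai model (profile '%s', ablation '%s', %d classes)\n",
              x$config$profile, x$config$ablation, x$config$n_classes))
  cat(sprintf("  trained %d epochs on %d images (%s optimizer)\n",
              nrow(x$history), x$n_train, x$optimizer$name))
  cat(sprintf("  final train acc %.4f | val acc %.4f\n",
              h$train_acc, h$val_acc))
  invisible(x)
}

#' @export
summary.cytoxai <- function(object, ...) {
  print(object)
  prof <- profile_model(object$config)
  cat(sprintf("  parameters %s, approx. MACs per image %s\n",
              format(prof$parameters, big.mark = ","),
              format(prof$macs, big.mark = ",")))
  cat("  training history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Predict from a fitted model
#'
#' @param object A fitted [cytoxai()] model.
#' @param newdata A manifest data frame or an image array
#'   (`H x W x 3 (x B)`); manifests are loaded at the model's input side.
#' @param type `"class"` (factor of predicted labels), `"prob"`,
#'   `"logits"`, or `"policy"` (the per-sample attribution-method weights).
#' @param batch_size Forward batch size (default 32).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.cytoxai <- function(object, newdata,
                            type = c("class", "prob", "logits", "policy"),
                            batch_size = 32L, ...) {
  type <- match.arg(type)
  images <- if (is.data.frame(newdata))
    load_manifest_images(as_manifest(newdata), object$config$side)
  else as_image_batch(newdata)
  out <- forward_batched(object$net, images, batch_size)
  switch(type,
         class = factor(object$encoder$vocabulary[
           max.col(out$probs, ties.method = "first")],
           levels = object$encoder$vocabulary),
         prob = structure(out$probs,
                          dimnames = list(NULL, object$encoder$vocabulary)),
         logits = out$logits,
         policy = {
           if (is.null(out$policy))
             stop("this configuration has no policy head")
           structure(out$policy, dimnames = list(NULL, xai_methods()))
         })
}

#' Plot training history
#'
#' @param x A fitted [cytoxai()] model.
#' @param ... Unused.
#' @export
plot.cytoxai <- function(x, ...) {
  h <- x$history
  old <- par(mfrow = c(1, 2)); on.exit(par(old))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Loss", ylim = range(c(h$train_loss, h$val_loss)))
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", c("train", "val"), lty = 1:2, bty = "n")
  plot(h$epoch, h$train_acc, type = "l", xlab = "epoch", ylab = "accuracy",
       main = "Accuracy", ylim = c(0, 1))
  lines(h$epoch, h$val_acc, lty = 2)
  legend("bottomright", c("train", "val"), lty = 1:2, bty = "n")
  invisible(x)
}

#' k-fold cross-validation
#'
#' Trains `k` independent models (fresh initialization and optimizer state
#' per fold, seeded from `seed` and the fold index), evaluates each on its
#' held-out fold, and aggregates: mean accuracy is the unweighted mean of
#' the per-fold accuracies, and mean loss the mean of the per-fold
#' validation losses.
#'
#' @param manifest Manifest to cross-validate on.
#' @param config,optimizer,epochs,batch_size,seed,lambda_x,quality_n,quality_mode
#'   Passed to [cytoxai()].
#' @param k Number of folds (default 5).
#' @param checkpoint_dir Optional directory; fold models are saved there as
#'   `fold_<i>.rds`.
#' @param verbose Print per-fold progress.
#' @return Object of class `cytoxai_cv`: `folds` (per-fold
#'   `metrics_report`s), `fold_accuracy`, `mean_accuracy`, `mean_loss`.
#' @export
cross_validate <- function(manifest, config = NULL, optimizer = NULL,
                           k = 5L, epochs = 10L, batch_size = 32L,
                           seed = 1L, lambda_x = 0.1, quality_n = 4L,
                           quality_mode = "per_epoch", ema_decay = "epoch",
                           clip_norm = Inf, agc_lambda = 0.5,
                           checkpoint_dir = NULL, verbose = FALSE) {
  folds <- kfold_split(manifest, k = k, seed = seed)
  reports <- vector("list", k)
  losses <- numeric(k)
  for (i in seq_len(k)) {
    if (verbose) message(sprintf("fold %d/%d", i, k))
    ck <- if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      file.path(checkpoint_dir, sprintf("fold_%d.rds", i))
    } else NULL
    fit <- cytoxai(folds[[i]]$train, val = folds[[i]]$val, config = config,
                   optimizer = optimizer, epochs = epochs,
                   batch_size = batch_size, seed = derive_seed(seed, i),
                   lambda_x = lambda_x, quality_n = quality_n,
                   quality_mode = quality_mode, ema_decay = ema_decay,
                   clip_norm = clip_norm, agc_lambda = agc_lambda,
                   checkpoint = ck, verbose = verbose)
    reports[[i]] <- evaluate(fit, folds[[i]]$val, batch_size = batch_size)
    losses[i] <- fit$history$val_loss[nrow(fit$history)]
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  structure(list(folds = reports, fold_accuracy = acc,
                 mean_accuracy = mean(acc), mean_loss = mean(losses),
                 k = k, seed = as.integer(seed)),
            class = "cytoxai_cv")
}

#' @export
print.cytoxai_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  cat("  fold accuracies:", paste(sprintf("%.4f", x$fold_accuracy),
                                  collapse = ", "), "\n")
  cat(sprintf("  mean accuracy %.4f | mean val loss %.4f\n",
              x$mean_accuracy, x$mean_loss))
  invisible(x)
}

#' Parameter and multiply-accumulate profile of a configuration
#'
#' Counts the exact number of trainable parameters (by instantiating the
#' configuration) and estimates multiply-accumulate operations per image
#' from per-layer closed forms: `Hout*Wout*Cout*Cin*k^2` per convolution,
#' `in*out` per linear map, and `4*N*D^2 + 2*N^2*D` per attention block
#' plus its MLP.
#'
#' @param config A [model_config()].
#' @return List with `parameters` (exact count) and `macs` (estimate).
#' @export
profile_model <- function(config) {
  stopifnot(inherits(config, "cytoxai_config"))
  net <- init_net(config, seed = 1L)
  n_par <- nn_count(net$params)
  side <- config$side
  macs <- 0
  cin <- 3L; h <- side
  for (s in config$stages) {
    h <- h %/% s$s
    macs <- macs + h * h * s$out * cin * s$k^2
    cin <- s$out
  }
  C <- cnn_channels(config)
  if (has_gate(config)) {
    hid <- max(1L, C %/% config$gate_reduction)
    macs <- macs + C * hid * 2
  }
  if (has_vit(config)) {
    v <- config$vit
    N1 <- (side %/% v$P)^2 + 1L
    macs <- macs + (N1 - 1L) * v$D * v$P^2 * 3       # patch projection
    per_block <- 4 * N1 * v$D^2 + 2 * N1^2 * v$D +
      2 * N1 * v$D * round(v$D * v$mlp_ratio)
    macs <- macs + v$L * per_block
    macs <- macs + N1 * v$D^2 + N1 * v$D              # concept scorer
  }
  fuse_in <- C + if (has_vit(config)) config$vit$D else 0L
  if (has_bridge(config)) {
    macs <- macs + if (config$ablation == "no_bridge")
      fuse_in * config$bridge_out
    else fuse_in * config$bridge_hidden +
      config$bridge_hidden * config$bridge_out
  }
  cls_in <- if (has_bridge(config)) config$bridge_out else C
  macs <- macs + cls_in * config$cls_hidden +
    config$cls_hidden * config$n_classes
  if (has_policy(config))
    macs <- macs + config$bridge_out * config$policy_hidden +
      config$policy_hidden * config$n_methods
  list(parameters = n_par, macs = macs)
}
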