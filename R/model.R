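# Model configuration, parameter initialization, and the assembled
# forward/backward passes of the hybrid classifier.

ablation_names <- function()
  c("full", "no_bridge", "no_meta_xai", "no_morph", "no_vit", "cnn_only")

has_vit <- function(cfg) !cfg$ablation %in% c("no_vit", "cnn_only")
has_bridge <- function(cfg) !cfg$ablation %in% c("cnn_only")
has_gate <- function(cfg) cfg$ablation != "no_morph"
has_policy <- function(cfg) !cfg$ablation %in% c("no_meta_xai", "cnn_only")

#' Configure the hybrid classifier
#'
#' Two built-in profiles are provided. `"tiny"` is a three-stage, 32-channel
#' convolutional encoder with a small transformer (patch 8, width 64, two
#' blocks), cheap enough for CPU training and for the whole test suite.
#' `"b0"` follows the published feature contracts of the full-scale model: a
#' stride-32 convolutional encoder with C = 1280 output channels and a
#' transformer with patch 16, width 768, depth 6, heads 8, so the pooled
#' widths are 1280 (CNN) and 768 (transformer) and the fused vector is 256
#' wide.
#'
#' @param profile `"tiny"` or `"b0"`.
#' @param n_classes Number of diagnostic classes K (default 4).
#' @param side Input image side in pixels (default 64 for tiny, 128 for b0);
#'   must be divisible by the CNN stride product and the patch size.
#' @param ablation One of `"full"`, `"no_bridge"`, `"no_meta_xai"`,
#'   `"no_morph"`, `"no_vit"`, `"cnn_only"` (see [ablate()]).
#' @param gate_reduction Channel reduction of the morphological gate's
#'   hidden layer (squeeze-excitation convention, default 16).
#' @param bridge_hidden Hidden width of the fusion layer (default 256 tiny /
#'   512 b0; the fused output width is fixed at 256).
#' @param cls_hidden Hidden width of the classifier head (default 256).
#' @param use_positions Add learnable positional encodings to patch tokens
#'   (default TRUE; disabling makes token pooling patch-permutation
#'   invariant, which the tests exploit).
#' @return An object of class `cytoxai_config`.
#' @export
model_config <- function(profile = c("tiny", "b0"), n_classes = 4L,
                         side = NULL, ablation = "full",
                         gate_reduction = 16L, bridge_hidden = NULL,
                         cls_hidden = 256L, use_positions = TRUE) {
  profile <- match.arg(profile)
  if (!ablation %in% ablation_names())
    stop("unknown ablation '", ablation, "'; one of: ",
         paste(ablation_names(), collapse = ", "))
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (profile == "tiny") {
    stages <- list(list(out = 16L, k = 3L, s = 2L, p = 1L),
                   list(out = 32L, k = 3L, s = 2L, p = 1L),
                   list(out = 32L, k = 3L, s = 2L, p = 1L))
    vit <- list(P = 8L, D = 64L, L = 2L, heads = 4L, mlp_ratio = 2)
    side <- side %||% 64L
    bridge_hidden <- bridge_hidden %||% 256L
  } else {
    stages <- list(list(out = 32L, k = 3L, s = 2L, p = 1L),
                   list(out = 64L, k = 3L, s = 2L, p = 1L),
                   list(out = 128L, k = 3L, s = 2L, p = 1L),
                   list(out = 320L, k = 3L, s = 2L, p = 1L),
                   list(out = 1280L, k = 3L, s = 2L, p = 1L))
    vit <- list(P = 16L, D = 768L, L = 6L, heads = 8L, mlp_ratio = 4)
    side <- side %||% 128L
    bridge_hidden <- bridge_hidden %||% 512L
  }
  side <- check_count(side, "side", min = 16L)
  stride_prod <- prod(vapply(stages, function(s) s$s, numeric(1)))
  if (side %% stride_prod != 0L)
    stop_field("side", sprintf("must be divisible by the CNN stride product %d",
                               stride_prod))
  if (side %% vit$P != 0L)
    stop_field("side", sprintf("must be divisible by the patch size %d",
                               vit$P))
  structure(list(profile = profile, stages = stages, vit = vit,
                 side = side, n_classes = n_classes, ablation = ablation,
                 gate_reduction = as.integer(gate_reduction),
                 bridge_hidden = as.integer(bridge_hidden),
                 bridge_out = 256L, cls_hidden = as.integer(cls_hidden),
                 policy_hidden = 64L, n_methods = 4L,
                 use_positions = isTRUE(use_positions),
                 stride_prod = stride_prod),
            class = "cytoxai_config")
}

#' Derive an ablated model configuration
#'
#' Returns the base configuration with one architectural component removed:
#' `no_bridge` replaces the bounded fusion layer by a plain linear
#' projection to 256; `no_meta_xai` drops the policy head (and with it the
#' auxiliary explanation-quality loss); `no_morph` fixes the channel gate
#' to 1; `no_vit` removes the transformer branch (the fusion sees only the
#' pooled CNN vector); `cnn_only` classifies the pooled CNN features
#' directly; `full` is the identity.
#'
#' @param config A [model_config()].
#' @param name Ablation name.
#' @return The modified configuration.
#' @export
ablate <- function(config, name) {
  stopifnot(inherits(config, "cytoxai_config"))
  if (!name %in% ablation_names())
    stop("unknown ablation '", name, "'; one of: ",
         paste(ablation_names(), collapse = ", "))
  config$ablation <- name
  config
}

#' @export
print.cytoxai_config <- function(x, ...) {
  C <- x$stages[[length(x$stages)]]$out
  cat(sprintf("cytoxai model config: profile '%s', ablation '%s'\n",
              x$profile, x$ablation))
  cat(sprintf("  input %dx%d, CNN C=%d (stride %d), ViT P=%d D=%d L=%d heads=%d\n",
              x$side, x$side, C, x$stride_prod, x$vit$P, x$vit$D, x$vit$L,
              x$vit$heads))
  cat(sprintf("  fused width %d, classes %d\n", x$bridge_out, x$n_classes))
  invisible(x)
}

cnn_channels <- function(cfg) cfg$stages[[length(cfg$stages)]]$out

# ---- initialization ----------------------------------------------------

he_mat <- function(nout, nin, fan) matrix(rnorm(nout * nin, 0,
                                                sqrt(2 / fan)), nout, nin)

# Xavier scale for layers feeding saturating nonlinearities (tanh,
# sigmoid, softmax heads): keeps pre-activations in the responsive range
# so early optimizer steps cannot park the fusion layer in saturation.
xa_mat <- function(nout, nin) matrix(rnorm(nout * nin, 0,
                                           sqrt(1 / (nout + nin))),
                                     nout, nin)

init_gate <- function(C, reduction) {
  hid <- max(4L, C %/% reduction)
  list(W1 = he_mat(hid, C, C), W2 = xa_mat(C, hid))
}

#' Initialize network parameters
#'
#' Builds the full nested parameter list for a configuration, seeded. He
#' initialization for ReLU-followed weights, scaled-normal (sd 0.02) for
#' token/positional embeddings, zeros for biases.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `cytoxai_net` (list with `params`, `config`).
#' @export
init_net <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cytoxai_config"))
  cfg <- config
  with_seed(seed, {
    params <- list()
    cin <- 3L
    params$cnn <- lapply(cfg$stages, function(s) {
      fan <- s$k * s$k * cin
      W <- he_mat(s$out, fan, fan)
      # conv bias + batch-norm scale/shift per output channel
      p <- list(W = W, b = numeric(s$out), g = rep(1, s$out),
                beta = numeric(s$out))
      cin <<- s$out
      p
    })
    C <- cnn_channels(cfg)
    if (has_gate(cfg)) params$gate <- init_gate(C, cfg$gate_reduction)
    if (has_vit(cfg)) {
      v <- cfg$vit
      R <- v$P * v$P * 3L
      params$vit <- list(
        patch = list(W = he_mat(v$D, R, R), b = numeric(v$D)),
        cls = rnorm(v$D, 0, 0.02),
        pos = matrix(rnorm(v$D * ((cfg$side %/% v$P)^2 + 1L), 0, 0.02),
                     v$D),
        blocks = lapply(seq_len(v$L), function(l) {
          Dm <- as.integer(round(v$D * v$mlp_ratio))
          # transformer projections follow the ViT convention (normal,
          # sd 0.02), residual outputs further scaled by 1/sqrt(2L): the
          # pre-norm stack starts near-identity, which keeps the
          # attention landscape flat enough for momentum SGD
          tn <- function(nout, nin) matrix(rnorm(nout * nin, 0, 0.02),
                                           nout, nin)
          rs <- 1 / sqrt(2 * v$L)
          list(ln1 = list(g = rep(1, v$D), b = numeric(v$D)),
               attn = list(Wq = tn(v$D, v$D), bq = numeric(v$D),
                           Wk = tn(v$D, v$D), bk = numeric(v$D),
                           Wv = tn(v$D, v$D), bv = numeric(v$D),
                           Wo = tn(v$D, v$D) * rs, bo = numeric(v$D)),
               ln2 = list(g = rep(1, v$D), b = numeric(v$D)),
               mlp = list(W1 = tn(Dm, v$D), b1 = numeric(Dm),
                          W2 = tn(v$D, Dm) * rs, b2 = numeric(v$D)))
        }),
        lnf = list(g = rep(1, v$D), b = numeric(v$D)),
        concept = list(W = he_mat(v$D, v$D, v$D), v = rnorm(v$D, 0, 0.02)))
    }
    fuse_in <- C + if (has_vit(cfg)) cfg$vit$D else 0L
    if (has_bridge(cfg)) {
      params$bridge <- if (cfg$ablation == "no_bridge")
        list(W = xa_mat(cfg$bridge_out, fuse_in))
      else
        list(W1 = he_mat(cfg$bridge_hidden, fuse_in, fuse_in),
             W2 = xa_mat(cfg$bridge_out, cfg$bridge_hidden))
      # balance the fusion input at init: the transformer vector has more
      # dimensions and larger per-dimension variance than the pooled CNN
      # vector, so equal init weights let it drown the morphology
      # features; start with its columns down-weighted and let training
      # grow them back as they earn it
      if (has_vit(cfg) && cfg$ablation != "no_bridge")
        params$bridge$W1[, (C + 1L):fuse_in] <-
          params$bridge$W1[, (C + 1L):fuse_in] * 0.25
    }
    cls_in <- if (has_bridge(cfg)) cfg$bridge_out else C
    params$cls <- list(W1 = he_mat(cfg$cls_hidden, cls_in, cls_in),
                       W2 = xa_mat(cfg$n_classes, cfg$cls_hidden),
                       b = numeric(cfg$n_classes))
    if (has_policy(cfg))
      params$policy <- list(W1 = he_mat(cfg$policy_hidden, cfg$bridge_out,
                                        cfg$bridge_out),
                            b1 = numeric(cfg$policy_hidden),
                            W2 = xa_mat(cfg$n_methods, cfg$policy_hidden),
                            b2 = numeric(cfg$n_methods))
    buffers <- list(cnn = lapply(cfg$stages, function(st)
      list(rm = numeric(st$out), rv = rep(1, st$out))))
    structure(list(params = params, config = cfg, buffers = buffers),
              class = "cytoxai_net")
  })
}

# ---- nested-list utilities --------------------------------------------

nn_map <- function(f, x) {
  if (is.list(x)) return(lapply(x, nn_map, f = f))
  f(x)
}

nn_map2 <- function(f, x, y) {
  if (is.list(x)) return(mapply(nn_map2, x, y,
                                MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(x, y)
}

nn_flatten <- function(x) unlist(x, use.names = FALSE)

nn_zeros_like <- function(x) nn_map(function(a) a * 0, x)

nn_count <- function(x) length(nn_flatten(x))

nn_global_norm <- function(x) sqrt(sum(nn_flatten(x)^2))

# ---- forward -----------------------------------------------------------

# x: (H, W, 3, B). Returns user-facing outputs plus a cache for backward.
net_forward <- function(net, x, keep_cache = TRUE, train = FALSE,
                        bn_momentum = 0.1) {
  cfg <- net$config; params <- net$params
  buffers <- net$buffers
  d <- dim(x)
  stopifnot(length(d) == 4L, d[3] == 3L)
  B <- d[4]
  cache <- list(B = B)

  # CNN stack: conv -> batch norm -> ReLU per stage
  h <- x
  conv_caches <- vector("list", length(params$cnn))
  for (i in seq_along(params$cnn)) {
    s <- cfg$stages[[i]]
    cf <- conv2d_fwd(h, params$cnn[[i]]$W, params$cnn[[i]]$b,
                     s$k, s$k, s$s, s$p)
    if (train) {
      bf <- bn_fwd(cf$out, params$cnn[[i]]$g, params$cnn[[i]]$beta)
      buffers$cnn[[i]]$rm <- (1 - bn_momentum) * buffers$cnn[[i]]$rm +
        bn_momentum * bf$mu
      buffers$cnn[[i]]$rv <- (1 - bn_momentum) * buffers$cnn[[i]]$rv +
        bn_momentum * bf$va
      bn_out <- bf$out; bn_cache <- bf$cache
    } else {
      bn_out <- bn_eval(cf$out, params$cnn[[i]]$g, params$cnn[[i]]$beta,
                        buffers$cnn[[i]]$rm, buffers$cnn[[i]]$rv)
      # evaluation-mode batch norm is a fixed per-channel affine map; its
      # input gradient is a channel rescaling (enough for attribution
      # backward passes, which never update parameters)
      bn_cache <- list(eval_scale = params$cnn[[i]]$g /
                         sqrt(buffers$cnn[[i]]$rv + 1e-5))
    }
    rf <- relu_fwd(bn_out)
    conv_caches[[i]] <- list(conv = cf$cache, bn = bn_cache,
                             relu = rf$cache)
    h <- rf$out
  }
  F_cnn <- h                       # (H', W', C, B), post-ReLU
  fd <- dim(F_cnn); HW <- fd[1] * fd[2]; C <- fd[3]
  Fmat <- matrix(F_cnn, HW, C * B)

  if (has_gate(cfg)) {
    z <- matrix(colMeans(Fmat), C, B)
    a1 <- params$gate$W1 %*% z
    h1 <- pmax(a1, 0)
    u <- params$gate$W2 %*% h1
    w <- 1 / (1 + exp(-u))         # (C, B), strictly in (0,1)
    Fatt_mat <- sweep(Fmat, 2, as.vector(w), "*")
  } else {
    z <- NULL; a1 <- NULL; h1 <- NULL; w <- NULL
    Fatt_mat <- Fmat
  }
  f_cnn <- matrix(colMeans(Fatt_mat), C, B)

  # transformer branch
  f_vit <- NULL; alpha <- NULL; vit_cache <- NULL
  if (has_vit(cfg)) {
    vc <- vit_forward(params$vit, cfg, x)
    f_vit <- vc$f_vit; alpha <- vc$alpha
    vit_cache <- vc
  }

  # fusion
  if (has_bridge(cfg)) {
    cat_vec <- if (has_vit(cfg)) rbind(f_cnn, f_vit) else f_cnn
    if (cfg$ablation == "no_bridge") {
      fb <- params$bridge$W %*% cat_vec
      br_cache <- list(cat = cat_vec, fb = fb)
    } else {
      ba <- params$bridge$W1 %*% cat_vec
      bh <- pmax(ba, 0)
      bu <- params$bridge$W2 %*% bh
      fb <- tanh(bu)
      br_cache <- list(cat = cat_vec, ba = ba, bh = bh, fb = fb)
    }
    cls_in <- fb
  } else {
    fb <- NULL; br_cache <- NULL
    cls_in <- f_cnn
  }

  # classifier head
  ca <- params$cls$W1 %*% cls_in
  ch <- pmax(ca, 0)
  logits <- params$cls$W2 %*% ch + params$cls$b   # (K, B)
  probs <- softmax_cols(logits)

  # policy head
  policy <- NULL; pol_cache <- NULL
  if (has_policy(cfg)) {
    pa <- params$policy$W1 %*% fb + params$policy$b1
    ph <- pmax(pa, 0)
    pu <- params$policy$W2 %*% ph + params$policy$b2
    policy <- softmax_cols(pu)
    pol_cache <- list(pa = pa, ph = ph, policy = policy)
  }

  if (keep_cache)
    cache <- c(cache, list(conv = conv_caches, train = train,
                           F_dim = fd, HW = HW, C = C,
                           Fmat = Fmat, Fatt_mat = Fatt_mat,
                           z = z, a1 = a1, h1 = h1, w = w,
                           vit = vit_cache, bridge = br_cache,
                           cls_in = cls_in, ca = ca, ch = ch,
                           probs = probs, pol = pol_cache))
  list(logits = t(logits), probs = t(probs),
       policy = if (!is.null(policy)) t(policy) else NULL,
       f_cnn = t(f_cnn),
       f_vit = if (!is.null(f_vit)) t(f_vit) else NULL,
       f_bridge = if (!is.null(fb)) t(fb) else NULL,
       gate = if (!is.null(w)) t(w) else NULL,
       alpha = if (!is.null(alpha)) t(alpha) else NULL,
       feature_map = F_cnn,
       buffers = buffers,
       cache = if (keep_cache) cache else NULL)
}

# Transformer branch forward: images -> tokens -> pooled concept vector.
vit_forward <- function(vp, cfg, x) {
  v <- cfg$vit; P <- v$P; D <- v$D
  d <- dim(x); B <- d[4]
  npatch_side <- d[1] %/% P
  N <- npatch_side^2
  ii <- im2col_index(d[1], d[2], 3L, B, P, P, P)
  cols <- matrix(as.vector(x)[ii$idx], nrow = nrow(ii$idx))  # (P*P*3, N*B)
  tmat <- vp$patch$W %*% cols + vp$patch$b             # (D, N*B)
  tokens <- array(0, dim = c(D, N + 1L, B))
  tokens[, 1L, ] <- vp$cls
  tokens[, -1L, ] <- tmat
  if (cfg$use_positions)
    tokens <- tokens + array(rep(as.vector(vp$pos), B), dim = dim(tokens))
  N1 <- N + 1L
  Xmat <- matrix(tokens, D, N1 * B)
  blk_caches <- vector("list", v$L)
  for (l in seq_len(v$L)) {
    bf <- vit_block_fwd(vp$blocks[[l]], Xmat, D, N1, B, v$heads)
    blk_caches[[l]] <- bf$cache
    Xmat <- bf$out
  }
  lf <- layernorm_fwd(Xmat, vp$lnf$g, vp$lnf$b)
  TL <- lf$out                                          # (D, N1*B)
  cc <- concept_fwd(vp$concept, TL, D, N1, B)
  list(f_vit = cc$f, alpha = cc$alpha,
       cols = cols, idx = ii$idx, x_dim = d, N = N, N1 = N1, B = B, D = D,
       blocks = blk_caches, lnf = lf$cache, TL = TL, concept = cc$cache)
}

vit_block_fwd <- function(bp, Xmat, D, N1, B, heads) {
  l1 <- layernorm_fwd(Xmat, bp$ln1$g, bp$ln1$b)
  mf <- mha_fwd(l1$out, bp$attn, heads, N1, B)
  X2 <- Xmat + mf$out
  l2 <- layernorm_fwd(X2, bp$ln2$g, bp$ln2$b)
  m1 <- linear_fwd(l2$out, bp$mlp$W1, bp$mlp$b1)
  g1 <- gelu_fwd(m1$out)
  m2 <- linear_fwd(g1$out, bp$mlp$W2, bp$mlp$b2)
  list(out = X2 + m2$out,
       cache = list(l1 = l1$cache, mha = mf$cache, l2 = l2$cache,
                    m1 = m1$cache, g1 = g1$cache, m2 = m2$cache,
                    N1 = N1, B = B, heads = heads))
}

concept_fwd <- function(cp, TL, D, N1, B) {
  pre <- cp$W %*% TL                   # (D, N1*B)
  hh <- pmax(pre, 0)
  s <- matrix(as.vector(cp$v %*% hh), N1, B)
  smax <- apply(s, 2, max)
  e <- exp(sweep(s, 2, smax))
  alpha <- sweep(e, 2, colSums(e), "/")           # (N1, B)
  tok <- array(TL, dim = c(D, N1, B))
  f <- matrix(0, D, B)
  for (b in seq_len(B)) f[, b] <- tok[, , b] %*% alpha[, b]
  list(f = f, alpha = alpha,
       cache = list(pre = pre, hh = hh, alpha = alpha, TL = TL,
                    N1 = N1, B = B))
}

# ---- backward ----------------------------------------------------------

# dlogits, dpolicy: user-facing (B x K), (B x 4) or NULL.
# Returns grads (nested like params), dFcnn, and optionally dinput.
net_backward <- function(net, cache, dlogits, dpolicy = NULL,
                         wrt_input = FALSE) {
  cfg <- net$config; params <- net$params
  B <- cache$B
  grads <- nn_zeros_like(params)

  dlog <- t(dlogits)                     # (K, B)
  # classifier head
  grads$cls$W2 <- tcrossprod(dlog, cache$ch)
  grads$cls$b <- rowSums(dlog)
  dch <- crossprod(params$cls$W2, dlog)
  dca <- dch * (cache$ca > 0)
  grads$cls$W1 <- tcrossprod(dca, cache$cls_in)
  dcls_in <- crossprod(params$cls$W1, dca)

  dfb <- NULL
  if (has_bridge(cfg)) dfb <- dcls_in else dfcnn_direct <- dcls_in

  # policy head
  if (has_policy(cfg) && !is.null(dpolicy)) {
    dpol <- t(dpolicy)                  # (4, B)
    dpu <- softmax_cols_bwd(cache$pol$policy, dpol)
    grads$policy$W2 <- tcrossprod(dpu, cache$pol$ph)
    grads$policy$b2 <- rowSums(dpu)
    dph <- crossprod(params$policy$W2, dpu)
    dpa <- dph * (cache$pol$pa > 0)
    grads$policy$W1 <- tcrossprod(dpa, cache$bridge$fb)
    grads$policy$b1 <- rowSums(dpa)
    dfb <- dfb + crossprod(params$policy$W1, dpa)
  }

  # fusion
  if (has_bridge(cfg)) {
    if (cfg$ablation == "no_bridge") {
      grads$bridge$W <- tcrossprod(dfb, cache$bridge$cat)
      dcat <- crossprod(params$bridge$W, dfb)
    } else {
      dbu <- dfb * (1 - cache$bridge$fb^2)
      grads$bridge$W2 <- tcrossprod(dbu, cache$bridge$bh)
      dbh <- crossprod(params$bridge$W2, dbu)
      dba <- dbh * (cache$bridge$ba > 0)
      grads$bridge$W1 <- tcrossprod(dba, cache$bridge$cat)
      dcat <- crossprod(params$bridge$W1, dba)
    }
    C <- cache$C
    df_cnn <- dcat[seq_len(C), , drop = FALSE]
    df_vit <- if (has_vit(cfg)) dcat[-seq_len(C), , drop = FALSE] else NULL
  } else {
    df_cnn <- dfcnn_direct
    df_vit <- NULL
  }

  # transformer branch
  dinput_vit <- NULL
  if (has_vit(cfg) && !is.null(df_vit)) {
    vb <- vit_backward(params$vit, cfg, cache$vit, df_vit, wrt_input)
    grads$vit <- vb$grads
    dinput_vit <- vb$dinput
  }

  # CNN pooling + gate
  HW <- cache$HW; C <- cache$C
  dFatt_mat <- matrix(rep(as.vector(df_cnn), each = HW) / HW, HW, C * B)
  if (has_gate(cfg)) {
    w <- cache$w
    dF_mat <- sweep(dFatt_mat, 2, as.vector(w), "*")
    dw <- matrix(colSums(dFatt_mat * cache$Fmat), C, B)
    du <- dw * w * (1 - w)
    grads$gate$W2 <- tcrossprod(du, cache$h1)
    dh1 <- crossprod(params$gate$W2, du)
    da1 <- dh1 * (cache$a1 > 0)
    grads$gate$W1 <- tcrossprod(da1, cache$z)
    dz <- crossprod(params$gate$W1, da1)      # (C, B)
    dF_mat <- dF_mat + matrix(rep(as.vector(dz), each = HW) / HW, HW, C * B)
  } else {
    dF_mat <- dFatt_mat
  }
  dF <- array(dF_mat, dim = cache$F_dim)
  dFcnn <- dF                                  # gradient at last conv output

  # CNN stack backward. Training caches carry batch statistics; eval
  # caches treat batch norm as the fixed affine it is at inference.
  dh <- dF
  for (i in rev(seq_along(params$cnn))) {
    dh <- relu_bwd(cache$conv[[i]]$relu, dh)
    bnc <- cache$conv[[i]]$bn
    if (is.null(bnc$eval_scale)) {
      bb <- bn_bwd(bnc, dh)
      grads$cnn[[i]]$g <- bb$dg
      grads$cnn[[i]]$beta <- bb$dbeta
      dbn <- bb$dx
    } else {
      dd <- dim(dh)
      dbn <- dh * rep(rep(bnc$eval_scale, each = dd[1] * dd[2]),
                      times = dd[4])
    }
    cb <- conv2d_bwd(cache$conv[[i]]$conv, dbn)
    grads$cnn[[i]]$W <- cb$dW
    grads$cnn[[i]]$b <- cb$db
    dh <- cb$dx
  }
  dinput <- NULL
  if (wrt_input) {
    dinput <- dh
    if (!is.null(dinput_vit)) dinput <- dinput + dinput_vit
  }
  list(grads = grads, dFcnn = dFcnn, dinput = dinput)
}

vit_backward <- function(vp, cfg, vc, df_vit, wrt_input = FALSE) {
  D <- vc$D; N1 <- vc$N1; B <- vc$B
  g <- nn_zeros_like(vp)
  cb <- concept_bwd(vp$concept, vc$concept, df_vit)
  g$concept <- cb$grads
  dTL <- cb$dTL
  lb <- layernorm_bwd(vc$lnf, dTL)
  g$lnf$g <- lb$dg; g$lnf$b <- lb$db
  dX <- lb$dx
  for (l in rev(seq_len(cfg$vit$L))) {
    bb <- vit_block_bwd(vp$blocks[[l]], vc$blocks[[l]], dX)
    g$blocks[[l]] <- bb$grads
    dX <- bb$dx
  }
  dtokens <- array(dX, dim = c(D, N1, B))
  if (cfg$use_positions)
    g$pos <- matrix(rowSums(array(dtokens, dim = c(D * N1, B))), D, N1)
  else g$pos <- vp$pos * 0
  g$cls <- rowSums(matrix(dtokens[, 1L, ], D, B))
  dtmat <- matrix(dtokens[, -1L, , drop = FALSE], D, vc$N * B)
  g$patch$W <- tcrossprod(dtmat, vc$cols)
  g$patch$b <- rowSums(dtmat)
  dinput <- NULL
  if (wrt_input) {
    dcols <- crossprod(vp$patch$W, dtmat)
    # patches partition the image, so the gather index is a bijection
    dinput <- numeric(prod(vc$x_dim))
    dinput[vc$idx] <- dcols
    dim(dinput) <- vc$x_dim
  }
  list(grads = g, dinput = dinput)
}

vit_block_bwd <- function(bp, bc, dout) {
  # out = X2 + m2(g1(m1(ln2(X2)))), X2 = X + mha(ln1(X))
  m2b <- linear_bwd(bc$m2, dout)
  g1b <- gelu_bwd(bc$g1, m2b$dx)
  m1b <- linear_bwd(bc$m1, g1b)
  l2b <- layernorm_bwd(bc$l2, m1b$dx)
  dX2 <- dout + l2b$dx
  mb <- mha_bwd(bc$mha, dX2)
  l1b <- layernorm_bwd(bc$l1, mb$dx)
  list(dx = dX2 + l1b$dx,
       grads = list(ln1 = list(g = l1b$dg, b = l1b$db),
                    attn = mb$grads,
                    ln2 = list(g = l2b$dg, b = l2b$db),
                    mlp = list(W1 = m1b$dW, b1 = m1b$db,
                               W2 = m2b$dW, b2 = m2b$db)))
}

concept_bwd <- function(cp, cc, df) {
  D <- nrow(df); N1 <- cc$N1; B <- cc$B
  tok <- array(cc$TL, dim = c(D, N1, B))
  dalpha <- matrix(0, N1, B)
  dTL_arr <- array(0, dim = c(D, N1, B))
  for (b in seq_len(B)) {
    dalpha[, b] <- crossprod(tok[, , b], df[, b])
    dTL_arr[, , b] <- tcrossprod(df[, b], cc$alpha[, b])
  }
  ds <- cc$alpha * sweep(dalpha, 2, colSums(dalpha * cc$alpha))
  ds_vec <- as.vector(ds)                          # (N1*B)
  dv <- as.vector(cc$hh %*% ds_vec)
  dhh <- outer(cp$v, ds_vec)
  dpre <- dhh * (cc$pre > 0)
  dW <- tcrossprod(dpre, cc$TL)
  dTL <- matrix(dTL_arr, D, N1 * B) + crossprod(cp$W, dpre)
  list(dTL = dTL, grads = list(W = dW, v = dv))
}
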