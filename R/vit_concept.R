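# Module surface: patch embedding, transformer stack, conceptual attention.

#' Embed an image batch as a token sequence
#'
#' Cuts each image into non-overlapping `P x P` patches (column-of-patches
#' fastest), flattens and linearly projects them to width `D`, prepends the
#' learnable class token at index 1, and adds positional encodings when the
#' configuration enables them.
#'
#' @param images Array `H x W x 3 (x B)` in `[0,1]`; the side must be
#'   divisible by `P`.
#' @param cfg A [model_config()] (its `$vit` and `$use_positions` fields are
#'   used).
#' @param params Transformer parameter list as built by [init_net()]
#'   (`patch$W`, `patch$b`, `cls`, `pos`).
#' @return Token array `B x (N+1) x D` with `N = (side/P)^2`.
#' @export
patch_embed <- function(images, cfg, params) {
  x <- as_image_batch(images)
  d <- dim(x)
  P <- cfg$vit$P
  if (d[1] %% P != 0L || d[2] %% P != 0L)
    stop(sprintf("image side %dx%d is not divisible by patch size %d",
                 d[1], d[2], P))
  vc <- vit_partial_embed(params, cfg, x)
  aperm(vc$tokens, c(3, 2, 1))
}

vit_partial_embed <- function(vp, cfg, x) {
  d <- dim(x); B <- d[4]; P <- cfg$vit$P; D <- cfg$vit$D
  N <- (d[1] %/% P) * (d[2] %/% P)
  ii <- im2col_index(d[1], d[2], 3L, B, P, P, P)
  cols <- matrix(as.vector(x)[ii$idx], nrow = nrow(ii$idx))
  tmat <- vp$patch$W %*% cols + vp$patch$b
  tokens <- array(0, dim = c(D, N + 1L, B))
  tokens[, 1L, ] <- vp$cls
  tokens[, -1L, ] <- tmat
  if (cfg$use_positions)
    tokens <- tokens + array(rep(as.vector(vp$pos), B), dim = dim(tokens))
  list(tokens = tokens, N = N)
}

#' Apply the transformer encoder stack
#'
#' Runs `L` pre-norm encoder blocks (LayerNorm, multi-head self-attention,
#' residual; LayerNorm, GELU MLP, residual) followed by a final LayerNorm.
#' With `L = 0` blocks only the final LayerNorm is skipped and the input is
#' returned unchanged.
#'
#' @param tokens Token array `B x (N+1) x D`.
#' @param cfg A [model_config()].
#' @param params Transformer parameters (`blocks`, `lnf`).
#' @param final_norm Apply the final LayerNorm (default TRUE when at least
#'   one block is present).
#' @return Token array `B x (N+1) x D`.
#' @export
transformer_stack <- function(tokens, cfg, params,
                              final_norm = cfg$vit$L > 0L) {
  d <- dim(tokens)
  stopifnot(length(d) == 3L)
  B <- d[1]; N1 <- d[2]; D <- d[3]
  Xmat <- matrix(aperm(tokens, c(3, 2, 1)), D, N1 * B)
  for (l in seq_len(cfg$vit$L))
    Xmat <- vit_block_fwd(params$blocks[[l]], Xmat, D, N1, B,
                          cfg$vit$heads)$out
  if (final_norm)
    Xmat <- layernorm_fwd(Xmat, params$lnf$g, params$lnf$b)$out
  aperm(array(Xmat, dim = c(D, N1, B)), c(3, 2, 1))
}

#' Conceptual attention pooling over tokens
#'
#' Scores every token with `v' relu(W t_i)`, normalizes the scores to a
#' probability simplex with a softmax over tokens, and returns the
#' alpha-weighted token sum. With `v = 0` the weights are uniform
#' `1/(N+1)` regardless of the tokens.
#'
#' @param tokens Token array `B x (N+1) x D`.
#' @param params List with `W` (`D x D`) and `v` (length `D`).
#' @return List with `f_vit` (`B x D`) and `alpha` (`B x (N+1)`, rows on
#'   the simplex).
#' @export
conceptual_attention <- function(tokens, params) {
  d <- dim(tokens)
  stopifnot(length(d) == 3L)
  B <- d[1]; N1 <- d[2]; D <- d[3]
  TL <- matrix(aperm(tokens, c(3, 2, 1)), D, N1 * B)
  cc <- concept_fwd(params, TL, D, N1, B)
  list(f_vit = t(cc$f), alpha = t(cc$alpha))
}
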