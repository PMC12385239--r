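# Module surface: bounded fusion, classifier head, policy head, losses,
# and the illustrative rule verbalizer.

#' Bounded fusion of CNN and transformer features
#'
#' Concatenates the pooled CNN vector and the concept vector and passes the
#' result through the bias-free two-layer fusion
#' `tanh(W2 relu(W1 [f_cnn || f_vit]))`, producing a 256-wide vector with
#' entries strictly inside `(-1, 1)`.
#'
#' @param f_cnn Matrix `B x C`.
#' @param f_vit Matrix `B x D`, or `NULL` to fuse the CNN vector alone.
#' @param params List with `W1` (hidden x (C+D)) and `W2` (256 x hidden).
#' @return Matrix `B x 256`.
#' @export
bridge_forward <- function(f_cnn, f_vit, params) {
  x <- t(if (is.null(f_vit)) f_cnn else cbind(f_cnn, f_vit))
  if (ncol(params$W1) != nrow(x))
    stop(sprintf("fusion input width %d does not match W1 (%d columns)",
                 nrow(x), ncol(params$W1)))
  t(tanh(params$W2 %*% pmax(params$W1 %*% x, 0)))
}

#' Classifier head
#'
#' Two-layer head `W2 relu(W1 x) + b` followed by a numerically stable
#' softmax. The predicted class is the argmax with lowest-index
#' tie-breaking (ties are rare but the rule matters for degenerate
#' collapse fixtures).
#'
#' @param fb Matrix `B x n_in` of fused features.
#' @param params List with `W1`, `W2`, `b`.
#' @return List with `logits` (`B x K`), `probs` (`B x K`, rows on the
#'   simplex) and `class` (integer 0-based predicted codes).
#' @export
classify <- function(fb, params) {
  x <- t(fb)
  logits <- params$W2 %*% pmax(params$W1 %*% x, 0) + params$b
  probs <- softmax_cols(logits)
  list(logits = t(logits), probs = t(probs),
       class = apply(t(probs), 1, which.max) - 1L)
}

#' Policy over the four attribution methods
#'
#' The controller head `softmax(W2 relu(W1 z + b1) + b2)` maps the 256-wide
#' fused vector to a probability simplex over the four attribution methods
#' in the fixed order of [xai_methods()]. The hidden width is 64.
#'
#' @param fb Matrix `B x 256`.
#' @param params List with `W1` (64 x 256), `b1`, `W2` (4 x 64), `b2`.
#' @return Matrix `B x 4`; rows sum to 1, columns named by method.
#' @export
meta_xai_policy <- function(fb, params) {
  x <- t(fb)
  p <- t(softmax_cols(params$W2 %*% pmax(params$W1 %*% x + params$b1, 0) +
                        params$b2))
  colnames(p) <- xai_methods()
  p
}

#' Mean cross-entropy loss
#'
#' `-(1/B) sum_i log p_i[y_i]` over a batch, from predicted class
#' probabilities and 0-based true labels.
#'
#' @param probs Matrix `B x K` of class probabilities (rows on the simplex).
#' @param labels Integer vector of true classes in `0..K-1`.
#' @param eps Probability floor guarding `log(0)` (default 1e-12).
#' @return Non-negative scalar.
#' @examples
#' cross_entropy(matrix(0.25, 1, 4), 0)  # log(4)
#' @export
cross_entropy <- function(probs, labels, eps = 1e-12) {
  probs <- rbind(probs)
  B <- nrow(probs); K <- ncol(probs)
  labels <- as.integer(labels)
  if (length(labels) != B) stop("one label per row is required")
  if (any(labels < 0L | labels >= K))
    stop(sprintf("labels must lie in [0, %d)", K))
  -mean(log(pmax(probs[cbind(seq_len(B), labels + 1L)], eps)))
}

#' Composite classification + explanation-quality loss
#'
#' `L = L_CE + lambda_x * (1 - mean_b sum_k p_bk q_bk)`: the auxiliary term
#' rewards policies that put weight on attribution methods currently
#' scoring high explanation quality. With `lambda_x = 0` it reduces to the
#' cross-entropy exactly; with all qualities equal to `q` the auxiliary
#' term is `lambda_x * (1 - q)` for any valid policy.
#'
#' @param probs Matrix `B x K` of class probabilities.
#' @param labels Integer vector of true classes (0-based).
#' @param policy Matrix `B x 4` of method weights (rows on the simplex).
#' @param quality Matrix `B x 4` of per-method explanation-quality scores
#'   in `[0, 1]` (a length-4 vector is recycled across the batch).
#' @param lambda_x Auxiliary weight (default 0.1).
#' @return Scalar loss (non-negative for valid inputs).
#' @export
composite_loss <- function(probs, labels, policy = NULL, quality = NULL,
                           lambda_x = 0.1) {
  ce <- cross_entropy(probs, labels)
  if (lambda_x == 0) return(ce)
  if (is.null(policy)) stop("a policy is required when lambda_x > 0")
  if (is.null(quality)) stop("quality scores are required when lambda_x > 0")
  policy <- rbind(policy)
  if (is.vector(quality)) quality <- matrix(quality, nrow(policy),
                                            length(quality), byrow = TRUE)
  if (!all(is.finite(quality)) || any(quality < 0 | quality > 1))
    stop("quality scores must be finite and in [0, 1]")
  if (!all(dim(quality) == dim(policy)))
    stop("policy and quality must have matching dimensions")
  ce + lambda_x * (1 - mean(rowSums(policy * quality)))
}

#' Render illustrative IF-THEN rules from morphology descriptors
#'
#' Deterministic template rendering of the kind of fuzzy threshold rules
#' the fused representation is interpreted as ("IF nucleus size is large
#' AND chromatin texture is coarse, THEN cell is likely malignant"). This
#' is presentation only: the strings are filled from supplied descriptor
#' levels, not learned from data.
#'
#' @param descriptors Named character vector or list mapping descriptor
#'   names (e.g. `nc_ratio`, `chromatin`) to levels (e.g. `"high"`,
#'   `"coarse"`). Empty input yields an empty list.
#' @param conclusion Consequent text; by default inferred as "malignant"
#'   when any descriptor level is one of high/large/coarse, else "benign".
#' @param confidence Optional scalar in `[0,1]` rendered as a hedging
#'   adverb (possibly / likely / highly likely).
#' @return Character vector of IF-THEN rule strings (length 0 or 1).
#' @examples
#' verbalize_rules(c(nc_ratio = "high", chromatin = "coarse"))
#' @export
verbalize_rules <- function(descriptors, conclusion = NULL,
                            confidence = NULL) {
  descriptors <- unlist(descriptors)
  if (length(descriptors) == 0L) return(character(0))
  if (is.null(names(descriptors)) || any(!nzchar(names(descriptors))))
    stop("descriptors must be named")
  if (is.null(conclusion)) {
    malignant_levels <- c("high", "large", "coarse", "irregular")
    conclusion <- if (any(tolower(descriptors) %in% malignant_levels))
      "malignant" else "benign"
  }
  hedge <- "likely"
  if (!is.null(confidence)) {
    check_range(confidence, "confidence", 0, 1)
    hedge <- if (confidence < 0.5) "possibly" else
      if (confidence < 0.85) "likely" else "highly likely"
  }
  antecedents <- paste(sprintf("%s is %s", names(descriptors),
                               unname(descriptors)),
                       collapse = " AND ")
  sprintf("IF %s, THEN cell is %s %s", antecedents, hedge, conclusion)
}
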