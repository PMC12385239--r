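# Shared fixtures: closed-form toy models for the attribution oracles and
# small synthetic datasets built at test time.

# Linear-in-pixels model: logit_k = sum(W[[k]] * x) + b[k].
toy_linear_model <- function(W_list, b = numeric(length(W_list))) {
  manual_model(
    score_fn = function(images) {
      B <- dim(images)[4]
      t(vapply(seq_along(W_list), function(k)
        vapply(seq_len(B), function(i)
          sum(W_list[[k]] * images[, , , i]) + b[k], numeric(1)),
        numeric(B)))
    },
    gradient_fn = function(images, class_index) {
      g <- array(0, dim = dim(images))
      for (i in seq_len(dim(images)[4]))
        g[, , , i] <- W_list[[class_index + 1L]]
      g
    })
}

# Model whose logits depend only on the means of 4 grid segments, with an
# interaction term, so the induced coalition game is non-additive.
toy_segment_model <- function(side = 8L) {
  seg <- grid_segments(side, side, grid = 2L)
  seg_means <- function(img) {
    vapply(0:3, function(s) {
      m <- seg == s
      mean(img[, , 1][m] + img[, , 2][m] + img[, , 3][m]) / 3
    }, numeric(1))
  }
  coef1 <- c(2, -1, 0.5, 1)
  score <- function(s) sum(coef1 * s) + 1.5 * s[1] * s[4]
  grad_wrt_means <- function(s)
    coef1 + c(1.5 * s[4], 0, 0, 1.5 * s[1])
  list(
    model = manual_model(
      score_fn = function(images) {
        B <- dim(images)[4]
        cbind(vapply(seq_len(B), function(i)
          score(seg_means(images[, , , i])), numeric(1)), 0)
      },
      gradient_fn = function(images, class_index) {
        g <- array(0, dim = dim(images))
        if (class_index != 0L) return(g)
        npix <- 3 * sum(seg == 0)      # pixels (x channels) per segment
        for (i in seq_len(dim(images)[4])) {
          gm <- grad_wrt_means(seg_means(images[, , , i]))
          plane <- matrix(gm[as.vector(seg) + 1L], side, side) / npix
          for (c in 1:3) g[, , c, i] <- plane
        }
        g
      }),
    segments = seg, seg_means = seg_means, score = score)
}

# Seeded synthetic two- or four-class smear dataset on disk (tempdir).
toy_smear_data <- function(classes = c("benign", "pro"), n_per_class = 10L,
                           side = 32L, seed = 1L) {
  dir <- tempfile("smears")
  spec <- smear_spec(classes, rep(n_per_class, length(classes)),
                     image_side = side, seed = seed)
  man <- generate_dataset(spec, dir, write_manifest = FALSE)
  list(manifest = man, dir = dir, spec = spec)
}

# The desk-scale study fit (4 classes x 200 images at 64 px, SGD preset,
# 10 epochs, batch 32) is expensive, so it is trained once per session and
# shared between the tests that need it.
.study_cache <- new.env(parent = emptyenv())

study_dataset <- function() {
  if (is.null(.study_cache$data)) {
    dir <- tempfile("study")
    spec <- smear_spec(c("benign", "early", "pre", "pro"),
                       rep(200L, 4L), image_side = 64L, seed = 20L)
    .study_cache$data <- list(manifest = generate_dataset(spec, dir,
                                                          write_manifest = FALSE),
                              dir = dir)
  }
  .study_cache$data
}

study_fit <- function() {
  if (is.null(.study_cache$fit)) {
    data <- study_dataset()
    split <- fixed_split(data$manifest, frac = 0.2, seed = 11L)
    .study_cache$fit <- list(
      fit = cytoxai(split$train, val = split$val,
                    config = model_config("tiny", n_classes = 4L, side = 64L),
                    optimizer = optimizer_spec("sgd"),
                    epochs = 10L, batch_size = 32L, seed = 11L),
      split = split)
  }
  .study_cache$fit
}
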