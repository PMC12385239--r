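# Attribution methods against independent closed-form and brute-force
# oracles.

test_that("integrated gradients is exact on a linear model and zero on a
           zero path", {
  set.seed(30)
  d <- c(6L, 6L, 3L)
  W0 <- array(rnorm(prod(d)), dim = d)
  W1 <- array(rnorm(prod(d)), dim = d)
  model <- toy_linear_model(list(W0, W1), b = c(0.2, -0.1))
  Q <- array(runif(prod(d)), dim = d)
  B <- array(runif(prod(d)), dim = d)
  for (steps in c(1L, 4L, 32L)) {
    att <- integrated_gradients(model, Q, baseline = B, steps = steps,
                                class_index = 1L)
    expect_equal(att$values, (Q - B) * W1, tolerance = 1e-10)
    expect_lt(att$completeness_gap, 1e-8)
  }
  # identical image and baseline: zero attribution exactly
  att0 <- integrated_gradients(model, Q, baseline = Q, steps = 8L,
                               class_index = 0L)
  expect_true(all(att0$values == 0))
  expect_error(integrated_gradients(model, Q,
                                    baseline = array(0, dim = c(2, 2, 3)),
                                    class_index = 0L), "shape")
})

test_that("integrated-gradients completeness gap is small at 256 steps and
           shrinks as steps double", {
  # smooth nonlinear toy: logit_0 = a' tanh(W x)
  set.seed(31)
  d <- c(6L, 6L, 3L)
  W <- matrix(rnorm(8 * prod(d), sd = 0.3), 8, prod(d))
  a <- rnorm(8)
  toy <- manual_model(
    score_fn = function(images)
      cbind(vapply(seq_len(dim(images)[4]), function(i)
        sum(a * tanh(W %*% as.vector(images[, , , i]))), numeric(1)), 0),
    gradient_fn = function(images, class_index) {
      g <- array(0, dim = dim(images))
      if (class_index != 0L) return(g)
      for (i in seq_len(dim(images)[4])) {
        t <- tanh(W %*% as.vector(images[, , , i]))
        g[, , , i] <- array(crossprod(W, a * (1 - t^2)), dim = d)
      }
      g
    })
  Q <- array(runif(prod(d)), dim = d)
  gaps <- vapply(c(8L, 32L, 256L), function(s)
    integrated_gradients(toy, Q, steps = s,
                         class_index = 0L)$completeness_gap, numeric(1))
  att <- integrated_gradients(toy, Q, steps = 256L, class_index = 0L)
  expect_lte(gaps[3], 0.01 * abs(att$delta_logit))
  expect_true(all(diff(gaps) <= 1e-9))   # monotone shrinkage 8 -> 256
  # on a real (kinked) network the gap is still finite and the map shaped
  cfg <- model_config("tiny", n_classes = 3L, side = 16L)
  net <- init_net(cfg, seed = 31L)
  Qn <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  attn <- integrated_gradients(net, Qn, steps = 32L, class_index = 0L)
  expect_true(is.finite(attn$completeness_gap))
  expect_equal(dim(attn$values), c(16L, 16L, 3L))
})

test_that("exact Shapley values satisfy the classic axioms", {
  # additivity: an additive game returns its own coefficients
  cc <- c(1.5, -2, 0.25, 3)
  phi <- shap_exact(function(s) sum(cc[s]), 4L)
  expect_equal(phi, cc, tolerance = 1e-12)
  # symmetry: the cardinality game splits equally
  expect_equal(shap_exact(function(s) length(s), 3L), rep(1, 3),
               tolerance = 1e-12)
  # efficiency + dummy on random games
  for (i in 1:8) {
    set.seed(40 + i)
    theta <- sample(3:8, 1)
    tbl <- rnorm(2^theta)
    vf <- function(s) tbl[sum(2^(s - 1)) + 1L]
    phi <- shap_exact(vf, theta)
    expect_equal(sum(phi), vf(seq_len(theta)) - vf(integer(0)),
                 tolerance = 1e-10)
    # dummy player: a game ignoring player 1 gives it zero value
    vf_dummy <- function(s) tbl[sum(2^(setdiff(s, 1L) - 1)) + 1L]
    expect_equal(shap_exact(vf_dummy, theta)[1], 0, tolerance = 1e-12)
    # two symmetric players receive equal value
    vf_sym <- function(s) length(intersect(s, 1:2)) + sum(tbl[s])
    phi_s <- shap_exact(vf_sym, theta)
    expect_equal(phi_s[1] - tbl[1], phi_s[2] - tbl[2], tolerance = 1e-10)
  }
  expect_error(shap_exact(function(s) 0, 13L), "12")
})

test_that("gradient-sampled Shapley is exact for linear models and zero at
           its own background", {
  set.seed(50)
  d <- c(6L, 6L, 3L)
  W0 <- array(rnorm(prod(d)), dim = d)
  model <- toy_linear_model(list(W0, -W0))
  Q <- array(runif(prod(d)), dim = d)
  bg <- array(runif(prod(d)), dim = d)
  att <- shap_gradient(model, Q, background = bg, n_samples = 16L,
                       seed = 3L, class_index = 0L)
  expect_equal(att$values, (Q - bg) * W0, tolerance = 1e-10)
  att0 <- shap_gradient(model, Q, background = Q, n_samples = 8L, seed = 3L,
                        class_index = 0L)
  expect_true(all(abs(att0$values) < 1e-12))
  expect_error(shap_gradient(model, Q, background = list()), "non-empty")
})

test_that("segment-summed gradient Shapley matches exact Shapley on a
           4-superpixel game within 10%", {
  toy <- toy_segment_model(side = 8L)
  set.seed(51)
  Q <- array(runif(8 * 8 * 3, 0.5, 1), dim = c(8, 8, 3))
  bg <- array(0, dim = c(8, 8, 3))
  # induced coalition game: keep segments in S at their input values,
  # set the rest to background, read the class-0 score
  vf <- function(s) {
    img <- bg
    for (k in s) {
      m <- toy$segments == (k - 1L)
      for (c in 1:3) {
        pl <- img[, , c]; pl[m] <- Q[, , c][m]; img[, , c] <- pl
      }
    }
    predict_scores(toy$model, img)[1, 1]
  }
  phi <- shap_exact(vf, 4L)
  att <- shap_gradient(toy$model, Q, background = bg, n_samples = 2000L,
                       seed = 7L, class_index = 0L)
  seg_sum <- vapply(0:3, function(k) {
    m <- toy$segments == k
    sum(att$values[, , 1][m] + att$values[, , 2][m] + att$values[, , 3][m])
  }, numeric(1))
  expect_equal(sum(phi), vf(1:4) - vf(integer(0)), tolerance = 1e-10)
  expect_lt(max(abs(seg_sum - phi)) / max(abs(phi)), 0.10)
})

test_that("LIME at lambda 0 matches the weighted least-squares closed form", {
  toy <- toy_segment_model(side = 8L)
  set.seed(60)
  Q <- array(runif(8 * 8 * 3, 0.4, 1), dim = c(8, 8, 3))
  att <- lime_explain(toy$model, Q, segments = toy$segments,
                      n_samples = 40L, lambda_l1 = 0, kernel_width = 1e6,
                      seed = 9L, class_index = 0L,
                      fill = c(0, 0, 0))
  # reconstruct the same design from the same seed and solve the normal
  # equations independently
  S <- 4L
  Z <- cytoxai:::with_seed(9L, {
    Z <- matrix(rbinom(39L * S, 1L, 0.5), 39L, S)
    rbind(rep(1L, S), Z)
  })
  y <- apply(Z, 1, function(z) {
    img <- Q
    off <- z[as.vector(toy$segments) + 1L] == 0L
    for (c in 1:3) {
      pl <- img[, , c]; pl[matrix(off, 8, 8)] <- 0; img[, , c] <- pl
    }
    pr <- predict_scores(toy$model, img)[1, ]
    exp(pr[1]) / sum(exp(pr))
  })
  X <- cbind(1, Z)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(att$intercept, beta[1], tolerance = 1e-8)
  expect_equal(att$values, beta[-1], tolerance = 1e-8)
})

test_that("LIME recovers planted linear coefficients and is invariant to
           segment relabeling", {
  # model linear in the segment indicators: fill = 0 and unit segments
  side <- 8L
  seg <- grid_segments(side, side, grid = 2L)
  coefs <- c(0.8, -0.5, 0.3, 0.1)
  lin <- manual_model(score_fn = function(images) {
    B <- dim(images)[4]
    cbind(vapply(seq_len(B), function(i) {
      s <- vapply(0:3, function(k) mean(images[, , 1, i][seg == k]),
                  numeric(1))
      sum(coefs * s)
    }, numeric(1)), 0)
  })
  Q <- array(1, dim = c(side, side, 3))
  att <- lime_explain(lin, Q, segments = seg, n_samples = 48L,
                      lambda_l1 = 1e-10, kernel_width = 1e6, seed = 2L,
                      class_index = 0L, fill = c(0, 0, 0), output = "logit")
  expect_equal(att$values, coefs, tolerance = 1e-6)
  # relabel segments by a permutation: weights follow the labels
  perm <- c(2L, 0L, 3L, 1L)
  seg2 <- matrix(perm[as.vector(seg) + 1L], side, side)
  att2 <- lime_explain(lin, Q, segments = seg2, n_samples = 48L,
                       lambda_l1 = 1e-10, kernel_width = 1e6, seed = 2L,
                       class_index = 0L, fill = c(0, 0, 0),
                       output = "logit")
  expect_equal(att2$values[perm + 1L], att$values, tolerance = 1e-6)
})

test_that("LIME on a constant predictor yields zero weights and the constant
           intercept", {
  const <- manual_model(score_fn = function(images)
    matrix(c(0.3, 0), dim(images)[4], 2, byrow = TRUE))
  Q <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  att <- lime_explain(const, Q, n_samples = 24L, lambda_l1 = 0.01,
                      seed = 4L, class_index = 0L, output = "logit")
  expect_true(all(abs(att$values) < 1e-10))
  expect_equal(att$intercept, 0.3, tolerance = 1e-10)
})

test_that("grad-cam matches hand computation on a single-channel toy model
           and dies under non-positive weights", {
  # toy: activations = channel-1 plane of the image; logit_0 = sum(w * T)
  set.seed(70)
  w_plane <- matrix(runif(16, 0.5, 1), 4, 4)
  mk_toy <- function(sign) manual_model(
    score_fn = function(images)
      cbind(vapply(seq_len(dim(images)[4]), function(i)
        sign * sum(w_plane * images[1:4, 1:4, 1, i]), numeric(1)), 0),
    features_fn = function(image) array(image[1:4, 1:4, 1], dim = c(4, 4, 1)),
    feature_gradient_fn = function(image, class_index)
      array(if (class_index == 0L) sign * w_plane else 0, dim = c(4, 4, 1)))
  img <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  att <- grad_cam(mk_toy(1), img, class_index = 0L, upsample = FALSE)
  kappa <- mean(w_plane)
  expect_equal(att$values, pmax(kappa * img[1:4, 1:4, 1], 0),
               tolerance = 1e-10)
  expect_true(all(att$values >= 0))
  # negated head: all channel weights non-positive, the map is killed
  att_neg <- grad_cam(mk_toy(-1), img, class_index = 0L, upsample = FALSE)
  expect_true(all(att_neg$values == 0))
})

test_that("backprop channel weights agree with finite differences on a tiny
           nonlinear model", {
  # logit = sum(w * tanh(T)) with T = the image's first channel
  set.seed(71)
  w_plane <- matrix(rnorm(16), 4, 4)
  toy <- manual_model(
    score_fn = function(images)
      cbind(vapply(seq_len(dim(images)[4]), function(i)
        sum(w_plane * tanh(images[, , 1, i])), numeric(1)), 0),
    features_fn = function(image) array(image[, , 1], dim = c(4, 4, 1)),
    feature_gradient_fn = function(image, class_index)
      array(w_plane * (1 - tanh(image[, , 1])^2), dim = c(4, 4, 1)))
  img <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  ana <- feature_gradient(toy, img, 0L)
  eps <- 1e-3
  num <- array(0, dim = c(4, 4, 1))
  for (u in 1:4) for (v in 1:4) {
    ip <- img; ip[u, v, 1] <- ip[u, v, 1] + eps
    im <- img; im[u, v, 1] <- im[u, v, 1] - eps
    num[u, v, 1] <- (predict_scores(toy, ip)[1, 1] -
                       predict_scores(toy, im)[1, 1]) / (2 * eps)
  }
  expect_equal(ana, num, tolerance = 1e-3)
  expect_equal(mean(ana), mean(num), tolerance = 1e-3)
})

test_that("explanation quality scores IoU and fidelity sanely", {
  mask <- matrix(0L, 8, 8); mask[3:6, 3:6] <- 1L
  perfect <- cytoxai:::new_attribution(mask * 1.0, "grad_cam", 0L)
  expect_equal(explanation_quality(perfect, mask = mask), 1.0)
  disjoint_vals <- matrix(0, 8, 8); disjoint_vals[1:2, 1:8] <- 1
  disjoint <- cytoxai:::new_attribution(disjoint_vals, "grad_cam", 0L)
  expect_equal(explanation_quality(disjoint, mask = mask), 0.0)
  expect_error(explanation_quality(perfect, mask = matrix(0L, 8, 8)),
               "empty mask")
  # fidelity of a constant predictor is zero
  const <- manual_model(score_fn = function(images)
    matrix(c(2, 1), dim(images)[4], 2, byrow = TRUE))
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  att <- cytoxai:::new_attribution(matrix(runif(64), 8, 8), "grad_cam", 0L)
  expect_equal(explanation_quality(att, model = const, image = img), 0)
})

test_that("method selection follows argmax with the documented tie-break", {
  sel <- select_explanation(rbind(c(0.34, 0.29, 0.22, 0.15),
                                  c(0.25, 0.25, 0.25, 0.25),
                                  c(0, 0, 1, 0),
                                  c(0, 0, 0, 1)))
  expect_equal(as.character(sel$method),
               c("grad_cam", "grad_cam", "integrated_gradients", "lime"))
  expect_equal(sel$weight, c(0.34, 0.25, 1, 1))
  expect_error(select_explanation(c(0.5, 0.2, 0.2, 0.2)), "simplex")
})

test_that("grid segments partition the image", {
  seg <- grid_segments(13L, 9L, grid = 3L)
  expect_equal(sort(unique(as.vector(seg))), 0:8)
  expect_equal(dim(seg), c(13L, 9L))
})
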