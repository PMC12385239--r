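# Splits, optimizers, metrics, training, cross-validation, ablations,
# profiling.

random_manifest <- function(n, k, seed) {
  set.seed(seed)
  as_manifest(data.frame(path = sprintf("img_%03d.png", seq_len(n)),
                         label = sample(paste0("c", seq_len(k)), n,
                                        replace = TRUE,
                                        prob = runif(k) + 0.2)))
}

test_that("the fixed split is stratified, disjoint and deterministic", {
  man <- as_manifest(data.frame(path = sprintf("p%d.png", 1:100),
                                label = rep(c("a", "b", "c", "d"),
                                            each = 25)))
  sp <- fixed_split(man, frac = 0.2, seed = 3L)
  expect_equal(nrow(sp$val), 20L)
  expect_equal(nrow(sp$train), 80L)
  expect_true(all(class_counts(sp$val) == 5L))
  expect_length(intersect(sp$train$path, sp$val$path), 0L)
  sp2 <- fixed_split(man, frac = 0.2, seed = 3L)
  expect_identical(sp, sp2)
  expect_false(identical(sp, fixed_split(man, frac = 0.2, seed = 4L)))
  # disjointness and coverage on random manifests
  for (i in 1:10) {
    m <- random_manifest(60, 3, 200 + i)
    if (any(class_counts(m) < 2)) next
    s <- fixed_split(m, frac = 0.25, seed = i)
    expect_length(intersect(s$train$path, s$val$path), 0L)
    expect_setequal(c(s$train$path, s$val$path), m$path)
    vc <- class_counts(s$val); tc <- class_counts(m)[names(vc)]
    expect_true(all(abs(vc - 0.25 * tc) <= 1))
  }
  tiny <- as_manifest(data.frame(path = c("a.png", "b.png"),
                                 label = c("x", "y")))
  expect_error(fixed_split(tiny, 0.2, 1L), "at least 2")
})

test_that("k-fold splits partition the manifest with stratified folds", {
  man <- as_manifest(data.frame(path = sprintf("p%d.png", 1:10),
                                label = rep(c("a", "b"), each = 5)))
  folds <- kfold_split(man, k = 5L, seed = 2L)
  expect_length(folds, 5L)
  vals <- lapply(folds, function(f) f$val$path)
  expect_true(all(lengths(vals) == 2L))
  expect_setequal(unlist(vals), man$path)
  expect_equal(sum(lengths(vals)), nrow(man))
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(vals[[i]], vals[[j]]), 0L)
  for (f in folds) {
    expect_setequal(c(f$train$path, f$val$path), man$path)
    expect_length(intersect(f$train$path, f$val$path), 0L)
  }
  expect_identical(kfold_split(man, k = 5L, seed = 2L), folds)
  # arbitrary sizes
  for (n in c(7L, 23L, 41L)) {
    m <- random_manifest(n, 3, n)
    fl <- kfold_split(m, k = 5L, seed = 1L)
    expect_setequal(unlist(lapply(fl, function(f) f$val$path)), m$path)
  }
  expect_error(kfold_split(man[1:3, ], k = 5L), "at least 5")
})

test_that("optimizer presets descend and keep independent state", {
  # one-parameter quadratic: L(w) = (w - 3)^2
  for (name in c("sgd", "nadam", "fractional_radam")) {
    spec <- optimizer_spec(name)
    params <- list(w = 0)
    opt <- make_optimizer(spec, params)
    vals <- numeric(10)
    for (t in 1:10) {
      grads <- list(w = 2 * (params$w - 3))
      params <- opt$step(params, grads)
      vals[t] <- abs(params$w - 3)
    }
    expect_true(all(diff(vals) < 0), info = name)
  }
  # independence of two instances
  spec <- optimizer_spec("sgd")
  p <- list(w = 1)
  o1 <- make_optimizer(spec, p); o2 <- make_optimizer(spec, p)
  invisible(o1$step(p, list(w = 1)))
  expect_equal(o2$state$t, 0L)
  expect_true(all(unlist(o2$state$v) == 0))
  expect_error(optimizer_spec("adagrad"))
})

test_that("fractional decay at exponent zero reproduces plain rectified
           Adam", {
  # independent scalar RAdam oracle
  radam_oracle <- function(g_fn, w0, lr, n, b1 = 0.9, b2 = 0.999,
                           eps = 1e-8) {
    w <- w0; m <- 0; v <- 0
    rho_inf <- 2 / (1 - b2) - 1
    out <- numeric(n)
    for (t in 1:n) {
      g <- g_fn(w)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t)
      rho <- rho_inf - 2 * t * b2^t / (1 - b2^t)
      if (rho > 4) {
        r <- sqrt(((rho - 4) * (rho - 2) * rho_inf) /
                    ((rho_inf - 4) * (rho_inf - 2) * rho))
        w <- w - lr * r * mh / (sqrt(v / (1 - b2^t)) + eps)
      } else w <- w - lr * mh
      out[t] <- w
    }
    out
  }
  spec <- optimizer_spec("fractional_radam", decay_exponent = 0)
  params <- list(w = 0.5)
  opt <- make_optimizer(spec, params)
  traj <- numeric(12)
  for (t in 1:12) {
    params <- opt$step(params, list(w = 2 * (params$w - 3)))
    traj[t] <- params$w
  }
  want <- radam_oracle(function(w) 2 * (w - 3), 0.5, 5e-4, 12)
  expect_equal(traj, want, tolerance = 1e-12)
  # a positive exponent slows the trajectory down
  spec2 <- optimizer_spec("fractional_radam", decay_exponent = 0.5)
  p2 <- list(w = 0.5); opt2 <- make_optimizer(spec2, p2)
  for (t in 1:12) p2 <- opt2$step(p2, list(w = 2 * (p2$w - 3)))
  expect_lt(p2$w, params$w)
})

test_that("metric identities hold on hand-computed confusion fixtures", {
  # perfect predictions
  rep1 <- metrics_report(c(0, 1, 2, 0), c(0, 1, 2, 0),
                         scores = diag(3)[c(1, 2, 3, 1), ])
  expect_equal(rep1$accuracy, 1.0)
  expect_equal(rep1$f1_macro, 1.0)
  expect_equal(rep1$roc_auc, 1.0)
  # degenerate all-one-class collapse on a balanced binary set:
  # confusion [[5,0],[5,0]] -> accuracy .5, macro recall .5, macro F1 1/3
  suppressWarnings(
    rep2 <- metrics_report(rep(c(0, 1), each = 5), rep(0, 10), k = 2L))
  expect_equal(unname(rep2$confusion), rbind(c(5L, 0L), c(5L, 0L)))
  expect_equal(rep2$accuracy, 0.5)
  expect_equal(rep2$recall_macro, 0.5)
  expect_equal(rep2$f1_macro, 1 / 3, tolerance = 1e-12)
  expect_warning(metrics_report(rep(c(0, 1), each = 5), rep(0, 10), k = 2L),
                 "no predictions")
  # weighted recall equals accuracy
  set.seed(33)
  tr <- sample(0:2, 60, replace = TRUE)
  pr <- ifelse(runif(60) < 0.7, tr, sample(0:2, 60, replace = TRUE))
  rep3 <- suppressWarnings(metrics_report(tr, pr, k = 3L))
  expect_equal(rep3$recall_weighted, rep3$accuracy, tolerance = 1e-12)
  expect_equal(unname(rowSums(rep3$confusion)),
               as.vector(table(factor(tr, 0:2))))
})

test_that("binary ROC-AUC equals the normalized Mann-Whitney statistic", {
  set.seed(34)
  truth <- rep(c(0L, 1L), c(30, 20))
  scores <- cbind(runif(50), c(runif(30), runif(20) + 0.3))
  rep <- metrics_report(truth, as.integer(scores[, 2] > 0.5),
                        scores = scores, k = 2L)
  w <- stats::wilcox.test(scores[31:50, 2], scores[1:30, 2],
                          exact = FALSE)$statistic
  expect_equal(rep$roc_auc, unname(w) / (30 * 20), tolerance = 1e-10)
  if (requireNamespace("pROC", quietly = TRUE)) {
    pr <- pROC::auc(pROC::roc(truth, scores[, 2], quiet = TRUE,
                              direction = "<"))
    expect_equal(rep$roc_auc, as.numeric(pr), tolerance = 1e-10)
  }
})

test_that("training on separable synthetic data reaches high accuracy and
           beats a label-shuffled control", {
  data <- toy_smear_data(c("benign", "pro"), n_per_class = 24L, side = 32L,
                         seed = 41L)
  split <- fixed_split(data$manifest, frac = 0.25, seed = 5L)
  fit <- cytoxai(split$train, val = split$val,
                 config = model_config("tiny", n_classes = 2L, side = 32L),
                 optimizer = optimizer_spec("sgd"),
                 epochs = 20L, batch_size = 12L, seed = 5L,
                 quality_mode = "none")
  expect_gte(fit$history$train_acc[20], 0.95)
  expect_equal(nrow(fit$history), 20L)
  # label-shuffled control stays near chance
  shuf <- split$train
  shuf$label <- cytoxai:::with_seed(99L, sample(shuf$label))
  fit_shuf <- cytoxai(as_manifest(shuf), val = split$val,
                      config = model_config("tiny", n_classes = 2L,
                                            side = 32L),
                      optimizer = optimizer_spec("sgd"),
                      epochs = 20L, batch_size = 12L, seed = 5L,
                      quality_mode = "none")
  expect_gte(fit$history$val_acc[20] - fit_shuf$history$val_acc[20], 0.3)
})

test_that("training is seeded-deterministic and validates its contract", {
  data <- toy_smear_data(c("benign", "pro"), n_per_class = 8L, side = 32L,
                         seed = 42L)
  split <- fixed_split(data$manifest, frac = 0.25, seed = 1L)
  args <- list(split$train, val = split$val,
               config = model_config("tiny", n_classes = 2L, side = 32L),
               optimizer = optimizer_spec("sgd"), epochs = 2L,
               batch_size = 8L, seed = 9L, quality_mode = "none")
  f1 <- do.call(cytoxai, args)
  f2 <- do.call(cytoxai, args)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
  expect_error(do.call(cytoxai, modifyList(args, list(epochs = 0L))),
               "epochs")
  expect_error(cytoxai(split$train[0, ], val = split$val), "empty")
})

test_that("the composite quality signal trains and logs a policy", {
  data <- toy_smear_data(c("benign", "pro"), n_per_class = 6L, side = 32L,
                         seed = 43L)
  split <- fixed_split(data$manifest, frac = 0.25, seed = 1L)
  fit <- cytoxai(split$train, val = split$val,
                 config = model_config("tiny", n_classes = 2L, side = 32L),
                 optimizer = optimizer_spec("sgd"), epochs = 1L,
                 batch_size = 8L, seed = 2L, lambda_x = 0.1,
                 quality_n = 2L)
  expect_true(all(is.finite(fit$quality)))
  expect_true(all(fit$quality >= 0 & fit$quality <= 1))
  pol <- predict(fit, split$val, type = "policy")
  expect_equal(rowSums(pol), rep(1, nrow(split$val)), tolerance = 1e-6)
  sel <- select_explanation(pol)
  expect_true(all(sel$method %in% xai_methods()))
})

test_that("evaluation, prediction and checkpointing work end to end", {
  data <- toy_smear_data(c("benign", "pro"), n_per_class = 8L, side = 32L,
                         seed = 44L)
  split <- fixed_split(data$manifest, frac = 0.25, seed = 1L)
  ck <- tempfile(fileext = ".rds")
  fit <- cytoxai(split$train, val = split$val,
                 config = model_config("tiny", n_classes = 2L, side = 32L),
                 optimizer = optimizer_spec("sgd"), epochs = 2L,
                 batch_size = 8L, seed = 3L, quality_mode = "none",
                 checkpoint = ck)
  expect_true(file.exists(ck))
  rep <- suppressWarnings(evaluate(ck, split$val))
  expect_s3_class(rep, "metrics_report")
  expect_equal(sum(rep$confusion), nrow(split$val))
  cl <- predict(fit, split$val, type = "class")
  expect_s3_class(cl, "factor")
  expect_length(cl, nrow(split$val))
  pr <- predict(fit, split$val, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(split$val)), tolerance = 1e-9)
  # label outside the vocabulary is rejected
  bad <- split$val; bad$label[1] <- "mystery"
  expect_error(evaluate(fit, as_manifest(bad)), "mystery")
})

test_that("cross-validation aggregates fold metrics by the printed mean", {
  data <- toy_smear_data(c("benign", "pro"), n_per_class = 10L, side = 32L,
                         seed = 45L)
  cv <- cross_validate(data$manifest,
                       config = model_config("tiny", n_classes = 2L,
                                             side = 32L),
                       optimizer = optimizer_spec("sgd"), k = 5L,
                       epochs = 1L, batch_size = 8L, seed = 6L,
                       quality_mode = "none")
  expect_length(cv$fold_accuracy, 5L)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy), tolerance = 1e-12)
  cv2 <- cross_validate(data$manifest,
                        config = model_config("tiny", n_classes = 2L,
                                              side = 32L),
                        optimizer = optimizer_spec("sgd"), k = 5L,
                        epochs = 1L, batch_size = 8L, seed = 6L,
                        quality_mode = "none")
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)
})

test_that("ablations alter the architecture as declared", {
  base <- model_config("tiny", n_classes = 3L, side = 16L)
  expect_identical(ablate(base, "full"), base)
  expect_error(ablate(base, "no_everything"), "unknown ablation")
  x <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  # cnn_only is strictly smaller than the full model
  p_full <- profile_model(base)
  p_cnn <- profile_model(ablate(base, "cnn_only"))
  expect_lt(p_cnn$parameters, p_full$parameters)
  expect_lt(p_cnn$macs, p_full$macs)
  # no_morph equals the gate forced to w = 1 (pooled raw features)
  net_nm <- init_net(ablate(base, "no_morph"), seed = 8L)
  fw <- cytoxai:::net_forward(net_nm, x, keep_cache = FALSE)
  expect_equal(fw$f_cnn, pool_cnn(cnn_forward(x, net_nm)), tolerance = 1e-12)
  expect_null(fw$gate)
  # no_meta_xai and cnn_only drop the policy head
  for (ab in c("no_meta_xai", "cnn_only")) {
    fwa <- cytoxai:::net_forward(init_net(ablate(base, ab), seed = 8L), x,
                                 keep_cache = FALSE)
    expect_null(fwa$policy)
  }
  # no_vit removes the transformer branch
  fwv <- cytoxai:::net_forward(init_net(ablate(base, "no_vit"), seed = 8L),
                               x, keep_cache = FALSE)
  expect_null(fwv$f_vit)
  expect_equal(dim(fwv$f_bridge), c(2L, 256L))
  # no_bridge output is unbounded linear fusion (not tanh-squashed)
  net_nb <- init_net(ablate(base, "no_bridge"), seed = 8L)
  fwb <- cytoxai:::net_forward(net_nb, x, keep_cache = FALSE)
  expect_equal(dim(fwb$f_bridge), c(2L, 256L))
})

test_that("the parameter profile matches closed-form counting", {
  cfg <- model_config("tiny", n_classes = 4L, side = 64L)
  prof <- profile_model(cfg)
  # closed forms per layer, written out independently of the instantiation
  conv <- (3 * 9 + 1) * 16 + (16 * 9 + 1) * 32 + (32 * 9 + 1) * 32 +
    2 * (16 + 32 + 32)                          # batch-norm scale/shift
  gate <- 4 * 32 + 32 * 4                       # hidden = max(4, 32/16)
  n_tok <- (64 / 8)^2 + 1
  patch <- (8 * 8 * 3) * 64 + 64                # projection + bias
  embed <- 64 + n_tok * 64                      # class token + positions
  block <- (2 * 64 + 2 * 64) +                  # two layer norms
    4 * (64 * 64 + 64) +                        # q, k, v, o
    (64 * 128 + 128) + (128 * 64 + 64)          # mlp at ratio 2
  lnf <- 2 * 64
  concept <- 64 * 64 + 64
  bridge <- (32 + 64) * 256 + 256 * 256
  cls <- 256 * 256 + 256 * 4 + 4
  policy <- 256 * 64 + 64 + 64 * 4 + 4
  expect_equal(prof$parameters,
               conv + gate + patch + embed + 2 * block + lnf + concept +
                 bridge + cls + policy)
  # a single extra class costs exactly one more output row + bias
  cfg5 <- model_config("tiny", n_classes = 5L, side = 64L)
  expect_equal(profile_model(cfg5)$parameters - prof$parameters, 256L + 1L)
})
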