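test_that("qwk loss limits: perfect agreement 0, uniform predictions 1", {
  set.seed(1)
  for (K in c(2, 5)) {
    y <- sample(0:(K - 1), 40, TRUE)
    onehot <- matrix(1e-12, 40, K)
    onehot[cbind(1:40, y + 1)] <- 1
    onehot <- onehot / rowSums(onehot)
    expect_equal(qwk_loss(onehot, y), 0, tolerance = 1e-9)
    expect_equal(qwk_loss(matrix(1 / K, 40, K), y), 1, tolerance = 1e-6)
  }
})

test_that("qwk loss equals 1 - classical kappa on one-hot predictions", {
  set.seed(2)
  for (rep in 1:60) {
    K <- sample(2:9, 1)
    n <- sample(20:60, 1)
    y <- sample(0:(K - 1), n, TRUE)
    p <- sample(0:(K - 1), n, TRUE)
    if (length(unique(y)) == 1 && all(y == p)) next  # degenerate kappa
    onehot <- matrix(0, n, K); onehot[cbind(1:n, p + 1)] <- 1
    expect_equal(qwk_loss(onehot, y), 1 - oracle_qck(y, p, K),
                 tolerance = 1e-10)
  }
})

test_that("analytic loss gradients match numerical differentiation", {
  set.seed(3)
  n <- 6; K <- 4
  A <- matrix(rnorm(n * K), n, K)
  y <- sample(0:(K - 1), n, TRUE)
  w <- runif(n, 0.5, 2)
  al <- runif(K, 0.5, 2)
  P <- wearmood:::softmax_rows(A)
  num_grad <- function(f) {
    g <- A * 0
    base <- f(P)
    for (i in seq_along(A)) {
      e <- A; e[i] <- e[i] + 1e-6
      g[i] <- (f(wearmood:::softmax_rows(e)) - base) / 1e-6
    }
    g
  }
  cases <- list(
    cce = list(a = wearmood:::.loss_cce(P, y, w, al)$dlogits,
               f = function(p) wearmood:::.loss_cce(p, y, w, al)$loss),
    focal = list(a = wearmood:::.loss_focal(P, y, w, al, 2)$dlogits,
                 f = function(p) wearmood:::.loss_focal(p, y, w, al, 2)$loss),
    qwk = list(a = wearmood:::.loss_qwk(P, y, w)$dlogits,
               f = function(p) wearmood:::.loss_qwk(p, y, w)$loss))
  for (cs in cases)
    expect_lt(max(abs(num_grad(cs$f) - cs$a)), 1e-5)
})

test_that("focal loss reduces to cross-entropy at gamma 0, uniform alpha", {
  set.seed(4)
  for (rep in 1:20) {
    K <- sample(2:5, 1); n <- 30
    P <- wearmood:::softmax_rows(matrix(rnorm(n * K), n, K))
    y <- sample(0:(K - 1), n, TRUE)
    ce <- mean(-log(P[cbind(1:n, y + 1)]))
    expect_equal(focal_loss(P, y, gamma = 0), ce, tolerance = 1e-8)
  }
  # p_y -> 1 drives the loss to 0 for any gamma
  p <- c(1 - 1e-9, 1e-9)
  expect_lt(focal_loss(p, 0, gamma = 2), 1e-8)
  # hand arithmetic for the confidence-focusing ratio at gamma 2
  l_hi <- focal_loss(c(0.9, 0.1), 0, gamma = 2)
  l_lo <- focal_loss(c(0.1, 0.9), 0, gamma = 2)
  expect_equal(l_hi / l_lo, abs(0.01 * log(0.9)) / abs(0.81 * log(0.1)))
})

test_that("probability thresholding rescales by training frequency", {
  expect_equal(probability_threshold(c(0.5, 0.5), c(0.9, 0.1), eps = 0),
               c(0.1, 0.9))
  p <- c(0.2, 0.3, 0.5)
  expect_equal(probability_threshold(p, rep(1 / 3, 3)), p, tolerance = 1e-6)
  # always a probability vector; idempotent under uniform frequencies
  set.seed(5)
  P <- wearmood:::softmax_rows(matrix(rnorm(40), 10, 4))
  f <- c(0.7, 0.2, 0.05, 0.05)
  Q <- probability_threshold(P, f)
  expect_equal(rowSums(Q), rep(1, 10))
  expect_true(all(Q >= 0))
  U <- probability_threshold(P, rep(0.25, 4))
  expect_equal(probability_threshold(U, rep(0.25, 4)), U, tolerance = 1e-9)
  # a zero-frequency rank dominates after adjustment unless its p is 0
  q <- probability_threshold(c(0.5, 0.4, 0.1), c(0.6, 0.4, 0), eps = 1e-8)
  expect_gt(q[3], 0.99)
})

test_that("alpha weights are inverse-frequency with mean one", {
  a <- alpha_weights(c(0.8, 0.15, 0.05))
  expect_equal(mean(a), 1)
  expect_true(all(diff(a) > 0))
})

test_that("encoder maps every modality to identical block shapes", {
  fit <- small_fit()
  segs <- subset_segments(fit$dat$segs, 1:5)
  enc <- encode(fit$model, segs)
  shapes <- vapply(enc$blocks, dim, numeric(3))
  expect_equal(ncol(shapes), 5)  # five modalities
  expect_true(all(shapes[2, ] == fit$model$cfg$L))
  expect_true(all(shapes[3, ] == fit$model$cfg$d))
  expect_equal(dim(enc$concat)[3], 5 * fit$model$cfg$d)
  # zeroed channel: finite response (bias pattern)
  segs0 <- segs
  segs0$channels$EDA[] <- 0
  expect_true(all(is.finite(encode(fit$model, segs0)$blocks$EDA)))
})

test_that("dropping a modality shrinks the concatenation width by d", {
  fit <- small_fit()
  dat <- fit$dat
  cfg <- model_config(epochs = 1, seed = 1, drop_channel = "TEMP")
  m <- train_model(dat$segs, dat$split, cfg)
  enc <- encode(m, subset_segments(dat$segs, 1:3))
  expect_equal(length(enc$blocks), 4)
  expect_equal(dim(enc$concat)[3], 4 * cfg$d)
})

test_that("representations are deterministic, finite and label-blind", {
  fit <- small_fit()
  segs <- subset_segments(fit$dat$segs, 1:8)
  h1 <- represent(fit$model, segs)
  h2 <- represent(fit$model, segs)
  expect_identical(h1, h2)
  expect_true(all(is.finite(h1)))
  expect_equal(dim(h1), c(8, fit$model$cfg$D))
  relabelled <- segs
  relabelled$labels[] <- 0L
  expect_identical(represent(fit$model, relabelled), h1)
})

test_that("28 item heads with schema rank counts, rows on the simplex", {
  fit <- small_fit()
  h <- represent(fit$model, subset_segments(fit$dat$segs, 1:4))
  preds <- predict_items(fit$model, h)
  items <- combined_items()
  expect_length(preds, 28)
  expect_equal(names(preds), items$id)
  for (j in seq_len(28)) {
    expect_equal(ncol(preds[[j]]), items$n_ranks[j])
    expect_equal(rowSums(preds[[j]]), rep(1, 4), tolerance = 1e-6)
  }
  # heads are independent: perturbing one head leaves the others unchanged
  m2 <- fit$model
  m2$params$ip[[3]]$W[, 1] <- m2$params$ip[[3]]$W[, 1] + 1
  preds2 <- predict_items(m2, h)
  expect_false(isTRUE(all.equal(preds2[[3]], preds[[3]])))
  for (j in setdiff(1:28, 3)) expect_equal(preds2[[j]], preds[[j]])
})

test_that("critic outputs a distribution over training subjects", {
  fit <- small_fit()
  h <- represent(fit$model, subset_segments(fit$dat$segs, 1:6))
  cp <- critic_forward(fit$model, h)
  expect_equal(colnames(cp), fit$model$subjects)
  expect_equal(rowSums(cp), rep(1, 6), tolerance = 1e-6)
})

test_that("toy training is finite, seeded-reproducible, and learns", {
  fit <- small_fit()
  curves <- fit$model$curves
  expect_true(all(is.finite(curves$task_loss)))
  expect_true(all(is.finite(curves$critic_loss)))
  # both the multi-task loss and the critic loss decrease on the toy run
  expect_lt(tail(curves$task_loss, 1), curves$task_loss[1])
  expect_lt(tail(curves$critic_loss, 1), curves$critic_loss[1])
  # above-chance validation agreement on planted-signal data
  expect_gt(tail(curves$val_qck, 1), 0)
  # same seed twice gives identical training trajectories
  m2 <- train_model(fit$dat$segs, fit$dat$split,
                    model_config(epochs = 4, seed = 11))
  expect_equal(m2$curves, curves)
})

test_that("prediction contracts: shape, thresholding, tau mismatch", {
  fit <- small_fit()
  segs <- subset_segments(fit$dat$segs, fit$dat$split$test[1:10])
  p_off <- predict_model(fit$model, segs, threshold = FALSE)
  p_on <- predict_model(fit$model, segs, threshold = TRUE)
  expect_equal(dim(p_off$ranks), c(10, 28))
  expect_equal(names(p_on$probs), names(p_off$probs))  # same item inventory
  # printed predictions respect rank steps
  items <- combined_items()
  expect_true(all(p_off$printed[, items$rank_step == 2] %% 2 == 0))
  # thresholding can flip an argmax (shown on the canonical example)
  adj <- probability_threshold(c(0.5, 0.5), c(0.9, 0.1), eps = 0)
  expect_equal(which.max(adj), 2)
  # tau mismatch is caught by name
  bad <- segs; bad$tau <- 32
  expect_error(predict_model(fit$model, bad), "tau")
})

test_that("checkpoints round-trip through JSON with identical predictions", {
  fit <- small_fit()
  segs <- subset_segments(fit$dat$segs, 1:6)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  back <- load_model(path)
  p1 <- predict_model(fit$model, segs)
  p2 <- predict_model(back, segs)
  expect_equal(p2$ranks, p1$ranks)
  expect_equal(p2$probs, p1$probs, tolerance = 1e-12)
  expect_equal(back$cfg, fit$model$cfg)
})
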