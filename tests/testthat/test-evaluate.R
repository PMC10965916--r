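test_that("quadratic kappa endpoints and worked case", {
  expect_equal(qck(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0), 3), 1)
  expect_equal(qck(c(0, 0, 1, 1), c(1, 1, 0, 0), 2), -1)
  y <- c(0, 1, 2, 2, 0); p <- c(0, 2, 2, 1, 0)
  expect_equal(qck(y, p, 3), oracle_qck(y, p, 3), tolerance = 1e-12)
  expect_warning(out <- qck(c(1, 1, 1), c(1, 1, 1), 3), "degenerate")
  expect_equal(out, 1)
})

test_that("qck agrees with the brute-force oracle on random vectors", {
  set.seed(6)
  for (rep in 1:200) {
    K <- sample(2:9, 1); n <- sample(10:80, 1)
    y <- sample(0:(K - 1), n, TRUE)
    p <- sample(0:(K - 1), n, TRUE)
    if (length(unique(y)) == 1 && all(y == p)) next
    expect_equal(qck(y, p, K), oracle_qck(y, p, K), tolerance = 1e-12)
  }
})

test_that("qck is invariant to constant rank shifts", {
  set.seed(7)
  y <- sample(0:2, 50, TRUE); p <- sample(0:2, 50, TRUE)
  expect_equal(qck(y + 2, p + 2, 5), qck(y, p, 3), tolerance = 1e-12)
})

test_that("macro F1 penalizes majority-vote predictions", {
  expect_equal(macro_f1(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2), 3), 1)
  # true counts [9, 1], constant majority prediction
  y <- c(rep(0, 9), 1); p <- rep(0, 10)
  expect_equal(macro_f1(y, p, 2), ((2 * 9) / (2 * 9 + 1) + 0) / 2)
  expect_lt(macro_f1(y, p, 2), mean(y == p))  # far below accuracy
  set.seed(8)
  for (rep in 1:100) {
    K <- sample(2:6, 1); n <- sample(10:50, 1)
    y <- sample(0:(K - 1), n, TRUE); p <- sample(0:(K - 1), n, TRUE)
    expect_equal(macro_f1(y, p, K), oracle_macro_f1(y, p), tolerance = 1e-12)
  }
})

test_that("entropy correlation is plain Pearson R with guards", {
  H <- c(0.2, 0.8, 1.4)
  expect_equal(entropy_correlation(0.1 + 0.5 * H, H), 1)
  x <- c(0.3, 0.9, 0.6)
  num <- sum((x - mean(x)) * (H - mean(H)))
  den <- sqrt(sum((x - mean(x))^2) * sum((H - mean(H))^2))
  expect_equal(entropy_correlation(x, H), num / den)
  set.seed(9)
  expect_lt(abs(entropy_correlation(rnorm(2000), rnorm(2000))), 0.08)
  expect_error(entropy_correlation(rep(0.5, 5), 1:5), "zero variance")
})

test_that("total-score RMSE from item predictions", {
  items <- combined_items()
  n <- 40
  truth <- matrix(0L, n, 28, dimnames = list(NULL, items$id))
  expect_equal(total_rmse(truth, truth), c(HDRS = 0, YMRS = 0))
  # every HDRS item over-predicted by one step of 1 -> total error 17
  over <- truth
  over[, items$scale == "HDRS"] <- 1L
  expect_equal(total_rmse(over, truth)[["HDRS"]], 17)
  expect_equal(total_rmse(over, truth)[["YMRS"]], 0)
  set.seed(10)
  for (rep in 1:20) {
    pr <- matrix(sample(0:4, n * 28, TRUE), n, 28)
    tr <- matrix(sample(0:4, n * 28, TRUE), n, 28)
    hd <- which(items$scale == "HDRS")
    brute <- sqrt(mean((rowSums(pr[, hd]) - rowSums(tr[, hd]))^2))
    expect_equal(total_rmse(pr, tr)[["HDRS"]], brute, tolerance = 1e-12)
  }
})

test_that("glasso satisfies its optimality conditions", {
  set.seed(11)
  p <- 6
  A <- matrix(rnorm(p * p), p)
  S <- cov2cor(crossprod(A) / p + diag(p))
  rho <- 0.1
  fit <- glasso_fit(S, rho)
  W <- fit$w; Th <- fit$theta
  expect_equal(W %*% Th, diag(p), tolerance = 1e-3)
  # KKT: |W - S| <= rho off-diagonal, equality with sign on active edges
  D <- W - S
  off <- upper.tri(S)
  expect_true(all(abs(D[off]) <= rho + 1e-6))
  act <- off & abs(Th) > 1e-8
  if (any(act))
    expect_equal(D[act], rho * sign(Th[act]), tolerance = 1e-4)
  expect_equal(diag(W), diag(S) + rho, tolerance = 1e-8)
  # penalty -> 0 recovers the analytic inverse
  f0 <- glasso_fit(S, 1e-7)
  expect_equal(f0$theta, solve(S), tolerance = 1e-4)
})

test_that("independent residuals give a near-empty network", {
  set.seed(12)
  n <- 800
  pr <- matrix(sample(0:3, n * 28, TRUE), n, 28)
  tr <- matrix(sample(0:3, n * 28, TRUE), n, 28)
  net <- residual_diagnostics(pr, tr, min_n = 200)
  expect_lte(nrow(net$edges), 5)
  ev <- eigen(net$theta, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_true(isSymmetric(net$pcor))
  expect_true(all(diag(net$pcor) == 0))
  expect_error(residual_diagnostics(pr[1:50, ], tr[1:50, ]), "at least")
})

test_that("zero-variance residual columns are handled with a warning", {
  set.seed(13)
  n <- 300
  pr <- matrix(sample(0:3, n * 28, TRUE), n, 28)
  tr <- pr
  tr[, 3:28] <- matrix(sample(0:3, n * 26, TRUE), n, 26)
  expect_warning(net <- residual_diagnostics(pr, tr, min_n = 200),
                 "zero-variance")
  expect_true(all(is.finite(net$pcor)))
})

test_that("drift curves report per-interval per-item agreement", {
  fit <- small_fit()
  # far intervals from short re-rendered sessions with a tiny close region
  cfg <- synth_config(n_subjects = 3, session_rate = 0, duration_h = 1.1,
                      drift_onset_h = 0.1, drift_mag = 0, seed = 61)
  co <- sample_cohort(cfg)
  sess <- lapply(seq_along(co$sessions), function(i)
    render_session(co$sessions[[i]], co$profiles[[i]], cfg))
  far <- far_interval_segments(sess, 16, co$labels, close_h = 0.1)
  expect_equal(length(far), 2)  # (1.1 - 0.1) h = two 30-min intervals
  dr <- drift_evaluation(fit$model, far)
  expect_equal(nrow(dr), 2)
  expect_equal(dr$interval, names(far))
  expect_true(all(c("HDRS_qck", "YMRS_qck", "overall_qck") %in% names(dr)))
  expect_true(all(combined_items()$id %in% names(dr)))
  expect_true(all(dr$n_segments > 0))
})

test_that("per-subject F1 and Bonferroni-corrected screens", {
  set.seed(14)
  n <- 120
  subs <- rep(sprintf("S%02d", 1:10), each = 12)
  items <- combined_items()
  tr <- matrix(sample(0:2, n * 28, TRUE), n, 28)
  pr <- tr
  flip <- matrix(runif(n * 28) < 0.3, n, 28)
  pr[flip] <- (tr[flip] + 1L) %% 3L
  cov <- data.frame(subject_id = sprintf("S%02d", 1:10),
                    age = rnorm(10, 45, 12),
                    sex = rep(c("F", "M"), 5),
                    hdrs_total = rpois(10, 8), ymrs_total = rpois(10, 6))
  out <- subject_scores(pr, tr, subs, covariates = cov)
  expect_equal(nrow(out$per_subject), 10)
  expect_true(all(out$per_subject$f1m >= 0 & out$per_subject$f1m <= 1))
  expect_equal(nrow(out$screens), 4)
  # Bonferroni over 4 screens at alpha 0.05 is a per-test 0.0125 threshold
  expect_equal(out$screens$p_bonferroni, pmin(1, out$screens$p * 4))
  expect_equal(out$screens$significant, out$screens$p < 0.05 / 4)
  # subjects with < 2 segments are excluded with a warning
  expect_warning(
    out2 <- subject_scores(pr[1:13, ], tr[1:13, ],
                           c(rep("A", 12), "B")), "excluding")
  expect_equal(out2$per_subject$subject_id, "A")
})

test_that("a synthetic null keeps the screens quiet at the family level", {
  set.seed(15)
  hits <- replicate(40, {
    n_sub <- 12
    subs <- rep(sprintf("S%02d", 1:n_sub), each = 8)
    tr <- matrix(sample(0:2, length(subs) * 28, TRUE), length(subs), 28)
    pr <- tr
    flip <- matrix(runif(length(tr)) < 0.25, nrow(tr), 28)
    pr[flip] <- (tr[flip] + 1L) %% 3L   # errors independent of subject
    cov <- data.frame(subject_id = sprintf("S%02d", 1:n_sub),
                      age = rnorm(n_sub, 45, 10),
                      sex = rep(c("F", "M"), n_sub / 2),
                      hdrs_total = rpois(n_sub, 8),
                      ymrs_total = rpois(n_sub, 6))
    any(subject_scores(pr, tr, subs, covariates = cov)$screens$significant)
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("metric report aggregates per item and per scale", {
  fit <- small_fit()
  test_idx <- fit$dat$split$test
  pred <- predict_model(fit$model, subset_segments(fit$dat$segs, test_idx))
  rep <- metric_report(pred$ranks, fit$dat$segs$labels[test_idx, ])
  expect_equal(nrow(rep$per_item), 28)
  expect_true(all(rep$per_item$qck >= -1 & rep$per_item$qck <= 1))
  expect_true(all(rep$per_item$f1 >= 0 & rep$per_item$f1 <= 1))
  expect_true(all(rep$total_rmse >= 0))
  expect_equal(unname(rep$item_avg["overall_qck"]), mean(rep$per_item$qck))
  d <- withr::local_tempdir()
  write_eval_tables(rep, d)
  expect_true(file.exists(file.path(d, "item_qck.tsv")))
  back <- read.delim(file.path(d, "item_qck.tsv"))
  expect_equal(back$qck, rep$per_item$qck, tolerance = 1e-12)
})

test_that("channel ablation reports per-item deltas against the baseline", {
  # planted contrast: only ACC carries label signal, BVP is pure noise
  set.seed(16)
  sch <- build_schemas()
  items <- combined_items()
  n_sess <- 8; per <- 30; tau <- 16
  n <- n_sess * per
  lab_rows <- list(); sets <- list()
  for (s in seq_len(n_sess)) {
    lat <- (s - 1) / (n_sess - 1)
    v <- vapply(seq_len(28), function(j)
      wearmood:::.discretize_item(lat, items[j, ], synth_config()), 0L)
    lab_rows[[s]] <- c(list(session_id = sprintf("P%02d_T1", s),
                            subject_id = sprintf("P%02d", s),
                            interview_time = 0), setNames(as.list(v), items$id))
    amp <- 0.3 + lat
    acc <- array(rnorm(per * tau * 32 * 3, 0, amp), c(per, tau * 32, 3))
    sets[[s]] <- structure(list(
      manifest = data.frame(session_id = sprintf("P%02d_T1", s),
                            subject_id = sprintf("P%02d", s),
                            window_index = seq_len(per),
                            offset = (seq_len(per) - 1) * tau),
      channels = list(ACC = acc,
                      BVP = matrix(rnorm(per * tau * 64), per),
                      EDA = matrix(rnorm(per * tau * 4), per),
                      HR = matrix(rnorm(per * tau), per),
                      TEMP = matrix(rnorm(per * tau), per)),
      tau = tau), class = "segment_set")
  }
  segs <- do.call(bind_segments, sets)
  labels <- do.call(rbind, lapply(lab_rows, as.data.frame))
  segs <- attach_labels(segs, labels)
  split <- make_splits(segs, seed = 2)
  rep <- channel_ablation(segs, split, model_config(epochs = 5, seed = 4),
                          modalities = c("ACC", "BVP"))
  expect_equal(nrow(rep), 2 * 28)
  expect_error(channel_ablation(segs, split, modalities = "PPG"), "unknown")
  d_acc <- mean(rep$delta_qck[rep$modality == "ACC"])
  d_bvp <- mean(rep$delta_qck[rep$modality == "BVP"])
  expect_lt(d_acc, -0.2)        # removing the informative channel hurts
  expect_lt(abs(d_bvp), 0.15)   # removing a noise channel is neutral
  expect_lt(d_acc, d_bvp)
})
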