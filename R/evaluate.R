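#' Evaluation suite
#'
#' Per-item quadratic weighted Cohen's kappa and macro F1, item-average
#' summaries, correlation of item performance with label entropy, drift
#' curves over far-from-interview intervals, residual diagnostics with a
#' regularized partial-correlation network, per-subject performance
#' screens, total-score RMSE and leave-one-channel-out ablations.
#'
#' @name evaluate
NULL

#' Quadratic weighted Cohen's kappa
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with `w_jk = (j - k)^2`, `O` the
#' confusion matrix of the two raters and `E` the outer product of their
#' marginals scaled to the sample size. Chance-corrected agreement that
#' penalizes disagreements by squared rank distance; values lie in
#' `[-1, 1]`. When both raters are constant and identical the statistic is
#' degenerate (no disagreement, no chance variation) and is defined as 1
#' with a warning, keeping drift curves total.
#'
#' @param true,pred integer rank vectors in `[0, K - 1]`, equal length.
#' @param K number of ranks.
#' @return The quadratic kappa.
#' @export
qck <- function(true, pred, K) {
  stopifnot(length(true) == length(pred), length(true) > 0)
  true <- as.integer(true); pred <- as.integer(pred)
  stopifnot(all(true >= 0 & true < K), all(pred >= 0 & pred < K))
  N <- length(true)
  O <- table(factor(true, levels = 0:(K - 1)),
             factor(pred, levels = 0:(K - 1)))
  W <- outer(0:(K - 1), 0:(K - 1), function(a, b) (a - b)^2)
  E <- outer(rowSums(O), colSums(O)) / N
  den <- sum(W * E)
  if (den == 0) {
    warning("degenerate agreement (both raters constant and identical); ",
            "kappa defined as 1")
    return(1)
  }
  1 - sum(W * O) / den
}

#' Macro-averaged F1
#'
#' Unweighted mean of per-rank F1 scores over the ranks present in either
#' vector (never-occurring schema ranks are excluded rather than counted
#' as zero).
#'
#' @inheritParams qck
#' @return F1^M in `[0, 1]`.
#' @export
macro_f1 <- function(true, pred, K) {
  stopifnot(length(true) == length(pred), length(true) > 0)
  present <- sort(unique(c(true, pred)))
  f1 <- vapply(present, function(k) {
    tp <- sum(true == k & pred == k)
    fp <- sum(true != k & pred == k)
    fn <- sum(true == k & pred != k)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}

#' Pearson correlation between item performance and label entropy
#'
#' @param item_qck per-item QCK values.
#' @param item_entropy matching per-item Shannon entropies.
#' @return Pearson R.
#' @export
entropy_correlation <- function(item_qck, item_entropy) {
  stopifnot(length(item_qck) == length(item_entropy))
  if (stats::sd(item_qck) == 0 || stats::sd(item_entropy) == 0)
    stop("zero variance: entropy correlation undefined", call. = FALSE)
  stats::cor(item_qck, item_entropy)
}

#' Per-item and summary metrics on a prediction set
#'
#' @param pred_ranks `n x 28` matrix of 0-based unit-step predictions.
#' @param true_printed `n x 28` matrix of true printed item values.
#' @param schemas output of [build_schemas()].
#' @return A `metric_report`: `per_item` table (item, scale, qck, f1,
#'   entropy, rho where defined), `item_avg` (overall/HDRS/YMRS mean QCK
#'   and F1), `entropy_R`, and `total_rmse` per scale.
#' @export
metric_report <- function(pred_ranks, true_printed,
                          schemas = build_schemas()) {
  items <- combined_items(schemas)
  true_idx <- unit_step_labels(true_printed, schemas)
  per_item <- do.call(rbind, lapply(seq_len(nrow(items)), function(j) {
    K <- items$n_ranks[j]
    counts <- tabulate(true_idx[, j] + 1L, nbins = K)
    data.frame(
      item = items$id[j], scale = items$scale[j],
      qck = qck(true_idx[, j], pred_ranks[, j], K),
      f1 = macro_f1(true_idx[, j], pred_ranks[, j], K),
      entropy = shannon_entropy(counts),
      rho = if (all(counts > 0)) imbalance_ratio(counts) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  item_avg <- c(
    overall_qck = mean(per_item$qck),
    HDRS_qck = mean(per_item$qck[per_item$scale == "HDRS"]),
    YMRS_qck = mean(per_item$qck[per_item$scale == "YMRS"]),
    overall_f1 = mean(per_item$f1),
    HDRS_f1 = mean(per_item$f1[per_item$scale == "HDRS"]),
    YMRS_f1 = mean(per_item$f1[per_item$scale == "YMRS"]))
  eR <- if (stats::sd(per_item$qck) > 0 && stats::sd(per_item$entropy) > 0)
    entropy_correlation(per_item$qck, per_item$entropy) else NA_real_
  step <- items$rank_step
  pred_printed <- sweep(pred_ranks, 2, step, `*`)
  structure(list(per_item = per_item, item_avg = item_avg,
                 entropy_R = eR,
                 total_rmse = total_rmse(pred_printed, true_printed,
                                         schemas)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> item-average QCK %.3f (HDRS %.3f, YMRS %.3f), F1 %.3f\n",
    x$item_avg["overall_qck"], x$item_avg["HDRS_qck"],
    x$item_avg["YMRS_qck"], x$item_avg["overall_f1"]))
  cat(sprintf("  total-score RMSE: HDRS %.3f, YMRS %.3f; entropy R %.3f\n",
              x$total_rmse["HDRS"], x$total_rmse["YMRS"], x$entropy_R))
  invisible(x)
}

#' RMSE of predicted total scores
#'
#' Item predictions are summed to scale totals (on the printed-value
#' scale) and compared with the true totals.
#'
#' @param pred_printed,true_printed `n x 28` matrices of printed item
#'   values (HDRS columns then YMRS columns).
#' @param schemas output of [build_schemas()].
#' @return Named vector `c(HDRS = ..., YMRS = ...)`.
#' @export
total_rmse <- function(pred_printed, true_printed,
                       schemas = build_schemas()) {
  items <- combined_items(schemas)
  out <- c(HDRS = NA_real_, YMRS = NA_real_)
  for (sc in c("HDRS", "YMRS")) {
    cols <- which(items$scale == sc)
    pt <- rowSums(pred_printed[, cols, drop = FALSE])
    tt <- rowSums(true_printed[, cols, drop = FALSE])
    out[sc] <- sqrt(mean((pt - tt)^2))
  }
  out
}

#' Build far-from-interview segment sets, one per 30-minute interval
#'
#' @param sessions list of (quality-controlled) [e4_session()] objects.
#' @param tau window length (s).
#' @param labels session-label table.
#' @param schemas output of [build_schemas()].
#' @param close_h close-region length in hours.
#' @return A list of labelled `segment_set`s named by interval
#'   (`"5:00-5:30"`, ...), aligned across sessions; empty intervals are
#'   dropped.
#' @export
far_interval_segments <- function(sessions, tau, labels,
                                  schemas = build_schemas(),
                                  close_h = 5) {
  max_far <- 0L
  parts <- lapply(sessions, close_far_partition, close_h = close_h)
  max_far <- max(c(0L, vapply(parts, function(p) length(p$far), 0L)))
  if (max_far == 0L) return(list())
  out <- list()
  for (k in seq_len(max_far)) {
    sets <- list()
    for (i in seq_along(sessions)) {
      if (length(parts[[i]]$far) < k) next
      s <- segment_session(sessions[[i]], tau, parts[[i]]$far[[k]])
      if (n_segments(s) > 0) sets[[length(sets) + 1L]] <- s
    }
    if (!length(sets)) next
    segs <- do.call(bind_segments, sets)
    segs <- attach_labels(segs, labels, schemas)
    a <- close_h * 3600 + (k - 1L) * 1800
    lab <- sprintf("%d:%02d-%d:%02d", a %/% 3600, (a %% 3600) %/% 60,
                   (a + 1800) %/% 3600, ((a + 1800) %% 3600) %/% 60)
    out[[lab]] <- segs
  }
  out
}

#' Performance drift over far-from-interview intervals
#'
#' Applies a trained model to each 30-minute interval's segments and
#' reports per-item QCK plus the HDRS/YMRS item averages in time order.
#' Intervals with no retained segments are recorded as missing.
#'
#' @param model a trained `wearmood_model`.
#' @param far_list output of [far_interval_segments()].
#' @param threshold apply probability thresholding.
#' @return A `drift_curve` data.frame: `interval`, `n_segments`,
#'   `HDRS_qck`, `YMRS_qck`, `overall_qck`, then one column per item.
#' @export
drift_evaluation <- function(model, far_list, threshold = FALSE) {
  items <- model$items
  rows <- lapply(names(far_list), function(lab) {
    segs <- far_list[[lab]]
    base <- data.frame(interval = lab, n_segments = n_segments(segs),
                       stringsAsFactors = FALSE)
    if (n_segments(segs) == 0) {
      qcks <- rep(NA_real_, nrow(items))
    } else {
      pred <- predict_model(model, segs, threshold = threshold)
      y <- unit_step_labels(segs$labels, model$schemas)
      qcks <- vapply(seq_len(nrow(items)), function(j)
        qck(y[, j], pred$ranks[, j], items$n_ranks[j]), 0)
    }
    base$HDRS_qck <- mean(qcks[items$scale == "HDRS"])
    base$YMRS_qck <- mean(qcks[items$scale == "YMRS"])
    base$overall_qck <- mean(qcks)
    for (j in seq_len(nrow(items))) base[[items$id[j]]] <- qcks[j]
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("drift_curve", class(out))
  out
}

#' Residual diagnostics with a regularized partial-correlation network
#'
#' Signed errors (prediction minus truth) are put on the unit-step scale
#' (double-weighted items rescaled to step one), their Pearson correlation
#' matrix is estimated, and a graphical lasso with EBIC selection yields a
#' sparse partial-correlation network over the 28 items, with per-node
#' predictability (variance explained by neighbours) and optional
#' bootstrap edge-inclusion frequencies.
#'
#' @param pred_ranks,true_ranks `n x 28` matrices of 0-based unit-step
#'   ranks.
#' @param schemas output of [build_schemas()].
#' @param min_n minimum number of segments required.
#' @param ebic_gamma EBIC gamma.
#' @param n_boot bootstrap draws for edge-inclusion frequencies (0 = off;
#'   refits at the selected penalty).
#' @param seed seed for the bootstrap.
#' @return A `residual_network`: `residuals`, `pcor` (28 x 28 adjacency),
#'   `theta`, `predictability`, `lambda`, `edges` (edge list with partial
#'   correlations) and `boot_freq` (or `NULL`).
#' @export
residual_diagnostics <- function(pred_ranks, true_ranks,
                                 schemas = build_schemas(),
                                 min_n = 200, ebic_gamma = 0.5,
                                 n_boot = 0, seed = 1L) {
  items <- combined_items(schemas)
  stopifnot(ncol(pred_ranks) == nrow(items))
  n <- nrow(pred_ranks)
  if (n < min_n)
    stop(sprintf("need at least %d segments for residual diagnostics", min_n),
         call. = FALSE)
  res <- pred_ranks - true_ranks
  colnames(res) <- items$id
  sds <- apply(res, 2, stats::sd)
  S <- diag(ncol(res))
  ok <- sds > 0
  if (any(!ok))
    warning("zero-variance residual column(s): ",
            paste(items$id[!ok], collapse = ", "),
            "; their correlations set to 0")
  S[ok, ok] <- stats::cor(res[, ok, drop = FALSE])
  dimnames(S) <- list(items$id, items$id)
  fit <- ebic_glasso(S, n, gamma = ebic_gamma)
  pc <- fit$pcor
  ut <- which(upper.tri(pc) & abs(pc) > 1e-8, arr.ind = TRUE)
  edges <- data.frame(node_i = items$id[ut[, 1]],
                      node_j = items$id[ut[, 2]],
                      pcor = pc[ut], stringsAsFactors = FALSE)
  boot_freq <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    count <- matrix(0, ncol(res), ncol(res))
    for (b in seq_len(n_boot)) {
      ib <- sample(n, n, replace = TRUE)
      Sb <- diag(ncol(res))
      sb <- apply(res[ib, , drop = FALSE], 2, stats::sd)
      okb <- sb > 0
      Sb[okb, okb] <- stats::cor(res[ib, okb, drop = FALSE])
      fb <- glasso_fit(Sb, fit$lambda)
      count <- count + (abs(partial_correlations(fb$theta)) > 1e-8)
    }
    boot_freq <- count / n_boot
    dimnames(boot_freq) <- dimnames(S)
  }
  structure(list(residuals = res, pcor = pc, theta = fit$theta,
                 predictability = stats::setNames(fit$predictability,
                                                  items$id),
                 lambda = fit$lambda, edges = edges,
                 boot_freq = boot_freq, path = fit$path),
            class = "residual_network")
}

#' Per-subject performance and clinical-demographic screens
#'
#' Computes the item-average macro F1 per subject, then screens it for
#' association with covariates: Pearson correlation tests against
#' continuous covariates and a two-sample t-test against a binary `sex`,
#' with Bonferroni correction over the screens performed.
#'
#' @param pred_ranks,true_ranks `n x 28` unit-step rank matrices.
#' @param subject_ids length-n subject of each segment.
#' @param covariates optional data.frame with `subject_id` and any of
#'   `age`, `sex`, `hdrs_total`, `ymrs_total`.
#' @param schemas output of [build_schemas()].
#' @param alpha familywise significance level.
#' @return List with `per_subject` (subject, n segments, f1m) and
#'   `screens` (covariate, statistic, p, p_bonferroni, significant), or
#'   `NULL` screens when no covariates are given.
#' @export
subject_scores <- function(pred_ranks, true_ranks, subject_ids,
                           covariates = NULL,
                           schemas = build_schemas(), alpha = 0.05) {
  items <- combined_items(schemas)
  subs <- unique(subject_ids)
  keep <- vapply(subs, function(s) sum(subject_ids == s) >= 2, TRUE)
  if (any(!keep))
    warning("excluding subject(s) with < 2 segments: ",
            paste(subs[!keep], collapse = ", "))
  subs <- subs[keep]
  f1m <- vapply(subs, function(s) {
    i <- subject_ids == s
    mean(vapply(seq_len(nrow(items)), function(j)
      macro_f1(true_ranks[i, j], pred_ranks[i, j], items$n_ranks[j]), 0))
  }, 0)
  per_subject <- data.frame(subject_id = subs,
                            n_segments = vapply(subs, function(s)
                              sum(subject_ids == s), 0L),
                            f1m = f1m, stringsAsFactors = FALSE)
  screens <- NULL
  if (!is.null(covariates)) {
    cv <- covariates[match(subs, covariates$subject_id), , drop = FALSE]
    rows <- list()
    if (stats::sd(f1m) == 0) {
      warning("all subjects share one F1^M value; associations undefined")
    } else {
      for (v in intersect(c("age", "hdrs_total", "ymrs_total"),
                          names(cv))) {
        ct <- stats::cor.test(f1m, cv[[v]])
        rows[[v]] <- data.frame(covariate = v, test = "pearson",
                                statistic = unname(ct$estimate),
                                p = ct$p.value)
      }
      if ("sex" %in% names(cv) && length(unique(cv$sex)) == 2) {
        tt <- stats::t.test(f1m ~ factor(cv$sex))
        rows$sex <- data.frame(covariate = "sex", test = "t",
                               statistic = unname(tt$statistic),
                               p = tt$p.value)
      }
    }
    if (length(rows)) {
      screens <- do.call(rbind, rows)
      screens$p_bonferroni <- stats::p.adjust(screens$p, "bonferroni")
      screens$significant <- screens$p_bonferroni < alpha
      rownames(screens) <- NULL
    }
  }
  list(per_subject = per_subject, screens = screens)
}

#' Leave-one-channel-out ablation
#'
#' Retrains the model with identical seed and configuration, each time
#' excluding one sensory modality, and reports per-item QCK differences
#' relative to the all-channel baseline on the test split.
#'
#' @param segs labelled `segment_set`.
#' @param split a `dataset_split`.
#' @param cfg a [model_config()] (its `drop_channel` must be `NULL`).
#' @param modalities modalities to leave out (default all five).
#' @param schemas output of [build_schemas()].
#' @param threshold apply probability thresholding when predicting.
#' @param baseline optionally a pre-trained all-channel model to reuse.
#' @return An `ablation_report` data.frame: `modality`, `item`,
#'   `qck_baseline`, `qck_ablated`, `delta_qck` (5 modalities x 28 items
#'   by default).
#' @export
channel_ablation <- function(segs, split, cfg = model_config(),
                             modalities = names(e4_rates()),
                             schemas = build_schemas(),
                             threshold = FALSE, baseline = NULL) {
  stopifnot(is.null(cfg$drop_channel))
  bad <- setdiff(modalities, names(e4_rates()))
  if (length(bad))
    stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
  items <- combined_items(schemas)
  y <- unit_step_labels(segs$labels, schemas)
  test_qck <- function(model) {
    pred <- predict_model(model, subset_segments(segs, split$test),
                          threshold = threshold)
    vapply(seq_len(nrow(items)), function(j)
      qck(y[split$test, j], pred$ranks[, j], items$n_ranks[j]), 0)
  }
  if (is.null(baseline))
    baseline <- train_model(segs, split, cfg, schemas)
  q0 <- test_qck(baseline)
  out <- list()
  for (m in modalities) {
    cfg_m <- cfg
    cfg_m$drop_channel <- m
    fit <- train_model(segs, split, cfg_m, schemas)
    qm <- test_qck(fit)
    out[[m]] <- data.frame(modality = m, item = items$id,
                           qck_baseline = q0, qck_ablated = qm,
                           delta_qck = qm - q0, stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("ablation_report", class(rep))
  rep
}

#' Write the evaluation tables as columnar text
#'
#' @param report a `metric_report`.
#' @param dir output directory.
#' @param drift optional `drift_curve`.
#' @param network optional `residual_network`.
#' @return `dir`, invisibly.
#' @export
write_eval_tables <- function(report, dir, drift = NULL, network = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_item, file.path(dir, "item_qck.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- data.frame(metric = c(names(report$item_avg), "entropy_R",
                                "rmse_HDRS", "rmse_YMRS"),
                     value = c(unname(report$item_avg), report$entropy_R,
                               unname(report$total_rmse)))
  utils::write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(drift))
    utils::write.table(as.data.frame(drift), file.path(dir, "drift.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(network))
    utils::write.table(network$edges, file.path(dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
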