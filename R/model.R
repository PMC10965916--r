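#' The classifier-critic network
#'
#' The model maps a tau-second multichannel segment to 28 probability
#' distributions, one per HDRS/YMRS item, through three modules: a channel
#' encoder (EN) projecting every sensory modality onto a common `(L, d)`
#' shape regardless of native sampling rate, a representation module (RM)
#' pooling the encoded blocks into a shared feature vector `h`, and 28
#' parallel item predictors (IP), one softmax head per item. A patient
#' critic (CR) is trained to recognise the recording subject from `h` and
#' competes in an adversarial game (gradient reversal with weight lambda)
#' against EN and RM, pushing the representation towards subject
#' invariance. Everything — forward pass, analytic gradients for the
#' cross-entropy, focal and quadratic-weighted-kappa losses, and the Adam
#' optimizer — is implemented in plain matrix code so the package runs on
#' one CPU with no deep-learning runtime.
#'
#' @name model
NULL

#' Model configuration
#'
#' @param tau segment length in wall-time seconds (16 by default, the
#'   best-performing window length).
#' @param L number of encoded time frames per segment (common to all
#'   modalities).
#' @param d encoder width per modality (each modality becomes an `L x d`
#'   block).
#' @param D size of the shared representation `h`.
#' @param lambda critic penalty weight (0.07 by default; 0 disables the
#'   adversarial game).
#' @param loss_type per-item loss: `"qwk"` (quadratic weighted kappa,
#'   batch-level), `"cce"` or `"focal"`.
#' @param focal_gamma focusing exponent of the focal loss.
#' @param imbalance imbalance strategy: `"none"`, `"focal"`
#'   (inverse-frequency alpha weights + focal loss), `"threshold"`
#'   (inference-time probability thresholding), `"resample-ros"` or
#'   `"resample-rus"` (severity-bin resampling with loss re-weighting).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch minibatch size (the kappa loss is a batch-level quantity;
#'   128 keeps its chance-agreement term stable).
#' @param critic_hidden hidden width of the critic MLP.
#' @param critic_steps critic-only update steps per minibatch (a
#'   better-trained critic gives the reversal a sharper signal).
#' @param drop_channel optional modality to leave out
#'   (`"ACC"`, `"BVP"`, `"EDA"`, `"HR"`, `"TEMP"`) for ablations.
#' @param eps_threshold epsilon added to rank frequencies when
#'   thresholding.
#' @param eps_log clamp for logs and the kappa-loss denominator guard.
#' @param seed integer seed fixing initialization and batch order.
#' @return A list of class `model_config`.
#' @export
model_config <- function(tau = 16, L = 8, d = 8, D = 32,
                         lambda = 0.07,
                         loss_type = c("qwk", "cce", "focal"),
                         focal_gamma = 2,
                         imbalance = c("none", "focal", "threshold",
                                       "resample-ros", "resample-rus"),
                         lr = 0.01, epochs = 10, batch = 128,
                         critic_hidden = 32, critic_steps = 3,
                         drop_channel = NULL,
                         eps_threshold = 1e-8, eps_log = 1e-10,
                         seed = 1L) {
  loss_type <- match.arg(loss_type)
  imbalance <- match.arg(imbalance)
  stopifnot(lambda >= 0, focal_gamma >= 0, tau >= L, tau %% L == 0)
  if (!is.null(drop_channel))
    drop_channel <- match.arg(drop_channel, names(e4_rates()))
  cfg <- list(tau = tau, L = L, d = d, D = D, lambda = lambda,
              loss_type = loss_type, focal_gamma = focal_gamma,
              imbalance = imbalance, lr = lr, epochs = epochs,
              batch = batch, critic_hidden = critic_hidden,
              critic_steps = critic_steps,
              drop_channel = drop_channel,
              eps_threshold = eps_threshold, eps_log = eps_log,
              seed = as.integer(seed))
  class(cfg) <- "model_config"
  cfg
}

.model_modalities <- function(cfg) {
  setdiff(names(e4_rates()), cfg$drop_channel)
}

# ---- featurization -------------------------------------------------------

# Frame one modality matrix (n x S) into (n*L) x (S/L) with row order
# (segment-major, frame-minor).
.frame_modality <- function(X, L) {
  n <- nrow(X); S <- ncol(X)
  stopifnot(S %% L == 0)
  f <- S %/% L
  tmp <- array(t(X), dim = c(f, L * n))
  t(matrix(tmp, nrow = f))
}

# Framed design matrices per modality; ACC's three axes enter as one
# modality with three features per time step.
featurize_segments <- function(segs, cfg, scaler = NULL) {
  stopifnot(inherits(segs, "segment_set"))
  if (segs$tau != cfg$tau)
    stop(sprintf("segment tau (%s) does not match model tau (%s)",
                 segs$tau, cfg$tau), call. = FALSE)
  L <- cfg$L
  feats <- list()
  for (mod in .model_modalities(cfg)) {
    if (mod == "ACC") {
      F_ <- do.call(cbind, lapply(1:3, function(ax)
        .frame_modality(segs$channels$ACC[, , ax], L)))
    } else {
      F_ <- .frame_modality(segs$channels[[mod]], L)
    }
    feats[[mod]] <- F_
  }
  if (is.null(scaler)) {
    scaler <- lapply(feats, function(F_) {
      s <- stats::sd(F_); list(m = mean(F_), s = if (s > 0) s else 1)
    })
  }
  for (mod in names(feats))
    feats[[mod]] <- (feats[[mod]] - scaler[[mod]]$m) / scaler[[mod]]$s
  list(feats = feats, scaler = scaler, n = n_segments(segs), L = L)
}

# rows of the framed matrices belonging to segments `idx`
.frame_rows <- function(idx, L) rep((idx - 1L) * L, each = L) + seq_len(L)

# ---- parameters ----------------------------------------------------------

.init_params <- function(cfg, frame_dims, n_ranks, n_subjects, seed) {
  set.seed(seed)
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  mods <- names(frame_dims)
  en <- lapply(mods, function(m)
    list(W = he(frame_dims[[m]], cfg$d), b = rep(0, cfg$d)))
  names(en) <- mods
  width <- cfg$d * length(mods)
  list(
    en = en,
    rm = list(W = he(width, cfg$D), b = rep(0, cfg$D)),
    ip = lapply(n_ranks, function(K)
      list(W = he(cfg$D, K) / 10, b = rep(0, K))),
    cr = list(W1 = he(cfg$D, cfg$critic_hidden),
              b1 = rep(0, cfg$critic_hidden),
              W2 = he(cfg$critic_hidden, n_subjects) / 10,
              b2 = rep(0, n_subjects))
  )
}

# ---- forward pass --------------------------------------------------------

# Returns h plus caches needed for the backward pass.
.forward_features <- function(params, fx, idx, cfg) {
  L <- cfg$L
  rows <- .frame_rows(idx, L)
  n <- length(idx)
  mods <- names(params$en)
  A <- list(); Zp <- list()
  for (m in mods) {
    Xm <- fx$feats[[m]][rows, , drop = FALSE]
    a <- sweep(Xm %*% params$en[[m]]$W, 2, params$en[[m]]$b, `+`)
    z <- relu(a)                                 # (n*L) x d
    # global average pool over the L frames of each segment
    pooled <- rowsum(z, rep(seq_len(n), each = L), reorder = FALSE) / L
    rownames(pooled) <- NULL
    A[[m]] <- a; Zp[[m]] <- pooled
  }
  Z <- do.call(cbind, Zp)                        # n x (d * n_mod)
  u <- sweep(Z %*% params$rm$W, 2, params$rm$b, `+`)
  h <- relu(u)
  list(h = h, u = u, Z = Z, A = A, rows = rows, idx = idx, n = n)
}

.forward_items <- function(params, h) {
  lapply(params$ip, function(p)
    softmax_rows(sweep(h %*% p$W, 2, p$b, `+`)))
}

.critic_grads <- function(params, h, ys, eps) {
  n <- nrow(h)
  crf <- .forward_critic(params, h)
  pys <- pmax(crf$probs[cbind(seq_len(n), ys)], eps)
  Dc2 <- crf$probs / n
  Dc2[cbind(seq_len(n), ys)] <- Dc2[cbind(seq_len(n), ys)] - 1 / n
  dz1 <- Dc2 %*% t(params$cr$W2) * (crf$a1 > 0)
  list(loss = mean(-log(pys)),
       grads = list(W1 = crossprod(h, dz1), b1 = colSums(dz1),
                    W2 = crossprod(crf$z1, Dc2), b2 = colSums(Dc2)),
       dh = dz1 %*% t(params$cr$W1))
}

.forward_critic <- function(params, h) {
  a1 <- sweep(h %*% params$cr$W1, 2, params$cr$b1, `+`)
  z1 <- relu(a1)
  probs <- softmax_rows(sweep(z1 %*% params$cr$W2, 2, params$cr$b2, `+`))
  list(probs = probs, a1 = a1, z1 = z1)
}

# ---- losses (value + gradient w.r.t. logits) ----------------------------

.grad_from_gprobs <- function(P, G) P * (G - rowSums(G * P))

.loss_cce <- function(P, y, w, alpha = NULL, eps = 1e-10) {
  n <- nrow(P); K <- ncol(P)
  a <- if (is.null(alpha)) rep(1, K) else alpha
  py <- pmax(P[cbind(seq_len(n), y + 1L)], eps)
  coef <- w * a[y + 1L]
  W <- sum(coef)
  loss <- sum(-coef * log(py)) / W
  G <- -P * (coef / W)
  G[cbind(seq_len(n), y + 1L)] <- G[cbind(seq_len(n), y + 1L)] + coef / W
  list(loss = loss, dlogits = -G)
}

.loss_focal <- function(P, y, w, alpha, gamma, eps = 1e-10) {
  n <- nrow(P)
  py <- pmax(P[cbind(seq_len(n), y + 1L)], eps)
  a <- alpha[y + 1L] * w
  W <- sum(w)
  loss <- sum(a * (1 - py)^gamma * (-log(py))) / W
  # d/dp[-(1-p)^g log p] = g(1-p)^(g-1) log p - (1-p)^g / p
  gy <- a * (gamma * (1 - py)^pmax(gamma - 1, 0) * log(py) -
               (1 - py)^gamma / py) / W
  # dL/da_k = gy * p_y * (1{k==y} - p_k)
  gyp <- gy * py
  D <- -P * gyp
  D[cbind(seq_len(n), y + 1L)] <- D[cbind(seq_len(n), y + 1L)] + gyp
  list(loss = loss, dlogits = D)
}

.qwk_weight_matrix <- function(K) {
  j <- 0:(K - 1)
  outer(j, j, function(a, b) (a - b)^2) / max(1, (K - 1)^2)
}

.loss_qwk <- function(P, y, w, eps = 1e-10) {
  n <- nrow(P); K <- ncol(P)
  W <- .qwk_weight_matrix(K)
  u <- w; N <- sum(u)
  Wy <- W[y + 1L, , drop = FALSE]              # n x K
  O <- sum(u * rowSums(Wy * P))
  hj <- as.numeric(tapply(u, factor(y, levels = 0:(K - 1)), sum))
  hj[is.na(hj)] <- 0
  ck <- as.numeric(t(W) %*% hj)                # length K
  Sk <- as.numeric(t(P) %*% u)
  E <- sum(ck * Sk) / N
  loss <- O / (E + eps)
  G <- (u * Wy - (loss / N) * outer(u, ck)) / (E + eps)
  list(loss = loss, dlogits = .grad_from_gprobs(P, G))
}

#' Quadratic-weighted-kappa loss of a batch of item predictions
#'
#' A differentiable batch-level surrogate of `1 - quadratic Cohen's
#' kappa`: with weights `w_jk = (j-k)^2/(K-1)^2`, the observed
#' disagreement `O` is the probability-weighted penalty of the batch and
#' the chance disagreement `E` pairs the true-rank marginal with the mean
#' predicted distribution. Equals `1 - kappa_quadratic` exactly when the
#' probabilities are one-hot.
#'
#' @param probs `n x K` matrix of per-rank probabilities.
#' @param true_ranks 0-based unit-step rank indices, length `n`.
#' @param weights optional per-sample loss weights.
#' @param eps numerical guard added to the denominator.
#' @return A scalar loss (0 = perfect agreement).
#' @export
qwk_loss <- function(probs, true_ranks, weights = NULL, eps = 1e-10) {
  probs <- as.matrix(probs)
  if (is.null(weights)) weights <- rep(1, nrow(probs))
  stopifnot(ncol(probs) >= 2, length(true_ranks) == nrow(probs))
  .loss_qwk(probs, as.integer(true_ranks), weights, eps)$loss
}

#' Focal loss
#'
#' `-alpha_y (1 - p_y)^gamma log p_y`, averaged over the batch: a
#' cross-entropy whose per-rank alpha weights correct for rank frequency
#' while the `(1 - p_y)^gamma` factor focuses training on confidently
#' wrong predictions. With `gamma = 0` and uniform alpha it reduces to the
#' categorical cross-entropy.
#'
#' @param probs `n x K` matrix (or length-K vector) of probabilities.
#' @param true_ranks 0-based rank indices.
#' @param alpha per-rank weights (length K); default uniform.
#' @param gamma focusing exponent, `>= 0`.
#' @return Mean focal loss over the batch.
#' @export
focal_loss <- function(probs, true_ranks, alpha = NULL, gamma = 2) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  K <- ncol(probs)
  if (is.null(alpha)) alpha <- rep(1, K)
  stopifnot(gamma >= 0, length(alpha) == K)
  .loss_focal(probs, as.integer(true_ranks), rep(1, nrow(probs)),
              alpha, gamma)$loss
}

#' Inverse-frequency alpha weights from training rank frequencies
#' @param freqs per-rank training frequencies (length K, summing to 1).
#' @param eps guard against empty ranks.
#' @return Weights proportional to `1/(freq + eps)`, normalized to mean 1.
#' @export
alpha_weights <- function(freqs, eps = 1e-8) {
  a <- 1 / (freqs + eps)
  a / mean(a)
}

#' Probability thresholding for imbalanced inference
#'
#' Divides each rank's predicted probability by that rank's training-set
#' frequency (plus `eps` to cover empty ranks) and renormalizes, boosting
#' under-represented ranks at inference time.
#'
#' @param probs probability vector or `n x K` matrix.
#' @param freqs training rank frequencies (length K).
#' @param eps small positive constant.
#' @return Adjusted probabilities on the simplex.
#' @export
probability_threshold <- function(probs, freqs, eps = 1e-8) {
  stopifnot(eps >= 0)
  if (is.vector(probs)) {
    q <- probs / (freqs + eps)
    return(q / sum(q))
  }
  q <- sweep(probs, 2, freqs + eps, `/`)
  q / rowSums(q)
}

# ---- Adam ----------------------------------------------------------------

.adam_new <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = c("matrix", "numeric"))
}

# update one leaf; returns list(p, st)
.adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, e = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g * g
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + e), st = st)
}

# ---- training ------------------------------------------------------------

#' Train the classifier-critic model
#'
#' Single-pass adversarial optimization: on every minibatch the critic
#' parameters descend their subject cross-entropy while the encoder and
#' representation module receive the task gradient minus `lambda` times
#' the critic gradient (gradient reversal), so the shared representation
#' is pushed to score symptoms well while confusing the subject critic.
#' Item losses are summed unweighted over the 28 items; resampling weights
#' (when the imbalance strategy is `resample-*`) multiply each segment's
#' loss contribution.
#'
#' @param segs a labelled `segment_set` covering all splits.
#' @param split a `dataset_split` from [make_splits()].
#' @param cfg a [model_config()].
#' @param schemas output of [build_schemas()].
#' @param verbose print per-epoch progress.
#' @return A `wearmood_model`: parameters, config, scaler, subject
#'   inventory, training rank frequencies and per-epoch `curves`
#'   (task loss, critic loss, validation item-average QCK).
#' @export
train_model <- function(segs, split, cfg = model_config(),
                        schemas = build_schemas(), verbose = FALSE) {
  items <- combined_items(schemas)
  y_all <- unit_step_labels(segs$labels, schemas)
  fx <- featurize_segments(segs, cfg)
  frame_dims <- lapply(fx$feats, ncol)

  if (cfg$imbalance %in% c("resample-ros", "resample-rus")) {
    rs <- resample_training(
      split, if (cfg$imbalance == "resample-ros") "ROS" else "RUS",
      seed = derive_seed(cfg$seed, "resample"))
    tr_idx <- rs$idx; tr_w <- rs$weights
  } else {
    tr_idx <- split$train; tr_w <- rep(1, length(tr_idx))
  }
  subjects <- sort(unique(segs$manifest$subject_id[tr_idx]))
  subj_of <- match(segs$manifest$subject_id, subjects)
  if (anyNA(subj_of[tr_idx]))
    stop("training segment with unknown subject", call. = FALSE)

  alphas <- lapply(seq_len(nrow(items)), function(j) {
    if (cfg$imbalance == "focal") alpha_weights(split$rank_freqs[[j]])
    else rep(1, items$n_ranks[j])
  })

  params <- .init_params(cfg, frame_dims, items$n_ranks,
                         length(subjects),
                         derive_seed(cfg$seed, "init"))
  opt <- .adam_new(params)
  t_step <- 0L
  n_items <- nrow(items)
  curves <- data.frame(epoch = integer(0), task_loss = numeric(0),
                       critic_loss = numeric(0), val_qck = numeric(0))
  set.seed(derive_seed(cfg$seed, "batches"))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(tr_idx))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch))
    ep_task <- 0; ep_cr <- 0; nb <- 0
    for (bt in batches) {
      idx <- tr_idx[bt]; w <- tr_w[bt]
      fw <- .forward_features(params, fx, idx, cfg)
      n <- fw$n
      dh_task <- matrix(0, n, cfg$D)
      grads_ip <- vector("list", n_items)
      task_loss <- 0
      for (j in seq_len(n_items)) {
        pj <- params$ip[[j]]
        P <- softmax_rows(sweep(fw$h %*% pj$W, 2, pj$b, `+`))
        yj <- y_all[idx, j]
        lg <- switch(cfg$loss_type,
          qwk = .loss_qwk(P, yj, w, cfg$eps_log),
          cce = .loss_cce(P, yj, w, alphas[[j]], cfg$eps_log),
          focal = .loss_focal(P, yj, w, alphas[[j]], cfg$focal_gamma,
                              cfg$eps_log))
        # multi-task objective = mean of the item losses, so the critic
        # penalty lambda is weighed against one item-scale loss
        task_loss <- task_loss + lg$loss / n_items
        dl <- lg$dlogits / n_items
        grads_ip[[j]] <- list(W = crossprod(fw$h, dl), b = colSums(dl))
        dh_task <- dh_task + dl %*% t(pj$W)
      }
      # critic on the same batch
      ys <- subj_of[idx]
      cg <- .critic_grads(params, fw$h, ys, cfg$eps_log)
      cr_loss <- cg$loss; g_cr <- cg$grads; dh_cr <- cg$dh

      if (!is.finite(task_loss) || !is.finite(cr_loss))
        stop(sprintf(
          "training diverged at epoch %d (task=%.3g, critic=%.3g)",
          epoch, task_loss, cr_loss), call. = FALSE)

      # gradient reversal: feature extractor ascends the critic loss
      dh <- dh_task - cfg$lambda * dh_cr
      du <- dh * (fw$u > 0)
      g_rm <- list(W = crossprod(fw$Z, du), b = colSums(du))
      dZ <- du %*% t(params$rm$W)
      mods <- names(params$en)
      g_en <- list()
      for (mi in seq_along(mods)) {
        m <- mods[mi]
        dpool <- dZ[, (mi - 1L) * cfg$d + seq_len(cfg$d), drop = FALSE]
        dA <- (dpool[rep(seq_len(n), each = cfg$L), , drop = FALSE] /
                 cfg$L) * (fw$A[[m]] > 0)
        Xm <- fx$feats[[m]][fw$rows, , drop = FALSE]
        g_en[[m]] <- list(W = crossprod(Xm, dA), b = colSums(dA))
      }

      t_step <- t_step + 1L
      upd <- function(path, grad) {
        p <- params[[path]]; s <- opt[[path]]
        for (nm in names(grad)) {
          r <- .adam_step(p[[nm]], grad[[nm]], s[[nm]], cfg$lr, t_step)
          p[[nm]] <- r$p; s[[nm]] <- r$st
        }
        params[[path]] <<- p; opt[[path]] <<- s
      }
      for (m in mods) {
        r1 <- .adam_step(params$en[[m]]$W, g_en[[m]]$W, opt$en[[m]]$W,
                         cfg$lr, t_step)
        r2 <- .adam_step(params$en[[m]]$b, g_en[[m]]$b, opt$en[[m]]$b,
                         cfg$lr, t_step)
        params$en[[m]]$W <- r1$p; opt$en[[m]]$W <- r1$st
        params$en[[m]]$b <- r2$p; opt$en[[m]]$b <- r2$st
      }
      upd("rm", g_rm)
      for (j in seq_len(n_items)) {
        r1 <- .adam_step(params$ip[[j]]$W, grads_ip[[j]]$W,
                         opt$ip[[j]]$W, cfg$lr, t_step)
        r2 <- .adam_step(params$ip[[j]]$b, grads_ip[[j]]$b,
                         opt$ip[[j]]$b, cfg$lr, t_step)
        params$ip[[j]]$W <- r1$p; opt$ip[[j]]$W <- r1$st
        params$ip[[j]]$b <- r2$p; opt$ip[[j]]$b <- r2$st
      }
      upd("cr", g_cr)
      # additional critic-only steps on the same representations
      if (cfg$critic_steps > 1) {
        for (cs in seq_len(cfg$critic_steps - 1L)) {
          cg <- .critic_grads(params, fw$h, ys, cfg$eps_log)
          upd("cr", cg$grads)
        }
      }
      ep_task <- ep_task + task_loss; ep_cr <- ep_cr + cr_loss
      nb <- nb + 1
    }
    model_now <- structure(
      list(params = params, cfg = cfg, scaler = fx$scaler,
           subjects = subjects, rank_freqs = split$rank_freqs,
           items = items, schemas = schemas),
      class = "wearmood_model")
    vq <- NA_real_
    if (length(split$val)) {
      pv <- .predict_on_features(model_now, fx, split$val)
      vq <- mean(vapply(seq_len(n_items), function(j)
        qck(y_all[split$val, j], pv$ranks[, j], items$n_ranks[j]), 0))
    }
    curves <- rbind(curves, data.frame(
      epoch = epoch, task_loss = ep_task / nb, critic_loss = ep_cr / nb,
      val_qck = vq))
    if (verbose)
      message(sprintf("epoch %d: task %.4f critic %.4f val QCK %.3f",
                      epoch, ep_task / nb, ep_cr / nb, vq))
  }
  model <- structure(
    list(params = params, cfg = cfg, scaler = fx$scaler,
         subjects = subjects, rank_freqs = split$rank_freqs,
         items = items, schemas = schemas, curves = curves),
    class = "wearmood_model")
  model
}

#' @export
print.wearmood_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<wearmood_model> tau=%ds, loss=%s, lambda=%.3g, imbalance=%s, ",
    "%d items, %d training subjects\n"),
    x$cfg$tau, x$cfg$loss_type, x$cfg$lambda, x$cfg$imbalance,
    nrow(x$items), length(x$subjects)))
  invisible(x)
}

.predict_on_features <- function(model, fx, idx,
                                 threshold = FALSE) {
  fw <- .forward_features(model$params, fx, idx, model$cfg)
  probs <- .forward_items(model$params, fw$h)
  names(probs) <- model$items$id
  if (threshold) {
    for (j in seq_along(probs))
      probs[[j]] <- probability_threshold(
        probs[[j]], model$rank_freqs[[j]], model$cfg$eps_threshold)
  }
  ranks <- vapply(probs, function(P) max.col(P, ties.method = "first") - 1L,
                  integer(fw$n))
  if (fw$n == 1L) ranks <- matrix(ranks, nrow = 1,
                                  dimnames = list(NULL, model$items$id))
  list(probs = probs, ranks = ranks, h = fw$h)
}

#' Predict item scores for a segment set
#'
#' @param model a trained `wearmood_model`.
#' @param segs a `segment_set` with the model's tau.
#' @param threshold apply probability thresholding with the stored
#'   training rank frequencies.
#' @return A list with `probs` (per-item probability matrices), `ranks`
#'   (`n x 28` matrix of 0-based unit-step predictions), `printed`
#'   (predictions on the printed rank-value scale) and `h` (the shared
#'   representations).
#' @export
predict_model <- function(model, segs, threshold = FALSE) {
  stopifnot(inherits(model, "wearmood_model"))
  fx <- featurize_segments(segs, model$cfg, scaler = model$scaler)
  out <- .predict_on_features(model, fx, seq_len(n_segments(segs)),
                              threshold = threshold)
  step <- model$items$rank_step
  out$printed <- sweep(out$ranks, 2, step, `*`)
  out
}

#' Encode a segment set into per-modality blocks
#'
#' The channel encoder maps every modality onto a common `L x d` block;
#' the blocks are returned per modality (`n x L x d` arrays) together with
#' their feature-axis concatenation.
#'
#' @param model a trained `wearmood_model` (or one fresh from
#'   initialization).
#' @param segs a `segment_set`.
#' @return List with `blocks` (per modality) and `concat`
#'   (`n x L x (d * n_modalities)`).
#' @export
encode <- function(model, segs) {
  cfg <- model$cfg
  fx <- featurize_segments(segs, cfg, scaler = model$scaler)
  fw <- .forward_features(model$params, fx, seq_len(n_segments(segs)), cfg)
  n <- fw$n; L <- cfg$L; d <- cfg$d
  blocks <- lapply(fw$A, function(a) {
    z <- relu(a)
    arr <- array(0, dim = c(n, L, d))
    for (l in seq_len(L)) arr[, l, ] <- z[seq(l, n * L, by = L), ]
    arr
  })
  concat <- array(0, dim = c(n, L, d * length(blocks)))
  for (mi in seq_along(blocks))
    concat[, , (mi - 1) * d + seq_len(d)] <- blocks[[mi]]
  list(blocks = blocks, concat = concat)
}

#' Shared representation h of a segment set
#'
#' @inheritParams encode
#' @return An `n x D` matrix of representations.
#' @export
represent <- function(model, segs) {
  fx <- featurize_segments(segs, model$cfg, scaler = model$scaler)
  .forward_features(model$params, fx,
                    seq_len(n_segments(segs)), model$cfg)$h
}

#' Item-predictor heads applied to representations
#'
#' @param model a `wearmood_model`.
#' @param h `n x D` matrix of representations (from [represent()]).
#' @return Named list of 28 probability matrices, one per item, each row
#'   on the simplex.
#' @export
predict_items <- function(model, h) {
  out <- .forward_items(model$params, h)
  names(out) <- model$items$id
  out
}

#' Critic probabilities over the training subjects
#'
#' @inheritParams predict_items
#' @return `n x n_subjects` matrix of softmax probabilities (columns named
#'   by subject).
#' @export
critic_forward <- function(model, h) {
  p <- .forward_critic(model$params, h)$probs
  colnames(p) <- model$subjects
  p
}

# ---- checkpoint I/O ------------------------------------------------------

#' Save / load a model checkpoint as self-describing JSON text
#'
#' @param model a `wearmood_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  ser <- list(
    cfg = unclass(model$cfg),
    subjects = model$subjects,
    rank_freqs = model$rank_freqs,
    scaler = model$scaler,
    params = rapply(model$params, function(x) {
      if (is.matrix(x)) list(dim = dim(x), x = as.numeric(x))
      else list(dim = NULL, x = as.numeric(x))
    }, how = "list", classes = c("matrix", "numeric")),
    curves = model$curves
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @param schemas output of [build_schemas()].
#' @export
load_model <- function(path, schemas = build_schemas()) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- ser$cfg
  cfg$drop_channel <- if (is.null(cfg$drop_channel) ||
                          !length(cfg$drop_channel)) NULL
                      else cfg$drop_channel
  cfg <- do.call(model_config, cfg)
  revive <- function(node) {
    if (is.list(node) && !is.null(node$x)) {
      if (!is.null(node$dim) && length(node$dim))
        return(matrix(node$x, node$dim[1], node$dim[2]))
      return(as.numeric(node$x))
    }
    lapply(node, revive)
  }
  structure(
    list(params = revive(ser$params), cfg = cfg,
         scaler = lapply(ser$scaler, function(s) list(m = s$m, s = s$s)),
         subjects = ser$subjects,
         rank_freqs = lapply(ser$rank_freqs, function(f) unlist(f)),
         items = combined_items(schemas), schemas = schemas,
         curves = as.data.frame(ser$curves)),
    class = "wearmood_model")
}
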