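# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

# A minimal clean session built directly from arrays (fast, no rendering):
# constant plausible values everywhere, duration in seconds.
flat_session <- function(duration = 120, session_id = "FLAT_T1",
                         subject_id = "SFLAT", eda = 2, hr = 70,
                         temp = 33.5) {
  r <- e4_rates()
  e4_session(session_id, subject_id, start_time = 1600000000,
             channels = list(
               ACC = matrix(c(0, 0, 0.95), duration * r[["ACC"]], 3,
                            byrow = TRUE),
               BVP = sin(2 * pi * (hr / 60) *
                           seq_len(duration * r[["BVP"]]) / r[["BVP"]]),
               EDA = rep(eda, duration * r[["EDA"]]),
               HR = rep(hr, duration * r[["HR"]]),
               TEMP = rep(temp, duration * r[["TEMP"]])))
}

# Render a small labelled cohort into one segment set (+ split).
render_cohort_segments <- function(cfg, tau = 16, split_seed = 5,
                                   region = NULL) {
  co <- sample_cohort(cfg)
  prof_of <- function(sid)
    co$profiles[[match(sid, vapply(co$profiles, `[[`, "", "subject_id"))]]
  sets <- list()
  for (tr in co$sessions) {
    s <- render_session(tr, prof_of(tr$subject_id), cfg)
    reg <- if (is.null(region)) c(0, session_duration(s)) else region
    sg <- segment_session(s, tau, reg)
    if (n_segments(sg) > 0) sets[[tr$session_id]] <- sg
  }
  segs <- do.call(bind_segments, sets)
  segs <- attach_labels(segs, co$labels)
  split <- make_splits(segs, seed = split_seed)
  list(cohort = co, segs = segs, split = split)
}

# Small trained model shared by model/evaluate tests.
small_fit <- function() {
  if (!is.null(.fx$fit)) return(.fx$fit)
  cfg <- synth_config(n_subjects = 6, session_rate = 1, duration_h = 0.15,
                      drift_mag = 0, seed = 101)
  dat <- render_cohort_segments(cfg)
  model <- train_model(dat$segs, dat$split,
                       model_config(epochs = 4, seed = 11))
  .fx$fit <- list(dat = dat, model = model)
  .fx$fit
}

# Independent brute-force quadratic-kappa oracle from the confusion matrix.
oracle_qck <- function(true, pred, K) {
  N <- length(true)
  O <- matrix(0, K, K)
  for (i in seq_len(N)) O[true[i] + 1, pred[i] + 1] <- O[true[i] + 1, pred[i] + 1] + 1
  W <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K) W[a, b] <- (a - b)^2
  E <- outer(rowSums(O), colSums(O)) / N
  num <- 0; den <- 0
  for (a in 1:K) for (b in 1:K) {
    num <- num + W[a, b] * O[a, b]
    den <- den + W[a, b] * E[a, b]
  }
  1 - num / den
}

# Independent per-class F1 oracle (loops, no vectorized reuse).
oracle_macro_f1 <- function(true, pred) {
  classes <- sort(unique(c(true, pred)))
  f1s <- numeric(0)
  for (k in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (pred[i] == k && true[i] == k) tp <- tp + 1
      if (pred[i] == k && true[i] != k) fp <- fp + 1
      if (pred[i] != k && true[i] == k) fn <- fn + 1
    }
    f1s <- c(f1s, if (2 * tp + fp + fn == 0) NA else 2 * tp / (2 * tp + fp + fn))
  }
  mean(f1s)
}
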