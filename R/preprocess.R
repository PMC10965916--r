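#' Quality control, segmentation and dataset assembly
#'
#' Raw sessions are quality-controlled with published plausibility rules
#' for wrist-worn EDA/TEMP plus a heart-rate range rule, segmented into
#' non-overlapping tau-second windows, partitioned into close-to-interview
#' (first five hours) and far-from-interview (subsequent 30-minute
#' intervals) regions, and assembled into train/validation/test splits.
#'
#' @name preprocess
NULL

#' Default quality-control rules
#'
#' The EDA/TEMP rules follow the published wearable-EDA quality pipeline
#' (values and slopes outside plausibility, with a 5-second dilation
#' around violations); the heart-rate range rule is an addition for the
#' E4's HR stream. All constants are configurable.
#'
#' @param eda_range plausible EDA interval in microsiemens.
#' @param eda_slope_max maximum plausible |dEDA/dt| in uS/s.
#' @param temp_range plausible skin-temperature interval in Celsius.
#' @param hr_range plausible heart-rate interval in bpm.
#' @param dilation_s seconds of data invalidated around any EDA/TEMP rule
#'   violation.
#' @export
qc_rules <- function(eda_range = c(0.05, 60), eda_slope_max = 10,
                     temp_range = c(30, 40), hr_range = c(25, 250),
                     dilation_s = 5) {
  list(eda_range = eda_range, eda_slope_max = eda_slope_max,
       temp_range = temp_range, hr_range = hr_range,
       dilation_s = dilation_s)
}

# sample indices -> 0-based wall-time seconds at a given rate
.samples_to_seconds <- function(idx, rate) unique((idx - 1L) %/% rate)

#' Quality-control a session
#'
#' Marks invalid: EDA outside the plausible range, EDA slope magnitude
#' above threshold, TEMP outside the plausible range, any sample within
#' `dilation_s` seconds of an EDA/TEMP violation, and HR outside the
#' plausible range. An invalid wall-time second in any channel invalidates
#' that second in every channel (cross-channel alignment is done at 1-s
#' resolution, the coarsest native rate).
#'
#' @param session an [e4_session()].
#' @param rules a [qc_rules()] list.
#' @return A list with `session` (validity masks attached) and
#'   `discard_fraction`, the fraction of wall-time invalidated.
#' @export
quality_control <- function(session, rules = qc_rules()) {
  stopifnot(inherits(session, "e4_session"))
  extra <- setdiff(names(rules), names(qc_rules()))
  if (length(extra))
    stop("unknown quality-control rule(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  ch <- session$channels
  r <- session$rates
  dur <- as.integer(floor(session_duration(session)))

  eda <- ch$EDA
  bad_eda <- eda < rules$eda_range[1] | eda > rules$eda_range[2]
  slope <- abs(diff(eda)) * r[["EDA"]]
  bad_slope_idx <- which(slope > rules$eda_slope_max)
  bad_eda[bad_slope_idx] <- TRUE
  bad_eda[bad_slope_idx + 1L] <- TRUE
  bad_temp <- ch$TEMP < rules$temp_range[1] | ch$TEMP > rules$temp_range[2]
  bad_hr <- ch$HR < rules$hr_range[1] | ch$HR > rules$hr_range[2]

  sec_dil <- c(.samples_to_seconds(which(bad_eda), r[["EDA"]]),
               .samples_to_seconds(which(bad_temp), r[["TEMP"]]))
  if (length(sec_dil)) {
    d <- rules$dilation_s
    sec_dil <- unique(unlist(lapply(sec_dil, function(s)
      max(0L, s - d):min(dur - 1L, s + d))))
  }
  bad_sec <- sort(unique(c(sec_dil,
                           .samples_to_seconds(which(bad_hr), r[["HR"]]))))
  valid <- lapply(names(ch), function(name) {
    n <- if (name == "ACC") nrow(ch$ACC) else length(ch[[name]])
    v <- rep(TRUE, n)
    if (length(bad_sec)) {
      rate <- r[[name]]
      idx <- as.integer(outer(seq_len(rate), bad_sec * rate, `+`))
      v[idx[idx <= n]] <- FALSE
    }
    v
  })
  names(valid) <- names(ch)
  session$valid <- valid
  list(session = session, discard_fraction = length(bad_sec) / dur)
}

# 0-based invalid wall-time seconds of a QC'd session (integer vector)
.invalid_seconds <- function(session) {
  if (is.null(session$valid)) return(integer(0))
  .samples_to_seconds(which(!session$valid$HR), session$rates[["HR"]])
}

#' Close-/far-from-interview partition of a session
#'
#' @param session an [e4_session()], or directly a session duration in
#'   seconds.
#' @param close_h length of the close-to-interview region in hours.
#' @param far_interval_s length of each far interval in seconds.
#' @return A list with `close = c(start, end)` in wall-time seconds from
#'   the interview, and `far`, a list of `c(start, end)` 30-minute
#'   intervals tiling the remainder (a partial trailing interval is
#'   discarded).
#' @export
close_far_partition <- function(session, close_h = 5,
                                far_interval_s = 1800) {
  dur <- if (is.numeric(session)) session else session_duration(session)
  close_end <- min(close_h * 3600, dur)
  far <- list()
  s <- close_h * 3600
  while (s + far_interval_s <= dur + 1e-9) {
    far[[length(far) + 1L]] <- c(s, s + far_interval_s)
    s <- s + far_interval_s
  }
  list(close = c(0, close_end), far = far)
}

#' Segment a region of a session into non-overlapping tau-second windows
#'
#' Consecutive half-open windows `[t, t + tau)` tile the region; windows
#' containing any invalid wall-time instant (after [quality_control()])
#' are dropped whole, preserving the strict non-overlap tiling. All
#' retained segments inherit the session's 28 item scores.
#'
#' @param session an [e4_session()] (quality-controlled or not).
#' @param tau window length in wall-time seconds.
#' @param region `c(start, end)` in seconds from session start.
#' @return A `segment_set`: a list with `manifest` (session_id,
#'   subject_id, window_index, offset) and `channels`, per-channel sample
#'   blocks stacked as matrices (ACC as an `n x 32*tau x 3` array).
#' @export
segment_session <- function(session, tau, region = NULL) {
  stopifnot(tau > 0)
  if (is.null(region)) region <- c(0, session_duration(session))
  a <- region[1]; b <- region[2]
  n_win <- max(0L, floor((b - a) / tau))
  if (n_win == 0L) return(empty_segment_set(tau))
  starts <- a + (seq_len(n_win) - 1L) * tau
  bad <- .invalid_seconds(session)
  keep <- rep(TRUE, n_win)
  if (length(bad)) {
    # window k covers seconds [starts_k, starts_k + tau)
    for (k in seq_len(n_win)) {
      if (any(bad >= starts[k] & bad < starts[k] + tau)) keep[k] <- FALSE
    }
  }
  starts <- starts[keep]
  widx <- which(keep)
  n <- length(starts)
  if (n == 0L) return(empty_segment_set(tau))
  r <- session$rates
  block <- function(x, rate) {
    idx <- outer(seq_len(tau * rate), starts * rate, `+`)  # col per window
    matrix(x[as.integer(idx)], nrow = n, ncol = tau * rate, byrow = TRUE)
  }
  acc <- array(0, dim = c(n, tau * r[["ACC"]], 3))
  for (ax in 1:3) acc[, , ax] <- block(session$channels$ACC[, ax], r[["ACC"]])
  segs <- list(
    manifest = data.frame(
      session_id = session$session_id, subject_id = session$subject_id,
      window_index = widx, offset = starts, stringsAsFactors = FALSE),
    channels = list(ACC = acc,
                    BVP = block(session$channels$BVP, r[["BVP"]]),
                    EDA = block(session$channels$EDA, r[["EDA"]]),
                    HR = block(session$channels$HR, r[["HR"]]),
                    TEMP = block(session$channels$TEMP, r[["TEMP"]])),
    tau = tau
  )
  class(segs) <- "segment_set"
  segs
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments, tau = %d s, %d session(s)\n",
              n_segments(x), x$tau,
              length(unique(x$manifest$session_id))))
  invisible(x)
}

#' Number of segments in a segment set
#' @param segs a `segment_set`.
#' @export
n_segments <- function(segs) nrow(segs$manifest)

#' An empty segment set
#' @param tau window length (s).
#' @export
empty_segment_set <- function(tau) {
  structure(list(
    manifest = data.frame(session_id = character(0),
                          subject_id = character(0),
                          window_index = integer(0), offset = numeric(0),
                          stringsAsFactors = FALSE),
    channels = NULL, tau = tau), class = "segment_set")
}

#' Concatenate segment sets (same tau)
#' @param ... `segment_set` objects.
#' @export
bind_segments <- function(...) {
  sets <- Filter(function(s) n_segments(s) > 0, list(...))
  if (!length(sets)) return(empty_segment_set(NA))
  tau <- sets[[1]]$tau
  stopifnot(all(vapply(sets, function(s) s$tau == tau, TRUE)))
  out <- sets[[1]]
  out$manifest <- do.call(rbind, lapply(sets, `[[`, "manifest"))
  out$channels <- list(
    ACC = do.call(function(...) {
      arrs <- list(...)
      n <- sum(vapply(arrs, function(a) dim(a)[1], 1))
      r <- array(0, dim = c(n, dim(arrs[[1]])[2], 3))
      at <- 0L
      for (a in arrs) { r[at + seq_len(dim(a)[1]), , ] <- a; at <- at + dim(a)[1] }
      r
    }, lapply(sets, function(s) s$channels$ACC)),
    BVP = do.call(rbind, lapply(sets, function(s) s$channels$BVP)),
    EDA = do.call(rbind, lapply(sets, function(s) s$channels$EDA)),
    HR = do.call(rbind, lapply(sets, function(s) s$channels$HR)),
    TEMP = do.call(rbind, lapply(sets, function(s) s$channels$TEMP)))
  if (!is.null(out$labels))
    out$labels <- do.call(rbind, lapply(sets, `[[`, "labels"))
  out
}

#' Subset a segment set by row indices
#' @param segs a `segment_set`; `idx` integer indices.
#' @export
subset_segments <- function(segs, idx) {
  out <- segs
  out$manifest <- segs$manifest[idx, , drop = FALSE]
  out$channels <- list(ACC = segs$channels$ACC[idx, , , drop = FALSE],
                       BVP = segs$channels$BVP[idx, , drop = FALSE],
                       EDA = segs$channels$EDA[idx, , drop = FALSE],
                       HR = segs$channels$HR[idx, , drop = FALSE],
                       TEMP = segs$channels$TEMP[idx, , drop = FALSE])
  if (!is.null(segs$labels))
    out$labels <- segs$labels[idx, , drop = FALSE]
  out
}

#' Attach per-segment item labels from a session-label table
#'
#' Every segment inherits its recording session's 28 printed item scores.
#'
#' @param segs a `segment_set`.
#' @param labels label table (see [read_labels()]).
#' @param schemas output of [build_schemas()].
#' @return The segment set with a `labels` matrix (printed values).
#' @export
attach_labels <- function(segs, labels, schemas = build_schemas()) {
  lm <- label_matrix(labels, schemas)
  pos <- match(segs$manifest$session_id, rownames(lm))
  if (anyNA(pos))
    stop("segments reference sessions missing from the label table",
         call. = FALSE)
  segs$labels <- lm[pos, , drop = FALSE]
  rownames(segs$labels) <- NULL
  segs
}

#' Severity label used for resampling
#'
#' The HDRS and YMRS totals are binned with each scale's severity table
#' and the pair is collapsed to its more severe non-remission component
#' (ties resolved towards HDRS); sessions in remission on both scales are
#' labelled `"remission"`.
#'
#' @param label_row named vector/1-row matrix of the 28 printed scores.
#' @param schemas output of [build_schemas()].
#' @return A single character label, e.g. `"HDRS:severe"`.
#' @export
derive_resample_label <- function(label_row, schemas = build_schemas()) {
  v <- unlist(label_row)
  h_tot <- total_score(v[schemas$HDRS$items$id], schemas$HDRS)
  y_tot <- total_score(v[schemas$YMRS$items$id], schemas$YMRS)
  h_bin <- severity_bin(h_tot, schemas$HDRS)
  y_bin <- severity_bin(y_tot, schemas$YMRS)
  h_idx <- match(h_bin, schemas$HDRS$severity_bins$label)
  y_idx <- match(y_bin, schemas$YMRS$severity_bins$label)
  if (h_idx == 1L && y_idx == 1L) return("remission")
  if (y_idx > h_idx) paste0("YMRS:", y_bin) else paste0("HDRS:", h_bin)
}

#' Random train/validation/test split, stratified by recording session
#'
#' Within every session, segments are allocated at the requested ratios so
#' each split sees every session (the critic requires training subjects to
#' recur). Per-item training rank frequencies are recorded for later use
#' by probability thresholding and the focal loss.
#'
#' @param segs a labelled `segment_set` (see [attach_labels()]).
#' @param ratios train/validation/test proportions (sum to 1).
#' @param seed integer seed.
#' @param by stratification unit: `"session"` (default) keeps every
#'   session represented in all splits; `"subject"` holds whole subjects
#'   out of validation/test.
#' @param schemas output of [build_schemas()].
#' @return A `dataset_split`: integer index vectors `train`, `val`,
#'   `test`; `rank_freqs`, a per-item list of training rank frequencies on
#'   the unit-step index scale; `bin_label`, the per-segment severity
#'   label.
#' @export
make_splits <- function(segs, ratios = c(0.70, 0.15, 0.15), seed = 1L,
                        by = c("session", "subject"),
                        schemas = build_schemas()) {
  by <- match.arg(by)
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3)
  n <- n_segments(segs)
  if (n < 3) stop("need at least 3 segments to split", call. = FALSE)
  if (is.null(segs$labels)) stop("attach labels before splitting",
                                 call. = FALSE)
  set.seed(seed)
  train <- val <- test <- integer(0)
  if (by == "session") {
    for (sid in unique(segs$manifest$session_id)) {
      idx <- sample(which(segs$manifest$session_id == sid))
      k <- length(idx)
      n_tr <- round(ratios[1] * k)
      n_va <- round(ratios[2] * k)
      train <- c(train, idx[seq_len(n_tr)])
      val <- c(val, idx[n_tr + seq_len(min(n_va, k - n_tr))])
      test <- c(test, idx[setdiff(seq_len(k), seq_len(n_tr + n_va))])
    }
  } else {
    subs <- sample(unique(segs$manifest$subject_id))
    n_tr <- max(1L, round(ratios[1] * length(subs)))
    n_va <- max(1L, round(ratios[2] * length(subs)))
    tr_s <- subs[seq_len(n_tr)]
    va_s <- subs[n_tr + seq_len(min(n_va, length(subs) - n_tr - 1L))]
    train <- which(segs$manifest$subject_id %in% tr_s)
    val <- which(segs$manifest$subject_id %in% va_s)
    test <- setdiff(seq_len(n), c(train, val))
  }
  items <- combined_items(schemas)
  y_idx <- unit_step_labels(segs$labels, schemas)
  rank_freqs <- lapply(seq_len(nrow(items)), function(j) {
    k <- items$n_ranks[j]
    tab <- tabulate(y_idx[train, j] + 1L, nbins = k)
    f <- tab / sum(tab)
    names(f) <- as.character(0:(k - 1L))
    f
  })
  names(rank_freqs) <- items$id
  bin_label <- vapply(seq_len(n), function(i)
    derive_resample_label(segs$labels[i, ], schemas), "")
  structure(list(train = sort(train), val = sort(val), test = sort(test),
                 rank_freqs = rank_freqs, bin_label = bin_label),
            class = "dataset_split")
}

#' Convert a printed-value label matrix to 0-based unit-step rank indices
#' @param labels printed-value matrix (columns in combined-item order).
#' @param schemas output of [build_schemas()].
#' @export
unit_step_labels <- function(labels, schemas = build_schemas()) {
  items <- combined_items(schemas)
  out <- labels
  for (j in seq_len(nrow(items)))
    out[, j] <- rescale_rank_step(labels[, j], items[j, ])
  storage.mode(out) <- "integer"
  out
}

#' Resample training segments by severity bin, with loss re-weighting
#'
#' Random over-sampling (ROS) duplicates segments of under-represented
#' severity bins up to the majority-bin count; random under-sampling (RUS)
#' subsamples over-represented bins down to the minority count. The loss
#' weight of each segment is the ratio `original_count / resampled_count`
#' of its bin, so every bin's expected total loss contribution is
#' unchanged.
#'
#' @param split a `dataset_split`.
#' @param strategy `"ROS"` or `"RUS"`.
#' @param seed integer seed.
#' @return A list with `idx` (resampled training indices into the segment
#'   set) and `weights` (matching per-segment loss weights).
#' @export
resample_training <- function(split, strategy = c("ROS", "RUS"),
                              seed = 1L) {
  strategy <- match.arg(strategy)
  set.seed(seed)
  bins <- split$bin_label[split$train]
  tab <- table(bins)
  target <- if (strategy == "ROS") max(tab) else min(tab)
  idx <- integer(0); w <- numeric(0)
  for (b in names(tab)) {
    members <- split$train[bins == b]
    k <- length(members)
    if (k == 0L) next
    if (target >= k) {
      res <- c(members, sample(members, target - k, replace = TRUE))
    } else {
      res <- sample(members, target)
    }
    idx <- c(idx, res)
    w <- c(w, rep(k / target, length(res)))
  }
  ord <- sample(length(idx))  # shuffle bins together
  list(idx = idx[ord], weights = w[ord])
}
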