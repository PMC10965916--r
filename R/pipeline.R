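#' End-to-end pipeline orchestration
#'
#' Runs simulate -> preprocess -> train -> evaluate -> ablate as stages
#' over on-disk artifacts, with a single configuration and deterministic
#' seeding: the master seed fans out into per-stage seeds by stable
#' hashing, and every artifact directory is stamped with the
#' configuration hash so stage mismatches are detected.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param synth a [synth_config()].
#' @param model a [model_config()].
#' @param qc a [qc_rules()] list.
#' @param ratios train/validation/test ratios.
#' @param split_by `"session"` or `"subject"` stratification.
#' @param close_h close-to-interview region length (hours).
#' @param seed master seed (fans out to stage seeds).
#' @return A list of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), model = model_config(),
                       qc = qc_rules(), ratios = c(0.70, 0.15, 0.15),
                       split_by = "session", close_h = 5, seed = 1L) {
  cfg <- list(synth = synth, model = model, qc = qc, ratios = ratios,
              split_by = split_by, close_h = close_h,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / restore a run configuration (JSON round-trip stable)
#' @param cfg a [run_config()]; `path` a file path.
#' @export
.strip_class <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_class) else x
}

write_run_config <- function(cfg, path) {
  jsonlite::write_json(.strip_class(cfg), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mc <- x$model
  mc$drop_channel <- if (!length(mc$drop_channel)) NULL else mc$drop_channel
  run_config(synth = do.call(synth_config, x$synth),
             model = do.call(model_config, mc),
             qc = x$qc, ratios = x$ratios, split_by = x$split_by,
             close_h = x$close_h, seed = x$seed)
}

#' Hash of a run configuration
#' @param cfg a [run_config()].
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(.strip_class(cfg),
                        auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("%08x", fnv1a(as.character(s)))
}

.stamp <- function(dir, stage, cfg) {
  jsonlite::write_json(list(stage = stage, config_hash = config_hash(cfg),
                            seed = cfg$seed),
                       file.path(dir, paste0(stage, ".meta.json")),
                       auto_unbox = TRUE)
}

.check_stage <- function(dir, stage, cfg) {
  f <- file.path(dir, paste0(stage, ".meta.json"))
  if (!file.exists(f))
    stop(sprintf("missing artifacts of upstream stage '%s'; run it first",
                 stage), call. = FALSE)
  meta <- jsonlite::read_json(f)
  if (!identical(meta$config_hash, config_hash(cfg)))
    stop(sprintf("stage '%s' artifacts were produced under a different %s",
                 stage, "configuration (hash mismatch)"), call. = FALSE)
  invisible(TRUE)
}

# Rebuild the close-region segment set recorded in a manifest.
.segments_from_manifest <- function(out_dir, cfg, schemas) {
  manifest <- utils::read.csv(file.path(out_dir, "manifest.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(session_id = "character"))
  cohort <- read_cohort(file.path(out_dir, "data"))
  sets <- list()
  for (sid in unique(manifest$session_id)) {
    qc <- quality_control(cohort$sessions[[sid]], cfg$qc)
    part <- close_far_partition(qc$session, close_h = cfg$close_h)
    segs <- segment_session(qc$session, cfg$model$tau, part$close)
    want <- manifest$window_index[manifest$session_id == sid]
    keep <- match(want, segs$manifest$window_index)
    if (anyNA(keep))
      stop("manifest window missing from re-segmented session ", sid,
           call. = FALSE)
    sets[[sid]] <- subset_segments(segs, keep)
  }
  segs <- do.call(bind_segments, sets)
  segs <- attach_labels(segs, cohort$labels, schemas)
  ord <- order(match(paste(segs$manifest$session_id,
                           segs$manifest$window_index),
                     paste(manifest$session_id, manifest$window_index)))
  subset_segments(segs, ord)
}

.split_from_manifest <- function(out_dir, segs, cfg, schemas) {
  manifest <- utils::read.csv(file.path(out_dir, "manifest.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(session_id = "character"))
  key <- paste(segs$manifest$session_id, segs$manifest$window_index)
  mkey <- paste(manifest$session_id, manifest$window_index)
  tag <- manifest$split[match(key, mkey)]
  items <- combined_items(schemas)
  y <- unit_step_labels(segs$labels, schemas)
  train <- which(tag == "train")
  rank_freqs <- lapply(seq_len(nrow(items)), function(j) {
    k <- items$n_ranks[j]
    tab <- tabulate(y[train, j] + 1L, nbins = k)
    f <- tab / sum(tab); names(f) <- as.character(0:(k - 1L)); f
  })
  names(rank_freqs) <- items$id
  structure(list(train = train, val = which(tag == "val"),
                 test = which(tag == "test"),
                 rank_freqs = rank_freqs,
                 bin_label = vapply(seq_len(n_segments(segs)), function(i)
                   derive_resample_label(segs$labels[i, ], schemas), "")),
            class = "dataset_split")
}

#' Run pipeline stages over on-disk artifacts
#'
#' Each stage reads the previous stage's artifacts from `out_dir`:
#' `simulate` writes the synthetic cohort (E4 dialect + labels.csv) under
#' `out_dir/data`; `preprocess` writes the QC log and the segment/split
#' manifest; `train` writes the model checkpoint and training curves;
#' `evaluate` writes the metric tables (and drift tables when
#' far-from-interview intervals exist); `ablate` writes the
#' leave-one-channel-out report.
#'
#' @param cfg a [run_config()].
#' @param stages subset of `c("simulate", "preprocess", "train",
#'   "evaluate", "ablate")`, in order.
#' @param out_dir artifact directory.
#' @param verbose log progress.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "preprocess",
                                         "train", "evaluate"),
                         out_dir, verbose = TRUE) {
  stages <- match.arg(stages, c("simulate", "preprocess", "train",
                                "evaluate", "ablate"),
                      several.ok = TRUE)
  schemas <- build_schemas()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  if ("simulate" %in% stages) {
    say("[simulate] drawing cohort (seed %d)", cfg$synth$seed)
    cohort <- sample_cohort(cfg$synth, schemas)
    rendered <- lapply(cohort$sessions, function(tr) {
      prof <- cohort$profiles[[match(tr$subject_id,
                                     vapply(cohort$profiles,
                                            `[[`, "", "subject_id"))]]
      render_session(tr, prof, cfg$synth)
    })
    write_cohort(rendered, cohort$labels, file.path(out_dir, "data"))
    .stamp(out_dir, "simulate", cfg)
    say("[simulate] wrote %d sessions", length(rendered))
  }

  if ("preprocess" %in% stages) {
    .check_stage(out_dir, "simulate", cfg)
    cohort <- read_cohort(file.path(out_dir, "data"))
    qc_log <- list(); sets <- list()
    for (sid in names(cohort$sessions)) {
      qc <- quality_control(cohort$sessions[[sid]], cfg$qc)
      qc_log[[sid]] <- data.frame(session_id = sid,
                                  discard_fraction = qc$discard_fraction)
      part <- close_far_partition(qc$session, close_h = cfg$close_h)
      segs <- segment_session(qc$session, cfg$model$tau, part$close)
      if (n_segments(segs) > 0) sets[[sid]] <- segs
    }
    segs <- do.call(bind_segments, sets)
    segs <- attach_labels(segs, cohort$labels, schemas)
    split <- make_splits(segs, cfg$ratios,
                         seed = derive_seed(cfg$seed, "split"),
                         by = cfg$split_by, schemas = schemas)
    tag <- rep("train", n_segments(segs))
    tag[split$val] <- "val"; tag[split$test] <- "test"
    manifest <- cbind(segs$manifest[, c("session_id", "window_index",
                                        "offset")],
                      region = "close", split = tag)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, qc_log),
                     file.path(out_dir, "qc_log.csv"),
                     row.names = FALSE, quote = FALSE)
    .stamp(out_dir, "preprocess", cfg)
    say("[preprocess] %d segments (train %d / val %d / test %d), %s",
        n_segments(segs), length(split$train), length(split$val),
        length(split$test),
        sprintf("median discard %.1f%%",
                100 * stats::median(vapply(qc_log, `[[`, 0,
                                           "discard_fraction"))))
  }

  if ("train" %in% stages) {
    .check_stage(out_dir, "preprocess", cfg)
    segs <- .segments_from_manifest(out_dir, cfg, schemas)
    split <- .split_from_manifest(out_dir, segs, cfg, schemas)
    mcfg <- cfg$model
    mcfg$seed <- derive_seed(cfg$seed, "train")
    model <- train_model(segs, split, mcfg, schemas)
    save_model(model, file.path(out_dir, "model.json"))
    utils::write.table(model$curves, file.path(out_dir, "curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stamp(out_dir, "train", cfg)
    say("[train] final task loss %.4f, val QCK %.3f",
        utils::tail(model$curves$task_loss, 1),
        utils::tail(model$curves$val_qck, 1))
  }

  if ("evaluate" %in% stages) {
    .check_stage(out_dir, "train", cfg)
    model <- load_model(file.path(out_dir, "model.json"), schemas)
    segs <- .segments_from_manifest(out_dir, cfg, schemas)
    split <- .split_from_manifest(out_dir, segs, cfg, schemas)
    thr <- model$cfg$imbalance == "threshold"
    test <- subset_segments(segs, split$test)
    pred <- predict_model(model, test, threshold = thr)
    y_true <- test$labels
    report <- metric_report(pred$ranks, y_true, schemas)
    cohort <- read_cohort(file.path(out_dir, "data"))
    qcd <- lapply(cohort$sessions, function(s)
      quality_control(s, cfg$qc)$session)
    far <- far_interval_segments(qcd, cfg$model$tau, cohort$labels,
                                 schemas, close_h = cfg$close_h)
    drift <- if (length(far)) drift_evaluation(model, far,
                                               threshold = thr) else NULL
    network <- NULL
    if (n_segments(test) >= 200) {
      network <- residual_diagnostics(
        pred$ranks, unit_step_labels(y_true, schemas), schemas)
    }
    write_eval_tables(report, file.path(out_dir, "eval"),
                      drift = drift, network = network)
    sub <- subject_scores(pred$ranks, unit_step_labels(y_true, schemas),
                          test$manifest$subject_id, schemas = schemas)
    utils::write.table(sub$per_subject,
                       file.path(out_dir, "eval", "subject_f1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stamp(out_dir, "evaluate", cfg)
    say("[evaluate] item-average QCK %.3f on %d test segments",
        report$item_avg["overall_qck"], n_segments(test))
  }

  if ("ablate" %in% stages) {
    .check_stage(out_dir, "train", cfg)
    segs <- .segments_from_manifest(out_dir, cfg, schemas)
    split <- .split_from_manifest(out_dir, segs, cfg, schemas)
    model <- load_model(file.path(out_dir, "model.json"), schemas)
    mcfg <- cfg$model
    mcfg$seed <- derive_seed(cfg$seed, "train")
    rep <- channel_ablation(segs, split, mcfg, schemas = schemas,
                            baseline = model)
    utils::write.table(rep, file.path(out_dir, "ablation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stamp(out_dir, "ablate", cfg)
    say("[ablate] wrote ablation.tsv")
  }
  invisible(out_dir)
}
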