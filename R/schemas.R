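#' Item and scale schemas for HDRS-17 and YMRS
#'
#' The Hamilton Depression Rating Scale (HDRS-17) and the Young Mania Rating
#' Scale (YMRS) are clinician-rated ordinal instruments. Each item admits a
#' small number of ranks; four YMRS items (Y5, Y6, Y8, Y9) are
#' double-weighted, i.e. their printed rank values advance in steps of two
#' (0, 2, 4, 6, 8). Internally the package always works with 0-based
#' unit-step rank *indices*; printed rank values appear only at I/O
#' boundaries.
#'
#' @details An item schema row has columns:
#'   \describe{
#'     \item{id}{item code, \code{H1}..\code{H17} or \code{Y1}..\code{Y11}}
#'     \item{label}{human-readable symptom name}
#'     \item{n_ranks}{number of admissible ranks}
#'     \item{rank_step}{step between printed rank values (1 or 2)}
#'     \item{max_value}{highest printed rank value,
#'       \code{(n_ranks - 1) * rank_step}}
#'   }
#'
#' @name schemas
NULL

.hdrs_items <- function() {
  lab <- c("depressed mood", "feelings of guilt", "suicide",
           "insomnia early", "insomnia middle", "insomnia late",
           "work and activities", "retardation", "agitation",
           "anxiety psychic", "anxiety somatic",
           "somatic symptoms gastrointestinal", "somatic symptoms general",
           "genital symptoms", "hypochondriasis", "weight loss", "insight")
  maxv <- c(4, 4, 4, 2, 2, 2, 4, 4, 4, 4, 4, 2, 2, 2, 4, 2, 2)
  data.frame(
    id = paste0("H", seq_len(17)),
    label = lab,
    n_ranks = maxv + 1L,
    rank_step = 1L,
    max_value = as.integer(maxv),
    stringsAsFactors = FALSE
  )
}

.ymrs_items <- function() {
  lab <- c("elevated mood", "increased motor activity-energy",
           "sexual interest", "sleep", "irritability",
           "speech (rate and amount)", "language-thought disorder",
           "content", "disruptive-aggressive behavior", "appearance",
           "insight")
  step <- c(1, 1, 1, 1, 2, 2, 1, 2, 2, 1, 1)
  maxv <- ifelse(step == 2, 8L, 4L)
  data.frame(
    id = paste0("Y", seq_len(11)),
    label = lab,
    n_ranks = 5L,
    rank_step = as.integer(step),
    max_value = as.integer(maxv),
    stringsAsFactors = FALSE
  )
}

#' Default severity-bin tables
#'
#' Consensus total-score bands used to derive a single severity label per
#' session (e.g. for resampling). The exact edges are an editorial
#' reconstruction of the usual clinical bands (remission at total <= 7 for
#' both scales) and are configurable.
#'
#' @param scale `"HDRS"` or `"YMRS"`.
#' @return A data.frame with columns `label`, `lo`, `hi` (closed integer
#'   intervals partitioning `[0, max_total]`).
#' @export
default_severity_bins <- function(scale = c("HDRS", "YMRS")) {
  scale <- match.arg(scale)
  if (scale == "HDRS") {
    data.frame(
      label = c("remission", "mild", "moderate", "severe", "very severe"),
      lo = c(0L, 8L, 14L, 19L, 23L),
      hi = c(7L, 13L, 18L, 22L, 52L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      label = c("remission", "mild", "moderate", "severe", "very severe"),
      lo = c(0L, 8L, 15L, 20L, 26L),
      hi = c(7L, 14L, 19L, 25L, 60L),
      stringsAsFactors = FALSE
    )
  }
}

new_scale_schema <- function(name, items, severity_bins) {
  stopifnot(is.data.frame(items), is.data.frame(severity_bins))
  if (any(items$max_value != (items$n_ranks - 1L) * items$rank_step))
    stop("item schema violates max_value = (n_ranks - 1) * rank_step")
  structure(
    list(name = name, items = items, severity_bins = severity_bins),
    class = "scale_schema"
  )
}

#' @export
print.scale_schema <- function(x, ...) {
  cat(sprintf("<scale_schema> %s: %d items, max total %d\n",
              x$name, nrow(x$items), max_total(x)))
  invisible(x)
}

#' Build the HDRS-17 and YMRS scale schemas
#'
#' @param hdrs_bins,ymrs_bins severity-bin tables; defaults from
#'   [default_severity_bins()].
#' @return A named list with elements `HDRS` and `YMRS`, each a
#'   `scale_schema` (item table + severity bins).
#' @examples
#' sch <- build_schemas()
#' max_total(sch$HDRS)  # 52
#' max_total(sch$YMRS)  # 60
#' @export
build_schemas <- function(hdrs_bins = default_severity_bins("HDRS"),
                          ymrs_bins = default_severity_bins("YMRS")) {
  list(
    HDRS = new_scale_schema("HDRS", .hdrs_items(), hdrs_bins),
    YMRS = new_scale_schema("YMRS", .ymrs_items(), ymrs_bins)
  )
}

#' Maximum achievable total score of a scale
#' @param scale a `scale_schema`.
#' @return Integer sum of per-item `max_value`.
#' @export
max_total <- function(scale) {
  stopifnot(inherits(scale, "scale_schema"))
  sum(scale$items$max_value)
}

#' Admissible printed rank values of one item
#' @param item one row of an item schema table.
#' @return Integer vector `0, rank_step, ..., max_value`.
#' @export
item_rank_values <- function(item) {
  seq(0L, item$max_value, by = item$rank_step)
}

.check_admissible <- function(value, item) {
  ok <- !is.na(value) & value >= 0 & value <= item$max_value &
    (value %% item$rank_step == 0)
  if (!all(ok))
    stop(sprintf("inadmissible score %s for item %s (admissible: %s)",
                 paste(value[!ok], collapse = ","), item$id,
                 paste(item_rank_values(item), collapse = ",")),
         call. = FALSE)
  invisible(TRUE)
}

#' Total score of a scale from per-item printed rank values
#'
#' @param item_scores named numeric vector or list mapping item id to its
#'   printed rank value; every item of the scale must be present.
#' @param scale a `scale_schema`.
#' @return Integer total (sum of printed rank values).
#' @export
total_score <- function(item_scores, scale) {
  stopifnot(inherits(scale, "scale_schema"))
  item_scores <- unlist(item_scores)
  missing <- setdiff(scale$items$id, names(item_scores))
  if (length(missing))
    stop("missing items: ", paste(missing, collapse = ", "), call. = FALSE)
  tot <- 0L
  for (i in seq_len(nrow(scale$items))) {
    it <- scale$items[i, ]
    v <- item_scores[[it$id]]
    .check_admissible(v, it)
    tot <- tot + as.integer(v)
  }
  tot
}

#' Severity bin containing a total score
#'
#' @param total integer total score in `[0, max_total]`.
#' @param scale a `scale_schema`.
#' @return The bin label (character).
#' @export
severity_bin <- function(total, scale) {
  stopifnot(inherits(scale, "scale_schema"))
  if (any(total < 0 | total > max_total(scale)))
    stop(sprintf("total outside [0, %d]", max_total(scale)), call. = FALSE)
  b <- scale$severity_bins
  idx <- vapply(total, function(t) which(t >= b$lo & t <= b$hi)[1], 1L)
  b$label[idx]
}

#' Majority-to-minority imbalance ratio of a rank distribution
#'
#' For one item, the ratio between the cardinality of the most populated
#' rank and that of the least populated rank. Undefined when a rank has
#' zero count: restrict the distribution to observed ranks first.
#'
#' @param counts non-negative per-rank counts.
#' @return `max(counts) / min(counts)`.
#' @examples
#' imbalance_ratio(c(100, 90, 50, 30, 10))  # 10
#' @export
imbalance_ratio <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 1, all(counts >= 0))
  if (any(counts == 0))
    stop("imbalance ratio undefined with an empty rank; ",
         "restrict counts to observed ranks", call. = FALSE)
  max(counts) / min(counts)
}

#' Sample Shannon entropy of a rank distribution
#'
#' Natural-log entropy of the empirical rank distribution. Correlation
#' analyses against entropy are invariant to the log base (a base change is
#' a positive rescaling), so the base is a free convention.
#'
#' @param counts non-negative per-rank counts, at least one positive.
#' @return `-sum(p * log(p))` over ranks with positive count.
#' @export
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 1, all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero counts", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Rescale a printed rank value to a unit-step rank index
#'
#' Double-weighted YMRS items print ranks 0,2,...,8; for cross-item
#' comparability (e.g. residual analysis) scores are rescaled to a unit
#' step by dividing by the item's rank step.
#'
#' @param score printed rank value(s), admissible for the item.
#' @param item one row of an item schema table.
#' @return Integer 0-based unit-step rank index.
#' @export
rescale_rank_step <- function(score, item) {
  .check_admissible(score, item)
  as.integer(score %/% item$rank_step)
}

#' Combined 28-item table (HDRS then YMRS)
#' @param schemas output of [build_schemas()].
#' @return A 28-row item table with an extra `scale` column.
#' @export
combined_items <- function(schemas = build_schemas()) {
  h <- schemas$HDRS$items; h$scale <- "HDRS"
  y <- schemas$YMRS$items; y$scale <- "YMRS"
  rbind(h, y)
}

#' Write / read the item schema as a plain-text table
#'
#' @param path file path for the tab-separated schema table.
#' @param schemas output of [build_schemas()].
#' @return `write_schema_table` returns `path` invisibly;
#'   `read_schema_table` returns the item table.
#' @export
write_schema_table <- function(path, schemas = build_schemas()) {
  utils::write.table(combined_items(schemas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schema_table
#' @export
read_schema_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
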