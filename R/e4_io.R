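#' Empatica E4-style recording sessions and their CSV export dialect
#'
#' An E4 export is one directory per recording session holding one CSV per
#' channel (`ACC.csv`, `BVP.csv`, `EDA.csv`, `HR.csv`, `TEMP.csv`): line 1
#' is the session start as a UNIX timestamp (repeated across ACC's three
#' axis columns), line 2 the sampling rate in Hz, and every subsequent line
#' one sample (three comma-separated axis values for ACC). No `IBI.csv` is
#' produced or read: the inter-beat-interval stream is excluded because of
#' its long runs of missing values on wrist-worn recordings.
#'
#' @name e4_io
NULL

#' Native E4 sampling rates (Hz) per channel
#' @export
e4_rates <- function() c(ACC = 32, BVP = 64, EDA = 4, HR = 1, TEMP = 1)

#' Construct a recording-session object
#'
#' @param session_id,subject_id identifiers.
#' @param start_time session start as UNIX timestamp (seconds).
#' @param channels named list: `ACC` an n x 3 matrix, `BVP`, `EDA`, `HR`,
#'   `TEMP` numeric vectors, each at its native rate.
#' @param interview_time offset (s) of the clinical interview from session
#'   start; 0 when the wristband is handed over at the interview.
#' @return An object of class `e4_session`.
#' @export
e4_session <- function(session_id, subject_id, start_time, channels,
                       interview_time = 0) {
  rates <- e4_rates()
  stopifnot(setequal(names(channels), names(rates)))
  stopifnot(is.matrix(channels$ACC), ncol(channels$ACC) == 3)
  dur <- nrow(channels$ACC) / rates[["ACC"]]
  for (ch in c("BVP", "EDA", "HR", "TEMP")) {
    got <- length(channels[[ch]]) / rates[[ch]]
    if (abs(got - dur) > 1 / rates[[ch]] + 1e-9)
      stop(sprintf("channel %s implies duration %.2f s, ACC implies %.2f s",
                   ch, got, dur), call. = FALSE)
  }
  structure(
    list(session_id = session_id, subject_id = subject_id,
         start_time = start_time, interview_time = interview_time,
         channels = channels, rates = rates,
         valid = NULL),  # filled by quality_control(); NULL = all valid
    class = "e4_session"
  )
}

#' @export
print.e4_session <- function(x, ...) {
  cat(sprintf("<e4_session> %s (subject %s), %.2f h, channels: %s\n",
              x$session_id, x$subject_id, session_duration(x) / 3600,
              paste(names(x$channels), collapse = " ")))
  invisible(x)
}

#' Duration of a session in seconds
#' @param session an `e4_session`.
#' @export
session_duration <- function(session) {
  nrow(session$channels$ACC) / session$rates[["ACC"]]
}

.fmt_e4 <- function(x) sprintf("%.6f", x)

#' Write one session in the E4 CSV dialect
#'
#' @param session an `e4_session`.
#' @param dir output directory (created; one file per channel).
#' @return `dir`, invisibly.
#' @export
write_e4_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- session$rates
  ts <- .fmt_e4(session$start_time)
  acc <- session$channels$ACC
  acc_lines <- c(paste(rep(ts, 3), collapse = ","),
                 paste(rep(.fmt_e4(r[["ACC"]]), 3), collapse = ","),
                 paste(.fmt_e4(acc[, 1]), .fmt_e4(acc[, 2]),
                       .fmt_e4(acc[, 3]), sep = ","))
  writeLines(acc_lines, file.path(dir, "ACC.csv"))
  for (ch in c("BVP", "EDA", "HR", "TEMP")) {
    writeLines(c(ts, .fmt_e4(r[[ch]]), .fmt_e4(session$channels[[ch]])),
               file.path(dir, paste0(ch, ".csv")))
  }
  invisible(dir)
}

#' Read one session from the E4 CSV dialect
#'
#' @param dir session directory written by [write_e4_session()].
#' @param session_id,subject_id,interview_time metadata not carried by the
#'   channel files themselves (normally taken from `labels.csv`).
#' @return An `e4_session`.
#' @export
read_e4_session <- function(dir, session_id = basename(dir),
                            subject_id = NA_character_,
                            interview_time = 0) {
  read_ch <- function(name, ncol = 1) {
    lines <- readLines(file.path(dir, paste0(name, ".csv")))
    header <- as.numeric(strsplit(lines[1], ",")[[1]])
    rate <- as.numeric(strsplit(lines[2], ",")[[1]])[1]
    body <- lines[-(1:2)]
    if (ncol == 1) {
      vals <- as.numeric(body)
    } else {
      vals <- matrix(as.numeric(unlist(strsplit(body, ",", fixed = TRUE))),
                     ncol = ncol, byrow = TRUE)
    }
    list(start = header[1], rate = rate, x = vals)
  }
  acc <- read_ch("ACC", 3)
  bvp <- read_ch("BVP"); eda <- read_ch("EDA")
  hr <- read_ch("HR"); temp <- read_ch("TEMP")
  want <- e4_rates()
  got <- c(ACC = acc$rate, BVP = bvp$rate, EDA = eda$rate,
           HR = hr$rate, TEMP = temp$rate)
  if (any(abs(got - want) > 1e-6))
    stop("sampling rates in ", dir, " are not the native E4 rates",
         call. = FALSE)
  e4_session(session_id, subject_id, acc$start,
             list(ACC = acc$x, BVP = bvp$x, EDA = eda$x, HR = hr$x,
                  TEMP = temp$x),
             interview_time = interview_time)
}

#' Write / read the session-label table
#'
#' `labels.csv` has one row per session: `session_id`, `subject_id`,
#' `interview_time`, then the 28 printed item scores `H1`..`H17`,
#' `Y1`..`Y11`.
#'
#' @param labels data.frame in that layout.
#' @param path file path.
#' @return `read_labels` returns the data.frame.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(session_id = "character",
                                 subject_id = "character"))
}

#' Item-score columns of a label table as a matrix of printed values
#' @param labels label table from [read_labels()].
#' @param schemas output of [build_schemas()].
#' @return Integer matrix, one row per session, 28 item columns.
#' @export
label_matrix <- function(labels, schemas = build_schemas()) {
  ids <- combined_items(schemas)$id
  m <- as.matrix(labels[, ids, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- labels$session_id
  m
}
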