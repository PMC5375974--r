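CAD_COLUMNS <- c("officer_id", "call_id", "call_type", "priority",
                 "received", "dispatched", "arrive1", "arrive2",
                 "transport", "cleared", "canceled", "canceled_time")
AVL_COLUMNS <- c("time", "x", "y", "speed", "status", "call_id", "officer_id")

empty_cad_log <- function() {
  df <- data.frame(officer_id = character(0), call_id = character(0),
                   call_type = character(0), priority = integer(0),
                   received = numeric(0), dispatched = numeric(0),
                   arrive1 = numeric(0), arrive2 = numeric(0),
                   transport = numeric(0), cleared = numeric(0),
                   canceled = logical(0), canceled_time = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Validate a CAD event log
#'
#' Checks column presence, coerces types, and enforces per-call lifecycle
#' order (`received <= dispatched <= arrive1 <= arrive2 <= transport <=
#' cleared` over the timestamps present); canceled calls must carry no
#' arrive/transport/cleared times. Violations are errors naming the call id.
#'
#' @param df data frame with the columns documented in [read_cad_log()].
#' @return the validated data frame with class `cad_log`.
#' @export
as_cad_log <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(CAD_COLUMNS, names(df))
  if (length(missing_cols))
    stop("CAD log missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, CAD_COLUMNS]
  for (col in c("received", "dispatched", "arrive1", "arrive2",
                "transport", "cleared", "canceled_time", "priority")) {
    v <- df[[col]]
    if (is.character(v)) v[!nzchar(v)] <- NA
    vn <- suppressWarnings(as.numeric(v))
    if (any(is.na(vn) & !is.na(v)))
      stop(sprintf("unparseable timestamp or number in CAD column %s", col),
           call. = FALSE)
    df[[col]] <- if (col == "priority") as.integer(vn) else vn
  }
  df$canceled <- as.logical(df$canceled)
  lifecycle <- c("received", "dispatched", "arrive1", "arrive2",
                 "transport", "cleared")
  for (i in seq_len(nrow(df))) {
    ts <- unlist(df[i, lifecycle])
    if (isTRUE(df$canceled[i])) {
      if (any(!is.na(ts[c("arrive1", "arrive2", "transport", "cleared")])))
        stop(sprintf("call %s: canceled call carries arrive/transport/cleared times",
                     df$call_id[i]), call. = FALSE)
      if (!is.na(df$canceled_time[i]) &&
          df$canceled_time[i] < df$dispatched[i])
        stop(sprintf("call %s: canceled_time precedes dispatched",
                     df$call_id[i]), call. = FALSE)
    } else {
      present <- ts[!is.na(ts)]
      if (length(present) > 1 && any(diff(present) < 0))
        stop(sprintf("call %s: lifecycle timestamps out of order",
                     df$call_id[i]), call. = FALSE)
    }
  }
  class(df) <- c("cad_log", "data.frame")
  df
}

#' Validate an AVL ping track
#'
#' @param df data frame with the columns documented in [read_avl_track()].
#' @return the validated data frame with class `avl_track`, time-sorted
#'   input required (nondecreasing).
#' @export
as_avl_track <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(AVL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("AVL track missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, AVL_COLUMNS]
  for (col in c("time", "x", "y", "speed")) {
    vn <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(vn) & !is.na(df[[col]]) & nzchar(as.character(df[[col]]))))
      stop(sprintf("unparseable timestamp or number in AVL column %s", col),
           call. = FALSE)
    df[[col]] <- vn
  }
  if (nrow(df) > 1 && any(diff(df$time) < 0))
    stop("AVL ping times must be nondecreasing", call. = FALSE)
  df$call_id <- as.character(df$call_id)
  df$call_id[!is.na(df$call_id) & !nzchar(df$call_id)] <- NA_character_
  class(df) <- c("avl_track", "data.frame")
  df
}

read_channel_csv <- function(path, channels) {
  if (!file.exists(path))
    stop("missing channel file: ", basename(path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2)
    stop("malformed header in ", basename(path),
         ": expected start-time and sample-rate rows", call. = FALSE)
  parse_row <- function(s, what) {
    v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
    if (any(is.na(v)))
      stop("malformed ", what, " row in ", basename(path), call. = FALSE)
    v
  }
  start <- parse_row(lines[1], "start-time header")
  rate <- parse_row(lines[2], "sample-rate header")
  if (diff(range(start)) > 1e-6 || diff(range(rate)) > 1e-9)
    stop("malformed header in ", basename(path),
         ": per-column start times / rates disagree", call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    ncol_seen <- lengths(parts)
    if (any(ncol_seen != channels))
      stop("channel count: ", basename(path), " has ",
           ncol_seen[which(ncol_seen != channels)[1]],
           " column(s), expected ", channels, call. = FALSE)
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    if (any(is.na(vals)))
      stop("non-numeric samples in ", basename(path), call. = FALSE)
    values <- if (channels == 1L) vals
              else matrix(vals, ncol = channels, byrow = TRUE)
  } else {
    values <- if (channels == 1L) numeric(0) else
      matrix(numeric(0), ncol = channels)
  }
  list(start = start[1], rate = rate[1], values = values)
}

#' Read a per-channel CSV session directory
#'
#' Expects the wrist-device export dialect: one CSV per channel
#' (`EDA.csv`, `TEMP.csv`, `ACC.csv`, `BVP.csv`, `IBI.csv`), where row 1
#' holds the session start time (UNIX seconds, repeated per column for the
#' 3-column acceleration file), row 2 the sample rate, and every following
#' row one sample. The IBI file instead has a single start-time row followed
#' by `offset,duration` rows (seconds from start, interval length).
#' Per-channel start times must agree.
#'
#' @param path directory containing the five channel files.
#' @return a validated [sensor_session()].
#' @export
read_e4_session <- function(path) {
  if (!dir.exists(path))
    stop("missing channel file: session directory not found: ", path,
         call. = FALSE)
  eda <- read_channel_csv(file.path(path, "EDA.csv"), 1L)
  temp <- read_channel_csv(file.path(path, "TEMP.csv"), 1L)
  acc <- read_channel_csv(file.path(path, "ACC.csv"), 3L)
  bvp <- read_channel_csv(file.path(path, "BVP.csv"), 1L)

  ibi_path <- file.path(path, "IBI.csv")
  if (!file.exists(ibi_path))
    stop("missing channel file: IBI.csv", call. = FALSE)
  ibi_lines <- readLines(ibi_path)
  if (!length(ibi_lines))
    stop("malformed header in IBI.csv: empty file", call. = FALSE)
  ibi_start <- suppressWarnings(as.numeric(ibi_lines[1]))
  if (is.na(ibi_start))
    stop("malformed start-time row in IBI.csv", call. = FALSE)
  body <- ibi_lines[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("channel count: IBI.csv rows must be offset,duration pairs",
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    if (any(is.na(vals)))
      stop("non-numeric samples in IBI.csv", call. = FALSE)
    m <- matrix(vals, ncol = 2, byrow = TRUE)
    ibi <- data.frame(offset = m[, 1], duration = m[, 2])
  } else {
    ibi <- data.frame(offset = numeric(0), duration = numeric(0))
  }

  starts <- c(eda$start, temp$start, acc$start, bvp$start, ibi_start)
  if (diff(range(starts)) > 1e-6)
    stop("mismatched per-channel start times", call. = FALSE)

  sensor_session(
    eda = raw_stream(eda$start, eda$rate, eda$values),
    temp = raw_stream(temp$start, temp$rate, temp$values),
    acc = raw_stream(acc$start, acc$rate, acc$values),
    bvp = raw_stream(bvp$start, bvp$rate, bvp$values),
    ibi = ibi
  )
}

fmt_num <- function(x) sprintf("%.6f", x)

#' Write a sensor session as a per-channel CSV directory
#'
#' Inverse of [read_e4_session()]: writes the five channel files in the
#' dialect that reader accepts, with numeric formatting preserving
#' round-trip equality within 1e-6.
#'
#' @param session a [sensor_session()].
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_e4_session <- function(session, path) {
  stopifnot(inherits(session, "sensor_session"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok || file.access(path, 2) != 0)
    stop("unwritable path: ", path, call. = FALSE)
  write_one <- function(stream, file) {
    k <- n_channels(stream)
    header <- c(paste(rep(fmt_num(stream$start_time), k), collapse = ","),
                paste(rep(fmt_num(stream$sample_rate), k), collapse = ","))
    body <- if (k == 1L) fmt_num(stream$values)
            else apply(stream$values, 1, function(r)
              paste(fmt_num(r), collapse = ","))
    writeLines(c(header, body), file.path(path, file))
  }
  write_one(session$eda, "EDA.csv")
  write_one(session$temp, "TEMP.csv")
  write_one(session$acc, "ACC.csv")
  write_one(session$bvp, "BVP.csv")
  ibi_lines <- c(fmt_num(session$start_time),
                 if (nrow(session$ibi))
                   paste(fmt_num(session$ibi$offset),
                         fmt_num(session$ibi$duration), sep = ","))
  writeLines(ibi_lines, file.path(path, "IBI.csv"))
  invisible(path)
}

read_context_csv <- function(path, mandatory, validator, label) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop(label, " missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), mandatory)
  if (length(extra)) {
    message(label, ": ignoring unknown column(s): ",
            paste(extra, collapse = ", "))
    df <- df[, mandatory, drop = FALSE]
  }
  validator(df)
}

#' Read a CAD event-log CSV
#'
#' Header-bearing CSV with columns `officer_id, call_id, call_type,
#' priority, received, dispatched, arrive1, arrive2, transport, cleared,
#' canceled, canceled_time`; timestamps are UNIX seconds, missing optional
#' lifecycle timestamps are empty fields, `canceled` is 0/1. Unknown columns
#' are ignored with a message; lifecycle violations are errors naming the
#' call id.
#'
#' @param path CSV file path.
#' @return a validated `cad_log` data frame.
#' @export
read_cad_log <- function(path)
  read_context_csv(path, CAD_COLUMNS, as_cad_log, "CAD log")

#' Write a CAD event log CSV
#'
#' @param cad a `cad_log` data frame.
#' @param path target CSV file.
#' @return `path`, invisibly.
#' @export
write_cad_log <- function(cad, path) {
  cad <- as_cad_log(cad)
  out <- as.data.frame(cad)
  out$canceled <- as.integer(out$canceled)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an AVL ping-track CSV
#'
#' Header-bearing CSV with columns `time, x, y, speed, status, call_id,
#' officer_id`: UNIX seconds, planar xy in meters, speed in m/s, a status
#' string, and the linked call id (empty when unallocated). Unknown columns
#' are ignored with a message.
#'
#' @param path CSV file path.
#' @return a validated `avl_track` data frame.
#' @export
read_avl_track <- function(path)
  read_context_csv(path, AVL_COLUMNS, as_avl_track, "AVL track")

#' Write an AVL ping track CSV
#'
#' @param avl an `avl_track` data frame.
#' @param path target CSV file.
#' @return `path`, invisibly.
#' @export
write_avl_track <- function(avl, path) {
  avl <- as_avl_track(avl)
  write.csv(as.data.frame(avl), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a window table (or fused table) CSV
#'
#' One row per 20-second window, one column per metric, the 19 metric
#' columns first and in fixed order; any fused context columns follow.
#' Missing values are written as empty fields.
#'
#' @param table a `window_table` or `fused_table` data frame.
#' @param path target CSV file.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(WINDOW_METRICS, names(table))
  if (length(missing_cols))
    stop("window table missing metric column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(table), WINDOW_METRICS)
  out <- as.data.frame(table)[, c(WINDOW_METRICS, extra)]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a window-table CSV
#'
#' @param path CSV file written by [write_window_table()].
#' @return a `window_table` data frame (plus any extra fused columns); the
#'   window grid start is recovered from the first time stamp.
#' @export
read_window_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(WINDOW_METRICS, names(df))
  if (length(missing_cols))
    stop("window table missing metric column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in WINDOW_METRICS)   # all-NA columns must stay numeric
    df[[col]] <- as.numeric(df[[col]])
  if ("allocated" %in% names(df)) df$allocated <- as.logical(df$allocated)
  class(df) <- c(if ("allocated" %in% names(df)) "fused_table",
                 "window_table", "data.frame")
  attr(df, "window_width") <- 20
  if (nrow(df)) attr(df, "start_time") <- df$time_stamp[1]
  df
}
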