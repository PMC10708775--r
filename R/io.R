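#' Write a vitals stream to delimited text
#'
#' Comma-delimited with the fixed header
#' `person_id,device_id,step,spo2,pulse,temp,battery,x,y`. Missing readings
#' are absent rows. Round-trips losslessly through [read_stream()].
#'
#' @param stream Data frame in the stream schema (one or many persons).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  cols <- c("person_id", "device_id", "step", "spo2", "pulse", "temp",
            "battery", "x", "y")
  stopifnot(all(cols %in% names(stream)))
  utils::write.csv(stream[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vitals stream written by [write_stream()]
#'
#' @param path File path.
#' @return Data frame in the stream schema, sorted by person then step.
#' @export
read_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character",
                                       device_id = "character"))
  df[order(df$person_id, df$step), , drop = FALSE]
}

#' Write an event log as JSON-lines
#'
#' One object per injected ground-truth event:
#' `{person_id, kind, start, end}` with kind one of
#' `artifact`, `saturation`, `dropout`.
#'
#' @param events Event-log data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      writeLines(jsonlite::toJSON(as.list(events[i, , drop = FALSE][1, ]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a JSON-lines event log
#' @param path File path.
#' @return Event-log data frame (zero rows if the file is empty).
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(person_id = character(), kind = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  }))
}

# Shared JSON-lines writer for decision and alert logs.
write_jsonl <- function(df, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE][1, ]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
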