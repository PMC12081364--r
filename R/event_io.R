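EVENT_COLS <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "BQL",
                "EGFR", "BW", "TBIL", "ALB", "BLM")

#' Validate an event-record table
#'
#' Checks the NONMEM-style event-record contract: required columns, EVID
#' coded 1 (dose) / 0 (observation), dose rows carrying a positive amount
#' (umol) and duration (h) and no observation, observation rows carrying a
#' concentration and no amount, and non-negative times sorted within
#' subject.  Problems are reported with the offending row numbers.
#'
#' @param events A data.frame of event records.
#' @return The validated data.frame, invisibly.
#' @export
validate_events <- function(events) {
  miss <- setdiff(EVENT_COLS, names(events))
  if (length(miss))
    stop("event table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- function(rows, msg) {
    if (any(rows))
      stop(msg, " (rows ", paste(utils::head(which(rows), 5), collapse = ", "),
           if (sum(rows) > 5) ", ..." else "", ")", call. = FALSE)
  }
  bad(!events$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  bad(!is.finite(events$TIME) | events$TIME < 0,
      "TIME must be finite and non-negative")
  dose <- events$EVID == 1L
  bad(dose & (is.na(events$AMT) | events$AMT <= 0),
      "dose rows need a positive AMT")
  bad(dose & (is.na(events$DUR) | events$DUR <= 0),
      "dose rows need a positive infusion DUR")
  bad(dose & !is.na(events$DV), "dose rows must not carry an observation")
  bad(!dose & is.na(events$DV), "observation rows need a DV")
  bad(!dose & !is.na(events$AMT), "observation rows must not carry an AMT")
  for (id in unique(events$ID)) {
    tt <- events$TIME[events$ID == id]
    if (is.unsorted(tt))
      stop("times not sorted within subject ", id, call. = FALSE)
  }
  invisible(events)
}

#' Read an event-record CSV
#'
#' Reads the flat event-record dialect used throughout the package:
#' header \code{ID,TIME,EVID,AMT,DUR,DV,BQL,EGFR,BW,TBIL,ALB,BLM}, times in
#' hours with a decimal point, EVID 1 for dose rows and 0 for observation
#' rows, empty cells for fields that do not apply.  The file is validated
#' on read and errors name the offending rows.
#'
#' @param path File path.
#' @return A validated event-record data.frame.
#' @export
read_event_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, EVENT_COLS))
    stop("unexpected header in ", path, "; expected ",
         paste(EVENT_COLS, collapse = ","), call. = FALSE)
  events <- utils::read.csv(path, colClasses = c(ID = "integer",
                                                 EVID = "integer",
                                                 BQL = "integer",
                                                 BLM = "integer"))
  validate_events(events)
  events
}

#' Write an event-record CSV
#'
#' @param events Event-record data.frame (validated before writing).
#' @param path Destination path.
#' @return \code{path}, invisibly.
#' @export
write_event_csv <- function(events, path) {
  validate_events(events)
  utils::write.csv(events[, EVENT_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
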