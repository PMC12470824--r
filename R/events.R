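# List-mode event data model, plain-text I/O and effective-Compton-event
# screening.  The canonical whitespace-delimited schema (one row per
# event) is:
#   event_id side x0 y0 z0 xs ys zs xa ya za Es Ea
# with positions in mm, energies in keV and truth columns NA when the
# source position is unknown.  Lines starting with '#' are comments.

.EVENT_COLS <- c("event_id", "side", "x0", "y0", "z0", "xs", "ys", "zs",
                 "xa", "ya", "za", "Es", "Ea")

#' Construct a ComptonEvents container
#'
#' @param data data.frame with the canonical columns (see
#'   [ComptonEvents-class]).
#' @param metadata optional provenance list.
#' @return a validated [ComptonEvents-class].
#' @export
comptonEvents <- function(data, metadata = list()) {
  new("ComptonEvents", data = as.data.frame(data), metadata = metadata)
}

#' Write events to the canonical list-mode text format
#'
#' Fixed six-decimal formatting; output is bit-stable across runs.
#'
#' @param events a [ComptonEvents-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEvents <- function(events, path) {
  d <- events@data
  lines <- c("# ccxfct list-mode events",
             paste(.EVENT_COLS, collapse = " "))
  if (nrow(d)) {
    num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
    body <- paste(d$event_id, d$side, num(d$x0), num(d$y0), num(d$z0),
                  num(d$xs), num(d$ys), num(d$zs),
                  num(d$xa), num(d$ya), num(d$za),
                  num(d$Es), num(d$Ea))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read events from the canonical list-mode text format
#'
#' Preserves event order; tolerates '#' comment lines.  A malformed row
#' raises an error naming its line number; a missing required column is a
#' schema error.
#'
#' @param path input file path.
#' @return a [ComptonEvents-class].
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  body <- trimws(raw[keep])
  if (length(body) == 0L)
    stop("no header line found in ", path)
  hdr <- strsplit(body[1L], "\\s+")[[1L]]
  miss <- setdiff(.EVENT_COLS, hdr)
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         " in header (line ", lineNo[1L], ")")
  rows <- body[-1L]
  rowLine <- lineNo[-1L]
  if (length(rows) == 0L)
    return(comptonEvents(.emptyEventFrame()))
  parts <- strsplit(rows, "\\s+")
  nf <- lengths(parts)
  if (any(nf != length(hdr)))
    stop("malformed row at line ", rowLine[which(nf != length(hdr))[1L]],
         ": expected ", length(hdr), " fields, found ",
         nf[which(nf != length(hdr))[1L]])
  m <- do.call(rbind, parts)
  colnames(m) <- hdr
  m <- m[, .EVENT_COLS, drop = FALSE]
  numCols <- setdiff(.EVENT_COLS, c("event_id", "side"))
  d <- data.frame(event_id = NA_integer_, side = m[, "side"],
                  stringsAsFactors = FALSE)
  ids <- suppressWarnings(as.integer(m[, "event_id"]))
  if (anyNA(ids))
    stop("malformed row at line ", rowLine[which(is.na(ids))[1L]],
         ": non-integer event_id")
  d$event_id <- ids
  for (cc in numCols) {
    v <- suppressWarnings(as.numeric(m[, cc]))
    bad <- is.na(v) & m[, cc] != "NA"
    if (any(bad))
      stop("malformed row at line ", rowLine[which(bad)[1L]],
           ": cannot parse column ", cc)
    d[[cc]] <- v
  }
  comptonEvents(d[, .EVENT_COLS])
}

.emptyEventFrame <- function() {
  d <- data.frame(event_id = integer(), side = character(),
                  stringsAsFactors = FALSE)
  for (cc in setdiff(.EVENT_COLS, c("event_id", "side")))
    d[[cc]] <- numeric()
  d[, .EVENT_COLS]
}

#' Effective-event screening configuration
#'
#' @param minDistance minimum scatter-to-absorption distance, mm
#'   (default 1.0).
#' @param windowCenter total-energy window center, keV (default the Au
#'   K-alpha1 line, 68.8).
#' @param windowHalfwidth half-width of the total-energy window, keV
#'   (default 2.0).
#' @param requireContainment check that the scatter point lies in a
#'   scatter layer and the absorption point in the same side's absorber
#'   (default TRUE).
#' @return classed list of settings.
#' @export
filterConfig <- function(minDistance = 1.0, windowCenter = 68.8,
                         windowHalfwidth = 2.0, requireContainment = TRUE) {
  stopifnot(minDistance >= 0, windowHalfwidth >= 0, windowCenter > 0)
  structure(list(minDistance = minDistance, windowCenter = windowCenter,
                 windowHalfwidth = windowHalfwidth,
                 requireContainment = requireContainment),
            class = "ccxfct_filterconfig")
}

#' Screen effective Compton events
#'
#' Applies, in fixed order: (i) layer containment -- scatter point inside
#' a scatter layer and absorption point inside the same side's absorber;
#' (ii) scatter-absorption distance `>= minDistance`; (iii) total
#' deposited energy within `windowCenter +/- windowHalfwidth` (complete
#' absorption of the fluorescence photon).  Each event is counted against
#' the first rule it fails.
#'
#' @param events a [ComptonEvents-class].
#' @param cfg a [filterConfig()].
#' @param geometry a [DetectorGeometry-class] (used by the containment
#'   rule).
#' @return list with `events` (the kept [ComptonEvents-class]) and
#'   `report` (named counts: input, kept, rejectedContainment,
#'   rejectedDistance, rejectedEnergy).
#' @export
filterEffective <- function(events, cfg = filterConfig(),
                            geometry = detectorGeometry()) {
  d <- events@data
  n <- nrow(d)
  if (n == 0L)
    return(list(events = events,
                report = c(input = 0L, kept = 0L, rejectedContainment = 0L,
                           rejectedDistance = 0L, rejectedEnergy = 0L)))
  ok <- rep(TRUE, n)
  rejC <- rejD <- rejE <- 0L
  if (isTRUE(cfg$requireContainment)) {
    rs <- as.matrix(d[, c("xs", "ys", "zs")])
    ra <- as.matrix(d[, c("xa", "ya", "za")])
    pass <- rep(FALSE, n)
    for (s in c("A", "B")) {
      bx <- detectorBoxes(geometry, s)
      pass <- pass | (d$side == s & pointInBox(rs, bx$scatter) &
                      pointInBox(ra, bx$absorber))
    }
    rejC <- sum(ok & !pass)
    ok <- ok & pass
  }
  dist <- sqrt((d$xs - d$xa)^2 + (d$ys - d$ya)^2 + (d$zs - d$za)^2)
  passD <- dist >= cfg$minDistance
  rejD <- sum(ok & !passD)
  ok <- ok & passD
  passE <- abs(d$Es + d$Ea - cfg$windowCenter) <= cfg$windowHalfwidth
  rejE <- sum(ok & !passE)
  ok <- ok & passE
  kept <- comptonEvents(d[ok, , drop = FALSE], events@metadata)
  list(events = kept,
       report = c(input = n, kept = sum(ok),
                  rejectedContainment = as.integer(rejC),
                  rejectedDistance = as.integer(rejD),
                  rejectedEnergy = as.integer(rejE)))
}
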