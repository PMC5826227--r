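#' AER event streams
#'
#' An event stream is the universal currency of the simulator: an ordered
#' table of address-events \code{(t, x, y, p, k)} where \code{t} is a
#' timestamp in integer clock ticks, \code{(x, y)} is the pixel address
#' (0-based), \code{p} is the polarity (+1 or -1) and \code{k} is an optional
#' kernel id (0-based; present on unit-input events, \code{NA} on sensor
#' events). Streams carry their address space and the real duration of one
#' tick as attributes.
#'
#' Timestamps are stored as doubles holding exact integers: a 32-bit R
#' integer cannot index 100 s of simulated time at 20 ns per tick. Where the
#' hardware's 32-bit global counter semantics matter (rate saturation), the
#' wrap is applied explicitly.
#'
#' @param t numeric vector of non-negative integer-valued timestamps (ticks).
#' @param x,y integer pixel addresses, 0-based, within \code{address_space}.
#' @param p polarities, each +1 or -1.
#' @param k optional 0-based kernel ids (\code{NA} for sensor events).
#' @param address_space length-2 vector \code{c(x_size, y_size)}: valid
#'   addresses are \code{0..x_size-1} and \code{0..y_size-1}.
#' @param tick_seconds real duration of one tick; default 20 ns
#'   (a 50 MHz clock).
#' @param duration optional stream duration in ticks (used by
#'   \code{\link{stream_stats}}); defaults to the last timestamp.
#' @param sort sort events by \code{t} (stable) instead of requiring sorted
#'   input.
#' @return An object of class \code{event_stream} (a data frame with columns
#'   \code{t, x, y, p, k}).
#' @seealso \code{\link{read_events}}, \code{\link{apply_slowdown}}
#' @export
event_stream <- function(t = numeric(), x = integer(), y = integer(),
                         p = integer(), k = NA_integer_,
                         address_space = c(128L, 128L),
                         tick_seconds = 20e-9, duration = NULL,
                         sort = FALSE) {
  n <- length(t)
  t <- as.numeric(t)
  x <- as.integer(x)
  y <- as.integer(y)
  p <- as.integer(p)
  if (n) {                           # scalars recycle
    if (length(x) == 1L) x <- rep_len(x, n)
    if (length(y) == 1L) y <- rep_len(y, n)
    if (length(p) == 1L) p <- rep_len(p, n)
  }
  k <- rep_len(as.integer(k), if (n) n else 0L)
  stopifnot(length(x) == n, length(y) == n, length(p) == n)
  if (n) {
    if (any(t < 0) || any(t != floor(t)))
      stop("timestamps must be non-negative integers (in ticks)")
    if (!all(p %in% c(-1L, 1L)))
      stop("polarity must be +1 or -1")
    if (any(x < 0L | x >= address_space[1]) || any(y < 0L | y >= address_space[2]))
      stop("event address outside the declared address space")
    if (any(!is.na(k) & k < 0L))
      stop("kernel ids must be non-negative")
    if (is.unsorted(t)) {
      if (sort) {
        o <- order(t)  # stable: ties keep file order
        t <- t[o]; x <- x[o]; y <- y[o]; p <- p[o]; k <- k[o]
      } else {
        stop("events are not sorted by timestamp (use sort = TRUE to sort)")
      }
    }
  }
  ev <- data.frame(t = t, x = x, y = y, p = p, k = k)
  attr(ev, "address_space") <- as.integer(address_space)
  attr(ev, "tick_seconds") <- tick_seconds
  attr(ev, "duration") <- if (is.null(duration)) {
    if (n) t[n] else 0
  } else as.numeric(duration)
  class(ev) <- c("event_stream", "data.frame")
  ev
}

#' @export
print.event_stream <- function(x, ...) {
  as_ <- attr(x, "address_space")
  cat(sprintf("<event_stream> %d events, address space %dx%d, tick %.3g s, duration %s ticks\n",
              nrow(x), as_[1], as_[2], attr(x, "tick_seconds"),
              format(attr(x, "duration"), big.mark = ",")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

new_stream_like <- function(template, t, x, y, p, k, duration = NULL) {
  event_stream(t, x, y, p, k,
               address_space = attr(template, "address_space"),
               tick_seconds = attr(template, "tick_seconds"),
               duration = duration)
}

#' Read an AER event stream from disk
#'
#' Two dialects are supported. \code{csv}: one event per line as
#' \code{t,x,y,p[,k]}, header line optional. \code{aedat}: the plain binary
#' record dialect commonly used for DVS exports -- per event a big-endian
#' 16-bit address word followed by a big-endian 32-bit timestamp (6 bytes),
#' address packed DVS128-style: bit 0 = polarity (1 for +1), bits 1..7 = x,
#' bits 8..14 = y. The aedat dialect carries no kernel id.
#'
#' @param path file to read.
#' @param format \code{"csv"} or \code{"aedat"}.
#' @param address_space,tick_seconds stream metadata (not stored in either
#'   dialect); see \code{\link{event_stream}}.
#' @param sort accept unsorted timestamps and sort them (stable); otherwise
#'   unsorted input is a validation error.
#' @return An \code{\link{event_stream}}.
#' @export
read_events <- function(path, format = c("csv", "aedat"),
                        address_space = c(128L, 128L), tick_seconds = 20e-9,
                        sort = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && grepl("^\\s*t\\s*,", lines[1L])) lines <- lines[-1L]
    if (!length(lines))
      return(event_stream(address_space = address_space,
                          tick_seconds = tick_seconds))
    parts <- strsplit(lines, ",", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf < 4L | nf > 5L)
    if (length(bad))
      stop(sprintf("parse error at line %d: expected 4 or 5 fields, got %d",
                   bad[1L], nf[bad[1L]]))
    num <- suppressWarnings(lapply(parts, as.numeric))
    badn <- which(vapply(num, anyNA, logical(1)))
    if (length(badn))
      stop(sprintf("parse error at line %d: non-numeric field", badn[1L]))
    m <- vapply(num, function(v) c(v, rep(NA_real_, 5L - length(v))), numeric(5))
    event_stream(m[1, ], m[2, ], m[3, ], m[4, ], m[5, ],
                 address_space = address_space, tick_seconds = tick_seconds,
                 sort = sort)
  } else {
    raw <- readBin(path, "raw", n = file.size(path))
    if (length(raw) %% 6L != 0L)
      stop(sprintf("parse error: aedat file length %d is not a multiple of the 6-byte record",
                   length(raw)))
    n <- length(raw) %/% 6L
    if (n == 0L)
      return(event_stream(address_space = address_space,
                          tick_seconds = tick_seconds))
    b <- as.integer(raw)
    dim(b) <- c(6L, n)
    addr <- b[1, ] * 256 + b[2, ]
    t <- ((b[3, ] * 256 + b[4, ]) * 256 + b[5, ]) * 256 + b[6, ]
    p <- ifelse(bitwAnd(addr, 1L) == 1L, 1L, -1L)
    x <- bitwAnd(addr %/% 2L, 127L)
    y <- bitwAnd(addr %/% 256L, 127L)
    event_stream(t, x, y, p, NA_integer_,
                 address_space = address_space, tick_seconds = tick_seconds,
                 sort = sort)
  }
}

#' Write an AER event stream to disk
#'
#' See \code{\link{read_events}} for the dialects. CSV is written with a
#' header \code{t,x,y,p,k} (k blank when absent); the aedat dialect drops the
#' kernel id and requires x, y < 128 and t < 2^32.
#'
#' @param stream an \code{\link{event_stream}}.
#' @param path output file.
#' @param format \code{"csv"} or \code{"aedat"}.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(stream, path, format = c("csv", "aedat")) {
  format <- match.arg(format)
  if (format == "csv") {
    kf <- ifelse(is.na(stream$k), "", as.character(stream$k))
    lines <- sprintf("%s,%d,%d,%d,%s",
                     format(stream$t, scientific = FALSE, trim = TRUE),
                     stream$x, stream$y, stream$p, kf)
    writeLines(c("t,x,y,p,k", lines), path)
  } else {
    if (nrow(stream)) {
      if (any(stream$x > 127L) || any(stream$y > 127L))
        stop("aedat dialect only addresses 128x128")
      if (any(stream$t >= 2^32))
        stop("aedat dialect stores 32-bit timestamps")
    }
    addr <- stream$y * 256L + stream$x * 2L + as.integer(stream$p == 1L)
    t <- stream$t
    bytes <- rbind(addr %/% 256L, addr %% 256L,
                   floor(t / 2^24) %% 256, floor(t / 2^16) %% 256,
                   floor(t / 2^8) %% 256, t %% 256)
    writeBin(as.raw(as.integer(bytes)), path)
  }
  invisible(path)
}

#' Slow down the play-back of an event stream
#'
#' Multiplies every timestamp (and the stream duration) by an integer
#' slow-down factor, reducing the instantaneous event rate while preserving
#' order -- the software analogue of playing a recorded stimulus back slower.
#' Network time constants must be scaled separately if matched behavior is
#' wanted.
#'
#' @param stream an \code{\link{event_stream}}.
#' @param factor positive integer slow-down factor (1 = identity).
#' @return The scaled \code{event_stream}.
#' @export
apply_slowdown <- function(stream, factor) {
  if (length(factor) != 1L || is.na(factor) || factor < 1 || factor != floor(factor))
    stop("slow-down factor must be a positive integer")
  out <- new_stream_like(stream, stream$t * factor, stream$x, stream$y,
                         stream$p, stream$k,
                         duration = attr(stream, "duration") * factor)
  out
}
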