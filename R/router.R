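#' Node addresses on the 2D mesh
#'
#' Each node of the array is identified by its grid coordinates
#' \code{(col, row)}, both 1-based. Events travel the mesh carrying a
#' destination address in their routing header (destination-driven
#' protocol); routers never inspect payloads.
#'
#' @param col,row grid coordinates (1-based).
#' @return A \code{node_address} object.
#' @export
node_address <- function(col, row) {
  a <- list(col = as.integer(col), row = as.integer(row))
  class(a) <- "node_address"
  a
}

#' @export
format.node_address <- function(x, ...) sprintf("(%d,%d)", x$col, x$row)

#' @export
print.node_address <- function(x, ...) {
  cat("<node_address>", format(x), "\n"); invisible(x)
}

addr_key <- function(col, row) sprintf("%d,%d", col, row)

#' Routing table of a node
#'
#' The list of destinations for events generated by the node's local
#' convolutional unit. Each destination carries the kernel id the receiving
#' unit must apply (how a multi-kernel unit knows which source feature map an
#' event came from) and an optional subsample flag (the link right-shifts
#' both coordinates by one bit, merging each 2x2 window into one pixel).
#'
#' @param col,row destination grid coordinates (vectors, 1-based).
#' @param k kernel id written into each clone (0-based).
#' @param subsample logical: apply \code{\link{subsample_address}} on this
#'   link.
#' @return A \code{routing_table} (data frame with columns
#'   \code{col, row, k, subsample}).
#' @export
routing_table <- function(col = integer(), row = integer(), k = 0L,
                          subsample = FALSE) {
  n <- length(col)
  tb <- data.frame(col = as.integer(col), row = as.integer(row),
                   k = rep_len(as.integer(k), n),
                   subsample = rep_len(subsample, n))
  if (anyDuplicated(tb[c("col", "row")]))
    stop("routing table destinations must be distinct")
  class(tb) <- c("routing_table", "data.frame")
  tb
}

#' Route an incoming event at a mesh node
#'
#' Destination-driven forwarding: if the header address equals the node
#' address the event is delivered to the local convolutional unit; otherwise
#' it is forwarded one hop along a shortest path, using deterministic
#' dimension-order (column first: East/West, then North/South). Path lengths
#' therefore equal the Manhattan distance between source and destination.
#'
#' @param node the \code{\link{node_address}} of the router.
#' @param header the destination \code{\link{node_address}} in the event
#'   header.
#' @param grid_shape \code{c(rows, cols)} of the mesh, for header validation.
#' @return \code{list(action = "deliver_local")} or
#'   \code{list(action = "forward", port = "N"|"S"|"E"|"W")}. North is
#'   decreasing row, East increasing column.
#' @export
route_incoming <- function(node, header, grid_shape = NULL) {
  if (!is.null(grid_shape)) {
    if (header$col < 1L || header$col > grid_shape[2] ||
        header$row < 1L || header$row > grid_shape[1])
      stop(sprintf("routing error: header %s outside %dx%d grid",
                   format(header), grid_shape[1], grid_shape[2]))
  }
  if (header$col == node$col && header$row == node$row)
    return(list(action = "deliver_local"))
  port <- if (header$col > node$col) "E"
  else if (header$col < node$col) "W"
  else if (header$row > node$row) "S"
  else "N"
  list(action = "forward", port = port)
}

#' Wrap a locally generated event for the mesh
#'
#' The router clones the unit's output event once per routing-table
#' destination, writing the destination address in each clone's header and
#' the per-destination kernel id into the payload. Subsampling links
#' right-shift the payload address. An empty table makes the node a sink.
#'
#' @param node the source \code{\link{node_address}} (recorded on clones).
#' @param ev a list/one-row data frame with fields \code{t, x, y, p}.
#' @param table the node's \code{\link{routing_table}}.
#' @return A data frame of routed events with columns \code{dst_col,
#'   dst_row, t, x, y, p, k} (zero rows for a sink).
#' @export
wrap_outgoing <- function(node, ev, table) {
  n <- nrow(table)
  if (n == 0L)
    return(data.frame(dst_col = integer(), dst_row = integer(),
                      t = numeric(), x = integer(), y = integer(),
                      p = integer(), k = integer()))
  x <- rep(as.integer(ev$x[1]), n)
  y <- rep(as.integer(ev$y[1]), n)
  ss <- which(table$subsample)
  if (length(ss)) {
    x[ss] <- x[ss] %/% 2L
    y[ss] <- y[ss] %/% 2L
  }
  data.frame(dst_col = table$col, dst_row = table$row,
             t = rep(as.numeric(ev$t[1]), n), x = x, y = y,
             p = rep(as.integer(ev$p[1]), n), k = table$k)
}

#' Hop count of the dimension-order path between two nodes
#'
#' @param a,b \code{\link{node_address}} objects.
#' @return Number of hops (equals the Manhattan distance).
#' @export
hop_count <- function(a, b) abs(a$col - b$col) + abs(a$row - b$row)

#' Subsample an event address by one bit
#'
#' Drops the least significant bit of both coordinates (integer halving), so
#' all events in each 2x2 window are summed into a single destination pixel.
#' Timestamp, polarity and kernel id are unchanged.
#'
#' @param ev an \code{\link{event_stream}} (or any data frame with
#'   \code{x, y} columns).
#' @return The stream with halved addresses (and halved address space, when
#'   present).
#' @export
subsample_address <- function(ev) {
  ev$x <- ev$x %/% 2L
  ev$y <- ev$y %/% 2L
  as_ <- attr(ev, "address_space")
  if (!is.null(as_)) attr(ev, "address_space") <- pmax(as_ %/% 2L, 1L)
  ev
}
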