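#' Multi-layer network configuration
#'
#' Describes a grid of mesh nodes (convolutional units and router-only
#' pass-through nodes), the routing tables that wire them into a multi-layer
#' ConvNet, the splitter targets fed by the network input, and the merger
#' sources whose output events form the network output. Subsampling between
#' layers is a property of links: flagged routing entries right-shift event
#' addresses by one bit (2x2 windows collapse onto one pixel).
#'
#' @param grid_shape \code{c(rows, cols)} of the mesh.
#' @param nodes named list keyed \code{"col,row"}; each element either a
#'   \code{\link{unit_config}} or the string \code{"router"} for a
#'   router-only node.
#' @param routing named list keyed \code{"col,row"} of
#'   \code{\link{routing_table}}s for locally generated events (missing or
#'   empty = sink).
#' @param input_targets a \code{\link{routing_table}}: where the input
#'   splitter clones each network-input event.
#' @param output_sources data frame with columns \code{col, row}: nodes
#'   whose output events are also collected by the output merger.
#' @param tick_seconds tick duration; the engine equates one tick with one
#'   clock cycle of the cost model.
#' @return A validated \code{network_config}.
#' @export
network_config <- function(grid_shape, nodes, routing = list(),
                           input_targets, output_sources,
                           tick_seconds = 20e-9) {
  grid_shape <- as.integer(grid_shape)
  keys <- names(nodes)
  if (is.null(keys) || anyDuplicated(keys))
    stop("nodes must be a uniquely named list keyed \"col,row\"")
  coords <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
  cc <- as.integer(coords[, 1]); rr <- as.integer(coords[, 2])
  if (any(is.na(cc)) || any(cc < 1L | cc > grid_shape[2] |
                            rr < 1L | rr > grid_shape[1]))
    stop("node address outside the grid")
  is_conv <- vapply(nodes, inherits, logical(1), what = "unit_config")
  for (nm in names(routing)) {
    if (!nm %in% keys) stop("routing entry for unknown node ", nm)
    tb <- routing[[nm]]
    dk <- addr_key(tb$col, tb$row)
    miss <- !dk %in% keys
    if (any(miss))
      stop("dangling routing destination ", dk[which(miss)[1]],
           " from node ", nm)
    if (any(!is_conv[match(dk, keys)]))
      stop("routing destination ", dk[which(!is_conv[match(dk, keys)])[1]],
           " is router-only (cannot receive unit events)")
  }
  itk <- addr_key(input_targets$col, input_targets$row)
  if (any(!itk %in% keys) || any(!is_conv[match(itk, keys)]))
    stop("input targets must be convolutional nodes on the grid")
  osk <- addr_key(output_sources$col, output_sources$row)
  if (any(!osk %in% keys)) stop("output source off-grid")
  cfg <- list(grid_shape = grid_shape, nodes = nodes, routing = routing,
              input_targets = input_targets,
              output_sources = output_sources,
              tick_seconds = tick_seconds)
  class(cfg) <- "network_config"
  cfg
}

#' Architecture statistics of a network
#'
#' Closed-form counts from the configuration: neurons are summed pixel
#' counts over convolutional nodes; kernels are summed kernel inventories;
#' synapses use full fan-in counting -- for each destination node, its
#' neuron count times the total number of kernel weights it holds (each
#' weight is one synapse per destination neuron; border clipping is
#' ignored).
#'
#' @param cfg a \code{\link{network_config}}.
#' @return \code{list(neurons, synapses, kernels, conv_nodes)}.
#' @export
count_architecture <- function(cfg) {
  neurons <- 0; synapses <- 0; kernels <- 0L; conv_nodes <- 0L
  for (nd in cfg$nodes) {
    if (!inherits(nd, "unit_config")) next
    conv_nodes <- conv_nodes + 1L
    npix <- nd$n_x * nd$n_y
    neurons <- neurons + npix
    kernels <- kernels + length(nd$kernels)
    w <- sum(vapply(nd$kernels, function(k) k$xk_max * k$yk_max, numeric(1)))
    synapses <- synapses + npix * w
  }
  list(neurons = neurons, synapses = synapses, kernels = kernels,
       conv_nodes = conv_nodes)
}

#' Build a simulator instance
#'
#' Instantiates all convolutional units in their initial state and indexes
#' the routing structures. Router-only nodes carry no state: hop-by-hop
#' forwarding is hop-minimal and event-conserving (see
#' \code{\link{route_incoming}}), so the engine delivers clones to their
#' destination units directly, with zero transit latency.
#'
#' @param cfg a \code{\link{network_config}}.
#' @return A \code{conv_network} simulator instance for
#'   \code{\link{simulate_network}}.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  keys <- names(cfg$nodes)
  is_conv <- vapply(cfg$nodes, inherits, logical(1), what = "unit_config")
  conv_keys <- keys[is_conv]
  units <- cfg$nodes[is_conv]
  states <- lapply(units, conv_unit_state)
  net <- list(cfg = cfg, conv_keys = conv_keys, units = units,
              states = states)
  class(net) <- "conv_network"
  net
}

#' Run the discrete-event simulation
#'
#' Drives a time-sorted input stream through the network under the traffic
#' control rule: at the instant an input event is offered, it is dropped
#' (not delayed) if any node's output FIFO is full (\code{full_FIFO}) or an
#' input-target node's input FIFO is full; otherwise the splitter clones it
#' to all input targets. Accepted events keep their original timestamps.
#' Each unit serves its input FIFO one event at a time; service time is the
#' cost-model latency (one tick per clock cycle), a unit does not start an
#' event while its output FIFO is full, and the router moves a unit's output
#' clones to their destination input FIFOs as soon as all of them have
#' space. Unit-internal leakage and refresh fire at their counter
#' boundaries. The run is deterministic: ties are resolved in node-index
#' order.
#'
#' @param net a \code{conv_network} from \code{\link{build_network}} (not
#'   modified: each call starts from the built initial state).
#' @param stream the input \code{\link{event_stream}}.
#' @return A \code{sim_log}: \code{list(offered, processed_inputs,
#'   dropped_inputs, per_node, output, cycles)} where \code{per_node} is a
#'   data frame of per-unit event counts and \code{output} a data frame of
#'   merged output events \code{(t, x, y, p, src)}, \code{src} being the
#'   source node key.
#' @export
simulate_network <- function(net, stream) {
  cfg <- net$cfg
  keys <- net$conv_keys
  nn <- length(keys)
  idx <- seq_len(nn)
  names(idx) <- keys
  units <- net$units
  envs <- lapply(seq_len(nn), function(i) unit_env(units[[i]], net$states[[i]]))
  taken <- integer(nn)    # outputs already moved from each env's buffer
  tick <- cfg$tick_seconds

  # per-node queues and service bookkeeping
  in_q <- vector("list", nn)
  out_q <- vector("list", nn)
  busy <- rep(Inf, nn)
  cur <- vector("list", nn)
  d_in <- vapply(units, `[[`, integer(1), "fifo_depth_in")
  d_out <- vapply(units, `[[`, integer(1), "fifo_depth_out")
  kcost <- lapply(units, function(u)
    vapply(u$kernels, event_cost, numeric(1), model = u$cost))
  n_proc <- integer(nn)   # unit events consumed
  n_emit <- integer(nn)   # unit events emitted

  routing <- cfg$routing
  route_of <- lapply(keys, function(k) {
    tb <- routing[[k]]
    if (is.null(tb)) routing_table() else tb
  })
  dest_idx <- lapply(route_of, function(tb) idx[addr_key(tb$col, tb$row)])
  is_source <- keys %in% addr_key(cfg$output_sources$col,
                                  cfg$output_sources$row)
  it <- cfg$input_targets
  it_idx <- idx[addr_key(it$col, it$row)]

  out_t <- numeric(0); out_x <- integer(0); out_y <- integer(0)
  out_p <- integer(0); out_src <- character(0)
  offered <- 0L; dropped <- 0L
  cycles_total <- 0

  # deliver the head of every non-empty output FIFO whose destinations all
  # have space; repeat until no progress (a completion may unblock a chain)
  drain <- function() {
    repeat {
      progress <- FALSE
      for (i in which(lengths(out_q) > 0L)) {
        ev <- out_q[[i]][[1L]]
        di <- dest_idx[[i]]
        if (length(di) && any(lengths(in_q)[di] >= d_in[di])) next
        tb <- route_of[[i]]
        if (length(di)) for (j in seq_along(di)) {
          e <- ev
          if (tb$subsample[j]) { e[2] <- e[2] %/% 2; e[3] <- e[3] %/% 2 }
          e[5] <- tb$k[j]
          in_q[[di[j]]][[length(in_q[[di[j]]]) + 1L]] <<- e
        }
        if (is_source[i]) {
          out_t[length(out_t) + 1L] <<- ev[1]
          out_x[length(out_x) + 1L] <<- ev[2]
          out_y[length(out_y) + 1L] <<- ev[3]
          out_p[length(out_p) + 1L] <<- ev[4]
          out_src[length(out_src) + 1L] <<- keys[i]
        }
        out_q[[i]][[1L]] <<- NULL
        progress <- TRUE
      }
      if (!progress) break
    }
  }

  start_idle <- function(now) {
    for (i in which(is.infinite(busy))) {
      if (!length(in_q[[i]])) next
      if (length(out_q[[i]]) >= d_out[i]) next   # full_FIFO stalls the unit
      ev <- in_q[[i]][[1L]]
      in_q[[i]][[1L]] <<- NULL
      cur[[i]] <<- c(ev, start = now)
      busy[i] <<- now + kcost[[i]][ev[5] + 1]
    }
  }

  ts <- stream$t; xs <- stream$x; ys <- stream$y; ps <- stream$p
  n_in <- length(ts)
  j <- 1L

  repeat {
    tc <- if (any(is.finite(busy))) min(busy) else Inf
    te <- if (j <= n_in) ts[j] else Inf
    if (!is.finite(tc) && !is.finite(te)) break
    if (tc <= te) {
      i <- which(busy == tc)[1L]
      ev <- cur[[i]]
      en <- envs[[i]]
      m <- unit_step(en, ev[6], ev[2], ev[3], ev[4], ev[5])
      n_proc[i] <- n_proc[i] + 1L
      if (m) {
        n_emit[i] <- n_emit[i] + m
        for (q in (taken[i] + 1L):en$n_out)
          out_q[[i]][[length(out_q[[i]]) + 1L]] <-
            c(en$out_t[q], en$out_x[q], en$out_y[q], en$out_p[q], 0)
        taken[i] <- en$n_out
      }
      busy[i] <- Inf
      cur[i] <- list(NULL)
      drain()
      start_idle(tc)
    } else {
      offered <- offered + 1L
      full_out <- any(lengths(out_q) >= d_out)
      full_entry <- any(lengths(in_q)[it_idx] >= d_in[it_idx])
      if (full_out || full_entry) {
        dropped <- dropped + 1L
      } else {
        for (q in seq_len(nrow(it))) {
          x <- xs[j]; y <- ys[j]
          if (it$subsample[q]) { x <- x %/% 2L; y <- y %/% 2L }
          i <- it_idx[q]
          in_q[[i]][[length(in_q[[i]]) + 1L]] <- c(ts[j], x, y, ps[j], it$k[q])
        }
        start_idle(te)
      }
      j <- j + 1L
    }
  }
  drain()
  cycles_total <- sum(vapply(envs, function(e) e$cycles, numeric(1)))

  o <- order(out_t)
  output <- data.frame(t = out_t[o], x = as.integer(out_x[o]),
                       y = as.integer(out_y[o]), p = as.integer(out_p[o]),
                       src = out_src[o])
  attr(output, "tick_seconds") <- tick
  attr(output, "duration") <- attr(stream, "duration")
  coords <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
  log <- list(offered = offered,
              processed_inputs = offered - dropped,
              dropped_inputs = dropped,
              per_node = data.frame(node = keys,
                                    col = as.integer(coords[, 1]),
                                    row = as.integer(coords[, 2]),
                                    events_processed = n_proc,
                                    events_emitted = n_emit),
              output = output,
              cycles = cycles_total)
  class(log) <- "sim_log"
  log
}

#' @export
print.sim_log <- function(x, ...) {
  cat(sprintf("<sim_log> offered %d | processed %d | dropped %d | output events %d\n",
              x$offered, x$processed_inputs, x$dropped_inputs,
              nrow(x$output)))
  invisible(x)
}
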