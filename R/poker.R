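#' Gabor-like integer kernel
#'
#' Oriented edge-extractor weights of the kind used in the first layer of
#' the poker-symbol network, quantized to integers.
#'
#' @param theta orientation in radians.
#' @param size kernel size.
#' @param amp peak amplitude before rounding.
#' @return A \code{\link{kernel_spec}} (center shift 0).
#' @export
gabor_kernel <- function(theta, size = 10L, amp = 60) {
  r <- (size - 1) / 2
  g <- expand.grid(x = seq_len(size) - 1 - r, y = seq_len(size) - 1 - r)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  sigma <- size / 5
  lambda <- size / 2
  w <- amp * exp(-(xr^2 + 0.5 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * xr / lambda)
  kernel_spec(matrix(round_half_away(w), size, size))
}

# deterministic small-integer pattern kernels for the deeper layers (the
# trained weights are not published; these are synthetic stand-ins)
pattern_kernel <- function(size, phase, amp = 24, shift = 0L) {
  g <- expand.grid(x = seq_len(size), y = seq_len(size))
  w <- amp * sin(1.7 * g$x + 2.3 * g$y + phase) *
    cos(0.9 * g$x - 1.3 * g$y + 0.5 * phase)
  kernel_spec(matrix(round_half_away(w), size, size),
              shift_x = shift, shift_y = shift)
}

#' The 22-node poker-symbol ConvNet (synthetic weights)
#'
#' Builds the 4-layer, 22-convolutional-node network used for poker card
#' symbol recognition, laid out on a 6x4 mesh: column 1 holds the six
#' 28x28 C1 nodes (one 10x10 oriented-edge kernel each), column 2 the four
#' 10x10 C3 nodes (six 5x5 kernels each) plus two router-only nodes,
#' column 3 six of the eight 1x1 C5 nodes (four 5x5 kernels each; the other
#' two sit in column 4), and column 4 the four 1x1 C6 output nodes (eight
#' 1x1 kernels each). The C1-C3 and C3-C5 links subsample addresses by one
#' bit (28x28 -> 14x14 and 10x10 -> 5x5). Totals: 5,116 neurons, 531,232
#' synapses, 94 kernels.
#'
#' Thresholds, leakage rates and rate-saturation periods follow the
#' hardware-scaled parameter stage (threshold 128 per layer; leakage rates
#' 143.62 / 81.16 / 21.00 / 42.41 per second; rate saturation 0.10 ms in C3
#' and 0.46 ms in C5). The trained kernel weights were never published, so
#' the bundled weights are deterministic synthetic stand-ins (Gabor-like
#' filters in C1, fixed small-integer patterns elsewhere): architecture
#' counts and dataflow are faithful, recognition performance is not claimed.
#'
#' @param tick_seconds tick duration (default 20 ns: one tick per clock
#'   cycle of the 50 MHz reference implementation, which is what the engine's
#'   cost model assumes).
#' @param fifo_depth_in,fifo_depth_out FIFO capacities for every node.
#' @return A \code{\link{network_config}}.
#' @export
poker_network <- function(tick_seconds = 20e-9, fifo_depth_in = 64L,
                          fifo_depth_out = 64L) {
  lr <- c(C1 = 143.62, C3 = 81.16, C5 = 21.00, C6 = 42.41)
  tl <- vapply(lr, function(r) leak_schedule(r, tick_seconds)$t_leak,
               numeric(1))
  t_r3 <- round(0.10e-3 / tick_seconds)
  t_r5 <- round(0.46e-3 / tick_seconds)
  mk <- function(n, kernels, t_leak, t_r = 0, in_as, out_as)
    unit_config(n, n, kernels, th = 128L, t_leak = t_leak,
                n_leak = 1L, t_r = t_r,
                b_tr = if (t_r > 0) max(7L, floor(log2(t_r))) else 15L,
                in_addr_space = in_as, out_addr_space = out_as,
                fifo_depth_in = fifo_depth_in,
                fifo_depth_out = fifo_depth_out)
  nodes <- list()
  routing <- list()
  # C1: column 1, rows 1..6; one 10x10 Gabor each; fan out to all 4 C3 nodes
  for (i in 1:6) {
    k <- gabor_kernel((i - 1) * pi / 6)
    k$shift_x <- k$shift_x - 2L; k$shift_y <- k$shift_y - 2L
    k <- kernel_spec(k$weights, k$shift_x, k$shift_y)
    nodes[[addr_key(1L, i)]] <- mk(28L, list(k), tl["C1"],
                                   in_as = c(32L, 32L), out_as = c(28L, 28L))
    routing[[addr_key(1L, i)]] <-
      routing_table(col = rep(2L, 4), row = 1:4, k = i - 1L, subsample = TRUE)
  }
  c5_addr <- data.frame(col = c(3L, 3L, 3L, 3L, 3L, 3L, 4L, 4L),
                        row = c(1L, 2L, 3L, 4L, 5L, 6L, 5L, 6L))
  # C3: column 2, rows 1..4; six 5x5 kernels (one per C1 map)
  for (j in 1:4) {
    ks <- lapply(1:6, function(m)
      pattern_kernel(5L, phase = j + 0.7 * m, shift = -2L))
    nodes[[addr_key(2L, j)]] <- mk(10L, ks, tl["C3"], t_r = t_r3,
                                   in_as = c(14L, 14L), out_as = c(10L, 10L))
    routing[[addr_key(2L, j)]] <-
      routing_table(col = c5_addr$col, row = c5_addr$row, k = j - 1L,
                    subsample = TRUE)
  }
  nodes[[addr_key(2L, 5L)]] <- "router"
  nodes[[addr_key(2L, 6L)]] <- "router"
  # C5: eight 1x1 nodes; four 5x5 kernels (one per C3 map)
  for (m in 1:8) {
    ks <- lapply(1:4, function(j)
      pattern_kernel(5L, phase = 2.1 * m + j, shift = -2L))
    nodes[[addr_key(c5_addr$col[m], c5_addr$row[m])]] <-
      mk(1L, ks, tl["C5"], t_r = t_r5,
         in_as = c(5L, 5L), out_as = c(1L, 1L))
    routing[[addr_key(c5_addr$col[m], c5_addr$row[m])]] <-
      routing_table(col = rep(4L, 4), row = 1:4, k = m - 1L)
  }
  # C6: column 4, rows 1..4; eight 1x1 kernels (one per C5 map); sinks
  syms <- c("spade", "heart", "diamond", "club")
  for (j in 1:4) {
    ks <- lapply(1:8, function(m)
      kernel_spec(round_half_away(40 * sin(1.3 * m * j + m + j))))
    nodes[[addr_key(4L, j)]] <- mk(1L, ks, tl["C6"],
                                   in_as = c(1L, 1L), out_as = c(1L, 1L))
  }
  network_config(grid_shape = c(6L, 4L), nodes = nodes, routing = routing,
                 input_targets = routing_table(col = rep(1L, 6), row = 1:6,
                                               k = 0L),
                 output_sources = data.frame(col = rep(4L, 4), row = 1:4),
                 tick_seconds = tick_seconds)
}

#' Output-neuron labels of the poker network
#'
#' Maps the four C6 node keys to their symbol classes, for
#' \code{\link{classify_symbols}}.
#'
#' @return A named character vector.
#' @export
poker_neuron_map <- function() {
  c("4,1" = "spade", "4,2" = "heart", "4,3" = "diamond", "4,4" = "club")
}
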