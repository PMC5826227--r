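# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the dense convolution oracle accumulates shifted
# kernels into a plain matrix, the rate-saturation oracle stores the full
# 32-bit t_lim, and the drop-rule oracle replays the traffic-control queueing
# step by step.

# dense accumulation of an event stream: sum of polarity-signed kernels
# centered per event, clipped at the array border; no thresholds, no leak
dense_conv_oracle <- function(stream, kern, n_x, n_y, init) {
  acc <- matrix(as.numeric(init), n_x, n_y)
  for (i in seq_len(nrow(stream))) {
    cx <- stream$x[i] + kern$ox
    cy <- stream$y[i] + kern$oy
    for (a in seq_along(cx)) for (b in seq_along(cy)) {
      if (cx[a] >= 0 && cx[a] < n_x && cy[b] >= 0 && cy[b] < n_y)
        acc[cx[a] + 1L, cy[b] + 1L] <-
          acc[cx[a] + 1L, cy[b] + 1L] + stream$p[i] * kern$weights[a, b]
    }
  }
  acc
}

# full-resolution refractory oracle: one entry, exact t_lim, exact delta-t
rs_oracle_new <- function() list(tlim = -1, pend = FALSE)
rs_oracle_step <- function(o, t, t_r) {
  allowed <- t > o$tlim
  if (allowed) {
    dt <- if (o$pend) min(max(t - o$tlim, 0), t_r) else 0
    o$tlim <- t + t_r - dt
    o$pend <- FALSE
  } else o$pend <- TRUE
  list(allowed = allowed, o = o)
}

# random event stream helper
rand_stream <- function(n, n_x, n_y, t_max = 10000, k = 0L, seed = 1) {
  set.seed(seed)
  event_stream(sort(sample.int(t_max, n, replace = TRUE)),
               sample.int(n_x, n, replace = TRUE) - 1L,
               sample.int(n_y, n, replace = TRUE) - 1L,
               sample(c(-1L, 1L), n, replace = TRUE), k,
               address_space = c(n_x, n_y))
}

# a minimal single-conv-node network: one unit at (1,1), splitter feeds it,
# its outputs go to the merger
single_node_net <- function(ucfg, tick_seconds = 20e-9) {
  network_config(grid_shape = c(1L, 1L),
                 nodes = list("1,1" = ucfg),
                 routing = list(),
                 input_targets = routing_table(col = 1L, row = 1L, k = 0L),
                 output_sources = data.frame(col = 1L, row = 1L),
                 tick_seconds = tick_seconds)
}
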