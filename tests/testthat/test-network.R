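test_that("the poker network builds with the published architecture counts", {
  cfg <- poker_network()
  expect_equal(prod(cfg$grid_shape), 24)       # 6x4 mesh
  a <- count_architecture(cfg)
  expect_equal(a$conv_nodes, 22L)              # plus 2 router-only slots
  expect_equal(a$neurons, 6 * 784 + 4 * 100 + 8 + 4)      # 5,116
  expect_equal(a$synapses,
               6 * 784 * 100 + 4 * 100 * 6 * 25 + 8 * 4 * 25 + 4 * 8)
  expect_equal(a$synapses, 531232)
  expect_equal(a$kernels, 94L)
  net <- build_network(cfg)
  expect_length(net$conv_keys, 22L)
})

test_that("configs validate destinations, grid bounds and node kinds", {
  u <- unit_config(2, 2, kernel_spec(1), th = 10)
  mk <- function(routing) network_config(
    grid_shape = c(2, 2),
    nodes = list("1,1" = u, "2,1" = u, "1,2" = "router"),
    routing = routing,
    input_targets = routing_table(col = 1L, row = 1L, k = 0L),
    output_sources = data.frame(col = 2L, row = 1L))
  expect_s3_class(mk(list("1,1" = routing_table(col = 2L, row = 1L, k = 0L))),
                  "network_config")
  expect_error(mk(list("1,1" = routing_table(col = 2L, row = 2L, k = 0L))),
               "dangling")
  expect_error(mk(list("1,1" = routing_table(col = 1L, row = 2L, k = 0L))),
               "router-only")
  expect_error(network_config(grid_shape = c(1, 1),
                              nodes = list("5,5" = u), routing = list(),
                              input_targets = routing_table(),
                              output_sources = data.frame(col = 5, row = 5)),
               "outside the grid")
  # degenerate single-node net builds and runs
  expect_s3_class(build_network(single_node_net(u)), "conv_network")
  # empty (router-only) network counts to zero
  ecfg <- network_config(grid_shape = c(1, 1),
                         nodes = list("1,1" = "router"), routing = list(),
                         input_targets = routing_table(),
                         output_sources = data.frame(col = integer(),
                                                     row = integer()))
  expect_equal(unlist(count_architecture(ecfg)),
               c(neurons = 0, synapses = 0, kernels = 0, conv_nodes = 0))
})

test_that("an uncongested run drops nothing and keeps source timestamps", {
  # pass-through node: 1x1 kernel with weight = threshold fires per event
  u <- unit_config(8, 8, kernel_spec(10), th = 10, fifo_depth_in = 512L,
                   fifo_depth_out = 512L)
  net <- build_network(single_node_net(u))
  set.seed(21)
  s <- event_stream((1:150) * 1000, sample.int(8, 150, TRUE) - 1L,
                    sample.int(8, 150, TRUE) - 1L, 1L,
                    address_space = c(8, 8))
  log <- simulate_network(net, s)
  expect_equal(log$dropped_inputs, 0L)
  expect_equal(log$processed_inputs, log$offered)
  expect_equal(log$offered, 150L)
  # every input fires exactly one output, stamped start + T_event
  expect_equal(nrow(log$output), 150L)
  expect_equal(sort(log$output$t - 63), sort(s$t))
  expect_equal(log$per_node$events_processed, 150L)
})

test_that("congestion drops inputs per the replayed drop-rule oracle", {
  # 10x10 kernel: service 1647 ticks/event; burst every 500 ticks; tiny FIFOs
  u <- unit_config(10, 10, kernel_spec(matrix(0, 10, 10)), th = 10,
                   fifo_depth_in = 4L, fifo_depth_out = 4L)
  net <- build_network(single_node_net(u))
  n <- 120L
  s <- event_stream((1:n) * 500, 5L, 5L, 1L, address_space = c(10, 10))
  log <- simulate_network(net, s)
  expect_gt(log$dropped_inputs, 0L)
  expect_equal(log$processed_inputs + log$dropped_inputs, log$offered)
  # independent queue replay: single server, service 1647 ticks, waiting
  # room 4, drop when the waiting queue is full at arrival
  busy <- -Inf; queue <- 0L; accepted <- logical(n)
  for (i in seq_len(n)) {
    t <- 500 * i
    while (is.finite(busy) && busy <= t) {
      if (queue > 0L) { queue <- queue - 1L; busy <- busy + 1647 }
      else busy <- -Inf
    }
    if (is.finite(busy)) {
      accepted[i] <- queue < 4L
      if (accepted[i]) queue <- queue + 1L
    } else {
      accepted[i] <- TRUE
      busy <- t + 1647
    }
  }
  expect_equal(log$processed_inputs, sum(accepted))
})

test_that("the processed fraction is non-increasing in offered rate", {
  u <- unit_config(10, 10, kernel_spec(matrix(0, 10, 10)), th = 10,
                   fifo_depth_in = 8L, fifo_depth_out = 8L)
  net <- build_network(single_node_net(u))
  base <- event_stream((1:150) * 400, 5L, 5L, 1L, address_space = c(10, 10))
  frac <- sapply(c(8, 4, 2, 1), function(slow) {
    log <- simulate_network(net, apply_slowdown(base, slow))
    log$processed_inputs / log$offered
  })
  expect_true(all(diff(frac) <= 1e-12))        # slower playback, higher frac
  expect_equal(frac[1], 1)                     # uncongested limit
})

test_that("simulation is deterministic and conserves events", {
  cfg <- poker_network()
  traj <- data.frame(t = (1:12) * 50000, dx = 1L, dy = 0L)
  stim <- gen_moving_symbol("diamond", traj, start = c(4L, 10L),
                            tick_seconds = 20e-9)
  net <- build_network(cfg)
  l1 <- simulate_network(net, stim)
  l2 <- simulate_network(net, stim)
  expect_identical(l1$output, l2$output)
  expect_identical(l1$per_node, l2$per_node)
  expect_equal(l1$processed_inputs + l1$dropped_inputs, l1$offered)
  expect_equal(l1$offered, nrow(stim))
  # mesh conservation: C1 consumed exactly what the splitter accepted
  c1 <- l1$per_node$events_processed[l1$per_node$col == 1L]
  expect_equal(c1, rep(l1$processed_inputs, 6L))
})

test_that("subsampling links halve addresses between layers", {
  # two-node chain: (1,1) 4x4 pass-through -> subsample -> (2,1) 2x2 counter
  u1 <- unit_config(4, 4, kernel_spec(10), th = 10)
  u2 <- unit_config(2, 2, kernel_spec(10), th = 10,
                    in_addr_space = c(2L, 2L))
  cfg <- network_config(
    grid_shape = c(1, 2),
    nodes = list("1,1" = u1, "2,1" = u2),
    routing = list("1,1" = routing_table(col = 2L, row = 1L, k = 0L,
                                         subsample = TRUE)),
    input_targets = routing_table(col = 1L, row = 1L, k = 0L),
    output_sources = data.frame(col = 2L, row = 1L))
  s <- event_stream(c(1000, 2000, 3000), c(3L, 2L, 0L), c(3L, 2L, 1L), 1L,
                    address_space = c(4L, 4L))
  log <- simulate_network(build_network(cfg), s)
  expect_equal(nrow(log$output), 3L)
  expect_equal(log$output$x, c(1L, 1L, 0L))    # (3,2,0) >> 1
  expect_equal(log$output$y, c(1L, 1L, 0L))
  expect_true(all(log$output$src == "2,1"))
})

test_that("network configs round-trip through JSON and match the bundled fixture", {
  cfg <- poker_network()
  f <- withr::local_tempfile(fileext = ".json")
  write_network_config(cfg, f)
  cfg2 <- read_network_config(f)
  expect_equal(cfg2, cfg)
  fixture <- system.file("extdata", "poker_network_synthetic.json",
                         package = "evconvnet")
  expect_true(nzchar(fixture))
  expect_equal(read_network_config(fixture), cfg)
})
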