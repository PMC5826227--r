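#' Kernel specification
#'
#' A convolutional kernel as stored in the unit's kernel memory: a 2D integer
#' weight matrix indexed \code{weights[x, y]} plus a center shift. An input
#' event at \code{(x, y)} applies the kernel to the pixel window centered at
#' \code{(x + shift_x, y + shift_y)}; for a kernel of size K the window spans
#' offsets \code{-floor((K-1)/2) .. K-1-floor((K-1)/2)} (symmetric for odd K,
#' one extra pixel on the high side for even K).
#'
#' @param weights integer matrix, dimension \code{c(xk_max, yk_max)}; a bare
#'   scalar is accepted for a 1x1 kernel. Signed 8-bit range by default.
#' @param shift_x,shift_y signed center shift in pixels.
#' @return A \code{kernel_spec} object.
#' @export
kernel_spec <- function(weights, shift_x = 0L, shift_y = 0L) {
  if (!is.matrix(weights)) weights <- matrix(weights, nrow = length(weights))
  storage.mode(weights) <- "double"  # canonical storage (exact JSON round-trip)
  if (any(weights != round(weights))) stop("kernel weights must be integers")
  if (any(abs(weights) > 32767)) stop("kernel weight out of range")
  k <- list(weights = weights,
            xk_max = nrow(weights), yk_max = ncol(weights),
            shift_x = as.integer(shift_x), shift_y = as.integer(shift_y))
  # precomputed window offsets relative to the (shifted) center
  k$ox <- seq_len(k$xk_max) - 1L - (k$xk_max - 1L) %/% 2L + k$shift_x
  k$oy <- seq_len(k$yk_max) - 1L - (k$yk_max - 1L) %/% 2L + k$shift_y
  class(k) <- "kernel_spec"
  k
}

#' Event-latency cost model
#'
#' Clock-cycle budget of one event through a node: router-in header check,
#' controller initialisation (address calculation, clipping), the convolution
#' proper at a fixed number of cycles per kernel weight, and router-out.
#' Defaults are the measured figures of the reference FPGA implementation at
#' a 50 MHz clock.
#'
#' @param t_router_in,t_ini,t_router_out fixed components, in clock cycles.
#' @param cycles_per_weight convolution cycles per kernel weight.
#' @param t_clk clock period in seconds (default 20 ns).
#' @return A \code{cost_model} object.
#' @export
cost_model <- function(t_router_in = 6L, t_ini = 37L, cycles_per_weight = 16L,
                       t_router_out = 4L, t_clk = 20e-9) {
  m <- list(t_router_in = t_router_in, t_ini = t_ini,
            cycles_per_weight = cycles_per_weight,
            t_router_out = t_router_out, t_clk = t_clk)
  class(m) <- "cost_model"
  m
}

#' Per-event processing latency
#'
#' \code{T_event = T_router_in + T_ini + cycles_per_weight * xk_max * yk_max
#' + T_router_out} clock cycles. With the defaults a 10x10 kernel costs
#' 1600 cycles of convolution (32 us at 20 ns per cycle).
#'
#' @param kernel a \code{\link{kernel_spec}}.
#' @param model a \code{\link{cost_model}}.
#' @param seconds return seconds instead of cycles.
#' @return Latency in clock cycles (or seconds).
#' @export
event_cost <- function(kernel, model = cost_model(), seconds = FALSE) {
  cyc <- model$t_router_in + model$t_ini +
    model$cycles_per_weight * kernel$xk_max * kernel$yk_max +
    model$t_router_out
  if (seconds) cyc * model$t_clk else cyc
}

#' Convolutional unit configuration
#'
#' Parameters of one event-driven convolutional unit: the integrate-and-fire
#' pixel array, its threshold arithmetic, global leakage, and the rate
#' saturation (refractory) mechanism. Pixel state is unsigned,
#' \code{n_bits} wide, with reset value \code{th}, negative threshold 0 and
#' positive threshold \code{2*th}; capping \code{th} at
#' \code{2^(n_bits-2)} (128 for the default 9 bits) keeps accumulation from
#' wrapping.
#'
#' The rate saturation period \code{t_r} (in ticks) must satisfy
#' \code{2^(b_tr-7) <= t_r <= 2^(b_tr+1)-1} where \code{b_tr} is the most
#' significant bit of \code{t_r} chosen before implementation; \code{t_r = 0}
#' disables the mechanism. \code{t_leak = Inf} disables leakage.
#'
#' @param n_x,n_y pixel array dimensions.
#' @param kernels list of \code{\link{kernel_spec}} (kernel id k selects
#'   \code{kernels[[k+1]]}).
#' @param th threshold, positive integer \code{<= 2^(n_bits-2)}.
#' @param n_bits pixel state register width (default 9).
#' @param t_leak leak period in ticks (\code{Inf} = no leakage).
#' @param n_leak leak amplitude in state units per pulse.
#' @param t_r rate saturation period in ticks (0 = disabled).
#' @param b_tr MSB index of \code{t_r}, \code{7 <= b_tr <= 31}.
#' @param in_addr_space,out_addr_space address spaces \code{c(x, y)} of input
#'   and output events (output defaults to the array size).
#' @param fifo_depth_in,fifo_depth_out FIFO capacities (network engine).
#' @param dt_correction apply the delta-t correction that measures the next
#'   refractory window from the previous allowed-fire time instead of the
#'   actual (delayed) fire time; keeps the saturated output rate at
#'   \code{1/t_r}. Disable only to study the uncorrected behavior.
#' @param cost the \code{\link{cost_model}} used for latency accounting.
#' @param leak_scan_cycles optional per-pixel cycle charge of a leak scan
#'   (default 0: leakage is logically instantaneous).
#' @return A \code{unit_config} object.
#' @export
unit_config <- function(n_x, n_y, kernels, th,
                        n_bits = 9L, t_leak = Inf, n_leak = 1L,
                        t_r = 0, b_tr = 15L,
                        in_addr_space = NULL, out_addr_space = NULL,
                        fifo_depth_in = 64L, fifo_depth_out = 64L,
                        dt_correction = TRUE, cost = cost_model(),
                        leak_scan_cycles = 0L) {
  if (inherits(kernels, "kernel_spec")) kernels <- list(kernels)
  stopifnot(n_x >= 1, n_y >= 1, length(kernels) >= 1)
  if (th < 1 || th != floor(th)) stop("threshold must be a positive integer")
  if (th > 2^(n_bits - 2))
    stop(sprintf("threshold %d exceeds 2^(n_bits-2) = %d: accumulation could wrap",
                 th, 2^(n_bits - 2)))
  if (t_r > 0) {
    if (b_tr < 7 || b_tr > 31) stop("b_tr must be in [7, 31]")
    if (t_r < 2^(b_tr - 7) || t_r > 2^(b_tr + 1) - 1)
      stop(sprintf("t_r must lie in [2^(b_tr-7), 2^(b_tr+1)-1] = [%s, %s]",
                   format(2^(b_tr - 7), scientific = FALSE),
                   format(2^(b_tr + 1) - 1, scientific = FALSE)))
  }
  cfg <- list(n_x = as.integer(n_x), n_y = as.integer(n_y),
              kernels = kernels, th = as.integer(th),
              n_bits = as.integer(n_bits),
              t_leak = unname(t_leak), n_leak = as.integer(n_leak),
              t_r = t_r, b_tr = as.integer(b_tr),
              in_addr_space = if (is.null(in_addr_space))
                c(n_x, n_y) else as.integer(in_addr_space),
              out_addr_space = if (is.null(out_addr_space))
                c(n_x, n_y) else as.integer(out_addr_space),
              fifo_depth_in = as.integer(fifo_depth_in),
              fifo_depth_out = as.integer(fifo_depth_out),
              dt_correction = isTRUE(dt_correction),
              cost = cost,
              leak_scan_cycles = as.integer(leak_scan_cycles))
  class(cfg) <- "unit_config"
  cfg
}

#' Initial state of a convolutional unit
#'
#' All pixels start at the reset value \code{th}; every rate-saturation entry
#' starts cleared (\code{tlim8b = 0}, overflow and delta-t flags down), so the
#' first firing of each pixel is always allowed (except in the degenerate
#' first time quantum, where \code{t8b == 0} cannot exceed a cleared
#' \code{tlim8b}).
#'
#' @param cfg a \code{\link{unit_config}}.
#' @return A \code{conv_unit_state} object.
#' @export
conv_unit_state <- function(cfg) {
  z <- matrix(0, cfg$n_x, cfg$n_y)
  st <- list(pixels = matrix(as.numeric(cfg$th), cfg$n_x, cfg$n_y),
             rs = list(tlim8b = z, f_of = z > 1, f_dt = z > 1),
             leak_pulses = z, refresh_pulses = z,
             counter = 0, fifo_out_occupancy = 0L)
  class(st) <- "conv_unit_state"
  st
}

# 8-bit slice of a tick count: bits b_tr .. b_tr-7 of the wrapped 32-bit counter
t8b_slice <- function(t, b_tr) floor((t %% 2^32) / 2^(b_tr - 7)) %% 256

#' Rate-saturation gate: may this pixel fire now?
#'
#' Hardware-faithful check against the stored 8-bit slice of the pixel's
#' earliest allowed fire time. The 8-bit slice \code{t8b} (bits
#' \code{b_tr..b_tr-7}) of the global counter is compared with the stored
#' \code{tlim8b}; the fire is allowed iff \code{t8b > tlim8b} and the
#' overflow flag is down. A denied attempt raises the pixel's delta-t pending
#' flag (the caller holds the pixel at the crossed threshold).
#'
#' All rate-saturation operations are vectorized over entries: \code{entry}
#' is a list with equal-shaped fields \code{tlim8b}, \code{f_of},
#' \code{f_dt}.
#'
#' @param entry rate-saturation entry (or vector/matrix of entries).
#' @param t global counter value(s) in ticks.
#' @param b_tr MSB index of the rate-saturation period.
#' @return \code{list(allowed = logical, entry = updated entry)}.
#' @export
rate_sat_allow <- function(entry, t, b_tr) {
  t8b <- t8b_slice(t, b_tr)
  allowed <- (t8b > entry$tlim8b) & !entry$f_of
  entry$f_dt <- entry$f_dt | !allowed
  list(allowed = allowed, entry = entry)
}

#' Rate-saturation bookkeeping after an emitted event
#'
#' Called exactly when an output event is emitted at counter value \code{t}.
#' The next allowed fire time is \code{t_lim = t + t_r - dt}, where the
#' delta-t correction \code{dt} is the (8-bit-quantized) delay the previous
#' fire suffered beyond its own \code{t_lim} -- nonzero only when the pending
#' flag was raised. Only the 8-bit slice of the new \code{t_lim} is stored;
#' if the addition carries past bit \code{b_tr} (stored slice numerically
#' below \code{t8b}), the overflow flag is raised.
#'
#' @inheritParams rate_sat_allow
#' @param t_r rate saturation period in ticks.
#' @return The updated entry.
#' @export
rate_sat_update <- function(entry, t, t_r, b_tr) {
  q <- 2^(b_tr - 7)
  t_r <- max(round(t_r / q), 1) * q   # period resolution is the quantum
  t8b <- t8b_slice(t, b_tr)
  dt <- ifelse(entry$f_dt, pmin(pmax((t8b - entry$tlim8b) * q, 0), t_r), 0)
  tlim <- (t %% 2^32) + t_r - dt
  entry$tlim8b <- floor(tlim / q) %% 256
  entry$f_of <- entry$tlim8b < t8b
  entry$f_dt <- entry$f_dt & FALSE
  entry
}

#' Periodic refresh of the rate-saturation memory
#'
#' A refresh pulse fires every time the global counter reaches
#' \code{t_refresh = 2^(b_tr+1) - 1} (all bits \code{b_tr..0} set). For every
#' entry: an overflow flag that is up is lowered (the carry is now absorbed
#' by the counter wrap); otherwise \code{tlim8b} is cleared, marking the
#' refractory window as over. Two consecutive refreshes with no intervening
#' fire always leave an entry fully cleared.
#'
#' @param entry rate-saturation entry (or entries); a full
#'   \code{\link{conv_unit_state}} is also accepted, in which case its whole
#'   rate-saturation memory is refreshed.
#' @return The refreshed entry (or state).
#' @export
rate_sat_refresh <- function(entry) {
  if (inherits(entry, "conv_unit_state")) {
    entry$rs <- rate_sat_refresh(entry$rs)
    return(entry)
  }
  had_of <- entry$f_of
  entry$f_of <- entry$f_of & FALSE
  entry$tlim8b[!had_of] <- 0
  entry
}

# apply n pending refresh pulses elementwise (n capped at 2: refresh is
# idempotent after two passes)
refresh_n <- function(entry, n) {
  two <- n >= 2
  one <- n == 1
  entry$tlim8b[two] <- 0
  entry$f_of[two] <- FALSE
  if (any(one)) {
    had <- entry$f_of & one
    entry$f_of[had] <- FALSE
    entry$tlim8b[one & !had] <- 0
  }
  entry
}

#' Apply one global leakage pulse
#'
#' Moves every pixel \code{n_leak} state units toward the reset value
#' \code{th}, clamping at \code{th} (never crossing it). Repeated application
#' is a contraction: all pixels converge to the reset value.
#'
#' @param state a \code{\link{conv_unit_state}}.
#' @param cfg the \code{\link{unit_config}}.
#' @return The updated state.
#' @export
apply_leakage <- function(state, cfg) {
  state$pixels <- leak_toward(state$pixels, cfg$th, cfg$n_leak)
  state
}

leak_toward <- function(v, th, amount) {
  if (length(amount) != length(v)) amount <- rep_len(amount, length(v))
  up <- v > th
  dn <- v < th
  v[up] <- pmax(v[up] - amount[up], th)
  v[dn] <- pmin(v[dn] + amount[dn], th)
  v
}

# number of leak pulses with pulse time <= t (pulses at t_leak, 2*t_leak, ...)
n_leak_pulses <- function(t, t_leak) if (is.finite(t_leak)) floor(t / t_leak) else 0
# number of refresh pulses in effect at time t. Pulses fire at W-1, 2W-1, ...
# (W = 2^(b_tr+1)) but take effect from the NEXT tick: a threshold attempt in
# the same tick as the pulse still sees the pre-refresh flags, otherwise a
# cleared f_of would let the stale same-window comparison fire early.
n_refresh_pulses <- function(t, b_tr) floor(t / 2^(b_tr + 1))

#' Process one input event through a convolutional unit
#'
#' Implements the controller's per-event sequence: fetch the kernel named by
#' the event's kernel id, locate the pixel window (center shift applied,
#' out-of-array portions clipped, whole-window misses discarded), add the
#' (polarity-signed) kernel weights to the pixel states, and for every pixel
#' that reaches the positive threshold \code{2*th} (or the negative
#' threshold 0) consult the rate-saturation gate: allowed pixels emit an
#' output event (polarity +1 / -1) and reset to \code{th}; denied pixels are
#' held at the crossed threshold with the delta-t pending flag raised.
#' Pending leakage pulses and rate-saturation refreshes up to the event time
#' are applied first (leakage has the highest priority). Multiple output
#' events from one input event are emitted in row-major scan order and all
#' carry the completion timestamp \code{t + cycles} (one tick per clock
#' cycle).
#'
#' @param state a \code{\link{conv_unit_state}}.
#' @param ev a one-row \code{\link{event_stream}} (or list with fields
#'   \code{t, x, y, p, k}).
#' @param cfg the \code{\link{unit_config}}.
#' @return \code{list(state, events, cycles)}: the new state, an
#'   \code{\link{event_stream}} of output events, and the clock cycles
#'   consumed.
#' @export
process_event <- function(state, ev, cfg) {
  stream <- event_stream(ev$t[1], ev$x[1], ev$y[1], ev$p[1],
                         if (is.null(ev$k)) NA else ev$k[1],
                         address_space = cfg$in_addr_space,
                         tick_seconds = cfg$cost$t_clk)
  r <- process_stream(state, stream, cfg)
  list(state = r$state, events = r$events, cycles = r$cycles)
}

# Mutable working representation of a unit: an environment holding the
# state matrices plus precomputed per-kernel offsets and costs. Shared by
# process_stream and the network engine so there is a single implementation
# of the per-event semantics.
unit_env <- function(cfg, state = NULL) {
  if (is.null(state)) state <- conv_unit_state(cfg)
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  e$pixels <- state$pixels
  e$tlim8b <- state$rs$tlim8b
  e$f_of <- state$rs$f_of
  e$f_dt <- state$rs$f_dt
  e$leak_p <- state$leak_pulses
  e$refr_p <- state$refresh_pulses
  e$counter <- state$counter
  e$kcost <- vapply(cfg$kernels, event_cost, numeric(1), model = cfg$cost)
  e$cost_discard <- cfg$cost$t_router_in + cfg$cost$t_ini
  e$reg_max <- 2^cfg$n_bits - 1
  e$th2 <- 2 * cfg$th
  e$q <- 2^(cfg$b_tr - 7)
  e$t_r_q <- max(round(cfg$t_r / e$q), 1) * e$q  # period resolution = quantum
  e$window <- 2^(cfg$b_tr + 1)
  cap <- 256L
  e$out_t <- numeric(cap); e$out_x <- integer(cap)
  e$out_y <- integer(cap); e$out_p <- integer(cap)
  e$n_out <- 0L
  e$cycles <- 0
  e$n_disc <- 0L
  e
}

# One input event through the unit held in env `e` at counter time t.
# Appends any output events (row-major scan order, stamped t + T_event) to
# the env's output buffers and returns their count.
unit_step <- function(e, t, x, y, p, k) {
  cfg <- e$cfg
  if (is.na(k)) k <- 0L
  if (k < 0L || k >= length(cfg$kernels))
    stop(sprintf("unknown kernel id %d (unit has %d kernels)",
                 k, length(cfg$kernels)))
  kern <- cfg$kernels[[k + 1L]]
  n_x <- cfg$n_x; n_y <- cfg$n_y
  xw <- x + kern$ox
  yw <- y + kern$oy
  vx <- xw >= 0L & xw < n_x
  vy <- yw >= 0L & yw < n_y
  if (!any(vx) || !any(vy)) {        # whole window misses the array
    e$n_disc <- e$n_disc + 1L
    e$cycles <- e$cycles + e$cost_discard
    e$counter <- t
    return(0L)
  }
  cost <- e$kcost[k + 1L]
  e$cycles <- e$cycles + cost
  th <- cfg$th; th2 <- e$th2
  xi <- xw[vx] + 1L
  yi <- yw[vy] + 1L
  block <- e$pixels[xi, yi, drop = FALSE]
  if (is.finite(cfg$t_leak)) {       # lazy leakage sync for the window
    np <- floor(t / cfg$t_leak)
    d <- np - e$leak_p[xi, yi, drop = FALSE]
    if (any(d > 0)) block <- leak_toward(block, th, d * cfg$n_leak)
    e$leak_p[xi, yi] <- np
  }
  block <- block + p * kern$weights[vx, vy, drop = FALSE]
  pos <- block >= th2
  neg <- block <= 0
  cand <- pos | neg
  n_emit <- 0L
  if (any(cand)) {
    ci <- which(cand)
    cx <- xi[(ci - 1L) %% length(xi) + 1L]
    cy <- yi[(ci - 1L) %/% length(xi) + 1L]
    li <- (cy - 1L) * n_x + cx       # linear indices into full matrices
    if (cfg$t_r > 0) {
      nr <- floor(t / e$window)        # lazy refresh sync for candidates
      dr <- nr - e$refr_p[li]
      if (any(dr > 0)) {
        en <- refresh_n(list(tlim8b = e$tlim8b[li], f_of = e$f_of[li]), dr)
        e$tlim8b[li] <- en$tlim8b
        e$f_of[li] <- en$f_of
        e$refr_p[li] <- nr
      }
      t8b <- t8b_slice(t, cfg$b_tr)
      allowed <- (t8b > e$tlim8b[li]) & !e$f_of[li]
      if (!all(allowed)) {
        den <- li[!allowed]
        e$f_dt[den] <- TRUE
        block[ci[!allowed]] <- ifelse(pos[ci[!allowed]], th2, 0)
      }
      if (any(allowed)) {
        fi <- li[allowed]
        dt <- if (cfg$dt_correction)
          ifelse(e$f_dt[fi], pmin(pmax((t8b - e$tlim8b[fi]) * e$q, 0),
                                  e$t_r_q), 0)
        else 0
        tl8 <- floor(((t %% 2^32) + e$t_r_q - dt) / e$q) %% 256
        e$tlim8b[fi] <- tl8
        e$f_of[fi] <- tl8 < t8b
        e$f_dt[fi] <- FALSE
        block[ci[allowed]] <- th
      }
    } else {
      allowed <- rep(TRUE, length(ci))
      block[ci] <- th
    }
    n_emit <- sum(allowed)
    if (n_emit) {
      ex <- cx[allowed] - 1L
      ey <- cy[allowed] - 1L
      ep <- ifelse(pos[ci[allowed]], 1L, -1L)
      o <- order(ey, ex)             # row-major scan order
      if (e$n_out + n_emit > length(e$out_t)) {
        cap <- max(2L * length(e$out_t), e$n_out + n_emit)
        length(e$out_t) <- cap; length(e$out_x) <- cap
        length(e$out_y) <- cap; length(e$out_p) <- cap
      }
      idx <- e$n_out + seq_len(n_emit)
      e$out_t[idx] <- t + cost
      e$out_x[idx] <- ex[o]
      e$out_y[idx] <- ey[o]
      e$out_p[idx] <- ep[o]
      e$n_out <- e$n_out + n_emit
    }
  }
  block[block < 0] <- 0              # saturating register arithmetic
  block[block > e$reg_max] <- e$reg_max
  e$pixels[xi, yi] <- block
  e$counter <- t
  n_emit
}

# sync every pixel's lazy leakage/refresh bookkeeping to time t_end and
# return an immutable conv_unit_state
unit_sync_state <- function(e, t_end = e$counter) {
  cfg <- e$cfg
  pixels <- e$pixels
  if (is.finite(cfg$t_leak)) {
    np <- floor(t_end / cfg$t_leak)
    d <- np - e$leak_p
    if (any(d > 0)) {
      amt <- d * cfg$n_leak
      up <- d > 0 & pixels > cfg$th
      dn <- d > 0 & pixels < cfg$th
      pixels[up] <- pmax(pixels[up] - amt[up], cfg$th)
      pixels[dn] <- pmin(pixels[dn] + amt[dn], cfg$th)
    }
    e$leak_p[] <- np
    if (cfg$leak_scan_cycles > 0)
      e$cycles <- e$cycles + np * cfg$n_x * cfg$n_y * cfg$leak_scan_cycles
  }
  tlim8b <- e$tlim8b; f_of <- e$f_of
  if (cfg$t_r > 0) {
    nr <- floor(t_end / e$window)
    en <- refresh_n(list(tlim8b = tlim8b, f_of = f_of), nr - e$refr_p)
    tlim8b <- en$tlim8b; f_of <- en$f_of
    e$refr_p[] <- nr
  }
  e$pixels <- pixels
  e$tlim8b <- tlim8b
  e$f_of <- f_of
  st <- list(pixels = pixels,
             rs = list(tlim8b = tlim8b, f_of = f_of, f_dt = e$f_dt),
             leak_pulses = e$leak_p, refresh_pulses = e$refr_p,
             counter = t_end, fifo_out_occupancy = 0L)
  class(st) <- "conv_unit_state"
  st
}

unit_output_stream <- function(e, template) {
  len <- seq_len(e$n_out)
  event_stream(e$out_t[len], e$out_x[len], e$out_y[len], e$out_p[len],
               NA_integer_,
               address_space = e$cfg$out_addr_space,
               tick_seconds = attr(template, "tick_seconds"),
               duration = attr(template, "duration"),
               sort = TRUE)
}

#' Process an event stream through one convolutional unit
#'
#' Sequentially applies \code{\link{process_event}} semantics to a whole
#' (time-sorted) stream in logical time: the unit's global counter follows
#' the event timestamps, leakage pulses and rate-saturation refreshes fire at
#' their counter boundaries, and queueing delay is not modeled (the network
#' engine owns queueing). This is the standalone/characterization mode of the
#' unit. Output events are stamped \code{t + T_event} with one tick per clock
#' cycle.
#'
#' @param state a \code{\link{conv_unit_state}}.
#' @param stream an \code{\link{event_stream}} of unit-input events; events
#'   without a kernel id use kernel 0.
#' @param cfg the \code{\link{unit_config}}.
#' @return \code{list(state, events, cycles, n_in, n_discarded)}: final state
#'   (leak/refresh synced to the last timestamp), output
#'   \code{\link{event_stream}}, total clock cycles, events offered, events
#'   whose whole window missed the array.
#' @export
process_stream <- function(state, stream, cfg) {
  e <- unit_env(cfg, state)
  ts <- stream$t; xs <- stream$x; ys <- stream$y
  ps <- stream$p; ks <- stream$k
  n <- length(ts)
  for (i in seq_len(n))
    unit_step(e, ts[i], xs[i], ys[i], ps[i], ks[i])
  st <- unit_sync_state(e, if (n) ts[n] else state$counter)
  list(state = st, events = unit_output_stream(e, stream),
       cycles = e$cycles, n_in = n, n_discarded = e$n_disc)
}
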