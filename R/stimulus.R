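# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Single-address spike train with normally distributed inter-spike intervals
#'
#' The characterization stimulus for a convolutional node: a train of events
#' at one fixed address whose inter-spike intervals are drawn from
#' Normal(mean = 1/f_in, sd = std_frac/f_in); non-positive draws are
#' resampled. Timestamps are the cumulative sums, quantized to ticks.
#'
#' @param f_in mean input frequency in Hz (> 0).
#' @param duration train duration in seconds.
#' @param std_frac ISI standard deviation as a fraction of the mean
#'   (default 0.10; 0 gives a perfectly periodic train).
#' @param address \code{c(x, y)} of the driven pixel (0-based).
#' @param p polarity of every event.
#' @param seed integer seed (\code{NULL}: use the current RNG stream).
#' @param tick_seconds tick duration (default 1 us -- a prescaled counter;
#'   the hardware tick is configurable precisely because the mapping between
#'   refractory periods and the raw 50 MHz counter is a design choice).
#' @param address_space declared address space of the stream.
#' @return An \code{\link{event_stream}} whose \code{duration} attribute is
#'   the full requested duration in ticks (possibly empty if the duration
#'   admits no event).
#' @export
gen_isi_train <- function(f_in, duration, std_frac = 0.10,
                          address = c(0L, 0L), p = 1L, seed = NULL,
                          tick_seconds = 1e-6,
                          address_space = c(1L, 1L)) {
  stopifnot(f_in > 0, std_frac >= 0, std_frac < 1, duration >= 0)
  mu <- 1 / f_in
  sd <- std_frac / f_in
  with_seed(seed, {
    n_guess <- max(16L, ceiling(duration * f_in * 1.25 + 8 * sqrt(duration * f_in)))
    isi <- numeric(0)
    total <- 0
    while (total < duration) {
      draw <- stats::rnorm(n_guess, mu, sd)
      while (any(draw <= 0)) {
        bad <- draw <= 0
        draw[bad] <- stats::rnorm(sum(bad), mu, sd)
      }
      isi <- c(isi, draw)
      total <- sum(isi)
    }
    t_sec <- cumsum(isi)
    t_sec <- t_sec[t_sec <= duration]
    ticks <- round(t_sec / tick_seconds)
    event_stream(ticks, rep(address[1], length(ticks)),
                 rep(address[2], length(ticks)),
                 rep(as.integer(p), length(ticks)), NA_integer_,
                 address_space = address_space,
                 tick_seconds = tick_seconds,
                 duration = round(duration / tick_seconds))
  })
}

#' Poker-symbol bitmap stencils
#'
#' Parametric binary masks (nominally 11x11) for the four card symbols,
#' built from half-plane and disc predicates. These are synthetic stand-ins
#' used by the moving-symbol DVS emulator; they are not derived from any
#' recorded footage.
#'
#' @param symbol one of \code{"club", "diamond", "heart", "spade"}.
#' @param size odd mask size (default 11).
#' @return A logical matrix \code{mask[x, y]} (y increases downward).
#' @export
symbol_mask <- function(symbol = c("club", "diamond", "heart", "spade"),
                        size = 11L) {
  symbol <- match.arg(symbol)
  stopifnot(size >= 5L, size %% 2L == 1L)
  r <- (size - 1) / 2
  g <- expand.grid(x = -r:r, y = -r:r)  # y positive downward
  u <- g$x / r
  v <- g$y / r
  m <- switch(symbol,
    diamond = abs(u) + abs(v) <= 1,
    heart = {
      lobes <- ((u - 0.38)^2 + (v + 0.45)^2 <= 0.17) |
               ((u + 0.38)^2 + (v + 0.45)^2 <= 0.17)
      tip <- (v >= -0.25) & (abs(u) <= 0.95 * (1 - (v + 0.25) / 1.25)) & v <= 1
      lobes | tip
    },
    spade = {
      lobes <- ((u - 0.38)^2 + (v - 0.28)^2 <= 0.15) |
               ((u + 0.38)^2 + (v - 0.28)^2 <= 0.15)
      tip <- (v <= 0.42) & (abs(u) <= 0.95 * (0.42 - v) / 1.35) & v >= -1
      stem <- abs(u) <= 0.16 & v >= 0.2
      lobes | tip | stem
    },
    club = {
      top <- (u^2 + (v + 0.52)^2) <= 0.2
      left <- ((u + 0.45)^2 + (v - 0.1)^2) <= 0.2
      right <- ((u - 0.45)^2 + (v - 0.1)^2) <= 0.2
      stem <- abs(u) <= 0.16 & v >= 0
      top | left | right | stem
    })
  matrix(m, size, size)
}

render_mask <- function(mask, pos, field) {
  occ <- matrix(FALSE, field[1], field[2])
  w <- which(mask, arr.ind = TRUE)
  xs <- pos[1] + w[, 1] - 1L
  ys <- pos[2] + w[, 2] - 1L
  keep <- xs >= 0L & xs < field[1] & ys >= 0L & ys < field[2]
  occ[cbind(xs[keep] + 1L, ys[keep] + 1L)] <- TRUE
  occ
}

#' DVS-like event stream from a symbol moving across a field
#'
#' Emulates a dynamic vision sensor observing a high-contrast symbol: the
#' symbol mask is rendered along a trajectory of displacement steps and a
#' pixel emits an ON event (+1) when its occupancy rises and an OFF event
#' (-1) when it falls (simplified binary-contrast rule -- no photometry, no
#' sensor noise spectra). The initial placement emits the onset ON
#' transient. Optional Gaussian timing jitter is seeded and the stream
#' re-sorted.
#'
#' @param symbol symbol name for \code{\link{symbol_mask}}, or a logical
#'   mask matrix.
#' @param trajectory data frame with columns \code{t, dx, dy}: at tick
#'   \code{t} the symbol moves by \code{(dx, dy)} pixels. Timestamps must be
#'   increasing; positions are clipped at the field border.
#' @param field \code{c(x, y)} field size (default 32x32).
#' @param start \code{c(x, y)} initial top-left position of the mask.
#' @param t0 tick of the onset transient.
#' @param jitter_sd timing jitter s.d. in ticks (0 = none).
#' @param seed integer seed (only used when jitter is enabled).
#' @param tick_seconds tick duration.
#' @return An \code{\link{event_stream}} over the field's address space.
#' @export
gen_moving_symbol <- function(symbol, trajectory, field = c(32L, 32L),
                              start = c(0L, 0L), t0 = 0,
                              jitter_sd = 0, seed = NULL,
                              tick_seconds = 1e-6) {
  mask <- if (is.matrix(symbol)) symbol else symbol_mask(symbol)
  field <- as.integer(field)
  clip <- function(pos) c(min(max(pos[1], -nrow(mask) + 1L), field[1] - 1L),
                          min(max(pos[2], -ncol(mask) + 1L), field[2] - 1L))
  pos <- clip(as.integer(start))
  occ <- render_mask(mask, pos, field)
  on0 <- which(occ, arr.ind = TRUE)
  t <- rep(t0, nrow(on0)); x <- on0[, 1] - 1L; y <- on0[, 2] - 1L
  p <- rep(1L, nrow(on0))
  if (!is.null(trajectory) && nrow(trajectory)) {
    if (is.unsorted(trajectory$t, strictly = TRUE))
      stop("trajectory timestamps must be strictly increasing")
    for (i in seq_len(nrow(trajectory))) {
      pos <- clip(pos + c(trajectory$dx[i], trajectory$dy[i]))
      new <- render_mask(mask, pos, field)
      rise <- which(new & !occ, arr.ind = TRUE)
      fall <- which(!new & occ, arr.ind = TRUE)
      nr <- nrow(rise); nf <- nrow(fall)
      if (nr + nf) {
        t <- c(t, rep(trajectory$t[i], nr + nf))
        x <- c(x, rise[, 1] - 1L, fall[, 1] - 1L)
        y <- c(y, rise[, 2] - 1L, fall[, 2] - 1L)
        p <- c(p, rep(1L, nr), rep(-1L, nf))
      }
      occ <- new
    }
  }
  if (jitter_sd > 0) {
    t <- with_seed(seed, pmax(round(t + stats::rnorm(length(t), 0, jitter_sd)), 0))
  }
  event_stream(t, x, y, p, NA_integer_, address_space = field,
               tick_seconds = tick_seconds, sort = TRUE)
}
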