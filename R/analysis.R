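#' Saturation curve of a single integrate-and-fire pixel
#'
#' Characterizes the rate-saturation mechanism the way the node is
#' characterized on hardware: a unit with a 1x1 kernel of value
#' \code{weight} and threshold \code{th} is driven at one address by an
#' ISI-normal spike train of mean frequency \code{f_in} (sd 10% of the
#' mean), and the output frequency is measured as output count over
#' stimulus duration. Below the boundary \code{th / t_r} the response is
#' linear, \code{f_out = f_in / th}; above it the output saturates at
#' \code{f_sat = 1 / t_r}.
#'
#' @param f_in_grid input frequencies in Hz.
#' @param t_r_values rate saturation periods in seconds (one curve each).
#' @param th pixel threshold (default 10, the characterization setting).
#' @param weight 1x1 kernel value.
#' @param duration stimulus duration per measurement, seconds.
#' @param reps repetitions per grid point (mean and sd are reported).
#' @param std_frac ISI sd as a fraction of the mean.
#' @param seed root seed; each (t_r, f_in, rep) derives its own sub-seed.
#' @param tick_seconds tick duration (default 1 us; see
#'   \code{\link{gen_isi_train}}).
#' @return A \code{saturation_curve} data frame with columns
#'   \code{t_r, f_in, f_out_mean, f_out_sd, n_events}.
#' @export
characterize_saturation <- function(f_in_grid, t_r_values, th = 10L,
                                    weight = 1L, duration = 10,
                                    reps = 3L, std_frac = 0.10,
                                    seed = 1L, tick_seconds = 1e-6) {
  rows <- list()
  sub <- 0L
  for (t_r_s in t_r_values) {
    t_r <- round(t_r_s / tick_seconds)
    b_tr <- max(7L, floor(log2(t_r)))
    cfg <- unit_config(1, 1, kernel_spec(weight), th = th,
                       t_r = t_r, b_tr = b_tr)
    for (f_in in f_in_grid) {
      f_out <- numeric(reps)
      nev <- 0
      for (r in seq_len(reps)) {
        sub <- sub + 1L
        train <- gen_isi_train(f_in, duration, std_frac = std_frac,
                               seed = seed * 100003L + sub,
                               tick_seconds = tick_seconds)
        res <- process_stream(conv_unit_state(cfg), train, cfg)
        f_out[r] <- nrow(res$events) / duration
        nev <- nev + nrow(train)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(t_r = t_r_s, f_in = f_in, f_out_mean = mean(f_out),
                   f_out_sd = stats::sd(f_out), n_events = nev)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Classify symbol intervals from output-layer events
#'
#' Implements the decision rule of the recognition experiments: for each
#' stimulus interval, count the positive events emitted by each output
#' neuron; the interval is classified as the neuron with the strict maximum
#' count. Ties and silent intervals are unclassified and counted incorrect.
#'
#' @param output a data frame of output events with columns
#'   \code{t, p, src} (as in \code{\link{simulate_network}}'s SimLog).
#' @param intervals data frame with columns \code{t_start, t_end, label}
#'   (ticks; non-overlapping; an event at \code{t} belongs to
#'   \code{t_start <= t < t_end}).
#' @param neuron_map named character vector mapping source node keys to
#'   class labels, e.g. \code{c("4,1" = "club", ...)}.
#' @return A \code{recognition_result}: \code{list(counts, decisions,
#'   n_correct, rate)} with \code{rate} in percent.
#' @export
classify_symbols <- function(output, intervals, neuron_map) {
  o <- order(intervals$t_start)
  intervals <- intervals[o, ]
  if (nrow(intervals) > 1L &&
      any(intervals$t_start[-1L] < intervals$t_end[-nrow(intervals)]))
    stop("intervals overlap")
  labels <- sort(unique(unname(neuron_map)))
  counts <- matrix(0L, nrow(intervals), length(labels),
                   dimnames = list(NULL, labels))
  pos <- output[output$p == 1L & output$src %in% names(neuron_map), ]
  if (nrow(pos)) {
    lab <- neuron_map[pos$src]
    iv <- findInterval(pos$t, intervals$t_start)
    inside <- iv >= 1L & pos$t < intervals$t_end[pmax(iv, 1L)]
    for (q in which(inside))
      counts[iv[q], lab[q]] <- counts[iv[q], lab[q]] + 1L
  }
  decide <- function(v) {
    m <- max(v)
    if (m == 0L || sum(v == m) > 1L) NA_character_ else labels[which.max(v)]
  }
  decisions <- apply(counts, 1L, decide)
  correct <- !is.na(decisions) & decisions == intervals$label
  res <- list(counts = cbind(intervals[c("t_start", "t_end", "label")],
                             as.data.frame(counts)),
              decisions = decisions,
              n_correct = sum(correct),
              rate = 100 * sum(correct) / nrow(intervals))
  class(res) <- "recognition_result"
  res
}

#' @export
print.recognition_result <- function(x, ...) {
  cat(sprintf("<recognition_result> %d/%d correct (%.1f%%)\n",
              x$n_correct, length(x$decisions), x$rate))
  invisible(x)
}

#' Event-stream statistics
#'
#' Count, duration and mean event rate of a stream, with the rate formatted
#' in eps / Keps / Meps.
#'
#' @param stream an \code{\link{event_stream}} (or data frame with a
#'   \code{t} column and \code{tick_seconds}/\code{duration} attributes).
#' @param duration_s override the stream duration, in seconds.
#' @return \code{list(count, duration_s, rate_eps, rate_label)}.
#' @export
stream_stats <- function(stream, duration_s = NULL) {
  count <- nrow(stream)
  if (is.null(duration_s)) {
    tick <- attr(stream, "tick_seconds")
    dur <- attr(stream, "duration")
    if (is.null(dur)) dur <- if (count) max(stream$t) - min(stream$t) else 0
    duration_s <- dur * (if (is.null(tick)) 1 else tick)
  }
  if (duration_s == 0 && count > 1L)
    stop("zero duration with more than one event")
  rate <- if (duration_s > 0) count / duration_s else 0
  label <- if (rate >= 1e6) sprintf("%.2f Meps", rate / 1e6)
  else if (rate >= 1e3) sprintf("%.0f Keps", rate / 1e3)
  else sprintf("%.2f eps", rate)
  list(count = count, duration_s = duration_s, rate_eps = rate,
       rate_label = label)
}

#' Energy per classification and classifications per joule
#'
#' @param power_w mean power draw in watts (> 0).
#' @param t_symbol_s time each symbol is presented, in seconds (> 0).
#' @return \code{list(energy_j, per_joule)} with
#'   \code{energy_j = power_w * t_symbol_s} and
#'   \code{per_joule = 1 / energy_j} (their product is exactly 1).
#' @export
energy_metrics <- function(power_w, t_symbol_s) {
  if (power_w <= 0 || t_symbol_s <= 0)
    stop("power and symbol time must be positive")
  e <- power_w * t_symbol_s
  list(energy_j = e, per_joule = 1 / e)
}
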