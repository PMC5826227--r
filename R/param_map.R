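#' Per-layer network parameters
#'
#' The frame-domain parameter set of a multi-layer net, one row per
#' convolutional layer: threshold \code{th} (state units), leakage rate
#' \code{lr} (threshold units per second -- the ratio between the threshold
#' and the time leakage would take to pull it to the reset value), and rate
#' saturation period \code{t_r} (seconds; 0 = none).
#'
#' @param layer layer names.
#' @param th thresholds (> 0; fractional values allowed before scaling).
#' @param lr leakage rates in 1/s.
#' @param t_r rate saturation periods in seconds.
#' @return A \code{layer_params} data frame.
#' @export
layer_params <- function(layer, th, lr, t_r = 0) {
  if (any(th <= 0)) stop("thresholds must be positive")
  if (any(t_r < 0)) stop("rate saturation periods must be non-negative")
  p <- data.frame(layer = as.character(layer), th = as.numeric(th),
                  lr = as.numeric(lr), t_r = rep_len(as.numeric(t_r),
                                                     length(layer)))
  class(p) <- c("layer_params", "data.frame")
  p
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Stage-one parameter mapping: scale to the hardware threshold
#'
#' Deterministic first stage of the frame-to-event mapping: every layer's
#' threshold is scaled up to the hardware maximum (default 128 with 9-bit
#' state registers), its kernel weights are multiplied by the same factor and
#' rounded to the nearest integer (ties away from zero), and its leakage
#' rate -- defined relative to the threshold -- is scaled by the same factor.
#' Rate saturation periods are time constants and are unchanged. In the
#' noiseless linear regime the threshold-crossings-per-second of each layer
#' (kernel x rate / threshold) are preserved up to weight rounding.
#'
#' @param src a \code{\link{layer_params}} object.
#' @param target_th hardware threshold to scale to (integer, default 128).
#' @param kernels optional named list (by layer) of lists of
#'   \code{\link{kernel_spec}}s to scale alongside.
#' @return \code{list(params, kernels, factors)}: the scaled
#'   \code{layer_params} (idempotent once \code{th == target_th}), the
#'   scaled kernels (or \code{NULL}) and the per-layer scale factors.
#' @export
scale_parameters <- function(src, target_th = 128L, kernels = NULL) {
  if (any(src$th <= 0)) stop("thresholds must be positive")
  factors <- target_th / src$th
  out <- src
  out$th <- rep(as.numeric(target_th), nrow(src))
  out$lr <- src$lr * factors
  if (!is.null(kernels)) {
    nms <- names(kernels)
    if (is.null(nms) || !all(nms %in% src$layer))
      stop("kernels must be a list named by layer")
    kernels <- lapply(seq_along(kernels), function(i) {
      f <- factors[match(nms[i], src$layer)]
      lapply(kernels[[i]], function(k)
        kernel_spec(round_half_away(k$weights * f), k$shift_x, k$shift_y))
    })
    names(kernels) <- nms
  }
  list(params = out, kernels = kernels, factors = factors)
}

#' Leak pulse schedule realizing a leakage rate
#'
#' Picks \code{(n_leak, t_leak)} so that \code{n_leak / (t_leak * tick)}
#' approximates a leakage rate given in state units per second, with
#' \code{n_leak = 1} (the finest pulse granularity).
#'
#' @param lr leakage rate, state units per second.
#' @param tick_seconds tick duration.
#' @param n_leak pulse amplitude.
#' @return \code{list(n_leak, t_leak)} with \code{t_leak} in ticks
#'   (\code{Inf} when \code{lr} is 0).
#' @export
leak_schedule <- function(lr, tick_seconds, n_leak = 1L) {
  if (lr <= 0) return(list(n_leak = n_leak, t_leak = Inf))
  list(n_leak = n_leak,
       t_leak = max(1, round(n_leak / (lr * tick_seconds))))
}

#' Stage-two parameter mapping: simulated-annealing fine-tuner
#'
#' Generic seeded simulated annealing over a \code{\link{layer_params}} set,
#' maximizing a user objective evaluated by simulator runs. Proposals are
#' Gaussian on the log scale for the time constants (\code{t_r}, \code{lr})
#' and integer random-walk steps on the thresholds; acceptance follows the
#' Metropolis rule \code{exp(delta_score / temperature)} with geometric
#' cooling. The best-seen parameters are returned. This tuner makes no claim
#' of reproducing any published optimized parameter set: those depended on
#' hardware-in-the-loop evaluation with an unavailable recording.
#'
#' @param initial a \code{\link{layer_params}} object.
#' @param objective function \code{layer_params -> numeric score} (higher is
#'   better). Non-finite scores reject the proposal (and are counted).
#' @param schedule \code{list(t0, cooling, iters)}: initial temperature,
#'   geometric cooling factor per iteration, iteration count.
#' @param seed integer seed for the proposal stream.
#' @param sigma_time log-scale proposal s.d. for time constants.
#' @param th_step maximum threshold step per proposal.
#' @param th_max upper bound for thresholds (hardware cap).
#' @return \code{list(params, score, accepted, rejected_nonfinite, trace)}.
#' @export
anneal_parameters <- function(initial, objective,
                              schedule = list(t0 = 1, cooling = 0.97,
                                              iters = 100L),
                              seed = 1L, sigma_time = 0.2, th_step = 8L,
                              th_max = 128L) {
  with_seed(seed, {
    cur <- initial
    cur_score <- objective(cur)
    if (!is.finite(cur_score)) stop("objective is non-finite at the initial point")
    best <- cur; best_score <- cur_score
    temp <- schedule$t0
    acc <- 0L; rej_nf <- 0L
    trace <- numeric(schedule$iters)
    for (it in seq_len(schedule$iters)) {
      prop <- cur
      nl <- nrow(prop)
      prop$t_r <- ifelse(prop$t_r > 0,
                         prop$t_r * exp(stats::rnorm(nl, 0, sigma_time)),
                         prop$t_r)
      prop$lr <- pmax(prop$lr * exp(stats::rnorm(nl, 0, sigma_time)), 1e-12)
      step <- sample(seq(-th_step, th_step), nl, replace = TRUE)
      prop$th <- pmin(pmax(prop$th + step, 1), th_max)
      s <- objective(prop)
      if (!is.finite(s)) {
        rej_nf <- rej_nf + 1L
      } else if (s >= cur_score ||
                 stats::runif(1) < exp((s - cur_score) / temp)) {
        cur <- prop; cur_score <- s; acc <- acc + 1L
        if (s > best_score) { best <- prop; best_score <- s }
      }
      trace[it] <- cur_score
      temp <- temp * schedule$cooling
    }
    list(params = best, score = best_score, accepted = acc,
         rejected_nonfinite = rej_nf, trace = trace)
  })
}

#' Read / write layer parameters as JSON
#'
#' Plain JSON mirroring the parameter-table columns
#' \code{layer, th, lr, t_r}.
#'
#' @param params a \code{\link{layer_params}} object.
#' @param path file path.
#' @return \code{read_layer_params} returns a \code{layer_params};
#'   \code{write_layer_params} returns \code{path} invisibly.
#' @export
write_layer_params <- function(params, path) {
  jsonlite::write_json(as.data.frame(params), path, digits = NA)
  invisible(path)
}

#' @rdname write_layer_params
#' @export
read_layer_params <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  layer_params(d$layer, d$th, d$lr, d$t_r)
}
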