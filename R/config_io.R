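#' Read and write network configurations as JSON
#'
#' Plain-text interchange for \code{\link{network_config}} objects: a JSON
#' document with sections \code{grid}, \code{tick_seconds}, \code{nodes}
#' (each with its unit parameters and kernel blocks), \code{routing},
#' \code{input_targets} and \code{output_sources}. Disabled leakage
#' (\code{t_leak = Inf}) is stored as 0. Round-trips are exact.
#'
#' @param cfg a \code{\link{network_config}}.
#' @param path file path.
#' @return \code{read_network_config} returns a \code{network_config};
#'   \code{write_network_config} returns \code{path} invisibly.
#' @export
write_network_config <- function(cfg, path) {
  node_json <- lapply(names(cfg$nodes), function(key) {
    cr <- as.integer(strsplit(key, ",")[[1]])
    nd <- cfg$nodes[[key]]
    if (!inherits(nd, "unit_config"))
      return(list(col = cr[1], row = cr[2], type = "router"))
    list(col = cr[1], row = cr[2], type = "conv",
         n_x = nd$n_x, n_y = nd$n_y, th = nd$th, n_bits = nd$n_bits,
         t_leak = if (is.finite(nd$t_leak)) nd$t_leak else 0,
         n_leak = nd$n_leak, t_r = nd$t_r, b_tr = nd$b_tr,
         in_addr_space = nd$in_addr_space,
         out_addr_space = nd$out_addr_space,
         fifo_depth_in = nd$fifo_depth_in,
         fifo_depth_out = nd$fifo_depth_out,
         dt_correction = nd$dt_correction,
         kernels = lapply(nd$kernels, function(k)
           list(shift_x = k$shift_x, shift_y = k$shift_y,
                weights = k$weights)))
  })
  routing_json <- lapply(names(cfg$routing), function(key) {
    cr <- as.integer(strsplit(key, ",")[[1]])
    list(col = cr[1], row = cr[2],
         dest = as.data.frame(cfg$routing[[key]]))
  })
  doc <- list(grid = cfg$grid_shape, tick_seconds = cfg$tick_seconds,
              nodes = node_json, routing = routing_json,
              input_targets = as.data.frame(cfg$input_targets),
              output_sources = cfg$output_sources)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- list()
  for (nd in doc$nodes) {
    key <- addr_key(nd$col, nd$row)
    if (identical(nd$type, "router")) {
      nodes[[key]] <- "router"
      next
    }
    kernels <- lapply(nd$kernels, function(k) {
      w <- do.call(rbind, lapply(k$weights, unlist))
      kernel_spec(w, k$shift_x, k$shift_y)
    })
    nodes[[key]] <- unit_config(
      nd$n_x, nd$n_y, kernels, th = nd$th, n_bits = nd$n_bits,
      t_leak = if (nd$t_leak == 0) Inf else nd$t_leak,
      n_leak = nd$n_leak, t_r = nd$t_r, b_tr = nd$b_tr,
      in_addr_space = unlist(nd$in_addr_space),
      out_addr_space = unlist(nd$out_addr_space),
      fifo_depth_in = nd$fifo_depth_in,
      fifo_depth_out = nd$fifo_depth_out,
      dt_correction = isTRUE(nd$dt_correction))
  }
  routing <- list()
  for (rt in doc$routing) {
    d <- rt$dest
    routing[[addr_key(rt$col, rt$row)]] <-
      routing_table(col = vapply(d, `[[`, numeric(1), "col"),
                    row = vapply(d, `[[`, numeric(1), "row"),
                    k = vapply(d, `[[`, numeric(1), "k"),
                    subsample = vapply(d, function(e)
                      isTRUE(e$subsample), logical(1)))
  }
  it <- doc$input_targets
  os <- doc$output_sources
  network_config(
    grid_shape = unlist(doc$grid),
    nodes = nodes, routing = routing,
    input_targets = routing_table(
      col = vapply(it, `[[`, numeric(1), "col"),
      row = vapply(it, `[[`, numeric(1), "row"),
      k = vapply(it, `[[`, numeric(1), "k"),
      subsample = vapply(it, function(e) isTRUE(e$subsample), logical(1))),
    output_sources = data.frame(
      col = vapply(os, `[[`, numeric(1), "col"),
      row = vapply(os, `[[`, numeric(1), "row")),
    tick_seconds = doc$tick_seconds)
}
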