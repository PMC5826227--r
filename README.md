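# evconvnet

Discrete-event simulation of modular **event-driven convolutional
networks** for neuromorphic vision — the class of architectures that
process address-event representation (AER) spike streams from dynamic
vision sensors (DVS) on FPGAs, rather than frames on CPUs/GPUs.

The package is written for researchers who want to study, configure or
extend such hardware architectures in software: it reproduces the
behavior of a configurable convolutional node (integrate-and-fire pixel
array with multi-kernel convolution, global leakage, and a
hardware-faithful 8-bit *rate-saturation* mechanism emulating the neural
refractory period), the destination-driven 2D mesh routing that assembles
nodes into multi-layer ConvNets, the traffic-control scheme that drops
input events under congestion while preserving spatio-temporal
correlation, and the two-stage mapping of frame-trained parameters onto
the event-driven hardware.

## The model in brief

Each unit holds an `n_x x n_y` array of I&F pixels with reset value `Th`,
thresholds `0` and `2*Th`. An input event `(t, x, y, p, k)` adds the
`p`-signed weights of kernel `k` around `(x + shift_x, y + shift_y)`;
pixels reaching a threshold emit an output event and reset — unless the
pixel is inside its refractory window `T_R`, in which case it is held at
threshold and the event leaves with the first input after the window,
the delay compensated in the next window (`t_lim = t0 + T_R - dt`) so the
saturated output rate is exactly `1/T_R`. The hardware stores only 8 bits
of `t_lim` (bits `b_TR .. b_TR-7`) plus an overflow flag maintained by a
periodic refresh; the simulator reproduces that register behavior
bit-exactly. Per-event latency follows
`T_event = 6 + 37 + 16*size_kernel + 4` clock cycles (20 ns each).

A single pixel with a unity 1x1 kernel and `Th = 10` therefore responds
linearly, `f_out = f_in/10`, up to the boundary `Th/T_R`, and saturates at
`f_sat = 1/T_R` beyond it — e.g. 19.53 Hz for `T_R = 51.2 ms`.

## Worked example: characterizing the refractory mechanism

```r
library(evconvnet)

curve <- characterize_saturation(f_in_grid = c(100, 500, 2000),
                                 t_r_values = 51.2e-3, th = 10,
                                 duration = 10, reps = 3, seed = 1)
print(curve, digits = 4)
#>      t_r f_in f_out_mean f_out_sd n_events
#> 1 0.0512  100      9.967  0.05774     3003
#> 2 0.0512  500     19.500  0.00000    14986
#> 3 0.0512 2000     19.600  0.00000    60021
```

At 100 Hz the pixel is linear (`f_out = f_in/10 ~ 10 Hz`); at 500 Hz and
2 kHz — both above the 195.3 Hz boundary — the output pins to
`1/51.2 ms = 19.53 Hz` regardless of drive. The same numbers are
available from the command line:

```sh
inst/exec/evconvnet characterize-refractory --tr 0.0512 \
    --fin-grid 100,500,2000 --duration 10 --reps 3 --seed 1 --out curve.csv
```

The bundled 22-node poker-symbol network (6x4 mesh, 4 convolutional
layers, synthetic stand-in weights — the trained ones were never
published) reports its architecture:

```sh
inst/exec/evconvnet count-arch --config poker
#> neurons=5116
#> synapses=531232
#> kernels=94
#> conv_nodes=22
```

and runs end to end on a synthetic moving-symbol DVS stimulus:

```r
cfg  <- poker_network()
stim <- gen_moving_symbol("club", data.frame(t = (1:30) * 50000,
                                             dx = 1, dy = 0),
                          start = c(2, 10), tick_seconds = 20e-9)
simulate_network(build_network(cfg), stim)
#> <sim_log> offered 538 | processed 302 | dropped 236 | output events 12
```

The drop count is the traffic-control mechanism at work: offered input
events are discarded (never delayed) while any node's FIFO chain is
saturated, and the processed subset keeps its original timestamps. Energy
bookkeeping follows the same arithmetic as the hardware evaluation:

```r
energy_metrics(7.7e-3, 25e-3)
#> $energy_j   192.5e-6        # 192.5 uJ per classification
#> $per_joule  5194.805        # classifications per joule
```

## Package layout

| module | contents |
|---|---|
| `R/events.R` | AER streams, CSV/AEDAT I/O, slow-down scaling |
| `R/conv_unit.R` | kernels, cost model, I&F unit, leakage, rate saturation |
| `R/router.R` | mesh addresses, routing tables, dimension-order forwarding |
| `R/network.R` | network assembly, discrete-event engine, traffic control |
| `R/poker.R`, `R/config_io.R` | bundled 22-node fixture and JSON configs |
| `R/param_map.R` | frame-to-event scaling and simulated-annealing tuner |
| `R/stimulus.R` | ISI trains and moving-symbol DVS emulation |
| `R/analysis.R` | saturation curves, classification, stream/energy stats |
| `R/cli.R`, `inst/exec/evconvnet` | command-line interface |

See `vignettes/event-driven-convnet-methods.Rmd` for the model, its
assumptions, numerical choices and known limitations.
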