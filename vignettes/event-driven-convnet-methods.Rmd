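---
title: "Methods: event-driven convolution with a hardware rate-saturation mechanism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-driven convolution with a hardware rate-saturation mechanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evconvnet)
```

## The model

`evconvnet` simulates modular event-driven convolutional networks of the
kind implemented on FPGAs for neuromorphic vision. Visual input arrives as
an address-event representation (AER) stream: each spike is a tuple
$(t, x, y, p)$ with a timestamp in clock ticks, a pixel address and a
polarity $p \in \{+1, -1\}$, as produced by a dynamic vision sensor (DVS).

The processing element is a convolutional unit: an $n_x \times n_y$ array
of integrate-and-fire (I&F) pixels with a shared multi-kernel memory. An
input event $(t, x, y, p, k)$ adds the polarity-signed weights of kernel
$k$ to the pixel window centered at $(x + \mathrm{shift}_x,
y + \mathrm{shift}_y)$, clipping portions outside the array and discarding
events whose whole window misses it. Pixel state is unsigned fixed-point
(`n_bits`, default 9) with reset value $Th$, negative threshold $0$ and
positive threshold $2\,Th$; a pixel that reaches a threshold emits an
output event of the corresponding polarity and resets to $Th$, subject to
the rate-saturation gate below. A global leakage process moves every pixel
$N_{leak}$ units toward the reset value every $T_{leak}$ ticks, never
crossing it, so quiescent pixels forget.

Units are assembled on a 2D mesh. Each node couples a unit with a
destination-driven router: locally generated events are cloned once per
routing-table destination, each clone carrying the kernel id under which
the destination must process it (this is how a multi-kernel unit knows
which source feature map an event came from), and headers are forwarded
hop-minimally in dimension order (column first). Links flagged as
subsampling right-shift both address coordinates by one bit, folding each
$2 \times 2$ window onto one pixel between layers.

## The rate-saturation (refractory) mechanism

The biological refractory period is emulated by a per-pixel minimum
separation $T_R$ between output spikes. After a fire at $t_0$ the next
allowed fire time is

$$t_{lim} = t_0 + T_R - \Delta t,$$

where $\Delta t$ compensates delayed fires: a pixel that reaches its
threshold before $t_{lim}$ is held at the threshold (flag $f_{\Delta t}$)
and the pending event leaves with the first input event after $t_{lim}$;
the *next* window is then measured from the previous $t_{lim}$ rather than
from the late fire. Under supra-saturation drive this makes the mean output
rate exactly $1/T_R$; without the correction it falls below (both behaviors
are testable via the `dt_correction` switch).

The hardware stores only 8 bits of $t_{lim}$ — bits $b_{TR} \dots
b_{TR}-7$ of the 32-bit global counter, a resolution quantum $q =
2^{b_{TR}-7}$ — plus an overflow flag $f_{of}$ for windows that carry past
bit $b_{TR}$, maintained by a refresh pulse every $2^{b_{TR}+1}-1$ ticks
(lower $f_{of}$ if raised, else clear the slice). `rate_sat_allow`,
`rate_sat_update` and `rate_sat_refresh` implement exactly this register
behavior, vectorized over entries.

Three numerical consequences, verified against a full-resolution oracle
that stores the exact 32-bit $t_{lim}$ (`tests/testthat/test-rate_sat.R`
and the acceptance suite):

* **Period resolution.** Only the 8-bit slice of $t_{lim}$ survives, so the
  effective resolution of $T_R$ is the quantum $q$; `rate_sat_update`
  quantizes $T_R$ internally. With $T_R$ an exact multiple of $q$ (true of
  every period the hardware characterization uses, e.g. $51.2\,$ms
  $= 200\,q$ at $b_{TR} = 15$ with 1 µs ticks) the stored window advances
  by exactly $T_R/q$ quanta per delayed fire and the slice arithmetic
  cannot drift.
* **Refresh ordering.** A refresh pulse takes effect strictly after its
  tick. Applying it in the same tick as a threshold attempt would clear
  $f_{of}$ and let the stale same-window comparison fire up to a whole
  window early; with strict ordering the mechanism never fires more than
  one quantum before the true $t_{lim}$, on every random schedule tested.
* **Information loss at refresh crossings.** When a refresh clears the
  slice of a pixel whose threshold is pending, the mechanism can no longer
  know how far before the window boundary the true $t_{lim}$ lay; its
  $\Delta t$ under-corrects by at most one inter-attempt gap and the
  following fires are late — never early. This conservatism is inherent to
  the 8-bit storage (the hardware has it too) and is negligible when
  inter-spike intervals are small against the refresh period, which is the
  mechanism's stated operating regime. The tests assert strict never-early
  safety everywhere and exact one-quantum agreement outside these
  refresh-crossing streaks and the degenerate first quantum of each window
  (where $t^{8b} = 0$ can never exceed a cleared slice).

## Timing, cost model and the simulation engine

One event through a node costs
$T_{event} = T_{router,in} + T_{ini} + 16 \cdot |kernel| + T_{router,out}$
clock cycles ($6 + 37 + 16\,x_k y_k + 4$ by default; a $10 \times 10$
kernel therefore needs 32 µs of convolution at the 50 MHz reference
clock). Timestamps are integer ticks stored in doubles — R's 32-bit
integers cannot index 100 s at 20 ns — and the 32-bit counter wrap is
applied where the rate-saturation slices are taken. `tick_seconds` is
exposed rather than hard-wired because the mapping between the published
refractory periods and the raw counter (a prescaler) is a configuration
choice; the network engine equates one tick with one clock cycle, while
single-unit characterization conventionally uses 1 µs ticks.

`simulate_network` is a logical-time discrete-event engine, not a
clock-stepped one: each unit serves its input FIFO one event at a time
(service time $T_{event}$), stalls while its output FIFO is full, and the
router moves clones to destination input FIFOs as soon as all of them have
space, with zero transit latency (hop-minimality and event conservation of
the mesh are properties of the router module, tested separately). Ties are
broken in node-index order, so runs are bit-reproducible.

Traffic control drops network-input events — never internal ones — at the
instant they are offered, whenever any node's `full_FIFO` is active.
Because a terminal node draining into the merger can never fill its output
FIFO, the published single-node congestion behavior can only arise from
input-side backpressure, so the engine also drops when an entry node's
input FIFO is full; this is the same principle (drop at the boundary, do
not delay) applied at the first queue of the chain. Accepted events keep
their source timestamps, preserving the spatio-temporal correlation of the
processed subset; unit outputs are stamped with their completion time.
When one processed event emits more outputs than the output FIFO's
remaining capacity, the queue transiently overshoots (the hardware would
stall mid-kernel; the simulator keeps whole-event atomicity) and
`full_FIFO` stays active until it drains.

## Parameter mapping

Frame-trained networks are mapped in two stages. Stage one is
deterministic: all thresholds scale to the hardware maximum ($Th = 128$
with 9-bit state, the cap that prevents accumulator wrap), kernel weights
scale proportionally and round to integers (ties away from zero), leakage
rates — defined as threshold units per second — scale with the threshold,
and rate-saturation periods are untouched. Applied to the published
frame-domain parameters this reproduces the published hardware-scaled rates
to within 0.3% (the residual is the unpublished weight rounding). Stage two
is a generic seeded simulated-annealing tuner (`anneal_parameters`):
log-scale Gaussian proposals on time constants, integer steps on
thresholds, Metropolis acceptance with geometric cooling. It makes no claim
of reproducing the published optimized row: that optimization ran against
FPGA hardware in the loop with a recording that is not redistributable.

## Synthetic stimuli and what a green test establishes

`gen_isi_train` reproduces the node-characterization stimulus: one address,
inter-spike intervals $\mathcal{N}(1/f_{in}, (0.1/f_{in})^2)$ with
non-positive draws resampled, quantized to ticks. `gen_moving_symbol` is a
deliberately simple DVS stand-in: a binary suit stencil translated across a
$32 \times 32$ field, emitting ON/OFF events where pixel occupancy rises or
falls, with optional seeded jitter. It exercises the full network path
(splitter, multi-kernel convolution, subsampling links, merger,
classification bookkeeping) deterministically. It does not model DVS
photometry — log-intensity thresholds, latency jitter, noise spectra — nor
the recorded 40-card stimulus, and the bundled network carries synthetic
stand-in weights (oriented Gabor-like filters in the first layer, fixed
integer patterns elsewhere; the trained weights were never published). A
green end-to-end test therefore establishes correct event-driven dataflow,
counts and timing under the stated model — not recognition performance on
real recordings, which is why the published recognition rates are replaced
by property-based acceptance criteria.

## Numerical choices and degenerate inputs

* Kernel windows of even size place the extra pixel on the high side of
  the shifted center; weights are signed integers.
* Multiple pixels firing from one input event emit in row-major scan
  order, all stamped with the same completion time.
* Pixel arithmetic saturates at the register bounds rather than wrapping.
* Leakage is logically instantaneous at its boundaries (an optional
  per-pixel cycle charge exists for studying scan stalls) and has priority
  over events sharing the same tick; internally both leakage and refresh
  are applied lazily per pixel, which is exact because entries are only
  read at touches — returned states are synchronized to the last
  timestamp.
* An empty stream, an empty routing table (sink node) and a too-short
  stimulus duration are all valid degenerate inputs, not errors; unsorted
  event files are an error unless sorting is requested explicitly.
* Ties in timestamps preserve stream order; engine ties complete in
  node-index order.

## Known limitations

The mesh is simulated at flit-free logical level: per-hop link occupancy
and SERDES behavior are out of scope, so congestion *inside* the mesh is
represented only through FIFO occupancy and backpressure. The classifier
implements the strict-maximum positive-count rule with ties and silence
deliberately unclassified (counted incorrect). The AEDAT dialect is the
plain 6-byte record (16-bit DVS128 address + 32-bit timestamp), without
header extensions, and cannot carry kernel ids.
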