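## Event-anchored relative time.
##
## A trial is described by eight sensor events on a per-trial clock (ms):
## BPR start-button press (defined as 0), LED cue onset, RLS start-button
## release, TCH object touch, MOV object-movement onset, HLD hold onset,
## REW reward, WDR withdrawal. The relative-time grid uses the six epochs
## between the seven events BPR, LED, RLS, TCH, HLD, REW, WDR (MOV is used
## only by the screening epochs, not by the grid) and splits each epoch into
## four equal-duration quartile bins: 24 bins per trial.

GRID_EVENTS <- c("BPR", "LED", "RLS", "TCH", "HLD", "REW", "WDR")
ALL_EVENTS  <- c("BPR", "LED", "RLS", "TCH", "MOV", "HLD", "REW", "WDR")

#' Action-period bin indices
#'
#' The action period runs from start-button release to reward: epochs
#' RLS-TCH, TCH-HLD and HLD-REW, i.e. bins 9 to 20 of the 24-bin grid.
#' @return integer vector `9:20`.
#' @export
action_period_bins <- function() 9:20

validate_events <- function(events, need_mov = FALSE) {
  wanted <- if (need_mov) ALL_EVENTS else GRID_EVENTS
  if (!all(wanted %in% names(events)))
    stop("events must contain named timestamps: ", paste(wanted, collapse = ", "))
  ev <- as.numeric(events[wanted])
  names(ev) <- wanted
  if (abs(ev[["BPR"]]) > 1e-9) stop("BPR must be 0 on the per-trial clock")
  d <- diff(ev)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("event times must be strictly increasing: %s (%g ms) !< %s (%g ms)",
                 wanted[i], ev[i], wanted[i + 1L], ev[i + 1L]))
  }
  ev
}

#' Quartile bin grid for one trial
#'
#' Divides each of the six inter-event epochs into four equal-duration bins,
#' yielding 24 half-open bins `[edge_i, edge_{i+1})` spanning BPR to WDR.
#' MOV is ignored for the grid.
#'
#' @param events named numeric vector of event times in ms (per-trial clock,
#'   `BPR = 0`); must contain at least the seven grid events.
#' @return object of class `bin_grid`: list with `edges` (25 strictly
#'   increasing timestamps), `widths` (24 bin widths, ms) and `epoch_index`
#'   (bin -> epoch 1..6).
#' @examples
#' ev <- c(BPR = 0, LED = 400, RLS = 800, TCH = 1200,
#'         HLD = 1600, REW = 2000, WDR = 2400)
#' quartile_edges(ev)$widths  # all 100 ms
#' @export
quartile_edges <- function(events) {
  ev <- validate_events(events)
  ev <- ev[GRID_EVENTS]
  edges <- numeric(25)
  for (e in 1:6) {
    a <- ev[e]; b <- ev[e + 1L]
    edges[(4 * (e - 1) + 1):(4 * e + 1)] <- seq(a, b, length.out = 5L)
  }
  structure(list(edges = unname(edges),
                 widths = diff(unname(edges)),
                 epoch_index = rep(1:6, each = 4L)),
            class = "bin_grid")
}

#' Per-bin discharge rates
#'
#' Counts spikes per grid bin under the half-open convention (a spike exactly
#' on an interior edge belongs to the bin to its right) and converts to Hz.
#' Spikes outside `[BPR, WDR)` are ignored.
#'
#' @param spike_times numeric vector of spike times (ms, per-trial clock).
#' @param grid a `bin_grid` from [quartile_edges()].
#' @return numeric vector of 24 rates in Hz.
#' @export
bin_rates <- function(spike_times, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- bin_counts(spike_times, grid)
  counts / (grid$widths / 1000)
}

bin_counts <- function(spike_times, grid) {
  counts <- integer(24)
  if (length(spike_times)) {
    idx <- findInterval(spike_times, grid$edges)
    idx <- idx[idx >= 1L & idx <= 24L]
    if (length(idx)) {
      tb <- tabulate(idx, nbins = 24L)
      counts <- tb
    }
  }
  counts
}

#' Screening epoch windows
#'
#' The five epochs used by the mirror-neuron screen: baseline
#' `[LED - 750, LED - 250)`, approach `[RLS, TCH)`, manipulation-I
#' `[TCH, MOV)`, manipulation-II `[MOV, HLD)` and hold `[HLD, HLD + 150)`.
#' If `LED - 750` precedes the trial start the baseline window is truncated
#' at BPR and flagged.
#'
#' @param events named numeric event vector including MOV.
#' @return data.frame with columns `window`, `start`, `end`, `truncated`.
#' @export
epoch_windows <- function(events) {
  ev <- validate_events(events, need_mov = TRUE)
  base_start <- ev[["LED"]] - 750
  truncated <- base_start < ev[["BPR"]]
  if (truncated) base_start <- ev[["BPR"]]
  data.frame(
    window = c("baseline", "approach", "manipulation1", "manipulation2", "hold"),
    start = c(base_start, ev[["RLS"]], ev[["TCH"]], ev[["MOV"]], ev[["HLD"]]),
    end = c(ev[["LED"]] - 250, ev[["TCH"]], ev[["MOV"]], ev[["HLD"]],
            ev[["HLD"]] + 150),
    truncated = c(truncated, FALSE, FALSE, FALSE, FALSE),
    row.names = NULL)
}

#' Per-window discharge rates for the screening epochs
#'
#' @param spike_times numeric spike times (ms).
#' @param windows data.frame from [epoch_windows()].
#' @return numeric vector of rates (Hz), one per window; rates use the actual
#'   covered window duration (relevant for truncated baselines).
#' @export
window_rates <- function(spike_times, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    a <- windows$start[i]; b <- windows$end[i]
    dur <- b - a
    if (dur <= 0) return(0)
    sum(spike_times >= a & spike_times < b) / (dur / 1000)
  }, numeric(1))
}
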