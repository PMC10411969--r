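## Action segments: maximal runs of consecutive action-period bins carrying
## the same code type. Obs-only bins (action coded only when observed)
## count as non-shared; uncoded bins break runs. With 12 action-period bins
## a segment has a start 1..12 and a duration 1..12, giving 78 possible
## segments.

#' Extract maximal action segments from one neuron's bin labels
#'
#' @param bin_labels character vector of 12 labels in
#'   `{"shared", "non_shared", "obs_only", "none"}`, ordered by
#'   action-period bin (1..12 relative coordinates).
#' @param neuron_id id attached to the output rows.
#' @return data.frame with columns `neuron_id`, `code_type`
#'   (`shared`/`non_shared`), `start` (1..12), `duration` (1..12).
#' @examples
#' extract_segments(c("shared", "shared", "non_shared", "none", "obs_only",
#'                    rep("none", 7)))
#' @export
extract_segments <- function(bin_labels, neuron_id = NA_integer_) {
  stopifnot(length(bin_labels) == 12L,
            all(bin_labels %in% c("shared", "non_shared", "obs_only", "none")))
  merged <- ifelse(bin_labels == "obs_only", "non_shared", bin_labels)
  r <- rle(merged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  data.frame(neuron_id = rep(neuron_id, sum(keep)),
             code_type = r$values[keep],
             start = starts[keep],
             duration = r$lengths[keep])
}

#' Segments for a whole label table
#'
#' @param labels a `bin_labels` data.frame (neuron_id, bin, label); bins are
#'   mapped from grid coordinates (9..20) to action-period coordinates
#'   (1..12).
#' @return data.frame of segments across all neurons.
#' @export
population_segments <- function(labels) {
  ap <- action_period_bins()
  out <- lapply(split(labels, labels$neuron_id), function(d) {
    lab <- rep("none", 12L)
    lab[match(d$bin, ap)] <- d$label
    extract_segments(lab, neuron_id = d$neuron_id[1L])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Start x duration segment histogram
#'
#' @param segments data.frame from [extract_segments()] /
#'   [population_segments()].
#' @param normalize if `TRUE`, counts are divided by the total number of
#'   bins of the segment's code type (the sum of its segment durations).
#' @param n_bins number of action-period bins (default 12).
#' @return list per code type with `matrix` (start x duration),
#'   `by_start` and `by_duration` marginals, and `total_bins`.
#' @export
segment_histogram <- function(segments, normalize = FALSE, n_bins = 12L) {
  out <- list()
  for (ct in c("shared", "non_shared")) {
    seg <- segments[segments$code_type == ct, , drop = FALSE]
    m <- matrix(0, n_bins, n_bins,
                dimnames = list(start = seq_len(n_bins),
                                duration = seq_len(n_bins)))
    if (nrow(seg)) {
      for (i in seq_len(nrow(seg)))
        m[seg$start[i], seg$duration[i]] <- m[seg$start[i], seg$duration[i]] + 1
    }
    total_bins <- sum(seg$duration)
    if (normalize && total_bins > 0) m <- m / total_bins
    out[[ct]] <- list(matrix = m,
                      by_start = rowSums(m),
                      by_duration = colSums(m),
                      total_bins = total_bins)
  }
  out
}

#' Number of possible action segments
#'
#' A segment of duration `d` can start at `n_bins - d + 1` positions;
#' summing over durations gives `n_bins * (n_bins + 1) / 2` (78 for 12
#' bins).
#' @param n_bins number of bins (>= 1).
#' @return integer count.
#' @examples
#' n_possible_segments(12)  # 78
#' @export
n_possible_segments <- function(n_bins) {
  stopifnot(n_bins >= 1)
  as.integer(n_bins * (n_bins + 1) / 2)
}
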