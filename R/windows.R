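#' Build a sliding-window grid over a contig
#'
#' Windows are 0-based half-open intervals `[k*step, k*step + size)` for
#' `k = 0, 1, ...` while `k*step < contig_length`; the final window is
#' truncated at the contig end. `step = size` gives a non-overlapping grid.
#'
#' @param contig_length Contig length in bp.
#' @param size Window size in bp (default 10 kb).
#' @param step Step between window starts in bp (default 5 kb); must satisfy
#'   `0 < step <= size`.
#' @param contig Contig label attached to each window.
#' @param ds Optional [hap_data]; when given, a `n_sites` column counts the
#'   retained SNPs inside each window.
#' @return A tibble with columns `contig`, `start`, `end` (0-based
#'   half-open) and optionally `n_sites`.
#' @export
make_windows <- function(contig_length, size = 1e4, step = 5e3,
                         contig = "chr1", ds = NULL) {
  if (size <= 0 || step <= 0) abort("`size` and `step` must be positive")
  if (step > size) abort("`step` must not exceed `size`")
  if (contig_length <= 0) abort("`contig_length` must be positive")
  starts <- step * (seq_len(ceiling(contig_length / step)) - 1)
  starts <- starts[starts < contig_length]
  w <- tibble(contig = contig, start = starts,
              end = pmin(starts + size, contig_length))
  if (!is.null(ds)) w$n_sites <- count_window_sites(ds, w)
  w
}

#' Count retained SNPs per window
#' @param ds A [hap_data] object.
#' @param windows A window tibble from [make_windows()].
#' @return Integer vector, one count per window.
#' @export
count_window_sites <- function(ds, windows) {
  idx <- window_site_range(ds$positions, windows)
  as.integer(pmax(idx$hi - idx$lo + 1L, 0L))
}

# For each window [start, end) (0-based half-open) return the index range
# lo..hi of 1-based positions falling inside (pos - 1 in [start, end), i.e.
# start < pos <= end for integer positions). hi < lo means empty.
window_site_range <- function(positions, windows) {
  lo <- findInterval(windows$start, positions) + 1L
  hi <- findInterval(windows$end, positions)
  list(lo = lo, hi = hi)
}

# Sum a per-site vector over each window via cumulative sums.
window_sums <- function(positions, values, windows) {
  cs <- c(0, cumsum(ifelse(is.na(values), 0, values)))
  idx <- window_site_range(positions, windows)
  cs[idx$hi + 1L] - cs[idx$lo]
}
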