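# All-cycle ED/ES identification from the LV area curve, and per-cycle area
# refinement. ED frames are the prominent maxima of the curve, ES frames the
# prominent minima; the refinement pools percentile-selected areas around
# each raw extreme to suppress isolated segmentation outliers.

#' Peak-detection parameters
#'
#' @param min_distance minimum frame distance (the "horizontal stepsize")
#'   between retained peaks; default 20 frames.
#' @param prominence_fraction peaks must have topographic prominence strictly
#'   greater than this fraction of the curve's global range; default 0.5.
#' @return A `PeakParams`.
#' @export
peak_params <- function(min_distance = 20L, prominence_fraction = 0.5) {
  stop_if(min_distance < 1, "min_distance must be >= 1")
  stop_if(prominence_fraction <= 0 || prominence_fraction >= 1,
          "prominence_fraction must lie in (0, 1)")
  structure(list(min_distance = as.integer(min_distance),
                 prominence_fraction = prominence_fraction),
            class = "PeakParams")
}

# interior local maxima; a plateau contributes its middle index
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) out <- c(out, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# topographic prominence of peak i: height above the higher of the two
# deepest saddles on the way to the nearest higher ground (or signal edge)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    left <- if (i > 1) {
      seg <- x[(i - 1):1]
      higher <- which(seg > x[i])
      min(if (length(higher)) seg[1:higher[1]] else seg)
    } else x[i]
    right <- if (i < length(x)) {
      seg <- x[(i + 1):length(x)]
      higher <- which(seg > x[i])
      min(if (length(higher)) seg[1:higher[1]] else seg)
    } else x[i]
    x[i] - max(left, right)
  }, numeric(1))
}

# prominence-filtered peaks with a minimum mutual distance; taller peaks win
find_peaks <- function(x, params) {
  rng <- max(x) - min(x)
  if (rng == 0) return(integer(0))
  cand <- local_maxima(x)
  if (length(cand) == 0) return(integer(0))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom > params$prominence_fraction * rng]
  if (length(cand) <= 1) return(cand)
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= params$min_distance)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Detect all ED/ES frame pairs from an area curve
#'
#' ED candidates are local maxima of the area curve whose topographic
#' prominence exceeds `prominence_fraction` of the global range
#' (max - min) and which are at least `min_distance` frames apart; ES
#' candidates come from the same rule applied to the negated curve. Each ED
#' is paired with the first ES after it and before the next ED; EDs without
#' such an ES are dropped. A constant curve (or one shorter than
#' `2 * min_distance`) yields an empty cycle set, not an error.
#'
#' @param curve an `AreaCurve`.
#' @param params a [peak_params()].
#' @return A `CycleSet`: list with `pairs` (data.frame of 0-based
#'   `ed_frame`, `es_frame`) and `curve_ref`.
#' @export
detect_ed_es <- function(curve, params = peak_params()) {
  x <- curve$areas
  empty <- function() structure(list(pairs = data.frame(ed_frame = integer(0),
                                                        es_frame = integer(0)),
                                     curve_ref = curve), class = "CycleSet")
  if (length(x) < 2 * params$min_distance) {
    warning("curve shorter than 2 * min_distance; no cycles detected")
    return(empty())
  }
  eds <- find_peaks(x, params)
  ess <- find_peaks(-x, params)
  if (length(eds) == 0 || length(ess) == 0) return(empty())
  pairs <- NULL
  for (k in seq_along(eds)) {
    nxt <- if (k < length(eds)) eds[k + 1] else Inf
    cand <- ess[ess > eds[k] & ess < nxt]
    if (length(cand) > 0) pairs <- rbind(pairs, c(eds[k], cand[1]))
  }
  if (is.null(pairs)) return(empty())
  structure(list(pairs = data.frame(ed_frame = curve$frame_indices[pairs[, 1]],
                                    es_frame = curve$frame_indices[pairs[, 2]]),
                 curve_ref = curve), class = "CycleSet")
}

#' Number of cycles in a CycleSet
#' @param cycles a `CycleSet`.
#' @return integer.
#' @export
n_cycles <- function(cycles) nrow(cycles$pairs)

#' Refined ED/ES areas for one cycle (improved Jeffrey's method)
#'
#' Pools three selections and averages them to the refined ED area of the
#' given cycle: (1) the area at the cycle's raw ED frame; (2) the top
#' `ceiling(fraction * n)` areas of the whole curve (descending); (3) the top
#' `ceiling(fraction * m)` areas among the frames from this cycle's ED to its
#' ES inclusive. The ES area is refined analogously with ascending sorts and
#' the raw ES frame. With `pooling = "pooled"` (default) the refined area is
#' the mean of the pooled multiset; `"three_part"` averages the three parts'
#' means instead. `fraction = 0` degenerates to the raw single-frame areas.
#'
#' @param curve an `AreaCurve`.
#' @param cycles a `CycleSet` on that curve.
#' @param cycle_index 1-based cycle number.
#' @param fraction percentile fraction, default 0.10 (the "top 10%").
#' @param pooling `"pooled"` or `"three_part"`.
#' @return named numeric `c(a_ed =, a_es =)`; errors if the refinement does
#'   not satisfy `a_ed > a_es`.
#' @export
refine_jeffrey <- function(curve, cycles, cycle_index, fraction = 0.10,
                           pooling = c("pooled", "three_part")) {
  pooling <- match.arg(pooling)
  stop_if(cycle_index < 1 || cycle_index > n_cycles(cycles),
          sprintf("cycle_index %s out of range", cycle_index))
  stop_if(fraction < 0 || fraction > 1, "fraction must lie in [0, 1]")
  x <- curve$areas
  i_ed <- match(cycles$pairs$ed_frame[cycle_index], curve$frame_indices)
  i_es <- match(cycles$pairs$es_frame[cycle_index], curve$frame_indices)
  if (fraction == 0) {
    out <- c(a_ed = x[i_ed], a_es = x[i_es])
  } else {
    window <- x[i_ed:i_es]
    n_top <- max(1L, ceiling(fraction * length(x)))
    m_top <- max(1L, ceiling(fraction * length(window)))
    parts_ed <- list(x[i_ed],
                     sort(x, decreasing = TRUE)[seq_len(n_top)],
                     sort(window, decreasing = TRUE)[seq_len(m_top)])
    parts_es <- list(x[i_es],
                     sort(x)[seq_len(n_top)],
                     sort(window)[seq_len(m_top)])
    agg <- function(parts) {
      if (pooling == "pooled") mean(unlist(parts))
      else mean(vapply(parts, mean, numeric(1)))
    }
    out <- c(a_ed = agg(parts_ed), a_es = agg(parts_es))
  }
  stop_if(out["a_ed"] <= out["a_es"],
          sprintf("degenerate cycle %d: refined a_ed <= a_es", cycle_index))
  out
}

#' Baseline percentile ED/ES areas
#'
#' The 90th and 10th percentiles of the whole area curve (linear
#' interpolation between order statistics) serve as the ED and ES areas.
#'
#' @param curve an `AreaCurve`.
#' @param probs percentile pair `(ed, es)`, default `c(0.9, 0.1)`.
#' @return named numeric `c(a_ed =, a_es =)`.
#' @export
baseline_percentile <- function(curve, probs = c(0.9, 0.1)) {
  stop_if(length(curve$areas) == 0, "empty curve")
  q <- quantile(curve$areas, probs, names = FALSE, type = 7)
  c(a_ed = q[1], a_es = q[2])
}

#' Per-cycle refined ED/ES areas
#'
#' Applies the chosen area-refinement method to every cycle.
#'
#' @param curve an `AreaCurve`.
#' @param cycles a `CycleSet`.
#' @param method `"jeffrey"` (default), `"raw"` (single-frame areas) or
#'   `"percentile"` (whole-curve 90th/10th percentiles, identical for all
#'   cycles).
#' @param fraction,pooling passed to [refine_jeffrey()].
#' @return data.frame with one row per cycle: `a_ed`, `a_es`, `method`.
#' @export
refined_areas <- function(curve, cycles, method = c("jeffrey", "raw", "percentile"),
                          fraction = 0.10, pooling = "pooled") {
  method <- match.arg(method)
  k <- n_cycles(cycles)
  if (k == 0) return(data.frame(a_ed = numeric(0), a_es = numeric(0),
                                method = character(0)))
  vals <- switch(method,
    jeffrey = t(vapply(seq_len(k), function(i)
      refine_jeffrey(curve, cycles, i, fraction, pooling), numeric(2))),
    raw = t(vapply(seq_len(k), function(i)
      refine_jeffrey(curve, cycles, i, fraction = 0), numeric(2))),
    percentile = matrix(rep(baseline_percentile(curve), each = k), nrow = k)
  )
  data.frame(a_ed = vals[, 1], a_es = vals[, 2], method = method)
}
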