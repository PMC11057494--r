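# Ground-truthed synthetic echo generator: a pulsating ellipse standing in
# for the LV blood pool, with sinus or AF-like rhythm, speckle texture and an
# outlier injector. Analytic areas/lengths give every downstream stage an
# exact truth to test against.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards; used throughout so that every stochastic component is
#' reproducible without side effects.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rhythm specification for the synthetic heart
#'
#' @param n_cycles number of cardiac cycles (>= 1).
#' @param mean_period mean cycle length in frames (>= 4).
#' @param period_cv coefficient of variation of the cycle length: 0 gives a
#'   regular sinus rhythm, values around 0.2-0.4 an AF-like irregular rhythm.
#'   Cycle lengths are drawn from a log-normal with this CV and clipped at 4
#'   frames.
#' @param seed integer RNG seed for the period draw.
#' @param periods optional explicit cycle lengths in frames (length
#'   `n_cycles`, each >= 4); overrides the log-normal draw.
#' @return A `RhythmSpec`.
#' @export
rhythm_spec <- function(n_cycles, mean_period = 50, period_cv = 0, seed = 1L,
                        periods = NULL) {
  stop_if(n_cycles < 1, "n_cycles must be >= 1")
  stop_if(mean_period < 4, "mean_period must be >= 4 frames")
  stop_if(period_cv < 0, "period_cv must be >= 0")
  if (!is.null(periods)) {
    stop_if(length(periods) != n_cycles, "periods must have length n_cycles")
    stop_if(any(periods < 4), "realised cycle lengths must be >= 4 frames")
    mean_period <- mean(periods)
  }
  structure(list(n_cycles = as.integer(n_cycles), mean_period = mean_period,
                 period_cv = period_cv, seed = as.integer(seed),
                 periods = if (is.null(periods)) NULL else as.integer(periods)),
            class = "RhythmSpec")
}

#' LV shape specification for the synthetic heart
#'
#' @param long_axis_ed,short_axis_ed ellipse axes (full lengths, px) at
#'   end-diastole.
#' @param per_cycle_ef target ejection fraction (percent, strictly in
#'   (0, 100)) per cycle; recycled to `n_cycles` if scalar.
#' @param canvas `(rows, cols)` of the rendered frames.
#' @param centre ellipse centre `(row, col)`; default canvas centre.
#' @param orientation long-axis angle in radians from the column (x) axis.
#' @return An `LVShapeSpec`.
#' @export
lv_shape_spec <- function(long_axis_ed, short_axis_ed, per_cycle_ef,
                          canvas = c(112L, 112L), centre = (canvas - 1) / 2,
                          orientation = 0) {
  stop_if(any(per_cycle_ef <= 0 | per_cycle_ef >= 100),
          "per-cycle EF targets must lie strictly in (0, 100)")
  stop_if(long_axis_ed <= 0 || short_axis_ed <= 0, "axes must be positive")
  structure(list(long_axis_ed = long_axis_ed, short_axis_ed = short_axis_ed,
                 per_cycle_ef = per_cycle_ef, canvas = as.integer(canvas),
                 centre = centre, orientation = orientation),
            class = "LVShapeSpec")
}

# realised cycle lengths in frames; log-normal when period_cv > 0
realise_periods <- function(rhythm) {
  if (!is.null(rhythm$periods)) return(rhythm$periods)
  if (rhythm$period_cv == 0) return(rep(round(rhythm$mean_period), rhythm$n_cycles))
  sdlog <- sqrt(log(1 + rhythm$period_cv^2))
  meanlog <- log(rhythm$mean_period) - sdlog^2 / 2
  with_seed(rhythm$seed,
            pmax(4L, as.integer(round(rlnorm(rhythm$n_cycles, meanlog, sdlog)))))
}

# raised-cosine contraction profile: 1 at cycle start (ED), 0 at the ES phase
# placed 40% into the cycle (systole shorter than diastole)
contraction_profile <- function(u, es_phase = 0.4) {
  ifelse(u <= es_phase,
         (1 + cos(pi * u / es_phase)) / 2,
         (1 - cos(pi * (u - es_phase) / (1 - es_phase))) / 2)
}

#' Per-frame LV axis curves for a synthetic rhythm
#'
#' Within each cycle the axes interpolate from their ED to their ES values by
#' a raised-cosine profile with the ES phase at 40% of the cycle. The ES axes
#' follow from the cycle's EF target by an isotropic shrink `s`: with
#' `L_es = s * L_ed` and `D_es = s * D_ed`, the area-length EF is
#' `1 - (L_es * D_es^2)/(L_ed * D_ed^2) = 1 - s^3`, so `s = (1 - EF/100)^(1/3)`.
#' A lead-in of 45% of the mean period precedes the first ED (the clip opens
#' just after an end-systole), so every true ED is an interior maximum with
#' near-full topographic prominence.
#'
#' @param rhythm a [rhythm_spec()].
#' @param shape an [lv_shape_spec()].
#' @return List with per-frame `long` and `short` axes (px), truth
#'   `ed_frames`/`es_frames` (0-based), `periods`, `per_cycle_ef` and
#'   `overall_ef`.
#' @export
make_axis_curves <- function(rhythm, shape) {
  ef <- rep(shape$per_cycle_ef, length.out = rhythm$n_cycles)
  stop_if(any(ef <= 0 | ef >= 100), "EF targets must lie strictly in (0, 100)")
  periods <- realise_periods(rhythm)
  lead <- as.integer(round(0.45 * rhythm$mean_period))
  starts <- lead + cumsum(c(0L, periods[-length(periods)]))  # 0-based ED frames
  total <- lead + sum(periods)
  t <- seq_len(total) - 1L
  cyc <- findInterval(t, starts)          # 0 during lead-in
  cyc[cyc == 0L] <- 1L                    # lead-in follows cycle 1's profile
  u <- (t - starts[cyc]) / periods[cyc]
  u <- u - floor(u)                       # lead-in wraps to the cycle tail
  g <- contraction_profile(u)
  s <- (1 - ef / 100)^(1 / 3)
  sc <- s[cyc]
  long <- shape$long_axis_ed * (sc + (1 - sc) * g)
  short <- shape$short_axis_ed * (sc + (1 - sc) * g)
  list(long = long, short = short,
       ed_frames = starts,
       es_frames = as.integer(starts + round(0.4 * periods)),
       periods = periods, lead = lead,
       per_cycle_ef = ef, overall_ef = mean(ef))
}

#' Render ellipse masks from axis curves
#'
#' Frame `t`'s mask is the filled ellipse with semi-axes `(long/2, short/2)`
#' rotated by the shape's orientation, using the pixel-centre-inside
#' convention. The analytic area `pi * long * short / 4` is recorded per
#' frame.
#'
#' @param axis_curves output of [make_axis_curves()], or any list with
#'   per-frame `long` and `short` vectors.
#' @param shape an [lv_shape_spec()].
#' @return List with `masks` (logical `(row, col, frame)` array) and
#'   `analytic_area` (px^2 per frame).
#' @export
render_masks <- function(axis_curves, shape) {
  H <- shape$canvas[1]; W <- shape$canvas[2]
  th <- shape$orientation
  a <- axis_curves$long / 2; b <- axis_curves$short / 2
  ext_x <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ext_y <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  bad <- which(shape$centre[2] - ext_x < -0.5 | shape$centre[2] + ext_x > W - 0.5 |
               shape$centre[1] - ext_y < -0.5 | shape$centre[1] + ext_y > H - 0.5)
  stop_if(length(bad) > 0,
          sprintf("ellipse exceeds the canvas at frame %d (0-based)", bad[1] - 1L))
  xs <- matrix(rep(0:(W - 1), each = H), nrow = H)  # x = column index
  ys <- matrix(rep(0:(H - 1), times = W), nrow = H) # y = row index
  dx <- xs - shape$centre[2]; dy <- ys - shape$centre[1]
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  n <- length(a)
  masks <- array(FALSE, dim = c(H, W, n))
  for (i in seq_len(n)) {
    masks[, , i] <- (xr / a[i])^2 + (yr / b[i])^2 <= 1
  }
  list(masks = masks, analytic_area = pi * axis_curves$long * axis_curves$short / 4)
}

# binary dilation by a (2r+1)-square structuring element, via shifted ORs
dilate_square <- function(m, r = 2L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (di in -r:r) for (dj in -r:r) {
    si <- max(1, 1 - di):min(H, H - di)
    sj <- max(1, 1 - dj):min(W, W - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] | m[si, sj]
  }
  out
}

#' Add speckle texture to a mask stack
#'
#' Builds an intensity template per frame — dark blood pool (LV interior),
#' bright endocardial rim, mid-grey surrounding tissue — and applies
#' multiplicative uniform speckle noise. Deterministic for a fixed seed.
#'
#' @param masks logical `(row, col, frame)` array (e.g. from [render_masks()]).
#' @param snr signal-to-noise ratio (> 0); the uniform noise half-width is
#'   `sqrt(3)/snr`, so larger values give cleaner frames.
#' @param seed integer RNG seed.
#' @param levels intensities `c(interior, rim, background)` of the template.
#' @return An [echo_video()].
#' @export
add_speckle <- function(masks, snr = 8, seed = 1L, levels = c(0.10, 0.85, 0.40)) {
  stop_if(snr <= 0, "snr must be > 0")
  d <- min(1, sqrt(3) / snr)
  n <- dim(masks)[3]
  frames <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m <- masks[, , i]
      rim <- dilate_square(m, 2L) & !m
      tmpl <- matrix(levels[3], nrow(m), ncol(m))
      tmpl[m] <- levels[1]
      tmpl[rim] <- levels[2]
      noise <- matrix(runif(length(tmpl), 1 - d, 1 + d), nrow(m), ncol(m))
      pmin(pmax(tmpl * noise, 0), 1)
    })
  })
  echo_video(frames, id = sprintf("synthetic-%d", seed), source = "synthetic")
}

#' Inject outlier frames into an area curve
#'
#' Multiplies the areas of the listed frames by `factor`, leaving the rest
#' unchanged — emulates isolated segmentation failures.
#'
#' @param curve an `AreaCurve` (see [area_curve()]).
#' @param frames 0-based frame indices to corrupt.
#' @param factor positive multiplier (e.g. 0.5 for a dropout, 1.5 for a bleed).
#' @return The corrupted `AreaCurve`.
#' @export
corrupt_curve <- function(curve, frames, factor) {
  stop_if(factor <= 0, "factor must be > 0")
  idx <- match(frames, curve$frame_indices)
  stop_if(anyNA(idx), sprintf("frame index %s out of range",
                              frames[which(is.na(idx))[1]]))
  curve$areas[idx] <- curve$areas[idx] * factor
  curve
}

#' Simulate a complete ground-truthed echo video
#'
#' Convenience wrapper chaining [make_axis_curves()], [render_masks()] and
#' [add_speckle()].
#'
#' @param rhythm a [rhythm_spec()].
#' @param shape an [lv_shape_spec()].
#' @param snr speckle signal-to-noise ratio; `Inf` for a noiseless template.
#' @param seed RNG seed for the speckle.
#' @return A `SyntheticEcho`: list with `video` ([echo_video()]), `masks`
#'   (logical array) and `truth` (per-frame analytic `area` px^2 and
#'   `long_axis` px, `ed_frames`, `es_frames` (0-based), `per_cycle_ef`,
#'   `overall_ef`).
#' @export
simulate_echo <- function(rhythm, shape, snr = 8, seed = rhythm$seed) {
  ax <- make_axis_curves(rhythm, shape)
  rm_ <- render_masks(ax, shape)
  video <- add_speckle(rm_$masks, snr = if (is.finite(snr)) snr else 1e9, seed = seed)
  structure(list(
    video = video, masks = rm_$masks,
    truth = list(area = rm_$analytic_area, long_axis = ax$long,
                 short_axis = ax$short,
                 ed_frames = ax$ed_frames, es_frames = ax$es_frames,
                 periods = ax$periods,
                 per_cycle_ef = ax$per_cycle_ef, overall_ef = ax$overall_ef)
  ), class = "SyntheticEcho")
}
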