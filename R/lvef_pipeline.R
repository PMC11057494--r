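# Quantitative core: single-plane area-length volumes, per-cycle and
# all-cycle ejection fraction, heart-failure phenotype classification,
# end-to-end orchestration and the beat-to-beat visualiser payload.

#' Single-plane area-length LV volume
#'
#' The ellipsoid single-plane (area-length) model: `V = 8 A^2 / (3 pi L)`,
#' with `A` the LV area, `L` the LV length (apex to mid-annulus). For an
#' ideal ellipse of axes `(L, D)` (so `A = pi L D / 4`) this equals the
#' prolate-spheroid volume `pi L D^2 / 6` exactly.
#'
#' @param a LV area (px^2), >= 0; vectorised.
#' @param l LV length (px), > 0.
#' @return volume in px^3 (any consistent unit system works; EF is
#'   dimensionless).
#' @export
volume_area_length <- function(a, l) {
  stop_if(any(l <= 0), "LV length must be positive")
  stop_if(any(a < 0), "LV area must be non-negative")
  8 * a^2 / (3 * pi * l)
}

#' Ejection fraction of one cardiac cycle
#'
#' `EF = (EDV - ESV) / EDV * 100` percent.
#'
#' @param edv end-diastolic volume, > 0.
#' @param esv end-systolic volume.
#' @return EF in percent; vectorised.
#' @export
cycle_ef <- function(edv, esv) {
  stop_if(any(edv <= 0), "EDV must be positive")
  100 * (edv - esv) / edv
}

#' All-cycle mean ejection fraction
#'
#' The final LVEF is the arithmetic mean of the per-cycle EF values over all
#' `N` detected cycles; a single-cycle estimate is the `N = 1` special case.
#'
#' @param cycle_efs numeric vector of per-cycle EF percents, length >= 1.
#' @return mean EF in percent.
#' @export
mean_ef <- function(cycle_efs) {
  stop_if(length(cycle_efs) == 0, "no cycles: cannot average an empty EF list")
  mean(cycle_efs)
}

#' Heart-failure phenotype from LVEF
#'
#' HFrEF for EF < 40, HFmrEF for 40 <= EF < 50, HFpEF for EF >= 50 (both
#' boundaries follow the guideline bands; 40.0 itself is HFmrEF).
#'
#' @param ef LVEF in percent, within \[0, 100\].
#' @return one of `"HFrEF"`, `"HFmrEF"`, `"HFpEF"`.
#' @export
classify_hf <- function(ef) {
  stop_if(any(is.na(ef)) || any(ef < 0 | ef > 100), "EF must lie in [0, 100]")
  ifelse(ef < 40, "HFrEF", ifelse(ef < 50, "HFmrEF", "HFpEF"))
}

# internal constructor keeping the result invariants in one place
new_lvef_result <- function(cycles, mean_ef = NULL, phenotype = NULL,
                            status = "ok") {
  n <- nrow(cycles)
  if (is.null(mean_ef)) mean_ef <- if (n > 0) mean(cycles$ef) else NA_real_
  if (is.null(phenotype))
    phenotype <- if (is.na(mean_ef)) "none" else classify_hf(mean_ef)
  structure(list(cycles = cycles, n_cycles = n, mean_ef = mean_ef,
                 phenotype = phenotype,
                 hfref_flag = !is.na(mean_ef) && mean_ef < 40,
                 status = status),
            class = "LVEFResult")
}

#' @export
print.LVEFResult <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<LVEFResult: %s>\n", x$status)); return(invisible(x))
  }
  cat(sprintf("<LVEFResult: %d cycle(s), per-cycle EF %s%%, mean EF %.2f%% -> %s>\n",
              x$n_cycles, paste(sprintf("%.2f", x$cycles$ef), collapse = "/"),
              x$mean_ef, x$phenotype))
  invisible(x)
}

#' Pipeline configuration
#'
#' @param peaks a [peak_params()].
#' @param area_method per-cycle area source: `"jeffrey"` (default),
#'   `"raw"` or `"percentile"` (see [refined_areas()]).
#' @param jeffrey_fraction,jeffrey_pooling passed to the refinement.
#' @param length_source `"model"` (ensemble prediction from mask features,
#'   the default), `"height"` (the principal-axis height of the mask —
#'   exact for synthetic ellipses), or `"trace"` (measured from an
#'   annotation's axis chord when one is supplied).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(peaks = peak_params(),
                            area_method = c("jeffrey", "raw", "percentile"),
                            jeffrey_fraction = 0.10,
                            jeffrey_pooling = "pooled",
                            length_source = c("model", "height", "trace")) {
  list(peaks = peaks, area_method = match.arg(area_method),
       jeffrey_fraction = jeffrey_fraction, jeffrey_pooling = jeffrey_pooling,
       length_source = match.arg(length_source))
}

#' Run the full LVEF pipeline
#'
#' Segments every frame (or takes precomputed masks), builds the area curve,
#' detects all ED/ES pairs, refines the per-cycle areas, predicts the LV
#' length at each cycle's ED and ES frame, converts to area-length volumes,
#' averages EF over all cycles and classifies the HF phenotype. A video with
#' no detectable cycles yields a result with status `"insufficient cycles"`,
#' not an error.
#'
#' @param input an [echo_video()] (requires `seg_model`) or a logical
#'   `(row, col, frame)` mask array/list (bypasses segmentation).
#' @param seg_model a trained `SegModel`, or `NULL` when masks are given.
#' @param length_model a fitted `LengthModel` (required when
#'   `length_source = "model"`).
#' @param config a [pipeline_config()].
#' @param traces optional list of `TraceAnnotation`s (for
#'   `length_source = "trace"`), indexed by 0-based frame.
#' @return list with `result` (an `LVEFResult`) and `series` (a
#'   `BeatToBeatSeries`, see [build_visualiser()]).
#' @export
run_pipeline <- function(input, seg_model = NULL, length_model = NULL,
                         config = pipeline_config(), traces = NULL) {
  if (inherits(input, "EchoVideo")) {
    stop_if(is.null(seg_model), "a raw video requires a segmentation model")
    masks <- segment_video(seg_model, input)
  } else {
    masks <- input
    if (is.list(masks)) masks <- array(unlist(masks),
                                       dim = c(dim(masks[[1]]), length(masks)))
  }
  curve <- area_curve(masks)
  cycles <- detect_ed_es(curve, config$peaks)
  k <- n_cycles(cycles)
  if (k == 0) {
    result <- new_lvef_result(empty_cycle_frame(), status = "insufficient cycles")
    return(list(result = result, series = build_visualiser(curve, cycles, result)))
  }
  areas <- refined_areas(curve, cycles, method = config$area_method,
                         fraction = config$jeffrey_fraction,
                         pooling = config$jeffrey_pooling)
  frame_length <- function(frame0) {
    mask <- masks[, , match(frame0, curve$frame_indices)]
    switch(config$length_source,
      model = {
        stop_if(is.null(length_model),
                "length_source = 'model' requires a fitted length model")
        predict_length(length_model, extract_features(mask))
      },
      height = extract_features(mask)$height,
      trace = {
        ann <- Filter(function(a) a$frame_index == frame0, traces)
        stop_if(length(ann) == 0,
                sprintf("no trace annotation for frame %d", frame0))
        pts <- ann[[1]]$points
        lv_length(pts[ann[[1]]$axis_pair[1], ], pts[ann[[1]]$axis_pair[2], ])
      })
  }
  l_ed <- vapply(cycles$pairs$ed_frame, frame_length, numeric(1))
  l_es <- vapply(cycles$pairs$es_frame, frame_length, numeric(1))
  edv <- volume_area_length(areas$a_ed, l_ed)
  esv <- volume_area_length(areas$a_es, l_es)
  efs <- cycle_ef(edv, esv)
  cyc <- data.frame(cycle_index = seq_len(k),
                    ed_frame = cycles$pairs$ed_frame,
                    es_frame = cycles$pairs$es_frame,
                    a_ed = areas$a_ed, a_es = areas$a_es,
                    l_ed = l_ed, l_es = l_es,
                    edv = edv, esv = esv, ef = efs)
  result <- new_lvef_result(cyc)
  list(result = result, series = build_visualiser(curve, cycles, result))
}

empty_cycle_frame <- function() {
  data.frame(cycle_index = integer(0), ed_frame = integer(0),
             es_frame = integer(0), a_ed = numeric(0), a_es = numeric(0),
             l_ed = numeric(0), l_es = numeric(0), edv = numeric(0),
             esv = numeric(0), ef = numeric(0))
}

#' Beat-to-beat visualiser payload
#'
#' Assembles the 1-D beat-to-beat view: LV area against frame number with
#' ED/ES markers, one EF label per cycle, and a banner carrying the all-cycle
#' mean EF and HF phenotype (or a "no cycles" notice). Serialisable to JSON.
#'
#' @param curve an `AreaCurve`.
#' @param cycles the `CycleSet` detected on it.
#' @param result the corresponding `LVEFResult`.
#' @return A `BeatToBeatSeries` list.
#' @export
build_visualiser <- function(curve, cycles, result) {
  stop_if(n_cycles(cycles) != result$n_cycles,
          "cycle count mismatch between CycleSet and LVEFResult")
  banner <- if (result$status == "ok")
    sprintf("Mean LVEF %.2f%% over %d cycle(s): %s", result$mean_ef,
            result$n_cycles, result$phenotype)
  else "no cycles detected"
  structure(list(
    frame_indices = curve$frame_indices,
    areas = curve$areas,
    ed_markers = cycles$pairs$ed_frame,
    es_markers = cycles$pairs$es_frame,
    ef_labels = if (result$n_cycles > 0) sprintf("%.2f%%", result$cycles$ef)
                else character(0),
    mean_ef = result$mean_ef,
    phenotype = result$phenotype,
    banner = banner
  ), class = "BeatToBeatSeries")
}

#' Plot a beat-to-beat series
#'
#' @param x a `BeatToBeatSeries`.
#' @param ... passed to `plot()`.
#' @export
plot.BeatToBeatSeries <- function(x, ...) {
  plot(x$frame_indices, x$areas, type = "l", xlab = "frame",
       ylab = expression(LV ~ area ~ (px^2)), main = x$banner, ...)
  if (length(x$ed_markers) > 0) {
    ed_i <- match(x$ed_markers, x$frame_indices)
    es_i <- match(x$es_markers, x$frame_indices)
    graphics::points(x$ed_markers, x$areas[ed_i], pch = 19, col = "firebrick")
    graphics::points(x$es_markers, x$areas[es_i], pch = 19, col = "steelblue")
    graphics::text(x$ed_markers, x$areas[ed_i], x$ef_labels, pos = 3, cex = 0.8)
  }
  invisible(x)
}
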