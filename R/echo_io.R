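#' Construct an EchoVideo
#'
#' An `EchoVideo` is the pipeline's raw input: a stack of grey-scale frames
#' with intensities in \[0, 1\], stored as a numeric array with dimensions
#' `(row, col, frame)`.
#'
#' @param frames numeric array `(row, col, frame)` or a list of matrices of
#'   one shape; intensities in \[0, 1\].
#' @param id character identifier.
#' @param fps frames per second, or `NA` when unknown.
#' @param source free-text provenance tag.
#' @return An object of class `EchoVideo` with fields `id`, `frames`, `fps`,
#'   `source`.
#' @export
echo_video <- function(frames, id = "video", fps = NA_real_, source = "memory") {
  if (is.list(frames)) {
    shp <- dim(frames[[1]])
    stop_if(!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))),
            "all frames must share one (row, col) shape")
    frames <- array(unlist(frames), dim = c(shp, length(frames)))
  }
  stop_if(length(dim(frames)) != 3L, "frames must be a (row, col, frame) array")
  stop_if(dim(frames)[3] < 1L, "an EchoVideo needs at least one frame")
  stop_if(any(!is.finite(frames)) || min(frames) < 0 || max(frames) > 1,
          "frame intensities must be finite and within [0, 1]")
  structure(list(id = id, frames = frames, fps = fps, source = source),
            class = "EchoVideo")
}

#' @export
print.EchoVideo <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<EchoVideo '%s': %d frames of %dx%d, fps=%s>\n",
              x$id, d[3], d[1], d[2],
              if (is.na(x$fps)) "?" else format(x$fps)))
  invisible(x)
}

#' Number of frames in an EchoVideo
#' @param video an [echo_video()].
#' @return integer frame count.
#' @export
n_frames <- function(video) dim(video$frames)[3]

#' Read an echo video from disk
#'
#' Reads a multi-page TIFF frame stack into an [echo_video()]. Intensities
#' are normalised by the sample dtype maximum (255 for 8-bit sources), so all
#' values fall in \[0, 1\]. Colour pages are converted to grey by channel
#' averaging. When `target_size` is given, frames are resized bilinearly and
#' clipped back to \[0, 1\].
#'
#' AVI/MP4 containers require a codec library that is not bundled; convert
#' such loops to multi-page TIFF first (e.g. `ffmpeg -i in.avi out.tiff`).
#'
#' @param path file path to a `.tif`/`.tiff` frame stack.
#' @param target_size optional `(rows, cols)` integer pair, e.g. `c(112, 112)`.
#' @return An [echo_video()].
#' @export
read_video <- function(path, target_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("avi", "mp4", "mov")) {
    stop(sprintf(paste0("cannot decode '%s': compressed video containers (.%s) ",
                        "need an external codec; convert to multi-page TIFF"),
                 path, ext), call. = FALSE)
  }
  stop_if(!ext %in% c("tif", "tiff"),
          sprintf("unsupported video format '.%s' for '%s'", ext, path))
  stop_if(!file.exists(path), sprintf("cannot read video: no such file '%s'", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop(sprintf(
                      "cannot read video '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  stop_if(length(pages) == 0L, sprintf("'%s' contains zero frames", path))
  grey <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p[, , seq_len(min(3L, dim(p)[3])), drop = FALSE],
                                         c(1, 2), mean)
    p
  })
  if (!is.null(target_size)) {
    grey <- lapply(grey, resize_frame, target_size = target_size, mask = FALSE)
  }
  echo_video(grey, id = sub("\\.[^.]*$", "", basename(path)), source = path)
}

# bilinear (intensities) or nearest-neighbour (masks) resize; masks must stay
# binary, so no interpolation is allowed for them
resize_frame <- function(frame, target_size, mask = FALSE) {
  out <- EBImage::resize(frame, w = target_size[1], h = target_size[2],
                         filter = if (mask) "none" else "bilinear")
  out <- matrix(as.numeric(out), nrow = target_size[1])
  if (mask) out else pmin(pmax(out, 0), 1)
}

#' Write a frame stack to a multi-page TIFF
#'
#' @param frames an [echo_video()], a `(row, col, frame)` array in \[0, 1\],
#'   or a logical mask array of the same layout.
#' @param path output path.
#' @param bits bits per sample (8 or 16); 8-bit quantises to 1/255 steps.
#' @return `path`, invisibly.
#' @export
write_video <- function(frames, path, bits = 8L) {
  if (inherits(frames, "EchoVideo")) frames <- frames$frames
  frames <- frames * 1.0
  pages <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read EchoNet-style volume tracings
#'
#' Parses a `VolumeTracings`-dialect CSV (columns `FileName, X1, Y1, X2, Y2,
#' Frame`; one chord per row; the first row of each `(FileName, Frame)` block
#' is the long-axis chord). Chords of a block are assembled into one trace
#' annotation: row *i* contributes points *2i-1* `(X1, Y1)` and *2i*
#' `(X2, Y2)`, so a 21-row block yields 42 coordinates. The long-axis pair is
#' recorded in `axis_pair` (indices 1 and 2 by construction).
#'
#' Coordinates are 0-based `(x = column, y = row)` pixel-centre positions;
#' frame indices are 0-based.
#'
#' @param path CSV path.
#' @param one_based set `TRUE` when the source's `Frame` column is 1-based;
#'   indices are then shifted to the package's 0-based convention.
#' @return Named list mapping video id to a list of `TraceAnnotation` objects
#'   (fields `video_id`, `frame_index`, `points` (n x 2 matrix), `axis_pair`).
#' @export
read_tracings <- function(path, one_based = FALSE) {
  stop_if(!file.exists(path), sprintf("no such tracings file '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("FileName", "X1", "Y1", "X2", "Y2", "Frame")
  missing_cols <- setdiff(need, names(df))
  stop_if(length(missing_cols) > 0,
          sprintf("tracings CSV missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  for (cn in c("X1", "Y1", "X2", "Y2", "Frame")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    stop_if(length(bad) > 0,
            sprintf("non-numeric value in column %s at row %d", cn, bad[1]))
    df[[cn]] <- v
  }
  if (one_based) df$Frame <- df$Frame - 1
  key <- paste(df$FileName, df$Frame, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    blk <- df[key == k, , drop = FALSE]
    pts <- matrix(NA_real_, nrow = 2L * nrow(blk), ncol = 2)
    pts[seq(1, nrow(pts), by = 2), ] <- cbind(blk$X1, blk$Y1)
    pts[seq(2, nrow(pts), by = 2), ] <- cbind(blk$X2, blk$Y2)
    colnames(pts) <- c("x", "y")
    ann <- structure(list(video_id = blk$FileName[1],
                          frame_index = as.integer(blk$Frame[1]),
                          points = pts, axis_pair = c(1L, 2L)),
                     class = "TraceAnnotation")
    vid <- ann$video_id
    out[[vid]] <- c(out[[vid]], list(ann))
  }
  out
}

#' Order a trace annotation's chords as a closed polygon
#'
#' The non-axis chords are parallel cross-sections of the ventricle: walking
#' down one side (`X1, Y1`) and back up the other (`X2, Y2`) yields a simple
#' polygon suitable for [polygon_area()] / [rasterise_polygon()].
#'
#' @param ann a `TraceAnnotation` from [read_tracings()].
#' @return n x 2 matrix of polygon vertices `(x, y)`.
#' @export
trace_polygon <- function(ann) {
  pts <- ann$points
  body <- setdiff(seq_len(nrow(pts)), ann$axis_pair)
  stop_if(length(body) < 4, "trace has too few chord points for a polygon")
  side1 <- pts[body[seq(1, length(body), by = 2)], , drop = FALSE]
  side2 <- pts[body[seq(2, length(body), by = 2)], , drop = FALSE]
  rbind(side1, side2[rev(seq_len(nrow(side2))), , drop = FALSE])
}

#' Read an EchoNet-style label file
#'
#' Parses a `FileList`-dialect CSV carrying reference EF/EDV/ESV labels.
#'
#' @param path CSV with at least `FileName, EF, EDV, ESV` columns; optional
#'   `EDFrame`, `ESFrame` (0-based).
#' @return data.frame with columns `video_id`, `ef_ref`, `edv_ref`, `esv_ref`,
#'   `ed_frame`, `es_frame`.
#' @export
read_labels <- function(path) {
  stop_if(!file.exists(path), sprintf("no such label file '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("FileName", "EF", "EDV", "ESV")
  missing_cols <- setdiff(need, names(df))
  stop_if(length(missing_cols) > 0,
          sprintf("label CSV missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  ef <- suppressWarnings(as.numeric(df$EF))
  bad <- which(is.na(ef) & !is.na(df$EF))
  stop_if(length(bad) > 0, sprintf("non-numeric EF at row %d", bad[1]))
  oob <- which(ef < 0 | ef > 100)
  stop_if(length(oob) > 0,
          sprintf("EF outside [0, 100] at row %d (value %s)", oob[1], ef[oob[1]]))
  data.frame(
    video_id = df$FileName,
    ef_ref   = ef,
    edv_ref  = suppressWarnings(as.numeric(df$EDV)),
    esv_ref  = suppressWarnings(as.numeric(df$ESV)),
    ed_frame = if ("EDFrame" %in% names(df)) as.integer(df$EDFrame)
               else rep(NA_integer_, nrow(df)),
    es_frame = if ("ESFrame" %in% names(df)) as.integer(df$ESFrame)
               else rep(NA_integer_, nrow(df)),
    stringsAsFactors = FALSE
  )
}

#' Write an LVEF result report
#'
#' Serialises an `LVEFResult` (see [run_pipeline()]) to JSON (nested) or flat
#' CSV. Numeric fields are written at full double precision so that
#' [read_report()] reproduces them exactly.
#'
#' @param result an `LVEFResult`.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stop_if(!inherits(result, "LVEFResult"), "result must be an LVEFResult")
  if (format == "json") {
    payload <- list(
      n_cycles = result$n_cycles,
      mean_ef = result$mean_ef,
      phenotype = result$phenotype,
      hfref_flag = result$hfref_flag,
      status = result$status,
      cycles = result$cycles
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", dataframe = "rows")
  } else {
    cy <- result$cycles
    if (nrow(cy) == 0L) cy <- cy[NA_integer_, , drop = FALSE][0, , drop = FALSE]
    flat <- cbind(cy,
                  n_cycles = result$n_cycles,
                  mean_ef = result$mean_ef,
                  phenotype = result$phenotype,
                  hfref_flag = result$hfref_flag,
                  status = result$status)
    num <- vapply(flat, is.numeric, logical(1)) & names(flat) != "n_cycles"
    flat[num] <- lapply(flat[num], function(v) sprintf("%.17g", v))
    write.csv(flat, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read an LVEF result report written by [write_report()]
#'
#' @param path report path.
#' @param format `"json"` or `"csv"`.
#' @return An `LVEFResult`.
#' @export
read_report <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  stop_if(!file.exists(path), sprintf("no such report '%s'", path))
  cyc_cols <- c("cycle_index", "ed_frame", "es_frame", "a_ed", "a_es",
                "l_ed", "l_es", "edv", "esv", "ef")
  if (format == "json") {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    cycles <- as.data.frame(p$cycles)
    if (nrow(cycles) == 0L)
      cycles <- stats::setNames(as.data.frame(rep(list(numeric(0)), length(cyc_cols))),
                                cyc_cols)
    new_lvef_result(cycles = cycles,
                    mean_ef = if (is.null(p$mean_ef)) NA_real_ else p$mean_ef,
                    phenotype = p$phenotype, status = p$status)
  } else {
    flat <- read.csv(path, stringsAsFactors = FALSE)
    cycles <- flat[, intersect(cyc_cols, names(flat)), drop = FALSE]
    cycles[] <- lapply(cycles, as.numeric)
    if (nrow(flat) > 0 && "cycle_index" %in% names(cycles))
      cycles$cycle_index <- as.integer(cycles$cycle_index)
    new_lvef_result(cycles = cycles,
                    mean_ef = if (nrow(flat) > 0) as.numeric(flat$mean_ef[1]) else NA_real_,
                    phenotype = if (nrow(flat) > 0) flat$phenotype[1] else "none",
                    status = if (nrow(flat) > 0) flat$status[1] else "insufficient cycles")
  }
}
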