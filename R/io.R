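## Readers/writers: TIFF stacks and PNG frame directories for video,
## delimited text for detection matrices, signal tables, spike matrices
## and motion tracks, structured text (JSON) for configuration echoes.

#' Read a grayscale video stream
#'
#' @param path a multi-page TIFF file or a directory of numbered
#'   PNG/TIFF frames (zero-padded names sort numerically).
#' @param format `"auto"`, `"tiff_stack"` or `"frame_dir"`.
#' @return list of numeric frames with intensities in [0, 255].
#' @export
readFrames <- function(path, format = c("auto", "tiff_stack", "frame_dir")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "frame_dir" else "tiff_stack"
  }
  if (format == "tiff_stack") {
    if (!file.exists(path)) stop("stream error: no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    return(lapply(pages, .toGray255))
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("stream error: no frames in ", path)
  lapply(files, function(f) {
    img <- if (grepl("\\.png$", f)) png::readPNG(f) else tiff::readTIFF(f)
    .toGray255(img)
  })
}

.toGray255 <- function(img) {
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 255
}

#' Frame-stream closure over a video source
#'
#' Returns a function yielding successive frames (for [imgSrcActor()]);
#' reading past the last frame is a stream error carrying the index.
#'
#' @inheritParams readFrames
#' @return function() -> frame.
#' @export
readFrameStream <- function(path, format = c("auto", "tiff_stack",
                                             "frame_dir")) {
  frames <- readFrames(path, format)
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(frames)) stop("stream error: no frame ", i)
    frames[[i]]
  }
}

#' Write frames to disk
#'
#' @param frames list of frames or an H x W x T array, values in
#'   [0, 255].
#' @param path output TIFF path (multi-page) or directory (PNG frames).
#' @param format `"tiff_stack"` or `"frame_dir"`.
#' @export
writeFrames <- function(frames, path, format = c("tiff_stack", "frame_dir")) {
  format <- match.arg(format)
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  }
  scaled <- lapply(frames, function(f) clamp(f / 255, 0, 1))
  if (format == "tiff_stack") {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L, compression = "none")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (t in seq_along(scaled)) {
      png::writePNG(scaled[[t]],
                    file.path(path, sprintf("frame_%05d.png", t)))
    }
  }
  invisible(path)
}

#' @rdname detectionMatrixIO
#' @param delta detection matrix data.frame(x, y, radius).
#' @param path file path.
#' @export
writeDetectionMatrix <- function(delta, path) {
  out <- data.frame(neuron_id = seq_len(nrow(delta)), x = delta$x,
                    y = delta$y, radius = delta$radius)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detection-matrix serialization
#'
#' Comma-separated with header `neuron_id,x,y,radius`; `neuron_id` is the
#' stable training discovery order and indexes signal-table columns.
#'
#' @name detectionMatrixIO
#' @export
readDetectionMatrix <- function(path) {
  d <- read.csv(path)
  data.frame(x = d$x, y = d$y, radius = d$radius)
}

#' @rdname tableIO
#' @param signals L x nu matrix of delta-F/F values.
#' @param path file path.
#' @export
writeSignalTable <- function(signals, path) {
  out <- data.frame(frame_index = seq_len(nrow(signals)), signals)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Delimited-text tables (signal table, motion track, spikes)
#'
#' Comma-separated, header row, frame-major.
#'
#' @name tableIO
#' @export
readSignalTable <- function(path) {
  d <- read.csv(path)
  as.matrix(d[, -1, drop = FALSE])
}

#' @rdname tableIO
#' @param track data.frame(frame, tx, ty, theta).
#' @export
writeMotionTrack <- function(track, path) {
  write.csv(track, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readMotionTrack <- function(path) read.csv(path)

#' @rdname tableIO
#' @param spikes nNeurons x T binary matrix.
#' @export
writeSpikes <- function(spikes, path) {
  write.csv(data.frame(frame = seq_len(ncol(spikes)), t(spikes)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readSpikes <- function(path) {
  d <- read.csv(path)
  t(as.matrix(d[, -1, drop = FALSE]))
}

#' Write / read a structured configuration echo
#'
#' Every output bundle carries its configuration verbatim for
#' provenance.
#'
#' @param config named list.
#' @param path file path (JSON text).
#' @name configIO
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname configIO
#' @export
readRunConfig <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a simulation bundle to a directory
#'
#' Writes frames (TIFF stack or PNG directory), per-neuron binary mask
#' TIFFs with a delimited index file, the spike matrix, the motion track
#' and the echoed configuration, plus a checksum manifest.
#'
#' @param bundle a [SimulationBundle-class] object.
#' @param dir output directory.
#' @param format video format.
#' @export
writeBundle <- function(bundle, dir, format = c("tiff_stack", "frame_dir")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vpath <- if (format == "tiff_stack") file.path(dir, "frames.tiff")
           else file.path(dir, "frames")
  writeFrames(frames(bundle), vpath, format)
  masks <- neuronMasks(bundle)
  mdir <- file.path(dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  H <- masks$dim[1]; W <- masks$dim[2]
  for (i in seq_along(masks$pix)) {
    m <- matrix(0, H, W)
    m[masks$pix[[i]]] <- 1
    tiff::writeTIFF(m, file.path(mdir, sprintf("mask_%03d.tiff", i)),
                    bits.per.sample = 8L, compression = "none")
  }
  write.csv(cbind(masks$info,
                  centroid_x = masks$info$cx, centroid_y = masks$info$cy),
            file.path(dir, "mask_index.csv"), row.names = FALSE)
  writeSpikes(spikes(bundle), file.path(dir, "spikes.csv"))
  writeMotionTrack(motionTrack(bundle), file.path(dir, "motion_track.csv"))
  writeRunConfig(simConfig(bundle), file.path(dir, "config.json"))
  .writeManifest(dir)
  invisible(dir)
}

.writeManifest <- function(dir) {
  files <- setdiff(list.files(dir, recursive = TRUE), "MANIFEST.txt")
  sums <- vapply(files, function(f) {
    unname(tools::md5sum(file.path(dir, f)))
  }, "")
  writeLines(paste(sums, files), file.path(dir, "MANIFEST.txt"))
  invisible(NULL)
}
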