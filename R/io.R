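# Stack and table I/O. TIFF stacks are written as 16-bit multipage files with
# intensities divided by `scale`; reading multiplies back, so integer-valued
# inputs in [0, scale] round-trip bit-exactly. No per-frame rescaling is ever
# applied (ROI-level normalization happens in the trace extraction).

#' Read a time-lapse channel from a multipage TIFF or an image-sequence directory
#'
#' Directories are read as ordered PNG/TIFF sequences, one frame per file, in
#' lexical filename order (name frames `frame_000.png`, `frame_001.png`, ...).
#'
#' @param path A multipage TIFF file or a directory of single-frame PNG/TIFF
#'   files.
#' @param channel Channel label stored on the result.
#' @param calibration A [calibration()].
#' @param scale Intensity scale: stored sample values are `pixels / scale`.
#'   Must match the value used by [write_stack()].
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, channel = "red",
                       calibration = apoptomap::calibration(), scale = 255) {
  if (!file.exists(path))
    abort(paste0("Cannot read '", path, "': no such file or directory."),
          class = "apoptomap_io_error")
  frames <-
    if (dir.exists(path)) {
      files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) == 0L)
        abort(paste0("No PNG/TIFF frames found in '", path, "'."),
              class = "apoptomap_io_error")
      lapply(files, read_frame_file)
    } else {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, collapse_gray)
    }
  dims <- vapply(frames, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad) > 0L)
    abort(sprintf("Frames have mixed dimensions: frame %d is %dx%d, expected %dx%d.",
                  bad[1], dims[1, bad[1]], dims[2, bad[1]], dims[1, 1], dims[2, 1]),
          class = "apoptomap_format_error")
  px <- array(unlist(frames, use.names = FALSE),
              dim = c(dims[1, 1], dims[2, 1], length(frames)))
  # undo the write-side division; snap to the 16-bit grid to keep integer
  # inputs exact through the float round trip
  px <- round(px * scale, 6)
  frame_stack(px, channel = channel, calibration = calibration)
}

read_frame_file <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
         else tiff::readTIFF(f)
  collapse_gray(img)
}

# multi-sample pages (e.g. RGB) are averaged to one gray sample
collapse_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  img
}

#' Write a frame_stack to a multipage 16-bit TIFF
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @param scale Intensity scale; see [read_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale = 255) {
  stopifnot(inherits(stack, "frame_stack"))
  if (max(stack) > scale)
    abort("Stack intensities exceed `scale`; increase `scale`.",
          class = "apoptomap_config_error")
  frames <- lapply(seq_len(n_frames(stack)), function(t) get_frame(stack, t) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

# event tables -----------------------------------------------------------

#' Validate, write and read death-event tables
#'
#' An event table has one row per called apoptosis:
#' `track_id`, `x`, `y` (px, 1-based), `radius` (px), `death_frame`
#' (1-based frame index, or `NA` for a track that never died).
#'
#' @param events A data frame with the columns above.
#' @param dims Optional `c(D1, D2)` (and optionally `T` as a third element)
#'   against which coordinates and frames are checked.
#' @return `validate_events()` returns the events as a tibble, invisibly
#'   erroring on violations; the read/write pair round-trips losslessly.
#' @export
validate_events <- function(events, dims = NULL) {
  events <- as_tibble(events)
  need <- c("track_id", "x", "y", "radius", "death_frame")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols) > 0L)
    abort(paste0("Event table lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "apoptomap_validation_error")
  if (nrow(events) == 0L) return(events[need])
  if (any(events$x < 1 | events$y < 1, na.rm = TRUE))
    abort("Event coordinates must be >= 1.", class = "apoptomap_validation_error")
  if (any(events$radius <= 0, na.rm = TRUE))
    abort("Event radii must be positive.", class = "apoptomap_validation_error")
  if (any(events$death_frame < 1, na.rm = TRUE))
    abort("death_frame must be >= 1.", class = "apoptomap_validation_error")
  if (!is.null(dims)) {
    if (any(events$x > dims[2] | events$y > dims[1], na.rm = TRUE))
      abort("Event coordinates fall outside the frame.",
            class = "apoptomap_validation_error")
    if (length(dims) >= 3L && any(events$death_frame > dims[3], na.rm = TRUE))
      abort("death_frame exceeds the stack duration.",
            class = "apoptomap_validation_error")
  }
  events[need]
}

#' @rdname validate_events
#' @param path CSV file path.
#' @export
write_event_table <- function(events, path, dims = NULL) {
  events <- validate_events(events, dims)
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname validate_events
#' @export
read_event_table <- function(path, dims = NULL) {
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          track_id = readr::col_integer(),
                          x = readr::col_double(),
                          y = readr::col_double(),
                          radius = readr::col_double(),
                          death_frame = readr::col_integer()))
  validate_events(ev, dims)
}
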