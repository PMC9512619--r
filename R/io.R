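#' Read and write pipeline tables
#'
#' Plain-text interchange for the pipeline's tabular artifacts: frame
#' labels (`frame_index`, `label`), fidget events (`onset_frame`,
#' `offset_frame`, `duration_frames`, optional `magnitude`), stimulus
#' tables, running speed (`frame_index`, `speed_cm_s`) and wide dF/F
#' matrices (one row per neuron, one column per frame).
#'
#' @param x Object to write (tibble, or matrix for dF/F).
#' @param path File path.
#' @name fidget-io
NULL

#' @rdname fidget-io
#' @export
write_events_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname fidget-io
#' @export
read_events_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(across(c("onset_frame", "offset_frame"), as.integer))
}

#' @rdname fidget-io
#' @export
write_labels_csv <- function(x, path) {
  readr::write_csv(tibble(frame_index = x$frame, label = as.character(x$label)),
                   path)
  invisible(path)
}

#' @rdname fidget-io
#' @export
read_labels_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(frame = as.integer(.data$frame_index),
           label = factor(.data$label, levels = behavior_levels())) |>
    select("frame", "label")
}

#' @rdname fidget-io
#' @export
write_dff_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname fidget-io
#' @export
read_dff_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' @rdname fidget-io
#' @export
write_running_csv <- function(x, path) {
  readr::write_csv(tibble(frame_index = seq_along(x), speed_cm_s = x), path)
  invisible(path)
}

#' @rdname fidget-io
#' @export
read_running_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)$speed_cm_s
}

#' @rdname fidget-io
#' @param dir Directory of 8-bit grayscale PNG frames
#'   (`frame_000001.png`, ...).
#' @export
write_frames_png <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_len(dim(x)[3])) {
    png::writePNG(x[, , f], file.path(dir, sprintf("frame_%06d.png", f)))
  }
  invisible(dir)
}

#' @rdname fidget-io
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) abort("no PNG frames found")
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 3) first <- first[, , 1]
  out <- array(0, dim = c(nrow(first), ncol(first), length(files)))
  out[, , 1] <- first
  for (f in seq_along(files)[-1]) {
    img <- png::readPNG(files[f])
    if (length(dim(img)) == 3) img <- img[, , 1]
    out[, , f] <- img
  }
  out
}

#' @rdname fidget-io
#' @param truth Per-neuron truth tibble and event table (a list), as in a
#'   `synth_session`'s `truth`/`events` fields.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fidget-io
#' @export
read_truth_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(out, function(el) if (is.data.frame(el)) as_tibble(el) else el)
}
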