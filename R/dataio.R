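# Frame, mask, feature-table and manifest I/O.
#
# Conventions: frames are H x W x 3 arrays of integers in [0, 255], row-major
# with the origin at the top-left; masks are logical H x W matrices stored on
# disk as single-channel PNGs with 0 = FALSE and 255 = TRUE.

#' Read an RGB frame from a PNG file
#'
#' Returns an `H x W x 3` array of integers in `[0, 255]`. Grayscale images
#' are replicated to three identical channels; an alpha channel, if present,
#' is dropped.
#'
#' @param path Path to a PNG image.
#' @return An `H x W x 3` numeric array with values in `[0, 255]`.
#' @export
load_frame <- function(path) {
  if (!file.exists(path)) stop("cannot read frame: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext != "png")
    stop("cannot read frame '", path, "': only PNG input is supported")
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot decode PNG '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  nch <- dim(img)[3]
  if (nch == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  else if (nch == 2L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]  # gray+alpha
  else img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an RGB frame to a PNG file
#'
#' @param frame An `H x W x 3` array with values in `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot_frame(frame)
  png::writePNG(frame / 255, target = path)
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are stored as single-channel PNGs containing only the values 0
#' (background) and 255 (foreground); the round-trip is lossless at the bit
#' level. `load_mask()` rejects files containing any other pixel value.
#'
#' @param mask A logical matrix.
#' @param path PNG path.
#' @return `load_mask()` returns a logical matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot_mask(mask)
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' @rdname write_mask
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  vals <- round(img * 255)
  if (!all(vals %in% c(0, 255)))
    stop("mask '", path, "' is not binary: contains values other than 0/255")
  vals == 255
}

#' Sample frames uniformly from a video record
#'
#' Selects up to `n` frames at uniform stride over the ordered frame list of
#' a clip (0-based indices `floor(i * L / n)`, `i = 0, ..., n-1`), always
#' including the first frame and preserving order. Deterministic: the same
#' record and `n` always give the same frames. When `n` exceeds the number of
#' available frames all frames are returned.
#'
#' @param record A video record as returned by [video_record()].
#' @param n Number of frames to sample (positive integer).
#' @param load If `TRUE` (default) load and return the frames; otherwise
#'   return the selected file paths.
#' @return A list of frames (or a character vector of paths).
#' @export
sample_frames <- function(record, n, load = TRUE) {
  paths <- record$frame_paths
  if (length(paths) == 0L) stop("no frames")
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  idx <- sample_frame_indices(length(paths), n)
  sel <- paths[idx + 1L]
  if (!load) return(sel)
  lapply(sel, load_frame)
}

#' @rdname sample_frames
#' @param n_available Number of frames available in the clip.
#' @return `sample_frame_indices()` returns the selected 0-based indices.
#' @export
sample_frame_indices <- function(n_available, n) {
  if (n_available < 1L) stop("no frames")
  n_take <- min(n, n_available)
  unique(as.integer(floor((seq_len(n_take) - 1) * n_available / n_take)))
}

#' Construct a video record
#'
#' A video record ties a clip id to its ordered frame files and, optionally,
#' the three evaluator scores and/or the consensus bleeding level.
#'
#' @param video_id Character id, unique within a dataset.
#' @param frame_paths Ordered character vector of frame files (non-empty).
#' @param evaluator_scores Optional integer triple, each in `[0, 3]`.
#' @param consensus_label Optional consensus rank in `[0, 3]`.
#' @return A list of class `"video_record"`.
#' @export
video_record <- function(video_id, frame_paths, evaluator_scores = NULL,
                         consensus_label = NULL) {
  if (length(frame_paths) == 0L) stop("frame_paths must be non-empty")
  if (!is.null(evaluator_scores)) {
    if (length(evaluator_scores) != 3L || any(evaluator_scores < 0 | evaluator_scores > 3))
      stop("evaluator_scores must be three integers in [0, 3]")
  }
  if (!is.null(consensus_label) && (consensus_label < 0 || consensus_label > 3))
    stop("consensus_label must be in [0, 3]")
  structure(list(video_id = as.character(video_id),
                 frame_paths = as.character(frame_paths),
                 evaluator_scores = evaluator_scores,
                 consensus_label = consensus_label),
            class = "video_record")
}

feature_header <- c("video_id", "bleeding_ratio", "region_count", "label")

#' Read and write per-video feature tables
#'
#' The on-disk format is a CSV with header
#' `video_id,bleeding_ratio,region_count,label`. Ids and labels round-trip
#' exactly; features are written with full double precision.
#'
#' @param table A data frame with the four columns above.
#' @param path CSV path.
#' @return `read_features()` returns the data frame; `write_features()`
#'   returns `path` invisibly.
#' @export
write_features <- function(table, path) {
  if (!all(feature_header %in% names(table)))
    stop("feature table must have columns: ", paste(feature_header, collapse = ","))
  tab <- table[, feature_header, drop = FALSE]
  tab$bleeding_ratio <- sprintf("%.17g", tab$bleeding_ratio)
  tab$region_count <- sprintf("%.17g", tab$region_count)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("cannot read features: no such file: ", path)
  first <- readLines(path, n = 1L)
  got <- strsplit(first, ",", fixed = TRUE)[[1]]
  if (!identical(got, feature_header))
    stop("bad feature file header; expected: ", paste(feature_header, collapse = ","))
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses =
                    c(video_id = "character", bleeding_ratio = "numeric",
                      region_count = "numeric", label = "integer"))
  tab
}

#' Read and write dataset manifests
#'
#' A manifest is a JSON file listing, per video: `video_id`, `frames`
#' (relative frame paths), optional `scores` (the three evaluator scores),
#' optional `label` (consensus rank), and optional `split`
#' (`train`/`val`/`test`).
#'
#' @param manifest A list with element `records` (list of [video_record()])
#'   and optional named character vector `split` (video_id -> split name).
#' @param path JSON path.
#' @return `read_manifest()` returns the manifest list; `write_manifest()`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  ids <- vapply(manifest$records, function(r) r$video_id, "")
  if (anyDuplicated(ids)) stop("video ids in manifest must be unique")
  recs <- lapply(manifest$records, function(r) {
    out <- list(video_id = r$video_id, frames = as.list(r$frame_paths))
    if (!is.null(r$evaluator_scores)) out$scores <- as.integer(r$evaluator_scores)
    if (!is.null(r$consensus_label)) out$label <- as.integer(r$consensus_label)
    if (!is.null(manifest$split) && r$video_id %in% names(manifest$split)) {
      sp <- manifest$split[[r$video_id]]
      if (!sp %in% c("train", "val", "test")) stop("invalid split value: ", sp)
      out$split <- sp
    }
    out
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: no such file: ", path)
  recs <- jsonlite::read_json(path)
  split <- character(0)
  records <- lapply(recs, function(r) {
    if (!is.null(r$split)) split[[r$video_id]] <<- r$split
    video_record(r$video_id, unlist(r$frames),
                 evaluator_scores = if (!is.null(r$scores)) unlist(r$scores),
                 consensus_label = r$label)
  })
  list(records = records, split = if (length(split)) split else NULL)
}
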