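# Synthetic surgical-frame generator.
#
# The clinical TURP clips behind this kind of system are private, so the
# package ships a generator that emulates their relevant structure: a pinkish
# tissue background, dark-red blood blobs whose expected count and area grow
# with the ordinal bleeding level 0-3, and (optionally) the bright red glow
# of the electrosurgical cutting loop -- the confound the segmenter removes.
# Blood colours are chosen so their BT.601 Cr/Cb values pass the default red
# thresholds; the loop is painted brighter and also red, so a naive red-pixel
# count overestimates bleeding whenever the loop is visible. Everything is
# seeded and byte-deterministic.

#' Per-level generator parameters
#'
#' Expected blood-blob count and total blood area fraction per frame, for
#' each bleeding level 0 (excellent) to 3 (bad). Both increase strictly with
#' the level. `color_jitter` is the standard deviation (8-bit channel units)
#' of per-blob colour variation.
#'
#' @param overrides Optional named list, one entry per level (`"0"`..`"3"`),
#'   each itself a named list of fields to replace.
#' @return A data frame with columns `level`, `blob_count_mean`,
#'   `blob_area_frac`, `color_jitter`.
#' @export
default_level_params <- function(overrides = NULL) {
  p <- data.frame(level = 0:3,
                  blob_count_mean = c(1, 4, 9, 16),
                  blob_area_frac = c(0.005, 0.03, 0.10, 0.25),
                  color_jitter = rep(6, 4))
  if (!is.null(overrides)) {
    for (lv in names(overrides)) {
      row <- match(as.integer(lv), p$level)
      if (is.na(row)) stop("unknown level in overrides: ", lv)
      for (f in names(overrides[[lv]])) p[row, f] <- overrides[[lv]][[f]]
    }
  }
  p
}

# BT.601 full-range Cr of an RGB triple; used to sanity-check painted colors.
cr_of <- function(rgb) 128 + 0.5 * rgb[1] - 0.418688 * rgb[2] - 0.081312 * rgb[3]

#' Generate one synthetic surgical frame
#'
#' Paints a noisy pink tissue background, `Poisson(blob_count_mean)` rotated
#' elliptical dark-red blood blobs (their union is the blood mask) and, when
#' `loop_present`, a bright red arc with a Gaussian glow standing in for the
#' cutting loop; the arc's radius, span, thickness and glow width vary from
#' frame to frame, so the loop's red footprint is independent of the bleeding
#' level. Pixels of blood hidden behind the loop are excluded from the blood
#' mask. Deterministic for a fixed seed.
#'
#' @param level Bleeding level in `0:3`.
#' @param loop_present Paint the cutting-loop artifact?
#' @param size Integer `(H, W)`, both at least 32.
#' @param seed Integer seed.
#' @param params Level parameter table from [default_level_params()].
#' @param noise_sd Per-pixel Gaussian noise sd (8-bit units); `0` for
#'   noise-free frames.
#' @return A list of class `"synth_frame"` with elements `frame`
#'   (`H x W x 3`, integers in `[0, 255]`), `loop_mask`, `blood_mask`
#'   (logical `H x W`), `level`, `seed`.
#' @export
generate_frame <- function(level, loop_present = TRUE, size = c(128L, 128L),
                           seed = 1L, params = default_level_params(),
                           noise_sd = 3) {
  if (!is.numeric(level) || length(level) != 1L || !(level %in% params$level))
    stop("invalid level: must be one of ", paste(params$level, collapse = ", "))
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 32L || W < 32L) stop("frame size must be at least 32x32")
  lp <- params[params$level == level, ]

  with_local_seed(seed, {
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)

    # tissue background: flat pink + smooth illumination wave
    base <- c(190, 160, 150)
    amp <- runif(1, 4, 10)
    dir <- runif(1, 0, 2 * pi)
    phase <- runif(1, 0, 2 * pi)
    freq <- runif(1, 0.5, 1.2)
    ill <- amp * sin((cos(dir) * xx + sin(dir) * yy) / max(H, W) * 2 * pi * freq + phase)
    R <- base[1] + ill; G <- base[2] + ill; B <- base[3] + ill

    # blood blobs
    blood_mask <- matrix(FALSE, H, W)
    n_blobs <- rpois(1, lp$blob_count_mean)
    if (n_blobs > 0) {
      area_target <- lp$blob_area_frac * H * W / lp$blob_count_mean
      for (k in seq_len(n_blobs)) {
        area <- area_target * exp(rnorm(1, -0.045, 0.3))
        rho <- runif(1, 1, 2.5)
        a <- sqrt(area * rho / pi); b <- sqrt(area / (rho * pi))
        th <- runif(1, 0, pi)
        mar <- min(sqrt(area / pi), W / 3, H / 3)
        cx <- runif(1, 1 + mar, W - mar); cy <- runif(1, 1 + mar, H - mar)
        dx <- xx - cx; dy <- yy - cy
        u <- (dx * cos(th) + dy * sin(th)) / a
        v <- (-dx * sin(th) + dy * cos(th)) / b
        blob <- (u * u + v * v) <= 1
        col <- c(150, 30, 40) + rnorm(3, 0, lp$color_jitter)
        col <- pmin(pmax(col, c(130, 10, 20)), c(180, 60, 70))
        R[blob] <- col[1]; G[blob] <- col[2]; B[blob] <- col[3]
        blood_mask <- blood_mask | blob
      }
    }

    # cutting-loop arc with glow
    loop_mask <- matrix(FALSE, H, W)
    if (isTRUE(loop_present)) {
      cx <- runif(1, 0.35, 0.65) * W
      cy <- runif(1, 0.75, 1.05) * H
      r <- runif(1, 0.25, 0.45) * min(H, W)
      span <- runif(1, 1.5, 2.5)
      phi0 <- -pi / 2 + rnorm(1, 0, 0.2)
      dx <- xx - cx; dy <- yy - cy
      d <- sqrt(dx * dx + dy * dy)
      ang <- atan2(dy, dx)
      adiff <- abs(((ang - phi0 + pi) %% (2 * pi)) - pi)
      e1 <- c(cx + r * cos(phi0 - span / 2), cy + r * sin(phi0 - span / 2))
      e2 <- c(cx + r * cos(phi0 + span / 2), cy + r * sin(phi0 + span / 2))
      dist_arc <- ifelse(adiff <= span / 2, abs(d - r),
                         pmin(sqrt((xx - e1[1])^2 + (yy - e1[2])^2),
                              sqrt((xx - e2[1])^2 + (yy - e2[2])^2)))
      thick <- runif(1, 1.5, 3)
      glow <- runif(1, 2, 5)
      alpha <- exp(-pmax(dist_arc - thick, 0)^2 / (2 * glow^2))
      loop_mask <- alpha >= 0.2
      lcol <- c(255, 90, 70) + rnorm(3, 0, 5)
      lcol <- pmin(pmax(lcol, c(240, 70, 50)), c(255, 110, 90))
      lm <- loop_mask
      R[lm] <- alpha[lm] * lcol[1] + (1 - alpha[lm]) * R[lm]
      G[lm] <- alpha[lm] * lcol[2] + (1 - alpha[lm]) * G[lm]
      B[lm] <- alpha[lm] * lcol[3] + (1 - alpha[lm]) * B[lm]
      blood_mask <- blood_mask & !loop_mask
    }

    if (noise_sd > 0) {
      R <- R + rnorm(H * W, 0, noise_sd)
      G <- G + rnorm(H * W, 0, noise_sd)
      B <- B + rnorm(H * W, 0, noise_sd)
    }
    frame <- array(0, c(H, W, 3))
    frame[, , 1] <- R; frame[, , 2] <- G; frame[, , 3] <- B
    frame <- round(pmin(pmax(frame, 0), 255))

    structure(list(frame = frame, loop_mask = loop_mask,
                   blood_mask = blood_mask, level = as.integer(level),
                   seed = as.integer(seed)),
              class = "synth_frame")
  })
}

#' Generate a synthetic video (a sequence of frames at one bleeding level)
#'
#' Per-frame seeds are derived deterministically from the master seed, so the
#' same call always reproduces the same clip.
#'
#' @inheritParams generate_frame
#' @param n_frames Number of frames (at least 1).
#' @param video_id Clip identifier; autogenerated when `NULL`.
#' @return A list with `record` (a [video_record()] carrying the level as
#'   consensus label) and `frames` (list of `"synth_frame"`).
#' @export
generate_video <- function(level, n_frames = 20L, loop_present = TRUE,
                           seed = 1L, size = c(128L, 128L),
                           params = default_level_params(), noise_sd = 3,
                           video_id = NULL) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (is.null(video_id)) video_id <- sprintf("synth_L%d_s%d", level, seed)
  frames <- lapply(seq_len(n_frames), function(i)
    generate_frame(level, loop_present, size, derive_seed(seed, i), params, noise_sd))
  record <- video_record(video_id,
                         sprintf("%s/frame_%04d.png", video_id, seq_len(n_frames)),
                         consensus_label = as.integer(level))
  list(record = record, frames = frames)
}

#' Generate a balanced labeled dataset of synthetic videos
#'
#' Produces `videos_per_level` clips for each of the four bleeding levels.
#' When `out_dir` is given, frames and their loop/blood masks are written as
#' PNGs under `out_dir/videos/<id>/` (`frame_%04d.png`, `loop_%04d.png`,
#' `blood_%04d.png`) along with `manifest.json` at the root.
#'
#' @inheritParams generate_video
#' @param videos_per_level Clips per level (at least 1).
#' @param out_dir Optional output directory.
#' @return A list of class `"synth_dataset"` with `manifest` (records +
#'   optional split) and `videos` (list of `generate_video()` results).
#' @export
generate_dataset <- function(videos_per_level = 10L, n_frames = 20L,
                             loop_present = TRUE, seed = 1L,
                             out_dir = NULL, size = c(128L, 128L),
                             params = default_level_params(), noise_sd = 3) {
  if (videos_per_level < 1L) stop("videos_per_level must be >= 1")
  videos <- list()
  for (lv in 0:3) {
    for (v in seq_len(videos_per_level)) {
      id <- sprintf("video_%d_%02d", lv, v)
      vid <- generate_video(lv, n_frames, loop_present,
                            derive_seed(seed, lv * 1000L + v), size, params,
                            noise_sd, video_id = id)
      videos[[id]] <- vid
    }
  }
  records <- lapply(videos, function(v) v$record)
  if (!is.null(out_dir)) {
    ok <- dir.create(file.path(out_dir, "videos"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(file.path(out_dir, "videos")))
      stop("cannot create output directory: ", out_dir)
    for (id in names(videos)) {
      vd <- file.path(out_dir, "videos", id)
      dir.create(vd, showWarnings = FALSE)
      fr <- videos[[id]]$frames
      paths <- character(length(fr))
      for (i in seq_along(fr)) {
        paths[i] <- file.path(vd, sprintf("frame_%04d.png", i))
        write_frame(fr[[i]]$frame, paths[i])
        write_mask(fr[[i]]$loop_mask, file.path(vd, sprintf("loop_%04d.png", i)))
        write_mask(fr[[i]]$blood_mask, file.path(vd, sprintf("blood_%04d.png", i)))
      }
      videos[[id]]$record$frame_paths <- paths
    }
    records <- lapply(videos, function(v) v$record)
    write_manifest(list(records = records), file.path(out_dir, "manifest.json"))
  }
  structure(list(manifest = list(records = records, split = NULL),
                 videos = videos),
            class = "synth_dataset")
}
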