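#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti for the package's array-based objects. Dynamic
#' images round-trip with a JSON frame-timing sidecar (PET) or a repetition
#' time (BOLD).
#'
#' @param image A `dynamic_image`.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param timing_path Path for the frame-timing JSON sidecar; defaults to
#'   `path` with a `.timing.json` suffix (PET only).
#' @return `path`, invisibly.
#' @export
write_dynamic_image <- function(image, path, timing_path = NULL) {
  stopifnot(inherits(image, "dynamic_image"))
  nii <- RNifti::asNifti(image$data,
                         pixdim = c(image$voxel_size_mm, 1))
  RNifti::writeNifti(nii, path)
  if (inherits(image$timing, "frame_schedule")) {
    if (is.null(timing_path)) timing_path <- paste0(path, ".timing.json")
    write_frame_timing(image$timing, timing_path)
  }
  invisible(path)
}

#' @rdname write_dynamic_image
#' @param modality `"PET"` or `"BOLD"`.
#' @param tr_s Repetition time in seconds (BOLD input without a sidecar).
#' @export
read_dynamic_image <- function(path, timing_path = NULL, tr_s = NULL,
                               modality = c("PET", "BOLD")) {
  modality <- match.arg(modality)
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim = dim(nii))
  vox <- RNifti::pixdim(nii)[1:3]
  if (modality == "PET") {
    if (is.null(timing_path)) timing_path <- paste0(path, ".timing.json")
    timing <- read_frame_timing(timing_path)
  } else {
    if (is.null(tr_s)) stop("BOLD input requires tr_s")
    timing <- tr_s
  }
  dynamic_image(arr, timing = timing, voxel_size_mm = vox,
                modality = modality)
}

#' Frame-timing sidecar I/O
#'
#' The sidecar is a JSON list of `{start_min, duration_min}` records.
#'
#' @param sched A `frame_schedule`.
#' @param path File path.
#' @return [read_frame_timing()] returns a `frame_schedule`.
#' @export
write_frame_timing <- function(sched, path) {
  stopifnot(inherits(sched, "frame_schedule"))
  frames <- lapply(seq_along(sched$start_min), function(i) {
    list(start_min = sched$start_min[i], duration_min = sched$duration_min[i])
  })
  jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_timing
#' @export
read_frame_timing <- function(path) {
  frames <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame_schedule(frames$start_min, frames$duration_min)
}

#' Write an atlas label volume as integer NIfTI
#' @param atlas A `pet_atlas`.
#' @param path Output path.
#' @export
write_label_volume <- function(atlas, path) {
  stopifnot(inherits(atlas, "pet_atlas"))
  nii <- RNifti::asNifti(atlas$label_volume,
                         pixdim = c(atlas$voxel_size_mm, 1),
                         datatype = "int16")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' BP_ND series table I/O
#'
#' Tab-separated region-by-frame table; a one-line `#`-prefixed header names
#' the reference region and the retained window.
#'
#' @param bp A `bp_series`.
#' @param path File path.
#' @return [read_bp_series()] returns a `bp_series`.
#' @export
write_bp_series <- function(bp, path, provenance = NULL) {
  stopifnot(inherits(bp, "bp_series"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  writeLines(sprintf("# reference=%s retained_window_min=%.6g,%.6g",
                     bp$reference, bp$retained_window_min[1],
                     bp$retained_window_min[2]), con)
  df <- data.frame(position = bp$region_positions,
                   abbreviation = rownames(bp$values),
                   bp$values, check.names = FALSE)
  colnames(df)[-(1:2)] <- sprintf("%.6g", bp$frame_mid_min)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bp_series
#' @export
read_bp_series <- function(path) {
  hdr <- leading_comments(path)
  header <- grep("reference=", hdr$lines, value = TRUE)[1]
  m <- regmatches(header,
                  regexec("reference=(\\S+) retained_window_min=([^,]+),(\\S+)",
                          header))[[1]]
  if (length(m) != 4L) stop("malformed bp_series header in ", path)
  df <- utils::read.delim(path, skip = hdr$n, check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  mids <- as.numeric(colnames(vals))
  dimnames(vals) <- list(df$abbreviation, NULL)
  bp_series(vals, df$position, mids,
            reference = m[2],
            retained_window_min = as.numeric(m[3:4]))
}

#' Connectome matrix I/O
#'
#' Tab-separated R x R matrix with position-ordered headers; metadata
#' (subject, window, modality) travels in `#`-prefixed comment lines.
#'
#' @param conn A `connectome`.
#' @param path File path.
#' @return [read_connectome()] returns a `connectome`.
#' @export
write_connectome <- function(conn, path, provenance = NULL) {
  stopifnot(inherits(conn, "connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  writeLines(sprintf("# subject=%s modality=%s window_min=%s",
                     if (is.null(conn$subject_id)) "NA" else conn$subject_id,
                     conn$modality,
                     if (is.null(conn$window_min)) "NA,NA"
                     else paste(sprintf("%.6g", conn$window_min),
                                collapse = ",")), con)
  df <- as.data.frame(conn$z)
  colnames(df) <- conn$region_positions
  utils::write.table(cbind(position = conn$region_positions, df), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  hdr <- leading_comments(path)
  header <- grep("subject=", hdr$lines, value = TRUE)[1]
  m <- regmatches(header,
                  regexec("subject=(\\S+) modality=(\\S+) window_min=(\\S+)",
                          header))[[1]]
  df <- utils::read.delim(path, skip = hdr$n, check.names = FALSE)
  z <- as.matrix(df[, -1, drop = FALSE])
  dimnames(z) <- NULL
  win <- suppressWarnings(as.numeric(strsplit(m[4], ",")[[1]]))
  structure(list(z = z, region_positions = as.integer(df$position),
                 subject_id = if (m[2] == "NA") NULL else m[2],
                 window_min = if (anyNA(win)) NULL else win,
                 modality = m[3]),
            class = "connectome")
}

# leading '#'-prefixed comment lines of a text table
leading_comments <- function(path) {
  lines <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0L || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  list(lines = lines, n = length(lines))
}

#' Export group-connectome edge statistics as an edge list
#'
#' One row per unique edge: `region_i`, `region_j`, `mean_z`, `t`, `p`,
#' `fwe_pass`.
#'
#' @param gc A `group_connectome`.
#' @param path Optional file path; when given, the table is also written
#'   tab-separated.
#' @return The edge-list data.frame.
#' @export
group_edge_table <- function(gc, path = NULL) {
  stopifnot(inherits(gc, "group_connectome"))
  idx <- which(upper.tri(gc$mean_z), arr.ind = TRUE)
  pos <- gc$region_positions
  df <- data.frame(region_i = pos[idx[, 1]], region_j = pos[idx[, 2]],
                   mean_z = gc$mean_z[idx], t = gc$edge_t[idx],
                   p = gc$edge_p[idx], fwe_pass = gc$fwe_mask[idx])
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
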