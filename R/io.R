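# Formats: tab-delimited patterns/RDMs (full %.17g precision so round-trips
# are exact), JSON maps, line-delimited JSON frame streams, NIfTI via RNifti.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a pattern table
#'
#' Tab-delimited matrix: first column `voxel` (1-based index), remaining
#' columns one condition or trial each, header row carrying the (unique)
#' labels. Round-trips are lossless.
#'
#' @param x An [anchor_set()] or a `patterns x voxels` numeric matrix with
#'   unique rownames.
#' @param path File path.
#' @return `write_patterns` returns `path` invisibly; `read_patterns`
#'   returns an [anchor_set()] (with `source` set to the file path).
#' @export
write_patterns <- function(x, path) {
  if (inherits(x, "anchor_set")) x <- x$patterns
  x <- as.matrix(x)
  labels <- rownames(x)
  if (is.null(labels)) stop("pattern matrix needs rownames (labels)")
  if (anyDuplicated(labels)) stop("duplicate pattern labels")
  df <- data.frame(voxel = seq_len(ncol(x)))
  for (i in seq_along(labels)) df[[labels[i]]] <- fmt_num(x[i, ])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "numeric")
  if (names(df)[1L] != "voxel") stop("first column must be 'voxel'")
  labels <- names(df)[-1L]
  if (anyDuplicated(labels)) {
    stop("duplicate condition label(s) in header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  rownames(m) <- labels
  anchor_set(m, labels, source = path)
}

#' Write / read an RDM
#'
#' Tab-delimited square matrix with a `# metric:` comment line, a header of
#' labels and a leading label column. Reading validates symmetry and names
#' the worst offending cell on failure.
#'
#' @param rdm An [rdm].
#' @param path File path.
#' @return `write_rdm` returns `path` invisibly; `read_rdm` returns an
#'   [rdm].
#' @export
write_rdm <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# metric: ", rdm$metric), con)
  writeLines(paste(c("label", rdm$labels), collapse = "\t"), con)
  for (i in seq_along(rdm$labels)) {
    writeLines(paste(c(rdm$labels[i], fmt_num(rdm$matrix[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  lines <- readLines(path)
  metric <- "euclidean"
  meta <- grep("^# metric:", lines, value = TRUE)
  if (length(meta)) metric <- trimws(sub("^# metric:", "", meta[1L]))
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- labels
  new_rdm(m, labels, metric = metric)
}

#' Write / read a semantic map
#'
#' JSON serialization of everything needed to re-project patterns:
#' labels, dimensions, canonical coordinates, retained eigenvalues, the
#' landmark projection basis (eigenvectors and squared-distance column
#' means), the orientation transform and the metric. Round-trips preserve
#' projections to full precision.
#'
#' @param map A [semantic_map][embed_rdm()].
#' @param path File path.
#' @return `write_map` returns `path` invisibly; `read_map` returns a
#'   `semantic_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "semantic_map"))
  payload <- list(
    labels = map$labels, dims = map$dims, coords = map$coords,
    eigenvalues = map$eigenvalues,
    basis_vectors = map$basis$vectors, basis_mu = map$basis$mu,
    rotation = map$rotation, orientation = map$orientation,
    metric = map$metric, metric_options = map$metric_options,
    retained_variance = map$retained_variance
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- matrix(as.numeric(p$coords), length(p$labels), p$dims)
  dimnames(coords) <- list(p$labels, paste0("dim", seq_len(p$dims)))
  structure(
    list(labels = p$labels, coords = coords, dims = as.integer(p$dims),
         eigenvalues = as.numeric(p$eigenvalues),
         basis = list(
           vectors = matrix(as.numeric(p$basis_vectors), length(p$labels),
                            length(p$eigenvalues)),
           values = as.numeric(p$eigenvalues),
           mu = as.numeric(p$basis_mu)),
         rotation = matrix(as.numeric(p$rotation), p$dims, p$dims),
         orientation = p$orientation, metric = p$metric,
         metric_options = as.list(p$metric_options),
         retained_variance = as.numeric(p$retained_variance)),
    class = "semantic_map"
  )
}

#' Stream feedback frames to / from a line-delimited JSON file
#'
#' One JSON record per line, append-only, so a display process can tail
#' the file while the session is running. `read_frames` returns every
#' complete frame; a truncated final line (e.g. mid-write) is skipped and
#' flagged via the `"partial"` attribute.
#'
#' @param frames A list of `feedback_frame` objects (or one frame).
#' @param path File path.
#' @param append Append to an existing stream (default `TRUE`)?
#' @return `write_frames` returns `path` invisibly; `read_frames` returns
#'   a list of `feedback_frame` objects.
#' @export
write_frames <- function(frames, path, append = TRUE) {
  if (inherits(frames, "feedback_frame")) frames <- list(frames)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (fr in frames) {
    rec <- unclass(fr)
    rec$thermometer_fills <- as.list(rec$thermometer_fills)  # keep names
    writeLines(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE,
                                null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  partial <- FALSE
  frames <- list()
  for (ln in lines) {
    fr <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
                   error = function(e) NULL)
    if (is.null(fr)) {
      partial <- TRUE
      next
    }
    fills <- unlist(fr$thermometer_fills)
    frames[[length(frames) + 1L]] <- new_feedback_frame(
      t_index = fr$t_index,
      cms_coords = if (is.null(fr$cms_coords)) NULL else
        as.numeric(fr$cms_coords),
      target_label = fr$target_label, strength = fr$strength,
      marker_size = if (is.null(fr$marker_size)) NA_real_ else fr$marker_size,
      thermometer_fills = if (is.null(fills)) numeric(0) else fills,
      arrow_angle = if (is.null(fr$arrow_angle)) NA_real_ else fr$arrow_angle,
      dist = if (is.null(fr$dist)) NA_real_ else fr$dist,
      similarity = if (is.null(fr$similarity)) NA_real_ else fr$similarity,
      degenerate = isTRUE(fr$degenerate))
  }
  attr(frames, "partial") <- partial
  frames
}

#' Write a simulated volume stream as a NIfTI series plus ROI mask
#'
#' Arranges the stream's voxels at the `TRUE` positions of a 3-D mask
#' (ascending linear index — the same fixed ordering
#' [read_nifti_roi()] uses) and writes a 4-D series and the 3-D mask.
#'
#' @param volumes `T x V` matrix of voxel time series.
#' @param mask 3-D logical/0-1 array with exactly `V` nonzero cells.
#' @param series_path,mask_path Output NIfTI paths (`.nii` / `.nii.gz`).
#' @return Invisibly, `c(series_path, mask_path)`.
#' @export
write_nifti_series <- function(volumes, mask, series_path, mask_path) {
  volumes <- as.matrix(volumes)
  mask <- array(as.numeric(mask) != 0, dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  idx <- which(mask)
  if (length(idx) != ncol(volumes)) {
    stop("mask has ", length(idx), " voxels but stream has ", ncol(volumes))
  }
  arr <- array(0, dim = c(dim(mask), nrow(volumes)))
  nvox <- prod(dim(mask))
  for (t in seq_len(nrow(volumes))) {
    arr[idx + (t - 1L) * nvox] <- volumes[t, ]
  }
  RNifti::writeNifti(RNifti::asNifti(arr), series_path)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask), dim(mask))),
                     mask_path)
  invisible(c(series_path, mask_path))
}

#' Extract ROI voxel time series from a NIfTI pair
#'
#' Reads a 4-D series and a 3-D mask on the same grid and returns the
#' `T x V` matrix of in-mask voxel time courses. Voxel ordering is fixed
#' as the ascending linear (column-major) index within the mask, so
#' projection bases computed from the extracted matrix remain valid across
#' reads; the ordering is recorded in the `"voxel_index"` attribute.
#'
#' @param series_path Path to the 4-D NIfTI series.
#' @param mask_path Path to the 3-D NIfTI ROI mask (nonzero = in-ROI).
#' @return `T x V` numeric matrix with attribute `voxel_index`.
#' @export
read_nifti_roi <- function(series_path, mask_path) {
  series <- RNifti::readNifti(series_path)
  mask <- RNifti::readNifti(mask_path)
  sd4 <- dim(series)
  if (length(sd4) != 4L) stop("series must be 4-D")
  if (!all(dim(mask) == sd4[1:3])) {
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match series grid ", paste(sd4[1:3], collapse = "x"))
  }
  idx <- which(mask != 0)
  if (!length(idx)) stop("ROI mask is empty")
  nvox <- prod(sd4[1:3])
  out <- vapply(seq_len(sd4[4L]), function(t) {
    series[idx + (t - 1L) * nvox]
  }, numeric(length(idx)))
  out <- t(out)
  attr(out, "voxel_index") <- idx
  out
}

#' Write a run manifest
#'
#' Every command-line run writes one manifest: the echoed configuration,
#' seeds, input/output paths, package version and a timestamp. Re-running
#' with the recorded configuration and seed reproduces the outputs
#' bit-identically.
#'
#' @param path Output path (JSON).
#' @param command Subcommand name.
#' @param config Named list of configuration values (must include any
#'   seeds).
#' @param inputs,outputs Character vectors of paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = list(),
                           inputs = character(0), outputs = character(0)) {
  manifest <- list(
    command = command, config = config,
    inputs = as.character(inputs), outputs = as.character(outputs),
    package_version = as.character(utils::packageVersion("semanticnf")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
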