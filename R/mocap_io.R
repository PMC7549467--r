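#' Marker-trajectory recording container
#'
#' A recording holds one functional movement: per-marker 3D position series
#' (mm) sampled at a fixed interval, plus participant/limb/activity
#' metadata. All marker series must have the same length and contain no
#' missing values (gap filling is out of scope; files with gaps are
#' rejected).
#'
#' @param markers named list of numeric matrices, one per marker, each with
#'   columns `x`, `y`, `z` and one row per frame.
#' @param sample_interval sampling interval T in seconds (> 0).
#' @param meta named list of metadata (`participant`, `group`, `limb_role`,
#'   `activity`, ...).
#' @return an object of class `recording`.
#' @export
recording <- function(markers, sample_interval, meta = list()) {
  if (!is.list(markers) || !length(markers) || is.null(names(markers)) ||
      any(!nzchar(names(markers)))) {
    stop_invalid("`markers` must be a nonempty named list of position matrices")
  }
  lens <- vapply(markers, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    stop_invalid("all marker series must share the same length")
  }
  for (m in names(markers)) {
    p <- markers[[m]]
    if (!is.matrix(p) || ncol(p) != 3L) {
      stop_invalid(paste0("marker ", m, " must be an n x 3 matrix"))
    }
    if (any(!is.finite(p))) {
      stop_invalid(paste0("marker ", m, " contains missing/non-finite samples"))
    }
  }
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      !is.finite(sample_interval) || sample_interval <= 0) {
    stop_invalid("`sample_interval` must be a single positive number")
  }
  structure(
    list(markers = markers, sample_interval = sample_interval, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  n <- nrow(x$markers[[1]])
  cat(sprintf("Recording: %d markers x %d frames @ %g Hz\n",
              length(x$markers), n, 1 / x$sample_interval))
  cat("  markers:", paste(names(x$markers), collapse = ", "), "\n")
  m <- x$meta
  cat(sprintf("  participant=%s group=%s role=%s activity=%s\n",
              m$participant %||% NA, m$group %||% NA,
              m$limb_role %||% NA, m$activity %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_frames <- function(rec) nrow(rec$markers[[1]])

#' Write a recording to the package's CSV dialect
#'
#' One RFC-4180-style CSV per recording with a mandatory header
#' `frame,time,<M>_x,<M>_y,<M>_z,...`, a 0-based frame index, `time =
#' frame * T`, and fixed 6-decimal formatting (so write-read-write is
#' byte-identical).
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (!length(rec$markers)) stop_format("refusing to write a recording with no markers")
  n <- n_frames(rec)
  cols <- list(frame = seq_len(n) - 1L,
               time = (seq_len(n) - 1L) * rec$sample_interval)
  for (m in names(rec$markers)) {
    p <- rec$markers[[m]]
    cols[[paste0(m, "_x")]] <- p[, 1]
    cols[[paste0(m, "_y")]] <- p[, 2]
    cols[[paste0(m, "_z")]] <- p[, 3]
  }
  header <- paste(names(cols), collapse = ",")
  body <- do.call(paste, c(
    list(cols$frame),
    lapply(cols[-1], function(v) sprintf("%.6f", v)),
    sep = ","
  ))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_io(paste0("cannot open for writing: ", path))
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a recording from the package's CSV dialect
#'
#' @param path CSV file written by [write_recording()] (or conforming to the
#'   same dialect).
#' @param meta named list of metadata to attach.
#' @return a [recording()]; markers appear in declared column order.
#' @export
read_recording <- function(path, meta = list()) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop_format("file has no data rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 5L || header[1] != "frame" || header[2] != "time") {
    stop_format("header must start with frame,time and at least one marker triple")
  }
  mcols <- header[-(1:2)]
  if (length(mcols) %% 3L != 0L) {
    stop_format("marker columns must come in _x,_y,_z triples")
  }
  mnames <- unique(sub("_[xyz]$", "", mcols))
  expect <- as.vector(vapply(mnames, function(m) paste0(m, c("_x", "_y", "_z")),
                             character(3)))
  if (!identical(mcols, expect)) {
    stop_format("marker columns must be ordered <M>_x,<M>_y,<M>_z per marker")
  }
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop_format(sprintf("ragged row at line %d: %d fields, expected %d",
                        bad + 1L, nf[bad], length(header)))
  }
  vals <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                 nrow = length(rows), byrow = TRUE)
  if (any(!is.finite(vals))) {
    bad <- which(rowSums(!is.finite(vals)) > 0)[1]
    stop_format(sprintf("missing or non-numeric value at line %d", bad + 1L))
  }
  n <- nrow(vals)
  if (n < 2L) stop_format("recording must have at least 2 frames")
  tvec <- vals[, 2]
  tt <- (tvec[n] - tvec[1]) / (n - 1)
  if (!is.finite(tt) || tt <= 0) stop_format("non-positive sample interval")
  markers <- list()
  for (k in seq_along(mnames)) {
    p <- vals[, (2 + 3 * (k - 1) + 1):(2 + 3 * k), drop = FALSE]
    colnames(p) <- c("x", "y", "z")
    markers[[mnames[k]]] <- p
  }
  recording(markers, sample_interval = tt, meta = meta)
}

#' Write / read a cohort as one directory of CSV files
#'
#' `write_cohort()` writes one recording CSV per file plus a
#' `metadata.csv` table (`recording_id`, `participant_id`, `group`, `limb`,
#' `role`, `activity`, `file`). `read_cohort()` reads it back.
#'
#' @param cohort a `mocap_cohort` from [generate_cohort()].
#' @param dir directory (created if needed).
#' @return `write_cohort()` returns the directory invisibly;
#'   `read_cohort()` returns a `mocap_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mocap_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort$meta
  meta$file <- paste0(meta$recording_id, ".csv")
  for (i in seq_len(nrow(meta))) {
    write_recording(cohort$recordings[[i]], file.path(dir, meta$file[i]))
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "metadata.csv")
  if (!file.exists(mpath)) stop_io(paste0("no metadata.csv in ", dir))
  meta <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    read_recording(file.path(dir, meta$file[i]), meta = list(
      participant = meta$participant_id[i], group = meta$group[i],
      limb_role = meta$role[i], activity = meta$activity[i],
      side = ifelse(meta$limb[i] == "L", "left", "right")
    ))
  })
  structure(list(recordings = recs, meta = meta[names(meta) != "file"],
                 config = NULL),
            class = "mocap_cohort")
}
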