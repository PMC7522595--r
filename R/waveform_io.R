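#' Read a multichannel waveform file
#'
#' Reads the package's plain-text waveform dialect: UTF-8, comma-separated,
#' with `#`-prefixed header lines carrying `fs_hz`, `units` (one per column,
#' comma-separated), `condition` and `animal_id`; the first non-comment row
#' holds the channel labels and every following row one sample per channel.
#' Time is implicit from the sampling rate.
#'
#' Non-finite samples (`NaN`, `Inf`, empty cells) are a hard error naming the
#' offending data row: silently imputing them would corrupt downstream
#' ensemble averages.
#'
#' @param path Path to a waveform file.
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "corohemo_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) > 0 && !identical(hdr_idx, seq_along(hdr_idx))) {
    abort("header ('#') lines must precede all data lines",
          class = "corohemo_format_error")
  }
  hdr <- lines[hdr_idx]
  meta <- list()
  for (ln in hdr) {
    kv <- sub("^#\\s*", "", ln)
    if (!grepl("=", kv, fixed = TRUE)) {
      abort(sprintf("garbled header line: '%s'", ln),
            class = "corohemo_format_error")
    }
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    meta[[key]] <- val
  }
  if (is.null(meta$fs_hz)) {
    abort("missing required header line '# fs_hz=<rate>'",
          class = "corohemo_format_error")
  }
  fs <- suppressWarnings(as.numeric(meta$fs_hz))
  if (is.na(fs) || fs <= 0) {
    abort(sprintf("garbled header line: '# fs_hz=%s'", meta$fs_hz),
          class = "corohemo_format_error")
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) {
    abort("file has no data rows after the channel-label row",
          class = "corohemo_format_error")
  }
  labels <- trimws(strsplit(body[1L], ",", fixed = TRUE)[[1L]])
  if (anyDuplicated(labels) || any(labels == "")) {
    abort("channel labels must be unique and non-empty",
          class = "corohemo_format_error")
  }
  units <- rep("a.u.", length(labels))
  if (!is.null(meta$units)) {
    units <- trimws(strsplit(meta$units, ",", fixed = TRUE)[[1L]])
    if (length(units) != length(labels)) {
      abort(sprintf("units header lists %d entries for %d channels",
                    length(units), length(labels)),
            class = "corohemo_format_error")
    }
  }
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != length(labels))) {
    bad <- which(nfield != length(labels))[1L]
    abort(sprintf("row %d has %d fields, expected %d", bad, nfield[bad],
                  length(labels)),
          class = "corohemo_structure_error")
  }
  mat <- matrix(suppressWarnings(as.numeric(trimws(unlist(rows)))),
                ncol = length(labels), byrow = TRUE)
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite sample in data row %d, channel '%s'",
                  bad[["row"]], labels[bad[["col"]]]),
          class = "corohemo_validation_error")
  }
  channels <- setNames(
    lapply(seq_along(labels), function(j) {
      trace(mat[, j], fs = fs, unit = units[j], label = labels[j])
    }),
    labels
  )
  extra <- meta[setdiff(names(meta), c("fs_hz", "units", "animal_id", "condition"))]
  recording(channels,
            animal_id = meta$animal_id %||% "unknown",
            condition = meta$condition %||% "P0",
            meta = extra)
}

#' Write a recording to the waveform dialect
#'
#' Inverse of [read_recording()]: values are written with 15 significant
#' digits so a write/read round trip preserves samples to better than 1e-9
#' relative.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "coro_recording"))
  labs <- names(rec$channels)
  units <- vapply(rec$channels, function(tr) tr$unit, character(1))
  hdr <- c(
    sprintf("# fs_hz=%s", format(recording_fs(rec), digits = 15)),
    sprintf("# animal_id=%s", rec$animal_id),
    sprintf("# condition=%s", rec$condition),
    sprintf("# units=%s", paste(units, collapse = ","))
  )
  if (length(rec$meta)) {
    hdr <- c(hdr, sprintf("# %s=%s", names(rec$meta),
                          vapply(rec$meta, as.character, character(1))))
  }
  mat <- vapply(rec$channels, function(tr) tr$samples,
                numeric(length(rec$channels[[1]]$samples)))
  body <- apply(mat, 1L, function(r) {
    paste(vapply(r, function(v) format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE), character(1)),
          collapse = ",")
  })
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr, paste(labs, collapse = ","), body), con)
  invisible(path)
}

#' Angiographic first-fill annotation
#'
#' Records the first frame at which contrast fills each vessel in a coronary
#' angiogram, together with the acquisition frame rate. The flow delay-time
#' statistic ([compute_dt()]) needs entries for both `LAD` and `LCX`.
#'
#' @param fills Named integer vector of first-fill frame indices (frame 0 is
#'   the first acquired frame); names are vessel names, normalized to upper
#'   case.
#' @param frame_rate Acquisition frame rate in frames/s (protocol value: 30).
#' @return A `coro_angio` object.
#' @export
angio_annotation <- function(fills, frame_rate = 30) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    abort("frame_rate must be a positive scalar (frames/s)",
          class = "corohemo_validation_error")
  }
  if (length(fills) == 0L || is.null(names(fills)) || any(names(fills) == "")) {
    abort("fills must be a named vector of frame indices",
          class = "corohemo_validation_error")
  }
  names(fills) <- toupper(names(fills))
  if (anyDuplicated(names(fills))) {
    abort(sprintf("duplicate vessel entry '%s'",
                  names(fills)[duplicated(names(fills))][1L]),
          class = "corohemo_validation_error")
  }
  if (any(!is.finite(fills)) || any(fills < 0) || any(fills != round(fills))) {
    abort("first-fill frames must be non-negative integers",
          class = "corohemo_validation_error")
  }
  structure(
    list(frame_rate = as.numeric(frame_rate),
         fills = setNames(as.integer(round(fills)), names(fills))),
    class = "coro_angio"
  )
}

#' @export
print.coro_angio <- function(x, ...) {
  cat(sprintf("<coro_angio> %g frames/s\n", x$frame_rate))
  for (v in names(x$fills)) cat(sprintf("  %-6s first fill at frame %d\n", v, x$fills[[v]]))
  invisible(x)
}

#' Read an angiographic annotation file
#'
#' Expects a CSV with a `# frame_rate=<fps>` comment line and the header
#' `vessel,first_fill_frame`, one row per vessel.
#'
#' @param path Path to the annotation file.
#' @return A [angio_annotation()].
#' @export
read_angio_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "corohemo_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  fr_line <- grep("^#\\s*frame_rate\\s*=", lines, value = TRUE)
  if (length(fr_line) == 0L) {
    abort("missing '# frame_rate=' header", class = "corohemo_format_error")
  }
  frame_rate <- suppressWarnings(as.numeric(sub("^[^=]*=", "", fr_line[1L])))
  if (is.na(frame_rate)) {
    abort(sprintf("garbled header line: '%s'", fr_line[1L]),
          class = "corohemo_format_error")
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L || trimws(body[1L]) != "vessel,first_fill_frame") {
    abort("expected header row 'vessel,first_fill_frame'",
          class = "corohemo_format_error")
  }
  parts <- strsplit(body[-1L], ",", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort("annotation rows must have exactly two fields",
          class = "corohemo_structure_error")
  }
  vessels <- vapply(parts, function(p) trimws(p[1L]), character(1))
  raw <- vapply(parts, function(p) trimws(p[2L]), character(1))
  frames <- suppressWarnings(as.numeric(raw))
  if (any(is.na(frames)) || any(frames != round(frames))) {
    abort(sprintf("non-integer first-fill frame '%s' for vessel '%s'",
                  raw[is.na(frames) | frames != round(frames)][1L],
                  vessels[is.na(frames) | frames != round(frames)][1L]),
          class = "corohemo_validation_error")
  }
  angio_annotation(setNames(frames, vessels), frame_rate = frame_rate)
}

#' Write an angiographic annotation file
#'
#' @param a A [angio_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_angio_annotation <- function(a, path) {
  stopifnot(inherits(a, "coro_angio"))
  writeLines(c(sprintf("# frame_rate=%g", a$frame_rate),
               "vessel,first_fill_frame",
               sprintf("%s,%d", names(a$fills), a$fills)),
             path)
  invisible(path)
}
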