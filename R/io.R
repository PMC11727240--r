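# Recording file format: `<name>.csv` with header `t_s,<site>,...` and one
# row per sample, plus a `<name>.json` sidecar carrying fs, label, seed,
# subject_id, units and channel order. Round-trips are lossless well beyond
# 9 significant digits (values are written at full double precision).

.sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a recording to CSV + JSON sidecar
#'
#' @param rec An `occl_recording`.
#' @param path Output path, with or without the `.csv` extension; the JSON
#'   sidecar is written next to it.
#' @return `path` (invisibly, with extension).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "occl_recording"))
  if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
  m <- recording_meta(rec)
  readr::write_csv(tibble::as_tibble(rec), path, progress = FALSE)
  jsonlite::write_json(
    list(fs = m$fs, label = m$label, seed = m$seed,
         subject_id = m$subject_id, units = "V", channels = m$channels),
    .sidecar_path(path),
    auto_unbox = TRUE, null = "null", na = "null", digits = NA
  )
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Validates the sidecar (positive `fs`, channel list matching the CSV
#' header) and rejects malformed files with field-level messages.
#'
#' @param path Path to the `.csv` file (sidecar found automatically).
#' @return An `occl_recording`.
#' @export
read_recording <- function(path) {
  if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar for ", path, " (expected ", sidecar, ")",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("fs", "channels")) {
    if (is.null(meta[[field]])) {
      stop("sidecar ", sidecar, " is missing required field `", field, "`",
           call. = FALSE)
    }
  }
  if (!is.numeric(meta$fs) || length(meta$fs) != 1 || meta$fs <= 0) {
    stop("sidecar field `fs` must be a single positive number, got ",
         deparse(meta$fs), call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expected <- c("t_s", meta$channels)
  if (!identical(names(tab), expected)) {
    stop("CSV header does not match sidecar channel list: header has [",
         paste(names(tab), collapse = ", "), "], sidecar lists [",
         paste(expected, collapse = ", "), "]", call. = FALSE)
  }
  new_recording(as.matrix(tab[meta$channels]), fs = meta$fs,
                channels = meta$channels,
                label = meta$label %||% NA_character_,
                seed = meta$seed %||% NA_integer_,
                subject_id = meta$subject_id %||% NA_character_)
}
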