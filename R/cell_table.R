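#' Read a single-slide cell table
#'
#' Reads a delimited text table of detected or annotated cells. The file must
#' have a header with columns `id,x,y,class,source`; coordinates are stored in
#' pixels and converted to micrometres using `scale` (image convention:
#' origin top-left, y increasing downward). The class vocabulary is closed to
#' [cell_classes()]; unknown labels are an error, never silently remapped.
#'
#' @param path Path to a comma-delimited UTF-8 file.
#' @param scale Micrometres per pixel (> 0). Use `scale = 1` if the file
#'   already stores micrometres.
#' @param species_code Optional species code recorded as an attribute.
#' @return A tibble with columns `cell_id`, `x`, `y` (µm), `cls`, `source`,
#'   carrying attributes `slide_id` (file stem), `species_code` and
#'   `microns_per_pixel`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,x,y,class,source",
#'              "a,10,20,cancer,annotation",
#'              "b,30,40,lymphocyte,annotation"), f)
#' read_cell_table(f, scale = 0.456)
read_cell_table <- function(path, scale = 1, species_code = NA_character_) {
  stopifnot(is.numeric(scale), length(scale) == 1L)
  if (!is.finite(scale) || scale <= 0) {
    abort("`scale` (microns per pixel) must be a positive number.")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE, fileEncoding = "UTF-8")
  needed <- c("id", "x", "y", "class", "source")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Cell table ", path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", "),
                 ". Expected header: id,x,y,class,source."))
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad) > 0) {
    abort(paste0("Non-numeric or non-finite coordinate in row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 " of ", path, "."))
  }
  if (any(x < 0) || any(y < 0)) {
    abort(paste0("Negative coordinate in row(s) ",
                 paste(head(which(x < 0 | y < 0), 5), collapse = ", "),
                 "; positions must be >= 0 (origin top-left)."))
  }
  bad_cls <- setdiff(unique(raw$class), CELL_CLASSES)
  if (length(bad_cls) > 0) {
    abort(paste0("Unknown cell class label(s): ",
                 paste(bad_cls, collapse = ", "),
                 ". Allowed labels: ", paste(CELL_CLASSES, collapse = ", "), "."))
  }
  bad_src <- setdiff(unique(raw$source), c("annotation", "prediction"))
  if (length(bad_src) > 0) {
    abort(paste0("Unknown source label(s): ", paste(bad_src, collapse = ", "),
                 ". Allowed: annotation, prediction."))
  }
  out <- tibble(
    cell_id = raw$id,
    x = x * scale,
    y = y * scale,
    cls = raw$class,
    source = raw$source
  )
  dup <- out |>
    dplyr::count(.data$source, .data$cell_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicated cell id(s) within a source: ",
                 paste(head(dup$cell_id, 5), collapse = ", "), "."))
  }
  attr(out, "slide_id") <- sub("\\.[^.]*$", "", basename(path))
  attr(out, "species_code") <- species_code
  attr(out, "microns_per_pixel") <- scale
  out
}

#' Write a cell table
#'
#' Inverse of [read_cell_table()]: positions in µm are converted back to
#' pixels with `scale`, so `write_cell_table()` followed by
#' `read_cell_table()` with the same scale round-trips.
#'
#' @param cells Tibble with columns `cell_id`, `x`, `y`, `cls`, `source`.
#' @param path Output file path.
#' @param scale Micrometres per pixel used to encode coordinates.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, scale = 1) {
  stopifnot(all(c("cell_id", "x", "y", "cls", "source") %in% names(cells)))
  if (!is.finite(scale) || scale <= 0) abort("`scale` must be positive.")
  out <- data.frame(
    id = cells$cell_id,
    x = cells$x / scale,
    y = cells$y / scale,
    class = cells$cls,
    source = cells$source
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write survival tables
#'
#' Per-subject survival records: follow-up `time` in days, `event` (1 = death,
#' 0 = censored), `age` in years, AI-based `lymphocyte_pct` and the
#' colocalisation score on the 0-100 scale (`coloc100`).
#'
#' @param path File path (comma-delimited, header required).
#' @return `read_survival_table()` returns a tibble; `write_survival_table()`
#'   returns `path` invisibly.
#' @export
read_survival_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  needed <- c("subject_id", "time", "event", "age", "lymphocyte_pct", "coloc100")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Survival table missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  out <- as_tibble(raw[needed])
  validate_survival(out)
  out
}

#' @param records Tibble of survival records.
#' @rdname read_survival_table
#' @export
write_survival_table <- function(records, path) {
  validate_survival(records)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_survival <- function(records) {
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    abort("Survival `time` must be finite and > 0.")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (death).")
  }
  if (any(records$coloc100 < 0 | records$coloc100 > 100, na.rm = TRUE)) {
    abort("`coloc100` must lie in [0, 100].")
  }
  invisible(records)
}
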