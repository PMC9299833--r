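## Plain-text readers/writers for the pipeline's interchange formats:
## traces (CSV + JSON sidecar), train and screen tables (CSV), bouton
## geometries (JSON), and optional TIFF export of rendered images.

#' Write / read a trace as CSV with a JSON sidecar
#'
#' The CSV holds `time_s` and `signal`; the sidecar (same path with
#' `.json` appended) records `dt`, `units`, `polarity` and any extra
#' metadata supplied.
#'
#' @param trace an `ephys_trace`.
#' @param path CSV file path.
#' @param meta optional named list merged into the sidecar.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  stopifnot(inherits(trace, "ephys_trace"))
  d <- data.frame(time_s = (seq_along(trace$samples) - 1) * trace$dt,
                  signal = trace$samples)
  utils::write.csv(d, path, row.names = FALSE)
  side <- c(list(dt = trace$dt, units = trace$units,
                 polarity = trace$polarity), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- utils::read.csv(path)
  new_trace(d$signal, dt = side$dt, units = side$units,
            polarity = side$polarity)
}

#' Write / read a train table as CSV
#'
#' Columns: `cell_id`, `train_id`, `stimulus_index`, `amplitude`. The
#' stimulation frequency is carried in an accompanying JSON sidecar.
#'
#' @param trains a `train_set` data frame.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_trains <- function(trains, path) {
  utils::write.csv(as.data.frame(trains), path, row.names = FALSE)
  jsonlite::write_json(list(freq = attr(trains, "freq")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trains
#' @export
read_trains <- function(path) {
  d <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(d, "freq") <- jsonlite::read_json(sidecar,
                                           simplifyVector = TRUE)$freq
  class(d) <- c("train_set", "data.frame")
  d
}

#' Write / read a screen table as CSV
#'
#' Columns: `line_id`, `genotype_class`, `condition`, `nmj_id`,
#' `modality`, `value`.
#'
#' @param table a `screen_table` data frame.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_screen <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen
#' @export
read_screen <- function(path) {
  d <- utils::read.csv(path)
  class(d) <- c("screen_table", "data.frame")
  d
}

#' Write / read bouton geometries as JSON
#'
#' Stores, per bouton, the boundary polygon and both channels' point
#' coordinate lists, all in nm.
#'
#' @param boutons list of `bouton_geometry` objects.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_boutons <- function(boutons, path) {
  payload <- lapply(boutons, function(b)
    list(polygon = unname(apply(b$polygon, 1, as.list)),
         reference = unname(apply(b$reference, 1, as.list)),
         target = unname(apply(b$target, 1, as.list))))
  jsonlite::write_json(list(units = "nm", boutons = payload), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boutons
#' @export
read_boutons <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_mat <- function(lst) {
    if (length(lst) == 0L) return(matrix(numeric(0), ncol = 2))
    do.call(rbind, lapply(lst, function(p) c(p[[1]], p[[2]])))
  }
  lapply(raw$boutons, function(b)
    structure(list(polygon = to_mat(b$polygon),
                   reference = to_mat(b$reference),
                   target = to_mat(b$target)),
              class = "bouton_geometry"))
}

#' Export a rendered two-channel image as TIFF
#'
#' Writes the two channels as a two-sample-per-pixel TIFF (intensities
#' rescaled to [0, 1]) plus a JSON sidecar with the pixel size in nm.
#' Requires the optional `tiff` package.
#'
#' @param img a `puncta_image`.
#' @param path TIFF file path.
#' @return the path, invisibly.
#' @export
write_puncta_tiff <- function(img, path) {
  stopifnot(inherits(img, "puncta_image"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  mx <- max(img$reference, img$target, 1e-12)
  arr <- array(c(img$reference, img$target),
               dim = c(dim(img$reference), 2L)) / mx
  tiff::writeTIFF(arr, path)
  jsonlite::write_json(list(pixel_size_nm = img$pixel_size,
                            origin_nm = img$origin, scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
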