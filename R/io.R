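## Readers and writers for the portable on-disk formats: columnar CSV/TSV
## tables, single-plane TIFF with a YAML calibration sidecar, JSON ground
## truth.

#' Write / read a sweep as a columnar CSV
#'
#' Long format: one row per sample with \code{time_ms, voltage_mV} plus
#' constant annotation columns.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep"))
  utils::write.csv(data.frame(time_ms = sweep$time_ms,
                              voltage_mV = sweep$voltage_mV,
                              stim_onset_ms = sweep$stim_onset_ms,
                              stim_level = sweep$stim_level,
                              epoch = sweep$epoch,
                              slice_id = sweep$slice_id,
                              animal_id = sweep$animal_id),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  d <- utils::read.csv(path)
  new_sweep(d$time_ms, d$voltage_mV, d$stim_onset_ms[1], d$stim_level[1],
            as.character(d$epoch[1]), as.character(d$slice_id[1]),
            as.character(d$animal_id[1]))
}

#' Write / read an LTP session as one long CSV (sweep_id, minute, samples)
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "ephys_session"))
  rows <- lapply(seq_along(session$sweeps), function(i) {
    s <- session$sweeps[[i]]
    data.frame(sweep_id = i, minute = session$minute[i],
               time_ms = s$time_ms, voltage_mV = s$voltage_mV,
               stim_onset_ms = s$stim_onset_ms, epoch = s$epoch)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  d <- utils::read.csv(path)
  ids <- unique(d$sweep_id)
  sweeps <- lapply(ids, function(i) {
    di <- d[d$sweep_id == i, ]
    new_sweep(di$time_ms, di$voltage_mV, di$stim_onset_ms[1],
              epoch = as.character(di$epoch[1]))
  })
  minute <- vapply(ids, function(i) d$minute[d$sweep_id == i][1], numeric(1))
  structure(list(sweeps = sweeps, minute = minute, tbs_minute = 0),
            class = "ephys_session")
}

#' Write / read a dialysate fraction table (animal_id, t_h, conc)
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "dialysate_series"))
  utils::write.csv(data.frame(animal_id = series$animal_id,
                              t_h = series$t_h, conc = series$conc),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  new_dialysate_series(d$t_h, d$conc, as.character(d$animal_id[1]))
}

#' Write / read a calibrated image plane as TIFF + YAML sidecar
#'
#' Intensities are stored as 32-bit float TIFF; pixel size and channel label
#' live in \code{<path>.yaml}.
#' @export
write_plane_tiff <- function(plane, path) {
  stopifnot(inherits(plane, "image_plane"))
  scale <- max(plane$intensity, 1)
  tiff::writeTIFF(plane$intensity / scale, path, bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_size_um = plane$pixel_size_um,
                        channel = plane$channel,
                        intensity_scale = scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_plane_tiff
#' @export
read_plane_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  new_image_plane(m * (side$intensity_scale %||% 1),
                  side$pixel_size_um, side$channel)
}

#' Write / read a PRM peak-area manifest CSV
#' @export
write_prm_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prm_csv
#' @export
read_prm_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a count matrix (genes x samples TSV) and sample metadata CSV
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(data.frame(gene = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  m
}

#' Write a ground-truth record as JSON
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
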