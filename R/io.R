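#' Read a frame stack from TIFF files
#'
#' Accepts either a multi-page TIFF or a directory of single-frame TIFF
#' files. Directory frames are ordered by natural numeric sort of the file
#' names (`f_10.tif` after `f_9.tif`, not after `f_1.tif`). RGB frames are
#' reduced to the green channel at read time, so all downstream code sees
#' single-channel stacks; 8- and 16-bit integer data are promoted to double
#' without rescaling.
#'
#' @param path Multi-page TIFF file or directory of TIFF frames.
#' @param fps Frame rate of the recording, frames per second.
#' @param origin Source-video index of the first frame (0-based,
#'   informational).
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, fps, origin = 0L) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no TIFF files found in ", path)
    files <- files[natural_order(basename(files))]
    pages <- lapply(files, function(f)
      tiff::readTIFF(f, as.is = TRUE, info = TRUE))
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else {
    stop("path does not exist: ", path)
  }
  pages <- lapply(pages, green_channel)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("frames have mixed dimensions")
  d <- dims[[1L]]
  frames <- array(NA_real_, dim = c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  frame_stack(frames, fps = fps, origin = origin)
}

natural_order <- function(names) {
  num <- suppressWarnings(as.numeric(sub(".*?([0-9]+)[^0-9]*$", "\\1", names)))
  order(is.na(num), num, names)
}

green_channel <- function(page) {
  bits <- attr(page, "bits.per.sample")
  page <- unclass(page)
  multichannel <- length(dim(page)) == 3L
  if (multichannel) {
    ch <- if (dim(page)[3L] >= 3L) 2L else 1L
    page <- page[, , ch]
  }
  # multi-channel pages come back rescaled to [0, 1]; restore the stored
  # integer scale so 8/16-bit input is promoted to float without rescaling
  if (multichannel && !is.null(bits) && max(page) <= 1)
    page <- round(page * (2^bits - 1))
  page * 1.0
}

#' Write a frame stack as single-frame TIFF files
#'
#' Exports each frame as `frame_0001.tif`, ... with integer quantization at
#' the requested bit depth. Intensities are rounded and clipped to the
#' representable range at export only; in-memory arithmetic is never clipped.
#' A stack of integer-valued intensities within range round-trips bit-exactly
#' through [read_stack()].
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if missing).
#' @param bits Bit depth, 8 or 16.
#' @return Invisibly, the written file names.
#' @export
write_stack <- function(stack, dir, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maxv <- 2^bits - 1
  d <- dim(stack$frames)
  files <- file.path(dir, sprintf("frame_%04d.tif", seq_len(d[1L])))
  for (i in seq_len(d[1L])) {
    img <- stack$frames[i, , ]
    img[] <- pmin(maxv, pmax(0, round(img)))
    tiff::writeTIFF(img / maxv, files[i], bits.per.sample = bits)
  }
  invisible(files)
}

#' Write pulse maps to CSV
#'
#' Serializes the amplitude, trough and qc maps as headerless CSV grids
#' (`H` rows by `W` comma-separated columns, '.' decimal separator, LF line
#' endings, full double precision), plus a JSON sidecar echoing provenance.
#' Output bytes are deterministic for identical inputs.
#'
#' @param maps A [fit_stack()] result.
#' @param outdir Output directory (created if missing).
#' @param sidecar Optional named list merged into the JSON sidecar (e.g. the
#'   run configuration and seed).
#' @return Invisibly, the written file paths.
#' @export
write_maps <- function(maps, outdir, sidecar = list()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(amplitude = file.path(outdir, "amplitude.csv"),
             trough = file.path(outdir, "trough.csv"),
             qc = file.path(outdir, "qc.csv"))
  write_matrix_csv(maps$amplitude, paths[["amplitude"]])
  write_matrix_csv(maps$trough, paths[["trough"]])
  write_matrix_csv(maps$qc, paths[["qc"]], integer = TRUE)
  sidecar <- c(list(package = "retivel",
                    version = as.character(utils::packageVersion("retivel")),
                    order = maps$order, fps = maps$fps),
               sidecar)
  side_path <- file.path(outdir, "maps.json")
  jsonlite::write_json(sidecar, side_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sidecar = side_path))
}

write_matrix_csv <- function(m, path, integer = FALSE) {
  fmt <- function(v) {
    out <- if (integer) as.character(v) else
      formatC(v, format = "g", digits = 17)
    out[is.na(v)] <- "NA"
    out
  }
  lines <- apply(m, 1L, function(r) paste(fmt(r), collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a CSV map written by [write_maps()]
#'
#' @param path CSV file of a headerless numeric grid.
#' @return A numeric matrix.
#' @export
read_map <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              na.strings = "NA"))
}

#' Write an analysis report as JSON
#'
#' Serializes a named list (for example a [estimate_pwv()] result plus
#' resolution limits) to pretty-printed JSON with full numeric precision and
#' a provenance block (package version, optional config echo and seed).
#'
#' @param report Named list of results.
#' @param path Output file.
#' @param config Optional configuration list echoed under `$provenance`.
#' @param seed Optional seed echoed under `$provenance`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, config = NULL, seed = NULL) {
  out <- c(unclass(report),
           list(provenance = list(
             package = "retivel",
             version = as.character(utils::packageVersion("retivel")),
             config = config, seed = seed)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Maps a YAML file onto [simulation_config()]; the `vessel_path` entry is a
#' list of `[row, col]` pairs.
#'
#' @param path YAML file.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$vessel_path))
    cfg$vessel_path <- do.call(rbind, cfg$vessel_path)
  if (!is.null(cfg$waveform))
    cfg$waveform <- do.call(rbind, cfg$waveform)
  if (!is.null(cfg$drift)) cfg$drift <- as.numeric(cfg$drift)
  do.call(simulation_config, cfg)
}

#' Read cardiac timing and frame rate from a YAML config
#'
#' Expects keys `fps`, `cycle_boundaries` (list of frame indices) and
#' `cycle_time_s`.
#'
#' @param path YAML file.
#' @return List with `timing` (a [cardiac_timing()]) and `fps`.
#' @export
read_timing_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("fps", "cycle_boundaries", "cycle_time_s"))
    if (is.null(cfg[[key]])) stop("config is missing key '", key, "'")
  list(timing = cardiac_timing(unlist(cfg$cycle_boundaries),
                               cfg$cycle_time_s),
       fps = cfg$fps)
}
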