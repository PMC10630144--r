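#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Expected-value stacks are stored as 32-bit float; integer photon-count
#' frames as 16-bit unsigned (values above 65535 are clipped). Axial
#' positions and plane metadata go to `<path>.json`.
#'
#' @param images list of matrices, or a 3D array (slice x rows x cols).
#' @param path output TIFF path.
#' @param bits 32 (float) or 16 (unsigned integer counts).
#' @param metadata named list stored in the sidecar.
#' @export
write_stack_tiff <- function(images, path, bits = 32, metadata = list()) {
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[1]), function(i) images[i, , ])
  if (bits == 16) {
    pages <- lapply(images, function(im) pmin(pmax(im, 0), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    metadata$scale <- 65535
  } else {
    # the tiff writer stores samples on [0, 1]; scale into that range and
    # record the factor in the sidecar
    scale <- max(1e-12, vapply(images, max, 0))
    tiff::writeTIFF(lapply(images, function(im) pmax(im, 0) / scale),
                    path, bits.per.sample = 32, reduce = FALSE)
    metadata$scale <- scale
  }
  metadata$bits <- bits
  metadata$n_pages <- length(images)
  jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#' @param path TIFF path.
#' @return list with `images` (list of matrices) and `metadata`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  metadata <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  scale <- if (!is.null(metadata$scale)) metadata$scale else 1
  images <- lapply(pages, function(p) p * scale)
  list(images = images, metadata = metadata)
}

#' Export simulated frames and their generating truth
#'
#' Writes one 16-bit multi-page TIFF per detection plane plus a CSV truth
#' table (frame, x, y, z, photons).
#'
#' @param frames list from [simulate_frames()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
export_frames <- function(frames, dir, prefix = "frames") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in 1:2) {
    path <- file.path(dir, sprintf("%s_plane%d.tif", prefix, p))
    write_stack_tiff(lapply(frames, function(f) f$pixels[[p]]), path,
                     bits = 16, metadata = list(plane = p))
    paths <- c(paths, path)
  }
  truth <- do.call(rbind, lapply(seq_along(frames), function(i) {
    tr <- frames[[i]]$truth
    if (nrow(tr) == 0) return(NULL)
    cbind(frame = i, tr)
  }))
  tpath <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(truth, tpath, row.names = FALSE)
  invisible(c(paths, tpath))
}

#' Export a closed-loop trace as a delimited table
#' @param trace [run_closed_loop()] trace.
#' @param path CSV path.
#' @export
export_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  cmd <- attr(trace, "commanded")
  colnames(cmd) <- paste0("cmd_", seq_len(ncol(cmd)))
  utils::write.csv(cbind(df, cmd), path, row.names = FALSE)
  invisible(path)
}

config_sections <- c("optics", "acquisition", "training", "loop",
                     "metric_ao", "seed", "output_dir")

#' Load and validate a structured run configuration
#'
#' YAML file with optional sections `optics`, `acquisition`, `training`,
#' `loop`, `metric_ao` plus top-level `seed` and `output_dir`. Every
#' section is validated through its constructor; unknown keys (at the top
#' level or inside a section) are rejected.
#'
#' @param path YAML file path.
#' @return list with constructed configuration objects.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_sections)
  if (length(unknown) > 0)
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "))
  build <- function(section, fn) {
    if (is.null(raw[[section]])) return(fn())
    args <- raw[[section]]
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0)
      stop("unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  list(optics = build("optics", optical_config),
       acquisition = build("acquisition", acquisition_config),
       training = build("training", training_config),
       loop = build("loop", loop_config),
       metric_ao = build("metric_ao", metric_ao_config),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir)
}
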