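# File-format plumbing: PNG frame export and YAML (de)serialisation of
# simulation configurations.

#' Write a frame sequence as 8-bit grayscale PNGs
#'
#' One file per frame named `<patient>_<frame:05d>.png`, with the ground
#' truth masks alongside as `..._stone.png` and `..._kidney.png`, plus the
#' per-frame labels in the expanded CSV dialect.
#'
#' @param seq A [generate_sequence()] result.
#' @param dir Output directory (created if missing).
#' @param patient_id Patient identifier used in file names.
#' @return The directory, invisibly.
#' @export
write_sequence_png <- function(seq, dir, patient_id = "P01") {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in seq$frames) {
    stem <- file.path(dir, sprintf("%s_%05d", patient_id, f$frame))
    png::writePNG(f$image / 255, paste0(stem, ".png"))
    png::writePNG(f$stone_mask + 0, paste0(stem, "_stone.png"))
    png::writePNG(f$kidney_mask + 0, paste0(stem, "_kidney.png"))
  }
  write_frame_labels(seq$labels, patient_id,
                     file.path(dir, paste0(patient_id, "_labels.csv")))
  invisible(dir)
}

#' Read a grayscale PNG frame back as a matrix
#'
#' @param path PNG path.
#' @param as_mask Round to 0/1 integers.
#' @return Numeric matrix in `[0, 1]` (or 0/1 integer matrix).
#' @export
read_frame_png <- function(path, as_mask = FALSE) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (as_mask) matrix(as.integer(round(img)), nrow(img), ncol(img)) else img
}

#' Serialise a simulation configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$focal_zone <- unclass(lst$focal_zone)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @return `read_sim_config` returns the reconstructed [sim_config()].
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  fz <- focal_zone(center = lst$focal_zone$center,
                   semi_axes = lst$focal_zone$semi_axes,
                   shape = lst$focal_zone$shape)
  sim_config(image_height = lst$image_height, image_width = lst$image_width,
             frame_rate = lst$frame_rate, duration = lst$duration,
             respiratory_period = lst$respiratory_period,
             dwell_exponent = lst$dwell_exponent,
             motion_amplitude = lst$motion_amplitude,
             motion_direction = lst$motion_direction,
             stone_axes = lst$stone_axes,
             stone_intensity = lst$stone_intensity,
             kidney_intensity = lst$kidney_intensity,
             background_intensity = lst$background_intensity,
             shadow_attenuation = lst$shadow_attenuation,
             speckle_shape = lst$speckle_shape,
             kidney_axes = lst$kidney_axes,
             kidney_center = lst$kidney_center,
             focal_zone = fz, stone_start = lst$stone_start,
             seed = lst$seed)
}
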