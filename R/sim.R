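#' Simulation configuration for synthetic ultrasound sequences
#'
#' Describes one simulated treatment video: a speckled kidney with a bright
#' stone echo that moves along a periodic respiratory trajectory dwelling at
#' end-expiration, imaged at a fixed frame rate with a fixed focal zone.
#' The generator exists because the study's raw ultrasound videos are
#' private patient data; it gives every downstream stage (segmentation,
#' focus decision, statistics) ground truth to be tested against.
#'
#' The respiratory path is one-dimensional, `s(t) = A * sin^(2p)(pi*t/T)`,
#' mapped onto a line in the image plane. The exponent `p` (dwell_exponent)
#' flattens the minima: the larger it is, the longer the stone stands nearly
#' still at end-expiration before a fast transit to the inspiration extreme,
#' which is the clinically exploitable dwell. At `t = 0` the stone sits at
#' its end-expiration position, which by default is the focal-zone centre.
#'
#' @param image_height,image_width Frame geometry in pixels.
#' @param frame_rate Frames per second (the study device captured 15).
#' @param duration Sequence length in seconds.
#' @param respiratory_period Breathing period in seconds (typical adult at
#'   rest: 3-5 s).
#' @param dwell_exponent Dimensionless >= 1; 1 gives a pure squared sinusoid,
#'   larger values lengthen the end-expiration dwell.
#' @param motion_amplitude Peak stone displacement in pixels.
#' @param motion_direction Unit-normalised length-2 vector, direction of the
#'   respiratory line in the image plane (default cranio-caudal, i.e. along
#'   `y`).
#' @param stone_axes Length-2 ellipse semi-axes of the stone in pixels.
#' @param stone_intensity,kidney_intensity,background_intensity Mean gray
#'   levels (0-255 scale) of stone echo, kidney parenchyma and surround.
#' @param shadow_attenuation Multiplicative intensity factor of the acoustic
#'   shadow cast below the stone (stones are strong reflectors, so the
#'   column beneath them is darkened).
#' @param speckle_shape Shape parameter of the multiplicative gamma speckle
#'   (mean 1, variance `1/speckle_shape`); smaller is noisier.
#' @param kidney_axes,kidney_center Kidney ellipse geometry in pixels.
#' @param focal_zone A [focal_zone()]; default centred at the stone's
#'   end-expiration position.
#' @param stone_start Length-2 `(x, y)` stone centre at end-expiration;
#'   default the focal-zone centre.
#' @param seed Integer seed; frame `i` uses sub-seed `seed + i` so frames
#'   are individually reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(image_height = 64L, image_width = 64L,
                       frame_rate = 15, duration = 20,
                       respiratory_period = 4, dwell_exponent = 4,
                       motion_amplitude = 18,
                       motion_direction = c(0, 1),
                       stone_axes = c(4, 3),
                       stone_intensity = 230, kidney_intensity = 90,
                       background_intensity = 30,
                       shadow_attenuation = 0.45,
                       speckle_shape = 8,
                       kidney_axes = c(26, 22), kidney_center = c(32, 30),
                       focal_zone = NULL, stone_start = NULL,
                       seed = 1L) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (respiratory_period <= 0) stop("respiratory_period must be positive")
  if (motion_amplitude <= 0) stop("motion_amplitude must be positive")
  if (dwell_exponent < 1) stop("dwell_exponent must be >= 1")
  if (any(stone_axes <= 0) || any(kidney_axes <= 0))
    stop("geometric quantities must be positive")
  dirn <- as.numeric(motion_direction)
  dirn <- dirn / sqrt(sum(dirn^2))
  if (is.null(stone_start)) stone_start <- c(32, 22)
  if (is.null(focal_zone))
    focal_zone <- focal_zone(center = stone_start, semi_axes = c(6, 7))
  cfg <- structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         frame_rate = frame_rate, duration = duration,
         respiratory_period = respiratory_period,
         dwell_exponent = dwell_exponent,
         motion_amplitude = motion_amplitude, motion_direction = dirn,
         stone_axes = as.numeric(stone_axes),
         stone_intensity = stone_intensity,
         kidney_intensity = kidney_intensity,
         background_intensity = background_intensity,
         shadow_attenuation = shadow_attenuation,
         speckle_shape = speckle_shape,
         kidney_axes = as.numeric(kidney_axes),
         kidney_center = as.numeric(kidney_center),
         focal_zone = focal_zone, stone_start = as.numeric(stone_start),
         seed = as.integer(seed)),
    class = "sim_config")
  # the stone must stay inside the image over the whole trajectory
  ends <- rbind(cfg$stone_start,
                cfg$stone_start + motion_amplitude * dirn)
  lo <- apply(ends, 2L, min) - stone_axes
  hi <- apply(ends, 2L, max) + stone_axes
  if (lo[1L] < 0 || lo[2L] < 0 ||
      hi[1L] > image_width - 1L || hi[2L] > image_height - 1L)
    stop("stone trajectory leaves the image; shrink motion_amplitude or move stone_start")
  cfg
}

#' Respiratory stone trajectory
#'
#' Deterministically maps the periodic one-dimensional respiratory path
#' `s(t) = A * sin^(2p)(pi*t/T)` into per-frame stone-centre positions. The
#' minima of `s` are flat for `p > 1`: near end-expiration the stone is
#' almost standing still, which is the optimal interval for firing.
#'
#' @param config A [sim_config()].
#' @return A data.frame of class `motion_trajectory` with columns `frame`
#'   (0-based), `t` (seconds), `x`, `y` (pixels), one row per frame.
#' @export
respiratory_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$frame_rate * config$duration)
  t <- (seq_len(n) - 1L) / config$frame_rate
  s <- config$motion_amplitude *
    sin(pi * t / config$respiratory_period)^(2 * config$dwell_exponent)
  pos <- cbind(config$stone_start[1L] + s * config$motion_direction[1L],
               config$stone_start[2L] + s * config$motion_direction[2L])
  out <- data.frame(frame = seq_len(n) - 1L, t = t,
                    x = pos[, 1L], y = pos[, 2L])
  class(out) <- c("motion_trajectory", "data.frame")
  out
}

#' Render one synthetic ultrasound frame
#'
#' Composes a smooth anatomy image (dark surround, brighter kidney ellipse,
#' bright elliptical stone echo with an acoustic-shadow column beneath it),
#' multiplies it by gamma-distributed speckle, and returns the frame
#' together with its ground truth: exact stone and kidney masks, the exact
#' pixel-counted overlap of the stone with the focal zone, and the
#' resulting in/out-of-focus label under the >= 50% rule.
#'
#' @param trajectory A [respiratory_trajectory()].
#' @param frame_index 0-based frame index into the trajectory.
#' @param config The [sim_config()] that produced the trajectory.
#' @return A list of class `frame_packet`: `image` (matrix, gray levels
#'   0-255), `stone_mask`, `kidney_mask` (0/1 matrices), `true_overlap`,
#'   `true_label` (`"in_focus"`/`"out_of_focus"`), `frame` (index).
#' @export
render_frame <- function(trajectory, frame_index, config) {
  stopifnot(inherits(config, "sim_config"))
  row <- which(trajectory$frame == frame_index)
  if (length(row) != 1L) stop("frame_index not covered by the trajectory")
  h <- config$image_height; w <- config$image_width
  center <- c(trajectory$x[row], trajectory$y[row])

  stone <- .ellipse_mask(center, config$stone_axes, h, w)
  if (sum(stone) == 0L ||
      center[1L] - config$stone_axes[1L] < 0 ||
      center[1L] + config$stone_axes[1L] > w - 1L ||
      center[2L] - config$stone_axes[2L] < 0 ||
      center[2L] + config$stone_axes[2L] > h - 1L)
    stop("stone outside image bounds at frame ", frame_index)
  kidney <- .ellipse_mask(config$kidney_center, config$kidney_axes, h, w)

  base <- matrix(config$background_intensity, h, w)
  base[kidney == 1L] <- config$kidney_intensity
  # acoustic shadow: attenuate the column below the stone
  sx <- abs(matrix(rep(0:(w - 1L), each = h), h, w) - center[1L]) <=
    config$stone_axes[1L]
  sy <- matrix(rep(0:(h - 1L), times = w), h, w) >
    center[2L] + config$stone_axes[2L]
  base[sx & sy] <- base[sx & sy] * config$shadow_attenuation
  base[stone == 1L] <- config$stone_intensity

  img <- withr::with_seed(config$seed + as.integer(frame_index), {
    speckle <- matrix(stats::rgamma(h * w, shape = config$speckle_shape,
                                    rate = config$speckle_shape), h, w)
    pmin(pmax(base * speckle, 0), 255)
  })

  fz <- zone_mask(config$focal_zone, h, w)
  ov <- sum(stone * fz) / sum(stone)
  structure(list(image = img, stone_mask = stone, kidney_mask = kidney,
                 true_overlap = ov,
                 true_label = if (ov >= 0.5) "in_focus" else "out_of_focus",
                 frame = as.integer(frame_index)),
            class = "frame_packet")
}

#' Generate a full labelled frame sequence
#'
#' @param config A [sim_config()].
#' @return A list of class `frame_sequence`: `frames` (list of
#'   [render_frame()] packets), `labels` (integer 0/1 vector, 1 = in focus,
#'   one per frame), `trajectory`, `config`.
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  traj <- respiratory_trajectory(config)
  frames <- lapply(traj$frame, render_frame, trajectory = traj,
                   config = config)
  labels <- vapply(frames, function(f) as.integer(f$true_label == "in_focus"),
                   integer(1))
  structure(list(frames = frames, labels = labels, trajectory = traj,
                 config = config),
            class = "frame_sequence")
}

# Half-overlap displacement: largest displacement along the motion
# direction at which the stone still has >= 50% of its pixels in the focal
# zone. Monotone in the displacement, found by bisection on the exact
# pixel-counted overlap.
.half_overlap_distance <- function(config) {
  h <- config$image_height; w <- config$image_width
  fz <- zone_mask(config$focal_zone, h, w)
  ov_at <- function(d) {
    cen <- config$stone_start + d * config$motion_direction
    st <- .ellipse_mask(cen, config$stone_axes, h, w)
    sum(st * fz) / max(1, sum(st))
  }
  lo <- 0; hi <- config$motion_amplitude
  if (ov_at(hi) >= 0.5) return(hi)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (ov_at(mid) >= 0.5) lo <- mid else hi <- mid
  }
  lo
}

#' Simulate a multi-patient cohort
#'
#' Generates one labelled sequence per patient with heterogeneous hit
#' rates. Each patient receives a target hit rate `q`; the focal-zone
#' placement and motion amplitude that realise it are solved in closed
#' form from the dwell model. With the focal zone at the end-expiration
#' position, the fraction of time with `s(t) <= d` is
#' `(2/pi) * asin((d/A)^(1/(2p)))`, so `A = d / sin(pi*q/2)^(2p)`, where
#' `d` is the exact displacement at which focal overlap drops below 50%.
#' Because the dwell concentrates time at end-expiration, low hit rates
#' would need amplitudes far beyond the image; when the required `A`
#' exceeds what the image admits, the patient's focal zone is placed at
#' the inspiration end of the path instead (a poorly targeted patient),
#' where the in-focus fraction is `1 - (2/pi) * asin((1 - d/A)^(1/(2p)))`
#' and `A = d / (1 - sin(pi*(1-q)/2)^(2p))`. `jitter = 0` gives every
#' patient the same target rate; `jitter = 1` spreads targets evenly over
#' `rate_range`. Stone size is additionally perturbed per patient.
#'
#' @param n_patients At least 3 (patient-based cross-validation needs
#'   disjoint train/validation/test patients).
#' @param config Base [sim_config()] shared by the cohort.
#' @param jitter Scalar in `[0, 1]` scaling the spread of target hit rates
#'   around their centre.
#' @param rate_range Length-2 range of target hit rates at `jitter = 1`.
#' @param seed Integer seed for the per-patient perturbations.
#' @return A list of class `cohort`; one element per patient: `patient_id`,
#'   `config`, `frames`, `labels`, `target_rate`.
#' @export
simulate_cohort <- function(n_patients = 11L, config = sim_config(),
                            jitter = 1, rate_range = c(0.2, 0.9),
                            seed = 100L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 3L)
    stop("n_patients must be >= 3 for train/validation/test splitting")
  if (jitter < 0 || jitter > 1) stop("jitter must be in [0, 1]")
  centre <- mean(rate_range)
  half <- diff(rate_range) / 2 * jitter
  targets <- if (n_patients == 1L) centre else
    seq(centre - half, centre + half, length.out = n_patients)
  per_patient <- withr::with_seed(as.integer(seed), list(
    targets = sample(targets),   # no systematic order across patient ids
    axes_jit = matrix(stats::runif(2L * n_patients, 1 - 0.25 * jitter,
                                   1 + 0.25 * jitter), n_patients, 2L)))
  targets <- per_patient$targets
  axes_jit <- per_patient$axes_jit
  cohort <- lapply(seq_len(n_patients), function(i) {
    cfg <- config
    cfg$stone_axes <- pmax(2, config$stone_axes * axes_jit[i, ])
    cfg$seed <- as.integer(seed + i * 10000L)
    cfg$focal_zone$center <- cfg$stone_start
    d_half <- .half_overlap_distance(cfg)
    q <- min(max(targets[i], 0.02), 0.995)
    p2 <- 2 * cfg$dwell_exponent
    max_amp <- .max_amplitude(cfg)
    amp <- d_half / sin(pi * q / 2)^p2
    if (amp > max_amp) {
      # poorly targeted patient: focal zone at the inspiration end
      amp <- min(d_half / (1 - sin(pi * (1 - q) / 2)^p2), max_amp)
      cfg$focal_zone$center <- cfg$stone_start + amp * cfg$motion_direction
    }
    cfg$motion_amplitude <- amp
    seqn <- generate_sequence(cfg)
    list(patient_id = sprintf("P%02d", i), config = cfg,
         frames = seqn$frames, labels = seqn$labels, target_rate = targets[i])
  })
  class(cohort) <- "cohort"
  cohort
}

# Largest motion amplitude keeping the stone inside the image.
.max_amplitude <- function(config) {
  dirn <- config$motion_direction
  lim <- Inf
  if (dirn[1L] > 0) lim <- min(lim, (config$image_width - 1L -
    config$stone_axes[1L] - config$stone_start[1L]) / dirn[1L])
  if (dirn[1L] < 0) lim <- min(lim, (config$stone_start[1L] -
    config$stone_axes[1L]) / -dirn[1L])
  if (dirn[2L] > 0) lim <- min(lim, (config$image_height - 1L -
    config$stone_axes[2L] - config$stone_start[2L]) / dirn[2L])
  if (dirn[2L] < 0) lim <- min(lim, (config$stone_start[2L] -
    config$stone_axes[2L]) / -dirn[2L])
  lim
}

#' Hit-rate summary of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A data.frame with one row per patient: `patient_id`, `n_focus`,
#'   `n_total`, `rate` -- the same shape as the per-patient frame-count
#'   table used by the statistics layer.
#' @export
cohort_patient_frames <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$patient_id, n_focus = sum(p$labels),
               n_total = length(p$labels),
               rate = mean(p$labels))))
}
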