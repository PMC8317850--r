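# Shared fixtures built in code.

# Published per-patient frame counts (the 8 analyzable patients).
table3_counts <- function() {
  data.frame(
    patient_id = c("2", "4", "5", "6", "7", "8", "10", "11"),
    n_focus = c(1588L, 1414L, 1774L, 1851L, 1697L, 2082L, 789L, 438L),
    n_total = c(2974L, 2397L, 2798L, 3382L, 3544L, 3926L, 3699L, 492L)
  )
}

# Published test-data confusion counts.
table1_cm <- function() confusion_matrix(tp = 5987, fp = 1961,
                                         fn = 4700, tn = 5792)

# A small 32x32 simulation config for fast sequence/training tests.
small_sim_config <- function(...) {
  sim_config(image_height = 32L, image_width = 32L,
             kidney_axes = c(13, 11), kidney_center = c(16, 15),
             stone_axes = c(2.5, 2), stone_start = c(16, 11),
             focal_zone = focal_zone(c(16, 11), c(3, 3.5)),
             motion_amplitude = 9, ...)
}

# Random 0/1 label vector.
random_labels <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, rbinom(n, 1L, p))
}
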