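# Synthetic multimodal gait cohorts.
#
# The generator emulates the structure of a treadmill-free overground gait
# dataset: per trial a marker tensor (585 x 156 at 100 Hz), a GRF tensor
# (585 x 24, downsampled from 1500 Hz plates), an EMG tensor (8985 x 8 at
# 1500 Hz) and a forces-and-moments tensor (8985 x 12), with a walking-speed
# class in {0,1,2,3} and a subject identifier.  It is not a biomechanical
# model: its purpose is to plant known class-discriminative structure
# (channel groups whose amplitude depends on the class, speed-dependent
# stride frequency, GRF peaks and EMG duty cycle) so that classifiers and
# explanation methods can be tested against a ground truth.

#' Walking-speed classes
#'
#' Four speed classes: very slow (0-0.4 m/s), slow (0.4-0.8 m/s),
#' moderate / self-selected (0.8-1.2 m/s) and fast preferred.  The fast
#' range is configurable because only its label, not its bounds, is fixed
#' by the recording protocol.
#'
#' @param fast_range numeric length-2, bounds (m/s) of class 3.
#' @return data.frame with columns `index` (0-3), `label`, `lo`, `hi`.
#' @examples
#' speed_classes()
#' @export
speed_classes <- function(fast_range = c(1.2, 1.8)) {
  stopifnot(length(fast_range) == 2L, fast_range[1] < fast_range[2],
            fast_range[1] >= 1.2)
  out <- data.frame(
    index = 0:3,
    label = c("very_slow", "slow", "moderate", "fast"),
    lo = c(0, 0.4, 0.8, fast_range[1]),
    hi = c(0.4, 0.8, 1.2, fast_range[2]),
    stringsAsFactors = FALSE
  )
  stopifnot(all(diff(out$lo) > 0), all(out$lo < out$hi),
            all(out$hi[-4] <= out$lo[-1]))
  out
}

#' Default planted class-discriminative marker channels
#'
#' Channel groups (over the 156 marker channels) that receive a
#' class-specific amplitude boost in the generator, one group per speed
#' class: right shoulder-girdle markers for class 0, left shoulder-girdle
#' markers for class 1, left calcaneus/metatarsal markers for class 2 and
#' the four malleolus markers for class 3.  These anatomical groups make
#' recovery of the planted truth by an explanation method a meaningful
#' test; any other grouping can be passed to [generate_cohort()].
#'
#' @return Named list `"0"`..`"3"` of integer channel vectors.
#' @export
default_planted_channels <- function() {
  list(
    "0" = marker_channels(c("R_SIA", "R_SRS", "R_SAA")),
    "1" = marker_channels(c("L_SIA", "L_SRS", "L_SAA")),
    "2" = marker_channels(c("L_FCC", "L_FM1", "L_FM2")),
    "3" = marker_channels(c("L_FAL", "L_TAM", "R_FAL", "R_TAM"))
  )
}

#' Draw per-subject random effects
#'
#' Each subject gets a stature scale, an amplitude scale, a global phase
#' offset and a cadence offset, drawn once and reused for every trial of
#' that subject.  This is what makes subject-wise cross-validation
#' splits meaningful on synthetic data.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return data.frame with one row per subject.
#' @export
sample_subject_profiles <- function(n_subjects, seed) {
  assert_that(is_count(n_subjects), "n_subjects must be a positive integer")
  with_seed(derive_seed(seed, 101), {
    data.frame(
      subject_id = seq_len(n_subjects),
      height_factor = stats::rnorm(n_subjects, 1, 0.05),
      amplitude_factor = stats::rnorm(n_subjects, 1, 0.10),
      phase_offset = stats::runif(n_subjects, 0, 2 * pi),
      cadence_offset_hz = stats::rnorm(n_subjects, 0, 0.08),
      stringsAsFactors = FALSE
    )
  })
}

# Deterministic per-channel "anatomy": offsets, base amplitudes and phases
# for the marker channels.  Fixed across subjects and trials.
marker_channel_params <- function(n_channels = 156L) {
  c_idx <- seq_len(n_channels)
  list(
    offset = 300 * sin(0.37 * c_idx) + 100 * cos(1.3 * c_idx),
    amplitude = 15 + 10 * abs(sin(0.13 * c_idx)),
    phase = 2 * pi * ((c_idx * 0.6180339887) %% 1)
  )
}

# Double-hump vertical-load shape on a cyclic phase grid.  `phase` in
# [0, 1) within the gait cycle; stance occupies [0, stance_frac).
grf_cycle_shape <- function(phase, stance_frac = 0.62) {
  s <- phase / stance_frac
  in_stance <- phase < stance_frac
  hump <- function(centre, width) exp(-0.5 * ((s - centre) / width)^2)
  (hump(0.25, 0.10) + hump(0.75, 0.10) + 0.65 * hump(0.5, 0.18)) * in_stance
}

#' Generate one synthetic gait trial
#'
#' @param subject one row of [sample_subject_profiles()].
#' @param speed_class class index in 0..3.
#' @param seed integer seed for this trial's noise stream.
#' @param classes speed-class table, see [speed_classes()].
#' @param planted planted channel groups, see [default_planted_channels()].
#' @param planted_multiplier amplitude multiplier (default 2) applied to
#'   the planted marker channels of the trial's own class.
#' @param noise_sd marker additive noise (mm).
#' @param n_cycles gait cycles per trial (default 2: one left, one right).
#' @return A `gait_trial`: list with matrices `markers` (585 x 156),
#'   `grf` (585 x 24), `emg` (8985 x 8), `fm` (8985 x 12), the class,
#'   subject id, walking speed, per-modality true (unpadded) lengths and
#'   the planted-channel annotation.
#' @export
generate_trial <- function(subject, speed_class, seed,
                           classes = speed_classes(),
                           planted = default_planted_channels(),
                           planted_multiplier = 2.0,
                           noise_sd = 2.0,
                           n_cycles = 2L) {
  assert_that(speed_class %in% classes$index, "invalid speed class index")
  cls <- classes[classes$index == speed_class, ]
  reg <- modality_registry()
  Tm <- 585L; Th <- 8985L

  with_seed(seed, {
    v <- stats::runif(1, cls$lo, cls$hi)
    # stride frequency grows with speed; subject cadence offset adds overlap
    # between adjacent classes so trial length alone is not fully separating
    f <- max(0.3, 0.5 + 0.5 * v + subject$cadence_offset_hz +
               stats::rnorm(1, 0, 0.03))

    len_lo <- min(Tm, max(40L, round(n_cycles * 100 / f)))
    len_hi <- min(Th, max(600L, round(n_cycles * 1500 / f)))

    ## --- markers (100 Hz grid) ------------------------------------------
    pars <- marker_channel_params()
    t_lo <- (seq_len(len_lo) - 1) / 100
    amp <- pars$amplitude * subject$amplitude_factor
    pl <- planted[[as.character(speed_class)]]
    assert_that(length(pl) > 0, "planted channel group must be non-empty")
    amp[pl] <- amp[pl] * planted_multiplier
    phase_mat <- outer(2 * pi * f * t_lo, rep(1, 156L)) +
      matrix(pars$phase + subject$phase_offset, len_lo, 156L, byrow = TRUE)
    markers_core <- matrix(pars$offset * subject$height_factor,
                           len_lo, 156L, byrow = TRUE) +
      sweep(sin(phase_mat), 2L, amp, `*`) +
      matrix(stats::rnorm(len_lo * 156L, 0, noise_sd), len_lo, 156L)
    markers <- matrix(0, Tm, 156L)
    markers[seq_len(len_lo), ] <- markers_core

    ## --- GRF (two plates, downsampled onto the 585-frame grid) ----------
    cyc <- (f * t_lo) %% 1
    peak <- 800 * (1 + 0.2 * v) * subject$height_factor
    fz <- list(grf_cycle_shape(cyc), grf_cycle_shape((cyc + 0.5) %% 1))
    grf <- matrix(0, Tm, 24L)
    for (p in 1:2) {
      base <- (p - 1L) * 9L
      shape <- fz[[p]]
      stance <- shape > 1e-3
      grf[seq_len(len_lo), base + 1L] <- 0.15 * peak * shape *
        sin(2 * pi * cyc)                                   # Fx (shear a-p)
      grf[seq_len(len_lo), base + 2L] <- 0.08 * peak * shape *
        cos(2 * pi * cyc)                                   # Fy (shear m-l)
      grf[seq_len(len_lo), base + 3L] <- peak * shape       # Fz (vertical)
      grf[seq_len(len_lo), base + 4:6] <- grf[seq_len(len_lo), base + 1:3] *
        0.12 * subject$height_factor                        # moments
      cop <- 250 * ((cyc / 0.62) - 0.5) * stance            # heel -> toe
      grf[seq_len(len_lo), base + 7L] <- cop                # COP x (mm)
      grf[seq_len(len_lo), base + 8L] <- 40 * cos(2 * pi * cyc) * stance
      grf[seq_len(len_lo), base + 9L] <- 0                  # COP z
    }
    grf[seq_len(len_lo), 19:24] <- grf[seq_len(len_lo), 1:6] +
      grf[seq_len(len_lo), 10:15]                           # both-feet sums
    grf[seq_len(len_lo), ] <- grf[seq_len(len_lo), ] +
      matrix(stats::rnorm(len_lo * 24L, 0, 0.01 * peak), len_lo, 24L)

    ## --- EMG (8 electrodes, 1500 Hz) ------------------------------------
    t_hi <- (seq_len(len_hi) - 1) / 1500
    cyc_hi <- (f * t_hi) %% 1
    duty <- max(0.12, 0.45 - 0.15 * v)   # burst duty cycle shrinks with speed
    emg <- matrix(0, Th, 8L)
    for (ch in 1:8) {
      centre <- ((ch - 1) / 8 + 0.1) %% 1
      d <- pmin(abs(cyc_hi - centre), 1 - abs(cyc_hi - centre))
      env <- exp(-0.5 * (d / (duty / 2.355))^2)   # FWHM = duty fraction
      emg[seq_len(len_hi), ch] <- 0.5 * subject$amplitude_factor * env *
        abs(stats::rnorm(len_hi)) + stats::rnorm(len_hi, 0, 0.02)
    }

    ## --- F&M (per-foot forces and moments, 1500 Hz) ---------------------
    fm <- matrix(0, Th, 12L)
    lever <- 0.1 * subject$height_factor
    for (p in 1:2) {
      shape_hi <- grf_cycle_shape((cyc_hi + (p - 1) * 0.5) %% 1)
      base <- (p - 1L) * 6L
      fm[seq_len(len_hi), base + 1L] <- 0.15 * peak * shape_hi * sin(2 * pi * cyc_hi)
      fm[seq_len(len_hi), base + 2L] <- 0.08 * peak * shape_hi * cos(2 * pi * cyc_hi)
      fm[seq_len(len_hi), base + 3L] <- peak * shape_hi
      fm[seq_len(len_hi), base + 4:6] <- fm[seq_len(len_hi), base + 1:3] * lever
    }
    fm[seq_len(len_hi), ] <- fm[seq_len(len_hi), ] +
      matrix(stats::rnorm(len_hi * 12L, 0, 0.01 * peak), len_hi, 12L)

    trial <- list(
      markers = markers, grf = grf, emg = emg, fm = fm,
      speed_class = as.integer(speed_class),
      subject_id = as.integer(subject$subject_id),
      speed_mps = v,
      true_length = c(markers = len_lo, grf = len_lo,
                      emg = len_hi, fm = len_hi),
      planted_channels = planted
    )
    class(trial) <- "gait_trial"
    trial
  })
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> subject %d, class %d (%.2f m/s), markers %dx%d (true length %d)\n",
    x$subject_id, x$speed_class, x$speed_mps,
    nrow(x$markers), ncol(x$markers), x$true_length[["markers"]]))
  invisible(x)
}

#' Generate a synthetic multimodal gait cohort
#'
#' Draws `n_subjects` subject profiles and, for every subject and every
#' speed class, `trials_per_subject_per_class` trials.  The cohort is fully
#' determined by `seed`: the same call yields bit-identical tensors.
#'
#' @inheritParams generate_trial
#' @param n_subjects number of subjects (>= 2).
#' @param trials_per_subject_per_class trials per subject and class.
#' @param seed integer seed.
#' @return A `gait_cohort`: list with `trials` (list of `gait_trial`),
#'   `labels` (data.frame `trial_id`, `subject_id`, `class`), `subjects`
#'   and a `manifest` recording shapes, rates, seed and planted channels.
#' @examples
#' cohort <- generate_cohort(n_subjects = 2, trials_per_subject_per_class = 1,
#'                           seed = 1)
#' nrow(cohort$labels)  # 2 subjects x 4 classes
#' @export
generate_cohort <- function(n_subjects, trials_per_subject_per_class = 1L,
                            seed = 1L,
                            classes = speed_classes(),
                            planted = default_planted_channels(),
                            planted_multiplier = 2.0,
                            noise_sd = 2.0,
                            n_cycles = 2L) {
  assert_that(is_count(n_subjects) && n_subjects >= 2,
              "n_subjects must be an integer >= 2")
  assert_that(is_count(trials_per_subject_per_class),
              "trials_per_subject_per_class must be a positive integer")
  subjects <- sample_subject_profiles(n_subjects, seed)
  trials <- list()
  labels <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (cls in classes$index) {
      for (r in seq_len(trials_per_subject_per_class)) {
        k <- k + 1L
        trial_seed <- derive_seed(seed, s, cls, r)
        trials[[k]] <- generate_trial(
          subjects[s, ], cls, trial_seed, classes = classes,
          planted = planted, planted_multiplier = planted_multiplier,
          noise_sd = noise_sd, n_cycles = n_cycles)
        labels[[k]] <- data.frame(
          trial_id = sprintf("S%03d_C%d_T%02d", s, cls, r),
          subject_id = s, class = as.integer(cls),
          stringsAsFactors = FALSE)
      }
    }
  }
  labels <- do.call(rbind, labels)
  reg <- modality_registry()
  manifest <- list(
    n_subjects = n_subjects,
    trials_per_subject_per_class = trials_per_subject_per_class,
    n_trials = k,
    seed = as.integer(seed),
    classes = classes,
    planted_channels = lapply(planted, as.integer),
    planted_multiplier = planted_multiplier,
    noise_sd = noise_sd,
    n_cycles = n_cycles,
    modalities = reg,
    grf_layout = c(
      "plate1 Fx,Fy,Fz, Mx,My,Mz, COPx,COPy,COPz",
      "plate2 Fx,Fy,Fz, Mx,My,Mz, COPx,COPy,COPz",
      "both-plate force and moment sums Fx,Fy,Fz,Mx,My,Mz")
  )
  out <- list(trials = trials, labels = labels, subjects = subjects,
              manifest = manifest)
  class(out) <- "gait_cohort"
  out
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials, %d subjects, %d classes (seed %d)\n",
              length(x$trials), x$manifest$n_subjects,
              nrow(x$manifest$classes), x$manifest$seed))
  invisible(x)
}

#' Per-channel signal power of a trial
#'
#' Mean squared amplitude about the channel mean, computed over the
#' unpadded frames only.  Planted channels of a trial's own class show
#' elevated power, which is the ground truth that explanation methods are
#' tested against.
#'
#' @param trial a `gait_trial`.
#' @param modality modality name.
#' @return numeric vector, one value per channel.
#' @export
channel_power <- function(trial, modality = "markers") {
  x <- trial[[modality]]
  assert_that(!is.null(x), sprintf("unknown modality '%s'", modality))
  n <- trial$true_length[[modality]]
  x <- x[seq_len(n), , drop = FALSE]
  apply(x, 2L, stats::var)
}
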