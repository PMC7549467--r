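#' Class effect: a parametric description of movement impairment
#'
#' Bundles the kinematic deficits that distinguish post-stroke from healthy
#' lifting movements into a small set of generative knobs: longer movement
#' time, lower peak velocity, movement segmentation (sub-movements, which
#' raise the jerk cost), action tremor, and increased proximal (arm/shoulder)
#' displacement. The all-default call is the null effect: an unimpaired
#' movement.
#'
#' @param duration_factor multiplicative scaling of movement time (>= 1 for
#'   impaired movement).
#' @param peak_velocity_factor scaling of peak speed at fixed amplitude and
#'   duration, in `(0, 1]`; 1 reproduces the minimum-jerk speed profile.
#' @param n_submovements integer >= 1; values above 1 split the lift into
#'   overlapping shorter sub-movements, increasing the jerk cost.
#' @param tremor_amplitude RMS amplitude (mm) of band-limited (4-10 Hz)
#'   action tremor, modulated by movement speed.
#' @param proximal_compensation extra displacement fraction added to the
#'   proximal markers (MPH, ACR); >= 0.
#' @param markers marker names the effect applies to, or `NULL` (default)
#'   for all four. Restricting the effect to one marker supports
#'   marker-sensitivity experiments with a known ground truth.
#' @return an object of class `class_effect`.
#' @seealso [paretic_effect()], [nonparetic_effect()] for the default
#'   impaired presets; [generate_recording()].
#' @export
class_effect <- function(duration_factor = 1, peak_velocity_factor = 1,
                         n_submovements = 1L, tremor_amplitude = 0,
                         proximal_compensation = 0, markers = NULL) {
  if (!is.numeric(duration_factor) || duration_factor <= 0) {
    stop_invalid("`duration_factor` must be > 0")
  }
  if (!is.numeric(peak_velocity_factor) || peak_velocity_factor <= 0 ||
      peak_velocity_factor > 1) {
    stop_invalid("`peak_velocity_factor` must be in (0, 1]")
  }
  if (!is_count(n_submovements, min = 1L)) {
    stop_invalid("`n_submovements` must be an integer >= 1")
  }
  if (!is.numeric(tremor_amplitude) || tremor_amplitude < 0) {
    stop_invalid("`tremor_amplitude` must be >= 0")
  }
  if (!is.numeric(proximal_compensation) || proximal_compensation < 0) {
    stop_invalid("`proximal_compensation` must be >= 0")
  }
  if (!is.null(markers)) {
    bad <- setdiff(markers, upper_limb_markers())
    if (length(bad)) {
      stop_invalid(paste0("unknown markers: ", paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      duration_factor = duration_factor,
      peak_velocity_factor = peak_velocity_factor,
      n_submovements = as.integer(n_submovements),
      tremor_amplitude = tremor_amplitude,
      proximal_compensation = proximal_compensation,
      markers = markers
    ),
    class = "class_effect"
  )
}

#' @rdname class_effect
#' @export
paretic_effect <- function(markers = NULL) {
  class_effect(1.5, 0.6, 3L, 1.5, 0.3, markers = markers)
}

#' @rdname class_effect
#' @export
nonparetic_effect <- function(markers = NULL) {
  class_effect(1.15, 0.85, 2L, 0.5, 0.1, markers = markers)
}

is_null_effect <- function(e) {
  e$duration_factor == 1 && e$peak_velocity_factor == 1 &&
    e$n_submovements == 1L && e$tremor_amplitude == 0 &&
    e$proximal_compensation == 0
}

#' The four upper-limb marker names used throughout the package
#'
#' FN = index finger nail (hand), LEP = lateral epicondyle (forearm),
#' MPH = mid-humerus (arm), ACR = acromion (shoulder).
#' @return character vector of length 4.
#' @export
upper_limb_markers <- function() c("FN", "LEP", "MPH", "ACR")

activity_codes <- function() c("DG", "SC", "LC")

# Task geometry (mm): vertical lift height, anterior reach, lateral drift.
# Cylinders are lifted to head height, the glass only to mouth level.
activity_params <- function(activity) {
  switch(activity,
    DG = list(lift = 250, reach = 180, lateral = 40),
    SC = list(lift = 380, reach = 120, lateral = 40),
    LC = list(lift = 400, reach = 140, lateral = 40),
    stop_invalid(paste0("unknown activity code: ", activity))
  )
}

# Displacement amplitude of each marker relative to the hand: distal
# segments travel the most along the kinematic chain.
marker_scales <- function() c(FN = 1, LEP = 0.55, MPH = 0.30, ACR = 0.12)

# Resting marker positions (mm) for a right upper limb, seated:
# x lateral (right positive), y vertical, z anterior.
marker_offsets <- function() {
  rbind(
    FN  = c(250, 750, 150),
    LEP = c(220, 950, 80),
    MPH = c(200, 1150, 40),
    ACR = c(180, 1350, 0)
  )
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults reproduce the study cohort structure: 35 post-stroke
#' participants (group G1) and 19 healthy controls (G2), each recorded on
#' both limbs performing three lifting activities (DG, SC, LC) at 100 Hz,
#' i.e. (35 x 2 + 19 x 2) x 3 = 324 recordings.
#'
#' @param n_stroke,n_control participant counts (defaults 35 and 19).
#' @param activities subset of `c("DG", "SC", "LC")`.
#' @param paretic_effect,nonparetic_effect,control_effect [class_effect()]
#'   objects for the paretic limb, the non-paretic limb of stroke
#'   participants (milder, reflecting bilateral involvement) and control
#'   limbs (null by default).
#' @param sample_rate sampling frequency in Hz (default 100).
#' @param rest_padding range (s) of the uniformly drawn rest interval before
#'   and after the movement.
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_stroke = 35L, n_control = 19L,
                          activities = activity_codes(),
                          paretic_effect = actimage::paretic_effect(),
                          nonparetic_effect = actimage::nonparetic_effect(),
                          control_effect = class_effect(),
                          sample_rate = 100, rest_padding = c(0.5, 1.0),
                          seed = 1L) {
  if (!is_count(n_stroke, min = 0L) || !is_count(n_control, min = 0L)) {
    stop_invalid("`n_stroke` and `n_control` must be non-negative integers")
  }
  if (!length(activities) || !all(activities %in% activity_codes())) {
    stop_invalid("`activities` must be a nonempty subset of DG, SC, LC")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop_invalid("`sample_rate` must be positive")
  }
  stopifnot(inherits(paretic_effect, "class_effect"),
            inherits(nonparetic_effect, "class_effect"),
            inherits(control_effect, "class_effect"))
  structure(
    list(
      n_stroke = as.integer(n_stroke), n_control = as.integer(n_control),
      activities = activities, paretic_effect = paretic_effect,
      nonparetic_effect = nonparetic_effect, control_effect = control_effect,
      sample_rate = sample_rate, rest_padding = rest_padding,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Composite lift-then-lower displacement at times `t` (s, from movement
# onset). The lift of amplitude A over `dur_up` is a superposition of
# `n_sub` overlapping sub-movements of amplitude A/n_sub; the lowering is a
# single segment. Everything is built from C^2 blended shapes, so the
# composite is C^2 with finite jerk cost.
lift_lower <- function(t, amplitude, dur_up, dur_hold, dur_down,
                       n_sub = 1L, velocity_factor = 1, gap_frac = 0.15) {
  if (n_sub == 1L) {
    up <- amplitude * blend_shape(t / dur_up, velocity_factor)
  } else {
    gap <- gap_frac * dur_up
    d_sub <- dur_up - (n_sub - 1) * gap
    up <- 0
    for (i in seq_len(n_sub) - 1L) {
      up <- up + (amplitude / n_sub) *
        blend_shape((t - i * gap) / d_sub, velocity_factor)
    }
  }
  down <- amplitude * blend_shape((t - dur_up - dur_hold) / dur_down,
                                  velocity_factor)
  up - down
}

#' Generate one synthetic lifting recording
#'
#' Simulates the four upper-limb markers (FN, LEP, MPH, ACR) of one
#' lifting-and-lowering movement. The hand marker follows a composition of
#' minimum-jerk-based segments (lift, hold, lower); proximal markers follow
#' amplitude-scaled copies plus any proximal compensation; the impairment
#' described by `effect` stretches movement time, flattens the speed
#' profile, splits the lift into sub-movements and adds speed-modulated
#' band-limited tremor. Left-side recordings are exact lateral (x) mirror
#' images of the right-side construction. Rest padding is included at both
#' ends so that movement clipping is exercised downstream.
#'
#' @param activity one of `"DG"`, `"SC"`, `"LC"`.
#' @param limb_side `"left"` or `"right"`.
#' @param effect a [class_effect()].
#' @param seed integer seed; the function is deterministic given `seed`.
#' @param sample_rate Hz (default 100).
#' @param rest_padding length-2 range (s) for the uniform rest padding at
#'   each end; use `c(0, 0)` for an unpadded recording.
#' @param meta optional named list merged into the recording metadata
#'   (`participant`, `group`, `limb_role`, ...).
#' @return a [recording()] with a `truth` element holding the true movement
#'   window (`onset_s`, `offset_s` and 1-based sample indices `start`,
#'   `end`) of the hand marker.
#' @export
generate_recording <- function(activity, limb_side = c("right", "left"),
                               effect = class_effect(), seed = 1L,
                               sample_rate = 100, rest_padding = c(0.5, 1.0),
                               meta = list()) {
  limb_side <- match.arg(limb_side)
  if (!is.character(activity) || length(activity) != 1L ||
      !activity %in% activity_codes()) {
    stop_invalid(paste0("unknown activity code: ",
                        paste(activity, collapse = ",")))
  }
  stopifnot(inherits(effect, "class_effect"))
  ap <- activity_params(activity)
  scales <- marker_scales()
  offsets <- marker_offsets()
  mk <- upper_limb_markers()
  affected <- if (is.null(effect$markers)) mk else effect$markers
  tt <- 1 / sample_rate

  with_seed(seed, {
    jit_d <- stats::runif(1, 0.9, 1.1)
    jit_a <- stats::runif(1, 0.95, 1.05)
    pad1 <- stats::runif(1, rest_padding[1], rest_padding[2])
    pad2 <- stats::runif(1, rest_padding[1], rest_padding[2])

    base_up <- 1.2 * jit_d
    base_hold <- 0.2
    base_down <- 1.2 * jit_d

    # Per-marker effect parameters (null for unaffected markers).
    eff_of <- function(m) {
      if (m %in% affected) effect else class_effect()
    }
    move_dur <- vapply(mk, function(m) {
      e <- eff_of(m)
      (base_up + base_down) * e$duration_factor + base_hold
    }, numeric(1))

    total <- pad1 + max(move_dur) + pad2
    n <- floor(total * sample_rate) + 1L
    t <- (seq_len(n) - 1L) * tt
    tm <- t - pad1  # time from movement onset

    markers <- list()
    for (m in mk) {
      e <- eff_of(m)
      sc <- scales[[m]] * jit_a
      if (m %in% c("MPH", "ACR") && m %in% affected) {
        sc <- sc + effect$proximal_compensation
      }
      du <- base_up * e$duration_factor
      dd <- base_down * e$duration_factor
      amp <- c(x = ap$lateral, y = ap$lift, z = ap$reach) * sc
      clean <- vapply(c("x", "y", "z"), function(ax) {
        lift_lower(tm, amp[[ax]], du, base_hold, dd,
                   n_sub = e$n_submovements,
                   velocity_factor = e$peak_velocity_factor)
      }, numeric(n))
      if (e$tremor_amplitude > 0) {
        # speed envelope of the noise-free trajectory: action tremor
        v <- sqrt(rowSums(rbind(0, diff(clean))^2)) / tt
        env <- if (max(v) > 0) v / max(v) else v
        for (ax in 1:3) {
          f <- stats::runif(6, 4, 10)
          ph <- stats::runif(6, 0, 2 * pi)
          aw <- stats::rnorm(6)
          raw <- sapply(seq_len(6), function(j) {
            aw[j] * sin(2 * pi * f[j] * t + ph[j])
          })
          raw <- rowSums(raw)
          raw <- raw / stats::sd(raw)
          clean[, ax] <- clean[, ax] + e$tremor_amplitude * env * raw
        }
      }
      pos <- sweep(clean, 2, offsets[m, ], "+")
      colnames(pos) <- c("x", "y", "z")
      markers[[m]] <- pos
    }

    if (limb_side == "left") {
      markers <- lapply(markers, function(p) {
        p[, "x"] <- -p[, "x"]
        p
      })
    }
    suffix <- if (limb_side == "left") "L" else "R"
    names(markers) <- paste0(mk, suffix)

    fn_end <- pad1 + move_dur[["FN"]]
    truth <- list(
      onset_s = pad1, offset_s = fn_end,
      start = floor(pad1 * sample_rate) + 1L,
      end = min(n, floor(fn_end * sample_rate) + 1L)
    )
    meta <- utils::modifyList(
      list(participant = NA_character_, group = NA_character_,
           limb_role = limb_side, activity = activity, side = limb_side),
      meta
    )
    rec <- recording(markers, sample_interval = tt, meta = meta)
    rec$truth <- truth
    rec
  })
}

#' Generate a synthetic cohort of lifting recordings
#'
#' Builds the full study-shaped dataset: every participant contributes both
#' limbs in every activity. Stroke participants (G1) get a pseudo-randomly
#' assigned paretic side; their paretic limb uses `paretic_effect`, the
#' other limb the milder `nonparetic_effect`; control participants (G2) use
#' `control_effect` on both limbs.
#'
#' @param config a [cohort_config()].
#' @return an object of class `mocap_cohort`: a list with `recordings`
#'   (list of [recording()] objects), `meta` (one row per recording:
#'   `recording_id`, `participant_id`, `group`, `limb`, `role`, `activity`)
#'   and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_stroke = 2, n_control = 1,
#'                                      activities = "DG", seed = 7))
#' coh$meta
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  acts <- config$activities
  n_rec <- (config$n_stroke + config$n_control) * 2L * length(acts)
  sides <- c("left", "right")

  paretic_side <- with_seed(config$seed,
    sample(sides, max(config$n_stroke, 1L), replace = TRUE))
  seeds <- derive_seeds(config$seed + 1L, max(n_rec, 1L))

  recs <- vector("list", n_rec)
  meta <- vector("list", n_rec)
  i <- 0L
  add <- function(pid, group, side, role, eff, act) {
    i <<- i + 1L
    recs[[i]] <<- generate_recording(
      act, limb_side = side, effect = eff, seed = seeds[i],
      sample_rate = config$sample_rate, rest_padding = config$rest_padding,
      meta = list(participant = pid, group = group, limb_role = role)
    )
    meta[[i]] <<- data.frame(
      recording_id = sprintf("R%04d", i), participant_id = pid,
      group = group, limb = ifelse(side == "left", "L", "R"),
      role = role, activity = act, stringsAsFactors = FALSE
    )
  }
  for (p in seq_len(config$n_stroke)) {
    pid <- sprintf("S%02d", p)
    for (side in sides) {
      role <- if (side == paretic_side[p]) "paresis" else "non-paresis"
      eff <- if (role == "paresis") config$paretic_effect else config$nonparetic_effect
      for (act in acts) add(pid, "G1", side, role, eff, act)
    }
  }
  for (p in seq_len(config$n_control)) {
    pid <- sprintf("C%02d", p)
    for (side in sides) {
      for (act in acts) add(pid, "G2", side, side, config$control_effect, act)
    }
  }
  meta <- if (n_rec) do.call(rbind, meta) else
    data.frame(recording_id = character(), participant_id = character(),
               group = character(), limb = character(), role = character(),
               activity = character(), stringsAsFactors = FALSE)
  structure(list(recordings = recs, meta = meta, config = config),
            class = "mocap_cohort")
}

#' @export
print.mocap_cohort <- function(x, ...) {
  cat("Synthetic motion-capture cohort:", nrow(x$meta), "recordings\n")
  if (nrow(x$meta)) {
    cat("  groups: ", paste(sprintf("%s=%d", names(table(x$meta$group)),
                                    table(x$meta$group)), collapse = ", "), "\n")
    cat("  activities:", paste(unique(x$meta$activity), collapse = ", "), "\n")
  }
  invisible(x)
}
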