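#' Table of simulation variable ranges
#'
#' Hard ranges of the six modulated simulation variables: number of
#' targets 3-20, target size 0.3-3 units, horizontal target speed
#' 0-5 m/s, target hardness 1-20 units, daylight 0-10 units, rain
#' intensity 0-1 units.
#'
#' @return data.frame with rownames per variable and columns `lo`, `hi`.
#' @export
difficulty_ranges <- function() {
  data.frame(lo = c(3, 0.3, 0, 1, 0, 0),
             hi = c(20, 3, 5, 20, 10, 1),
             row.names = c("n_targets", "target_size", "target_speed",
                           "target_hardness", "daylight", "rain"))
}

#' Simulation difficulty configuration
#'
#' One point in the simulation's modulation space.  Every field is
#' validated against its hard range (see [difficulty_ranges()]).
#'
#' @param n_targets Number of targets, 3-20.
#' @param target_size Target size in units, 0.3-3.
#' @param target_speed Horizontal target speed in m/s, 0-5.
#' @param target_hardness Target hardness in units, 1-20.
#' @param daylight Daylight level in units, 0-10.
#' @param rain Rain intensity in units, 0-1.
#' @return An object of class `difficulty_config`.
#' @export
difficulty_config <- function(n_targets = 10, target_size = 1,
                              target_speed = 0, target_hardness = 1,
                              daylight = 10, rain = 0) {
  cfg <- list(n_targets = n_targets, target_size = target_size,
              target_speed = target_speed, target_hardness = target_hardness,
              daylight = daylight, rain = rain)
  r <- difficulty_ranges()
  for (f in rownames(r)) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < r[f, "lo"] || v > r[f, "hi"]) {
      stop(f, " = ", v, " outside its range [", r[f, "lo"], ", ",
           r[f, "hi"], "]")
    }
  }
  structure(cfg, class = "difficulty_config")
}

#' Session difficulty presets
#'
#' The three scripted scenarios: easy — 10 static targets; medium — 10
#' targets moving at 0.5 m/s; hard — 20 targets at 1 m/s.  Size and
#' hardness are constant across levels (hardness 1: the weapon's power
#' equals it, so one shot destroys a target); baseline reuses the easy
#' layout (the trainee does not shoot during baseline).
#'
#' @param level `"baseline"`, `"easy"`, `"medium"` or `"hard"`.
#' @return A [difficulty_config].
#' @export
difficulty_preset <- function(level = c("easy", "medium", "hard", "baseline")) {
  level <- match.arg(level)
  switch(level,
         baseline = ,
         easy = difficulty_config(n_targets = 10, target_speed = 0),
         medium = difficulty_config(n_targets = 10, target_speed = 0.5),
         hard = difficulty_config(n_targets = 20, target_speed = 1))
}

#' The biocybernetic adaptation rule
#'
#' Parameters of the buffered zone controller: incoming heart-rate and
#' frontal-theta samples are averaged over a sliding buffer, compared
#' against the trainer's HR target zone (default 100-115 BPM) and a
#' theta concentration threshold, and turned into difficulty modulation
#' steps.  The increase step hardens the scene (speed +0.25 m/s, size
#' x0.9, targets +1, rain +0.1, daylight -0.5); the decrease step is its
#' inverse.  Hardness is never modulated (it is tied to the weapon).
#'
#' @param hr_zone Length-2 numeric, target HR zone in BPM (lower < upper).
#' @param theta_threshold Concentration threshold in Bels: the increase
#'   branch only fires while averaged frontal theta exceeds it.
#' @param buffer_len Sliding-buffer length in samples (>= 1); at the
#'   1-Hz plant sampling of [run_closed_loop()] the default 30 is 30 s.
#' @param update_period Seconds between rule evaluations.
#' @param increase,decrease Named step lists: additive `target_speed`,
#'   `n_targets`, `rain`, `daylight` and multiplicative `size_factor`.
#' @return An object of class `adaptive_rule`.
#' @export
adaptive_rule <- function(hr_zone = c(100, 115), theta_threshold = 1.45,
                          buffer_len = 30, update_period = 5,
                          increase = list(target_speed = 0.25,
                                          size_factor = 0.9, n_targets = 1,
                                          rain = 0.1, daylight = -0.5),
                          decrease = list(target_speed = -0.25,
                                          size_factor = 1 / 0.9,
                                          n_targets = -1, rain = -0.1,
                                          daylight = 0.5)) {
  stopifnot(length(hr_zone) == 2, hr_zone[1] < hr_zone[2],
            buffer_len >= 1, update_period > 0)
  structure(list(hr_zone = hr_zone, theta_threshold = theta_threshold,
                 buffer_len = as.integer(buffer_len),
                 update_period = update_period,
                 increase = increase, decrease = decrease),
            class = "adaptive_rule")
}

#' Sliding-buffer average of a metric stream
#'
#' Arithmetic mean over the most recent `buffer_len` samples, emitted
#' only once the buffer is full: sample `i` of the output averages input
#' samples `i .. i + buffer_len - 1`.
#'
#' @param stream Numeric vector of metric samples.
#' @param buffer_len Buffer length in samples (>= 1).
#' @return Numeric vector of length `length(stream) - buffer_len + 1`
#'   (length 0 while the buffer is not yet full).
#' @examples
#' buffered_average(c(100, 110, 120), 3)  # 110
#' @export
buffered_average <- function(stream, buffer_len) {
  stopifnot(buffer_len >= 1)
  n <- length(stream)
  if (n < buffer_len) return(numeric(0))
  cs <- cumsum(c(0, stream))
  (cs[(buffer_len + 1):(n + 1)] - cs[1:(n - buffer_len + 1)]) / buffer_len
}

#' Evaluate the adaptation rule on averaged metrics
#'
#' The decision table of the zone controller:
#' * averaged HR below the zone's lower bound *and* averaged theta above
#'   the concentration threshold — the trainee is under-challenged:
#'   increase difficulty;
#' * averaged HR inside the zone — hold (zero step);
#' * averaged HR above the zone's upper bound — decrease difficulty.
#'
#' Only the increase branch is prescribed by the psychophysiological
#' model; hold and decrease complete the controller so its behaviour is
#' bounded.  Below-zone HR with theta at or under the threshold also
#' holds (the concentration gate is closed).
#'
#' @param rule An [adaptive_rule].
#' @param hr_avg Buffered-average heart rate in BPM.
#' @param theta_avg Buffered-average frontal theta in Bels.
#' @return An object of class `modulation_decision`: `direction`
#'   (`"increase"`, `"hold"`, `"decrease"`), `step` (named list, empty
#'   for hold) and `rationale`.
#' @export
evaluate_rule <- function(rule, hr_avg, theta_avg) {
  stopifnot(inherits(rule, "adaptive_rule"))
  if (!is.finite(hr_avg) || !is.finite(theta_avg)) {
    stop("averaged metrics must be finite")
  }
  zone <- rule$hr_zone
  if (hr_avg > zone[2]) {
    dec <- list(direction = "decrease", step = rule$decrease,
                rationale = "hr above target zone")
  } else if (hr_avg >= zone[1]) {
    dec <- list(direction = "hold", step = list(),
                rationale = "hr inside target zone")
  } else if (theta_avg > rule$theta_threshold) {
    dec <- list(direction = "increase", step = rule$increase,
                rationale = "hr below target zone, concentration present")
  } else {
    dec <- list(direction = "hold", step = list(),
                rationale = "hr below zone but concentration gate closed")
  }
  structure(dec, class = "modulation_decision")
}

#' Apply a modulation decision to a difficulty configuration
#'
#' Adds the decision's step vector and clamps every field to its hard
#' range, so an emitted configuration is always valid; clamping is
#' idempotent.  A hold decision returns the configuration unchanged.
#'
#' @param cfg A [difficulty_config].
#' @param decision A [modulation_decision].
#' @return The modulated [difficulty_config].
#' @export
apply_modulation <- function(cfg, decision) {
  stopifnot(inherits(cfg, "difficulty_config"),
            inherits(decision, "modulation_decision"))
  if (decision$direction == "hold") return(cfg)
  st <- decision$step
  r <- difficulty_ranges()
  clamp <- function(v, f) min(max(v, r[f, "lo"]), r[f, "hi"])
  difficulty_config(
    n_targets = clamp(cfg$n_targets + (st$n_targets %||% 0), "n_targets"),
    target_size = clamp(cfg$target_size * (st$size_factor %||% 1), "target_size"),
    target_speed = clamp(cfg$target_speed + (st$target_speed %||% 0), "target_speed"),
    target_hardness = clamp(cfg$target_hardness + (st$target_hardness %||% 0),
                            "target_hardness"),
    daylight = clamp(cfg$daylight + (st$daylight %||% 0), "daylight"),
    rain = clamp(cfg$rain + (st$rain %||% 0), "rain"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the closed biocybernetic loop against the simulated trainee
#'
#' Alternates plant steps (1-s resolution) with rule evaluations every
#' `update_period` seconds: HR and theta samples stream into sliding
#' buffers, buffered averages are compared against the rule, and the
#' resulting modulation is applied to the difficulty configuration that
#' drives the plant's setpoint.  Deterministic under `seed`.
#'
#' @param rule An [adaptive_rule].
#' @param state Initial [plant_state].
#' @param difficulty Initial [difficulty_config] (default: easy preset).
#' @param duration Session length in seconds (>= 10 update periods).
#' @param seed Integer seed.
#' @param dt Plant step in seconds (default 1).
#' @param ... Plant parameters passed to [plant_step()] (`tau`,
#'   `noise_sd`, `theta_noise_sd`).
#' @return data.frame trajectory with one row per plant step: `time`,
#'   `hr`, `theta`, the six difficulty fields, `decision`, and the
#'   biofeedback `calmness` and `focus` (NA until the buffer fills).
#' @export
run_closed_loop <- function(rule = adaptive_rule(), state = plant_state(),
                            difficulty = difficulty_preset("easy"),
                            duration = 600, seed = 1, dt = 1, ...) {
  stopifnot(inherits(rule, "adaptive_rule"))
  if (duration < 10 * rule$update_period) {
    stop("duration must cover at least 10 update periods")
  }
  n_steps <- floor(duration / dt)
  withr::with_seed(seed, {
    hr_buf <- numeric(0)
    th_buf <- numeric(0)
    rows <- vector("list", n_steps)
    decision <- "hold"
    for (i in seq_len(n_steps)) {
      state <- plant_step(state, difficulty, dt, seed = NULL, ...)
      hr_buf <- c(hr_buf, state$hr)
      th_buf <- c(th_buf, state$theta)
      if (length(hr_buf) > rule$buffer_len) {
        hr_buf <- hr_buf[-1]
        th_buf <- th_buf[-1]
      }
      calm <- NA_real_
      foc <- NA_real_
      if (length(hr_buf) == rule$buffer_len &&
          (state$time %% rule$update_period) < dt / 2) {
        hr_avg <- mean(hr_buf)
        th_avg <- mean(th_buf)
        d <- evaluate_rule(rule, hr_avg, th_avg)
        decision <- d$direction
        difficulty <- apply_modulation(difficulty, d)
        bf <- biofeedback_metrics(hr_avg, th_avg, rule)
        calm <- bf$calmness
        foc <- bf$focus
      }
      rows[[i]] <- data.frame(time = state$time, hr = state$hr,
                              theta = state$theta,
                              n_targets = difficulty$n_targets,
                              target_size = difficulty$target_size,
                              target_speed = difficulty$target_speed,
                              target_hardness = difficulty$target_hardness,
                              daylight = difficulty$daylight,
                              rain = difficulty$rain,
                              decision = decision,
                              calmness = calm, focus = foc)
    }
    traj <- do.call(rbind, rows)
    class(traj) <- c("loop_trajectory", class(traj))
    traj
  })
}

#' Biofeedback display metrics
#'
#' Two unit-interval gauges shown back to the trainee:
#' * calmness — 1 at the center of the HR target zone, falling linearly
#'   to 0 at twice the zone half-width from the center;
#' * focus — an affine ramp of averaged frontal theta from a floor
#'   0.5 Bel below the concentration threshold (focus 0) up to the
#'   threshold itself (focus 1), clamped to \[0, 1\].
#'
#' @param hr_avg Buffered-average HR in BPM.
#' @param theta_avg Buffered-average frontal theta in Bels.
#' @param rule An [adaptive_rule].
#' @return List: `calmness`, `focus`, both in \[0, 1\].
#' @export
biofeedback_metrics <- function(hr_avg, theta_avg, rule = adaptive_rule()) {
  zone <- rule$hr_zone
  center <- mean(zone)
  halfwidth <- diff(zone) / 2
  calmness <- 1 - min(max(abs(hr_avg - center) / (2 * halfwidth), 0), 1)
  floor_th <- rule$theta_threshold - 0.5
  focus <- (theta_avg - floor_th) / (rule$theta_threshold - floor_th)
  list(calmness = calmness, focus = min(max(focus, 0), 1))
}

#' Shooting performance ratio
#'
#' Destroyed targets over shot bullets.
#'
#' @param shots Number of bullets shot (>= 0).
#' @param destroyed Number of destroyed targets (<= shots).
#' @return Ratio in \[0, 1\]; `NA` with a warning when no shot was fired.
#' @examples
#' shooting_performance(50, 32)  # 0.64
#' @export
shooting_performance <- function(shots, destroyed) {
  stopifnot(shots >= 0, destroyed >= 0)
  if (destroyed > shots) stop("destroyed targets cannot exceed shots")
  if (shots == 0) {
    warning("no shots fired; performance undefined")
    return(NA_real_)
  }
  destroyed / shots
}
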