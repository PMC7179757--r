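#' Trainee plant state
#'
#' The "plant", in control terms, is the simulated trainee the adaptation
#' rule acts on: a heart rate, a frontal theta log-power and a latent
#' arousal level, each relaxing toward a difficulty-dependent setpoint.
#'
#' @param hr Heart rate in beats/min (> 0).
#' @param theta Frontal theta log-power in Bels.
#' @param arousal Latent dimensionless arousal in \[0, 1\].
#' @param time Simulation clock in seconds.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(hr = 70, theta = 2.0, arousal = 0, time = 0) {
  vals <- c(hr = hr, theta = theta, arousal = arousal, time = time)
  if (any(!is.finite(vals))) stop("plant_state fields must be finite")
  if (hr <= 0) stop("hr must be positive")
  structure(as.list(vals), class = "plant_state")
}

#' Normalized difficulty index of a simulation configuration
#'
#' The mean of the min-max-normalized simulation variables, oriented so
#' that larger means harder: target speed, target count, inverse target
#' size, target hardness, rain intensity and darkness (1 - daylight).
#' Ranges come from the simulation variable table; the index lies in
#' \[0, 1\] for any in-range configuration and is monotone in every
#' component-wise hardening.
#'
#' @param cfg A [difficulty_config].
#' @return Scalar in \[0, 1\].
#' @export
difficulty_index <- function(cfg) {
  stopifnot(inherits(cfg, "difficulty_config"))
  r <- difficulty_ranges()
  comp <- c(
    (cfg$n_targets - r["n_targets", "lo"]) / diff(unlist(r["n_targets", ])),
    1 - (cfg$target_size - r["target_size", "lo"]) / diff(unlist(r["target_size", ])),
    (cfg$target_speed - r["target_speed", "lo"]) / diff(unlist(r["target_speed", ])),
    (cfg$target_hardness - r["target_hardness", "lo"]) / diff(unlist(r["target_hardness", ])),
    1 - (cfg$daylight - r["daylight", "lo"]) / diff(unlist(r["daylight", ])),
    (cfg$rain - r["rain", "lo"]) / diff(unlist(r["rain", ]))
  )
  mean(comp)
}

#' Difficulty-to-physiology setpoint maps
#'
#' `hr_setpoint()` maps the normalized difficulty index linearly from a
#' resting 70 BPM (index 0) to a maximal-stress 125 BPM (index 1), chosen
#' so the trainer's 100-115 BPM zone is reachable but not trivially so.
#' `theta_setpoint()` applies the opposite-signed map for frontal theta
#' (2.0 Bels at rest down to 1.5 Bels under maximal load), mirroring the
#' observed decline of frontal theta with difficulty.
#'
#' @param difficulty A [difficulty_config].
#' @param rest,max_stress Endpoint values of the linear map.
#' @return Scalar setpoint.
#' @export
hr_setpoint <- function(difficulty, rest = 70, max_stress = 125) {
  rest + (max_stress - rest) * difficulty_index(difficulty)
}

#' @rdname hr_setpoint
#' @export
theta_setpoint <- function(difficulty, rest = 2.0, max_stress = 1.5) {
  rest + (max_stress - rest) * difficulty_index(difficulty)
}

#' Advance the trainee plant by one time step
#'
#' First-order relaxation of heart rate (and theta, and arousal) toward
#' the setpoint implied by the current difficulty:
#' `hr <- hr + (dt/tau) * (setpoint - hr) + noise`.  The time constant
#' `tau = 20` s is the physiologic order of magnitude of an HR response.
#' With `noise_sd = 0` the trajectory is the exact iterated linear map and
#' converges geometrically to the setpoint.
#'
#' @param state A [plant_state].
#' @param difficulty A [difficulty_config]; out-of-range values are an
#'   error.
#' @param dt Time step in seconds (> 0).
#' @param seed Optional integer seed; if `NULL` the ambient RNG stream is
#'   used (as inside [run_closed_loop()], which seeds once).
#' @param tau Relaxation time constant in seconds.
#' @param noise_sd HR noise sd in BPM per sqrt-second.
#' @param theta_noise_sd Theta noise sd in Bels per sqrt-second.
#' @return The advanced [plant_state].
#' @export
plant_step <- function(state, difficulty, dt, seed = NULL,
                       tau = 20, noise_sd = 1, theta_noise_sd = 0.02) {
  stopifnot(inherits(state, "plant_state"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  step_fun <- function() {
    a <- dt / tau
    sp_hr <- hr_setpoint(difficulty)
    sp_th <- theta_setpoint(difficulty)
    idx <- difficulty_index(difficulty)
    hr <- state$hr + a * (sp_hr - state$hr) +
      if (noise_sd > 0) stats::rnorm(1, 0, noise_sd * sqrt(dt)) else 0
    th <- state$theta + a * (sp_th - state$theta) +
      if (theta_noise_sd > 0) stats::rnorm(1, 0, theta_noise_sd * sqrt(dt)) else 0
    ar <- state$arousal + a * (idx - state$arousal)
    plant_state(hr = max(hr, 20), theta = th, arousal = ar,
                time = state$time + dt)
  }
  if (is.null(seed)) step_fun() else withr::with_seed(seed, step_fun())
}
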