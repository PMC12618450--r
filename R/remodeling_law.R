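#' Bone remodeling parameters
#'
#' Constants of the strain-energy-density (SED) driven remodeling law with a
#' lazy zone and quadratic overload resorption.  The rate of apparent
#' density change for a bone element with stimulus \eqn{S = U/\rho} (J/g) is
#' \deqn{d\rho/dt = B(S - (1+\delta)k) - D(S - (1+\delta)k)^2}{
#'       drho/dt = B(S-(1+d)k) - D(S-(1+d)k)^2}
#' above the lazy zone, zero inside it, and
#' \eqn{B(S - (1-\delta)k)} below it.  Setting \code{D = 0} recovers the
#' classical linear law without overload resorption.
#'
#' Time is the dimensionless "time:unit" the constants imply; densities are
#' clamped to \code{[rho_min, rho_max]} at every step.  During a coupled
#' run the stimulus is frozen over \code{resolve_every} Euler steps between
#' finite element re-solves, and homeostasis is declared when the maximum
#' relative density change over a trailing window of
#' \code{check_horizon} checkpoints falls below \code{convergence_tol} (or
#' every element sits at a bound or inside the lazy zone).
#'
#' @param B Remodeling rate constant, default 1.0.
#' @param D Overload-resorption constant, default 60 (0 disables overload).
#' @param k Reference stimulus, J/g, default 0.004.
#' @param delta Lazy-zone half-width fraction, default 0.10.
#' @param dt Forward-Euler time increment, default 0.01.
#' @param rho_min,rho_max Density bounds, g/cm^3, defaults 0.01 and 2.
#' @param s_baseline Homeostatic baseline stimulus, J/g, added to the
#'   mechanical stimulus during coupled runs (default 0).  Setting it to
#'   \code{k} represents the physiological background loading under which
#'   unperturbed bone sits inside the lazy zone, so that only the
#'   swelling-induced stimulus perturbs the remodeling balance; with the
#'   default 0 an unloaded model is in global disuse.
#' @param convergence_tol Relative density change defining homeostasis,
#'   default 0.02.
#' @param resolve_every Euler steps per finite element re-solve (the frozen
#'   stimulus window W), default 100.
#' @param check_horizon Number of trailing checkpoints over which the
#'   convergence change is measured, default 10.
#' @param max_steps Safety cap on checkpoints in a coupled run, default 600.
#' @return An object of class \code{"remodeling_params"}.
#' @export
remodeling_params <- function(B = 1.0, D = 60, k = 0.004, delta = 0.10,
                              dt = 0.01, rho_min = 0.01, rho_max = 2.0,
                              s_baseline = 0,
                              convergence_tol = 0.02, resolve_every = 100,
                              check_horizon = 10, max_steps = 600) {
  stopifnot(B > 0, D >= 0, k > 0, dt > 0, delta >= 0, delta < 1,
            rho_min < rho_max, rho_min > 0, convergence_tol > 0,
            s_baseline >= 0,
            resolve_every >= 1, check_horizon >= 1, max_steps >= 1)
  structure(list(B = B, D = D, k = k, delta = delta, dt = dt,
                 rho_min = rho_min, rho_max = rho_max,
                 s_baseline = s_baseline,
                 convergence_tol = convergence_tol,
                 resolve_every = as.integer(resolve_every),
                 check_horizon = as.integer(check_horizon),
                 max_steps = as.integer(max_steps)),
            class = "remodeling_params")
}

#' Density rate of the remodeling law
#'
#' Piecewise rate d(rho)/dt as a function of stimulus.  The lazy-zone
#' boundaries are inclusive: the rate is exactly zero at S = (1 +/- delta)k,
#' removing a measure-zero ambiguity of the piecewise definition.
#'
#' @param S Stimulus, J/g (non-negative), vectorised.
#' @param p A \code{\link{remodeling_params}} object.
#' @return d(rho)/dt in g/cm^3 per time unit.
#' @export
density_rate <- function(S, p = remodeling_params()) {
  stopifnot(all(S >= 0))
  hi <- (1 + p$delta) * p$k
  lo <- (1 - p$delta) * p$k
  rate <- numeric(length(S))
  over <- S > hi
  under <- S < lo
  x <- S[over] - hi
  rate[over] <- p$B * x - p$D * x^2
  rate[under] <- p$B * (S[under] - lo)
  rate
}

#' Landmarks of the overload rate curve
#'
#' For D > 0 the apposition branch peaks at
#' \code{S_peak = (1+delta)k + B/(2D)} with rate \code{B^2/(4D)} and crosses
#' zero (onset of net overload resorption) at
#' \code{S_zero = (1+delta)k + B/D}.
#'
#' @param p A \code{\link{remodeling_params}} object with \code{D > 0}.
#' @return A list with \code{S_peak}, \code{rate_peak}, \code{S_zero}.
#' @export
rate_curve_landmarks <- function(p = remodeling_params()) {
  if (p$D <= 0) stop("no landmarks: D = 0 (linear law has no overload branch)")
  hi <- (1 + p$delta) * p$k
  list(S_peak = hi + p$B / (2 * p$D),
       rate_peak = p$B^2 / (4 * p$D),
       S_zero = hi + p$B / p$D)
}

#' One forward-Euler density step with clamping
#'
#' @param rho Density, g/cm^3 (within bounds), vectorised.
#' @param S Stimulus, J/g, same length or scalar.
#' @param p A \code{\link{remodeling_params}} object.
#' @return Updated density clamp(rho + dt * rate, rho_min, rho_max).
#' @export
step_density <- function(rho, S, p = remodeling_params()) {
  rho1 <- rho + p$dt * density_rate(S, p)
  pmin(pmax(rho1, p$rho_min), p$rho_max)
}

#' Iterate a single element under a constant (frozen) stimulus
#'
#' Repeats the Euler update with S held fixed until the density stops
#' changing, which happens only at a density bound or when S lies inside
#' the lazy zone.  The per-step change is constant in this regime, so the
#' trajectory is linear in time until the clamp absorbs it.
#'
#' @param rho0 Initial density, g/cm^3.
#' @param S Constant stimulus, J/g.
#' @param p A \code{\link{remodeling_params}} object.
#' @param max_steps Step cap (the constant-rate trajectory needs at most
#'   (rho_max - rho_min) / (dt * |rate|) steps).
#' @return A list with \code{rho} (final density), \code{steps} taken, and
#'   \code{rate} (the constant rate).
#' @export
remodel_fixed_stimulus <- function(rho0, S, p = remodeling_params(),
                                   max_steps = 1e7) {
  stopifnot(rho0 >= p$rho_min, rho0 <= p$rho_max)
  rate <- density_rate(S, p)
  if (rate == 0) return(list(rho = rho0, steps = 0L, rate = rate))
  # constant rate: jump to the absorbing bound directly, counting steps
  bound <- if (rate > 0) p$rho_max else p$rho_min
  steps <- ceiling((bound - rho0) / (p$dt * rate))
  steps <- min(steps, max_steps)
  rho <- pmin(pmax(rho0 + steps * p$dt * rate, p$rho_min), p$rho_max)
  list(rho = rho, steps = as.integer(steps), rate = rate)
}

#' Iterate a single element with frozen strain energy, stimulus U/rho
#'
#' Holds the element's strain energy density U fixed and recomputes the
#' stimulus S = U/rho after every Euler step, integrating until remodeling
#' ceases (the stimulus enters the lazy zone, a bound absorbs the density,
#' or the update falls below machine resolution).  When the equilibrium is
#' interior, the density converges to \code{rho = U / ((1+delta)k)} (from
#' below the zone) or \code{U / ((1-delta)k)} (from above).
#'
#' @param rho0 Initial density, g/cm^3.
#' @param U Frozen strain energy density, J/cm^3.
#' @param p A \code{\link{remodeling_params}} object.
#' @param record_every If positive, record (step, rho, S) every this many
#'   steps for trajectory comparison; 0 records nothing.
#' @param max_steps Step cap.
#' @return A list with \code{rho}, \code{S} (final stimulus), \code{steps},
#'   \code{converged}, and (if recorded) a data frame \code{trajectory}.
#' @export
remodel_fixed_energy <- function(rho0, U, p = remodeling_params(),
                                 record_every = 0, max_steps = 5e6) {
  stopifnot(U >= 0, rho0 >= p$rho_min, rho0 <= p$rho_max)
  rho <- rho0
  rec <- if (record_every > 0) {
    list(step = integer(), rho = numeric(), S = numeric())
  }
  converged <- FALSE
  step <- 0L
  # scalar constants hoisted out of the hot loop
  hi <- (1 + p$delta) * p$k; lo <- (1 - p$delta) * p$k
  B <- p$B; D <- p$D; dt <- p$dt
  rmin <- p$rho_min; rmax <- p$rho_max
  while (step < max_steps) {
    S <- U / rho
    if (S > hi) {
      x <- S - hi
      rate <- B * x - D * x * x
    } else if (S < lo) {
      rate <- B * (S - lo)
    } else { converged <- TRUE; break }            # lazy zone
    if (rate == 0) { converged <- TRUE; break }
    rho1 <- rho + dt * rate
    if (rho1 < rmin) rho1 <- rmin else if (rho1 > rmax) rho1 <- rmax
    step <- step + 1L
    if (record_every > 0 && step %% record_every == 0) {
      rec$step <- c(rec$step, step)
      rec$rho <- c(rec$rho, rho1)
      rec$S <- c(rec$S, U / rho1)
    }
    if (rho1 == rho) { converged <- TRUE; break }  # bound or underflow
    rho <- rho1
  }
  out <- list(rho = rho, S = U / rho, steps = step, converged = converged)
  if (record_every > 0) out$trajectory <- as.data.frame(rec)
  out
}
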