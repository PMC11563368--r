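# Synthetic MTU loading scenarios: quasi-static series equilibrium between
# a minimal isometric muscle belly and a Hill-type tendon, driven by
# parametric MTU-length and activation profiles.

#' Minimal isometric muscle belly
#'
#' The simplest contractile-element model under which series equilibrium
#' with a monotone tendon is well posed: a Gaussian active force-length
#' curve, \eqn{f_a(\lambda) = e^{-((\lambda-1)/w)^2}} with
#' \eqn{\lambda = l_{CE}/l_{CE,opt}}, equal to 1 at the optimum length, and
#' an exponential passive curve \eqn{f_p(\lambda) = e^{k(\lambda-1)} - 1}
#' active only beyond the optimum length. Normalised belly force is
#' \eqn{a f_a + f_p}; no force-velocity or activation dynamics.
#'
#' @param width active force-length width `w` (dimensionless), positive.
#' @param passive_k passive exponential stiffness `k` (dimensionless),
#'   positive.
#' @return object of class `muscle_belly`.
#' @export
muscle_belly <- function(width = 0.45, passive_k = 1.7) {
  stopifnot(width > 0, passive_k > 0)
  structure(list(width = width, passive_k = passive_k),
            class = "muscle_belly")
}

#' Normalised belly force at a contractile-element length
#'
#' @param belly a [muscle_belly()].
#' @param l_ce contractile-element length in m (force is 0 at or below 0).
#' @param l_ce_opt optimum contractile-element length in m.
#' @param a activity in `[0, 1]`.
#' @return normalised force (units of f_max).
#' @export
belly_force <- function(belly, l_ce, l_ce_opt, a) {
  stopifnot(inherits(belly, "muscle_belly"))
  lam <- l_ce / l_ce_opt
  f_act <- exp(-((lam - 1) / belly$width)^2)
  f_pas <- ifelse(lam > 1, exp(belly$passive_k * (lam - 1)) - 1, 0)
  ifelse(l_ce <= 0, 0, a * f_act + f_pas)
}

#' Quasi-static tendon strain at series equilibrium
#'
#' Solves for the tendon strain \eqn{\varepsilon} (percent) at which the
#' belly force at \eqn{l_{CE} = l_{MTU} - l_{SEE,0}(1+\varepsilon/100)}
#' balances the tendon force \eqn{f_{max}\, F_t(\varepsilon)}, by bisection
#' until the force residual is below `tol_rel * f_max`. If the MTU is slack
#' (no positive-force solution at zero strain) the strain is 0.
#'
#' @param l_mtu_m MTU length in m, positive.
#' @param a activity in `[0, 1]`.
#' @param belly a [muscle_belly()].
#' @param tendon a [tendon_curve][tmm_tendon].
#' @param l_see_0_m tendon slack length in m, positive.
#' @param l_ce_opt_m optimum contractile-element length in m, positive.
#' @param tol_rel relative force tolerance of the bisection.
#' @return tendon strain in percent.
#' @export
equilibrium_tendon_strain <- function(l_mtu_m, a, belly, tendon,
                                      l_see_0_m, l_ce_opt_m,
                                      tol_rel = 1e-8) {
  stopifnot(l_mtu_m > 0, a >= 0, a <= 1, l_see_0_m > 0, l_ce_opt_m > 0,
            inherits(belly, "muscle_belly"), inherits(tendon, "tendon_curve"))
  resid <- function(eps) {
    l_ce <- l_mtu_m - l_see_0_m * (1 + eps / 100)
    belly_force(belly, l_ce, l_ce_opt_m, a) - tendon_force(tendon, eps)
  }
  if (resid(0) <= tol_rel) return(0)  # slack or balanced at zero strain
  lo <- 0
  hi <- 1
  while (resid(hi) > 0) {
    hi <- hi * 2
    if (hi > tendon$domain[2]) {
      if (resid(tendon$domain[2]) > 0) {
        stop(sprintf(paste0(
          "series equilibrium not bracketable: belly force still exceeds ",
          "tendon force at the domain edge %g%% strain ",
          "(l_mtu = %g m, a = %g, l_see_0 = %g m)"),
          tendon$domain[2], l_mtu_m, a, l_see_0_m), call. = FALSE)
      }
      hi <- tendon$domain[2]
      break
    }
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r <- resid(mid)
    if (abs(r) < tol_rel) return(mid)
    if (r > 0) lo <- mid else hi <- mid
  }
  stop(sprintf("bisection did not reach |residual| < %g within 200 iterations (residual %g)",
               tol_rel, resid((lo + hi) / 2)), call. = FALSE)
}

#' Synthetic loading scenario specification
#'
#' Two scenario kinds with parametric, infinitely differentiable profiles:
#' \describe{
#'   \item{`gait_like`}{one raised-cosine MTU-lengthening cycle with a
#'     synchronous activation bump, emulating the stance-to-swing loading
#'     of a plantar flexor over a partial gait cycle;}
#'   \item{`overstretch_ramp`}{a linear MTU-length ramp at constant
#'     activation, emulating the progressive over-stretch a muscle spanning
#'     a separating joint experiences during model repositioning.}
#' }
#' An optional `slack_reduction` fraction shortens the muscle's tendon
#' slack length before simulation, introducing tendon pre-strain at the
#' first sample. Optional Gaussian strain noise is seeded and reproducible.
#'
#' @param kind scenario kind.
#' @param duration duration in s, positive.
#' @param sample_rate sampling rate in Hz, positive.
#' @param t_start start time in s.
#' @param baseline_length baseline MTU length in m; defaults to
#'   `l_ce_opt + l_see_0` of the simulated muscle (taut, unstrained).
#' @param amplitude MTU lengthening amplitude in m.
#' @param phase profile phase offset in radians (`gait_like` only).
#' @param activation_base,activation_peak activity bounds in `[0, 1]`.
#' @param slack_reduction tendon slack-length reduction fraction in `[0, 1)`.
#' @param noise_sd standard deviation of additive strain noise in percent.
#' @param seed integer seed for the noise.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("gait_like", "overstretch_ramp"),
                          duration = 0.25, sample_rate = 400,
                          t_start = 0.83, baseline_length = NULL,
                          amplitude = 0.006, phase = 0,
                          activation_base = 0.05, activation_peak = 0.4,
                          slack_reduction = 0, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(duration > 0, sample_rate > 0, amplitude >= 0,
            activation_base >= 0, activation_base <= 1,
            activation_peak >= 0, activation_peak <= 1,
            slack_reduction >= 0, slack_reduction < 1, noise_sd >= 0)
  structure(
    list(kind = kind, duration = duration, sample_rate = sample_rate,
         t_start = t_start, baseline_length = baseline_length,
         amplitude = amplitude, phase = phase,
         activation_base = activation_base,
         activation_peak = activation_peak,
         slack_reduction = slack_reduction, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

scenario_profiles <- function(spec, baseline) {
  tt <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  u <- tt / spec$duration
  if (spec$kind == "gait_like") {
    bump <- 0.5 * (1 - cos(2 * pi * u + spec$phase))
    l_mtu <- baseline + spec$amplitude * bump
    act <- spec$activation_base +
      (spec$activation_peak - spec$activation_base) * bump
  } else {
    l_mtu <- baseline + spec$amplitude * u
    act <- rep(spec$activation_base, length(u))
  }
  list(time = spec$t_start + tt, l_mtu = l_mtu, activity = pmin(pmax(act, 0), 1))
}

#' Generate a synthetic MTU trace
#'
#' Runs the quasi-static series-equilibrium solve of
#' [equilibrium_tendon_strain()] at every sample of the scenario's MTU
#' length and activation profiles. The MTU force is the tendon force at the
#' equilibrium strain, \eqn{F = f_{max} F_t(\varepsilon)}. Deterministic
#' given `(spec, muscle)`; with `noise_sd > 0`, seeded Gaussian noise is
#' added to the strain series only.
#'
#' @param spec a [scenario_spec()].
#' @param muscle a [muscle_param_set()]; the spec's `slack_reduction` is
#'   applied on top of the muscle's slack length.
#' @param belly a [muscle_belly()].
#' @return an [mtu_trace()] with force, strain and activity series.
#' @export
generate_trace <- function(spec, muscle = default_audit_muscle(),
                           belly = muscle_belly()) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(muscle, "muscle_param_set"))
  l_see_0 <- apply_slack_reduction(muscle$l_see_0, spec$slack_reduction)
  baseline <- spec$baseline_length
  if (is.null(baseline)) baseline <- muscle$l_ce_opt + muscle$l_see_0
  prof <- scenario_profiles(spec, baseline)
  eps <- vapply(seq_along(prof$time), function(i) {
    equilibrium_tendon_strain(prof$l_mtu[i], prof$activity[i], belly,
                              muscle$tendon, l_see_0, muscle$l_ce_opt)
  }, numeric(1))
  force <- muscle$f_max * tendon_force(muscle$tendon, eps)
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    eps <- pmax(eps + stats::rnorm(length(eps), sd = spec$noise_sd), 0)
  }
  mtu_trace(time = prof$time, mtu_force = force, tendon_strain = eps,
            activity = prof$activity, muscle = muscle)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default muscle for the bundled scenarios
#'
#' A plantar-flexor-like muscle: maximum isometric force 1558 N
#' (PCSA 67.7 cm^2 at 23 N/cm^2), optimum contractile-element length
#' 0.10 m, tendon slack length 0.361 m, Thelen-type tendon. The slack
#' length matches a human medial gastrocnemius; a 20% reduction of it is
#' the canonical ill-tuned parameterisation the audit should flag.
#'
#' @param slack_reduction slack-length reduction fraction.
#' @return a [muscle_param_set()].
#' @export
default_audit_muscle <- function(slack_reduction = 0) {
  muscle_param_set(
    name = "gastrocnemius_like", f_max = 1558, l_ce_opt = 0.10,
    l_see_0 = 0.361, tendon = tmm_tendon(), slack_reduction = slack_reduction
  )
}
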