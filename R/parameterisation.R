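# MTU parameterisation: adapting literature segment lengths to a model's
# MTU length and applying slack-length perturbations.

#' Muscle-tendon segment lengths
#'
#' @param l_ce_opt optimum contractile-element length in m, positive.
#' @param l_see_0 tendon slack length in m, positive.
#' @return object of class `segment_lengths`.
#' @export
segment_lengths <- function(l_ce_opt, l_see_0) {
  if (!is.numeric(l_ce_opt) || l_ce_opt <= 0 ||
      !is.numeric(l_see_0) || l_see_0 <= 0) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  structure(list(l_ce_opt = l_ce_opt, l_see_0 = l_see_0),
            class = "segment_lengths")
}

#' Scale literature segment lengths onto a model's MTU length
#'
#' Literature optimum contractile-element and tendon slack lengths rarely
#' sum to the MTU length present in a given model. Both are rescaled
#' proportionally so that \eqn{l_{MTU,mdl} = l_{CE,opt} + l_{SEE,0}} holds
#' while the literature ratio between the two segments is preserved.
#'
#' @param l_mtu_model_m total MTU length in the model, in m, positive.
#' @param lit [segment_lengths()] from the literature.
#' @return a [segment_lengths()] summing exactly to `l_mtu_model_m`.
#' @examples
#' scale_segment_lengths(0.33, segment_lengths(0.10, 0.20))
#' @export
scale_segment_lengths <- function(l_mtu_model_m, lit) {
  stopifnot(inherits(lit, "segment_lengths"))
  if (!is.numeric(l_mtu_model_m) || length(l_mtu_model_m) != 1L ||
      is.na(l_mtu_model_m) || l_mtu_model_m <= 0) {
    stop("`l_mtu_model_m` must be a positive scalar", call. = FALSE)
  }
  k <- l_mtu_model_m / (lit$l_ce_opt + lit$l_see_0)
  segment_lengths(lit$l_ce_opt * k, lit$l_see_0 * k)
}

#' Reduce a tendon slack length by a fraction
#'
#' The perturbation used to emulate an ill-tuned tendon slack length: a
#' 20% reduction of a gastrocnemius slack length of 0.361 m gives 0.2888 m
#' and introduces substantial tendon pre-strain at the start of a gait
#' cycle.
#'
#' @param l_see_0_m tendon slack length in m, positive.
#' @param fraction reduction fraction in `[0, 1)`.
#' @return reduced slack length `l_see_0_m * (1 - fraction)`.
#' @export
apply_slack_reduction <- function(l_see_0_m, fraction) {
  if (!is.numeric(l_see_0_m) || any(l_see_0_m <= 0)) {
    stop("`l_see_0_m` must be positive", call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1) {
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  }
  l_see_0_m * (1 - fraction)
}

#' Muscle parameter set
#'
#' Unit-consistent Hill-type parameters of one muscle-tendon unit. If
#' `f_max` is omitted it is computed from `pcsa` and `sigma_max` via
#' [fmax_from_pcsa()]. If `l_mtu_model` is supplied, the literature segment
#' lengths are rescaled with [scale_segment_lengths()] so they sum to the
#' model's MTU length. A `slack_reduction` fraction is applied to the
#' (possibly rescaled) slack length last, mirroring a deliberate
#' parameterisation error.
#'
#' @param name muscle label.
#' @param f_max maximum isometric force in N (optional if `pcsa` given).
#' @param l_ce_opt optimum contractile-element length in m.
#' @param l_see_0 tendon slack length in m.
#' @param tendon a [tendon_curve][tmm_tendon].
#' @param pcsa physiological cross-sectional area in cm^2 (optional).
#' @param sigma_max maximum isometric stress in N/cm^2.
#' @param l_mtu_model model MTU length in m (optional).
#' @param slack_reduction slack-length reduction fraction in `[0, 1)`.
#' @return object of class `muscle_param_set`.
#' @export
muscle_param_set <- function(name, f_max = NULL, l_ce_opt, l_see_0,
                             tendon = tmm_tendon(), pcsa = NULL,
                             sigma_max = 23, l_mtu_model = NULL,
                             slack_reduction = 0) {
  if (is.null(f_max)) {
    if (is.null(pcsa)) {
      stop("supply `f_max` or `pcsa` for muscle '", name, "'", call. = FALSE)
    }
    f_max <- fmax_from_pcsa(pcsa, sigma_max)
  }
  if (!is.numeric(f_max) || f_max <= 0) stop("`f_max` must be positive", call. = FALSE)
  stopifnot(inherits(tendon, "tendon_curve"))
  seg <- segment_lengths(l_ce_opt, l_see_0)
  if (!is.null(l_mtu_model)) seg <- scale_segment_lengths(l_mtu_model, seg)
  l_see <- apply_slack_reduction(seg$l_see_0, slack_reduction)
  structure(
    list(name = name, f_max = f_max, l_ce_opt = seg$l_ce_opt,
         l_see_0 = l_see, l_see_0_original = seg$l_see_0,
         slack_reduction = slack_reduction, tendon = tendon,
         pcsa = pcsa, sigma_max = sigma_max),
    class = "muscle_param_set"
  )
}

#' @export
print.muscle_param_set <- function(x, ...) {
  cat(sprintf(
    "<muscle_param_set> %s: Fmax %.1f N, l_ce_opt %.4f m, l_see_0 %.4f m (%s tendon)%s\n",
    x$name, x$f_max, x$l_ce_opt, x$l_see_0, x$tendon$family,
    if (x$slack_reduction > 0)
      sprintf(", slack reduced %.0f%%", 100 * x$slack_reduction) else ""))
  invisible(x)
}
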