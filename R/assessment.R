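# Injury grading of MTU time series against force-based MSIC thresholds
# and strain-based minor TSIC thresholds.

#' Muscle-tendon-unit time series
#'
#' A uniformly ordered trace of MTU force, tendon strain and muscular
#' activity, owned by one muscle. Activity may be omitted; the assessments
#' then assume full activity (a = 1), which for the usual MSIC scaling is
#' the conservative choice, and say so in a warning.
#'
#' @param time time in s, strictly increasing, length >= 2.
#' @param mtu_force MTU force in N (optional, needed for MSIC).
#' @param tendon_strain tendon strain in percent (optional, needed for TSIC).
#' @param activity muscular activity in `[0, 1]` (optional).
#' @param muscle a [muscle_param_set()] or a label; `f_max` is required for
#'   MSIC grading.
#' @return object of class `mtu_trace`.
#' @export
mtu_trace <- function(time, mtu_force = NULL, tendon_strain = NULL,
                      activity = NULL, muscle = NULL) {
  time <- as.numeric(time)
  if (length(time) < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing", call. = FALSE)
  n <- length(time)
  chk <- function(v, nm) {
    if (is.null(v)) return(NULL)
    v <- as.numeric(v)
    if (length(v) != n) {
      stop(sprintf("`%s` length (%d) differs from `time` length (%d)",
                   nm, length(v), n), call. = FALSE)
    }
    v
  }
  mtu_force <- chk(mtu_force, "mtu_force")
  tendon_strain <- chk(tendon_strain, "tendon_strain")
  activity <- chk(activity, "activity")
  if (is.null(mtu_force) && is.null(tendon_strain)) {
    stop("trace needs at least one of `mtu_force`, `tendon_strain`", call. = FALSE)
  }
  if (!is.null(activity) && (any(activity < 0) || any(activity > 1))) {
    stop("`activity` must lie in [0, 1]", call. = FALSE)
  }
  label <- if (inherits(muscle, "muscle_param_set")) muscle$name
           else if (is.character(muscle)) muscle else "muscle"
  structure(
    list(time = time, mtu_force = mtu_force, tendon_strain = tendon_strain,
         activity = activity, muscle = muscle, label = label),
    class = "mtu_trace"
  )
}

#' @export
print.mtu_trace <- function(x, ...) {
  cat(sprintf("<mtu_trace> %s: %d samples on t = [%.3f, %.3f] s (%s%s%s)\n",
              x$label, length(x$time), x$time[1], x$time[length(x$time)],
              if (is.null(x$mtu_force)) "" else "force ",
              if (is.null(x$tendon_strain)) "" else "strain ",
              if (is.null(x$activity)) "" else "activity"))
  invisible(x)
}

#' MSIC force thresholds
#'
#' The force-based muscle strain injury criterion scales with the muscle's
#' maximum isometric force and the momentary activity. Minor and major
#' thresholds are supplied either as functions `function(f_max, a)`
#' returning N, or as coefficient pairs `c(c0, c1)` for the linear-in-
#' activity template \eqn{F_{thr} = F_{max}(c_0 + c_1 a)}. The published
#' minor/major coefficients live in the MSIC literature and are not bundled
#' here; the package default (`minor = c(1, 0)`, `major = c(2.5, 0)`) is an
#' illustrative placeholder documented as such. The rupture threshold is
#' fixed at the force to failure \eqn{F_{tf} = 3 F_{max}}, independent of
#' activity.
#'
#' @param minor,major threshold specifications as above.
#' @return object of class `msic_thresholds` with elements `minor`,
#'   `major` (functions of `(f_max, a)`) and `rupture_factor = 3`.
#' @export
msic_thresholds <- function(minor = c(1, 0), major = c(2.5, 0)) {
  as_fun <- function(spec, nm) {
    if (is.function(spec)) return(spec)
    if (is.numeric(spec) && length(spec) == 2L) {
      force(spec)
      return(function(f_max, a) f_max * (spec[1] + spec[2] * a))
    }
    stop(sprintf("`%s` must be a function(f_max, a) or c(c0, c1)", nm),
         call. = FALSE)
  }
  structure(
    list(minor = as_fun(minor, "minor"), major = as_fun(major, "major"),
         rupture_factor = 3),
    class = "msic_thresholds"
  )
}

check_msic_ordering <- function(thr, f_max) {
  a <- seq(0, 1, by = 0.05)
  lo <- thr$minor(f_max, a)
  hi <- thr$major(f_max, a)
  ru <- thr$rupture_factor * f_max
  if (any(lo > hi + 1e-9) || any(hi > ru + 1e-9)) {
    stop("MSIC threshold ordering minor <= major <= rupture violated for some activity",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' First crossing of a threshold
#'
#' Earliest time at which `values >= threshold`, with the crossing time
#' linearly interpolated between the bracketing samples; a sample exactly
#' at the threshold counts as crossed. Returns `NA` if the threshold is
#' never reached.
#'
#' @param time sample times, strictly increasing.
#' @param values sampled series, same length as `time`.
#' @param threshold scalar threshold.
#' @return crossing time in s, or `NA_real_`.
#' @examples
#' detect_first_crossing(c(0, 1), c(0, 2), 1)  # 0.5
#' @export
detect_first_crossing <- function(time, values, threshold) {
  if (length(time) != length(values)) {
    stop("`time` and `values` must have equal length", call. = FALSE)
  }
  hit <- which(values >= threshold)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1L]
  if (i == 1L || values[i] == threshold) return(time[i])
  # interpolate between the last sub-threshold sample and the crossing one
  t0 <- time[i - 1L]; t1 <- time[i]
  v0 <- values[i - 1L]; v1 <- values[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

new_events <- function(muscle = character(), criterion = character(),
                       grade = character(), t_cross = numeric(),
                       peak_value = numeric(), threshold = numeric(),
                       beyond_validated = logical()) {
  structure(
    data.frame(muscle = muscle, criterion = criterion, grade = grade,
               t_cross = t_cross, peak_value = peak_value,
               threshold = threshold, beyond_validated = beyond_validated,
               stringsAsFactors = FALSE),
    class = c("injury_events", "data.frame")
  )
}

#' Grade a trace against the minor TSIC threshold
#'
#' Reports at most one event: the first crossing of the minor tendon-strain
#' threshold, with the trace's peak strain recorded as the event's peak
#' value. Only the minor grade is evaluated; the Hill-type tendon curves
#' reproduce toe plus linear elasticity only and lose validity at the
#' large strains where major injury or rupture would occur.
#'
#' @param trace an [mtu_trace()] carrying `tendon_strain`.
#' @param minor_threshold_pct minor TSIC threshold in percent strain,
#'   positive (tendon-specific; see [derive_minor_threshold()]).
#' @return an event data frame with 0 or 1 rows.
#' @export
assess_tsic <- function(trace, minor_threshold_pct) {
  stopifnot(inherits(trace, "mtu_trace"))
  if (!is.numeric(minor_threshold_pct) || length(minor_threshold_pct) != 1L ||
      is.na(minor_threshold_pct) || minor_threshold_pct <= 0) {
    stop("`minor_threshold_pct` must be a positive scalar", call. = FALSE)
  }
  if (is.null(trace$tendon_strain)) {
    stop("trace has no `tendon_strain` series", call. = FALSE)
  }
  t_cross <- detect_first_crossing(trace$time, trace$tendon_strain,
                                   minor_threshold_pct)
  if (is.na(t_cross)) return(new_events())
  new_events(muscle = trace$label, criterion = "TSIC", grade = "minor",
             t_cross = t_cross, peak_value = max(trace$tendon_strain),
             threshold = minor_threshold_pct, beyond_validated = FALSE)
}

#' Grade a trace against the MSIC force thresholds
#'
#' Evaluates each sample's MTU force against the minor and major thresholds
#' computed from the muscle's maximum isometric force and the momentary
#' activity, and against the fixed rupture threshold of three maximum
#' isometric forces. The first crossing of each grade is reported. Major
#' and rupture events are flagged `beyond_validated`: the tendon/muscle
#' material models lose validity in the plastic range, so only the minor
#' grade is inside the validated assessment range.
#'
#' @param trace an [mtu_trace()] carrying `mtu_force` and a muscle with
#'   `f_max`.
#' @param thresholds an [msic_thresholds()].
#' @return an event data frame with 0-3 rows (highest grade first).
#' @export
assess_msic <- function(trace, thresholds = msic_thresholds()) {
  stopifnot(inherits(trace, "mtu_trace"), inherits(thresholds, "msic_thresholds"))
  if (is.null(trace$mtu_force)) stop("trace has no `mtu_force` series", call. = FALSE)
  if (!inherits(trace$muscle, "muscle_param_set")) {
    stop("trace needs a muscle_param_set (for f_max) to grade MSIC", call. = FALSE)
  }
  f_max <- trace$muscle$f_max
  check_msic_ordering(thresholds, f_max)
  a <- trace$activity
  if (is.null(a)) {
    warning("trace has no activity series; assuming full activity (a = 1)",
            call. = FALSE)
    a <- rep(1, length(trace$time))
  }
  grades <- list(
    rupture = rep(thresholds$rupture_factor * f_max, length(a)),
    major = thresholds$major(f_max, a),
    minor = thresholds$minor(f_max, a)
  )
  peak <- max(trace$mtu_force)
  rows <- lapply(names(grades), function(g) {
    thr <- grades[[g]]
    # crossing of a time-varying threshold: first zero-upcrossing of the margin
    t_cross <- detect_first_crossing(trace$time, trace$mtu_force - thr, 0)
    if (is.na(t_cross)) return(NULL)
    new_events(muscle = trace$label, criterion = "MSIC", grade = g,
               t_cross = t_cross, peak_value = peak,
               threshold = if (length(unique(thr)) == 1L) thr[1] else NA_real_,
               beyond_validated = g != "minor")
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(new_events())
  out <- do.call(rbind, rows)
  class(out) <- c("injury_events", "data.frame")
  out
}

#' Audit a model's muscle traces for strain injuries
#'
#' Runs both injury criteria on every trace: TSIC against each muscle's
#' minor tendon-strain threshold and MSIC against the activity-scaled force
#' thresholds. The model passes the audit if and only if no injury event of
#' any kind is detected anywhere — the operating assumption being that
#' physiological movement must not injure a correctly built and
#' parameterised model.
#'
#' @param traces a list of [mtu_trace()] objects (or a single trace).
#' @param tsic_thresholds minor TSIC thresholds in percent strain: a single
#'   number applied to all muscles, or a named vector keyed by muscle
#'   label. Muscles without a threshold (or traces without strain) skip
#'   TSIC; traces without force or `f_max` skip MSIC.
#' @param msic an [msic_thresholds()].
#' @return object of class `injury_report`: list with `events` (ordered by
#'   muscle, then time), `passes`, `n_traces`, `schema_version`.
#' @export
audit_model <- function(traces, tsic_thresholds, msic = msic_thresholds()) {
  if (inherits(traces, "mtu_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("need at least one trace", call. = FALSE)
  stopifnot(all(vapply(traces, inherits, logical(1), "mtu_trace")))
  events <- new_events()
  for (tr in traces) {
    thr <- if (length(tsic_thresholds) == 1L && is.null(names(tsic_thresholds))) {
      tsic_thresholds
    } else {
      unname(tsic_thresholds[tr$label])
    }
    if (!is.null(tr$tendon_strain) && length(thr) == 1L && !is.na(thr)) {
      events <- rbind(events, assess_tsic(tr, thr))
    }
    if (!is.null(tr$mtu_force) && inherits(tr$muscle, "muscle_param_set")) {
      events <- rbind(events, assess_msic(tr, msic))
    }
  }
  events <- events[order(events$muscle, events$t_cross), , drop = FALSE]
  rownames(events) <- NULL
  class(events) <- c("injury_events", "data.frame")
  structure(
    list(events = events, passes = nrow(events) == 0L,
         n_traces = length(traces), schema_version = "1.0"),
    class = "injury_report"
  )
}

#' @export
print.injury_report <- function(x, ...) {
  cat(sprintf("<injury_report> %d trace(s): %s\n", x$n_traces,
              if (x$passes) "PASS (no strain injuries detected)"
              else sprintf("FAIL (%d injury event(s))", nrow(x$events))))
  if (!x$passes) print.data.frame(x$events, digits = 4, row.names = FALSE)
  invisible(x)
}
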