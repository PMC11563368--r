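# Shared fixtures, built in code at test time.

# linear strain ramp trace between two times
ramp_trace <- function(t0 = 0.83, t1 = 1.08, strain0 = 3.84, strain1 = 5.45,
                       n = 26, muscle = "gastrocnemius_like") {
  tt <- seq(t0, t1, length.out = n)
  strain <- strain0 + (strain1 - strain0) * (tt - t0) / (t1 - t0)
  mtu_trace(time = tt, tendon_strain = strain, muscle = muscle)
}

# force trace with constant activity and attached muscle (for MSIC)
force_trace <- function(force, time = seq(0, 1, length.out = length(force)),
                        activity = rep(0, length(force)),
                        f_max = 1000, name = "m") {
  m <- muscle_param_set(name = name, f_max = f_max, l_ce_opt = 0.1,
                        l_see_0 = 0.2)
  mtu_trace(time = time, mtu_force = force, activity = activity, muscle = m)
}

# brute-force first-crossing oracle: scan samples, interpolate each segment
oracle_first_crossing <- function(time, values, threshold) {
  n <- length(values)
  if (values[1] >= threshold) return(time[1])
  for (i in 2:n) {
    if (values[i] >= threshold) {
      if (values[i] == threshold) return(time[i])
      frac <- (threshold - values[i - 1]) / (values[i] - values[i - 1])
      return(time[i - 1] + frac * (time[i] - time[i - 1]))
    }
  }
  NA_real_
}

# brute-force intersection oracle: bisection on seg(x) - line(x)
oracle_intersection <- function(seg, line, lo = -100, hi = 100,
                                tol = 1e-12) {
  g <- function(x) (seg$slope * x + seg$intercept) -
    (line$slope * x + line$intercept)
  stopifnot(g(lo) * g(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
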