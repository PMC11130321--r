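# Shared helpers for the suite: independent oracles and tiny builders.

# Brute-force minimization of the 1-D soft-margin hinge objective over a
# dense (boundary, w) grid. Independent of the scan solver: evaluates the
# objective J(w, t) = w^2/2 + C sum u_i max(0, 1 - y_i w (x_i - t))
# directly at every grid point.
brute_force_svm <- function(x, y, u, C,
                            t_grid = seq(min(x) - 2, max(x) + 2, length.out = 801),
                            w_grid = seq(0, 5, length.out = 801)) {
  best <- list(objective = Inf, t = NA, w = NA)
  for (t in t_grid) {
    g <- y * (x - t)
    h <- pmax(0, 1 - outer(g, w_grid))
    dim(h) <- c(length(g), length(w_grid))
    J <- w_grid^2 / 2 + C * colSums(u * h)
    k <- which.min(J)
    if (J[k] < best$objective) {
      best <- list(objective = J[k], t = t, w = w_grid[k])
    }
  }
  best
}

# A hand-built current-clamp trace with stylized spikes at given times:
# baseline -70 mV, each spike a 1 ms triangular excursion to +30 mV.
toy_spike_trace <- function(spike_times_ms, total_ms = 400,
                            sampling_khz = 10, baseline_mv = -70) {
  t <- seq(0, total_ms, by = 1 / sampling_khz)
  v <- rep(baseline_mv, length(t))
  for (s in spike_times_ms) {
    up <- which(t >= s & t < s + 0.5)
    down <- which(t >= s + 0.5 & t < s + 1)
    v[up] <- baseline_mv + (30 - baseline_mv) * seq_along(up) / length(up)
    v[down] <- 30 - (30 - baseline_mv) * seq_along(down) / length(down)
  }
  cc_trace(t, v, injected_pa = rep(0, length(t)), sampling_khz = sampling_khz)
}

# The two-class I_h-slope cohort drawn from the reported group
# statistics (82 low-slope and 65 high-slope neurons; SD recovered from
# the group SEMs as SEM * sqrt(group n)).
slope_group_cohort <- function(seed) {
  circuitmapr:::with_local_seed(seed, tibble::tibble(
    slope = c(rnorm(82, -3.1, 2.6 * sqrt(13)),
              rnorm(65, 82.5, 8.6 * sqrt(17))),
    type = rep(c("Pyr_LP", "Pyr_ORBvl"), c(82, 65))
  ))
}

# A flat voltage-clamp trace with a rectangular current pulse, for exact
# charge arithmetic.
rect_pulse_trace <- function(amp_pa, from_ms, to_ms, total_ms = 600,
                             sampling_khz = 10) {
  t <- seq(0, total_ms, by = 1 / sampling_khz)
  i <- ifelse(t >= from_ms & t < to_ms, amp_pa, 0)
  vc_trace(t, i, sampling_khz)
}
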