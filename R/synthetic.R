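#' Specification of a synthetic single-cell population
#'
#' Describes a simulated imaging experiment: `n_cells` cells drawn from a
#' mixture of oscillating, plateau and non-responding phenotypes, recorded
#' at `sampling_dt` for `duration` seconds with stimulation at `stim_time`.
#' Defaults mirror the wild-type statistics of the recordings this package
#' emulates: mixture 0.65 / 0.26 / 0.09 and oscillation counts centered at
#' 6 per 14-minute window (drawn uniformly from `freq_range`), on a Fura2
#' ratio scale (baseline 0.3, spike amplitude 0.5) with Gaussian noise.
#'
#' @param n_cells number of cells (>= 1).
#' @param class_mix probabilities for (oscillating, plateau, non_responder);
#'   must sum to 1.
#' @param freq_range integer range of oscillations per counting window.
#' @param amplitude spike amplitude over baseline (signal units).
#' @param baseline resting signal level.
#' @param noise_sd standard deviation of i.i.d. Gaussian noise (>= 0).
#' @param sampling_dt sampling interval, s.
#' @param duration total recording length, s.
#' @param stim_time stimulation time, s.
#' @param count_window counting window after stimulation, s.
#' @param seed integer seed making the population reproducible.
#' @return list of class `"population_spec"`.
#' @export
population_spec <- function(n_cells = 100,
                            class_mix = c(oscillating = 0.65, plateau = 0.26,
                                          non_responder = 0.09),
                            freq_range = c(4L, 8L),
                            amplitude = 0.5,
                            baseline = 0.3,
                            noise_sd = 0.02,
                            sampling_dt = 2,
                            duration = 960,
                            stim_time = 60,
                            count_window = 840,
                            seed = 1L) {
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (length(class_mix) != 3 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    stop("`class_mix` must be three non-negative probabilities summing to 1")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (freq_range[1] < 2) stop("oscillating cells need at least 2 peaks per window")
  if (duration < stim_time + count_window) {
    stop("`duration` must cover stim_time + count_window")
  }
  names(class_mix) <- c("oscillating", "plateau", "non_responder")
  structure(list(n_cells = as.integer(n_cells), class_mix = class_mix,
                 freq_range = as.integer(freq_range), amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 sampling_dt = sampling_dt, duration = duration,
                 stim_time = stim_time, count_window = count_window,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# asymmetric calcium-spike pulse: gamma-like fast rise / slower decay,
# unit peak at t0 + rise
spike_pulse <- function(t, t0, rise = 8, shape = 2) {
  x <- (t - t0) / rise
  out <- numeric(length(t))
  pos <- x > 0
  out[pos] <- x[pos]^shape * exp(shape * (1 - x[pos]))
  out
}

# smooth step used for plateau onset
rise_sigmoid <- function(t, t0, tau = 8) 1 / (1 + exp(-(t - t0) / tau))

#' Generate a labeled synthetic trace population
#'
#' Constructs traces whose ground-truth class is known by construction and
#' satisfies the classification rules with margin:
#' * oscillating: `n` spikes (uniform in `freq_range`) evenly spaced with
#'   jitter inside the counting window, each returning to baseline;
#' * plateau: fast rise at stimulation, then a hold at 55% of the peak
#'   (well above the 25% rule line) for the rest of the recording;
#' * non-responder: flat, or a single initial spike (50/50).
#'
#' @param spec a [population_spec()].
#' @return list of class `"labeled_trace_set"`: `traces` (long data.frame
#'   `cell_id`, `time_s`, `value`), `meta` (`cell_id`, `stim_time`,
#'   `coverslip_id`), `labels` (`cell_id`, `label`, `n_oscillations`), and
#'   `spec`.
#' @examples
#' ts <- gen_population(population_spec(n_cells = 5, seed = 42))
#' table(ts$labels$label)
#' @export
gen_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  t <- seq(0, spec$duration, by = spec$sampling_dt)
  classes <- sample(names(spec$class_mix), spec$n_cells, replace = TRUE,
                    prob = spec$class_mix)
  win <- spec$count_window

  traces <- vector("list", spec$n_cells)
  labels <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    cls <- classes[i]
    v <- rep(spec$baseline, length(t))
    n_osc <- NA_integer_
    if (cls == "oscillating") {
      n_osc <- sample(seq(spec$freq_range[1], spec$freq_range[2]), 1L)
      # spikes inside the window, last decay complete before the window ends
      first <- spec$stim_time + 40
      last <- spec$stim_time + win - 80
      centers <- seq(first, last, length.out = n_osc)
      gap <- if (n_osc > 1) diff(centers)[1] else last - first
      centers <- centers + stats::runif(n_osc, -0.12, 0.12) * gap
      centers <- pmin(pmax(centers, spec$stim_time + 25), spec$stim_time + win - 70)
      amp <- spec$amplitude * stats::runif(n_osc, 0.85, 1.15)
      for (k in seq_len(n_osc)) v <- v + amp[k] * spike_pulse(t, centers[k] - 8)
    } else if (cls == "plateau") {
      peak_amp <- spec$amplitude
      hold <- 0.55 * peak_amp
      onset <- rise_sigmoid(t, spec$stim_time + 15)
      sag <- hold + (peak_amp - hold) * exp(-pmax(t - spec$stim_time - 15, 0) / 60)
      v <- v + onset * sag
    } else if (stats::runif(1) < 0.5) {
      v <- v + spec$amplitude * spike_pulse(t, spec$stim_time + 12)
    }
    if (spec$noise_sd > 0) v <- v + stats::rnorm(length(t), sd = spec$noise_sd)
    id <- sprintf("cell_%03d", i)
    traces[[i]] <- data.frame(cell_id = id, time_s = t, value = v,
                              stringsAsFactors = FALSE)
    labels[[i]] <- data.frame(cell_id = id, label = cls,
                              n_oscillations = n_osc, stringsAsFactors = FALSE)
  }
  structure(list(
    traces = do.call(rbind, traces),
    meta = data.frame(cell_id = sprintf("cell_%03d", seq_len(spec$n_cells)),
                      stim_time = spec$stim_time, coverslip_id = 1L,
                      stringsAsFactors = FALSE),
    labels = do.call(rbind, labels),
    spec = spec), class = "labeled_trace_set")
}

#' Generate three-cube FRET triples with known true efficiency
#'
#' Intensities are constructed by inverting the standard sensitized-emission
#' relation, so that at zero noise `efret(fret_fc(...), I_DD, G)` returns
#' `true_E` exactly for every record: `Fc = G * I_DD * E / (1 - E)` and
#' `I_DA = Fc + bleed_d * I_DD + bleed_a * I_AA`.
#'
#' @param true_E ground-truth apparent efficiency in `[0, 1)`.
#' @param n number of records.
#' @param bleed_d,bleed_a crosstalk factors.
#' @param G calibration factor.
#' @param noise_sd Gaussian noise added to each of the three channels
#'   (intensity units).
#' @param seed integer seed.
#' @return data.frame with `I_DD`, `I_AA`, `I_DA` plus attribute `true_E`.
#' @export
gen_fret_set <- function(true_E, n = 100, bleed_d = 0.5, bleed_a = 0.06,
                         G = 2.5, noise_sd = 0, seed = 1L) {
  if (true_E < 0 || true_E >= 1) stop("`true_E` must be in [0, 1)")
  set.seed(seed)
  I_DD <- stats::runif(n, 500, 1500)
  I_AA <- stats::runif(n, 500, 1500)
  Fc <- G * I_DD * true_E / (1 - true_E)
  I_DA <- Fc + bleed_d * I_DD + bleed_a * I_AA
  if (noise_sd > 0) {
    I_DD <- I_DD + stats::rnorm(n, sd = noise_sd)
    I_AA <- I_AA + stats::rnorm(n, sd = noise_sd)
    I_DA <- I_DA + stats::rnorm(n, sd = noise_sd)
  }
  structure(data.frame(I_DD = I_DD, I_AA = I_AA, I_DA = I_DA),
            true_E = true_E, bleed_d = bleed_d, bleed_a = bleed_a, G = G)
}

#' Generate a noisy influx calibration from known binding constants
#'
#' Forward-computes the seven genotype influx targets from the dimer model
#' and applies multiplicative Gaussian noise `d * (1 + noise_frac * eps)`.
#' The ground-truth constants are attached, making this the round-trip
#' input for [fit_all_K()].
#'
#' @param K a [binding_constants()] vector (ground truth).
#' @param totals an [isoform_totals()].
#' @param a a [dimer_conductances()].
#' @param noise_frac relative noise level (0 for exact targets).
#' @param seed integer seed.
#' @return an [influx_calibration()] with attribute `K_true`.
#' @export
gen_calibration <- function(K, totals, a, noise_frac = 0, seed = 1L) {
  genos <- calibration_genotypes()
  d <- vapply(genos, function(g) {
    st <- solve_equilibrium(apply_genotype(totals, orai_genotype(g)), K)
    total_influx(st, a)
  }, numeric(1))
  if (noise_frac > 0) {
    set.seed(seed)
    d <- d * (1 + noise_frac * stats::rnorm(length(d)))
    d <- pmax(d, 0)
  }
  out <- influx_calibration(d11 = d[["d11"]], d12 = d[["d12"]], d13 = d[["d13"]],
                            d22 = d[["d22"]], d23 = d[["d23"]], d33 = d[["d33"]],
                            d123 = d[["d123"]])
  attr(out, "K_true") <- K
  out
}
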