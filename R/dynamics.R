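#' Whole-cell calcium oscillator parameters
#'
#' A two-compartment (cytosol + ER), well-mixed calcium model with
#' deterministic IP3 receptors. Release through the IP3R uses a fast
#' activation by agonist (`p`, in uM, standing in for agonist concentration)
#' and cytosolic calcium, and a slower calcium-dependent inactivation gate
#' `h` relaxing with time constant `ipr_tau`. Uptake is a Hill-2 SERCA pump;
#' a linear leak completes the ER exchange. Plasma-membrane entry is the
#' dimer-model influx `J_in` scaled by `influx_scale` and gated by a
#' decreasing sigmoid of ER calcium (store-operated entry); extrusion is a
#' Hill-2 plasma-membrane pump. PM fluxes are small relative to ER exchange,
#' so oscillations are driven by ER release while their frequency is paced
#' by the net calcium load, i.e. by `J_in`.
#'
#' Defaults are tuned so that the wild-type influx produces oscillations
#' with periods around a minute over an agonist band up to `p` ~ 1 uM,
#' terminating in a raised plateau at high `p`, and so that the resting
#' store gives a mostly-closed SOCE sigmoid (s ~ 0.1). Exact kinetic
#' constants are tuning parameters, not claims; only orderings and
#' monotonicities are treated as results.
#'
#' @param p agonist surrogate (uM).
#' @param ipr_max_flux maximal IP3R flux coefficient (1/s).
#' @param ipr_act_Kp agonist (IP3) activation constant (uM).
#' @param ipr_act_K calcium activation constant (uM).
#' @param ipr_inh_K calcium inactivation constant of the `h` gate (uM).
#' @param ipr_tau relaxation time of the `h` gate (s).
#' @param serca_vmax,serca_K SERCA maximal rate (uM/s) and half-activation (uM).
#' @param leak linear ER leak coefficient (1/s).
#' @param gamma cytosol/ER effective volume ratio (dimensionless).
#' @param influx_scale converts dimer-model influx `J_in` to uM/s.
#' @param store_sigmoid_K,store_sigmoid_n half-point (uM) and Hill exponent of
#'   the decreasing sigmoid of ER calcium that gates store-operated entry.
#' @param pm_extrusion_vmax,pm_extrusion_K plasma-membrane pump rate (uM/s)
#'   and half-activation (uM).
#' @return list of class `"oscillator_params"`.
#' @export
oscillator_params <- function(p = 0.3,
                              ipr_max_flux = 1,
                              ipr_act_Kp = 0.5,
                              ipr_act_K = 0.1,
                              ipr_inh_K = 0.4,
                              ipr_tau = 40,
                              serca_vmax = 0.225,
                              serca_K = 0.15,
                              leak = 5e-4,
                              gamma = 5.5,
                              influx_scale = 0.075,
                              store_sigmoid_K = 26,
                              store_sigmoid_n = 4,
                              pm_extrusion_vmax = 0.005,
                              pm_extrusion_K = 0.3) {
  prm <- list(p = p, ipr_max_flux = ipr_max_flux, ipr_act_Kp = ipr_act_Kp,
              ipr_act_K = ipr_act_K, ipr_inh_K = ipr_inh_K, ipr_tau = ipr_tau,
              serca_vmax = serca_vmax, serca_K = serca_K, leak = leak,
              gamma = gamma, influx_scale = influx_scale,
              store_sigmoid_K = store_sigmoid_K, store_sigmoid_n = store_sigmoid_n,
              pm_extrusion_vmax = pm_extrusion_vmax, pm_extrusion_K = pm_extrusion_K)
  # leak and PM fluxes may be zero (closed-cell configurations)
  nonneg <- c("p", "leak", "influx_scale", "pm_extrusion_vmax")
  if (any(unlist(prm[nonneg]) < 0)) stop("rate parameters must be >= 0")
  if (any(unlist(prm[setdiff(names(prm), nonneg)]) <= 0)) {
    stop("kinetic parameters must be > 0")
  }
  structure(prm, class = "oscillator_params")
}

#' Stimulation protocol
#'
#' An ordered list of segments, each holding the agonist surrogate `p`,
#' whether external calcium is present, and whether SERCA is active
#' (thapsigargin is modeled by switching SERCA flux to exactly zero).
#'
#' @param duration segment durations (s, > 0).
#' @param p per-segment agonist surrogate (recycled).
#' @param external_Ca_on per-segment logical: calcium entry enabled.
#' @param serca_on per-segment logical: SERCA pump active.
#' @return data.frame of class `"cell_protocol"`.
#' @export
cell_protocol <- function(duration, p, external_Ca_on = TRUE, serca_on = TRUE) {
  n <- length(duration)
  if (n < 1 || any(duration <= 0)) stop("need at least one segment with duration > 0")
  structure(data.frame(duration = duration,
                       p = rep_len(p, n),
                       external_Ca_on = rep_len(external_Ca_on, n),
                       serca_on = rep_len(serca_on, n)),
            class = c("cell_protocol", "data.frame"))
}

#' Initial cell state
#'
#' @param c cytosolic calcium (uM).
#' @param c_er ER calcium (uM).
#' @param h IP3R inactivation gate in \[0, 1\].
#' @return named numeric vector.
#' @export
cell_state <- function(c = 0.05, c_er = 30, h = 0.9) {
  if (c < 0 || c_er < 0 || h < 0 || h > 1) stop("invalid cell state")
  c(c = c, c_er = c_er, h = h)
}

# right-hand side shared by all protocols
oscillator_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    po_single <- (p / (p + ipr_act_Kp)) * (c / (c + ipr_act_K)) * h
    j_rel <- (ipr_max_flux * po_single^3 + leak) * (c_er - c)
    j_serca <- serca_on * serca_vmax * c^2 / (serca_K^2 + c^2)
    s_store <- store_sigmoid_K^store_sigmoid_n /
      (store_sigmoid_K^store_sigmoid_n + c_er^store_sigmoid_n)
    j_in <- external_Ca_on * influx_scale * genotype_J * s_store
    j_pm <- pm_extrusion_vmax * c^2 / (pm_extrusion_K^2 + c^2)
    h_inf <- ipr_inh_K / (ipr_inh_K + c)
    list(c(c = j_rel - j_serca + j_in - j_pm,
           c_er = gamma * (j_serca - j_rel),
           h = (h_inf - h) / ipr_tau))
  })
}

#' Simulate the calcium model under a protocol
#'
#' Integrates the cytosol/ER/gate system segment by segment with the stiff
#' solver in [deSolve::ode()] (lsoda, rtol 1e-8), sampling the solution on a
#' fixed grid.
#'
#' @param params an [oscillator_params()]; its `p` is overridden per segment.
#' @param protocol a [cell_protocol()].
#' @param genotype_J dimer-model influx for the simulated genotype
#'   (multiplied by `influx_scale`).
#' @param init initial state from [cell_state()].
#' @param sample_dt output sampling interval (s, default 1).
#' @param solver_tol relative tolerance passed to the integrator.
#' @return data.frame of class `"sim_trace"` with columns `t`, `c`, `c_er`,
#'   `h`, `segment`.
#' @examples
#' pr <- cell_protocol(duration = c(60, 300), p = c(0, 0.3))
#' tr <- simulate_cell(oscillator_params(), pr, genotype_J = 0.045)
#' @export
simulate_cell <- function(params, protocol, genotype_J = 0.045,
                          init = cell_state(), sample_dt = 1, solver_tol = 1e-8) {
  stopifnot(inherits(params, "oscillator_params"), solver_tol > 0, genotype_J >= 0)
  if (!inherits(protocol, "cell_protocol")) stop("`protocol` must be a cell_protocol")
  state <- init
  t0 <- 0
  pieces <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    seg <- protocol[i, ]
    parms <- unclass(params)
    parms$p <- seg$p
    parms$serca_on <- as.numeric(seg$serca_on)
    parms$external_Ca_on <- as.numeric(seg$external_Ca_on)
    parms$genotype_J <- genotype_J
    times <- seq(0, seg$duration, by = sample_dt)
    sol <- deSolve::ode(y = state, times = times, func = oscillator_rhs,
                        parms = parms, method = "lsoda",
                        rtol = solver_tol, atol = solver_tol * 1e-2)
    if (attr(sol, "istate")[1] < 0) stop("integration failed in segment ", i)
    sol <- as.data.frame(sol)
    if (min(sol$c, sol$c_er) < -1e-6) stop("negative-state excursion in segment ", i)
    state <- c(c = max(sol$c[nrow(sol)], 0), c_er = max(sol$c_er[nrow(sol)], 0),
               h = min(max(sol$h[nrow(sol)], 0), 1))
    sol$time <- sol$time + t0
    sol$segment <- i
    t0 <- t0 + seg$duration
    pieces[[i]] <- if (i < nrow(protocol)) sol[-nrow(sol), ] else sol
  }
  out <- do.call(rbind, pieces)
  names(out)[names(out) == "time"] <- "t"
  rownames(out) <- NULL
  out <- structure(out, class = c("sim_trace", "data.frame"))
  attr(out, "protocol") <- protocol
  out
}

#' Agonist staircase protocol
#'
#' Convenience wrapper: one dwell per agonist level (preceded by a short
#' rest segment at `p = 0` so the cell starts from its resting state), with
#' external calcium present and SERCA active throughout.
#'
#' @inheritParams simulate_cell
#' @param p_levels increasing agonist levels (uM).
#' @param dwell time spent at each level (s).
#' @param rest duration of the initial unstimulated segment (s; 0 to skip).
#' @return a `"sim_trace"`; segment 1 is the rest period when `rest > 0`.
#' @export
agonist_staircase <- function(params, genotype_J, p_levels, dwell = 1680,
                              rest = 240, init = cell_state(), sample_dt = 2,
                              solver_tol = 1e-8) {
  if (is.unsorted(p_levels, strictly = FALSE)) stop("`p_levels` must be increasing")
  durations <- rep(dwell, length(p_levels))
  ps <- p_levels
  if (rest > 0) { durations <- c(rest, durations); ps <- c(0, ps) }
  simulate_cell(params, cell_protocol(durations, ps), genotype_J,
                init = init, sample_dt = sample_dt, solver_tol = solver_tol)
}

#' Thapsigargin / calcium re-addition protocol
#'
#' Models maximal store depletion: SERCA flux is set to zero throughout.
#' First segment: no external calcium, the store drains through the leak and
#' IP3R. Second segment: external calcium restored; the resulting rise is
#' the store-operated entry read-out.
#'
#' @inheritParams simulate_cell
#' @param t_zero_Ca duration of the calcium-free depletion segment (s).
#' @param t_readd duration of the re-addition segment (s).
#' @param rest duration of an initial untreated segment (s; 0 to skip).
#' @return a `"sim_trace"`; the re-addition segment is the last one.
#' @export
thapsigargin_protocol <- function(params, genotype_J, t_zero_Ca = 1600,
                                  t_readd = 1200, rest = 240, init = cell_state(),
                                  sample_dt = 2, solver_tol = 1e-8) {
  stopifnot(t_zero_Ca > 0, t_readd > 0)
  durations <- c(t_zero_Ca, t_readd)
  ext <- c(FALSE, TRUE); serca <- c(FALSE, FALSE); ps <- c(0, 0)
  if (rest > 0) {
    durations <- c(rest, durations); ext <- c(TRUE, ext)
    serca <- c(TRUE, serca); ps <- c(0, ps)
  }
  simulate_cell(params, cell_protocol(durations, ps, ext, serca), genotype_J,
                init = init, sample_dt = sample_dt, solver_tol = solver_tol)
}

#' Store-operated entry peak from a re-addition trace
#'
#' Height of the cytosolic calcium rise in the final (re-addition) segment
#' over the level just before re-addition.
#'
#' @param trace a `"sim_trace"` from [thapsigargin_protocol()].
#' @return non-negative peak height (uM).
#' @export
readd_peak <- function(trace) {
  last_seg <- max(trace$segment)
  pre <- trace$c[trace$segment == last_seg - 1]
  max(0, max(trace$c[trace$segment == last_seg]) - pre[length(pre)])
}

#' Per-segment summary of a staircase simulation
#'
#' For each protocol segment (after discarding `skip` seconds of
#' transient), counts oscillation peaks (local maxima above
#' `peak_fraction` of the segment's dynamic range, separated by at least
#' `min_sep` s), and reports the post-transient mean and coefficient of
#' variation of cytosolic calcium. A segment is labeled `"plateau"` when
#' its CV falls below `cv_plateau` while the mean sits above the resting
#' level of the first segment, `"oscillating"` when it has two or more
#' peaks, and `"quiescent"` otherwise.
#'
#' @param trace a `"sim_trace"` from [agonist_staircase()] or
#'   [simulate_cell()].
#' @param skip transient discarded at the start of each segment, s.
#' @param cv_plateau CV threshold below which a raised segment counts as a
#'   plateau.
#' @param peak_fraction fraction of the segment range a local maximum must
#'   exceed.
#' @param min_sep minimum peak separation, s.
#' @param min_range dynamic range (uM) below which a segment has no peaks.
#' @return data.frame: `segment`, `p`, `n_peaks`, `freq_per_min`, `mean_c`,
#'   `cv`, `label`.
#' @export
staircase_summary <- function(trace, skip = 720, cv_plateau = 0.1,
                              peak_fraction = 0.25, min_sep = 30,
                              min_range = 0.05) {
  proto <- attr(trace, "protocol")
  segs <- sort(unique(trace$segment))
  rest_level <- mean(trace$c[trace$segment == segs[1]])
  rows <- lapply(segs, function(s) {
    sel <- trace$segment == s
    tt <- trace$t[sel]; v <- trace$c[sel]
    # never discard more than 40% of a (possibly short) segment
    eff_skip <- min(skip, 0.4 * (tt[length(tt)] - tt[1]))
    keep <- tt >= tt[1] + eff_skip
    tt <- tt[keep]; v <- v[keep]
    rng <- max(v) - min(v)
    n <- if (rng >= min_range) {
      length(find_peaks(tt, v, min(v) + peak_fraction * rng, min_sep))
    } else 0L
    cv <- stats::sd(v) / mean(v)
    label <- if (cv < cv_plateau && mean(v) > rest_level + min_range) {
      "plateau"
    } else if (n >= 2) "oscillating" else "quiescent"
    data.frame(segment = s,
               p = if (!is.null(proto)) proto$p[s] else NA_real_,
               n_peaks = n,
               freq_per_min = 60 * n / (tt[length(tt)] - tt[1]),
               mean_c = mean(v), cv = cv, label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
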