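#' Classification rules for single-cell calcium traces
#'
#' Operationalizes the three-group classification used for Fura2 recordings:
#' oscillating cells (regenerative spikes, each returning to baseline before
#' the next), plateau cells (signal sustained at >= 25% of the initial peak
#' for at least 5 minutes after stimulation), and non-responders (no
#' response, or a single initial spike returning to baseline). Counting is
#' restricted to a 14-minute window after stimulation.
#'
#' The published counts were manual; the numeric knobs below make the rule
#' reproducible:
#' * baseline = median of the 60 s window before stimulation;
#' * a candidate peak is a local maximum exceeding
#'   `baseline + peak_prominence * (global peak - baseline)`, with candidate
#'   maxima closer than `min_peak_separation` merged (highest kept);
#' * "returns to baseline" means dropping below
#'   `baseline + baseline_return_tol * (global peak - baseline)` between
#'   consecutive peaks.
#'
#' @param plateau_fraction fraction of the initial peak that must be
#'   sustained for a plateau (default 0.25).
#' @param plateau_min_duration minimum sustained time, s (default 300).
#' @param baseline_return_tol fraction of the peak-to-baseline span below
#'   which the signal counts as back at baseline (default 0.2).
#' @param count_window length of the counting window after stimulation, s
#'   (default 840 = 14 min).
#' @param peak_prominence minimum peak height as a fraction of the
#'   peak-to-baseline span (default 0.1).
#' @param min_peak_separation minimum spacing between counted peaks, s
#'   (default 30).
#' @param baseline_window length of the pre-stimulation window used for the
#'   baseline estimate, s (default 60).
#' @param smooth_window width of the moving-average filter applied before
#'   peak detection, s (default 10; 0 disables). Acquisition noise otherwise
#'   produces spurious local maxima on spike flanks.
#' @param min_response minimum peak-to-baseline span (signal units) for a
#'   trace to count as responding at all (default 0.05); below it the cell
#'   is a non-responder. The published rule gives no numeric threshold for
#'   "no response"; this operational choice is exposed here.
#' @return list of class `"classification_rules"`.
#' @export
classification_rules <- function(plateau_fraction = 0.25,
                                 plateau_min_duration = 300,
                                 baseline_return_tol = 0.2,
                                 count_window = 840,
                                 peak_prominence = 0.1,
                                 min_peak_separation = 30,
                                 baseline_window = 60,
                                 smooth_window = 10,
                                 min_response = 0.05) {
  stopifnot(plateau_fraction > 0, plateau_fraction < 1,
            plateau_min_duration > 0, count_window > 0,
            baseline_return_tol > 0, peak_prominence > 0,
            min_peak_separation > 0, baseline_window > 0, smooth_window >= 0,
            min_response >= 0)
  structure(list(plateau_fraction = plateau_fraction,
                 plateau_min_duration = plateau_min_duration,
                 baseline_return_tol = baseline_return_tol,
                 count_window = count_window,
                 peak_prominence = peak_prominence,
                 min_peak_separation = min_peak_separation,
                 baseline_window = baseline_window,
                 smooth_window = smooth_window,
                 min_response = min_response),
            class = "classification_rules")
}

# centered moving average with shrinking edge windows
running_mean <- function(v, k) {
  if (k <= 1) return(v)
  n <- length(v)
  half <- k %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# local maxima above an absolute threshold, with minimum separation
# (closer maxima merged, keeping the highest)
find_peaks <- function(t, v, threshold, min_sep) {
  idx <- which(diff(sign(diff(v))) < 0) + 1
  idx <- idx[v[idx] >= threshold]
  if (!length(idx)) return(integer(0))
  keep <- integer(0)
  for (i in idx) {
    if (length(keep) && t[i] - t[keep[length(keep)]] < min_sep) {
      if (v[i] > v[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  keep
}

# shared geometry for classification and counting
trace_features <- function(t, v, stim_time, rules) {
  if (is.unsorted(t, strictly = TRUE)) stop("trace time must be strictly increasing")
  if (max(t) < stim_time + rules$count_window) {
    stop("trace too short: must span stim_time + count_window")
  }
  pre <- v[t >= stim_time - rules$baseline_window & t <= stim_time]
  if (!length(pre)) stop("no samples in the pre-stimulation baseline window")
  baseline <- stats::median(pre)
  win <- t >= stim_time & t <= stim_time + rules$count_window
  tw <- t[win]; vw <- v[win]
  if (rules$smooth_window > 0 && length(tw) > 2) {
    dt <- stats::median(diff(tw))
    vw <- running_mean(vw, max(1L, round(rules$smooth_window / dt)))
  }
  span <- max(vw) - baseline
  peak_thr <- baseline + rules$peak_prominence * span
  return_level <- baseline + rules$baseline_return_tol * span
  peaks <- if (span >= rules$min_response) {
    find_peaks(tw, vw, peak_thr, rules$min_peak_separation)
  } else integer(0)
  list(baseline = baseline, t = tw, v = vw, span = span,
       peaks = peaks, return_level = return_level)
}

# peaks that return to baseline before the next peak (the last peak is
# counted unconditionally: the window may truncate its decay)
returning_peaks <- function(ft) {
  p <- ft$peaks
  if (length(p) < 2) return(p)
  keep <- vapply(seq_len(length(p) - 1), function(i) {
    min(ft$v[p[i]:p[i + 1]]) <= ft$return_level
  }, logical(1))
  c(p[-length(p)][keep], p[length(p)])
}

#' Classify a single-cell calcium trace
#'
#' Applies the three-group rule (see [classification_rules()]). Plateau is
#' tested first: the signal must stay at or above
#' `baseline + plateau_fraction * (initial peak - baseline)` continuously
#' for at least `plateau_min_duration` seconds within the counting window.
#' Otherwise the trace is oscillating if it contains at least two counted
#' peaks each returning to baseline before the next; a flat trace or a
#' single spike is a non-responder.
#'
#' @param t,v time (s, strictly increasing) and signal (Fura2 ratio or
#'   simulated cytosolic calcium) vectors of equal length.
#' @param stim_time stimulation time (s); the counting window starts here.
#' @param rules a [classification_rules()] object.
#' @return list of class `"trace_classification"`: `label` (one of
#'   `"oscillating"`, `"plateau"`, `"non_responder"`), `n_oscillations`
#'   (integer, NA unless oscillating), `baseline`, `peak_times`.
#' @export
classify_trace <- function(t, v, stim_time, rules = classification_rules()) {
  stopifnot(length(t) == length(v))
  ft <- trace_features(t, v, stim_time, rules)

  label <- NULL
  n_osc <- NA_integer_

  if (ft$span > 0 && length(ft$peaks)) {
    # plateau: longest contiguous run at/above the 25%-of-initial-peak level
    initial_peak <- ft$v[ft$peaks[1]]
    level <- ft$baseline + rules$plateau_fraction * (initial_peak - ft$baseline)
    above <- ft$v >= level
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    run_durs <- ifelse(r$values, ft$t[ends] - ft$t[starts], 0)
    if (max(run_durs) >= rules$plateau_min_duration) label <- "plateau"
  }

  if (is.null(label)) {
    rp <- returning_peaks(ft)
    if (length(rp) >= 2) {
      label <- "oscillating"
      n_osc <- length(rp)
    } else {
      label <- "non_responder"
    }
  }

  structure(list(label = label, n_oscillations = n_osc,
                 baseline = ft$baseline,
                 peak_times = ft$t[ft$peaks]),
            class = "trace_classification")
}

#' Count oscillations in the 14-minute window
#'
#' Number of qualifying peaks (each returning to baseline before the next)
#' within `count_window` after stimulation. Intended for traces already
#' classified as oscillating; for other traces it simply reports the number
#' of qualifying peaks.
#'
#' @inheritParams classify_trace
#' @return integer count.
#' @export
count_oscillations <- function(t, v, stim_time, rules = classification_rules()) {
  stopifnot(length(t) == length(v))
  ft <- trace_features(t, v, stim_time, rules)
  length(returning_peaks(ft))
}

#' Classify a population of traces in long format
#'
#' @param traces data.frame with columns `cell_id`, `time_s`, `value`.
#' @param meta data.frame with columns `cell_id`, `stim_time`, and
#'   optionally `coverslip_id`.
#' @param rules a [classification_rules()].
#' @return data.frame with one row per cell: `cell_id`, `coverslip_id` (if
#'   given), `label`, `n_oscillations`.
#' @export
classify_cells <- function(traces, meta, rules = classification_rules()) {
  stopifnot(all(c("cell_id", "time_s", "value") %in% names(traces)),
            all(c("cell_id", "stim_time") %in% names(meta)))
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$cell_id[i]
    tr <- traces[traces$cell_id == id, ]
    cl <- classify_trace(tr$time_s, tr$value, meta$stim_time[i], rules)
    out <- data.frame(cell_id = id, label = cl$label,
                      n_oscillations = cl$n_oscillations,
                      stringsAsFactors = FALSE)
    if ("coverslip_id" %in% names(meta)) out$coverslip_id <- meta$coverslip_id[i]
    out
  })
  do.call(rbind, rows)
}

#' Per-coverslip summary of trace classifications
#'
#' @param labels character vector of per-cell labels (`"oscillating"`,
#'   `"plateau"`, `"non_responder"`).
#' @param n_oscillations optional numeric vector of per-cell oscillation
#'   counts (NA for non-oscillating cells).
#' @return list of class `"coverslip_summary"`: `pct_oscillating`,
#'   `pct_plateau`, `pct_nonresponding` (they sum to 100), `n_cells`, and
#'   `mean_oscillations` over oscillating cells (NaN if none).
#' @examples
#' summarize_coverslip(rep(c("oscillating", "plateau", "non_responder"), c(13, 5, 2)))
#' @export
summarize_coverslip <- function(labels, n_oscillations = NULL) {
  if (!length(labels)) stop("no cells to summarize")
  bad <- setdiff(unique(labels), c("oscillating", "plateau", "non_responder"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  n <- length(labels)
  mean_osc <- if (is.null(n_oscillations)) NA_real_ else {
    mean(n_oscillations[labels == "oscillating"], na.rm = TRUE)
  }
  structure(list(
    pct_oscillating = 100 * sum(labels == "oscillating") / n,
    pct_plateau = 100 * sum(labels == "plateau") / n,
    pct_nonresponding = 100 * sum(labels == "non_responder") / n,
    n_cells = n,
    mean_oscillations = mean_osc), class = "coverslip_summary")
}

#' Store-operated entry magnitude from a re-addition trace
#'
#' Peak signal after calcium re-addition minus the mean of a pre-re-addition
#' baseline window. Negative excursions are clipped to zero and flagged via
#' the `"clipped"` attribute.
#'
#' @inheritParams classify_trace
#' @param readd_time time of calcium re-addition (s).
#' @param baseline_window length of the pre-re-addition window, s.
#' @return non-negative SOCE magnitude in signal units.
#' @export
soce_magnitude <- function(t, v, readd_time, baseline_window = 60) {
  stopifnot(length(t) == length(v))
  if (missing(readd_time) || is.null(readd_time) || is.na(readd_time)) {
    stop("`readd_time` is required for SOCE quantification")
  }
  pre <- v[t >= readd_time - baseline_window & t < readd_time]
  post <- v[t >= readd_time]
  if (!length(pre) || !length(post)) stop("trace does not bracket `readd_time`")
  delta <- max(post) - mean(pre)
  structure(max(delta, 0), clipped = delta < 0)
}

#' Fast calcium-dependent inactivation: remaining current fraction
#'
#' Fraction of the peak current remaining at `t_eval` (146 ms by
#' convention) after the start of a voltage step, with linear interpolation
#' at the evaluation time. Current sign is ignored (inward currents are
#' negative); the peak is the largest-magnitude sample.
#'
#' @param t time since pulse start, ms.
#' @param current current samples (any sign).
#' @param t_eval evaluation time, ms (default 146).
#' @return remaining fraction `I(t_eval) / I(peak)`.
#' @examples
#' t <- seq(0, 150, by = 1)
#' cdi_remaining_fraction(t, -exp(-t / 100))  # ~ exp(-1.46)
#' @export
cdi_remaining_fraction <- function(t, current, t_eval = 146) {
  stopifnot(length(t) == length(current))
  if (min(t) > 0 || max(t) < t_eval) stop("trace must cover [0, t_eval]")
  peak <- max(abs(current))
  if (peak == 0) stop("zero peak current: remaining fraction undefined")
  i_eval <- stats::approx(t, abs(current), xout = t_eval)$y
  i_eval / peak
}

#' Three-cube FRET: crosstalk-corrected intensity and apparent efficiency
#'
#' `fret_fc()` computes the corrected FRET intensity
#' `Fc = I_DA - bleed_d * I_DD - bleed_a * I_AA`, where `bleed_d` (Fd/Dd)
#' and `bleed_a` (Fa/Da) are the donor and acceptor crosstalk factors. `Fc`
#' may legitimately be negative in noisy data and is returned as-is.
#'
#' `efret()` converts `Fc` to the apparent FRET efficiency. The standard
#' sensitized-emission form is `E = Fc / (Fc + G * I_DD)`; the
#' `"replication"` variant `E = Fc * Fc / (Fc + G * I_DD)` reproduces a
#' published rendering of the formula (dimensionally inconsistent; kept only
#' for comparison).
#'
#' @param I_DD,I_AA,I_DA background-subtracted donor, acceptor and FRET
#'   channel intensities (vectors recycled to common length).
#' @param bleed_d,bleed_a donor and acceptor bleed-through factors (>= 0).
#' @return `fret_fc()`: corrected FRET intensity (same units as inputs).
#' @examples
#' fc <- fret_fc(I_DD = 1000, I_AA = 800, I_DA = 700, bleed_d = 0.5, bleed_a = 0.05)
#' efret(fc, I_DD = 1000, G = 2.5)
#' @export
fret_fc <- function(I_DD, I_AA, I_DA, bleed_d, bleed_a) {
  if (any(bleed_d < 0) || any(bleed_a < 0)) stop("bleed factors must be >= 0")
  I_DA - bleed_d * I_DD - bleed_a * I_AA
}

#' @rdname fret_fc
#' @param Fc corrected FRET intensity from [fret_fc()].
#' @param G calibration factor (> 0).
#' @param formula `"standard"` or `"replication"` (see Details).
#' @return `efret()`: apparent FRET efficiency (in \[0, 1\] for the standard
#'   formula on noiseless data).
#' @export
efret <- function(Fc, I_DD, G, formula = c("standard", "replication")) {
  formula <- match.arg(formula)
  if (any(G <= 0)) stop("`G` must be > 0")
  denom <- Fc + G * I_DD
  if (any(denom == 0)) stop("Fc + G * I_DD is zero: efficiency undefined")
  switch(formula,
         standard = Fc / denom,
         replication = Fc * Fc / denom)
}

#' NFAT nuclear translocation ratio
#'
#' Nuclear over total-cell fluorescence at 510 nm.
#'
#' @param nuclear_F510,total_F510 intensities with
#'   `0 <= nuclear_F510 <= total_F510` and `total_F510 > 0`.
#' @return ratio in \[0, 1\].
#' @export
nfat_ratio <- function(nuclear_F510, total_F510) {
  if (any(total_F510 <= 0)) stop("total fluorescence must be > 0")
  if (any(nuclear_F510 < 0) || any(nuclear_F510 > total_F510)) {
    stop("need 0 <= nuclear <= total")
  }
  nuclear_F510 / total_F510
}
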