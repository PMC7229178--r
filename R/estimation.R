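#' Influx calibration targets
#'
#' The seven genotype influx targets used to calibrate the dimer binding
#' constants: `d_ij` is the population influx when only isoforms `i` and `j`
#' are present, and `d_123` the wild-type influx. Defaults are the reference
#' targets `d11 = 0.06, d12 = d13 = 0.05, d22 = d23 = 0.002, d33 = 0.001,
#' d123 = 0.045`. Only relative sizes matter; the whole set can be rescaled.
#'
#' @param d11,d12,d13,d22,d23,d33,d123 non-negative influx rates.
#' @param scale common multiplier applied to all targets.
#' @return named numeric vector of class `"influx_calibration"`.
#' @export
influx_calibration <- function(d11 = 0.06, d12 = 0.05, d13 = 0.05,
                               d22 = 0.002, d23 = 0.002, d33 = 0.001,
                               d123 = 0.045, scale = 1) {
  x <- scale * c(d11 = as.numeric(d11)[1], d12 = as.numeric(d12)[1],
                 d13 = as.numeric(d13)[1], d22 = as.numeric(d22)[1],
                 d23 = as.numeric(d23)[1], d33 = as.numeric(d33)[1],
                 d123 = as.numeric(d123)[1])
  if (any(!is.finite(x)) || any(x < 0)) stop("influx targets must be finite and >= 0")
  structure(x, class = "influx_calibration")
}

# genotype (present isoforms) associated with each calibration target
calibration_genotypes <- function() {
  list(d11 = c(1L), d12 = c(1L, 2L), d13 = c(1L, 3L), d22 = c(2L),
       d23 = c(2L, 3L), d33 = c(3L), d123 = c(1L, 2L, 3L))
}

#' Homodimer binding constant from a double-knockout influx target
#'
#' With a single isoform present, the influx equation `d = alpha K O^2` and
#' ORAI conservation can be solved in closed form. Two conservation
#' conventions are supported:
#' * `"mass_balance"`: `O + 2 K O^2 = I`, giving `O = I - 2 d / alpha`;
#' * `"doubled_monomer"`: `2 O + 2 K O^2 = I` (monomer counted twice), giving
#'   `O = I / 2 - d / alpha`.
#' In both, `K = d / (alpha O^2)`. The mass-balance form is the default; the
#' alternative replicates a published variant of the algebra and is retained
#' for comparison. Either way feasibility requires `I > 2 d / alpha`.
#'
#' @param I total isoform amount (> 0).
#' @param d influx target (>= 0).
#' @param alpha homodimer conductance (> 0).
#' @param convention `"mass_balance"` or `"doubled_monomer"`.
#' @return list of class `"homodimer_solution"` with `O_free`, `K`,
#'   `convention`.
#' @examples
#' solve_homodimer_K(1, 0.06, 2)                       # O 0.94, K ~0.034
#' solve_homodimer_K(1, 0.06, 2, "doubled_monomer")         # O 0.47, K ~0.136
#' @export
solve_homodimer_K <- function(I, d, alpha, convention = c("mass_balance", "doubled_monomer")) {
  convention <- match.arg(convention)
  stopifnot(I > 0, alpha > 0, d >= 0)
  if (I <= 2 * d / alpha) {
    stop(sprintf(
      "infeasible homodimer target: need I > 2 d / alpha (I = %g, 2 d / alpha = %g)",
      I, 2 * d / alpha))
  }
  O <- switch(convention,
              mass_balance = I - 2 * d / alpha,
              doubled_monomer   = I / 2 - d / alpha)
  structure(list(O_free = O, K = d / (alpha * O^2), convention = convention),
            class = "homodimer_solution")
}

# influx predicted for a two-isoform genotype at a trial cross constant.
# K_known = c(Kii, Kjj); alpha_triplet = c(a_ii, a_ij, a_jj); I_pair = c(Ii, Ij)
cross_pair_influx <- function(K_cross, K_known, I_pair, alpha_triplet, tol = 1e-12) {
  K <- binding_constants(0, 0, 0, 0, 0, 0)
  K["K11"] <- K_known[1]; K["K22"] <- K_known[2]; K["K12"] <- K_cross
  st <- solve_equilibrium(isoform_totals(I_pair[1], I_pair[2], 0), K, tol = tol)
  alpha_triplet[1] * st$O11 + alpha_triplet[2] * st$O12 + alpha_triplet[3] * st$O22
}

#' Cross binding constant from a single-knockout influx target
#'
#' With two isoforms present the three unknowns (the two free monomers and
#' the cross constant `K_ij`) reduce to a one-dimensional root problem: for
#' each trial `K_ij` the two conservation equations fix `O_i` and `O_j`, and
#' the cross constant is the root of the influx equation
#' `d_ij = a_ii K_ii O_i^2 + a_ij K_ij O_i O_j + a_jj K_jj O_j^2`.
#' The scan runs over `scan_range` (default 1-500) on a log grid; a
#' bracketed sign change is refined by [stats::uniroot()] to 1e-8. If
#' several brackets exist the smallest root is returned with a warning.
#'
#' @param K_known length-2 numeric: the two homodimer constants
#'   `(K_ii, K_jj)` from [solve_homodimer_K()].
#' @param I_pair length-2 numeric: totals of the two present isoforms.
#' @param alpha_triplet length-3 numeric: `(a_ii, a_ij, a_jj)`.
#' @param d_pair the single-knockout influx target.
#' @param scan_range interval scanned for the root (positive).
#' @param n_grid number of log-spaced scan points.
#' @return the fitted cross constant (scalar).
#' @export
solve_cross_K <- function(K_known, I_pair, alpha_triplet, d_pair,
                          scan_range = c(1, 500), n_grid = 200L) {
  stopifnot(length(K_known) == 2, length(I_pair) == 2, length(alpha_triplet) == 3,
            all(scan_range > 0), scan_range[1] < scan_range[2])
  f <- function(k) cross_pair_influx(k, K_known, I_pair, alpha_triplet) - d_pair
  grid <- exp(seq(log(scan_range[1]), log(scan_range[2]), length.out = n_grid))
  fg <- vapply(grid, f, numeric(1))
  sign_change <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (any(fg == 0)) return(grid[which(fg == 0)[1]])
  if (!length(sign_change)) {
    stop(sprintf(
      "no root for the cross constant in [%g, %g]: influx spans [%.4g, %.4g], target %.4g",
      scan_range[1], scan_range[2], min(fg) + d_pair, max(fg) + d_pair, d_pair))
  }
  if (length(sign_change) > 1) {
    warning("multiple roots bracketed for the cross constant; returning the smallest")
  }
  i <- sign_change[1]
  stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-8)$root
}

#' Feasibility boundary of the cross-constant root problem
#'
#' The single-knockout root problem has a solution only in part of
#' conductance space: when the cross-dimer conductance `a_ij` is too large
#' relative to `a_ii`, sequestering monomers into cross dimers can no longer
#' lower the predicted influx to the target `d_ij`, and no root exists. This
#' continuation scans the ratio `a_ii / a_ij` over a grid, records where the
#' root exists, and refines the single crossing by bisection.
#'
#' @inheritParams solve_cross_K
#' @param a_ii the homodimer conductance of the dominant isoform, held fixed.
#' @param a_jj the homodimer conductance of the partner isoform.
#' @param ratio_grid increasing grid of `a_ii / a_ij` ratios to scan (should
#'   span at least one decade).
#' @param refine_iter bisection iterations used to sharpen the boundary.
#' @return list of class `"feasibility_report"` with `ratio_boundary` (NA if
#'   no crossing in the grid), `boundary_found`, and `scanned_grid`
#'   (data.frame of ratio, alpha_cross, root_exists).
#' @export
feasibility_boundary <- function(K_known, I_pair, a_ii, a_jj, d_pair,
                                 ratio_grid = exp(seq(log(1), log(100), length.out = 25)),
                                 scan_range = c(1, 500), refine_iter = 40L) {
  stopifnot(all(diff(ratio_grid) > 0), max(ratio_grid) / min(ratio_grid) >= 10)
  root_at <- function(ratio) {
    a_ij <- a_ii / ratio
    tryCatch({
      solve_cross_K(K_known, I_pair, c(a_ii, a_ij, a_jj), d_pair, scan_range)
      TRUE
    }, error = function(e) FALSE)
  }
  exists_flag <- vapply(ratio_grid, root_at, logical(1))
  grid_df <- data.frame(ratio = ratio_grid, alpha_cross = a_ii / ratio_grid,
                        root_exists = exists_flag)
  if (all(exists_flag) || all(!exists_flag)) {
    return(structure(list(ratio_boundary = NA_real_, boundary_found = FALSE,
                          scanned_grid = grid_df), class = "feasibility_report"))
  }
  i <- which(diff(exists_flag) != 0)[1]
  lo <- ratio_grid[i]; hi <- ratio_grid[i + 1]
  lo_exists <- exists_flag[i]
  for (it in seq_len(refine_iter)) {
    mid <- sqrt(lo * hi)
    if (root_at(mid) == lo_exists) lo <- mid else hi <- mid
  }
  structure(list(ratio_boundary = sqrt(lo * hi), boundary_found = TRUE,
                 scanned_grid = grid_df), class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  if (x$boundary_found) {
    cat(sprintf("feasibility boundary: a_ii / a_ij ~ %.4g\n", x$ratio_boundary))
  } else {
    cat("no feasibility boundary inside the scanned grid\n")
  }
  cat(sprintf("  scanned %d ratios in [%.3g, %.3g]; root exists at %d of them\n",
              nrow(x$scanned_grid), min(x$scanned_grid$ratio),
              max(x$scanned_grid$ratio), sum(x$scanned_grid$root_exists)))
  invisible(x)
}

#' Initial binding constants from the algebraic/scan stages
#'
#' Runs the staged calibration: homodimer constants from the three
#' double-knockout targets in closed form, then the three cross constants by
#' one-dimensional root scans against the single-knockout targets. Scans
#' without a root fall back to the geometric midpoint of `scan_range` so a
#' full starting vector is always produced for the least-squares stage.
#'
#' @param calibration an [influx_calibration()].
#' @param totals an [isoform_totals()].
#' @param a a [dimer_conductances()].
#' @param convention conservation convention for the homodimer stage.
#' @param scan_range scan interval for the cross-constant roots.
#' @return a [binding_constants()] vector.
#' @export
init_from_algebra <- function(calibration, totals, a,
                              convention = c("mass_balance", "doubled_monomer"),
                              scan_range = c(1, 500)) {
  convention <- match.arg(convention)
  d <- unclass(calibration); I <- unclass(totals); av <- unclass(a)
  K11 <- solve_homodimer_K(I["I1"], d["d11"], av["a11"], convention)$K
  K22 <- solve_homodimer_K(I["I2"], d["d22"], av["a22"], convention)$K
  K33 <- solve_homodimer_K(I["I3"], d["d33"], av["a33"], convention)$K
  fallback <- sqrt(prod(scan_range))
  cross <- function(Kii, Kjj, Ii, Ij, aii, aij, ajj, dij) {
    tryCatch(solve_cross_K(c(Kii, Kjj), c(Ii, Ij), c(aii, aij, ajj), dij, scan_range),
             error = function(e) fallback)
  }
  K12 <- cross(K11, K22, I["I1"], I["I2"], av["a11"], av["a12"], av["a22"], d["d12"])
  K13 <- cross(K11, K33, I["I1"], I["I3"], av["a11"], av["a13"], av["a33"], d["d13"])
  K23 <- cross(K22, K33, I["I2"], I["I3"], av["a22"], av["a23"], av["a33"], d["d23"])
  binding_constants(K11 = K11, K12 = K12, K13 = K13, K22 = K22, K23 = K23, K33 = K33)
}

#' Least-squares fit of all six binding constants
#'
#' Minimizes the misfit between the seven genotype influx targets and the
#' influxes predicted by the equilibrium model, over the six binding
#' constants parametrized in log space (positivity is automatic). Uses
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]); deterministic given `init`.
#'
#' @inheritParams init_from_algebra
#' @param init starting [binding_constants()], typically from
#'   [init_from_algebra()].
#' @param weighting `"absolute"` (plain residuals, default) or `"relative"`
#'   (residuals divided by the targets, useful because the targets span a
#'   ~60-fold range).
#' @return object of class `"crac_fit"`: list with `K_estimates`,
#'   `residuals` (named, at the solution), `rss`, `init_rss`, `converged`,
#'   `n_iter`, `weighting`.
#' @export
fit_all_K <- function(calibration, totals, a, init,
                      weighting = c("absolute", "relative")) {
  weighting <- match.arg(weighting)
  d <- unclass(calibration)
  attributes(d) <- list(names = names(d))
  w <- if (weighting == "relative") 1 / pmax(d, .Machine$double.eps) else rep(1, length(d))
  genos <- calibration_genotypes()
  resid_fun <- function(logK) {
    # clamp so optimizer probes cannot overflow the exponential; a probe the
    # solver cannot evaluate gets a large finite residual instead of NaN
    if (any(!is.finite(logK))) return(rep(1e6, length(d)))
    kk <- exp(pmin(pmax(logK, -60), 60))
    K <- binding_constants(K11 = kk[1], K12 = kk[2], K13 = kk[3],
                           K22 = kk[4], K23 = kk[5], K33 = kk[6])
    pred <- vapply(genos, function(g) {
      tryCatch(
        total_influx(solve_equilibrium(apply_genotype(totals, orai_genotype(g)), K), a),
        error = function(e) NA_real_)
    }, numeric(1))
    r <- (pred - d) * w
    r[!is.finite(r)] <- 1e6
    r
  }
  logK0 <- log(pmax(unclass(init)[c("K11", "K12", "K13", "K22", "K23", "K33")],
                    .Machine$double.eps))
  init_res <- resid_fun(logK0)
  fit <- minpack.lm::nls.lm(par = logK0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  res <- resid_fun(fit$par)
  names(res) <- names(d)
  structure(list(
    K_estimates = {
      kk <- exp(pmin(pmax(fit$par, -60), 60))
      binding_constants(K11 = kk[1], K12 = kk[2], K13 = kk[3],
                        K22 = kk[4], K23 = kk[5], K33 = kk[6])
    },
    residuals = res,
    rss = sum(res^2),
    init_rss = sum(init_res^2),
    converged = fit$info %in% 1:4,
    n_iter = fit$niter,
    weighting = weighting), class = "crac_fit")
}

#' @export
print.crac_fit <- function(x, ...) {
  cat("CRAC dimer binding-constant fit (", x$weighting, " residuals)\n", sep = "")
  print(round(unclass(x$K_estimates), 4))
  cat(sprintf("  rss %.4g (init %.4g), %d iterations, converged: %s\n",
              x$rss, x$init_rss, x$n_iter, x$converged))
  invisible(x)
}
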