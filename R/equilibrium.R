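#' Model parameter constructors
#'
#' The influx model tracks the three ORAI isoforms as monomers `O1, O2, O3`
#' that pair into six dimer species `O11 .. O33` at equilibrium
#' (`O_ij = K_ij O_i O_j`), each dimer carrying a conductance `alpha_ij`.
#' These constructors validate the parameter triples/sextets used throughout.
#' Units are arbitrary: only ratios of totals, binding constants and
#' conductances are meaningful.
#'
#' @param I1,I2,I3 total isoform amounts (concentration units, >= 0).
#' @return a named numeric vector with class `"isoform_totals"`,
#'   `"binding_constants"` or `"dimer_conductances"`.
#' @examples
#' isoform_totals(1, 0.2, 0.2)
#' binding_constants(K11 = 14, K22 = 1.5, K33 = 0.93, K12 = 19, K13 = 17, K23 = 14)
#' @export
isoform_totals <- function(I1, I2, I3) {
  x <- c(I1 = as.numeric(I1)[1], I2 = as.numeric(I2)[1], I3 = as.numeric(I3)[1])
  if (any(!is.finite(x)) || any(x < 0)) stop("isoform totals must be finite and >= 0")
  structure(x, class = "isoform_totals")
}

#' @rdname isoform_totals
#' @param K11,K12,K13,K22,K23,K33 dimer association constants
#'   (1/concentration, >= 0); `K_ij` is symmetric by construction.
#' @export
binding_constants <- function(K11, K12, K13, K22, K23, K33) {
  x <- c(K11 = as.numeric(K11)[1], K12 = as.numeric(K12)[1], K13 = as.numeric(K13)[1],
         K22 = as.numeric(K22)[1], K23 = as.numeric(K23)[1], K33 = as.numeric(K33)[1])
  if (any(!is.finite(x)) || any(x < 0)) stop("binding constants must be finite and >= 0")
  structure(x, class = "binding_constants")
}

#' @rdname isoform_totals
#' @param a11,a12,a13,a22,a23,a33 per-dimer conductances (1/time, >= 0).
#' @export
dimer_conductances <- function(a11, a12, a13, a22, a23, a33) {
  x <- c(a11 = as.numeric(a11)[1], a12 = as.numeric(a12)[1], a13 = as.numeric(a13)[1],
         a22 = as.numeric(a22)[1], a23 = as.numeric(a23)[1], a33 = as.numeric(a33)[1])
  if (any(!is.finite(x)) || any(x < 0)) stop("conductances must be finite and >= 0")
  structure(x, class = "dimer_conductances")
}

#' Reference parameter set for the ORAI dimer model
#'
#' The totals, fitted binding constants and conductances used for the
#' simulations in this package: `I = (1, 0.2, 0.2)`,
#' `K = (K11 14, K22 1.5, K33 0.93, K12 19, K13 17, K23 14)`,
#' `alpha = (a11 2, a22 1, a33 0.7, a12 0.1, a13 0.1, a23 0.1)`. `K13` is
#' also reported elsewhere as 7; pass `K13 = 7` to use that variant.
#'
#' @param K13 value for the ORAI1-ORAI3 binding constant (default 17).
#' @return list with elements `I`, `K`, `alpha`.
#' @export
orai_reference_params <- function(K13 = 17) {
  list(
    I = isoform_totals(1, 0.2, 0.2),
    K = binding_constants(K11 = 14, K12 = 19, K13 = K13, K22 = 1.5, K23 = 14, K33 = 0.93),
    alpha = dimer_conductances(a11 = 2, a12 = 0.1, a13 = 0.1, a22 = 1, a23 = 0.1, a33 = 0.7)
  )
}

#' Genotypes: which ORAI isoforms are present
#'
#' A genotype is the subset of `{1, 2, 3}` of ORAI isoforms a cell line still
#' expresses; knockouts are modeled by zeroing the missing totals.
#' `orai_genotype_panel()` returns the standard seven-genotype panel (WT, the
#' three single knockouts as two-isoform cells, the three double knockouts as
#' single-isoform cells) plus the triple knockout.
#'
#' @param present integer vector, subset of `1:3` (may be empty for the
#'   triple knockout).
#' @return `orai_genotype()`: an object of class `"orai_genotype"`.
#' @examples
#' apply_genotype(isoform_totals(1, 0.2, 0.2), orai_genotype(c(1, 2)))
#' @export
orai_genotype <- function(present = 1:3) {
  present <- sort(unique(as.integer(present)))
  if (length(present) && (any(present < 1) || any(present > 3))) {
    stop("`present` must be a subset of 1:3")
  }
  structure(list(present = present), class = "orai_genotype")
}

#' @rdname orai_genotype
#' @param include_tko include the triple knockout in the panel.
#' @return `orai_genotype_panel()`: a named list of genotypes.
#' @export
orai_genotype_panel <- function(include_tko = TRUE) {
  panel <- list(
    WT          = orai_genotype(1:3),
    ORAI3_SKO   = orai_genotype(c(1, 2)),
    ORAI2_SKO   = orai_genotype(c(1, 3)),
    ORAI1_SKO   = orai_genotype(c(2, 3)),
    ORAI2_3_DKO = orai_genotype(1),
    ORAI1_3_DKO = orai_genotype(2),
    ORAI1_2_DKO = orai_genotype(3)
  )
  if (include_tko) panel$ORAI_TKO <- orai_genotype(integer(0))
  panel
}

#' @rdname orai_genotype
#' @param totals an [isoform_totals()] vector.
#' @param genotype an [orai_genotype()].
#' @return `apply_genotype()`: the totals with absent isoforms set to 0.
#' @export
apply_genotype <- function(totals, genotype) {
  stopifnot(inherits(genotype, "orai_genotype"))
  out <- unclass(totals)
  absent <- setdiff(1:3, genotype$present)
  out[absent] <- 0
  structure(out, class = "isoform_totals")
}

dimer_pairs <- matrix(c(1, 1, 1, 2, 1, 3, 2, 2, 2, 3, 3, 3),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(c("11", "12", "13", "22", "23", "33"), NULL))

# dimer concentrations from free monomers: O_ij = K_ij O_i O_j
dimers_from_monomers <- function(O, K) {
  d <- K * O[dimer_pairs[, 1]] * O[dimer_pairs[, 2]]
  names(d) <- paste0("O", rownames(dimer_pairs))
  d
}

# residual of the three conservation equations
# O_i + 2 K_ii O_i^2 + sum_{j != i} K_ij O_i O_j - I_i
conservation_residual <- function(O, I, K) {
  c(2 * K["K11"] * O[1]^2 + K["K12"] * O[1] * O[2] + K["K13"] * O[1] * O[3] + O[1] - I[1],
    K["K12"] * O[1] * O[2] + 2 * K["K22"] * O[2]^2 + K["K23"] * O[2] * O[3] + O[2] - I[2],
    K["K13"] * O[1] * O[3] + K["K23"] * O[2] * O[3] + 2 * K["K33"] * O[3]^2 + O[3] - I[3])
}

#' Solve the ORAI dimer mass-action equilibrium
#'
#' Finds the unique non-negative free-monomer concentrations `(O1, O2, O3)`
#' satisfying mass conservation
#' `O_i + 2 K_ii O_i^2 + sum_{j != i} K_ij O_i O_j = I_i`, then fills in the
#' six dimer concentrations `O_ij = K_ij O_i O_j`.
#'
#' The solver is a damped Newton iteration on `log O_i` (positivity is
#' automatic), started from `O_i = I_i`; isoforms with `I_i = 0` are held at
#' zero and dropped from the system. If Newton stalls, the solver falls back
#' to the globally convergent damped fixed-point map
#' `O_i <- I_i / (1 + 2 K_ii O_i + sum_{j != i} K_ij O_j)`.
#'
#' @param totals an [isoform_totals()] vector (knockouts already applied).
#' @param K a [binding_constants()] vector.
#' @param tol maximum allowed absolute conservation residual (default 1e-10).
#' @param max_iter iteration cap for each stage.
#' @return an object of class `"equilibrium_state"`: a list with monomers
#'   `O1..O3`, dimers `O11..O33`, and `conservation_residual`.
#' @examples
#' p <- orai_reference_params()
#' st <- solve_equilibrium(p$I, p$K)
#' total_influx(st, p$alpha)
#' @export
solve_equilibrium <- function(totals, K, tol = 1e-10, max_iter = 200L) {
  stopifnot(tol > 0)
  I <- as.numeric(unclass(totals))
  Kv <- unclass(K)
  active <- which(I > 0)
  O <- numeric(3)

  if (length(active)) {
    Kmat <- matrix(0, 3, 3)
    Kmat[cbind(dimer_pairs[, 1], dimer_pairs[, 2])] <- Kv
    Kmat[cbind(dimer_pairs[, 2], dimer_pairs[, 1])] <- Kv

    fres <- function(Oa) {
      Of <- numeric(3); Of[active] <- Oa
      conservation_residual(Of, I, Kv)[active]
    }
    # Newton on u = log(O) over the active subsystem
    u <- log(I[active])
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      Oa <- exp(u)
      r <- fres(Oa)
      if (max(abs(r)) < tol) { ok <- TRUE; break }
      # Jacobian wrt O, then chain rule for log-space
      n <- length(active)
      J <- matrix(0, n, n)
      for (ii in seq_len(n)) {
        i <- active[ii]
        for (jj in seq_len(n)) {
          j <- active[jj]
          if (i == j) {
            others <- setdiff(active, i)
            Of <- numeric(3); Of[active] <- Oa
            J[ii, jj] <- 1 + 4 * Kmat[i, i] * Of[i] + sum(Kmat[i, others] * Of[others])
          } else {
            Of <- numeric(3); Of[active] <- Oa
            J[ii, jj] <- Kmat[i, j] * Of[i]
          }
        }
      }
      Jlog <- sweep(J, 2, Oa, `*`)
      step <- tryCatch(solve(Jlog, r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      lambda <- 1
      r0 <- sum(r^2)
      repeat {
        u_new <- u - lambda * step
        r_new <- fres(exp(u_new))
        if (all(is.finite(r_new)) && sum(r_new^2) < r0) { u <- u_new; break }
        lambda <- lambda / 2
        if (lambda < 1e-8) { u <- u - 1e-8 * step; break }
      }
    }
    if (!ok) {
      # damped fixed-point fallback: contraction toward the unique root
      Oa <- pmin(exp(u), I[active])
      for (it in seq_len(50 * max_iter)) {
        Of <- numeric(3); Of[active] <- Oa
        denom <- vapply(active, function(i) {
          1 + 2 * Kmat[i, i] * Of[i] + sum(Kmat[i, setdiff(active, i)] * Of[setdiff(active, i)])
        }, numeric(1))
        prop <- I[active] / denom
        Oa_new <- 0.5 * Oa + 0.5 * prop
        if (max(abs(fres(Oa_new))) < tol) { Oa <- Oa_new; ok <- TRUE; break }
        Oa <- Oa_new
      }
      if (!ok) {
        stop(sprintf("equilibrium solver did not converge: residual %.3e",
                     max(abs(fres(Oa)))))
      }
      u <- log(Oa)
    }
    O[active] <- exp(u)
  }

  dim6 <- dimers_from_monomers(O, Kv)
  res <- conservation_residual(O, I, Kv)
  structure(
    c(as.list(c(O1 = O[1], O2 = O[2], O3 = O[3])), as.list(dim6),
      list(conservation_residual = max(abs(res)))),
    class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("ORAI dimer equilibrium state\n")
  cat(sprintf("  monomers: O1 = %.4g, O2 = %.4g, O3 = %.4g\n", x$O1, x$O2, x$O3))
  cat(sprintf("  dimers:   O11 = %.4g, O12 = %.4g, O13 = %.4g\n", x$O11, x$O12, x$O13))
  cat(sprintf("            O22 = %.4g, O23 = %.4g, O33 = %.4g\n", x$O22, x$O23, x$O33))
  cat(sprintf("  max conservation residual: %.2e\n", x$conservation_residual))
  invisible(x)
}

#' Population calcium influx through the dimer pool
#'
#' `J_in = sum_ij alpha_ij O_ij` over the six dimer species.
#'
#' @param state an `"equilibrium_state"` from [solve_equilibrium()].
#' @param a a [dimer_conductances()] vector.
#' @return non-negative influx rate (same arbitrary units as `alpha * O`).
#' @export
total_influx <- function(state, a) {
  av <- unclass(a)
  sum(av * c(state$O11, state$O12, state$O13, state$O22, state$O23, state$O33))
}

#' Influx across a panel of knockout genotypes
#'
#' For each genotype, masks the totals, solves the equilibrium and computes
#' the population influx. This is the forward model behind the influx
#' calibration targets `d_11 .. d_33, d_123`.
#'
#' @inheritParams solve_equilibrium
#' @param a a [dimer_conductances()] vector.
#' @param genotypes named list of [orai_genotype()] objects (default: the
#'   standard eight-genotype panel).
#' @return data.frame with one row per genotype: monomers, dimers, `J_in`,
#'   and `J_rel` (influx relative to WT when a genotype named `WT` is in the
#'   panel, otherwise relative to the maximum).
#' @export
genotype_influx_table <- function(totals, K, a, genotypes = orai_genotype_panel(),
                                  tol = 1e-10) {
  rows <- lapply(names(genotypes), function(g) {
    st <- tryCatch(
      solve_equilibrium(apply_genotype(totals, genotypes[[g]]), K, tol = tol),
      error = function(e) stop(sprintf("genotype %s: %s", g, conditionMessage(e))))
    data.frame(genotype = g,
               O1 = st$O1, O2 = st$O2, O3 = st$O3,
               O11 = st$O11, O12 = st$O12, O13 = st$O13,
               O22 = st$O22, O23 = st$O23, O33 = st$O33,
               J_in = total_influx(st, a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref <- if ("WT" %in% out$genotype) out$J_in[out$genotype == "WT"] else max(out$J_in)
  out$J_rel <- if (ref > 0) out$J_in / ref else NA_real_
  out
}

#' Calibrated genotype influx for simulations
#'
#' The dimer model fixes influx only up to an arbitrary unit; the
#' oscillation model consumes influx on the scale of the calibration
#' targets (wild type = `wt_reference`). This helper computes the model
#' influx for a genotype and rescales it so that the wild-type influx
#' equals `wt_reference`.
#'
#' @inheritParams genotype_influx_table
#' @param genotype an [orai_genotype()].
#' @param wt_reference influx value assigned to the wild type (default
#'   0.045, the wild-type calibration target).
#' @return scalar influx on the calibrated scale.
#' @export
calibrated_influx <- function(totals, K, a, genotype, wt_reference = 0.045) {
  wt <- total_influx(solve_equilibrium(totals, K), a)
  if (wt <= 0) stop("wild-type influx is zero; cannot calibrate")
  g <- total_influx(solve_equilibrium(apply_genotype(totals, genotype), K), a)
  wt_reference * g / wt
}
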