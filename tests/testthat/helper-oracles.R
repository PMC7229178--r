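# independent oracles and shared fixtures, kept deliberately naive

# brute-force canonicalization count used to cross-check Burnside counts
oracle_class_count <- function(n_colors, mode) {
  length(enumerate_arrangements(n_colors, mode))
}

# damped fixed-point iteration for the dimer equilibrium, independent of the
# Newton solver: O_i <- I_i / (1 + 2 K_ii O_i + sum_{j != i} K_ij O_j)
oracle_fixed_point <- function(I, Kv, n_iter = 5000) {
  Km <- matrix(0, 3, 3)
  Km[cbind(c(1, 1, 1, 2, 2, 3), c(1, 2, 3, 2, 3, 3))] <- Kv
  Km <- pmax(Km, t(Km))
  O <- I
  for (i in seq_len(n_iter)) {
    denom <- 1 + 2 * diag(Km) * O + as.numeric(Km %*% O) - diag(Km) * O
    O <- 0.5 * O + 0.5 * I / denom
  }
  O
}

random_K_draw <- function() {
  ks <- 10^stats::runif(6, -2, 2)
  binding_constants(K11 = ks[1], K12 = ks[2], K13 = ks[3],
                    K22 = ks[4], K23 = ks[5], K33 = ks[6])
}

ref <- orai_reference_params()
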