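# Shared helpers: small random configurations and an independent
# free-energy-perturbation (exponential averaging) estimator used as a
# cross-check oracle for TI.

random_config <- function(n, seed, spread = 6, type = "X") {
  set.seed(seed)
  configuration(matrix(runif(3 * n, 0, spread), ncol = 3),
                rep(type, n))
}

single_type_table <- function(C12 = 6e5, C6 = 600, C4 = 0, Q = 0.5,
                              type = "X") {
  pair_table(data.frame(type_i = type, type_j = type,
                        C12 = C12, C6 = C6, C4 = C4),
             charges = setNames(Q, type))
}

# FEP estimate of Delta G(A -> B) from samples x drawn in state A:
# -kT log < exp(-(U_B - U_A)/kT) >_A, with a blocked standard error.
fep_estimate <- function(x, uA, uB, temperature = 300) {
  kT <- lj1264::R_GAS * temperature
  w <- exp(-(uB(x) - uA(x)) / kT)
  nb <- length(w) %/% 100
  bm <- colMeans(matrix(w[seq_len(nb * 100)], nrow = 100))
  list(delta_G = -kT * log(mean(w)),
       se = kT * sd(bm) / sqrt(nb) / mean(w))
}

# mid-precision sampler config used across tests
quick_cfg <- function(n_steps, seed, ...) {
  sampler_config(n_steps = n_steps, seed = seed, thin = 1, ...)
}
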