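# Shared fixtures and independent oracles, built in code at test time.

# small deterministic view
tiny_view <- function(values = matrix(c(1, 2, 3, 4, 5, 6), 3, 2),
                      features = c("g1", "g2", "g3"),
                      samples = c("s1", "s2"), name = "test") {
  omics_view(values, features, samples, name)
}

# small two-view cohort used across classifier tests
small_cohort <- function(seed = 1, n = 120, noise_b = 1.0) {
  simulate_cohort(n = n, D_a = 80, D_b = 40, k_subtypes = 4, m_latent = 3,
                  support_size = 8, effect_size = 3, noise_sd_a = 0.5,
                  noise_sd_b = noise_b, seed = seed)
}

# four well-separated spherical blobs in 2-D fused coordinates
blob_fused <- function(n_per = 50, sep = 20, seed = 5) {
  set.seed(seed)
  lab <- rep(1:4, each = n_per)
  ctr <- matrix(c(0, 0, sep, 0, 0, sep, sep, sep), 4, 2, byrow = TRUE)
  X <- ctr[lab, ] + matrix(rnorm(4 * n_per * 2), 4 * n_per, 2)
  Z <- t(X)
  colnames(Z) <- sprintf("s%03d", seq_len(ncol(Z)))
  list(Z = Z, labels = label_vector(colnames(Z), lab))
}

# brute-force delta-grid maximizer for the L1-constrained unit problem:
# sweeps delta over a dense grid (with one refinement pass), keeps the
# feasible u with the largest u'a.  Independent of the bisection code path.
l1_grid_oracle <- function(a, c, n_grid = 4000) {
  best <- NULL
  best_obj <- -Inf
  sweep_grid <- function(deltas) {
    for (d in deltas) {
      s <- sign(a) * pmax(abs(a) - d, 0)
      nrm <- sqrt(sum(s^2))
      if (nrm == 0) next
      u <- s / nrm
      if (sum(abs(u)) <= c + 1e-9) {
        obj <- sum(u * a)
        if (obj > best_obj) {
          best_obj <<- obj
          best <<- list(u = u, delta = d)
        }
      }
    }
  }
  hi <- max(abs(a))
  sweep_grid(seq(0, hi, length.out = n_grid))
  step <- hi / (n_grid - 1)
  for (r in 1:3) {
    sweep_grid(seq(max(0, best$delta - step), min(hi, best$delta + step),
                   length.out = n_grid))
    step <- 2 * step / (n_grid - 1)
  }
  best$u
}
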