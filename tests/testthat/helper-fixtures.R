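# shared fixtures: default growth laws, canonical kinetics, small numerical
# oracles used across test files

laws_default <- growth_laws()

canon_kin <- function(alpha, laws = laws_default) shape_to_kinetics(alpha, laws)

# all fixed-point growth rates of the full single-drug kinetic system at a
# given extracellular concentration: sign changes of aex_of_y(y) - target
# on a dense y grid, refined by uniroot
full_model_roots <- function(target, kin, laws, enzyme = NULL) {
  yg <- seq(1e-5, 1 - 1e-10, length.out = 20000)
  f <- aex_of_y(yg, kin, laws, enzyme) - target
  s <- which(f[-1] * f[-length(f)] < 0)
  vapply(s, function(i)
    uniroot(function(y) aex_of_y(y, kin, laws, enzyme) - target,
            lower = yg[i], upper = yg[i + 1], tol = 1e-14)$root,
    numeric(1))
}

# central finite-difference Jacobian
num_jacobian <- function(f, x, eps = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# steady single-drug state vector (a, r_u, r_b) implied by growth laws at
# relative growth y
single_state_at <- function(y, kin, laws) {
  lam <- y * laws$lambda0
  r_b <- laws$delta_r * (1 - y)
  a <- if (y == 1) 0 else
    r_b * (lam + kin$k_off) * laws$kappa_t / (kin$k_on * lam)
  c(a = a, r_u = laws$r_min + lam / laws$kappa_t, r_b = r_b)
}
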