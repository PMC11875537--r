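# Independent reference implementations used as oracles: plain-R loops
# written directly from the model equations, deliberately separate from
# the package's compiled right-hand sides.

# general growth-effect variant (multispecies / two-species / delta /
# epistasis); s, p in natural units, no numerical guards beyond the
# extinct-species convention p/s = 0 at s = 0
ref_rhs_general <- function(model, s, p) {
  m <- model$m
  mu <- growth_rates(model)
  lam <- model$lam
  G <- model$gamma
  kap <- model$kappa
  D <- model$D
  eta <- if (length(model$eta) == 1L) array(model$eta, c(m, m, m)) else model$eta
  r <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m)
    if (s[i] > 0) r[i, j] <- min(max(p[i, j] / s[i], 0), 1)
  ds <- numeric(m)
  dp <- matrix(0, m, m)
  for (i in 1:m) {
    others <- setdiff(1:m, i)
    comp <- 1 - s[i] -
      sum(vapply(others, function(j)
        (G[i, j] + model$delta * r[j, i]) * s[j], 0))
    f <- prod(vapply(others, function(j) 1 + lam[i, j] * r[i, j], 0))
    ds[i] <- mu[i] * f * s[i] * comp - D * s[i]
    for (j in others) {
      ks <- setdiff(1:m, c(i, j))
      g <- if (length(ks)) prod(1 + lam[i, ks] * r[i, ks]) else 1
      pool <- sum(vapply(1:m, function(k) eta[j, k, i] * p[k, j], 0))
      dp[i, j] <- mu[i] * (1 + lam[i, j]) * g * p[i, j] * comp +
        (s[i] - p[i, j]) * pool - (D + kap[i, j]) * p[i, j]
    }
  }
  diag(dp) <- ds
  list(s = ds, p = dp)
}

# dimensionless two-species form with carrying-capacity ratio rho
# (p1 = carriers in species 1 of the species-2 plasmid and vice versa)
ref_rhs_two_species <- function(model, s1, s2, p1, p2) {
  mu <- growth_rates(model)
  lam1 <- model$lam[1, 1]; lam2 <- model$lam[2, 2]
  g2 <- model$gamma[1, 2]; g1 <- model$gamma[2, 1]
  eta <- if (length(model$eta) == 1L) model$eta else model$eta[1]
  kap <- model$kappa[1, 2]
  D <- model$D; rho <- model$rho
  mu1e <- mu[1] * (1 + lam2 * (if (s1 > 0) p1 / s1 else 0))
  mu2e <- mu[2] * (1 + lam1 * (if (s2 > 0) p2 / s2 else 0))
  c(ds1 = mu1e * s1 * (1 - s1 - g2 * s2) - D * s1,
    ds2 = mu2e * s2 * (1 - s2 - g1 * s1) - D * s2,
    dp1 = mu[1] * (1 + lam2) * p1 * (1 - s1 - g2 * s2) +
      eta * (rho * s2 + p1) * (s1 - p1) - (D + kap) * p1,
    dp2 = mu[2] * (1 + lam1) * p2 * (1 - s2 - g1 * s1) +
      eta * (s1 / rho + p2) * (s2 - p2) - (D + kap) * p2)
}

# strong-selection variant
ref_rhs_selection <- function(model, s, p) {
  m <- model$m
  mu <- growth_rates(model)
  G <- model$gamma
  D <- model$D
  eta <- model$eta
  ds <- dp <- numeric(m)
  for (i in 1:m) {
    comp <- 1 - s[i] - sum(vapply(setdiff(1:m, i), function(j)
      G[i, j] * s[j], 0))
    ds[i] <- mu[i] * p[i] * comp - D * s[i]
    pool <- sum(vapply(1:m, function(j) eta[j, i] * p[j], 0))
    dp[i] <- mu[i] * p[i] * comp + (s[i] - p[i]) * pool -
      model$kappa[i] * p[i] - D * p[i]
  }
  list(s = ds, p = dp)
}

random_valid_state <- function(model) {
  m <- model$m
  s <- runif(m)
  if (model$variant == "selection") {
    p <- runif(m) * s
    return(community_state(model, s, p))
  }
  if (model$variant == "classic_lv") return(community_state(model, s))
  p <- matrix(runif(m * m), m, m) * s
  diag(p) <- s
  community_state(model, s, p)
}
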