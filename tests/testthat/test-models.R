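# Model construction, right-hand sides, and the closed-form
# Lotka-Volterra results.

test_that("constructor normalizes parameters and enforces invariants", {
  mod <- community_model("multispecies", m = 3, mu0 = 0.5,
                         mu = c(0.4, 0.5, 0.6), gamma = 1.1, eta = 0.1)
  expect_equal(growth_rates(mod), c(0.4, 0.5, 0.6))
  # no-epistasis expansion: the effect travels with the plasmid
  expect_equal(mod$lam[1, 3], mod$lam[3, 3])
  expect_equal(diag(mod$gamma), rep(0, 3))

  expect_error(community_model("multispecies", m = 2, lam = -1.2),
               "1 \\+ lam")
  expect_error(community_model("multispecies", m = 2, D = -0.1), ">= 0")
  expect_error(community_model("niche", m = 4), "niche")
  expect_error(community_model("selection", m = 3, donor_index = 5),
               "donor")
  expect_error(community_model("multispecies", m = 2,
                               eta = matrix(0.1, 2, 2)),
               "eta")
})

test_that("epistasis parameterization fills the lam matrix from xi", {
  mod <- community_model("epistasis", m = 2, mu0 = 0.5,
                         lam = matrix(c(0.2, 0, 0, -0.1), 2, 2),
                         xi = c(0.5, -0.5))
  expect_equal(mod$lam[2, 1], 0.5 * 0.2)    # xi1 * lam11
  expect_equal(mod$lam[1, 2], -0.5 * -0.1)  # xi2 * lam22
  # set_growth_rates preserves the epistasis ratios
  mod2 <- set_growth_rates(mod, c(0.55, 0.45))
  expect_equal(mod2$lam[2, 1] / mod2$lam[1, 1], 0.5)
})

test_that("effective growth rates follow the carrier-fraction product", {
  mod <- community_model("two_species_hgt", m = 2, mu0 = 0.5,
                         lam = c(0, -0.04), eta = 0.1)
  # no acquired MGE: mu unchanged
  st <- community_state(mod, c(0.5, 0.5))
  expect_equal(effective_growth_rates(mod, st), growth_rates(mod))
  # full carriage of a lambda = -0.04 plasmid: 0.96 * mu
  p <- matrix(0, 2, 2); p[1, 2] <- 0.5
  st <- community_state(mod, c(0.5, 0.5), p)
  expect_equal(effective_growth_rates(mod, st)[1],
               0.96 * growth_rates(mod)[1])
  # extinct species: ratio taken as 0, rate finite
  st0 <- community_state(mod, c(0, 0.5))
  expect_equal(effective_growth_rates(mod, st0), growth_rates(mod))

  # m = 5 full carriage: mu_i * prod_{j != i} (1 + lam_j)
  mod5 <- preset_community("five_species")
  lamj <- diag(mod5$lam)
  s <- rep(0.2, 5)
  p <- matrix(s, 5, 5)
  st5 <- community_state(mod5, s, p)
  expected <- growth_rates(mod5) *
    vapply(1:5, function(i) prod(1 + lamj[-i]), 0)
  expect_equal(effective_growth_rates(mod5, st5), expected)
})

test_that("compiled RHS matches the reference equations on random states", {
  set.seed(101)
  mods <- list(
    preset_community("five_species", eta = 0.4),
    community_model("interaction_mod", m = 3, mu0 = 0.5,
                    mu = c(0.4, 0.5, 0.6), gamma = 1.1, eta = 0.2,
                    delta = 0.5),
    community_model("epistasis", m = 2, mu0 = 0.5,
                    lam = matrix(c(0.2, 0, 0, -0.1), 2, 2),
                    xi = c(-0.5, 0.8), eta = 0.3),
    community_model("multispecies", m = 4, mu0 = 0.5,
                    mu = c(0.45, 0.5, 0.55, 0.6),
                    gamma = matrix(runif(16, 0.9, 1.3), 4, 4), eta = 0.1))
  for (mod in mods) {
    for (rep in 1:30) {
      st <- random_valid_state(mod)
      got <- community_rhs(mod, st)
      want <- ref_rhs_general(mod, st$s, st$p)
      expect_equal(got$s, want$s, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
})

test_that("selection RHS matches its reference equations", {
  set.seed(33)
  mod <- preset_community("selection_community", m = 4,
                          mu = c(0.4, 0.5, 0.6, 0.45), eta = 0.2)
  for (rep in 1:30) {
    st <- random_valid_state(mod)
    got <- community_rhs(mod, st)
    want <- ref_rhs_selection(mod, st$s, st$p)
    expect_equal(got$s, want$s, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # eta = 0, no carriers: non-donors just decay at D
  mod0 <- set_eta(mod, 0)
  st <- community_state(mod0, rep(0.5, 4))
  d <- community_rhs(mod0, st)
  expect_equal(d$s[2:4], -mod0$D * st$s[2:4])
})

test_that("two-species dimensionless form is reproduced, including rho", {
  for (rho in c(1, 2.5)) {
    mod <- community_model("two_species_hgt", m = 2, mu0 = 0.5,
                           mu = c(0.4, 0.6), gamma = 1.1, eta = 0.2,
                           rho = rho)
    set.seed(7)
    for (rep in 1:20) {
      s <- runif(2); p12 <- runif(1) * s[1]; p21 <- runif(1) * s[2]
      pm <- matrix(0, 2, 2); pm[1, 2] <- p12; pm[2, 1] <- p21
      st <- community_state(mod, s, pm)
      got <- community_rhs(mod, st)
      want <- ref_rhs_two_species(mod, s[1], s[2], p12, p21)
      expect_equal(unname(c(got$s, got$p[1, 2], got$p[2, 1])),
                   unname(want), tolerance = 1e-12)
    }
  }
})

test_that("with no carriers and no transfer the model reduces to classic LV", {
  set.seed(11)
  for (rep in 1:100) {
    m <- sample(2:6, 1)
    mu <- runif(m, 0.3, 0.7)
    G <- matrix(runif(m * m, 0.8, 1.3), m, m)
    multi <- community_model("multispecies", m = m, mu0 = 0.5, mu = mu,
                             gamma = G, eta = 0)
    lv <- community_model("classic_lv", m = m, mu = mu, gamma = G)
    s <- runif(m)
    p <- matrix(0, m, m); diag(p) <- s
    d_multi <- community_rhs(multi, community_state(multi, s, p))
    d_lv <- community_rhs(lv, community_state(lv, s))
    expect_equal(d_multi$s, d_lv$s, tolerance = 1e-13)
  }
})

test_that("LV fixed points match the closed forms and the RHS vanishes there", {
  mod <- community_model("classic_lv", m = 2, mu = c(0.5, 0.5),
                         gamma = 1.1, D = 0.2)
  fp <- lv_fixed_points(mod)
  expect_equal(unname(fp$points["g2", ]), c(0, 0.6))
  expect_equal(unname(fp$points["g3", ]), c(0.6, 0))
  expect_equal(unname(fp$points["g4", ]), rep(0.6 / 2.1, 2),
               tolerance = 1e-12)
  for (k in 1:4) {
    d <- community_rhs(mod, community_state(mod, fp$points[k, ]))
    expect_lt(max(abs(d$s)), 1e-12)
  }
  # coexistence point also agrees with direct numerical root-finding
  # (Newton iteration on the RHS with a finite-difference Jacobian)
  f <- function(x) community_rhs(mod, community_state(mod, x))$s
  x <- c(0.3, 0.3)
  h <- 1e-7
  for (it in 1:25) {
    J <- cbind((f(x + c(h, 0)) - f(x - c(h, 0))) / (2 * h),
               (f(x + c(0, h)) - f(x - c(0, h))) / (2 * h))
    x <- x - solve(J, f(x))
  }
  expect_equal(x, unname(fp$points["g4", ]), tolerance = 1e-9)

  # asymmetric rates: only the fast grower's boundary state is stable
  mod2 <- community_model("classic_lv", m = 2, mu = c(0.3, 0.8),
                          gamma = 1.1, D = 0.2)
  fp2 <- lv_fixed_points(mod2)
  expect_true(fp2$stability[2])    # g2: species 2 alone
  expect_false(fp2$stability[3])   # g3: species 1 alone
  # degenerate competition product: no coexistence point
  g <- matrix(0, 2, 2); g[1, 2] <- 2; g[2, 1] <- 0.5
  fp3 <- lv_fixed_points(community_model("classic_lv", m = 2,
                                         mu = c(0.5, 0.5), gamma = g))
  expect_false(fp3$present[4])
})

test_that("analytic bistability condition", {
  lv <- function(mu1, mu2, g1, g2, D = 0.2) {
    G <- matrix(0, 2, 2); G[2, 1] <- g1; G[1, 2] <- g2
    community_model("classic_lv", m = 2, mu = c(mu1, mu2), gamma = G, D = D)
  }
  expect_true(lv_bistable(lv(0.5, 0.5, 1.1, 1.1)))
  expect_false(lv_bistable(lv(0.4, 0.6, 1.1, 1.1)))  # phi2/phi1 = 4/3 > 1.1
  expect_false(lv_bistable(lv(0.5, 0.5, 0.9, 0.9)))  # thresholds are 1
  nv <- lv_bistable(lv(0.15, 0.5, 2, 2))             # species 1 not viable
  expect_false(nv)
  expect_equal(attr(nv, "nonviable"), 1L)
  # agreement with the per-point Jacobian stability flags
  set.seed(5)
  for (rep in 1:50) {
    mod <- lv(runif(1, 0.25, 1), runif(1, 0.25, 1),
              runif(1, 0.5, 1.5), runif(1, 0.5, 1.5))
    fp <- lv_fixed_points(mod)
    expect_equal(as.logical(lv_bistable(mod)),
                 fp$stability[2] && fp$stability[3])
  }
})

test_that("transfer-rate unit conversion", {
  expect_equal(eta_to_empirical(1e-2, 1e9), 1e-11)
  expect_equal(eta_to_empirical(1e-2, 1e12), 1e-14)
  expect_equal(eta_from_empirical(1e-11, 1e9), 1e-2)
  expect_equal(eta_from_empirical(0, 1e9), 0)
})

test_that("models round-trip through JSON", {
  mods <- list(
    preset_community("five_species", eta = 0.4),
    community_model("niche", m = 4, mu0 = 0.5, mu = c(0.4, 0.5, 0.6, 0.45),
                    gamma = 1.2, eta = 0.1, niche_map = c(1, 2, 1, 2),
                    niche_capacity = c(0.8, 0.6)),
    preset_community("selection_community", m = 3, eta = 0.2),
    community_model("epistasis", m = 2, mu0 = 0.5,
                    lam = matrix(c(0.2, 0, 0, -0.1), 2, 2), xi = c(0.5, 0.5)))
  for (mod in mods) {
    path <- withr::local_tempfile(fileext = ".json")
    write_community_model(mod, path)
    back <- read_community_model(path)
    for (field in c("variant", "m", "mu0", "lam", "gamma", "kappa", "D"))
      expect_equal(back[[field]], mod[[field]], info = mod$variant)
    expect_equal(as.vector(back$eta), as.vector(mod$eta))
  }
  expect_error(read_community_model('{"m": 2}'), "schema_version")
})
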