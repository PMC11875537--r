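# Initial-condition sampling, attractor clustering, chi, and the
# randomized-parameter analyses.

test_that("initial-condition sampler respects bounds, modes and seeds", {
  mod <- preset_community("five_species", eta = 0.2)
  inits <- sample_initial_conditions(mod, 200, seed = 3)
  expect_length(inits, 200)
  S <- t(vapply(inits, function(st) st$s, numeric(5)))
  expect_true(all(S > 0 & S < 1))
  for (st in inits[1:20]) {
    off <- st$p[row(st$p) != col(st$p)]
    expect_true(all(off == 0))                 # native carriers only
    expect_equal(diag(st$p), st$s)
  }
  rnd <- sample_initial_conditions(mod, 20, seed = 3,
                                   carrier_mode = "random")
  some_off <- vapply(rnd, function(st)
    any(st$p[row(st$p) != col(st$p)] > 0), logical(1))
  expect_true(all(some_off))
  for (st in rnd) expect_true(all(st$p <= st$s + 1e-12))

  again <- sample_initial_conditions(mod, 200, seed = 3)
  expect_identical(lapply(inits, unclass), lapply(again, unclass))
  # enlarging the ensemble preserves the earlier substreams
  more <- sample_initial_conditions(mod, 300, seed = 3)
  expect_identical(lapply(more[1:200], unclass), lapply(inits, unclass))
})

test_that("clustering implements the strict-threshold transitive closure", {
  # two states closer than the threshold: one attractor
  expect_equal(cluster_attractors(rbind(c(0.5, 0.5), c(0.52, 0.48)),
                                  threshold = 0.05)$n_attractors, 1L)
  # chain a-b-c with a-c farther than the threshold: still one group
  chain <- rbind(c(0.50, 0.50), c(0.54, 0.50), c(0.58, 0.50))
  expect_equal(cluster_attractors(chain, threshold = 0.05)$n_attractors, 1L)
  # distances exactly at the threshold do not join
  expect_equal(cluster_attractors(rbind(c(0, 0), c(0.05, 0)),
                                  threshold = 0.05)$n_attractors, 2L)
  # well-separated groups and their basin counts
  S <- rbind(matrix(rep(c(0.6, 0), 3), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 0.6), 2), ncol = 2, byrow = TRUE))
  att <- cluster_attractors(S, threshold = 0.05)
  expect_equal(att$n_attractors, 2L)
  expect_setequal(att$basin_counts, c(3L, 2L))
  expect_equal(att$representatives[order(att$representatives[, 1]), ],
               rbind(c(0, 0.6), c(0.6, 0)))
})

test_that("clustering partition is invariant under input order", {
  set.seed(17)
  centers <- rbind(c(0.7, 0, 0), c(0, 0.65, 0), c(0, 0, 0.6))
  S <- centers[sample(1:3, 60, replace = TRUE), ] +
    matrix(rnorm(180, sd = 0.003), 60, 3)
  ref <- cluster_attractors(S, threshold = 0.05)
  for (rep in 1:5) {
    perm <- sample(60)
    att <- cluster_attractors(S[perm, ], threshold = 0.05)
    expect_equal(att$n_attractors, ref$n_attractors)
    expect_equal(sort(att$basin_counts), sort(ref$basin_counts))
  }
})

test_that("chi follows the entropy formula and its invariances", {
  expect_equal(multistability_coefficient(500), 1)
  expect_equal(multistability_coefficient(c(250, 250)), 2)
  x <- c(300, 150, 50) / 500
  expect_equal(multistability_coefficient(c(300, 150, 50)),
               exp(-sum(x * log(x))))
  expect_error(multistability_coefficient(integer(0)), "empty")
  expect_error(multistability_coefficient(c(3, 0)), "positive")
  set.seed(23)
  for (rep in 1:50) {
    counts <- sample(1:200, sample(1:6, 1), replace = TRUE)
    chi <- multistability_coefficient(counts)
    # label permutation invariance
    perm <- counts[sample(length(counts))]
    expect_equal(multistability_coefficient(perm), chi)
    # 1 <= chi <= number of basins, with equality for even basins
    expect_gte(chi, 1 - 1e-12)
    expect_lte(chi, length(counts) + 1e-12)
  }
  for (k in 1:6)
    expect_equal(multistability_coefficient(rep(7, k)), k)
})

test_that("stable-state counts replay exactly under a fixed master seed", {
  mod <- preset_community("five_species", eta = 0.4)
  a <- count_stable_states(mod, n_init = 60, seed = 12)
  b <- count_stable_states(mod, n_init = 60, seed = 12)
  expect_identical(a$basin_counts, b$basin_counts)
  expect_identical(a$representatives, b$representatives)
})

test_that("phase diagram agrees with the analytic oracle away from the boundary", {
  mod <- community_model("classic_lv", m = 2, mu = c(0.5, 0.5),
                         gamma = 1.1, D = 0.2)
  mu_vals <- c(0.3, 0.5, 0.7)
  pd <- phase_diagram(mod, mu_vals, mu_vals, n_init = 60,
                      threshold = 0.01, seed = 14)
  expect_equal(nrow(pd$grid), 9)
  analytic <- mapply(function(m1, m2)
    as.logical(lv_bistable(set_growth_rates(mod, c(m1, m2)))),
    pd$grid$mu1, pd$grid$mu2)
  # all cells sit well away from the analytic boundary phi2/phi1 = 1.1
  # (off-diagonal growth-rate ratios give phi ratios >= 1.19), so finite
  # ensembles cannot miss a vanishing minority basin
  expect_equal(pd$grid$bistable, analytic)
  expect_equal(pd$bistable_area_fraction, mean(analytic))
})

test_that("paired bistability fractions respond to delta as expected", {
  tm <- community_model("interaction_mod", m = 2, mu0 = 0.5, gamma = 1.1,
                        eta = 0, kappa = 0.005, D = 0.2, delta = 0.5)
  bf <- bistability_fraction(growth_rate_sampler(tm), n_draws = 12,
                             n_init = 30, threshold = 0.01, seed = 9,
                             eta_values = c(0, 0.3))
  expect_true(all(diff(bf$fraction) >= 0))
  single <- bistability_fraction(growth_rate_sampler(tm), n_draws = 12,
                                 n_init = 30, threshold = 0.01, seed = 9)
  expect_gte(single, 0)
  expect_lte(single, 1)
  expect_length(attr(single, "n_states"), 12)
})

test_that("eta scan summarizes replicates and finds an onset", {
  tmpl <- community_model("multispecies", m = 5, mu0 = 0.5, gamma = 1.1,
                          eta = 0, kappa = 0.005, D = 0.2)
  sc <- eta_scan(tmpl, eta_values = c(0, 0.2, 0.4), n_replicates = 3,
                 n_init = 60, threshold = 0.05, seed = 6)
  expect_equal(nrow(sc$runs), 9)
  expect_equal(nrow(sc$summary), 3)
  expect_true(all(sc$runs$n_states >= 1))
  expect_true(all(sc$runs$chi >= 1 - 1e-12))
  expect_true(all(sc$runs$chi <= sc$runs$n_states + 1e-12))
  # HGT should raise the mean attractor count in this regime
  expect_gt(sc$summary$mean_n_states[3], sc$summary$mean_n_states[1])
  expect_false(is.na(sc$onset_eta))
})

test_that("sampled models always satisfy the model invariants", {
  set.seed(41)
  for (rep in 1:300) {
    m <- sample(4:10, 1)
    spec <- sampler_spec(
      m = m,
      growth = list(list(type = "uniform", min = 0.3, max = 0.7),
                    list(type = "lambda_width", alpha = 0.8),
                    list(type = "fixed", mu = 0.5))[[sample(3, 1)]],
      gamma = if (runif(1) < 0.5) 1.1 else
        list(mean = runif(1, 0.8, 1.3), half_width = runif(1, 0, 0.2)),
      eta = runif(1, 0, 0.4),
      niche = runif(1) < 0.3,
      selection = if (runif(1) < 0.2)
        list(donor = sample(m, 1), mu_range = c(0.3, 0.7)))
    mod <- sample_community_model(spec)
    expect_s3_class(mod, "community_model")   # constructor validates
    expect_true(all(1 + mod$lam > 0))
    if (mod$variant == "niche") {
      l <- length(mod$niche_capacity)
      expect_gte(l, 2); expect_lte(l, spec$m / 2)
      expect_true(all(mod$niche_map %in% seq_len(l)))
    }
  }
})

test_that("sampled growth rates match their distribution", {
  spec <- sampler_spec(m = 2, growth = list(type = "uniform",
                                            min = 0.3, max = 0.7))
  set.seed(55)
  mus <- replicate(10000, growth_rates(sample_community_model(spec))[1])
  ks <- stats::ks.test(mus, "punif", 0.3, 0.7)
  expect_gt(ks$p.value, 0.01)
  # lambda-width scheme stays inside mu0 * (1 +/- alpha)
  spec2 <- sampler_spec(m = 3, growth = list(type = "lambda_width",
                                             alpha = 0.4))
  set.seed(56)
  mus2 <- replicate(200, growth_rates(sample_community_model(spec2)))
  expect_true(all(mus2 >= 0.3 & mus2 <= 0.7))
})

test_that("presets carry the documented parameterizations", {
  m5 <- preset_community("five_species")
  expect_equal(growth_rates(m5), c(0.52, 0.48, 0.44, 0.60, 0.31))
  expect_equal(diag(m5$lam), c(0.04, -0.04, -0.12, 0.2, -0.38))
  expect_equal(m5$gamma[1, 2], 1.05)
  expect_equal(growth_rates(preset_community("two_species_slow_fast")),
               c(0.3, 0.8))
  expect_equal(growth_rates(preset_community("two_species_near_neutral")),
               c(0.4, 0.6))
  sel <- preset_community("selection_community", m = 8)
  expect_equal(sel$gamma[2, 1], 1.5)
  expect_equal(sel$donor_index, 1L)
  expect_setequal(preset_names(),
                  c("two_species_slow_fast", "two_species_near_neutral",
                    "five_species", "selection_two_species",
                    "selection_community"))
})
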