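# Randomized model generators covering the study's parameter
# randomization schemes, plus the packaged worked-example
# parameterizations.

#' Specify a model randomization scheme
#'
#' Describes how to draw a `community_model`: the growth-rate scheme,
#' the competition scheme, and optional niche or selection structure.
#'
#' Growth schemes (`growth`):
#' * `list(type = "fixed", mu = ...)` - fixed growth rates;
#' * `list(type = "uniform", min = , max = )` - \eqn{\mu_i \sim U};
#' * `list(type = "lambda_width", alpha = )` -
#'   \eqn{\lambda_i \sim U(-\alpha, \alpha)}, \eqn{\mu_i =
#'   \mu_{i0}(1+\lambda_i)}; `alpha < 1` keeps growth rates positive.
#'
#' Competition schemes (`gamma`): a scalar, or
#' `list(mean = , half_width = )` drawing each off-diagonal
#' \eqn{\gamma_{ij} \sim U(mean - hw, mean + hw)}.
#'
#' `niche = TRUE` randomizes the number of niches l uniformly in
#' `2..m/2` (requires m >= 4), draws each niche capacity from U(0, 1]
#' and allocates each species to a random niche. `selection =
#' list(donor = , mu_range = )` switches to the strong-selection
#' variant with \eqn{\mu_i \sim U(mu_range)}.
#'
#' @param m species count.
#' @param mu0 basal growth rate(s) (1/hr).
#' @param growth growth-rate scheme (see Details).
#' @param gamma competition scheme.
#' @param eta,kappa,D transfer, loss and dilution rates (1/hr).
#' @param niche logical: randomize a niche structure.
#' @param selection `NULL` or a list with `donor` and `mu_range`.
#' @return object of class `sampler_spec`.
#' @export
sampler_spec <- function(m, mu0 = 0.5,
                         growth = list(type = "fixed", mu = 0.5),
                         gamma = 1.1, eta = 0, kappa = 0.005, D = 0.2,
                         niche = FALSE, selection = NULL) {
  m <- as.integer(m)
  if (!growth$type %in% c("fixed", "uniform", "lambda_width"))
    stop("unknown growth scheme: ", growth$type)
  if (growth$type == "lambda_width" && growth$alpha >= 1)
    stop("'alpha' must be < 1 so that 1 + lambda > 0")
  if (niche && m < 4L)
    stop("niche randomization (l >= 2) requires m >= 4")
  if (is.list(gamma) && (is.null(gamma$mean) || is.null(gamma$half_width)))
    stop("gamma scheme must be a scalar or list(mean, half_width)")
  structure(list(m = m, mu0 = mu0, growth = growth, gamma = gamma,
                 eta = eta, kappa = kappa, D = D, niche = niche,
                 selection = selection),
            class = "sampler_spec")
}

#' Draw a community model from a sampler specification
#'
#' @param spec a [sampler_spec()].
#' @param seed optional seed.
#' @return a validated `community_model`.
#' @export
sample_community_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sampler_spec"))
  if (!is.null(seed)) set.seed(seed)
  m <- spec$m
  gamma <- spec$gamma
  if (is.list(gamma)) {
    G <- matrix(runif(m * m, gamma$mean - gamma$half_width,
                      gamma$mean + gamma$half_width), m, m)
    diag(G) <- 0
    gamma <- G
  }
  if (!is.null(spec$selection)) {
    mu <- runif(m, spec$selection$mu_range[1], spec$selection$mu_range[2])
    return(community_model("selection", m = m, mu = mu, gamma = gamma,
                           eta = spec$eta, kappa = spec$kappa, D = spec$D,
                           donor_index = spec$selection$donor))
  }
  mu <- switch(spec$growth$type,
    fixed = rep_len(spec$growth$mu, m),
    uniform = runif(m, spec$growth$min, spec$growth$max),
    lambda_width = rep_len(spec$mu0, m) *
      (1 + runif(m, -spec$growth$alpha, spec$growth$alpha)))
  if (spec$niche) {
    # draw l uniformly from {2, ..., floor(m/2)}; note sample(2:2, 1)
    # would silently widen the range
    l <- sample.int(m %/% 2L - 1L, 1L) + 1L
    community_model("niche", m = m, mu0 = spec$mu0, mu = mu, gamma = gamma,
                    eta = spec$eta, kappa = spec$kappa, D = spec$D,
                    niche_map = sample.int(l, m, replace = TRUE),
                    niche_capacity = runif(l))
  } else {
    community_model("multispecies", m = m, mu0 = spec$mu0, mu = mu,
                    gamma = gamma, eta = spec$eta, kappa = spec$kappa,
                    D = spec$D)
  }
}

#' Packaged worked-example parameterizations
#'
#' `preset_community()` returns the parameter sets used throughout the
#' package's examples and tests; `preset_names()` lists them. All share
#' kappa = 0.005/hr and D = 0.2/hr:
#'
#' * `"two_species_slow_fast"` - two species with a large growth-rate
#'   difference (mu = 0.3, 0.8/hr; mu0 = 0.5/hr; gamma = 1.1). Strong
#'   competitor wins regardless of HGT: monostable.
#' * `"two_species_near_neutral"` - mu = 0.4, 0.6/hr, otherwise as
#'   above. HGT switches this community from monostable to bistable.
#' * `"five_species"` - five competitors, mu0 = 0.5/hr, mu = 0.52,
#'   0.48, 0.44, 0.60, 0.31/hr, gamma = 1.05. Monostable without HGT;
#'   four attractors at eta = 0.4/hr.
#' * `"selection_two_species"` - strong-selection variant, m = 2,
#'   gamma = 1.1, species 1 is the MGE donor.
#' * `"selection_community"` - strong-selection variant with m
#'   species, gamma = 1.5, species 1 the donor.
#'
#' @param name preset name.
#' @param eta MGE transfer rate (1/hr).
#' @param m species count (`"selection_community"` only).
#' @param mu growth rates for the selection presets (default 0.5/hr;
#'   typically redrawn per replicate from U(0.3, 0.7)).
#' @return a `community_model`.
#' @examples
#' preset_community("five_species", eta = 0.4)
#' @export
preset_community <- function(name = preset_names(), eta = 0, m = 5,
                             mu = 0.5) {
  name <- match.arg(name)
  switch(name,
    two_species_slow_fast = community_model(
      "two_species_hgt", m = 2, mu0 = 0.5, mu = c(0.3, 0.8),
      gamma = 1.1, eta = eta, kappa = 0.005, D = 0.2),
    two_species_near_neutral = community_model(
      "two_species_hgt", m = 2, mu0 = 0.5, mu = c(0.4, 0.6),
      gamma = 1.1, eta = eta, kappa = 0.005, D = 0.2),
    five_species = community_model(
      "multispecies", m = 5, mu0 = 0.5,
      mu = c(0.52, 0.48, 0.44, 0.60, 0.31),
      gamma = 1.05, eta = eta, kappa = 0.005, D = 0.2),
    selection_two_species = community_model(
      "selection", m = 2, mu = rep_len(mu, 2), gamma = 1.1, eta = eta,
      kappa = 0.005, D = 0.2, donor_index = 1L),
    selection_community = community_model(
      "selection", m = m, mu = rep_len(mu, m), gamma = 1.5, eta = eta,
      kappa = 0.005, D = 0.2, donor_index = 1L))
}

#' @rdname preset_community
#' @export
preset_names <- function() {
  c("two_species_slow_fast", "two_species_near_neutral", "five_species",
    "selection_two_species", "selection_community")
}
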