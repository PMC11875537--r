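#' Community model variants
#'
#' Names of the supported model variants. All variants share the same core:
#' generalized Lotka-Volterra competition between `m` species diluted at
#' rate `D`, with mobile genetic elements (MGEs, e.g. conjugative plasmids)
#' transferred between species at rate `eta` and lost at rate `kappa`.
#' They differ in how carriage of an MGE feeds back on the dynamics:
#'
#' * `"multispecies"` - MGEs multiply host growth rates; the general
#'   m-species form.
#' * `"two_species_hgt"` - the dimensionless two-species special case
#'   (supports unequal carrying capacities through `rho`).
#' * `"classic_lv"` - no MGEs at all; plain Lotka-Volterra with dilution.
#' * `"interaction_mod"` - MGE carriage additionally modifies interspecies
#'   competition by `delta` times the donor's carrier fraction.
#' * `"epistasis"` - growth effects depend on the host genome; the effect
#'   of plasmid j in species i is `lam[i, j]`, parameterized by the
#'   epistasis ratios `xi`.
#' * `"selection"` - strong environmental (e.g. antibiotic) selection:
#'   only MGE carriers grow, non-carriers are washed out at `D`.
#' * `"niche"` - species live in niches with their own carrying
#'   capacities; only species sharing a niche compete.
#'
#' @export
community_variants <- function() {
  c("multispecies", "two_species_hgt", "classic_lv", "interaction_mod",
    "epistasis", "selection", "niche")
}

#' Construct a community model
#'
#' Builds the full parameterization of one model variant. Rates are per
#' hour; abundances are dimensionless (relative to carrying capacity).
#'
#' The per-species maximum growth rate is \eqn{\mu_i = \mu_{i0}(1 +
#' \lambda_{ii})}: a basal, chromosomally determined rate times the effect
#' of the species' own resident MGE. Either supply `lam` directly, or
#' supply `mu` and let the diagonal effects be derived as
#' \eqn{\lambda_{ii} = \mu_i/\mu_{i0} - 1}. Off-diagonal effects default
#' to the no-epistasis rule \eqn{\lambda_{ij} = \lambda_{jj}} (an MGE
#' carries its growth effect with it, independent of the host).
#'
#' @param variant one of [community_variants()].
#' @param m number of species.
#' @param mu0 basal growth rates (1/hr), recycled to length `m`. For the
#'   `"selection"` and `"classic_lv"` variants this is the growth rate
#'   itself (use `mu` as a synonym).
#' @param mu optional maximum growth rates \eqn{\mu_i}; translated into
#'   diagonal `lam` entries for growth-effect variants.
#' @param lam MGE growth effects: scalar, length-`m` vector of per-plasmid
#'   effects, or full `m x m` matrix with `lam[i, j]` the effect of the
#'   species-j-originated MGE in species i. All entries must exceed -1.
#' @param gamma competition strengths: scalar (applied to every ordered
#'   pair) or `m x m` matrix with `gamma[i, j]` the effect of species j on
#'   species i (the diagonal is unused and forced to 0).
#' @param eta MGE transfer rate (1/hr): scalar, or an `m x m x m` array
#'   `eta[j, k, i]` (plasmid j, donor k, recipient i); for `"selection"`
#'   a scalar or `m x m` matrix `eta[j, i]` (donor j, recipient i).
#' @param kappa MGE loss rate (1/hr): scalar or `m x m` matrix
#'   (`"selection"`: scalar or length-`m` vector).
#' @param D dilution/death rate (1/hr).
#' @param delta competition modification by carriage
#'   (`"interaction_mod"`): the effective competition of species j on i is
#'   `gamma[i, j] + delta * p[j, i] / s[j]`.
#' @param rho carrying-capacity ratio of species 2 to species 1
#'   (`"two_species_hgt"` only).
#' @param xi length-2 epistasis ratios `(xi1, xi2)` for the
#'   `"epistasis"` variant: `lam[2, 1] = xi1 * lam[1, 1]` and
#'   `lam[1, 2] = xi2 * lam[2, 2]`. Positive values are magnitude
#'   epistasis, negative values sign epistasis.
#' @param niche_map integer vector mapping each species to a niche
#'   (`"niche"` only).
#' @param niche_capacity carrying capacity of each niche, in (0, 1].
#' @param donor_index index of the initial MGE donor (`"selection"`).
#' @return an object of class `community_model`.
#' @examples
#' mod <- community_model("multispecies", m = 5,
#'                        mu = c(0.52, 0.48, 0.44, 0.60, 0.31),
#'                        gamma = 1.05, eta = 0.4)
#' growth_rates(mod)
#' @export
community_model <- function(variant = community_variants(), m,
                            mu0 = 0.5, mu = NULL, lam = 0, gamma = 1.1,
                            eta = 0, kappa = 0.005, D = 0.2, delta = 0,
                            rho = 1, xi = NULL, niche_map = NULL,
                            niche_capacity = NULL, donor_index = 1L) {
  variant <- match.arg(variant)
  m <- as.integer(m)
  if (m < 1) stop("'m' must be a positive integer")
  mu0 <- rep_len(as.numeric(mu0), m)

  if (!is.null(mu) && !missing(lam))
    stop("supply either 'mu' or 'lam', not both")
  if (variant %in% c("classic_lv", "selection")) {
    if (!is.null(mu)) mu0 <- rep_len(as.numeric(mu), m)
    lam <- matrix(0, m, m)
  } else {
    if (!is.null(mu)) {
      mu <- rep_len(as.numeric(mu), m)
      lam <- mu / mu0 - 1         # per-plasmid effects, no epistasis
    }
    lam <- .expand_lam(lam, m)
    if (!is.null(xi)) {
      if (m != 2L || variant != "epistasis")
        stop("'xi' is only meaningful for the two-species 'epistasis' variant")
      lam <- lam_epistasis(lam[1, 1], lam[2, 2], xi[1], xi[2])
    }
  }

  gamma <- .expand_square(gamma, m, "gamma")
  diag(gamma) <- 0

  if (variant == "selection") {
    kappa <- rep_len(as.numeric(kappa), m)
    if (length(eta) == 1L) eta <- matrix(as.numeric(eta), m, m)
    if (!is.matrix(eta) || any(dim(eta) != m))
      stop("'eta' must be a scalar or m x m matrix for the selection variant")
  } else {
    kappa <- .expand_square(kappa, m, "kappa")
    if (length(eta) != 1L &&
        !(is.array(eta) && length(dim(eta)) == 3 && all(dim(eta) == m)))
      stop("'eta' must be a scalar or an m x m x m array")
  }

  model <- structure(list(
    variant = variant, m = m, mu0 = mu0, lam = lam, gamma = gamma,
    eta = eta, kappa = kappa, D = as.numeric(D), delta = as.numeric(delta),
    rho = as.numeric(rho), xi = xi,
    niche_map = if (!is.null(niche_map)) as.integer(niche_map),
    niche_capacity = if (!is.null(niche_capacity)) as.numeric(niche_capacity),
    donor_index = as.integer(donor_index)),
    class = "community_model")
  validate_community_model(model)
  model
}

.expand_lam <- function(lam, m) {
  if (is.matrix(lam)) {
    if (any(dim(lam) != m)) stop("'lam' matrix must be m x m")
    return(lam)
  }
  lam <- as.numeric(lam)
  if (length(lam) == 1L) lam <- rep(lam, m)
  if (length(lam) != m) stop("'lam' must be scalar, length m, or m x m")
  matrix(lam, m, m, byrow = TRUE)   # lam[i, j] = effect of plasmid j
}

.expand_square <- function(x, m, name) {
  if (is.matrix(x)) {
    if (any(dim(x) != m)) stop(sprintf("'%s' matrix must be m x m", name))
    return(x)
  }
  if (length(x) != 1L) stop(sprintf("'%s' must be a scalar or m x m matrix", name))
  matrix(as.numeric(x), m, m)
}

#' Validate a community model
#'
#' Checks the structural invariants: non-negative rates, `1 + lam > 0`
#' everywhere, non-negative maximum growth rates, consistent niche map,
#' and a valid donor for the selection variant. Called by the constructor;
#' exported so that externally modified or deserialized models can be
#' re-checked.
#'
#' @param model a `community_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_community_model <- function(model) {
  stopifnot(inherits(model, "community_model"))
  m <- model$m
  if (any(model$mu0 < 0)) stop("basal growth rates must be >= 0")
  if (any(1 + model$lam <= 0)) stop("all 1 + lam[i, j] must be > 0")
  if (any(growth_rates(model) < 0)) stop("mu = mu0 * (1 + lam_ii) must be >= 0")
  if (any(model$gamma < 0)) stop("competition strengths must be >= 0")
  if (any(model$kappa < 0) || any(model$eta < 0) || model$D < 0)
    stop("rates eta, kappa, D must be >= 0")
  if (model$rho <= 0) stop("'rho' must be positive")
  if (model$variant == "niche") {
    nm <- model$niche_map; nc <- model$niche_capacity
    if (is.null(nm) || is.null(nc))
      stop("niche variant requires 'niche_map' and 'niche_capacity'")
    if (length(nm) != m || any(nm < 1) || any(nm > length(nc)))
      stop("'niche_map' values must index 'niche_capacity'")
    if (any(nc <= 0) || any(nc > 1))
      stop("'niche_capacity' values must lie in (0, 1]")
  }
  if (model$variant == "selection") {
    if (model$donor_index < 1 || model$donor_index > m)
      stop("'donor_index' must be in 1..m")
  }
  invisible(model)
}

#' Maximum per-capita growth rates
#'
#' \eqn{\mu_i = \mu_{i0} (1 + \lambda_{ii})} for growth-effect variants;
#' for `"classic_lv"` and `"selection"` the stored rates themselves.
#'
#' @param model a `community_model`.
#' @return numeric vector of length `m` (1/hr).
#' @export
growth_rates <- function(model) {
  model$mu0 * (1 + diag(model$lam))
}

#' Epistatic growth-effect matrix for two species
#'
#' Builds the 2 x 2 `lam` matrix from the plasmids' effects in their own
#' hosts and the epistasis ratios `xi1 = lam21/lam11`,
#' `xi2 = lam12/lam22`.
#'
#' @param lam11,lam22 effect of each plasmid in its species of origin.
#' @param xi1,xi2 epistasis ratios; positive = magnitude epistasis,
#'   negative = sign epistasis.
#' @return 2 x 2 matrix with `lam[i, j]` the effect of plasmid j in
#'   species i.
#' @export
lam_epistasis <- function(lam11, lam22, xi1, xi2) {
  matrix(c(lam11, xi1 * lam11, xi2 * lam22, lam22), 2, 2)
}

#' @export
print.community_model <- function(x, ...) {
  cat("Community model (", x$variant, "), m = ", x$m, " species\n", sep = "")
  cat("  mu      :", paste(signif(growth_rates(x), 4), collapse = " "), "/hr\n")
  g <- x$gamma[row(x$gamma) != col(x$gamma)]
  cat("  gamma   :", if (length(unique(g)) == 1L) unique(g) else
    paste0("[", signif(min(g), 3), ", ", signif(max(g), 3), "]"), "\n")
  et <- if (length(x$eta) == 1L) x$eta else
    paste0("[", signif(min(x$eta), 3), ", ", signif(max(x$eta), 3), "]")
  cat("  eta     :", et, "/hr   kappa:",
      signif(max(x$kappa), 4), "/hr   D:", x$D, "/hr\n")
  if (x$delta != 0) cat("  delta   :", x$delta, "\n")
  if (x$variant == "niche")
    cat("  niches  :", length(x$niche_capacity), "(map:",
        paste(x$niche_map, collapse = " "), ")\n")
  if (x$variant == "selection")
    cat("  donor   : species", x$donor_index, "\n")
  invisible(x)
}

#' Replace growth rates of a model
#'
#' Sets the maximum growth rates \eqn{\mu_i}, preserving the variant's
#' structure: growth-effect variants update the `lam` diagonal (and keep
#' epistasis ratios `xi` if present), `"classic_lv"` and `"selection"`
#' update the rates directly.
#'
#' @param model a `community_model`.
#' @param mu new growth rates (recycled to length `m`).
#' @return the updated model.
#' @export
set_growth_rates <- function(model, mu) {
  mu <- rep_len(as.numeric(mu), model$m)
  if (model$variant %in% c("classic_lv", "selection")) {
    model$mu0 <- mu
  } else {
    lam_diag <- mu / model$mu0 - 1
    if (!is.null(model$xi)) {
      model$lam <- lam_epistasis(lam_diag[1], lam_diag[2],
                                 model$xi[1], model$xi[2])
    } else {
      model$lam <- matrix(lam_diag, model$m, model$m, byrow = TRUE)
    }
  }
  validate_community_model(model)
}

#' Replace the MGE transfer rate of a model
#'
#' @param model a `community_model`.
#' @param eta new transfer rate (scalar or full array, see
#'   [community_model()]).
#' @return the updated model.
#' @export
set_eta <- function(model, eta) {
  model$eta <- eta
  if (model$variant == "selection" && length(eta) == 1L)
    model$eta <- matrix(as.numeric(eta), model$m, model$m)
  validate_community_model(model)
}

# ---- community state ----------------------------------------------------

#' Construct a community state
#'
#' A state holds the species abundances `s` and the carrier subpopulation
#' abundances `p`. For growth-effect variants `p` is an `m x m` matrix
#' with `p[i, j]` the abundance of species-i cells carrying the
#' species-j-originated MGE; the diagonal is defined as `p[i, i] = s[i]`
#' (species never lose their own resident MGE completely). For the
#' `"selection"` variant `p` is a length-`m` vector of carrier abundances.
#' The `"classic_lv"` variant has no carriers (`p = NULL`).
#'
#' @param model a `community_model`.
#' @param s species abundances, length `m`, each in `[0, 1]` initially.
#' @param p carrier abundances; `NULL` builds the default: `p[i, i] = s`,
#'   off-diagonal 0 (selection: all of the donor's cells carry the MGE,
#'   no other species does).
#' @return an object of class `community_state`.
#' @export
community_state <- function(model, s, p = NULL) {
  m <- model$m
  s <- as.numeric(s)
  if (length(s) != m) stop("'s' must have length m")
  if (any(s < 0)) stop("abundances must be >= 0")
  if (model$variant == "classic_lv") {
    p <- NULL
  } else if (model$variant == "selection") {
    if (is.null(p)) {
      p <- numeric(m)
      p[model$donor_index] <- s[model$donor_index]
    }
    p <- as.numeric(p)
    if (length(p) != m) stop("'p' must have length m for the selection variant")
    if (any(p < -1e-12) || any(p > s + 1e-9))
      stop("carrier abundances must satisfy 0 <= p_i <= s_i")
  } else {
    if (is.null(p)) {
      p <- matrix(0, m, m)
      diag(p) <- s
    }
    if (!is.matrix(p) || any(dim(p) != m)) stop("'p' must be an m x m matrix")
    diag(p) <- s
    if (any(p < -1e-12) || any(p > s + 1e-9))
      stop("carrier abundances must satisfy 0 <= p_ij <= s_i")
  }
  structure(list(s = s, p = p), class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat("Community state, m =", length(x$s), "\n")
  cat("  s:", paste(signif(x$s, 4), collapse = " "), "\n")
  if (!is.null(x$p)) {
    tot <- if (is.matrix(x$p)) rowSums(x$p) - diag(x$p) else x$p
    cat("  acquired-MGE carriers per species:",
        paste(signif(tot, 4), collapse = " "), "\n")
  }
  invisible(x)
}

# ---- model-level operations ---------------------------------------------

#' Effective growth rates at a state
#'
#' For growth-effect variants, \eqn{\mu_i^e = \mu_i \prod_{j \ne i} (1 +
#' \lambda_{ij} p_{ij}/s_i)}: every acquired MGE multiplies the host's
#' growth rate. The carrier fraction \eqn{p_{ij}/s_i} of an extinct
#' species (\eqn{s_i = 0}) is taken as 0. For the `"selection"` variant
#' the effective per-capita rate is \eqn{\mu_i p_i / s_i} (only carriers
#' grow).
#'
#' @param model a `community_model`.
#' @param state a `community_state`.
#' @return numeric vector of per-capita growth rates (1/hr).
#' @export
effective_growth_rates <- function(model, state) {
  mu <- growth_rates(model)
  if (model$variant == "classic_lv") return(mu)
  s <- state$s
  if (model$variant == "selection") {
    r <- ifelse(s > 0, pmin(pmax(state$p / s, 0), 1), 0)
    return(mu * r)
  }
  m <- model$m
  r <- state$p / ifelse(s > 0, s, Inf)   # 0 when s_i = 0
  r <- pmin(pmax(r, 0), 1)
  fac <- 1 + model$lam * r
  diag(fac) <- 1
  mu * apply(fac, 1, prod)
}

#' Evaluate the model right-hand side
#'
#' Time derivatives of all state components at `state`, exactly as used by
#' the integrator (compiled code; single source of truth).
#'
#' @param model a `community_model`.
#' @param state a `community_state`.
#' @return a list with components `s` and `p` shaped like the state
#'   (for growth-effect variants the `p` diagonal carries
#'   \eqn{dp_{ii}/dt = ds_i/dt}).
#' @export
community_rhs <- function(model, state) {
  pv <- .pack_parms(model)
  y <- .state_to_y(model, state)
  dy <- .Call(C_eval_derivs, pv, y)
  .y_to_state(model, dy, clamp = FALSE)
}

# ---- classic LV closed forms --------------------------------------------

#' Fixed points of the two-species Lotka-Volterra model
#'
#' The classic two-species competition model with dilution has four fixed
#' points: extinction `g1 = (0, 0)`, the two single-species states
#' `g2 = (0, 1 - D/mu2)` and `g3 = (1 - D/mu1, 0)`, and the coexistence
#' point `g4` solving \eqn{s_1 + \gamma_2 s_2 = \phi_1},
#' \eqn{\gamma_1 s_1 + s_2 = \phi_2} with \eqn{\phi_i = (\mu_i - D)/\mu_i}.
#' Stability is read off the eigenvalues of the 2 x 2 Jacobian at each
#' point. When \eqn{\gamma_1 \gamma_2 = 1} the coexistence point is
#' degenerate and reported absent.
#'
#' Here `gamma1` is the competition exerted by species 1 on species 2
#' (`model$gamma[2, 1]`) and `gamma2` the reverse, following the
#' two-species convention.
#'
#' @param model a `community_model` with `variant = "classic_lv"`, m = 2.
#' @return object of class `lv_fixed_points`: a list with `points`
#'   (4 x 2 matrix, rows g1-g4; g4 row `NA` if absent), `stability`
#'   (logical, `NA` for an absent point), and `present`.
#' @export
lv_fixed_points <- function(model) {
  stopifnot(model$variant == "classic_lv", model$m == 2L)
  mu <- growth_rates(model)
  D <- model$D
  g1 <- model$gamma[2, 1]   # effect of species 1 on species 2
  g2 <- model$gamma[1, 2]
  pts <- rbind(g1 = c(0, 0),
               g2 = c(0, 1 - D / mu[2]),
               g3 = c(1 - D / mu[1], 0),
               g4 = c(NA_real_, NA_real_))
  present <- c(TRUE, TRUE, TRUE, abs(g1 * g2 - 1) > 1e-12)
  if (present[4]) {
    phi <- (mu - D) / mu
    pts["g4", ] <- c(phi[1] - g2 * phi[2], phi[2] - g1 * phi[1]) / (1 - g1 * g2)
  }
  jac <- function(s1, s2) {
    matrix(c(mu[1] * (1 - 2 * s1 - g2 * s2) - D,
             -mu[2] * g1 * s2,
             -mu[1] * g2 * s1,
             mu[2] * (1 - 2 * s2 - g1 * s1) - D), 2, 2)
  }
  stability <- rep(NA, 4)
  for (k in which(present)) {
    ev <- eigen(jac(pts[k, 1], pts[k, 2]), only.values = TRUE)$values
    stability[k] <- max(Re(ev)) < 0
  }
  structure(list(points = pts, stability = stability, present = present,
                 model = model),
            class = "lv_fixed_points")
}

#' @export
print.lv_fixed_points <- function(x, ...) {
  cat("Lotka-Volterra fixed points:\n")
  for (k in 1:4) {
    if (!x$present[k]) {
      cat(sprintf("  %s: absent (gamma1 * gamma2 = 1)\n", rownames(x$points)[k]))
    } else {
      cat(sprintf("  %s: (%.4f, %.4f)  %s\n", rownames(x$points)[k],
                  x$points[k, 1], x$points[k, 2],
                  if (x$stability[k]) "stable" else "unstable"))
    }
  }
  invisible(x)
}

#' Analytic bistability condition for two competing species
#'
#' The two-species Lotka-Volterra system is bistable (both single-species
#' states stable) iff \eqn{\gamma_1 > \phi_2/\phi_1} and
#' \eqn{\gamma_2 > \phi_1/\phi_2}, where \eqn{\phi_i = (\mu_i - D)/\mu_i}.
#' If either species is not viable on its own (\eqn{\mu_i \le D}) the
#' system cannot be bistable; `FALSE` is returned with attribute
#' `nonviable` naming the species.
#'
#' @param model a `community_model` with `variant = "classic_lv"`, m = 2.
#' @return logical scalar.
#' @export
lv_bistable <- function(model) {
  stopifnot(model$variant == "classic_lv", model$m == 2L)
  mu <- growth_rates(model)
  D <- model$D
  if (any(mu <= D)) {
    out <- FALSE
    attr(out, "nonviable") <- which(mu <= D)
    return(out)
  }
  phi <- (mu - D) / mu
  gamma1 <- model$gamma[2, 1]
  gamma2 <- model$gamma[1, 2]
  gamma1 > phi[2] / phi[1] && gamma2 > phi[1] / phi[2]
}

# ---- rate conversion ----------------------------------------------------

#' Convert between empirical and model transfer rates
#'
#' Empirically measured conjugation efficiencies `eta_c`
#' (1/(cells/mL)/hr, mass-action constants on absolute densities) relate
#' to the dimensionless-abundance model rate by `eta = Nm * eta_c`, where
#' `Nm` is the maximum carrying capacity in cells/mL.
#'
#' @param eta_c per-cell transfer rate.
#' @param Nm carrying capacity (cells/mL).
#' @return model transfer rate (1/hr).
#' @export
eta_from_empirical <- function(eta_c, Nm) {
  stopifnot(all(eta_c >= 0), all(Nm >= 0))
  Nm * eta_c
}

#' @rdname eta_from_empirical
#' @param eta model transfer rate (1/hr).
#' @export
eta_to_empirical <- function(eta, Nm) {
  stopifnot(all(eta >= 0), all(Nm > 0))
  eta / Nm
}
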