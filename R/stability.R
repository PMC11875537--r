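# Ensemble-based stability landscape analysis: random initializations,
# attractor clustering, the multistability coefficient chi, phase
# diagrams, bistability fractions and transfer-rate scans.

# Independent per-initialization seeds derived from one master stream:
# drawn sequentially, so enlarging n keeps earlier substreams unchanged.
.spawn_seeds <- function(n) {
  floor(runif(n) * 2147483646) + 1
}

#' Sample random initial conditions
#'
#' Species abundances are drawn independently from U(0, 1). In the
#' default carrier mode each species starts carrying only its own MGE
#' (`p[i, i] = s_i`, off-diagonal 0; selection variant: only the donor
#' carries). Mode `"random"` instead draws every off-diagonal carrier
#' abundance from U(0, s_i).
#'
#' @param model a `community_model`.
#' @param n_init number of initial conditions.
#' @param seed master seed; each initialization gets its own recorded
#'   substream seed so ensembles are replayable.
#' @param carrier_mode `"native"` or `"random"`.
#' @return list of `community_state`, with the substream seeds attached
#'   as attribute `"seeds"`.
#' @export
sample_initial_conditions <- function(model, n_init, seed = NULL,
                                      carrier_mode = c("native", "random")) {
  carrier_mode <- match.arg(carrier_mode)
  stopifnot(n_init >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- .spawn_seeds(n_init)
  m <- model$m
  states <- vector("list", n_init)
  for (k in seq_len(n_init)) {
    set.seed(seeds[k])
    s <- runif(m)
    p <- NULL
    if (carrier_mode == "random" && .variant_code(model$variant) == 1L) {
      p <- matrix(runif(m * m), m, m) * s   # p[i, j] ~ U(0, s_i)
      diag(p) <- s
    }
    states[[k]] <- community_state(model, s, p)
  }
  attr(states, "seeds") <- seeds
  states
}

#' Run a random-initialization ensemble
#'
#' Integrates the model to steady state from `n_init` random initial
#' compositions (see [sample_initial_conditions()]), recording
#' convergence flags, residuals and per-initialization seeds.
#'
#' @inheritParams sample_initial_conditions
#' @param horizon,tol,max_horizon steady-state settings, see
#'   [find_steady_state()].
#' @param ... further arguments for [find_steady_state()].
#' @return object of class `community_ensemble`: list with `model`, `s`
#'   (n_init x m matrix of steady-state abundances), `converged`,
#'   `residual`, `t_final`, `seeds`, `n_init`.
#' @export
run_ensemble <- function(model, n_init = 500, seed = NULL,
                         carrier_mode = c("native", "random"),
                         horizon = 2000, tol = 1e-6, max_horizon = 10000,
                         ...) {
  carrier_mode <- match.arg(carrier_mode)
  inits <- sample_initial_conditions(model, n_init, seed, carrier_mode)
  m <- model$m
  S <- matrix(NA_real_, n_init, m)
  converged <- logical(n_init)
  residual <- t_final <- numeric(n_init)
  for (k in seq_len(n_init)) {
    ss <- find_steady_state(model, inits[[k]], horizon = horizon, tol = tol,
                            max_horizon = max_horizon, ...)
    S[k, ] <- ss$state$s
    converged[k] <- ss$converged
    residual[k] <- ss$residual
    t_final[k] <- ss$t_final
  }
  structure(list(model = model, s = S, converged = converged,
                 residual = residual, t_final = t_final,
                 seeds = attr(inits, "seeds"), n_init = n_init),
            class = "community_ensemble")
}

#' @export
print.community_ensemble <- function(x, ...) {
  cat("Ensemble of", x$n_init, "initializations,",
      sum(x$converged), "converged\n")
  invisible(x)
}

#' @export
as.data.frame.community_ensemble <- function(x, ...) {
  df <- as.data.frame(x$s)
  names(df) <- paste0("s_", seq_len(ncol(x$s)))
  cbind(data.frame(seed = x$seeds, converged = x$converged,
                   residual = x$residual), df)
}

#' Ensemble method for community models
#'
#' `simulate()` on a `community_model` runs a random-initialization
#' ensemble; a convenience wrapper around [run_ensemble()].
#'
#' @param object a `community_model`.
#' @param nsim number of initializations.
#' @param seed master seed.
#' @param ... passed to [run_ensemble()].
#' @return a `community_ensemble`.
#' @export
simulate.community_model <- function(object, nsim = 500, seed = NULL, ...) {
  run_ensemble(object, n_init = nsim, seed = seed, ...)
}

# strict single-linkage components: i ~ j iff d_ij < threshold
.distance_components <- function(S, threshold) {
  n <- nrow(S)
  if (n == 1L) return(1L)
  dm <- as.matrix(dist(S))
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      k <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(dm[k, ] < threshold & labels == 0L)
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Group ensemble steady states into attractors
#'
#' Single-linkage grouping on the species composition: two steady states
#' belong to the same attractor iff they are connected by a chain of
#' pairwise Euclidean distances (on the `s` vector only) each smaller
#' than `threshold`. Abundances below the extinction floor are zeroed
#' first so near-extinct tails do not split clusters. Non-converged
#' ensemble members are excluded (and counted in `n_excluded`).
#'
#' @param x a `community_ensemble`, or a numeric matrix of steady-state
#'   abundances (one row per run, all treated as converged).
#' @param threshold clustering distance; the conventional defaults are
#'   0.01 for two-species analyses and 0.05 for larger communities.
#' @param floor extinction floor applied before clustering.
#' @param exclude_unconverged drop ensemble members whose residual never
#'   fell below tolerance. Set to `FALSE` for fixed-window protocols
#'   where slow transients are clustered as-is (see [eta_scan()]).
#' @return object of class `attractor_set`: list with `representatives`
#'   (one row per attractor: mean composition), `basin_counts`, `chi`
#'   (see [multistability_coefficient()]), `threshold`, `n_attractors`,
#'   `n_members`, `n_excluded`.
#' @export
cluster_attractors <- function(x, threshold = NULL, floor = 1e-6,
                               exclude_unconverged = TRUE) {
  if (inherits(x, "community_ensemble")) {
    if (is.null(threshold))
      threshold <- if (x$model$m == 2L) 0.01 else 0.05
    keep <- if (exclude_unconverged) x$converged else rep(TRUE, x$n_init)
    S <- x$s[keep, , drop = FALSE]
    n_excluded <- sum(!keep)
  } else {
    S <- as.matrix(x)
    n_excluded <- 0L
    if (is.null(threshold)) threshold <- if (ncol(S) == 2L) 0.01 else 0.05
  }
  if (nrow(S) == 0L)
    stop("no converged ensemble members to cluster")
  S[S < floor] <- 0
  labels <- .distance_components(S, threshold)
  counts <- as.integer(table(labels))
  reps <- t(vapply(seq_along(counts), function(cl)
    colMeans(S[labels == cl, , drop = FALSE]), numeric(ncol(S))))
  structure(list(representatives = reps, basin_counts = counts,
                 chi = multistability_coefficient(counts),
                 threshold = threshold, n_attractors = length(counts),
                 n_members = nrow(S), n_excluded = n_excluded,
                 labels = labels),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(x$n_attractors, "attractor(s) from", x$n_members,
      "steady states (threshold", x$threshold, ")\n")
  cat("  basin counts:", paste(x$basin_counts, collapse = " "),
      "  chi =", signif(x$chi, 5), "\n")
  if (x$n_excluded > 0)
    cat("  excluded (non-converged):", x$n_excluded, "\n")
  invisible(x)
}

#' Multistability coefficient
#'
#' The effective number of basins of attraction,
#' \deqn{\chi = \exp(-\sum_i x_i \log x_i),}
#' where \eqn{x_i} is the relative size of basin i, estimated as the
#' fraction of converged initializations reaching attractor i. Equals 1
#' for a monostable system, equals the attractor count when basins are
#' equal-sized, and weights small basins down otherwise, which makes it
#' robust to the spurious tiny clusters that finite ensembles produce.
#'
#' @param basin_counts positive counts (or relative sizes) per basin.
#' @return numeric scalar \eqn{\ge 1}.
#' @export
multistability_coefficient <- function(basin_counts) {
  if (length(basin_counts) == 0L) stop("empty basin counts")
  if (any(basin_counts <= 0)) stop("basin counts must be positive")
  x <- basin_counts / sum(basin_counts)
  exp(-sum(x * log(x)))
}

#' Count the stable states of a community
#'
#' Composes [sample_initial_conditions()], [find_steady_state()] and
#' [cluster_attractors()]: the ensemble estimate of the number of
#' alternative stable states and the multistability coefficient.
#'
#' @inheritParams run_ensemble
#' @param threshold clustering threshold; default 0.01 for m = 2,
#'   0.05 otherwise.
#' @param ... passed to [run_ensemble()].
#' @return an `attractor_set` with the ensemble attached as attribute
#'   `"ensemble"`.
#' @examples
#' \donttest{
#' mod <- preset_community("five_species", eta = 0.4)
#' count_stable_states(mod, n_init = 100, seed = 1)
#' }
#' @export
count_stable_states <- function(model, n_init = 500, threshold = NULL,
                                seed = NULL, ...) {
  ens <- run_ensemble(model, n_init = n_init, seed = seed, ...)
  att <- cluster_attractors(ens, threshold = threshold)
  attr(att, "ensemble") <- ens
  att
}

#' Phase diagram over growth rates
#'
#' For every combination of the two species' growth rates, runs an
#' ensemble and marks the cell bistable iff more than one attractor is
#' found.
#'
#' @param model a two-species template `community_model`; growth rates
#'   are replaced cell by cell via [set_growth_rates()].
#' @param mu1_values,mu2_values growth-rate grids (1/hr).
#' @param n_init initializations per cell.
#' @param threshold clustering threshold.
#' @param seed master seed (one substream per cell).
#' @param ... passed to [run_ensemble()].
#' @return object of class `phase_diagram`: list with `grid` (data.frame
#'   `mu1, mu2, n_states, bistable`) and `bistable_area_fraction`.
#' @export
phase_diagram <- function(model, mu1_values, mu2_values, n_init = 200,
                          threshold = 0.01, seed = NULL, ...) {
  stopifnot(model$m == 2L)
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(mu1 = mu1_values, mu2 = mu2_values)
  cell_seeds <- .spawn_seeds(nrow(cells))
  n_states <- integer(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    mk <- set_growth_rates(model, c(cells$mu1[k], cells$mu2[k]))
    att <- count_stable_states(mk, n_init = n_init, threshold = threshold,
                               seed = cell_seeds[k], ...)
    n_states[k] <- att$n_attractors
  }
  grid <- cbind(cells, n_states = n_states, bistable = n_states > 1L)
  structure(list(grid = grid,
                 bistable_area_fraction = mean(grid$bistable),
                 model = model, n_init = n_init, threshold = threshold,
                 seed = seed),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("Phase diagram:", nrow(x$grid), "cells, bistable fraction",
      signif(x$bistable_area_fraction, 4), "\n")
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  mu1 <- sort(unique(x$grid$mu1))
  mu2 <- sort(unique(x$grid$mu2))
  z <- matrix(x$grid$n_states[order(x$grid$mu2, x$grid$mu1)],
              length(mu1), length(mu2))
  image(mu1, mu2, z, col = hcl.colors(max(z), "Blues", rev = TRUE),
        xlab = expression(mu[1] ~ (hr^-1)),
        ylab = expression(mu[2] ~ (hr^-1)), ...)
  invisible(x)
}

#' Fraction of parameterizations that are bistable
#'
#' Draws `n_draws` models from `sampler` and reports the fraction whose
#' ensemble yields at least two attractors. When `eta_values` is given,
#' every drawn model is evaluated at each transfer rate (a paired
#' design: the same growth-rate draws underlie every eta), which is how
#' the effect of HGT on the bistable area is isolated from sampling
#' noise.
#'
#' @param sampler a function of no arguments returning a two-species
#'   `community_model`; it consumes the current RNG stream (see
#'   [growth_rate_sampler()] and [lambda_width_sampler()]).
#' @param n_draws number of parameter draws.
#' @param n_init initializations per ensemble.
#' @param threshold clustering threshold.
#' @param seed master seed.
#' @param eta_values optional transfer rates at which to evaluate every
#'   draw.
#' @param ... passed to [run_ensemble()].
#' @return if `eta_values` is `NULL`, a single fraction with the
#'   per-draw attractor counts as attribute `"n_states"`; otherwise a
#'   data.frame with columns `eta`, `fraction`.
#' @export
bistability_fraction <- function(sampler, n_draws = 500, n_init = 200,
                                 threshold = 0.01, seed = NULL,
                                 eta_values = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  draw_seeds <- .spawn_seeds(n_draws)
  run_seeds <- .spawn_seeds(n_draws)
  models <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    set.seed(draw_seeds[k])
    models[[k]] <- sampler()
  }
  count1 <- function(mod, sd) {
    cluster_attractors(run_ensemble(mod, n_init = n_init, seed = sd, ...),
                       threshold = threshold)$n_attractors
  }
  if (is.null(eta_values)) {
    n_states <- vapply(seq_len(n_draws), function(k)
      count1(models[[k]], run_seeds[k]), integer(1))
    out <- mean(n_states > 1L)
    attr(out, "n_states") <- n_states
    return(out)
  }
  frac <- vapply(eta_values, function(e) {
    mean(vapply(seq_len(n_draws), function(k)
      count1(set_eta(models[[k]], e), run_seeds[k]), integer(1)) > 1L)
  }, numeric(1))
  data.frame(eta = eta_values, fraction = frac)
}

#' Samplers for randomized two-species parameterizations
#'
#' `growth_rate_sampler()` randomizes the two maximum growth rates
#' uniformly in `range`. `lambda_width_sampler()` randomizes the MGE
#' growth effects \eqn{\lambda_i \sim U(-\alpha, \alpha)} (so
#' \eqn{\mu_i = \mu_{i0}(1+\lambda_i)}); `alpha` measures how far the
#' community is from ecological neutrality.
#'
#' @param model template `community_model` (m = 2).
#' @param range growth-rate range (1/hr).
#' @return a function of no arguments returning a model, for
#'   [bistability_fraction()].
#' @export
growth_rate_sampler <- function(model, range = c(0, 1)) {
  force(model); force(range)
  function() set_growth_rates(model, runif(2, range[1], range[2]))
}

#' @rdname growth_rate_sampler
#' @param alpha half-width of the uniform lambda distribution (< 1).
#' @export
lambda_width_sampler <- function(model, alpha) {
  stopifnot(alpha < 1)
  force(model); force(alpha)
  function() {
    lam <- runif(2, -alpha, alpha)
    set_growth_rates(model, model$mu0 * (1 + lam))
  }
}

#' Scan attractor counts over the HGT rate
#'
#' For each transfer rate, repeats the stable-state count over
#' `n_replicates` communities that differ only in their randomized
#' growth rates (drawn once per replicate and shared across the whole
#' eta grid), and summarizes mean and standard deviation of the
#' attractor count and of the multistability coefficient chi. Also
#' reports the onset rate: the smallest nonzero eta whose mean count
#' exceeds the eta = 0 mean (requires 0 in `eta_values`).
#'
#' The scan uses the fixed experimental window: every run is integrated
#' for exactly `horizon` hours and all final states are clustered,
#' converged or not. At small transfer rates, plasmid sweeps are much
#' slower than the window; letting the integrator run to true
#' equilibrium instead would complete those sweeps and shift the
#' apparent onset of multistability to arbitrarily small eta. The
#' residuals are still recorded, so slow transients remain visible.
#'
#' @param model template `community_model` (growth rates are replaced
#'   per replicate).
#' @param eta_values transfer rates to scan (include 0 for the onset).
#' @param n_replicates growth-rate draws.
#' @param n_init initializations per ensemble.
#' @param threshold clustering threshold.
#' @param seed master seed.
#' @param mu_range range of the replicate growth rates (1/hr).
#' @param horizon fixed integration window (hr).
#' @param ... passed to [run_ensemble()].
#' @return object of class `eta_scan`: list with `runs` (data.frame
#'   `eta, replicate, n_states, chi`), `summary` (per-eta mean/sd), and
#'   `onset_eta`.
#' @export
eta_scan <- function(model, eta_values, n_replicates = 10, n_init = 500,
                     threshold = 0.05, seed = NULL,
                     mu_range = c(0.3, 0.7), horizon = 2000, ...) {
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- .spawn_seeds(n_replicates)
  run_seeds <- matrix(.spawn_seeds(n_replicates * length(eta_values)),
                      n_replicates, length(eta_values))
  runs <- expand.grid(replicate = seq_len(n_replicates), eta = eta_values)
  runs$n_states <- NA_integer_
  runs$chi <- NA_real_
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    mu <- runif(model$m, mu_range[1], mu_range[2])
    mod_r <- set_growth_rates(model, mu)
    for (e in seq_along(eta_values)) {
      att <- cluster_attractors(
        run_ensemble(set_eta(mod_r, eta_values[e]), n_init = n_init,
                     seed = run_seeds[r, e], horizon = horizon,
                     max_horizon = horizon, ...),
        threshold = threshold, exclude_unconverged = FALSE)
      k <- which(runs$replicate == r & runs$eta == eta_values[e])
      runs$n_states[k] <- att$n_attractors
      runs$chi[k] <- att$chi
    }
  }
  agg <- function(v) {
    data.frame(eta = eta_values,
               mean = vapply(eta_values, function(e)
                 mean(v[runs$eta == e]), numeric(1)),
               sd = vapply(eta_values, function(e)
                 sd(v[runs$eta == e]), numeric(1)))
  }
  sm <- agg(runs$n_states)
  names(sm) <- c("eta", "mean_n_states", "sd_n_states")
  sc <- agg(runs$chi)
  sm$mean_chi <- sc$mean
  sm$sd_chi <- sc$sd
  onset <- NA_real_
  if (any(eta_values == 0)) {
    base <- sm$mean_n_states[sm$eta == 0]
    cand <- sm$eta[sm$eta > 0 & sm$mean_n_states > base]
    if (length(cand)) onset <- min(cand)
  }
  structure(list(runs = runs[order(runs$eta, runs$replicate), ],
                 summary = sm, onset_eta = onset, model = model,
                 threshold = threshold, seed = seed),
            class = "eta_scan")
}

#' @export
print.eta_scan <- function(x, ...) {
  cat("HGT-rate scan (", nrow(x$summary), "rates x",
      max(x$runs$replicate), "replicates )\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.na(x$onset_eta))
    cat("onset of multistability: eta =", x$onset_eta, "/hr\n")
  invisible(x)
}

#' @export
plot.eta_scan <- function(x, ...) {
  s <- x$summary
  matplot(s$eta, cbind(s$mean_n_states, s$mean_chi), type = "b",
          pch = c(19, 17), lty = 1, log = if (all(s$eta > 0)) "x" else "",
          xlab = expression(eta ~ (hr^-1)),
          ylab = "attractors / chi", ...)
  legend("topleft", c("stable states", expression(chi)),
         pch = c(19, 17), col = 1:2, bty = "n")
  invisible(x)
}
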