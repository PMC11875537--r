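# Grid metacommunities: patches running the same community model,
# coupled by nearest-neighbour dispersal.

#' Construct a metacommunity model
#'
#' A `u x v` grid of patches, each governed by the same community model,
#' exchanging both species and carrier subpopulations with their four
#' nearest neighbours at dispersal rate `omega` (no-flux boundaries:
#' edge patches simply have fewer neighbours). Carriers migrate with
#' their hosts at the same rate.
#'
#' @param patch_model a growth-effect `community_model` shared by all
#'   patches.
#' @param u,v grid dimensions.
#' @param omega dispersal rate between adjacent patches (1/hr). The
#'   default keeps dispersal slow relative to local population dynamics
#'   (rates of order 0.1-0.5/hr), so patches can settle into different
#'   attractors instead of being synchronized by mixing; much faster
#'   dispersal homogenizes the grid.
#' @return object of class `metacommunity_model`.
#' @export
metacommunity_model <- function(patch_model, u = 10, v = 10, omega = 0.001) {
  stopifnot(inherits(patch_model, "community_model"),
            u >= 1, v >= 1, omega >= 0)
  if (.variant_code(patch_model$variant) != 1L)
    stop("metacommunities support the growth-effect model variants")
  structure(list(patch_model = patch_model, u = as.integer(u),
                 v = as.integer(v), omega = as.numeric(omega)),
            class = "metacommunity_model")
}

#' @export
print.metacommunity_model <- function(x, ...) {
  cat("Metacommunity:", x$u, "x", x$v, "patches, omega =", x$omega,
      "/hr\n")
  print(x$patch_model)
  invisible(x)
}

# patch (a, b) lives at linear index a + u * (b - 1)
.patch_index <- function(meta, a, b) a + meta$u * (b - 1L)

#' Sample a random metacommunity state
#'
#' Every patch is initialized independently with the single-community
#' sampler (species abundances U(0, 1), native carriers).
#'
#' @param meta a `metacommunity_model`.
#' @param seed master seed.
#' @param carrier_mode see [sample_initial_conditions()].
#' @return object of class `metacommunity_state`: list of
#'   `community_state`, one per patch in column-major grid order.
#' @export
sample_metacommunity_state <- function(meta, seed = NULL,
                                       carrier_mode = c("native", "random")) {
  carrier_mode <- match.arg(carrier_mode)
  n <- meta$u * meta$v
  patches <- sample_initial_conditions(meta$patch_model, n, seed,
                                       carrier_mode)
  structure(list(patches = patches, u = meta$u, v = meta$v),
            class = "metacommunity_state")
}

#' @export
print.metacommunity_state <- function(x, ...) {
  cat("Metacommunity state:", x$u, "x", x$v, "patches,",
      length(x$patches[[1]]$s), "species each\n")
  invisible(x)
}

#' Long-format view of a metacommunity state
#'
#' @param x a `metacommunity_state`.
#' @param ... unused.
#' @return data.frame with columns `a`, `b`, `entity`, `value`.
#' @export
as.data.frame.metacommunity_state <- function(x, ...) {
  m <- length(x$patches[[1]]$s)
  ent <- c(paste0("s_", seq_len(m)),
           paste0("p_", rep(seq_len(m), m), "_", rep(seq_len(m), each = m)))
  do.call(rbind, lapply(seq_along(x$patches), function(q) {
    a <- ((q - 1L) %% x$u) + 1L
    b <- ((q - 1L) %/% x$u) + 1L
    st <- x$patches[[q]]
    data.frame(a = a, b = b, entity = ent,
               value = c(st$s, as.vector(st$p)))
  }))
}

.meta_pack_parms <- function(meta) {
  as.double(c(3, meta$u, meta$v, meta$omega,
              .pack_parms(meta$patch_model)))
}

.meta_state_to_y <- function(meta, state) {
  unlist(lapply(state$patches, function(st)
    .state_to_y(meta$patch_model, st)), use.names = FALSE)
}

.meta_y_to_state <- function(meta, y, clamp = TRUE) {
  m <- meta$patch_model$m
  nb <- m + m * m
  n <- meta$u * meta$v
  patches <- lapply(seq_len(n), function(q)
    .y_to_state(meta$patch_model, y[(q - 1L) * nb + seq_len(nb)],
                clamp = clamp))
  structure(list(patches = patches, u = meta$u, v = meta$v),
            class = "metacommunity_state")
}

#' Dispersal fluxes on a metacommunity state
#'
#' The dispersal gain of every state component in every patch:
#' \eqn{H(a,b) = \omega \sum_{\mathrm{neighbours}} (y_{nb} - y_{self})},
#' summed over the existing left/right/up/down neighbours (edge patches
#' have fewer). Pairwise antisymmetry makes the total flux of every
#' component vanish over the grid.
#'
#' @param meta a `metacommunity_model`.
#' @param state a `metacommunity_state`.
#' @return matrix with one row per patch (column-major grid order) and
#'   one column per state component (`s_i`, then `p_i_j`).
#' @export
dispersal_flux <- function(meta, state) {
  m <- meta$patch_model$m
  u <- meta$u; v <- meta$v
  Y <- t(vapply(state$patches, function(st)
    .state_to_y(meta$patch_model, st), numeric(m + m * m)))
  H <- matrix(0, nrow(Y), ncol(Y))
  for (b in seq_len(v)) for (a in seq_len(u)) {
    q <- .patch_index(meta, a, b)
    for (nb in list(c(a - 1L, b), c(a + 1L, b), c(a, b - 1L), c(a, b + 1L))) {
      if (nb[1] < 1L || nb[1] > u || nb[2] < 1L || nb[2] > v) next
      qn <- .patch_index(meta, nb[1], nb[2])
      H[q, ] <- H[q, ] + meta$omega * (Y[qn, ] - Y[q, ])
    }
  }
  colnames(H) <- .state_names(meta$patch_model)
  H
}

#' Integrate a metacommunity
#'
#' Integrates the coupled patch-plus-dispersal system. The default
#' solver is the non-stiff Adams method: the coupled system is large
#' (u*v*(m + m^2) equations) and a stiff solver's dense Jacobian would
#' dominate the cost.
#'
#' @param meta a `metacommunity_model`.
#' @param init a `metacommunity_state`.
#' @param t_end integration horizon (hr).
#' @param rtol,atol integration tolerances.
#' @param method deSolve method name.
#' @return a `metacommunity_state` at `t_end`, with attributes
#'   `"residual"` (max |dy/dt| at the final state) and `"t_final"`.
#' @export
integrate_metacommunity <- function(meta, init, t_end = 2000,
                                    rtol = 1e-6, atol = 1e-9,
                                    method = "adams") {
  pv <- .meta_pack_parms(meta)
  .install_parms(pv)
  y0 <- .meta_state_to_y(meta, init)
  out <- deSolve::ode(y = y0, times = c(0, t_end), func = "plv_derivs",
                      dllname = "plasmidLV", initfunc = "plv_initmod",
                      parms = numeric(0), rtol = rtol, atol = atol,
                      method = method)
  istate <- attributes(out)$istate
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("metacommunity integration failed (istate = %d)", istate[1]))
  y <- out[nrow(out), -1L]
  final <- .meta_y_to_state(meta, y)
  attr(final, "residual") <- max(abs(.Call(C_eval_derivs, pv,
                                           as.double(.meta_state_to_y(meta, final)))))
  attr(final, "t_final") <- t_end
  final
}

#' Exponential Shannon diversity (effective species number)
#'
#' \deqn{\exp(-\sum_i q_i \log q_i), \quad q_i = s_i / \sum_j s_j.}
#' Zero-abundance species contribute nothing; m equally abundant species
#' give exactly m.
#'
#' @param abundances non-negative abundance vector with at least one
#'   positive entry.
#' @return effective species number \eqn{\ge 1}.
#' @export
shannon_diversity <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be >= 0")
  tot <- sum(abundances)
  if (tot <= 0) stop("Shannon diversity undefined for an all-zero vector")
  q <- abundances[abundances > 0] / tot
  exp(-sum(q * log(q)))
}

#' Regional and local diversity of a metacommunity
#'
#' Regional diversity is the effective species number of the
#' patch-summed abundances (each species' total across the grid); local
#' diversity is the effective species number within each patch.
#'
#' @param state a `metacommunity_state`.
#' @param floor abundances below this are treated as extinct.
#' @return list with `regional` (scalar) and `local` (one value per
#'   patch).
#' @export
regional_local_diversity <- function(state, floor = 1e-6) {
  S <- t(vapply(state$patches, function(st) st$s,
                numeric(length(state$patches[[1]]$s))))
  S[S < floor] <- 0
  list(regional = shannon_diversity(colSums(S)),
       local = apply(S, 1, function(r)
         if (sum(r) > 0) shannon_diversity(r) else NA_real_))
}
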