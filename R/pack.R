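# Internal: flatten models and states into the numeric layouts consumed by
# the compiled derivatives (see src/derivs.c for the layout contract).

.variant_code <- function(variant) {
  switch(variant,
         classic_lv = 0L,
         selection = 2L,
         1L)  # all growth-effect variants share the general code
}

.eta_array <- function(model) {
  m <- model$m
  if (length(model$eta) == 1L) array(model$eta, c(m, m, m)) else model$eta
}

.pack_parms <- function(model) {
  m <- model$m
  code <- .variant_code(model$variant)
  if (code == 0L) {
    pv <- c(0, m, model$D, growth_rates(model), as.vector(model$gamma))
  } else if (code == 2L) {
    pv <- c(2, m, model$D, growth_rates(model), as.vector(model$gamma),
            model$kappa, as.vector(model$eta))
  } else {
    if (model$variant == "niche") {
      l <- length(model$niche_capacity)
      nmap <- as.numeric(model$niche_map)
      ncap <- model$niche_capacity
    } else {
      l <- 0L
      nmap <- numeric(m)
      ncap <- numeric(0)
    }
    pv <- c(1, m, model$D, model$rho,
            if (model$variant == "interaction_mod") model$delta else 0,
            l, growth_rates(model), as.vector(model$lam),
            as.vector(model$gamma), as.vector(model$kappa),
            as.vector(.eta_array(model)), nmap, ncap)
  }
  as.double(pv)
}

.state_to_y <- function(model, state) {
  code <- .variant_code(model$variant)
  if (code == 0L) as.double(state$s)
  else if (code == 2L) as.double(c(state$s, state$p))
  else {
    p <- state$p
    diag(p) <- state$s
    as.double(c(state$s, p))
  }
}

.y_to_state <- function(model, y, clamp = TRUE) {
  m <- model$m
  y <- unname(y)
  code <- .variant_code(model$variant)
  if (code == 0L) {
    s <- y[seq_len(m)]
    if (clamp) s <- pmax(s, 0)
    return(structure(list(s = s, p = NULL), class = "community_state"))
  }
  s <- y[seq_len(m)]
  if (code == 2L) {
    p <- y[m + seq_len(m)]
    if (clamp) {
      s <- pmax(s, 0)
      p <- pmin(pmax(p, 0), s)
    }
  } else {
    p <- matrix(y[m + seq_len(m * m)], m, m)
    if (clamp) {
      s <- pmax(s, 0)
      p <- pmin(pmax(p, 0), matrix(s, m, m))
      diag(p) <- s
    }
  }
  structure(list(s = s, p = p), class = "community_state")
}

.state_names <- function(model) {
  m <- model$m
  code <- .variant_code(model$variant)
  sn <- paste0("s_", seq_len(m))
  if (code == 0L) return(sn)
  if (code == 2L) return(c(sn, paste0("p_", seq_len(m))))
  idx <- expand.grid(i = seq_len(m), j = seq_len(m))
  c(sn, paste0("p_", idx$i, "_", idx$j))
}

.install_parms <- function(pv) {
  invisible(.Call(C_set_parms, pv))
}
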