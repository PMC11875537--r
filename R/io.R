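# JSON serialization of community models. Matrices are stored as row-major
# flat lists; the eta tensor as a row-major (last index fastest) flat list
# with its dimensions.

.to_rowmajor <- function(x) as.vector(t(x))
.from_rowmajor <- function(x, m) matrix(as.numeric(x), m, m, byrow = TRUE)

#' Write a community model to JSON
#'
#' Serializes the full parameterization (schema version `"1.0"`). All
#' rates are in 1/hr; matrices are row-major lists.
#'
#' @param model a `community_model`.
#' @param path file path; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_community_model <- function(model, path = NULL) {
  m <- model$m
  doc <- list(
    schema_version = "1.0",
    variant = model$variant,
    m = m,
    mu0 = model$mu0,
    lam = .to_rowmajor(model$lam),
    gamma = .to_rowmajor(model$gamma),
    kappa = if (is.matrix(model$kappa)) .to_rowmajor(model$kappa) else model$kappa,
    D = model$D, delta = model$delta, rho = model$rho)
  if (length(model$eta) == 1L) {
    doc$eta <- as.numeric(model$eta)
  } else if (is.matrix(model$eta)) {
    doc$eta <- .to_rowmajor(model$eta)
    doc$eta_dim <- dim(model$eta)
  } else {
    doc$eta <- as.vector(aperm(model$eta, c(3, 2, 1)))
    doc$eta_dim <- dim(model$eta)
  }
  if (!is.null(model$xi)) doc$xi <- model$xi
  if (!is.null(model$niche_map)) doc$niche_map <- model$niche_map
  if (!is.null(model$niche_capacity)) doc$niche_capacity <- model$niche_capacity
  if (model$variant == "selection") doc$donor_index <- model$donor_index
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a community model from JSON
#'
#' @param path file path or JSON string produced by
#'   [write_community_model()].
#' @return a validated `community_model`.
#' @export
read_community_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$schema_version))
    stop("not a community model document: missing 'schema_version'")
  m <- as.integer(doc$m)
  eta <- doc$eta
  if (!is.null(doc$eta_dim)) {
    dims <- as.integer(doc$eta_dim)
    eta <- if (length(dims) == 2L) {
      matrix(as.numeric(eta), dims[1], dims[2], byrow = TRUE)
    } else {
      aperm(array(as.numeric(eta), rev(dims)), c(3, 2, 1))
    }
  }
  kappa <- doc$kappa
  if (doc$variant != "selection" && length(kappa) == m * m)
    kappa <- .from_rowmajor(kappa, m)
  community_model(
    variant = doc$variant, m = m, mu0 = doc$mu0,
    lam = .from_rowmajor(doc$lam, m),
    gamma = .from_rowmajor(doc$gamma, m),
    eta = eta, kappa = kappa, D = doc$D,
    delta = if (!is.null(doc$delta)) doc$delta else 0,
    rho = if (!is.null(doc$rho)) doc$rho else 1,
    xi = doc$xi,
    niche_map = doc$niche_map, niche_capacity = doc$niche_capacity,
    donor_index = if (!is.null(doc$donor_index)) doc$donor_index else 1L)
}
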