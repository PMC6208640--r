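#' Toy stoichiometric model
#'
#' A minimal constraint-based metabolic model: a stoichiometric matrix over
#' internal metabolites, flux bounds, a biomass reaction, and a set of
#' exchange reactions each connecting one internal metabolite to one external
#' metabolite of the shared environment. The standard sign convention is
#' used: a negative exchange flux is uptake, a positive one secretion.
#'
#' @param id model/organism identifier.
#' @param S stoichiometric matrix, internal metabolites (rows, named) x
#'   reactions (columns, named); \code{S[m, r]} is the number of molecules of
#'   \code{m} produced (positive) or consumed (negative) per unit flux of
#'   \code{r}.
#' @param lb,ub named flux bounds per reaction (mmol/gDW/h); \code{Inf}
#'   allowed.
#' @param exchange named character vector mapping exchange reaction names to
#'   external metabolite names (one external metabolite per exchange
#'   reaction).
#' @param biomass name of the biomass (growth) reaction.
#' @return object of class \code{"toy_model"}.
#' @export
toy_model <- function(id, S, lb, ub, exchange, biomass) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("S needs metabolite row names and reaction column names")
  }
  rxns <- colnames(S)
  lb <- lb[rxns]
  ub <- ub[rxns]
  if (anyNA(lb) || anyNA(ub)) stop("bounds missing for some reactions")
  if (any(lb > ub)) stop("inconsistent bounds: lb > ub")
  if (!biomass %in% rxns) stop("biomass reaction not in model")
  if (ub[[biomass]] < 0) stop("biomass reaction must allow non-negative flux")
  if (!all(names(exchange) %in% rxns)) stop("unknown exchange reactions")
  if (anyDuplicated(unname(exchange))) {
    stop("each external metabolite must map to exactly one exchange reaction")
  }
  for (e in names(exchange)) {
    touched <- which(S[, e] != 0)
    if (length(touched) != 1L) {
      stop(sprintf("exchange reaction '%s' must touch exactly one metabolite", e))
    }
  }
  structure(list(id = id, S = S, lb = lb, ub = ub,
                 mets = rownames(S), rxns = rxns,
                 exchange = exchange, biomass = biomass),
            class = "toy_model")
}

#' @export
print.toy_model <- function(x, ...) {
  cat(sprintf("toy_model '%s': %d metabolites, %d reactions (%d exchanges)\n",
              x$id, length(x$mets), length(x$rxns), length(x$exchange)))
  invisible(x)
}

# large finite stand-in for unbounded fluxes in the LP
.FBA_BIG <- 1e3

#' Flux balance analysis on a toy model
#'
#' Maximizes the biomass flux subject to the steady-state constraint
#' \code{S v = 0} and the flux bounds, optionally tightened by per-metabolite
#' uptake caps (the environment's availability limit). Solved as a linear
#' program (a package-internal two-phase simplex with Bland's rule,
#' exact on these small dense problems) after shifting fluxes to non-negative
#' variables. The zero flux vector is always feasible for a valid model, so
#' an infeasible LP signals an internal inconsistency.
#'
#' @param model a [toy_model()].
#' @param uptake_caps named non-negative vector of maximum uptake rates
#'   (mmol/gDW/h) per external metabolite; metabolites not listed keep the
#'   model's own lower bounds.
#' @return list with \code{flux} (named vector) and \code{growth} (biomass
#'   flux, >= 0 up to solver tolerance).
#' @export
fba_solve <- function(model, uptake_caps = NULL) {
  stopifnot(inherits(model, "toy_model"))
  lb <- model$lb
  ub <- model$ub
  if (!is.null(uptake_caps)) {
    for (e in names(model$exchange)) {
      m <- model$exchange[[e]]
      if (m %in% names(uptake_caps)) {
        lb[[e]] <- max(lb[[e]], -uptake_caps[[m]])
      }
    }
  }
  lb <- pmax(lb, -.FBA_BIG)
  ub <- pmin(ub, .FBA_BIG)
  if (any(lb > ub)) stop("inconsistent bounds after applying uptake caps")
  nr <- length(model$rxns)
  cc <- numeric(nr)
  cc[match(model$biomass, model$rxns)] <- 1
  # shift x = v - lb >= 0; Sv = 0 becomes Sx = -S lb; v <= ub becomes x <= ub - lb
  beq <- as.numeric(-model$S %*% lb)
  sol <- tryCatch(
    .simplex_box_eq(cc, unname(model$S), beq, ub - lb),
    error = function(e) {
      stop("LP solver failed on model '", model$id, "': ",
           conditionMessage(e))
    })
  v <- sol$x + lb
  names(v) <- model$rxns
  list(flux = v, growth = max(unname(v[model$biomass]), 0))
}

#' Write a toy model to JSON
#'
#' Stores metabolites, reactions, the stoichiometric matrix as (metabolite,
#' reaction, coefficient) triplets, bounds, the exchange map and the biomass
#' reaction.
#'
#' @param model a [toy_model()].
#' @param path output path.
#' @export
toy_model_to_json <- function(model, path) {
  nz <- which(model$S != 0, arr.ind = TRUE)
  obj <- list(format = "cocultr-toymodel", version = 1L, id = model$id,
              metabolites = model$mets, reactions = model$rxns,
              stoichiometry = list(metabolite = model$mets[nz[, 1L]],
                                   reaction = model$rxns[nz[, 2L]],
                                   coefficient = model$S[nz]),
              lb = as.list(model$lb), ub = as.list(model$ub),
              exchange = as.list(model$exchange), biomass = model$biomass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a toy model from JSON
#' @param path a file written by [toy_model_to_json()].
#' @return a [toy_model()].
#' @export
toy_model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cocultr-toymodel")) stop("not a cocultr toy model file")
  mets <- as.character(obj$metabolites)
  rxns <- as.character(obj$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  tri <- obj$stoichiometry
  S[cbind(match(tri$metabolite, mets), match(tri$reaction, rxns))] <-
    as.numeric(tri$coefficient)
  # JSON carries Inf as the string "Inf"; restore numeric bounds
  num_vec <- function(x) {
    u <- unlist(x)
    stats::setNames(as.numeric(u), names(u))
  }
  toy_model(id = obj$id, S = S,
            lb = num_vec(obj$lb), ub = num_vec(obj$ub),
            exchange = unlist(obj$exchange), biomass = obj$biomass)
}
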