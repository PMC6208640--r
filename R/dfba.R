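#' Batch coculture environment
#'
#' Time-stepping parameters and initial conditions for a well-mixed batch
#' dynamic-FBA simulation: external metabolite amounts (mmol), forward-Euler
#' timestep (h), step budget, a global maximum uptake rate and initial
#' biomass (gDW) per organism.
#'
#' @param amounts named non-negative vector of initial external metabolite
#'   amounts (mmol).
#' @param dt timestep in hours, > 0.
#' @param n_steps maximum number of steps.
#' @param vmax maximum uptake rate (mmol/gDW/h); scalar or named per
#'   metabolite.
#' @param biomass0 initial biomass per organism (gDW); scalar or named per
#'   organism id.
#' @return object of class \code{"batch_environment"}.
#' @export
batch_environment <- function(amounts, dt = 0.1, n_steps = 240L, vmax = 10,
                              biomass0 = 0.01) {
  if (any(amounts < 0)) stop("metabolite amounts must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (any(vmax < 0) || any(biomass0 <= 0)) {
    stop("vmax must be >= 0 and initial biomass > 0")
  }
  structure(list(amounts = amounts, dt = dt, n_steps = as.integer(n_steps),
                 vmax = vmax, biomass0 = biomass0),
            class = "batch_environment")
}

#' Batch dynamic-FBA simulation of one culture
#'
#' Forward-Euler batch stepper. At every step each organism's uptake of each
#' external metabolite is capped at
#' \code{min(Vmax, amount / (demanding_biomass * dt))}, where demanding
#' biomass is the total biomass of organisms whose bounds permit uptake of
#' that metabolite (a scarce pool is shared in proportion to biomass); each
#' organism then solves FBA under those caps, biomass updates as
#' \code{B <- B * (1 + mu * dt)} and metabolite pools as
#' \code{m <- m + sum(v_exch * B) * dt}. The run terminates after
#' \code{n_steps} or as soon as every growth rate falls below \code{mu_tol}.
#' The stepper is fully deterministic. Competition and cross-feeding are
#' emergent: nothing in the update rule encodes interactions explicitly.
#'
#' @param models list of [toy_model()]s sharing the external metabolite
#'   universe (typically 1 for monoculture, 2 for coculture).
#' @param env a [batch_environment()].
#' @param mu_tol growth-rate threshold below which an organism counts as
#'   non-growing.
#' @return object of class \code{"sim_outcome"}: \code{biomass} (steps+1 x
#'   organisms trajectory), \code{final} (named final biomass),
#'   \code{amounts} (steps+1 x metabolites trajectory), \code{flux}
#'   (steps x organisms x metabolites exchange-flux array, per-gDW rates),
#'   \code{dt}, \code{steps_run}.
#' @export
dfba_run <- function(models, env, mu_tol = 1e-9) {
  stopifnot(inherits(env, "batch_environment"))
  if (inherits(models, "toy_model")) models <- list(models)
  if (!length(models)) stop("at least one model required")
  orgs <- vapply(models, function(m) m$id, character(1))
  if (anyDuplicated(orgs)) stop("duplicate organism ids")
  mets <- sort(unique(c(names(env$amounts),
                        unlist(lapply(models, function(m) unname(m$exchange))))))
  amounts <- stats::setNames(numeric(length(mets)), mets)
  amounts[names(env$amounts)] <- env$amounts
  vmax <- if (length(env$vmax) == 1L) {
    stats::setNames(rep(env$vmax, length(mets)), mets)
  } else {
    v <- stats::setNames(rep(Inf, length(mets)), mets)
    v[names(env$vmax)] <- env$vmax
    v
  }
  B <- if (length(env$biomass0) == 1L) {
    stats::setNames(rep(env$biomass0, length(orgs)), orgs)
  } else {
    env$biomass0[orgs]
  }
  if (anyNA(B)) stop("initial biomass missing for some organisms")

  # per-organism uptake capability (effective lower bound < 0) per metabolite
  can_uptake <- matrix(FALSE, length(orgs), length(mets),
                       dimnames = list(orgs, mets))
  for (k in seq_along(models)) {
    m <- models[[k]]
    for (e in names(m$exchange)) {
      if (m$lb[[e]] < 0) can_uptake[k, m$exchange[[e]]] <- TRUE
    }
  }

  dt <- env$dt
  n_steps <- env$n_steps
  biomass_traj <- matrix(NA_real_, n_steps + 1L, length(orgs),
                         dimnames = list(NULL, orgs))
  amount_traj <- matrix(NA_real_, n_steps + 1L, length(mets),
                        dimnames = list(NULL, mets))
  flux <- array(0, dim = c(n_steps, length(orgs), length(mets)),
                dimnames = list(NULL, orgs, mets))
  biomass_traj[1L, ] <- B
  amount_traj[1L, ] <- amounts
  cache <- new.env(parent = emptyenv())

  steps_run <- 0L
  for (s in seq_len(n_steps)) {
    demand <- as.numeric(B %*% can_uptake) # demanding biomass per metabolite
    mu <- numeric(length(orgs))
    dm <- stats::setNames(numeric(length(mets)), mets)
    for (k in seq_along(models)) {
      m <- models[[k]]
      up_mets <- mets[can_uptake[k, ]]
      caps <- stats::setNames(numeric(length(up_mets)), up_mets)
      for (mt in up_mets) {
        caps[[mt]] <- min(vmax[[mt]], amounts[[mt]] / (demand[match(mt, mets)] * dt))
      }
      key <- paste(m$id, paste(signif(caps, 12), collapse = ","), sep = "|")
      sol <- cache[[key]]
      if (is.null(sol)) {
        sol <- fba_solve(m, uptake_caps = caps)
        cache[[key]] <- sol
      }
      mu[k] <- sol$growth
      ex <- sol$flux[names(m$exchange)]
      tgt <- unname(m$exchange)
      flux[s, k, tgt] <- ex
      dm[tgt] <- dm[tgt] + ex * B[k] * dt
    }
    amounts <- amounts + dm
    neg <- amounts < 0
    if (any(amounts < -1e-9)) {
      stop("internal consistency error: metabolite amount went negative beyond tolerance")
    }
    amounts[neg] <- 0
    B <- B * (1 + mu * dt)
    steps_run <- s
    biomass_traj[s + 1L, ] <- B
    amount_traj[s + 1L, ] <- amounts
    if (all(mu < mu_tol)) break
  }
  keep <- seq_len(steps_run + 1L)
  structure(list(biomass = biomass_traj[keep, , drop = FALSE],
                 final = B,
                 amounts = amount_traj[keep, , drop = FALSE],
                 flux = flux[seq_len(steps_run), , , drop = FALSE],
                 dt = dt, steps_run = steps_run,
                 organisms = orgs, mets = mets),
            class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf("sim_outcome: %d organism(s), %d steps; final biomass: %s\n",
              length(x$organisms), x$steps_run,
              paste(sprintf("%s=%.4g", x$organisms, x$final), collapse = ", ")))
  invisible(x)
}

# metabolites actually taken up / secreted by each organism during a run:
# a flux counts if it moves more than `mass_tol` mmol in some single step
.active_exchanges <- function(outcome, mass_tol = 1e-9) {
  n_org <- length(outcome$organisms)
  up <- matrix(FALSE, n_org, length(outcome$mets),
               dimnames = list(outcome$organisms, outcome$mets))
  sec <- up
  steps <- outcome$steps_run
  if (steps == 0L) return(list(uptake = up, secretion = sec))
  for (k in seq_len(n_org)) {
    moved <- outcome$flux[, k, , drop = FALSE] *
      outcome$biomass[seq_len(steps), k] * outcome$dt
    dim(moved) <- c(steps, length(outcome$mets))
    up[k, ] <- apply(moved, 2L, function(z) any(z < -mass_tol))
    sec[k, ] <- apply(moved, 2L, function(z) any(z > mass_tol))
  }
  list(uptake = up, secretion = sec)
}

#' Simulate all monocultures and pairwise cocultures of a community
#'
#' Runs every organism alone and every unordered pair together, all from the
#' same initial environment, and assembles (i) the relative-yield interaction
#' table (diagonal = monoculture final biomass B_ii) and (ii) the
#' ground-truth mechanism table derived from the coculture exchange-flux time
#' series: a metabolite is \emph{contended} by a pair when both organisms
#' take it up at some step, and \emph{facilitative} for responder i with
#' partner j when j secretes it and i takes it up at some step.
#'
#' @param models list of [toy_model()]s.
#' @param env a [batch_environment()] used identically for every run.
#' @param require_mono_growth if TRUE (default), organisms whose monoculture
#'   shows no growth get NA responses (their relative yield is considered
#'   unreliable); their pairs are excluded from datasets.
#' @param mass_tol minimum mmol moved in a single step for a flux to count
#'   towards the mechanism truth sets.
#' @return list with \code{table} (an [interaction_table()], relative_yield
#'   mode), \code{mechanisms} (data.frame responder/partner/type/metabolite),
#'   \code{mono_final} (named B_ii), \code{env}.
#' @export
pairwise_campaign <- function(models, env, require_mono_growth = TRUE,
                              mass_tol = 1e-9) {
  n <- length(models)
  if (n < 2L) stop("need at least 2 organisms")
  orgs <- vapply(models, function(m) m$id, character(1))
  b0 <- if (length(env$biomass0) == 1L) {
    stats::setNames(rep(env$biomass0, n), orgs)
  } else {
    env$biomass0[orgs]
  }
  mono_final <- stats::setNames(numeric(n), orgs)
  for (k in seq_len(n)) {
    mono_final[k] <- dfba_run(models[k], env)$final
  }
  grew <- mono_final - b0 > 1e-9

  X <- matrix(NA_real_, n, n, dimnames = list(orgs, orgs))
  diag(X) <- mono_final
  mech <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      out <- dfba_run(models[c(i, j)], env)
      ok_i <- !require_mono_growth || grew[i]
      ok_j <- !require_mono_growth || grew[j]
      if (ok_i) X[i, j] <- relative_yield(out$final[[orgs[i]]], mono_final[[i]])
      if (ok_j) X[j, i] <- relative_yield(out$final[[orgs[j]]], mono_final[[j]])
      act <- .active_exchanges(out, mass_tol = mass_tol)
      contended <- out$mets[act$uptake[1L, ] & act$uptake[2L, ]]
      fac_ij <- out$mets[act$secretion[2L, ] & act$uptake[1L, ]] # j feeds i
      fac_ji <- out$mets[act$secretion[1L, ] & act$uptake[2L, ]]
      if (length(contended)) {
        mech[[length(mech) + 1L]] <- data.frame(
          responder = rep(c(orgs[i], orgs[j]), each = length(contended)),
          partner = rep(c(orgs[j], orgs[i]), each = length(contended)),
          type = "competition", metabolite = rep(contended, 2L),
          stringsAsFactors = FALSE)
      }
      if (length(fac_ij)) {
        mech[[length(mech) + 1L]] <- data.frame(
          responder = orgs[i], partner = orgs[j], type = "facilitation",
          metabolite = fac_ij, stringsAsFactors = FALSE)
      }
      if (length(fac_ji)) {
        mech[[length(mech) + 1L]] <- data.frame(
          responder = orgs[j], partner = orgs[i], type = "facilitation",
          metabolite = fac_ji, stringsAsFactors = FALSE)
      }
    }
  }
  mechanisms <- if (length(mech)) {
    do.call(rbind, mech)
  } else {
    data.frame(responder = character(), partner = character(),
               type = character(), metabolite = character(),
               stringsAsFactors = FALSE)
  }
  list(table = interaction_table(X, response_mode = "relative_yield"),
       mechanisms = mechanisms, mono_final = mono_final, env = env)
}
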