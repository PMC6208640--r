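#' Build a linear-pathway toy model
#'
#' Constructs a small organism: each usable substrate is taken up through an
#' exchange reaction, converted to a biomass precursor at a fixed yield
#' (optionally emitting a by-product that is secreted), and the precursor is
#' drained by the biomass reaction. Decoy exchanges give the organism the
#' genomic \emph{capability} to take up or secrete a metabolite without any
#' internal reaction that could carry flux: the trait bit is 1 but the flux
#' is always 0, mirroring annotated-but-unused transporters.
#'
#' @param id organism id.
#' @param substrates named numeric vector: usable external metabolites and
#'   their biomass yields (gDW per mmol).
#' @param vmax uptake bound magnitude for usable substrates (mmol/gDW/h).
#' @param byproducts optional named numeric vector: by-product metabolite ->
#'   mmol secreted per mmol of the \emph{first} substrate consumed.
#' @param decoy_uptake,decoy_secretion external metabolites the organism can
#'   formally exchange but never does.
#' @return a [toy_model()].
#' @export
toy_pathway_model <- function(id, substrates, vmax = 10, byproducts = NULL,
                              decoy_uptake = character(),
                              decoy_secretion = character()) {
  if (!length(substrates) || is.null(names(substrates))) {
    stop("substrates must be a named yield vector")
  }
  subs <- names(substrates)
  bp <- names(byproducts)
  decoy_uptake <- setdiff(decoy_uptake, c(subs, bp))
  decoy_secretion <- setdiff(decoy_secretion, c(subs, bp, decoy_uptake))
  mets <- c(subs, bp, "precursor", decoy_uptake, decoy_secretion)
  rxns <- c(paste0("EX_", c(subs, bp, decoy_uptake, decoy_secretion)),
            paste0("CNV_", subs), "BIOMASS")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- stats::setNames(rep(0, length(rxns)), rxns)
  ub <- stats::setNames(rep(Inf, length(rxns)), rxns)
  exchange <- character()
  for (m in subs) {
    S[m, paste0("EX_", m)] <- -1
    lb[paste0("EX_", m)] <- -vmax
    ub[paste0("EX_", m)] <- 0
    S[m, paste0("CNV_", m)] <- -1
    S["precursor", paste0("CNV_", m)] <- substrates[[m]]
    exchange[paste0("EX_", m)] <- m
  }
  if (length(bp)) {
    # by-products accompany consumption of the first substrate
    for (p in bp) {
      S[p, paste0("CNV_", subs[1L])] <- byproducts[[p]]
      S[p, paste0("EX_", p)] <- -1
      ub[paste0("EX_", p)] <- Inf
      exchange[paste0("EX_", p)] <- p
    }
  }
  for (d in decoy_uptake) {
    S[d, paste0("EX_", d)] <- -1
    lb[paste0("EX_", d)] <- -vmax
    ub[paste0("EX_", d)] <- 0
    exchange[paste0("EX_", d)] <- d
  }
  for (d in decoy_secretion) {
    S[d, paste0("EX_", d)] <- -1
    exchange[paste0("EX_", d)] <- d
  }
  S["precursor", "BIOMASS"] <- -1
  toy_model(id = id, S = S, lb = lb, ub = ub, exchange = exchange,
            biomass = "BIOMASS")
}

#' Presence/absence exchange traits of toy models
#'
#' One binary feature per (external metabolite, direction): \code{upt_m} is 1
#' when the model's exchange bounds permit uptake of \code{m} (lower bound
#' < 0), \code{sec_m} when they permit secretion (upper bound > 0). Traits
#' describe capabilities only; they never depend on simulated fluxes.
#'
#' @param models list of [toy_model()]s.
#' @param metabolites external metabolite universe (default: sorted union of
#'   all exchange targets).
#' @return a [trait_matrix()] with \code{2 * length(metabolites)} features.
#' @export
traits_from_models <- function(models, metabolites = NULL) {
  if (inherits(models, "toy_model")) models <- list(models)
  if (is.null(metabolites)) {
    metabolites <- sort(unique(unlist(lapply(models, function(m)
      unname(m$exchange)))))
  }
  orgs <- vapply(models, function(m) m$id, character(1))
  vals <- matrix(0L, length(models), 2L * length(metabolites),
                 dimnames = list(orgs, c(paste0("upt_", metabolites),
                                         paste0("sec_", metabolites))))
  for (k in seq_along(models)) {
    m <- models[[k]]
    for (e in names(m$exchange)) {
      tgt <- m$exchange[[e]]
      if (!tgt %in% metabolites) next
      if (m$lb[[e]] < 0) vals[k, paste0("upt_", tgt)] <- 1L
      if (m$ub[[e]] > 0) vals[k, paste0("sec_", tgt)] <- 1L
    }
  }
  trait_matrix(vals)
}

#' Generate a toy community with planted interaction mechanisms
#'
#' Builds a reproducible set of linear-pathway toy models plus a batch
#' environment, such that the simulated pairwise campaign produces known
#' interactions:
#' \describe{
#'   \item{single_competition}{each organism grows on exactly one substrate;
#'     organisms are grouped so that members of a group share a substrate and
#'     therefore compete over exactly one metabolite, while pairs from
#'     different groups do not interact.}
#'   \item{mixed}{each organism carries a broad uptake repertoire (several
#'     capabilities for supplied substrates, several more for metabolites the
#'     medium does not supply) plus decoy secretion capabilities; pairs
#'     compete over however many supplied substrates their diets share, so
#'     outcomes range from neutral to strongly negative while most trait bits
#'     are irrelevant to the medium — the regime in which a trained
#'     classifier should beat naive trait-overlap baselines.}
#'   \item{cross_feeding}{producer/consumer pairs: the producer secretes a
#'     by-product the consumer can grow on; consumers also get a small
#'     private substrate so they grow (weakly) in monoculture.}
#' }
#'
#' @param n_organisms number of organisms (>= 2).
#' @param n_metabolites size of the external metabolite universe; must be at
#'   least the number of substrate groups.
#' @param scenario one of \code{"single_competition"}, \code{"mixed"},
#'   \code{"cross_feeding"}.
#' @param seed integer seed; the community and environment are reproducible
#'   from it.
#' @param group_size organisms per shared substrate
#'   (\code{single_competition}).
#' @param n_supplied size of the supplied-substrate pool in the medium
#'   (\code{mixed}).
#' @param diet_supplied,diet_unsupplied per-organism number of uptake
#'   capabilities drawn from the supplied pool and from the rest of the
#'   universe (\code{mixed}); only the supplied ones can carry flux, so the
#'   unsupplied ones dilute naive trait-overlap measures exactly like
#'   medium-irrelevant transporters in a real genome annotation.
#' @param n_decoy_secretion secretion capabilities per organism that never
#'   carry flux (\code{mixed}).
#' @param supply initial amount (mmol) of every growth substrate.
#' @param vmax maximum uptake rate (mmol/gDW/h).
#' @param dt,n_steps,biomass0 see [batch_environment()].
#' @param yield_range biomass yields are drawn uniformly from this range
#'   (gDW per mmol).
#' @return list with \code{models}, \code{env}, \code{metabolites} and
#'   \code{design} (data.frame of organism, substrate, role notes).
#' @export
generate_community <- function(n_organisms = 20L, n_metabolites = 50L,
                               scenario = c("single_competition", "mixed",
                                            "cross_feeding"),
                               seed = 1L, group_size = 4L,
                               n_supplied = 10L, diet_supplied = 2L,
                               diet_unsupplied = 8L, n_decoy_secretion = 3L,
                               supply = 10, vmax = 10, dt = 0.1,
                               n_steps = 240L, biomass0 = 0.01,
                               yield_range = c(0.4, 0.8)) {
  scenario <- match.arg(scenario)
  if (n_organisms < 2L) stop("need at least 2 organisms")
  set.seed(seed)
  mets <- sprintf("M%03d", seq_len(n_metabolites))
  orgs <- sprintf("org%02d", seq_len(n_organisms))
  models <- vector("list", n_organisms)
  design <- data.frame(organism = orgs, substrate = NA_character_,
                       role = "competitor", partner = NA_character_,
                       byproduct = NA_character_, stringsAsFactors = FALSE)
  amounts <- stats::setNames(numeric(n_metabolites), mets)

  if (scenario == "single_competition") {
    n_groups <- ceiling(n_organisms / group_size)
    if (n_groups > n_metabolites) {
      stop("n_metabolites must be at least the number of substrate groups")
    }
    substrates <- sample(mets, n_groups)
    assign_group <- (sample(n_organisms) - 1L) %% n_groups + 1L
    yields <- stats::runif(n_organisms, yield_range[1L], yield_range[2L])
    for (k in seq_len(n_organisms)) {
      sub <- substrates[assign_group[k]]
      design$substrate[k] <- sub
      models[[k]] <- toy_pathway_model(orgs[k],
                                       substrates = stats::setNames(yields[k], sub),
                                       vmax = vmax)
    }
    amounts[substrates] <- supply
  } else if (scenario == "mixed") {
    if (n_supplied > n_metabolites) stop("n_supplied exceeds the universe")
    if (diet_supplied < 1L || diet_supplied > n_supplied) {
      stop("diet_supplied must be between 1 and n_supplied")
    }
    if (diet_unsupplied > n_metabolites - n_supplied) {
      stop("diet_unsupplied exceeds the unsupplied universe")
    }
    supplied <- sample(mets, n_supplied)
    unsupplied <- setdiff(mets, supplied)
    for (k in seq_len(n_organisms)) {
      diet <- c(sample(supplied, diet_supplied),
                sample(unsupplied, diet_unsupplied))
      yields <- stats::runif(length(diet), yield_range[1L], yield_range[2L])
      dec_s <- sample(setdiff(mets, diet),
                      min(n_decoy_secretion, n_metabolites - length(diet)))
      design$substrate[k] <- paste(sort(intersect(diet, supplied)),
                                   collapse = ",")
      models[[k]] <- toy_pathway_model(orgs[k],
                                       substrates = stats::setNames(yields, diet),
                                       vmax = vmax, decoy_secretion = dec_s)
    }
    amounts[supplied] <- supply
  } else { # cross_feeding
    n_pairs <- floor(n_organisms / 2L)
    if (2L * n_pairs + n_pairs > n_metabolites) {
      stop("not enough metabolites for producer substrates, private substrates and by-products")
    }
    picked <- sample(mets, 3L * n_pairs)
    prod_subs <- picked[seq_len(n_pairs)]
    priv_subs <- picked[n_pairs + seq_len(n_pairs)]
    byprods <- picked[2L * n_pairs + seq_len(n_pairs)]
    for (q in seq_len(n_pairs)) {
      kp <- 2L * q - 1L
      kc <- 2L * q
      yp <- stats::runif(1, yield_range[1L], yield_range[2L])
      models[[kp]] <- toy_pathway_model(
        orgs[kp], substrates = stats::setNames(yp, prod_subs[q]), vmax = vmax,
        byproducts = stats::setNames(0.5, byprods[q]))
      design[kp, c("substrate", "role", "partner", "byproduct")] <-
        list(prod_subs[q], "producer", orgs[kc], byprods[q])
      yc <- stats::runif(2, yield_range[1L], yield_range[2L])
      models[[kc]] <- toy_pathway_model(
        orgs[kc],
        substrates = stats::setNames(yc, c(priv_subs[q], byprods[q])),
        vmax = vmax)
      design[kc, c("substrate", "role", "partner", "byproduct")] <-
        list(priv_subs[q], "consumer", orgs[kp], byprods[q])
      amounts[prod_subs[q]] <- supply
      amounts[priv_subs[q]] <- supply * 0.2 # weak private growth in monoculture
    }
    if (n_organisms %% 2L == 1L) {
      k <- n_organisms
      sub <- setdiff(mets, picked)[1L]
      models[[k]] <- toy_pathway_model(
        orgs[k],
        substrates = stats::setNames(stats::runif(1, yield_range[1L],
                                                  yield_range[2L]), sub),
        vmax = vmax)
      design$substrate[k] <- sub
      amounts[sub] <- supply
    }
  }
  env <- batch_environment(amounts, dt = dt, n_steps = n_steps, vmax = vmax,
                           biomass0 = biomass0)
  list(models = models, env = env, metabolites = mets, design = design,
       scenario = scenario, seed = seed)
}

#' Generate an auxotroph-style community with rule-based responses
#'
#' Emulates the structure of a coculture study of single-auxotrophy strains:
#' each strain lacks exactly one biosynthetic capability (its auxotrophy) and
#' its trait vector is all ones except at that position. The synthetic fold
#' change of responder i with partner j is drawn log-normally around a high
#' mean when the partner possesses the capability i is missing (it can
#' cross-feed the needed compound) and around a low mean otherwise.
#' Auxotrophies are drawn from a pool smaller than the number of strains so
#' that same-auxotrophy pairs — which cannot rescue each other — occur and
#' both response classes are present. The ground-truth mechanism of pair
#' (i, j) is the responder's missing capability (and the partner's matching
#' one).
#'
#' @param n_strains number of strains (>= 3).
#' @param amino_acids capability universe; default 14 amino acids.
#' @param n_auxotrophies size of the pool auxotrophies are drawn from;
#'   must be < n_strains to guarantee shared auxotrophies.
#' @param strong_mean,weak_mean fold-change geometric means of the two
#'   response regimes (a cutoff of 2 separates them when noise is moderate).
#' @param noise_sd standard deviation of the log fold-change noise.
#' @param seed integer seed.
#' @return list with \code{traits} ([trait_matrix()]), \code{table}
#'   (fold-change [interaction_table()]), \code{truths} (per-sample list of
#'   true capability candidates), \code{auxotrophy} (named vector),
#'   \code{candidate_map} (for [net_contributions()]).
#' @export
generate_auxotroph_community <- function(n_strains = 14L,
                                         amino_acids = c("arg", "cys", "gly",
                                                         "his", "ile", "leu",
                                                         "lys", "met", "phe",
                                                         "pro", "ser", "thr",
                                                         "trp", "tyr"),
                                         n_auxotrophies = min(10L, length(amino_acids)),
                                         strong_mean = 4, weak_mean = 1,
                                         noise_sd = 0.25, seed = 1L) {
  if (n_strains < 3L) stop("need at least 3 strains")
  if (n_auxotrophies < 2L || n_auxotrophies > length(amino_acids)) {
    stop("n_auxotrophies must be between 2 and the capability universe size")
  }
  set.seed(seed)
  pool <- amino_acids[seq_len(n_auxotrophies)]
  aux <- sample(pool, n_strains, replace = TRUE)
  if (length(unique(aux)) == 1L) { # degenerate draw: force both classes
    aux[n_strains] <- setdiff(pool, aux[1L])[1L]
  }
  strains <- sprintf("del_%s_%02d", aux, seq_len(n_strains))
  vals <- matrix(1L, n_strains, length(amino_acids),
                 dimnames = list(strains, amino_acids))
  vals[cbind(seq_len(n_strains), match(aux, amino_acids))] <- 0L
  traits <- trait_matrix(vals)

  X <- matrix(NA_real_, n_strains, n_strains, dimnames = list(strains, strains))
  truths <- list()
  for (i in seq_len(n_strains)) {
    for (j in seq_len(n_strains)) {
      if (i == j) next
      complement <- aux[i] != aux[j]
      mu <- if (complement) strong_mean else weak_mean
      X[i, j] <- exp(log(mu) + stats::rnorm(1, 0, noise_sd))
      truths[[paste(strains[i], strains[j], sep = ":")]] <- aux[i]
    }
  }
  cmap <- data.frame(candidate = amino_acids,
                     responder_feature = amino_acids,
                     partner_feature = paste0(amino_acids, "_p"),
                     stringsAsFactors = FALSE)
  list(traits = traits,
       table = interaction_table(X, response_mode = "fold_change"),
       truths = truths,
       auxotrophy = stats::setNames(aux, strains),
       candidate_map = cmap)
}
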