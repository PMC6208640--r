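#' Per-feature local increments along one tree's decision path
#'
#' Walks the sample's root-to-leaf path. At each internal node splitting on
#' feature f, the change in the positive-class fraction between the child the
#' sample is routed to and the node itself is added to f's total (a feature
#' splitting several times on one path accumulates). The increments telescope:
#' their sum equals the leaf fraction minus the root fraction.
#'
#' @param tree a \code{decision_tree} with class counts at every node.
#' @param composite binary composite vector (length = number of features the
#'   tree may split on).
#' @return numeric vector of per-feature increments, with attributes
#'   \code{y_root} and \code{y_leaf} (positive-class fractions at the path's
#'   ends).
#' @export
path_increments <- function(tree, composite) {
  if (!inherits(tree, "decision_tree")) stop("not a decision_tree")
  tot <- tree$n_neg + tree$n_pos
  y <- ifelse(tot > 0, tree$n_pos / tot, NA_real_)
  phi <- numeric(length(composite))
  node <- 1L
  if (is.na(y[node])) stop("malformed tree: empty class counts at root")
  repeat {
    f <- tree$split[node]
    if (is.na(f)) break
    if (f > length(composite)) stop("composite vector shorter than tree's feature space")
    child <- if (composite[f] == 1L) tree$right[node] else tree$left[node]
    if (is.na(child) || is.na(y[child])) {
      stop("malformed tree: missing child or class counts at node ", node)
    }
    phi[f] <- phi[f] + (y[child] - y[node])
    node <- child
  }
  attr(phi, "y_root") <- y[1L]
  attr(phi, "y_leaf") <- y[node]
  phi
}

#' Per-sample feature contributions of a forest prediction
#'
#' Decomposes a forest's predicted positive-class fraction for one sample
#' into a baseline (the mean root-node positive fraction over the counted
#' trees) plus one additive contribution per feature: the mean over counted
#' trees of the path increments from [path_increments()]. For a training
#' sample, contributions are computed on the trees for which the sample is
#' out-of-bag (\code{mode = "oob"}); for new samples all trees are used.
#' With the default \code{denominator = "counted"},
#' \code{baseline + sum(phi)} equals the mean leaf positive fraction over the
#' counted trees exactly; \code{denominator = "total"} divides the sums by
#' the full tree count instead (a sensitivity variant in which the identity
#' does not hold).
#'
#' @param model a [train_forest()] model.
#' @param composite binary composite vector (length 2n).
#' @param sample_id training-set row index; required in \code{"oob"} mode.
#' @param mode \code{"oob"} or \code{"all_trees"}.
#' @param denominator \code{"counted"} (default) or \code{"total"}.
#' @return object of class \code{"contribution_vector"}: named \code{phi}
#'   (length 2n), \code{baseline}, \code{leaf_fraction}, \code{counted_trees},
#'   \code{mode}, \code{denominator}, the input vector \code{x} and the
#'   model's class names.
#' @export
feature_contributions <- function(model, composite, sample_id = NULL,
                                  mode = c("oob", "all_trees"),
                                  denominator = c("counted", "total")) {
  stopifnot(inherits(model, "pair_forest"))
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  composite <- as.integer(composite)
  if (length(composite) != length(model$feature_names)) {
    stop("composite vector length does not match the model's feature space")
  }
  if (mode == "oob") {
    if (is.null(sample_id)) stop("oob mode requires the training sample id")
    if (sample_id < 1L || sample_id > model$n_train) stop("sample_id out of range")
    counted <- which(model$inbag[sample_id, ] == 0L)
    if (!length(counted)) {
      stop("sample is in-bag for every tree: no out-of-bag trees to count")
    }
  } else {
    counted <- seq_len(model$ntree)
  }
  phi_sum <- numeric(length(composite))
  root_sum <- 0
  leaf_sum <- 0
  for (t in counted) {
    inc <- path_increments(model$trees[[t]], composite)
    phi_sum <- phi_sum + as.vector(inc)
    root_sum <- root_sum + attr(inc, "y_root")
    leaf_sum <- leaf_sum + attr(inc, "y_leaf")
  }
  denom <- if (denominator == "counted") length(counted) else model$ntree
  phi <- phi_sum / denom
  names(phi) <- model$feature_names
  structure(list(phi = phi,
                 baseline = root_sum / denom,
                 leaf_fraction = leaf_sum / denom,
                 counted_trees = length(counted),
                 mode = mode, denominator = denominator,
                 sample_id = sample_id, x = composite,
                 class_names = model$class_names),
            class = "contribution_vector")
}

#' @export
print.contribution_vector <- function(x, ...) {
  cat(sprintf(
    "contribution_vector (%s, %d trees): baseline %.4f + sum(phi) %.4f = %.4f leaf fraction\n",
    x$mode, x$counted_trees, x$baseline, sum(x$phi), x$baseline + sum(x$phi)))
  top <- sort(abs(x$phi), decreasing = TRUE)
  print(utils::head(x$phi[names(top)], 5L))
  invisible(x)
}

#' Build a candidate map for competition mechanisms
#'
#' Each candidate metabolite maps to the responder-half and partner-half
#' uptake features, the pair whose summed contributions score competition for
#' that metabolite.
#'
#' @param metabolites candidate metabolite names.
#' @param uptake_prefix prefix of uptake feature names (default matches
#'   [traits_from_models()]).
#' @return data.frame with columns \code{candidate},
#'   \code{responder_feature}, \code{partner_feature}.
#' @export
candidate_map_competition <- function(metabolites, uptake_prefix = "upt_") {
  data.frame(candidate = metabolites,
             responder_feature = paste0(uptake_prefix, metabolites),
             partner_feature = paste0(uptake_prefix, metabolites, "_p"),
             stringsAsFactors = FALSE)
}

#' Build a candidate map for facilitation (cross-feeding) mechanisms
#'
#' Each candidate maps to the responder-half uptake feature and the
#' partner-half secretion feature: the responder benefits when it can consume
#' what the partner secretes.
#'
#' @inheritParams candidate_map_competition
#' @param secretion_prefix prefix of secretion feature names.
#' @export
candidate_map_facilitation <- function(metabolites, uptake_prefix = "upt_",
                                       secretion_prefix = "sec_") {
  data.frame(candidate = metabolites,
             responder_feature = paste0(uptake_prefix, metabolites),
             partner_feature = paste0(secretion_prefix, metabolites, "_p"),
             stringsAsFactors = FALSE)
}

#' Rank candidate mechanisms by net feature contribution
#'
#' Sums, for every candidate, the contribution of its responder-half feature
#' and of its partner-half feature, and sorts the candidates. Rankings for
#' competitive mechanisms are read from the negative end (features pulling the
#' prediction towards the negative class rank first); facilitative mechanisms
#' read from the positive end. Ties are broken by candidate name. Candidates
#' whose features are 0 in both halves of the sample are ranked but flagged
#' (\code{zero_presence}); their contributions can still be nonzero only
#' through the value-0 branch of splits.
#'
#' @param contrib a [feature_contributions()] result.
#' @param candidate_map data.frame with columns \code{candidate},
#'   \code{responder_feature}, \code{partner_feature}; the feature pairs must
#'   be disjoint across candidates.
#' @param direction \code{"from_negative_end"} or \code{"from_positive_end"}.
#' @return data.frame of class \code{"mechanism_ranking"} with \code{rank},
#'   \code{candidate}, \code{net}, \code{zero_presence}; attribute
#'   \code{direction}.
#' @export
net_contributions <- function(contrib, candidate_map,
                              direction = c("from_negative_end",
                                            "from_positive_end")) {
  stopifnot(inherits(contrib, "contribution_vector"))
  direction <- match.arg(direction)
  cm <- as.data.frame(candidate_map, stringsAsFactors = FALSE)
  need <- c("candidate", "responder_feature", "partner_feature")
  if (!all(need %in% names(cm))) {
    stop("candidate_map needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(cm$candidate)) stop("duplicate candidate names")
  feats <- c(cm$responder_feature, cm$partner_feature)
  if (anyDuplicated(feats)) {
    stop("feature listed twice across candidates: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  missing_f <- setdiff(feats, names(contrib$phi))
  if (length(missing_f)) {
    stop("candidate features not in the model's feature space: ",
         paste(utils::head(missing_f, 5L), collapse = ", "))
  }
  net <- unname(contrib$phi[cm$responder_feature] + contrib$phi[cm$partner_feature])
  xr <- contrib$x[match(cm$responder_feature, names(contrib$phi))]
  xp <- contrib$x[match(cm$partner_feature, names(contrib$phi))]
  zero_presence <- xr == 0L & xp == 0L
  ord <- if (direction == "from_negative_end") {
    order(net, cm$candidate)
  } else {
    order(-net, cm$candidate)
  }
  out <- data.frame(rank = seq_along(ord), candidate = cm$candidate[ord],
                    net = net[ord], zero_presence = zero_presence[ord],
                    stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  class(out) <- c("mechanism_ranking", class(out))
  out
}

#' Rank of the first true mechanism in a ranking
#'
#' The 1-based position, reading in the ranking's direction, of the first
#' candidate that belongs to the ground-truth mechanism set: the number of
#' candidate experiments one would run before hitting a real mechanism when
#' following the ranking.
#'
#' @param ranking a [net_contributions()] ranking.
#' @param truth non-empty character vector of true candidates, all present in
#'   the ranking.
#' @return integer rank >= 1.
#' @export
first_true_rank <- function(ranking, truth) {
  stopifnot(inherits(ranking, "mechanism_ranking"))
  if (!length(truth)) stop("truth set is empty")
  if (!all(truth %in% ranking$candidate)) {
    stop("truth candidates missing from ranking: ",
         paste(setdiff(truth, ranking$candidate), collapse = ", "))
  }
  min(which(ranking$candidate %in% truth))
}

#' Expected rank of the first true candidate under random querying
#'
#' When candidates are investigated one at a time in uniformly random order
#' without replacement, the expected 1-based position of the first true
#' candidate among \code{n_candidates} with \code{n_true} true ones is
#' \code{(n_candidates + 1) / (n_true + 1)}.
#'
#' @param n_candidates total number of candidates.
#' @param n_true number of true candidates, \code{1 <= n_true <= n_candidates}.
#' @return expected rank (experiments needed on average).
#' @examples
#' expected_random_rank(194, 1) # 97.5
#' @export
expected_random_rank <- function(n_candidates, n_true) {
  if (n_true < 1 || n_true > n_candidates) {
    stop("n_true must be between 1 and n_candidates")
  }
  (n_candidates + 1) / (n_true + 1)
}

#' Evaluate mechanism-query cost over a labeled dataset
#'
#' For every sample with a known mechanism set, computes feature
#' contributions, ranks the candidates by net contribution (direction chosen
#' by the sample's class) and records the rank of the first true mechanism,
#' next to the analytic random-query baseline for the same candidate count.
#' Samples with an empty truth set are skipped with a warning.
#'
#' @param model a [train_forest()] model trained on \code{dataset}.
#' @param dataset the training \code{composite_dataset}.
#' @param truths named list: for each dataset row name
#'   (\code{"responder:partner"}), the character vector of true candidates.
#' @param candidate_map see [net_contributions()].
#' @param direction_map named character vector mapping class names to ranking
#'   directions; default: negative class from the negative end, positive
#'   class from the positive end.
#' @param mode contribution mode, \code{"oob"} (default) or
#'   \code{"all_trees"}.
#' @return list with \code{per_sample} (data.frame of sample, class, rank,
#'   n_true, expected_random) and \code{summary} (medians and means of both).
#' @export
query_count_evaluation <- function(model, dataset, truths, candidate_map,
                                   direction_map = NULL, mode = "oob") {
  stopifnot(inherits(dataset, "composite_dataset"))
  if (is.null(direction_map)) {
    neg <- model$class_names[["negative"]]
    pos <- model$class_names[["positive"]]
    direction_map <- stats::setNames(c("from_negative_end", "from_positive_end"),
                                     c(neg, pos))
  }
  keys <- rownames(dataset$design)
  eval_keys <- intersect(keys, names(truths))
  n_empty <- sum(vapply(truths[eval_keys], length, integer(1)) == 0L)
  if (n_empty > 0L) {
    warning(n_empty, " sample(s) with empty truth set skipped")
  }
  eval_keys <- eval_keys[vapply(truths[eval_keys], length, integer(1)) > 0L]
  if (!length(eval_keys)) stop("no samples with a non-empty truth set")
  n_cand <- nrow(candidate_map)
  rows <- lapply(eval_keys, function(k) {
    i <- match(k, keys)
    cls <- as.character(dataset$labels[i])
    contrib <- feature_contributions(model, dataset$design[i, ],
                                     sample_id = i, mode = mode)
    ranking <- net_contributions(contrib, candidate_map,
                                 direction = direction_map[[cls]])
    truth <- intersect(truths[[k]], candidate_map$candidate)
    if (!length(truth)) return(NULL)
    data.frame(sample = k, class = cls,
               rank = first_true_rank(ranking, truth),
               n_true = length(truth),
               expected_random = expected_random_rank(n_cand, length(truth)),
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  list(per_sample = per_sample,
       summary = list(median_rank = stats::median(per_sample$rank),
                      mean_rank = mean(per_sample$rank),
                      median_random = stats::median(per_sample$expected_random),
                      mean_random = mean(per_sample$expected_random),
                      n_samples = nrow(per_sample),
                      n_candidates = n_cand))
}

#' Convert a mechanism table to a per-sample truth list
#'
#' @param mechanisms data.frame with columns \code{responder},
#'   \code{partner}, \code{type}, \code{metabolite} (as written by
#'   [pairwise_campaign()]).
#' @param type keep only mechanisms of this type (\code{"competition"} or
#'   \code{"facilitation"}); \code{NULL} keeps all.
#' @return named list keyed by \code{"responder:partner"}.
#' @export
truth_list <- function(mechanisms, type = NULL) {
  m <- mechanisms
  if (!is.null(type)) m <- m[m$type == type, , drop = FALSE]
  if (!nrow(m)) return(list())
  split(m$metabolite, paste(m$responder, m$partner, sep = ":"))
}
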