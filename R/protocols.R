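#' Pair-respecting train/test split
#'
#' Splits a composite dataset at the level of unordered organism pairs: the
#' two ordered observations of a pair, (i, j) and (j, i), always land on the
#' same side of the split, so a classifier is never tested on the mirror
#' image of a pair it trained on.
#'
#' @param dataset a \code{composite_dataset}.
#' @param fraction fraction of unordered pairs assigned to training,
#'   strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with integer row indices \code{train} and \code{test}.
#' @export
paired_split <- function(dataset, fraction, seed = 1L) {
  stopifnot(inherits(dataset, "composite_dataset"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  key <- paste(pmin(dataset$pairs$responder, dataset$pairs$partner),
               pmax(dataset$pairs$responder, dataset$pairs$partner),
               sep = "|")
  u <- unique(key)
  n_train <- round(fraction * length(u))
  if (n_train < 1L || n_train >= length(u)) {
    stop("fraction leaves an empty training or test set")
  }
  set.seed(seed)
  train_pairs <- sample(u, n_train)
  train <- which(key %in% train_pairs)
  list(train = train, test = setdiff(seq_along(key), train))
}

.subset_dataset <- function(dataset, rows) {
  out <- dataset
  out$pairs <- dataset$pairs[rows, , drop = FALSE]
  out$design <- dataset$design[rows, , drop = FALSE]
  out$labels <- dataset$labels[rows]
  out
}

#' Learning curve over training fractions
#'
#' For each training fraction, repeatedly draws a pair-respecting split,
#' trains a forest on the training side and scores balanced accuracy on the
#' held-out side; the median over repeats is the curve value. Splits whose
#' training side contains a single class are redrawn (up to
#' \code{max_redraw} times).
#'
#' @param dataset a \code{composite_dataset}.
#' @param fractions training fractions; default the standard grid from 0.05
#'   to 0.95.
#' @param n_repeats splits per fraction (>= 10 recommended).
#' @param ntree,mtry,min_node forest hyperparameters.
#' @param seed integer seed; expands to one substream per (fraction, repeat).
#' @param max_redraw redraw budget for degenerate splits.
#' @return object of class \code{"learning_curve_result"}: \code{results}
#'   (data.frame fraction/repeat/balanced_accuracy) and \code{medians}
#'   (data.frame fraction/median).
#' @export
learning_curve <- function(dataset,
                           fractions = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                                         0.6, 0.7, 0.8, 0.9, 0.95),
                           n_repeats = 10L, ntree = 500L, mtry = NULL,
                           min_node = 1L, seed = 1L, max_redraw = 100L) {
  stopifnot(inherits(dataset, "composite_dataset"))
  positive <- dataset$positive_class
  rows <- list()
  idx <- 0L
  for (fi in seq_along(fractions)) {
    for (r in seq_len(n_repeats)) {
      idx <- idx + 1L
      sp <- NULL
      for (attempt in 0:max_redraw) {
        sub_seed <- .tree_seed(seed, 100000L * fi + 1000L * r + attempt)
        cand <- paired_split(dataset, fractions[fi], seed = sub_seed)
        if (nlevels(droplevels(dataset$labels[cand$train])) == 2L) {
          sp <- cand
          break
        }
      }
      if (is.null(sp)) {
        stop(sprintf("could not draw a two-class training set at fraction %.2f",
                     fractions[fi]))
      }
      model <- train_forest(.subset_dataset(dataset, sp$train), ntree = ntree,
                            mtry = mtry, min_node = min_node,
                            seed = .tree_seed(seed, idx))
      pred <- predict(model, dataset$design[sp$test, , drop = FALSE])
      ba <- tryCatch(
        balanced_accuracy_score(dataset$labels[sp$test], pred$class, positive),
        error = function(e) NA_real_) # test side may hold a single class
      rows[[idx]] <- data.frame(fraction = fractions[fi], repeat_id = r,
                                balanced_accuracy = ba)
    }
  }
  results <- do.call(rbind, rows)
  medians <- stats::aggregate(balanced_accuracy ~ fraction, data = results,
                              FUN = stats::median, na.action = stats::na.omit)
  names(medians)[2L] <- "median"
  structure(list(results = results, medians = medians,
                 n_repeats = n_repeats, seed = seed,
                 n_samples = nrow(dataset$design)),
            class = "learning_curve_result")
}

#' @export
print.learning_curve_result <- function(x, ...) {
  cat(sprintf("learning_curve_result: %d samples, %d repeats per fraction\n",
              x$n_samples, x$n_repeats))
  print(x$medians, row.names = FALSE)
  invisible(x)
}

#' Learning curves across community sizes
#'
#' For each requested community size, draws random organism subsets, builds
#' the corresponding sub-dataset and computes its learning curve; reports the
#' per-size median curve. Subsets are drawn independently, so organisms may
#' recur across draws of the same size.
#'
#' @param traits a [trait_matrix()].
#' @param table an [interaction_table()].
#' @param rule a [label_rule()].
#' @param sizes community sizes to evaluate (each <= number of organisms).
#' @param n_communities random subsets per size.
#' @param ... passed to [learning_curve()] (fractions, n_repeats, ntree, ...).
#' @param seed integer seed.
#' @return list with \code{curves} (data.frame size/community/fraction/
#'   median) and \code{median_by_size} (size/fraction/median across
#'   communities).
#' @export
community_size_sweep <- function(traits, table, rule,
                                 sizes = c(10, 20, 30, 40, 50, 60, 70, 80, 90),
                                 n_communities = 5L, seed = 1L, ...) {
  orgs <- rownames(table)
  sizes <- sizes[sizes <= length(orgs)]
  if (!length(sizes)) stop("all requested sizes exceed the community size")
  rows <- list()
  for (s in sizes) {
    for (cm in seq_len(n_communities)) {
      set.seed(.tree_seed(seed, 1000L * s + cm))
      chosen <- if (s == length(orgs)) orgs else sample(orgs, s)
      sub_tab <- interaction_table(unclass(table)[chosen, chosen, drop = FALSE],
                                   response_mode = attr(table, "response_mode"))
      ds <- assemble_dataset(traits, sub_tab, rule)
      lc <- learning_curve(ds, seed = .tree_seed(seed, 7L * s + cm), ...)
      rows[[length(rows) + 1L]] <- cbind(size = s, community = cm, lc$medians)
    }
  }
  curves <- do.call(rbind, rows)
  med <- stats::aggregate(median ~ size + fraction, data = curves,
                          FUN = stats::median)
  list(curves = curves, median_by_size = med)
}

#' Balanced-subsample training for rare classes
#'
#' When one class is rare, trains repeated forests on balanced subsets: every
#' repeat keeps all rare-class samples and draws an equal number of
#' majority-class samples without replacement, then scores out-of-bag
#' balanced accuracy on that balanced training set.
#'
#' @param dataset a \code{composite_dataset}.
#' @param n_repeats number of balanced subsamples.
#' @param ntree,mtry,min_node forest hyperparameters.
#' @param seed integer seed.
#' @param keep_models return the trained models (FALSE by default; they can
#'   be large).
#' @return list with \code{balanced_accuracy} (per repeat), \code{median},
#'   \code{rare_class}, \code{n_rare}, and optionally \code{models}.
#' @export
balanced_subsample_train <- function(dataset, n_repeats = 100L, ntree = 500L,
                                     mtry = NULL, min_node = 1L, seed = 1L,
                                     keep_models = FALSE) {
  stopifnot(inherits(dataset, "composite_dataset"))
  tab <- table(dataset$labels)
  if (length(tab) != 2L || any(tab == 0L)) stop("both classes must be present")
  rare <- names(tab)[which.min(tab)]
  major <- names(tab)[which.max(tab)]
  if (tab[[rare]] > tab[[major]]) stop("rare class larger than majority class")
  rare_rows <- which(dataset$labels == rare)
  major_rows <- which(dataset$labels == major)
  bas <- numeric(n_repeats)
  models <- if (keep_models) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    set.seed(.tree_seed(seed, r))
    rows <- c(rare_rows, sample(major_rows, length(rare_rows)))
    sub <- .subset_dataset(dataset, rows)
    model <- train_forest(sub, ntree = ntree, mtry = mtry,
                          min_node = min_node, seed = .tree_seed(seed, r + 500000L))
    ov <- oob_votes(model, sub)
    keep <- !is.na(ov$fraction)
    bas[r] <- balanced_accuracy_score(sub$labels[keep], ov$predicted[keep],
                                      dataset$positive_class)
    if (keep_models) models[[r]] <- model
  }
  out <- list(balanced_accuracy = bas, median = stats::median(bas),
              rare_class = rare, n_rare = length(rare_rows))
  if (keep_models) out$models <- models
  out
}
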