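#' Gini impurity of a two-class node
#'
#' \code{1 - p1^2 - p2^2} where \code{p_c} is the class proportion at the
#' node. Ranges from 0 (pure node) to 0.5 (perfectly mixed). Used as the
#' split criterion when growing trees: the chosen split maximizes the
#' weighted impurity decrease.
#'
#' @param class_counts pair of non-negative integers (count of each class);
#'   total must be > 0.
#' @return impurity in \code{[0, 0.5]}.
#' @examples
#' gini_impurity(c(3, 1)) # 0.375
#' @export
gini_impurity <- function(class_counts) {
  if (length(class_counts) != 2L || any(class_counts < 0)) {
    stop("class_counts must be two non-negative counts")
  }
  tot <- sum(class_counts)
  if (tot == 0) stop("gini impurity undefined for an empty node")
  p <- class_counts / tot
  1 - sum(p^2)
}

# vectorized gini from positive counts / totals; empty nodes contribute 0
.gini2 <- function(pos, tot) {
  out <- numeric(length(tot))
  nz <- tot > 0
  p <- pos[nz] / tot[nz]
  out[nz] <- 1 - p^2 - (1 - p)^2
  out
}

.tree_seed <- function(seed, t) {
  as.integer((as.double(seed) + 7919 * as.double(t)) %% 2147483646) + 1L
}

#' Grow a single decision tree on binary features
#'
#' Recursively partitions the in-bag samples: at each node a random subset of
#' \code{mtry} features is drawn without replacement and the feature whose
#' 0-vs-1 split maximizes the Gini impurity decrease is chosen (ties broken
#' towards the lowest feature index). Growth stops when a node is pure, holds
#' fewer than \code{min_node} samples, or no candidate split reduces
#' impurity. Class counts of the in-bag samples reaching each node are
#' recorded at every node; they are the raw material of the per-sample
#' feature-contribution decomposition.
#'
#' Uses the current RNG state; callers (e.g. [train_forest()]) seed it.
#'
#' @param design integer 0/1 matrix, samples x features.
#' @param labels integer 0/1 vector (1 = positive class), one per design row.
#' @param in_bag integer vector of row indices drawn with replacement
#'   (a multiset; duplicates are meaningful).
#' @param mtry number of candidate features per split.
#' @param min_node minimum node size still eligible for splitting.
#' @return object of class \code{"decision_tree"}: parallel vectors
#'   \code{split} (feature index, NA at leaves), \code{left}, \code{right}
#'   (child node ids; left = feature value 0), \code{n_neg}, \code{n_pos}
#'   (in-bag class counts at the node). Node 1 is the root.
#' @export
grow_tree <- function(design, labels, in_bag, mtry, min_node = 1L) {
  if (!length(in_bag)) stop("empty in-bag set")
  n_feat <- ncol(design)
  if (mtry < 1L || mtry > n_feat) stop("mtry must be in [1, n_features]")
  if (min_node < 1L) stop("min_node must be >= 1")

  cap <- 2L * length(in_bag) + 1L
  split <- rep(NA_integer_, cap)
  left <- rep(NA_integer_, cap)
  right <- rep(NA_integer_, cap)
  n_neg <- integer(cap)
  n_pos <- integer(cap)

  n_nodes <- 1L
  stack <- vector("list", 64L)
  stack[[1L]] <- list(id = 1L, idx = in_bag)
  top <- 1L
  while (top > 0L) {
    fr <- stack[[top]]
    top <- top - 1L
    idx <- fr$idx
    id <- fr$id
    y <- labels[idx]
    tot <- length(idx)
    pos <- sum(y)
    n_neg[id] <- tot - pos
    n_pos[id] <- pos
    if (pos == 0L || pos == tot || tot < min_node) next

    fs <- sort.int(sample.int(n_feat, mtry))
    xs <- design[idx, fs, drop = FALSE]
    n_r <- colSums(xs)
    n_rpos <- as.numeric(crossprod(xs, y))
    n_l <- tot - n_r
    n_lpos <- pos - n_rpos
    g_parent <- .gini2(pos, tot)
    gain <- g_parent -
      (n_l * .gini2(n_lpos, n_l) + n_r * .gini2(n_rpos, n_r)) / tot
    ok <- n_l > 0 & n_r > 0 & gain > 1e-12
    if (!any(ok)) next
    cand <- which(ok)
    best <- cand[which.max(gain[cand])] # ties: first, i.e. lowest feature index
    f <- fs[best]

    mask <- design[idx, f] == 1L
    lid <- n_nodes + 1L
    rid <- n_nodes + 2L
    n_nodes <- rid
    if (rid > cap) stop("internal error: tree node capacity exceeded")
    split[id] <- f
    left[id] <- lid
    right[id] <- rid
    if (top + 2L > length(stack)) stack <- c(stack, vector("list", length(stack)))
    stack[[top + 1L]] <- list(id = rid, idx = idx[mask])
    stack[[top + 2L]] <- list(id = lid, idx = idx[!mask])
    top <- top + 2L
  }
  keep <- seq_len(n_nodes)
  structure(list(split = split[keep], left = left[keep], right = right[keep],
                 n_neg = n_neg[keep], n_pos = n_pos[keep]),
            class = "decision_tree")
}

# vectorized root-to-leaf descent; returns leaf node id per row of x
.tree_descend <- function(tree, x) {
  node <- rep(1L, nrow(x))
  repeat {
    sp <- tree$split[node]
    act <- which(!is.na(sp))
    if (!length(act)) break
    goes_right <- x[cbind(act, sp[act])] == 1L
    node[act] <- ifelse(goes_right, tree$right[node[act]], tree$left[node[act]])
  }
  node
}

# per-node positive-class fraction
.tree_y <- function(tree) {
  tot <- tree$n_neg + tree$n_pos
  ifelse(tot > 0, tree$n_pos / tot, NA_real_)
}

# a tree's vote (TRUE = positive class) for given leaf ids; leaf tie -> negative
.tree_vote <- function(tree, leaf) {
  tree$n_pos[leaf] > tree$n_neg[leaf]
}

#' Train a random forest of bootstrap trees
#'
#' Each tree receives a bootstrap resample of the training set (same size,
#' drawn with replacement); samples not drawn for a tree are that tree's
#' out-of-bag (OOB) samples, recorded in the model for OOB evaluation and
#' OOB feature contributions. One RNG substream is derived per tree from the
#' single seed, so increasing \code{ntree} never reshuffles earlier trees.
#' The bootstrap treats the dataset rows independently; the constraint that
#' the two orders of a pair travel together applies to train/test splits
#' ([paired_split()]), not to the bootstrap.
#'
#' @param x a \code{composite_dataset} (from [assemble_dataset()]) or an
#'   integer 0/1 design matrix.
#' @param y class labels (factor) when \code{x} is a matrix; ignored for a
#'   composite dataset.
#' @param ntree number of trees.
#' @param mtry candidate features per split; default
#'   \code{floor(sqrt(ncol(design)))}.
#' @param min_node minimum splittable node size.
#' @param seed integer seed; the forest is fully reproducible from it.
#' @param positive_class which class votes are counted for; default: second
#'   factor level (composite datasets carry their own).
#' @return object of class \code{"pair_forest"}: trees, hyperparameters,
#'   feature and class names, and the in-bag count matrix
#'   (\code{n_train x ntree}).
#' @export
train_forest <- function(x, y = NULL, ntree = 500L, mtry = NULL,
                         min_node = 1L, seed = 1L, positive_class = NULL) {
  if (inherits(x, "composite_dataset")) {
    design <- x$design
    y <- x$labels
    if (is.null(positive_class)) positive_class <- x$positive_class
  } else {
    design <- as.matrix(x)
    if (is.null(y)) stop("labels y required when x is a matrix")
    y <- as.factor(y)
    if (is.null(positive_class)) positive_class <- levels(y)[nlevels(y)]
  }
  storage.mode(design) <- "integer"
  if (!all(design %in% c(0L, 1L))) {
    stop("design matrix must be binary; categorical/continuous features are not supported")
  }
  n <- nrow(design)
  p <- ncol(design)
  if (n < 2L) stop("need at least 2 training samples")
  y <- as.factor(y)
  lev <- levels(droplevels(y))
  if (length(lev) != 2L) stop("training labels must contain exactly two classes")
  if (!positive_class %in% lev) stop("positive_class not among label classes")
  negative_class <- setdiff(lev, positive_class)
  y01 <- as.integer(as.character(y) == positive_class)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- as.integer(mtry)
  ntree <- as.integer(ntree)
  if (ntree < 1L) stop("ntree must be >= 1")

  trees <- vector("list", ntree)
  inbag <- matrix(0L, n, ntree)
  for (t in seq_len(ntree)) {
    set.seed(.tree_seed(seed, t))
    ib <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(design, y01, ib, mtry = mtry, min_node = min_node)
    inbag[, t] <- tabulate(ib, nbins = n)
  }
  structure(list(trees = trees, ntree = ntree, mtry = mtry,
                 min_node = as.integer(min_node), seed = as.integer(seed),
                 feature_names = colnames(design),
                 class_names = c(negative = negative_class,
                                 positive = positive_class),
                 n_train = n, inbag = inbag),
            class = "pair_forest")
}

#' @export
print.pair_forest <- function(x, ...) {
  cat(sprintf(
    "pair_forest: %d trees, mtry=%d, %d features, classes %s (negative) / %s (positive)\n",
    x$ntree, x$mtry, length(x$feature_names),
    x$class_names[["negative"]], x$class_names[["positive"]]))
  invisible(x)
}

.check_design <- function(model, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(model$feature_names)) {
    stop(sprintf("composite vector length %d does not match model's %d features",
                 ncol(newdata), length(model$feature_names)))
  }
  storage.mode(newdata) <- "integer"
  newdata
}

#' Predict coculture outcomes with a trained forest
#'
#' Every tree votes the majority class of the leaf the sample lands in; the
#' reported fraction is the share of trees voting for the positive class over
#' all trees. A sample is called positive when the fraction exceeds 0.5; a
#' fraction of exactly 0.5 is called for the negative class (deterministic
#' tie rule).
#'
#' @param object a [train_forest()] model.
#' @param newdata composite vector or matrix (samples x 2n features).
#' @param ... unused.
#' @return data.frame with \code{class} (factor negative/positive class
#'   names) and \code{fraction} (positive-vote share).
#' @export
predict.pair_forest <- function(object, newdata, ...) {
  x <- .check_design(object, newdata)
  votes <- integer(nrow(x))
  for (t in seq_len(object$ntree)) {
    tree <- object$trees[[t]]
    votes <- votes + .tree_vote(tree, .tree_descend(tree, x))
  }
  frac <- votes / object$ntree
  cls <- ifelse(frac > 0.5, object$class_names[["positive"]],
                object$class_names[["negative"]])
  data.frame(class = factor(cls, levels = unname(object$class_names)),
             fraction = frac, row.names = rownames(x))
}

#' Out-of-bag vote summary on the training set
#'
#' For each training sample, the fraction of positive-class votes over the
#' trees for which the sample was out-of-bag. Samples that were in-bag for
#' every tree are flagged (NA fraction, \code{n_trees = 0}) rather than
#' failing; with realistic tree counts this is vanishingly rare.
#'
#' @param model a [train_forest()] model.
#' @param x the training \code{composite_dataset} or its design matrix.
#' @return data.frame of class \code{"vote_summary"} with \code{fraction},
#'   \code{n_trees} (counted trees) and \code{predicted}; attribute
#'   \code{mode = "oob"}.
#' @export
oob_votes <- function(model, x) {
  design <- if (inherits(x, "composite_dataset")) x$design else as.matrix(x)
  design <- .check_design(model, design)
  if (nrow(design) != model$n_train) {
    stop("oob_votes requires the training set itself")
  }
  n <- nrow(design)
  pos_votes <- integer(n)
  counted <- integer(n)
  for (t in seq_len(model$ntree)) {
    tree <- model$trees[[t]]
    oob <- model$inbag[, t] == 0L
    if (!any(oob)) next
    v <- .tree_vote(tree, .tree_descend(tree, design[oob, , drop = FALSE]))
    pos_votes[oob] <- pos_votes[oob] + v
    counted[oob] <- counted[oob] + 1L
  }
  frac <- ifelse(counted > 0L, pos_votes / counted, NA_real_)
  cls <- ifelse(is.na(frac), NA_character_,
                ifelse(frac > 0.5, model$class_names[["positive"]],
                       model$class_names[["negative"]]))
  out <- data.frame(fraction = frac, n_trees = counted,
                    predicted = factor(cls, levels = unname(model$class_names)),
                    row.names = rownames(design))
  attr(out, "mode") <- "oob"
  attr(out, "positive_class") <- model$class_names[["positive"]]
  class(out) <- c("vote_summary", class(out))
  out
}

#' Balanced accuracy from confusion counts
#'
#' \code{[TP/(TP+FN) + TN/(TN+FP)] / 2}: the mean of sensitivity and
#' specificity, robust to class imbalance.
#'
#' @param tp,fn,tn,fp confusion matrix counts; each class must have at least
#'   one true member.
#' @return balanced accuracy in \code{[0, 1]}.
#' @examples
#' balanced_accuracy(90, 10, 60, 40) # 0.75
#' @export
balanced_accuracy <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0 || tn + fp <= 0) {
    stop("balanced accuracy undefined: a class has no true members")
  }
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Balanced accuracy of predicted vs true labels
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param positive the positive class value.
#' @return balanced accuracy in \code{[0, 1]}.
#' @export
balanced_accuracy_score <- function(truth, predicted, positive) {
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  balanced_accuracy(tp, fn, tn, fp)
}

#' ROC curve and AUC from forest vote fractions
#'
#' Sweeps the classification threshold over the (out-of-bag) positive-vote
#' fraction. Uncounted samples (OOB for zero trees) are dropped with their
#' labels before the sweep.
#'
#' @param votes a [oob_votes()] summary or a numeric vector of positive-class
#'   vote fractions.
#' @param labels true class labels, aligned with \code{votes}.
#' @param positive positive class value; taken from the vote summary when
#'   available.
#' @return list with \code{auc} and the ROC \code{curve} (see
#'   [score_threshold_roc()]).
#' @export
roc_auc <- function(votes, labels, positive = NULL) {
  if (inherits(votes, "vote_summary")) {
    if (is.null(positive)) positive <- attr(votes, "positive_class")
    keep <- !is.na(votes$fraction)
    score_threshold_roc(votes$fraction[keep], labels[keep], positive = positive)
  } else {
    score_threshold_roc(as.numeric(votes), labels, positive = positive)
  }
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' For each tree and each feature used by that tree, the tree's accuracy on
#' its out-of-bag samples is compared with the accuracy after permuting that
#' feature's values among those samples; the decreases are averaged over all
#' trees. Features used by no tree have importance exactly 0 (a permutation
#' cannot change any decision path).
#'
#' @param model a [train_forest()] model.
#' @param x the training \code{composite_dataset} or design matrix.
#' @param y training labels (taken from the dataset when omitted).
#' @param seed integer seed for the permutations.
#' @return named numeric vector of mean accuracy decreases, one per feature.
#' @export
permutation_importance <- function(model, x, y = NULL, seed = 1L) {
  if (inherits(x, "composite_dataset")) {
    design <- x$design
    if (is.null(y)) y <- x$labels
  } else {
    design <- as.matrix(x)
    if (is.null(y)) stop("labels y required when x is a matrix")
  }
  design <- .check_design(model, design)
  y01 <- as.integer(as.character(y) == model$class_names[["positive"]])
  p <- length(model$feature_names)
  imp <- numeric(p)
  set.seed(.tree_seed(seed, 0L))
  for (t in seq_len(model$ntree)) {
    tree <- model$trees[[t]]
    oob <- which(model$inbag[, t] == 0L)
    if (!length(oob)) next
    xo <- design[oob, , drop = FALSE]
    yo <- y01[oob]
    acc0 <- mean(.tree_vote(tree, .tree_descend(tree, xo)) == yo)
    used <- sort.int(unique(tree$split[!is.na(tree$split)]))
    for (f in used) {
      orig <- xo[, f]
      xo[, f] <- orig[sample.int(length(oob))]
      acc1 <- mean(.tree_vote(tree, .tree_descend(tree, xo)) == yo)
      xo[, f] <- orig
      imp[f] <- imp[f] + (acc0 - acc1)
    }
  }
  imp <- imp / model$ntree
  names(imp) <- model$feature_names
  imp
}
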