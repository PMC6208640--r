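#' Interaction (response) table
#'
#' Square table of coculture responses: entry \code{X[i, j]} is the measured
#' response of organism \code{i} grown together with organism \code{j}. The
#' two orders are distinct observations (\code{X[i, j] != X[j, i]} in
#' general). In \code{relative_yield} mode the diagonal holds the monoculture
#' final biomass \code{B_ii} used as the reference; in the other modes the
#' diagonal is ignored. Off-diagonal \code{NA}s mark unmeasured pairs (sparse
#' designs are allowed).
#'
#' @param responses square numeric matrix with matching row/column names
#'   (organism ids).
#' @param response_mode one of \code{"relative_yield"}, \code{"fold_change"},
#'   \code{"survival"}, \code{"raw"}.
#' @return the matrix with class \code{"interaction_table"} and a
#'   \code{response_mode} attribute.
#' @export
interaction_table <- function(responses,
                              response_mode = c("relative_yield",
                                                "fold_change", "survival",
                                                "raw")) {
  response_mode <- match.arg(response_mode)
  responses <- as.matrix(responses)
  if (nrow(responses) != ncol(responses)) {
    stop("interaction table must be square")
  }
  if (is.null(rownames(responses))) {
    rownames(responses) <- colnames(responses)
  }
  if (is.null(rownames(responses))) {
    stop("interaction table needs organism ids as dimnames")
  }
  if (is.null(colnames(responses))) colnames(responses) <- rownames(responses)
  if (!identical(rownames(responses), colnames(responses))) {
    stop("row and column organism ids must match")
  }
  if (anyDuplicated(rownames(responses))) stop("duplicate organism ids")
  storage.mode(responses) <- "double"
  attr(responses, "response_mode") <- response_mode
  class(responses) <- c("interaction_table", class(matrix()))
  responses
}

#' Read an interaction table from a TSV file
#'
#' Expects a square matrix with a shared header: first column organism id,
#' remaining columns one per partner. \code{NA} marks unmeasured pairs.
#'
#' @param path path to the tab-separated file.
#' @inheritParams interaction_table
#' @export
read_interaction_table <- function(path,
                                   response_mode = c("relative_yield",
                                                     "fold_change",
                                                     "survival", "raw")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  interaction_table(m, response_mode = match.arg(response_mode))
}

#' Write an interaction table to a TSV file
#' @param table an [interaction_table()].
#' @param path output path.
#' @export
write_interaction_table <- function(table, path) {
  df <- data.frame(organism = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction_table (%s): %d organisms, %d measured ordered pairs\n",
              attr(x, "response_mode"), nrow(x),
              sum(!is.na(x)) - sum(!is.na(diag(unclass(x))))))
  invisible(x)
}

#' Relative yield of a coculture response
#'
#' \code{(B_ij - B_ii) / B_ii}: the normalized change in final biomass of the
#' responder in coculture versus monoculture. Negative values mean the
#' partner is detrimental, 0 means no effect, positive values a benefit.
#'
#' @param b_ij final biomass of the responder in coculture (may be a vector).
#' @param b_ii final biomass of the responder in monoculture; must be > 0.
#' @return dimensionless relative yield(s).
#' @examples
#' relative_yield(2, 4)  # -0.5
#' @export
relative_yield <- function(b_ij, b_ii) {
  if (any(!is.finite(b_ii)) || any(b_ii <= 0)) {
    stop("monoculture biomass B_ii must be positive: relative yield undefined")
  }
  (b_ij - b_ii) / b_ii
}

#' Label rule for turning numeric responses into binary classes
#'
#' Three rules are supported:
#' \describe{
#'   \item{sign}{relative yields: class \code{"negative"} when the response is
#'     below \code{-tol}, \code{"nonnegative"} otherwise (zero counts as
#'     nonnegative; \code{tol} absorbs floating-point noise from simulated
#'     yields).}
#'   \item{cutoff}{fold changes: \code{"weak"} when response <= \code{cutoff}
#'     (a fold change of exactly the cutoff is weak), \code{"strong"} above.}
#'   \item{binary}{responses already coded 0/1 are passed through, 0 mapping
#'     to the first class name and 1 to the second.}
#' }
#' The positive class (the class whose vote fraction forests report) defaults
#' to the second class of each rule and can be overridden.
#'
#' @param mode \code{"sign"}, \code{"cutoff"} or \code{"binary"}.
#' @param cutoff numeric cutoff, required for \code{mode = "cutoff"}.
#' @param classes length-2 character vector of class names in order
#'   (first, second).
#' @param positive_class which class is "positive" for votes/ROC.
#' @param tol tolerance around zero for the sign rule.
#' @export
label_rule <- function(mode = c("sign", "cutoff", "binary"), cutoff = NULL,
                       classes = NULL, positive_class = NULL, tol = 1e-9) {
  mode <- match.arg(mode)
  if (mode == "cutoff" && (is.null(cutoff) || !is.finite(cutoff))) {
    stop("cutoff rule needs a finite cutoff")
  }
  if (is.null(classes)) {
    classes <- switch(mode,
                      sign = c("negative", "nonnegative"),
                      cutoff = c("weak", "strong"),
                      binary = c("0", "1"))
  }
  if (length(classes) != 2L || anyDuplicated(classes)) {
    stop("classes must be two distinct names")
  }
  if (is.null(positive_class)) positive_class <- classes[2L]
  if (!positive_class %in% classes) stop("positive_class must be one of classes")
  structure(list(mode = mode, cutoff = cutoff, classes = classes,
                 positive_class = positive_class, tol = tol),
            class = "label_rule")
}

#' Apply a label rule to numeric responses
#' @param rule a [label_rule()].
#' @param x numeric responses.
#' @return factor with the rule's two class levels.
#' @export
apply_label_rule <- function(rule, x) {
  stopifnot(inherits(rule, "label_rule"))
  lab <- switch(rule$mode,
    sign = ifelse(x < -rule$tol, rule$classes[1L], rule$classes[2L]),
    cutoff = ifelse(x <= rule$cutoff, rule$classes[1L], rule$classes[2L]),
    binary = {
      if (!all(x %in% c(0, 1))) stop("binary rule requires 0/1 responses")
      rule$classes[ifelse(x == 0, 1L, 2L)]
    })
  factor(lab, levels = rule$classes)
}

#' Assemble a labeled composite dataset from traits and interactions
#'
#' Builds one design row per measured ordered off-diagonal pair (i, j): the
#' concatenation of the responder's and the partner's trait vectors, labeled
#' by applying the label rule to the recorded response. Diagonal entries are
#' never included. Unmeasured pairs (NA) are skipped unless explicitly
#' requested via \code{pairs}, in which case a missing response is an error.
#'
#' @param traits a [trait_matrix()].
#' @param table an [interaction_table()] over the same organisms.
#' @param rule a [label_rule()].
#' @param pairs optional 2-column matrix/data.frame of (responder, partner)
#'   organism ids restricting the dataset; default: all measured pairs.
#' @return object of class \code{"composite_dataset"}: list with
#'   \code{pairs} (data.frame responder/partner/response/label),
#'   \code{design} (N x 2n integer matrix), \code{labels} (factor),
#'   \code{feature_names}, \code{classes}, \code{positive_class},
#'   \code{label_rule}.
#' @export
assemble_dataset <- function(traits, table, rule, pairs = NULL) {
  stopifnot(inherits(traits, "trait_matrix"),
            inherits(table, "interaction_table"),
            inherits(rule, "label_rule"))
  orgs <- rownames(table)
  missing_orgs <- setdiff(orgs, rownames(traits))
  if (length(missing_orgs)) {
    stop("organisms without trait vectors: ",
         paste(missing_orgs, collapse = ", "))
  }
  tab <- unclass(table)
  if (is.null(pairs)) {
    idx <- which(!is.na(tab), arr.ind = TRUE)
    idx <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
    # deterministic row-major order: responder, then partner
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    pr <- data.frame(responder = orgs[idx[, 1L]], partner = orgs[idx[, 2L]],
                     stringsAsFactors = FALSE)
  } else {
    pr <- as.data.frame(pairs, stringsAsFactors = FALSE)[, 1:2]
    names(pr) <- c("responder", "partner")
    if (any(pr$responder == pr$partner)) {
      stop("diagonal pairs (i, i) are not part of a composite dataset")
    }
    resp <- tab[cbind(match(pr$responder, orgs), match(pr$partner, orgs))]
    if (anyNA(resp)) {
      bad <- pr[is.na(resp), , drop = FALSE]
      stop("missing responses for pairs: ",
           paste(paste(bad$responder, bad$partner, sep = ":"), collapse = ", "))
    }
  }
  if (nrow(pr) == 0L) stop("no measured off-diagonal pairs")
  pr$response <- tab[cbind(match(pr$responder, orgs), match(pr$partner, orgs))]
  pr$label <- apply_label_rule(rule, pr$response)

  n <- ncol(traits)
  ri <- match(pr$responder, rownames(traits))
  pi <- match(pr$partner, rownames(traits))
  design <- cbind(unclass(traits)[ri, , drop = FALSE],
                  unclass(traits)[pi, , drop = FALSE])
  colnames(design) <- composite_feature_names(colnames(traits))
  rownames(design) <- paste(pr$responder, pr$partner, sep = ":")
  structure(list(pairs = pr,
                 design = design,
                 labels = pr$label,
                 feature_names = colnames(design),
                 classes = rule$classes,
                 positive_class = rule$positive_class,
                 label_rule = rule),
            class = "composite_dataset")
}

#' @export
print.composite_dataset <- function(x, ...) {
  cat(sprintf("composite_dataset: %d ordered pairs, %d composite features\n",
              nrow(x$design), ncol(x$design)))
  print(table(x$labels))
  invisible(x)
}

#' Write the pair manifest of a composite dataset
#'
#' Records exactly which ordered pairs entered a dataset (sparse designs make
#' this non-obvious), with responses and labels.
#'
#' @param dataset a [assemble_dataset()] result.
#' @param path output TSV path.
#' @export
write_pair_manifest <- function(dataset, path) {
  utils::write.table(dataset$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
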