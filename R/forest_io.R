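#' Serialize a forest model to versioned JSON
#'
#' Writes the complete model — hyperparameters, class and feature names,
#' per-tree node arrays (split feature name, child ids, in-bag class counts)
#' and per-tree in-bag count vectors — so a round trip through
#' [forest_from_json()] reproduces the model exactly (all stored quantities
#' are integers or names).
#'
#' @param model a [train_forest()] model.
#' @param path output path (\code{.json}).
#' @export
forest_to_json <- function(model, path) {
  stopifnot(inherits(model, "pair_forest"))
  trees <- lapply(model$trees, function(tr) {
    list(node_id = seq_along(tr$split),
         split_feature = ifelse(is.na(tr$split), NA_character_,
                                model$feature_names[tr$split]),
         left = tr$left, right = tr$right,
         n_neg = tr$n_neg, n_pos = tr$n_pos)
  })
  obj <- list(format = "cocultr-forest", version = 1L,
              ntree = model$ntree, mtry = model$mtry,
              min_node = model$min_node, seed = model$seed,
              n_train = model$n_train,
              class_names = as.list(model$class_names),
              feature_names = model$feature_names,
              trees = trees,
              inbag = lapply(seq_len(model$ntree),
                             function(t) model$inbag[, t]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' Load a forest model from JSON
#'
#' @param path a file written by [forest_to_json()].
#' @return a \code{pair_forest} model identical to the serialized one.
#' @export
forest_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "cocultr-forest")) stop("not a cocultr forest file")
  if (!identical(as.integer(obj$version), 1L)) {
    stop("unsupported forest format version: ", obj$version)
  }
  feature_names <- as.character(obj$feature_names)
  trees <- lapply(obj$trees, function(tr) {
    split_name <- as.character(tr$split_feature)
    split <- match(split_name, feature_names)
    as_int_na <- function(v) {
      v[vapply(v, is.null, logical(1))] <- NA
      as.integer(unlist(lapply(v, function(e) if (is.null(e)) NA else e)))
    }
    structure(list(split = as.integer(split),
                   left = as_int_na(tr$left), right = as_int_na(tr$right),
                   n_neg = as.integer(unlist(tr$n_neg)),
                   n_pos = as.integer(unlist(tr$n_pos))),
              class = "decision_tree")
  })
  inbag <- if (is.matrix(obj$inbag)) {
    t(obj$inbag) # jsonlite simplifies the per-tree vectors to ntree x n
  } else {
    do.call(cbind, lapply(obj$inbag, as.integer))
  }
  storage.mode(inbag) <- "integer"
  structure(list(trees = trees, ntree = as.integer(obj$ntree),
                 mtry = as.integer(obj$mtry),
                 min_node = as.integer(obj$min_node),
                 seed = as.integer(obj$seed),
                 feature_names = feature_names,
                 class_names = c(negative = obj$class_names$negative,
                                 positive = obj$class_names$positive),
                 n_train = as.integer(obj$n_train), inbag = inbag),
            class = "pair_forest")
}
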