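#' Binary trait matrix
#'
#' A trait matrix encodes each organism of a community as a binary vector:
#' element \code{k} of the row for organism \code{i} is 1 if the organism
#' possesses trait \code{k} (an exchange reaction, a biosynthetic capability,
#' a functional module, ...) and 0 otherwise. Trait vectors must not be
#' derived from the measured coculture responses themselves.
#'
#' @param values numeric/integer matrix of 0/1 values, organisms in rows,
#'   traits in columns.
#' @param organism_ids character vector of unique organism identifiers;
#'   defaults to \code{rownames(values)}.
#' @param feature_names character vector of unique trait names; defaults to
#'   \code{colnames(values)}.
#' @return an integer matrix of class \code{"trait_matrix"} with organism ids
#'   as row names and feature names as column names.
#' @examples
#' tm <- trait_matrix(rbind(a = c(1, 0, 1), b = c(0, 1, 1)),
#'                    feature_names = c("f1", "f2", "f3"))
#' @export
trait_matrix <- function(values, organism_ids = rownames(values),
                         feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(organism_ids)) {
    organism_ids <- paste0("org", seq_len(nrow(values)))
  }
  if (is.null(feature_names)) {
    stop("trait matrix needs feature names")
  }
  if (ncol(values) < 1L) {
    stop("trait matrix must have at least one feature")
  }
  if (length(organism_ids) != nrow(values) ||
      length(feature_names) != ncol(values)) {
    stop("dimension mismatch between values and names")
  }
  if (anyDuplicated(organism_ids)) {
    stop("duplicate organism ids: ",
         paste(unique(organism_ids[duplicated(organism_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  bad <- which(!(values %in% c(0, 1)), arr.ind = FALSE)
  if (length(bad)) {
    k <- bad[1L]
    i <- (k - 1L) %% nrow(values) + 1L
    j <- (k - 1L) %/% nrow(values) + 1L
    stop(sprintf("non-binary trait value %s at organism '%s', feature '%s'",
                 format(values[k]), organism_ids[i], feature_names[j]))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(organism_ids, feature_names)
  class(values) <- c("trait_matrix", class(matrix()))
  values
}

#' Read a trait matrix from a TSV file
#'
#' Expects a header line \code{organism<TAB>feat1<TAB>...} followed by one row
#' per organism with 0/1 values. Row and column order of the file is kept.
#'
#' @param path path to the tab-separated file.
#' @return a [trait_matrix()].
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("trait matrix file must have at least one feature column")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  trait_matrix(vals, organism_ids = ids, feature_names = colnames(df)[-1L])
}

#' Write a trait matrix to a TSV file
#'
#' @param traits a [trait_matrix()].
#' @param path output path.
#' @export
write_trait_matrix <- function(traits, path) {
  df <- data.frame(organism = rownames(traits), unclass(traits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d organisms x %d binary features\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L))
  invisible(x)
}

#' Composite (concatenated) pair vector
#'
#' Builds the composite representation of an ordered coculture pair: the
#' trait vector of the responder (the organism whose response is being
#' predicted) followed by the trait vector of its partner. The ordering makes
#' the representation asymmetric: the composite for (i, j) differs from the
#' one for (j, i) whenever the two organisms differ.
#'
#' @param f_i binary trait vector of the responder.
#' @param f_j binary trait vector of the partner, same length as \code{f_i}.
#' @return integer vector of length \code{2 * length(f_i)}; if \code{f_i} is
#'   named, partner positions carry the suffix \code{"_p"}.
#' @examples
#' build_composite(c(1, 0), c(0, 1)) # 1 0 0 1
#' @export
build_composite <- function(f_i, f_j) {
  if (length(f_i) != length(f_j)) {
    stop("trait vectors must have equal length")
  }
  if (!all(f_i %in% c(0, 1)) || !all(f_j %in% c(0, 1))) {
    stop("trait vectors must be binary")
  }
  out <- as.integer(c(f_i, f_j))
  if (!is.null(names(f_i))) {
    names(out) <- c(names(f_i), paste0(names(f_j), "_p"))
  }
  out
}

#' Composite feature names for a trait universe
#'
#' Responder-half features keep the trait name; partner-half features carry
#' the suffix \code{"_p"}, the convention used in importance and contribution
#' reports.
#'
#' @param feature_names trait names (length n).
#' @return character vector of length 2n.
#' @export
composite_feature_names <- function(feature_names) {
  c(feature_names, paste0(feature_names, "_p"))
}

#' Jaccard distance between two binary trait vectors
#'
#' \code{1 - |intersection| / |union|} over positions set to 1. Used as the
#' naive single-score baseline classifier: similar trait profiles (small
#' distance) suggest overlapping nutrient requirements, hence competition.
#'
#' @param f_i,f_j binary vectors of equal length, not both all-zero.
#' @return a number in \code{[0, 1]}.
#' @examples
#' jaccard_distance(c(1, 1, 0, 1), c(1, 0, 0, 1)) # 1/3
#' @export
jaccard_distance <- function(f_i, f_j) {
  if (length(f_i) != length(f_j)) stop("trait vectors must have equal length")
  a <- f_i != 0
  b <- f_j != 0
  u <- sum(a | b)
  if (u == 0L) stop("Jaccard distance undefined: both vectors are all-zero")
  1 - sum(a & b) / u
}
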