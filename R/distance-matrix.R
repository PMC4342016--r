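#' Validate and canonicalize a species distance matrix
#'
#' Distance matrices are plain base matrices with identical row and column
#' labels, a zero diagonal, symmetric non-negative entries. All matrices in
#' the package are emitted with lexicographically sorted labels so that file
#' diffs are reproducible.
#'
#' @param x square numeric matrix with dimnames.
#' @param sort_labels reorder rows/columns into lexicographic label order.
#' @return the validated matrix (invisibly the same object).
#' @export
as_distance_matrix <- function(x, sort_labels = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix.")
  }
  labs <- rownames(x)
  if (is.null(labs) || is.null(colnames(x)) || !identical(labs, colnames(x))) {
    abort("`x` must carry identical row and column labels.")
  }
  if (anyDuplicated(labs)) {
    abort(paste0("Duplicate labels: ",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  }
  if (any(x < 0)) abort("Distances must be non-negative.")
  if (any(abs(diag(x)) > 1e-12)) abort("Diagonal must be zero.")
  if (max(abs(x - t(x))) > 1e-8) abort("Matrix must be symmetric.")
  x <- (x + t(x)) / 2
  diag(x) <- 0
  if (sort_labels) {
    ord <- order(labs)
    x <- x[ord, ord, drop = FALSE]
  }
  x
}

#' Unit (taxonomic) distance matrix
#'
#' The taxonomic facet treats every pair of distinct species as maximally
#' dissimilar: d_ij = 1 for i != j, 0 on the diagonal. With this matrix Rao's
#' quadratic entropy reduces to the Gini-Simpson index 1 - sum(p^2).
#'
#' @param species character vector of species labels.
#' @return labelled distance matrix.
#' @export
#' @examples
#' taxonomic_distances(c("A", "B", "C"))
taxonomic_distances <- function(species) {
  species <- as.character(species)
  if (length(species) < 1) abort("Need at least one species.")
  if (anyDuplicated(species)) abort("Species labels must be unique.")
  n <- length(species)
  d <- matrix(1, n, n, dimnames = list(species, species))
  diag(d) <- 0
  as_distance_matrix(d)
}

#' Read / write a labelled distance matrix as CSV
#'
#' First column and header row hold the species labels.
#'
#' @param path file path.
#' @rdname distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as_distance_matrix(as.matrix(df))
}

#' @param d distance matrix.
#' @rdname distance_csv
#' @export
write_distance_csv <- function(d, path) {
  d <- as_distance_matrix(d)
  write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}
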