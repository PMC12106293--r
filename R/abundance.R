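#' Sample-by-feature abundance matrix
#'
#' The basic container for one omic layer: a numeric samples x features
#' matrix whose `NA` cells are the missingness mask, tagged with the omic
#' ("protein" or "metabolite") and the measurement scale ("raw" positive
#' abundances, or "log2").
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   row and column names; `NA` marks missing cells.
#' @param omic "protein" or "metabolite".
#' @param scale "raw" or "log2".
#' @return an `AbundanceMatrix` object.
#' @export
abundance_matrix <- function(values, omic = c("protein", "metabolite"),
                             scale = c("raw", "log2")) {
  omic <- match.arg(omic)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample (row) and feature (column) names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids")
  structure(list(values = values, omic = omic, scale = scale),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix [%s, %s]: %d samples x %d features, %.1f%% missing\n",
              x$omic, x$scale, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' Sample identifiers of an abundance matrix
#' @param m an `AbundanceMatrix`.
#' @return character vector.
#' @export
sample_ids <- function(m) rownames(m$values)

#' Feature identifiers of an abundance matrix
#' @param m an `AbundanceMatrix`.
#' @return character vector.
#' @export
feature_ids <- function(m) colnames(m$values)

#' Missingness mask of an abundance matrix
#' @param m an `AbundanceMatrix`.
#' @return logical matrix, TRUE = missing.
#' @export
missing_mask <- function(m) is.na(m$values)

replace_values <- function(m, values) {
  m$values <- values
  m
}

subset_samples <- function(m, keep) {
  m$values <- m$values[keep, , drop = FALSE]
  m
}

subset_features <- function(m, keep) {
  m$values <- m$values[, keep, drop = FALSE]
  m
}

#' Write an abundance matrix as TSV
#'
#' Rows are samples, the header holds feature ids, the first column is
#' `sample_id`; missing cells are written as `NA`.
#'
#' @param m an `AbundanceMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' @param path TSV written by [write_abundance_tsv()] (first column
#'   `sample_id`, empty cells or `NA` read as missing).
#' @param omic omic tag of the layer.
#' @param scale measurement scale flag.
#' @return an `AbundanceMatrix`.
#' @export
read_abundance_tsv <- function(path, omic, scale = "raw") {
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  storage.mode(values) <- "double"
  abundance_matrix(values, omic = omic, scale = scale)
}
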