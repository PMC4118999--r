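#' Read and write spot-list tables
#'
#' Spot lists travel as CSV with columns `gel_id, spot_id, x, y, sigma,
#' raw_intensity, normalized_intensity` (and `response` when available).
#'
#' @param spots a `spot_list` (see [detect_spots()]).
#' @param path CSV file path.
#' @return `write_spot_list()` returns `path` invisibly;
#'   `read_spot_list()` returns a `spot_list`.
#' @export
write_spot_list <- function(spots, path) {
  df <- cbind(gel_id = attr(spots, "gel_id") %||% "", as.data.frame(spots))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_list
#' @export
read_spot_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gel_id <- if ("gel_id" %in% names(df)) df$gel_id[1L] %||% "" else ""
  df$gel_id <- NULL
  if (!"response" %in% names(df)) df$response <- NA_real_
  if (!"normalized_intensity" %in% names(df)) df$normalized_intensity <- NA_real_
  new_spot_list(df, gel_id, NULL)
}

#' Read and write gels-by-spots matrices
#'
#' Matrices are stored as CSV with a leading `sample_id` column and one
#' column per spot. Intensity matrices keep `NA` as empty cells.
#'
#' @param mat matrix with row names (sample ids) and column names (spots).
#' @param path CSV file path.
#' @return `write_matrix_csv()` returns `path` invisibly;
#'   `read_matrix_csv()` returns a matrix (integer when all cells are 0/1).
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- if (all(m %in% c(0, 1, NA))) "integer" else "double"
  m
}

#' Read and write sample partitions
#'
#' Partitions are CSV files with columns `sample_id, cluster`.
#'
#' @param partition named vector (sample -> cluster label).
#' @param path CSV file path.
#' @return `write_partition()` returns `path` invisibly;
#'   `read_partition()` returns a named integer vector.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(data.frame(sample_id = names(partition),
                              cluster = as.vector(partition)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$cluster), as.character(df$sample_id))
}

#' Write a dendrogram in Newick format
#'
#' @param dend an `hclust` object, e.g. from [ward_linkage()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  n <- nrow(dend$merge)
  node <- function(code, parent_h) {
    if (code < 0L) {
      sprintf("%s:%g", dend$labels[-code], parent_h)
    } else {
      h <- dend$height[code]
      sprintf("(%s,%s):%g", node(dend$merge[code, 1L], h),
              node(dend$merge[code, 2L], h), parent_h - h)
    }
  }
  root_h <- dend$height[n]
  txt <- sprintf("(%s,%s);", node(dend$merge[n, 1L], root_h),
                 node(dend$merge[n, 2L], root_h))
  writeLines(txt, path)
  invisible(path)
}
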