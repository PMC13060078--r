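#' LC-MS feature table
#'
#' Container for an untargeted LC-MS feature quantification table: one row per
#' chromatographic feature (an m/z - retention time pair) and one column per
#' sample, holding integrated peak areas. A value of 0 means "not detected";
#' after the robust centered log-ratio transform non-detects are carried as
#' `NA` and the `values` field records which scale the matrix is on.
#'
#' @param features data.frame with columns `feature_id` (unique), `mz` (Da,
#'   in (0, 5000)) and `rt` (minutes, >= 0).
#' @param areas numeric matrix, features x samples, non-negative (or `NA`
#'   after transformation). Row order matches `features`.
#' @param sample_ids character vector of unique sample identifiers aligned
#'   with the columns of `areas`.
#' @param values scale of the matrix: raw `"areas"`, `"log"` (pseudocount +
#'   natural log), `"rclr"` or `"residuals"`.
#' @return An object of class `feature_table`.
#' @examples
#' ft <- feature_table(
#'   data.frame(feature_id = c("F1", "F2"), mz = c(200.1, 450.2), rt = c(1.2, 5.5)),
#'   matrix(c(0, 10, 20, 30, 40, 50), nrow = 2, byrow = TRUE),
#'   sample_ids = c("S1", "S2", "S3")
#' )
#' ft
#' @export
feature_table <- function(features, areas, sample_ids, values = "areas") {
  stopifnot(is.data.frame(features))
  if (!all(c("feature_id", "mz", "rt") %in% names(features)))
    stop("`features` needs columns feature_id, mz, rt")
  areas <- as.matrix(areas)
  if (nrow(areas) != nrow(features))
    stop("areas has ", nrow(areas), " rows but features describes ", nrow(features))
  if (length(sample_ids) != ncol(areas))
    stop("sample_ids length ", length(sample_ids), " != ", ncol(areas), " area columns")
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id: ", features$feature_id[duplicated(features$feature_id)][1])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_id: ", sample_ids[duplicated(sample_ids)][1])
  if (values == "areas" && any(areas < 0, na.rm = TRUE)) {
    bad <- which(areas < 0, arr.ind = TRUE)[1, ]
    stop("negative peak area at feature ", features$feature_id[bad[1]],
         ", sample ", sample_ids[bad[2]])
  }
  if (any(features$mz <= 0 | features$mz >= 5000))
    stop("m/z out of range (0, 5000) for feature ",
         features$feature_id[which(features$mz <= 0 | features$mz >= 5000)[1]])
  if (any(features$rt < 0))
    stop("negative retention time for feature ",
         features$feature_id[which(features$rt < 0)[1]])
  values <- match.arg(values, c("areas", "log", "rclr", "residuals"))
  dimnames(areas) <- list(features$feature_id, sample_ids)
  structure(
    list(features = features, areas = areas,
         sample_ids = as.character(sample_ids), values = values),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (values: %s)\n",
              nrow(x$areas), ncol(x$areas), x$values))
  cat(sprintf("  m/z %.4f-%.4f, RT %.2f-%.2f min, %.1f%% non-detected\n",
              min(x$features$mz), max(x$features$mz),
              min(x$features$rt), max(x$features$rt),
              100 * mean(x$areas == 0 | is.na(x$areas))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$areas)

# subset rows (features) by logical/integer index, keeping alignment
ft_subset <- function(x, keep) {
  feature_table(x$features[keep, , drop = FALSE],
                x$areas[keep, , drop = FALSE],
                x$sample_ids, values = x$values)
}

# replace the matrix, recording the new scale
ft_replace <- function(x, areas, values) {
  y <- x
  y$areas <- areas
  dimnames(y$areas) <- dimnames(x$areas)
  y$values <- values
  y
}

# columns that belong to study samples (not blanks), in table order
non_blank_samples <- function(table, metadata) {
  blanks <- metadata$sample_id[metadata$is_blank]
  setdiff(table$sample_ids, blanks)
}
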