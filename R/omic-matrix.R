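#' Construct and validate an omic sample-by-feature matrix
#'
#' The basic data container of the package is a numeric matrix with samples
#' as rows and features (genes, lipids, bacteria, SNPs, ...) as columns.
#' Row names carry sample identifiers and column names carry feature names;
#' both must be unique and every entry must be finite.
#'
#' @param values numeric matrix, samples as rows.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   row names of `values`.
#' @param feature_names character vector of feature names; defaults to the
#'   column names of `values`.
#' @return A validated numeric matrix with dimnames set.
#' @export
omic_matrix <- function(values, sample_ids = rownames(values),
                        feature_names = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_names))
    feature_names <- paste0("F", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(sample_ids),
                           as.character(feature_names))
  validate_omic_matrix(values)
  values
}

#' Validate an omic matrix
#'
#' Checks the container invariants: unique sample ids and feature names,
#' at least 3 samples and 2 features, and all entries finite.
#'
#' @param x numeric matrix with dimnames.
#' @param check_finite require all entries finite (set `FALSE` before
#'   imputation).
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_omic_matrix <- function(x, check_finite = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("omic matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("omic matrix must carry sample ids (rownames) and feature names (colnames)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate feature names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (nrow(x) < 3L) stop("at least 3 samples are required")
  if (ncol(x) < 2L) stop("at least 2 features are required")
  if (check_finite && !all(is.finite(x)))
    stop("omic matrix contains non-finite entries")
  invisible(x)
}

#' Construct sample group labels
#'
#' @param groups character vector of group names, one per sample.
#' @param sample_ids sample identifiers; defaults to `names(groups)`.
#' @param group_order optional ordering of the distinct groups; the first
#'   group is drawn in red, the second in black, in all outputs. Defaults
#'   to order of first appearance.
#' @return Named character vector with a `group_order` attribute.
#' @export
sample_labels <- function(groups, sample_ids = names(groups),
                          group_order = NULL) {
  groups <- as.character(groups)
  if (is.null(sample_ids))
    stop("sample ids are required (as names of 'groups' or explicitly)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in labels")
  names(groups) <- as.character(sample_ids)
  if (is.null(group_order)) group_order <- unique(groups)
  if (!setequal(group_order, unique(groups)))
    stop("'group_order' must list exactly the distinct groups")
  attr(groups, "group_order") <- group_order
  groups
}

group_order <- function(labels) {
  go <- attr(labels, "group_order")
  if (is.null(go)) unique(labels) else go
}

# Check labels against a matrix; returns labels restricted/ordered to samples.
align_labels <- function(x, labels, min_per_group = 2L) {
  if (is.null(names(labels))) stop("labels must be named by sample id")
  missing <- setdiff(names(labels), rownames(x))
  if (length(missing))
    stop("labelled samples absent from matrix: ",
         paste(missing, collapse = ", "))
  unlabelled <- setdiff(rownames(x), names(labels))
  if (length(unlabelled))
    stop("samples without labels: ", paste(unlabelled, collapse = ", "))
  out <- labels[rownames(x)]
  attr(out, "group_order") <- group_order(labels)
  tab <- table(out)
  if (any(tab < min_per_group))
    stop("each group needs at least ", min_per_group, " samples; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  out
}
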