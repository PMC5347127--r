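#' Leave-one-out loadings matrix
#'
#' Repeats the PCA with each sample removed in turn, keeping the loadings
#' of the fixed component, and collects them next to the full-data
#' loadings: a features x (n_samples + 1) matrix whose first column is
#' the full-data fit. Because the sign of a principal component is
#' arbitrary, each column is aligned to the full-data column by flipping
#' it when their inner product is negative; the flips are recorded.
#'
#' @param x omic matrix (already preprocessed).
#' @param pc_index component to track (fixed across iterations).
#' @param centering `"centered"` or `"noncentered"`.
#' @param labels optional sample labels; a removal that would leave a
#'   group with fewer than 2 samples is skipped with a warning.
#' @return Object of class `pccorr_loocv_loadings`: `loadings` (columns
#'   `full`, then one per sample), `flipped` (logical per column),
#'   `skipped` (sample ids), `pc_index`, `centering`.
#' @export
loocv_loadings <- function(x, pc_index = 1L, centering = "centered",
                           labels = NULL) {
  validate_omic_matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("LOOCV needs at least 4 samples")
  if (!is.null(labels)) labels <- align_labels(x, labels)
  full <- fit_pca(x, centering = centering, k = pc_index)
  ref <- full$loadings[, pc_index]
  cols <- matrix(NA_real_, nrow = ncol(x), ncol = n + 1L,
                 dimnames = list(colnames(x), c("full", rownames(x))))
  cols[, 1L] <- ref
  flipped <- logical(n + 1L)
  skipped <- character()
  for (s in seq_len(n)) {
    if (!is.null(labels)) {
      left <- table(labels[-s])
      if (any(left < 2L)) {
        skipped <- c(skipped, rownames(x)[s])
        warning("skipping removal of ", rownames(x)[s],
                ": a group would drop below 2 samples")
        next
      }
    }
    p <- fit_pca(x[-s, , drop = FALSE], centering = centering,
                 k = pc_index)
    v <- p$loadings[, pc_index]
    if (sum(v * ref) < 0) {
      v <- -v
      flipped[s + 1L] <- TRUE
    }
    cols[, s + 1L] <- v
  }
  keep <- !colSums(is.na(cols)) > 0
  structure(list(loadings = cols[, keep, drop = FALSE],
                 flipped = flipped[keep], skipped = skipped,
                 pc_index = as.integer(pc_index), centering = centering),
            class = "pccorr_loocv_loadings")
}

#' Per-iteration PC-corr matrices for LOOCV
#'
#' Processes every loadings column (heuristic normalization + scaling)
#' and builds the PC-corr matrix for the corresponding dataset: the full
#' data for the first column, the data with that sample removed for the
#' others — each iteration's Pearson correlations are computed on its own
#' reduced sample set. Features whose maximum absolute processed loading
#' across all columns falls below the cut-off are excluded up front: by
#' the min-operator bound no edge touching them can reach the cut-off in
#' any iteration, so the filter only saves time and cannot change any
#' thresholded network.
#'
#' @param x omic matrix used for the LOOCV (same one passed to
#'   [loocv_loadings()]).
#' @param coll a `pccorr_loocv_loadings` collection.
#' @param cutoff the cut-off that will be applied downstream (drives the
#'   speed filter). Use `0` to disable filtering.
#' @return List: `matrices` (one `pccorr_matrix` per column, named as the
#'   columns), `kept` (features retained by the filter).
#' @export
loocv_pccorr_matrices <- function(x, coll, cutoff) {
  stopifnot(inherits(coll, "pccorr_loocv_loadings"))
  L <- coll$loadings
  vnew <- apply(L, 2L, function(v) process_loadings(v)$v_new)
  kept <- rownames(L)[apply(abs(vnew), 1L, max) >= cutoff]
  if (length(kept) < 2L)
    stop("fewer than 2 features pass the loading speed filter at cut-off ",
         cutoff)
  mats <- vector("list", ncol(L))
  names(mats) <- colnames(L)
  for (j in seq_len(ncol(L))) {
    rows <- if (colnames(L)[j] == "full") rownames(x)
            else setdiff(rownames(x), colnames(L)[j])
    nl <- process_loadings(L[, j])
    nl$v_raw <- nl$v_raw[kept]
    nl$v_star <- nl$v_star[kept]
    nl$v_new <- nl$v_new[kept]
    cc <- pearson_matrix(x[rows, kept, drop = FALSE])
    mats[[j]] <- build_pccorr_matrix(nl = nl, corr = cc)
  }
  list(matrices = mats, kept = kept)
}

#' Combine LOOCV PC-corr matrices
#'
#' Entrywise aggregation of the per-iteration matrices by average, median
#' or minimum absolute value. For `min_abs` the magnitude is the exact
#' minimum of the per-iteration magnitudes — so thresholding the combined
#' matrix yields the intersection of the per-iteration networks over
#' sign-stable edges — and the sign is taken from the first (full-data)
#' matrix; entries whose sign varies across iterations are flagged
#' sign-unstable.
#'
#' @param mats list of `pccorr_matrix` objects over identical features.
#' @param method `"average"`, `"median"` or `"min_abs"`.
#' @return A `pccorr_matrix` with the combined weights (v_new from the
#'   first matrix); for `min_abs`, a logical `sign_unstable` matrix is
#'   attached.
#' @export
combine_networks <- function(mats, method = c("average", "median",
                                              "min_abs")) {
  method <- match.arg(method)
  if (length(mats) < 2L) stop("need at least 2 matrices to combine")
  feats <- colnames(mats[[1L]]$weights)
  for (m in mats)
    if (!identical(colnames(m$weights), feats))
      stop("matrices have mismatched feature sets")
  arr <- simplify2array(lapply(mats, function(m) m$weights))
  w <- switch(method,
    average = apply(arr, c(1L, 2L), mean),
    median = apply(arr, c(1L, 2L), stats::median),
    min_abs = {
      mag <- apply(abs(arr), c(1L, 2L), min)
      sign(mats[[1L]]$weights) * mag
    })
  dimnames(w) <- dimnames(mats[[1L]]$weights)
  out <- structure(list(weights = w, corr = NULL,
                        v_new = mats[[1L]]$v_new,
                        method = method),
                   class = "pccorr_matrix")
  if (method == "min_abs") {
    sgn <- sign(arr)
    unstable <- apply(sgn, c(1L, 2L), function(s) {
      s <- s[s != 0]
      length(s) > 0L && any(s != s[1L])
    })
    dimnames(unstable) <- dimnames(w)
    out$sign_unstable <- unstable
  }
  out
}

#' LOOCV robustness report
#'
#' Thresholds the original and the three combined matrices at the same
#' cut-off, compares the four networks by node and edge membership, and
#' reports the fraction of the original network's edges retained in the
#' minimum-absolute-value (intersection) network as the robustness score.
#'
#' @param original the full-data `pccorr_matrix`.
#' @param combined named list with elements `average`, `median`,
#'   `min_abs` (as from [combine_networks()]).
#' @param cutoff the cut-off adopted for the original PC-corr network.
#' @param labels,data optional, for node group attribution.
#' @return List: `venn` (4-way membership counts), `retention`
#'   (edge-retention fraction, `NA` for an empty original network),
#'   `networks` (the four thresholded networks), `n_sign_unstable`.
#' @export
loocv_report <- function(original, combined, cutoff, labels = NULL,
                         data = NULL) {
  nets <- list(
    original = suppressWarnings(
      threshold_network(original, cutoff, labels, data,
                        metadata = list(method = "pccorr"))),
    average = suppressWarnings(
      threshold_network(combined$average, cutoff, labels, data,
                        metadata = list(method = "loocv_average"))),
    median = suppressWarnings(
      threshold_network(combined$median, cutoff, labels, data,
                        metadata = list(method = "loocv_median"))),
    min_abs = suppressWarnings(
      threshold_network(combined$min_abs, cutoff, labels, data,
                        metadata = list(method = "loocv_min_abs"))))
  venn <- venn_compare(original = nets$original, average = nets$average,
                       median = nets$median, min_abs = nets$min_abs)
  orig_edges <- edge_keys(nets$original$edges)
  retention <- if (length(orig_edges) == 0L) NA_real_ else
    mean(orig_edges %in% edge_keys(nets$min_abs$edges))
  n_unstable <- if (!is.null(combined$min_abs$sign_unstable))
    sum(combined$min_abs$sign_unstable[upper.tri(
      combined$min_abs$sign_unstable)]) else NA_integer_
  list(venn = venn, retention = retention, networks = nets,
       n_sign_unstable = n_unstable)
}

#' Run the full LOOCV robustness analysis
#'
#' Convenience wrapper chaining [loocv_loadings()],
#' [loocv_pccorr_matrices()], [combine_networks()] (all three methods)
#' and [loocv_report()].
#'
#' @inheritParams loocv_loadings
#' @param cutoff cut-off for the thresholded networks and speed filter.
#' @return The [loocv_report()] list, plus `flips` and `skipped`.
#' @export
run_loocv <- function(x, pc_index = 1L, centering = "centered",
                      cutoff = 0.6, labels = NULL) {
  coll <- loocv_loadings(x, pc_index, centering, labels)
  lm <- loocv_pccorr_matrices(x, coll, cutoff)
  combined <- list(average = combine_networks(lm$matrices, "average"),
                   median = combine_networks(lm$matrices, "median"),
                   min_abs = combine_networks(lm$matrices, "min_abs"))
  rep <- loocv_report(lm$matrices[[1L]], combined, cutoff, labels, x)
  rep$flips <- sum(coll$flipped)
  rep$skipped <- coll$skipped
  rep
}
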