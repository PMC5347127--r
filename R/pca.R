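#' Preprocess an omic matrix before PCA
#'
#' @param x omic matrix (samples as rows).
#' @param method `"none"`, `"zscore_features"` (each feature to mean 0,
#'   sd 1 with the n-1 denominator; constant features are left at 0 with a
#'   warning) or `"log_shift"` (`log10(x + shift)`).
#' @param shift additive constant for `log_shift`; every shifted entry must
#'   be positive.
#' @return The preprocessed matrix, same shape and dimnames.
#' @export
preprocess_matrix <- function(x, method = c("none", "zscore_features",
                                            "log_shift"), shift = 1) {
  method <- match.arg(method)
  validate_omic_matrix(x)
  out <- switch(method,
    none = x,
    zscore_features = {
      mu <- colMeans(x)
      sdv <- apply(x, 2L, stats::sd)
      const <- sdv == 0
      if (any(const)) {
        warning("constant features set to 0 under zscore: ",
                paste(colnames(x)[const], collapse = ", "))
        sdv[const] <- 1
      }
      sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
    },
    log_shift = {
      if (min(x) + shift <= 0)
        stop("log_shift requires every entry + shift to be positive")
      log10(x + shift)
    })
  if (!all(is.finite(out)))
    stop("non-finite values after preprocessing")
  out
}

#' Mode-impute an integer-coded matrix
#'
#' Genotype matrices are commonly coded 0 (homozygous wild-type),
#' 1 (heterozygous), 2 (homozygous variant) with a designated code for
#' missing calls. Each missing entry is replaced by the most frequent
#' observed code of its own feature column; ties are broken toward the
#' smallest code.
#'
#' @param x integer-coded matrix (samples as rows).
#' @param missing_code the code marking a missing call (default 3). `NA`
#'   entries are treated as missing too.
#' @return The matrix with missing entries imputed.
#' @export
impute_mode <- function(x, missing_code = 3L) {
  validate_omic_matrix(x, check_finite = FALSE)
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    miss <- is.na(col) | col == missing_code
    if (!any(miss)) next
    obs <- col[!miss]
    if (length(obs) == 0L)
      stop("feature entirely missing: ", colnames(x)[j])
    tab <- table(obs)
    modes <- as.numeric(names(tab)[tab == max(tab)])
    x[miss, j] <- min(modes)
  }
  x
}

#' Principal component analysis, centered or non-centered
#'
#' Thin wrapper around the singular value decomposition: loadings are the
#' right singular vectors of the (optionally column-centered) data matrix,
#' so every loading column has unit Euclidean norm, and the scores are the
#' data (centered if requested) projected onto them. Non-centered PCA
#' (SVD of the raw matrix) is useful when the cluster structure lives in
#' the overall signal magnitude rather than around the mean.
#'
#' The sign of each component is fixed by flipping the loading column so
#' that its entry of largest magnitude is positive; eigenvector sign is
#' otherwise arbitrary and downstream outputs need determinism.
#'
#' @param x omic matrix (samples as rows).
#' @param centering `"centered"` or `"noncentered"`.
#' @param k number of components; defaults to `min(dim(x))`.
#' @return Object of class `pccorr_pca`: list with `scores`
#'   (samples x k), `loadings` (features x k), `explained_variance`
#'   (fractions), `centering`, and `rank` (components beyond the matrix
#'   rank are flagged by `rank`).
#' @export
fit_pca <- function(x, centering = c("centered", "noncentered"), k = NULL) {
  centering <- match.arg(centering)
  validate_omic_matrix(x)
  kmax <- min(dim(x))
  if (is.null(k)) k <- kmax
  if (k > kmax) stop("k must be <= min(n_samples, n_features)")
  xc <- if (centering == "centered") scale(x, center = TRUE, scale = FALSE)
        else x
  sv <- svd(xc, nu = 0, nv = k)
  # deterministic sign: largest-|loading| entry positive
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1L))
  sv$v[, flip] <- -sv$v[, flip]
  loadings <- sv$v
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(k))
  scores <- xc %*% loadings
  rownames(scores) <- rownames(x)
  d2 <- sv$d^2
  ev <- if (sum(d2) > 0) (d2 / sum(d2))[seq_len(k)] else rep(0, k)
  tol <- max(dim(xc)) * .Machine$double.eps * max(sv$d)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev, centering = centering,
                 rank = sum(sv$d > tol), k = k),
            class = "pccorr_pca")
}

#' @export
print.pccorr_pca <- function(x, ...) {
  cat(sprintf("PCA (%s): %d components, top explained fractions %s\n",
              x$centering, x$k,
              paste(signif(utils::head(x$explained_variance, 3), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Test group discrimination along one principal component
#'
#' For two groups, a two-sided Mann-Whitney (Wilcoxon rank-sum) test on
#' the PC scores; the exact distribution is used whenever possible (small
#' samples, no ties), otherwise the normal approximation with tie
#' correction. With three or more groups a Kruskal-Wallis test is used.
#'
#' @param pca a `pccorr_pca` fit.
#' @param labels sample labels (see [sample_labels()]).
#' @param pc_index which component to test (1-based).
#' @return List of class `pccorr_discrimination`: `pc_index`, `centering`,
#'   `p_value`, `direction` (group -> `"high"`/`"low"` by median score).
#' @export
score_discrimination <- function(pca, labels, pc_index = 1L) {
  stopifnot(inherits(pca, "pccorr_pca"))
  if (pc_index < 1L || pc_index > ncol(pca$scores))
    stop("pc_index out of range")
  sc <- pca$scores[, pc_index]
  labels <- align_labels(pca_matrix_stub(pca), labels)
  go <- group_order(labels)
  groups <- split(sc, factor(labels, levels = go))
  if (length(go) == 2L) {
    p <- suppressWarnings(
      stats::wilcox.test(groups[[1L]], groups[[2L]],
                         alternative = "two.sided")$p.value)
  } else {
    p <- stats::kruskal.test(sc, factor(labels))$p.value
  }
  med <- vapply(groups, stats::median, numeric(1L))
  extremes <- c(which.max(med), which.min(med))
  direction <- ifelse(seq_along(go) == which.max(med), "high", "low")
  names(direction) <- go
  structure(list(pc_index = as.integer(pc_index),
                 centering = pca$centering, p_value = p,
                 direction = direction),
            class = "pccorr_discrimination")
}

# minimal matrix stand-in so align_labels can check sample ids on scores
pca_matrix_stub <- function(pca) {
  m <- pca$scores
  if (is.null(colnames(m))) colnames(m) <- paste0("PC", seq_len(ncol(m)))
  m
}

#' Select the discriminative principal component
#'
#' Evaluates the requested centerings for components `1..max_pc`, scoring
#' each with [score_discrimination()], and returns the most significant
#' candidate (ties prefer centered PCA, then the lower PC index).
#' Significance of the winner is judged after Bonferroni correction over
#' the number of candidates evaluated, so that scanning several components
#' does not inflate the chance of declaring a discrimination in pure
#' noise. If even the best candidate is not significant the result carries
#' `significant = FALSE`: without a sample discrimination along some
#' component the PC-corr construction has nothing to explain.
#'
#' @param x omic matrix.
#' @param labels sample labels.
#' @param max_pc highest component index scanned (default 3).
#' @param alpha significance level on the corrected p-value (default 0.05).
#' @param centering `"auto"` (evaluate both), `"centered"` or
#'   `"noncentered"`.
#' @return A `pccorr_discrimination` augmented with `p_adjusted`,
#'   `n_candidates`, `significant`, and the winning `pca` fit.
#' @export
select_discriminative_pc <- function(x, labels, max_pc = 3L, alpha = 0.05,
                                     centering = "auto") {
  validate_omic_matrix(x)
  labels <- align_labels(x, labels)
  centerings <- if (identical(centering, "auto"))
    c("centered", "noncentered") else match.arg(centering,
                                                c("centered", "noncentered"))
  max_pc <- min(max_pc, min(dim(x)))
  best <- NULL
  n_cand <- 0L
  for (ctr in centerings) {
    pca <- fit_pca(x, centering = ctr, k = max_pc)
    for (pc in seq_len(max_pc)) {
      d <- score_discrimination(pca, labels, pc)
      n_cand <- n_cand + 1L
      better <- is.null(best) || d$p_value < best$p_value ||
        (d$p_value == best$p_value && ctr == "centered" &&
           best$centering != "centered") ||
        (d$p_value == best$p_value && ctr == best$centering &&
           pc < best$pc_index)
      if (better) { best <- d; best$pca <- pca }
    }
  }
  best$n_candidates <- n_cand
  best$p_adjusted <- min(1, best$p_value * n_cand)
  best$significant <- best$p_adjusted <= alpha
  best$alpha <- alpha
  best
}

#' @export
print.pccorr_discrimination <- function(x, ...) {
  cat(sprintf("PC%d (%s): Mann-Whitney p = %.4g", x$pc_index, x$centering,
              x$p_value))
  if (!is.null(x$p_adjusted))
    cat(sprintf(" (corrected %.4g over %d candidates; %s)",
                x$p_adjusted, x$n_candidates,
                if (isTRUE(x$significant)) "significant"
                else "not significant"))
  cat("\n")
  invisible(x)
}
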