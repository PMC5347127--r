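#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction, clipped to [0, 1].
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and names.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("p-values contain NA")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Univariate feature screen (Mann-Whitney + BH)
#'
#' Tests every feature for a difference between the two sample groups with
#' a two-sided Mann-Whitney test, adjusts the p-values with
#' Benjamini-Hochberg, and flags features significant at adjusted
#' p <= `alpha`. This is the feature-selection step of the P-value and
#' P-value MI baseline networks; it is univariate by construction, which
#' is exactly what the multivariate PC-corr construction is compared
#' against.
#'
#' @param x omic matrix (preprocessed the same way as for PCA).
#' @param labels two-group sample labels.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return Data frame (class `pccorr_screen`) with one row per feature:
#'   `feature`, `p_raw`, `p_adjusted`, `significant`, `median_diff`
#'   (first group minus second, in label order).
#' @export
feature_screen <- function(x, labels, alpha = 0.05) {
  validate_omic_matrix(x)
  labels <- align_labels(x, labels)
  go <- group_order(labels)
  if (length(go) != 2L)
    stop("the feature screen requires exactly 2 groups")
  a <- labels == go[1L]
  b <- labels == go[2L]
  p_raw <- vapply(seq_len(ncol(x)), function(j)
    suppressWarnings(stats::wilcox.test(x[a, j], x[b, j],
                                        alternative = "two.sided")$p.value),
    numeric(1L))
  med_diff <- vapply(seq_len(ncol(x)), function(j)
    stats::median(x[a, j]) - stats::median(x[b, j]), numeric(1L))
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(feature = colnames(x), p_raw = p_raw,
                    p_adjusted = p_adj, significant = p_adj <= alpha,
                    median_diff = med_diff, stringsAsFactors = FALSE)
  attr(out, "group_order") <- go
  class(out) <- c("pccorr_screen", class(out))
  out
}

# node table for the screen-based networks: colour by median difference
screen_nodes <- function(edges, screen, go) {
  keep <- sort(unique(c(edges$source, edges$target)))
  rows <- screen[match(keep, screen$feature), ]
  md <- rows$median_diff
  intensity <- if (all(md == 0)) rep(0, length(md)) else abs(md) / max(abs(md))
  palette <- ifelse(md >= 0, "red", "black")
  deg <- table(c(edges$source, edges$target))
  data.frame(feature = keep, loading = md,
             group = ifelse(md >= 0, go[1L], go[2L]),
             color = mapply(node_color, palette, intensity,
                            USE.NAMES = FALSE),
             degree = as.integer(deg[keep]), stringsAsFactors = FALSE)
}

no_network <- function(reason, method, cutoff) {
  new_network(empty_edges(), empty_nodes(),
              metadata = list(cutoff = cutoff, method = method),
              exists = FALSE, reason = reason)
}

#' The P-value correlation network
#'
#' Pearson correlation network restricted to the features that pass the
#' univariate screen ([feature_screen()]); edges keep pairs with
#' `|r| >= cutoff` and singletons are removed. Nodes carry the difference
#' of group medians (the quantity the Mann-Whitney test ranks). When
#' fewer than two features are significant the network does not exist;
#' this is returned as a result object (with `exists = FALSE`), not an
#' error, because it is a legitimate scientific outcome.
#'
#' @param x omic matrix.
#' @param labels two-group sample labels.
#' @param cutoff correlation threshold in (0, 1].
#' @param screen optional precomputed [feature_screen()] result.
#' @param alpha screen significance level.
#' @return A `pccorr_network`; check `$exists`.
#' @export
build_pvalue_network <- function(x, labels, cutoff, screen = NULL,
                                 alpha = 0.05) {
  if (is.null(screen)) screen <- feature_screen(x, labels, alpha)
  go <- attr(screen, "group_order")
  sig <- screen$feature[screen$significant]
  if (length(sig) < 2L)
    return(no_network(sprintf(
      "only %d significant feature(s) after BH; no P-value network",
      length(sig)), "pvalue", cutoff))
  cc <- pearson_matrix(x[, sig, drop = FALSE])
  net <- suppressWarnings(
    threshold_network(cc, cutoff, metadata = list(method = "pvalue")))
  if (nrow(net$edges) > 0L)
    net$nodes <- screen_nodes(net$edges, screen, go)
  net
}

#' Find the cut-off matching a target node count
#'
#' For comparing a large baseline network with a PC-corr network, the
#' baseline is also cut at the level that leaves approximately the same
#' number of nodes. Sweeps cut-offs on a 0.01 grid and returns the
#' largest cut-off whose surviving node count is at least `target_n` and
#' closest to it (ties to the higher cut-off).
#'
#' @param w a `pccorr_matrix` or symmetric weight matrix.
#' @param target_n desired node count.
#' @param grid cut-off grid to sweep (default `seq(0.01, 1, 0.01)`).
#' @return The selected cut-off (scalar).
#' @export
match_node_count_cutoff <- function(w, target_n,
                                    grid = seq(0.01, 1, by = 0.01)) {
  if (inherits(w, "pccorr_matrix")) w <- w$weights
  if (target_n > ncol(w))
    stop("target_n exceeds the number of features")
  grid <- round(grid, 10)
  counts <- vapply(grid, function(co) {
    keep <- abs(w) >= co - 1e-9
    diag(keep) <- FALSE
    sum(rowSums(keep) > 0)
  }, numeric(1L))
  ok <- which(counts >= target_n)
  if (length(ok) == 0L) return(grid[1L])
  best <- ok[counts[ok] == min(counts[ok])]
  grid[max(best)]
}

#' Gaussian mutual information from a Pearson correlation
#'
#' The mutual information of a bivariate normal with correlation `r`:
#' `MI = -log(1 - r^2) / 2` (nats). `|r| = 1` would be infinite and is
#' capped at the value for `r = 0.999999`, with a warning.
#'
#' @param r correlation(s) in [-1, 1].
#' @return Non-negative mutual information value(s).
#' @export
gaussian_mi <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  capped <- abs(r) >= 1
  if (any(capped)) {
    warning("|r| = 1 capped at 0.999999 for MI")
    r[capped] <- sign(r[capped]) * 0.999999
  }
  -0.5 * log(1 - r^2)
}

#' Context likelihood of relatedness (CLR) transform
#'
#' Converts a mutual-information matrix to association scores that are
#' high when a pair's MI stands out against the background of both
#' features' MI profiles: per row, `z_i = max(0, (mi_ij - mean_i) / sd_i)`
#' (diagonal excluded; `sd_i = 0` gives `z_i = 0`), and
#' `CLR_ij = sqrt(z_i^2 + z_j^2)`.
#'
#' @param mi symmetric non-negative MI matrix with zero diagonal.
#' @return Symmetric CLR score matrix, zero diagonal.
#' @export
clr_scores <- function(mi) {
  if (!isSymmetric(unname(mi), tol = 1e-8)) stop("MI matrix must be symmetric")
  n <- ncol(mi)
  z <- matrix(0, n, n, dimnames = dimnames(mi))
  for (i in seq_len(n)) {
    row <- mi[i, -i]
    mu <- mean(row)
    sdv <- stats::sd(row)
    if (is.na(sdv) || sdv == 0) next
    z[i, -i] <- pmax(0, (row - mu) / sdv)
  }
  out <- sqrt(z^2 + t(z)^2)
  diag(out) <- 0
  out
}

#' The P-value MI network (CLR over Gaussian MI)
#'
#' Mutual-information network restricted to the univariately significant
#' features: Gaussian MI is computed from the pairwise Pearson
#' correlations, transformed with CLR, and the CLR scores are min-max
#' rescaled onto [0, 1] so the same cut-off scale as the PC-corr and
#' P-value networks applies. Node attributes follow the P-value network
#' conventions.
#'
#' @inheritParams build_pvalue_network
#' @return A `pccorr_network`; check `$exists`.
#' @export
build_pvalue_mi_network <- function(x, labels, cutoff, screen = NULL,
                                    alpha = 0.05) {
  if (is.null(screen)) screen <- feature_screen(x, labels, alpha)
  go <- attr(screen, "group_order")
  sig <- screen$feature[screen$significant]
  if (length(sig) < 2L)
    return(no_network(sprintf(
      "only %d significant feature(s) after BH; no P-value MI network",
      length(sig)), "pvalue_mi", cutoff))
  cc <- pearson_matrix(x[, sig, drop = FALSE])
  diag(cc) <- 0
  mi <- suppressWarnings(gaussian_mi(cc))
  clr <- clr_scores(mi)
  rng <- range(clr[upper.tri(clr)])
  scaled <- if (diff(rng) > 0) (clr - rng[1L]) / diff(rng) else clr * 0
  diag(scaled) <- 0
  net <- suppressWarnings(
    threshold_network(scaled, cutoff, metadata = list(method = "pvalue_mi")))
  if (nrow(net$edges) > 0L)
    net$nodes <- screen_nodes(net$edges, screen, go)
  net
}

#' Venn comparison of networks
#'
#' Set comparison of node names and unordered edge pairs across two or
#' more networks sharing a feature namespace.
#'
#' @param ... two to four `pccorr_network` objects (a non-existing network
#'   contributes empty sets). Named arguments name the networks.
#' @return For two networks, a list with `nodes` and `edges`, each a
#'   named count vector `(only_A, shared, only_B)`. For more, counts of
#'   every membership pattern (e.g. `"1101"`) plus per-network totals.
#' @export
venn_compare <- function(...) {
  nets <- list(...)
  if (length(nets) < 2L) stop("need at least two networks")
  nm <- names(nets)
  if (is.null(nm) || any(nm == ""))
    nm <- LETTERS[seq_along(nets)]
  node_sets <- lapply(nets, function(n) unique(n$nodes$feature))
  edge_sets <- lapply(nets, function(n) unique(edge_keys(n$edges)))
  names(node_sets) <- names(edge_sets) <- nm
  if (length(nets) == 2L) {
    pair <- function(s) c(only_A = length(setdiff(s[[1]], s[[2]])),
                          shared = length(intersect(s[[1]], s[[2]])),
                          only_B = length(setdiff(s[[2]], s[[1]])))
    return(list(nodes = pair(node_sets), edges = pair(edge_sets)))
  }
  pattern_counts <- function(sets) {
    all_items <- unique(unlist(sets))
    if (length(all_items) == 0L) return(stats::setNames(integer(), character()))
    memb <- vapply(sets, function(s) all_items %in% s, logical(length(all_items)))
    if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1L)
    pat <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
    table(pat)
  }
  list(networks = nm,
       nodes = pattern_counts(node_sets),
       edges = pattern_counts(edge_sets),
       node_totals = lengths(node_sets),
       edge_totals = lengths(edge_sets))
}
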