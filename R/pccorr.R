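#' Normalize PC loadings with the lognormal-inspired heuristic
#'
#' Raw PC loadings are unit-norm as a vector (the squared loadings of a
#' component sum to one), so their individual magnitudes shrink with the
#' number of features and their distribution is not comparable with
#' Pearson correlation coefficients. The heuristic maps each loading
#' through a sign-preserving logarithm,
#' `V*(i) = sign(V(i)) * log10(1 + |V(i)| / mean(|V|))`,
#' which reduces skewness and stabilizes the spread; the scaling factor is
#' tuned automatically from the average absolute loading.
#'
#' @param v_raw numeric vector of loadings for one component (typically a
#'   column of `fit_pca(x)$loadings`), optionally named by feature.
#' @return Object of class `pccorr_loadings` with fields `v_raw`,
#'   `v_star`, `mean_abs` (and `v_new = NULL` until [scale_loadings()] is
#'   applied).
#' @seealso [scale_loadings()], [process_loadings()]
#' @export
normalize_loadings <- function(v_raw) {
  v_raw <- stats::setNames(as.numeric(v_raw), names(v_raw))
  if (length(v_raw) == 0L || !all(is.finite(v_raw)))
    stop("loadings must be a finite numeric vector")
  mean_abs <- mean(abs(v_raw))
  if (mean_abs == 0) stop("all loadings are zero; nothing to normalize")
  v_star <- sign(v_raw) * log10(1 + abs(v_raw) / mean_abs)
  structure(list(v_raw = v_raw, v_star = v_star, v_new = NULL,
                 mean_abs = mean_abs),
            class = "pccorr_loadings")
}

#' Scale normalized loadings onto the interval [-1, 1]
#'
#' Divides the heuristic-normalized loadings by their maximum absolute
#' value, so the most extreme feature gets +/-1 and signs are preserved:
#' `Vnew(i) = V*(i) / max(|V*|)`.
#'
#' @param nl a `pccorr_loadings` object from [normalize_loadings()].
#' @return The same object with `v_new` filled in.
#' @export
scale_loadings <- function(nl) {
  stopifnot(inherits(nl, "pccorr_loadings"))
  m <- max(abs(nl$v_star))
  nl$v_new <- nl$v_star / m
  nl
}

#' Normalize and scale loadings in one step
#'
#' @param v_raw numeric vector of loadings for one component.
#' @return A `pccorr_loadings` object with `v_new` populated.
#' @export
process_loadings <- function(v_raw) scale_loadings(normalize_loadings(v_raw))

#' Pairwise Pearson correlation between features
#'
#' @param x omic matrix (samples as rows). Constant features get
#'   correlation 0 to every other feature (with a warning) rather than
#'   `NA`: real omic tables contain constant columns and they simply
#'   cannot carry edges.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(x) {
  validate_omic_matrix(x)
  sdv <- apply(x, 2L, stats::sd)
  const <- sdv == 0
  if (any(const))
    warning("constant features get correlation 0: ",
            paste(colnames(x)[const], collapse = ", "))
  cc <- suppressWarnings(stats::cor(x))
  cc[const, ] <- 0
  cc[, const] <- 0
  diag(cc) <- 1
  cc
}

#' The PC-corr edge value
#'
#' Fuses the Pearson correlation of two features with their processed
#' loadings through a minimum operator:
#' `sign(c_ij) * min(|c_ij|, |v_i|, |v_j|)`.
#' The magnitude is high only when correlation and both loadings are
#' simultaneously high (an AND gate); the sign is the correlation's.
#'
#' @param c_ij Pearson correlation(s), in `[-1, 1]`.
#' @param v_i,v_j processed loadings of the two features, in `[-1, 1]`.
#' @return The signed edge value(s); vectorized over all three arguments.
#' @export
pccorr_edge <- function(c_ij, v_i, v_j) {
  if (any(abs(c(c_ij, v_i, v_j)) > 1 + 1e-12))
    stop("all inputs must lie in [-1, 1]")
  sign(c_ij) * pmin(abs(c_ij), abs(v_i), abs(v_j))
}

#' Build the full PC-corr weighted matrix
#'
#' @param x omic matrix used for the pairwise Pearson correlations;
#'   ignored if `corr` is supplied directly.
#' @param nl processed loadings ([process_loadings()]) for the chosen
#'   component; feature count (and names, when present) must match.
#' @param corr optional precomputed correlation matrix.
#' @return Object of class `pccorr_matrix`: `weights` (signed, symmetric,
#'   zero diagonal), `corr`, and `v_new`.
#' @export
build_pccorr_matrix <- function(x = NULL, nl, corr = NULL) {
  stopifnot(inherits(nl, "pccorr_loadings"))
  if (is.null(nl$v_new)) nl <- scale_loadings(nl)
  if (is.null(corr)) {
    if (is.null(x)) stop("supply either 'x' or 'corr'")
    corr <- pearson_matrix(x)
  }
  v <- nl$v_new
  if (length(v) != ncol(corr))
    stop("loadings length (", length(v), ") does not match feature count (",
         ncol(corr), ")")
  if (!is.null(names(v)) && !is.null(colnames(corr)) &&
      !identical(names(v), colnames(corr)))
    stop("feature names of loadings and correlation matrix disagree")
  w <- sign(corr) * pmin(abs(corr), outer(abs(v), abs(v), pmin))
  diag(w) <- 0
  dimnames(w) <- dimnames(corr)
  structure(list(weights = w, corr = corr, v_new = v),
            class = "pccorr_matrix")
}

#' @export
print.pccorr_matrix <- function(x, ...) {
  cat(sprintf("PC-corr matrix: %d features, max |weight| %.3g\n",
              ncol(x$weights), max(abs(x$weights))))
  invisible(x)
}

node_color <- function(palette, intensity) {
  intensity <- pmin(pmax(intensity, 0), 1)
  if (palette == "red")
    grDevices::rgb(1, 1 - intensity, 1 - intensity)
  else
    grDevices::rgb(1 - intensity, 1 - intensity, 1 - intensity)
}

#' Threshold a PC-corr matrix into a network
#'
#' Keeps edges with `|weight| >= cutoff`, removes singleton nodes (no
#' surviving edge), and assembles the edge and node tables. Each node
#' carries its processed loading, a group attribution, a display colour
#' (red-to-white for the first group, black-to-white for the second,
#' linear in `|v_new|`), and its degree (for display sizing).
#'
#' When `labels` and `data` are given, a node is assigned to the group
#' whose samples have the higher median value of that feature; the first
#' group in the label order is the "red" one. Without labels, nodes are
#' grouped by the sign of their loading (positive = red).
#'
#' @param pcc a `pccorr_matrix` (or any symmetric signed weight matrix).
#' @param cutoff edge threshold in (0, 1].
#' @param labels optional sample labels.
#' @param data optional omic matrix for the median-based group
#'   attribution (must be given with `labels`).
#' @param metadata named list merged into the network metadata.
#' @return A `pccorr_network` (possibly empty, with a warning).
#' @export
threshold_network <- function(pcc, cutoff, labels = NULL, data = NULL,
                              metadata = list()) {
  if (cutoff <= 0 || cutoff > 1) stop("cut-off must lie in (0, 1]")
  if (inherits(pcc, "pccorr_matrix")) {
    w <- pcc$weights
    v <- pcc$v_new
  } else {
    w <- pcc
    v <- rep(NA_real_, ncol(w))
    names(v) <- colnames(w)
  }
  feats <- colnames(w)
  if (is.null(feats)) feats <- paste0("F", seq_len(ncol(w)))
  idx <- which(abs(w) >= cutoff & upper.tri(w), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no edge survives the cut-off ", cutoff)
    net <- new_network(empty_edges(), empty_nodes(),
                       metadata = c(list(cutoff = cutoff), metadata))
    return(net)
  }
  weight <- w[idx]
  edges <- data.frame(source = pmin(feats[idx[, 1L]], feats[idx[, 2L]]),
                      target = pmax(feats[idx[, 1L]], feats[idx[, 2L]]),
                      weight = weight,
                      sign = ifelse(weight >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  keep <- sort(unique(c(edges$source, edges$target)))
  deg <- table(c(edges$source, edges$target))
  loading <- v[keep]
  if (!is.null(labels) && !is.null(data)) {
    labels <- align_labels(data, labels)
    go <- group_order(labels)
    grp <- vapply(keep, function(f) {
      med <- vapply(go, function(g)
        stats::median(data[labels == g, f]), numeric(1L))
      go[which.max(med)]
    }, character(1L))
    palette <- ifelse(grp == go[1L], "red", "black")
  } else {
    pos <- is.na(loading) | loading >= 0
    grp <- ifelse(is.na(loading), "unassigned",
                  ifelse(loading >= 0, "positive", "negative"))
    palette <- ifelse(pos, "red", "black")
  }
  intensity <- abs(loading)
  intensity[!is.finite(intensity)] <- 1
  color <- mapply(node_color, palette, intensity, USE.NAMES = FALSE)
  nodes <- data.frame(feature = keep, loading = unname(loading),
                      group = unname(grp), color = color,
                      degree = as.integer(deg[keep]),
                      stringsAsFactors = FALSE)
  new_network(edges, nodes, metadata = c(list(cutoff = cutoff), metadata))
}

#' Frustration of a signed discriminative network
#'
#' In a frustration-free PC-corr network, positive edges join nodes whose
#' loadings share a sign (same colour family) and negative edges join
#' nodes of opposite loading sign. An edge is frustrated when it breaks
#' this pattern: a positive edge between opposite-sign nodes, or a
#' negative edge between same-sign nodes.
#'
#' @param net a `pccorr_network` whose node table carries loadings.
#' @return List with `fraction` (frustrated / total edges; 0 for an empty
#'   network by convention) and `frustrated` (the offending edge rows).
#' @export
compute_frustration <- function(net) {
  stopifnot(inherits(net, "pccorr_network"))
  edges <- net$edges
  if (nrow(edges) == 0L)
    return(list(fraction = 0, frustrated = empty_edges(),
                note = "empty network"))
  nsign <- sign(stats::setNames(net$nodes$loading, net$nodes$feature))
  same <- nsign[edges$source] * nsign[edges$target] > 0
  frustrated <- (edges$weight > 0 & !same) | (edges$weight < 0 & same)
  list(fraction = mean(frustrated),
       frustrated = edges[frustrated, , drop = FALSE])
}

#' Resolve frustration in a PC-corr network
#'
#' Applies one of the cut-off rules: report the frustration level only;
#' drop the frustrated edges when they are less than 5% of all edges
#' (refusing otherwise); or raise the cut-off in steps of 0.01 until no
#' frustration remains (or the network empties).
#'
#' @param pcc a `pccorr_matrix`.
#' @param cutoff starting cut-off.
#' @param policy `"report"`, `"drop"` or `"raise"`.
#' @param labels,data passed to [threshold_network()].
#' @param drop_threshold maximum frustration fraction at which `"drop"` is
#'   allowed (default 0.05).
#' @param step cut-off increment for `"raise"` (default 0.01, matching the
#'   two-decimal cut-offs in common use).
#' @return The resolved `pccorr_network`; its metadata records the policy,
#'   the final cut-off, the frustration fraction before and after, any
#'   removed edges, and — for a refused drop — `refused = TRUE`.
#' @export
resolve_frustration <- function(pcc, cutoff,
                                policy = c("report", "drop", "raise"),
                                labels = NULL, data = NULL,
                                drop_threshold = 0.05, step = 0.01) {
  policy <- match.arg(policy)
  net <- threshold_network(pcc, cutoff, labels, data)
  fr <- compute_frustration(net)
  log <- list(policy = policy, initial_cutoff = cutoff,
              initial_frustration = fr$fraction)
  if (policy == "report" || fr$fraction == 0) {
    net$metadata <- c(net$metadata, log,
                      list(final_frustration = fr$fraction))
    return(net)
  }
  if (policy == "drop") {
    if (fr$fraction >= drop_threshold) {
      net$metadata <- c(net$metadata, log,
                        list(refused = TRUE,
                             message = sprintf(
                               "frustration %.1f%% >= %.0f%%: drop refused; raise the cut-off instead",
                               100 * fr$fraction, 100 * drop_threshold)))
      return(net)
    }
    bad <- edge_keys(fr$frustrated)
    keep <- !(edge_keys(net$edges) %in% bad)
    edges <- net$edges[keep, , drop = FALSE]
    nodes_keep <- sort(unique(c(edges$source, edges$target)))
    nodes <- net$nodes[net$nodes$feature %in% nodes_keep, , drop = FALSE]
    deg <- table(c(edges$source, edges$target))
    nodes$degree <- as.integer(deg[nodes$feature])
    out <- new_network(edges, nodes, metadata = c(
      net$metadata, log,
      list(removed_edges = fr$frustrated, final_frustration = 0)))
    return(out)
  }
  # raise
  co <- cutoff
  repeat {
    co <- round(co + step, 10)
    if (co > 1) {
      net <- threshold_network(pcc, 1, labels, data)
      fr <- compute_frustration(net)
      break
    }
    net <- suppressWarnings(threshold_network(pcc, co, labels, data))
    fr <- compute_frustration(net)
    if (fr$fraction == 0) break
  }
  net$metadata <- c(net$metadata, log,
                    list(final_cutoff = min(co, 1),
                         final_frustration = fr$fraction))
  net
}
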