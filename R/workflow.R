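#' Run the full PC-corr workflow
#'
#' Chains preprocessing, PCA and discriminative-component selection,
#' loading normalization, PC-corr matrix construction, thresholding with
#' the chosen frustration policy, and (optionally) the baseline
#' comparison networks and the LOOCV robustness analysis.
#'
#' @param x omic matrix (samples as rows).
#' @param labels optional sample labels; required for `pc = "auto"` and
#'   for the comparison networks.
#' @param cutoff edge cut-off in (0, 1] (default 0.6).
#' @param pc `"auto"` (select the most discriminative component) or a
#'   component index.
#' @param centering `"auto"`, `"centered"` or `"noncentered"`.
#' @param normalization preprocessing method, see [preprocess_matrix()].
#' @param frustration_policy `"report"`, `"drop"` or `"raise"`.
#' @param compare `"none"`, `"pvalue"`, `"pvalue_mi"` or `"both"`.
#' @param loocv run the leave-one-out robustness analysis?
#' @param alpha significance level for PC selection and feature screen.
#' @param max_pc highest component scanned under `pc = "auto"`.
#' @return Object of class `pccorr_result`: the thresholded `network`,
#'   the `pccorr` matrix, `discrimination`, `loadings`, optional
#'   `comparison` networks with `venn` counts, optional `loocv` report,
#'   and a JSON-ready `report` list.
#' @export
pc_corr <- function(x, labels = NULL, cutoff = 0.6, pc = "auto",
                    centering = "auto", normalization = "none",
                    frustration_policy = "report", compare = "none",
                    loocv = FALSE, alpha = 0.05, max_pc = 3L) {
  if (cutoff <= 0 || cutoff > 1) stop("cut-off must lie in (0, 1]")
  validate_omic_matrix(x)
  xp <- preprocess_matrix(x, normalization)
  if (identical(pc, "auto")) {
    if (is.null(labels))
      stop("pc = \"auto\" needs sample labels for the discrimination test")
    disc <- select_discriminative_pc(xp, labels, max_pc = max_pc,
                                     alpha = alpha, centering = centering)
    if (!disc$significant)
      stop("no significant PC: no component discriminates the groups ",
           "(best corrected p = ", signif(disc$p_adjusted, 3),
           "); the PC-corr construction cannot be used here")
    pca <- disc$pca
    pc_index <- disc$pc_index
    ctr <- disc$centering
  } else {
    pc_index <- as.integer(pc)
    ctr <- if (identical(centering, "auto")) "centered" else centering
    pca <- fit_pca(xp, centering = ctr, k = pc_index)
    disc <- if (!is.null(labels))
      score_discrimination(pca, labels, pc_index) else NULL
  }
  nl <- process_loadings(pca$loadings[, pc_index])
  pcc <- build_pccorr_matrix(xp, nl)
  net <- resolve_frustration(pcc, cutoff, frustration_policy,
                             labels = labels, data = xp)
  net$metadata$method <- "pccorr"
  net$metadata$pc_index <- pc_index
  net$metadata$centering <- ctr
  comparison <- NULL
  if (compare != "none") {
    if (is.null(labels)) stop("comparison networks need sample labels")
    screen <- feature_screen(xp, labels, alpha)
    comparison <- list(screen = screen)
    if (compare %in% c("pvalue", "both")) {
      pv <- build_pvalue_network(xp, labels, cutoff, screen = screen)
      comparison$pvalue <- pv
      comparison$venn_pvalue <- venn_compare(pccorr = net, pvalue = pv)
    }
    if (compare %in% c("pvalue_mi", "both")) {
      pm <- build_pvalue_mi_network(xp, labels, cutoff, screen = screen)
      comparison$pvalue_mi <- pm
      comparison$venn_pvalue_mi <- venn_compare(pccorr = net,
                                                pvalue_mi = pm)
    }
  }
  loocv_res <- NULL
  if (isTRUE(loocv))
    loocv_res <- run_loocv(xp, pc_index = pc_index, centering = ctr,
                           cutoff = cutoff, labels = labels)
  report <- list(
    pc_index = pc_index,
    centering = ctr,
    cutoff = cutoff,
    final_cutoff = net$metadata$final_cutoff %||% cutoff,
    normalization = normalization,
    discrimination_p = if (!is.null(disc)) disc$p_value else NA,
    frustration = net$metadata$final_frustration %||%
      net$metadata$initial_frustration %||% 0,
    frustration_policy = frustration_policy,
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges))
  if (!is.null(comparison)) {
    if (!is.null(comparison$venn_pvalue))
      report$venn_pvalue <- comparison$venn_pvalue
    if (!is.null(comparison$venn_pvalue_mi))
      report$venn_pvalue_mi <- comparison$venn_pvalue_mi
  }
  if (!is.null(loocv_res)) {
    report$loocv_retention <- loocv_res$retention
    report$loocv_flips <- loocv_res$flips
  }
  structure(list(network = net, pccorr = pcc, loadings = nl,
                 discrimination = disc, comparison = comparison,
                 loocv = loocv_res, report = report,
                 preprocessed = xp),
            class = "pccorr_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pccorr_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "PC-corr analysis: PC%d (%s), cut-off %.3g -> %d nodes, %d edges\n",
    r$pc_index, r$centering, r$final_cutoff, r$n_nodes, r$n_edges))
  if (!is.na(r$discrimination_p))
    cat(sprintf("  discrimination p = %.4g\n", r$discrimination_p))
  cat(sprintf("  frustration: %.1f%% (policy %s)\n",
              100 * r$frustration, r$frustration_policy))
  if (!is.null(r$loocv_retention))
    cat(sprintf("  LOOCV edge retention: %.3f\n", r$loocv_retention))
  invisible(x)
}
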