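#' Describe a two-group synthetic design with planted structure
#'
#' The generator plants three kinds of structure in a two-group Gaussian
#' matrix: blocks of equicorrelated features whose group means differ
#' (discriminative *and* correlated — what a discriminative correlation
#' network should recover), equicorrelated blocks with no group shift
#' (correlated only), and single shifted features (discriminative only).
#' Features outside any block are i.i.d. noise.
#'
#' @param n_per_group samples per group (length-2 vector or scalar).
#' @param blocks data frame with columns `size`, `rho` (within-block
#'   pairwise correlation, in [0, 1)), `delta` (group-mean shift in sd
#'   units) and `sign` (+1/-1 direction of the shift); one row per block.
#' @param n_noise number of i.i.d. noise features.
#' @param noise_sd standard deviation of every feature (default 1).
#' @param seed integer seed (mandatory: designs are reproducible objects).
#' @return Object of class `pccorr_design`.
#' @export
planted_design <- function(n_per_group, blocks = NULL, n_noise = 0,
                           noise_sd = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (is.null(blocks))
    blocks <- data.frame(size = integer(), rho = numeric(),
                         delta = numeric(), sign = numeric())
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("size", "rho", "delta", "sign") %in% names(blocks)))
  if (any(blocks$size < 1L)) stop("block sizes must be >= 1")
  if (any(blocks$rho < 0 | blocks$rho >= 1))
    stop("rho must lie in [0, 1) for a positive-definite equicorrelation")
  if (nrow(blocks) + n_noise == 0 ||
      sum(blocks$size) + n_noise < 2)
    stop("design must contain at least 2 features")
  structure(list(n_per_group = as.integer(n_per_group), blocks = blocks,
                 n_noise = as.integer(n_noise), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "pccorr_design")
}

#' Generate a synthetic two-group omic matrix
#'
#' Samples each block from an equicorrelated multivariate normal (every
#' pair of features within a block has correlation `rho`), using the
#' one-factor construction `sqrt(rho) * g + sqrt(1 - rho) * e` with a
#' shared per-sample factor `g`; the second group's means are shifted by
#' `delta * noise_sd * sign`. Noise features are i.i.d. normal with no
#' shift. Fully deterministic given the design's seed.
#'
#' @param design a `pccorr_design`.
#' @return List: `matrix` (omic matrix), `labels` (groups `"A"` and
#'   `"B"`, `"A"` first), `truth` (data frame: `feature`, `block` — 0 for
#'   noise —, `is_discriminative`, `is_correlated`, `shift_sign`).
#' @export
generate_planted <- function(design) {
  stopifnot(inherits(design, "pccorr_design"))
  set.seed(design$seed)
  n1 <- design$n_per_group[1L]
  n2 <- design$n_per_group[2L]
  n <- n1 + n2
  grp <- rep(c("A", "B"), c(n1, n2))
  cols <- list()
  truth <- list()
  bl <- design$blocks
  for (b in seq_len(nrow(bl))) {
    m <- bl$size[b]
    rho <- bl$rho[b]
    g <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * m), n, m)
    xb <- sqrt(rho) * g + sqrt(1 - rho) * e
    xb <- xb * design$noise_sd
    if (bl$delta[b] != 0)
      xb[grp == "B", ] <- xb[grp == "B", ] +
        bl$delta[b] * design$noise_sd * bl$sign[b]
    colnames(xb) <- sprintf("b%d_f%d", b, seq_len(m))
    cols[[b]] <- xb
    truth[[b]] <- data.frame(
      feature = colnames(xb), block = b,
      is_discriminative = bl$delta[b] != 0,
      is_correlated = rho > 0 && m > 1L,
      shift_sign = if (bl$delta[b] != 0) bl$sign[b] else 0,
      stringsAsFactors = FALSE)
  }
  if (design$n_noise > 0L) {
    xn <- matrix(stats::rnorm(n * design$n_noise, sd = design$noise_sd),
                 n, design$n_noise)
    colnames(xn) <- sprintf("noise_f%d", seq_len(design$n_noise))
    cols <- c(cols, list(xn))
    truth <- c(truth, list(data.frame(
      feature = colnames(xn), block = 0L, is_discriminative = FALSE,
      is_correlated = FALSE, shift_sign = 0, stringsAsFactors = FALSE)))
  }
  x <- do.call(cbind, cols)
  rownames(x) <- sprintf("S%02d", seq_len(n))
  labels <- sample_labels(grp, sample_ids = rownames(x),
                          group_order = c("A", "B"))
  list(matrix = omic_matrix(x), labels = labels,
       truth = do.call(rbind, truth))
}

#' Preset synthetic scenarios
#'
#' Named designs emulating the regimes a discriminative correlation
#' network analysis meets in practice:
#' \describe{
#'   \item{`and_gate`}{n = 20 vs 20. One discriminative *and* correlated
#'     block (10 features, rho 0.8, shift 3 sd), one correlated-only
#'     block (10 features, rho 0.8, no shift), five discriminative-only
#'     singletons (shift 0.8 sd, alternating sign — kept moderate because
#'     a between-group shift by itself induces pooled correlation
#'     `(d1*d2/4)/sqrt((1+d1^2/4)(1+d2^2/4))` between any two shifted
#'     features, and the singletons must stay below the 0.5 cut-off to
#'     remain "uncorrelated"), 25 noise features. Only the first block
#'     should survive the min-operator AND gate.}
#'   \item{`metagenomics_like`}{n = 8 vs 8. Six sub-blocks of 5 tightly
#'     co-varying features (rho 0.75) each weakly shifted by 0.6 sd,
#'     three per direction, plus 30 noise features. The shift is spread
#'     over 30 features, so no single feature survives BH correction at
#'     these sample sizes, while their linear combination separates the
#'     groups along a PC and the sub-blocks provide strong
#'     within-module correlations — the situation in which a univariate
#'     screen has nothing to show but a discriminative correlation
#'     network exists.}
#'   \item{`lipidomics_like`}{n = 15 vs 15. Blocks of mixed strength
#'     (8 features rho 0.8 shift 2.5; 6 features rho 0.7 shift 1.8
#'     opposite sign; 5 features rho 0.6 unshifted) plus 20 noise.}
#'   \item{`null`}{n = 20 vs 20, 50 i.i.d. noise features; no structure.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return A `pccorr_design`.
#' @export
scenario_preset <- function(name = c("and_gate", "metagenomics_like",
                                     "lipidomics_like", "null"), seed) {
  name <- match.arg(name)
  switch(name,
    and_gate = planted_design(
      n_per_group = 20,
      blocks = data.frame(
        size = c(10L, 10L, 1L, 1L, 1L, 1L, 1L),
        rho = c(0.8, 0.8, 0, 0, 0, 0, 0),
        delta = c(3, 0, 0.8, 0.8, 0.8, 0.8, 0.8),
        sign = c(1, 1, 1, -1, 1, -1, 1)),
      n_noise = 25, seed = seed),
    metagenomics_like = planted_design(
      n_per_group = 8,
      blocks = data.frame(size = rep(5L, 6), rho = rep(0.75, 6),
                          delta = rep(0.6, 6),
                          sign = c(1, 1, 1, -1, -1, -1)),
      n_noise = 30, seed = seed),
    lipidomics_like = planted_design(
      n_per_group = 15,
      blocks = data.frame(size = c(8L, 6L, 5L), rho = c(0.8, 0.7, 0.6),
                          delta = c(2.5, 1.8, 0), sign = c(1, -1, 1)),
      n_noise = 20, seed = seed),
    null = planted_design(n_per_group = 20, n_noise = 50, seed = seed))
}
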