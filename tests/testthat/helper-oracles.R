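# Independent oracles and small fixture builders shared across tests.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(ii) sum(r[ii]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  mu <- nx * length(y) / 2
  sets <- utils::combn(length(pooled), nx)
  us <- apply(sets, 2L, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up, written out from the definition:
# adjusted p for the i-th smallest p is min over j >= i of m * p_(j) / j.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  adj
}

# Scalar sign * min oracle for the edge fusion.
edge_oracle <- function(c_ij, v_i, v_j) {
  s <- if (c_ij > 0) 1 else if (c_ij < 0) -1 else 0
  s * min(abs(c_ij), abs(v_i), abs(v_j))
}

# Nested-loop Pearson correlation.
cor_loop <- function(x) {
  p <- ncol(x)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- x[, i] - mean(x[, i])
    xj <- x[, j] - mean(x[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# Construct a pccorr_matrix directly from hand-set weights and loadings.
make_pcc <- function(weights, v_new) {
  stopifnot(identical(colnames(weights), names(v_new)))
  structure(list(weights = weights, corr = sign(weights), v_new = v_new),
            class = "pccorr_matrix")
}

# Symmetric weight matrix from an edge list given as list(c("A","B",0.7), ...)
weights_from_edges <- function(nodes, edges) {
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) {
    w[e[[1]], e[[2]]] <- as.numeric(e[[3]])
    w[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  }
  w
}

jaccard <- function(a, b) {
  if (length(union(a, b)) == 0L) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

# Tiny deterministic omic matrix fixture.
tiny_matrix <- function(n = 6L, p = 4L, seed = 42L) {
  set.seed(seed)
  omic_matrix(matrix(rnorm(n * p), n, p,
                     dimnames = list(paste0("s", seq_len(n)),
                                     paste0("f", seq_len(p)))))
}

tiny_labels <- function(n = 6L) {
  sample_labels(rep(c("A", "B"), each = n / 2),
                sample_ids = paste0("s", seq_len(n)))
}
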