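# Fixtures are built in code; no binary files.

# Tiny deterministic dataset: J SNPs, n samples, dosages drawn iid.
tiny_dataset <- function(n = 20, J = 4, seed = 42, family = NULL) {
  set.seed(seed)
  X <- matrix(sample(0:2, n * J, replace = TRUE), n, J,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("snp_", seq_len(J))))
  genotype_dataset(X, y = rnorm(n), family = family)
}

# Mask from a named list gene -> member SNP ids.
mask_from_list <- function(snp_ids, genes) {
  vals <- sapply(genes, function(members)
    as.integer(snp_ids %in% members))
  annotation_mask(matrix(vals, nrow = length(snp_ids),
                         dimnames = list(snp_ids, names(genes))),
                  snp_ids, names(genes))
}

# Random valid GRN for property tests.
random_grn <- function(seed) {
  set.seed(seed)
  n1 <- sample(0:5, 1); n2 <- sample(0:4, 1)
  ids1 <- if (n1) paste0("snp_", seq_len(n1)) else character()
  ids2 <- if (n2) paste0("gene_", seq_len(n2)) else character()
  nodes <- rbind(
    if (n1) data.frame(id = ids1, level = 1L, score = runif(n1),
                       score_kind = "pip", significant = TRUE,
                       orphan = sample(c(TRUE, FALSE), n1, TRUE),
                       stringsAsFactors = FALSE),
    if (n2) data.frame(id = ids2, level = 2L, score = runif(n2),
                       score_kind = "pip", significant = TRUE,
                       orphan = FALSE, stringsAsFactors = FALSE))
  edges <- NULL
  if (n1 && n2) {
    cross <- expand.grid(source = ids1, target = ids2,
                         stringsAsFactors = FALSE)
    cross <- cross[runif(nrow(cross)) < 0.4, , drop = FALSE]
    if (nrow(cross))
      edges <- data.frame(cross, directed = TRUE, kind = "cross_level",
                          weight = NA_real_, stringsAsFactors = FALSE)
  }
  if (n2 >= 2) {
    pairs <- t(combn(ids2, 2))
    pairs <- pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE]
    if (nrow(pairs))
      edges <- rbind(edges,
                     data.frame(source = pairs[, 1], target = pairs[, 2],
                                directed = FALSE, kind = "within_level",
                                weight = round(runif(nrow(pairs)), 6),
                                stringsAsFactors = FALSE))
  }
  memberships <- if (n1 && n2)
    lapply(setNames(ids1, ids1), function(i)
      sample(ids2, sample(0:n2, 1))) else list()
  grn(nodes = if (is.null(nodes)) NULL else nodes, edges = edges,
      memberships = memberships,
      metadata = list(l1_cutoff = runif(1), backend = "ssvi",
                      note = paste0("fixture_", seed)))
}

# Closed-form t-test oracle for a simple linear regression slope, written
# against lm() so it is independent of the vectorized implementation.
lm_slope_pvalue <- function(y, x) {
  if (sd(x) == 0) return(1)
  fit <- summary(lm(y ~ x))
  unname(fit$coefficients["x", "Pr(>|t|)"])
}

# Independent enumeration oracle: same posterior sums as
# exact_pip_enumeration but via combn subsets and dense solve(), no
# bit tricks, no Cholesky.
naive_enumeration_pips <- function(y, Z, pi0, sb2) {
  K <- ncol(Z); n <- length(y)
  yty <- sum(y^2)
  subsets <- unlist(lapply(0:K, function(k)
    combn(K, k, simplify = FALSE)), recursive = FALSE)
  logw <- vapply(subsets, function(S) {
    k <- length(S)
    lp <- k * log(pi0) + (K - k) * log(1 - pi0)
    if (k == 0) return(lp - (n / 2) * log(yty))
    Zs <- Z[, S, drop = FALSE]
    A <- crossprod(Zs) + diag(1 / sb2, k)
    rss <- yty - drop(t(crossprod(Zs, y)) %*% solve(A, crossprod(Zs, y)))
    lp - 0.5 * determinant(A)$modulus - (k / 2) * log(sb2) -
      (n / 2) * log(rss)
  }, numeric(1))
  w <- exp(logw - max(logw)); w <- w / sum(w)
  pip <- numeric(K)
  for (i in seq_along(subsets)) pip[subsets[[i]]] <- pip[subsets[[i]]] + w[i]
  pip
}

# AUC of scores ranking positives above negatives (Mann-Whitney form).
rank_auc <- function(scores, is_positive) {
  r <- rank(scores)
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

edge_keys_test <- function(edges) grnperturb:::edge_keys(edges)

# LD pair with genotype correlation ~ r by construction: snp_b copies
# snp_a and resamples each entry with probability 1 - r.
simulate_ld_pair <- function(n, maf = 0.3, r = 0.95, seed = 1) {
  set.seed(seed)
  a <- rbinom(n, 2, maf)
  b <- a
  flip <- runif(n) < (1 - r)
  b[flip] <- rbinom(sum(flip), 2, maf)
  X <- cbind(snp_a = a, snp_b = b)
  rownames(X) <- paste0("s", seq_len(n))
  X
}

# One causal SNP in a tight LD pair; the effect explains h2 of var(y).
# h2 = 0.08 keeps the causal SNP individually well above the PIP = 0.5
# threshold at n = 500 while the partner's conditional (residual) signal
# stays below it — the regime where knockout handoff is visible.
ld_pair_study <- function(seed, n = 500, r = 0.95, h2 = 0.08,
                          causal = "snp_a") {
  X <- simulate_ld_pair(n, maf = 0.3, r = r, seed = seed)
  Xs <- standardize_columns(X)
  set.seed(seed + 10000)
  g <- Xs[, causal]
  eps <- rnorm(n)
  eps <- qr.resid(qr(cbind(1, g)), eps)
  eps <- eps / sd(eps)
  y <- g + eps * sd(g) * sqrt((1 - h2) / h2)
  d <- genotype_dataset(X, y)
  m <- mask_from_list(colnames(X), list(gene_1 = colnames(X)))
  list(data = d, mask = m, causal = causal)
}
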