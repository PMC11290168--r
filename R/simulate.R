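#' @name simulate
#' @title Synthetic genotype/phenotype generator
#' @description
#' Generates genotype matrices with linkage-disequilibrium (LD) blocks and
#' family structure, block-contiguous SNP-to-gene annotation masks, and
#' phenotypes with a known sparse additive architecture. The defaults of
#' \code{simulate_dataset} ("mouse-like-mini") are a scaled-down stand-in
#' for a heterogeneous-stock mouse study: a few hundred related animals in
#' a modest number of families, dosage genotypes in \{0, 1, 2\}, and a
#' quantitative trait driven by a handful of causal SNPs. All generators
#' are pure functions of their seed and parameters.
NULL

#' Simulate a genotype matrix with LD blocks and families
#'
#' Genotypes are drawn through a Gaussian copula: a latent AR(1) normal
#' vector per sample (correlation \code{within_block_r} between adjacent
#' SNPs inside a block, independence across blocks) is discretized through
#' binomial(2, maf) quantiles. Discretization attenuates the realized
#' genotype correlation slightly below the latent target. Family structure
#' enters as a per-family shift of each SNP's allele frequency on the logit
#' scale (sd 0.3), which is what makes family-mean imputation meaningful.
#'
#' @param n samples.
#' @param J SNPs.
#' @param maf_range length-2 vector (lo, hi), 0 < lo <= hi < 0.5.
#' @param n_families number of (balanced) families.
#' @param ld_block_size SNPs per LD block (>= 1; 1 = independence).
#' @param within_block_r latent adjacent-SNP correlation in [0, 1).
#' @param seed integer seed.
#' @return A [genotype_dataset] with a constant zero phenotype placeholder
#'   (use [simulate_phenotype] to draw y) and family labels.
#' @export
simulate_genotypes <- function(n, J, maf_range = c(0.1, 0.5 - 1e-6),
                               n_families = 10L, ld_block_size = 1L,
                               within_block_r = 0, seed = 1L) {
  lo <- maf_range[1L]; hi <- maf_range[2L]
  if (!(lo > 0 && lo <= hi && hi < 0.5))
    stop_usage("maf_range must satisfy 0 < lo <= hi < 0.5")
  if (ld_block_size < 1L) stop_usage("ld_block_size must be >= 1")
  if (within_block_r < 0 || within_block_r >= 1)
    stop_usage("within_block_r must lie in [0, 1)")
  set.seed(seed)
  maf <- stats::runif(J, lo, hi)
  family <- sort(rep_len(paste0("fam_", seq_len(n_families)), n))
  # per-family logit-scale allele-frequency jitter
  fam_shift <- matrix(stats::rnorm(n_families * J, sd = 0.3),
                      nrow = n_families,
                      dimnames = list(unique(family), NULL))
  block <- (seq_len(J) - 1L) %/% ld_block_size
  r <- within_block_r
  # latent AR(1) within blocks: u_j = r * u_{j-1} + sqrt(1-r^2) * e_j
  E <- matrix(stats::rnorm(n * J), nrow = n)
  U <- E
  if (r > 0 && J > 1L) {
    for (j in 2:J) {
      if (block[j] == block[j - 1L])
        U[, j] <- r * U[, j - 1L] + sqrt(1 - r^2) * E[, j]
    }
  }
  P <- stats::pnorm(U)
  X <- matrix(0, n, J)
  fam_idx <- match(family, rownames(fam_shift))
  for (j in seq_len(J)) {
    logit_f <- log(maf[j] / (1 - maf[j])) + fam_shift[fam_idx, j]
    f <- pmin(pmax(1 / (1 + exp(-logit_f)), 0.01), 0.99)
    X[, j] <- stats::qbinom(P[, j], size = 2L, prob = f)
  }
  dimnames(X) <- list(paste0("sample_", seq_len(n)),
                      paste0("snp_", seq_len(J)))
  genotype_dataset(X, y = numeric(n), family = family)
}

#' Simulate a block-contiguous SNP-to-gene annotation mask
#'
#' Assigns contiguous runs of SNPs to genes; a fraction of SNPs is left
#' unannotated (all-zero rows) in contiguous intergenic stretches scattered
#' between genes, so that [assign_intergenic] has realistic work to do.
#' Every gene receives at least one SNP.
#'
#' @param J SNPs.
#' @param G genes.
#' @param snps_per_gene_range length-2 integer range of SNPs per gene.
#' @param intergenic_fraction fraction of SNPs left unannotated, in [0, 1).
#' @param seed integer seed.
#' @return An [annotation_mask] (J x G).
#' @export
simulate_mask <- function(J, G, snps_per_gene_range = c(2L, 6L),
                          intergenic_fraction = 0, seed = 1L) {
  lo <- snps_per_gene_range[1L]; hi <- snps_per_gene_range[2L]
  if (lo < 1L || lo > hi) stop_usage("invalid snps_per_gene_range")
  if (intergenic_fraction < 0 || intergenic_fraction >= 1)
    stop_usage("intergenic_fraction must lie in [0, 1)")
  n_intergenic <- round(intergenic_fraction * J)
  n_annotated <- J - n_intergenic
  if (n_annotated < G * lo)
    stop_usage("infeasible: ", n_annotated, " annotated SNPs cannot give ",
               G, " genes at least ", lo, " SNPs each")
  set.seed(seed)
  sizes <- rep(lo, G)
  spare <- n_annotated - sum(sizes)
  # distribute the remaining annotated SNPs over genes up to hi
  while (spare > 0L) {
    room <- which(sizes < hi)
    pick <- if (length(room)) room[sample.int(length(room), 1L)]
            else sample.int(G, 1L)
    sizes[pick] <- sizes[pick] + 1L
    spare <- spare - 1L
  }
  # interleave intergenic stretches between genes
  gaps <- integer(G + 1L)
  remaining <- n_intergenic
  while (remaining > 0L) {
    slot <- sample.int(G + 1L, 1L)
    gaps[slot] <- gaps[slot] + 1L
    remaining <- remaining - 1L
  }
  vals <- matrix(0L, nrow = J, ncol = G)
  row <- gaps[1L]
  for (g in seq_len(G)) {
    vals[(row + 1L):(row + sizes[g]), g] <- 1L
    row <- row + sizes[g] + gaps[g + 1L]
  }
  annotation_mask(vals, paste0("snp_", seq_len(J)),
                  paste0("gene_", seq_len(G)))
}

#' Simulate a sparse additive phenotype
#'
#' Draws \code{causal_k} causal SNPs uniformly at random, samples their
#' effects from \code{effect_distribution}, and adds noise scaled so that
#' the in-sample genetic variance fraction \code{var(X beta) / var(y)}
#' equals \code{h2} exactly (the noise is orthogonalized against the
#' genetic values before scaling). \code{h2 = 0} yields pure noise with the
#' causal set recorded at zero effect.
#'
#' @param X genotype matrix (or a [genotype_dataset], whose X is used).
#' @param causal_k number of causal SNPs, <= J.
#' @param h2 target in-sample heritability in [0, 1).
#' @param effect_distribution \code{"normal"} (standard normal effects on
#'   standardized dosages) or \code{"constant"} (all effects 1).
#' @param seed integer seed.
#' @return List with \code{y} and \code{truth} (class
#'   \code{simulation_truth}): causal SNP ids and effects, target and
#'   realized h2, seed and parameter echo.
#' @export
simulate_phenotype <- function(X, causal_k, h2,
                               effect_distribution = c("normal", "constant"),
                               seed = 1L) {
  effect_distribution <- match.arg(effect_distribution)
  if (inherits(X, "genotype_dataset")) X <- X$X
  J <- ncol(X); n <- nrow(X)
  if (causal_k > J) stop_usage("causal_k exceeds the number of SNPs")
  if (h2 < 0 || h2 >= 1) stop_usage("h2 must lie in [0, 1)")
  set.seed(seed)
  causal <- sort(sample.int(J, causal_k))
  beta <- switch(effect_distribution,
                 normal = stats::rnorm(causal_k),
                 constant = rep(1, causal_k))
  Xs <- standardize_columns(X)
  g <- as.vector(Xs[, causal, drop = FALSE] %*% beta)
  eps <- stats::rnorm(n)
  if (h2 == 0 || stats::var(g) == 0) {
    beta <- beta * 0
    y <- eps
    realized <- 0
  } else {
    # orthogonalize noise against [1, g] then scale for exact in-sample h2
    basis <- cbind(1, g)
    eps_perp <- qr.resid(qr(basis), eps)
    eps_perp <- eps_perp / stats::sd(eps_perp)
    y <- g + eps_perp * stats::sd(g) * sqrt((1 - h2) / h2)
    realized <- stats::var(g) / stats::var(y)
  }
  truth <- structure(
    list(causal_snp_ids = colnames(X)[causal],
         effects = stats::setNames(beta, colnames(X)[causal]),
         target_h2 = h2, realized_h2 = realized, seed = as.integer(seed),
         params = list(causal_k = causal_k,
                       effect_distribution = effect_distribution)),
    class = "simulation_truth")
  list(y = y, truth = truth)
}

#' Causal genes implied by a truth object and mask
#' @param truth a \code{simulation_truth}.
#' @param mask an [annotation_mask].
#' @return Character vector of gene ids containing at least one causal SNP.
#' @export
causal_genes <- function(truth, mask) {
  rows <- intersect(truth$causal_snp_ids, rownames(mask))
  colnames(mask)[colSums(unclass(mask)[rows, , drop = FALSE]) > 0L]
}

#' Inject missing genotypes at random
#' @param data a [genotype_dataset].
#' @param rate per-entry missingness probability.
#' @param seed integer seed.
#' @return The dataset with entries set to NA.
#' @export
inject_missing <- function(data, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop_usage("rate must lie in [0, 1)")
  set.seed(seed)
  X <- data$X
  drop <- matrix(stats::runif(length(X)) < rate, nrow = nrow(X))
  # keep at least one observed value per SNP so imputation stays defined
  for (j in which(colSums(!drop) == 0L)) drop[1L, j] <- FALSE
  X[drop] <- NA_real_
  genotype_dataset(X, data$y, covariates = data$covariates,
                   family = data$family)
}

#' One-call simulated study ("mouse-like-mini" preset)
#'
#' Bundles [simulate_genotypes], [simulate_mask] and [simulate_phenotype]
#' with defaults emulating a reduced heterogeneous-stock mouse study:
#' n = 200 samples in 10 families, J = 1000 SNPs, G = 250 genes, 5 causal
#' SNPs at h2 = 0.6.
#'
#' @param n,J,G,n_families,causal_k,h2 see the component generators.
#' @param ld_block_size,within_block_r LD structure (defaults: blocks of 5
#'   at latent r = 0.5).
#' @param effect_distribution passed to [simulate_phenotype]; use
#'   \code{"constant"} for equal-magnitude effects in recovery benchmarks.
#' @param intergenic_fraction fraction of unannotated SNPs (default 0.1).
#' @param missing_rate optional missingness injection rate (default 0).
#' @param seed integer seed; sub-generators derive distinct seeds from it.
#' @return List with \code{data} ([genotype_dataset]), \code{mask},
#'   \code{truth}.
#' @export
simulate_dataset <- function(n = 200L, J = 1000L, G = 250L,
                             n_families = 10L, causal_k = 5L, h2 = 0.6,
                             ld_block_size = 5L, within_block_r = 0.5,
                             intergenic_fraction = 0.1, missing_rate = 0,
                             effect_distribution = "normal", seed = 1L) {
  seed <- as.integer(seed)
  data <- simulate_genotypes(n, J, n_families = n_families,
                             ld_block_size = ld_block_size,
                             within_block_r = within_block_r,
                             seed = seed)
  mask <- simulate_mask(J, G, intergenic_fraction = intergenic_fraction,
                        seed = seed + 1L)
  ph <- simulate_phenotype(data$X, causal_k = causal_k, h2 = h2,
                           effect_distribution = effect_distribution,
                           seed = seed + 2L)
  data <- genotype_dataset(data$X, ph$y, family = data$family)
  if (missing_rate > 0)
    data <- inject_missing(data, missing_rate, seed = seed + 3L)
  list(data = data, mask = mask, truth = ph$truth)
}
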