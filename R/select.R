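#' Backend hyperparameter configuration
#'
#' Hyperparameters of the reference spike-and-slab backend. The prior
#' inclusion probability \code{pi} defaults to \code{min(0.1, 10 / K)} when
#' left \code{NULL} (set at fit time from the number of columns K). The slab
#' variance is derived from the heritability proxy as
#' \code{sigma_beta2 = h2 / ((1 - h2) * pi * K)} unless given explicitly;
#' this sizes the prior so that \code{pi * K} active standardized columns
#' explain about a fraction \code{h2} of the phenotypic variance.
#'
#' @param pi prior inclusion probability in (0, 1), or \code{NULL} for the
#'   K-dependent default.
#' @param h2 heritability proxy in (0, 1) used to size the slab; default 0.5.
#' @param sigma_beta2 explicit slab variance (relative to the residual
#'   variance); overrides \code{h2} when non-NULL.
#' @param tol convergence tolerance on the max absolute PIP change per
#'   sweep; default 1e-4.
#' @param max_iterations maximum coordinate-ascent sweeps; default 500.
#' @param seed integer seed recorded with every fit.
#' @return An object of class \code{backend_config}.
#' @export
backend_config <- function(pi = NULL, h2 = 0.5, sigma_beta2 = NULL,
                           tol = 1e-4, max_iterations = 500L, seed = 1L) {
  if (!is.null(pi) && (pi <= 0 || pi >= 1))
    stop_usage("pi must lie in (0, 1)")
  if (h2 <= 0 || h2 >= 1) stop_usage("h2 must lie in (0, 1)")
  if (!is.null(sigma_beta2) && sigma_beta2 <= 0)
    stop_usage("sigma_beta2 must be positive")
  if (tol <= 0) stop_usage("tol must be positive")
  structure(list(pi = pi, h2 = h2, sigma_beta2 = sigma_beta2, tol = tol,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "backend_config")
}

resolve_hyper <- function(config, K) {
  pi <- config$pi %||% min(0.1, 10 / K)
  sb2 <- config$sigma_beta2 %||%
    (config$h2 / ((1 - config$h2) * pi * K))
  list(pi = pi, sigma_beta2 = sb2)
}

#' Spike-and-slab regression by coordinate-ascent variational inference
#'
#' Fits the sparse linear model
#' \deqn{y = Z\beta + \epsilon,\quad \epsilon \sim N(0, \sigma^2 I),\quad
#'   \beta_k \sim \pi\, N(0, \sigma^2\sigma_\beta^2) + (1-\pi)\,\delta_0}
#' with the classic fully-factorized variational approximation: each
#' coordinate carries an inclusion probability \eqn{\alpha_k} (the PIP), a
#' conditional posterior mean \eqn{\mu_k} and variance \eqn{s_k^2}, updated
#' in fixed column order with a closed-form residual-variance update after
#' each sweep. Iteration stops when the largest PIP change in a sweep falls
#' below \code{config$tol} or after \code{config$max_iterations} sweeps; a
#' non-converged fit returns with \code{converged = FALSE} and a warning,
#' never silently. Initialization is the symmetric point
#' \eqn{\alpha_k = \pi, \mu_k = 0}, so exchangeable columns receive equal
#' PIPs and the fit is deterministic.
#'
#' @param y numeric response of length N (typically centered).
#' @param Z N x K design with standardized columns; no missing values.
#' @param config a [backend_config].
#' @return List with \code{alpha} (PIPs), \code{mu}, \code{s2},
#'   \code{sigma2}, \code{converged}, \code{n_iterations}, and the resolved
#'   \code{pi} and \code{sigma_beta2}.
#' @export
fit_spike_slab_vi <- function(y, Z, config = backend_config()) {
  Z <- as.matrix(Z)
  if (!all(is.finite(y)) || !all(is.finite(Z)))
    stop_validation("non-finite values in y or Z")
  n <- length(y); K <- ncol(Z)
  if (nrow(Z) != n) stop_dimension("nrow(Z) != length(y)")
  if (K < 1L) stop_usage("design must have at least one column")
  hp <- resolve_hyper(config, K)
  pi0 <- hp$pi; sb2 <- hp$sigma_beta2
  d <- colSums(Z^2)
  alpha <- rep(pi0, K)
  mu <- numeric(K)
  b <- alpha * mu
  r <- y - as.vector(Z %*% b)
  sigma2 <- stats::var(y)
  if (sigma2 == 0) sigma2 <- 1
  logit_pi <- log(pi0) - log1p(-pi0)
  converged <- FALSE
  it <- 0L
  s2 <- numeric(K)
  for (it in seq_len(config$max_iterations)) {
    alpha_old <- alpha
    for (k in seq_len(K)) {
      s2[k] <- sigma2 / (d[k] + 1 / sb2)
      ztr <- sum(Z[, k] * r) + d[k] * b[k]
      mu[k] <- s2[k] / sigma2 * ztr
      logit_a <- logit_pi + 0.5 * log(s2[k] / (sigma2 * sb2)) +
        mu[k]^2 / (2 * s2[k])
      alpha[k] <- 1 / (1 + exp(-logit_a))
      b_new <- alpha[k] * mu[k]
      r <- r - Z[, k] * (b_new - b[k])
      b[k] <- b_new
    }
    var_b <- alpha * (s2 + mu^2) - b^2
    sigma2 <- (sum(r^2) + sum(d * var_b) +
                 sum(alpha * (s2 + mu^2)) / sb2) / (n + sum(alpha))
    if (max(abs(alpha - alpha_old)) < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("spike-and-slab VI did not converge in ",
            config$max_iterations, " sweeps", call. = FALSE)
  list(alpha = alpha, mu = mu, s2 = s2, sigma2 = sigma2,
       converged = converged, n_iterations = it,
       pi = pi0, sigma_beta2 = sb2)
}

#' Exact posterior inclusion probabilities by model enumeration
#'
#' Test oracle: enumerates all \eqn{2^K} subsets S of columns, scores each
#' with the closed-form marginal likelihood of the conjugate
#' normal-inverse-gamma model matching the spike-and-slab slab
#' (\eqn{\beta_S | \sigma^2 \sim N(0, \sigma^2\sigma_\beta^2 I)}, Jeffreys
#' prior on \eqn{\sigma^2}), and accumulates
#' \eqn{PIP_k = \sum_{S \ni k} w_S} with
#' \eqn{w_S \propto \pi^{|S|}(1-\pi)^{K-|S|}\, m(S)}. Restricted to
#' \eqn{K \le 12}.
#'
#' @inheritParams fit_spike_slab_vi
#' @return List with \code{pip} (length K) and \code{log_weights}
#'   (length \eqn{2^K}, normalized).
#' @export
exact_pip_enumeration <- function(y, Z, config = backend_config()) {
  Z <- as.matrix(Z)
  K <- ncol(Z); n <- length(y)
  if (K > 12L) stop_usage("exact enumeration supports K <= 12, got ", K)
  hp <- resolve_hyper(config, K)
  pi0 <- hp$pi; sb2 <- hp$sigma_beta2
  yty <- sum(y^2)
  ZtZ <- crossprod(Z)
  Zty <- crossprod(Z, y)
  n_models <- 2L^K
  logw <- numeric(n_models)
  for (m in 0:(n_models - 1L)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(K - 1L))) != 0L)
    ksz <- length(S)
    log_prior <- ksz * log(pi0) + (K - ksz) * log1p(-pi0)
    if (ksz == 0L) {
      logml <- -(n / 2) * log(yty)
    } else {
      A <- ZtZ[S, S, drop = FALSE] + diag(1 / sb2, ksz)
      cholA <- chol(A)
      v <- backsolve(cholA, Zty[S], transpose = TRUE)
      rss <- yty - sum(v^2)
      logml <- -sum(log(diag(cholA))) - (ksz / 2) * log(sb2) -
        (n / 2) * log(rss)
    }
    logw[m + 1L] <- log_prior + logml
  }
  logw <- logw - max(logw)
  w <- exp(logw); w <- w / sum(w)
  pip <- numeric(K)
  for (m in 0:(n_models - 1L)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(K - 1L))) != 0L)
    pip[S] <- pip[S] + w[m + 1L]
  }
  list(pip = pip, log_weights = log(w))
}

#' Container for a backend fit
#' @param level1,level2 [score_table]s at levels 1 and 2.
#' @param backend backend name string.
#' @param converged logical.
#' @param n_iterations integer.
#' @param seed integer seed used.
#' @param details list of backend-specific metadata.
#' @return An object of class \code{selection_result}.
#' @export
selection_result <- function(level1, level2, backend, converged = TRUE,
                             n_iterations = 1L, seed = NA_integer_,
                             details = list()) {
  stopifnot(attr(level1, "level") == 1L, attr(level2, "level") == 2L)
  structure(list(level1 = level1, level2 = level2, backend = backend,
                 converged = converged,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), details = details),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d level-1 and %d level-2 scores (%s), converged = %s\n",
              x$backend, nrow(x$level1), nrow(x$level2),
              attr(x$level1, "score_kind"), x$converged))
  invisible(x)
}

#' Two-level spike-and-slab fit (SNPs and genes)
#'
#' Runs [fit_spike_slab_vi] on the standardized genotype matrix (level 1)
#' and, separately, on the gene-level design from [build_group_features]
#' (level 2). Both score tables carry PIPs. The data must be preprocessed:
#' no missing genotypes, variable ids equal to the mask's row ids.
#'
#' @param data a [genotype_dataset].
#' @param mask an [annotation_mask].
#' @param config a [backend_config].
#' @return A [selection_result] with \code{score_kind = "pip"} tables.
#' @export
fit_two_level <- function(data, mask, config = backend_config()) {
  if (anyNA(data$X)) stop_usage("impute missing genotypes before fitting")
  y <- data$y - mean(data$y)
  Z1 <- standardize_columns(data$X)
  fit1 <- fit_spike_slab_vi(y, Z1, config)
  H <- build_group_features(data, mask)
  fit2 <- fit_spike_slab_vi(y, H, config)
  selection_result(
    level1 = score_table(colnames(data$X), fit1$alpha, 1L, "pip"),
    level2 = score_table(colnames(mask), fit2$alpha, 2L, "pip"),
    backend = "ssvi",
    converged = fit1$converged && fit2$converged,
    n_iterations = max(fit1$n_iterations, fit2$n_iterations),
    seed = config$seed,
    details = list(pi = c(level1 = fit1$pi, level2 = fit2$pi),
                   sigma_beta2 = c(level1 = fit1$sigma_beta2,
                                   level2 = fit2$sigma_beta2),
                   sigma2 = c(level1 = fit1$sigma2, level2 = fit2$sigma2),
                   h2 = config$h2, tol = config$tol,
                   max_iterations = config$max_iterations))
}

#' Gene-level significance by the minSNP rule
#'
#' Level 1: each SNP's score is the two-sided p-value of the slope t-test in
#' the simple linear regression \code{y ~ intercept + X[, j]}. Level 2: each
#' gene's score is the minimum p-value over its annotated SNPs (no
#' multiplicity correction by default, per the minSNP convention; set
#' \code{sidak = TRUE} for a Sidak-corrected variant). Genes with no
#' annotated SNPs are excluded and listed in \code{details$genes_excluded}.
#' Constant SNP columns receive p-value 1 and are flagged in
#' \code{details$degenerate_fits}.
#'
#' @param data a preprocessed [genotype_dataset] with \code{n >= 3}.
#' @param mask an [annotation_mask].
#' @param sidak apply a Sidak correction \code{1 - (1 - p)^m} to gene
#'   p-values, where m is the gene's SNP count; default \code{FALSE}.
#' @return A [selection_result] with \code{score_kind = "pvalue"} tables.
#' @export
minsnp_backend <- function(data, mask, sidak = FALSE) {
  if (anyNA(data$X)) stop_usage("impute missing genotypes before fitting")
  n <- nrow(data$X)
  if (n < 3L) stop_usage("minSNP needs n >= 3 samples")
  if (!identical(colnames(data$X), rownames(mask)))
    stop_validation("variable ids do not match mask rows")
  y <- data$y
  X <- data$X
  sx <- apply(X, 2L, stats::sd)
  degenerate <- sx == 0
  rvec <- rep(0, ncol(X))
  ok <- !degenerate & stats::sd(y) > 0
  if (any(ok))
    rvec[ok] <- suppressWarnings(as.vector(stats::cor(y, X[, ok, drop = FALSE])))
  rvec[!is.finite(rvec)] <- 0
  rvec <- pmax(pmin(rvec, 1), -1)
  tstat <- rvec * sqrt((n - 2) / pmax(1 - rvec^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[degenerate] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  snp_ids <- colnames(X)
  gene_sizes <- colSums(mask)
  excluded <- colnames(mask)[gene_sizes == 0L]
  kept <- colnames(mask)[gene_sizes > 0L]
  gene_p <- vapply(kept, function(g) {
    members <- which(mask[, g] == 1L)
    pm <- min(p[members])
    if (sidak) pm <- 1 - (1 - pm)^length(members)
    pm
  }, numeric(1L))
  gene_p <- pmin(pmax(gene_p, .Machine$double.xmin), 1)
  selection_result(
    level1 = score_table(snp_ids, p, 1L, "pvalue"),
    level2 = score_table(kept, gene_p, 2L, "pvalue"),
    backend = "minsnp",
    converged = TRUE, n_iterations = 1L,
    details = list(genes_excluded = excluded,
                   degenerate_fits = snp_ids[degenerate],
                   sidak = sidak))
}

# --- backend registry ------------------------------------------------------
# Backends are registered by name so third-party selection methods can be
# plugged in without touching core code. A backend is a function
# (data, mask, config) -> selection_result.
.backend_registry <- new.env(parent = emptyenv())

#' Register or look up a selection backend
#'
#' @param name backend name.
#' @param fn function \code{(data, mask, config) -> selection_result}.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
get_backend <- function(name) {
  if (!exists(name, envir = .backend_registry, inherits = FALSE))
    stop_usage("unknown backend \"", name, "\"; registered: ",
               paste(list_backends(), collapse = ", "))
  get(name, envir = .backend_registry, inherits = FALSE)
}

#' @rdname register_backend
#' @export
list_backends <- function() sort(ls(.backend_registry))

register_builtin_backends <- function() {
  register_backend("ssvi", function(data, mask, config)
    fit_two_level(data, mask, config))
  register_backend("minsnp", function(data, mask, config)
    minsnp_backend(data, mask))
}

.onLoad <- function(libname, pkgname) {
  register_builtin_backends()
}
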