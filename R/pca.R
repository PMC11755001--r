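#' Iterative low-rank imputation of missing rates
#'
#' Regularized iterative principal components imputation: missing cells are
#' initialized at their column means, then the algorithm alternates between
#' a rank-`n_components` SVD reconstruction of the column-centered matrix
#' and replacement of the missing cells by that reconstruction, until the
#' largest absolute change in an imputed cell falls below `tol`. The imputed
#' values are thereby chosen to minimally perturb the first
#' `n_components` principal components of the observed data; observed cells
#' are never altered.
#'
#' @param x numeric matrix with NA for missing cells; every row and column
#'   needs at least two observed cells.
#' @param n_components reconstruction rank (default 4, capped at the matrix
#'   dimensions minus one).
#' @param tol convergence tolerance on imputed cells.
#' @param max_iter iteration cap; exceeding it is an error (with the recent
#'   change trace in the message).
#' @param regularized shrink each retained singular value by the estimated
#'   noise variance (the mean of the trailing eigenvalues), as in
#'   regularized iterative PCA. This damps components with eigenvalues
#'   close to the noise floor, preventing the limit cycles the plain
#'   alternating algorithm falls into when eigenvalues near the rank cutoff
#'   cross; on noiseless low-rank matrices the shrinkage vanishes and the
#'   plain reconstruction is recovered.
#' @return list with `completed` (the matrix with imputed cells), `mask`
#'   (logical matrix marking imputed cells), `iterations`.
#' @export
impute_missing <- function(x, n_components = 4L, tol = 1e-6,
                           max_iter = 1000L, regularized = TRUE) {
  x <- as.matrix(x)
  mask <- is.na(x)
  if (!any(mask)) {
    return(list(completed = x, mask = mask, iterations = 0L))
  }
  if (any(rowSums(!mask) < 2L)) stop("every row needs at least two observed cells")
  if (any(colSums(!mask) < 2L)) stop("every column needs at least two observed cells")
  r <- min(n_components, nrow(x) - 1L, ncol(x) - 1L)
  mu <- colMeans(x, na.rm = TRUE)
  completed <- x
  completed[mask] <- matrix(mu, nrow(x), ncol(x), byrow = TRUE)[mask]
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    mu <- colMeans(completed)
    centered <- sweep(completed, 2L, mu)
    sv <- svd(centered)
    d <- sv$d[seq_len(r)]
    if (regularized && length(sv$d) > r) {
      lam <- sv$d^2
      sigma2 <- mean(lam[(r + 1L):length(lam)])
      d <- d * pmax(0, (lam[seq_len(r)] - sigma2) / lam[seq_len(r)])
    }
    recon <- sweep(sv$u[, seq_len(r), drop = FALSE] %*%
                     (diag(d, r) %*% t(sv$v[, seq_len(r), drop = FALSE])),
                   2L, mu, "+")
    delta <- max(abs(recon[mask] - completed[mask]))
    completed[mask] <- recon[mask]
    trace <- c(utils::tail(trace, 9L), delta)
    if (delta < tol) {
      return(list(completed = completed, mask = mask, iterations = it))
    }
  }
  stop("imputation did not converge within ", max_iter,
       " iterations; recent changes: ",
       paste(signif(trace, 3), collapse = ", "))
}

#' Principal components of a completed rate matrix
#'
#' Eigendecomposition of the correlation structure (columns centered and
#' scaled to unit variance). Components follow a fixed sign convention —
#' each is oriented so that its largest-magnitude loading is positive —
#' making labels and cross-site comparisons reproducible despite the
#' arbitrariness of eigenvector signs.
#'
#' @param x complete numeric matrix (species x rates).
#' @return object of class `pca_result`: `eigenvalues`, `var_prop`,
#'   `loadings` (rates x components), `scores` (species x components), `n`.
#' @export
pca_axes <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("matrix contains non-finite cells; impute first")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eigenvalues <- pc$sdev^2
  loadings <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(eigenvalues = eigenvalues,
                 var_prop = eigenvalues / sum(eigenvalues),
                 loadings = loadings, scores = scores, n = nrow(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of %d observations x %d variables\n", x$n, length(x$eigenvalues)))
  cat("  variance proportions:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$var_prop, 4L)), collapse = ", "),
      "...\n")
  invisible(x)
}

# eigenvalues of the correlation matrix, via SVD of the scaled data
cor_eigenvalues <- function(x_scaled) {
  svd(x_scaled, nu = 0, nv = 0)$d^2 / (nrow(x_scaled) - 1L)
}

#' Permutation test for principal component significance
#'
#' Compares every observed eigenvalue against its null distribution over
#' `n_perm` datasets in which each column is independently permuted across
#' rows — destroying all correlation structure while preserving column
#' margins. The p-value of component k is the fraction of permuted k-th
#' eigenvalues at least as large as the observed one. On components with
#' p < `alpha`, rates with absolute loading >= `loading_threshold` are
#' flagged as significantly related. Permutations act on the completed
#' (post-imputation) matrix and are seeded; p-values do not depend on the
#' row order of the input.
#'
#' @param x complete numeric matrix.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param loading_threshold absolute loading cutoff for flags.
#' @param alpha eigenvalue significance level.
#' @return list with `p_values`, `significant` (per component),
#'   `loading_flags` (rates x components logical), and the observed
#'   `pca` ([pca_axes()] result).
#' @export
permutation_test <- function(x, n_perm = 1000L, seed = 1L,
                             loading_threshold = 0.3, alpha = 0.05) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  x <- as.matrix(x)
  obs <- pca_axes(x)
  n <- nrow(x); p <- ncol(x)
  # canonical column order makes the null draws independent of row order
  sorted_scaled <- apply(scale(x), 2L, sort)
  set.seed(as.integer(seed))
  exceed <- numeric(p)
  xp <- matrix(0, n, p)
  for (b in seq_len(n_perm)) {
    for (j in seq_len(p)) xp[, j] <- sorted_scaled[sample.int(n), j]
    lambda <- cor_eigenvalues(xp)
    exceed <- exceed + (lambda >= obs$eigenvalues - 1e-12)
  }
  p_values <- exceed / n_perm
  significant <- p_values < alpha
  flags <- abs(obs$loadings) >= loading_threshold
  flags[, !significant] <- FALSE
  list(p_values = p_values, significant = significant,
       loading_flags = flags, pca = obs)
}

#' Label the demographic trade-off axes
#'
#' Applies the rule-based interpretation of the principal components: a
#' component on which significant growth and survival loadings point in
#' opposite directions captures the growth-survival trade-off
#' (`"growth_survival"`); a component on which significant seedling-class
#' and tree-class loadings of the same rate type (growth with growth, or
#' survival with survival) point in opposite directions captures the
#' stature-recruitment trade-off (`"ontogenetic"`). A component can show
#' both sign patterns at once: under the 0.3 loading rule an axis often
#' flags only e.g. tree growth and seedling survival, a pattern that is
#' simultaneously type-opposed and stage-opposed. Such ambiguous components
#' are resolved by what determines the sign structure of the full loading
#' vector: the component is projected onto the rate-type contrast (all
#' growth against all survival) and onto the life-stage contrast (all
#' seedling-class against all tree-class rates), and the dominant contrast
#' decides. Unambiguous components are labeled directly from their flags;
#' a component with no qualifying opposition is `"unlabeled"`.
#'
#' @param loadings rates x components loading matrix (rownames must match
#'   [rate_columns()] for the growth/survival columns in use).
#' @param loading_flags logical matrix of significant loadings, same shape.
#' @return character vector of labels, one per component.
#' @export
label_tradeoffs <- function(loadings, loading_flags) {
  info <- rate_columns()
  idx <- match(rownames(loadings), info$column)
  rate_type <- info$rate_type[idx]
  stage <- info$stage[idx]
  class_of <- sub("^(growth|surv)_", "", rownames(loadings))
  labels <- character(ncol(loadings))
  for (k in seq_len(ncol(loadings))) {
    l <- loadings[, k]; f <- loading_flags[, k]
    g <- f & rate_type %in% "growth"
    s <- f & rate_type %in% "survival"
    one_sign <- function(idx) length(unique(sign(l[idx]))) == 1L
    # growth-vs-survival signature: any flagged growth loading opposed to
    # any flagged survival loading
    gs_any <- any(g) && any(s) && any(outer(sign(l)[g], sign(l)[s], "*") < 0)
    # ontogenetic signatures: stage opposition within one rate type, or a
    # flag pattern whose signs are fully segregated by life stage
    onto <- FALSE
    for (rt in c("growth", "survival")) {
      sl <- f & rate_type %in% rt & stage %in% "seedling"
      tl <- f & rate_type %in% rt & stage %in% "tree"
      if (any(sl) && any(tl) && any(outer(sign(l)[sl], sign(l)[tl], "*") < 0)) {
        onto <- TRUE
      }
    }
    gt <- (g | s) & !is.na(stage)
    seedling_idx <- gt & stage %in% "seedling"
    tree_idx <- gt & stage %in% "tree"
    stage_segregated <- any(seedling_idx) && any(tree_idx) &&
      one_sign(seedling_idx) && one_sign(tree_idx) &&
      sign(l[seedling_idx][1L]) * sign(l[tree_idx][1L]) < 0
    onto <- onto || stage_segregated
    if (gs_any && onto) {
      # both signatures: decide by the dominant contrast of the full
      # loading vector over the growth/survival columns
      gs_cols <- rate_type %in% c("growth", "survival")
      type_sign <- ifelse(rate_type == "growth", 1, -1)
      stage_sign <- ifelse(stage %in% "seedling", 1, -1)
      proj_type <- abs(sum((l * type_sign)[gs_cols]))
      proj_stage <- abs(sum((l * stage_sign)[gs_cols]))
      labels[k] <- if (proj_type >= proj_stage) "growth_survival" else "ontogenetic"
    } else {
      labels[k] <- if (gs_any) "growth_survival"
        else if (onto) "ontogenetic"
        else "unlabeled"
    }
  }
  labels
}

#' Extract and test the demographic trade-off axes
#'
#' Glue over the module: imputes the missing cells of a rates matrix,
#' computes the principal components, runs the eigenvalue permutation test
#' and labels the components.
#'
#' @param rates a [assemble_rates_matrix()] result (or plain matrix with NA).
#' @param config a [pipeline_config()] supplying `n_permutations`,
#'   `loading_threshold` and the seed.
#' @return object of class `tradeoff_pca`: the [pca_axes()] fields plus
#'   `p_values`, `significant`, `loading_flags`, `labels`, `mask` (imputed
#'   cells), `completed`.
#' @export
tradeoff_pca <- function(rates, config = pipeline_config()) {
  x <- if (inherits(rates, "rates_matrix")) rates$values else as.matrix(rates)
  x <- x[, colSums(!is.na(x)) >= 2L, drop = FALSE]   # drop unobserved columns
  imp <- impute_missing(x, n_components = 4L, max_iter = 20000L)
  pt <- permutation_test(imp$completed,
                         n_perm = config$n_permutations,
                         seed = derive_seed(config$rng_seed, "permutation"),
                         loading_threshold = config$loading_threshold)
  res <- pt$pca
  res$p_values <- pt$p_values
  res$significant <- pt$significant
  res$loading_flags <- pt$loading_flags
  res$labels <- label_tradeoffs(res$loadings, res$loading_flags)
  res$mask <- imp$mask
  res$completed <- imp$completed
  class(res) <- c("tradeoff_pca", "pca_result")
  res
}

#' @export
print.tradeoff_pca <- function(x, ...) {
  cat(sprintf("trade-off PCA: %d species, PC1+PC2 = %.1f%% of variance\n",
              x$n, 100 * sum(x$var_prop[1:2])))
  for (k in 1:2) {
    cat(sprintf("  PC%d: %.1f%% (p = %.3f) -> %s\n", k,
                100 * x$var_prop[k], x$p_values[k], x$labels[k]))
  }
  invisible(x)
}

#' Tucker congruence between two axes
#'
#' Absolute congruence coefficient `|<x, y>| / (||x|| ||y||)` between two
#' vectors (loadings or scores); 1 means identical up to sign and scale.
#'
#' @param x,y numeric vectors of equal length.
#' @return congruence in \[0, 1\].
#' @export
congruence <- function(x, y) {
  stopifnot(length(x) == length(y))
  abs(sum(x * y)) / sqrt(sum(x^2) * sum(y^2))
}
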