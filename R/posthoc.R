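#' Fit a trait onto the trade-off plane
#'
#' Two-dimensional linear trend-surface ("vector") fit of a species trait
#' onto the first two principal component scores, via [vegan::envfit()]:
#' the arrow is the direction of steepest increase of the trait in the
#' (PC1, PC2) plane scaled to unit length, r2 is the proportion of trait
#' variation it explains, and the p-value is obtained by permuting trait
#' values across species. Strictly positive, right-skewed traits (sample
#' skewness > 1) are log-transformed first. Significance uses a
#' Bonferroni-adjusted threshold (default p < 0.0125 for four traits).
#'
#' @param scores_2d species x 2 matrix of PC scores (rownames = species).
#' @param trait named numeric vector of trait values (NA allowed; at least
#'   5 species must overlap the scores).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alpha significance threshold.
#' @param trait_name label carried into the result.
#' @return object of class `trait_fit`: `direction` (unit vector),
#'   `r_squared`, `p_value`, `significant`, `n`, `logged`.
#' @export
trait_fit <- function(scores_2d, trait, n_perm = 999L, seed = 1L,
                      alpha = 0.0125, trait_name = deparse(substitute(trait))) {
  scores_2d <- as.matrix(scores_2d)
  stopifnot(ncol(scores_2d) == 2L)
  if (!is.null(names(trait)) && !is.null(rownames(scores_2d))) {
    trait <- trait[rownames(scores_2d)]
  }
  ok <- stats::complete.cases(scores_2d) & !is.na(trait)
  if (sum(ok) < 5L) stop("trait observed for fewer than 5 species with scores")
  v <- trait[ok]; sc <- scores_2d[ok, , drop = FALSE]
  if (stats::sd(v) == 0) stop("constant trait: ", trait_name)
  logged <- FALSE
  if (all(v > 0) && skewness(v) > 1) {
    v <- log(v); logged <- TRUE
  }
  set.seed(as.integer(seed))
  ef <- vegan::envfit(sc, data.frame(trait = v), permutations = n_perm)
  direction <- as.numeric(ef$vectors$arrows[1L, ])
  r2 <- unname(ef$vectors$r[1L])
  p <- unname(ef$vectors$pvals[1L])
  structure(list(trait = trait_name,
                 direction = direction / sqrt(sum(direction^2)),
                 r_squared = r2,
                 p_value = p,
                 significant = p < alpha,
                 n = sum(ok), logged = logged),
            class = "trait_fit")
}

skewness <- function(v) {
  m <- mean(v); s <- stats::sd(v)
  if (s == 0) return(0)
  mean((v - m)^3) / s^3
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("%s: direction (%.2f, %.2f), r2 = %.2f, p = %.4f%s (n = %d)\n",
              x$trait, x$direction[1], x$direction[2], x$r_squared,
              x$p_value, if (x$significant) " *" else "", x$n))
  invisible(x)
}

#' Procrustes comparison of two ordinations
#'
#' Symmetric Procrustes superposition of two point configurations (factor
#' loadings, or species scores, on the first two components of two sites):
#' both are centered and scaled to unit sum of squares, the optimal
#' orthogonal rotation is found by SVD, and the similarity is reported as
#' `r = sqrt(1 - m2)` with `m2` the minimized residual sum of squares.
#' Significance comes from vegan's protest permutation test. When the
#' configurations are loadings from sites with different estimable rate
#' columns, the comparison is restricted to the shared rows (at least 3).
#'
#' @param conf_a,conf_b numeric matrices with matching rownames (points) and
#'   the same number of columns.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `procrustes_result`: `r`, `m2`, `rotation`,
#'   `scale`, `translation`, `p_value`, `n_points`.
#' @export
procrustes_compare <- function(conf_a, conf_b, n_perm = 999L, seed = 1L) {
  conf_a <- as.matrix(conf_a); conf_b <- as.matrix(conf_b)
  if (!is.null(rownames(conf_a)) && !is.null(rownames(conf_b))) {
    shared <- intersect(rownames(conf_a), rownames(conf_b))
    conf_a <- conf_a[shared, , drop = FALSE]
    conf_b <- conf_b[shared, , drop = FALSE]
  }
  if (nrow(conf_a) < 3L) stop("need at least 3 shared points")
  stopifnot(nrow(conf_a) == nrow(conf_b), ncol(conf_a) == ncol(conf_b))
  pr <- vegan::procrustes(conf_a, conf_b, symmetric = TRUE)
  set.seed(as.integer(seed))
  pt <- vegan::protest(conf_a, conf_b, permutations = n_perm)
  structure(list(r = sqrt(max(0, 1 - pr$ss)), m2 = pr$ss,
                 rotation = pr$rotation, scale = pr$scale,
                 translation = pr$translation,
                 p_value = pt$signif, n_points = nrow(conf_a)),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: r = %.3f (m2 = %.3f), p = %.4f, %d points\n",
              x$r, x$m2, x$p_value, x$n_points))
  invisible(x)
}

#' Weighted global PCA across sites
#'
#' Pools the per-site (already per-site normalized) rate matrices and runs a
#' principal components analysis in which every species is weighted by the
#' inverse of its site's species count, so each site contributes equally
#' regardless of richness. Missing cells are imputed with the same iterative
#' algorithm as the site analyses; eigenvalue significance uses the same
#' column-permutation test, computed on the weighted correlation structure.
#'
#' @param rate_matrices_by_site named list (>= 2 sites) of species x rate
#'   matrices (NA for missing cells; identical column layout).
#' @param config a [pipeline_config()].
#' @return object of class `tradeoff_pca` with additional fields `weights`
#'   and `site` (per pooled row).
#' @export
global_weighted_pca <- function(rate_matrices_by_site,
                                config = pipeline_config()) {
  if (length(rate_matrices_by_site) < 2L) stop("need at least 2 sites")
  mats <- lapply(rate_matrices_by_site, function(m) {
    if (inherits(m, "rates_matrix")) m$values else as.matrix(m)
  })
  cols <- colnames(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(colnames(m), cols), logical(1L)))) {
    stop("site matrices must share the same column layout")
  }
  x <- do.call(rbind, mats)
  site <- rep(names(mats), vapply(mats, nrow, integer(1L)))
  w <- 1 / vapply(mats, nrow, integer(1L))[site]
  w <- w / sum(w)
  keep <- colSums(!is.na(x)) >= 2L
  x <- x[, keep, drop = FALSE]
  imp <- impute_missing(x, n_components = 4L, max_iter = 20000L)
  res <- weighted_pca(imp$completed, w)
  # permutation null for the weighted eigenvalues
  set.seed(derive_seed(config$rng_seed, "permutation"))
  n <- nrow(x); p <- ncol(x)
  exceed <- numeric(p)
  xp <- imp$completed
  for (b in seq_len(config$n_permutations)) {
    for (j in seq_len(p)) xp[, j] <- imp$completed[sample.int(n), j]
    exceed <- exceed + (weighted_pca(xp, w, eigenvalues_only = TRUE) >=
                          res$eigenvalues - 1e-12)
  }
  res$p_values <- exceed / config$n_permutations
  res$significant <- res$p_values < 0.05
  res$loading_flags <- abs(res$loadings) >= config$loading_threshold
  res$loading_flags[, !res$significant] <- FALSE
  res$labels <- label_tradeoffs(res$loadings, res$loading_flags)
  res$mask <- imp$mask
  res$completed <- imp$completed
  res$weights <- w
  res$site <- site
  class(res) <- c("tradeoff_pca", "pca_result")
  res
}

# PCA of the weighted correlation structure: rows weighted by w (summing to
# one), columns centered and scaled by their weighted moments.
weighted_pca <- function(x, w, eigenvalues_only = FALSE) {
  w <- w / sum(w)
  mu <- colSums(x * w)
  xc <- sweep(x, 2L, mu)
  sd_w <- sqrt(colSums(xc^2 * w))
  xs <- sweep(xc, 2L, sd_w, "/")
  sv <- svd(sqrt(w) * xs)
  eigenvalues <- sv$d^2
  if (eigenvalues_only) return(eigenvalues)
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(loadings))))
  scores <- xs %*% loadings
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

#' Core and full life-history hull areas
#'
#' Minimum convex polygons covering given fractions of the species scores
#' in the (PC1, PC2) plane, by convex-hull peeling: the hull vertex farthest
#' from the centroid of the remaining points is removed until
#' `ceiling(f * n)` points remain, whose convex hull is returned. The 10%
#' polygon delineates the core of a site's occupied life-history space, the
#' 90% polygon its extent without extreme species; a fraction of 1 returns
#' the full hull.
#'
#' @param scores_2d species x 2 score matrix (>= 5 rows).
#' @param fractions coverage fractions in (0, 1].
#' @return object of class `hull_set`: per fraction a list with `polygon`
#'   (vertex coordinates, counterclockwise), `area`, `n_points`.
#' @export
hull_areas <- function(scores_2d, fractions = c(0.10, 0.90)) {
  pts <- as.matrix(scores_2d)
  stopifnot(ncol(pts) == 2L)
  if (nrow(pts) < 5L) stop("need at least 5 species with scores")
  out <- lapply(sort(fractions), function(f) {
    target <- ceiling(f * nrow(pts))
    cur <- pts
    while (nrow(cur) > target) {
      centroid <- colMeans(cur)
      hull <- grDevices::chull(cur)
      d <- sqrt(colSums((t(cur[hull, , drop = FALSE]) - centroid)^2))
      cur <- cur[-hull[which.max(d)], , drop = FALSE]
    }
    hull <- grDevices::chull(cur)
    poly <- cur[hull, , drop = FALSE]
    area <- polygon_area(poly)
    if (area == 0) warning("degenerate (collinear) point set: zero-area polygon")
    list(polygon = poly, area = area, n_points = nrow(cur))
  })
  names(out) <- sprintf("f%.2f", sort(fractions))
  structure(out, class = "hull_set")
}

# shoelace formula; chull returns vertices clockwise, so take the absolute
polygon_area <- function(poly) {
  if (nrow(poly) < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' @export
print.hull_set <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("  %s: area %.3f (%d points)\n", nm, x[[nm]]$area,
                x[[nm]]$n_points))
  }
  invisible(x)
}
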