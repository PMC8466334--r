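#' PCA factor extraction with the eigenvalue-greater-than-one rule
#'
#' Eigen-decomposes the correlation matrix of the input and retains every
#' component with eigenvalue strictly greater than 1 (Kaiser criterion),
#' collapsing the collinear compound space to a small number of factors. If
#' no eigenvalue exceeds 1 the single largest component is retained with a
#' warning. Factor scores are standardized to unit variance per factor (the
#' regression-method estimator, which for principal components equals the
#' standardized component scores); the sign of each loading vector is fixed
#' so its largest-magnitude entry is positive.
#'
#' @param clr_matrix Numeric matrix, samples in rows (at least 3), compounds
#'   in columns (at least 2), no constant column.
#' @return A list of class `factor_model`: `n_factors`, `eigenvalues` (all),
#'   `explained_pct` (percent of total variance carried by the retained
#'   factors), `scores` (samples x n_factors, unit variance), `loadings`
#'   (compounds x n_factors, variable-factor correlations).
#' @export
pca_factor_scores <- function(clr_matrix) {
  x <- as.matrix(clr_matrix)
  if (nrow(x) < 3) stop("PCA needs at least 3 samples")
  if (ncol(x) < 2) stop("PCA needs at least 2 compounds")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    cn <- colnames(x)[sds == 0]
    if (is.null(cn)) cn <- which(sds == 0)
    stop("constant column(s), correlation undefined: ",
         paste(cn, collapse = ", "))
  }
  z <- scale(x, center = TRUE, scale = TRUE)
  ev <- eigen(stats::cor(x), symmetric = TRUE)
  lambda <- ev$values
  keep <- which(lambda > 1)
  if (length(keep) == 0) {
    warning("no eigenvalue > 1; retaining the single largest component")
    keep <- 1L
  }
  vec <- ev$vectors[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading entry positive
  for (k in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  lam <- lambda[keep]
  scores <- sweep(z %*% vec, 2, sqrt(lam), "/")
  loadings <- sweep(vec, 2, sqrt(lam), "*")
  dimnames(scores) <- list(rownames(x), paste0("F", seq_along(keep)))
  dimnames(loadings) <- list(colnames(x), paste0("F", seq_along(keep)))
  structure(list(n_factors = length(keep),
                 eigenvalues = lambda,
                 explained_pct = 100 * sum(lam) / ncol(x),
                 scores = scores,
                 loadings = loadings),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("PCA:", x$n_factors, "factors (eigenvalue > 1) explaining",
      sprintf("%.2f%%", x$explained_pct), "of the variance\n")
  invisible(x)
}

#' Squared-Euclidean-distance matrix
#'
#' `SED(a, b) = sum_f (score_af - score_bf)^2` over the factor scores; small
#' values indicate high similarity.
#'
#' @param scores Numeric matrix, samples in rows (e.g. factor scores).
#' @return Symmetric matrix with zero diagonal.
#' @export
sed_matrix <- function(scores) {
  d <- as.matrix(stats::dist(scores, method = "euclidean"))^2
  diag(d) <- 0
  d
}

#' Label sample pairs as same-nest or different-nest
#'
#' Builds the pair set entering the similarity GLM. If the two source groups
#' are identical, all unordered within-group pairs are used (e.g. mark vs
#' mark: for n nests with 2 sleeves each, `choose(2n, 2)` pairs of which n
#' are same-nest). If the groups differ, all cross-group pairs are used
#' (e.g. gland or bouquet vs mark). A pair is `same` when both samples carry
#' the same nest/bee ID.
#'
#' @param sed SED matrix with sample IDs as dimnames.
#' @param meta Sample metadata (`sample_id`, `nest_id`, `source`).
#' @param group_a_sources,group_b_sources Character vectors of sources
#'   defining the two groups.
#' @return A list of class `pair_set`: `pairs` (data frame `a`, `b`, `sed`,
#'   `same`) and `pruned` (empty data frame; filled by [prune_outliers()]).
#' @export
label_pairs <- function(sed, meta, group_a_sources,
                        group_b_sources = group_a_sources) {
  if (length(group_a_sources) == 0 || length(group_b_sources) == 0)
    stop("source groups must be non-empty")
  ids_a <- meta$sample_id[meta$source %in% group_a_sources]
  ids_b <- meta$sample_id[meta$source %in% group_b_sources]
  if (length(ids_a) == 0 || length(ids_b) == 0)
    stop("empty sample group")
  if (!all(c(ids_a, ids_b) %in% rownames(sed)))
    stop("samples missing from the SED matrix")
  nest <- stats::setNames(meta$nest_id, meta$sample_id)
  same_group <- setequal(ids_a, ids_b)
  if (same_group) {
    ids <- sort(ids_a)
    cmb <- utils::combn(ids, 2)
    a <- cmb[1, ]; b <- cmb[2, ]
  } else {
    g <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
    a <- g$a; b <- g$b
  }
  pairs <- data.frame(a = a, b = b,
                      sed = sed[cbind(a, b)],
                      same = nest[a] == nest[b],
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 pruned = pairs[0, , drop = FALSE]),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat("Pair set:", nrow(x$pairs), "pairs (",
      sum(x$pairs$same), "same,", sum(!x$pairs$same), "different ),",
      nrow(x$pruned), "pruned\n")
  invisible(x)
}

#' Prune extreme isolated SED values
#'
#' Removes pairs whose SED exceeds the conventional extreme-outlier fence
#' `Q3 + k_iqr * IQR` (quartiles by linear interpolation, type 7), computed
#' over all pairs pooled. Removed pairs are logged with their values.
#'
#' @param pairset A [label_pairs()] result.
#' @param k_iqr Fence multiplier (default 3, the "extreme value" fence).
#' @return The pruned `pair_set`; removed pairs appended to `$pruned`.
#' @export
prune_outliers <- function(pairset, k_iqr = 3) {
  stopifnot(inherits(pairset, "pair_set"))
  s <- pairset$pairs$sed
  if (length(s) < 4) stop("pruning needs at least 4 pairs")
  q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + k_iqr * (q[2] - q[1])
  out <- s > fence
  removed <- pairset$pairs[out, , drop = FALSE]
  if (nrow(removed)) removed$reason <- sprintf("sed > %.6g", fence)
  pairset$pairs <- pairset$pairs[!out, , drop = FALSE]
  pairset$pruned <- rbind(pairset$pruned,
                          removed[, names(pairset$pairs), drop = FALSE])
  pairset
}

#' Binomial-logit GLM Wald test of similarity
#'
#' Tests whether same-individual pairs are more similar than
#' different-individual pairs: logistic regression of the pair label (same =
#' 1) on the SED value, fitted by maximum likelihood (iteratively reweighted
#' least squares). Reports the Wald chi-square `W = (beta1 / se1)^2` for the
#' SED coefficient with its 1-df p-value.
#'
#' @param pairset A `pair_set` (typically after [prune_outliers()]).
#' @return A list of class `glm_wald`: `beta0`, `beta1`, `se1`, `W`, `p`,
#'   `n` (pairs used).
#' @export
wald_glm <- function(pairset) {
  stopifnot(inherits(pairset, "pair_set"))
  y <- as.numeric(pairset$pairs$same)
  x <- pairset$pairs$sed
  if (length(unique(y)) < 2)
    stop("both same and different pairs are required")
  # complete separation: SED perfectly splits the classes
  if (max(x[y == 1]) < min(x[y == 0]) || max(x[y == 0]) < min(x[y == 1]))
    stop("complete separation: SED perfectly splits same from different ",
         "pairs; Wald statistic undefined (maximum likelihood diverges)")
  fit <- stats::glm(y ~ x, family = stats::binomial(link = "logit"),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  co <- summary(fit)$coefficients
  beta1 <- co["x", "Estimate"]
  se1 <- co["x", "Std. Error"]
  W <- (beta1 / se1)^2
  structure(list(beta0 = co["(Intercept)", "Estimate"],
                 beta1 = beta1, se1 = se1, W = W,
                 p = stats::pchisq(W, df = 1, lower.tail = FALSE),
                 n = length(y)),
            class = "glm_wald")
}

#' @export
print.glm_wald <- function(x, ...) {
  cat(sprintf("Binomial-logit GLM: n = %d, W = %.3f, p = %.4g\n",
              x$n, x$W, x$p))
  invisible(x)
}

#' Median and range of SED per pair class
#'
#' @param pairset A `pair_set`.
#' @return Data frame with one row per class (`same`, `different`): `median`,
#'   `min`, `max`, `n`.
#' @export
summarize_similarity <- function(pairset) {
  stopifnot(inherits(pairset, "pair_set"))
  out <- lapply(c(same = TRUE, different = FALSE), function(cl) {
    s <- pairset$pairs$sed[pairset$pairs$same == cl]
    if (length(s) == 0) stop("empty pair class")
    data.frame(median = stats::median(s), min = min(s), max = max(s),
               n = length(s))
  })
  res <- do.call(rbind, out)
  res <- cbind(class = rownames(res), res)
  rownames(res) <- NULL
  res
}
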