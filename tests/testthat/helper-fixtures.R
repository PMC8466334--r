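# Small in-code fixtures and independent oracles shared across test files.

# A tiny hand-built peak table: n_marks mark samples over two nests plus an
# optional control sleeve, with named compounds.
toy_peak_table <- function(areas, sources, nests = NULL) {
  ids <- rownames(areas)
  if (is.null(nests)) nests <- sub("_.*$", "", ids)
  meta <- data.frame(sample_id = ids, nest_id = nests, source = sources,
                     stringsAsFactors = FALSE)
  ann <- data.frame(name = colnames(areas),
                    compound_class = "alkane",
                    chain_length = 20 + seq_len(ncol(areas)),
                    db_position = NA_integer_,
                    kovats = 100 * (20 + seq_len(ncol(areas))),
                    stringsAsFactors = FALSE)
  peak_table(areas, meta, ann)
}

# Independent Newton-Raphson maximum-likelihood logistic regression oracle.
nr_logistic <- function(x, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  b <- c(0, 0)
  H <- NULL
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% b)
    p <- 1 / (1 + exp(-eta))
    g <- crossprod(X, y - p)
    H <- crossprod(X, X * (p * (1 - p)))
    b <- b + solve(H, g)
    if (max(abs(g)) < tol) break
  }
  se <- unname(sqrt(diag(solve(H))))
  list(beta = as.vector(b), se = se, W = unname((b[2] / se[2])^2))
}

# Brute-force squared Euclidean distances.
brute_sed <- function(scores) {
  n <- nrow(scores)
  out <- matrix(0, n, n, dimnames = list(rownames(scores), rownames(scores)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sum((scores[i, ] - scores[j, ])^2)
    }
  }
  out
}

# Members of the cluster formed at merge step k of an hclust object.
hclust_members <- function(hc, k) {
  m <- hc$merge[k, ]
  unlist(lapply(m, function(x) if (x < 0) -x else hclust_members(hc, x)))
}

# The marks-only similarity analysis (filter -> quantile normalize -> clr ->
# PCA -> SED -> pairs -> prune -> GLM) without reporting, used by the
# replicate-based tests.
marks_analysis <- function(config, prune_k = 3) {
  sim <- simulate_dataset(config)
  tb <- sim$peak_table
  rep <- filter_substances(tb, c("mark1", "mark2"))
  ids <- tb$sample_meta$sample_id[tb$sample_meta$source %in%
                                    c("mark1", "mark2")]
  m <- tb$areas[ids, rep$retained, drop = FALSE]
  clr <- clr_transform(quantile_normalize(m))
  fm <- pca_factor_scores(clr)
  sed <- sed_matrix(fm$scores)
  ps <- prune_outliers(label_pairs(sed, tb$sample_meta, c("mark1", "mark2")),
                       k_iqr = prune_k)
  list(glm = wald_glm(ps), summary = summarize_similarity(ps),
       factor_model = fm, pairset = ps, sim = sim)
}
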