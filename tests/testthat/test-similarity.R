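test_that("PCA factor extraction follows the eigenvalue-greater-than-one rule", {
  # six perfectly correlated variables: one factor, eigenvalue 6, 100%
  set.seed(1)
  base <- stats::rnorm(20)
  x <- sapply(1:6, function(k) k * base + k)
  fm <- suppressWarnings(pca_factor_scores(x))
  expect_equal(fm$n_factors, 1)
  expect_equal(fm$eigenvalues[1], 6, tolerance = 1e-9)
  expect_equal(fm$explained_pct, 100, tolerance = 1e-9)

  # random matrix: eigenvalues, retention and explained % match prcomp
  set.seed(2)
  y <- matrix(stats::rnorm(20 * 6), nrow = 20)
  fm <- pca_factor_scores(y)
  pc <- stats::prcomp(y, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  expect_equal(fm$eigenvalues, ev, tolerance = 1e-9)
  expect_equal(fm$n_factors, sum(ev > 1))
  expect_equal(fm$explained_pct, 100 * sum(ev[ev > 1]) / ncol(y),
               tolerance = 1e-9)
  # scores are standardized and match the standardized principal components
  expect_equal(unname(apply(fm$scores, 2, stats::sd)),
               rep(1, fm$n_factors), tolerance = 1e-9)
  for (k in seq_len(fm$n_factors)) {
    oracle <- pc$x[, k] / pc$sdev[k]
    expect_equal(abs(stats::cor(fm$scores[, k], oracle)), 1,
                 tolerance = 1e-9)
  }
  # every retained eigenvalue exceeds 1
  expect_true(all(fm$eigenvalues[seq_len(fm$n_factors)] > 1))

  y_const <- cbind(y, fixed = 1)
  expect_error(pca_factor_scores(y_const), "fixed")
})

test_that("SED matrix equals the brute-force double loop", {
  expect_equal(sed_matrix(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)
  expect_equal(sed_matrix(rbind(a = c(0, 0), b = c(1, 1)))["a", "b"], 2)
  set.seed(3)
  for (r in 1:5) {
    s <- matrix(stats::rnorm(12 * 4), nrow = 12,
                dimnames = list(paste0("s", 1:12), NULL))
    d <- sed_matrix(s)
    expect_equal(d, brute_sed(s), tolerance = 1e-12)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("pair labelling reproduces the design combinatorics", {
  make_design <- function(n) {
    ids <- c(outer(c("_m1", "_m2"), sprintf("N%02d", 1:n),
                   function(s, b) paste0(b, s)))
    meta <- data.frame(sample_id = ids, nest_id = substr(ids, 1, 3),
                       source = rep(c("mark1", "mark2"), n))
    set.seed(n)
    scores <- matrix(stats::rnorm(2 * n * 3), ncol = 3,
                     dimnames = list(ids, NULL))
    list(sed = sed_matrix(scores), meta = meta)
  }
  for (n in c(1, 5, 25)) {
    d <- make_design(n)
    ps <- label_pairs(d$sed, d$meta, c("mark1", "mark2"))
    expect_equal(nrow(ps$pairs), choose(2 * n, 2))
    expect_equal(sum(ps$pairs$same), n)
    expect_equal(sum(!ps$pairs$same), choose(2 * n, 2) - n)
    # no self-pairs, unordered and unique
    expect_true(all(ps$pairs$a != ps$pairs$b))
    key <- apply(ps$pairs[, c("a", "b")], 1,
                 function(r) paste(sort(r), collapse = "|"))
    expect_false(any(duplicated(key)))
    # same label matches nest identity, pair by pair
    nest <- stats::setNames(d$meta$nest_id, d$meta$sample_id)
    expect_equal(ps$pairs$same,
                 nest[ps$pairs$a] == nest[ps$pairs$b],
                 ignore_attr = TRUE)
  }

  # cross-group labelling: gland extracts against marks
  d <- make_design(4)
  meta <- rbind(d$meta,
                data.frame(sample_id = sprintf("N%02d_gl", 1:4),
                           nest_id = sprintf("N%02d", 1:4),
                           source = "gland"))
  set.seed(99)
  scores <- matrix(stats::rnorm(12 * 3), ncol = 3,
                   dimnames = list(meta$sample_id, NULL))
  ps <- label_pairs(sed_matrix(scores), meta, "gland", c("mark1", "mark2"))
  expect_equal(nrow(ps$pairs), 4 * 8)
  expect_equal(sum(ps$pairs$same), 8)  # each gland matches its 2 own marks
  expect_error(label_pairs(d$sed, d$meta, "blank"), "empty")
})

test_that("outlier pruning removes only values beyond the extreme fence", {
  meta <- data.frame(sample_id = paste0("s", 1:10),
                     nest_id = rep(c("A", "B", "C", "D", "E"), each = 2),
                     source = rep(c("mark1", "mark2"), 5))
  fake_pairs <- function(seds, same) {
    structure(list(pairs = data.frame(a = paste0("a", seq_along(seds)),
                                      b = paste0("b", seq_along(seds)),
                                      sed = seds, same = same),
                   pruned = data.frame()),
              class = "pair_set")
  }
  # toy set {1,2,2,3,100}: Q3 = 3, IQR = 1, fence = 6 -> only 100 removed
  ps <- fake_pairs(c(1, 2, 2, 3, 100), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  pr <- prune_outliers(ps)
  expect_equal(pr$pairs$sed, c(1, 2, 2, 3))
  expect_equal(pr$pruned$sed, 100)
  # all values within the fence: unchanged
  ps2 <- fake_pairs(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(prune_outliers(ps2)$pairs$sed, c(1, 2, 3, 4))
  expect_error(prune_outliers(fake_pairs(c(1, 2, 3), c(TRUE, FALSE, TRUE))),
               "at least 4")
})

test_that("the Wald GLM matches an independent Newton-Raphson oracle", {
  fake_pairs <- function(seds, same) {
    structure(list(pairs = data.frame(a = paste0("a", seq_along(seds)),
                                      b = paste0("b", seq_along(seds)),
                                      sed = seds, same = same),
                   pruned = data.frame()),
              class = "pair_set")
  }
  # symmetric groups: zero slope, zero Wald statistic
  g0 <- wald_glm(fake_pairs(c(1, 3, 1, 3), c(TRUE, TRUE, FALSE, FALSE)))
  expect_lt(abs(g0$beta1), 1e-8)
  expect_lt(g0$W, 1e-8)

  # overlapping toy groups against the hand-rolled maximum-likelihood fit
  # (classes overlap over 2..4 so the MLE exists and is finite)
  sed <- c(1, 2, 3, 4, 2, 3, 4, 5)
  same <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  g <- wald_glm(fake_pairs(sed, same))
  oracle <- nr_logistic(sed, as.numeric(same))
  expect_equal(g$beta1, oracle$beta[2], tolerance = 1e-6)
  expect_equal(g$se1, oracle$se[2], tolerance = 1e-6)
  expect_equal(g$W, oracle$W, tolerance = 1e-6)
  expect_equal(g$p, stats::pchisq(oracle$W, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(g$n, 8)

  # W is invariant under positive affine rescaling of the SED values
  g2 <- wald_glm(fake_pairs(10 * sed + 3, same))
  expect_equal(g2$W, g$W, tolerance = 1e-6)

  # complete separation refuses a Wald value
  expect_error(wald_glm(fake_pairs(c(1, 2, 3, 4),
                                   c(TRUE, TRUE, FALSE, FALSE))),
               "separation")
  expect_error(wald_glm(fake_pairs(c(1, 2), c(TRUE, TRUE))), "both same")
})

test_that("similarity summaries report median and range per class", {
  ps <- structure(list(pairs = data.frame(
    a = letters[1:5], b = LETTERS[1:5],
    sed = c(5, 1, 2, 3, 4),
    same = c(TRUE, FALSE, FALSE, FALSE, FALSE)),
    pruned = data.frame()), class = "pair_set")
  s <- summarize_similarity(ps)
  same <- s[s$class == "same", ]
  diff <- s[s$class == "different", ]
  expect_equal(c(same$median, same$min, same$max, same$n), c(5, 5, 5, 1))
  expect_equal(c(diff$median, diff$min, diff$max, diff$n), c(2.5, 1, 4, 4))
})
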