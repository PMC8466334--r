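# independent studentized-residual computation for a simple regression
hand_studentized <- function(x, y) {
  n <- length(x)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  e <- y - (b0 + b1 * x)
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  s <- sqrt(sum(e^2) / (n - 2))
  e / (s * sqrt(1 - h))
}

test_that("Kovats band keeps on-line compounds and eliminates the deserter", {
  kv <- c(a = 2100, b = 2200, c = 2300, d = 2400, e = 2500, f = 2600)
  gland <- c(a = 1, b = 2, c = 1.5, d = 3, e = 2.5, f = 1)
  # quotients exactly on an ascending line -> everything retained
  mark <- gland * exp(0.2 + 0.001 * kv)
  # zero-residual line: lm warns about the essentially perfect fit
  band <- suppressWarnings(dufour_band_selection(mark, gland, kv))
  expect_setequal(band$retained, names(kv))
  expect_length(band$eliminated, 0)
  expect_equal(band$fit$slope, 0.001, tolerance = 1e-9)

  # one compound 50x above the band at its Kovats index
  kv2 <- c(kv, g = 2350)
  gland2 <- c(gland, g = 2)
  mark2 <- gland2 * exp(0.2 + 0.001 * kv2)
  mark2["g"] <- mark2["g"] * 50
  band2 <- dufour_band_selection(mark2, gland2, kv2)
  expect_equal(band2$eliminated, "g")
  expect_setequal(band2$retained, names(kv))
  # studentized residuals agree with a hand computation
  stud <- hand_studentized(kv2, log(mark2 / gland2))
  expect_equal(unname(band2$residuals[names(kv2)]), unname(stud),
               tolerance = 1e-9)

  # compounds without positive gland means never enter fit or retention
  mark3 <- c(mark2, h = 5)
  gland3 <- c(gland2, h = 0)
  kv3 <- c(kv2, h = 2450)
  band3 <- dufour_band_selection(mark3, gland3, kv3)
  expect_equal(band3$excluded, "h")
  expect_false("h" %in% c(band3$retained, band3$eliminated))

  expect_error(dufour_band_selection(mark[1:2], gland[1:2], kv[1:2]),
               "fewer than 3")
})

test_that("exogenous filter follows the strict two-fold enrichment rule", {
  head_m <- c(x = 1, y = 1, z = 1, w = 0)
  gland_m <- c(x = 1, y = 1, z = 1, w = 0)
  mark_m <- c(x = 2,    # ratio 1 -> retained
              y = 6,    # ratio 3 -> discarded
              z = 4,    # ratio exactly 2 -> retained (strict inequality)
              w = 1)    # no bee source -> discarded
  res <- exogenous_filter(mark_m, head_m, gland_m)
  expect_setequal(res$retained, c("x", "z"))
  expect_setequal(res$discarded, c("y", "w"))
  expect_equal(unname(res$reasons["y"]), "enriched")
  expect_equal(unname(res$reasons["w"]), "no_bee_source")
  expect_equal(unname(res$ratio[c("x", "y", "z")]), c(1, 3, 2))
  expect_true(is.infinite(res$ratio["w"]))
})

test_that("contribution factors encode proportional and dominant regimes", {
  h <- c(p = 2, q = 5, r = 1.5, s = 0)
  g <- c(p = 2, q = 1, r = 1, s = 3)
  cf <- contribution_factors(h, g)
  f <- cf$factors
  rownames(f) <- f$compound
  expect_equal(unname(unlist(f["p", c("factor_head", "factor_gland")])),
               c(1, 1))    # r = 1
  expect_equal(unname(unlist(f["q", c("factor_head", "factor_gland")])),
               c(1, 0))    # r = 5 > 2
  expect_equal(unname(unlist(f["r", c("factor_head", "factor_gland")])),
               c(1, 1))    # r = 1.5: proportional contribution
  expect_equal(unname(unlist(f["s", c("factor_head", "factor_gland")])),
               c(0, 1))    # head absent -> gland only
  expect_true(all(f$factor_head + f$factor_gland >= 1))
  expect_true(all(cf$ratio >= 1))

  expect_error(contribution_factors(c(a = 0), c(a = 0)), "discarded upstream")

  # symmetry: exchanging the head/gland labels swaps the factors
  set.seed(19)
  hh <- stats::setNames(stats::rlnorm(20), paste0("k", 1:20))
  gg <- stats::setNames(stats::rlnorm(20), paste0("k", 1:20))
  a <- contribution_factors(hh, gg)$factors
  b <- contribution_factors(gg, hh)$factors
  expect_equal(a$factor_head, b$factor_gland)
  expect_equal(a$factor_gland, b$factor_head)
})

test_that("bee bouquets sum the factored source contributions", {
  cf <- list(factors = data.frame(compound = c("c1", "c2", "c3"),
                                  factor_head = c(1, 1, 0),
                                  factor_gland = c(1, 0, 1)))
  bouquet <- estimate_bee_bouquet(c(c1 = 2, c2 = 4, c3 = 6),
                                  c(c1 = 1, c2 = 3, c3 = 5), cf)
  expect_equal(unname(bouquet), c(3, 4, 5))
  expect_error(estimate_bee_bouquet(c(c1 = 2), c(c1 = 1), cf), "missing")
})

test_that("marks built as an exact head+gland sum pass both attribution filters", {
  cfg <- simulation_config(n_bees = 6, seed = 41, sigma_individual = 0,
                           sigma_drift = 0, sigma_noise = 0,
                           sigma_intensity = 0, mix_gland = 0.5,
                           mix_cuticle = 0.5, env_enrichment = 0)
  sim <- simulate_dataset(cfg)
  att <- attribute_sources(sim$peak_table)
  expect_length(att$exogenous_discarded, 0)
  expect_length(att$band$eliminated, 0)
  expect_setequal(att$dufour_retained, att$universe)
  expect_setequal(att$bouquet_compounds, att$universe)
})

test_that("attribution on default simulations recovers the environmental compounds", {
  sim <- simulate_dataset(simulation_config(seed = 55))
  att <- attribute_sources(sim$peak_table)
  env <- names(sim$truth_source)[sim$truth_source == "environment"]
  expect_setequal(att$exogenous_discarded, env)
  expect_equal(length(att$bouquet_compounds), 49)
  expect_true(all(att$source_ratio >= 1))
  # bouquets defined exactly on the non-discarded compounds
  expect_setequal(colnames(att$bouquets), att$bouquet_compounds)
  expect_equal(nrow(att$bouquets), 25)
  # a bee without a gland extract is an error naming the bee
  tb <- sim$peak_table
  keep <- !(tb$sample_meta$nest_id == "N05" & tb$sample_meta$source == "gland")
  tb2 <- peak_table(tb$areas[tb$sample_meta$sample_id[keep], ],
                    tb$sample_meta[keep, ], tb$annotations)
  expect_error(attribute_sources(tb2), "N05")
})

test_that("total-sum scaling yields unit row sums and rejects zero rows", {
  m <- matrix(c(1, 2, 3, 4), nrow = 2)
  expect_equal(rowSums(total_sum_scale(m)), c(1, 1))
  expect_error(total_sum_scale(rbind(c(0, 0), c(1, 1))), "positive row sums")
})
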