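#' Total-sum scaling of samples over a compound universe
#'
#' Scales each sample's areas over the given compounds to sum to 1, the
#' "normalized to the same peak area sum" step that precedes the source
#' attribution means.
#'
#' @param matrix Numeric matrix, samples in rows.
#' @return Matrix with unit row sums.
#' @export
total_sum_scale <- function(matrix) {
  rs <- rowSums(matrix)
  if (any(rs <= 0)) stop("total-sum scaling needs positive row sums")
  sweep(matrix, 1, rs, "/")
}

#' Dufour-origin selection by the Kovats regression band
#'
#' Mark compounds that truly originate from Dufour's gland secretion are
#' expected to scatter around a slowly ascending regression line when the
#' log quotient of mean mark area over mean gland area is plotted against
#' the compound's Kovats index (a volatility proxy). Compounds deserting
#' from this band have been enriched in the marks by other volatile sources
#' and are eliminated from the gland-related tag analysis.
#'
#' The band is operationalized as an ordinary least-squares fit of
#' `ln(mark_mean / gland_mean)` on the Kovats index, retaining compounds
#' whose internally studentized residual has absolute value at most
#' `band_k`. Compounds with non-positive gland (or mark) means are excluded
#' from the fit and from the retained set.
#'
#' @param mark_means,gland_means Named numeric vectors of mean normalized
#'   peak areas per compound (same names).
#' @param kovats Named numeric vector of Kovats indices.
#' @param band_k Half-width of the band in studentized-residual units
#'   (default 2).
#' @return A list of class `kovats_band`: `retained` (compound names),
#'   `eliminated`, `excluded` (no positive gland/mark mean), `fit` (list with
#'   `slope`, `intercept`, `residual_sd`), and `residuals` (studentized, named).
#' @export
dufour_band_selection <- function(mark_means, gland_means, kovats,
                                  band_k = 2) {
  nm <- names(mark_means)
  if (is.null(nm) || is.null(names(gland_means)) || is.null(names(kovats)))
    stop("mark_means, gland_means and kovats must be named")
  gland_means <- gland_means[nm]
  kovats <- kovats[nm]
  if (any(is.na(gland_means)) || any(is.na(kovats)))
    stop("gland_means/kovats missing for some compounds")
  usable <- gland_means > 0 & mark_means > 0
  if (sum(usable) < 3)
    stop("fewer than 3 compounds with positive gland and mark means; ",
         "band fit undefined")
  lq <- log(mark_means[usable] / gland_means[usable])
  kv <- kovats[usable]
  fit <- stats::lm(lq ~ kv)
  stud <- stats::rstandard(fit)
  keep <- abs(stud) <= band_k
  structure(list(retained = names(lq)[keep],
                 eliminated = names(lq)[!keep],
                 excluded = nm[!usable],
                 band_k = band_k,
                 fit = list(slope = unname(stats::coef(fit)[2]),
                            intercept = unname(stats::coef(fit)[1]),
                            residual_sd = summary(fit)$sigma),
                 residuals = stats::setNames(as.numeric(stud), names(lq))),
            class = "kovats_band")
}

#' Exogenous-enrichment filter
#'
#' Discards compounds whose presence in nest marks cannot be explained by
#' the bee's own volatile sources: a compound is discarded when its mean
#' normalized mark area exceeds `enrichment_threshold` times the sum of its
#' mean head and gland areas (strictly; a mark mean of exactly twice the bee
#' sum is retained). Compounds with no bee source at all (head + gland mean
#' = 0) are discarded with reason `no_bee_source`.
#'
#' @param mark_means,head_means,gland_means Named numeric vectors over the
#'   compound universe (substances present in head and/or gland extracts as
#'   well as in marks).
#' @param enrichment_threshold Fold-enrichment limit (default 2).
#' @return List with `retained`, `discarded`, `reasons` (named character:
#'   `enriched` or `no_bee_source`), and `ratio` (named numeric,
#'   mark/(head+gland); `Inf` when no bee source).
#' @export
exogenous_filter <- function(mark_means, head_means, gland_means,
                             enrichment_threshold = 2) {
  nm <- names(mark_means)
  if (is.null(nm)) stop("means must be named")
  head_means <- head_means[nm]
  gland_means <- gland_means[nm]
  if (any(is.na(head_means)) || any(is.na(gland_means)))
    stop("head_means/gland_means missing for some compounds")
  bee_sum <- head_means + gland_means
  ratio <- ifelse(bee_sum > 0, mark_means / bee_sum, Inf)
  names(ratio) <- nm
  no_source <- bee_sum == 0
  enriched <- !no_source & ratio > enrichment_threshold
  discarded <- nm[no_source | enriched]
  reasons <- ifelse(no_source[no_source | enriched], "no_bee_source",
                    "enriched")
  list(retained = nm[!(no_source | enriched)],
       discarded = discarded,
       reasons = stats::setNames(reasons, discarded),
       ratio = ratio)
}

#' Head/gland contribution factors
#'
#' For each retained compound the ratio `r = max(head, gland) / min(head,
#' gland)` of the mean normalized areas decides how the two bee sources
#' contribute to the mark: for `r` between one and `ratio_threshold`
#' (inclusive) a proportional contribution of both sources is assumed,
#' encoded as factors (1, 1); for larger ratios only the source with the
#' higher amount is considered, factors (1, 0) or (0, 1). A compound present
#' in only one source gets the factor 1 for that source.
#'
#' @param head_means,gland_means Named numeric vectors (retained compounds).
#' @param ratio_threshold Upper limit of the proportional regime (default 2).
#' @return List with `factors` (data frame: compound, factor_head,
#'   factor_gland) and `ratio` (named numeric, `>= 1`, `Inf` for single-source
#'   compounds) for inspection of the empirical ratio distribution.
#' @export
contribution_factors <- function(head_means, gland_means,
                                 ratio_threshold = 2) {
  nm <- names(head_means)
  if (is.null(nm) || is.null(names(gland_means))) stop("means must be named")
  gland_means <- gland_means[nm]
  if (any(is.na(gland_means))) stop("gland_means missing for some compounds")
  if (any(head_means < 0) || any(gland_means < 0))
    stop("means must be non-negative")
  both_zero <- head_means == 0 & gland_means == 0
  if (any(both_zero))
    stop("compound(s) with zero head and gland means should have been ",
         "discarded upstream: ", paste(nm[both_zero], collapse = ", "))
  hi <- pmax(head_means, gland_means)
  lo <- pmin(head_means, gland_means)
  r <- ifelse(lo > 0, hi / lo, Inf)
  prop <- is.finite(r) & r <= ratio_threshold
  fh <- ifelse(prop, 1, as.numeric(head_means >= gland_means))
  fg <- ifelse(prop, 1, as.numeric(gland_means > head_means))
  # single-source compounds: dominant source 1, the other 0 (covered above:
  # a zero mean can never be the strictly larger source)
  list(factors = data.frame(compound = nm, factor_head = fh,
                            factor_gland = fg, stringsAsFactors = FALSE),
       ratio = stats::setNames(r, nm))
}

#' Estimated individual bouquet of one bee
#'
#' Applies the contribution factors to the normalized peak values of the
#' bee's two extracts and sums the estimated contribution of each source per
#' substance.
#'
#' @param head_values,gland_values Named numeric vectors of the bee's
#'   normalized head and gland peak values.
#' @param contribution A [contribution_factors()] result.
#' @return Named numeric vector: `factor_head * head + factor_gland * gland`
#'   per retained compound.
#' @export
estimate_bee_bouquet <- function(head_values, gland_values, contribution) {
  f <- contribution$factors
  hv <- head_values[f$compound]
  gv <- gland_values[f$compound]
  if (any(is.na(hv)) || any(is.na(gv)))
    stop("head/gland values missing for some retained compounds")
  stats::setNames(f$factor_head * hv + f$factor_gland * gv, f$compound)
}

#' Full source attribution of nest-mark compounds
#'
#' Runs the complete origin-of-volatiles analysis on a peak table:
#' \enumerate{
#'   \item Choose the compound universe: substances present in head and/or
#'     Dufour's gland extracts as well as in nest marks.
#'   \item Normalize every involved sample (marks, heads, glands) to the same
#'     peak-area sum over the universe (total-sum scaling), then compute mean
#'     normalized areas per source. This scaling removes per-sample intensity
#'     differences while preserving exact mixing proportions, so marks that
#'     truly are sums of the bee sources stay sums after normalization.
#'   \item Kovats band selection of Dufour-origin mark compounds
#'     ([dufour_band_selection()]).
#'   \item Exogenous-enrichment filter and contribution factors
#'     ([exogenous_filter()], [contribution_factors()]).
#'   \item Per-bee estimated total bouquets ([estimate_bee_bouquet()]).
#' }
#' Mark compounds absent from both bee extracts never enter the universe and
#' are recorded as exogenous with reason `no_bee_source`.
#'
#' @param table A [peak_table()] containing mark, head and gland samples.
#' @param presence_threshold Area above which a compound counts as present.
#' @param band_k Kovats band half-width (studentized residuals), default 2.
#' @param enrichment_threshold Exogenous fold-enrichment limit, default 2.
#' @param ratio_threshold Proportional-contribution limit, default 2.
#' @return A list of class `attribution_model`: `universe`, `dufour_retained`,
#'   `band` (the `kovats_band`), `exogenous_discarded`, `exogenous_reasons`,
#'   `bouquet_compounds`, `contribution` (factors + ratio distribution),
#'   `source_ratio`, `means` (list of mark/head/gland mean vectors), and
#'   `bouquets` (bees x compounds matrix of estimated individual bouquets).
#' @export
attribute_sources <- function(table, presence_threshold = 0, band_k = 2,
                              enrichment_threshold = 2, ratio_threshold = 2) {
  stopifnot(inherits(table, "peak_table"))
  src <- table$sample_meta$source
  is_mark <- grepl("^mark", src)
  is_head <- src == "head"
  is_gland <- src == "gland"
  if (!any(is_mark) || !any(is_head) || !any(is_gland))
    stop("attribution needs mark, head and gland samples")

  present_in <- function(rows) {
    apply(table$areas[rows, , drop = FALSE] > presence_threshold, 2, any)
  }
  in_marks <- present_in(is_mark)
  in_bee <- present_in(is_head) | present_in(is_gland)
  universe <- colnames(table$areas)[in_marks & in_bee]
  mark_only <- colnames(table$areas)[in_marks & !in_bee]
  if (length(universe) < 3) stop("compound universe too small (< 3)")

  keep <- is_mark | is_head | is_gland
  sub <- table$areas[keep, universe, drop = FALSE]
  norm <- total_sum_scale(sub)
  srcs <- src[keep]
  mark_means <- colMeans(norm[grepl("^mark", srcs), , drop = FALSE])
  head_means <- colMeans(norm[srcs == "head", , drop = FALSE])
  gland_means <- colMeans(norm[srcs == "gland", , drop = FALSE])

  band <- dufour_band_selection(mark_means, gland_means,
                                stats::setNames(table$annotations$kovats,
                                                table$annotations$name),
                                band_k = band_k)
  exo <- exogenous_filter(mark_means, head_means, gland_means,
                          enrichment_threshold = enrichment_threshold)
  contrib <- contribution_factors(head_means[exo$retained],
                                  gland_means[exo$retained],
                                  ratio_threshold = ratio_threshold)

  exogenous_discarded <- c(exo$discarded, mark_only)
  exogenous_reasons <- c(exo$reasons,
                         stats::setNames(rep("no_bee_source",
                                             length(mark_only)), mark_only))

  bees <- unique(table$sample_meta$nest_id[is_head | is_gland])
  bouquets <- matrix(NA_real_, length(bees), length(exo$retained),
                     dimnames = list(bees, exo$retained))
  meta <- table$sample_meta
  for (b in bees) {
    hid <- meta$sample_id[meta$nest_id == b & meta$source == "head"]
    gid <- meta$sample_id[meta$nest_id == b & meta$source == "gland"]
    if (length(hid) != 1 || length(gid) != 1)
      stop("bee ", b, " lacks a head or gland extract")
    bouquets[b, ] <- estimate_bee_bouquet(norm[hid, ], norm[gid, ], contrib)
  }

  structure(list(universe = universe,
                 dufour_retained = band$retained,
                 band = band,
                 exogenous_discarded = exogenous_discarded,
                 exogenous_reasons = exogenous_reasons,
                 exogenous_ratio = exo$ratio,
                 bouquet_compounds = exo$retained,
                 contribution = contrib,
                 source_ratio = contrib$ratio,
                 means = list(mark = mark_means, head = head_means,
                              gland = gland_means),
                 bouquets = bouquets),
            class = "attribution_model")
}

#' @export
print.attribution_model <- function(x, ...) {
  cat("Source attribution:\n")
  cat("  compound universe (bee extracts & marks):", length(x$universe), "\n")
  cat("  Dufour band retained:", length(x$dufour_retained),
      "(slope", signif(x$band$fit$slope, 3), ")\n")
  cat("  exogenous discarded:", length(x$exogenous_discarded), "\n")
  cat("  bouquet compounds:", length(x$bouquet_compounds),
      "over", nrow(x$bouquets), "bees\n")
  invisible(x)
}
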