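#' Compound classes recognized by the pipeline
#'
#' @keywords internal
#' @noRd
COMPOUND_CLASSES <- c("alkane", "alkene", "ester", "aldehyde", "alcohol",
                      "methyl_branched")

#' Reference mixing weights of the default panel
#'
#' The default compound panel is calibrated so that a nest mark mixed as
#' `0.30 x gland + 0.15 x head/cuticle + 0.55 x environment` reproduces the
#' compound-class proportions observed in O. cornuta nest-entrance extracts.
#' These weights are also the defaults of [simulation_config()].
#'
#' @keywords internal
#' @noRd
PANEL_MIX <- c(gland = 0.30, cuticle = 0.15, environment = 0.55)

#' Default GC/MS compound panel for the nest-mark simulator
#'
#' Builds a 59-compound panel of long-chain cuticular and glandular lipids
#' (n-alkanes C21-C31, 5-/7-/9-alkenes, fatty-acid esters, primary aldehydes,
#' primary alcohols, and methyl-branched alkanes) together with the expected
#' relative abundance of each compound in the three volatile sources the
#' analysis distinguishes: Dufour's gland secretion, the head/cuticle extract,
#' and the nesting environment (nest material plus floral residues).
#'
#' Class proportions per source follow the composition reported for
#' O. cornuta: gland extracts dominated by alkenes (~78.7%) with ~19.1%
#' alkanes and ~1% primary alcohols; head extracts with ~37.1% alkanes and
#' ~60.0% alkenes; nest marks with ~44.7% alkanes, ~39.8% alkenes (double
#' bonds mostly in position 7), ~9.1% aldehydes and ~0.5% esters. Primary
#' aldehydes (and two long-chain alcohols) occur in marks only and carry an
#' environment source label; the environment profile of the remaining
#' compounds is defined as the residual abundance a mark mixed with the
#' reference weights (gland 0.30, cuticle 0.15, environment 0.55) needs in
#' order to hit the mark targets exactly.
#'
#' Kovats retention indices follow the n-alkane convention (chain length C
#' maps to 100*C); alkenes sit slightly below the same-chain alkane.
#'
#' @return A data frame of class `compound_panel` with one row per compound
#'   and columns `name`, `compound_class`, `chain_length`, `db_position`
#'   (`NA` except for alkenes), `kovats`, and the source means `mean_gland`,
#'   `mean_head`, `mean_env` (each source column sums to 1).
#' @examples
#' panel <- default_compound_panel()
#' tapply(panel$mean_gland, panel$compound_class, sum)
#' @export
default_compound_panel <- function() {
  row <- function(name, class, chain, db, kovats, share) {
    data.frame(name = name, compound_class = class, chain_length = chain,
               db_position = db, kovats = kovats, share = share,
               stringsAsFactors = FALSE)
  }

  ## ---- within-class relative profiles (each block sums to 1) ------------
  # n-alkanes C21-C31, odd chains dominate (~95.5%), pentacosane prominent
  alkane_names <- c("heneicosane", "docosane", "tricosane", "tetracosane",
                    "pentacosane", "hexacosane", "heptacosane", "octacosane",
                    "nonacosane", "triacontane", "hentriacontane")
  alkane_chain <- 21:31
  alkane_share <- c(0.050, 0.009, 0.220, 0.009, 0.380, 0.009, 0.200, 0.009,
                    0.070, 0.009, 0.035)
  alkanes <- row(alkane_names, "alkane", alkane_chain, NA_integer_,
                 100 * alkane_chain, alkane_share)

  # mono-alkenes; db position 7 dominates, 7-pentacosene the major compound.
  # Within-position chain profiles are shared across sources; the position
  # split differs between sources (marks 5/7/9 = 1.0/33.5/5.3 of 39.8;
  # head and gland 1.8/51.9/6.4 of 60.1).
  alkene_tab <- data.frame(
    name = c("7-tricosene", "7-tetracosene", "7-pentacosene", "7-heptacosene",
             "7-nonacosene",
             "5-pentacosene", "5-heptacosene", "5-nonacosene",
             "9-tricosene", "9-pentacosene", "9-heptacosene", "9-nonacosene"),
    chain = c(23, 24, 25, 27, 29, 25, 27, 29, 23, 25, 27, 29),
    db = c(rep(7L, 5), rep(5L, 3), rep(9L, 4)),
    within = c(0.15, 0.02, 0.55, 0.20, 0.08,   # within position 7
               0.50, 0.30, 0.20,               # within position 5
               0.20, 0.40, 0.25, 0.15),        # within position 9
    stringsAsFactors = FALSE
  )
  pos_share_mark <- c(`5` = 1.0, `7` = 33.5, `9` = 5.3) / 39.8
  pos_share_bee  <- c(`5` = 1.8, `7` = 51.9, `9` = 6.4) / 60.1
  alkene_kovats <- 100 * alkene_tab$chain +
    c(`5` = -28, `7` = -25, `9` = -22)[as.character(alkene_tab$db)]
  alkenes <- row(alkene_tab$name, "alkene", alkene_tab$chain, alkene_tab$db,
                 alkene_kovats, NA_real_)
  alkene_share_mark <- alkene_tab$within *
    pos_share_mark[as.character(alkene_tab$db)]
  alkene_share_bee <- alkene_tab$within *
    pos_share_bee[as.character(alkene_tab$db)]

  # fatty-acid methyl/ethyl/isopropyl esters (C16-C20 acids), trace amounts
  ester_tab <- data.frame(
    name = c("methyl palmitoleate", "methyl palmitate", "ethyl palmitoleate",
             "ethyl palmitate", "isopropyl palmitate", "methyl oleate",
             "methyl stearate", "ethyl oleate", "ethyl stearate",
             "isopropyl stearate", "methyl eicosanoate", "ethyl eicosanoate"),
    chain = c(16, 16, 16, 16, 16, 18, 18, 18, 18, 18, 20, 20),
    kovats = c(1901, 1926, 1968, 1993, 2023, 2085, 2128, 2175, 2195, 2223,
               2327, 2394),
    share = c(0.06, 0.12, 0.05, 0.10, 0.08, 0.08, 0.12, 0.07, 0.10, 0.07,
              0.08, 0.07),
    stringsAsFactors = FALSE
  )
  esters <- row(ester_tab$name, "ester", ester_tab$chain, NA_integer_,
                ester_tab$kovats, ester_tab$share)

  # primary aldehydes C15-C24; five occur in trace amounts in bee extracts,
  # three are found in nest entrances only (environment source)
  aldehyde_tab <- data.frame(
    name = c("pentadecanal", "hexadecanal", "heptadecanal", "octadecanal",
             "eicosanal", "docosanal", "tricosanal", "tetracosanal"),
    chain = c(15, 16, 17, 18, 20, 22, 23, 24),
    share = c(0.08, 0.14, 0.10, 0.22, 0.18, 0.12, 0.08, 0.08),
    mark_only = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  aldehydes <- row(aldehyde_tab$name, "aldehyde", aldehyde_tab$chain,
                   NA_integer_, 100 * aldehyde_tab$chain + 22,
                   aldehyde_tab$share)
  ald_bee_share <- ifelse(aldehyde_tab$mark_only, 0,
                          aldehyde_tab$share / sum(aldehyde_tab$share[!aldehyde_tab$mark_only]))

  # primary alcohols; the four long-chain ones are glandular, the two
  # shorter ones occur in marks only (environment source)
  alcohol_tab <- data.frame(
    name = c("1-hexadecanol", "1-octadecanol", "1-docosanol", "1-tetracosanol",
             "1-hexacosanol", "1-octacosanol"),
    chain = c(16, 18, 22, 24, 26, 28),
    bee_share = c(0, 0, 0.30, 0.35, 0.20, 0.15),
    env_only_share = c(0.55, 0.45, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  alcohols <- row(alcohol_tab$name, "alcohol", alcohol_tab$chain, NA_integer_,
                  100 * alcohol_tab$chain + 75, NA_real_)

  # methyl-branched alkanes (3-/11-/13-methyl), mostly cuticular
  mb_tab <- data.frame(
    name = c("11-methyltricosane", "3-methyltricosane", "11-methylpentacosane",
             "13-methylpentacosane", "3-methylpentacosane",
             "11-methylheptacosane", "13-methylheptacosane",
             "3-methylheptacosane", "11-methylnonacosane",
             "13-methylnonacosane"),
    chain = c(23, 23, 25, 25, 25, 27, 27, 27, 29, 29),
    kovats = c(2333, 2373, 2533, 2537, 2573, 2733, 2737, 2773, 2933, 2937),
    share = c(0.06, 0.04, 0.20, 0.16, 0.10, 0.14, 0.12, 0.08, 0.06, 0.04),
    stringsAsFactors = FALSE
  )
  mbs <- row(mb_tab$name, "methyl_branched", mb_tab$chain, NA_integer_,
             mb_tab$kovats, mb_tab$share)

  panel <- rbind(alkanes, alkenes, esters, aldehydes, alcohols, mbs)

  ## ---- class totals per source ------------------------------------------
  # gland: alkenes 78.7%, alkanes 19.1%, alcohols 1.0%, esters 0.5%,
  #        aldehydes 0.1%, methyl-branched 0.6%
  gland_tot <- c(alkane = 0.191, alkene = 0.787, ester = 0.005,
                 aldehyde = 0.001, alcohol = 0.010, methyl_branched = 0.006)
  # head/cuticle: alkanes 37.1%, alkenes 60.0%, remainder trace
  head_tot <- c(alkane = 0.371, alkene = 0.600, ester = 0.001,
                aldehyde = 0.001, alcohol = 0.002, methyl_branched = 0.025)
  # nest-mark targets: alkanes 44.7%, alkenes 39.8%, aldehydes 9.1%,
  # esters 0.5%; the 5.9% remainder split over alcohols (1.2% glandular +
  # 1.7% environment-only) and methyl-branched alkanes (3.0%)
  mark_tot <- c(alkane = 0.447, alkene = 0.398, ester = 0.005,
                aldehyde = 0.091, alcohol = 0.029, methyl_branched = 0.030)
  stopifnot(abs(sum(gland_tot) - 1) < 1e-12, abs(sum(head_tot) - 1) < 1e-12,
            abs(sum(mark_tot) - 1) < 1e-12)

  expand <- function(tot, shares) tot * shares

  cls <- panel$compound_class
  mean_gland <- mean_head <- mark_mean <- numeric(nrow(panel))

  sel <- cls == "alkane"
  mean_gland[sel] <- expand(gland_tot["alkane"], alkane_share)
  mean_head[sel]  <- expand(head_tot["alkane"], alkane_share)
  mark_mean[sel]  <- expand(mark_tot["alkane"], alkane_share)

  sel <- cls == "alkene"
  mean_gland[sel] <- expand(gland_tot["alkene"], alkene_share_bee)
  mean_head[sel]  <- expand(head_tot["alkene"], alkene_share_bee)
  mark_mean[sel]  <- expand(mark_tot["alkene"], alkene_share_mark)

  sel <- cls == "ester"
  mean_gland[sel] <- expand(gland_tot["ester"], ester_tab$share)
  mean_head[sel]  <- expand(head_tot["ester"], ester_tab$share)
  mark_mean[sel]  <- expand(mark_tot["ester"], ester_tab$share)

  sel <- cls == "aldehyde"
  mean_gland[sel] <- expand(gland_tot["aldehyde"], ald_bee_share)
  mean_head[sel]  <- expand(head_tot["aldehyde"], ald_bee_share)
  mark_mean[sel]  <- expand(mark_tot["aldehyde"], aldehyde_tab$share)

  sel <- cls == "alcohol"
  mean_gland[sel] <- expand(gland_tot["alcohol"], alcohol_tab$bee_share)
  mean_head[sel]  <- expand(head_tot["alcohol"], alcohol_tab$bee_share)
  mark_mean[sel]  <- 0.012 * alcohol_tab$bee_share +
    0.017 * alcohol_tab$env_only_share

  sel <- cls == "methyl_branched"
  mean_gland[sel] <- expand(gland_tot["methyl_branched"], mb_tab$share)
  mean_head[sel]  <- expand(head_tot["methyl_branched"], mb_tab$share)
  mark_mean[sel]  <- expand(mark_tot["methyl_branched"], mb_tab$share)

  ## ---- environment source = residual of the reference mark mixture ------
  mean_env <- (mark_mean - PANEL_MIX["gland"] * mean_gland -
                 PANEL_MIX["cuticle"] * mean_head) / PANEL_MIX["environment"]
  stopifnot(all(mean_env > -1e-12))
  mean_env <- pmax(mean_env, 0)

  panel$share <- NULL
  panel$mean_gland <- mean_gland
  panel$mean_head <- mean_head
  panel$mean_env <- mean_env
  rownames(panel) <- NULL
  validate_compound_panel(panel)
  class(panel) <- c("compound_panel", "data.frame")
  panel
}

#' Validate a compound panel
#'
#' @param panel data frame with the columns of [default_compound_panel()].
#' @return The panel, invisibly, after checking invariants: unique names,
#'   positive Kovats indices strictly increasing with chain length within
#'   each class, and at least one positive source mean per compound.
#' @keywords internal
validate_compound_panel <- function(panel) {
  need <- c("name", "compound_class", "chain_length", "db_position", "kovats",
            "mean_gland", "mean_head", "mean_env")
  missing <- setdiff(need, names(panel))
  if (length(missing))
    stop("compound panel lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(panel$name))
    stop("duplicate compound names: ",
         paste(unique(panel$name[duplicated(panel$name)]), collapse = ", "))
  if (!all(panel$compound_class %in% COMPOUND_CLASSES))
    stop("unknown compound class: ",
         paste(setdiff(panel$compound_class, COMPOUND_CLASSES), collapse = ", "))
  if (any(!is.finite(panel$kovats)) || any(panel$kovats <= 0))
    stop("Kovats indices must be positive and finite")
  src <- panel[, c("mean_gland", "mean_head", "mean_env")]
  if (any(src < 0)) stop("source means must be non-negative")
  if (any(rowSums(src) <= 0))
    stop("every compound needs a positive mean in at least one source")
  # Kovats strictly increasing with chain length within a class
  for (cl in unique(panel$compound_class)) {
    sub <- panel[panel$compound_class == cl, ]
    if (nrow(sub) < 2) next
    agg_max <- tapply(sub$kovats, sub$chain_length, max)
    agg_min <- tapply(sub$kovats, sub$chain_length, min)
    ord <- order(as.numeric(names(agg_max)))
    if (length(ord) > 1 &&
        any(agg_max[ord][-length(ord)] >= agg_min[ord][-1]))
      stop("Kovats indices not increasing with chain length in class ", cl)
  }
  invisible(panel)
}
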