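#' Configuration for the synthetic nest-mark dataset generator
#'
#' Assembles and validates the parameters of the generative model behind
#' [simulate_dataset()]. The defaults reproduce the study design the pipeline
#' targets: 25 nesting bees, two sequential entrance sleeves per nest, one
#' head extract and one Dufour's gland extract per bee, plus three control
#' sleeves exposed to ambient conditions only.
#'
#' All variance parameters are standard deviations on the natural-log scale:
#' peak areas span several orders of magnitude, so every noise source is
#' multiplicative (log-normal).
#'
#' @param n_bees Number of nesting bees/nests (default 25; at least 2, since a
#'   single nest cannot yield different-nest comparisons).
#' @param marks_per_bee Number of sequential mark sleeves per nest (default 2).
#' @param n_control_sleeves Number of unnested control sleeves (default 3).
#' @param compound_panel Compound panel (see [default_compound_panel()]).
#' @param sigma_individual Log-scale SD of the per-bee, per-compound
#'   multiplicative deviation of the latent gland and head bouquets from the
#'   panel source means. This is the individual chemical signature.
#' @param sigma_drift Log-scale SD of the temporal drift applied to the second
#'   sleeve of each nest (tag instability between sequential sleeves).
#' @param sigma_noise Log-scale SD of per-cell measurement noise.
#' @param sigma_intensity Log-scale SD of the per-sample total-intensity
#'   factor (extract amount/body-size effects; removed downstream by quantile
#'   normalization and clr).
#' @param mix_gland Weight of Dufour's gland secretion in a mark.
#' @param mix_cuticle Weight of the head/cuticle bouquet in a mark.
#' @param env_enrichment Multiplier on the environment source profile added to
#'   marks. `mix_gland + mix_cuticle` must not exceed 1.
#' @param control_level Multiplier on the environment profile for control
#'   sleeves (ambient exposure only, well below nested sleeves).
#' @param base_area Arbitrary-unit scale of peak areas.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_bees = 25,
                              marks_per_bee = 2,
                              n_control_sleeves = 3,
                              compound_panel = default_compound_panel(),
                              sigma_individual = 0.40,
                              sigma_drift = 0.15,
                              sigma_noise = 0.10,
                              sigma_intensity = 0.50,
                              mix_gland = 0.30,
                              mix_cuticle = 0.15,
                              env_enrichment = 0.55,
                              control_level = 0.05,
                              base_area = 1e6,
                              seed = 1L) {
  cfg <- list(n_bees = as.integer(n_bees),
              marks_per_bee = as.integer(marks_per_bee),
              n_control_sleeves = as.integer(n_control_sleeves),
              compound_panel = compound_panel,
              sigma_individual = sigma_individual,
              sigma_drift = sigma_drift,
              sigma_noise = sigma_noise,
              sigma_intensity = sigma_intensity,
              mix_gland = mix_gland,
              mix_cuticle = mix_cuticle,
              env_enrichment = env_enrichment,
              control_level = control_level,
              base_area = base_area,
              seed = as.integer(seed))
  sds <- c("sigma_individual", "sigma_drift", "sigma_noise", "sigma_intensity")
  for (s in sds)
    if (!is.finite(cfg[[s]]) || cfg[[s]] < 0)
      stop("negative or non-finite ", s)
  if (cfg$n_bees < 2)
    stop("n_bees must be >= 2: a single nest cannot yield different-nest pairs")
  if (cfg$marks_per_bee < 1) stop("marks_per_bee must be >= 1")
  if (cfg$n_control_sleeves < 0) stop("n_control_sleeves must be >= 0")
  if (cfg$mix_gland < 0 || cfg$mix_cuticle < 0 ||
      cfg$mix_gland + cfg$mix_cuticle > 1)
    stop("mix weights must be non-negative with mix_gland + mix_cuticle <= 1")
  if (cfg$env_enrichment < 0) stop("env_enrichment must be >= 0")
  if (cfg$control_level < 0) stop("control_level must be >= 0")
  validate_compound_panel(cfg$compound_panel)
  class(cfg) <- "simulation_config"
  cfg
}

#' Ground-truth source labels of a compound panel
#'
#' Classifies every panel compound as `gland`, `head`, `both`, or
#' `environment` according to the generative source means. A compound is
#' `environment` when it has no bee source at all, or when its expected
#' environmental contribution to a mark (at the panel's reference mixing
#' weights) exceeds ten times the bee-derived contribution, i.e. its presence
#' in marks is driven by the surroundings even though trace amounts occur in
#' bee extracts.
#'
#' @param panel A compound panel.
#' @return Named character vector (compound -> label).
#' @export
truth_source_labels <- function(panel) {
  validate_compound_panel(panel)
  bee_part <- PANEL_MIX["gland"] * panel$mean_gland +
    PANEL_MIX["cuticle"] * panel$mean_head
  env_part <- PANEL_MIX["environment"] * panel$mean_env
  lab <- ifelse(bee_part == 0 | env_part > 10 * bee_part, "environment",
         ifelse(panel$mean_head == 0, "gland",
         ifelse(panel$mean_gland == 0, "head", "both")))
  stats::setNames(lab, panel$name)
}

#' Simulate a multi-source GC/MS peak-area dataset
#'
#' Generates the full sampling design the pipeline analyses: per bee a latent
#' Dufour's gland bouquet and a latent head/cuticle bouquet (panel source
#' means perturbed compound-wise by `exp(N(0, sigma_individual^2))`), nest
#' marks mixed as `mix_gland * gland + mix_cuticle * head + env_enrichment *
#' environment`, the second and later sleeves additionally perturbed by
#' `exp(N(0, sigma_drift^2))`, head and gland extract samples equal to the
#' latent bouquets, and control sleeves carrying the environment profile only.
#' Every sample is scaled by a log-normal intensity factor and every cell by
#' log-normal measurement noise.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_dataset` with elements `peak_table`
#'   (see [peak_table()]), `truth_bouquets` (list of `gland` and `head`
#'   latent bee x compound matrices), `truth_source` (named character vector,
#'   see [truth_source_labels()]), and `config`.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_bees = 4, seed = 7))
#' dim(sim$peak_table$areas)
#' @export
simulate_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config")
  panel <- config$compound_panel
  p <- nrow(panel)
  nb <- config$n_bees
  nm <- config$marks_per_bee

  # keep the caller's RNG state untouched
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  bee_ids <- sprintf("N%02d", seq_len(nb))
  lnoise <- function(n, sd) if (sd == 0) rep(1, n) else exp(stats::rnorm(n, 0, sd))

  gland_lat <- head_lat <- matrix(0, nb, p,
                                  dimnames = list(bee_ids, panel$name))
  for (b in seq_len(nb)) {
    gland_lat[b, ] <- panel$mean_gland * lnoise(p, config$sigma_individual)
    head_lat[b, ]  <- panel$mean_head * lnoise(p, config$sigma_individual)
  }

  env_mark <- config$env_enrichment * panel$mean_env
  rows <- list(); meta <- list()
  add <- function(id, nest, source, latent) {
    rows[[length(rows) + 1]] <<- latent
    meta[[length(meta) + 1]] <<- data.frame(sample_id = id, nest_id = nest,
                                            source = source,
                                            stringsAsFactors = FALSE)
  }
  for (b in seq_len(nb)) {
    base_mark <- config$mix_gland * gland_lat[b, ] +
      config$mix_cuticle * head_lat[b, ] + env_mark
    for (m in seq_len(nm)) {
      mk <- base_mark
      if (m > 1) mk <- mk * lnoise(p, config$sigma_drift)
      add(sprintf("%s_m%d", bee_ids[b], m), bee_ids[b],
          sprintf("mark%d", m), mk)
    }
    add(sprintf("%s_head", bee_ids[b]), bee_ids[b], "head", head_lat[b, ])
    add(sprintf("%s_gland", bee_ids[b]), bee_ids[b], "gland", gland_lat[b, ])
  }
  for (k in seq_len(config$n_control_sleeves)) {
    add(sprintf("CTRL%d", k), sprintf("CTRL%d", k), "control_sleeve",
        config$control_level * panel$mean_env)
  }

  areas <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  rownames(areas) <- meta$sample_id
  for (i in seq_len(nrow(areas))) {
    areas[i, ] <- areas[i, ] * config$base_area *
      lnoise(1, config$sigma_intensity) * lnoise(p, config$sigma_noise)
  }
  if (any(rowSums(areas) <= 0))
    stop("internal error: generated a sample with no positive area")

  annotations <- panel[, c("name", "compound_class", "chain_length",
                           "db_position", "kovats")]
  pt <- peak_table(areas, meta, annotations)
  structure(list(peak_table = pt,
                 truth_bouquets = list(gland = gland_lat, head = head_lat),
                 truth_source = truth_source_labels(panel),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic nest-mark dataset:",
      nrow(x$peak_table$areas), "samples x",
      ncol(x$peak_table$areas), "compounds\n")
  cat("  bees:", x$config$n_bees,
      " marks/bee:", x$config$marks_per_bee,
      " control sleeves:", x$config$n_control_sleeves, "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the standard pipeline input files via [write_peak_table()] plus a
#' `truth.json` holding the ground-truth bouquets and source labels.
#'
#' @param sim A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  if (!inherits(sim, "synthetic_dataset")) stop("not a synthetic_dataset")
  paths <- write_peak_table(sim$peak_table, dir)
  truth <- list(source = as.list(sim$truth_source),
                bouquets = list(gland = as.data.frame(sim$truth_bouquets$gland),
                                head = as.data.frame(sim$truth_bouquets$head)))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth = truth_path))
}
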