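#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs. Exactly one of `input`
#' (paths to `areas.csv`, `samples.csv`, `compounds.csv`) or `simulation`
#' (a [simulation_config()]) must be supplied.
#'
#' @param input Optional named list/vector with elements `areas`, `samples`,
#'   `compounds` (CSV paths).
#' @param simulation Optional [simulation_config()].
#' @param comparison Which similarity analyses to run; any of `"marks"`,
#'   `"gland-vs-marks"`, `"bouquet-vs-marks"`.
#' @param presence_threshold Substance-filter presence threshold.
#' @param band_k Kovats band half-width.
#' @param enrichment_threshold Exogenous fold-enrichment limit.
#' @param ratio_threshold Proportional-contribution limit.
#' @param prune_k IQR multiplier of the outlier fence.
#' @param seed Integer seed (overrides the simulation config's seed).
#' @param out_dir Output directory for artifacts; `NULL` for none.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            comparison = c("marks", "gland-vs-marks",
                                           "bouquet-vs-marks"),
                            presence_threshold = 0, band_k = 2,
                            enrichment_threshold = 2, ratio_threshold = 2,
                            prune_k = 3, seed = NULL, out_dir = NULL) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of input paths or a simulation config must be supplied")
  comparison <- match.arg(comparison, several.ok = TRUE)
  if (!is.null(simulation)) {
    if (!inherits(simulation, "simulation_config"))
      stop("simulation must be a simulation_config")
    if (!is.null(seed)) simulation$seed <- as.integer(seed)
  }
  if (!is.null(input)) {
    need <- c("areas", "samples", "compounds")
    if (!all(need %in% names(input)))
      stop("input needs elements: ", paste(need, collapse = ", "))
  }
  structure(list(input = input, simulation = simulation,
                 comparison = comparison,
                 presence_threshold = presence_threshold,
                 band_k = band_k,
                 enrichment_threshold = enrichment_threshold,
                 ratio_threshold = ratio_threshold,
                 prune_k = prune_k,
                 seed = if (is.null(seed) && !is.null(simulation))
                   simulation$seed else seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

run_similarity_stage <- function(mat, meta, group_a, group_b, prune_k) {
  clr <- clr_transform(quantile_normalize(mat))
  fm <- pca_factor_scores(clr)
  sed <- sed_matrix(fm$scores)
  ps <- label_pairs(sed, meta, group_a, group_b)
  ps <- prune_outliers(ps, k_iqr = prune_k)
  list(clr = clr, factor_model = fm, sed = sed, pairset = ps,
       glm = wald_glm(ps), summary = summarize_similarity(ps))
}

#' Run the full scent-mark analysis pipeline
#'
#' Executes simulate/read -> substance filter & private-substance screen ->
#' quantile normalization & clr -> source attribution -> similarity analyses
#' -> UPGMA heatmap reporting, writing every intermediate artifact when an
#' output directory is configured. Reruns with the same configuration and
#' seed are numerically identical.
#'
#' The three similarity analyses are:
#' \describe{
#'   \item{marks}{all retained mark compounds, mark-vs-mark pairs (same nest
#'     vs different nests).}
#'   \item{gland-vs-marks}{Dufour-band compounds, gland extracts crossed with
#'     marks (same bee vs different bees).}
#'   \item{bouquet-vs-marks}{estimated individual bouquets crossed with
#'     marks.}
#' }
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `table`,
#'   `filter_report`, `private`, `attribution` (when requested), one entry
#'   per comparison under `analyses`, `cluster` (sorted mark clustering +
#'   `tag_adjacency`), `summary` (plain list, also written as JSON), and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- character()

  ## stage: data
  sim <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_dataset(config$simulation)
    table <- sim$peak_table
    if (!is.null(out)) {
      p <- write_synthetic_dataset(sim, file.path(out, "input"))
      paths <- c(paths, p)
    }
  } else {
    table <- read_peak_table(config$input[["areas"]],
                             config$input[["samples"]],
                             config$input[["compounds"]])
  }
  meta <- table$sample_meta

  ## stage: preprocessing
  mark_sources <- intersect(c("mark1", "mark2"), meta$source)
  report <- filter_substances(table, mark_sources,
                              presence_threshold = config$presence_threshold)
  private <- detect_private_substances(table, report)
  mark_ids <- meta$sample_id[meta$source %in% mark_sources]
  marks <- table$areas[mark_ids, report$retained, drop = FALSE]

  analyses <- list()
  if ("marks" %in% config$comparison) {
    analyses[["marks"]] <- run_similarity_stage(
      marks, meta, mark_sources, mark_sources, config$prune_k)
  }

  ## stage: attribution (needed for the bee-vs-mark comparisons)
  attribution <- NULL
  need_attr <- any(c("gland-vs-marks", "bouquet-vs-marks") %in%
                     config$comparison)
  if (need_attr) {
    attribution <- attribute_sources(
      table,
      presence_threshold = config$presence_threshold,
      band_k = config$band_k,
      enrichment_threshold = config$enrichment_threshold,
      ratio_threshold = config$ratio_threshold)
  }

  if ("gland-vs-marks" %in% config$comparison) {
    gl_ids <- meta$sample_id[meta$source == "gland"]
    comp <- attribution$dufour_retained
    mat <- table$areas[c(gl_ids, mark_ids), comp, drop = FALSE]
    analyses[["gland-vs-marks"]] <- run_similarity_stage(
      mat, meta, "gland", mark_sources, config$prune_k)
  }

  if ("bouquet-vs-marks" %in% config$comparison) {
    comp <- attribution$bouquet_compounds
    bq <- attribution$bouquets
    rownames(bq) <- paste0(rownames(attribution$bouquets), "_bouquet")
    mat <- rbind(bq, table$areas[mark_ids, comp, drop = FALSE])
    bq_meta <- data.frame(sample_id = rownames(bq),
                          nest_id = rownames(attribution$bouquets),
                          source = "bouquet", stringsAsFactors = FALSE)
    meta2 <- rbind(meta[, c("sample_id", "nest_id", "source")], bq_meta)
    analyses[["bouquet-vs-marks"]] <- run_similarity_stage(
      mat, meta2, "bouquet", mark_sources, config$prune_k)
  }

  ## stage: reporting (marks heatmap, UPGMA + sorted dendrograms)
  cluster <- NULL
  if ("marks" %in% config$comparison) {
    clr <- analyses[["marks"]]$clr
    col_cl <- sort_dendrogram(upgma_cluster(as.matrix(stats::dist(clr))))
    row_cl <- sort_dendrogram(upgma_cluster(as.matrix(stats::dist(t(clr)))))
    adjacency <- tag_adjacency(col_cl, meta)
    cluster <- list(columns = col_cl, rows = row_cl,
                    tag_adjacency = adjacency)
    if (!is.null(out)) {
      ann_col <- data.frame(source = meta$source[match(rownames(clr),
                                                       meta$sample_id)],
                            row.names = rownames(clr))
      ann_row <- data.frame(
        class = table$annotations$compound_class[
          match(colnames(clr), table$annotations$name)],
        row.names = colnames(clr))
      hm <- render_heatmap(t(clr), row_cl, col_cl,
                           file.path(out, "marks_heatmap.png"),
                           annotation_row = ann_row,
                           annotation_col = ann_col)
      paths <- c(paths, heatmap = hm$image, leaf_orders = hm$leaf_orders)
    }
  }

  ## summary
  summarize_analysis <- function(a) {
    list(n_factors = a$factor_model$n_factors,
         explained_pct = a$factor_model$explained_pct,
         n_pairs = a$glm$n,
         n_pruned = nrow(a$pairset$pruned),
         W = a$glm$W, p = a$glm$p,
         median_sed = stats::setNames(a$summary$median, a$summary$class),
         class_n = stats::setNames(a$summary$n, a$summary$class))
  }
  summary <- list(
    n_samples = nrow(table$areas),
    n_compounds_initial = ncol(table$areas),
    n_compounds_retained = length(report$retained),
    dropped_absent = length(report$dropped_absent),
    dropped_background = length(report$dropped_background),
    private_substances = private,
    thresholds = list(presence = config$presence_threshold,
                      band_k = config$band_k,
                      enrichment = config$enrichment_threshold,
                      ratio = config$ratio_threshold,
                      prune_k = config$prune_k),
    seed = config$seed,
    analyses = lapply(analyses, summarize_analysis)
  )
  if (need_attr) {
    summary$attribution <- list(
      universe = length(attribution$universe),
      dufour_retained = length(attribution$dufour_retained),
      exogenous_discarded = length(attribution$exogenous_discarded),
      bouquet_compounds = length(attribution$bouquet_compounds))
  }
  if (!is.null(cluster)) summary$tag_adjacency <- cluster$tag_adjacency

  if (!is.null(out)) {
    sp <- file.path(out, "summary.json")
    jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    fp <- file.path(out, "filter_report.json")
    jsonlite::write_json(list(retained = report$retained,
                              dropped_absent = report$dropped_absent,
                              dropped_background = report$dropped_background,
                              private = private),
                         fp, auto_unbox = TRUE, pretty = TRUE)
    lg <- file.path(out, "run_log.txt")
    writeLines(c(paste("scentmark version:",
                       as.character(utils::packageVersion("scentmark"))),
                 paste("R version:", R.version.string),
                 paste("seed:", ifelse(is.null(config$seed), "NA",
                                       config$seed)),
                 paste("comparisons:", paste(config$comparison,
                                             collapse = ", "))),
               lg)
    for (nm in names(analyses)) {
      utils::write.csv(analyses[[nm]]$sed,
                       file.path(out, paste0("sed_", gsub("[^a-z]+", "_", nm),
                                             ".csv")))
    }
    paths <- c(paths, summary = sp, filter_report = fp, log = lg)
  }

  structure(list(table = table, simulation = sim, filter_report = report,
                 private = private, attribution = attribution,
                 analyses = analyses, cluster = cluster, summary = summary,
                 paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("scentmark pipeline run\n")
  cat("  samples:", x$summary$n_samples,
      " compounds retained:", x$summary$n_compounds_retained, "/",
      x$summary$n_compounds_initial, "\n")
  for (nm in names(x$analyses)) {
    a <- x$summary$analyses[[nm]]
    cat(sprintf("  %s: %d factors (%.2f%%), n = %d, W = %.3f, p = %.4g\n",
                nm, a$n_factors, a$explained_pct, a$n_pairs, a$W, a$p))
    cat(sprintf("    median SED same = %.3f (n = %d), different = %.3f (n = %d)\n",
                a$median_sed[["same"]], a$class_n[["same"]],
                a$median_sed[["different"]], a$class_n[["different"]]))
  }
  if (!is.null(x$summary$tag_adjacency))
    cat("  nests with adjacent tags in the mark dendrogram:",
        x$summary$tag_adjacency, "\n")
  invisible(x)
}
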