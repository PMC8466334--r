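SAMPLE_SOURCES <- c("mark1", "mark2", "head", "gland", "control_sleeve",
                    "blank")

# mark sources beyond the two-sleeve default design (mark3, ...) are legal
is_valid_source <- function(source) {
  source %in% SAMPLE_SOURCES | grepl("^mark[0-9]+$", source)
}

#' Construct and validate a peak table
#'
#' The central container of the pipeline: a samples x compounds matrix of
#' non-negative GC/MS peak areas (arbitrary integrated-area units) with
#' aligned sample metadata and compound annotations. Alignment is enforced by
#' ID matching: rows of `areas` are matched to `sample_meta$sample_id` and
#' columns to `annotations$name`, so file or argument order never matters.
#'
#' @param areas Numeric matrix, samples in rows (rownames = sample IDs),
#'   compounds in columns (colnames = compound names).
#' @param sample_meta Data frame with columns `sample_id`, `nest_id`,
#'   `source`; `source` must be one of `mark1`, `mark2`, `head`, `gland`,
#'   `control_sleeve`, `blank`.
#' @param annotations Data frame with columns `name`, `compound_class`,
#'   `chain_length`, `db_position`, `kovats`.
#' @return A list of class `peak_table` with elements `areas`, `sample_meta`,
#'   `annotations`, rows/columns ordered as in `areas`.
#' @export
peak_table <- function(areas, sample_meta, annotations) {
  if (!is.matrix(areas) || !is.numeric(areas))
    stop("areas must be a numeric matrix")
  if (is.null(rownames(areas)) || is.null(colnames(areas)))
    stop("areas must carry sample IDs as rownames and compound names as colnames")
  if (anyDuplicated(rownames(areas)))
    stop("duplicate sample IDs in areas: ",
         paste(unique(rownames(areas)[duplicated(rownames(areas))]),
               collapse = ", "))
  if (anyDuplicated(colnames(areas)))
    stop("duplicate compound names in areas: ",
         paste(unique(colnames(areas)[duplicated(colnames(areas))]),
               collapse = ", "))
  bad <- which(!is.finite(areas) | areas < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-finite peak area at [",
         rownames(areas)[bad[1, 1]], ", ", colnames(areas)[bad[1, 2]], "]",
         if (nrow(bad) > 1) paste0(" (and ", nrow(bad) - 1, " more)") else "")

  need_meta <- c("sample_id", "nest_id", "source")
  if (!all(need_meta %in% names(sample_meta)))
    stop("sample_meta needs columns: ", paste(need_meta, collapse = ", "))
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(sample_meta$sample_id[duplicated(sample_meta$sample_id)]),
               collapse = ", "))
  if (!all(is_valid_source(sample_meta$source)))
    stop("unknown sample source: ",
         paste(unique(sample_meta$source[!is_valid_source(sample_meta$source)]),
               collapse = ", "))
  miss <- setdiff(rownames(areas), sample_meta$sample_id)
  if (length(miss))
    stop("sample IDs missing from metadata: ", paste(miss, collapse = ", "))
  extra <- setdiff(sample_meta$sample_id, rownames(areas))
  if (length(extra))
    stop("metadata sample IDs missing from areas: ",
         paste(extra, collapse = ", "))
  # at most one sample per (nest, source) for non-control samples
  bee <- sample_meta[!sample_meta$source %in% c("control_sleeve", "blank"), ]
  key <- paste(bee$nest_id, bee$source)
  if (anyDuplicated(key))
    stop("more than one sample per nest and source: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  need_ann <- c("name", "compound_class", "chain_length", "db_position",
                "kovats")
  if (!all(need_ann %in% names(annotations)))
    stop("annotations need columns: ", paste(need_ann, collapse = ", "))
  if (anyDuplicated(annotations$name))
    stop("duplicate compound names in annotations: ",
         paste(unique(annotations$name[duplicated(annotations$name)]),
               collapse = ", "))
  miss <- setdiff(colnames(areas), annotations$name)
  if (length(miss))
    stop("compounds missing from annotations: ", paste(miss, collapse = ", "))
  extra <- setdiff(annotations$name, colnames(areas))
  if (length(extra))
    stop("annotated compounds missing from areas: ",
         paste(extra, collapse = ", "))
  if (any(!is.finite(annotations$kovats)) || any(annotations$kovats <= 0))
    stop("Kovats indices must be positive")

  sample_meta <- sample_meta[match(rownames(areas), sample_meta$sample_id), ,
                             drop = FALSE]
  annotations <- annotations[match(colnames(areas), annotations$name), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  rownames(annotations) <- NULL
  structure(list(areas = areas, sample_meta = sample_meta,
                 annotations = annotations),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("Peak table:", nrow(x$areas), "samples x", ncol(x$areas), "compounds\n")
  print(table(x$sample_meta$source))
  invisible(x)
}

#' Subset a peak table
#'
#' @param table A `peak_table`.
#' @param samples Sample IDs (or logical/integer index) to keep; default all.
#' @param compounds Compound names (or index) to keep; default all.
#' @return A `peak_table` restricted to the requested rows/columns.
#' @export
subset_peak_table <- function(table, samples = NULL, compounds = NULL) {
  stopifnot(inherits(table, "peak_table"))
  a <- table$areas
  if (!is.null(samples)) a <- a[samples, , drop = FALSE]
  if (!is.null(compounds)) a <- a[, compounds, drop = FALSE]
  peak_table(a,
             table$sample_meta[table$sample_meta$sample_id %in% rownames(a), ],
             table$annotations[table$annotations$name %in% colnames(a), ])
}

#' Read a peak table from CSV files
#'
#' Reads the three standard pipeline inputs: `areas.csv` (first column
#' `sample_id`, remaining columns one per compound), `samples.csv`
#' (`sample_id`, `nest_id`, `source`) and `compounds.csv` (`name`,
#' `compound_class`, `chain_length`, `db_position`, `kovats`). Alignment is
#' by ID, not file order; mismatches and invalid values are hard errors
#' naming the offenders.
#'
#' @param areas_path,meta_path,annot_path Paths to the three CSV files.
#' @return A validated [peak_table()].
#' @export
read_peak_table <- function(areas_path, meta_path, annot_path) {
  for (pth in c(areas_path, meta_path, annot_path))
    if (!file.exists(pth)) stop("file not found: ", pth)
  araw <- utils::read.csv(areas_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(araw)[1] != "sample_id")
    stop("first column of ", areas_path, " must be 'sample_id'")
  vals <- araw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stop("non-numeric area at [", araw$sample_id[bad[1]], ", ",
           names(vals)[j], "]")
    vals[[j]] <- v
  }
  areas <- as.matrix(vals)
  rownames(areas) <- araw$sample_id
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  annot <- utils::read.csv(annot_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  peak_table(areas, meta, annot)
}

#' Write a peak table to CSV files
#'
#' Emits `areas.csv`, `samples.csv` and `compounds.csv` into `dir`. Numeric
#' areas are written with 15 significant digits so that write -> read
#' round-trips agree to well below 1e-12 relative error, and the byte output
#' is deterministic for a given table.
#'
#' @param table A `peak_table`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_peak_table <- function(table, dir) {
  stopifnot(inherits(table, "peak_table"))
  if (ncol(table$areas) == 0) stop("peak table has no compounds; nothing to write")
  if (nrow(table$areas) == 0) stop("peak table has no samples; nothing to write")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) sub("^\\s+", "", formatC(x, digits = 15, format = "g"))
  fm <- matrix(fmt(as.vector(table$areas)), nrow = nrow(table$areas),
               dimnames = dimnames(table$areas))
  adf <- data.frame(sample_id = rownames(table$areas), fm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  paths <- c(areas = file.path(dir, "areas.csv"),
             samples = file.path(dir, "samples.csv"),
             compounds = file.path(dir, "compounds.csv"))
  utils::write.csv(adf, paths["areas"], row.names = FALSE, quote = FALSE)
  utils::write.csv(table$sample_meta, paths["samples"], row.names = FALSE,
                   quote = FALSE)
  ann <- table$annotations
  ann$kovats <- fmt(ann$kovats)
  utils::write.csv(ann, paths["compounds"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
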