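# Delimited-text readers and writers. All files are TSV (or CSV for
# weights, auto-detected), floats are written with 15 significant digits so
# round trips are lossless to ~1e-15 and outputs diff cleanly.

fmt_num <- function(x) sprintf("%.15g", x)

#' Read an inverse-weight matrix from a delimited text file
#'
#' Rows are channels, columns are components. The delimiter (tab or comma)
#' and an optional header row of component ids are auto-detected. The
#' matrix is validated like [inverse_weight_set()]: ragged rows,
#' non-numeric cells and zero-variance columns are rejected with the
#' offending coordinates.
#'
#' @param path Path to the weights file.
#' @param meta_path Optional path to a component metadata table (TSV with a
#'   `component_id` column).
#' @return An [inverse_weight_set()].
#' @export
read_weights <- function(path, meta_path = NULL) {
  if (!file.exists(path)) {
    stop_icclust("no such file: ", path, class = "icclust_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  m <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_icclust("non-numeric cell at row ", bad, ", column ", j,
                   class = "icclust_parse_error")
    }
    m[, j] <- v
  }
  meta <- if (!is.null(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  inverse_weight_set(m, meta)
}

#' @rdname read_weights
#' @param ws An [inverse_weight_set()].
#' @export
write_weights <- function(ws, path) {
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  lines <- apply(ws$weights, 1, function(row) {
    paste(fmt_num(row), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Write and read assignment tables
#'
#' The assignment table has one row per component with columns
#' `component_id`, `subject`, `cluster` (0 = others) and `sign` (the
#' polarity applied in the component's centroid; `NA` for outliers).
#' `read_assignment()` validates that component ids are contiguous and
#' returns the table; the partition vector is its `cluster` column.
#'
#' @param assignment Data frame as produced by [cluster_ics()] (element
#'   `assignment`), or an integer partition vector.
#' @param path File path.
#' @return `read_assignment()` returns the assignment data frame.
#' @export
write_assignment <- function(assignment, path) {
  if (!is.data.frame(assignment)) {
    assignment <- data.frame(component_id = seq_along(assignment),
                             subject = NA_character_,
                             cluster = as.integer(assignment),
                             sign = NA_real_, stringsAsFactors = FALSE)
  }
  df <- assignment
  df$sign <- ifelse(is.na(df$sign), "NA", fmt_num(df$sign))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("component_id", "cluster")
  if (!all(need %in% names(df))) {
    stop_icclust("assignment table must have columns: ",
                 paste(need, collapse = ", "), class = "icclust_io_error")
  }
  n <- nrow(df)
  if (!identical(sort(as.integer(df$component_id)), seq_len(n))) {
    stop_icclust("component_id must be the contiguous integers 1..", n,
                 class = "icclust_validation_error")
  }
  if (any(df$cluster < 0)) {
    stop_icclust("cluster labels must be >= 0 (0 = others)",
                 class = "icclust_validation_error")
  }
  df[order(df$component_id), , drop = FALSE]
}

#' Serialize a validity report as JSON
#'
#' Writes the report with stable field order (`QI`, `QIhat`, `Sh`, `DB`,
#' `RIm`, `n_clusters`, `n_others`, plus the per-cluster table) so
#' repeated runs diff cleanly.
#'
#' @param report A [cvi_report()].
#' @param path File path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cvi_report"))
  out <- list(QI = report$QI, QIhat = report$QIhat, Sh = report$Sh,
              DB = report$DB, RIm = report$RIm,
              n_clusters = report$n_clusters, n_others = report$n_others,
              per_cluster = report$per_cluster)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write centroid maps and the centroid-connection edge list
#'
#' Centroids: TSV with rows = channels and one column per cluster label.
#' Edges: TSV with columns `cluster`, `component_id`, `similarity`.
#'
#' @param result An `icclust_result` from [cluster_ics()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return The directory, invisibly. Files written: `assignment.tsv`,
#'   `metrics.json`, `centroids.tsv`, `edges.tsv`, `manifest.json`.
#' @export
write_run <- function(result, dir, seed = result$config$rng_seed) {
  stopifnot(inherits(result, "icclust_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_assignment(result$assignment, file.path(dir, "assignment.tsv"))
  write_report(result$report, file.path(dir, "metrics.json"))
  if (!is.null(result$centroids)) {
    hdr <- paste(colnames(result$centroids), collapse = "\t")
    lines <- apply(result$centroids, 1, function(row) {
      paste(fmt_num(row), collapse = "\t")
    })
    writeLines(c(hdr, lines), file.path(dir, "centroids.tsv"))
  }
  if (!is.null(result$edges)) {
    df <- result$edges
    df$similarity <- fmt_num(df$similarity)
    utils::write.table(df, file.path(dir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "icclust",
    version = as.character(utils::packageVersion("icclust")),
    seed = seed,
    k = result$k,
    config = unclass(result$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
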