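# Interchange formats: delimited ECG traces with JSON ground-truth
# sidecars, tab-separated genotype-count and expression tables.

#' Write a recording as delimited text
#'
#' Header `time_s,DI,...,V4`, one row per sample, voltages in mV. When the
#' recording carries synthetic ground truth it is written to a JSON sidecar
#' (`<path>.json`) holding the per-beat event times, the anomaly ledger and
#' the generating preset.
#'
#' @param recording an `ecg_recording`.
#' @param path output CSV path.
#' @param sidecar write the ground-truth sidecar when available.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, sidecar = TRUE) {
  stopifnot(inherits(recording, "ecg_recording"))
  df <- data.frame(time_s = recording_time(recording))
  for (l in names(recording$leads)) df[[l]] <- recording$leads[[l]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar && !is.null(recording$ground_truth)) {
    gt <- recording$ground_truth
    pr <- gt$preset
    pr$amplitudes <- as.data.frame(pr$amplitudes)
    side <- list(
      animal_id = recording$animal_id,
      genotype = recording$genotype,
      sampling_rate = recording$sampling_rate,
      duration = recording$duration,
      preset = unclass(pr),
      beats = gt$beats,
      anomalies = gt$anomalies
    )
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Validates the schema: all ten leads present (missing columns are named
#' in the error), strictly monotone uniformly sampled time.
#'
#' @param path CSV path.
#' @param animal_id,genotype labels (defaults from the sidecar when present).
#' @return an `ecg_recording` (without ground truth unless the sidecar is
#'   read alongside).
#' @export
read_recording <- function(path, animal_id = NULL, genotype = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing column: time_s")
  missing_leads <- setdiff(ECG_LEADS, names(df))
  if (length(missing_leads)) {
    stop("missing lead column(s): ", paste(missing_leads, collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stop("non-monotone time at row(s): ",
         paste(utils::head(which(dt <= 0) + 1L, 5), collapse = ", "))
  }
  if (diff(range(dt)) > 1e-9) {
    stop("non-uniform sampling: mixed sample intervals within one file")
  }
  fs <- 1 / mean(dt)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else NULL
  structure(list(
    animal_id = animal_id %||% side$animal_id %||% basename(path),
    genotype = genotype %||% side$genotype %||% NA_character_,
    sampling_rate = round(fs),
    duration = nrow(df) / round(fs),
    leads = lapply(stats::setNames(ECG_LEADS, ECG_LEADS), function(l) df[[l]]),
    ground_truth = NULL
  ), class = "ecg_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a genotype-count table
#'
#' Tab-separated columns: `cross`, `class`, `count`, `expected_ratio`.
#'
#' @param path TSV path.
#' @return list of [genotype_counts()] objects, one per cross.
#' @export
read_genotype_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cross", "class", "count", "expected_ratio")
  if (!all(need %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  lapply(split(df, df$cross), function(d) {
    genotype_counts(d$cross[1],
                    stats::setNames(d$count, d$class),
                    stats::setNames(d$expected_ratio, d$class))
  })
}

#' Write an expression experiment as tab-separated tables
#'
#' `<prefix>_log2.tsv` holds the gene x sample matrix; the companion
#' `<prefix>_genes.tsv` and `<prefix>_samples.tsv` hold the annotations.
#'
#' @param se a `SummarizedExperiment`.
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_expression <- function(se, prefix) {
  m <- .se_log2(se)
  p1 <- paste0(prefix, "_log2.tsv")
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     p1, sep = "\t", row.names = FALSE, quote = FALSE)
  p2 <- paste0(prefix, "_genes.tsv")
  utils::write.table(as.data.frame(SummarizedExperiment::rowData(se)),
                     p2, sep = "\t", row.names = FALSE, quote = FALSE)
  p3 <- paste0(prefix, "_samples.tsv")
  utils::write.table(as.data.frame(SummarizedExperiment::colData(se)),
                     p3, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read an expression experiment written by [write_expression()]
#'
#' @param prefix path prefix used at writing time.
#' @return a `SummarizedExperiment` with assay `log2`.
#' @export
read_expression <- function(prefix) {
  m <- utils::read.delim(paste0(prefix, "_log2.tsv"), check.names = FALSE)
  genes <- m$gene
  m <- as.matrix(m[, -1, drop = FALSE])
  rownames(m) <- genes
  rd <- utils::read.delim(paste0(prefix, "_genes.tsv"))
  cd <- utils::read.delim(paste0(prefix, "_samples.tsv"))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = m),
    rowData = S4Vectors::DataFrame(rd),
    colData = S4Vectors::DataFrame(cd, row.names = colnames(m))
  )
}
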