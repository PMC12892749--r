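#' Write per-region scores and a diagnostic report to disk
#'
#' Per-region metric scores go to `scores.tsv` (columns: region_id, band,
#' metric, raw, normalized, is_hub; one row per region per metric per
#' band), the diagnostic report to `report.json`. Both files round-trip
#' through [read_results].
#'
#' @param metrics named list of `node_metrics` objects (names = band) or a
#'   single object; may be `NULL`/empty.
#' @param report a `diagnostic_report` (see [diagnostics]) or `NULL`.
#' @param path output directory, created if absent.
#' @return `path`, invisibly.
#' @export
write_results <- function(metrics, report = NULL, path) {
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  if (file.access(path, 2L) != 0L) stop("unwritable output path: ", path)
  if (inherits(metrics, "node_metrics")) metrics <- list(metrics)
  rows <- list()
  for (band in names2(metrics)) {
    nm <- metrics[[band]]
    for (metric in c("dc", "dc_in", "dc_out")) {
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = seq_along(nm$auc[[metric]]),
        band = band, metric = metric,
        raw = nm$auc[[metric]],
        normalized = nm$normalized[[metric]],
        is_hub = seq_along(nm$auc[[metric]]) %in% nm$hubs[[metric]])
    }
  }
  if (length(rows) == 0L) {
    warning("no metrics supplied; writing header-only scores table")
    tab <- data.frame(region_id = integer(), band = character(),
                      metric = character(), raw = numeric(),
                      normalized = numeric(), is_hub = logical())
  } else tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(path, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report))
    jsonlite::write_json(unclass(report), file.path(path, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back results written by [write_results]
#' @param path directory containing `scores.tsv` / `report.json`.
#' @return list with elements `scores` (data.frame) and `report` (list or
#'   `NULL`).
#' @export
read_results <- function(path) {
  scores <- utils::read.delim(file.path(path, "scores.tsv"), sep = "\t")
  rp <- file.path(path, "report.json")
  report <- if (file.exists(rp)) jsonlite::read_json(rp, simplifyVector = TRUE)
            else NULL
  list(scores = scores, report = report)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- rep("", length(x))
  nm[nm == ""] <- as.character(seq_along(x))[nm == ""]
  nm
}

#' Per-patient clinical record
#'
#' @param patient_id text identifier.
#' @param resected_regions integer region ids (subset of 1..68) removed at
#'   surgery.
#' @param engel_class postoperative Engel outcome class, one of
#'   `"I"`, `"II"`, `"III"`, `"IV"` (class I = seizure-free, favorable).
#' @param n_regions atlas size for validation (default 68).
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(patient_id, resected_regions, engel_class,
                            n_regions = 68L) {
  resected_regions <- as.integer(resected_regions)
  if (!all(resected_regions %in% seq_len(n_regions)))
    stop("resected_regions must be region ids in 1..", n_regions)
  engel_class <- as.character(engel_class)
  if (!engel_class %in% c("I", "II", "III", "IV"))
    stop("engel_class must be one of I, II, III, IV")
  structure(list(patient_id = as.character(patient_id),
                 resected_regions = resected_regions,
                 engel_class = engel_class),
            class = "clinical_record")
}

#' Read per-patient clinical records from TSV
#'
#' Columns: `patient_id`, `resected_regions` (semicolon-separated 1-based
#' region ids), `engel_class` (I--IV).
#'
#' @param path TSV file.
#' @param n_regions atlas size for validation.
#' @return list of [clinical_record] objects.
#' @export
read_clinical <- function(path, n_regions = 68L) {
  if (!file.exists(path)) stop("cannot read clinical file: ", path)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    clinical_record(tab$patient_id[i],
                    as.integer(strsplit(as.character(tab$resected_regions[i]),
                                        ";", fixed = TRUE)[[1]]),
                    tab$engel_class[i], n_regions = n_regions))
}
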