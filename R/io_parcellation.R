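#' Cortical parcellation table
#'
#' Assignment of source-grid vertices to cortical regions. The default
#' atlas is the 68-region Desikan--Killiany parcellation (34 regions per
#' hemisphere). Region ids and vertex ids are 1-based in files and in this
#' table; array code indexes rows directly.
#'
#' @param region_id integer vector 1..n_regions.
#' @param region_name character region labels.
#' @param hemisphere `"left"` or `"right"` per region.
#' @param vertex_ids list of integer vectors: vertices belonging to each
#'   region. Sets must be disjoint and non-empty.
#' @param n_regions expected region count (default 68).
#' @return An object of class `parcellation_table`.
#' @export
parcellation_table <- function(region_id, region_name, hemisphere, vertex_ids,
                               n_regions = 68L) {
  region_id <- as.integer(region_id)
  if (length(region_id) != n_regions)
    stop("parcellation must have exactly ", n_regions, " regions, got ",
         length(region_id))
  if (!setequal(region_id, seq_len(n_regions)))
    stop("region ids must be 1..", n_regions)
  if (!all(hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  vertex_ids <- lapply(vertex_ids, as.integer)
  if (any(lengths(vertex_ids) == 0L)) stop("every region must be non-empty")
  all_v <- unlist(vertex_ids)
  if (anyDuplicated(all_v))
    stop("vertex sets overlap: vertex ",
         paste(unique(all_v[duplicated(all_v)]), collapse = ", "),
         " assigned to more than one region")
  ord <- order(region_id)
  structure(list(region_id = region_id[ord],
                 region_name = as.character(region_name)[ord],
                 hemisphere = as.character(hemisphere)[ord],
                 vertex_ids = vertex_ids[ord]),
            class = "parcellation_table")
}

#' @export
print.parcellation_table <- function(x, ...) {
  cat(sprintf("<parcellation_table> %d regions (%d left / %d right), %d vertices\n",
              length(x$region_id), sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right"), length(unlist(x$vertex_ids))))
  invisible(x)
}

#' Read a parcellation table
#'
#' Expects a TSV with columns `region_id`, `region_name`, `hemisphere` and
#' `vertex_ids` (semicolon-separated 1-based vertex indices). With no
#' `path`, the packaged Desikan--Killiany table is loaded (one centroid
#' vertex per region, the default source grid of the pipeline).
#'
#' @param path TSV file; `NULL` for the packaged Desikan--Killiany atlas.
#' @param n_regions expected region count (default 68).
#' @return A [parcellation_table].
#' @export
read_parcellation <- function(path = NULL, n_regions = 68L) {
  if (is.null(path))
    path <- system.file("extdata", "desikan_killiany_68.tsv",
                        package = "eznetsi", mustWork = TRUE)
  if (!file.exists(path)) stop("cannot read parcellation file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("region_id", "region_name", "hemisphere", "vertex_ids")
  if (!all(need %in% colnames(tab)))
    stop("parcellation table must have columns: ",
         paste(need, collapse = ", "))
  vids <- lapply(strsplit(as.character(tab$vertex_ids), ";", fixed = TRUE),
                 as.integer)
  parcellation_table(tab$region_id, tab$region_name, tab$hemisphere, vids,
                     n_regions = n_regions)
}

#' Identity parcellation for a region-centroid source grid
#'
#' One vertex per region (vertex i = region i), used when sources are
#' placed at region centroids so that source rows and regions coincide.
#'
#' @param n_regions number of regions/sources.
#' @return A [parcellation_table].
#' @export
centroid_parcellation <- function(n_regions) {
  half <- ceiling(n_regions / 2)
  parcellation_table(seq_len(n_regions),
                     sprintf("region_%02d", seq_len(n_regions)),
                     rep(c("left", "right"), c(half, n_regions - half)),
                     as.list(seq_len(n_regions)),
                     n_regions = n_regions)
}
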