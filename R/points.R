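# Point tables: data frames with a `label` column, numeric coordinate
# columns, and an optional final `truth` column carrying ground-truth
# cluster ids (ignored by clustering, used by evaluation).

as_point_table <- function(points) {
  if (is.matrix(points) && is.numeric(points)) {
    labels <- rownames(points)
    if (is.null(labels)) labels <- paste0("p", seq_len(nrow(points)))
    return(list(labels = as.character(labels),
                coords = unname(points), truth = NULL))
  }
  if (!is.data.frame(points))
    pf_stop("`points` must be a data frame or numeric matrix",
            "pfclust_argument_error")
  if (!"label" %in% names(points))
    pf_stop("point table needs a `label` column", "pfclust_format_error")
  labels <- as.character(points$label)
  truth <- NULL
  coord_cols <- setdiff(names(points), "label")
  if ("truth" %in% coord_cols) {
    truth <- points$truth
    coord_cols <- setdiff(coord_cols, "truth")
  }
  if (!length(coord_cols))
    pf_stop("point table has no coordinate columns", "pfclust_format_error")
  coords <- as.matrix(points[coord_cols])
  if (!is.numeric(coords))
    pf_stop("non-numeric coordinate columns in point table",
            "pfclust_format_error")
  if (anyDuplicated(labels))
    pf_stop(sprintf("duplicate point label: '%s'",
                    labels[anyDuplicated(labels)]),
            "pfclust_validation_error")
  if (any(!is.finite(coords)))
    pf_stop("non-finite coordinate in point table", "pfclust_validation_error")
  list(labels = labels, coords = unname(coords), truth = truth)
}

#' Read a point table from delimited text
#'
#' Expected layout: a header row, a `label` column, one column per
#' coordinate, and optionally a final `truth` column of ground-truth cluster
#' ids. Tab or comma delimited (auto-detected).
#'
#' @param path Path to the file.
#' @return A data frame with columns `label`, the coordinates, and `truth`
#'   when present.
#' @export
read_points <- function(path) {
  if (!file.exists(path))
    pf_stop(sprintf("no such file: %s", path), "pfclust_io_error")
  first <- readLines(path, n = 1L)
  if (!length(first))
    pf_stop(sprintf("empty file: %s", path), "pfclust_format_error")
  df <- tryCatch(
    read.table(path, header = TRUE, sep = detect_sep(first),
               check.names = FALSE, comment.char = ""),
    error = function(e) pf_stop(
      sprintf("cannot parse point table %s: %s", path, conditionMessage(e)),
      "pfclust_format_error"))
  as_point_table(df)  # validate
  df$label <- as.character(df$label)
  df
}

#' Write a point table as tab-delimited text
#'
#' Coordinates are written at full double precision, so a write/read round
#' trip is lossless well beyond 1e-9.
#'
#' @param points A point table data frame (see [read_points()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_points <- function(points, path) {
  as_point_table(points)  # validate
  df <- points
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) pf_stop(sprintf("cannot write %s", path), "pfclust_io_error")
  invisible(path)
}
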