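#' Read a community biomass table from delimited text
#'
#' The delimiter (tab or comma) is auto-detected from the header line; decimal
#' points are dots. The first column holds row identifiers. Orientation says
#' whether taxa are the rows or the columns of the file; the returned object
#' is always samples x taxa.
#'
#' @param path file path to a delimited text table.
#' @param orientation `"taxa_rows"` (taxa in rows, samples in columns) or
#'   `"taxa_cols"`.
#' @param label_path optional path to a two-column table (sample, class)
#'   mapping every sample to its class.
#' @return A validated [community_matrix()].
#' @export
read_community_table <- function(path,
                                 orientation = c("taxa_rows", "taxa_cols"),
                                 label_path = NULL) {
  orientation <- match.arg(orientation)
  m <- read_delim_matrix(path)
  if (orientation == "taxa_rows") m <- t(m)
  labels <- if (!is.null(label_path)) read_class_labels(label_path) else NULL
  community_matrix(m, class_label = labels)
}

#' Write a community biomass table
#'
#' Inverse of [read_community_table()]; always writes samples x taxa
#' (`taxa_cols` orientation) as tab-separated text with full precision.
#'
#' @param x a `community_matrix`.
#' @param path output file path.
#' @param label_path optional path for the two-column sample/class table.
#' @export
write_community_table <- function(x, path, label_path = NULL) {
  stopifnot(inherits(x, "community_matrix"))
  write_delim_matrix(x$biomass, path, id_name = "sample")
  if (!is.null(label_path)) {
    if (is.null(x$class_label)) stop("community matrix has no class labels")
    utils::write.table(
      data.frame(sample = sample_names(x), class = x$class_label),
      label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an environmental table (samples x variables)
#'
#' @param path delimited text file, samples in rows, first column = sample id.
#' @return An [environmental_table()].
#' @export
read_environmental_table <- function(path) {
  environmental_table(read_delim_matrix(path, allow_na = TRUE))
}

#' @rdname read_environmental_table
#' @param x an `environmental_table`.
#' @export
write_environmental_table <- function(x, path) {
  stopifnot(inherits(x, "environmental_table"))
  write_delim_matrix(x$values, path, id_name = "sample")
  invisible(path)
}

#' Read a two-column sample-to-class mapping
#'
#' @param path delimited text with columns sample, class (header required).
#' @return Named character vector, class per sample.
#' @export
read_class_labels <- function(path) {
  sep <- detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2) stop("label file needs two columns: sample, class")
  if (anyDuplicated(d[[1]]))
    stop("duplicate sample identifiers in label file")
  stats::setNames(as.character(d[[2]]), as.character(d[[1]]))
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

read_delim_matrix <- function(path, allow_na = FALSE) {
  sep <- detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = NA)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate identifiers in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  d <- d[, -1, drop = FALSE]
  if (anyDuplicated(colnames(d)))
    stop("duplicate identifiers in header: ",
         paste(unique(colnames(d)[duplicated(colnames(d))]), collapse = ", "))
  m <- as.matrix(d)
  if (is.character(m)) {
    suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) & !is.na(m) & m != "NA", arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                   colnames(d)[bad[1, 2]]))
    m <- num
  }
  storage.mode(m) <- "double"
  if (!allow_na && anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing value at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(d)[bad[1, 2]]))
  }
  rownames(m) <- ids
  m
}

write_delim_matrix <- function(m, path, id_name = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d)[1] <- id_name
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
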