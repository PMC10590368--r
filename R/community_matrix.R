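#' Community biomass matrix
#'
#' Container for a samples x taxa biomass table (mg l^-1), optionally carrying
#' a thermal-class label and a sampling date per sample. This is the central
#' input of the pipeline: every downstream stage (diversity, autoscaling,
#' correlation networks) consumes it.
#'
#' @param biomass numeric matrix, samples in rows, taxa in columns; must have
#'   unique, non-empty row and column names; values finite and >= 0.
#' @param class_label optional character vector naming a class per sample,
#'   either named by sample or in sample order; must cover every sample.
#' @param sample_date optional `Date` vector, one entry per sample.
#' @return An object of class `community_matrix`: a list with elements
#'   `biomass`, `class_label`, `sample_date`.
#' @examples
#' m <- matrix(rexp(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
#' cm <- community_matrix(m)
#' n_samples(cm)
#' @export
community_matrix <- function(biomass, class_label = NULL, sample_date = NULL) {
  biomass <- as.matrix(biomass)
  storage.mode(biomass) <- "double"
  if (is.null(rownames(biomass)) || is.null(colnames(biomass)))
    stop("biomass matrix must carry sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(biomass)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(biomass)[duplicated(rownames(biomass))]),
               collapse = ", "))
  if (anyDuplicated(colnames(biomass)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(biomass)[duplicated(colnames(biomass))]),
               collapse = ", "))
  bad <- which(!is.finite(biomass) | biomass < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-finite biomass at sample '%s', taxon '%s'",
                 rownames(biomass)[bad[1, 1]], colnames(biomass)[bad[1, 2]]))
  if (!is.null(class_label)) {
    class_label <- as.character(class_label)
    if (!is.null(names(class_label))) {
      missing <- setdiff(rownames(biomass), names(class_label))
      if (length(missing) > 0)
        stop("class_label missing for samples: ",
             paste(missing, collapse = ", "))
      class_label <- class_label[rownames(biomass)]
    } else {
      if (length(class_label) != nrow(biomass))
        stop("class_label must have one entry per sample")
      names(class_label) <- rownames(biomass)
    }
    if (anyNA(class_label)) stop("class_label contains NA")
  }
  if (!is.null(sample_date)) {
    sample_date <- as.Date(sample_date)
    if (length(sample_date) != nrow(biomass))
      stop("sample_date must have one entry per sample")
    names(sample_date) <- rownames(biomass)
  }
  structure(list(biomass = biomass, class_label = class_label,
                 sample_date = sample_date),
            class = "community_matrix")
}

#' @rdname community_matrix
#' @param x a `community_matrix`.
#' @export
n_samples <- function(x) nrow(x$biomass)

#' @rdname community_matrix
#' @export
n_taxa <- function(x) ncol(x$biomass)

#' @rdname community_matrix
#' @export
taxa_names <- function(x) colnames(x$biomass)

#' @rdname community_matrix
#' @export
sample_names <- function(x) rownames(x$biomass)

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d taxa\n",
              n_samples(x), n_taxa(x)))
  if (!is.null(x$class_label)) {
    tab <- table(x$class_label)
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a community matrix by class
#'
#' @param x a `community_matrix` with class labels.
#' @return Named list of single-class `community_matrix` objects.
#' @export
split_by_class <- function(x) {
  stopifnot(inherits(x, "community_matrix"))
  if (is.null(x$class_label)) stop("community matrix carries no class labels")
  lapply(split(sample_names(x), x$class_label), function(s) {
    community_matrix(x$biomass[s, , drop = FALSE],
                     class_label = x$class_label[s],
                     sample_date = if (is.null(x$sample_date)) NULL
                                   else x$sample_date[s])
  })
}

#' Environmental variable table
#'
#' Samples x variables table of physico-chemical measurements (temperature,
#' DO, pH, nutrients, suspended solids, ...). Values may be NA (explicitly
#' missing) but never infinite; variable names must be unique.
#'
#' @param values numeric matrix or data frame, samples in rows, variables in
#'   columns, with unique row and column names.
#' @return An object of class `environmental_table` wrapping the matrix.
#' @export
environmental_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("environmental table must carry sample and variable names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate variable names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(is.infinite(values)))
    stop("environmental values must be finite or NA")
  structure(list(values = values), class = "environmental_table")
}

#' @export
print.environmental_table <- function(x, ...) {
  cat(sprintf("environmental_table: %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Analysis configuration
#'
#' Run-level options shared across the pipeline.
#'
#' @param alpha two-sided significance level for edge inclusion
#'   (default 0.05, the P <= 0.05 edge rule).
#' @param correlation_method `"pearson"` (default) or `"spearman"`.
#' @param shannon_log_base logarithm base for diversity: `"e"` (default,
#'   nats), `"2"` or `"10"`.
#' @param min_occurrence_fraction fraction of samples in which a taxon must be
#'   non-zero to enter the network (default 0: every non-constant taxon).
#' @param path_metric_mode `"topological"` (hop counts, default) or
#'   `"weighted"` (|r| summed as edge length).
#' @param rng_seed integer seed used wherever the pipeline needs randomness.
#' @return An object of class `zoonet_config`.
#' @export
zoonet_config <- function(alpha = 0.05,
                          correlation_method = c("pearson", "spearman"),
                          shannon_log_base = c("e", "2", "10"),
                          min_occurrence_fraction = 0,
                          path_metric_mode = c("topological", "weighted"),
                          rng_seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
            is.numeric(min_occurrence_fraction),
            min_occurrence_fraction >= 0, min_occurrence_fraction <= 1)
  structure(list(alpha = alpha,
                 correlation_method = match.arg(correlation_method),
                 shannon_log_base = match.arg(shannon_log_base),
                 min_occurrence_fraction = min_occurrence_fraction,
                 path_metric_mode = match.arg(path_metric_mode),
                 rng_seed = as.integer(rng_seed)),
            class = "zoonet_config")
}

log_base_value <- function(base) {
  switch(base, e = exp(1), `2` = 2, `10` = 10,
         stop("unknown log base: ", base))
}
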