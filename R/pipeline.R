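#' Run the full analysis pipeline
#'
#' For each class: diversity summary, signed interaction network, global
#' network attributes and the per-taxon centrality table. Across classes:
#' group tests on per-sample diversity and total biomass, the pairwise
#' Jaccard similarity matrix, the class-aligned attribute comparison and,
#' when an environmental table is supplied, the boosted-trees variable
#' importance ranking.
#'
#' @param community a [community_matrix()]; when it carries class labels each
#'   class must have at least 4 samples (pairwise correlation significance is
#'   undefined below that).
#' @param env optional [environmental_table()] over the same samples.
#' @param config a [zoonet_config()].
#' @return Object of class `zoonet_report`: list with `config`, `diversity`,
#'   `jaccard`, `group_tests`, `networks`, `global_attributes`,
#'   `node_tables`, `comparison` (for >= 2 classes) and `importance` (when
#'   `env` given).
#' @export
run_pipeline <- function(community, env = NULL, config = zoonet_config()) {
  stopifnot(inherits(community, "community_matrix"))
  parts <- if (is.null(community$class_label))
             stats::setNames(list(community), "all")
           else split_by_class(community)
  small <- names(parts)[vapply(parts, n_samples, 1L) < 4]
  if (length(small) > 0)
    stop("classes with fewer than 4 samples (correlation significance ",
         "undefined): ", paste(small, collapse = ", "))
  networks <- lapply(parts, infer_network, config = config)
  globals <- lapply(networks, global_attributes,
                    mode = config$path_metric_mode)
  node_tables <- lapply(networks, node_table,
                        mode = config$path_metric_mode)
  diversity <- do.call(rbind, lapply(parts, diversity_report,
                                     log_base = config$shannon_log_base))
  rownames(diversity) <- NULL
  multi <- length(parts) >= 2
  report <- list(config = config, diversity = diversity,
                 networks = networks, global_attributes = globals,
                 node_tables = node_tables)
  if (multi) {
    report$jaccard <- jaccard_matrix(community)
    hvals <- lapply(parts, function(p) {
      b <- p$biomass[rowSums(p$biomass) > 0, , drop = FALSE]
      apply(b, 1, shannon_diversity, log_base = config$shannon_log_base)
    })
    bvals <- lapply(parts, function(p) rowSums(p$biomass))
    report$group_tests <- list(
      shannon = compare_groups(hvals, method = "anova_tukey",
                               alpha = config$alpha),
      biomass = compare_groups(bvals, method = "kruskal_wallis",
                               alpha = config$alpha))
    report$comparison <- compare_classes(networks,
                                         mode = config$path_metric_mode)
  }
  if (!is.null(env) && multi) {
    labels <- community$class_label[rownames(env$values)]
    if (anyNA(labels))
      stop("environmental table contains samples without class labels")
    report$importance <- rank_variables(env, labels,
                                        model = "boosted_trees",
                                        seed = config$rng_seed)
  }
  structure(report, class = "zoonet_report")
}

#' @export
print.zoonet_report <- function(x, ...) {
  cat("zoonet_report\n=============\n\nDiversity by class:\n")
  print(x$diversity, digits = 3)
  cat("\nGlobal network attributes:\n")
  for (nm in names(x$global_attributes)) {
    cat(sprintf("\n[%s]\n", nm))
    print(x$global_attributes[[nm]])
  }
  if (!is.null(x$jaccard)) {
    cat("\nJaccard similarity (%):\n")
    print(round(x$jaccard, 1))
  }
  if (!is.null(x$importance)) {
    cat("\nEnvironmental variable importance:\n")
    print(x$importance)
  }
  invisible(x)
}

#' Serialize a report to structured JSON
#'
#' Networks are embedded as edge tables; everything else is written as plain
#' data. Output is byte-stable for identical inputs, config and seed.
#'
#' @param report a `zoonet_report`.
#' @param path output file; omit to return the JSON string.
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "zoonet_report"))
  strip <- function(g) {
    lapply(unclass(g), function(v) if (is.numeric(v)) round(v, 10) else v)
  }
  out <- list(
    config = unclass(report$config),
    diversity = report$diversity,
    global_attributes = lapply(report$global_attributes, strip),
    node_tables = report$node_tables,
    edges = lapply(report$networks, network_edges),
    r_critical = lapply(report$networks, function(n) n$r_critical))
  if (!is.null(report$jaccard)) out$jaccard <- report$jaccard
  if (!is.null(report$group_tests))
    out$group_tests <- lapply(report$group_tests, function(t)
      list(method = t$method, statistic = t$statistic, p_value = t$p_value,
           letters = t$letters))
  if (!is.null(report$comparison))
    out$comparison <- report$comparison$attributes
  if (!is.null(report$importance))
    out$importance <- list(ranking = report$importance$ranking,
                           train_accuracy = report$importance$train_accuracy,
                           test_accuracy = report$importance$test_accuracy,
                           split_spec = report$importance$split_spec,
                           seed = report$importance$seed)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", matrix = "rowmajor",
                           pretty = TRUE, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Write Table-2/Table-3 shaped text summaries
#'
#' @param report a `zoonet_report`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the files written.
#' @export
write_summary_tables <- function(report, dir) {
  stopifnot(inherits(report, "zoonet_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  if (!is.null(report$comparison)) {
    f <- file.path(dir, "global_attributes.tsv")
    utils::write.table(report$comparison$attributes, f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(report$node_tables)) {
    f <- file.path(dir, sprintf("node_attributes_%s.tsv", nm))
    utils::write.table(report$node_tables[[nm]], f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "diversity.tsv")
  utils::write.table(report$diversity, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
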