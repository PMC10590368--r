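#' Shannon diversity H'
#'
#' H' = -sum p_i log(p_i) over taxa with positive biomass (or counts), in the
#' chosen logarithm base (natural log by default, i.e. nats).
#'
#' @param x nonnegative numeric vector of biomasses or counts, at least one
#'   positive entry.
#' @param log_base `"e"` (default), `"2"` or `"10"`.
#' @return H' >= 0.
#' @examples
#' shannon_diversity(rep(1, 4))          # log(4)
#' @export
shannon_diversity <- function(x, log_base = c("e", "2", "10")) {
  log_base <- match.arg(log_base)
  x <- as.numeric(x)
  if (any(x < 0, na.rm = TRUE)) stop("negative entries in abundance vector")
  if (!any(x > 0, na.rm = TRUE)) stop("all-zero abundance vector")
  as.numeric(vegan::diversity(x[!is.na(x)], index = "shannon",
                              base = log_base_value(log_base)))
}

#' Pielou evenness J'
#'
#' J' = H' / log(S) where S is the number of taxa with positive abundance.
#' Undefined (NA with a warning) for richness < 2.
#'
#' @inheritParams shannon_diversity
#' @return J' in `[0, 1]`, or NA for richness < 2.
#' @export
pielou_evenness <- function(x, log_base = c("e", "2", "10")) {
  log_base <- match.arg(log_base)
  x <- as.numeric(x)
  s <- sum(x > 0, na.rm = TRUE)
  if (s < 2) {
    warning("evenness undefined for richness < 2")
    return(NA_real_)
  }
  shannon_diversity(x, log_base) / log(s, base = log_base_value(log_base))
}

#' Jaccard similarity of two taxon sets, as a percentage
#'
#' P' = 100 |A intersect B| / |A union B|. Two empty sets are defined as
#' identical (100, with a warning).
#'
#' @param taxa_a,taxa_b character vectors of taxon identifiers (treated as
#'   sets).
#' @return Similarity percentage in `[0, 100]`.
#' @export
jaccard_similarity <- function(taxa_a, taxa_b) {
  a <- unique(as.character(taxa_a))
  b <- unique(as.character(taxa_b))
  if (length(a) == 0 && length(b) == 0) {
    warning("both taxon sets empty; similarity defined as 100")
    return(100)
  }
  100 * length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise Jaccard similarity matrix across classes
#'
#' Taxon sets per class are the taxa with positive biomass in at least one
#' sample of the class.
#'
#' @param x a [community_matrix()] with class labels.
#' @return Symmetric percentage matrix with 100 on the diagonal.
#' @export
jaccard_matrix <- function(x) {
  parts <- split_by_class(x)
  sets <- lapply(parts, function(p) taxa_names(p)[colSums(p$biomass > 0) > 0])
  k <- length(sets)
  m <- matrix(100, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j)
    m[i, j] <- m[j, i] <- jaccard_similarity(sets[[i]], sets[[j]])
  m
}

#' Per-class diversity summary
#'
#' Computes H', J' and richness per sample and reports their class mean and
#' SD alongside mean total biomass (mirroring the per-class mean +- SD
#' presentation of community summaries). Pooled-community values are also
#' returned.
#'
#' @param x a [community_matrix()] for one class (or with labels, one row per
#'   class is produced via [diversity_table()]).
#' @param log_base Shannon log base.
#' @return data.frame with one row: class, n_samples, richness (pooled),
#'   mean/sd of per-sample H', J', richness and total biomass, and pooled H'
#'   and J'.
#' @export
diversity_report <- function(x, log_base = c("e", "2", "10")) {
  stopifnot(inherits(x, "community_matrix"))
  log_base <- match.arg(log_base)
  b <- x$biomass
  ok <- rowSums(b) > 0
  h <- apply(b[ok, , drop = FALSE], 1, shannon_diversity, log_base = log_base)
  j <- suppressWarnings(
    apply(b[ok, , drop = FALSE], 1, pielou_evenness, log_base = log_base))
  rich <- rowSums(b > 0)
  pooled <- colSums(b)
  cls <- if (!is.null(x$class_label)) unique(x$class_label) else NA_character_
  data.frame(class = if (length(cls) == 1) cls else NA_character_,
             n_samples = nrow(b),
             richness_total = sum(pooled > 0),
             H_mean = mean(h), H_sd = stats::sd(h),
             J_mean = mean(j, na.rm = TRUE), J_sd = stats::sd(j, na.rm = TRUE),
             richness_mean = mean(rich), richness_sd = stats::sd(rich),
             biomass_mean = mean(rowSums(b)), biomass_sd = stats::sd(rowSums(b)),
             H_pooled = shannon_diversity(pooled, log_base),
             J_pooled = suppressWarnings(pielou_evenness(pooled, log_base)),
             stringsAsFactors = FALSE)
}

#' @rdname diversity_report
#' @export
diversity_table <- function(x, log_base = c("e", "2", "10")) {
  log_base <- match.arg(log_base)
  parts <- split_by_class(x)
  out <- do.call(rbind, lapply(parts, diversity_report, log_base = log_base))
  rownames(out) <- NULL
  out
}

#' Compare a measurement across classes
#'
#' Omnibus test of class differences: one-way ANOVA with Tukey's HSD
#' (`"anova_tukey"`) or the tie-corrected Kruskal-Wallis test
#' (`"kruskal_wallis"`). In ANOVA mode, when the omnibus p <= 0.05,
#' homogeneous-subset letters are assigned (groups sharing a letter do not
#' differ at the 0.05 level in Tukey's test).
#'
#' @param values named list of numeric vectors, one per class (>= 2 classes,
#'   >= 2 values each).
#' @param method `"anova_tukey"` or `"kruskal_wallis"`.
#' @param alpha significance level for the letter display (default 0.05).
#' @return List with `method`, `statistic` (F or H), `p_value`, `letters`
#'   (named character, NULL in Kruskal-Wallis mode or when omnibus p > alpha)
#'   and `pairwise` (Tukey table in ANOVA mode).
#' @export
compare_groups <- function(values, method = c("anova_tukey",
                                              "kruskal_wallis"),
                           alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.list(values), length(values) >= 2, !is.null(names(values)))
  if (any(vapply(values, length, 1L) < 2))
    stop("every class needs at least 2 values")
  y <- unlist(values, use.names = FALSE)
  grp <- factor(rep(names(values), vapply(values, length, 1L)),
                levels = names(values))
  # degenerate case: no variance anywhere and equal means
  if (stats::var(y) == 0)
    return(list(method = method, statistic = 0, p_value = 1,
                letters = NULL, pairwise = NULL))
  if (method == "kruskal_wallis") {
    kt <- stats::kruskal.test(y, grp)
    return(list(method = method, statistic = unname(kt$statistic),
                p_value = kt$p.value, letters = NULL, pairwise = NULL))
  }
  fit <- stats::aov(y ~ grp)
  sm <- summary(fit)[[1]]
  fstat <- sm[["F value"]][1]
  p <- sm[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$grp
  letters <- NULL
  if (is.finite(p) && p <= alpha)
    letters <- letter_display(names(values), tk[, "p adj"], alpha)
  list(method = method, statistic = unname(fstat), p_value = p,
       letters = letters, pairwise = tk)
}

# Compact letter display from pairwise adjusted p-values (names "b-a").
# Greedy insert-absorb: groups sharing a letter have pairwise p > alpha.
letter_display <- function(groups, pairwise_p, alpha = 0.05) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (nm in names(pairwise_p)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(pair) == 2 && all(pair %in% groups))
      sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <-
        pairwise_p[[nm]] <= alpha
  }
  subsets <- list()
  for (g in groups) {
    placed <- FALSE
    for (i in seq_along(subsets)) {
      if (!any(sig[g, subsets[[i]]])) {
        subsets[[i]] <- c(subsets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) subsets[[length(subsets) + 1]] <- g
  }
  out <- stats::setNames(rep("", k), groups)
  for (i in seq_along(subsets))
    for (g in subsets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' Spearman rank correlation with two-sided p-value
#'
#' Ties are mid-ranked; the p-value uses the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with `rho` and `p_value`; `rho` is NA (with a warning) when
#'   either vector is constant.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("rank correlation needs >= 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("rank correlation undefined for a constant vector")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
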