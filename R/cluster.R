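#' k-means profiling with elbow-based model selection
#'
#' Standardizes the effect table per condition (z-score), runs best-of-
#' `n_init` k-means for every k in `k_range`, and selects the elbow k as
#' the k maximizing the second difference of the within-cluster
#' sum-of-squares curve (the knee).  To guarantee a monotone within-SS
#' curve, each k is additionally warm-started from the previous solution's
#' centers plus the worst-fitted point.
#'
#' @param effects an [effect_table()] (cells x conditions).
#' @param k_range integer vector of cluster counts to scan.
#' @param seed integer seed (k-means is stochastic).
#' @param n_init random restarts per k.
#' @return object of class `cluster_profile`: list with `assignment`
#'   (named integer vector at the elbow k), `k`, `wss` (data.frame of the
#'   within-SS curve), `kmeans` (the selected [stats::kmeans()] fit) and
#'   `second_diff`.
#' @export
kmeans_profile <- function(effects, k_range = 1:10, seed = 1, n_init = 25) {
  stopifnot(inherits(effects, "effect_table"))
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(effects)) {
    stop("k_range exceeds the number of cells")
  }
  if (all(apply(unclass(effects), 2, stats::sd) == 0)) {
    warning("all cells identical: forcing k = 1")
    n <- nrow(effects)
    assignment <- rep(1L, n)
    names(assignment) <- rownames(effects)
    return(structure(list(assignment = assignment, k = 1L,
                          wss = data.frame(k = 1L, within_ss = 0),
                          kmeans = NULL, second_diff = NULL),
                     class = "cluster_profile"))
  }
  z <- standardize_effects(effects)
  n <- nrow(z)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fits <- vector("list", length(k_range))
  wss <- numeric(length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- suppressWarnings(stats::kmeans(z, centers = k, nstart = n_init,
                                          iter.max = 100))
    if (!is.null(prev)) {
      # warm start: previous centers plus the point they explain worst
      d2 <- rowSums((z - prev$centers[prev$cluster, , drop = FALSE])^2)
      extra_needed <- k - nrow(prev$centers)
      if (extra_needed > 0) {
        extra <- z[order(-d2)[seq_len(extra_needed)], , drop = FALSE]
        centers <- rbind(prev$centers, extra)
        if (anyDuplicated(centers) == 0) {
          warm <- suppressWarnings(tryCatch(
            stats::kmeans(z, centers = centers, iter.max = 100),
            error = function(e) NULL))
          if (!is.null(warm) && warm$tot.withinss < fit$tot.withinss) {
            fit <- warm
          }
        }
      }
    }
    fits[[i]] <- fit
    wss[i] <- fit$tot.withinss
    prev <- fit
  }
  # elbow: maximal second difference of the within-SS curve
  if (length(k_range) >= 3) {
    d2 <- wss[seq_len(length(wss) - 2)] - 2 * wss[seq(2, length(wss) - 1)] +
      wss[seq(3, length(wss))]
    names(d2) <- k_range[seq(2, length(k_range) - 1)]
    k_best <- k_range[which.max(d2) + 1]
  } else {
    d2 <- NULL
    k_best <- k_range[length(k_range)]
  }
  sel <- fits[[match(k_best, k_range)]]
  assignment <- sel$cluster
  names(assignment) <- rownames(z)
  structure(list(assignment = assignment, k = k_best,
                 wss = data.frame(k = k_range, within_ss = wss),
                 kmeans = sel, second_diff = d2),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("k-means profile: elbow k = %d over k = %s\n", x$k,
              paste(range(x$wss$k), collapse = "-")))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Ward hierarchical clustering of cells or conditions
#'
#' Clusters the z-scored effect profiles with Ward's agglomeration on
#' Euclidean distances.  `axis = "cells"` clusters the cells by their
#' condition profiles; `axis = "conditions"` clusters the conditions by
#' their standardized per-cell response vectors (the dendrogram that groups
#' pharmacologically related stimuli).
#'
#' @param effects an [effect_table()].
#' @param axis `"cells"` or `"conditions"`.
#' @return an [stats::hclust()] tree (class `profile_dendrogram`), heights
#'   non-decreasing along merges.
#' @export
hierarchical_profile <- function(effects, axis = c("cells", "conditions")) {
  axis <- match.arg(axis)
  stopifnot(inherits(effects, "effect_table"))
  z <- standardize_effects(effects)
  items <- if (axis == "cells") z else t(z)
  if (nrow(items) < 2) stop("need at least 2 items to cluster")
  h <- stats::hclust(stats::dist(items), method = "ward.D2")
  class(h) <- c("profile_dendrogram", "hclust")
  attr(h, "axis") <- axis
  h
}

#' @export
print.profile_dendrogram <- function(x, ...) {
  cat(sprintf("Ward dendrogram over %s (%d leaves)\n", attr(x, "axis"),
              length(x$labels)))
  invisible(x)
}

#' Export a dendrogram as Newick text
#' @param h a [hierarchical_profile()] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(h, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(stats::as.hclust(h)), file = path)
  invisible(path)
}

#' Condition contributions to the first two principal components
#'
#' PCA of the z-scored effect table; the contribution of condition `j` to
#' component `c` is its squared loading as a percentage of the component's
#' total squared loadings, so each component's contributions sum to 100.
#'
#' @param effects an [effect_table()] with at least 2 conditions and 3
#'   cells.
#' @return data.frame with columns `condition`, `pc1_contrib_pct`,
#'   `pc2_contrib_pct`; attribute `var_explained` holds the fraction of
#'   variance captured by each component.
#' @export
pca_contributions <- function(effects) {
  stopifnot(inherits(effects, "effect_table"))
  if (ncol(effects) < 2 || nrow(effects) < 3) {
    stop("PCA needs at least 2 conditions and 3 cells")
  }
  z <- standardize_effects(effects)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load2 <- p$rotation[, 1:2, drop = FALSE]^2
  contrib <- sweep(load2, 2, colSums(load2), "/") * 100
  out <- data.frame(condition = rownames(contrib),
                    pc1_contrib_pct = contrib[, 1],
                    pc2_contrib_pct = contrib[, 2], row.names = NULL)
  attr(out, "var_explained") <- p$sdev^2 / sum(p$sdev^2)
  out
}

# z-score per condition; zero-variance conditions are dropped with a warning
standardize_effects <- function(effects) {
  v <- unclass(effects)
  attr(v, "converged") <- NULL
  attr(v, "method_used") <- NULL
  attr(v, "method") <- NULL
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding zero-variance condition(s): %s",
                    paste(colnames(v)[sds == 0], collapse = ", ")))
    v <- v[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(v, center = TRUE, scale = sds)
}
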