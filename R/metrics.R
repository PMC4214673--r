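#' Fisher's discriminant ratio of labelled samples
#'
#' Measures class separability of a set of feature vectors as the
#' trace ratio of the between-class and within-class scatter matrices,
#' \deqn{FDR = trace(S_B) / trace(S_W),}
#' with \eqn{S_B = \sum_i n_i (\mu_i - \mu)(\mu_i - \mu)^T} over the
#' classes and \eqn{S_W = \sum_i \sum_{x \in i} (x - \mu_i)(x -
#' \mu_i)^T}.  The ratio is invariant to translation and to uniform
#' rescaling of the data.  Here the classes are odors and the samples
#' are firing-rate vectors (one dimension per glomerulus) or input
#' current vectors.
#'
#' @param X samples x features numeric matrix (no missing values).
#' @param labels class label per row; at least two classes, at least
#'   two samples per class.
#' @return non-negative scalar.
#' @examples
#' fisher_discriminant_ratio(matrix(c(0, 1, 3, 4)), c(1, 1, 2, 2))  # 9
#' @export
fisher_discriminant_ratio <- function(X, labels) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("one label per row required")
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least two classes")
  if (any(table(labels) < 2)) stop("need >= 2 samples per class")
  mu <- colMeans(X)
  tr_b <- 0
  tr_w <- 0
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    tr_b <- tr_b + nrow(Xi) * sum((mi - mu)^2)
    tr_w <- tr_w + sum(sweep(Xi, 2, mi)^2)
  }
  if (tr_w == 0) {
    stop("degenerate data: all samples identical within every class ",
         "(within-class scatter is zero)")
  }
  tr_b / tr_w
}

#' Pearson's product-moment correlation coefficient
#'
#' @param x,y numeric vectors of equal length `>= 2`; both must be
#'   non-constant (the coefficient is undefined otherwise).
#' @return scalar in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Correlation of a population response with stimulus concentration
#'
#' Quantifies how well a population's output encodes stimulus
#' intensity.  For each odor, the responses at its concentration
#' series are correlated with the concentration factors; the mean and
#' standard deviation of the per-odor coefficients are reported.
#'
#' Three readings of "response" are available:
#' \describe{
#'   \item{`pooled`}{every neuron's response is an observation: for an
#'     odor with `k` concentrations and `p` features, the correlation
#'     is computed over the `k * p` (response, concentration) pairs.
#'     Heterogeneity of the response across neurons within a stimulus
#'     counts against the correlation, so a population whose cells all
#'     track total stimulus intensity scores high while a
#'     combinatorially patterned population scores low.  This is the
#'     default and the reading used by the shipped experiments.}
#'   \item{`mean`}{each sample is scalarized as its mean over
#'     features before correlating (per-odor coefficients are then 1
#'     for any response exactly linear in concentration).}
#'   \item{`pc1`}{each sample is scalarized as its score on the first
#'     principal component of the full response matrix.}
#' }
#'
#' @param X samples x features response matrix (rates in Hz or input
#'   currents in pA).
#' @param odor odor label per sample.
#' @param concentration concentration factor per sample; every odor
#'   needs at least two distinct values.
#' @param method scalarization, see above.
#' @return list with `per_odor` (named coefficients), `mean`, `sd`,
#'   `method` and `excluded` (odors whose response was constant, for
#'   which the coefficient is undefined; they are reported and left
#'   out of the summary).
#' @export
concentration_correlation <- function(X, odor, concentration,
                                      method = c("pooled", "mean", "pc1")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  odor <- as.character(odor)
  odors <- unique(odor)
  for (o in odors) {
    if (length(unique(concentration[odor == o])) < 2) {
      stop("odor ", o, " has fewer than two distinct concentrations")
    }
  }
  scalar <- switch(method,
    mean = rowMeans(X),
    pc1 = stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1],
    pooled = NULL
  )
  per_odor <- stats::setNames(rep(NA_real_, length(odors)), odors)
  for (o in odors) {
    sel <- odor == o
    if (method == "pooled") {
      xx <- as.vector(X[sel, , drop = FALSE])
      yy <- rep(concentration[sel], times = ncol(X))
    } else {
      xx <- scalar[sel]
      yy <- concentration[sel]
    }
    if (stats::sd(xx) == 0) next  # flagged below
    per_odor[o] <- pearson_correlation(xx, yy)
  }
  excluded <- names(per_odor)[is.na(per_odor)]
  ok <- per_odor[!is.na(per_odor)]
  if (!length(ok)) stop("degenerate: every odor's response is constant")
  list(
    per_odor = per_odor,
    mean = mean(ok),
    sd = if (length(ok) > 1) stats::sd(ok) else 0,
    method = method,
    excluded = excluded
  )
}

#' Principal component scores and explained variance
#'
#' Column-mean-centered, unscaled PCA (all features share units).
#'
#' @param X samples x features matrix.
#' @param n_components number of components to return; default all.
#' @return list with `scores` (samples x `n_components`),
#'   `var_explained` (fractions for the returned components, ordered
#'   non-increasing) and `var_explained_all` (fractions for every
#'   component; they sum to 1).
#' @export
pca_scores <- function(X, n_components = NULL) {
  X <- as.matrix(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  k_max <- ncol(pc$x)
  if (is.null(n_components)) n_components <- k_max
  if (n_components > min(nrow(X) - 1, ncol(X))) {
    stop("n_components must be <= min(samples - 1, features)")
  }
  k <- seq_len(n_components)
  list(
    scores = pc$x[, k, drop = FALSE],
    var_explained = fr[k],
    var_explained_all = fr[seq_len(k_max)]
  )
}

#' Divisive hierarchical clustering via bisecting k-means
#'
#' Builds a cluster hierarchy top-down: starting from all samples in
#' one cluster, the cluster with the largest within-cluster sum of
#' squares is recursively split in two by k-means (Euclidean, several
#' seeded restarts, lowest inertia wins with ties broken by restart
#' index), until every cluster is a singleton.  The height of an
#' internal node is the mean Euclidean distance of the cluster's
#' members to the cluster centroid (duplicated points therefore merge
#' at height 0).
#'
#' @param X samples x features matrix, `>= 2` rows.
#' @param labels leaf names; default row names or `s1`, `s2`, ...
#' @param seed integer; the clustering is deterministic given the
#'   seed.
#' @param restarts k-means restarts per split.
#' @return a `glom_dendrogram`: list with `newick` (tree string with
#'   branch lengths), `labels`, `partitions` (`partitions[[k]]` is the
#'   integer membership vector after the first `k - 1` splits, i.e.
#'   the k-cluster partition induced by the split order), and the flat
#'   node table (`members`, `children`, `heights`).
#' @export
hierarchical_kmeans <- function(X, labels = NULL, seed = 1, restarts = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least two samples")
  if (is.null(labels)) {
    labels <- rownames(X)
    if (is.null(labels)) labels <- paste0("s", seq_len(n))
  }
  labels <- sanitize_newick_labels(labels)

  cluster_height <- function(idx) {
    if (length(idx) == 1) return(0)
    ctr <- colMeans(X[idx, , drop = FALSE])
    mean(sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2, ctr)^2)))
  }
  cluster_wss <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(sweep(X[idx, , drop = FALSE], 2,
              colMeans(X[idx, , drop = FALSE]))^2)
  }
  split_counter <- 0L
  bisect <- function(idx) {
    split_counter <<- split_counter + 1L
    Xi <- X[idx, , drop = FALSE]
    n_i <- length(idx)
    n_distinct <- nrow(unique(Xi))
    if (n_distinct < 2) {
      # all points identical: peel one off; height is 0 anyway
      return(list(idx[1], idx[-1]))
    }
    if (n_i == 2) {
      return(list(idx[1], idx[2]))  # the only bipartition
    }
    best <- NULL
    best_inertia <- Inf
    for (r in seq_len(restarts)) {
      km <- withr_seed(seed + 131L * split_counter + r, {
        suppressWarnings(
          stats::kmeans(Xi, centers = min(2L, n_distinct), nstart = 1)
        )
      })
      if (km$tot.withinss < best_inertia - 1e-12) {
        best_inertia <- km$tot.withinss
        best <- km$cluster
      }
    }
    if (length(unique(best)) < 2) {
      return(list(idx[1], idx[-1]))
    }
    list(idx[best == 1], idx[best == 2])
  }

  # queue-driven construction: the split order (largest within-cluster
  # sum of squares first) defines the k-cluster partitions
  node_of <- function(idx) list(members = idx, height = cluster_height(idx))
  partitions <- vector("list", n)
  memb <- rep(1L, n)
  partitions[[1]] <- memb
  nodes <- list(node_of(seq_len(n)))  # nodes[[1]] is the root
  kids <- list(NULL)
  open <- c(1L)              # node indices with >1 member, not yet split
  k <- 1L
  while (length(open)) {
    wss <- vapply(open, function(i) cluster_wss(nodes[[i]]$members),
                  numeric(1))
    pick <- open[which.max(wss)]
    open <- setdiff(open, pick)
    parts <- bisect(nodes[[pick]]$members)
    ids <- integer(2)
    for (j in 1:2) {
      nodes[[length(nodes) + 1L]] <- node_of(parts[[j]])
      ids[j] <- length(nodes)
      if (length(parts[[j]]) > 1) open <- c(open, length(nodes))
    }
    kids[[pick]] <- ids
    kids[ids] <- list(NULL)
    k <- k + 1L
    memb[parts[[2]]] <- k
    partitions[[k]] <- memb
  }
  # assemble newick from the flat representation
  to_newick <- function(i) {
    if (is.null(kids[[i]])) {
      if (length(nodes[[i]]$members) == 1) {
        return(labels[nodes[[i]]$members[1]])
      }
    }
    h <- nodes[[i]]$height
    parts <- vapply(kids[[i]], function(j) {
      bl <- max(h - nodes[[j]]$height, 0)
      paste0(to_newick(j), ":", format(bl, digits = 10))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  newick <- paste0(to_newick(1L), ";")
  structure(
    list(
      newick = newick,
      labels = labels,
      partitions = partitions,
      heights = vapply(nodes, `[[`, numeric(1), "height"),
      members = lapply(nodes, `[[`, "members"),
      children = kids
    ),
    class = "glom_dendrogram"
  )
}

sanitize_newick_labels <- function(x) {
  gsub("[,;:() \t]", "_", x)
}

#' @export
print.glom_dendrogram <- function(x, ...) {
  cat(sprintf("bisecting k-means dendrogram with %d leaves\n",
              length(x$labels)))
  invisible(x)
}

#' Cut a bisecting-k-means hierarchy into k clusters
#'
#' Returns the partition obtained after the first `k - 1` splits (the
#' splits are performed in order of decreasing within-cluster sum of
#' squares, so `k = 2` is the top split).
#'
#' @param dend a [hierarchical_kmeans()] result.
#' @param k number of clusters.
#' @return integer membership vector named by leaf labels.
#' @export
cut_clusters <- function(dend, k) {
  stopifnot(inherits(dend, "glom_dendrogram"))
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  stats::setNames(dend$partitions[[k]], dend$labels)
}

#' Convert to an ape phylogeny
#'
#' @param x a `glom_dendrogram`.
#' @param ... unused.
#' @return an [ape::read.tree()] phylo object.
#' @export
as_phylo <- function(x, ...) {
  stopifnot(inherits(x, "glom_dendrogram"))
  ape::read.tree(text = x$newick)
}

#' Write a dendrogram in Newick format
#'
#' @param dend a `glom_dendrogram`.
#' @param path file path.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "glom_dendrogram"))
  writeLines(dend$newick, path)
  invisible(path)
}
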