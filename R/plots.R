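#' Scores plot of the first two principal components
#'
#' Points are coloured by odor; increasing concentration is drawn as
#' increasing symbol size, so a population that normalizes away
#' concentration shows tight single-colour clusters while one that
#' encodes it shows colour-mixed rays.
#'
#' @param X samples x features matrix (rates or currents).
#' @param odor,concentration per-sample metadata.
#' @param main plot title.
#' @export
plot_pca_scores <- function(X, odor, concentration, main = "PCA scores") {
  pc <- pca_scores(X, n_components = 2)
  odor <- as.factor(odor)
  pal <- grDevices::hcl.colors(nlevels(odor), "Dark 3")
  cexs <- 0.6 + 1.4 * (rank(concentration) - 1) / max(1, length(concentration) - 1)
  graphics::plot(
    pc$scores[, 1], pc$scores[, 2],
    col = pal[as.integer(odor)], pch = 19, cex = cexs,
    xlab = sprintf("PC1 (%.1f%%)", 100 * pc$var_explained[1]),
    ylab = sprintf("PC2 (%.1f%%)", 100 * pc$var_explained[2]),
    main = main
  )
  graphics::legend("topright", legend = levels(odor), col = pal, pch = 19,
                   cex = 0.8, bty = "n")
  invisible(pc)
}

#' Plot a bisecting k-means dendrogram
#'
#' @param dend a [hierarchical_kmeans()] result.
#' @param main plot title.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot_dendrogram <- function(dend, main = "hierarchical clustering", ...) {
  phy <- as_phylo(dend)
  ape::plot.phylo(phy, cex = 0.6, main = main, ...)
  invisible(phy)
}

#' Plot the short-axon weight sweep curves
#'
#' Left axis: Fisher's discriminant ratio of the MC output, ET output
#' and input patterns; right panel: concentration correlation.
#'
#' @param sweep a [sa_weight_sweep()] result.
#' @export
plot_sweep <- function(sweep) {
  s <- sweep_summary(sweep)
  cv <- s$curves
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(
    cv$sa_weight, cbind(cv$fdr_mc, cv$fdr_et, cv$fdr_input),
    type = "b", pch = 19, lty = 1, col = c("firebrick", "steelblue", "grey40"),
    xlab = "SA synaptic weight (a.u.)", ylab = "Fisher discriminant ratio"
  )
  graphics::abline(v = s$argmax, lty = 3)
  graphics::legend("topright", c("MC", "ET", "input"), bty = "n",
                   col = c("firebrick", "steelblue", "grey40"), pch = 19)
  graphics::matplot(
    cv$sa_weight, cbind(cv$pcc_mc, cv$pcc_et, cv$pcc_input),
    type = "b", pch = 19, lty = 1, col = c("firebrick", "steelblue", "grey40"),
    xlab = "SA synaptic weight (a.u.)", ylab = "concentration PCC"
  )
  invisible(s)
}
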