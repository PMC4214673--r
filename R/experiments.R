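#' Metrics report for one labelled rate (or current) matrix
#'
#' Bundles the separability and concentration-coding measures used by
#' the experiments: Fisher's discriminant ratio with odors as classes,
#' per-odor concentration correlation (mean and sd across odors) and
#' PCA explained-variance fractions.
#'
#' @param X samples x features matrix.
#' @param odor,concentration per-sample metadata.
#' @param pcc_method scalarization for
#'   [concentration_correlation()].
#' @return list with `fdr`, `pcc_mean`, `pcc_sd`, `pcc_per_odor`,
#'   `pc1_var`, `var_explained` and `pca` scores.
#' @export
metrics_report <- function(X, odor, concentration, pcc_method = "pooled") {
  fdr <- tryCatch(fisher_discriminant_ratio(X, odor),
                  error = function(e) NA_real_)
  pcc <- tryCatch(
    concentration_correlation(X, odor, concentration, method = pcc_method),
    error = function(e) list(mean = NA_real_, sd = NA_real_,
                             per_odor = NULL, excluded = character(0))
  )
  pca <- pca_scores(X, n_components = min(3, nrow(X) - 1, ncol(X)))
  list(
    fdr = fdr,
    pcc_mean = pcc$mean,
    pcc_sd = pcc$sd,
    pcc_per_odor = pcc$per_odor,
    pcc_excluded = pcc$excluded,
    pc1_var = pca$var_explained_all[1],
    var_explained = pca$var_explained_all,
    pca = pca
  )
}

#' Odors-by-concentrations experiment
#'
#' Generates a seeded odor panel, builds the 6 odors x 6
#' concentrations stimulus set (36 stimuli), exposes the network to
#' each stimulus for the configured duration, and computes the metrics
#' report for the MC rates, the ET rates and the raw input currents.
#'
#' @param config a [network_config()].
#' @param seed panel seed (defaults to the config's `seed`).
#' @param pcc_method scalarization for the concentration correlation.
#' @return a `glom_experiment`: stimulus metadata, `mc_rates` and
#'   `et_rates` (36 x n_glomeruli, Hz), `input` currents (36 x
#'   n_glomeruli, pA), per-population `metrics`, the config snapshot
#'   and the seed.
#' @export
run_experiment1 <- function(config = network_config(), seed = NULL,
                            pcc_method = "pooled") {
  stopifnot(inherits(config, "network_config"))
  if (is.null(seed)) seed <- config$seed
  panel <- generate_odor_panel(6, config$n_glomeruli, seed = seed)
  set <- build_experiment1(panel)
  network <- build_glomerular_layer(config)
  out <- run_stimulus_set(network, set)
  metrics <- list(
    mc = metrics_report(out$mc_rates, set$odor, set$concentration, pcc_method),
    et = metrics_report(out$et_rates, set$odor, set$concentration, pcc_method),
    input = metrics_report(set$R, set$odor, set$concentration, pcc_method)
  )
  structure(
    list(
      panel = panel,
      odor = set$odor,
      concentration = set$concentration,
      input = set$R,
      mc_rates = out$mc_rates,
      et_rates = out$et_rates,
      metrics = metrics,
      config = config,
      seed = seed
    ),
    class = "glom_experiment"
  )
}

#' @export
print.glom_experiment <- function(x, ...) {
  cat(sprintf("glomerular experiment: %d stimuli, seed %s\n",
              nrow(x$mc_rates), format(x$seed)))
  f <- function(m) sprintf("FDR %.3f, PCC %.3f +/- %.3f, PC1 %.1f%%",
                           m$fdr, m$pcc_mean, m$pcc_sd, 100 * m$pc1_var)
  cat("  input:", f(x$metrics$input), "\n")
  cat("  MC   :", f(x$metrics$mc), "\n")
  cat("  ET   :", f(x$metrics$et), "\n")
  invisible(x)
}

#' Odor morphing experiment
#'
#' Simulates the 21-step binary-mixture series from odor C to odor E
#' (both at concentration factor 1) together with the 36 stimuli of
#' the odors-by-concentrations experiment (57 exposures in total), and
#' clusters the input patterns, the MC rates and the ET rates with
#' bisecting k-means.  Also returns the PCA of the MC output with the
#' morph-trajectory scores.
#'
#' @inheritParams run_experiment1
#' @param cluster_seed seed of the k-means restarts.
#' @return a `glom_morphing`: stimulus metadata (`alpha` is the
#'   mixing fraction, `NA` for the pure-odor grid), rate matrices,
#'   `trees` (dendrograms for input / MC / ET), and `mc_pca` scores.
#' @export
run_morphing <- function(config = network_config(), seed = NULL,
                         cluster_seed = 1) {
  stopifnot(inherits(config, "network_config"))
  if (is.null(seed)) seed <- config$seed
  panel <- generate_odor_panel(6, config$n_glomeruli, seed = seed)
  morph <- build_morph_series(panel)
  grid <- build_experiment1(panel)
  set <- combine_stimulus_sets(morph, grid)
  network <- build_glomerular_layer(config)
  out <- run_stimulus_set(network, set)
  leaf_labels <- ifelse(
    is.na(set$alpha),
    paste0(set$odor, "_", format(set$concentration, trim = TRUE)),
    paste0("mix_", format(round(set$alpha, 2), trim = TRUE))
  )
  trees <- list(
    input = hierarchical_kmeans(set$R, leaf_labels, seed = cluster_seed),
    mc = hierarchical_kmeans(out$mc_rates, leaf_labels, seed = cluster_seed),
    et = hierarchical_kmeans(out$et_rates, leaf_labels, seed = cluster_seed)
  )
  mc_pca <- pca_scores(out$mc_rates,
                       n_components = min(3, nrow(out$mc_rates) - 1))
  structure(
    list(
      panel = panel,
      odor = set$odor,
      concentration = set$concentration,
      alpha = set$alpha,
      labels = leaf_labels,
      input = set$R,
      mc_rates = out$mc_rates,
      et_rates = out$et_rates,
      trees = trees,
      mc_pca = mc_pca,
      config = config,
      seed = seed
    ),
    class = "glom_morphing"
  )
}

#' @export
print.glom_morphing <- function(x, ...) {
  cat(sprintf(
    "morphing experiment: %d stimuli (%d mixtures + %d grid), seed %s\n",
    length(x$odor), sum(!is.na(x$alpha)), sum(is.na(x$alpha)),
    format(x$seed)
  ))
  invisible(x)
}

#' Sweep of the short-axon synaptic weight
#'
#' Re-runs the odors-by-concentrations experiment for every
#' combination of short-axon weight and panel seed and tabulates the
#' identity and concentration metrics of the MC output, the ET output
#' and the raw input.
#'
#' @param config a [network_config()]; its `sa_weight` is overridden
#'   by the grid.
#' @param weights numeric grid of SA weights (arbitrary units).
#' @param seeds one panel seed per replicate.
#' @param pcc_method scalarization for the concentration correlation.
#' @param progress print one line per weight.
#' @return a `glom_sweep` data frame, one row per (seed, weight):
#'   `fdr_mc`, `fdr_et`, `fdr_input`, `pcc_mc`, `pcc_et`,
#'   `pcc_input`, `pc1_mc`, `pc1_et`, `pc1_input` and
#'   `mc_total_spikes`.  Use [sweep_summary()] for seed-averaged
#'   curves and the argmax.
#' @export
sa_weight_sweep <- function(config = network_config(), weights = 0:30,
                            seeds = 1:10, pcc_method = "pooled",
                            progress = FALSE) {
  stopifnot(inherits(config, "network_config"))
  if (!length(weights)) stop("weight grid must be non-empty")
  sets <- lapply(seeds, function(seed) {
    build_experiment1(generate_odor_panel(6, config$n_glomeruli, seed = seed))
  })
  m_in <- lapply(sets, function(set) {
    metrics_report(set$R, set$odor, set$concentration, pcc_method)
  })
  # all seeds' stimuli are simulated in one vectorized pass per weight
  # (stimulus columns are independent exposures)
  Rall <- t(do.call(rbind, lapply(sets, `[[`, "R")))
  n_per <- vapply(sets, function(set) nrow(set$R), integer(1))
  col_of <- rep(seq_along(seeds), n_per)
  rows <- vector("list", length(weights) * length(seeds))
  i <- 0L
  for (w in weights) {
    cfg <- config
    cfg$sa_weight <- w
    network <- build_glomerular_layer(cfg)
    sim <- simulate_network(network, Rall)
    dur_s <- sim$duration / 1000
    mc_all <- t(sim$counts[network$type == "MC", , drop = FALSE]) / dur_s
    et_all <- t(sim$counts[network$type == "ET", , drop = FALSE]) / dur_s
    for (s in seq_along(seeds)) {
      set <- sets[[s]]
      sel <- col_of == s
      m_mc <- metrics_report(mc_all[sel, , drop = FALSE], set$odor,
                             set$concentration, pcc_method)
      m_et <- metrics_report(et_all[sel, , drop = FALSE], set$odor,
                             set$concentration, pcc_method)
      i <- i + 1L
      rows[[i]] <- data.frame(
        seed = seeds[s], sa_weight = w,
        fdr_mc = m_mc$fdr, fdr_et = m_et$fdr, fdr_input = m_in[[s]]$fdr,
        pcc_mc = m_mc$pcc_mean, pcc_et = m_et$pcc_mean,
        pcc_input = m_in[[s]]$pcc_mean,
        pc1_mc = m_mc$pc1_var, pc1_et = m_et$pc1_var,
        pc1_input = m_in[[s]]$pc1_var,
        mc_total_spikes = sum(mc_all[sel, ]) * dur_s
      )
      if (progress) {
        cat(sprintf("seed %d sa_weight %g: MC FDR %.3f ET PCC %.3f\n",
                    seeds[s], w, m_mc$fdr, m_et$pcc_mean))
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("glom_sweep", "data.frame")
  attr(res, "config") <- config
  res
}

#' Seed-averaged sweep curves and the discrimination optimum
#'
#' @param sweep a [sa_weight_sweep()] result.
#' @return list with `curves` (data frame of seed-means per weight),
#'   `argmax` (weight maximising the mean MC FDR) and `at_argmax`
#'   (the mean metrics at that weight).
#' @export
sweep_summary <- function(sweep) {
  stopifnot(inherits(sweep, "glom_sweep"))
  num <- setdiff(names(sweep), c("seed", "sa_weight"))
  agg <- stats::aggregate(sweep[num], by = list(sa_weight = sweep$sa_weight),
                          FUN = mean)
  argmax <- agg$sa_weight[which.max(agg$fdr_mc)]
  list(
    curves = agg,
    argmax = argmax,
    at_argmax = agg[agg$sa_weight == argmax, , drop = FALSE]
  )
}

#' Persist an experiment to a directory
#'
#' Writes delimited-text rate matrices (and for morphing runs the
#' Newick dendrograms) plus a JSON run manifest holding the full
#' config snapshot and seeds, sufficient to re-run bit-identically.
#'
#' @param x a `glom_experiment`, `glom_morphing` or `glom_sweep`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("glomsim")),
    r_version = R.version.string,
    class = class(x)[1]
  )
  if (inherits(x, "glom_sweep")) {
    utils::write.table(x, file.path(dir, "sweep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    s <- sweep_summary(x)
    utils::write.table(s$curves, file.path(dir, "sweep_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$argmax <- s$argmax
    manifest$config <- unclass(attr(x, "config"))
  } else {
    write_rate_matrix(x$mc_rates, x$odor, x$concentration,
                      file.path(dir, "mc_rates.tsv"))
    write_rate_matrix(x$et_rates, x$odor, x$concentration,
                      file.path(dir, "et_rates.tsv"))
    write_rate_matrix(x$input, x$odor, x$concentration,
                      file.path(dir, "input_currents.tsv"))
    write_odor_panel(x$panel, file.path(dir, "odor_panel.tsv"))
    manifest$seed <- x$seed
    manifest$config <- unclass(x$config)
    if (inherits(x, "glom_morphing")) {
      for (nm in names(x$trees)) {
        write_newick(x$trees[[nm]], file.path(dir, paste0("dendrogram_", nm,
                                                          ".nwk")))
      }
    } else {
      manifest$metrics <- lapply(x$metrics, function(m) {
        list(fdr = m$fdr, pcc_mean = m$pcc_mean, pcc_sd = m$pcc_sd,
             pc1_var = m$pc1_var)
      })
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
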