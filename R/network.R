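#' Glomerular network configuration
#'
#' Collects every tunable of the glomerular-layer model.  Values not
#' supplied are taken from the shipped default configuration file (see
#' [default_config_path()]), which holds the calibrated synaptic
#' weights.
#'
#' Synaptic weights are peak current increments per presynaptic spike
#' (pA); synapses are current-based with a single exponential decay
#' constant `tau_syn`.  The inter-glomerular short-axon weight
#' `sa_weight` is expressed in the sweep's arbitrary units and mapped
#' to pA per spike through `sa_scale`.
#'
#' @param ... named overrides of the defaults.  Recognised keys:
#'   `n_glomeruli`, `cells_per_type`, `sa_weight`, `sa_scale`,
#'   `w_orn_mc`, `w_orn_et`, `w_orn_pg` (dimensionless gains on the
#'   ORN input current), `w_mc_pg`, `w_pg_mc`, `w_et_pg`, `w_et_sa`
#'   (pA per spike), `tau_syn` (ms), `dt` (ms), `duration` (ms),
#'   `seed`.
#' @param file optional path to a key-value configuration file whose
#'   entries are applied on top of the shipped defaults (and below
#'   `...` overrides).
#' @return an object of class `network_config` (named list).
#' @export
network_config <- function(..., file = NULL) {
  cfg <- read_config_file(default_config_path())
  if (!is.null(file)) {
    cfg <- utils::modifyList(cfg, read_config_file(file))
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, dots)
  }
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  if (cfg$n_glomeruli < 1) stop("n_glomeruli must be >= 1")
  if (cfg$cells_per_type < 1) stop("cells_per_type must be >= 1")
  w <- unlist(cfg[c("sa_weight", "sa_scale", "w_orn_mc", "w_orn_et",
                    "w_orn_pg", "w_mc_pg", "w_pg_mc", "w_et_pg",
                    "w_et_sa")])
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("synaptic weights must be finite and non-negative; ",
         "the inhibitory sign of PG->MC is applied internally")
  }
  if (cfg$tau_syn <= 0) stop("tau_syn must be positive")
  if (cfg$dt <= 0) stop("dt must be positive")
  if (cfg$duration <= 0) stop("duration must be positive")
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat("glomerular network configuration\n")
  for (k in names(x)) cat(sprintf("  %-14s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Path of the shipped default configuration
#'
#' The file holds the calibrated defaults as plain `key value` lines;
#' [config_dump()] prints them.
#' @return file path.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.txt", package = "glomsim",
              mustWork = TRUE)
}

#' Read a plain-text key-value configuration file
#'
#' Lines are `key value` pairs separated by whitespace; blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return named list with numeric values where possible.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[ \t]+")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    v <- paste(x[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, keys)
}

#' Print the full default configuration
#'
#' @param file connection or path passed to [cat()]; default stdout.
#' @export
config_dump <- function(file = "") {
  cfg <- read_config_file(default_config_path())
  for (k in names(cfg)) cat(sprintf("%s %s\n", k, format(cfg[[k]])), file = file,
                            append = TRUE)
  invisible(cfg)
}

#' Build the glomerular-layer network
#'
#' Each glomerulus holds one mitral (MC), one external tufted (ET),
#' one periglomerular (PG) and one short axon (SA) cell (multiplicity
#' is configurable via `cells_per_type`).  Within glomerulus `g` the
#' wiring is: ORN input drives MC, ET and PG; MC_g -> PG_g
#' (excitatory); PG_g -> MC_g (inhibitory, the only inhibitory synapse
#' in the model); ET_g -> PG_g and ET_g -> SA_g (excitatory).  Across
#' glomeruli, every SA_g projects excitatorily onto PG_h and ET_h of
#' every other glomerulus `h != g`, each such synapse carrying the
#' swept weight `sa_weight * sa_scale`.  The ET/SA sub-network
#' therefore receives no input from MC or PG cells.
#'
#' @param config a [network_config()].
#' @return an object of class `glom_network`: neuron bookkeeping
#'   (types, glomerulus membership), stacked Izhikevich parameters and
#'   the signed synaptic weight matrix `W` (`W[post, pre]`, pA per
#'   spike).
#' @export
build_glomerular_layer <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  G <- as.integer(config$n_glomeruli)
  m <- as.integer(config$cells_per_type)
  types_unit <- rep(c("MC", "ET", "PG", "SA"), each = m)
  type <- rep(types_unit, times = G)
  glom <- rep(seq_len(G), each = 4L * m)
  n <- length(type)
  labels <- paste0(type, "_", glom,
                   if (m > 1) paste0(".", rep(seq_len(m), times = 4L * G)) else "")
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  idx <- function(tp, g) which(type == tp & glom == g)
  sa_w <- config$sa_weight * config$sa_scale
  for (g in seq_len(G)) {
    mc <- idx("MC", g); et <- idx("ET", g)
    pg <- idx("PG", g); sa <- idx("SA", g)
    # weights divided by presynaptic multiplicity so total drive is
    # invariant under cells_per_type
    W[pg, mc] <- W[pg, mc] + config$w_mc_pg / m
    W[mc, pg] <- W[mc, pg] - config$w_pg_mc / m
    W[pg, et] <- W[pg, et] + config$w_et_pg / m
    W[sa, et] <- W[sa, et] + config$w_et_sa / m
    if (sa_w > 0 && G > 1) {
      others <- setdiff(seq_len(G), g)
      for (h in others) {
        W[idx("PG", h), sa] <- W[idx("PG", h), sa] + sa_w / m
        W[idx("ET", h), sa] <- W[idx("ET", h), sa] + sa_w / m
      }
    }
  }
  structure(
    list(
      config = config,
      n_neurons = n,
      n_glomeruli = G,
      type = type,
      glom = glom,
      labels = labels,
      params = stack_params(type),
      W = W
    ),
    class = "glom_network"
  )
}

#' @export
print.glom_network <- function(x, ...) {
  cat(sprintf(
    "glomerular network: %d glomeruli, %d neurons, %d synapses (sa_weight = %s a.u.)\n",
    x$n_glomeruli, x$n_neurons, sum(x$W != 0), format(x$config$sa_weight)
  ))
  invisible(x)
}

#' Current of an exponential synapse
#'
#' Each presynaptic spike at time `t0` contributes
#' `sign * weight * exp(-(t - t0) / tau)` pA for `t >= t0`;
#' contributions from successive spikes sum linearly.  This closed
#' form defines the kinetics realised incrementally inside the network
#' engine.
#'
#' @param spike_times presynaptic spike times, ms.
#' @param t evaluation time(s), ms (vectorized).
#' @param weight peak increment per spike, pA (non-negative).
#' @param sign `+1` excitatory, `-1` inhibitory.
#' @param tau decay constant, ms.
#' @return current at each `t`, pA.
#' @export
synaptic_current <- function(spike_times, t, weight, sign = 1, tau = 10) {
  stopifnot(weight >= 0, tau > 0, sign %in% c(-1, 1))
  vapply(t, function(tt) {
    active <- spike_times[spike_times <= tt]
    sign * weight * sum(exp(-(tt - active) / tau))
  }, numeric(1))
}

# Per-neuron external currents for a batch of stimuli.
# Rmat: n_glomeruli x n_stimuli.  Returns n_neurons x n_stimuli.
external_currents <- function(network, Rmat) {
  cfg <- network$config
  gain <- c(MC = cfg$w_orn_mc, ET = cfg$w_orn_et, PG = cfg$w_orn_pg, SA = 0)
  Iext <- Rmat[network$glom, , drop = FALSE] * gain[network$type]
  rownames(Iext) <- network$labels
  Iext
}

# Core fixed-step engine (compiled; see src/glom_engine.cpp).  Every
# stimulus column is an independent exposure: fresh initial
# conditions, one RK4 step per dt with currents held constant over
# the step, reset after the full step, then the aggregated
# exponential synaptic current is decayed and incremented by the
# weights of the spiking neurons.
simulate_network <- function(network, Rmat, duration = NULL, dt = NULL,
                             record_spikes = FALSE) {
  cfg <- network$config
  if (is.null(duration)) duration <- cfg$duration
  if (is.null(dt)) dt <- cfg$dt
  if (!is.matrix(Rmat)) Rmat <- matrix(Rmat, ncol = 1)
  if (nrow(Rmat) != network$n_glomeruli) {
    stop("stimulus length must equal n_glomeruli")
  }
  if (!all(is.finite(Rmat))) stop("non-finite stimulus")
  P <- network$params
  Iext <- external_currents(network, Rmat)
  n_steps <- as.integer(round(duration / dt))
  res <- simulate_network_core(
    P$C, P$k, P$v_r, P$v_t, P$a, P$b, P$v_peak, P$c, P$d,
    network$W, Iext, dt, n_steps, exp(-dt / cfg$tau_syn),
    record_spikes
  )
  counts <- res$counts
  dimnames(counts) <- list(network$labels, colnames(Rmat))
  spikes <- NULL
  if (record_spikes) {
    spikes <- data.frame(time = res$spike_time, neuron = res$spike_neuron,
                         stimulus = res$spike_stimulus)
  }
  list(counts = counts, spikes = spikes, duration = duration, dt = dt)
}

#' Run one stimulus through the network
#'
#' Injects the stimulus components as constant currents into the MC,
#' ET and PG cells of their glomeruli for the whole exposure and
#' returns the spike trains of all neurons.  The network state is
#' freshly initialised (membrane potentials at rest, recovery
#' variables and synaptic currents at zero), so successive calls are
#' independent exposures.
#'
#' @param network a [build_glomerular_layer()] result.
#' @param stimulus current vector, pA, length `n_glomeruli`.
#' @param duration exposure, ms (default from the config).
#' @return a `spike_record`: list with `times` (data frame `time_ms`,
#'   `neuron_id`), per-neuron `counts`, neuron bookkeeping and the
#'   exposure duration.
#' @export
run_stimulus <- function(network, stimulus, duration = NULL) {
  sim <- simulate_network(network, matrix(stimulus, ncol = 1),
                          duration = duration, record_spikes = TRUE)
  times <- data.frame(time_ms = sim$spikes$time,
                      neuron_id = sim$spikes$neuron)
  times <- times[order(times$neuron_id, times$time_ms), , drop = FALSE]
  rownames(times) <- NULL
  structure(
    list(times = times, counts = sim$counts[, 1],
         type = network$type, glom = network$glom,
         labels = network$labels, duration = sim$duration),
    class = "spike_record"
  )
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike_record: %d spikes from %d neurons over %g ms\n",
              nrow(x$times), length(x$counts), x$duration))
  invisible(x)
}

#' Spike times of one neuron
#'
#' @param record a `spike_record`.
#' @param neuron neuron index or label.
#' @return ordered numeric vector of spike times, ms.
#' @export
spike_times <- function(record, neuron) {
  if (is.character(neuron)) neuron <- match(neuron, record$labels)
  record$times$time_ms[record$times$neuron_id == neuron]
}

#' Mean-firing-rate readout of a projection-neuron population
#'
#' The model readout is the mean firing rate of each glomerulus's MC
#' (or ET) cells over the exposure: spike count divided by the
#' exposure duration in seconds.
#'
#' @param record a `spike_record` from [run_stimulus()].
#' @param population `"MC"` or `"ET"` (interneurons are accepted too).
#' @param duration readout window, ms; defaults to the record's
#'   exposure.
#' @return rate vector, Hz, one element per glomerulus (averaged over
#'   cell copies when `cells_per_type > 1`).
#' @export
mean_rate_readout <- function(record, population = c("MC", "ET", "PG", "SA"),
                              duration = NULL) {
  population <- match.arg(population)
  if (is.null(duration)) duration <- record$duration
  if (duration <= 0) stop("duration must be positive")
  sel <- record$type == population
  counts <- record$counts[sel]
  gl <- record$glom[sel]
  rates <- tapply(counts, gl, mean) / (duration / 1000)
  as.numeric(rates[order(as.integer(names(rates)))])
}

#' Run a whole stimulus set and collect rate matrices
#'
#' Simulates every stimulus of the set independently (the engine
#' batches them in one vectorized pass) and returns the mean-rate
#' readouts.
#'
#' @param network a `glom_network`.
#' @param set a `stimulus_set`.
#' @param duration exposure per stimulus, ms.
#' @return list with `mc_rates` and `et_rates` (stimuli x glomeruli
#'   matrices, Hz), `counts` (neurons x stimuli spike counts) and the
#'   stimulus metadata (`odor`, `concentration`, `alpha`).
#' @export
run_stimulus_set <- function(network, set, duration = NULL) {
  stopifnot(inherits(set, "stimulus_set"))
  sim <- simulate_network(network, t(set$R), duration = duration)
  dur_s <- sim$duration / 1000
  pop_rates <- function(pop) {
    sel <- network$type == pop
    cnt <- sim$counts[sel, , drop = FALSE]
    gl <- network$glom[sel]
    agg <- rowsum(cnt, gl) / as.vector(table(gl))
    out <- t(agg) / dur_s
    dimnames(out) <- list(rownames(set$R),
                          paste0("g", seq_len(network$n_glomeruli)))
    out
  }
  list(
    mc_rates = pop_rates("MC"),
    et_rates = pop_rates("ET"),
    counts = sim$counts,
    odor = set$odor,
    concentration = set$concentration,
    alpha = set$alpha,
    duration = sim$duration
  )
}

#' Export spike trains as delimited text
#'
#' Two columns: `time_ms`, `neuron_id`.
#'
#' @param record a `spike_record`.
#' @param path file path.
#' @export
write_spike_record <- function(record, path) {
  utils::write.table(record$times, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a labelled rate matrix as delimited text
#'
#' Header row carries stimulus id, odor label, concentration and one
#' column per glomerulus.
#'
#' @param rates stimuli x glomeruli matrix, Hz.
#' @param odor,concentration per-stimulus metadata.
#' @param path file path.
#' @export
write_rate_matrix <- function(rates, odor, concentration, path) {
  df <- data.frame(stimulus = rownames(rates), odor = odor,
                   concentration = concentration, rates,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
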