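#' Izhikevich parameters of the olfactory bulb cell types
#'
#' The glomerular layer is modelled with four cell types, each a
#' two-variable Izhikevich quadratic integrate-and-fire neuron:
#' mitral cells (`MC`), external tufted cells (`ET`), periglomerular
#' interneurons (`PG`) and short axon cells (`SA`).  MC and ET share
#' identical parameters, so any functional difference between their
#' outputs must come from network interactions rather than intrinsic
#' cell properties.
#'
#' @param type one of `"MC"`, `"ET"`, `"PG"`, `"SA"`.
#' @return an object of class `neuron_params`: a named list with fields
#'   `C` membrane capacitance (pF), `k` voltage-nonlinearity gain
#'   (GOhm^-1 mV^-1), `v_r` resting potential (mV), `v_t` instantaneous
#'   threshold (mV), `a` recovery rate (ms^-1), `b` recovery
#'   sensitivity (GOhm^-1; negative for PG and SA, whose recovery
#'   variable amplifies depolarization), `v_peak` spike cutoff (mV),
#'   `c` after-spike membrane reset (mV) and `d` after-spike recovery
#'   increment (numerically as tabulated).
#' @examples
#' neuron_params("MC")$C   # 40 pF
#' @export
neuron_params <- function(type = c("MC", "ET", "PG", "SA")) {
  type <- match.arg(type)
  p <- as.list(.ob_param_table[type, ])
  p$type <- type
  class(p) <- "neuron_params"
  validate_neuron_params(p)
  p
}

# One row per cell type; columns are the nine Izhikevich parameters.
.ob_param_table <- local({
  m <- rbind(
    MC = c(40,   1,     -55,   -50, 0.4,    2.6,  35, -50, 200),
    PG = c(5.9,  0.049, -53.1, -20, 0.0167, -0.94, 35, -20, 50),
    ET = c(40,   1,     -55,   -50, 0.4,    2.6,  35, -50, 200),
    SA = c(58,   0.061, -67,   -30, 0.049,  -0.68, 35, -30, 150)
  )
  colnames(m) <- c("C", "k", "v_r", "v_t", "a", "b", "v_peak", "c", "d")
  m
})

#' Parameter table of all four olfactory bulb cell types
#'
#' @return a data frame, one row per cell type (`MC`, `PG`, `ET`, `SA`),
#'   columns the nine Izhikevich parameters.
#' @export
ob_param_table <- function() {
  as.data.frame(.ob_param_table)
}

validate_neuron_params <- function(p) {
  num <- unlist(p[c("C", "k", "v_r", "v_t", "a", "b", "v_peak", "c", "d")])
  if (!all(is.finite(num))) stop("neuron parameters must be finite")
  if (p$C <= 0) stop("membrane capacitance C must be positive")
  if (p$k <= 0) stop("voltage gain k must be positive")
  if (!(p$v_r < p$v_t && p$v_t < p$v_peak)) {
    stop("require v_r < v_t < v_peak")
  }
  if (p$c > p$v_peak) stop("after-spike reset c must not exceed v_peak")
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("Izhikevich parameters [%s]\n", x$type))
  flds <- c("C", "k", "v_r", "v_t", "a", "b", "v_peak", "c", "d")
  print(unlist(x[flds]))
  invisible(x)
}

# Stack a list of neuron_params (or a character vector of types) into
# per-field numeric vectors for vectorized integration.
stack_params <- function(types) {
  if (is.character(types)) {
    m <- .ob_param_table[types, , drop = FALSE]
  } else {
    m <- do.call(rbind, lapply(types, function(p) {
      unlist(p[c("C", "k", "v_r", "v_t", "a", "b", "v_peak", "c", "d")])
    }))
  }
  lapply(seq_len(ncol(m)), function(j) m[, j]) |>
    stats::setNames(colnames(m))
}

#' Time derivatives of the Izhikevich model
#'
#' The membrane equation is
#' \deqn{C \, dv/dt = k (v - v_r)(v - v_t) - u + I}
#' \deqn{du/dt = a (b (v - v_r) - u)}
#' with `v` the membrane potential (mV) and `u` the recovery variable.
#' All arguments are vectorized; parameters recycle against the state.
#'
#' @param v membrane potential(s), mV.
#' @param u recovery variable(s).
#' @param params a `neuron_params` object, or a stacked parameter set.
#' @param I total input current, pA.
#' @return a list with components `dv` (mV/ms) and `du` (per ms).
#' @examples
#' p <- neuron_params("MC")
#' izh_derivatives(p$v_r, 0, p, 0)  # rest is a fixed point: c(0, 0)
#' @export
izh_derivatives <- function(v, u, params, I) {
  if (!all(is.finite(v)) || !all(is.finite(u)) || !all(is.finite(I))) {
    stop("non-finite state or current passed to izh_derivatives")
  }
  list(
    dv = (params$k * (v - params$v_r) * (v - params$v_t) - u + I) / params$C,
    du = params$a * (params$b * (v - params$v_r) - u)
  )
}

#' After-spike reset
#'
#' Whenever the membrane potential reaches the spike cutoff
#' (`v >= v_peak`, boundary inclusive) the neuron is reset:
#' `v <- c`, `u <- u + d`.  Vectorized.
#'
#' @inheritParams izh_derivatives
#' @return list with `v`, `u` after reset and logical `spiked`.
#' @export
izh_reset <- function(v, u, params) {
  spiked <- v >= params$v_peak
  v <- ifelse(spiked, params$c, v)
  u <- ifelse(spiked, u + params$d, u)
  list(v = v, u = u, spiked = spiked)
}

# One classical RK4 step of the membrane equations with the input
# current held constant over the step.  Works elementwise on vectors or
# on neuron x stimulus matrices (parameter vectors recycle down
# columns, i.e. per neuron).  Reset is applied AFTER the full step.
rk4_step <- function(v, u, P, I, dt) {
  f <- function(v, u) (P$k * (v - P$v_r) * (v - P$v_t) - u + I) / P$C
  g <- function(v, u) P$a * (P$b * (v - P$v_r) - u)
  h <- dt / 2
  k1v <- f(v, u);              k1u <- g(v, u)
  v2  <- v + h * k1v;          u2  <- u + h * k1u
  k2v <- f(v2, u2);            k2u <- g(v2, u2)
  v3  <- v + h * k2v;          u3  <- u + h * k2u
  k3v <- f(v3, u3);            k3u <- g(v3, u3)
  v4  <- v + dt * k3v;         u4  <- u + dt * k3u
  k4v <- f(v4, u4);            k4u <- g(v4, u4)
  list(
    v = v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v),
    u = u + dt / 6 * (k1u + 2 * k2u + 2 * k3u + k4u)
  )
}

#' One integration step for a heterogeneous neuron population
#'
#' Advances every neuron by one classical fourth-order Runge-Kutta step
#' of the membrane equations, with each neuron's input current held
#' constant over the step, then applies the after-spike reset.
#'
#' @param v,u numeric vectors of states, one element per neuron.
#' @param params a stacked parameter set (see [neuron_params()]); a
#'   character vector of cell types is also accepted.
#' @param I per-neuron input currents, pA.
#' @param dt time step, ms (default 0.1).
#' @return list with updated `v`, `u` and logical `spiked` flags.
#' @export
integrate_step <- function(v, u, params, I, dt = 0.1) {
  if (is.character(params) || inherits(params, "neuron_params")) {
    params <- stack_params(if (is.character(params)) params else list(params))
  }
  n <- length(v)
  if (length(u) != n || length(I) != n) {
    stop("v, u and I must have the same length")
  }
  if (dt <= 0) stop("dt must be positive")
  if (!all(is.finite(v)) || !all(is.finite(u)) || !all(is.finite(I))) {
    stop("non-finite state or current")
  }
  st <- rk4_step(v, u, params, I, dt)
  if (anyNA(st$v) || any(!is.finite(st$v))) {
    stop("NaN emerged during integration step")
  }
  spiked <- st$v >= params$v_peak
  v <- ifelse(spiked, params$c, st$v)
  u <- ifelse(spiked, st$u + params$d, st$u)
  list(v = v, u = u, spiked = spiked)
}

#' Simulate one isolated neuron under constant current
#'
#' Convenience driver used for frequency-current characterisation and
#' integration accuracy checks.  The neuron starts at rest
#' (`v = v_r`, `u = 0`).
#'
#' @param params a `neuron_params` object.
#' @param I constant input current, pA.
#' @param duration simulated time, ms.
#' @param dt integration step, ms.
#' @param record_trace if `TRUE`, return the membrane trace.  In the
#'   recorded trace (only) overshoot beyond `v_peak` is clamped to
#'   `v_peak`; the integrated state itself is never clamped.
#' @return list with `spike_times` (ms, spike time is the end of the
#'   step that triggered the reset), `n_spikes`, `rate_hz`, and if
#'   requested `trace` (data frame `time_ms`, `v`, `u`).
#' @export
simulate_neuron <- function(params, I, duration = 500, dt = 0.1,
                            record_trace = FALSE) {
  stopifnot(inherits(params, "neuron_params"))
  if (!is.finite(I)) stop("non-finite input current")
  n_steps <- as.integer(round(duration / dt))
  v <- params$v_r
  u <- 0
  spikes <- numeric(0)
  trace <- if (record_trace) {
    matrix(NA_real_, nrow = n_steps + 1L, ncol = 2L)
  }
  if (record_trace) trace[1L, ] <- c(v, u)
  P <- stack_params(params$type)
  for (s in seq_len(n_steps)) {
    st <- rk4_step(v, u, P, I, dt)
    if (!is.finite(st$v)) stop("NaN emerged at step ", s)
    if (st$v >= params$v_peak) {
      spikes <- c(spikes, s * dt)
      v <- params$c
      u <- st$u + params$d
      if (record_trace) trace[s + 1L, ] <- c(params$v_peak, u)
    } else {
      v <- st$v
      u <- st$u
      if (record_trace) trace[s + 1L, ] <- c(v, u)
    }
  }
  out <- list(
    spike_times = spikes,
    n_spikes = length(spikes),
    rate_hz = length(spikes) / (duration / 1000)
  )
  if (record_trace) {
    out$trace <- data.frame(
      time_ms = seq(0, by = dt, length.out = n_steps + 1L),
      v = trace[, 1L], u = trace[, 2L]
    )
  }
  out
}

#' Write membrane traces as wide delimited text
#'
#' One time column plus one potential column per neuron.
#'
#' @param traces a single trace data frame from [simulate_neuron()]
#'   (`record_trace = TRUE`), or a named list of them sharing a time
#'   grid.
#' @param path file path.
#' @export
write_membrane_traces <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(v = traces)
  if (is.null(names(traces))) names(traces) <- paste0("n", seq_along(traces))
  out <- data.frame(time_ms = traces[[1]]$time_ms)
  for (nm in names(traces)) out[[nm]] <- traces[[nm]]$v
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Frequency-current curve of an isolated neuron
#'
#' @param params a `neuron_params` object.
#' @param I_grid currents to probe, pA.
#' @param duration,dt simulation settings, ms.
#' @return data frame with columns `I_pA` and `rate_hz`.
#' @export
fi_curve <- function(params, I_grid, duration = 500, dt = 0.1) {
  rates <- vapply(
    I_grid,
    function(I) simulate_neuron(params, I, duration, dt)$rate_hz,
    numeric(1)
  )
  data.frame(I_pA = I_grid, rate_hz = rates)
}
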