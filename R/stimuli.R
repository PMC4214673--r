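#' Generate a random odor sensitivity panel
#'
#' Each odor is represented by a combinatorial receptor code: a vector
#' of sensitivities, one per glomerulus, drawn i.i.d. from a uniform
#' distribution on \[0, 40\] pA.  The sensitivity of glomerulus `g` to
#' an odor, multiplied by the (dimensionless) concentration factor,
#' gives the constant ORN input current injected into that glomerulus.
#'
#' @param n_odors number of odors (rows); labelled `A`, `B`, ... in row
#'   order.
#' @param n_glomeruli number of glomeruli (columns).
#' @param seed integer seed; the same seed always reproduces the same
#'   panel.
#' @param s_max upper bound of the sensitivity distribution and
#'   saturation ceiling of the ORN response, pA.
#' @return an `odor_panel`: a numeric matrix (odors x glomeruli) with
#'   odor labels as row names and attributes `seed` and `s_max`.
#' @examples
#' p <- generate_odor_panel(6, 16, seed = 1)
#' range(p)  # within [0, 40]
#' @export
generate_odor_panel <- function(n_odors = 6, n_glomeruli = 16, seed = 1,
                                s_max = 40) {
  if (n_odors < 1 || n_glomeruli < 1) stop("counts must be >= 1")
  S <- withr_seed(seed, {
    matrix(stats::runif(n_odors * n_glomeruli, 0, s_max),
           nrow = n_odors, ncol = n_glomeruli)
  })
  rownames(S) <- make_odor_labels(n_odors)
  colnames(S) <- paste0("g", seq_len(n_glomeruli))
  structure(S, seed = seed, s_max = s_max, class = c("odor_panel", "matrix"))
}

make_odor_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else paste0("odor", seq_len(n))
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' ORN input currents for one odor at one concentration
#'
#' The ORN response is linear in concentration, `R = S * C`, saturated
#' componentwise at the ceiling `s_max` (40 pA by default), reflecting
#' receptor saturation.
#'
#' @param s_row sensitivity vector of the odor, pA.
#' @param concentration dimensionless concentration factor, `>= 0`.
#' @param s_max saturation ceiling, pA.
#' @return current vector, pA, clipped to `[0, s_max]`.
#' @export
stimulus_from_odor <- function(s_row, concentration, s_max = 40) {
  if (!is.finite(concentration) || concentration < 0) {
    stop("concentration must be a finite non-negative number")
  }
  pmin(as.numeric(s_row) * concentration, s_max)
}

#' The six-odors by six-concentrations stimulus set
#'
#' Builds the Cartesian product of the panel's first six odors with the
#' concentration factors, in odor-major order with ascending
#' concentration within each odor (36 stimuli for the defaults).
#'
#' @param panel an [generate_odor_panel()] result with at least 6 odors.
#' @param concentrations dimensionless concentration factors.
#' @param n_odors how many panel rows to use.
#' @return a `stimulus_set`: list with `R` (stimuli x glomeruli current
#'   matrix, pA), `odor` (label per stimulus), `concentration` (factor
#'   per stimulus) and `s_max`.
#' @export
build_experiment1 <- function(panel,
                              concentrations = c(0.4, 0.6, 0.8, 1.0, 1.2, 1.4),
                              n_odors = 6) {
  stopifnot(inherits(panel, "odor_panel"))
  if (nrow(panel) < n_odors) stop("panel has fewer than ", n_odors, " odors")
  s_max <- attr(panel, "s_max")
  odors <- rownames(panel)[seq_len(n_odors)]
  grid <- expand.grid(
    concentration = concentrations, odor = odors,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("odor", "concentration")]
  R <- t(mapply(
    function(o, co) stimulus_from_odor(panel[o, ], co, s_max),
    grid$odor, grid$concentration
  ))
  dimnames(R) <- list(
    paste0(grid$odor, "_", format(grid$concentration, trim = TRUE)),
    colnames(panel)
  )
  new_stimulus_set(R, grid$odor, grid$concentration, s_max)
}

new_stimulus_set <- function(R, odor, concentration, s_max, alpha = NULL) {
  structure(
    list(R = R, odor = odor, concentration = concentration,
         s_max = s_max, alpha = alpha),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "stimulus_set: %d stimuli x %d glomeruli (%s)\n",
    nrow(x$R), ncol(x$R),
    if (is.null(x$alpha)) "odor/concentration grid" else "morphing series"
  ))
  invisible(x)
}

#' Binary-mixture morphing series between two odors
#'
#' Generates a graded series of binary mixtures interpolating between
#' two pure odors, both at a fixed concentration factor.  The mixture
#' at mixing fraction `alpha` is the convex combination
#' `(1 - alpha) * R_from + alpha * R_to`, so the series starts at the
#' pure `from` odor (`alpha = 0`) and ends at the pure `to` odor
#' (`alpha = 1`), with total concentration held constant.  Saturation
#' is applied after mixing (the endpoints at concentration 1 rarely
#' clip, so the distinction is minor).
#'
#' @param panel an odor panel containing both endpoint odors.
#' @param from,to odor labels of the endpoints (rows 3 and 5, "C" and
#'   "E", for the default panel).
#' @param n_steps number of mixtures including the two pure endpoints
#'   (21 gives a mixing-fraction step of 0.05).
#' @param concentration concentration factor of both endpoints.
#' @return a `stimulus_set` whose `alpha` field holds the mixing
#'   fraction of the `to` odor; labels are `mix_<alpha>`.
#' @export
build_morph_series <- function(panel, from = "C", to = "E", n_steps = 21,
                               concentration = 1) {
  stopifnot(inherits(panel, "odor_panel"))
  if (!all(c(from, to) %in% rownames(panel))) {
    stop("panel must contain odors ", from, " and ", to)
  }
  s_max <- attr(panel, "s_max")
  alpha <- seq(0, 1, length.out = n_steps)
  R_from <- as.numeric(panel[from, ]) * concentration
  R_to <- as.numeric(panel[to, ]) * concentration
  R <- t(vapply(
    alpha,
    function(a) pmin((1 - a) * R_from + a * R_to, s_max),
    numeric(ncol(panel))
  ))
  dimnames(R) <- list(paste0("mix_", format(alpha, trim = TRUE)),
                      colnames(panel))
  new_stimulus_set(R, odor = rep(paste0(from, ">", to), n_steps),
                   concentration = rep(concentration, n_steps),
                   s_max = s_max, alpha = alpha)
}

#' Concatenate stimulus sets
#'
#' @param ... `stimulus_set` objects over the same glomeruli.
#' @return a single `stimulus_set`; `alpha` is `NA` for members that
#'   are not mixtures.
#' @export
combine_stimulus_sets <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "stimulus_set")))
  ncols <- vapply(sets, function(s) ncol(s$R), integer(1))
  if (length(unique(ncols)) != 1) stop("glomerulus counts differ")
  alpha <- unlist(lapply(sets, function(s) {
    if (is.null(s$alpha)) rep(NA_real_, nrow(s$R)) else s$alpha
  }))
  new_stimulus_set(
    do.call(rbind, lapply(sets, `[[`, "R")),
    unlist(lapply(sets, `[[`, "odor")),
    unlist(lapply(sets, `[[`, "concentration")),
    sets[[1]]$s_max,
    alpha = alpha
  )
}

#' Write / read an odor panel as delimited text
#'
#' Panels round-trip through tab-separated text with `#`-prefixed
#' header metadata (seed, units, saturation ceiling).
#'
#' @param panel an `odor_panel`.
#' @param path file path.
#' @export
write_odor_panel <- function(panel, path) {
  stopifnot(inherits(panel, "odor_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# odor_panel seed=%s s_max=%s units=pA",
            attr(panel, "seed"), attr(panel, "s_max"))
  ), con)
  utils::write.table(unclass(panel), con, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_odor_panel
#' @export
read_odor_panel <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- parse_kv_comment(hdr)
  S <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, comment.char = "#"))
  structure(S, seed = as.integer(kv[["seed"]]),
            s_max = as.numeric(kv[["s_max"]]),
            class = c("odor_panel", "matrix"))
}

parse_kv_comment <- function(line) {
  toks <- strsplit(sub("^#\\s*\\S+\\s*", "", line), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  kv <- strsplit(toks, "=")
  stats::setNames(
    vapply(kv, `[`, character(1), 2),
    vapply(kv, `[`, character(1), 1)
  )
}

#' Write / read a stimulus set as delimited text
#'
#' @param set a `stimulus_set`.
#' @param path file path.
#' @export
write_stimulus_set <- function(set, path) {
  stopifnot(inherits(set, "stimulus_set"))
  df <- data.frame(
    stimulus = rownames(set$R),
    odor = set$odor,
    concentration = set$concentration,
    alpha = if (is.null(set$alpha)) NA_real_ else set$alpha,
    set$R,
    check.names = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stimulus_set s_max=%s units=pA", set$s_max), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  kv <- parse_kv_comment(readLines(path, n = 1))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE)
  R <- as.matrix(df[, -(1:4), drop = FALSE])
  rownames(R) <- df$stimulus
  alpha <- if (all(is.na(df$alpha))) NULL else df$alpha
  new_stimulus_set(R, df$odor, df$concentration,
                   as.numeric(kv[["s_max"]]), alpha = alpha)
}
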