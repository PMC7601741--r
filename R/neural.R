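# Convolution-based 'ERP' neural mass model: parameters, stimulus and
# source-level simulation.

#' Default neural-mass parameters for a network
#'
#' Returns a `neural_params` list holding every generative-model
#' parameter for the given network: per-edge extrinsic log-scalings
#' (`a_log`, 0 means nominal class strength), per-modulable-edge
#' log-modulations applied in the modulated block (`b_log`), per-input
#' log input gain (`c_gain`), and the intrinsic synaptic constants.
#'
#' Intrinsic defaults are the conventional ERP-model values: excitatory
#' and inhibitory rate constants `kappa_e = 250` 1/s and `kappa_i = 62.5`
#' 1/s (4 ms and 16 ms time constants), maximum postsynaptic amplitudes
#' `h_e = 4` mV and `h_i = 32` mV, intrinsic coupling gains
#' `gamma = (128, 102, 26, 26)`, and sigmoid slope
#' `sigmoid_slope = 0.56` 1/mV, at which the firing curve is near-linear
#' over the sub-mV operating range of the default stimulus. Nominal
#' extrinsic class strengths are forward 128, backward 256, lateral 32
#' (multiplied by `exp(a_log [+ b_log])` per edge); backward influences
#' largely cancel between their excitatory (pyramidal) and inhibitory
#' (interneuron) limbs, so their nominal strength is set higher to keep
#' them identifiable, while the network stays well damped under the
#' log-strength spreads the cohort generator produces.
#'
#' @param net a `lep_network`.
#' @param a_log,b_log,c_gain optional named numeric vectors overriding
#'   the zero defaults (names = edge names / input-region labels).
#' @param ... overrides for intrinsic constants (`kappa_e`, `kappa_i`,
#'   `h_e`, `h_i`, `gamma`, `sigmoid_slope`, `class_gains`).
#' @return object of class `neural_params`.
#' @export
neural_params <- function(net, a_log = NULL, b_log = NULL, c_gain = NULL,
                          ...) {
  en <- edge_names(net)
  em <- edge_names(net, modulable_only = TRUE)
  p <- list(
    a_log = stats::setNames(numeric(length(en)), en),
    b_log = stats::setNames(numeric(length(em)), em),
    c_gain = stats::setNames(numeric(length(net$input_regions)),
                             net$input_regions),
    kappa_e = 250, kappa_i = 62.5,
    h_e = 4, h_i = 32,
    gamma = c(128, 102, 26, 26),
    sigmoid_slope = 0.56,
    class_gains = c(forward = 128, backward = 256, lateral = 32))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown parameter: ", nm)
    p[[nm]] <- dots[[nm]]
  }
  fill <- function(def, ov, what) {
    if (is.null(ov)) return(def)
    bad <- setdiff(names(ov), names(def))
    if (length(bad)) stop("unknown ", what, " key: ", paste(bad, collapse = ", "))
    def[names(ov)] <- ov
    def
  }
  p$a_log <- fill(p$a_log, a_log, "a_log")
  p$b_log <- fill(p$b_log, b_log, "b_log")
  p$c_gain <- fill(p$c_gain, c_gain, "c_gain")
  stopifnot(p$kappa_e > 0, p$kappa_i > 0, p$h_e > 0, p$h_i > 0,
            p$sigmoid_slope > 0)
  structure(p, class = "neural_params")
}

#' Centered sigmoid firing curve
#'
#' Normalized population firing as a function of mean membrane potential:
#' `1 / (1 + exp(-slope * v)) - 1/2`. Odd, strictly increasing, bounded
#' in (-1/2, 1/2); slope/4 is the gain at the operating point v = 0.
#'
#' @param v membrane potential (mV); vectorized.
#' @param slope steepness (1/mV), > 0.
#' @return normalized firing rate(s) in (-0.5, 0.5).
#' @export
firing_rate <- function(v, slope) {
  stopifnot(slope > 0)
  1 / (1 + exp(-slope * v)) - 0.5
}

#' Effective multiplicative coupling of an edge
#'
#' The extrinsic strength scaling applied on top of the nominal class
#' gain: `exp(a_log)` in the baseline block and `exp(a_log + b_log)` in
#' the modulated block, so `b_log` is the log change in connectivity from
#' the first to the final block.
#'
#' @param a_log log-scaling of baseline strength (unitless).
#' @param b_log log-modulation (unitless).
#' @param modulated logical; is the modulated condition active?
#' @return multiplicative coupling factor (> 0).
#' @export
effective_strength <- function(a_log, b_log, modulated) {
  exp(a_log + ifelse(modulated, b_log, 0))
}

#' Stimulus specification and waveform
#'
#' The exogenous input u(t) is a smooth Gaussian bump: peak value
#' `amplitude` at `onset`, standard-deviation `width`, effective support
#' about onset +/- 3 width.
#'
#' @param onset peak time (s).
#' @param width Gaussian SD (s), > 0.
#' @param amplitude peak value (unitless).
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(onset = 0.1, width = 0.016, amplitude = 1) {
  stopifnot(width > 0)
  structure(list(onset = onset, width = width, amplitude = amplitude),
            class = "stimulus_spec")
}

#' @rdname stimulus_spec
#' @param stim a `stimulus_spec`.
#' @param times uniform time grid (s).
#' @return numeric vector u(t) on `times`.
#' @export
stimulus_waveform <- function(stim, times) {
  .check_uniform(times)
  stim$amplitude * exp(-(times - stim$onset)^2 / (2 * stim$width^2))
}

.check_uniform <- function(times) {
  if (length(times) < 2L) stop("time grid needs at least 2 points")
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
    stop("time grid must be uniform and increasing")
  invisible(dt[1])
}

# Effective coupling matrices for one condition.
.coupling_matrices <- function(net, params, condition) {
  mats <- network_matrices(net)
  labs <- net$regions$label
  n <- length(labs)
  a <- matrix(0, n, n, dimnames = list(labs, labs))
  e <- net$edges
  ti <- match(e$target, labs); si <- match(e$source, labs)
  en <- edge_names(net)
  for (k in seq_len(nrow(e))) {
    aa <- params$a_log[[en[k]]]
    bb <- if (condition == "modulated" && isTRUE(e$modulable[k]))
      params$b_log[[en[k]]] else 0
    a[ti[k], si[k]] <- exp(aa + bb)
  }
  g <- params$class_gains
  list(AF = mats$forward * a * g[["forward"]],
       AB = mats$backward * a * g[["backward"]],
       AL = mats$lateral * a * g[["lateral"]])
}

#' Simulate source dynamics of the ERP neural-mass network
#'
#' Integrates the coupled neural-mass equations over a uniform output
#' grid using fixed-step classical Runge-Kutta on an oversampled internal
#' grid, then returns the pyramidal depolarization of every region
#' (including hidden ones) at the output times. Forward connections drive
#' the spiny stellate population, backward connections drive the
#' pyramidal and inhibitory-interneuron populations, lateral connections
#' drive all three; the stimulus drives the stellate population of the
#' input region(s) with gain `input_gain_base * exp(c_gain)`.
#'
#' @param net a `lep_network`.
#' @param params a `neural_params` keyed to `net`.
#' @param stim a `stimulus_spec`.
#' @param condition `"baseline"` (b_log inactive) or `"modulated"`.
#' @param times uniform output time grid (s), starting at 0.
#' @param oversample internal RK4 steps per output step (>= 4).
#' @param input_gain_base nominal input gain multiplying `exp(c_gain)`.
#' @return object of class `source_trajectory`: list with `times`,
#'   `regions` and `depolarization` (regions x times matrix, mV).
#' @export
simulate_sources <- function(net, params, stim, condition = "baseline",
                             times, oversample = 4L,
                             input_gain_base = 24) {
  condition <- match.arg(condition, c("baseline", "modulated"))
  dt_out <- .check_uniform(times)
  en <- edge_names(net)
  if (!identical(sort(names(params$a_log)), sort(en)))
    stop("a_log keys do not match network edges")
  if (!identical(sort(names(params$b_log)),
                 sort(edge_names(net, modulable_only = TRUE))))
    stop("b_log keys do not match modulable edges")
  cm <- .coupling_matrices(net, params, condition)
  labs <- net$regions$label
  Cv <- numeric(length(labs))
  ii <- match(net$input_regions, labs)
  Cv[ii] <- input_gain_base * exp(params$c_gain[net$input_regions])
  oversample <- as.integer(oversample)
  stopifnot(oversample >= 1L)
  dt_fine <- dt_out / oversample
  t_fine <- seq(times[1], times[length(times)], by = dt_fine)
  # guard against rounding producing one sample too few
  nt_fine <- (length(times) - 1L) * oversample + 1L
  t_fine <- times[1] + dt_fine * (seq_len(nt_fine) - 1L)
  u <- stimulus_waveform(stim, t_fine)
  constants <- c(params$kappa_e, params$kappa_i, params$h_e, params$h_i,
                 params$gamma, params$sigmoid_slope)
  dep <- .erp_integrate(cm$AF + cm$AL, cm$AB + cm$AL, Cv, constants, u,
                        dt_fine, oversample)
  dimnames(dep) <- list(labs, NULL)
  structure(list(times = times, regions = labs, depolarization = dep,
                 condition = condition),
            class = "source_trajectory")
}

#' @export
print.source_trajectory <- function(x, ...) {
  cat("Source trajectory:", length(x$regions), "regions,",
      length(x$times), "samples,",
      sprintf("%.0f-%.0f ms", 1000 * min(x$times), 1000 * max(x$times)),
      sprintf("(%s condition)\n", x$condition))
  invisible(x)
}

#' Export a source trajectory as delimited text
#'
#' Writes one column per region (tab-separated, time first) plus a JSON
#' metadata sidecar (`<path>.json`) recording the grid and condition.
#'
#' @param traj a `source_trajectory`.
#' @param path output path for the TSV.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, t(traj$depolarization),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(schema = "lep-trajectory/1", regions = traj$regions,
               n_times = length(traj$times),
               dt = diff(traj$times[1:2]), condition = traj$condition)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
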