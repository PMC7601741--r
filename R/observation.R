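# Observation model: gain-matrix projection of source activity to
# channels, measurement noise, and the evoked-record container.

#' Evoked-response record
#'
#' One subject/block average: a channels x samples matrix in microvolts
#' with montage and timing metadata.
#'
#' @param data channels x samples numeric matrix (µV).
#' @param rate sampling rate (Hz), > 0.
#' @param window numeric length-2, epoch start/end (s).
#' @param channels character channel labels (defaults `ch01`, ...).
#' @param subject subject identifier.
#' @param group `"control"` or `"migraine"` (or NA for unlabelled data).
#' @param condition `"block1"` or `"block3"` (or other block tag).
#' @return object of class `evoked_record`.
#' @export
evoked_record <- function(data, rate, window, channels = NULL,
                          subject = NA_character_, group = NA_character_,
                          condition = NA_character_) {
  data <- as.matrix(data)
  if (is.null(channels))
    channels <- sprintf("ch%02d", seq_len(nrow(data)))
  stopifnot(rate > 0, length(window) == 2L, window[2] > window[1],
            length(channels) == nrow(data))
  rownames(data) <- channels
  structure(list(subject = subject, group = group, condition = condition,
                 data = data, rate = rate, window = as.numeric(window),
                 channels = channels),
            class = "evoked_record")
}

#' @export
print.evoked_record <- function(x, ...) {
  cat(sprintf("Evoked record [%s/%s/%s]: %d channels x %d samples, %g Hz, %g-%g ms\n",
              x$subject, x$group, x$condition, nrow(x$data), ncol(x$data),
              x$rate, 1000 * x$window[1], 1000 * x$window[2]))
  invisible(x)
}

#' Time axis of an evoked record
#' @param rec an `evoked_record`.
#' @return numeric vector of sample times (s).
#' @export
evoked_times <- function(rec) {
  seq(rec$window[1], rec$window[2], length.out = ncol(rec$data))
}

#' Lead field (gain matrix)
#'
#' Maps per-region pyramidal depolarization (mV) to channel potentials
#' (µV). Hidden regions must have an exactly zero column so they cannot
#' contribute to the sensors directly.
#'
#' @param gain channels x regions numeric matrix (µV/mV).
#' @param regions region labels (column order).
#' @param channels channel labels (row order; default `ch01`, ...).
#' @param hidden labels of hidden regions (their columns are checked to
#'   be zero).
#' @return object of class `lead_field`.
#' @export
lead_field <- function(gain, regions, channels = NULL, hidden = "THAL") {
  gain <- as.matrix(gain)
  if (is.null(channels))
    channels <- sprintf("ch%02d", seq_len(nrow(gain)))
  stopifnot(ncol(gain) == length(regions), nrow(gain) >= 1L,
            all(is.finite(gain)))
  dimnames(gain) <- list(channels, regions)
  for (h in intersect(hidden, regions))
    if (any(gain[, h] != 0))
      stop("hidden region ", h, " must have a zero gain column")
  structure(list(gain = gain, regions = regions, channels = channels,
                 hidden = intersect(hidden, regions)),
            class = "lead_field")
}

#' Synthetic smooth lead field
#'
#' Builds a reproducible random gain matrix standing in for an
#' anatomical forward model: each observed region projects a smooth
#' spatial profile (Gaussian bump over a virtual linear montage centred
#' at a region-specific random position) with random polarity and
#' strength; hidden regions get an exactly zero column. Columns for
#' observed regions are linearly independent whenever the channel count
#' is at least the number of observed regions.
#'
#' @param n_channels number of channels (>= 1).
#' @param net a `lep_network` (fixes region order and hidden regions).
#' @param seed integer seed making the matrix reproducible.
#' @param gain_scale overall scale (µV/mV) of the projections.
#' @return a `lead_field`.
#' @export
synthesize_leadfield <- function(n_channels, net, seed,
                                 gain_scale = 500) {
  stopifnot(n_channels >= 1L)
  labs <- net$regions$label
  obs <- net$regions$observed
  gain <- with_seed(seed, {
    pos <- seq(0, 1, length.out = n_channels)
    g <- matrix(0, n_channels, length(labs))
    for (j in which(obs)) {
      centre <- stats::runif(1)
      widthc <- stats::runif(1, 0.15, 0.35)
      pol <- sample(c(-1, 1), 1)
      amp <- stats::runif(1, 0.5, 1.5)
      bump <- exp(-(pos - centre)^2 / (2 * widthc^2))
      ripple <- 0.15 * sin(2 * pi * stats::runif(1) + pos * 2 * pi *
                             stats::runif(1, 1, 3))
      g[, j] <- gain_scale * pol * amp * (bump + ripple)
    }
    g
  })
  lead_field(gain, labs, hidden = labs[!obs])
}

#' Project source dynamics to channel space
#'
#' Noiseless linear observation: `data = gain %*% depolarization`.
#'
#' @param traj a `source_trajectory`.
#' @param lf a `lead_field` whose region order matches the trajectory.
#' @param ... metadata passed to [evoked_record()] (subject, group,
#'   condition).
#' @return noiseless `evoked_record` (µV).
#' @export
project_sources <- function(traj, lf, ...) {
  if (!identical(lf$regions, traj$regions))
    stop("region order mismatch between trajectory and lead field")
  data <- lf$gain %*% traj$depolarization
  rate <- 1 / diff(traj$times[1:2])
  evoked_record(data, rate = rate,
                window = range(traj$times), channels = lf$channels, ...)
}

#' Add i.i.d. Gaussian measurement noise to a record
#'
#' @param rec an `evoked_record`.
#' @param noise_sd noise standard deviation (µV), >= 0.
#' @param seed integer seed; the same seed reproduces the same noise.
#' @return noisy `evoked_record`.
#' @export
add_noise <- function(rec, noise_sd, seed) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(rec)
  eps <- with_seed(seed,
    matrix(stats::rnorm(length(rec$data), 0, noise_sd),
           nrow(rec$data), ncol(rec$data)))
  rec$data <- rec$data + eps
  rec
}

# Run code with a temporary RNG state; restores the caller's state.
#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so library code never perturbs user
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Evoked record I/O
#'
#' Records are stored as a tab-separated channels x samples matrix (one
#' row per channel, first column the channel label) plus a JSON sidecar
#' `<path>.json` with subject, group, condition, rate and window.
#'
#' @param rec an `evoked_record`.
#' @param path TSV file path.
#' @return `write_evoked` returns `path` invisibly; `read_evoked`
#'   returns an `evoked_record`.
#' @export
write_evoked <- function(rec, path) {
  df <- data.frame(channel = rec$channels, rec$data, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(schema = "lep-evoked/1", subject = rec$subject,
               group = rec$group, condition = rec$condition,
               rate = rec$rate, window = rec$window,
               channels = rec$channels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_evoked
#' @export
read_evoked <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema, "lep-evoked/1"))
    stop("unrecognised evoked schema: ", meta$schema)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  data <- unname(as.matrix(df[, -1, drop = FALSE]))
  evoked_record(data, rate = meta$rate, window = meta$window,
                channels = df$channel, subject = meta$subject,
                group = meta$group, condition = meta$condition)
}
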