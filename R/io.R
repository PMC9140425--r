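#' Write a stimulus trajectory to columnar text
#'
#' One time column followed by one column per channel, tab separated, with
#' the generation parameters echoed into a JSON sidecar
#' (\code{<path>.json}) for provenance.
#'
#' @param traj a \code{"stim_traj"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "stim_traj"))
  T <- ncol(traj$x)
  df <- data.frame(time = (seq_len(T) - 1) * traj$dt)
  for (i in seq_len(nrow(traj$x))) df[[paste0("x", i)]] <- traj$x[i, ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(dt = traj$dt, seed = traj$seed, bounds = traj$bounds,
               d = nrow(traj$x), T = T,
               stats = traj$stats[c("sigma_cross", "alpha_scale", "p_zero",
                                    "p_zero_binwidth")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a stimulus trajectory written by [write_trajectory()]
#'
#' @param path file written by [write_trajectory()].
#' @return A \code{"stim_traj"} (stats recomputed from the data).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(dt = if (nrow(df) > 1) df$time[2] - df$time[1] else 1,
            seed = NULL, bounds = NULL)
  x <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(x) <- NULL
  new_stim_traj(x, meta$dt, meta$seed, meta$bounds)
}

#' Write a spin raster to columnar text
#'
#' Integer \eqn{\pm1} matrix, one row per time step and one column per
#' neuron; metadata (bin width, seed, any extra fields) goes to a JSON
#' sidecar.
#'
#' @param raster \code{N x T} matrix of \eqn{\pm1}, or a
#'   \code{"target_code"}.
#' @param path output file.
#' @param dt bin width recorded in the sidecar.
#' @param meta extra named metadata for the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(raster, path, dt = NULL, meta = list()) {
  if (inherits(raster, "target_code")) {
    if (is.null(dt)) dt <- raster$dt
    meta$seed <- raster$seed
    raster <- raster$spikes
  }
  stopifnot(all(raster == 1 | raster == -1))
  utils::write.table(t(raster), path, sep = "\t", row.names = FALSE,
                     col.names = paste0("n", seq_len(nrow(raster))),
                     quote = FALSE)
  meta$dt <- dt
  meta$N <- nrow(raster)
  meta$T <- ncol(raster)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a spin raster written by [write_raster()]
#'
#' @param path file written by [write_raster()].
#' @return \code{N x T} integer matrix of \eqn{\pm1}.
#' @export
read_raster <- function(path) {
  m <- t(as.matrix(utils::read.table(path, header = TRUE, sep = "\t")))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Write a coupling matrix (with metadata) to columnar text
#'
#' @param J square matrix (e.g. \code{coef()} of a fit).
#' @param path output file.
#' @param meta named metadata (method, beta, seeds, ...) for the JSON
#'   sidecar.
#' @return \code{path}, invisibly.
#' @export
write_couplings <- function(J, path, meta = list()) {
  utils::write.table(as.matrix(J), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta$N <- nrow(J)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a coupling matrix written by [write_couplings()]
#' @param path file written by [write_couplings()].
#' @return Square numeric matrix.
#' @export
read_couplings <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  m
}
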