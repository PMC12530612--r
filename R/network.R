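#' Euclidean distance on the toroidal lattice
#'
#' Distances between grid positions with per-axis wraparound
#' \code{min(|d|, side - |d|)}, the metric used by the connectivity kernel.
#'
#' @param a,b integer coordinate pairs (row, col) in \code{[0, side)}, or
#'   two-column matrices of such pairs.
#' @param side lattice side length.
#' @return numeric distance(s) in grid units.
#' @examples
#' torus_distance(c(0, 0), c(79, 0), 80)  # wraps to 1
#' @export
torus_distance <- function(a, b, side) {
  a <- matrix(as.numeric(as.matrix(a)), ncol = 2)
  b <- matrix(as.numeric(as.matrix(b)), ncol = 2)
  if (any(a < 0) || any(b < 0) || any(a >= side) || any(b >= side))
    stop("coordinates must lie in [0, side)", call. = FALSE)
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  d <- abs(a - b)
  d <- pmin(d, side - d)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' Gaussian connection probability
#'
#' \eqn{p(d) = s \exp(-d^2/2\sigma^2)}, capped at 1.  A warning flags a
#' scale whose uncapped value exceeds 1 at \eqn{d = 0}, since the kernel can
#' then no longer realize its nominal out-degree.
#'
#' @param d distance in grid units (vectorized).
#' @param sigma Gaussian width in grid units (> 0).
#' @param scale kernel value at zero distance.
#' @return probabilities in [0, 1].
#' @export
connection_probability <- function(d, sigma, scale) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (scale > 1)
    warning("kernel scale exceeds 1 at d = 0; probabilities are capped",
            call. = FALSE)
  pmin(scale * exp(-d^2 / (2 * sigma^2)), 1)
}

#' Kernel scale realizing a target mean connection probability
#'
#' The total mass of the Gaussian kernel over all torus lattice offsets sets
#' the expected number of connections a neuron sends out.  Given a target
#' mean probability \code{p_mean} (expected out-degree
#' \code{p_mean * side^2}), this returns the scale \eqn{s} such that
#' \eqn{s \sum_{\Delta} \exp(-d(\Delta)^2/2\sigma^2) = p_{mean} \cdot side^2},
#' summing over the discrete lattice rather than the continuous integral.
#'
#' @param p_mean target mean connection probability over all ordered pairs.
#' @param sigma Gaussian width (grid units).
#' @param side lattice side length.
#' @return the scale (value of p at d = 0).
#' @export
kernel_scale <- function(p_mean, sigma, side) {
  off <- 0:(side - 1)
  w <- pmin(off, side - off)
  k <- exp(-outer(w^2, w^2, "+") / (2 * sigma^2))
  s <- p_mean * side^2 / sum(k)
  if (s > 1)
    warning("required kernel scale exceeds 1; target out-degree infeasible",
            call. = FALSE)
  s
}

#' Build a network realization
#'
#' Samples every recurrent connection class (\code{ee, ei, ie, ii}) with
#' independent Bernoulli draws per ordered pair, probability given by the
#' Gaussian torus kernel of the presynaptic population
#' (\code{sigma_E} for \code{ee}/\code{ei}, \code{sigma_I} for
#' \code{ie}/\code{ii}).  Self-connections within a population are excluded;
#' no multi-edges.  Topology is stored per class in compressed sparse row
#' form; synaptic weights stay class-level scalars so weight sweeps reuse
#' the same topology.
#'
#' @param conn a \code{\link{connectivity_config}}.
#' @param seed integer seed controlling the sampling.
#' @return an object of class \code{"sc_network"} with elements
#'   \code{adjacency} (per-class CSR lists), \code{conn}, \code{scales}
#'   (kernel scale per class), \code{seed}.
#' @export
build_network <- function(conn, seed = 1L) {
  stopifnot(inherits(conn, "connectivity_config"))
  side <- conn$grid_side
  sig <- c(ee = conn$sigma_E, ei = conn$sigma_E,
           ie = conn$sigma_I, ii = conn$sigma_I)
  scales <- vapply(names(sig), function(cl)
    kernel_scale(conn$p[[cl]], sig[[cl]], side), numeric(1))
  adjacency <- list()
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  for (cl in c("ee", "ei", "ie", "ii")) {
    adjacency[[cl]] <- cpp_build_class_adjacency(
      side, sig[[cl]], scales[[cl]],
      exclude_self = cl %in% c("ee", "ii"))
  }
  structure(list(adjacency = adjacency, conn = conn, scales = scales,
                 sigma = sig, seed = as.integer(seed)),
            class = "sc_network")
}

#' Resample one connection class in place
#'
#' Used by the E-E reduction experiment: rebuilds a single class (usually
#' \code{ee}) at a new mean connection probability while all other classes
#' keep their realized topology.
#'
#' @param network an \code{"sc_network"}.
#' @param class one of \code{"ee", "ei", "ie", "ii"}.
#' @param p_mean new mean connection probability for that class.
#' @param seed integer seed for the resampling.
#' @return the modified network.
#' @export
rebuild_class <- function(network, class, p_mean, seed = 1L) {
  stopifnot(inherits(network, "sc_network"),
            class %in% c("ee", "ei", "ie", "ii"))
  side <- network$conn$grid_side
  s <- kernel_scale(p_mean, network$sigma[[class]], side)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  network$adjacency[[class]] <- cpp_build_class_adjacency(
    side, network$sigma[[class]], s,
    exclude_self = class %in% c("ee", "ii"))
  network$scales[[class]] <- s
  network$conn$p[[class]] <- p_mean
  network
}

#' Realized out-degrees of one connection class
#'
#' @param network an \code{"sc_network"}.
#' @param class connection class name.
#' @return integer vector of out-degrees per presynaptic neuron.
#' @export
out_degrees <- function(network, class) {
  diff(network$adjacency[[class]]$row_ptr)
}

#' In-degrees of one connection class
#' @inheritParams out_degrees
#' @return integer vector of in-degrees per postsynaptic neuron.
#' @export
in_degrees <- function(network, class) {
  N <- network$conn$grid_side^2
  tabulate(network$adjacency[[class]]$targets + 1L, nbins = N)
}

#' @export
print.sc_network <- function(x, ...) {
  cat("sc_network:", x$conn$grid_side, "x", x$conn$grid_side,
      "torus per population (seed", x$seed, ")\n")
  for (cl in names(x$adjacency))
    cat(sprintf("  %s: %d edges (mean out-degree %.1f)\n", cl,
                length(x$adjacency[[cl]]$targets),
                mean(out_degrees(x, cl))))
  invisible(x)
}

#' Export a network as a plain-text edge list
#'
#' Writes one tab-separated row per edge (\code{pre}, \code{post},
#' \code{class}, \code{delay_ms}, \code{weight_nS}) plus a JSON header with
#' the configuration and seed, enough to re-run bit-identically.
#'
#' @param network an \code{"sc_network"}.
#' @param weights_nS named calibrated peak conductances per class (nS), as
#'   from \code{\link{calibrate_weights}}.
#' @param syn a \code{\link{synapse_params}} (delays).
#' @param file path of the edge-list file; a sidecar \code{<file>.json}
#'   header is written next to it.
#' @return \code{file}, invisibly.
#' @export
write_network <- function(network, weights_nS, syn, file) {
  rows <- lapply(names(network$adjacency), function(cl) {
    adj <- network$adjacency[[cl]]
    if (!length(adj$targets)) return(NULL)
    data.frame(pre = rep(seq_len(length(adj$row_ptr) - 1L) - 1L,
                         diff(adj$row_ptr)),
               post = adj$targets, class = cl,
               delay_ms = syn$delay[[cl]],
               weight_nS = unname(weights_nS[[cl]]))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  hdr <- list(grid_side = network$conn$grid_side, p = as.list(network$conn$p),
              sigma_E = network$conn$sigma_E, sigma_I = network$conn$sigma_I,
              seed = network$seed)
  jsonlite::write_json(hdr, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
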