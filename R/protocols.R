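#' Select the center subpopulation
#'
#' Deterministically picks the \code{count} lattice positions nearest the
#' grid center (ties broken by angle, then linear index), all of which must
#' lie within \code{radius} grid points.  With the defaults this is the
#' 314-neuron disc of radius 10 used for the center stimulus; the same
#' positions index both the excitatory and the inhibitory population.
#'
#' @param grid_side lattice side length.
#' @param radius maximal distance from the grid center (grid points).
#' @param count number of positions to take.
#' @return integer vector of 0-based position indices (row-major), with the
#'   selected (row, col) coordinates as attribute \code{"coords"}.
#' @export
select_center <- function(grid_side = 80, radius = 10, count = 314) {
  ctr <- (grid_side - 1) / 2
  pos <- expand.grid(row = 0:(grid_side - 1), col = 0:(grid_side - 1))
  d <- sqrt((pos$row - ctr)^2 + (pos$col - ctr)^2)
  ang <- atan2(pos$row - ctr, pos$col - ctr)
  ord <- order(d, ang, seq_len(nrow(pos)))
  if (count > sum(d <= radius + 1e-9))
    stop(sprintf("only %d lattice positions lie within radius %g; cannot select %d",
                 sum(d <= radius + 1e-9), radius, count), call. = FALSE)
  sel <- ord[seq_len(count)]
  idx <- as.integer(pos$row[sel] * grid_side + pos$col[sel])
  attr(idx, "coords") <- cbind(row = pos$row[sel], col = pos$col[sel])
  attr(idx, "distance") <- d[sel]
  idx
}

#' Select the surround subpopulation
#'
#' All positions of the \code{square_side} x \code{square_side} square
#' centered on the grid center, minus the center set.  With the 60-point
#' square and the 314-neuron center this yields 3,286 positions per
#' population (60^2 - 314).
#'
#' @param grid_side lattice side length.
#' @param square_side side of the surround square (grid points).
#' @param center_idx 0-based position indices of the center set.
#' @return integer vector of 0-based position indices.
#' @export
select_surround <- function(grid_side = 80, square_side = 60,
                            center_idx = integer()) {
  if (square_side > grid_side)
    stop("surround square larger than the grid", call. = FALSE)
  lo <- floor((grid_side - square_side) / 2)
  rows <- lo:(lo + square_side - 1)
  sq <- as.vector(outer(rows * grid_side, rows, "+"))
  setdiff(as.integer(sq), as.integer(center_idx))
}

#' Center/surround stimulation protocol
#'
#' Defines one of the four stimulus conditions applied on top of the
#' background drive.  The center stimulus is a synchronous volley of
#' \code{n_volley} retinal spikes (1.1 mV each after calibration) delivered
#' to every center neuron at its own time \code{T_center + r},
#' \code{r ~ U[0, jitter]} ms.  The surround stimulus drives every surround
#' neuron with an independent Poisson train at \code{surround_rate} Hz
#' restricted to \code{surround_window}.  In \code{center_after_surround}
#' the default 20 ms surround window terminates exactly at center onset
#' (the model timing; the slice collision protocol's 0-50 ms gaps are
#' available through \code{surround_window}); in
#' \code{center_during_surround} the center onset falls inside the
#' surround window.
#'
#' @param condition one of \code{"center_only"}, \code{"surround_only"},
#'   \code{"center_during_surround"}, \code{"center_after_surround"}.
#' @param T_center center volley onset (ms); defaults to 100 ms
#'   (\code{center_only}, \code{center_after_surround}) or the middle of the
#'   surround window (\code{center_during_surround}).
#' @param surround_window numeric (start, stop) ms of the surround drive.
#' @param surround_rate Poisson rate (Hz) per stimulated surround neuron.
#' @param t_stop end of the simulated window (ms).
#' @param n_volley retinal spikes per center neuron per volley.
#' @param jitter upper bound (ms) of the uniform per-neuron volley jitter.
#' @param center_radius,center_count,square_side geometry of the stimulated
#'   sets (see \code{\link{select_center}}, \code{\link{select_surround}}).
#' @param bg_rate_ex,bg_rate_ix background Poisson rates (Hz) per neuron,
#'   length-2 (E population, I population) or scalar; the excitatory rate is
#'   normally set with \code{\link{tune_background}}.
#' @return an object of class \code{"stimulus_protocol"}.
#' @export
stimulus_protocol <- function(condition = c("center_only", "surround_only",
                                            "center_during_surround",
                                            "center_after_surround"),
                              T_center = NULL,
                              surround_window = NULL,
                              surround_rate = 300,
                              t_stop = NULL,
                              n_volley = 10, jitter = 1,
                              center_radius = 10, center_count = 314,
                              square_side = 60,
                              bg_rate_ex = c(1425, 1425),
                              bg_rate_ix = c(400, 400)) {
  condition <- match.arg(condition)
  has_surround <- condition != "center_only"
  has_center <- condition != "surround_only"
  if (is.null(T_center))
    T_center <- if (condition == "center_during_surround") 70 else 100
  if (is.null(surround_window)) {
    surround_window <- switch(condition,
      center_after_surround = c(T_center - 20, T_center),
      center_during_surround = c(T_center - 10, T_center + 10),
      c(60, 80))
  }
  if (is.null(t_stop))
    t_stop <- max(T_center + 100, surround_window[2] + 100)
  if (surround_rate < 0) stop("surround_rate must be >= 0", call. = FALSE)
  if (diff(surround_window) < 0)
    stop("surround_window must be (start, stop) with stop >= start",
         call. = FALSE)
  if (condition == "center_during_surround" &&
      (T_center < surround_window[1] || T_center > surround_window[2]))
    stop("center_during_surround requires T_center inside surround_window",
         call. = FALSE)
  if (condition == "center_after_surround" && T_center < surround_window[2])
    stop("center_after_surround requires T_center at or after surround stop",
         call. = FALSE)
  if (length(bg_rate_ex) == 1) bg_rate_ex <- rep(bg_rate_ex, 2)
  if (length(bg_rate_ix) == 1) bg_rate_ix <- rep(bg_rate_ix, 2)
  if (any(bg_rate_ex < 0) || any(bg_rate_ix < 0))
    stop("background rates must be >= 0", call. = FALSE)
  structure(list(condition = condition, T_center = T_center,
                 surround_window = surround_window,
                 surround_rate = surround_rate, t_stop = t_stop,
                 n_volley = n_volley, jitter = jitter,
                 center_radius = center_radius, center_count = center_count,
                 square_side = square_side,
                 has_center = has_center, has_surround = has_surround,
                 bg_rate_ex = bg_rate_ex, bg_rate_ix = bg_rate_ix),
            class = "stimulus_protocol")
}

#' Center-volley external spike events
#'
#' One compound event of \code{n_volley} coincident retinal spikes per
#' center neuron (excitatory and inhibitory), at per-neuron times
#' \code{T_center + r}, \code{r ~ U[0, jitter]} ms.  Draws from the current
#' RNG state; seed it for reproducibility.
#'
#' @param center_idx 0-based center position indices.
#' @param N_E excitatory population size (inhibitory ids are offset by it).
#' @param T_center onset (ms).
#' @param w_retinal calibrated retinal peak conductance (nS) per spike.
#' @param n_volley spikes per compound event.
#' @param jitter uniform jitter upper bound (ms).
#' @return data.frame with columns \code{id} (global neuron id),
#'   \code{time} (ms), \code{amount} (nS peak-conductance increment).
#' @export
make_center_volley <- function(center_idx, N_E, T_center, w_retinal,
                               n_volley = 10, jitter = 1) {
  ids <- c(center_idx, N_E + center_idx)
  r <- stats::runif(length(ids), 0, jitter)
  data.frame(id = as.integer(ids), time = T_center + r,
             amount = n_volley * w_retinal)
}

#' Surround Poisson external spike events
#'
#' Independent Poisson spike trains, one per stimulated surround neuron
#' (both populations), restricted to the stimulation window and delivered
#' through the retinal-class synapse.
#'
#' @param surround_idx 0-based surround position indices.
#' @param N_E excitatory population size.
#' @param window numeric (start, stop) ms.
#' @param rate Poisson rate per neuron (Hz).
#' @param w_retinal peak conductance (nS) per stimulus spike.
#' @return event data.frame as in \code{\link{make_center_volley}}.
#' @export
make_surround_drive <- function(surround_idx, N_E, window, rate, w_retinal) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  ids <- c(surround_idx, N_E + surround_idx)
  dur <- diff(window)
  counts <- stats::rpois(length(ids), rate * dur / 1000)
  if (sum(counts) == 0)
    return(data.frame(id = integer(), time = numeric(), amount = numeric()))
  data.frame(id = rep(as.integer(ids), counts),
             time = window[1] + stats::runif(sum(counts), 0, dur),
             amount = w_retinal)
}

#' Run one simulated trial
#'
#' Simulates the full window at fixed step \code{dt}, applying the
#' background drive plus the protocol's center/surround stimuli, and records
#' the spike raster of both populations together with the excitatory and
#' inhibitory conductances and membrane potential of one center excitatory
#' neuron.  Identical \code{seed} gives bit-identical output.
#'
#' @param network an \code{"sc_network"} from \code{\link{build_network}}.
#' @param weights_nS named calibrated peak conductances (nS) including
#'   \code{retinal}, from \code{\link{calibrate_weights}}.
#' @param syn,neuron model parameters.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param seed integer trial seed.
#' @param record_neuron global id of the recorded neuron; by default one
#'   center excitatory neuron drawn from the seed (kept fixed across trials
#'   by passing it explicitly).
#' @param dt integration step (ms).
#' @param record_traces logical; record ge/gi/V at the recorded neuron.
#' @return an object of class \code{"trial_recording"}: \code{time} (ms),
#'   \code{ge}, \code{gi} (nS), \code{V} (mV), \code{spikes} (data.frame
#'   \code{id}, \code{pop}, \code{time}), plus protocol and seed metadata.
#' @export
run_trial <- function(network, weights_nS, syn, neuron, protocol,
                      seed = 1L, record_neuron = NULL, dt = 0.1,
                      record_traces = TRUE) {
  stopifnot(inherits(network, "sc_network"),
            inherits(protocol, "stimulus_protocol"))
  side <- network$conn$grid_side
  N_E <- network$conn$N_E
  center <- select_center(side, protocol$center_radius, protocol$center_count)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  if (is.null(record_neuron))
    record_neuron <- sample(center, 1)
  if (!(record_neuron %in% center))
    stop("record_neuron must belong to the center excitatory set",
         call. = FALSE)

  events <- data.frame(id = integer(), time = numeric(), amount = numeric())
  if (protocol$has_surround) {
    surround <- select_surround(side, protocol$square_side, center)
    events <- rbind(events, make_surround_drive(
      surround, N_E, protocol$surround_window, protocol$surround_rate,
      weights_nS[["retinal"]]))
  }
  if (protocol$has_center) {
    events <- rbind(events, make_center_volley(
      center, N_E, protocol$T_center, weights_nS[["retinal"]],
      protocol$n_volley, protocol$jitter))
  }
  d_ex_steps <- as.integer(round(syn$delay[["ex"]] / dt))
  ev_step <- as.integer(round(events$time / dt)) + d_ex_steps
  ord <- order(ev_step)
  n_steps <- as.integer(ceiling(protocol$t_stop / dt))
  keep <- ev_step[ord] < n_steps
  res <- cpp_simulate(
    n_steps, dt, neuron$C_m, neuron$g_L, neuron$E_L, neuron$V_th,
    as.integer(round(neuron$t_ref / dt)),
    N_E, network$conn$N_I,
    network$adjacency$ee, network$adjacency$ei,
    network$adjacency$ie, network$adjacency$ii,
    unname(syn$tau), as.integer(round(unname(syn$delay) / dt)),
    unname(weights_nS[c("ee", "ei", "ie", "ii")]),
    weights_nS[["ex"]], weights_nS[["ix"]],
    syn$E_rev_exc, syn$E_rev_inh,
    protocol$bg_rate_ex, protocol$bg_rate_ix,
    ev_step[ord][keep], events$id[ord][keep], events$amount[ord][keep],
    as.integer(record_neuron), record_traces)
  spikes <- data.frame(id = res$spike_id,
                       pop = ifelse(res$spike_id < N_E, "E", "I"),
                       time = res$spike_step * dt)
  structure(list(time = seq_len(n_steps) * dt, ge = res$ge, gi = res$gi,
                 V = res$V, spikes = spikes,
                 record_neuron = as.integer(record_neuron),
                 protocol = protocol, seed = as.integer(seed), dt = dt,
                 N_E = N_E, N_I = network$conn$N_I),
            class = "trial_recording")
}

#' Mean population firing rates
#'
#' @param x a \code{"trial_recording"} (or list of them, pooled) whose
#'   raster is evaluated.
#' @param window numeric (start, stop) ms; spikes outside are ignored.
#' @return list with \code{rate_E}, \code{rate_I} (Hz, mean over neurons)
#'   and the spike counts.
#' @export
population_rates <- function(x, window) {
  if (inherits(x, "trial_recording")) x <- list(x)
  if (diff(window) <= 0) stop("empty window", call. = FALSE)
  dur_s <- diff(window) / 1000 * length(x)
  nE <- sum(vapply(x, function(tr)
    sum(tr$spikes$pop == "E" & tr$spikes$time >= window[1] &
          tr$spikes$time <= window[2]), numeric(1)))
  nI <- sum(vapply(x, function(tr)
    sum(tr$spikes$pop == "I" & tr$spikes$time >= window[1] &
          tr$spikes$time <= window[2]), numeric(1)))
  list(rate_E = nE / (x[[1]]$N_E * dur_s), rate_I = nI / (x[[1]]$N_I * dur_s),
       n_spikes_E = nE, n_spikes_I = nI)
}

#' Tune the background excitatory rate to the sub-1 Hz regime
#'
#' Bisection on the per-neuron background excitatory Poisson rate until the
#' population mean firing rate over a stimulus-free window lands in
#' \code{(target_lo, target_hi)} Hz (the model's specified operating point
#' is a low-rate, inhibition-dominated background below 1 Hz).  The
#' inhibitory background rate stays fixed.
#'
#' @param network,weights_nS,syn,neuron model pieces as in
#'   \code{\link{run_trial}}.
#' @param bg_rate_ix fixed inhibitory background rate (Hz).
#' @param target_lo,target_hi acceptance band (Hz) for the population mean.
#' @param bounds search interval (Hz) for the excitatory rate.
#' @param t_sim simulated span (ms) per evaluation.
#' @param seed integer seed.
#' @param max_iter bisection cap.
#' @return list with \code{bg_rate_ex}, \code{rate} (population mean, Hz),
#'   \code{rate_E}, \code{rate_I}.
#' @export
tune_background <- function(network, weights_nS, syn, neuron,
                            bg_rate_ix = 400, target_lo = 0.2,
                            target_hi = 0.8, bounds = c(200, 10000),
                            t_sim = 500, seed = 1L, max_iter = 14) {
  eval_rate <- function(nu, s) {
    prot <- stimulus_protocol("surround_only", surround_rate = 0,
                              surround_window = c(0, 0), t_stop = t_sim,
                              bg_rate_ex = nu, bg_rate_ix = bg_rate_ix)
    tr <- run_trial(network, weights_nS, syn, neuron, prot, seed = s,
                    record_neuron = select_center(network$conn$grid_side)[1],
                    record_traces = FALSE)
    # discard a 100 ms transient
    population_rates(tr, c(100, t_sim))
  }
  lo <- bounds[1]; hi <- bounds[2]
  r_hi <- eval_rate(hi, seed)
  if ((r_hi$rate_E + r_hi$rate_I) / 2 < target_lo)
    stop("background tuning failed: upper bound still below target band",
         call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- eval_rate(mid, seed + i)
    m <- (r$rate_E + r$rate_I) / 2
    if (m > target_hi) hi <- mid
    else if (m < target_lo) lo <- mid
    else return(list(bg_rate_ex = mid, rate = m,
                     rate_E = r$rate_E, rate_I = r$rate_I))
  }
  stop(sprintf(
    "background tuning did not land in (%g, %g) Hz within %d iterations (last rate %.3g Hz at %.0f Hz input)",
    target_lo, target_hi, max_iter, m, mid), call. = FALSE)
}
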