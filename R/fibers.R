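# Fiber simulation, activation detection, bisection threshold search,
# quadratic threshold interpolation, population mapping, dose-response.

#' Simulation settings for fiber models
#'
#' @param dt_us Time step (default 1 us).
#' @param duration_ms Simulated time (default 50 ms; threshold searches may
#'   shorten it since detection happens within a few ms of onset).
#' @param temperature_C Temperature for channel kinetics (default 36).
#' @export
sim_settings <- function(dt_us = 1, duration_ms = 50, temperature_C = 36) {
  stopifnot_scalar_num(dt_us, "dt_us", 0, strict = TRUE)
  structure(list(dt_us = dt_us, duration_ms = duration_ms,
                 temperature_C = temperature_C),
            class = "sim_settings")
}

#' Simulate an MRG fiber under an extracellular potential waveform
#'
#' Backward-Euler integration of the double-cable model (semi-implicit
#' gating) with the extracellular potential applied per compartment as
#' `ve_shape x weight(t)`.
#'
#' @param fiber A [build_mrg_fiber()].
#' @param ve_shape_mV Extracellular potential per compartment at unit
#'   stimulus weight, mV (length = number of compartments, or scalar).
#' @param weights Stimulus weight per time step (length `n_steps + 1`); or
#'   a `stimulus` whose weight is evaluated on the time grid and scaled by
#'   its amplitude.
#' @param settings A [sim_settings()].
#' @return Object of class `fiber_sim`: `traces` (nodes x time, mV),
#'   `times_ms`, `node_z_um`, `blowup` flag.
#' @export
simulate_fiber <- function(fiber, ve_shape_mV, weights,
                           settings = sim_settings()) {
  el <- mrg_electrical(fiber)
  n <- nrow(fiber$compartments)
  if (length(ve_shape_mV) == 1) ve_shape_mV <- rep(ve_shape_mV, n)
  if (length(ve_shape_mV) != n) {
    nm_abort("LENGTH_MISMATCH", "ve_shape must have one value per compartment")
  }
  dt_ms <- settings$dt_us / 1000
  nsteps <- ceiling(settings$duration_ms / dt_ms)
  times <- seq(0, by = dt_ms, length.out = nsteps + 1)
  if (inherits(weights, "stimulus")) {
    weights <- stimulus_weight(weights, times) * weights$amplitude_mA
  }
  if (length(weights) != nsteps + 1) {
    nm_abort("LENGTH_MISMATCH", "weights must cover every time step")
  }
  tc <- settings$temperature_C
  k <- mrg_constants()
  res <- mrg_backward_euler(
    el$cm, el$gpas, el$epas, el$cmy, el$gmy, el$is_node,
    el$gnaf, el$gnap, el$gks, el$gax, el$gp,
    ve_shape_mV, weights, dt_ms, k$v_rest, k$ena, k$ek,
    2.2^((tc - 20) / 10), 2.9^((tc - 20) / 10), 3.0^((tc - 36) / 10),
    fiber$node_idx - 1L
  )
  if (res$blowup) nm_abort("NUMERICAL_BLOWUP", "non-finite membrane state")
  structure(list(traces = res$traces, times_ms = times,
                 node_z_um = fiber$compartments$z_um[fiber$node_idx],
                 node_idx = fiber$node_idx, blowup = res$blowup),
            class = "fiber_sim")
}

#' Detect activation on a membrane trace (rising-edge -30 mV crossing)
#'
#' @param trace Membrane potential samples at the detection node, mV.
#' @param threshold_mV Crossing level (default -30).
#' @return TRUE iff the trace crosses the level from below.
#' @export
detect_activation <- function(trace, threshold_mV = -30) {
  n <- length(trace)
  any(trace[-1] >= threshold_mV & trace[-n] < threshold_mV)
}

# Node of Ranvier closest to 90% of the fiber length.
detection_node <- function(fiber, fraction = 0.9) {
  z <- fiber$compartments$z_um
  target <- min(z) + fraction * (max(z) - min(z))
  which.min(abs(fiber$compartments$z_um[fiber$node_idx] - target))
}

#' Bisection search for the activation threshold of a fiber
#'
#' The initial bracket doubles from `seed_mA` until the fiber activates
#' (rising-edge -30 mV crossing at the node nearest 90% of fiber length);
#' bisection then narrows until upper and lower bounds are within 1% of
#' each other. The reported threshold is the upper bound, which is
#' guaranteed to activate.
#'
#' @param fiber A [build_mrg_fiber()].
#' @param ve_shape_mV Per-compartment extracellular potential for a 1 mA
#'   drive, mV (e.g. from field sampling and [superpose_contacts()]).
#' @param stim A [stimulus()]; its amplitude is the search variable.
#' @param settings A [sim_settings()].
#' @param seed_mA Starting amplitude for bracketing.
#' @param cap_mA Bracket cap; exceeding it raises `NO_ACTIVATION`.
#' @param rel_tol Termination half-width (default 0.01 = 1%).
#' @param .activated_fn Optional replacement for the simulate-and-detect
#'   predicate (amplitude -> logical); lets the search contract be verified
#'   against analytic mocks.
#' @return Object of class `threshold_result`: `threshold_mA`, bounds,
#'   iteration count, and the bracket history.
#' @export
find_threshold <- function(fiber, ve_shape_mV, stim = stimulus(),
                           settings = sim_settings(duration_ms = 10),
                           seed_mA = 0.01, cap_mA = 1000, rel_tol = 0.01,
                           .activated_fn = NULL) {
  activated <- .activated_fn %||% local({
    det <- detection_node(fiber)
    function(a_mA) {
      s <- stimulus(a_mA, stim$phase_us, stim$start_ms, stim$polarity)
      sim <- simulate_fiber(fiber, ve_shape_mV, s, settings)
      detect_activation(sim$traces[det, ])
    }
  })

  hist <- list()
  a <- seed_mA
  if (activated(a)) {
    upper <- a
    lower <- a
    repeat {
      lower <- lower / 2
      if (lower < 1e-9) {
        nm_abort("ALWAYS_ACTIVE",
                 "fiber activates at vanishing amplitude (instability)")
      }
      if (!activated(lower)) break
    }
  } else {
    lower <- a
    repeat {
      a <- a * 2
      if (a > cap_mA) nm_abort("NO_ACTIVATION", sprintf(
        "no activation up to %.0f mA", cap_mA))
      if (activated(a)) { upper <- a; break }
      lower <- a
    }
  }

  iters <- 0L
  while ((upper - lower) / upper > rel_tol) {
    iters <- iters + 1L
    mid <- (upper + lower) / 2
    if (activated(mid)) upper <- mid else lower <- mid
    hist[[iters]] <- c(lower = lower, upper = upper)
  }
  structure(list(threshold_mA = upper, lower_mA = lower, upper_mA = upper,
                 iterations = iters, activated_at_threshold = TRUE,
                 bracket_history = if (length(hist))
                   do.call(rbind, hist) else matrix(numeric(0), 0, 2)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %.4f mA (bounds %.4f-%.4f, %d bisections)\n",
              x$threshold_mA, x$lower_mA, x$upper_mA, x$iterations))
  invisible(x)
}

#' Least-squares quadratic fit of thresholds across fiber diameters
#'
#' @param diameters_um,thresholds_mA Paired samples (>= 3 distinct
#'   diameters); with exactly 3 the fit interpolates.
#' @return Object of class `threshold_fit`: coefficients `c0, c1, c2` of
#'   `t(d) = c0 + c1 d + c2 d^2` and `predict(d)`.
#' @export
fit_quadratic_thresholds <- function(diameters_um, thresholds_mA) {
  if (length(unique(diameters_um)) < 3) {
    nm_abort("INSUFFICIENT_POINTS", "need >= 3 distinct diameters")
  }
  X <- cbind(1, diameters_um, diameters_um^2)
  cf <- qr.coef(qr(X), thresholds_mA)
  pred <- function(d) cf[1] + cf[2] * d + cf[3] * d^2
  structure(list(c0 = unname(cf[1]), c1 = unname(cf[2]), c2 = unname(cf[3]),
                 predict = pred,
                 residuals = thresholds_mA - pred(diameters_um),
                 diameters_um = diameters_um, thresholds_mA = thresholds_mA),
            class = "threshold_fit")
}

#' Map per-fascicle quadratic threshold fits onto a fiber population
#'
#' Applies the exclusion rule (diameters below 2 um or above 16 um are
#' dropped and counted) and evaluates each kept fiber's fascicle quadratic
#' at its diameter.
#'
#' @param population Tibble with `fiber_id, x_um, y_um, diameter_um,
#'   fascicle_id` (e.g. [gen_fiber_population()]).
#' @param fits Named list of [fit_quadratic_thresholds()] results, names =
#'   fascicle ids.
#' @param d_min_um,d_max_um Exclusion bounds (defaults 2 and 16).
#' @return Object of class `threshold_map`: tibble of kept fibers with
#'   `threshold_mA`, plus `excluded` counts.
#' @export
assign_population_thresholds <- function(population, fits,
                                         d_min_um = 2, d_max_um = 16) {
  pop <- dplyr::mutate(
    tibble::as_tibble(population),
    too_small = .data$diameter_um < d_min_um,
    too_large = .data$diameter_um > d_max_um
  )
  kept <- dplyr::filter(pop, !.data$too_small & !.data$too_large)
  missing <- setdiff(unique(kept$fascicle_id), names(fits))
  if (length(missing)) {
    nm_abort("MISSING_FASCICLE_FIT", sprintf(
      "no threshold fit for fascicle(s) %s", paste(missing, collapse = ", ")))
  }
  kept$threshold_mA <- vapply(seq_len(nrow(kept)), function(i)
    fits[[as.character(kept$fascicle_id[i])]]$predict(kept$diameter_um[i]),
    numeric(1))
  structure(list(fibers = kept,
                 excluded = c(too_small = sum(pop$too_small),
                              too_large = sum(pop$too_large))),
            class = "threshold_map")
}

#' @export
print.threshold_map <- function(x, ...) {
  cat(sprintf("<threshold_map> %d fiber(s), excluded %d small / %d large\n",
              nrow(x$fibers), x$excluded["too_small"], x$excluded["too_large"]))
  invisible(x)
}

#' Dose-response (recruitment) curve from a set of thresholds
#'
#' @param thresholds_mA Fiber activation thresholds (non-excluded fibers),
#'   or a `threshold_map`.
#' @param amplitudes_mA Amplitude grid (sorted internally).
#' @return Object of class `dose_response`: tibble `amplitude_mA`,
#'   `fraction_activated`.
#' @export
dose_response_curve <- function(thresholds_mA, amplitudes_mA) {
  if (inherits(thresholds_mA, "threshold_map")) {
    thresholds_mA <- thresholds_mA$fibers$threshold_mA
  }
  if (length(thresholds_mA) < 1) {
    nm_abort("EMPTY_POPULATION", "no thresholds to summarize")
  }
  a <- sort(amplitudes_mA)
  frac <- vapply(a, function(x) mean(thresholds_mA <= x), numeric(1))
  structure(list(curve = tibble::tibble(amplitude_mA = a,
                                        fraction_activated = frac),
                 n_fibers = length(thresholds_mA)),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %d fiber(s), %d amplitude(s)\n",
              x$n_fibers, nrow(x$curve)))
  invisible(x)
}

#' Interpolate sampled potentials at fiber compartment centers
#'
#' Linear interpolation of 1-um line samples to the MRG compartment
#' spacings, in mV.
#'
#' @param samples Tibble from [sample_potentials_along_line()] (`arc_um`,
#'   `v_volts`), sampled along the fiber's path.
#' @param fiber A [build_mrg_fiber()]; compartment z positions are matched
#'   to arc positions (fiber assumed straight along the sampled line).
#' @param arc_offset_um Arc position of the fiber's first compartment.
#' @param extend Allow compartments beyond the sampled span to take the
#'   nearest sample (constant extension) instead of raising `OUT_OF_DOMAIN`;
#'   used when the whole-internode fiber layout slightly overhangs the line.
#' @return Numeric vector, mV per compartment.
#' @export
compartment_potentials <- function(samples, fiber, arc_offset_um = NULL,
                                   extend = FALSE) {
  z <- fiber$compartments$z_um
  arc <- samples$arc_um
  pos <- z - min(z) + (arc_offset_um %||% 0)
  if (!extend && any(pos < min(arc) - 1e-9 | pos > max(arc) + 1e-9)) {
    nm_abort("OUT_OF_DOMAIN", "fiber extends beyond the sampled line")
  }
  stats::approx(arc, samples$v_volts, pos, rule = 2)$y * 1000
}
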