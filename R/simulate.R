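#' Time integration and extraction analysis
#'
#' [simulate()] integrates a scenario with event handling (release,
#' rupture), returning a `clot_sim_result` with per-partition trajectories,
#' the detachment times and the extraction time. [pressure_sweep()] and
#' [minimum_release_force()] locate the minimum effective suction.
#'
#' @name simulate
NULL

.event_row <- function(time, type, index, detail = NA_real_) {
  data.frame(time = time, type = type, index = index, detail = detail)
}

.empty_events <- function() {
  data.frame(time = numeric(0), type = character(0), index = integer(0),
             detail = numeric(0))
}

.new_result <- function(scenario, model, time, x, v, attached, F_applied,
                        detach_times, events, ruptured, rupture_junction,
                        rupture_time) {
  res <- structure(
    list(scenario = scenario, model = model, time = time, x = x, v = v,
         attached = attached, F_applied = F_applied,
         detach_times = detach_times, events = events,
         ruptured = ruptured, rupture_junction = rupture_junction,
         rupture_time = rupture_time, extraction_time = NA_real_),
    class = "clot_sim_result")
  res$extraction_time <- extraction_time(res, scenario$extraction_distance)
  res
}

#' Simulate a scenario
#'
#' Integrates the model with `deSolve::lsodar`, which locates the release
#' and rupture events by root finding; integration restarts after each
#' event with the updated attachment set. Results are reported on a fixed
#' output grid (plus the exact event times), and the run is fully
#' deterministic: identical scenarios give bit-identical results.
#'
#' @param scenario a [scenario()].
#' @param t_end end time (s).
#' @param dt output sampling interval (s).
#' @param applied_force optional function of time (s) returning the applied
#'   force (N) on the proximal partition, overriding the scenario's
#'   pressure-derived forcing (used for force-controlled experiments and
#'   oracle checks).
#' @param initial_state optional list with entries `x`, `v` (numeric,
#'   length `n_partitions`) and `attached` (logical) to start from a
#'   non-default configuration.
#' @param rtol,atol solver tolerances.
#' @return object of class `clot_sim_result` with fields `time`, `x`, `v`,
#'   `attached` (matrices, one column per partition), `F_applied`,
#'   `detach_times` (s, `NA` when never released), `events`, `ruptured`,
#'   `rupture_junction`, `rupture_time` and `extraction_time` (proximal
#'   face, at the scenario's extraction distance).
#' @export
simulate <- function(scenario, t_end = 10, dt = 1e-3, applied_force = NULL,
                     initial_state = NULL, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(scenario, "clot_scenario"), t_end > 0, dt > 0)
  if (scenario$model_variant == "simple") {
    .simulate_simple(scenario, t_end, dt, applied_force, rtol, atol)
  } else {
    .simulate_extended(scenario, t_end, dt, applied_force, initial_state,
                       rtol, atol)
  }
}

.simulate_extended <- function(scenario, t_end, dt, applied_force,
                               initial_state, rtol, atol) {
  model <- build_extended_model(scenario)
  n <- nrow(model$partitions)
  Ffun <- if (is.null(applied_force)) make_applied_force(scenario) else
    applied_force
  attached <- model$attached
  x <- numeric(n)
  v <- numeric(n)
  if (!is.null(initial_state)) {
    if (!is.null(initial_state$x)) x <- initial_state$x
    if (!is.null(initial_state$v)) v <- initial_state$v
    if (!is.null(initial_state$attached)) attached <- initial_state$attached
  }
  grid <- seq(0, t_end, by = dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)

  times <- numeric(0)
  xs <- vs <- ats <- NULL
  events <- .empty_events()
  detach_times <- rep(NA_real_, n)
  detach_times[!attached] <- 0
  ruptured <- FALSE
  rupture_junction <- NA_integer_
  rupture_time <- NA_real_
  t0 <- 0

  release_partition <- function(j, t_ev) {
    attached[j] <<- FALSE
    detach_times[j] <<- t_ev
    events <<- rbind(events,
                     .event_row(t_ev, "release", j - 1L,
                                model$partitions$adhesion_force[j]),
                     .event_row(t_ev, "friction_dynamic", j - 1L))
    if (!is.null(scenario$artery$stenosis)) {
      model$partitions <<- repartition_after_motion(
        model$partitions, max(0, x[j]), scenario$artery, scenario$clot)
    }
    model$partitions$adhesion_force[j] <<- 0
  }

  max_segments <- 10L * n + 100L
  for (segment in seq_len(max_segments)) {
    # cascade releases whose triggers are already met at the segment start
    repeat {
      j <- which(attached)[1]
      if (is.na(j)) break
      trig <- .release_trigger(t0, x, v, j, model, Ffun)
      if (trig >= model$partitions$adhesion_force[j]) {
        release_partition(j, t0)
      } else break
    }
    seg_times <- unique(c(t0, grid[grid > t0]))
    if (length(seg_times) < 2L) break
    att_now <- attached
    out <- deSolve::lsodar(
      y = c(x, v), times = seg_times,
      func = function(t, y, parms) chain_rhs(t, y, model, att_now, Ffun),
      rootfunc = function(t, y, parms) .chain_root(t, y, model, att_now, Ffun),
      rtol = rtol, atol = atol)
    keep <- seq_len(nrow(out))
    if (length(times) && out[1, 1] == times[length(times)]) keep <- keep[-1L]
    if (length(keep)) {
      times <- c(times, out[keep, 1])
      xs <- rbind(xs, out[keep, 1L + seq_len(n), drop = FALSE])
      vs <- rbind(vs, out[keep, 1L + n + seq_len(n), drop = FALSE])
      ats <- rbind(ats, matrix(att_now, nrow = length(keep), ncol = n,
                               byrow = TRUE))
    }
    last <- out[nrow(out), ]
    t0 <- unname(last[1])
    x <- unname(last[1L + seq_len(n)])
    v <- unname(last[1L + n + seq_len(n)])
    iroot <- which(attr(out, "iroot") == 1L)
    if (is.null(attr(out, "troot")) || !length(iroot)) {
      break  # reached t_end without an event
    }
    if (2L %in% iroot) {
      rup <- rupture_check(model, x)
      ruptured <- TRUE
      rupture_junction <- rup$junction
      rupture_time <- t0
      events <- rbind(events, .event_row(t0, "rupture", rup$junction))
      break
    }
    if (1L %in% iroot) {
      # force the release at the located event time even if the trigger is
      # a rounding error below the threshold
      j <- which(attached)[1]
      if (!is.na(j)) release_partition(j, t0)
    }
    if (t0 >= t_end) break
  }

  colnames(xs) <- paste0("x_", seq_len(n) - 1L)
  colnames(vs) <- paste0("v_", seq_len(n) - 1L)
  colnames(ats) <- paste0("attached_", seq_len(n) - 1L)
  .new_result(scenario, model, times, xs, vs, ats,
              vapply(times, Ffun, numeric(1)), detach_times, events,
              ruptured, rupture_junction, rupture_time)
}

.simulate_simple <- function(scenario, t_end, dt, applied_force, rtol, atol) {
  model <- build_simple_model(scenario)
  mech <- scenario$mech
  Ffun <- if (is.null(applied_force)) make_applied_force(scenario) else
    applied_force
  m <- model$mass
  D <- scenario$clot$diameter
  grid <- seq(0, t_end, by = dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)

  rhs_anchored <- function(t, y, parms) {
    f <- Ffun(t) - mech$K_wall * y[1] - mech$R_wall * y[2] +
      linear_friction_force(mech$R_static, y[2])
    list(c(y[2], f / m))
  }
  rhs_free <- function(t, y, parms) {
    fric <- if (mech$dynamic_friction_mode == "linear") {
      linear_friction_force(mech$R_dynamic, y[2])
    } else {
      stokes_dynamic_friction(mech$C_form, mech$rho_blood, D, y[2],
                              v_reg = mech$v_regularization)
    }
    list(c(y[2], (Ffun(t) + fric) / m))
  }
  # release once the measurement-spring displacement F/K_eq reaches the
  # release displacement, i.e. once F reaches the movement threshold
  root_anchored <- function(t, y, parms) Ffun(t) - mech$F_move_threshold

  times <- numeric(0); xv <- NULL
  events <- .empty_events()
  release_time <- NA_real_
  y <- c(0, 0)
  t0 <- 0
  if (Ffun(0) >= mech$F_move_threshold) {
    release_time <- 0
  } else {
    out <- deSolve::lsodar(y = y, times = unique(c(0, grid)),
                           func = rhs_anchored, rootfunc = root_anchored,
                           rtol = rtol, atol = atol)
    times <- out[, 1]; xv <- out[, 2:3, drop = FALSE]
    if (!is.null(attr(out, "troot"))) {
      t0 <- out[nrow(out), 1]
      y <- unname(out[nrow(out), 2:3])
      release_time <- t0
      times <- times[-length(times)]
      xv <- xv[-nrow(xv), , drop = FALSE]
    } else {
      t0 <- t_end
    }
  }
  anchored_n <- length(times)
  if (!is.na(release_time) && t0 < t_end) {
    events <- rbind(events, .event_row(release_time, "release", 0L),
                    .event_row(release_time, "friction_dynamic", 0L))
    seg_times <- unique(c(t0, grid[grid > t0]))
    out <- deSolve::ode(y = y, times = seg_times, func = rhs_free,
                        method = "lsoda", rtol = rtol, atol = atol)
    times <- c(times, out[, 1])
    xv <- rbind(xv, out[, 2:3, drop = FALSE])
  }
  attached <- matrix(seq_along(times) <= anchored_n, ncol = 1)
  Fser <- vapply(times, Ffun, numeric(1))
  x <- matrix(xv[, 1], ncol = 1, dimnames = list(NULL, "x_0"))
  vm <- matrix(xv[, 2], ncol = 1, dimnames = list(NULL, "v_0"))
  colnames(attached) <- "attached_0"
  res <- .new_result(scenario, model, times, x, vm, attached, Fser,
                     release_time, events, FALSE, NA_integer_, NA_real_)
  # measurement-spring displacement is quasi-static: transmitted force / K_eq
  res$spring_displacement <- Fser / model$K_eq
  res
}

#' Extraction time
#'
#' First time at which the clot has displaced at least `distance` toward
#' the device, linearly interpolated between output samples; `NA` if the
#' distance is never covered within the simulated window. The default
#' `"proximal_face"` mode tracks the front partition (the face the device
#' suction acts on); `"whole_clot"` requires every partition - in
#' particular the distal end - to have covered the distance, i.e. the clot
#' as a whole has been pulled clear.
#'
#' @param result a `clot_sim_result`.
#' @param distance distance (m); defaults to the scenario's extraction
#'   distance.
#' @param mode `"proximal_face"` or `"whole_clot"`.
#' @return time (s) or `NA`.
#' @export
extraction_time <- function(result, distance = NULL,
                            mode = c("proximal_face", "whole_clot")) {
  mode <- match.arg(mode)
  if (is.null(distance)) distance <- result$scenario$extraction_distance
  stopifnot(distance > 0)
  s <- if (mode == "proximal_face") result$x[, 1] else
    apply(result$x, 1, min)
  idx <- which(s >= distance)[1]
  if (is.na(idx)) return(NA_real_)
  if (idx == 1L) return(result$time[1])
  t1 <- result$time[idx - 1L]; t2 <- result$time[idx]
  s1 <- s[idx - 1L]; s2 <- s[idx]
  if (s2 == s1) return(t2)
  t1 + (distance - s1) / (s2 - s1) * (t2 - t1)
}

#' @export
print.clot_sim_result <- function(x, ...) {
  cat("<clot_sim_result>", x$scenario$model_variant, "variant,",
      ncol(x$x), "partition(s),",
      sprintf("t in [0, %.3g] s (%d samples)\n",
              x$time[length(x$time)], length(x$time)))
  dt <- x$detach_times
  cat("  detachment times (s):",
      paste(ifelse(is.na(dt), "never", signif(dt, 4)), collapse = ", "), "\n")
  cat("  extraction time:",
      if (is.na(x$extraction_time)) "not reached" else
        sprintf("%.4g s (%.3g mm)", x$extraction_time,
                x$scenario$extraction_distance * 1e3), "\n")
  if (x$ruptured) {
    cat(sprintf("  RUPTURED at junction %d, t = %.4g s\n",
                x$rupture_junction, x$rupture_time))
  }
  invisible(x)
}

#' Sweep the aspiration pressure
#'
#' Runs the scenario at each constant gauge pressure, records the
#' extraction time per level, and refines the minimum effective suction by
#' bisection between the strongest failing and the weakest succeeding
#' level (tolerance: `tol_frac` of the bracket width).
#'
#' @param scenario a [scenario()].
#' @param pressures gauge pressures (Pa; negative = suction).
#' @param t_end,dt integration window and sampling (s).
#' @param extraction_mode passed to [extraction_time()].
#' @param refine bisect for the minimum effective suction?
#' @param tol_frac bisection tolerance as a fraction of the initial bracket.
#' @return object of class `sweep_result`: `pressures`, `extraction_times`
#'   (NA where extraction fails) and `min_pressure` (Pa, negative; NA when
#'   no level succeeds).
#' @export
pressure_sweep <- function(scenario, pressures, t_end = 10, dt = 1e-3,
                           extraction_mode = "proximal_face",
                           refine = TRUE, tol_frac = 0.01) {
  stopifnot(length(pressures) >= 1)
  run_at <- function(p) {
    sc <- scenario
    sc$forcing$aspiration <- list(type = "constant", pressure = p)
    res <- simulate(sc, t_end = t_end, dt = dt)
    extraction_time(res, mode = extraction_mode)
  }
  times <- vapply(pressures, run_at, numeric(1))
  ok <- !is.na(times)
  min_pressure <- NA_real_
  if (any(ok)) {
    suck <- abs(pressures)
    p_hi <- min(suck[ok])              # weakest suction that succeeds
    fail_below <- suck[!ok & suck < p_hi]
    p_lo <- if (length(fail_below)) max(fail_below) else 0
    if (refine && p_hi > p_lo) {
      tol <- tol_frac * (p_hi - p_lo)
      while (p_hi - p_lo > tol) {
        mid <- (p_hi + p_lo) / 2
        if (is.na(run_at(-mid))) p_lo <- mid else p_hi <- mid
      }
    }
    min_pressure <- -p_hi
  }
  structure(list(pressures = pressures, extraction_times = times,
                 min_pressure = min_pressure,
                 extraction_mode = extraction_mode),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(data.frame(pressure_kPa = x$pressures / 1e3,
                   extraction_time_s = x$extraction_times))
  cat("  minimum effective suction:",
      if (is.na(x$min_pressure)) "not bracketed" else
        sprintf("%.4g kPa", x$min_pressure / 1e3), "\n")
  invisible(x)
}

#' Minimum constant force that sets the clot moving
#'
#' Bisects constant applied forces between `lower` and `upper`, classifying
#' each run by whether a release event occurs within `t_end`. For the
#' single-body model this recovers the movement threshold (0.01 N with the
#' default parameters); for the chain model it recovers the adhesion force
#' of the proximal partition.
#'
#' @param scenario a [scenario()].
#' @param lower,upper bisection bracket (N); `lower` must fail and `upper`
#'   succeed.
#' @param tol absolute tolerance (N).
#' @param t_end classification window (s).
#' @return estimated threshold force (N).
#' @export
minimum_release_force <- function(scenario, lower = 1e-3, upper = 0.1,
                                  tol = 1e-4, t_end = 10) {
  moves <- function(F) {
    res <- simulate(scenario, t_end = t_end, dt = t_end / 10,
                    applied_force = function(t) rep_len(F, length(t)))
    any(res$events$type == "release")
  }
  if (moves(lower)) return(lower)
  if (!moves(upper)) return(NA_real_)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (moves(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Write simulation outputs
#'
#' Writes the time series as CSV (columns `t`, `x_i`, `v_i`, `attached_i`,
#' `F_applied`; one row per sample) and a JSON summary (scenario echo,
#' detachment times, extraction time, rupture flag, event log). Output is
#' bit-identical across runs for identical inputs.
#'
#' @param result a `clot_sim_result`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisible list of the paths written.
#' @export
write_outputs <- function(result, csv_path = NULL, json_path = NULL) {
  written <- list()
  if (!is.null(csv_path)) {
    df <- data.frame(t = result$time)
    df <- cbind(df, as.data.frame(result$x), as.data.frame(result$v),
                as.data.frame(result$attached) * 1L)
    df$F_applied <- result$F_applied
    tryCatch(utils::write.csv(df, csv_path, row.names = FALSE,
                              quote = FALSE),
             error = function(e) stop("failed to write CSV to ", csv_path,
                                      ": ", conditionMessage(e),
                                      call. = FALSE))
    written$csv <- csv_path
  }
  if (!is.null(json_path)) {
    summary <- list(
      scenario = .scenario_to_list(result$scenario),
      n_partitions = ncol(result$x),
      detachment_times = as.numeric(result$detach_times),
      extraction_distance = result$scenario$extraction_distance,
      extraction_time = result$extraction_time,
      ruptured = result$ruptured,
      rupture_junction = result$rupture_junction,
      rupture_time = result$rupture_time,
      events = result$events)
    tryCatch(jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                                  digits = NA, na = "null",
                                  dataframe = "rows"),
             error = function(e) stop("failed to write JSON to ", json_path,
                                      ": ", conditionMessage(e),
                                      call. = FALSE))
    written$json <- json_path
  }
  invisible(written)
}

.scenario_to_list <- function(sc) {
  list(model_variant = sc$model_variant,
       extraction_distance = sc$extraction_distance,
       artery = unclass(sc$artery),
       clot = unclass(sc$clot),
       mechanics = unclass(sc$mech),
       forcing = unclass(sc$forcing))
}
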