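#' Simulation options
#'
#' @param max_steps Hard iteration guard; the fatigue damping shrinks
#'   per-step losses only logarithmically, so a generous default keeps the
#'   guard inert in normal use.
#' @param interpolate_final_step Linearly scale the final step so the
#'   triggering side's cumulative casualties equal its historical total
#'   exactly (the other side's final-step loss is scaled by the same
#'   fraction). Per-step casualty quanta are on the order of 100 soldiers
#'   under the fighting-value scaling, so integer-step overshoot would
#'   otherwise inject comparable noise into the ABC distance.
#' @return A list of options.
#' @export
sim_options <- function(max_steps = 100000L, interpolate_final_step = TRUE) {
  if (max_steps < 1) stop("max_steps must be >= 1", call. = FALSE)
  list(max_steps = as.integer(max_steps),
       interpolate_final_step = isTRUE(interpolate_final_step))
}

#' Simulate one battle until historical casualties are reached
#'
#' Runs the chosen attrition law from the battle's historical initial sizes
#' until the first step at which either side's cumulative casualties reach
#' its historical total. With interpolation the final step is scaled so the
#' triggering side matches its total exactly. Annihilation (both per-step
#' losses zero, or both strengths exhausted) and the `max_steps` guard
#' terminate early with the corresponding flag; casualties are capped at the
#' initial sizes so a distance can always be computed.
#'
#' This is the reference implementation; the ABC engine uses an equivalent
#' compiled kernel (see [run_rejection()]), and the two are held to exact
#' agreement in the test suite.
#'
#' @param model Model name or code.
#' @param battle One-row `battle_dataset` (or a list with fields
#'   `size_blue`, `size_red`, `cas_blue`, `cas_red`).
#' @param P Odds ratio, positive.
#' @param opts [sim_options()].
#' @return A list: `sim_cas_blue`, `sim_cas_red`, `steps`, `termination`
#'   (one of `"historical_casualties_reached"`, `"annihilation"`,
#'   `"max_steps"`).
#' @export
simulate_to_casualties <- function(model, battle, P, opts = sim_options()) {
  if (P <= 0) stop("odds ratio P must be positive", call. = FALSE)
  B0 <- battle$size_blue; R0 <- battle$size_red
  hb <- battle$cas_blue; hr <- battle$cas_red
  if (length(B0) != 1) stop("simulate_to_casualties takes a single battle", call. = FALSE)
  if (B0 <= 0 || R0 <= 0 || hb <= 0 || hr <= 0) {
    stop("invalid battle: sizes and casualties must be positive", call. = FALSE)
  }
  code <- model_code(model)
  b <- scale_fighting_value(code, B0, R0)
  r <- enemy_value(b, P)

  B <- B0; R <- R0; cb <- 0; cr <- 0
  t <- 0L
  termination <- "max_steps"
  while (t < opts$max_steps) {
    loss <- step_losses(code, B, R, b, r, t)
    lb <- min(loss$blue, B)
    lr <- min(loss$red, R)
    if (lb <= 0 && lr <= 0) {
      termination <- "annihilation"
      break
    }
    if (cb + lb >= hb || cr + lr >= hr) {
      t <- t + 1L
      if (opts$interpolate_final_step) {
        fb <- if (lb > 0 && cb + lb >= hb) (hb - cb) / lb else Inf
        fr <- if (lr > 0 && cr + lr >= hr) (hr - cr) / lr else Inf
        frac <- max(0, min(fb, fr))
        cb <- cb + frac * lb
        cr <- cr + frac * lr
      } else {
        cb <- cb + lb
        cr <- cr + lr
      }
      termination <- "historical_casualties_reached"
      break
    }
    B <- B - lb; R <- R - lr
    cb <- cb + lb; cr <- cr + lr
    t <- t + 1L
  }
  list(sim_cas_blue = min(cb, B0), sim_cas_red = min(cr, R0),
       steps = t, termination = termination)
}

#' Free-running attrition trajectory
#'
#' Iterates a model for a fixed number of steps (or until annihilation /
#' `max_steps` when `n_steps = 0`), returning the full state time series —
#' the time-series view of the four laws' distinctive dynamics (e.g. the
#' fatigue law spreads the same casualties over a longer period than the
#' logarithmic law).
#'
#' @param model Model name or code.
#' @param B0,R0 Initial strengths, positive.
#' @param P Odds ratio, positive.
#' @param n_steps Number of steps; 0 means run to annihilation or the guard.
#' @param opts [sim_options()].
#' @return A data.frame with columns `t`, `B`, `R`, `cas_blue`, `cas_red`,
#'   `model`, `P`, one row per recorded state (including `t = 0`).
#' @export
simulate_trajectory <- function(model, B0, R0, P, n_steps = 0L,
                                opts = sim_options()) {
  if (B0 <= 0 || R0 <= 0) stop("initial strengths must be positive", call. = FALSE)
  if (P <= 0) stop("odds ratio P must be positive", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  code <- model_code(model)
  b <- scale_fighting_value(code, B0, R0)
  r <- enemy_value(b, P)
  limit <- if (n_steps == 0L) opts$max_steps else min(n_steps, opts$max_steps)

  ts <- vector("list", limit + 1L)
  B <- B0; R <- R0; cb <- 0; cr <- 0
  ts[[1]] <- c(0, B, R, 0, 0)
  t <- 0L
  while (t < limit) {
    loss <- step_losses(code, B, R, b, r, t)
    lb <- min(loss$blue, B)
    lr <- min(loss$red, R)
    if (n_steps == 0L && lb <= 0 && lr <= 0) break
    B <- B - lb; R <- R - lr
    cb <- cb + lb; cr <- cr + lr
    t <- t + 1L
    ts[[t + 1L]] <- c(t, B, R, cb, cr)
  }
  m <- do.call(rbind, ts[seq_len(t + 1L)])
  out <- data.frame(t = as.integer(m[, 1]), B = m[, 2], R = m[, 3],
                    cas_blue = m[, 4], cas_red = m[, 5])
  out$model <- model_name(code)
  out$P <- P
  out
}

#' Write a trajectory to CSV
#'
#' @param trajectory Output of [simulate_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
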