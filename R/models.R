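#' Competing Lanchester attrition laws
#'
#' The package compares four variants of the Lanchester attrition equations,
#' written as coupled difference equations over the strengths of a Blue and a
#' Red force. With per-step fighting values `b` (Blue) and \code{r = b * P} (Red):
#'
#' * `linear`: losses couple to both sizes, `B' = B - r*B*R`, `R' = R - b*R*B`
#'   (aimed fire is impossible; casualties scale with the number of encounters).
#' * `squared`: losses couple to the enemy size, `B' = B - r*R`, `R' = R - b*B`
#'   (aimed fire; numbers count quadratically in the classical square law).
#' * `logarithmic`: losses couple to a force's own size, `B' = B - r*B`,
#'   `R' = R - b*R`.
#' * `fatigue`: the logarithmic law with per-step losses damped by
#'   `ln(e + t)`, modelling a gradual decline in combat efficiency:
#'   `B' = B - r*B/ln(e + t)`, `R' = R - b*R/ln(e + t)`. At `t = 0` it
#'   coincides exactly with the logarithmic law.
#'
#' Models are identified by name; stable integer codes 1--4 (in the order
#' above) are used for serialization and in the compiled simulation kernel.
#'
#' @return `lanchester_models()` returns the four model names in code order.
#' @export
#' @examples
#' lanchester_models()
#' model_code("fatigue")
lanchester_models <- function() {
  c("linear", "squared", "logarithmic", "fatigue")
}

#' @rdname lanchester_models
#' @param model Model name (partial matching is not allowed) or an already
#'   valid integer code.
#' @export
model_code <- function(model) {
  if (is.numeric(model)) {
    code <- as.integer(model)
    if (any(is.na(code)) || any(code < 1L) || any(code > 4L)) {
      stop("model code must be an integer in 1..4", call. = FALSE)
    }
    return(code)
  }
  code <- match(model, lanchester_models())
  if (any(is.na(code))) {
    stop("unknown model: ", paste(model[is.na(code)], collapse = ", "),
         " (expected one of ", paste(lanchester_models(), collapse = ", "), ")",
         call. = FALSE)
  }
  code
}

#' @rdname lanchester_models
#' @param code Integer code in 1..4.
#' @export
model_name <- function(code) {
  lanchester_models()[model_code(code)]
}

#' Fighting-value scaling
#'
#' The Blue fighting value `b` is scaled so that, at the initial strengths, a
#' fighting value of 1 inflicts at most 100 casualties per time step. This
#' keeps the per-step casualty quantum comparable across battles of very
#' different sizes. For the linear law the loss term is `b*R*B`, so
#' `b = 100 / (B0 * R0)`; for the other three laws the loss term is linear in
#' one strength and `b = 100 / max(B0, R0)`.
#'
#' @param model Model name or code.
#' @param B0,R0 Initial strengths (soldiers), positive.
#' @return The Blue per-step fighting value `b`.
#' @export
#' @examples
#' scale_fighting_value("squared", 15000, 10000) # 1/150
scale_fighting_value <- function(model, B0, R0) {
  if (any(B0 <= 0) || any(R0 <= 0)) {
    stop("initial strengths must be positive", call. = FALSE)
  }
  code <- model_code(model)
  ifelse(code == 1L, 100 / (B0 * R0), 100 / pmax(B0, R0))
}

#' Red fighting value from the odds ratio
#'
#' Red's per-soldier lethality is expressed as a multiple `P` of Blue's:
#' \code{r = b * P}. `P = 2` means each Red soldier is as lethal as two Blue
#' soldiers.
#'
#' @param b Blue fighting value, positive.
#' @param P Odds ratio, positive.
#' @return Red fighting value `r`.
#' @export
enemy_value <- function(b, P) {
  if (any(b <= 0)) stop("fighting value b must be positive", call. = FALSE)
  if (any(P <= 0)) stop("odds ratio P must be positive", call. = FALSE)
  b * P
}

#' Force state constructor
#'
#' Tracks current strengths, the step counter and cumulative casualties of a
#' battle in progress. Conservation (initial strength = current strength +
#' cumulative casualties) holds at every step by construction.
#'
#' @param B0,R0 Initial strengths, positive.
#' @return A list with fields `B`, `R`, `t`, `cum_cas_blue`, `cum_cas_red`,
#'   `B0`, `R0` and `clamped` (whether a loss was ever clamped at the
#'   remaining strength).
#' @export
force_state <- function(B0, R0) {
  if (B0 <= 0 || R0 <= 0) stop("initial strengths must be positive", call. = FALSE)
  list(B = B0, R = R0, t = 0L, cum_cas_blue = 0, cum_cas_red = 0,
       B0 = B0, R0 = R0, clamped = FALSE)
}

# Per-step losses (before clamping) for each law; t is the number of
# completed steps, entering the fatigue damping ln(e + t).
step_losses <- function(code, B, R, b, r, t) {
  switch(code,
    list(blue = r * B * R, red = b * R * B),         # linear
    list(blue = r * R,     red = b * B),             # squared
    list(blue = r * B,     red = b * R),             # logarithmic
    {                                                # fatigue
      damp <- log(exp(1) + t)
      list(blue = r * B / damp, red = b * R / damp)
    })
}

#' Apply one attrition step
#'
#' Applies one synchronous update of the chosen law to a [force_state()].
#' Losses are clamped so strengths never go below zero; the clamp event is
#' recorded on the state. The step counter increments by one and cumulative
#' casualties are updated, so conservation holds exactly.
#'
#' @param model Model name or code.
#' @param state A [force_state()] with positive current strengths.
#' @param b Blue fighting value.
#' @param P Odds ratio; Red's value is \code{r = b * P}.
#' @return The updated state.
#' @export
#' @examples
#' s <- force_state(15000, 10000)
#' b <- scale_fighting_value("squared", 15000, 10000)
#' lanchester_step("squared", s, b, P = 1.5)[c("B", "R")] # 14900, 9900
lanchester_step <- function(model, state, b, P) {
  if (state$B <= 0 || state$R <= 0) {
    stop("both strengths must be positive to step", call. = FALSE)
  }
  code <- model_code(model)
  r <- enemy_value(b, P)
  loss <- step_losses(code, state$B, state$R, b, r, state$t)
  if (loss$blue > state$B || loss$red > state$R) state$clamped <- TRUE
  lb <- min(loss$blue, state$B)
  lr <- min(loss$red, state$R)
  state$B <- state$B - lb
  state$R <- state$R - lr
  state$cum_cas_blue <- state$cum_cas_blue + lb
  state$cum_cas_red <- state$cum_cas_red + lr
  state$t <- state$t + 1L
  state
}

#' Closed-form solution of the logarithmic law
#'
#' Serves as an exact oracle for the iterated logarithmic difference
#' equation: ignoring clamping, `B_t = B0 (1 - r)^t` and `R_t = R0 (1 - b)^t`.
#'
#' @param B0,R0 Initial strengths.
#' @param b Blue fighting value, in (0, 1).
#' @param P Odds ratio; requires \code{r = b * P} in (0, 1).
#' @param t Number of steps, non-negative integer.
#' @return Named vector `c(B = , R = )` after `t` steps.
#' @export
closed_form_log <- function(B0, R0, b, P, t) {
  r <- enemy_value(b, P)
  if (b >= 1 || r >= 1) stop("coefficients must be below 1", call. = FALSE)
  c(B = B0 * (1 - r)^t, R = R0 * (1 - b)^t)
}
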