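#' Posterior parameter summary
#'
#' Summarizes the accepted `(mu, sigma)` draws for one model (or all
#' accepted draws): mean, mode and empirical 2.5%/50%/97.5% quantiles per
#' parameter, plus the model's accepted proportion. The mode is the midpoint
#' of the maximal bin of a Freedman--Diaconis histogram by default; a kernel
#' density maximum is available as an alternative estimator.
#'
#' @param post An `abc_posterior`.
#' @param model Optional model name to restrict to; `NULL` summarizes all
#'   accepted runs.
#' @param mode_method `"histogram"` (Freedman--Diaconis maximal-bin
#'   midpoint) or `"density"` (kernel density maximum).
#' @return A `posterior_summary` list: per-parameter statistics, the model
#'   proportion, and metadata (`tau`, `n_runs`, `n_accepted`).
#' @export
summarize_posterior <- function(post, model = NULL,
                                mode_method = c("histogram", "density")) {
  mode_method <- match.arg(mode_method)
  acc <- post$accepted
  if (!is.null(model)) {
    model <- model_name(model_code(model))
    acc <- acc[acc$model == model, , drop = FALSE]
  }
  if (nrow(acc) == 0) {
    stop("no accepted runs", if (!is.null(model)) paste0(" for model ", model),
         call. = FALSE)
  }
  param_stats <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    c(mean = mean(x), mode = posterior_mode(x, mode_method),
      q2.5 = q[1], median = q[2], q97.5 = q[3])
  }
  structure(list(
    model = if (is.null(model)) "all" else model,
    mu = param_stats(acc$mu),
    sigma = param_stats(acc$sigma),
    proportion = nrow(acc) / nrow(post$accepted),
    tau = post$tau, n_runs = post$n_runs, n_accepted = nrow(acc),
    mode_method = mode_method
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%s; %d accepted, tau = %g)\n",
              x$model, x$n_accepted, x$tau))
  m <- rbind(mu = x$mu, sigma = x$sigma)
  print(round(m, 4))
  cat(sprintf("model proportion among accepted runs: %.3f\n", x$proportion))
  invisible(x)
}

#' Empirical mode of a posterior sample
#'
#' @param x Numeric sample.
#' @param method `"histogram"`: midpoint of the maximal bin of a
#'   Freedman--Diaconis histogram; `"density"`: location of the kernel
#'   density maximum.
#' @return The mode estimate.
#' @export
posterior_mode <- function(x, method = c("histogram", "density")) {
  method <- match.arg(method)
  if (length(unique(x)) == 1) return(x[1])
  if (method == "histogram") {
    h <- graphics::hist(x, breaks = "FD", plot = FALSE)
    i <- which.max(h$counts)
    (h$breaks[i] + h$breaks[i + 1]) / 2
  } else {
    d <- stats::density(x)
    d$x[which.max(d$y)]
  }
}

#' Model proportions across tolerance levels
#'
#' Re-thresholds a record store at each tolerance and tabulates the share of
#' each candidate model among the accepted runs — one row per tolerance.
#' Nothing is re-simulated.
#'
#' @param records `abc_records` from a hierarchical (or pooled) experiment.
#' @param tau_list Tolerances (accepted fractions).
#' @return data.frame with columns `tau`, `n_accepted`, then one proportion
#'   column per model; each row's proportions sum to 1.
#' @export
model_proportion_table <- function(records, tau_list) {
  models <- attr(records, "models")
  if (is.null(models)) models <- sort(unique(records$model))
  rows <- lapply(tau_list, function(tau) {
    post <- accept_at(records, tau)
    props <- as.numeric(post$counts) / sum(post$counts)
    out <- data.frame(tau = tau, n_accepted = nrow(post$accepted))
    out[models] <- as.list(props)
    out
  })
  do.call(rbind, rows)
}

#' Accepted runs ranked by distance
#'
#' @param post An `abc_posterior`.
#' @return data.frame with columns `rank` (1 = best), `model`, `mu`,
#'   `sigma`, `distance`, sorted ascending by distance.
#' @export
distance_rank_table <- function(post) {
  acc <- post$accepted
  if (nrow(acc) == 0) stop("empty posterior", call. = FALSE)
  ord <- order(acc$distance, acc$run_index)
  data.frame(rank = seq_len(nrow(acc)), model = acc$model[ord],
             mu = acc$mu[ord], sigma = acc$sigma[ord],
             distance = acc$distance[ord])
}

#' Accepted (mu, sigma) pairs for joint inspection
#'
#' Exports the accepted hyperparameter pairs together with their Spearman
#' rank correlation — the diagnostic behind the observation that large
#' `sigma` values are only accepted when `mu` is also large.
#'
#' @param post An `abc_posterior`.
#' @return List with `pairs` (data.frame `mu`, `sigma`) and
#'   `rank_correlation` (Spearman; `NA` when fewer than 3 pairs).
#' @export
joint_scatter_export <- function(post) {
  acc <- post$accepted
  if (nrow(acc) == 0) stop("empty posterior", call. = FALSE)
  rc <- if (nrow(acc) >= 3) {
    stats::cor(acc$mu, acc$sigma, method = "spearman")
  } else NA_real_
  list(pairs = data.frame(mu = acc$mu, sigma = acc$sigma),
       rank_correlation = rc)
}
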