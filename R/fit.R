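#' Fit stochastic Lanchester models to battle records by rejection ABC
#'
#' The main fitting front-end. Optionally restricts the dataset to one
#' historical period, runs the rejection sampler ([run_rejection()]) over
#' the candidate models, and thresholds at the requested tolerance. The
#' returned object supports `print`, `summary`, `coef`, `plot` and
#' `residuals`.
#'
#' @param data A `battle_dataset` (see [read_battles()],
#'   [generate_dataset()]).
#' @param models Candidate model name(s); see [lanchester_models()].
#' @param n_runs Number of rejection runs.
#' @param tau Tolerance as accepted fraction in (0, 1].
#' @param mode `"single_model"` or `"hierarchical"`; default chosen from the
#'   number of candidate models.
#' @param period Optional historical period 1..4 to fit.
#' @param prior [prior_config()].
#' @param opts [sim_options()].
#' @param seed Integer root seed; the fit is a pure function of
#'   `(data, configuration, seed)`.
#' @param chunk_size Internal run batching (no effect on results).
#' @return An object of class `abc_fit`: list with `records`
#'   (all runs), `posterior` (accepted set at `tau`), and the configuration.
#' @export
#' @examples
#' sim <- generate_dataset(synth_config(n_battles = 20, seed = 42))
#' fit <- abc_fit(sim$dataset, models = "fatigue", n_runs = 500, tau = 0.05,
#'                seed = 42)
#' coef(fit)
abc_fit <- function(data, models = lanchester_models(), n_runs = 10000L,
                    tau = 0.005,
                    mode = if (length(models) > 1) "hierarchical"
                           else "single_model",
                    period = NULL, prior = prior_config(),
                    opts = sim_options(), seed = 1L, chunk_size = 2000L) {
  if (!is.null(period)) data <- filter_period(data, period)
  if (nrow(data) == 0) stop("no battles to fit", call. = FALSE)
  records <- run_rejection(data, n_runs = n_runs, tau = tau, models = models,
                           mode = mode, prior = prior, opts = opts,
                           seed = seed, chunk_size = chunk_size)
  posterior <- accept_at(records, tau)
  posterior$mode <- attr(records, "mode")
  structure(list(records = records, posterior = posterior,
                 data = data, models = attr(records, "models"),
                 mode = attr(records, "mode"), n_runs = n_runs, tau = tau,
                 period = period, prior = prior, opts = opts, seed = seed,
                 call = match.call()),
            class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("Rejection-ABC Lanchester fit\n")
  cat(sprintf("  %d battles, %d runs, tau = %g (%d accepted), mode = %s\n",
              nrow(x$data), x$n_runs, x$tau, nrow(x$posterior$accepted),
              x$mode))
  cat("  models:", paste(x$models, collapse = ", "), "\n")
  cm <- coef(x)
  cat(sprintf("  posterior means: mu = %.3f, sigma = %.3f\n",
              cm["mu"], cm["sigma"]))
  if (x$mode != "single_model") {
    props <- as.numeric(x$posterior$counts) / sum(x$posterior$counts)
    cat("  model proportions:",
        paste(sprintf("%s=%.2f", names(x$posterior$counts), props),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
coef.abc_fit <- function(object, ...) {
  acc <- object$posterior$accepted
  c(mu = mean(acc$mu), sigma = mean(acc$sigma))
}

#' Summarize a rejection-ABC fit
#'
#' @param object An `abc_fit`.
#' @param mode_method Mode estimator, see [summarize_posterior()].
#' @param ... Unused.
#' @return A `summary.abc_fit`: overall and (in hierarchical mode)
#'   per-model posterior summaries plus Bayes factors.
#' @export
summary.abc_fit <- function(object, mode_method = "histogram", ...) {
  overall <- summarize_posterior(object$posterior, mode_method = mode_method)
  per_model <- NULL
  bf <- NULL
  if (object$mode != "single_model") {
    present <- names(object$posterior$counts)[object$posterior$counts > 0]
    per_model <- lapply(present, function(m) {
      summarize_posterior(object$posterior, model = m,
                          mode_method = mode_method)
    })
    names(per_model) <- present
    bf <- bayes_factors(object$posterior)
  }
  structure(list(overall = overall, per_model = per_model, bf = bf,
                 fit = object), class = "summary.abc_fit")
}

#' @export
print.summary.abc_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$overall)
  if (!is.null(x$bf)) {
    cat("\nPosterior model proportions:\n")
    print(round(x$bf$proportions, 4))
    cat("Bayes factors (row vs column):\n")
    print(round(x$bf$bf, 3))
  }
  invisible(x)
}

#' Central-value casualty residuals
#'
#' Simulates every fitted battle at the deterministic central odds ratio
#' `P = posterior mean of mu` under the highest-posterior model and returns
#' the signed relative casualty discrepancies per side,
#' `(simulated - historical) / historical`.
#'
#' @param object An `abc_fit`.
#' @param ... Unused.
#' @return Matrix with columns `blue` and `red`, one row per battle.
#' @export
residuals.abc_fit <- function(object, ...) {
  mu_hat <- unname(coef(object)["mu"])
  counts <- object$posterior$counts
  model <- if (object$mode == "single_model") object$models[1] else
    names(counts)[which.max(counts)]
  ds <- object$data
  out <- matrix(NA_real_, nrow(ds), 2,
                dimnames = list(ds$id, c("blue", "red")))
  for (j in seq_len(nrow(ds))) {
    sim <- simulate_to_casualties(model, ds[j, ], mu_hat, object$opts)
    out[j, ] <- c((sim$sim_cas_blue - ds$cas_blue[j]) / ds$cas_blue[j],
                  (sim$sim_cas_red - ds$cas_red[j]) / ds$cas_red[j])
  }
  out
}

#' Diagnostic plots for a rejection-ABC fit
#'
#' Base graphics diagnostics: `"joint"` — accepted (mu, sigma) scatter;
#' `"rank"` — accepted distances by rank, colored by model; `"posterior"` —
#' marginal histograms of mu and sigma; `"proportions"` — accepted model
#' shares (hierarchical fits).
#'
#' @param x An `abc_fit`.
#' @param type Plot type.
#' @param ... Passed to the underlying base graphics call.
#' @return `x`, invisibly.
#' @export
plot.abc_fit <- function(x, type = c("joint", "rank", "posterior",
                                     "proportions"), ...) {
  type <- match.arg(type)
  acc <- x$posterior$accepted
  if (type == "joint") {
    graphics::plot(acc$mu, acc$sigma, xlab = expression(mu),
                   ylab = expression(sigma),
                   main = "Accepted hyperparameter draws", ...)
  } else if (type == "rank") {
    tab <- distance_rank_table(x$posterior)
    cols <- match(tab$model, lanchester_models())
    graphics::plot(tab$rank, tab$distance, col = cols, pch = 16,
                   xlab = "rank", ylab = "distance",
                   main = "Accepted distances by rank", ...)
    graphics::legend("topleft", legend = lanchester_models(), col = 1:4,
                     pch = 16, bty = "n")
  } else if (type == "posterior") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    graphics::hist(acc$mu, breaks = "FD", main = expression(mu),
                   xlab = expression(mu), ...)
    graphics::hist(acc$sigma, breaks = "FD", main = expression(sigma),
                   xlab = expression(sigma), ...)
  } else {
    props <- as.numeric(x$posterior$counts) / sum(x$posterior$counts)
    graphics::barplot(props, names.arg = names(x$posterior$counts),
                      ylab = "accepted proportion",
                      main = "Posterior model proportions", ...)
  }
  invisible(x)
}
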