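make_posterior <- function(mu, sigma, model = "fatigue",
                           distance = seq_along(mu) / 1000) {
  rec <- data.frame(run_index = seq_along(mu), model = model,
                    mu = mu, sigma = sigma, distance = distance)
  attr(rec, "models") <- lanchester_models()
  attr(rec, "mode") <- "hierarchical"
  accept_at(rec, 1)
}

test_that("posterior summaries report mean, mode and quantiles", {
  post <- make_posterior(c(1, 1, 2), c(0.5, 0.5, 0.5))
  s <- summarize_posterior(post, model = "fatigue")
  expect_equal(unname(s$mu["mean"]), 4 / 3)
  # degenerate sample: every statistic collapses to the single value
  expect_equal(unname(s$sigma), rep(0.5, 5))
  expect_equal(s$proportion, 1)
  expect_error(summarize_posterior(post, model = "linear"), "no accepted")

  # quantiles are ordered on a spread-out sample
  set.seed(4)
  p2 <- make_posterior(stats::rnorm(500, 2, 0.3), stats::runif(500))
  s2 <- summarize_posterior(p2)
  expect_true(s2$mu["q2.5"] <= s2$mu["median"] &&
              s2$mu["median"] <= s2$mu["q97.5"])
})

test_that("histogram and density modes land near the analytic gamma mode", {
  set.seed(12)
  kappa <- 9; theta <- 0.25 # analytic mode (kappa - 1) * theta = 2
  x <- stats::rgamma(1e4, shape = kappa, scale = theta)
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  binw <- diff(h$breaks[1:2])
  expect_lt(abs(posterior_mode(x, "histogram") - 2), binw)
  # kernel smoothing of the right-skewed sample can shift the peak by up to
  # about a bandwidth, so allow two bin widths there
  expect_lt(abs(posterior_mode(x, "density") - 2), 2 * binw)
  expect_equal(posterior_mode(rep(3.3, 10)), 3.3)
})

test_that("model proportion table re-thresholds stored records per tau", {
  set.seed(3)
  n <- 1000
  rec <- data.frame(run_index = 1:n,
                    model = sample(lanchester_models(), n, replace = TRUE),
                    mu = stats::runif(n), sigma = stats::runif(n),
                    distance = stats::runif(n))
  attr(rec, "models") <- lanchester_models()
  attr(rec, "mode") <- "hierarchical"
  tab <- model_proportion_table(rec, c(0.5, 0.05, 0.01))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_accepted, c(500, 50, 10))
  props <- as.matrix(tab[, lanchester_models()])
  expect_equal(unname(rowSums(props)), rep(1, 3))
  # hand-thresholded cross-check at tau = 0.05
  best <- rec[order(rec$distance, rec$run_index)[1:50], ]
  expect_equal(unname(props[2, ]),
               as.numeric(table(factor(best$model,
                                       levels = lanchester_models()))) / 50)
  # single-model records give proportion 1 everywhere
  ds <- small_synth(4, 43)
  single <- run_rejection(ds, 100, 0.5, "squared", seed = 6)
  tab1 <- model_proportion_table(single, c(0.5, 0.1))
  expect_equal(tab1$squared, c(1, 1))
})

test_that("distance rank table is sorted with rank one the best run", {
  post <- make_posterior(c(1, 2, 3), c(1, 1, 1),
                         distance = c(0.2, 0.05, 0.1))
  tab <- distance_rank_table(post)
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$distance, c(0.05, 0.1, 0.2))
  expect_equal(tab$distance[1], min(post$accepted$distance))
  # length equals the accepted count of the originating tolerance
  ds <- small_synth(4, 47)
  rec <- run_rejection(ds, 1000, 0.05, "fatigue", seed = 8)
  expect_equal(nrow(distance_rank_table(accept_at(rec, 0.05))), 50)
})

test_that("joint scatter export carries pairs and a rank correlation", {
  set.seed(21)
  mu <- stats::runif(200, 1, 3)
  post <- make_posterior(mu, 0.2 + 0.3 * mu + stats::rnorm(200, 0, 0.05))
  js <- joint_scatter_export(post)
  expect_equal(nrow(js$pairs), 200)
  expect_gt(js$rank_correlation, 0.5) # constructed positive association
  expect_identical(js, joint_scatter_export(post)) # pure function
})

test_that("fit object methods expose the posterior coherently", {
  sim <- generate_dataset(synth_config(n_battles = 15, seed = 61))
  fit <- abc_fit(sim$dataset, models = lanchester_models(), n_runs = 800,
                 tau = 0.05, seed = 9)
  expect_s3_class(fit, "abc_fit")
  expect_named(coef(fit), c("mu", "sigma"))
  expect_equal(nrow(fit$posterior$accepted), 40)
  s <- summary(fit)
  expect_s3_class(s, "summary.abc_fit")
  expect_equal(sum(s$bf$proportions), 1)
  expect_output(print(fit), "Rejection-ABC")
  r <- residuals(fit)
  expect_equal(dim(r), c(15, 2))
  expect_true(all(is.finite(r)))
  # plotting runs headless onto a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit, type = "joint"))
  expect_invisible(plot(fit, type = "rank"))
  expect_invisible(plot(fit, type = "proportions"))
})
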