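# Helper: wrap a plain stats matrix as a ref_table for the ABC functions.
fake_ref_table <- function(stats_mat, scenario = NULL, params = NULL) {
  df <- data.frame(scenario = scenario %||% rep("s1", nrow(stats_mat)),
                   stringsAsFactors = FALSE)
  if (!is.null(params)) df <- cbind(df, params)
  df <- cbind(df, as.data.frame(stats_mat))
  class(df) <- c("ref_table", "data.frame")
  attr(df, "param_names") <- if (is.null(params)) character(0) else
    colnames(params)
  attr(df, "stat_names") <- colnames(stats_mat)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("MAD normalization matches a hand-computed oracle and drops flat columns", {
  stats_mat <- cbind(
    s1 = c(1, 2, 3, 4, 100),
    s2 = c(5, 5, 5, 5, 5),       # zero MAD -> dropped
    s3 = c(-2, 0, 1, 3, 8)
  )
  tab <- fake_ref_table(stats_mat)
  obs <- c(s1 = 2, s2 = 5, s3 = 1)
  expect_warning(normalize_reference(tab, obs, abc_config()), "zero-scale")
  norm <- suppressWarnings(normalize_reference(tab, obs, abc_config()))
  mad1 <- stats::mad(stats_mat[, "s1"])
  mad3 <- stats::mad(stats_mat[, "s3"])
  expect_equal(norm$stats[, "s1"], stats_mat[, "s1"] / mad1)
  expect_equal(unname(norm$observed), c(2 / mad1, 1 / mad3))
  expect_equal(norm$dropped, "s2")
  expect_true(is.na(norm$scale[["s2"]]))
  # rescaling an input column by a constant leaves normalized values alone
  stats_mat2 <- stats_mat
  stats_mat2[, "s1"] <- stats_mat2[, "s1"] * 1000
  tab2 <- fake_ref_table(stats_mat2)
  obs2 <- obs; obs2[["s1"]] <- obs2[["s1"]] * 1000
  norm2 <- suppressWarnings(normalize_reference(tab2, obs2, abc_config()))
  expect_equal(norm2$stats[, "s1"], norm$stats[, "s1"])
  expect_equal(norm2$observed, norm$observed)
})

test_that("rejection keeps the nearest rows with deterministic tie-breaks", {
  stats_mat <- cbind(a = c(1, 2, 3, 4), b = rep(0, 4))
  norm <- list(stats = stats_mat, observed = c(0, 0))
  kept <- reject_nearest(norm, abc_config(n_keep = 2))
  expect_equal(kept$indices, c(1, 2))
  kept_all <- reject_nearest(norm, abc_config(n_keep = 4))
  expect_equal(kept_all$indices, 1:4)

  # ties broken by row index
  norm_tie <- list(stats = cbind(a = c(1, 1, 1)), observed = 0)
  expect_equal(reject_nearest(norm_tie, abc_config(n_keep = 2))$indices,
               c(1, 2))

  # brute-force sort oracle on a random table
  set.seed(14)
  m <- matrix(rnorm(1000 * 5), ncol = 5)
  colnames(m) <- paste0("s", 1:5)
  obs <- rnorm(5)
  norm_big <- list(stats = m, observed = obs)
  kept_big <- reject_nearest(norm_big, abc_config(n_keep = 50))
  d_oracle <- apply(m, 1, function(r) sqrt(sum((r - obs)^2)))
  expect_equal(kept_big$indices, order(d_oracle)[1:50])
})

test_that("direct posterior probabilities are kept-fractions with sane CIs", {
  res <- posterior_direct(c("sc1", "sc1", "sc2"))
  expect_equal(res$prob, c(2 / 3, 1 / 3))
  expect_equal(sum(res$prob), 1)
  expect_true(all(res$lower <= res$prob & res$prob <= res$upper))
  expect_true(all(res$lower >= 0 & res$upper <= 1))

  res1 <- posterior_direct(rep("sc1", 10), scenarios = c("sc1", "sc2"))
  expect_equal(res1$prob, c(1, 0))
})

test_that("logistic posterior matches an independent multinomial MLE", {
  # small non-separated two-class design
  set.seed(5)
  X <- cbind(x1 = c(0.2, 1.1, 0.9, 1.8, 0.4, 1.5, 0.7, 1.2),
             x2 = c(1.0, 0.1, 0.8, 0.3, 0.2, 0.9, 0.5, 0.6))
  y <- c("a", "b", "a", "b", "a", "b", "b", "a")
  obs <- c(x1 = 1.0, x2 = 0.5)
  fit <- posterior_logistic(X, y, obs)
  oracle <- oracle_multinom_probs(X, y, as.numeric(obs))
  expect_equal(fit$prob, as.numeric(oracle), tolerance = 1e-5)
  expect_equal(sum(fit$prob), 1, tolerance = 1e-9)
  expect_true(all(fit$lower <= fit$prob & fit$prob <= fit$upper))

  # three classes
  set.seed(6)
  X3 <- matrix(rnorm(60), ncol = 2,
               dimnames = list(NULL, c("x1", "x2")))
  y3 <- rep(c("a", "b", "c"), each = 10)
  X3[, 1] <- X3[, 1] + rep(c(-0.5, 0, 0.5), each = 10)
  obs3 <- c(x1 = 0, x2 = 0)
  fit3 <- posterior_logistic(X3, y3, obs3)
  oracle3 <- oracle_multinom_probs(X3, y3, as.numeric(obs3))
  expect_equal(fit3$prob, as.numeric(oracle3), tolerance = 1e-4)
})

test_that("logistic posterior handles separation and uninformative covariates", {
  # perfectly separated along x1, observed deep on the class-a side
  X <- cbind(x1 = c(rep(-2, 10) + rnorm(10, 0, 0.1),
                    rep(2, 10) + rnorm(10, 0, 0.1)))
  y <- rep(c("a", "b"), each = 10)
  fit <- posterior_logistic(X, y, c(x1 = -2))
  expect_gt(fit$prob[fit$scenario == "a"], 0.99)
  expect_true(isTRUE(attr(fit, "regularized")))

  # uninformative covariates: probabilities near class frequencies
  set.seed(9)
  Xu <- cbind(x1 = rnorm(300))
  yu <- rep(c("a", "b"), times = c(100, 200))
  fitu <- posterior_logistic(Xu, yu, c(x1 = 0))
  expect_equal(fitu$prob[fitu$scenario == "a"], 1 / 3, tolerance = 0.1)
})

test_that("local-linear adjustment has the constant and exact-fit properties", {
  set.seed(10)
  m <- 60
  stats_mat <- cbind(s1 = rnorm(m), s2 = rnorm(m))
  d <- sqrt(rowSums(stats_mat^2))
  obs <- c(0, 0)

  # constant parameter: every summary equals the constant
  const <- data.frame(theta = rep(7, m))
  est <- estimate_params_loclinear(const, stats_mat, d, obs)
  expect_equal(est$median, 7)
  expect_equal(est$mean, 7)
  expect_equal(est$q2.5, 7)
  expect_equal(est$q97.5, 7)

  # parameter exactly linear in a statistic: posterior collapses onto the
  # regression prediction at the observed point
  lin <- data.frame(theta = 3 + 2 * stats_mat[, "s1"])
  est2 <- estimate_params_loclinear(lin, stats_mat, d, obs,
                                    log_transform = FALSE)
  expect_equal(est2$median, 3, tolerance = 1e-8)
  expect_equal(est2$q2.5, 3, tolerance = 1e-8)
  expect_equal(est2$q97.5, 3, tolerance = 1e-8)
  expect_equal(est2$adjustment, "local-linear")

  # rank-deficient design falls back to rejection-only
  degen <- cbind(s1 = rep(1, m), s2 = rep(1, m)) * 0
  est3 <- estimate_params_loclinear(lin, degen, d, c(0, 0),
                                    log_transform = FALSE)
  expect_equal(est3$adjustment, "rejection-only")
  expect_error(
    estimate_params_loclinear(lin[1:5, , drop = FALSE],
                              stats_mat[1:5, ], d[1:5], obs),
    ">= 10"
  )
})

test_that("adjusted draws respect prior support clamping", {
  set.seed(11)
  m <- 40
  stats_mat <- cbind(s1 = rnorm(m))
  d <- abs(stats_mat[, 1])
  pri <- prior_spec(list(theta = list(dist = "uniform", lower = 1,
                                      upper = 2)))
  params <- data.frame(theta = runif(m, 1, 2))
  est <- estimate_params_loclinear(params, stats_mat, d, c(s1 = 5),
                                   priors = pri)
  draws <- attr(est, "draws")
  expect_true(all(draws >= 1 & draws <= 2))
  expect_true(est$q2.5 <= est$median && est$median <= est$q97.5)
})

test_that("RMAE diagnostics behave for benchmark estimators", {
  scen <- demographic_scenario("s", list(population_spec("p", 8, NA)),
                               list())
  pri <- prior_spec(list(
    NE_p = list(dist = "uniform", lower = 100, upper = 10000),
    mu = list(dist = "uniform", lower = 1e-6, upper = 1e-6)
  ))
  model <- e2_mutation_model(sequence_length = 300)

  truth_est <- function(sv, truth) truth["NE_p"]
  r0 <- rmae_evaluate(scen, pri, model, truth_est, n_pods = 12,
                      rng_seed = 3, populations = "p", pairs = list())
  expect_equal(r0$rmae, 0)
  expect_false(r0$flag_high)

  double_est <- function(sv, truth) 2 * truth["NE_p"]
  r2 <- rmae_evaluate(scen, pri, model, double_est, n_pods = 12,
                      rng_seed = 3, populations = "p", pairs = list())
  expect_equal(r2$rmae, 1.0)
  expect_true(r2$flag_high)

  prior_median_est <- function(sv, truth) c(NE_p = 5050)
  rp <- rmae_evaluate(scen, pri, model, prior_median_est, n_pods = 40,
                      rng_seed = 4, populations = "p", pairs = list())
  expect_gt(rp$rmae, 0.2)
  expect_true(rp$flag_high)
})

test_that("PCA pre-evaluation flags observed vectors outside the cloud", {
  set.seed(15)
  m <- 200
  stats_mat <- matrix(rnorm(m * 4), ncol = 4,
                      dimnames = list(NULL, paste0("s", 1:4)))
  stats_mat[, 2] <- stats_mat[, 1] * 2 + rnorm(m, 0, 0.1)
  tab <- fake_ref_table(stats_mat)

  center_obs <- colMeans(stats_mat)
  chk <- prior_scenario_check(tab, center_obs)
  expect_true(chk$inside_cloud)
  expect_lt(sqrt(sum(chk$observed_coords^2)), 1e-8)

  far_obs <- center_obs + 100 * apply(stats_mat, 2, sd)
  chk2 <- prior_scenario_check(tab, far_obs)
  expect_false(chk2$inside_cloud)

  # component coordinates match a covariance eigen-decomposition up to sign
  norm <- normalize_reference(tab, center_obs, abc_config())
  eig <- eigen(stats::cov(norm$stats))
  centered <- sweep(norm$stats, 2, colMeans(norm$stats))
  proj <- centered %*% eig$vectors[, 1:2]
  for (k in 1:2) {
    agree <- max(abs(chk$sim_coords[, k] - proj[, k]))
    flipped <- max(abs(chk$sim_coords[, k] + proj[, k]))
    expect_lt(min(agree, flipped), 1e-8)
  }
})

test_that("goodness-of-fit scores are calibrated and catch misfit", {
  scen <- demographic_scenario("s", list(population_spec("p", 8, NA)),
                               list())
  model <- e2_mutation_model(sequence_length = 300)
  draws <- data.frame(NE_p = runif(50, 500, 1500),
                      mu = rep(1e-6, 50))
  # observed simulated from the same predictive: score should be moderate
  set.seed(20)
  g <- sample_genealogy(scen, params = c(NE_p = 1000, mu = 1e-6))
  mm <- model; mm$rate <- 1e-6
  obs_aln <- mutate_hky(g, mm, variant_only = TRUE)
  obs <- compute_statvector(obs_aln, "p", list())
  score <- goodness_of_fit(scen, draws, model, obs, n_rep = 60,
                           rng_seed = 21, populations = "p", pairs = list())
  expect_gte(as.numeric(score), 0.02)
  expect_lte(as.numeric(score), 1)

  # wildly inconsistent observed vector scores ~0
  obs_far <- obs
  obs_far[] <- obs_far + 1000
  score_far <- goodness_of_fit(scen, draws, model, obs_far, n_rep = 60,
                               rng_seed = 21, populations = "p",
                               pairs = list())
  expect_equal(as.numeric(score_far), 0)

  # n_rep = 1 is a boundary: score is 0 or 1
  s1 <- goodness_of_fit(scen, draws, model, obs, n_rep = 1, rng_seed = 22,
                        populations = "p", pairs = list())
  expect_true(as.numeric(s1) %in% c(0, 1))
})
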