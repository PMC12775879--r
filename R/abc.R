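# ABC machinery: normalization, rejection, scenario posteriors (direct and
# multinomial-logistic), Beaumont-style local-linear parameter adjustment,
# RMAE precision diagnostics, prior-scenario PCA pre-evaluation and
# posterior-predictive goodness-of-fit.

#' ABC configuration
#'
#' @param n_keep Number of nearest simulations to keep, or a tolerance
#'   fraction in `(0, 1]` (interpreted as a fraction when < 1).
#' @param normalization `"mad"` (robust, the default) or `"sd"`.
#' @param rng_seed Integer seed for any stochastic sub-step.
#' @return An `abc_config` object.
#' @export
abc_config <- function(n_keep = 0.01, normalization = c("mad", "sd"),
                       rng_seed = NULL) {
  normalization <- match.arg(normalization)
  if (n_keep <= 0) stop("n_keep must be positive")
  structure(list(n_keep = n_keep, normalization = normalization,
                 rng_seed = rng_seed),
            class = "abc_config")
}

ref_stat_matrix <- function(table) {
  stat_names <- attr(table, "stat_names")
  if (is.null(stat_names)) stop("table lacks stat_names attribute")
  as.matrix(table[, stat_names, drop = FALSE])
}

#' Normalize reference-table statistics against a robust scale
#'
#' Divides every statistic column (and the observed vector) by its scale —
#' median absolute deviation by default — computed over the table. Columns
#' with zero scale carry no distance information and are dropped, with a
#' warning.
#'
#' @param table A `ref_table` from [build_reference_table()].
#' @param observed Named statistic vector in the table's ordering (e.g. from
#'   [compute_statvector()]).
#' @param config An [abc_config()].
#' @return List with `stats` (normalized matrix), `observed` (normalized
#'   vector), `scale` (named; `NA` marks dropped columns) and `dropped`
#'   (names of dropped columns).
#' @export
normalize_reference <- function(table, observed, config = abc_config()) {
  stats_mat <- ref_stat_matrix(table)
  stat_names <- colnames(stats_mat)
  obs <- observed[stat_names]
  if (anyNA(obs)) stop("observed vector does not cover the table statistics")
  scale <- apply(stats_mat, 2, function(x) {
    if (config$normalization == "mad") stats::mad(x) else stats::sd(x)
  })
  dropped <- stat_names[scale == 0 | !is.finite(scale)]
  if (length(dropped) == length(stat_names)) {
    stop("all statistic columns have zero scale")
  }
  if (length(dropped) > 0) {
    warning("dropping zero-scale statistics from distance: ",
            paste(dropped, collapse = ", "))
  }
  keep <- setdiff(stat_names, dropped)
  out_scale <- scale
  out_scale[dropped] <- NA_real_
  list(
    stats = sweep(stats_mat[, keep, drop = FALSE], 2, scale[keep], "/"),
    observed = as.numeric(obs[keep]) / scale[keep],
    scale = out_scale,
    dropped = dropped
  )
}

resolve_n_keep <- function(n_keep, n_rows) {
  if (n_keep < 1) n_keep <- ceiling(n_keep * n_rows)
  n_keep <- as.integer(n_keep)
  if (n_keep > n_rows) stop("n_keep exceeds the table size")
  n_keep
}

#' Rejection step: keep the simulations nearest the observed vector
#'
#' Euclidean distance on the normalized statistics; ties broken by row
#' index.
#'
#' @param norm Output of [normalize_reference()].
#' @param config An [abc_config()].
#' @return List with `indices` (row indices into the table, sorted by
#'   distance), `distance` (their distances) and `n_keep`.
#' @export
reject_nearest <- function(norm, config = abc_config()) {
  n <- nrow(norm$stats)
  if (n == 0) stop("empty reference table")
  n_keep <- resolve_n_keep(config$n_keep, n)
  d <- sqrt(colSums((t(norm$stats) - norm$observed)^2))
  ord <- order(d, seq_len(n))[seq_len(n_keep)]
  list(indices = ord, distance = d[ord], n_keep = n_keep)
}

#' Scenario posterior probabilities by the direct (kept-fraction) method
#'
#' `P(scenario)` is its fraction among the kept simulations; the 95% CI uses
#' the binomial normal approximation, clipped to `[0, 1]`.
#'
#' @param scenario_ids Scenario labels of the kept simulations.
#' @param scenarios Optional full set of scenario labels (so scenarios that
#'   vanish from the kept set still get a row with probability 0).
#' @param level Confidence level.
#' @return A `model_choice` data.frame with columns `scenario`, `prob`,
#'   `lower`, `upper`; attributes `method = "direct"` and `n_kept`.
#' @export
posterior_direct <- function(scenario_ids, scenarios = NULL, level = 0.95) {
  if (length(scenario_ids) == 0) stop("no kept simulations")
  if (is.null(scenarios)) scenarios <- sort(unique(scenario_ids))
  m <- length(scenario_ids)
  z <- stats::qnorm(1 - (1 - level) / 2)
  counts <- vapply(scenarios, function(s) sum(scenario_ids == s), numeric(1))
  p <- counts / m
  se <- sqrt(p * (1 - p) / m)
  out <- data.frame(scenario = scenarios, prob = p,
                    lower = pmax(0, p - z * se),
                    upper = pmin(1, p + z * se),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "method") <- "direct"
  attr(out, "n_kept") <- m
  out
}

#' Scenario posterior probabilities by multinomial logistic regression
#'
#' Fits a polychotomous logistic regression of the scenario indicator on the
#' normalized statistics over the kept simulations and evaluates it at the
#' observed vector. CIs come from the delta method on the class
#' probabilities. Near-separated fits (runaway coefficients) are refitted
#' with a small ridge penalty (`nnet` weight decay) and flagged via the
#' `regularized` attribute.
#'
#' @param kept_stats Normalized statistic matrix of the kept simulations.
#' @param scenario_ids Their scenario labels (>= 2 distinct).
#' @param observed Normalized observed vector.
#' @param level Confidence level.
#' @param decay Ridge penalty used by the fallback refit.
#' @return A `model_choice` data.frame as in [posterior_direct()], with
#'   `method = "logistic"`.
#' @export
posterior_logistic <- function(kept_stats, scenario_ids, observed,
                               level = 0.95, decay = 0.01) {
  scenarios <- sort(unique(scenario_ids))
  if (length(scenarios) < 2) {
    stop("logistic posterior needs >= 2 scenarios among kept simulations")
  }
  df <- data.frame(kept_stats, check.names = FALSE)
  df$.scenario <- factor(scenario_ids, levels = scenarios)
  fit <- suppressWarnings(
    nnet::multinom(.scenario ~ ., data = df, trace = FALSE,
                   maxit = 1000, reltol = 1e-12)
  )
  regularized <- FALSE
  if (max(abs(stats::coef(fit))) > 20) {
    fit <- suppressWarnings(
      nnet::multinom(.scenario ~ ., data = df, trace = FALSE,
                     maxit = 1000, reltol = 1e-12, decay = decay)
    )
    regularized <- TRUE
  }
  newd <- as.data.frame(as.list(stats::setNames(observed,
                                                colnames(kept_stats))),
                        check.names = FALSE)
  p <- as.numeric(stats::predict(fit, newdata = newd, type = "probs"))
  if (length(scenarios) == 2) p <- c(1 - p, p)
  names(p) <- scenarios

  # delta method: gradient of softmax probabilities w.r.t. the stacked
  # coefficient vector (classes 2..K, reference class first).
  xt <- c(1, as.numeric(observed))
  K <- length(scenarios)
  npar <- (K - 1) * length(xt)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- rep(NA_real_, K)
  if (!is.null(V) && nrow(V) == npar) {
    grads <- matrix(0, nrow = npar, ncol = K)
    for (k in seq_len(K)) {
      for (j in 2:K) {
        block <- (j - 2) * length(xt) + seq_along(xt)
        grads[block, k] <- p[k] * ((k == j) - p[j]) * xt
      }
    }
    se <- sqrt(pmax(0, diag(t(grads) %*% V %*% grads)))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(scenario = scenarios, prob = p,
                    lower = pmax(0, p - z * se),
                    upper = pmin(1, p + z * se),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "method") <- "logistic"
  attr(out, "n_kept") <- length(scenario_ids)
  attr(out, "regularized") <- regularized
  out
}

# Weighted quantiles (type-7-like interpolation on the weighted CDF).
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) - 0.5 * w
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Local-linear regression adjustment of kept parameter draws
#'
#' Beaumont-style ABC regression: each parameter is regressed on the
#' normalized statistics over the kept simulations with Epanechnikov
#' weights on distance (bandwidth = the largest kept distance); the
#' adjusted draws are the regression prediction at the observed point plus
#' the residuals. Strictly positive parameters are adjusted on the log
#' scale and back-transformed. Posterior summaries are weighted quantiles
#' of the adjusted draws. A rank-deficient design falls back to
#' rejection-only summaries (`adjustment = "rejection-only"`).
#'
#' @param kept_params Data frame (or matrix) of kept parameter draws.
#' @param kept_stats Normalized statistics of the kept simulations.
#' @param distances Their distances from [reject_nearest()].
#' @param observed Normalized observed vector.
#' @param priors Optional [prior_spec()]; adjusted draws are clamped to the
#'   prior support (clamp counts reported in the `n_clamped` column).
#' @param log_transform Adjust strictly positive parameters on the log
#'   scale (default `TRUE`).
#' @return A `param_estimate` data.frame with one row per parameter:
#'   `parameter`, `median`, `mean`, `q2.5`, `q97.5`, `adjustment`,
#'   `n_clamped`; the adjusted draws are in `attr(, "draws")`.
#' @export
estimate_params_loclinear <- function(kept_params, kept_stats, distances,
                                      observed, priors = NULL,
                                      log_transform = TRUE) {
  kept_params <- as.data.frame(kept_params)
  m <- nrow(kept_params)
  if (m < 10) stop("local-linear adjustment needs >= 10 kept simulations")
  delta <- max(distances)
  w <- if (delta > 0) 1 - (distances / delta)^2 else rep(1, m)
  w[w <= 0] <- min(w[w > 0], 1e-8)  # keep boundary rows with tiny weight
  X <- cbind(1, sweep(as.matrix(kept_stats), 2, as.numeric(observed)))
  # a near-saturated design leaves no residual information: the adjusted
  # draws would collapse onto the regression prediction. Require a margin
  # of kept simulations over covariates before regressing.
  regression_ok <- m >= ncol(X) + 5
  draws <- matrix(NA_real_, m, ncol(kept_params),
                  dimnames = list(NULL, names(kept_params)))
  rows <- vector("list", ncol(kept_params))
  for (j in seq_along(kept_params)) {
    nm <- names(kept_params)[j]
    y <- kept_params[[j]]
    uselog <- log_transform && all(y > 0)
    yt <- if (uselog) log(y) else y
    adjustment <- "local-linear"
    if (stats::sd(yt) == 0) {
      adj <- yt
    } else if (!regression_ok) {
      adjustment <- "rejection-only"
      adj <- yt
    } else {
      fit <- stats::lm.wfit(x = X, y = yt, w = w)
      if (fit$rank < ncol(X)) {
        adjustment <- "rejection-only"
        adj <- yt
      } else {
        adj <- fit$coefficients[1] + fit$residuals
      }
    }
    vals <- if (uselog) exp(adj) else adj
    n_clamped <- 0L
    if (!is.null(priors) && nm %in% names(priors$priors)) {
      pr <- priors$priors[[nm]]
      n_clamped <- sum(vals < pr$lower | vals > pr$upper)
      vals <- pmin(pmax(vals, pr$lower), pr$upper)
    }
    draws[, j] <- vals
    q <- weighted_quantile(vals, w, c(0.025, 0.5, 0.975))
    rows[[j]] <- data.frame(
      parameter = nm, median = q[2],
      mean = sum(w * vals) / sum(w),
      q2.5 = q[1], q97.5 = q[3],
      adjustment = adjustment, n_clamped = n_clamped,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  attr(out, "weights") <- w
  out
}

#' Evaluate estimator precision by RMAE over pseudo-observed datasets
#'
#' Draws `n_pods` parameter sets from the priors, simulates a
#' pseudo-observed dataset (POD) for each, runs the supplied estimator and
#' reports, per parameter, the relative median absolute error
#' `median(|estimate - truth| / |truth|)`. Values above 0.2 are flagged as
#' imprecise. PODs with a zero true value are excluded for that parameter
#' (and counted).
#'
#' @param scenario A [demographic_scenario()].
#' @param priors A [prior_spec()].
#' @param model_template A [mutation_model()].
#' @param estimator `function(statvec, truth)` returning a named vector of
#'   point estimates for (a subset of) the drawn parameters. The second
#'   argument is supplied for benchmarking estimators only and must be
#'   ignored by real ones.
#' @param n_pods Number of PODs (>= 1).
#' @param rng_seed Integer seed.
#' @param populations,pairs Passed to [compute_statvector()].
#' @return An `rmae_report` data.frame with columns `parameter`, `rmae`,
#'   `flag_high`, `n_used`, `n_excluded`; attribute `n_pods`.
#' @export
rmae_evaluate <- function(scenario, priors, model_template, estimator,
                          n_pods, rng_seed = 1L, populations = NULL,
                          pairs = NULL) {
  stopifnot(n_pods >= 1)
  set.seed(rng_seed)
  pod_seeds <- sample.int(.Machine$integer.max - 1L, n_pods)
  if (is.null(populations)) {
    sampled <- Filter(function(p) p$sample_size > 0, scenario$populations)
    populations <- vapply(sampled, function(p) p$name, character(1))
  }
  errs <- list()
  for (i in seq_len(n_pods)) {
    set.seed(pod_seeds[i])
    truth <- draw_from_prior(priors)
    model <- model_template
    if ("mu" %in% names(truth)) model$rate <- truth[["mu"]]
    g <- sample_genealogy(scenario, truth)
    aln <- mutate_hky(g, model, variant_only = TRUE)
    sv <- compute_statvector(aln, populations, pairs)
    est <- estimator(sv, truth)
    rel <- abs(est - truth[names(est)]) / abs(truth[names(est)])
    rel[truth[names(est)] == 0] <- NA_real_
    errs[[i]] <- rel
  }
  par_names <- names(errs[[1]])
  emat <- do.call(rbind, lapply(errs, function(e) e[par_names]))
  rmae <- apply(emat, 2, stats::median, na.rm = TRUE)
  out <- data.frame(
    parameter = par_names,
    rmae = as.numeric(rmae),
    flag_high = as.numeric(rmae) > 0.2,
    n_used = colSums(!is.na(emat)),
    n_excluded = colSums(is.na(emat)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_pods") <- n_pods
  out
}

#' Pre-evaluate the scenario-prior combination by PCA
#'
#' Projects the normalized simulated statistic vectors onto their principal
#' components and the observed vector with them; the observed point is
#' "inside the cloud" when it falls within the axis-aligned 1st-99th
#' percentile box of the first two components.
#'
#' @param table A `ref_table`.
#' @param observed Named statistic vector.
#' @param config An [abc_config()].
#' @param max_rows Subsample cap for the PCA (seeded via the config).
#' @return List with `sim_coords` (first two PC coordinates of the
#'   simulations used), `observed_coords`, `inside_cloud`, and the `prcomp`
#'   object as `pca`.
#' @export
prior_scenario_check <- function(table, observed, config = abc_config(),
                                 max_rows = 10000L) {
  norm <- normalize_reference(table, observed, config)
  sims <- norm$stats
  if (nrow(sims) > max_rows) {
    if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
    sims <- sims[sample.int(nrow(sims), max_rows), , drop = FALSE]
  }
  if (nrow(sims) < ncol(sims)) {
    stop("PCA pre-evaluation needs at least as many rows as statistics")
  }
  pca <- stats::prcomp(sims, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pca$x))
  sim_coords <- pca$x[, seq_len(k), drop = FALSE]
  obs_coords <- stats::predict(pca, newdata = t(norm$observed))[1, seq_len(k)]
  lo <- apply(sim_coords, 2, stats::quantile, probs = 0.01)
  hi <- apply(sim_coords, 2, stats::quantile, probs = 0.99)
  inside <- all(obs_coords >= lo & obs_coords <= hi)
  list(sim_coords = sim_coords, observed_coords = obs_coords,
       inside_cloud = inside, pca = pca)
}

#' Posterior-predictive goodness-of-fit of the winning scenario
#'
#' Simulates `n_rep` datasets with parameters resampled from the posterior
#' draws, computes every replicate's summary statistics, and scores the
#' observed vector by the fraction of replicate distances to the predictive
#' cloud center that are at least as large as the observed distance
#' (distances on MAD-normalized statistics of the predictive cloud).
#'
#' @param scenario The winning [demographic_scenario()].
#' @param posterior_draws Data frame / matrix of posterior parameter draws
#'   (e.g. `attr(estimate, "draws")`).
#' @param model_template A [mutation_model()].
#' @param observed Named statistic vector.
#' @param n_rep Number of posterior-predictive replicates.
#' @param rng_seed Integer seed.
#' @param populations,pairs Passed to [compute_statvector()].
#' @return Score in `[0, 1]` (small values mean the observed data sit
#'   outside the predictive cloud); replicate distances in
#'   `attr(, "distances")`.
#' @export
goodness_of_fit <- function(scenario, posterior_draws, model_template,
                            observed, n_rep = 100, rng_seed = 1L,
                            populations = NULL, pairs = NULL) {
  posterior_draws <- as.data.frame(posterior_draws)
  if (nrow(posterior_draws) < 1) stop("need at least one posterior draw")
  set.seed(rng_seed)
  rows <- sample.int(nrow(posterior_draws), n_rep, replace = TRUE)
  if (is.null(populations)) {
    sampled <- Filter(function(p) p$sample_size > 0, scenario$populations)
    populations <- vapply(sampled, function(p) p$name, character(1))
  }
  sims <- NULL
  for (i in seq_len(n_rep)) {
    truth <- unlist(posterior_draws[rows[i], , drop = TRUE])
    model <- model_template
    if ("mu" %in% names(truth)) model$rate <- truth[["mu"]]
    g <- sample_genealogy(scenario, truth)
    aln <- mutate_hky(g, model, variant_only = TRUE)
    sv <- compute_statvector(aln, populations, pairs)
    if (is.null(sims)) {
      sims <- matrix(NA_real_, n_rep, length(sv),
                     dimnames = list(NULL, names(sv)))
    }
    sims[i, ] <- sv
  }
  obs <- as.numeric(observed[colnames(sims)])
  scale <- apply(sims, 2, stats::mad)
  keep <- which(scale > 0)
  if (length(keep) == 0) {
    # a single replicate (or fully degenerate cloud): compare unscaled
    keep <- seq_len(ncol(sims))
    scale[] <- 1
  }
  simn <- sweep(sims[, keep, drop = FALSE], 2, scale[keep], "/")
  obsn <- obs[keep] / scale[keep]
  center <- colMeans(simn)
  rep_d <- sqrt(colSums((t(simn) - center)^2))
  obs_d <- sqrt(sum((obsn - center)^2))
  score <- mean(rep_d >= obs_d)
  attr(score, "distances") <- rep_d
  attr(score, "observed_distance") <- obs_d
  score
}
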