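# Backward-in-time coalescent simulator for multi-population serial-founder
# scenarios with HKY mutation.
#
# Time is measured in generations, increasing into the past. Populations are
# constant-size; the only demographic events are instantaneous merges
# (backward in time, all surviving lineages of a source population join a
# sink population). Within each population, k active lineages coalesce at
# rate k(k-1)/(2*NE) per generation (haploid NE = effective number of gene
# copies).

#' Declare a sampled population
#'
#' @param name Population label (unique within a scenario).
#' @param sample_size Number of sequences sampled at present (>= 0).
#' @param effective_size Haploid effective size NE (> 0); may be left `NA`
#'   and supplied at simulation time as parameter `NE_<name>`.
#' @return A `population_spec` object.
#' @export
population_spec <- function(name, sample_size, effective_size = NA_real_) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  sample_size <- as.integer(sample_size)
  if (is.na(sample_size) || sample_size < 0) stop("sample_size must be >= 0")
  if (!is.na(effective_size) && effective_size <= 0) {
    stop("effective_size must be positive")
  }
  structure(list(name = name, sample_size = sample_size,
                 effective_size = effective_size),
            class = "population_spec")
}

#' Declare a multi-population divergence scenario
#'
#' Merge events are interpreted backward in time: at `time`, all surviving
#' lineages of `source` move into `sink` (forward in time, `source` was
#' founded from `sink` at that date). Times may be numbers or parameter
#' names (e.g. `"t1"`) resolved from the parameter draw at simulation time.
#'
#' @param scenario_id Label.
#' @param populations List of [population_spec()] objects (unique names).
#' @param merge_events List of `list(time =, source =, sink =)`.
#' @return A `demographic_scenario` object.
#' @export
demographic_scenario <- function(scenario_id, populations, merge_events = list()) {
  names_ <- vapply(populations, function(p) p$name, character(1))
  if (anyDuplicated(names_)) stop("population names must be unique")
  active <- names_
  for (ev in merge_events) {
    if (!all(c("time", "source", "sink") %in% names(ev))) {
      stop("merge events need time, source and sink")
    }
    if (!ev$source %in% names_ || !ev$sink %in% names_) {
      stop("merge event references an undeclared population")
    }
    if (is.numeric(ev$time) && ev$time <= 0) {
      stop("merge event times must be strictly positive")
    }
    if (!ev$source %in% active) {
      stop("population '", ev$source, "' is merged away twice")
    }
    if (!ev$sink %in% active) {
      stop("merge sink '", ev$sink, "' is no longer ancestral at that time")
    }
    active <- setdiff(active, ev$source)
  }
  if (length(active) != 1) {
    stop("after all merge events exactly one ancestral population must remain")
  }
  structure(list(scenario_id = scenario_id, populations = populations,
                 merge_events = merge_events, pop_names = names_),
            class = "demographic_scenario")
}

#' Declare parameter priors
#'
#' @param priors Named list; each element `list(dist = "uniform"|"loguniform",
#'   lower =, upper =)` with `lower < upper` (equal bounds give a point
#'   mass).
#' @param constraints List of 2-vectors of parameter names; `c("a","b")`
#'   requires `a < b` in every accepted draw.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(priors, constraints = list()) {
  stopifnot(is.list(priors), length(names(priors)) == length(priors))
  for (nm in names(priors)) {
    p <- priors[[nm]]
    if (!p$dist %in% c("uniform", "loguniform")) {
      stop("unknown prior distribution '", p$dist, "' for ", nm)
    }
    if (p$lower > p$upper) stop("prior lower > upper for ", nm)
    if (p$dist == "loguniform" && p$lower <= 0) {
      stop("loguniform prior needs positive bounds for ", nm)
    }
  }
  for (cc in constraints) {
    if (length(cc) != 2 || !all(cc %in% names(priors))) {
      stop("constraints must reference two declared parameters")
    }
  }
  structure(list(priors = priors, constraints = constraints),
            class = "prior_spec")
}

#' Declare an HKY mutation model
#'
#' @param rate Mutation rate per site per generation (mu > 0; 0 allowed for
#'   the degenerate no-mutation case).
#' @param kappa Transition/transversion parameter of HKY (> 0).
#' @param base_frequencies Four non-negative numbers summing to 1
#'   (A, C, G, T).
#' @param sequence_length Alignment length L in bp (>= 1).
#' @return A `mutation_model` object.
#' @export
mutation_model <- function(rate, kappa = 1,
                           base_frequencies = rep(0.25, 4),
                           sequence_length) {
  if (rate < 0) stop("mutation rate must be non-negative")
  if (kappa <= 0) stop("kappa must be positive")
  if (length(base_frequencies) != 4 || any(base_frequencies < 0) ||
      abs(sum(base_frequencies) - 1) > 1e-12) {
    stop("base_frequencies must be 4 non-negative values summing to 1")
  }
  sequence_length <- as.integer(sequence_length)
  if (sequence_length < 1) stop("sequence_length must be >= 1")
  structure(list(rate = rate, kappa = kappa,
                 base_frequencies = base_frequencies,
                 sequence_length = sequence_length),
            class = "mutation_model")
}

#' Draw one parameter vector from the priors
#'
#' Draws every parameter from its marginal prior and resamples the whole
#' vector until all order constraints hold.
#'
#' @param priors A [prior_spec()].
#' @param rng_seed Optional integer seed.
#' @param max_tries Resampling cap before an error is raised.
#' @return Named numeric vector.
#' @export
draw_from_prior <- function(priors, rng_seed = NULL, max_tries = 10000L) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nm <- names(priors$priors)
  for (try in seq_len(max_tries)) {
    draw <- vapply(priors$priors, function(p) {
      if (p$lower == p$upper) return(p$lower)
      if (p$dist == "uniform") {
        stats::runif(1, p$lower, p$upper)
      } else {
        exp(stats::runif(1, log(p$lower), log(p$upper)))
      }
    }, numeric(1))
    names(draw) <- nm
    ok <- all(vapply(priors$constraints,
                     function(cc) draw[[cc[1]]] < draw[[cc[2]]], logical(1)))
    if (ok) return(draw)
  }
  stop("could not satisfy prior order constraints in ", max_tries, " draws")
}

# Resolve an event time or effective size from the parameter draw.
resolve_value <- function(x, params, what) {
  if (is.numeric(x)) return(x)
  if (is.character(x) && !is.null(params) && x %in% names(params)) {
    return(params[[x]])
  }
  stop("cannot resolve ", what, " '", x, "' from parameters")
}

#' Simulate a genealogy under a divergence scenario
#'
#' Standard haploid coalescent within each population (pairwise coalescence
#' rate `1/NE` per generation); at each merge event the surviving source
#' lineages move into the sink. A merge whose source population has no
#' surviving lineages is a no-op.
#'
#' @param scenario A [demographic_scenario()].
#' @param params Named numeric vector covering `NE_<pop>` for populations
#'   without a fixed `effective_size` and any named event times.
#' @param rng_seed Optional integer seed.
#' @return A `genealogy`: list with `n_tips`, `parent` (index vector, `NA`
#'   at the root), `time` (node times in generations), `tip_label`,
#'   `tip_pop`.
#' @export
sample_genealogy <- function(scenario, params = NULL, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pops <- scenario$populations
  sizes <- vapply(pops, function(p) {
    if (!is.na(p$effective_size)) return(p$effective_size)
    resolve_value(paste0("NE_", p$name), params, "effective size")
  }, numeric(1))
  names(sizes) <- scenario$pop_names
  n_per <- vapply(pops, function(p) p$sample_size, integer(1))
  n <- sum(n_per)
  if (n == 0) stop("no lineages sampled")

  # single population, no events: closed-form waiting times
  if (length(pops) == 1 && length(scenario$merge_events) == 0) {
    return(sample_genealogy_single(n, sizes[[1]], pops[[1]]$name))
  }

  events <- scenario$merge_events
  ev_times <- vapply(events, function(ev) {
    resolve_value(ev$time, params, "event time")
  }, numeric(1))
  ord <- order(ev_times)
  events <- events[ord]
  ev_times <- ev_times[ord]

  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  node_time <- numeric(n_nodes)
  tip_pop <- rep(scenario$pop_names, times = n_per)
  tip_label <- unlist(lapply(seq_along(pops), function(i) {
    if (n_per[i] == 0) return(character(0))
    paste0(pops[[i]]$name, "_", seq_len(n_per[i]))
  }), use.names = FALSE)

  # active lineages per population
  lin <- lapply(seq_along(pops), function(i) {
    if (n_per[i] == 0) return(integer(0))
    which(tip_pop == scenario$pop_names[i])
  })
  names(lin) <- scenario$pop_names

  t_now <- 0
  next_ev <- 1L
  next_node <- n
  k_tot <- n
  while (k_tot > 1L) {
    ks <- lengths(lin)
    rates <- ifelse(ks >= 2, ks * (ks - 1) / (2 * sizes), 0)
    total <- sum(rates)
    t_coal <- if (total > 0) t_now + stats::rexp(1, total) else Inf
    if (next_ev <= length(events) && ev_times[next_ev] <= t_coal) {
      ev <- events[[next_ev]]
      t_now <- ev_times[next_ev]
      lin[[ev$sink]] <- c(lin[[ev$sink]], lin[[ev$source]])
      lin[[ev$source]] <- integer(0)
      next_ev <- next_ev + 1L
      next
    }
    if (!is.finite(t_coal)) {
      stop("lineages in unmergeable populations cannot coalesce; ",
           "check scenario events")
    }
    t_now <- t_coal
    pop_i <- sample.int(length(rates), 1L, prob = rates)
    members <- lin[[pop_i]]
    pick <- sample.int(length(members), 2L)
    next_node <- next_node + 1L
    parent[members[pick]] <- next_node
    node_time[next_node] <- t_now
    lin[[pop_i]] <- c(members[-pick], next_node)
    k_tot <- k_tot - 1L
  }
  structure(list(n_tips = n, parent = parent, time = node_time,
                 tip_label = tip_label, tip_pop = tip_pop),
            class = "genealogy")
}

# Fast path: standard single-population coalescent. Waiting time with k
# lineages is Exp(k(k-1)/(2*NE)); pairs merge uniformly at random.
sample_genealogy_single <- function(n, ne, pop_name) {
  n <- as.integer(n)
  k <- n:2
  waits <- stats::rexp(n - 1L, k * (k - 1) / (2 * ne))
  times <- cumsum(waits)
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    pick <- sample.int(length(active), 2L)
    node <- n + i
    parent[active[pick]] <- node
    node_time[node] <- times[i]
    active <- c(active[-pick], node)
  }
  structure(list(n_tips = n, parent = parent, time = node_time,
                 tip_label = paste0(pop_name, "_", seq_len(n)),
                 tip_pop = rep(pop_name, n)),
            class = "genealogy")
}

#' Total branch length of a genealogy, in generations
#' @param g A genealogy from [sample_genealogy()].
#' @return Sum of all branch lengths.
#' @export
total_branch_length <- function(g) {
  non_root <- which(!is.na(g$parent))
  sum(g$time[g$parent[non_root]] - g$time[non_root])
}

#' Time to the most recent common ancestor, in generations
#' @param g A genealogy from [sample_genealogy()].
#' @return TMRCA.
#' @export
tmrca <- function(g) max(g$time)

# HKY jump matrix conditional on a change: row i gives the distribution of
# the new base given a mutation event hits state i. Transitions are A<->G
# and C<->T (coding A=1, C=2, G=3, T=4).
hky_jump_matrix <- function(kappa, base_frequencies) {
  J <- matrix(0, 4, 4)
  transit <- matrix(FALSE, 4, 4)
  transit[1, 3] <- transit[3, 1] <- TRUE
  transit[2, 4] <- transit[4, 2] <- TRUE
  for (i in 1:4) {
    w <- base_frequencies * ifelse(transit[i, ], kappa, 1)
    w[i] <- 0
    J[i, ] <- w / sum(w)
  }
  J
}

#' Drop HKY mutations along a genealogy and return the resulting alignment
#'
#' The ancestral sequence is drawn from the model's base frequencies.
#' Mutation events fall as a Poisson process of rate `mu * L * length` per
#' branch; each event hits a uniformly chosen site and substitutes the
#' current base according to the HKY rates conditional on a change
#' (transitions weighted by kappa). Multiple hits per site are allowed
#' (finite-sites model); `infinite_sites = TRUE` forces every event onto a
#' fresh site instead (test-only shortcut).
#'
#' @param g A genealogy from [sample_genealogy()].
#' @param model A [mutation_model()].
#' @param rng_seed Optional integer seed.
#' @param variant_only If `TRUE`, return an alignment storing only the
#'   mutated columns (with `L` set to the full length) — the statistics in
#'   this package treat the omitted columns as monomorphic. Much faster for
#'   long sequences.
#' @param infinite_sites Assign each mutation event a distinct site.
#' @return A [seq_alignment()] of `n_tips` sequences of length `L`.
#' @export
mutate_hky <- function(g, model, rng_seed = NULL, variant_only = FALSE,
                       infinite_sites = FALSE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- g$n_tips
  L <- model$sequence_length
  core <- sim_tip_states(g, model$rate, model$kappa,
                         model$base_frequencies, L, infinite_sites)
  if (is.null(core)) {  # no mutation events
    if (variant_only) {
      aln <- seq_alignment(matrix(character(0), nrow = n, ncol = 0),
                           ids = g$tip_label, populations = g$tip_pop, L = L)
      attr(aln, "sites") <- integer(0)
      return(aln)
    }
    anc <- sample(VALID_BASES, L, replace = TRUE,
                  prob = model$base_frequencies)
    return(seq_alignment(matrix(rep(anc, each = n), nrow = n),
                         ids = g$tip_label, populations = g$tip_pop))
  }
  sites <- core$sites
  anc_state <- core$anc_state
  tip_chars <- matrix(VALID_BASES[core$states], nrow = n)
  if (variant_only) {
    aln <- seq_alignment(tip_chars, ids = g$tip_label,
                         populations = g$tip_pop, L = L)
    attr(aln, "sites") <- sites
    attr(aln, "ancestral") <- VALID_BASES[anc_state]
    return(aln)
  }
  # monomorphic background redrawn from base frequencies at non-mutated sites
  anc_bg <- sample(VALID_BASES, L, replace = TRUE,
                   prob = model$base_frequencies)
  mat <- matrix(rep(anc_bg, each = n), nrow = n)
  mat[, sites] <- tip_chars
  seq_alignment(mat, ids = g$tip_label, populations = g$tip_pop)
}

# Core of the mutation engine: integer tip states (1..4 coding A,C,G,T) at
# the mutated sites only. Returns NULL when no mutation event occurs.
sim_tip_states <- function(g, rate, kappa, base_frequencies, L,
                           infinite_sites = FALSE) {
  n <- g$n_tips
  non_root <- which(!is.na(g$parent))
  blen <- g$time[g$parent[non_root]] - g$time[non_root]
  n_mut <- stats::rpois(length(non_root), rate * L * blen)
  M <- sum(n_mut)
  if (M == 0) return(NULL)
  if (infinite_sites) {
    if (M > L) stop("more mutations than sites under infinite-sites")
    site_of_mut <- sample.int(L, M, replace = FALSE)
  } else {
    site_of_mut <- sample.int(L, M, replace = TRUE)
  }
  edge_of_mut <- rep(non_root, times = n_mut)
  # forward-in-time order within each branch: larger coalescent age first
  age_of_mut <- stats::runif(M, min = g$time[edge_of_mut],
                             max = g$time[g$parent[edge_of_mut]])
  sites <- sort(unique(site_of_mut))
  V <- length(sites)
  slot_of_mut <- match(site_of_mut, sites)
  anc_state <- sample.int(4, V, replace = TRUE, prob = base_frequencies)
  J <- hky_jump_matrix(kappa, base_frequencies)

  n_nodes <- 2L * n - 1L
  states <- matrix(0L, n_nodes, V)
  root <- which(is.na(g$parent))
  states[root, ] <- anc_state
  # parents precede children when processed by decreasing node time
  ord <- order(g$time, decreasing = TRUE)
  ord <- ord[ord != root]
  mut_by_edge <- split(seq_len(M), edge_of_mut)
  for (v in ord) {
    s <- states[g$parent[v], ]
    muts <- mut_by_edge[[as.character(v)]]
    if (!is.null(muts)) {
      muts <- muts[order(age_of_mut[muts], decreasing = TRUE)]
      for (m in muts) {
        j <- slot_of_mut[m]
        s[j] <- sample.int(4, 1L, prob = J[s[j], ])
      }
    }
    states[v, ] <- s
  }
  list(states = states[seq_len(n), , drop = FALSE], sites = sites,
       anc_state = anc_state)
}

#' Simulate one dataset: a prior draw plus the resulting alignment
#'
#' @param scenario A [demographic_scenario()].
#' @param priors A [prior_spec()]; parameter names `NE_<pop>`, event-time
#'   names referenced by the scenario, and optionally `mu` (mutation rate
#'   per site per generation, overriding the template's rate).
#' @param model_template A [mutation_model()] providing kappa, base
#'   frequencies and sequence length.
#' @param rng_seed Optional integer seed.
#' @param variant_only Passed to [mutate_hky()].
#' @return A `sim_dataset`: list with `params`, `alignment`, `scenario_id`,
#'   `seed`.
#' @export
simulate_dataset <- function(scenario, priors, model_template,
                             rng_seed = NULL, variant_only = FALSE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  params <- draw_from_prior(priors)
  model <- model_template
  if ("mu" %in% names(params)) model$rate <- params[["mu"]]
  g <- sample_genealogy(scenario, params)
  aln <- mutate_hky(g, model, variant_only = variant_only)
  structure(list(params = params, alignment = aln,
                 scenario_id = scenario$scenario_id,
                 seed = if (is.null(rng_seed)) NA_integer_ else rng_seed),
            class = "sim_dataset")
}

#' Build an ABC reference table by prior simulation
#'
#' Simulates `n_sims_per_scenario` datasets under every scenario and stores,
#' per row, the scenario id, the parameter draw and the full
#' summary-statistic vector of [compute_statvector()]. Per-row seeds are
#' derived from `rng_seed` (one block of seeds drawn up-front), so the table
#' is bit-identical across runs with the same root seed and any row can be
#' regenerated independently from its `row_seed` column.
#'
#' @param scenarios List of [demographic_scenario()] objects.
#' @param priors A [prior_spec()].
#' @param model_template A [mutation_model()].
#' @param n_sims_per_scenario Rows per scenario (>= 1).
#' @param rng_seed Integer root seed.
#' @param populations,pairs Passed to [compute_statvector()]; default to the
#'   sampled populations of the first scenario (fixed ordering across rows).
#' @param file Optional TSV path; rows are appended in chunks so very large
#'   tables need not be memory-resident. The finished table is still
#'   returned (read back) unless `file` is given and `return_table = FALSE`.
#' @param return_table Set `FALSE` with `file` to skip reading the table
#'   back into memory.
#' @param chunk_size Rows per streaming write.
#' @return A `data.frame` of class `ref_table` with columns `scenario`,
#'   `row_seed`, the parameters, the statistics and `flag_degenerate`;
#'   attributes `param_names` and `stat_names`.
#' @export
build_reference_table <- function(scenarios, priors, model_template,
                                  n_sims_per_scenario, rng_seed = 1L,
                                  populations = NULL, pairs = NULL,
                                  file = NULL, return_table = TRUE,
                                  chunk_size = 1000L) {
  stopifnot(length(scenarios) >= 1, n_sims_per_scenario >= 1)
  set.seed(rng_seed)
  total <- length(scenarios) * n_sims_per_scenario
  row_seeds <- sample.int(.Machine$integer.max - 1L, total)
  if (is.null(populations)) {
    sampled <- Filter(function(p) p$sample_size > 0,
                      scenarios[[1]]$populations)
    populations <- vapply(sampled, function(p) p$name, character(1))
  }
  if (is.null(pairs) && length(populations) > 1) {
    pairs <- utils::combn(populations, 2, simplify = FALSE)
  }

  param_names <- names(priors$priors)
  con <- NULL
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con), add = TRUE)
  }
  header_written <- FALSE
  stat_names <- NULL
  chunks <- list()
  buf <- NULL          # numeric matrix chunk (row_seed, params, stats, flag)
  buf_scen <- character(0)
  buf_n <- 0L
  flush <- function() {
    df <- data.frame(scenario = buf_scen, buf[seq_len(buf_n), , drop = FALSE],
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(con)) {
      fmt <- df
      num <- vapply(fmt, is.numeric, logical(1))
      fmt[num] <- lapply(fmt[num], function(x) sprintf("%.17g", x))
      utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = !header_written)
      header_written <<- TRUE
    }
    df
  }
  k <- 0L
  for (si in seq_along(scenarios)) {
    scen <- scenarios[[si]]
    for (r in seq_len(n_sims_per_scenario)) {
      k <- k + 1L
      set.seed(row_seeds[k])
      params <- draw_from_prior(priors)
      model <- model_template
      if ("mu" %in% names(params)) model$rate <- params[["mu"]]
      g <- sample_genealogy(scen, params)
      aln <- mutate_hky(g, model, variant_only = TRUE)
      sv <- compute_statvector(aln, populations, pairs)
      if (is.null(stat_names)) {
        stat_names <- names(sv)
        buf <- matrix(NA_real_, nrow = min(chunk_size, total),
                      ncol = 2L + length(param_names) + length(stat_names),
                      dimnames = list(NULL, c("row_seed", param_names,
                                              stat_names, "flag_degenerate")))
      }
      buf_n <- buf_n + 1L
      buf[buf_n, ] <- c(row_seeds[k], params[param_names], as.numeric(sv),
                        as.integer(any(attr(sv, "flags"))))
      buf_scen[buf_n] <- scen$scenario_id
      if (buf_n >= nrow(buf)) {
        chunks[[length(chunks) + 1L]] <- flush()
        buf_n <- 0L
        buf_scen <- character(0)
      }
    }
  }
  if (buf_n > 0) chunks[[length(chunks) + 1L]] <- flush()
  if (!return_table && !is.null(file)) return(invisible(file))
  tab <- do.call(rbind, chunks)
  rownames(tab) <- NULL
  class(tab) <- c("ref_table", "data.frame")
  attr(tab, "param_names") <- param_names
  attr(tab, "stat_names") <- stat_names
  tab
}

#' Write / read a reference table as tab-separated text
#'
#' Round-trips losslessly (full double precision).
#' @param table A `ref_table`.
#' @param path TSV path.
#' @return `write_ref_table`: the path, invisibly. `read_ref_table`: the
#'   table with its `param_names` / `stat_names` attributes restored.
#' @export
write_ref_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ref_table
#' @param param_names Parameter column names; inferred as the columns
#'   between `row_seed` and the first statistic if omitted.
#' @export
read_ref_table <- function(path, param_names = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(tab)
  if (is.null(param_names)) {
    # statistics columns follow the naming convention <stat>_<pop...>
    stat_start <- which(grepl("^(mpd|rarest_mean|rarest_var|K|S|fst)_", cols))[1]
    param_names <- setdiff(cols[seq_len(stat_start - 1)],
                           c("scenario", "row_seed"))
  }
  stat_names <- setdiff(cols, c("scenario", "row_seed", param_names,
                                "flag_degenerate"))
  class(tab) <- c("ref_table", "data.frame")
  attr(tab, "param_names") <- param_names
  attr(tab, "stat_names") <- stat_names
  tab
}
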