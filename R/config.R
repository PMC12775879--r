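# Scenario / prior configuration files and the default serial-founder
# study setup for mitogenome sub-haplogroup dispersal inference.

CONFIG_FORMAT_VERSION <- 1L

#' The two competing serial-founder dispersal scenarios
#'
#' Three metapopulations of a mitochondrial lineage: a European source
#' (`EUR`), western Africa (`WA`) and eastern Africa (`EA`). Scenario
#' `EUR_WA_EA`: WA is founded from EUR at `t2`, then EA from WA at `t1`
#' (`t1 < t2`, backward-in-time merges EA->WA at t1 and WA->EUR at t2).
#' Scenario `EUR_EA_WA` swaps the roles of WA and EA.
#'
#' @param n_eur,n_wa,n_ea Present-day sample sizes.
#' @return List of two [demographic_scenario()] objects.
#' @export
e2_scenarios <- function(n_eur = 10, n_wa = 10, n_ea = 6) {
  pops <- list(population_spec("EUR", n_eur),
               population_spec("WA", n_wa),
               population_spec("EA", n_ea))
  list(
    demographic_scenario("EUR_WA_EA", pops, list(
      list(time = "t1", source = "EA", sink = "WA"),
      list(time = "t2", source = "WA", sink = "EUR")
    )),
    demographic_scenario("EUR_EA_WA", pops, list(
      list(time = "t1", source = "WA", sink = "EA"),
      list(time = "t2", source = "EA", sink = "EUR")
    ))
  )
}

#' Default priors for the dispersal scenarios
#'
#' The mutation-rate prior is uniform on 1e-8 to 1e-7 per site per
#' generation. The effective-size and divergence-time priors are documented
#' placeholders (the study's own prior table is not public): haploid
#' `NE ~ U(100, 10000)` per population, `t1 ~ U(40, 4000)` and
#' `t2 ~ U(40, 8000)` generations with the order constraint `t1 < t2`.
#' Every bound is overridable.
#'
#' @param ne_bounds,t1_bounds,t2_bounds,mu_bounds Length-2 numeric bounds.
#' @return A [prior_spec()] with parameters `NE_EUR`, `NE_WA`, `NE_EA`,
#'   `t1`, `t2`, `mu` and the constraint `t1 < t2`.
#' @export
e2_priors <- function(ne_bounds = c(100, 10000),
                      t1_bounds = c(40, 4000),
                      t2_bounds = c(40, 8000),
                      mu_bounds = c(1e-8, 1e-7)) {
  u <- function(b) list(dist = "uniform", lower = b[1], upper = b[2])
  prior_spec(
    list(NE_EUR = u(ne_bounds), NE_WA = u(ne_bounds), NE_EA = u(ne_bounds),
         t1 = u(t1_bounds), t2 = u(t2_bounds), mu = u(mu_bounds)),
    constraints = list(c("t1", "t2"))
  )
}

#' Default HKY mutation model for mitogenome simulation
#'
#' Sequence length defaults to the 14,979 bp gap-free mitogenome alignment;
#' kappa and base frequencies default to 1 and uniform for pure simulation
#' (empirical values should be supplied when real data are analysed).
#'
#' @param sequence_length Alignment length in bp.
#' @param kappa HKY transition/transversion parameter.
#' @param base_frequencies Base frequencies (A, C, G, T).
#' @param rate Template mutation rate; overridden by the `mu` prior draw
#'   during simulation.
#' @return A [mutation_model()].
#' @export
e2_mutation_model <- function(sequence_length = 14979, kappa = 1,
                              base_frequencies = rep(0.25, 4),
                              rate = 5e-8) {
  mutation_model(rate = rate, kappa = kappa,
                 base_frequencies = base_frequencies,
                 sequence_length = sequence_length)
}

#' Write / read a scenario-prior configuration file
#'
#' YAML with a versioned header (`format_version`), declaring scenarios
#' (populations with sample sizes, merge events), priors, order constraints
#' and the mutation model.
#'
#' @param scenarios List of [demographic_scenario()] objects.
#' @param priors A [prior_spec()].
#' @param model A [mutation_model()].
#' @param path Output path.
#' @return `write_scenario_config`: the path, invisibly.
#'   `read_scenario_config`: `list(scenarios, priors, model)`.
#' @export
write_scenario_config <- function(scenarios, priors, model, path) {
  cfg <- list(
    format_version = CONFIG_FORMAT_VERSION,
    scenarios = lapply(scenarios, function(sc) {
      list(
        id = sc$scenario_id,
        populations = lapply(sc$populations, function(p) {
          out <- list(name = p$name, sample_size = p$sample_size)
          if (!is.na(p$effective_size)) out$effective_size <- p$effective_size
          out
        }),
        events = lapply(sc$merge_events, function(ev) {
          list(time = ev$time, source = ev$source, sink = ev$sink)
        })
      )
    }),
    priors = priors$priors,
    constraints = lapply(priors$constraints, as.list),
    mutation_model = list(
      rate = model$rate, kappa = model$kappa,
      base_frequencies = model$base_frequencies,
      sequence_length = model$sequence_length
    )
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$format_version) ||
      cfg$format_version > CONFIG_FORMAT_VERSION) {
    stop("unsupported config format version")
  }
  scenarios <- lapply(cfg$scenarios, function(sc) {
    pops <- lapply(sc$populations, function(p) {
      population_spec(p$name, p$sample_size,
                      if (is.null(p$effective_size)) NA_real_
                      else p$effective_size)
    })
    demographic_scenario(sc$id, pops, sc$events)
  })
  priors <- prior_spec(cfg$priors,
                       lapply(cfg$constraints, unlist))
  mm <- cfg$mutation_model
  model <- mutation_model(mm$rate, mm$kappa, unlist(mm$base_frequencies),
                          mm$sequence_length)
  list(scenarios = scenarios, priors = priors, model = model)
}
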