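# Sequence-level summary statistics.
#
# Conventions shared by every statistic:
#  * only A/C/G/T are "usable" bases; N and '-' are excluded pairwise
#    (pairwise deletion) from difference counts and from column tallies;
#  * a variant-only alignment (ncol(seqs) < L) is treated as having
#    monomorphic, unambiguous columns everywhere else, so per-site
#    denominators use L while difference counts use the stored columns.

# n x n matrices of pairwise difference counts and pairwise compared lengths.
pairwise_diff_matrix <- function(aln, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(aln$ids)
  m <- aln$seqs[idx, , drop = FALSE]
  n <- nrow(m)
  usable <- matrix(m %in% VALID_BASES, nrow = n)
  diffs <- matrix(0, n, n)
  ncomp <- matrix(aln$L - ncol(m), n, n)  # omitted columns always compared
  for (j in seq_len(ncol(m))) {
    ok <- usable[, j]
    both <- outer(ok, ok, "&")
    ncomp <- ncomp + both
    x <- m[, j]
    diffs <- diffs + (both & outer(x, x, "!="))
  }
  list(diffs = diffs, ncomp = ncomp, n = n)
}

#' Mean number of pairwise sequence differences
#'
#' Average over all unordered pairs of the number of sites at which both
#' sequences carry unambiguous, non-gap bases that differ.
#'
#' @param aln A [seq_alignment()].
#' @param population Population label (or vector of labels) to restrict to;
#'   `NULL` or `"all"` uses every sequence.
#' @return A single number.
#' @export
mean_pairwise_differences <- function(aln, population = NULL) {
  idx <- aln_select(aln, population)
  if (length(idx) < 2) stop("mean pairwise differences needs >= 2 sequences")
  pd <- pairwise_diff_matrix(aln, idx)
  mean(pd$diffs[upper.tri(pd$diffs)])
}

# Per-column tallies of usable bases within a selection: 4 x V matrix.
column_base_counts <- function(aln, idx) {
  m <- aln$seqs[idx, , drop = FALSE]
  counts <- matrix(0L, nrow = 4, ncol = ncol(m),
                   dimnames = list(VALID_BASES, NULL))
  for (b in seq_along(VALID_BASES)) {
    counts[b, ] <- colSums(m == VALID_BASES[b])
  }
  counts
}

#' Number of segregating sites
#'
#' Columns at which at least two distinct unambiguous bases occur among the
#' selected sequences.
#'
#' @inheritParams mean_pairwise_differences
#' @return Integer count.
#' @export
segregating_sites <- function(aln, population = NULL) {
  idx <- aln_select(aln, population)
  if (length(idx) < 2) stop("segregating sites needs >= 2 sequences")
  counts <- column_base_counts(aln, idx)
  sum(colSums(counts > 0) >= 2)
}

#' Mean and variance of rarest-allele counts at segregating sites
#'
#' For every segregating site, takes the copy number of the least frequent
#' base present among the selected sequences; returns the mean and variance
#' of those counts across segregating sites.
#'
#' @inheritParams mean_pairwise_differences
#' @param var_denominator `"S"` (population variance across segregating
#'   sites, the default) or `"S-1"` (sample variance).
#' @return Named numeric vector `c(mean =, variance =)`. When no site is
#'   segregating, both are the degenerate sentinel 0 and the result carries
#'   `attr(, "degenerate") = TRUE`.
#' @export
rarest_allele_stats <- function(aln, population = NULL,
                                var_denominator = c("S", "S-1")) {
  var_denominator <- match.arg(var_denominator)
  idx <- aln_select(aln, population)
  counts <- column_base_counts(aln, idx)
  seg <- colSums(counts > 0) >= 2
  if (!any(seg)) {
    out <- c(mean = 0, variance = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  rarest <- apply(counts[, seg, drop = FALSE], 2,
                  function(x) min(x[x > 0]))
  s <- length(rarest)
  mu <- mean(rarest)
  denom <- if (var_denominator == "S") s else max(s - 1, 1)
  v <- sum((rarest - mu)^2) / denom
  c(mean = mu, variance = v)
}

#' Haplotype count and haplotype diversity
#'
#' Haplotypes are exact string matches on the stored (uppercased) matrix;
#' diversity is the small-sample-corrected heterozygosity
#' `h = n/(n-1) * (1 - sum p_i^2)`, with `h = 0` for a single sequence.
#'
#' @inheritParams mean_pairwise_differences
#' @return Named vector `c(K =, h =)`.
#' @export
haplotype_stats <- function(aln, population = NULL) {
  idx <- aln_select(aln, population)
  n <- length(idx)
  keys <- apply(aln$seqs[idx, , drop = FALSE], 1, paste, collapse = "")
  p <- as.numeric(table(keys)) / n
  K <- length(p)
  h <- if (n == 1) 0 else (n / (n - 1)) * (1 - sum(p^2))
  c(K = K, h = h)
}

#' Nucleotide diversity (per site)
#'
#' Mean pairwise differences divided by the mean pairwise number of compared
#' (mutually unambiguous, non-gap) sites.
#'
#' @inheritParams mean_pairwise_differences
#' @return Per-site diversity.
#' @export
nucleotide_diversity <- function(aln, population = NULL) {
  idx <- aln_select(aln, population)
  if (length(idx) < 2) stop("nucleotide diversity needs >= 2 sequences")
  pd <- pairwise_diff_matrix(aln, idx)
  up <- upper.tri(pd$diffs)
  denom <- mean(pd$ncomp[up])
  if (denom == 0) stop("no mutually unambiguous sites to compare")
  mean(pd$diffs[up]) / denom
}

#' Pairwise F_ST from mean pairwise differences (Hudson-style)
#'
#' `F_ST = (pi_between - pi_within) / pi_between`, where `pi_within` is the
#' average of the two within-population mean pairwise difference values and
#' `pi_between` the mean over all cross-population pairs. Negative estimates
#' are clipped to 0; `pi_between = 0` is reported as 0 (no measurable
#' differentiation) with `attr(, "degenerate") = TRUE`.
#'
#' @param aln A [seq_alignment()].
#' @param popA,popB Population labels.
#' @return F_ST in `[0, 1]`.
#' @export
fst_pair <- function(aln, popA, popB) {
  ia <- aln_select(aln, popA)
  ib <- aln_select(aln, popB)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("F_ST needs >= 2 sequences in each population")
  }
  pd <- pairwise_diff_matrix(aln, c(ia, ib))
  na <- length(ia)
  nb <- length(ib)
  A <- seq_len(na)
  B <- na + seq_len(nb)
  within_a <- mean(pd$diffs[A, A][upper.tri(matrix(0, na, na))])
  within_b <- mean(pd$diffs[B, B][upper.tri(matrix(0, nb, nb))])
  between <- mean(pd$diffs[A, B])
  if (between == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  max(0, (between - (within_a + within_b) / 2) / between)
}

#' Compute the ABC summary-statistic vector
#'
#' One-sample statistics per population (mean pairwise differences, mean and
#' variance of rarest-allele counts at segregating sites) followed by
#' two-sample statistics per population pair (haplotype count of the pooled
#' pair, segregating sites, mean pairwise differences, F_ST), in a fixed
#' order with names `<stat>_<pop>` / `<stat>_<popA>_<popB>`.
#'
#' Degenerate statistics (no segregating site, or zero between-population
#' diversity) are stored as 0 and flagged in the `"flags"` attribute.
#'
#' @param aln A [seq_alignment()].
#' @param populations Character vector of population labels (fixes the
#'   ordering). Defaults to the distinct labels in `aln`.
#' @param pairs List of 2-vectors of population labels. Defaults to all
#'   unordered pairs of `populations`.
#' @return Named numeric vector with attribute `flags` (logical, same
#'   names) marking sentinel entries.
#' @export
compute_statvector <- function(aln, populations = NULL, pairs = NULL) {
  if (is.null(populations)) populations <- unique(aln$populations)
  if (is.null(pairs) && length(populations) > 1) {
    pairs <- utils::combn(populations, 2, simplify = FALSE)
  }
  stopifnot(all(populations %in% aln$populations))
  vals <- numeric(0)
  flags <- logical(0)
  push <- function(name, value) {
    flag <- isTRUE(attr(value, "degenerate"))
    attributes(value) <- NULL
    vals[name] <<- value
    flags[name] <<- flag
  }
  for (p in populations) {
    push(paste0("mpd_", p), mean_pairwise_differences(aln, p))
    ra <- rarest_allele_stats(aln, p)
    deg <- isTRUE(attr(ra, "degenerate"))
    push(paste0("rarest_mean_", p), structure(ra[["mean"]], degenerate = deg))
    push(paste0("rarest_var_", p), structure(ra[["variance"]], degenerate = deg))
  }
  for (pr in pairs) {
    tag <- paste0(pr[1], "_", pr[2])
    hs <- haplotype_stats(aln, pr)
    push(paste0("K_", tag), hs[["K"]])
    push(paste0("S_", tag), segregating_sites(aln, pr))
    push(paste0("mpd_", tag), mean_pairwise_differences(aln, pr))
    push(paste0("fst_", tag), fst_pair(aln, pr[1], pr[2]))
  }
  attr(vals, "flags") <- flags
  vals
}
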