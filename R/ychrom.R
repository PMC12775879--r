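# Male-specific Y chromosome (MSY) chain: depth-ratio sexing, the four-step
# hemizygous variant filter, and gene extraction/concatenation.
#
# Genotype codes in the internal matrix (sites x samples):
#   >= 0  allele index (0 = ref, k = k-th alt)
#   -1    heterozygous diploid call (an artifact at hemizygous sites)
#   NA    missing

#' Build a per-sample depth profile table
#'
#' @param sample_id Sample identifiers.
#' @param mean_depth_autosomes,mean_depth_X,mean_depth_Y Mean depth of
#'   coverage (x) over autosomes, X and Y.
#' @return A `depth_profile` data.frame.
#' @export
depth_profile <- function(sample_id, mean_depth_autosomes, mean_depth_X,
                          mean_depth_Y) {
  if (any(mean_depth_autosomes < 0 | mean_depth_X < 0 | mean_depth_Y < 0)) {
    stop("depths must be non-negative")
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    mean_depth_autosomes = mean_depth_autosomes,
                    mean_depth_X = mean_depth_X,
                    mean_depth_Y = mean_depth_Y,
                    stringsAsFactors = FALSE)
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Assign sexes from sequencing-depth ratios
#'
#' Males carry one X and one Y, so relative to autosomes their X depth is
#' about one half and their Y depth clearly positive; females show X depth
#' near the autosomal level and Y depth near zero. A sample is called male
#' when `Y/autosome >= y_ratio_threshold` and `X/autosome <
#' x_ratio_female_min`; female when `Y/autosome < y_ratio_threshold / 2`
#' and `X/autosome >= x_ratio_female_min`; anything else (including zero
#' autosomal depth) is unassigned.
#'
#' @param profiles A [depth_profile()] data.frame.
#' @param y_ratio_threshold Minimum Y/autosome ratio for a male call.
#' @param x_ratio_female_min Minimum X/autosome ratio for a female call.
#' @return Named character vector (`male` / `female` / `unassigned`);
#'   samples with non-positive autosomal depth are listed in
#'   `attr(, "errors")`.
#' @export
assign_sex <- function(profiles, y_ratio_threshold = 0.25,
                       x_ratio_female_min = 0.75) {
  out <- rep("unassigned", nrow(profiles))
  names(out) <- profiles$sample_id
  bad <- profiles$mean_depth_autosomes <= 0
  yr <- profiles$mean_depth_Y / profiles$mean_depth_autosomes
  xr <- profiles$mean_depth_X / profiles$mean_depth_autosomes
  male <- !bad & yr >= y_ratio_threshold & xr < x_ratio_female_min
  female <- !bad & yr < y_ratio_threshold / 2 & xr >= x_ratio_female_min
  out[male] <- "male"
  out[female] <- "female"
  if (any(bad)) {
    attr(out, "errors") <- data.frame(
      sample_id = profiles$sample_id[bad],
      reason = "non-positive autosomal depth",
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Construct a variant table
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated for multi-allelic sites). Positions must be
#'   unique and sorted within each chromosome.
#' @param genotypes Integer matrix, sites x samples, using the codes
#'   documented above (>= 0 allele index, -1 heterozygous, NA missing).
#' @param sex Optional named character vector of per-sample sexes.
#' @return A `variant_table` object.
#' @export
variant_table <- function(sites, genotypes, sex = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (nrow(sites) != nrow(genotypes)) {
    stop("sites and genotype matrix dimensions disagree")
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (anyDuplicated(p) || is.unsorted(p)) {
      stop("positions must be unique and sorted within each chromosome")
    }
  }
  if (is.null(colnames(genotypes))) {
    stop("genotype matrix needs sample names as column names")
  }
  if (!is.null(sex)) {
    missing_sex <- setdiff(colnames(genotypes), names(sex))
    if (length(missing_sex) > 0) {
      stop("sex not provided for: ", paste(missing_sex, collapse = ", "))
    }
  }
  structure(list(sites = sites, genotypes = genotypes, sex = sex),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n",
              nrow(x$sites), ncol(x$genotypes)))
  invisible(x)
}

# Parse a single GT string ("0", "1", "0/0", "0|1", "./.", ".") to the
# internal integer code.
parse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(a) {
    if (length(a) == 0 || anyNA(a) || all(a == ".")) return(NA_integer_)
    if (any(a == ".")) return(NA_integer_)
    v <- suppressWarnings(as.integer(a))
    if (anyNA(v)) return(NA_integer_)
    if (length(v) == 1 || v[1] == v[2]) return(v[1])
    -1L  # heterozygous
  }, integer(1))
}

#' Read an MSY variant table from a VCF file
#'
#' Accepts haploid (`0`, `1`) and diploid (`0/1`, `0|1`) GT encodings;
#' diploid calls with two different alleles become heterozygous codes,
#' `./.` or `.` become missing.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sex Optional named sex vector, e.g. from [assign_sex()].
#' @return A [variant_table()].
#' @export
read_msy_vcf <- function(path, sex = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  geno <- apply(gt_raw, 2, parse_gt)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(gt_raw),
                                         dimnames = dimnames(gt_raw))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  variant_table(sites[ord, , drop = FALSE], geno[ord, , drop = FALSE],
                sex = sex)
}

#' Four-step MSY variant filter
#'
#' In order: (1) drop female (and unassigned) samples; (2) drop sites whose
#' missing-genotype rate among the retained males is `>= max_missing`;
#' (3) drop sites with minor allele frequency `< min_maf` among non-missing,
#' non-heterozygous male calls (this removes monomorphic sites); (4) drop
#' sites with any heterozygous male call, leaving only hemizygous-clean
#' sites.
#'
#' @param table A [variant_table()] whose `sex` field is set.
#' @param max_missing Missing-rate cutoff (default 0.05).
#' @param min_maf Minor-allele-frequency cutoff (default 0.001).
#' @return List with `table` (the filtered [variant_table()]) and `counts`,
#'   the named per-step surviving-site counts
#'   (`initial`, `after_missing`, `after_maf`, `after_het`).
#' @export
filter_msy <- function(table, max_missing = 0.05, min_maf = 0.001) {
  if (is.null(table$sex)) stop("sexes must be assigned before filtering")
  males <- colnames(table$genotypes)[
    table$sex[colnames(table$genotypes)] == "male"]
  if (length(males) == 0) stop("no male samples to filter")
  g <- table$genotypes[, males, drop = FALSE]
  counts <- c(initial = nrow(g))

  miss_rate <- rowMeans(is.na(g))
  keep <- miss_rate < max_missing
  g <- g[keep, , drop = FALSE]
  sites <- table$sites[keep, , drop = FALSE]
  counts["after_missing"] <- nrow(g)

  maf <- apply(g, 1, function(row) {
    calls <- row[!is.na(row) & row >= 0]
    if (length(calls) == 0) return(0)
    tab <- table(calls)
    if (length(tab) < 2) return(0)
    min(tab) / sum(tab)
  })
  keep <- maf >= min_maf
  g <- g[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  counts["after_maf"] <- nrow(g)

  keep <- rowSums(g == -1L, na.rm = TRUE) == 0
  g <- g[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  counts["after_het"] <- nrow(g)

  sex <- table$sex[males]
  list(table = variant_table(sites, g, sex = sex), counts = counts)
}

#' Declare MSY gene intervals
#'
#' @param genes Data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive, non-overlapping).
#' @return A `gene_interval_set` data.frame.
#' @export
gene_interval_set <- function(genes) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stop("interval start > end")
  for (ch in unique(genes$chrom)) {
    gi <- genes[genes$chrom == ch, , drop = FALSE]
    gi <- gi[order(gi$start), , drop = FALSE]
    if (nrow(gi) > 1 && any(gi$start[-1] <= gi$end[-nrow(gi)])) {
      stop("gene intervals overlap on ", ch)
    }
  }
  class(genes) <- c("gene_interval_set", "data.frame")
  genes
}

#' Extract gene-interval sites and concatenate them into sequences
#'
#' Retains the sites falling inside any interval and, per sample,
#' concatenates the allele characters in interval order then position
#' order. Missing genotypes become `"N"` or the site's majority allele,
#' depending on `missing_fill`; residual heterozygous calls (which the
#' filter normally removes) become `"N"`.
#'
#' @param table A (filtered) [variant_table()].
#' @param genes A [gene_interval_set()].
#' @param missing_fill `"N"` (default) or `"majority"`.
#' @return Named character vector of equal-length sequences (length = number
#'   of retained sites); attribute `"sites"` holds the retained site table.
#' @export
concatenate_msy <- function(table, genes, missing_fill = c("N", "majority")) {
  missing_fill <- match.arg(missing_fill)
  pick <- integer(0)
  for (i in seq_len(nrow(genes))) {
    hit <- which(table$sites$chrom == genes$chrom[i] &
                 table$sites$pos >= genes$start[i] &
                 table$sites$pos <= genes$end[i])
    pick <- c(pick, hit[order(table$sites$pos[hit])])
  }
  if (length(pick) == 0) {
    warning("no variant sites fall inside the gene intervals")
    out <- stats::setNames(rep("", ncol(table$genotypes)),
                           colnames(table$genotypes))
    attr(out, "sites") <- table$sites[0, , drop = FALSE]
    return(out)
  }
  g <- table$genotypes[pick, , drop = FALSE]
  sites <- table$sites[pick, , drop = FALSE]
  allele_char <- function(site_i, code) {
    if (is.na(code)) {
      if (missing_fill == "N") return("N")
      row <- g[site_i, ]
      calls <- row[!is.na(row) & row >= 0]
      if (length(calls) == 0) return("N")
      code <- as.integer(names(which.max(table(calls))))
    }
    if (code == -1L) return("N")
    if (code == 0L) return(sites$ref[site_i])
    alts <- strsplit(sites$alt[site_i], ",")[[1]]
    if (code > length(alts)) stop("allele index beyond ALT list")
    alts[code]
  }
  seqs <- vapply(colnames(g), function(s) {
    paste(vapply(seq_len(nrow(g)),
                 function(i) allele_char(i, g[i, s]), character(1)),
          collapse = "")
  }, character(1))
  attr(seqs, "sites") <- sites
  seqs
}

#' Generate a synthetic MSY fixture with known truth
#'
#' Depth profiles consistent with the declared sexes (male Y around half the
#' autosomal depth, female Y near zero), and a Y-chromosome variant table
#' with controlled counts of high-missing, male-monomorphic and
#' heterozygous-contaminated sites, the remainder being clean polymorphic
#' sites. The truth record carries the declared sexes and the expected
#' per-step surviving-site counts of [filter_msy()] at its default
#' thresholds.
#'
#' @param n_males,n_females Sample counts.
#' @param n_sites Total site count (>= 3 when any special site is requested).
#' @param rng_seed Integer seed.
#' @param n_high_missing,n_monomorphic,n_het Counts of sites that are,
#'   respectively, >= 5% missing among males, monomorphic among males (but
#'   polymorphic in females), and carrying one heterozygous male call.
#' @return List with `profiles`, `table` (a [variant_table()] with sexes
#'   attached) and `truth` (sexes and expected filter counts).
#' @export
make_msy_fixture <- function(n_males, n_females, n_sites, rng_seed = 1L,
                             n_high_missing = 1L, n_monomorphic = 1L,
                             n_het = 1L) {
  stopifnot(n_males >= 0, n_females >= 0, n_sites >= 0,
            n_high_missing + n_monomorphic + n_het <= n_sites)
  set.seed(rng_seed)
  ids <- c(if (n_males > 0) paste0("M", seq_len(n_males)),
           if (n_females > 0) paste0("F", seq_len(n_females)))
  sex_true <- stats::setNames(
    c(rep("male", n_males), rep("female", n_females)), ids)
  auto <- stats::runif(length(ids), 25, 35)
  xr <- ifelse(sex_true == "male", stats::runif(length(ids), 0.45, 0.55),
               stats::runif(length(ids), 0.95, 1.05))
  yr <- ifelse(sex_true == "male", stats::runif(length(ids), 0.40, 0.55),
               stats::runif(length(ids), 0, 0.01))
  profiles <- depth_profile(ids, auto, auto * xr, auto * yr)

  bases <- c("A", "C", "G", "T")
  geno <- matrix(NA_integer_, n_sites, length(ids),
                 dimnames = list(NULL, ids))
  kind <- rep("clean", n_sites)
  if (n_sites > 0) {
    special <- sample.int(n_sites, n_high_missing + n_monomorphic + n_het)
    kind[special] <- rep(c("high_missing", "monomorphic", "het"),
                         c(n_high_missing, n_monomorphic, n_het))
  }
  male_idx <- which(sex_true == "male")
  female_idx <- which(sex_true == "female")
  for (s in seq_len(n_sites)) {
    # clean backbone: polymorphic among males, no missing, no hets
    g <- integer(length(ids))
    if (length(male_idx) >= 2) {
      n_alt <- sample(seq_len(length(male_idx) - 1), 1)
      g[male_idx[sample.int(length(male_idx), n_alt)]] <- 1L
    }
    if (length(female_idx) > 0) {
      g[female_idx] <- sample(0:1, length(female_idx), replace = TRUE)
    }
    if (kind[s] == "high_missing" && length(male_idx) > 0) {
      n_miss <- max(1L, ceiling(0.2 * length(male_idx)))
      g[male_idx[sample.int(length(male_idx), n_miss)]] <- NA_integer_
    } else if (kind[s] == "monomorphic") {
      g[male_idx] <- 0L
      if (length(female_idx) > 0) g[female_idx[1]] <- 1L
    } else if (kind[s] == "het" && length(male_idx) >= 3) {
      # keep the site polymorphic among the non-het males so that it
      # survives the MAF step and is removed by the heterozygosity step
      picks <- sample.int(length(male_idx), 3)
      g[male_idx] <- 0L
      g[male_idx[picks[1]]] <- -1L
      g[male_idx[picks[2]]] <- 1L
    } else if (kind[s] == "het" && length(male_idx) > 0) {
      g[male_idx[sample.int(length(male_idx), 1)]] <- -1L
    }
    geno[s, ] <- g
  }
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  sites <- data.frame(chrom = "Y", pos = seq_len(n_sites) * 100L,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  tab <- variant_table(sites, geno, sex = sex_true)
  truth <- list(
    sex = sex_true,
    expected_counts = c(
      initial = n_sites,
      after_missing = n_sites - n_high_missing,
      after_maf = n_sites - n_high_missing - n_monomorphic,
      after_het = n_sites - n_high_missing - n_monomorphic - n_het
    )
  )
  list(profiles = profiles, table = tab, truth = truth)
}
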