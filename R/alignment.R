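# Container for haploid sequence alignments with population labels.
#
# Sequences are stored as an n x V character matrix over {A,C,G,T,N,-}.
# V may be smaller than the declared alignment length L, in which case the
# omitted columns are, by construction, monomorphic and unambiguous (this is
# how simulated alignments are carried around without materialising
# megabase-scale constant background).  All statistics are written against
# that convention: difference counts use the stored columns, per-site
# denominators use L.

VALID_BASES <- c("A", "C", "G", "T")
ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a haploid sequence alignment
#'
#' @param sequences Either a character vector of equal-length strings or an
#'   n x V character matrix of single characters over `A,C,G,T,N,-`
#'   (lowercase accepted).
#' @param ids Sample identifiers; defaults to `seq_1 ... seq_n`. Must be
#'   unique.
#' @param populations Population label per sample; defaults to `"all"`.
#' @param L Total alignment length. Defaults to the number of stored columns.
#'   May exceed it, in which case the omitted columns are declared
#'   monomorphic and unambiguous (used by the simulator's variant-only
#'   representation).
#' @return An object of class `seq_alignment` with fields `ids`,
#'   `populations`, `seqs` (character matrix) and `L`.
#' @export
seq_alignment <- function(sequences, ids = NULL, populations = NULL, L = NULL) {
  if (is.character(sequences) && !is.matrix(sequences)) {
    if (length(sequences) == 0) stop("alignment needs at least one sequence")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1) stop("all sequences must have equal length")
    seqs <- matrix(unlist(strsplit(sequences, "")), nrow = length(sequences),
                   byrow = TRUE)
  } else if (is.matrix(sequences)) {
    seqs <- sequences
  } else {
    stop("sequences must be a character vector or matrix")
  }
  seqs[] <- toupper(seqs)
  bad <- setdiff(unique(as.vector(seqs)), ALPHABET)
  if (length(bad) > 0) {
    stop("invalid characters in alignment: ", paste(bad, collapse = ", "))
  }
  n <- nrow(seqs)
  if (is.null(ids)) ids <- paste0("seq_", seq_len(n))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (is.null(populations)) populations <- rep("all", n)
  if (length(ids) != n || length(populations) != n) {
    stop("ids and populations must match the number of sequences")
  }
  if (is.null(L)) L <- ncol(seqs)
  if (L < ncol(seqs)) stop("L cannot be smaller than the number of stored columns")
  structure(
    list(ids = as.character(ids), populations = as.character(populations),
         seqs = seqs, L = as.integer(L)),
    class = "seq_alignment"
  )
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences, L = %d (%d stored columns)\n",
              nrow(x$seqs), x$L, ncol(x$seqs)))
  tab <- table(x$populations)
  cat("populations:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# Row indices for a population selection; NULL or "all" selects everything.
aln_select <- function(aln, population = NULL) {
  if (is.null(population) || identical(population, "all")) {
    return(seq_along(aln$ids))
  }
  idx <- which(aln$populations %in% population)
  if (length(idx) == 0) {
    stop("no sequences with population label '",
         paste(population, collapse = ","), "'")
  }
  idx
}

#' Read a FASTA alignment with population labels
#'
#' Sample ids of the form `POP|id` encode population membership; a two-column
#' tab-separated population map (`sample_id<TAB>population`) can be supplied
#' instead and takes precedence.
#'
#' @param path FASTA file.
#' @param popmap Optional path to a population map.
#' @return A [seq_alignment()].
#' @export
read_alignment_fasta <- function(path, popmap = NULL) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(do.call(rbind, as.character(dna)))
  ids <- names(dna)
  pops <- rep("all", length(ids))
  if (any(grepl("|", ids, fixed = TRUE))) {
    pops <- sub("\\|.*$", "", ids)
    ids <- sub("^[^|]*\\|", "", ids)
  }
  if (!is.null(popmap)) {
    pm <- utils::read.table(popmap, sep = "\t", header = FALSE,
                            col.names = c("sample_id", "population"),
                            stringsAsFactors = FALSE)
    pops <- pm$population[match(ids, pm$sample_id)]
    if (anyNA(pops)) stop("population map does not cover all samples")
  }
  seq_alignment(seqs, ids = ids, populations = pops)
}

#' Write an alignment as FASTA plus a population map
#'
#' Headers are written as `POP|id`; a sidecar two-column tab-separated
#' population map is written next to the FASTA (suffix `.popmap.tsv`).
#' Variant-only alignments are expanded to full length with an `A` background.
#'
#' @param aln A [seq_alignment()].
#' @param path Output FASTA path.
#' @param width Line width for wrapped sequence output.
#' @return Invisibly, the FASTA path.
#' @export
write_alignment_fasta <- function(aln, path, width = 60) {
  mat <- expand_alignment_matrix(aln)
  headers <- paste0(aln$populations, "|", aln$ids)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(mat))) {
    writeLines(paste0(">", headers[i]), con)
    s <- paste(mat[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  utils::write.table(
    data.frame(sample_id = aln$ids, population = aln$populations),
    file = paste0(path, ".popmap.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Expand a variant-only alignment to its full n x L character matrix.
expand_alignment_matrix <- function(aln, background = "A") {
  if (ncol(aln$seqs) == aln$L) return(aln$seqs)
  mat <- matrix(background, nrow = nrow(aln$seqs), ncol = aln$L)
  sites <- attr(aln, "sites")
  if (is.null(sites)) sites <- seq_len(ncol(aln$seqs))
  mat[, sites] <- aln$seqs
  rownames(mat) <- aln$ids
  mat
}
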