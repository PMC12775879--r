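# Haplotype collapsing and haplogroup frequency summaries.

# Half-up rounding at `digits` decimals (R's round() is round-half-even;
# published frequency tables use the conventional half-up style).
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Collapse identical sequences into haplotypes
#'
#' Identical cleaned (uppercased, exact-match) sequences share a haplotype;
#' haplotype ids are ordered by decreasing frequency, ties by first
#' occurrence.
#'
#' @param aln A [seq_alignment()].
#' @return List with `haplotype` (integer id per sample, named by sample
#'   id) and `table` (data.frame `haplotype`, `count`).
#' @export
collapse_haplotypes <- function(aln) {
  keys <- apply(aln$seqs, 1, paste, collapse = "")
  first <- match(unique(keys), keys)
  counts <- as.numeric(table(keys)[unique(keys)])
  ord <- order(-counts, first)
  id_of_key <- stats::setNames(order(ord), unique(keys))  # key -> rank id
  hap <- as.integer(id_of_key[keys])
  names(hap) <- aln$ids
  tab <- data.frame(haplotype = seq_along(ord),
                    count = counts[ord], row.names = NULL)
  list(haplotype = hap, table = tab)
}

#' Haplogroup frequency table from per-sample assignments
#'
#' @param assignments Data frame with columns `sample_id` and `haplogroup`
#'   (one label per sample), or a character vector of labels.
#' @return A `frequency_table` data.frame with columns `haplogroup`,
#'   `count`, `percent` (one decimal, half-up) and `percent_int`
#'   (integer-rounded), ordered by decreasing count then label.
#' @export
haplogroup_percentages <- function(assignments) {
  labels <- if (is.data.frame(assignments)) {
    if (!is.null(assignments$sample_id) &&
        anyDuplicated(assignments$sample_id)) {
      stop("each sample must carry exactly one haplogroup label")
    }
    assignments$haplogroup
  } else {
    assignments
  }
  if (length(labels) == 0) stop("no haplogroup assignments")
  counts <- table(labels)
  df <- data.frame(haplogroup = names(counts),
                   count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$haplogroup), , drop = FALSE]
  total <- sum(df$count)
  df$percent <- round_half_up(100 * df$count / total, 1)
  df$percent_int <- as.integer(round_half_up(100 * df$count / total, 0))
  rownames(df) <- NULL
  class(df) <- c("frequency_table", "data.frame")
  attr(df, "total") <- total
  df
}

#' Write / read haplogroup assignment and frequency tables
#'
#' Assignments are two-column tab-separated (`sample_id`, `haplogroup`);
#' frequency tables are tab-separated with a header.
#'
#' @param path File path.
#' @return `read_haplogroup_assignments`: a data.frame.
#' @export
read_haplogroup_assignments <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("sample_id", "haplogroup"),
                    stringsAsFactors = FALSE)
}

#' @rdname read_haplogroup_assignments
#' @param x A `frequency_table`.
#' @export
write_frequency_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
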