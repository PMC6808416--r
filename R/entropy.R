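.shannon_bits <- function(p) {
  pos <- p > 0
  -sum(p[pos] * log2(p[pos]))
}

#' Whole-transcript heterogeneity entropy
#'
#' The mean Shannon entropy (base 2) of per-gene isoform abundance
#' fractions: for each gene the entropy of its isoform mixing ratios is
#' computed and the result is averaged over genes. A sample in which every
#' gene expresses a single isoform scores 0; heterogeneous isoform mixing
#' raises the score.
#'
#' @param genes Per-gene isoform fractions: either a list of numeric
#'   vectors (each summing to 1) or a data.frame with columns `gene_id`
#'   and `fraction`.
#' @return Non-negative numeric scalar (bits).
#' @export
#' @examples
#' transcript_entropy(list(c(0.5, 0.5), 1))   # (1 + 0) / 2 = 0.5
transcript_entropy <- function(genes) {
  if (is.data.frame(genes)) {
    stopifnot(all(c("gene_id", "fraction") %in% names(genes)))
    genes <- split(genes$fraction, genes$gene_id)
  }
  if (!is.list(genes) || length(genes) == 0L) {
    stop("'genes' must be a non-empty list of isoform fraction vectors")
  }
  ok <- vapply(genes, function(p) {
    is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) < 1e-6
  }, logical(1))
  if (!all(ok)) {
    stop("isoform fractions of gene ", names(genes)[!ok][1],
         " do not sum to 1")
  }
  mean(vapply(genes, .shannon_bits, numeric(1)))
}

#' Intron-level heterogeneity entropy of one sample
#'
#' A single-sample analog of [transcript_entropy()] computed on splice
#' junctions instead of annotated isoforms: junctions are grouped into
#' intronic splicing units, each unit's counts are normalized to a usage
#' distribution, and the mean Shannon entropy (base 2) over the `L` units
#' is returned. Filtering matches the sITH core so both measures see the
#' same unit set.
#'
#' @param profile A [junction_profile()].
#' @param min_members Minimum member junctions per unit (default 2).
#' @param min_reads Minimum total reads per unit (default 1).
#' @return Numeric scalar (bits), or `NA` with a warning if no unit
#'   survives filtering.
#' @export
intron_entropy <- function(profile, min_members = 2L, min_reads = 1) {
  stopifnot(inherits(profile, "junction_profile"))
  jx <- group_junctions(as.data.frame(profile)[profile$count > 0, ,
                                               drop = FALSE])
  if (nrow(jx) == 0L) {
    warning("no splicing units; intron entropy undefined")
    return(NA_real_)
  }
  u <- factor(jx$unit_id, levels = unique(jx$unit_id))
  ui <- as.integer(u)
  n_members <- as.vector(table(u))
  tot <- as.vector(rowsum(jx$count, ui))
  keep <- n_members >= min_members & tot >= min_reads
  if (!any(keep)) {
    warning("no splicing units survive filtering; intron entropy undefined")
    return(NA_real_)
  }
  p <- jx$count / tot[ui]
  term <- ifelse(p > 0, -p * log2(p), 0)
  ent <- as.vector(rowsum(term, ui))
  mean(ent[keep])
}

#' Read per-gene isoform fractions from TSV
#'
#' Reads a tab-separated file with header
#' `gene_id  isoform_id  fraction` and returns the per-gene fraction
#' vectors expected by [transcript_entropy()].
#'
#' @param file Path or connection.
#' @return Named list of numeric vectors, one per gene, each summing to 1.
#' @export
read_isoform_fractions <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "numeric"))
  if (!identical(names(tab), c("gene_id", "isoform_id", "fraction"))) {
    stop("isoform TSV must have header 'gene_id\\tisoform_id\\tfraction'")
  }
  if (any(tab$fraction < 0)) stop("isoform fractions must be non-negative")
  genes <- split(tab$fraction, tab$gene_id)
  bad <- vapply(genes, function(p) abs(sum(p) - 1) >= 1e-6, logical(1))
  if (any(bad)) {
    stop("isoform fractions of gene ", names(genes)[bad][1],
         " do not sum to 1")
  }
  genes
}
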