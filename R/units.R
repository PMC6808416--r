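#' Group splice junctions into intronic splicing units
#'
#' An intronic splicing unit is a maximal connected set of splice junctions
#' sharing a splice-site coordinate (donor or acceptor) on the same
#' chromosome and strand class. Formally, units are the connected components
#' of the graph whose vertices are splice-site coordinates and whose edges
#' are junctions; a junction sharing its donor with one neighbour and its
#' acceptor with another therefore lands in a single unit, so the output
#' partitions the input. Strand classes (`+`, `-`, unknown `.`) never merge:
#' antisense overlapping genes share coordinates but not splicing events.
#'
#' @param junctions A data.frame with columns `chrom`, `start`, `end`,
#'   `strand` (a [junction_profile()] works); extra columns are preserved.
#' @return The input data.frame with a `unit_id` column added
#'   (`"<chrom>:<min site>-<max site>(<strand>)"`, deterministic), rows
#'   ordered by unit and canonical member order (start, then end).
#' @export
#' @examples
#' jx <- data.frame(chrom = "chr1", start = c(100L, 100L, 100L),
#'                  end = c(200L, 300L, 400L), strand = "+")
#' group_junctions(jx)   # one unit, three members sharing a donor
group_junctions <- function(junctions) {
  jx <- as.data.frame(junctions)
  if (nrow(jx) == 0L) {
    jx$unit_id <- character(0)
    return(jx)
  }
  site_a <- paste(jx$chrom, jx$strand, jx$start, sep = "\r")
  site_b <- paste(jx$chrom, jx$strand, jx$end, sep = "\r")
  sites <- unique(c(site_a, site_b))
  g <- igraph::graph_from_edgelist(
    cbind(match(site_a, sites), match(site_b, sites)),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  unit_of_junction <- comp[match(site_a, sites)]

  # unit id from the component's coordinate span on its chrom/strand
  coord <- c(jx$start, jx$end)
  comp2 <- rep(unit_of_junction, 2L)
  lo <- tapply(coord, comp2, min)
  hi <- tapply(coord, comp2, max)
  ids <- sprintf("%s:%d-%d(%s)", jx$chrom,
                 as.integer(lo[as.character(unit_of_junction)]),
                 as.integer(hi[as.character(unit_of_junction)]),
                 jx$strand)
  jx$unit_id <- ids
  ord <- order(jx$chrom, as.integer(lo[as.character(unit_of_junction)]),
               as.integer(hi[as.character(unit_of_junction)]), jx$strand,
               jx$start, jx$end)
  jx <- jx[ord, , drop = FALSE]
  rownames(jx) <- NULL
  jx
}

#' Harmonize splicing units across a sample pair
#'
#' Builds splicing units on the union of the two samples' observed
#' junctions, so that the i-th unit describes the same intronic region in
#' both samples, and aligns both samples' counts to each unit's canonical
#' member order. A junction observed in only one sample appears with
#' count 0 in the other (pseudo-counting is applied later, in the
#' divergence step).
#'
#' @param p,q [junction_profile()] objects.
#' @return A data.frame in long format, one row per unit member:
#'   columns `unit_id`, `chrom`, `start`, `end`, `strand`, `count_p`,
#'   `count_q`, ordered by unit then member; attributes `sample_p`,
#'   `sample_q` carry the sample names.
#' @export
harmonize_units <- function(p, q) {
  stopifnot(inherits(p, "junction_profile"), inherits(q, "junction_profile"))
  dp <- as.data.frame(p)[p$count > 0, , drop = FALSE]
  dq <- as.data.frame(q)[q$count > 0, , drop = FALSE]
  keys_p <- .junction_key(dp)
  keys_q <- .junction_key(dq)
  all_keys <- union(keys_p, keys_q)
  idx_p <- match(all_keys, keys_p)
  idx_q <- match(all_keys, keys_q)
  in_p <- !is.na(idx_p)
  pick <- function(col) {
    ifelse(in_p, dp[[col]][idx_p], dq[[col]][idx_q])
  }
  un <- data.frame(chrom = pick("chrom"),
                   start = as.integer(pick("start")),
                   end = as.integer(pick("end")),
                   strand = pick("strand"))
  un$count_p <- ifelse(in_p, dp$count[idx_p], 0)
  un$count_q <- ifelse(is.na(idx_q), 0, dq$count[idx_q])
  un <- group_junctions(un)
  un <- un[c("unit_id", "chrom", "start", "end", "strand",
             "count_p", "count_q")]
  rownames(un) <- NULL
  structure(un, sample_p = sample_id(p), sample_q = sample_id(q))
}

#' Filter harmonized splicing units
#'
#' Drops units unusable for divergence scoring: units with fewer than
#' `min_members` member junctions in the union (a single-junction unit has
#' a degenerate one-point usage distribution whose divergence is always 0
#' and would dilute the sITH mean), and units whose total observed count in
#' either sample is below `min_reads` (a unit wholly unobserved in one
#' sample cannot be pseudo-counted, since the pseudo-count is a fraction of
#' that sample's unit total, which is zero).
#'
#' @param units Long-format unit table from [harmonize_units()].
#' @param min_members Minimum member junctions per unit (default 2).
#' @param min_reads Minimum per-sample total observed reads per unit
#'   (default 1, i.e. drop units absent from one sample).
#' @return A list with `kept` (the filtered table) and `drop_log`, a named
#'   integer vector tallying dropped units by reason
#'   (`too_few_members`, `absent_in_one_sample`).
#' @export
filter_units <- function(units, min_members = 2L, min_reads = 1) {
  stopifnot(min_members >= 1L, min_reads >= 0)
  u <- factor(units$unit_id, levels = unique(units$unit_id))
  n_members <- as.vector(table(u))
  tot_p <- as.vector(rowsum(units$count_p, u))
  tot_q <- as.vector(rowsum(units$count_q, u))
  too_few <- n_members < min_members
  absent <- !too_few & (tot_p < min_reads | tot_q < min_reads)
  keep_unit <- !too_few & !absent
  kept <- units[keep_unit[as.integer(u)], , drop = FALSE]
  rownames(kept) <- NULL
  attributes(kept)[c("sample_p", "sample_q")] <-
    attributes(units)[c("sample_p", "sample_q")]
  list(kept = kept,
       drop_log = c(too_few_members = sum(too_few),
                    absent_in_one_sample = sum(absent)))
}
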