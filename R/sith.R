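# Vectorized per-unit JSD over a filtered harmonized unit table.
# Equivalent to composing apply_pseudocounts / usage_distribution / jsd
# unit by unit; done with grouped column arithmetic so that scoring
# hundreds of samples stays cheap.
.unit_jsd_table <- function(kept, pseudo_denom = 100) {
  if (nrow(kept) == 0L) {
    return(data.frame(unit_id = character(), chrom = character(),
                      strand = character(), n_members = integer(),
                      jsd = numeric()))
  }
  u <- factor(kept$unit_id, levels = unique(kept$unit_id))
  ui <- as.integer(u)
  cp <- kept$count_p
  cq <- kept$count_q
  if (any(cp == 0 & cq == 0)) {
    stop("internal error: unit member unobserved in both samples")
  }
  tot_p <- as.vector(rowsum(cp, ui))[ui]
  tot_q <- as.vector(rowsum(cq, ui))[ui]
  cp <- ifelse(cp == 0, tot_p / pseudo_denom, cp)
  cq <- ifelse(cq == 0, tot_q / pseudo_denom, cq)
  p <- cp / as.vector(rowsum(cp, ui))[ui]
  q <- cq / as.vector(rowsum(cq, ui))[ui]
  m <- (p + q) / 2
  term_p <- ifelse(p > 0, p * log2(p / m), 0)
  term_q <- ifelse(q > 0, q * log2(q / m), 0)
  jsd_u <- (as.vector(rowsum(term_p, ui)) + as.vector(rowsum(term_q, ui))) / 2
  jsd_u <- pmin(pmax(jsd_u, 0), 1)
  first <- !duplicated(ui)
  data.frame(unit_id = kept$unit_id[first],
             chrom = kept$chrom[first],
             strand = kept$strand[first],
             n_members = as.vector(table(u)),
             jsd = jsd_u)
}

#' Spliceomic intratumor heterogeneity between two samples
#'
#' Computes the sITH score of sample `p` relative to reference sample `q`:
#' junctions of both samples are grouped into shared intronic splicing
#' units ([harmonize_units()]), unusable units are dropped
#' ([filter_units()]), splice sites unobserved in one sample are
#' pseudo-counted with 1/`pseudo_denom` of that sample's unit total, unit
#' counts are normalized to usage distributions, and the base-2
#' Jensen-Shannon divergence is computed per unit. sITH is the arithmetic
#' mean of the per-unit divergences over the `L` kept units and lies in
#' `[0, 1]`. The score is symmetric in `p` and `q`.
#'
#' In the intended use `p` is a bulk tumor sample and `q` a normal-tissue
#' reference, so the score isolates usage perturbations acquired during
#' cancer progression from heterogeneity innate to normal tissue.
#'
#' @param p,q [junction_profile()] objects (tumor and reference).
#' @param min_members,min_reads Unit filters; see [filter_units()].
#' @param pseudo_denom Pseudo-count denominator (default 100).
#' @return An object of class `sith_result`: a list with `sample_p`,
#'   `sample_q`, `unit_divergences` (data.frame with `unit_id`, `chrom`,
#'   `strand`, `n_members`, `jsd`), `L` (number of units used), `drop_log`,
#'   and `sith` (the mean divergence; `NA` if no unit survives filtering —
#'   never a silent 0).
#' @export
#' @examples
#' p <- junction_profile(data.frame(
#'   chrom = "chr1", start = 100L, end = c(200L, 300L, 400L),
#'   strand = "+", count = c(5, 3, 2)), "tumor")
#' q <- junction_profile(data.frame(
#'   chrom = "chr1", start = 100L, end = c(200L, 400L),
#'   strand = "+", count = c(4, 6)), "normal")
#' sith_pair(p, q)
sith_pair <- function(p, q, min_members = 2L, min_reads = 1,
                      pseudo_denom = 100) {
  h <- harmonize_units(p, q)
  f <- filter_units(h, min_members = min_members, min_reads = min_reads)
  ud <- .unit_jsd_table(f$kept, pseudo_denom = pseudo_denom)
  L <- nrow(ud)
  structure(list(sample_p = sample_id(p),
                 sample_q = sample_id(q),
                 unit_divergences = ud,
                 L = L,
                 drop_log = f$drop_log,
                 sith = if (L > 0L) mean(ud$jsd) else NA_real_),
            class = "sith_result")
}

#' @export
print.sith_result <- function(x, ...) {
  cat("sITH(", x$sample_p, ", ", x$sample_q, ") = ",
      if (is.na(x$sith)) "undefined (no usable splicing units)"
      else sprintf("%.6f", x$sith),
      "\n  units used (L): ", x$L,
      "\n  dropped: ", paste(names(x$drop_log), x$drop_log,
                             sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' sITH against multiple normal references
#'
#' Scores one tumor sample against each reference profile with
#' [sith_pair()] and averages the per-reference sITH values, mirroring the
#' use of a panel of normal tissues as the origin. A reference yielding an
#' undefined sITH (no usable units) makes the mean `NA`.
#'
#' @param tumor A [junction_profile()].
#' @param refs Non-empty list of reference [junction_profile()] objects.
#' @inheritParams sith_pair
#' @return A list with `sith` (mean over references) and `per_ref`
#'   (list of `sith_result`).
#' @export
sith_multi_ref <- function(tumor, refs, min_members = 2L, min_reads = 1,
                           pseudo_denom = 100) {
  if (!is.list(refs) || length(refs) == 0L ||
      inherits(refs, "junction_profile")) {
    stop("'refs' must be a non-empty list of junction profiles")
  }
  per_ref <- lapply(refs, function(r) {
    sith_pair(tumor, r, min_members = min_members, min_reads = min_reads,
              pseudo_denom = pseudo_denom)
  })
  list(sith = mean(vapply(per_ref, `[[`, numeric(1), "sith")),
       per_ref = per_ref)
}
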