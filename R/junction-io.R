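#' Read a STAR SJ.out.tab junction table
#'
#' Parses the 9-column, tab-separated, headerless `SJ.out.tab` file emitted
#' by the STAR aligner: column 1 chromosome, column 2 first intronic base
#' (1-based), column 3 last intronic base (1-based), column 4 strand code
#' (0 = unknown, 1 = `+`, 2 = `-`), column 7 uniquely mapping reads,
#' column 8 multimapping reads. By default the junction count is the number
#' of uniquely mapping reads; multimapper support is opt-in because it
#' inflates noise junctions. Junctions whose resulting count is 0 are
#' dropped. Strand-unknown junctions (STAR code 0, typical of noncanonical
#' splice sites) are retained as their own strand class.
#'
#' @param file Path to an SJ.out.tab file, or a connection.
#' @param include_multimappers If `TRUE`, count = unique + multimapping reads.
#' @param sample_id Sample name stored in the profile; defaults to the
#'   file name without extension.
#' @return A [junction_profile()].
#' @export
read_star_sj <- function(file, include_multimappers = FALSE,
                         sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (is.character(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else "sample"
  }
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(junction_profile(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), count = numeric()),
      sample_id = sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 9L)
  if (length(bad) > 0L) {
    stop("SJ.out.tab line ", bad[1], ": expected 9 tab-separated columns, found ",
         nf[bad[1]])
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  scode <- suppressWarnings(as.integer(m[, 4]))
  uniq <- suppressWarnings(as.numeric(m[, 7]))
  multi <- suppressWarnings(as.numeric(m[, 8]))
  bad <- which(is.na(start) | is.na(end) | is.na(scode) |
                 is.na(uniq) | is.na(multi))
  if (length(bad) > 0L) {
    stop("SJ.out.tab line ", bad[1], ": non-numeric coordinate or count field")
  }
  bad <- which(start > end)
  if (length(bad) > 0L) {
    stop("SJ.out.tab line ", bad[1], ": intron start ", start[bad[1]],
         " > end ", end[bad[1]])
  }
  bad <- which(!scode %in% 0:2)
  if (length(bad) > 0L) {
    stop("SJ.out.tab line ", bad[1], ": strand code must be 0, 1 or 2")
  }
  count <- if (include_multimappers) uniq + multi else uniq
  keep <- count > 0
  junction_profile(
    data.frame(chrom = m[keep, 1], start = start[keep], end = end[keep],
               strand = c(".", "+", "-")[scode[keep] + 1L],
               count = count[keep]),
    sample_id = sample_id)
}

.JUNCTION_TSV_HEADER <- c("chrom", "start", "end", "strand", "count")

#' Read a generic junction TSV
#'
#' Reads the package's generic junction dialect: a tab-separated file with
#' header `chrom  start  end  strand  count`, 1-based inclusive intron
#' coordinates, strand in `{+, -, .}` (`.` = unknown), and non-negative,
#' possibly fractional, counts.
#'
#' @param file Path or connection.
#' @param sample_id Sample name; defaults to the file name without extension.
#' @return A [junction_profile()].
#' @export
read_junction_tsv <- function(file, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (is.character(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else "sample"
  }
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L ||
      !identical(strsplit(lines[1], "\t", fixed = TRUE)[[1]],
                 .JUNCTION_TSV_HEADER)) {
    stop("junction TSV must start with header '",
         paste(.JUNCTION_TSV_HEADER, collapse = "\\t"), "'")
  }
  body <- lines[-1]
  if (length(body) == 0L) {
    return(junction_profile(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), count = numeric()),
      sample_id = sample_id))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 5L)
  if (length(bad) > 0L) {
    stop("junction TSV line ", bad[1] + 1L, ": expected 5 columns, found ",
         nf[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  count <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(count))
  if (length(bad) > 0L) {
    stop("junction TSV line ", bad[1] + 1L,
         ": non-numeric coordinate or count")
  }
  bad <- which(!m[, 4] %in% c("+", "-", "."))
  if (length(bad) > 0L) {
    stop("junction TSV line ", bad[1] + 1L, ": strand must be +, - or .")
  }
  bad <- which(count < 0)
  if (length(bad) > 0L) {
    stop("junction TSV line ", bad[1] + 1L, ": negative count")
  }
  bad <- which(start > end)
  if (length(bad) > 0L) {
    stop("junction TSV line ", bad[1] + 1L, ": intron start > end")
  }
  junction_profile(
    data.frame(chrom = m[, 1], start = start, end = end,
               strand = m[, 4], count = count),
    sample_id = sample_id)
}

#' Write a junction profile as generic junction TSV
#'
#' Rows are sorted by (chrom, start, end, strand). Integer counts are
#' written without a decimal point so that
#' `read_junction_tsv(write_junction_tsv(p))` round-trips exactly;
#' fractional counts (e.g. from in-silico mixtures) are written with 10
#' significant digits.
#'
#' @param profile A [junction_profile()].
#' @param file Path or connection to write to.
#' @return Invisibly, the path or connection written to.
#' @export
write_junction_tsv <- function(profile, file) {
  stopifnot(inherits(profile, "junction_profile"))
  cnt <- ifelse(profile$count == floor(profile$count),
                sprintf("%.0f", profile$count),
                sprintf("%.10g", profile$count))
  lines <- c(paste(.JUNCTION_TSV_HEADER, collapse = "\t"),
             if (nrow(profile) > 0L)
               paste(profile$chrom, profile$start, profile$end,
                     profile$strand, cnt, sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Write an sITH report
#'
#' Writes a tab-separated report for an [sith_pair()] result: a one-row
#' summary table (sample identifiers, sITH score, number of units used `L`,
#' dropped-unit tallies) and, optionally, a per-unit table (unit id,
#' location, member count, Jensen-Shannon divergence) separated by a blank
#' line. When no units survive filtering the sITH field is written as `NA`.
#'
#' @param result An object of class `sith_result`.
#' @param file Path or connection.
#' @param per_unit If `TRUE` (default), append the per-unit divergence table.
#' @return Invisibly, the path or connection written to.
#' @export
write_sith_report <- function(result, file, per_unit = TRUE) {
  stopifnot(inherits(result, "sith_result"))
  drop <- result$drop_log
  summary_header <- c("sample_p", "sample_q", "sith", "L",
                      paste0("dropped_", names(drop)))
  summary_row <- c(result$sample_p, result$sample_q,
                   ifelse(is.na(result$sith), "NA",
                          sprintf("%.10g", result$sith)),
                   result$L, unname(drop))
  lines <- c(paste(summary_header, collapse = "\t"),
             paste(summary_row, collapse = "\t"))
  if (per_unit && result$L > 0L) {
    ud <- result$unit_divergences
    lines <- c(lines, "",
               "unit_id\tchrom\tstrand\tn_members\tjsd",
               paste(ud$unit_id, ud$chrom, ud$strand, ud$n_members,
                     sprintf("%.10g", ud$jsd), sep = "\t"))
  }
  writeLines(lines, file)
  invisible(file)
}
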