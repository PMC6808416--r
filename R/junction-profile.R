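#' Splice-junction profile
#'
#' A junction profile is one sample's table of splice junctions with
#' supporting read counts. Each junction is an intron identified by
#' chromosome, 1-based inclusive coordinates of its first and last intronic
#' base, and a strand class (`"+"`, `"-"`, or `"."` for unknown). The
#' (chrom, start, end, strand) tuple is the junction key and must be unique
#' within a profile.
#'
#' @param junctions A data.frame with columns `chrom` (character),
#'   `start` (integer, 1-based first intronic base), `end` (integer, 1-based
#'   last intronic base), `strand` (one of `"+"`, `"-"`, `"."`), and
#'   `count` (non-negative numeric; fractional counts arise from in-silico
#'   mixtures and are allowed).
#' @param sample_id Character scalar naming the sample.
#'
#' @return An object of class `junction_profile` (a data.frame with a
#'   `sample_id` attribute), rows sorted by (chrom, start, end, strand).
#' @export
#' @examples
#' jp <- junction_profile(
#'   data.frame(chrom = "chr1", start = 101L, end = 200L,
#'              strand = "+", count = 5),
#'   sample_id = "toy")
#' jp
junction_profile <- function(junctions, sample_id = "sample") {
  required <- c("chrom", "start", "end", "strand", "count")
  missing_cols <- setdiff(required, names(junctions))
  if (length(missing_cols) > 0L) {
    stop("junction table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  jx <- as.data.frame(junctions)[required]
  jx$chrom <- as.character(jx$chrom)
  jx$start <- as.integer(jx$start)
  jx$end <- as.integer(jx$end)
  jx$strand <- as.character(jx$strand)
  jx$count <- as.numeric(jx$count)

  if (anyNA(jx$start) || anyNA(jx$end)) {
    stop("junction coordinates must be integers")
  }
  bad <- which(jx$start > jx$end)
  if (length(bad) > 0L) {
    stop("intron start > end for junction ", jx$chrom[bad[1]], ":",
         jx$start[bad[1]], "-", jx$end[bad[1]])
  }
  if (!all(jx$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  if (anyNA(jx$count) || any(jx$count < 0)) {
    stop("junction counts must be non-negative")
  }
  key <- .junction_key(jx)
  if (anyDuplicated(key)) {
    stop("duplicate junction key: ", key[duplicated(key)][1])
  }
  ord <- order(jx$chrom, jx$start, jx$end, jx$strand)
  jx <- jx[ord, , drop = FALSE]
  rownames(jx) <- NULL
  structure(jx,
            sample_id = as.character(sample_id)[1],
            class = c("junction_profile", "data.frame"))
}

.junction_key <- function(jx) {
  paste(jx$chrom, jx$start, jx$end, jx$strand, sep = "\r")
}

#' @export
print.junction_profile <- function(x, ...) {
  cat("junction_profile '", attr(x, "sample_id"), "': ",
      nrow(x), " junctions on ", length(unique(x$chrom)),
      " chromosome(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Sample identifier of a junction profile
#' @param profile A `junction_profile`.
#' @return Character scalar.
#' @export
sample_id <- function(profile) {
  attr(profile, "sample_id")
}

#' Compare two junction profiles for equality
#'
#' Profiles are equal when they contain the same junction keys with the same
#' counts (to numerical tolerance); sample identifiers are not compared.
#'
#' @param a,b `junction_profile` objects.
#' @param tolerance Numeric tolerance on counts.
#' @return Logical scalar.
#' @export
profiles_equal <- function(a, b, tolerance = 1e-9) {
  da <- as.data.frame(a)
  db <- as.data.frame(b)
  if (nrow(da) != nrow(db)) return(FALSE)
  if (!identical(.junction_key(da), .junction_key(db))) return(FALSE)
  isTRUE(all.equal(da$count, db$count, tolerance = tolerance))
}
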