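#' Construct a genome build table
#'
#' A genome build is the coordinate frame used by every other function in the
#' package: an ordered table of autosomes with chromosome lengths and
#' centromere intervals. Coordinates are 0-based half-open; the centromere
#' interval `[cen_start, cen_end)` separates the p arm `[0, cen_start)` from
#' the q arm `[cen_end, length)`.
#'
#' @param chrom character vector of unique chromosome labels.
#' @param length numeric vector of chromosome lengths in bp.
#' @param cen_start,cen_end numeric vectors delimiting each centromere.
#' @return a `data.frame` of class `genome_build` with columns
#'   `chrom`, `length`, `cen_start`, `cen_end`.
#' @export
genome_build <- function(chrom, length, cen_start, cen_end) {
  build <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                      cen_start = as.numeric(cen_start),
                      cen_end = as.numeric(cen_end),
                      stringsAsFactors = FALSE)
  class(build) <- c("genome_build", "data.frame")
  validate_build(build)
  build
}

#' Validate a genome build
#'
#' Checks the invariants `0 < cen_start < cen_end < length` and uniqueness of
#' chromosome names; errors with an informative message on violation.
#'
#' @param build a genome build table.
#' @return the build, invisibly.
#' @export
validate_build <- function(build) {
  stopifnot(is.data.frame(build),
            all(c("chrom", "length", "cen_start", "cen_end") %in% names(build)))
  if (anyDuplicated(build$chrom))
    stop("chromosome names must be unique")
  bad <- !(build$cen_start > 0 & build$cen_end > build$cen_start &
             build$length > build$cen_end)
  if (any(bad))
    stop("invalid chromosome geometry (need 0 < cen_start < cen_end < length) for: ",
         paste(build$chrom[bad], collapse = ", "))
  invisible(build)
}

#' Build a toy genome of equal-length chromosomes
#'
#' Convenience constructor for tests and simulations: `n_chrom` chromosomes of
#' identical length with a 3 Mb centromere centered at
#' `centromere_frac * chrom_length` (clipped to stay inside the chromosome).
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length chromosome length in bp (> 0).
#' @param centromere_frac centromere midpoint as a fraction of length,
#'   strictly inside (0, 1).
#' @return a `genome_build`.
#' @examples
#' make_toy_build(1, 100e6, 0.5)   # centromere [48.5 Mb, 51.5 Mb)
#' @export
make_toy_build <- function(n_chrom, chrom_length, centromere_frac = 0.5) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (chrom_length <= 0) stop("chrom_length must be positive")
  if (centromere_frac <= 0 || centromere_frac >= 1)
    stop("centromere_frac must lie strictly inside (0, 1)")
  half <- 1.5e6
  mid <- centromere_frac * chrom_length
  cs <- max(1, mid - half)
  ce <- min(chrom_length - 1, mid + half)
  genome_build(chrom = paste0("chr", seq_len(n_chrom)),
               length = rep(chrom_length, n_chrom),
               cen_start = rep(cs, n_chrom), cen_end = rep(ce, n_chrom))
}

#' The bundled hg19-like autosome table
#'
#' 22 autosomes with hg19 lengths and the conventional 3 Mb centromere gap
#' intervals, shipped as a plain-text table. This is a realistic default frame
#' for simulations; it is a stand-in, not an assay-certified reference.
#'
#' @return a `genome_build` of 22 autosomes.
#' @export
default_build <- function() {
  path <- system.file("extdata", "hg19_autosomes.tsv", package = "hrdscar")
  read_build_tsv(path)
}

#' Read / write a genome build TSV
#'
#' Tab-delimited, header `chrom length cen_start cen_end`, UTF-8,
#' 0-based half-open coordinates.
#'
#' @param path file path.
#' @return `read_build_tsv` returns a validated `genome_build`.
#' @export
read_build_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(d)))
    stop("build TSV must have columns: ", paste(need, collapse = ", "))
  genome_build(d$chrom, d$length, d$cen_start, d$cen_end)
}

#' @rdname read_build_tsv
#' @param build a `genome_build`.
#' @export
write_build_tsv <- function(build, path) {
  validate_build(build)
  d <- data.frame(chrom = build$chrom,
                  length = format(build$length, scientific = FALSE, trim = TRUE),
                  cen_start = format(build$cen_start, scientific = FALSE, trim = TRUE),
                  cen_end = format(build$cen_end, scientific = FALSE, trim = TRUE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.build_row <- function(build, chrom) {
  i <- match(chrom, build$chrom)
  if (is.na(i)) stop("chromosome not in build: ", chrom)
  build[i, ]
}

#' Split a genomic interval at the centromere
#'
#' Returns the p-arm and/or q-arm portions of `[start, end)`; any portion
#' inside the centromere interval is discarded. Needed by the TAI and
#' (arm-based) LST rules.
#'
#' @param chrom chromosome label present in `build`.
#' @param start,end 0-based half-open interval bounds, within the chromosome.
#' @param build a `genome_build`.
#' @return data.frame with columns `start`, `end`, `arm` ("p"/"q"), ordered,
#'   non-overlapping; zero rows if the interval lies wholly in the centromere.
#' @export
split_at_centromere <- function(chrom, start, end, build) {
  row <- .build_row(build, chrom)
  if (start < 0 || end > row$length || start >= end)
    stop("interval [", start, ", ", end, ") outside chromosome ", chrom)
  out <- list()
  if (start < row$cen_start)
    out[[length(out) + 1]] <- data.frame(start = start,
                                         end = min(end, row$cen_start),
                                         arm = "p", stringsAsFactors = FALSE)
  if (end > row$cen_end)
    out[[length(out) + 1]] <- data.frame(start = max(start, row$cen_end),
                                         end = end, arm = "q",
                                         stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      arm = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Generate a synthetic marker map
#'
#' Places `n_markers` unique marker positions across the build's chromosomes
#' proportionally to chromosome length (uniform within a chromosome), sorted by
#' (chrom, pos), and attaches a GC fraction drawn from a smooth low-frequency
#' sinusoid landscape per chromosome. The GC value stands for the GC content of
#' a fixed window (default 100 kb) around the marker; no reference sequence is
#' consulted.
#'
#' @param build a `genome_build`.
#' @param n_markers total marker count (>= 1).
#' @param seed integer seed; the same seed reproduces the identical map.
#' @param platform_name label stored as an attribute.
#' @param gc_window_kb window size the GC fraction notionally summarizes.
#' @return data.frame (class `marker_map`) with columns `chrom`, `pos`, `gc`.
#' @export
make_marker_map <- function(build, n_markers, seed, platform_name = "synthetic",
                            gc_window_kb = 100) {
  validate_build(build)
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (n_markers > sum(build$length)) stop("n_markers exceeds addressable positions")
  .with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_markers, build$length / sum(build$length)))
    # every chromosome must be addressable; shift overflow if a count exceeds length
    per <- lapply(seq_len(nrow(build)), function(i) {
      k <- counts[i]
      if (k == 0) return(NULL)
      pos <- sort(sample.int(build$length[i], k, replace = FALSE) - 1)
      data.frame(chrom = build$chrom[i], pos = as.numeric(pos),
                 stringsAsFactors = FALSE)
    })
    m <- do.call(rbind, per)
    # smooth GC landscape: two low-frequency sinusoids with per-chromosome phases
    phase <- matrix(runif(2 * nrow(build), 0, 2 * pi), ncol = 2)
    gi <- match(m$chrom, build$chrom)
    gc <- 0.45 +
      0.06 * sin(2 * pi * m$pos / 30e6 + phase[gi, 1]) +
      0.04 * sin(2 * pi * m$pos / 7e6 + phase[gi, 2])
    m$gc <- .clip(gc, 0.25, 0.75)
    attr(m, "platform_name") <- platform_name
    attr(m, "gc_window_kb") <- gc_window_kb
    class(m) <- c("marker_map", "data.frame")
    m
  })
}
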