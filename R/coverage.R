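#' Deletion-caller parameters
#'
#' Bundles the thresholds used throughout the read-depth pipeline: the
#' normalized-coverage fraction below which a bin counts as "low", the
#' minimum run of low bins that opens a deletion, the minimum run of
#' high bins that terminates one, the MAPQ filter applied when binning
#' alignments, the bin width, and the moving-average window used for
#' plotting.
#'
#' @param low_fraction bins with normalized coverage at or below this
#'   fraction of wild type are treated as low (default 0.1, i.e. <= 10%
#'   of the wild-type read count).
#' @param min_low_run minimum number of adjacent low bins that constitute
#'   a deletion (default 4, i.e. >= 4 Mb at the default bin size).
#' @param min_high_run minimum number of adjacent high bins required
#'   before a deletion is considered finished (default 4).
#' @param mapq_min minimum mapping quality for an alignment to be counted
#'   (default 30).
#' @param bin_size bin width in bp (default 1e6).
#' @param smoothing_window moving-average window, in bins, used for
#'   presentation only (default 4); calling always uses raw bin values.
#' @param residual_in_deletion residual coverage fraction assumed inside
#'   deletions by the simulators (default 0.02).
#' @return a list of class `caller_params`.
#' @export
caller_params <- function(low_fraction = 0.1, min_low_run = 4L, min_high_run = 4L,
                          mapq_min = 30L, bin_size = 1e6, smoothing_window = 4L,
                          residual_in_deletion = 0.02) {
  if (!is.numeric(low_fraction) || low_fraction <= 0 || low_fraction >= 1)
    stop("`low_fraction` must lie strictly between 0 and 1", call. = FALSE)
  if (min_low_run < 1 || min_high_run < 1)
    stop("`min_low_run` and `min_high_run` must be >= 1", call. = FALSE)
  if (bin_size <= 0) stop("`bin_size` must be positive", call. = FALSE)
  if (mapq_min < 0) stop("`mapq_min` must be non-negative", call. = FALSE)
  if (smoothing_window < 1) stop("`smoothing_window` must be >= 1", call. = FALSE)
  if (residual_in_deletion < 0 || residual_in_deletion >= 1)
    stop("`residual_in_deletion` must lie in [0, 1)", call. = FALSE)
  structure(list(
    low_fraction = low_fraction,
    min_low_run = as.integer(min_low_run),
    min_high_run = as.integer(min_high_run),
    mapq_min = as.integer(mapq_min),
    bin_size = bin_size,
    smoothing_window = as.integer(smoothing_window),
    residual_in_deletion = residual_in_deletion
  ), class = "caller_params")
}

new_binned_coverage <- function(bins, line_id, bin_size, total_reads) {
  structure(list(
    line_id = line_id,
    bin_size = bin_size,
    total_reads = total_reads,
    bins = bins
  ), class = "binned_coverage")
}

validate_bin_structure <- function(bins, bin_size) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  if (any(bins$end <= bins$start)) stop("bins must have end > start", call. = FALSE)
  if (any(bins$end - bins$start > bin_size + 1e-9))
    stop("bin width exceeds bin_size", call. = FALSE)
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))
      stop("bins on ", ch, " are not contiguous/non-overlapping", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build fixed-width genome bins
#'
#' @param chrom_lengths data frame with columns `chrom` and `length` (bp).
#' @param bin_size bin width in bp.
#' @return data frame of half-open bins `(chrom, start, end)`; the final
#'   bin of each chromosome (or chromosome part) is truncated at the
#'   chromosome length and may be shorter than `bin_size`.
#' @export
make_bins <- function(chrom_lengths, bin_size = 1e6) {
  stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
  out <- lapply(seq_len(nrow(chrom_lengths)), function(i) {
    len <- chrom_lengths$length[i]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    data.frame(chrom = chrom_lengths$chrom[i], start = start,
               end = pmin(start + bin_size, len))
  })
  do.call(rbind, out)
}

#' Bin read placements into fixed-width coverage bins
#'
#' Counts retained alignments per half-open bin `[start, end)`. A
#' placement is retained when its mapping quality is at least
#' `params$mapq_min` and its `proper` flag is `TRUE`; each retained
#' placement increments exactly one bin, chosen by its (0-based) start
#' position.
#'
#' @param placements data frame with columns `chrom`, `pos` (0-based
#'   alignment start), `mapq`, and optionally `proper` (logical; defaults
#'   to `TRUE` when absent). A `proper` of `FALSE` marks reads excluded
#'   upstream (non-primary, improper pair, or duplicate-marked).
#' @param chrom_lengths data frame with columns `chrom`, `length`; must
#'   cover every chromosome named in `placements`.
#' @param params a [caller_params()] object.
#' @param line_id label for the sequenced line.
#' @return a `binned_coverage` object; `total_reads` equals the number of
#'   retained placements.
#' @export
bin_alignments <- function(placements, chrom_lengths, params = caller_params(),
                           line_id = "line") {
  stopifnot(all(c("chrom", "pos", "mapq") %in% names(placements)))
  if (is.null(placements$proper)) placements$proper <- TRUE
  if (any(placements$pos < 0)) stop("placement positions must be >= 0", call. = FALSE)
  if (any(placements$mapq < 0)) stop("MAPQ must be >= 0", call. = FALSE)
  missing_chr <- setdiff(unique(placements$chrom), chrom_lengths$chrom)
  if (length(missing_chr))
    stop("chromosome(s) absent from chrom_lengths: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  len <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  bad <- placements$pos >= len[placements$chrom]
  if (any(bad)) {
    i <- which(bad)[1]
    stop("placement beyond chromosome length: ", placements$chrom[i],
         " position ", placements$pos[i], call. = FALSE)
  }
  keep <- placements$mapq >= params$mapq_min & placements$proper
  kept <- placements[keep, , drop = FALSE]
  bins <- make_bins(chrom_lengths, params$bin_size)
  key <- paste(bins$chrom, bins$start %/% params$bin_size)
  hit <- paste(kept$chrom, kept$pos %/% params$bin_size)
  bins$count <- as.integer(table(factor(hit, levels = key))[key])
  bins$count[is.na(bins$count)] <- 0L
  new_binned_coverage(bins, line_id, params$bin_size, sum(bins$count))
}

#' Normalize mutant coverage against a wild-type line
#'
#' Two-step normalization: each bin count is first divided by the total
#' retained read count of its own line, then by the corresponding
#' within-line value of the reference (wild-type) line. Bins where the
#' reference has zero reads (no capture signal) are masked (`NA` value)
#' rather than set to zero, so probe-free regions cannot masquerade as
#' deletions.
#'
#' @param mutant,reference `binned_coverage` objects with identical bin
#'   structure and positive `total_reads`.
#' @return a `normalized_coverage` object whose `bins` carry the mutant
#'   `count`, the normalized `value`, and a `masked` flag.
#' @export
normalize_coverage <- function(mutant, reference) {
  stopifnot(inherits(mutant, "binned_coverage"), inherits(reference, "binned_coverage"))
  mb <- mutant$bins; rb <- reference$bins
  if (nrow(mb) != nrow(rb) ||
      !all(mb$chrom == rb$chrom & mb$start == rb$start & mb$end == rb$end)) {
    diff_at <- if (nrow(mb) == nrow(rb)) {
      which(mb$chrom != rb$chrom | mb$start != rb$start | mb$end != rb$end)[1]
    } else min(nrow(mb), nrow(rb)) + 1L
    stop("bin structures differ (first difference at bin ", diff_at, ")",
         call. = FALSE)
  }
  if (mutant$total_reads <= 0 || reference$total_reads <= 0)
    stop("both lines must have total_reads > 0", call. = FALSE)
  masked <- rb$count == 0
  value <- (mb$count / mutant$total_reads) / (rb$count / reference$total_reads)
  value[masked] <- NA_real_
  bins <- data.frame(chrom = mb$chrom, start = mb$start, end = mb$end,
                     count = mb$count, value = value, masked = masked)
  structure(list(
    line_id = mutant$line_id,
    reference_line_id = reference$line_id,
    bin_size = mutant$bin_size,
    bins = bins
  ), class = "normalized_coverage")
}

#' Moving average over an ordered series of bin values
#'
#' Window-start aligned: element `i` of the output is the mean of inputs
#' `i .. i + window - 1`. `NA` (masked) entries are excluded from each
#' window mean; a window containing only masked entries yields `NA`.
#' Intended for presentation; deletion calling always uses raw values.
#'
#' @param values numeric vector, `NA` marking masked bins.
#' @param window window size in bins (>= 1).
#' @return numeric vector of length `length(values) - window + 1`.
#' @export
moving_average <- function(values, window = 4L) {
  window <- as.integer(window)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  n <- length(values)
  if (n < window)
    stop("series length (", n, ") is shorter than window (", window, ")",
         call. = FALSE)
  ok <- !is.na(values)
  v <- ifelse(ok, values, 0)
  cs <- cumsum(c(0, v))
  cn <- cumsum(c(0, ok))
  i <- seq_len(n - window + 1L)
  s <- cs[i + window] - cs[i]
  k <- cn[i + window] - cn[i]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

## ---- parts <-> full pseudomolecule coordinate lifting -----------------------

lift_table <- function(parts) {
  stopifnot(all(c("part1_id", "part2_id", "full_id", "part1_length") %in% names(parts)))
  if (any(parts$part1_length <= 0))
    stop("part1_length must be positive", call. = FALSE)
  ids <- c(parts$part1_id, parts$part2_id)
  if (anyDuplicated(ids))
    stop("each part id must map to exactly one full chromosome", call. = FALSE)
  data.frame(part = ids,
             full = c(parts$full_id, parts$full_id),
             offset = c(rep(0, nrow(parts)), parts$part1_length))
}

lift_frame <- function(df, parts, cols = c("start", "end"), reverse = FALSE) {
  lt <- lift_table(parts)
  if (!reverse) {
    known <- df$chrom %in% lt$part | df$chrom %in% parts$full_id
    if (!all(known))
      stop("unknown part id(s): ", paste(unique(df$chrom[!known]), collapse = ", "),
           call. = FALSE)
    idx <- match(df$chrom, lt$part)
    off <- ifelse(is.na(idx), 0, lt$offset[idx])
    for (cl in cols) df[[cl]] <- df[[cl]] + off
    df$chrom <- ifelse(is.na(idx), df$chrom, lt$full[idx])
  } else {
    known <- df$chrom %in% parts$full_id
    if (!all(known))
      stop("unknown full chromosome id(s): ",
           paste(unique(df$chrom[!known]), collapse = ", "), call. = FALSE)
    i <- match(df$chrom, parts$full_id)
    p1 <- parts$part1_length[i]
    on2 <- df[[cols[1]]] >= p1
    off <- ifelse(on2, p1, 0)
    for (cl in cols) df[[cl]] <- df[[cl]] - off
    df$chrom <- ifelse(on2, parts$part2_id[i], parts$part1_id[i])
  }
  ord <- order(match(df$chrom, unique(df$chrom)), df[[cols[1]]])
  df[ord, , drop = FALSE]
}

#' Lift coverage or calls from parts to full pseudomolecule coordinates
#'
#' Part-1 coordinates are unchanged; part-2 coordinates are shifted by
#' `part1_length`. Because the terminal bin of part 1 is usually shorter
#' than the bin size, lifted bin boundaries on the second half of a
#' chromosome are offset from whole multiples of the bin size.
#' Chromosome ids already in full coordinates pass through unchanged.
#'
#' @param x a `binned_coverage`, `normalized_coverage`, or data frame of
#'   intervals with columns `chrom`, `start`, `end` (e.g. deletion calls).
#' @param parts data frame with columns `part1_id`, `part2_id`, `full_id`,
#'   `part1_length`.
#' @return object of the same kind in full-chromosome coordinates.
#' @seealso [lift_full_to_parts()] for the inverse.
#' @export
lift_parts_to_full <- function(x, parts) {
  if (inherits(x, "binned_coverage") || inherits(x, "normalized_coverage")) {
    x$bins <- lift_frame(x$bins, parts, reverse = FALSE)
    rownames(x$bins) <- NULL
    x
  } else if (is.data.frame(x)) {
    out <- lift_frame(x, parts, reverse = FALSE)
    rownames(out) <- NULL
    out
  } else stop("cannot lift object of class ", class(x)[1], call. = FALSE)
}

#' Lift coverage or calls from full back to parts coordinates
#'
#' Inverse of [lift_parts_to_full()]: intervals starting at or beyond
#' `part1_length` are assigned to part 2 and shifted back.
#'
#' @inheritParams lift_parts_to_full
#' @return object of the same kind in parts coordinates.
#' @export
lift_full_to_parts <- function(x, parts) {
  if (inherits(x, "binned_coverage") || inherits(x, "normalized_coverage")) {
    x$bins <- lift_frame(x$bins, parts, reverse = TRUE)
    rownames(x$bins) <- NULL
    x
  } else if (is.data.frame(x)) {
    out <- lift_frame(x, parts, reverse = TRUE)
    rownames(out) <- NULL
    out
  } else stop("cannot lift object of class ", class(x)[1], call. = FALSE)
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat("Binned coverage:", x$line_id, "\n")
  cat("  bins:", nrow(x$bins), "of", format(x$bin_size, big.mark = ","),
      "bp on", length(unique(x$bins$chrom)), "chromosome(s)\n")
  cat("  total retained reads:", format(x$total_reads, big.mark = ","), "\n")
  invisible(x)
}

#' @export
print.normalized_coverage <- function(x, ...) {
  cat("Normalized coverage:", x$line_id, "vs", x$reference_line_id, "\n")
  cat("  bins:", nrow(x$bins), " masked:", sum(x$bins$masked), "\n")
  cat("  value range:", paste(signif(range(x$bins$value, na.rm = TRUE), 3),
                              collapse = " .. "), "\n")
  invisible(x)
}
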