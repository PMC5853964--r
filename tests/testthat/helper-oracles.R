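# Independent oracles and small constructors used across the suite.

# Brute-force formulation of the run rules, independent of the package's
# state-machine scanner: split the profile at maximal high runs of length
# >= min_high (terminators); within each segment a call starts at the
# first low run of length >= min_low and ends at the segment's last low
# bin.
oracle_calls <- function(low, min_low = 4L, min_high = 4L) {
  n <- length(low)
  r <- rle(!low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= min_high
  seg_start <- c(1L, ends[hit] + 1L)
  seg_end <- c(starts[hit] - 1L, n)
  out <- NULL
  for (k in seq_along(seg_start)) {
    a <- seg_start[k]; b <- seg_end[k]
    if (a > b) next
    lows <- low[a:b]
    rr <- rle(lows)
    e2 <- cumsum(rr$lengths)
    s2 <- e2 - rr$lengths + 1L
    q <- which(rr$values & rr$lengths >= min_low)
    if (!length(q)) next
    out <- rbind(out, c(a + s2[q[1]] - 1L, a + max(which(lows)) - 1L))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Build a normalized_coverage object directly from a value vector
# (NA = masked bin), one chromosome, 1 Mb bins.
nc_from_values <- function(values, bin_size = 1e6, chrom = "chr1",
                           line = "mut") {
  n <- length(values)
  bins <- data.frame(chrom = rep(chrom, n), start = (seq_len(n) - 1) * bin_size,
                     end = seq_len(n) * bin_size,
                     count = rep(NA_integer_, n), value = values,
                     masked = is.na(values))
  structure(list(line_id = line, reference_line_id = "wt",
                 bin_size = bin_size, bins = bins),
            class = "normalized_coverage")
}

bc_from_counts <- function(counts, bin_size = 1e6, chrom = "chr1",
                           line = "line") {
  n <- length(counts)
  bins <- data.frame(chrom = rep(chrom, n), start = (seq_len(n) - 1) * bin_size,
                     end = seq_len(n) * bin_size, count = as.integer(counts))
  delscan:::new_binned_coverage(bins, line, bin_size, sum(counts))
}

# Reduced two-chromosome spec (the homoeologous group-4 deletions) used
# for gene-model simulations.
group4_spec <- function() {
  full <- paragon_layout()
  genome_spec(full$chromosomes[full$chromosomes$chrom %in% c("chr4A", "chr4D"), ],
              full$deletions[full$deletions$chrom %in% c("chr4A", "chr4D"), ])
}

# The published per-line deletion-extent classifications implied by the
# screening narrative: lines giving a product with the anchor but no
# other marker have a distal deletion not including the anchor; lines
# lacking every product span all markers; the line lacking only the
# anchor product is anchor_only.
published_line_classes <- c(
  A1 = "distal_not_including_anchor",
  A2 = "spans_all_markers",
  A3 = "spans_all_markers",
  D1 = "distal_not_including_anchor",
  D2 = "distal_not_including_anchor",
  D3 = "spans_all_markers",
  D4 = "spans_all_markers",
  D5 = "anchor_only"
)
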