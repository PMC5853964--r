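## Readers and writers. Internal coordinates are 0-based half-open
## everywhere; 1-based formats (GFF3) are converted at the boundary.

#' Read binned coverage or read placements
#'
#' `dialect = "bedgraph"`: 4-column bedGraph (chrom, start, end, count;
#' 0-based half-open), `#` comment and `track` lines skipped. Intervals
#' must be non-overlapping and contiguous within each chromosome and
#' counts non-negative integers.
#' `dialect = "placements"`: TSV with columns `chrom`, `pos`, `mapq`,
#' `proper` (logical), returned as a placements data frame for
#' [bin_alignments()].
#'
#' @param path input file.
#' @param dialect `"bedgraph"` or `"placements"`.
#' @param line_id label for the line (bedgraph dialect).
#' @return a `binned_coverage` (bedgraph) or a placements data frame.
#' @export
read_coverage <- function(path, dialect = c("bedgraph", "placements"),
                          line_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(line_id)) line_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|$)", raw)
  lineno <- which(keep)
  if (!length(lineno)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(raw[keep], "\\s+")
  ncol_want <- if (dialect == "bedgraph") 4L else NA
  if (dialect == "bedgraph") {
    bad <- which(lengths(fields) < 4L)
    if (length(bad))
      stop("malformed line ", lineno[bad[1]], " in ", path,
           ": expected 4 columns", call. = FALSE)
    df <- data.frame(
      chrom = vapply(fields, `[[`, "", 1),
      start = as.numeric(vapply(fields, `[[`, "", 2)),
      end = as.numeric(vapply(fields, `[[`, "", 3)),
      count = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4))),
      stringsAsFactors = FALSE)
    bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$count))
    if (length(bad))
      stop("malformed line ", lineno[bad[1]], " in ", path, call. = FALSE)
    if (any(df$count < 0))
      stop("negative count at line ", lineno[which(df$count < 0)[1]], " in ",
           path, call. = FALSE)
    if (any(df$end <= df$start))
      stop("interval with end <= start at line ",
           lineno[which(df$end <= df$start)[1]], " in ", path, call. = FALSE)
    for (ch in unique(df$chrom)) {
      b <- df[df$chrom == ch, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
        stop("overlapping intervals on ", ch, " in ", path, call. = FALSE)
    }
    bin_size <- max(df$end - df$start)
    validate_bin_structure(df, bin_size)
    df$count <- as.integer(df$count)
    new_binned_coverage(df, line_id, bin_size, sum(df$count))
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "mapq")
    if (!all(need %in% names(df)))
      stop("placements TSV needs columns chrom, pos, mapq", call. = FALSE)
    if (is.null(df$proper)) df$proper <- TRUE
    df$proper <- as.logical(df$proper)
    df
  }
}

#' Write binned coverage as 4-column bedGraph
#'
#' Emits `chrom`, `start`, `end`, `count` (0-based half-open), readable
#' back with [read_coverage()].
#'
#' @param x a `binned_coverage`.
#' @param path output file.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "binned_coverage"))
  df <- x$bins[, c("chrom", "start", "end", "count")]
  write.table(format(df, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write binned or normalized coverage as TSV
#'
#' Columns: `line_id`, `chrom`, `start`, `end`, `count`, and for
#' normalized coverage additionally `normalized_value` and `masked`.
#' Readable back with [read_coverage_tsv()].
#'
#' @param x a `binned_coverage` or `normalized_coverage`.
#' @param path output file.
#' @export
write_coverage <- function(x, path) {
  if (inherits(x, "binned_coverage")) {
    df <- cbind(line_id = x$line_id, x$bins)
  } else if (inherits(x, "normalized_coverage")) {
    df <- data.frame(line_id = x$line_id, chrom = x$bins$chrom,
                     start = x$bins$start, end = x$bins$end,
                     count = x$bins$count,
                     normalized_value = x$bins$value, masked = x$bins$masked)
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
  write.table(format(df, scientific = FALSE, trim = TRUE, digits = 15), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coverage TSV written by [write_coverage()]
#'
#' @param path input file.
#' @return a `binned_coverage` or `normalized_coverage`, depending on
#'   the columns present.
#' @export
read_coverage_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  line_id <- unique(df$line_id)
  bin_size <- max(df$end - df$start)
  if ("normalized_value" %in% names(df)) {
    bins <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                       count = df$count,
                       value = suppressWarnings(as.numeric(df$normalized_value)),
                       masked = as.logical(df$masked))
    structure(list(line_id = line_id, reference_line_id = "reference",
                   bin_size = bin_size, bins = bins),
              class = "normalized_coverage")
  } else {
    bins <- df[, c("chrom", "start", "end", "count")]
    new_binned_coverage(bins, line_id, bin_size, sum(bins$count))
  }
}

#' Read or write a chromosome parts map
#'
#' TSV with columns `part1_id`, `part2_id`, `full_id`, `part1_length`.
#'
#' @param path file path.
#' @return data frame (reader); invisibly the path (writer).
#' @export
read_parts_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("part1_id", "part2_id", "full_id", "part1_length")
  if (!all(need %in% names(df)))
    stop("parts map needs columns ", paste(need, collapse = ", "), call. = FALSE)
  lift_table(df)  # validates
  df
}

#' @rdname read_parts_map
#' @param parts parts-map data frame.
#' @export
write_parts_map <- function(parts, path) {
  write.table(format(parts, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 `gene` features (all features when none are typed `gene`) or
#' BED intervals, via `rtracklayer`. GFF3 1-based closed coordinates
#' are converted to the package's 0-based half-open convention; BED is
#' already 0-based half-open. A `confidence` attribute is honoured when
#' present (else `"high"`), as is a logical `wildtype_covered` attribute
#' (else `TRUE`).
#'
#' @param path input file; format chosen by extension (`.gff`, `.gff3`
#'   vs `.bed`).
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `confidence`, `wildtype_covered`.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  first <- readLines(path, n = 1)
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) gr$ID else
      if (!is.null(gr$Name)) gr$Name else paste0("gene", seq_along(gr))
  } else if (ext == "bed") {
    if (grepl("^##gff", first))
      stop("file ", path, " has a .bed extension but GFF content", call. = FALSE)
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
  } else stop("unrecognized gene-model format: .", ext, call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  conf <- if ("confidence" %in% names(mc)) as.character(mc$confidence) else "high"
  cov <- if ("wildtype_covered" %in% names(mc)) {
    as.logical(mc$wildtype_covered)
  } else TRUE
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
             end = GenomicRanges::end(gr),
             confidence = conf, wildtype_covered = cov,
             stringsAsFactors = FALSE)
}

#' Write or read deletion calls as TSV
#'
#' Columns mirror the published deletion table: `line_id`, `chrom`,
#' `start`, `end`, `size_bp`, `n_low_bins`, `method`, `flags`.
#'
#' @param calls a `deletion_calls` data frame.
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  write.table(format(as.data.frame(calls), scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "")
  df$flags[is.na(df$flags)] <- ""
  class(df) <- c("deletion_calls", "data.frame")
  df
}

#' Read a marker panel or marker observations TSV
#'
#' Panel columns: `marker_id`, `order_index` (plus optional `arm`,
#' `genome`, `chrom`, `pos`). Observation columns: `plant_id`,
#' `marker_id`, `call`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_marker_panel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("marker_id", "order_index") %in% names(df)))
    stop("marker panel needs columns marker_id, order_index", call. = FALSE)
  df
}

#' @rdname read_marker_panel
#' @export
read_marker_observations <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("plant_id", "marker_id", "call") %in% names(df)))
    stop("observations need columns plant_id, marker_id, call", call. = FALSE)
  df
}
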