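## Published reference tables for the Paragon gamma-irradiation deletion
## mutants A1 and D4, plus a synthetic genome layout that reproduces
## their deletion architecture for simulation. Chromosome lengths for
## 1B and 4B are fixed by deletions that run to the chromosome end; the
## remaining lengths and all part1 split points are synthetic, chosen so
## every bin-method deletion interval is representable as whole bins
## after the parts-to-full coordinate lift.

#' Published deletion coordinates for Paragon lines A1 and D4
#'
#' The reported large deletions of the two gamma-irradiated Paragon
#' lines, at 1 Mb bin resolution (`method = "bin"`) or refined against
#' the gene models flanking each border (`method = "refined"`).
#' Coordinates are 0-based half-open; the printed size equals
#' `end - start` in every row.
#'
#' @param method `"bin"` or `"refined"`.
#' @return data frame with columns `line_id`, `chrom`, `start`, `end`,
#'   `size_bp`.
#' @export
paragon_deletions <- function(method = c("bin", "refined")) {
  method <- match.arg(method)
  bin <- data.frame(
    line_id = c(rep("A1", 4), rep("D4", 6)),
    chrom = c("chr1B", "chr4A", "chr5D", "chr6A",
              "chr1A", "chr1B", "chr4B", "chr4D", "chr6D", "chr7A"),
    start = c(182000000, 576555092, 422000000, 262000000,
              105000000, 640720154, 563014251, 0, 177000000, 332000000),
    end = c(190000000, 600555092, 440000000, 274000000,
            110000000, 689851870, 673617499, 21000000, 181000000, 336000000),
    size_bp = c(8000000, 24000000, 18000000, 12000000,
                5000000, 49131716, 110603248, 21000000, 4000000, 4000000),
    stringsAsFactors = FALSE)
  refined <- data.frame(
    line_id = c(rep("A1", 4), rep("D4", 6)),
    chrom = c("chr1B", "chr4A", "chr5D", "chr6A",
              "chr1A", "chr1B", "chr4B", "chr4D", "chr6D", "chr7A"),
    start = c(181218604, 576167498, 421138884, 260435891,
              104949904, 640164065, 562939364, 0, 176481122, 330452708),
    end = c(190284536, 601039825, 441103787, 276294537,
            110279278, 689851870, 673617499, 21516171, 181405837, 336755079),
    size_bp = c(9065932, 24872327, 19964903, 15858646,
                5329374, 49687805, 110678135, 21516171, 4924715, 6302371),
    stringsAsFactors = FALSE)
  if (method == "bin") bin else refined
}

#' Synthetic genome layout emulating the Paragon A1/D4 mutants
#'
#' A [genome_spec()] whose planted deletions are the published
#' bin-method intervals of lines A1 (four deletions) and D4 (six
#' deletions). Chromosome part splits are chosen so each interval maps
#' exactly onto whole 1 Mb bins after [lift_parts_to_full()], including
#' the intervals with uneven boundaries inherited from the shifted
#' second-half bins.
#'
#' @param artifact_6b also plant a shared low-coverage region on
#'   chromosome 6B (~258-263 Mb) in *both* lines, mimicking the
#'   background Paragon/Chinese Spring polymorphism that causes read
#'   misalignment in every line; useful for testing
#'   [flag_shared_calls()] (default `FALSE`).
#' @return a `genome_spec` with lines `A1` and `D4`.
#' @export
paragon_layout <- function(artifact_6b = FALSE) {
  chromosomes <- data.frame(
    chrom = c("chr1A", "chr1B", "chr4A", "chr4B", "chr4D",
              "chr5D", "chr6A", "chr6B", "chr6D", "chr7A"),
    length = c(594102056, 689851870, 744588157, 673617499, 509857067,
               566080677, 618079260, 720988478, 473592718, 736706236),
    part1_length = c(299326595, 453720154, 377555092, 352014251, 283463349,
                     451856684, 336174716, 350935606, 291783914, 407378954),
    stringsAsFactors = FALSE)
  dels <- paragon_deletions("bin")[, c("line_id", "chrom", "start", "end")]
  if (artifact_6b) {
    dels <- rbind(dels,
                  data.frame(line_id = c("A1", "D4"), chrom = "chr6B",
                             start = 258000000, end = 263000000,
                             stringsAsFactors = FALSE))
  }
  genome_spec(chromosomes, dels)
}

#' Published dominant-marker screening table (Paragon deletion lines)
#'
#' Marker calls for the 19 plants screened across the 4AL and 4DS
#' *Bgc-1* regions. Markers are ordered along each arm (most distal
#' first): TC37b, KT71, TC30b, TC34, 4G, with the D-genome-specific
#' 4N5.5 proximal to 4G on 4DS only. Calls: `present`, `absent`,
#' `faint`, or `nd` (not determined).
#'
#' @return long-format data frame: `arm`, `line`, `plant_id`,
#'   `marker_id`, `call`.
#' @export
paragon_marker_observations <- function() {
  m4al <- c("TC37b", "KT71", "TC30b", "TC34", "4G")
  m4ds <- c(m4al, "4N5.5")
  row <- function(arm, line, plant, calls) {
    markers <- if (arm == "4AL") m4al else m4ds
    data.frame(arm = arm, line = line,
               plant_id = paste(line, plant, sep = "_"),
               marker_id = markers, call = calls, stringsAsFactors = FALSE)
  }
  a <- "absent"; p <- "present"; f <- "faint"; nd <- "nd"
  do.call(rbind, list(
    row("4AL", "A1", 1, c(a, a, a, a, p)),
    row("4AL", "A1", 2, c(f, a, f, a, p)),
    row("4AL", "A2", 1, c(a, a, a, a, a)),
    row("4AL", "A2", 2, c(f, a, a, a, a)),
    row("4AL", "A2", 3, c(a, a, f, a, a)),
    row("4AL", "A2", 4, c(a, a, a, a, a)),
    row("4AL", "A3", 1, c(a, a, a, a, a)),
    row("4AL", "A3", 2, c(a, a, a, a, a)),
    row("4DS", "D1", 1, c(a, a, f, a, p, nd)),
    row("4DS", "D1", 2, c(a, a, f, a, p, nd)),
    row("4DS", "D2", 1, c(a, a, a, a, p, nd)),
    row("4DS", "D3", 1, c(a, a, a, a, a, a)),
    row("4DS", "D4", 1, c(a, a, a, a, a, a)),
    row("4DS", "D4", 2, c(a, a, a, a, a, a)),
    row("4DS", "D4", 3, c(a, a, a, a, a, a)),
    row("4DS", "D4", 4, c(f, a, a, a, a, a)),
    row("4DS", "D5", 1, c(p, p, p, p, a, p)),
    row("4DS", "D5", 2, c(p, p, p, p, a, p)),
    row("4DS", "D5", 3, c(p, p, p, p, a, p))
  ))
}

#' Marker panels for the 4AL and 4DS screening assays
#'
#' Ordered marker panels matching [paragon_marker_observations()]. The
#' anchor marker in both panels is 4G (the assay flanking the locus of
#' interest); all other markers lie distal to it, except the
#' D-genome-specific 4N5.5 which lies proximal.
#'
#' @param arm `"4AL"` or `"4DS"`.
#' @return data frame with columns `marker_id`, `arm`, `order_index`.
#' @export
paragon_marker_panel <- function(arm = c("4AL", "4DS")) {
  arm <- match.arg(arm)
  ids <- c("TC37b", "KT71", "TC30b", "TC34", "4G")
  if (arm == "4DS") ids <- c(ids, "4N5.5")
  data.frame(marker_id = ids, arm = arm, order_index = seq_along(ids),
             stringsAsFactors = FALSE)
}

#' Synthetic marker positions on the A1/D4 layout
#'
#' Places the 4AL panel inside the planted chr4A deletion of line A1
#' with the anchor 4G just beyond its border (so line A1 classifies as
#' a distal deletion not including the anchor), and the 4DS panel
#' entirely inside the chr4D deletion of line D4 (so D4 classifies as
#' spanning all markers) — reproducing the screening outcomes of the
#' two sequenced lines.
#'
#' @return data frame with columns `marker_id`, `arm`, `order_index`,
#'   `chrom`, `pos`.
#' @export
synthetic_marker_positions <- function() {
  p4al <- paragon_marker_panel("4AL")
  p4al$chrom <- "chr4A"
  p4al$pos <- c(580e6, 584e6, 588e6, 592e6, 601.5e6)
  p4ds <- paragon_marker_panel("4DS")
  p4ds$chrom <- "chr4D"
  p4ds$pos <- c(3e6, 6e6, 9e6, 12e6, 15e6, 19e6)
  p4al$marker_id <- paste0(p4al$marker_id, "_4A")
  p4ds$marker_id <- paste0(p4ds$marker_id, "_4D")
  rbind(p4al, p4ds)
}

#' Published F2 screening outcome for the A x D deletion crosses
#'
#' Of 457 F2 plants screened with the multiplex marker, one carried
#' homozygous deletions on both 4AL and 4DS.
#'
#' @return list with `total_screened` and `double_mutants`.
#' @export
paragon_f2_counts <- function() {
  list(total_screened = 457L, double_mutants = 1L)
}
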