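## Dominant PCR-marker genotyping. Markers are dominant: presence of a
## product cannot separate homozygous wild type from heterozygotes, so
## only homozygous deletions are identifiable.

#' Interpret a dominant PCR-marker call
#'
#' Absence of a PCR product, or near absence (a faint band), indicates a
#' putative deletion; a clear product indicates the gene is present. A
#' call recorded as not determined (`"nd"`) yields `NA`.
#'
#' @param call character vector of calls among `present`, `absent`,
#'   `faint`, `nd` (case-insensitive).
#' @return logical vector: `TRUE` when the marker region is putatively
#'   deleted, `NA` for not-determined calls.
#' @export
interpret_call <- function(call) {
  x <- tolower(as.character(call))
  known <- c("present", "absent", "faint", "nd")
  if (any(!x %in% known))
    stop("unknown marker call(s): ",
         paste(unique(call[!x %in% known]), collapse = ", "),
         " (expected present/absent/faint/nd)", call. = FALSE)
  out <- x %in% c("absent", "faint")
  out[x == "nd"] <- NA
  out
}

classify_deleted_pattern <- function(deleted, anchor_idx) {
  idx <- which(deleted)
  if (!length(idx)) return("no_deletion")
  if (length(idx) > 1 && any(diff(idx) != 1L)) return("inconsistent")
  if (length(idx) == length(deleted)) return("spans_all_markers")
  if (identical(idx, anchor_idx)) return("anchor_only")
  if (idx[1] == 1L && !(anchor_idx %in% idx)) return("distal_not_including_anchor")
  "interstitial"
}

#' Infer deletion extent from an ordered marker panel
#'
#' Given dominant-marker calls for one plant over a panel ordered along
#' the chromosome arm (most distal first), classifies the implied
#' deletion under the single-contiguous-deletion assumption. The anchor
#' marker is the assay closest to the locus of interest; a deletion that
#' removes every marker distal to the anchor but leaves the anchor
#' intact is classed `distal_not_including_anchor`.
#'
#' Classes: `no_deletion`, `spans_all_markers`,
#' `distal_not_including_anchor`, `anchor_only`, `interstitial`
#' (any other contiguous block), and `inconsistent` (non-contiguous
#' deleted markers, violating the single-deletion assumption).
#' Not-determined (`nd`) observations are excluded from inference.
#'
#' @param panel data frame with columns `marker_id` and `order_index`
#'   (unique; position along the arm, distal to proximal).
#' @param observations data frame with columns `marker_id` and `call`
#'   for a single plant (optionally `plant_id`, which must be unique);
#'   every panel marker must be observed.
#' @param anchor_marker `marker_id` of the anchor assay.
#' @return list of class `deletion_hypothesis` with fields `plant_id`,
#'   `classification`, `deleted_marker_ids`, and `low_confidence`
#'   (`TRUE` when any deleted call was only faint).
#' @export
infer_deletion_extent <- function(panel, observations, anchor_marker) {
  stopifnot(all(c("marker_id", "order_index") %in% names(panel)))
  if (anyDuplicated(panel$order_index))
    stop("panel order_index values must be unique", call. = FALSE)
  if (!anchor_marker %in% panel$marker_id)
    stop("anchor marker ", anchor_marker, " not in panel", call. = FALSE)
  plant <- if (!is.null(observations$plant_id)) unique(observations$plant_id) else "plant"
  if (length(plant) > 1)
    stop("observations contain multiple plants; classify one plant at a time",
         call. = FALSE)
  p <- panel[order(panel$order_index), , drop = FALSE]
  miss <- setdiff(p$marker_id, observations$marker_id)
  if (length(miss))
    stop("missing observation for marker(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  calls <- observations$call[match(p$marker_id, observations$marker_id)]
  deleted <- interpret_call(calls)
  keep <- !is.na(deleted)
  p <- p[keep, , drop = FALSE]
  deleted <- deleted[keep]
  calls <- calls[keep]
  anchor_idx <- match(anchor_marker, p$marker_id)
  if (is.na(anchor_idx))
    stop("anchor marker ", anchor_marker, " not determined for this plant",
         call. = FALSE)
  cls <- classify_deleted_pattern(deleted, anchor_idx)
  structure(list(
    plant_id = plant,
    arm = if (!is.null(panel$arm)) unique(panel$arm)[1] else NA_character_,
    classification = cls,
    deleted_marker_ids = p$marker_id[deleted],
    low_confidence = any(tolower(calls[deleted]) == "faint")
  ), class = "deletion_hypothesis")
}

#' @export
print.deletion_hypothesis <- function(x, ...) {
  cat("Deletion hypothesis for", x$plant_id, "\n")
  cat("  class:", x$classification,
      if (isTRUE(x$low_confidence)) "(low confidence: faint calls)" else "", "\n")
  cat("  deleted markers:",
      if (length(x$deleted_marker_ids)) paste(x$deleted_marker_ids, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Classify every plant of a marker screening table
#'
#' Convenience wrapper applying [infer_deletion_extent()] to each plant
#' of a long-format observation table.
#'
#' @param panel marker panel (see [infer_deletion_extent()]).
#' @param observations data frame with columns `plant_id`, `marker_id`,
#'   `call`.
#' @param anchor_marker anchor `marker_id`.
#' @return data frame with one row per plant: `plant_id`,
#'   `classification`, `deleted_markers` (comma separated),
#'   `low_confidence`.
#' @export
classify_marker_table <- function(panel, observations, anchor_marker) {
  plants <- unique(observations$plant_id)
  rows <- lapply(plants, function(pl) {
    h <- infer_deletion_extent(panel,
                               observations[observations$plant_id == pl, , drop = FALSE],
                               anchor_marker)
    data.frame(plant_id = pl, classification = h$classification,
               deleted_markers = paste(h$deleted_marker_ids, collapse = ","),
               low_confidence = h$low_confidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genotype a multiplex (homoeologue-non-specific) marker
#'
#' A multiplex assay amplifies one size-polymorphic product per gene
#' copy (here A1 and A2 on the A genome, plus B and D), separated by
#' capillary electrophoresis. Absence of the peak(s) for one genome, or
#' a very small peak relative to the others, indicates a putative
#' homozygous deletion on that genome. The A genome is called deleted
#' only when *both* A-genome products are missing. Because the marker is
#' dominant, heterozygotes are indistinguishable from wild type: the
#' call is homozygous-deletion-or-not, never heterozygous.
#'
#' @param products named vector with elements `A1`, `A2`, `B`, `D`:
#'   either character calls among `present`, `absent`, `very_small`, or
#'   numeric peak heights (0 or `NA` meaning no peak).
#' @param small_peak_ratio numeric peaks below this fraction of the
#'   median positive peak height are treated as very small (default 0.2).
#' @return list with `product_deleted` (per product), `genome_deleted`
#'   (named logical for A, B, D), `double_mutant` (A and D both
#'   homozygous deleted), and `zygosity = "homozygous_only"`.
#' @export
genotype_multiplex <- function(products, small_peak_ratio = 0.2) {
  need <- c("A1", "A2", "B", "D")
  miss <- setdiff(need, names(products))
  if (length(miss))
    stop("missing product channel(s): ", paste(miss, collapse = ", "), call. = FALSE)
  products <- products[need]
  if (is.numeric(products)) {
    h <- as.numeric(products)
    h[is.na(h)] <- 0
    pos <- h[h > 0]
    thr <- if (length(pos)) small_peak_ratio * median(pos) else 0
    deleted <- h <= 0 | h < thr
  } else {
    x <- tolower(as.character(products))
    known <- c("present", "absent", "very_small")
    if (any(!x %in% known))
      stop("unknown product call(s): ",
           paste(unique(products[!x %in% known]), collapse = ", "), call. = FALSE)
    deleted <- x %in% c("absent", "very_small")
  }
  names(deleted) <- need
  genome_deleted <- c(A = unname(deleted["A1"] & deleted["A2"]),
                      B = unname(deleted["B"]),
                      D = unname(deleted["D"]))
  list(product_deleted = deleted,
       genome_deleted = genome_deleted,
       double_mutant = unname(genome_deleted["A"] & genome_deleted["D"]),
       zygosity = "homozygous_only")
}
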