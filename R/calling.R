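## Run-length deletion calling on normalized binned coverage.
##
## A deletion opens at the first bin of a run of >= min_low_run adjacent
## low bins (value <= low_fraction) and closes at the last low bin that
## precedes a run of >= min_high_run adjacent high bins (or the
## chromosome end). Interior high runs shorter than min_high_run are
## absorbed. Masked bins are neutral: they count toward neither run and
## are reported inside a call when flanked by low bins.

scan_low_runs <- function(low, min_low, min_high) {
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- matrix(integer(0), ncol = 2)
  open_start <- NA_integer_
  last_low_end <- NA_integer_
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      if (is.na(open_start) && r$lengths[k] >= min_low) open_start <- starts[k]
      if (!is.na(open_start)) last_low_end <- ends[k]
    } else if (!is.na(open_start) && r$lengths[k] >= min_high) {
      out <- rbind(out, c(open_start, last_low_end))
      open_start <- NA_integer_
      last_low_end <- NA_integer_
    }
  }
  if (!is.na(open_start)) out <- rbind(out, c(open_start, last_low_end))
  out
}

empty_calls <- function() {
  data.frame(line_id = character(), chrom = character(),
             start = numeric(), end = numeric(), size_bp = numeric(),
             n_low_bins = integer(), method = character(), flags = character(),
             stringsAsFactors = FALSE)
}

#' Call large deletions from normalized coverage
#'
#' Applies the run-length criteria to each chromosome of a normalized
#' profile: a deletion is a block of at least `params$min_low_run`
#' adjacent bins with value `<= params$low_fraction`, and is finished
#' only once at least `params$min_high_run` adjacent bins exceed that
#' fraction (interior shorter high runs are absorbed). Masked bins are
#' neutral in both run counters. Calls are reported at bin resolution,
#' per chromosome, in coordinate order.
#'
#' @param cov a `normalized_coverage` object (see [normalize_coverage()]).
#' @param params a [caller_params()] object.
#' @return a data frame of class `deletion_calls` with columns `line_id`,
#'   `chrom`, `start`, `end`, `size_bp`, `n_low_bins`, `method` (`"bin"`),
#'   and `flags`. An empty profile yields an empty frame.
#' @export
call_deletions <- function(cov, params = caller_params()) {
  stopifnot(inherits(cov, "normalized_coverage"))
  if (!inherits(params, "caller_params")) params <- do.call(caller_params, params)
  res <- list()
  for (ch in unique(cov$bins$chrom)) {
    b <- cov$bins[cov$bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    um <- which(!b$masked)
    if (!length(um)) next
    low <- b$value[um] <= params$low_fraction
    runs <- scan_low_runs(low, params$min_low_run, params$min_high_run)
    if (!nrow(runs)) next
    for (i in seq_len(nrow(runs))) {
      s <- um[runs[i, 1]]; e <- um[runs[i, 2]]
      res[[length(res) + 1L]] <- data.frame(
        line_id = cov$line_id, chrom = ch,
        start = b$start[s], end = b$end[e],
        size_bp = b$end[e] - b$start[s],
        n_low_bins = sum(low[runs[i, 1]:runs[i, 2]]),
        method = "bin", flags = "", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty_calls()
  rownames(out) <- NULL
  class(out) <- c("deletion_calls", "data.frame")
  out
}

#' Flag deletion calls shared between independent lines
#'
#' A low-coverage region appearing at the same place in independent
#' mutants is more plausibly a background polymorphism against the
#' reference assembly (read misalignment) than a recurrent induced
#' deletion. Any call overlapping (by >= 1 bp) a call on the same
#' chromosome in another line gains the flag
#' `background_polymorphism_suspect` in every line carrying it. No call
#' is removed: the annotation is advisory.
#'
#' @param calls a `deletion_calls` data frame containing calls from two
#'   or more lines (`line_id` column), or a named list of per-line frames.
#' @return the combined calls with updated `flags`.
#' @export
flag_shared_calls <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- do.call(rbind, calls)
  if (length(unique(calls$line_id)) < 2) {
    message("flag_shared_calls: fewer than two lines; calls returned unchanged")
    return(calls)
  }
  n <- nrow(calls)
  shared <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ov <- calls$chrom == calls$chrom[i] & calls$line_id != calls$line_id[i] &
      calls$start < calls$end[i] & calls$end > calls$start[i]
    if (any(ov)) shared[i] <- TRUE
  }
  add_flag <- function(flags, flag) {
    ifelse(flags == "", flag, ifelse(grepl(flag, flags, fixed = TRUE),
                                     flags, paste(flags, flag, sep = ",")))
  }
  calls$flags[shared] <- add_flag(calls$flags[shared], "background_polymorphism_suspect")
  calls
}

#' Deletion size in base pairs
#'
#' @param call a deletion-call data frame (any number of rows) or a
#'   single call as a list with `start` and `end`.
#' @return numeric vector `end - start`.
#' @export
deletion_size <- function(call) {
  call$end - call$start
}

#' Refine deletion borders against gene models
#'
#' Re-estimates a bin-resolution deletion using gene models with
#' wild-type capture coverage. The refined interval spans from the end
#' of the last upstream gene whose mutant coverage exceeds
#' `low_fraction` (or the chromosome start when no such gene exists) to
#' the start of the first downstream gene exceeding `low_fraction` (or
#' the chromosome end). The flanking retained genes are reported. Because
#' borders are placed at the nearest *covered* flanking genes, sparse
#' annotation near a border inflates the refined size; refined intervals
#' therefore bracket the underlying deletion and may exceed the
#' bin-method extent.
#'
#' @param calls a `deletion_calls` data frame (one or more rows).
#' @param genes data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, and logical `wildtype_covered`; only wild-type-covered genes
#'   are considered.
#' @param per_gene_value named numeric vector: the mutant's normalized
#'   coverage over each gene.
#' @param low_fraction coverage threshold separating deleted from
#'   retained genes (default 0.1, matching the bin caller).
#' @param chrom_lengths optional data frame (`chrom`, `length`) used to
#'   close a refined interval at the chromosome end when no downstream
#'   covered gene exists.
#' @return a `deletion_calls` frame with `method = "refined"` plus
#'   `flank_left_gene` / `flank_right_gene` columns; calls without any
#'   low-coverage gene inside them are returned unchanged with a notice.
#' @export
refine_borders <- function(calls, genes, per_gene_value, low_fraction = 0.1,
                           chrom_lengths = NULL) {
  stopifnot(is.data.frame(calls), is.data.frame(genes))
  if (is.null(genes$wildtype_covered)) genes$wildtype_covered <- TRUE
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, , drop = FALSE]
    g <- genes[genes$chrom == cl$chrom & genes$wildtype_covered, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    v <- unname(per_gene_value[g$gene_id])
    low <- !is.na(v) & v <= low_fraction
    inside <- low & g$start < cl$end & g$end > cl$start
    if (!any(inside)) {
      message("refine_borders: no low-coverage gene inside call ", cl$chrom, ":",
              cl$start, "-", cl$end, "; bin-method call kept")
      cl$flank_left_gene <- NA_character_
      cl$flank_right_gene <- NA_character_
      out[[i]] <- cl
      next
    }
    a <- min(which(inside)); b <- max(which(inside))
    while (a > 1 && low[a - 1]) a <- a - 1
    while (b < nrow(g) && low[b + 1]) b <- b + 1
    left <- if (a > 1) a - 1L else NA_integer_
    right <- if (b < nrow(g)) b + 1L else NA_integer_
    new_start <- if (!is.na(left)) g$end[left] else 0
    new_end <- if (!is.na(right)) {
      g$start[right]
    } else if (!is.null(chrom_lengths) && cl$chrom %in% chrom_lengths$chrom) {
      chrom_lengths$length[match(cl$chrom, chrom_lengths$chrom)]
    } else {
      max(cl$end, g$end[b])
    }
    cl$start <- new_start
    cl$end <- new_end
    cl$size_bp <- new_end - new_start
    cl$method <- "refined"
    cl$flank_left_gene <- if (!is.na(left)) g$gene_id[left] else NA_character_
    cl$flank_right_gene <- if (!is.na(right)) g$gene_id[right] else NA_character_
    out[[i]] <- cl
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("deletion_calls", "data.frame")
  res
}

#' Genes overlapping a deletion call
#'
#' @param call single deletion call (one-row data frame or list with
#'   `chrom`, `start`, `end`).
#' @param genes data frame of gene models (`gene_id`, `chrom`, `start`,
#'   `end`, ...).
#' @return the rows of `genes` overlapping `[start, end)` by at least
#'   1 bp, each counted once.
#' @export
gene_content <- function(call, genes) {
  hit <- genes$chrom == call$chrom[1] & genes$start < call$end[1] &
    genes$end > call$start[1]
  out <- genes[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect homoeologous gene content of two deletions
#'
#' Reports pairs `(a, b)` with `a` among `genes_a`, `b` among `genes_b`,
#' related in the homoeology map. Each gene appears in at most one pair;
#' ties are broken greedily in coordinate order (first available partner
#' by position).
#'
#' @param genes_a,genes_b gene-model data frames, typically the
#'   [gene_content()] of two homoeologous deletions.
#' @param map data frame with columns `gene_a`, `gene_b`; the relation is
#'   queried symmetrically.
#' @return data frame with columns `gene_a`, `gene_b` (ids drawn from
#'   `genes_a` and `genes_b` respectively).
#' @export
intersect_homoeologues <- function(genes_a, genes_b, map) {
  ga <- genes_a[order(genes_a$chrom, genes_a$start), , drop = FALSE]
  gb <- genes_b[order(genes_b$chrom, genes_b$start), , drop = FALSE]
  rel <- rbind(data.frame(a = map$gene_a, b = map$gene_b, stringsAsFactors = FALSE),
               data.frame(a = map$gene_b, b = map$gene_a, stringsAsFactors = FALSE))
  rel <- rel[rel$a %in% ga$gene_id & rel$b %in% gb$gene_id, , drop = FALSE]
  used_b <- character(0)
  pairs <- list()
  for (a_id in ga$gene_id) {
    cand <- rel$b[rel$a == a_id]
    cand <- cand[!(cand %in% used_b)]
    if (!length(cand)) next
    cand <- cand[order(match(cand, gb$gene_id))]
    pairs[[length(pairs) + 1L]] <- data.frame(gene_a = a_id, gene_b = cand[1],
                                              stringsAsFactors = FALSE)
    used_b <- c(used_b, cand[1])
  }
  if (length(pairs)) do.call(rbind, pairs)
  else data.frame(gene_a = character(), gene_b = character(), stringsAsFactors = FALSE)
}

#' @export
print.deletion_calls <- function(x, ...) {
  cat("Deletion calls:", nrow(x), "call(s)")
  if (nrow(x)) cat(" in line(s)", paste(unique(x$line_id), collapse = ", "))
  cat("\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
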