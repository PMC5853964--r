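## Simulators emulating the statistical structure of the real inputs:
## exome-capture binned coverage with per-bin capture efficiency shared
## between lines and Poisson read noise, multi-deletion mutant genomes,
## gene models with homoeologue pairs, dominant-marker screening tables,
## and starch-granule micrographs.

#' Specify a synthetic genome with planted deletions
#'
#' @param chromosomes data frame with columns `chrom`, `length` (bp) and
#'   optionally `part1_length` (bp; `NA` for unsplit chromosomes). When
#'   present, coverage is simulated on the two chromosome parts
#'   (`<chrom>_part1` / `<chrom>_part2`) so the parts-to-full lift is
#'   exercised.
#' @param deletions data frame with columns `line_id`, `chrom`, `start`,
#'   `end` in full-chromosome coordinates; deletions must lie within
#'   chromosome bounds and not overlap within a line.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes, deletions) {
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)),
            all(c("line_id", "chrom", "start", "end") %in% names(deletions)))
  if (is.null(chromosomes$part1_length)) chromosomes$part1_length <- NA_real_
  bad_chr <- setdiff(deletions$chrom, chromosomes$chrom)
  if (length(bad_chr))
    stop("deletion on unknown chromosome: ", paste(bad_chr, collapse = ", "),
         call. = FALSE)
  len <- setNames(chromosomes$length, chromosomes$chrom)
  if (any(deletions$start < 0 | deletions$end > len[deletions$chrom] |
          deletions$end <= deletions$start))
    stop("deletions must lie within chromosome bounds with end > start",
         call. = FALSE)
  for (ln in unique(deletions$line_id)) {
    d <- deletions[deletions$line_id == ln, , drop = FALSE]
    for (ch in unique(d$chrom)) {
      x <- d[d$chrom == ch, , drop = FALSE]
      x <- x[order(x$start), , drop = FALSE]
      if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)]))
        stop("overlapping deletions in line ", ln, " on ", ch, call. = FALSE)
    }
  }
  structure(list(chromosomes = chromosomes, deletions = deletions),
            class = "genome_spec")
}

#' Parts map of a synthetic genome
#'
#' @param spec a [genome_spec()].
#' @return data frame (`part1_id`, `part2_id`, `full_id`, `part1_length`)
#'   covering the split chromosomes of `spec`.
#' @export
parts_map <- function(spec) {
  ch <- spec$chromosomes
  ch <- ch[!is.na(ch$part1_length), , drop = FALSE]
  if (!nrow(ch))
    return(data.frame(part1_id = character(), part2_id = character(),
                      full_id = character(), part1_length = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(part1_id = paste0(ch$chrom, "_part1"),
             part2_id = paste0(ch$chrom, "_part2"),
             full_id = ch$chrom,
             part1_length = ch$part1_length,
             stringsAsFactors = FALSE)
}

#' Coverage-simulation parameters
#'
#' @param mean_reads_per_bin expected read count per full-width bin at
#'   unit capture efficiency (default 100).
#' @param capture_efficiency_sd lognormal sigma of the per-bin capture
#'   efficiency factor shared between mutant and wild type (default 0.3).
#' @param residual_in_deletion fraction of normal coverage remaining
#'   inside a deletion — trace off-target capture (default 0.02).
#' @param poisson draw Poisson read noise (default `TRUE`); `FALSE`
#'   yields deterministic (noise-free) expected counts.
#' @param bin_size bin width in bp (default 1e6).
#' @return list of class `coverage_sim_params`.
#' @export
coverage_sim_params <- function(mean_reads_per_bin = 100,
                                capture_efficiency_sd = 0.3,
                                residual_in_deletion = 0.02,
                                poisson = TRUE, bin_size = 1e6) {
  stopifnot(mean_reads_per_bin > 0, capture_efficiency_sd >= 0,
            residual_in_deletion >= 0, residual_in_deletion < 1, bin_size > 0)
  structure(list(mean_reads_per_bin = mean_reads_per_bin,
                 capture_efficiency_sd = capture_efficiency_sd,
                 residual_in_deletion = residual_in_deletion,
                 poisson = poisson, bin_size = bin_size),
            class = "coverage_sim_params")
}

sim_part_bins <- function(spec, bin_size) {
  rows <- lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    ch <- spec$chromosomes$chrom[i]
    len <- spec$chromosomes$length[i]
    p1 <- spec$chromosomes$part1_length[i]
    if (is.na(p1) || p1 <= 0 || p1 >= len) {
      b <- make_bins(data.frame(chrom = ch, length = len), bin_size)
      b$full_chrom <- ch
      b$full_start <- b$start
      b$full_end <- b$end
    } else {
      b1 <- make_bins(data.frame(chrom = paste0(ch, "_part1"), length = p1), bin_size)
      b1$full_start <- b1$start
      b1$full_end <- b1$end
      b2 <- make_bins(data.frame(chrom = paste0(ch, "_part2"), length = len - p1),
                      bin_size)
      b2$full_start <- b2$start + p1
      b2$full_end <- b2$end + p1
      b <- rbind(b1, b2)
      b$full_chrom <- ch
    }
    b
  })
  do.call(rbind, rows)
}

deleted_fraction <- function(bins, dels) {
  f <- numeric(nrow(bins))
  if (!nrow(dels)) return(f)
  for (j in seq_len(nrow(dels))) {
    on <- bins$full_chrom == dels$chrom[j]
    ov <- pmax(0, pmin(bins$full_end[on], dels$end[j]) -
                  pmax(bins$full_start[on], dels$start[j]))
    f[on] <- f[on] + ov / (bins$full_end[on] - bins$full_start[on])
  }
  pmin(f, 1)
}

#' Simulate a mutant/wild-type binned coverage pair
#'
#' Per bin, one capture-efficiency factor `e ~ lognormal(0, sd)` is
#' drawn and shared by both lines; the wild-type count is
#' `Poisson(mean * e * w)` and the mutant count `Poisson(mean * e * w *
#' r)`, where `w` is the bin width relative to the full bin size and
#' `r` interpolates between 1 outside deletions and
#' `residual_in_deletion` inside (partially overlapped bins get the
#' overlap-weighted mixture). Coverage is emitted in parts coordinates
#' for split chromosomes, so the standard pipeline (normalize, lift,
#' call) applies.
#'
#' @param spec a [genome_spec()].
#' @param params a [coverage_sim_params()].
#' @param line which `line_id` of `spec$deletions` to simulate as the
#'   mutant (default: the first).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `mutant` and `wildtype` (`binned_coverage`),
#'   `truth` (the planted deletions of `line`, full coordinates),
#'   and `parts` (the [parts_map()]).
#' @export
simulate_coverage_pair <- function(spec, params = coverage_sim_params(),
                                   line = NULL, seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  if (!inherits(params, "coverage_sim_params"))
    params <- do.call(coverage_sim_params, params)
  if (!is.null(seed)) set.seed(seed)
  lines <- unique(spec$deletions$line_id)
  if (is.null(line)) line <- lines[1]
  dels <- spec$deletions[spec$deletions$line_id == line, , drop = FALSE]
  bins <- sim_part_bins(spec, params$bin_size)
  w <- (bins$end - bins$start) / params$bin_size
  e <- if (params$capture_efficiency_sd > 0) {
    rlnorm(nrow(bins), 0, params$capture_efficiency_sd)
  } else rep(1, nrow(bins))
  f <- deleted_fraction(bins, dels)
  r <- (1 - f) + f * params$residual_in_deletion
  mu_wt <- params$mean_reads_per_bin * e * w
  mu_mut <- mu_wt * r
  draw <- function(mu) if (params$poisson) rpois(length(mu), mu) else round(mu)
  base <- bins[, c("chrom", "start", "end")]
  wt <- base; wt$count <- draw(mu_wt)
  mut <- base; mut$count <- draw(mu_mut)
  list(
    mutant = new_binned_coverage(mut, line, params$bin_size, sum(mut$count)),
    wildtype = new_binned_coverage(wt, "wildtype", params$bin_size, sum(wt$count)),
    truth = dels,
    parts = parts_map(spec)
  )
}

#' Simulate gene models, homoeologue pairs, and per-gene coverage truth
#'
#' Places non-overlapping genes uniformly along each chromosome of the
#' spec, avoiding genes that straddle a planted deletion border (the
#' breakpoints fall between genes). Homoeologue pairs are built between
#' chromosomes of the same group on different subgenomes (e.g. `chr4A`
#' and `chr4D`): within each pair of planted deletions,
#' `homoeology_fraction` of the smaller gene set is paired in
#' coordinate order (these pairs are the planted shared homoeologues,
#' returned as truth), and the same fraction of the genes outside the
#' deletions is paired likewise.
#'
#' @param spec a [genome_spec()].
#' @param density genes per Mb (default 5).
#' @param homoeology_fraction fraction of genes with a homoeologous
#'   partner (default 0.4).
#' @param gene_width_range gene lengths drawn uniformly from this bp
#'   range (default 1000-5000).
#' @param residual per-gene mutant coverage inside deletions
#'   (default 0.02).
#' @param seed optional RNG seed.
#' @return list with `genes` (gene_id, chrom, start, end, confidence,
#'   wildtype_covered), `map` (gene_a, gene_b), `values` (per line: named
#'   vector of per-gene mutant coverage), and `truth` (`shared_pairs`:
#'   planted homoeologue pairs lying inside both deletions of a
#'   chromosome group).
#' @export
simulate_gene_models <- function(spec, density = 5, homoeology_fraction = 0.4,
                                 gene_width_range = c(1000, 5000),
                                 residual = 0.02, seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"), density > 0,
            homoeology_fraction >= 0, homoeology_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  all_dels <- spec$deletions
  place_chrom <- function(ch, len) {
    n <- max(1L, round(density * len / 1e6))
    dels <- all_dels[all_dels$chrom == ch, , drop = FALSE]
    starts <- numeric(0); ends <- numeric(0)
    tries <- 0L
    while (length(starts) < n && tries < 50L * n) {
      tries <- tries + 1L
      wd <- runif(1, gene_width_range[1], gene_width_range[2])
      s <- runif(1, 0, len - wd)
      e <- s + wd
      if (any(s < ends & e > starts)) next
      if (nrow(dels) && any(s < dels$end & e > dels$start &
                            !(s >= dels$start & e <= dels$end))) next
      starts <- c(starts, s); ends <- c(ends, e)
    }
    ord <- order(starts)
    data.frame(gene_id = sprintf("G%s.%04d", ch, seq_along(starts)),
               chrom = ch, start = round(starts[ord]), end = round(ends[ord]),
               confidence = "high", wildtype_covered = TRUE,
               stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    place_chrom(spec$chromosomes$chrom[i], spec$chromosomes$length[i])
  }))
  rownames(genes) <- NULL
  ## per-line per-gene mutant coverage truth
  values <- list()
  for (ln in unique(all_dels$line_id)) {
    d <- all_dels[all_dels$line_id == ln, , drop = FALSE]
    inside <- rep(FALSE, nrow(genes))
    for (j in seq_len(nrow(d)))
      inside <- inside | (genes$chrom == d$chrom[j] & genes$start >= d$start[j] &
                            genes$end <= d$end[j])
    values[[ln]] <- setNames(ifelse(inside, residual, 1), genes$gene_id)
  }
  ## homoeologue pairing within chromosome groups
  grp <- sub("^chr(\\d+)([A-Z])$", "\\1", spec$chromosomes$chrom)
  map <- list(); shared <- list()
  for (g in unique(grp[duplicated(grp)])) {
    chs <- spec$chromosomes$chrom[grp == g]
    for (i in seq_along(chs)) for (j in seq_along(chs)) {
      if (i >= j) next
      ga <- genes[genes$chrom == chs[i], , drop = FALSE]
      gb <- genes[genes$chrom == chs[j], , drop = FALSE]
      da <- all_dels[all_dels$chrom == chs[i], , drop = FALSE]
      db <- all_dels[all_dels$chrom == chs[j], , drop = FALSE]
      in_del <- function(gg, dd) {
        if (!nrow(dd)) return(rep(FALSE, nrow(gg)))
        Reduce(`|`, lapply(seq_len(nrow(dd)), function(k)
          gg$start >= dd$start[k] & gg$end <= dd$end[k]))
      }
      ia <- in_del(ga, da); ib <- in_del(gb, db)
      k_in <- round(homoeology_fraction * min(sum(ia), sum(ib)))
      if (k_in > 0) {
        pa <- head(ga$gene_id[ia], k_in)
        pb <- head(gb$gene_id[ib], k_in)
        map[[length(map) + 1L]] <- data.frame(gene_a = pa, gene_b = pb,
                                              stringsAsFactors = FALSE)
        shared[[length(shared) + 1L]] <- data.frame(gene_a = pa, gene_b = pb,
                                                    stringsAsFactors = FALSE)
      }
      k_out <- round(homoeology_fraction * min(sum(!ia), sum(!ib)))
      if (k_out > 0)
        map[[length(map) + 1L]] <- data.frame(gene_a = head(ga$gene_id[!ia], k_out),
                                              gene_b = head(gb$gene_id[!ib], k_out),
                                              stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
  list(genes = genes,
       map = if (length(map)) do.call(rbind, map) else empty,
       values = values,
       truth = list(shared_pairs = if (length(shared)) do.call(rbind, shared) else empty))
}

#' Simulate a dominant-marker screening table
#'
#' A marker is scored absent when its position lies inside a planted
#' deletion of the line; with probability `faint_rate` an absent marker
#' is reported `faint` instead (low residual amplification). All other
#' markers are `present`.
#'
#' @param spec a [genome_spec()].
#' @param panel data frame with columns `marker_id`, `chrom`, `pos`
#'   (bp, full coordinates) and `order_index`.
#' @param faint_rate probability that a deleted marker reads faint
#'   rather than absent (default 0.25).
#' @param seed optional RNG seed.
#' @return list with `observations` (plant_id, marker_id, call; one
#'   plant per line) and `truth` (plant_id, marker_id, deleted).
#' @export
simulate_marker_table <- function(spec, panel, faint_rate = 0.25, seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"),
            all(c("marker_id", "chrom", "pos") %in% names(panel)))
  if (!is.null(seed)) set.seed(seed)
  len <- setNames(spec$chromosomes$length, spec$chromosomes$chrom)
  if (any(!panel$chrom %in% names(len)) || any(panel$pos < 0) ||
      any(panel$pos >= len[panel$chrom]))
    stop("marker positions must lie within the spec's chromosomes", call. = FALSE)
  obs <- list(); truth <- list()
  for (ln in unique(spec$deletions$line_id)) {
    d <- spec$deletions[spec$deletions$line_id == ln, , drop = FALSE]
    deleted <- vapply(seq_len(nrow(panel)), function(i) {
      any(d$chrom == panel$chrom[i] & panel$pos[i] >= d$start & panel$pos[i] < d$end)
    }, logical(1))
    call <- ifelse(deleted,
                   ifelse(runif(nrow(panel)) < faint_rate, "faint", "absent"),
                   "present")
    obs[[ln]] <- data.frame(plant_id = ln, marker_id = panel$marker_id,
                            call = call, stringsAsFactors = FALSE)
    truth[[ln]] <- data.frame(plant_id = ln, marker_id = panel$marker_id,
                              deleted = deleted, stringsAsFactors = FALSE)
  }
  list(observations = do.call(rbind, obs), truth = do.call(rbind, truth))
}

#' Simulate a starch-granule micrograph
#'
#' Renders filled dark discs on a light background with mild Gaussian
#' pixel noise. Granule diameters are drawn from two lognormal classes:
#' small (B-granule-like; default mean area ~25 um^2) and large
#' (A-granule-like; default mean area ~300 um^2), with an exact count
#' `round(n_granules * small_fraction)` of small granules. Disc centres
#' are placed by rejection sampling so that the centre distance between
#' two discs is at least `(1 - overlap_fraction)` times the sum of their
#' radii (plus a 2 px gap when `overlap_fraction = 0`), and no disc
#' touches the image border.
#'
#' @param n_granules number of granules to render.
#' @param small_fraction fraction of granules in the small class.
#' @param small_meanlog,small_sdlog lognormal parameters of small-class
#'   diameters in um (defaults `log(5.2)`, 0.25).
#' @param large_meanlog,large_sdlog lognormal parameters of large-class
#'   diameters in um (defaults `log(18.5)`, 0.2).
#' @param overlap_fraction maximum allowed overlap of centre distance
#'   relative to touching distance (0 = no touching; default 0).
#' @param scale micrometres per pixel (default 0.5).
#' @param dim optional `c(width, height)` in px; sized automatically to
#'   a packing density of ~12% when omitted.
#' @param noise_sd Gaussian pixel-noise standard deviation (default
#'   0.02).
#' @param seed optional RNG seed.
#' @return list of class `sim_micrograph`: `image` (matrix in `[0, 1]`),
#'   `scale`, and `truth` (cx, cy in px, diameter_um, class).
#' @export
simulate_granule_image <- function(n_granules = 200, small_fraction = 0.5,
                                   small_meanlog = log(5.2), small_sdlog = 0.25,
                                   large_meanlog = log(18.5), large_sdlog = 0.2,
                                   overlap_fraction = 0, scale = 0.5,
                                   dim = NULL, noise_sd = 0.02, seed = NULL) {
  stopifnot(small_fraction >= 0, small_fraction <= 1,
            overlap_fraction >= 0, overlap_fraction < 1, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  n_small <- round(n_granules * small_fraction)
  n_large <- n_granules - n_small
  d_um <- c(if (n_small) rlnorm(n_small, small_meanlog, small_sdlog),
            if (n_large) rlnorm(n_large, large_meanlog, large_sdlog))
  cls <- c(rep("small", n_small), rep("large", n_large))
  r_px <- d_um / (2 * scale)
  if (n_granules == 0) {
    side <- if (is.null(dim)) c(256L, 256L) else as.integer(dim)
    img <- matrix(0.9, side[2], side[1])
    img <- img + rnorm(length(img), 0, noise_sd)
    return(structure(list(image = pmin(pmax(img, 0), 1), scale = scale,
                          truth = data.frame(cx = numeric(), cy = numeric(),
                                             diameter_um = numeric(),
                                             class = character())),
                     class = "sim_micrograph"))
  }
  if (is.null(dim)) {
    side <- max(256L, ceiling(sqrt(sum(pi * r_px^2) / 0.12)))
    dim <- c(side, side)
  }
  w <- dim[1]; h <- dim[2]
  ord <- order(-r_px)  # place large discs first
  cx <- numeric(n_granules); cy <- numeric(n_granules)
  gap <- if (overlap_fraction == 0) 2 else 0
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    placed <- ord[seq_len(ii - 1)]
    ok <- FALSE
    for (try in seq_len(5000)) {
      x <- runif(1, r_px[i] + 2, w - r_px[i] - 2)
      y <- runif(1, r_px[i] + 2, h - r_px[i] - 2)
      if (!length(placed) ||
          all(sqrt((cx[placed] - x)^2 + (cy[placed] - y)^2) >=
              (1 - overlap_fraction) * (r_px[placed] + r_px[i]) + gap)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("canvas too small to place ", n_granules, " granules",
                  call. = FALSE)
    cx[i] <- x; cy[i] <- y
  }
  img <- matrix(0.9, h, w)
  for (i in seq_len(n_granules)) {
    x0 <- max(1L, floor(cx[i] - r_px[i])); x1 <- min(w, ceiling(cx[i] + r_px[i]))
    y0 <- max(1L, floor(cy[i] - r_px[i])); y1 <- min(h, ceiling(cy[i] + r_px[i]))
    xs <- x0:x1; ys <- y0:y1
    dd <- outer((ys - cy[i])^2, (xs - cx[i])^2, `+`)
    sub <- img[ys, xs, drop = FALSE]
    sub[dd <= r_px[i]^2] <- 0.15
    img[ys, xs] <- sub
  }
  img <- img + rnorm(length(img), 0, noise_sd)
  structure(list(image = pmin(pmax(img, 0), 1), scale = scale,
                 truth = data.frame(cx = cx, cy = cy, diameter_um = d_um,
                                    class = cls, stringsAsFactors = FALSE)),
            class = "sim_micrograph")
}
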