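## Segregation arithmetic for multi-locus selfing crosses scored with
## dominant markers: only homozygous-deletion status is observable, so
## genotype classes are defined over which loci are homozygous deleted.

class_names <- function(locus_names) {
  n <- length(locus_names)
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))[, n:1, drop = FALSE]
  apply(grid, 1, function(hom) {
    if (!any(hom)) "none" else paste(locus_names[hom], collapse = "&")
  })
}

#' Expected F2 genotype-class proportions
#'
#' For an F2 generated by selfing an F1 heterozygous at each deletion
#' locus, a gamete carries the deletion allele with probability `p`
#' (0.5 under unbiased transmission), so a plant is homozygous deleted
#' at one locus with probability `p^2`; independent loci multiply. With
#' two unlinked loci and unbiased transmission the double homozygote
#' class is `(1/4)^2 = 1/16`.
#'
#' Classes partition the population by which loci are homozygous
#' deleted; the complement of "homozygous deleted" aggregates the
#' heterozygous and wild-type states that dominant markers cannot
#' separate.
#'
#' @param n_loci number of unlinked deletion loci (default 2).
#' @param transmission_prob per-locus probability that a gamete carries
#'   the deletion allele; recycled to `n_loci` (default 0.5).
#' @param locus_names labels for the loci (default `LETTERS`).
#' @return named numeric vector of class probabilities summing to 1;
#'   names like `"A&D"`, `"A"`, `"none"`.
#' @export
expected_genotype_proportions <- function(n_loci = 2L, transmission_prob = 0.5,
                                          locus_names = NULL) {
  n_loci <- as.integer(n_loci)
  stopifnot(n_loci >= 1)
  p <- rep_len(transmission_prob, n_loci)
  if (any(p < 0 | p > 1))
    stop("transmission probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(locus_names)) locus_names <- LETTERS[seq_len(n_loci)]
  q <- p^2
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n_loci))[, n_loci:1, drop = FALSE]
  probs <- apply(grid, 1, function(hom) prod(ifelse(hom, q, 1 - q)))
  setNames(probs, class_names(locus_names))
}

#' Observed proportion of a genotype class
#'
#' @param counts named vector of class counts, or a single count (then
#'   give `total`).
#' @param class class name to report when `counts` is named.
#' @param total total screened (only when `counts` is a single number).
#' @return list of class `observed_proportion` with `count`, `total`,
#'   and `percent` (exact, printed to one decimal place).
#' @export
observed_proportion <- function(counts, class = NULL, total = NULL) {
  if (length(counts) > 1 || !is.null(class)) {
    if (is.null(class) || !class %in% names(counts))
      stop("`class` must name an element of `counts`", call. = FALSE)
    count <- unname(counts[class])
    total <- sum(counts)
  } else {
    count <- counts
    if (is.null(total)) stop("`total` required with a single count", call. = FALSE)
  }
  if (total <= 0) stop("total screened must be > 0", call. = FALSE)
  if (count < 0 || count > total) stop("count must lie in [0, total]", call. = FALSE)
  structure(list(count = count, total = total, percent = 100 * count / total),
            class = "observed_proportion")
}

#' @export
print.observed_proportion <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%%\n", x$count, x$total, x$percent))
  invisible(x)
}

#' Transmission-bias test for genotype-class counts
#'
#' Goodness of fit of observed class counts against expected class
#' probabilities. When every expected count is at least 5 the Pearson
#' chi-square statistic `sum((O - E)^2 / E)` is referred to a chi-square
#' distribution with `classes - 1` degrees of freedom; otherwise the
#' exact binomial lower tail of the smallest-expectation class is
#' reported. Independently of the branch, naming a `focal_class` adds
#' the exact binomial lower-tail probability of seeing at most the
#' observed count in that class — the natural single-class question for
#' under-representation (e.g. 1 double homozygote of 457 against 1/16).
#'
#' @param observed named vector of class counts.
#' @param expected named vector of class probabilities (same names,
#'   summing to 1).
#' @param focal_class optional class name for the exact single-class
#'   lower tail.
#' @return list of class `transmission_bias_test` with `statistic`, `df`,
#'   `p_value`, `method`, and (when requested) `focal` containing the
#'   exact tail.
#' @export
transmission_bias_test <- function(observed, expected, focal_class = NULL) {
  if (is.null(names(observed)) || is.null(names(expected)) ||
      !setequal(names(observed), names(expected)))
    stop("`observed` and `expected` must share class names", call. = FALSE)
  expected <- expected[names(observed)]
  if (abs(sum(expected) - 1) > 1e-8)
    stop("expected probabilities must sum to 1", call. = FALSE)
  if (any(expected == 0 & observed > 0))
    stop("class with zero expected probability has observations", call. = FALSE)
  total <- sum(observed)
  if (total <= 0) stop("total observed count must be > 0", call. = FALSE)
  exp_counts <- total * expected
  keep <- expected > 0
  statistic <- sum((observed[keep] - exp_counts[keep])^2 / exp_counts[keep])
  df <- sum(keep) - 1L
  if (all(exp_counts[keep] >= 5)) {
    method <- "chisq"
    p_value <- pchisq(statistic, df = df, lower.tail = FALSE)
  } else {
    method <- "exact_binomial"
    small <- names(which.min(exp_counts[keep]))
    p_value <- pbinom(observed[[small]], total, expected[[small]])
  }
  out <- list(statistic = statistic, df = df, p_value = unname(p_value),
              method = method, total = total)
  if (!is.null(focal_class)) {
    if (!focal_class %in% names(observed))
      stop("`focal_class` must name an observed class", call. = FALSE)
    out$focal <- list(class = focal_class,
                      observed = unname(observed[focal_class]),
                      expected_prob = unname(expected[focal_class]),
                      p_lower = unname(pbinom(observed[[focal_class]], total,
                                              expected[[focal_class]])))
  }
  structure(out, class = "transmission_bias_test")
}

#' @export
print.transmission_bias_test <- function(x, ...) {
  cat("Transmission-bias goodness-of-fit (", x$method, ")\n", sep = "")
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$total))
  if (!is.null(x$focal))
    cat(sprintf("  exact lower tail for %s: P(X <= %d | p = %.4g) = %.3g\n",
                x$focal$class, x$focal$observed, x$focal$expected_prob,
                x$focal$p_lower))
  invisible(x)
}

#' Simulate F2 genotype classes
#'
#' Generative check for [expected_genotype_proportions()]: each plant
#' receives two independent gametes per locus, each carrying the
#' deletion allele with probability `transmission_prob`; the plant is
#' homozygous deleted at a locus when both gametes carry it.
#'
#' @param n number of F2 plants.
#' @param n_loci number of unlinked loci.
#' @param transmission_prob per-gamete deletion-allele probability.
#' @param locus_names locus labels (default `LETTERS`).
#' @return factor of genotype-class names with levels matching
#'   [expected_genotype_proportions()].
#' @export
simulate_f2 <- function(n, n_loci = 2L, transmission_prob = 0.5,
                        locus_names = NULL) {
  n_loci <- as.integer(n_loci)
  if (is.null(locus_names)) locus_names <- LETTERS[seq_len(n_loci)]
  p <- rep_len(transmission_prob, n_loci)
  hom <- vapply(seq_len(n_loci), function(i) {
    rbinom(n, 1L, p[i]) & rbinom(n, 1L, p[i])
  }, logical(n))
  hom <- matrix(hom, nrow = n)
  labs <- apply(hom, 1, function(h) {
    if (!any(h)) "none" else paste(locus_names[h], collapse = "&")
  })
  factor(labs, levels = class_names(locus_names))
}
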