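test_that("refined borders span from the last covered gene upstream to the first downstream", {
  genes <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                      start = c(100, 300, 500, 700),
                      end = c(200, 400, 600, 800),
                      confidence = "high", wildtype_covered = TRUE)
  v <- c(g1 = 1, g2 = 0, g3 = 0, g4 = 1)
  call <- structure(data.frame(line_id = "m", chrom = "chr1", start = 250,
                               end = 650, size_bp = 400, n_low_bins = 4L,
                               method = "bin", flags = ""),
                    class = c("deletion_calls", "data.frame"))
  r <- refine_borders(call, genes, v)
  expect_equal(r$start, 200)     # end of last retained gene upstream
  expect_equal(r$end, 700)       # start of first retained gene downstream
  expect_equal(r$method, "refined")
  expect_equal(r$flank_left_gene, "g1")
  expect_equal(r$flank_right_gene, "g4")
  expect_equal(deletion_size(r), r$size_bp)
})

test_that("calls with no low-coverage gene inside are returned unchanged", {
  genes <- data.frame(gene_id = paste0("g", 1:3), chrom = "chr1",
                      start = c(100, 300, 500), end = c(200, 400, 600),
                      confidence = "high", wildtype_covered = TRUE)
  v <- c(g1 = 1, g2 = 1, g3 = 1)
  call <- data.frame(line_id = "m", chrom = "chr1", start = 250, end = 650,
                     size_bp = 400, n_low_bins = 4L, method = "bin", flags = "")
  expect_message(r <- refine_borders(call, genes, v), "no low-coverage gene")
  expect_equal(r$start, 250)
  expect_equal(r$end, 650)
  expect_equal(r$method, "bin")
})

test_that("refinement brackets a planted deletion between the nearest covered genes", {
  set.seed(19)
  for (rep in 1:5) {
    len <- 2e8
    del <- sort(round(runif(2, 2e7, 1.8e8)))
    del[2] <- max(del[2], del[1] + 2e7)
    spec <- genome_spec(
      data.frame(chrom = "chr1", length = len, part1_length = NA),
      data.frame(line_id = "m", chrom = "chr1", start = del[1], end = del[2]))
    g <- simulate_gene_models(spec, density = 1, homoeology_fraction = 0,
                              seed = 100 + rep)
    call <- data.frame(line_id = "m", chrom = "chr1", start = del[1],
                       end = del[2], size_bp = diff(del), n_low_bins = 4L,
                       method = "bin", flags = "")
    r <- refine_borders(call, g$genes, g$values[["m"]],
                        chrom_lengths = spec$chromosomes)
    # closed-form expectation from generator truth: the nearest covered
    # (value > 0.1) genes outside the planted interval bound the result
    v <- g$values[["m"]][g$genes$gene_id]
    up <- g$genes$end[v > 0.1 & g$genes$end <= del[1]]
    dn <- g$genes$start[v > 0.1 & g$genes$start >= del[2]]
    expect_equal(r$start, if (length(up)) max(up) else 0)
    expect_equal(r$end, if (length(dn)) min(dn) else len)
    expect_lte(r$start, del[1])
    expect_gte(r$end, del[2])
  }
})

test_that("gene_content matches a brute-force overlap scan", {
  g <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                  start = c(10, 20, 40), end = c(20, 30, 50),
                  confidence = "high", wildtype_covered = TRUE)
  call <- list(chrom = "chr1", start = 0, end = 15)
  expect_equal(gene_content(call, g)$gene_id, "a")   # partial overlap counts
  call2 <- list(chrom = "chr1", start = 0, end = 20)
  expect_equal(gene_content(call2, g)$gene_id, "a")  # half-open: [20,30) excluded

  set.seed(5)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50), chrom = "chr1",
                      start = sort(sample(0:990, 50)) * 10, end = NA,
                      confidence = "high", wildtype_covered = TRUE)
  genes$end <- genes$start + sample(5:80, 50, replace = TRUE)
  for (i in 1:20) {
    s <- runif(1, 0, 9000); e <- s + runif(1, 10, 3000)
    call <- list(chrom = "chr1", start = s, end = e)
    brute <- genes$gene_id[vapply(seq_len(nrow(genes)), function(k) {
      max(genes$start[k], s) < min(genes$end[k], e)
    }, logical(1))]
    expect_equal(gene_content(call, genes)$gene_id, brute)
  }
})

test_that("homoeologue intersection recovers planted pairs and applies the tie rule", {
  # disjoint maps give an empty intersection
  ga <- data.frame(gene_id = c("a1", "a2"), chrom = "cA", start = c(1, 10),
                   end = c(5, 15))
  gb <- data.frame(gene_id = c("b1", "b2"), chrom = "cB", start = c(1, 10),
                   end = c(5, 15))
  empty_map <- data.frame(gene_a = "x1", gene_b = "y1")
  expect_equal(nrow(intersect_homoeologues(ga, gb, empty_map)), 0L)

  # one A-gene related to two B-genes: one pair, first partner by coordinate
  map <- data.frame(gene_a = c("a1", "a1"), gene_b = c("b2", "b1"))
  got <- intersect_homoeologues(ga, gb, map)
  expect_equal(nrow(got), 1L)
  expect_equal(got$gene_b, "b1")

  # each gene used at most once
  map2 <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b1"))
  got2 <- intersect_homoeologues(ga, gb, map2)
  expect_equal(nrow(got2), 1L)

  # planted shared homoeologues inside both group-4 deletions are recovered
  spec <- group4_spec()
  g <- simulate_gene_models(spec, density = 2, homoeology_fraction = 0.5,
                            seed = 23)
  k <- nrow(g$truth$shared_pairs)
  expect_gt(k, 0)
  callA <- paragon_deletions("bin")
  callA <- callA[callA$chrom == "chr4A", ]
  callD <- paragon_deletions("bin")
  callD <- callD[callD$chrom == "chr4D", ]
  pairs <- intersect_homoeologues(gene_content(callA, g$genes),
                                  gene_content(callD, g$genes), g$map)
  expect_equal(nrow(pairs), k)
  expect_setequal(pairs$gene_a, g$truth$shared_pairs$gene_a)

  # zero homoeology fraction gives an empty intersection
  g0 <- simulate_gene_models(spec, density = 2, homoeology_fraction = 0,
                             seed = 23)
  expect_equal(nrow(intersect_homoeologues(gene_content(callA, g0$genes),
                                           gene_content(callD, g0$genes),
                                           g0$map)), 0L)
})
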