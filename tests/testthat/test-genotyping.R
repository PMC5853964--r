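test_that("marker calls map to deletion status, faint counting as deleted", {
  expect_true(interpret_call("absent"))
  expect_true(interpret_call("faint"))
  expect_true(interpret_call("FAINT"))   # capitalization is immaterial
  expect_false(interpret_call("present"))
  expect_true(is.na(interpret_call("nd")))
  expect_error(interpret_call("maybe"), "unknown marker call")
})

test_that("deletion extent follows the contiguous-block taxonomy", {
  panel <- paragon_marker_panel("4AL")
  obs <- function(calls) data.frame(plant_id = "p", marker_id = panel$marker_id,
                                    call = calls)
  cls <- function(calls) infer_deletion_extent(panel, obs(calls), "4G")$classification

  expect_equal(cls(c("absent", "absent", "absent", "absent", "present")),
               "distal_not_including_anchor")
  expect_equal(cls(rep("absent", 5)), "spans_all_markers")
  expect_equal(cls(rep("present", 5)), "no_deletion")
  expect_equal(cls(c("present", "present", "present", "present", "absent")),
               "anchor_only")
  expect_equal(cls(c("present", "absent", "absent", "present", "present")),
               "interstitial")
  expect_equal(cls(c("absent", "present", "absent", "absent", "present")),
               "inconsistent")
  # partial distal block not reaching the anchor is still a distal deletion
  expect_equal(cls(c("absent", "absent", "present", "present", "present")),
               "distal_not_including_anchor")

  # the anchor-only call on the 4DS panel (with a proximal marker present)
  p4ds <- paragon_marker_panel("4DS")
  o <- data.frame(plant_id = "p", marker_id = p4ds$marker_id,
                  call = c(rep("present", 4), "absent", "present"))
  expect_equal(infer_deletion_extent(p4ds, o, "4G")$classification, "anchor_only")
})

test_that("inference is order-invariant and errors on missing markers", {
  panel <- paragon_marker_panel("4AL")
  obs <- data.frame(plant_id = "p", marker_id = panel$marker_id,
                    call = c("absent", "absent", "absent", "absent", "present"))
  shuffled <- obs[c(3, 5, 1, 4, 2), ]
  expect_equal(infer_deletion_extent(panel, shuffled, "4G")$classification,
               infer_deletion_extent(panel, obs, "4G")$classification)
  expect_error(infer_deletion_extent(panel, obs[-2, ], "4G"), "KT71")
})

test_that("every published screening row reproduces its line's classification", {
  tab <- paragon_marker_observations()
  for (arm in c("4AL", "4DS")) {
    panel <- paragon_marker_panel(arm)
    sub <- tab[tab$arm == arm, ]
    res <- classify_marker_table(panel, sub, "4G")
    lines <- sub$line[match(res$plant_id, sub$plant_id)]
    expect_equal(res$classification, unname(published_line_classes[lines]),
                 info = arm)
  }
  # 19 plants in total, each classified
  expect_equal(length(unique(tab$plant_id)), 19L)
})

test_that("faint-only evidence is marked low confidence", {
  panel <- paragon_marker_panel("4AL")
  obs <- data.frame(plant_id = "p", marker_id = panel$marker_id,
                    call = c("faint", "absent", "faint", "absent", "present"))
  h <- infer_deletion_extent(panel, obs, "4G")
  expect_true(h$low_confidence)
  expect_equal(h$classification, "distal_not_including_anchor")
})

test_that("multiplex genotyping requires both A products gone to call the A genome", {
  g <- genotype_multiplex(c(A1 = "absent", A2 = "absent", B = "present",
                            D = "absent"))
  expect_true(g$genome_deleted[["A"]])
  expect_true(g$genome_deleted[["D"]])
  expect_false(g$genome_deleted[["B"]])
  expect_true(g$double_mutant)

  all_present <- genotype_multiplex(c(A1 = "present", A2 = "present",
                                      B = "present", D = "present"))
  expect_false(any(all_present$genome_deleted))
  expect_false(all_present$double_mutant)

  one_a <- genotype_multiplex(c(A1 = "absent", A2 = "present", B = "present",
                                D = "present"))
  expect_false(one_a$genome_deleted[["A"]])

  # exhaustive rule table: A deleted iff both A products deleted
  states <- c("present", "absent")
  for (a1 in states) for (a2 in states) for (b in states) for (d in states) {
    g <- genotype_multiplex(c(A1 = a1, A2 = a2, B = b, D = d))
    expect_equal(unname(g$genome_deleted["A"]), a1 == "absent" && a2 == "absent")
    expect_equal(unname(g$genome_deleted["B"]), b == "absent")
    expect_equal(unname(g$genome_deleted["D"]), d == "absent")
    expect_equal(g$double_mutant,
                 unname(g$genome_deleted["A"] && g$genome_deleted["D"]))
  }
})

test_that("multiplex peak heights use the very-small-peak rule and never report heterozygotes", {
  g <- genotype_multiplex(c(A1 = 0, A2 = 100 * 0.19, B = 100, D = 100))
  expect_true(g$genome_deleted[["A"]])     # one absent + one very small
  expect_equal(g$zygosity, "homozygous_only")
  g2 <- genotype_multiplex(c(A1 = 50, A2 = 60, B = 100, D = 100))
  expect_false(any(g2$genome_deleted))
  expect_error(genotype_multiplex(c(A1 = 1, A2 = 1, B = 1)), "missing product")
})

test_that("simulated marker tables close the loop with extent inference", {
  spec <- paragon_layout()
  pos <- synthetic_marker_positions()
  sim <- simulate_marker_table(spec, pos, faint_rate = 0, seed = 2)

  p4al <- pos[pos$arm == "4AL", ]
  obs_a1 <- sim$observations[sim$observations$plant_id == "A1" &
                               sim$observations$marker_id %in% p4al$marker_id, ]
  h <- infer_deletion_extent(p4al, obs_a1, "4G_4A")
  expect_equal(h$classification, "distal_not_including_anchor")

  p4ds <- pos[pos$arm == "4DS", ]
  obs_d4 <- sim$observations[sim$observations$plant_id == "D4" &
                               sim$observations$marker_id %in% p4ds$marker_id, ]
  expect_equal(infer_deletion_extent(p4ds, obs_d4, "4G_4D")$classification,
               "spans_all_markers")

  # without deletions every marker is present
  empty <- genome_spec(spec$chromosomes,
                       data.frame(line_id = "wt", chrom = "chr4A",
                                  start = 0, end = 1)[0, ])
  expect_error(simulate_marker_table(empty, pos), NA)

  # faint and absent are interchangeable for inference
  sim_f <- simulate_marker_table(spec, pos, faint_rate = 1, seed = 2)
  obs_f <- sim_f$observations[sim_f$observations$plant_id == "A1" &
                                sim_f$observations$marker_id %in% p4al$marker_id, ]
  expect_true(all(obs_f$call[obs_f$marker_id != "4G_4A"] == "faint"))
  expect_equal(infer_deletion_extent(p4al, obs_f, "4G_4A")$classification,
               "distal_not_including_anchor")
})
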