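test_that("column spread is zero for superposed copies and half the separation for two", {
  tr_a <- line_trace("A")
  tr_b <- line_trace("B")
  msa0 <- two_struct_msa(tr_a, tr_b)
  prof0 <- column_profile(msa0)
  expect_true(all(prof0$rmsd == 0))

  tr_b2 <- tr_b
  tr_b2$y[15] <- 2.0       # CAs 2 A apart at column 15
  prof <- column_profile(two_struct_msa(tr_a, tr_b2))
  expect_equal(prof$rmsd[15], 1.0, tolerance = 1e-10)
  expect_true(all(prof$rmsd[-15] == 0))
})

test_that("partially occupied columns can never be anchors", {
  tr_a <- line_trace("A")
  tr_b <- line_trace("B")
  msa <- two_struct_msa(tr_a, tr_b)
  msa$cells["B", 10] <- NA_integer_
  msa$insertions$B <- data.frame(after_col = 9L, idx = 10L)
  prof <- column_profile(msa)
  expect_identical(prof$rmsd[10], Inf)
  expect_false(10L %in% call_anchors(prof))
})

test_that("column spread under isotropic noise matches the closed-form expectation", {
  # E[rmsd^2] about the centroid = 3 sigma^2 (n-1)/n per column
  sigma <- 0.3; n <- 5
  ens <- generate_ensemble(synthetic_spec(
    seed = 31, n_structures = n, core_blocks = c(125, 125),
    planted_regions = list(), noise_sigma = sigma,
    transforms = "identity"))
  prof <- column_profile(ens$msa)
  expected <- sigma * sqrt(3) * sqrt((n - 1) / n)
  expect_equal(mean(prof$rmsd), expected, tolerance = 0.07)
})

test_that("anchor calling applies strict cut-off and run thinning", {
  prof <- structure(data.frame(column = 1:5, occupancy = 2L,
                               rmsd = c(0.5, 3.0, 0.5, 2.0, 0.0)),
                    class = c("pvr_profile", "data.frame"), n_structures = 2L)
  expect_identical(as.integer(call_anchors(prof)), c(1L, 3L, 5L))
  # exactly 2.0 is not an anchor (strict <)
  expect_false(4L %in% call_anchors(prof))
  expect_identical(as.integer(call_anchors(prof, rmsd_cut = 2.5)),
                   c(1L, 3L, 4L, 5L))
  expect_identical(as.integer(call_anchors(prof, rmsd_cut = 3.5)), 1:5)
  prof2 <- structure(data.frame(column = 1:6, occupancy = 2L,
                                rmsd = c(0.1, 5, 0.1, 0.1, 5, 0.1)),
                     class = c("pvr_profile", "data.frame"),
                     n_structures = 2L)
  expect_identical(as.integer(call_anchors(prof2, min_run = 2)), c(3L, 4L))
  expect_error(call_anchors(prof, rmsd_cut = 0), "positive")
})

test_that("identical ensembles yield no PVRs and zero divergence", {
  ens <- generate_ensemble(small_spec(2, noise_sigma = 0,
                                      planted_regions = list()))
  msa <- star_align(ens$structures, "S1")
  tab <- delineate_pvrs(msa, call_anchors(column_profile(msa)))
  expect_identical(nrow(tab$pvrs), 0L)
  expect_true(all(tab$sigma_abs == 0))
})

test_that("a single planted region is delineated with exact lengths", {
  ens <- generate_ensemble(small_spec(7))   # lengths {0, 6, 15}, range 15
  msa <- star_align(ens$structures, "S1")
  tab <- delineate_pvrs(msa, call_anchors(column_profile(msa)))
  expect_identical(nrow(tab$pvrs), 1L)
  expect_identical(tab$pvrs$kind, "internal")
  expect_identical(tab$pvrs$length_range, 15L)
  expect_identical(unname(tab$sigma_abs), c(0, 6, 15))
  expect_error(delineate_pvrs(msa, integer()), "no conserved core")
})

test_that("terminal regions are delineated against a single anchor", {
  spec <- small_spec(19, n_structures = 3,
    planted_regions = list(list(position = 0, lengths = c(0, 2, 14)),
                           list(position = 2, lengths = c(16, 0, 3))))
  ens <- generate_ensemble(spec)
  msa <- star_align(ens$structures, "S1")
  tab <- delineate_pvrs(msa, call_anchors(column_profile(msa)))
  expect_identical(nrow(tab$pvrs), 2L)
  expect_setequal(tab$pvrs$kind, c("N_terminal", "C_terminal"))
  expect_identical(sort(tab$pvrs$length_range), c(14L, 16L))
})

test_that("anchor count grows with rmsd_cut and PVR count shrinks with range_cut", {
  ens <- generate_ensemble(small_spec(23, n_structures = 3,
    planted_regions = list(list(position = 1, lengths = c(0, 6, 15)))))
  msa <- star_align(ens$structures, "S1")
  prof <- column_profile(msa)
  cuts <- c(0.5, 1, 2, 4, 8)
  n_anchors <- vapply(cuts, function(ct) length(call_anchors(prof, ct)),
                      integer(1))
  expect_true(all(diff(n_anchors) >= 0))
  anchors <- call_anchors(prof)
  rcuts <- c(0, 5, 10, 14, 15, 50)
  n_pvrs <- vapply(rcuts, function(rc)
    nrow(delineate_pvrs(msa, anchors, range_cut = rc)$pvrs), integer(1))
  expect_true(all(diff(n_pvrs) <= 0))
  # strict threshold: range 15 is dropped at range_cut 15
  expect_identical(n_pvrs[rcuts == 14], 1L)
  expect_identical(n_pvrs[rcuts == 15], 0L)
})

test_that("sigma_abs is zero for the reference and rigid-motion invariant", {
  ens <- generate_ensemble(small_spec(29))
  run <- function(structures) {
    msa <- star_align(structures, "S1")
    delineate_pvrs(msa, call_anchors(column_profile(msa)))$sigma_abs
  }
  s0 <- run(ens$structures)
  expect_identical(unname(s0["S1"]), 0)
  set.seed(1)
  moved <- ens$structures
  moved[[2]] <- move_structure(moved[[2]], rand_rot(), rnorm(3, sd = 25))
  expect_identical(run(moved), s0)
})

test_that("the report lists one row per structure with consistent lengths", {
  ens <- generate_ensemble(small_spec(7))
  msa <- star_align(ens$structures, "S1")
  tab <- delineate_pvrs(msa, call_anchors(column_profile(msa)))
  rep <- pvr_report(tab, msa)
  expect_identical(nrow(rep$segments),
                   nrow(tab$pvrs) * length(msa$structure_ids))
  for (k in seq_len(nrow(rep$segments))) {
    row <- rep$segments[k, ]
    expect_identical(row$length,
                     unname(tab$lengths[row$structure_id, row$pvr_id]))
  }
  zero <- rep$segments$length == 0
  expect_true(all(rep$selections[zero] == ""))
  expect_true(all(grepl("^chain A and resi", rep$selections[!zero])))
})

test_that("planted regions are recovered with boundaries near the junctions", {
  for (sd in c(41, 42, 43)) {
    ens <- generate_ensemble(small_spec(sd))
    msa <- star_align(ens$structures, "S1")
    tab <- delineate_pvrs(msa, call_anchors(column_profile(msa)))
    expect_identical(nrow(tab$pvrs), 1L)
    # reference junction: core block boundary at column 40 (no ref loop)
    expect_lte(abs(tab$pvrs$start_anchor - 40), 2)
    expect_lte(abs(tab$pvrs$end_anchor - 41), 2)
  }
})
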