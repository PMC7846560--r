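test_that("kabsch recovers exact rigid motions", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.2, 1), 4, 3, byrow = TRUE)
  fit <- kabsch(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- kabsch(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(apply_transform(Q, fit), P, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-6)
})

test_that("kabsch errors on degenerate input", {
  P <- matrix(rnorm(12), 4, 3)
  expect_error(kabsch(P[1:2, ], P[1:2, ]), "at least 3")
  expect_error(kabsch(P, P[1:3, ]), "differ in length")
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(kabsch(line, line), "degenerate")
})

test_that("kabsch RMSD is invariant under common rigid motion and matches bio3d", {
  set.seed(42)
  for (k in 1:10) {
    P <- matrix(rnorm(15), 5, 3)
    Q <- P + matrix(rnorm(15, sd = 0.3), 5, 3)
    base <- kabsch(P, Q)$rmsd
    R <- rand_rot(); tv <- rnorm(3, sd = 10)
    moved <- kabsch(rigid_move(P, R, tv), rigid_move(Q, R, tv))$rmsd
    expect_equal(moved, base, tolerance = 1e-6)
  }
  # independent route: bio3d least-squares fit
  set.seed(7)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P + matrix(rnorm(30, sd = 0.5), 10, 3)
  fitted <- bio3d::fit.xyz(as.numeric(t(P)), as.numeric(t(Q)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  rmsd_bio3d <- sqrt(mean(colSums(matrix((as.numeric(t(P)) - fitted)^2,
                                         nrow = 3))))
  expect_equal(kabsch(P, Q)$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("TM-score closed forms hold and score is monotone in distance", {
  L <- 100
  expect_equal(tm_score(rep(0, L), L), 1.0)
  d0 <- tm_d0(L)
  expect_equal(tm_score(rep(d0, L), L), 0.5)
  expect_equal(tm_score(rep(0, L / 2), L), 0.5)
  expect_error(tm_score(rep(1, 10), 15), "L_norm")
  expect_error(tm_score(c(1, -1), 100), "negative")
  # monotone non-increasing as any distance grows
  d <- runif(50, 0, 8)
  s0 <- tm_score(d, L)
  for (i in c(1, 25, 50)) {
    d2 <- d; d2[i] <- d2[i] + 1
    expect_lte(tm_score(d2, L), s0)
  }
})

test_that("structure-based sequence identity is simple pair arithmetic", {
  mk <- function(ra, rb) {
    al <- structure(list(n_aligned = length(ra),
                         pairs = data.frame(resid_a = ra, resid_b = rb)),
                    class = "pvr_alignment")
    seq_identity(al)
  }
  expect_equal(mk(rep("ALA", 5), rep("ALA", 5)), 100)
  expect_equal(mk(rep("ALA", 5), rep("GLY", 5)), 0)
  expect_equal(mk(c(rep("ALA", 3), rep("SER", 7)),
                  c(rep("ALA", 3), rep("GLY", 7))), 30)
})

test_that("self-alignment is perfect; rigid copies align fully", {
  ens <- generate_ensemble(small_spec(3, noise_sigma = 0,
                                      transforms = "identity"))
  tr <- ca_trace(ens$structures[[1]], "A")
  al <- align_pair(tr, tr)
  expect_identical(al$n_aligned, nrow(tr))
  expect_equal(al$rmsd, 0, tolerance = 1e-8)
  expect_equal(al$tm_score, 1, tolerance = 1e-8)
  expect_equal(al$seq_identity, 100)
})

test_that("a planted insertion stays unaligned while the core pairs up", {
  spec <- small_spec(11, n_structures = 2,
                     planted_regions = list(list(position = 1,
                                                 lengths = c(0, 15))))
  ens <- generate_ensemble(spec)
  al <- align_pair(ca_trace(ens$structures[[1]], "A"),
                   ca_trace(ens$structures[[2]], "A"))
  # structure 2 = 40 core + 15 loop + 40 core; reference has no loop
  loop_idx <- 41:55
  expect_lte(sum(al$pairs$bi %in% loop_idx), 2)
  core_pairs <- al$pairs[!(al$pairs$bi %in% loop_idx), ]
  expected_bi <- ifelse(core_pairs$ai <= 40, core_pairs$ai, core_pairs$ai + 15)
  expect_gte(mean(core_pairs$bi == expected_bi), 0.99)
})

test_that("alignment is symmetric on rigid synthetic cases", {
  ens <- generate_ensemble(small_spec(5, noise_sigma = 0.1))
  a <- ca_trace(ens$structures[[1]], "A")
  b <- ca_trace(ens$structures[[2]], "A")
  ab <- align_pair(a, b)
  ba <- align_pair(b, a)
  key_ab <- paste(ab$pairs$ai, ab$pairs$bi)
  key_ba <- paste(ba$pairs$bi, ba$pairs$ai)
  expect_gte(length(intersect(key_ab, key_ba)) / length(key_ab), 0.98)
})

test_that("core correspondences are recovered at low noise", {
  spec <- synthetic_spec(seed = 21, n_structures = 2,
                         core_blocks = c(60, 60),
                         planted_regions = list(list(position = 1,
                                                     lengths = c(5, 20))),
                         noise_sigma = 0.3)
  ens <- generate_ensemble(spec)
  al <- align_pair(ca_trace(ens$structures[[1]], "A"),
                   ca_trace(ens$structures[[2]], "A"))
  # ground truth from the generator's alignment table
  truth <- ens$msa$cells
  got <- setNames(al$pairs$bi, al$pairs$ai)
  core_cols <- which(!is.na(truth[1, ]) & !is.na(truth[2, ]))
  correct <- sum(got[as.character(truth[1, core_cols])] == truth[2, core_cols],
                 na.rm = TRUE)
  expect_gte(correct / length(core_cols), 0.99)
})

test_that("subset selection applies strict thresholds", {
  mk <- function(n_aligned, rmsd)
    structure(list(n_aligned = n_aligned, rmsd = rmsd),
              class = "pvr_alignment")
  kept <- select_subset(list(mk(221, 5), mk(100, 2.9), mk(220, 3.0)))
  expect_length(kept, 2)
  expect_identical(vapply(kept, `[[`, numeric(1), "n_aligned"), c(221, 100))
})
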