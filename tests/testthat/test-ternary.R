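test_that("clip-normalisation maps raw triples onto the simplex", {
  # proportional triple reads directly as percentages
  expect_equal(unlist(to_ternary(0.3, 0.3, 0.4)[, c("c", "h", "r")]),
               c(c = 0.3, h = 0.3, r = 0.4))
  expect_equal(unlist(to_ternary(1, 0, 0)[, c("c", "h", "r")]),
               c(c = 1, h = 0, r = 0))
  # negative components clip to zero before normalising
  expect_equal(unlist(to_ternary(-0.2, 0.5, 0.5)[, c("c", "h", "r")]),
               c(c = 0, h = 0.5, r = 0.5))
  # all-nonpositive triple degenerates to the barycentre
  deg <- to_ternary(-1, -0.5, 0)
  expect_true(deg$degenerate)
  expect_equal(unlist(deg[, c("c", "h", "r")]), c(c = 1, h = 1, r = 1) / 3)
  expect_error(to_ternary(Inf, 0, 0), "non-finite")
})

test_that("the simplex mapping is scale-invariant and sums to one", {
  set.seed(1)
  m <- matrix(runif(300, -0.5, 1.5), 100, 3)
  out <- to_ternary(m)
  expect_equal(out$c + out$h + out$r, rep(1, 100), tolerance = 1e-9)
  expect_true(all(out$c >= 0 & out$h >= 0 & out$r >= 0))
  for (alpha in c(0.1, 2, 50)) {
    pos <- m[rowSums(pmax(m, 0)) > 0, ]
    expect_equal(to_ternary(alpha * pos), to_ternary(pos), tolerance = 1e-12)
  }
  sm <- to_ternary_softmax(m)
  expect_equal(sm$c + sm$h + sm$r, rep(1, 100), tolerance = 1e-9)
})

test_that("residual flags follow the thresholds and only fire when recovered", {
  flag <- function(c, h, lab = "recovered")
    residual_dili_flag(list(c = c, h = h, r = 1 - c - h), lab)
  expect_identical(flag(0.0, 0.41)$level, "major")
  expect_identical(flag(0.0, 0.41)$driver, "H")
  f <- flag(0.25, 0.18)
  expect_identical(f$level, "minor"); expect_identical(f$driver, "C")
  expect_identical(flag(0, 0)$level, "none")
  expect_identical(flag(0.22, 0.21)$driver, "both")
  expect_identical(flag(0.9, 0, lab = "cholestatic")$level, "none")
  # monotone: increasing the injury coordinate never lowers the level
  lv <- c(none = 0, minor = 1, major = 2)
  grid <- seq(0, 0.9, by = 0.05)
  levels <- lv[vapply(grid, function(g) flag(g, 0)$level, "")]
  expect_true(all(diff(levels) >= 0))
})

test_that("transition labelling identifies simplex moves", {
  # hepatocellular-to-cholestatic shift as seen in longitudinal episodes
  tr <- data.frame(c = c(0.03, 0.42), h = c(0.63, 0.26))
  tr$r <- 1 - tr$c - tr$h
  out <- classify_transition(tr)
  expect_identical(out$steps$move, "h_to_c")
  expect_identical(out$summary, "h_to_c")
  # constant trajectory is stable throughout
  cons <- data.frame(c = rep(0.3, 4), h = rep(0.3, 4), r = rep(0.4, 4))
  expect_true(all(classify_transition(cons)$steps$move == "stable"))
  expect_identical(classify_transition(cons)$summary, "stable")
  # a linear march to the recovered vertex is toward-recovery at every step
  n <- 5
  lin <- data.frame(c = seq(0.6, 0, length.out = n),
                    h = seq(0.4, 0, length.out = n))
  lin$r <- 1 - lin$c - lin$h
  out <- classify_transition(lin)
  expect_true(all(out$steps$move == "toward_recovery"))
  expect_identical(out$summary, "toward_recovery")
  single <- classify_transition(lin[1, ])
  expect_identical(single$summary, "single_timepoint")
  expect_identical(nrow(single$steps), 0L)
})

test_that("trajectories order timepoints and attach labels", {
  coords <- data.frame(sample_id = c("a2", "a1", "b1"),
                       c = c(0.2, 0.6, 0.1), h = c(0.1, 0.2, 0.1),
                       r = c(0.7, 0.2, 0.8))
  rec <- data.frame(sample_id = c("a1", "a2", "b1"),
                    patient_id = c("A", "A", "B"),
                    timepoint_index = c(1L, 2L, 1L))
  calls <- data.frame(sample_id = c("a1", "a2", "b1"),
                      label = c("cholestatic", "recovered", "recovered"))
  traj <- build_trajectories(coords, rec, calls)
  expect_named(traj, c("A", "B"))
  expect_identical(traj$A$sample_id, c("a1", "a2"))
  expect_identical(traj$A$label, c("cholestatic", "recovered"))
  expect_identical(classify_transition(traj$A)$steps$move, "toward_recovery")
})

test_that("ternary rendering places vertices correctly and writes the TSV", {
  coords <- data.frame(sample_id = c("vc", "vh", "vr"),
                       c = c(1, 0, 0), h = c(0, 1, 0), r = c(0, 0, 1),
                       label = c("cholestatic", "hepatocellular", "recovered"),
                       timepoint_index = 1:3)
  # the affine simplex-to-plane map puts the poles at the triangle corners
  xy <- diliternary:::simplex_to_plane(coords$c, coords$h, coords$r)
  expect_equal(unlist(xy[1, ]), c(x = 0, y = 0), tolerance = 1e-6)
  expect_equal(unlist(xy[2, ]), c(x = 1, y = 0), tolerance = 1e-6)
  expect_equal(unlist(xy[3, ]), c(x = 0.5, y = sqrt(3) / 2), tolerance = 1e-6)
  f <- withr::local_tempfile(fileext = ".png")
  out <- render_ternary(coords, f, title = "poles")
  expect_true(file.exists(f))
  expect_true(file.exists(out$tsv))
  back <- read.delim(out$tsv)
  expect_equal(back$c, coords$c, tolerance = 1e-6)
  expect_equal(back$r, coords$r, tolerance = 1e-6)
  expect_error(render_ternary(coords[0, ], f), "no coordinates")
})
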