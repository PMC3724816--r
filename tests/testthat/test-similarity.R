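test_that("pair point sets intersect self and cross tables by query gene", {
  self <- bmt("X", "X", c("g1", "g2", "g3"), c(-50, -60, -70))
  cross <- bmt("X", "Y", c("g1", "g3"), c(-10, -20), subj = c("h1", "h3"))
  pts <- pair_points(self, cross)
  expect_equal(pts$n, 2L)
  expect_equal(pts$x, c(-50, -70))
  expect_equal(pts$y, c(-10, -20))

  # identical tables put every point on the diagonal
  ptsd <- pair_points(self, self)
  expect_equal(ptsd$x, ptsd$y)

  empty <- bmt("X", "Y", character(0), numeric(0))
  expect_error(pair_points(self, empty), "no comparable points")
  other <- bmt("Z", "Y", "g1", -5)
  expect_error(pair_points(self, other), "taxon mismatch")
})

test_that("averaged coordinates are arithmetic means", {
  self <- bmt("X", "X", c("g1", "g2"), c(-10, -20))
  cross <- bmt("X", "Y", c("g1", "g2"), c(-5, -15), subj = c("h", "i"))
  expect_equal(average_coordinates(pair_points(self, cross)),
               c(AvE_X = -15, AvE_Y = -10))
  one <- bmt("X", "X", "g1", -50)
  onec <- bmt("X", "Y", "g1", -30, subj = "h")
  expect_equal(average_coordinates(pair_points(one, onec)),
               c(AvE_X = -50, AvE_Y = -30))
})

test_that("slope m hits its endpoints and the hand-worked case", {
  expect_identical(slope_m(-100, -100, cutoff = 1), 1)     # identical genomes
  expect_identical(slope_m(-100, 1, cutoff = 1), 0)        # no similarity
  expect_equal(slope_m(-101, -50, cutoff = 1), 0.5)        # (-51)/(-102)
  expect_error(slope_m(1, -50, cutoff = 1), "degenerate")
  expect_warning(m <- slope_m(-100, -100.01, cutoff = 1), "clamped")
  expect_identical(m, 1)
})

test_that("tan(theta) conventions agree at the endpoints", {
  expect_identical(tan_theta(1, "angle"), 0)
  expect_identical(tan_theta(1, "complement"), 0)
  expect_identical(tan_theta(0, "angle"), 1)
  expect_identical(tan_theta(0, "complement"), 1)
  expect_equal(tan_theta(0.5, "angle"), 1 / 3)
  expect_equal(tan_theta(0.5, "complement"), 0.5)
  expect_error(tan_theta(1.2), "\\[0, 1\\]")
})

test_that("tan(theta) is antitone in m and bounded in [0,1]", {
  m <- seq(0, 1, by = 0.05)
  for (conv in c("angle", "complement")) {
    tt <- tan_theta(m, conv)
    expect_true(all(diff(tt) < 0))
    expect_true(all(tt >= 0 & tt <= 1))
  }
})

test_that("shifting cross values toward the cut-off strictly decreases m", {
  set.seed(11)
  x <- stats::runif(50, -180, -5)
  self <- bmt("X", "X", paste0("g", 1:50), x)
  m_prev <- Inf
  for (shift in c(0, 20, 40, 60)) {
    y <- pmin(0.6 * x + shift, 1)
    cross <- bmt("X", "Y", paste0("g", 1:50), y,
                 subj = paste0("h", 1:50))
    sim <- pair_similarity(self, cross)
    expect_lt(sim$m, m_prev)
    m_prev <- sim$m
  }
})

test_that("all-ordered-pairs statistics keep both orientations", {
  tables <- gen_best_hit_tables(c("A", "B", "C"), gene_count = 40,
                                target_m = 0.6, seed = 5)
  sims <- tantheta_matrix(tables)
  expect_equal(nrow(sims), 6L)  # 3 taxa -> 6 ordered pairs
  expect_true(all(sims$tan_theta >= 0 & sims$tan_theta <= 1))

  expect_error(tantheta_matrix(tables[-2L]), "missing")
})

test_that("self-comparison yields m = 1 and tan(theta) = 0 exactly", {
  tables <- gen_best_hit_tables(c("A", "B"), gene_count = 30,
                                target_m = 0.5, seed = 9)
  self <- tables[[grep("^A\rA$", names(tables))]]
  sim <- pair_similarity(self, self)
  expect_identical(sim$m, 1)
  expect_identical(sim$tan_theta, 0)
})

test_that("noiseless synthetic tables reproduce the target slope", {
  tables <- gen_best_hit_tables(c("A", "B"), gene_count = 200,
                                target_m = 0.7, noise_sd = 0, seed = 2)
  sims <- tantheta_matrix(tables, convention = "angle")
  expect_equal(sims$m, rep(0.7, 2), tolerance = 1e-12)
  expect_equal(sims$tan_theta, rep(0.3 / 1.7, 2), tolerance = 1e-9)
})

test_that("reciprocal-best-hit filtering keeps only mutual pairs", {
  xy <- bmt("X", "Y", c("g1", "g2"), c(-40, -30), subj = c("h1", "h2"))
  yx <- bmt("Y", "X", c("h1", "h2"), c(-40, -25), subj = c("g1", "g9"))
  filt <- reciprocal_best_hits(xy, yx)
  expect_identical(filt$xy$records$query_gene, "g1")  # g2 -> h2 -> g9 drops
  expect_identical(filt$yx$records$query_gene, "h1")

  e1 <- bmt("X", "Y", character(0), numeric(0))
  e2 <- bmt("Y", "X", character(0), numeric(0))
  both <- reciprocal_best_hits(e1, e2)
  expect_equal(nrow(both$xy$records), 0L)

  expect_error(reciprocal_best_hits(xy, xy), "orientations")
})
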