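test_that("fragment_windows follows the floor contract", {
  w <- fragment_windows(5000)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$start, w$end), c(0, 5000))

  w <- fragment_windows(6000)
  expect_equal(w$start, c(0, 500, 1000))

  expect_warning(w0 <- fragment_windows(4999), "no windows")
  expect_equal(nrow(w0), 0)

  w <- fragment_windows(21000)
  expect_equal(nrow(w), 33)
})

test_that("tetra_odds is neutral on a homopolymer and conserves totals", {
  odds <- tetra_odds("AAAAA")
  expect_length(odds, 256)
  expect_equal(unname(odds["AAAA"]), 1)
  expect_true(all(odds == 1))

  set.seed(51)
  for (rep in 1:5) {
    w <- random_dna(3000, gc = runif(1, 0.3, 0.7))
    x <- Biostrings::DNAString(w)
    obs <- Biostrings::oligonucleotideFrequency(x, 4)
    f <- as.numeric(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
    f <- f / sum(f)
    expd <- sum(obs) * kronecker(f, kronecker(f, kronecker(f, f)))
    expect_equal(sum(expd), sum(obs), tolerance = 1e-9)
    odds <- tetra_odds(w)
    expect_true(all(is.finite(odds)) && all(odds >= 0))
  }
  # N-containing windows skip N positions but still conserve
  wn <- paste0(random_dna(1000), "NNN", random_dna(1000))
  expect_true(all(is.finite(tetra_odds(wn))))
  expect_error(tetra_odds("ANN"), "fewer than 4")
})

test_that("odds depend only on window content", {
  set.seed(52)
  w <- random_dna(5000)
  expect_identical(tetra_odds(w), tetra_odds(w))
})

test_that("uniform-random composition gives near-neutral odds", {
  set.seed(53)
  odds <- tetra_odds(random_dna(100000, gc = 0.5))
  expect_lt(mean(abs(odds - 1)), 0.2)
})

test_that("concat_and_profile fragments the concatenation", {
  set.seed(54)
  cassettes <- replicate(10, random_dna(2100))
  prof <- concat_and_profile(cassettes, "DGR")
  expect_s3_class(prof, "tetra_profiles")
  expect_equal(nrow(prof$odds), 33)  # floor((21000 - 5000)/500) + 1
  expect_equal(unique(prof$meta$group), "DGR")
  # single sequence equals fragment_windows + tetra_odds composition
  s <- random_dna(6000)
  p1 <- concat_and_profile(s, "genome")
  expect_equal(nrow(p1$odds), 3)
  expect_equal(unname(p1$odds[2, ]), unname(tetra_odds(substr(s, 501, 5500))))
  expect_error(concat_and_profile(random_dna(1000), "x"), "smaller window")
  expect_error(concat_and_profile(character(0), "x"))
})

test_that("NMDS is deterministic for a fixed seed and embeds planar data faithfully", {
  set.seed(55)
  pts <- matrix(rnorm(60), ncol = 2)
  d <- dist(pts)
  o1 <- nmds(d, seed = 7, n_starts = 5)
  o2 <- nmds(d, seed = 7, n_starts = 5)
  expect_identical(o1$coords, o2$coords)
  expect_identical(o1$stress, o2$stress)
  # planar configuration re-embeds with near-zero stress
  expect_lt(o1$stress, 0.05)
  expect_equal(unname(colMeans(o1$coords)), c(0, 0), tolerance = 1e-8)
  # Procrustes-aligned recovery of the original configuration
  pr <- vegan::procrustes(pts, o1$coords, symmetric = TRUE)
  scale_ref <- sqrt(mean(scale(pts, scale = FALSE)^2))
  expect_lt(sqrt(mean(residuals(pr)^2)), 0.1 * scale_ref)
})

test_that("NMDS on a symmetric 4-point configuration has minimal stress", {
  # equilateral triangle plus a replicate of one vertex
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0) + 1e-6)
  o <- nmds(dist(pts), seed = 3, n_starts = 10)
  expect_lt(o$stress, 0.01)
  expect_error(nmds(dist(pts[1:3, ]), seed = 1), "at least")
})

test_that("confidence ellipses follow the chi-square covariance construction", {
  # degenerate: identical points
  pts <- matrix(rep(c(2, 3), each = 10), ncol = 2)
  ell <- confidence_ellipse(pts, rep("g", 10))
  expect_equal(c(ell$semi_axis1, ell$semi_axis2), c(0, 0))
  expect_equal(c(ell$center_x, ell$center_y), c(2, 3))

  # isotropic Gaussian: both semi-axes near sqrt(qchisq(.95, 2))
  set.seed(56)
  g <- matrix(rnorm(20000), ncol = 2)
  ell <- confidence_ellipse(g, rep("g", 10000))
  expect_equal(ell$semi_axis1, sqrt(qchisq(0.95, 2)), tolerance = 0.05)
  expect_equal(ell$semi_axis2, sqrt(qchisq(0.95, 2)), tolerance = 0.05)

  # axis-aligned anisotropic: angle ~ 0 (mod pi), axis ratio ~ 2
  an <- cbind(rnorm(10000, sd = 2), rnorm(10000, sd = 1))
  ell <- confidence_ellipse(an, rep("g", 10000))
  ang <- abs(((ell$angle + pi / 2) %% pi) - pi / 2)
  expect_lt(ang, 0.1)
  expect_equal(ell$semi_axis1 / ell$semi_axis2, 2, tolerance = 0.1)

  # small groups are skipped with a warning
  expect_warning(e2 <- confidence_ellipse(g[1:5, ], c("a", "a", "b", "b", "b")),
                 "skipped")
  expect_equal(e2$group, "b")

  # higher level strictly contains the 0.95 ellipse
  e95 <- confidence_ellipse(an, rep("g", 10000), level = 0.95)
  e99 <- confidence_ellipse(an, rep("g", 10000), level = 0.99)
  expect_gt(e99$semi_axis1, e95$semi_axis1)
  expect_gt(e99$semi_axis2, e95$semi_axis2)
})

test_that("outlier flags isolate composition shifts from the genome core", {
  set.seed(57)
  core <- matrix(rnorm(400), ncol = 2)
  shifted <- matrix(rnorm(60, mean = 6), ncol = 2)
  coords <- rbind(core, shifted, c(0, 0))
  labels <- c(rep("genome", 200), rep("RT", 30), "center")
  ord <- structure(list(coords = coords, stress = 0, seed = 1, n_starts = 1,
                        meta = NULL), class = "dgr_ordination")
  rep_ <- outlier_report(ord, labels, "genome")
  expect_lt(rep_$fraction_by_group[["genome"]], 0.10)
  expect_gt(rep_$fraction_by_group[["RT"]], 0.5)
  # a point exactly at the core centroid is never flagged
  ctr_flag <- rep_$flags$outlier[labels == "center"]
  expect_false(ctr_flag)
})

test_that("windows from a GC-shifted composition ordinate as outliers", {
  set.seed(58)
  genome_prof <- concat_and_profile(random_dna(40000, gc = 0.45), "genome",
                                    window = 5000, step = 2000)
  shift_prof <- concat_and_profile(random_dna(15000, gc = 0.62), "RT",
                                   window = 5000, step = 2000)
  all_prof <- bind_profiles(genome_prof, shift_prof)
  ord <- nmds(all_prof, seed = 11, n_starts = 10)
  rep_ <- outlier_report(ord, genome_group_label = "genome")
  expect_gt(rep_$fraction_by_group[["RT"]], 0.5)
})
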