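test_that("zero-jitter models round-trip their generator parameters", {
  for (s in 1:5) {
    set.seed(s * 100)
    geom <- waxsboost:::.waxs_geom
    form <- runif(11) < 0.6
    tw0 <- ifelse(form, geom$twist_aform, geom$twist_bform)
    rs0 <- ifelse(form, geom$rise_aform, geom$rise_bform)
    p <- helical_params(8.6 + 1.4 * runif(1),
                        tw0 + runif(1, -2, 2) + runif(11, -0.5, 0.5),
                        rs0 + runif(1, -0.2, 0.2) + runif(11, -0.05, 0.05),
                        form, jitter_scale = 0,
                        conformation_id = sprintf("rt%d", s))
    m <- build_duplex(p)
    axis <- fit_helical_axis(m)
    expect_equal(compute_radius(m, axis), p$radius, tolerance = 1e-6)
    tr <- compute_twist_rise(m, axis)
    expect_equal(unname(tr["twist"]), mean(p$step_twist), tolerance = 1e-6)
    expect_equal(unname(tr["rise"]), mean(p$step_rise), tolerance = 1e-6)
    # per-step values, not just means
    sg <- waxsboost:::step_geometry(m, axis)
    expect_equal(sg$twist, p$step_twist, tolerance = 1e-6)
    expect_equal(sg$rise, p$step_rise, tolerance = 1e-6)
    # A-form class recovered exactly from geometry
    expect_identical(classify_aform_steps(m, axis)$flags, p$step_form)
  }
})

test_that("the fitted axis matches construction and transforms equivariantly", {
  p <- helical_params(9.4, rep(32.7, 11), rep(2.81, 11))
  m <- build_duplex(p)  # built about the z axis
  ax <- fit_helical_axis(m)
  expect_gt(abs(sum(ax$direction * c(0, 0, 1))), 1 - 1e-9)

  R <- rotation_matrix(3)
  m_rot <- transform_model(m, R, shift = c(4, -2, 9))
  ax_rot <- fit_helical_axis(m_rot)
  # direction rotates with the model (sign-insensitive)
  expect_gt(abs(sum(ax_rot$direction * as.numeric(t(R) %*% ax$direction))),
            1 - 1e-9)

  # jittered model: fitted axis within 5 degrees of a brute-force
  # principal-component fit of the bp centers
  pj <- helical_params(9.4, rep(32.7, 11), rep(2.81, 11), jitter_scale = 0.2)
  mj <- build_duplex(pj, seed = 4)
  axj <- fit_helical_axis(mj)
  ctrs <- waxsboost:::bp_centers(mj)
  pca_dir <- prcomp(ctrs)$rotation[, 1]
  expect_gt(abs(sum(axj$direction * pca_dir)), cos(5 * pi / 180))
})

test_that("radius equals the brute-force point-to-line mean and scales linearly", {
  p <- helical_params(9.0, rep(33, 11), rep(2.8, 11), jitter_scale = 0.3)
  m <- build_duplex(p, seed = 6)
  ax <- fit_helical_axis(m)
  P <- as.matrix(m$beads[m$beads$bead == "phosphate", c("x", "y", "z")])
  d_brute <- apply(P, 1, function(pt) {
    rel <- pt - ax$origin
    sqrt(sum((rel - sum(rel * ax$direction) * ax$direction)^2))
  })
  expect_equal(compute_radius(m, ax), mean(d_brute), tolerance = 1e-9)

  # doubling coordinates about the axis doubles the radius
  m0 <- build_duplex(helical_params(9.0, rep(33, 11), rep(2.8, 11)))
  m2 <- m0
  m2$beads$x <- 2 * m0$beads$x
  m2$beads$y <- 2 * m0$beads$y
  expect_equal(compute_radius(m2), 2 * compute_radius(m0), tolerance = 1e-6)
})

test_that("mirror-imaged (left-handed) duplexes are rejected", {
  m <- build_duplex(helical_params(9.4, rep(32.7, 11), rep(2.81, 11)))
  m$beads$x <- -m$beads$x   # reflection flips handedness
  expect_error(compute_twist_rise(m), "Left-handed")
})

test_that("the canonical A-form major groove is 8.7 A and shrinks on coupled unwinding", {
  expect_equal(major_groove_width(canonical_aform()), 8.7, tolerance = 1e-3)

  # divalent-ion-like compaction: twist and rise reduced together
  widths <- vapply(seq(0, 1, length.out = 5), function(t) {
    p <- helical_params(9.4, rep(32.7 - 8 * t, 11), rep(2.81 - 0.9 * t, 11))
    major_groove_width(build_duplex(p))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("groove width matches an exhaustive cross-strand scan and is discretization-stable", {
  p <- helical_params(9.2, rep(31.5, 11), rep(2.7, 11),
                      c(rep(TRUE, 8), rep(FALSE, 3)), jitter_scale = 0.1)
  m <- build_duplex(p, seed = 2)
  ax <- fit_helical_axis(m)
  got <- major_groove_width(m, ax)

  # brute-force oracle: plain double loop over dense spline samples with
  # the same base-orientation gate
  b <- m$beads
  getP <- function(strand) {
    pp <- b[b$bead == "phosphate" & b$strand == strand, ]
    bp <- if (strand == 1L) pp$residue else 13L - pp$residue
    pp <- pp[order(bp), ]
    fr <- waxsboost:::axis_frame(as.matrix(pp[, c("x", "y", "z")]), ax)
    cbind(fr$u1, fr$u2, fr$s)
  }
  P1 <- getP(1L); P2 <- getP(2L)
  f1 <- lapply(1:3, function(k) splinefun(1:12, P1[, k]))
  f2 <- lapply(1:3, function(k) splinefun(1:12, P2[, k]))
  bb <- b[b$bead == "base", ]
  bpb <- ifelse(bb$strand == 1L, bb$residue, 13L - bb$residue)
  frb <- waxsboost:::axis_frame(as.matrix(bb[, c("x", "y", "z")]), ax)
  azb <- waxsboost:::unwrap(vapply(1:12, function(i)
    atan2(mean(frb$u2[bpb == i]), mean(frb$u1[bpb == i])), numeric(1)))
  fpsi <- splinefun(1:12, azb)
  best <- Inf
  for (t1 in seq(3, 10, length.out = 300)) {
    a1 <- c(f1[[1]](t1), f1[[2]](t1), f1[[3]](t1))
    psi <- fpsi(t1) + pi
    for (t2 in seq(1, 12, length.out = 300)) {
      a2 <- c(f2[[1]](t2), f2[[2]](t2), f2[[3]](t2))
      mid <- (a1 + a2) / 2
      if (cos(atan2(mid[2], mid[1]) - psi) > 0) {
        best <- min(best, sqrt(sum((a1 - a2)^2)))
      }
    }
  }
  expect_equal(got, best, tolerance = 1e-9)
  expect_equal(got, major_groove_width(m, ax, n_dense = 1200), tolerance = 5e-3)
})

test_that("step classification covers the full class domain", {
  all_a <- build_duplex(helical_params(9.4, rep(32.7, 11), rep(2.81, 11),
                                       rep(TRUE, 11)))
  geom <- waxsboost:::.waxs_geom
  all_b <- build_duplex(helical_params(9.4, rep(geom$twist_bform, 11),
                                       rep(geom$rise_bform, 11),
                                       rep(FALSE, 11)))
  expect_identical(classify_aform_steps(all_a)$class, 11L)
  expect_identical(classify_aform_steps(all_b)$class, 0L)

  mixed <- build_duplex(helical_params(
    9.4, ifelse(1:11 <= 5, geom$twist_aform, geom$twist_bform),
    ifelse(1:11 <= 5, geom$rise_aform, geom$rise_bform),
    1:11 <= 5))
  expect_identical(classify_aform_steps(mixed)$class, 5L)
})

test_that("descriptors are invariant under rigid-body motion and bead reindexing", {
  p <- helical_params(9.3, rep(32, 11), rep(2.9, 11),
                      c(rep(TRUE, 7), rep(FALSE, 4)), jitter_scale = 0.15)
  m <- build_duplex(p, seed = 8)
  d0 <- duplex_descriptors(m)
  mt <- transform_model(m, rotation_matrix(5), shift = c(-7, 3, 12))
  d1 <- duplex_descriptors(mt)
  expect_equal(as.data.frame(d1[, -1]), as.data.frame(d0[, -1]),
               tolerance = 1e-9)

  m_shuf <- m
  m_shuf$beads <- m$beads[sample(nrow(m$beads)), ]
  d2 <- duplex_descriptors(m_shuf)
  expect_equal(as.data.frame(d2[, -1]), as.data.frame(d0[, -1]),
               tolerance = 1e-9)
})
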