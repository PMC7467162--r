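test_that("assembly replicates labels across conditions and matches a fresh descriptor pass", {
  ens <- sample_ensemble(2, seed = 21)
  ds <- assemble_dataset(ens)
  expect_equal(dim(ds$features), c(18, 191))
  expect_equal(nrow(ds$labels), 18)

  one <- ds$labels[ds$labels$conformation_id == ens[[1]]$conformation_id, ]
  expect_equal(nrow(one), 9)
  expect_equal(length(unique(one$radius)), 1)

  fresh <- ensemble_descriptors(ens)
  got <- ds$labels[!duplicated(ds$labels$conformation_id),
                   colnames(fresh)]
  expect_equal(as.data.frame(got), as.data.frame(fresh), tolerance = 1e-12)

  # features are logs of strictly positive intensities, and the log
  # transform preserves row-wise ordering
  expect_true(all(is.finite(ds$features)))
  r <- ds$features[1, ]
  expect_identical(order(r), order(10^r))
})

test_that("re-assembly of the same ensemble is bit-stable", {
  ens <- sample_ensemble(4, seed = 33)
  d1 <- assemble_dataset(ens)
  d2 <- assemble_dataset(ens)
  expect_identical(d1$features, d2$features)
  s1 <- split_by_conformation(d1, seed = 5)
  s2 <- split_by_conformation(d2, seed = 5)
  expect_identical(s1$split, s2$split)
})

test_that("conformation-grouped splitting honors fractions, grouping and the partition property", {
  ds <- fake_dataset(100)
  sp <- split_by_conformation(ds, seed = 3)
  tags <- tapply(sp$split, sp$labels$conformation_id, unique)
  expect_true(all(lengths(tags) == 1))                # grouping
  expect_equal(sum(unlist(tags) == "train"), 68)
  expect_equal(sum(unlist(tags) == "validation"), 17)
  expect_equal(sum(unlist(tags) == "test"), 15)
  expect_true(all(table(sp$split) %% 9 == 0))

  # property: partition + grouping hold for every seed
  ds2 <- fake_dataset(37, n_cond = 4)
  for (seed in 1:100) {
    s <- split_by_conformation(ds2, seed = seed)
    per_conf <- tapply(s$split, s$labels$conformation_id, function(x)
      length(unique(x)))
    expect_true(all(per_conf == 1))
    n <- tapply(s$labels$conformation_id, s$split, function(x)
      length(unique(x)))
    expect_equal(sum(n), 37)
    expect_equal(as.integer(n[c("train", "validation", "test")]),
                 c(37 - floor(0.17 * 37) - floor(0.15 * 37),
                   floor(0.17 * 37), floor(0.15 * 37)))
  }

  expect_error(split_by_conformation(ds, fractions = c(0.5, 0.5, 0.2)),
               "summing to 1")
})

test_that("noise injection is multiplicative with the stated relative scale", {
  ds <- fake_dataset(3)
  expect_identical(add_noise(ds, 0)$features, ds$features)

  # implied signal-to-noise of the 5% variant
  expect_equal(1 / 0.05, 20)

  # empirical spot check: sd of injected noise ~ level * I at n = 10000
  big <- fake_dataset(1, n_cond = 1, n_q = 3)
  big$features <- matrix(rep(big$features[1, ], each = 10000), 10000, 3)
  colnames(big$features) <- sprintf("q_%.3f", big$qgrid)
  big$labels <- big$labels[rep(1, 10000), ]
  big$labels$conformation_id <- sprintf("c%05d", 1:10000)
  noisy <- add_noise(big, 0.05, seed = 8)
  I0 <- 10^big$features[1, ]
  sds <- apply(10^noisy$features, 2, sd)
  expect_equal(sds, 0.05 * I0, tolerance = 0.05)
  mns <- colMeans(10^noisy$features)
  expect_equal(mns, I0, tolerance = 0.01)

  expect_error(add_noise(ds, 1.2), "\\[0, 1\\)")
})

test_that("q-resampling is the identity on the default grid and matches a spline oracle", {
  ens <- sample_ensemble(1, seed = 55)
  ds <- assemble_dataset(ens)
  expect_identical(resample_qgrid(ds, 191)$features, ds$features)

  for (np in c(100, 400)) {
    r <- resample_qgrid(ds, np)
    expect_equal(ncol(r$features), np)
    expect_length(r$qgrid, np)
    expect_equal(range(r$qgrid), range(ds$qgrid))
    # independent oracle: scalar splinefun per row over intensities
    f <- splinefun(ds$qgrid, 10^ds$features[1, ], method = "fmm")
    expect_equal(unname(10^r$features[1, ]), unname(f(r$qgrid)),
                 tolerance = 1e-8)
  }
  expect_error(resample_qgrid(ds, 1), "at least 2")
})

test_that("label randomization keeps features and stays inside observed domains", {
  ds <- fake_dataset(40)
  rl <- randomize_labels(ds, seed = 17)
  expect_identical(rl$features, ds$features)
  for (col in c("radius", "twist", "rise", "major_groove_width")) {
    expect_true(all(rl$labels[[col]] >= min(ds$labels[[col]]) &
                    rl$labels[[col]] <= max(ds$labels[[col]])))
    expect_false(identical(rl$labels[[col]], ds$labels[[col]]))
  }
  expect_true(all(rl$labels$aform_class %in% unique(ds$labels$aform_class)))
  # labels still replicate within a conformation
  per_conf <- tapply(rl$labels$radius, rl$labels$conformation_id,
                     function(x) length(unique(x)))
  expect_true(all(per_conf == 1))
})

test_that("the frozen test hash detects tampering", {
  ds <- split_by_conformation(fake_dataset(30), seed = 2)
  expect_silent(waxsboost:::assert_test_intact(ds))
  ds$features[which(ds$split == "test")[1], 1] <- 99
  expect_error(waxsboost:::assert_test_intact(ds), "Test rows have changed")
})
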