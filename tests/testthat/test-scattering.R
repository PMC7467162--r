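test_that("the default q grid has 191 points and fenceposts are enforced", {
  q <- make_qgrid()
  expect_length(q, 191)
  expect_equal(q[1], 0)
  expect_equal(q[191], 0.95)
  expect_equal(unique(round(diff(q), 10)), 0.005)

  expect_equal(make_qgrid(0, 1, 0.5), c(0, 0.5, 1))
  expect_error(make_qgrid(0, 1, 0.3), "divide")
  expect_error(make_qgrid(1, 0, 0.1), "smaller")
  expect_error(make_qgrid(0, 1, -0.1), "positive")
})

test_that("single- and two-bead profiles match their closed forms", {
  m <- canonical_aform()
  m$beads <- m$beads[1, ]
  m$beads$electrons <- 10
  q <- make_qgrid()
  prof <- debye_profile(m, q, r_bead = 2.5)
  expect_equal(prof$intensity, (10 * exp(-(q * 2.5)^2 / 2))^2, tolerance = 1e-12)
  expect_equal(prof$intensity[1], 100)

  m2 <- canonical_aform()
  m2$beads <- m2$beads[1:2, ]
  m2$beads$electrons <- 7
  m2$beads[, c("x", "y", "z")] <- list(c(0, 0), c(0, 0), c(0, 3.7))
  prof2 <- debye_profile(m2, q, r_bead = 0)
  qd <- q * 3.7
  expected <- 2 * 49 * (1 + ifelse(qd == 0, 1, sin(qd) / qd))
  expect_equal(prof2$intensity, expected, tolerance = 1e-12)
})

test_that("the 72-bead profile matches a brute-force double sum everywhere", {
  m <- sample_ensemble(1, seed = 77)[[1]]
  q <- make_qgrid()
  prof <- debye_profile(m, q, r_bead = 2.5)

  xyz <- as.matrix(m$beads[, c("x", "y", "z")])
  el <- m$beads$electrons
  oracle <- vapply(q, function(qq) {
    f <- el * exp(-(qq * 2.5)^2 / 2)
    s <- 0
    for (i in 1:72) for (j in 1:72) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s <- s + f[i] * f[j] * (if (qq * d == 0) 1 else sin(qq * d) / (qq * d))
    }
    s
  }, numeric(1))
  expect_equal(prof$intensity, oracle, tolerance = 1e-8)

  # I(0) equals the squared total electron count; positive everywhere
  expect_equal(prof$intensity[1], sum(el)^2)
  expect_true(all(prof$intensity > 0))
})

test_that("Debye profiles are invariant under rigid-body motion", {
  m <- sample_ensemble(1, seed = 12)[[1]]
  mt <- transform_model(m, rotation_matrix(2), shift = c(1, -9, 4))
  p0 <- debye_profile(m)
  p1 <- debye_profile(mt)
  expect_equal(p1$intensity, p0$intensity, tolerance = 1e-9)
})

test_that("the condition model is deterministic and yields nine corrected profiles", {
  conds <- default_conditions()
  expect_equal(nrow(conds), 9)
  expect_equal(sum(conds$salt == "KCl"), 5)
  expect_equal(sum(conds$salt == "MgCl2"), 4)
  expect_setequal(conds$concentration_mM[conds$salt == "KCl"],
                  c(30, 50, 100, 200, 500))
  expect_setequal(conds$concentration_mM[conds$salt == "MgCl2"],
                  c(0.25, 0.5, 1, 5))

  prof <- debye_profile(canonical_aform())
  out <- lapply(seq_len(nrow(conds)), function(j) apply_condition(prof, conds[j, ]))
  expect_length(out, 9)
  expect_setequal(vapply(out, attr, "", "condition"), conds$condition_id)

  # identity condition leaves the profile unchanged
  ident <- conds[1, ]
  ident$contrast_epsilon <- 0; ident$offset_frac <- 0
  expect_equal(apply_condition(prof, ident)$intensity, prof$intensity)
  expect_error(apply_condition(prof, "NaCl_1mM"), "Unknown condition")
})

test_that("the profile constructor validates its inputs", {
  p <- swaxs_profile(c(0, 0.1, 0.2), c(10, 9, 8), sigma = c(1, 1, 1))
  expect_s3_class(p, "swaxs_profile")
  expect_equal(nrow(p), 3)
  expect_error(swaxs_profile(c(0, 0.2, 0.1), c(1, 2, 3)), "increasing")
  expect_error(swaxs_profile(c(0, 0.1), c(1, 2, 3)), "length")
  expect_error(swaxs_profile(c(0, 0.1), c(1, 2), sigma = c(-1, 1)),
               "non-negative")
})

test_that("error propagation defaults to identity and is pluggable", {
  s <- c(0, 0.1, 0.5)
  expect_identical(propagate_error(s), s)
  expect_identical(propagate_error(0), 0)
  expect_error(propagate_error(c(-1, 0)), "non-negative")
  expect_error(propagate_error(0.1, snr = 0), "positive")
  rule <- function(sigma, snr) sigma * sqrt(1 + 1 / snr)
  expect_equal(propagate_error(c(1, 2), snr = c(4, 4), rule = rule),
               c(1, 2) * sqrt(1.25))
})

test_that("the offset fit has the weighted-mean closed form", {
  prof <- debye_profile(canonical_aform())
  q <- prof$q
  exp_same <- waxsboost:::new_profile(q, prof$intensity, sigma = rep(1, length(q)))
  expect_equal(fit_offset_c(prof, exp_same), 0)

  shifted <- waxsboost:::new_profile(q, prof$intensity + 12.5,
                                     sigma = rep(2, length(q)))
  expect_equal(fit_offset_c(prof, shifted), 12.5)

  # heteroscedastic case against a 1-D numerical minimizer
  set.seed(4)
  sig <- runif(length(q), 0.5, 5)
  pert <- waxsboost:::new_profile(q, prof$intensity + rnorm(length(q), 3, 2),
                                  sigma = sig)
  c_hat <- fit_offset_c(prof, pert)
  loss <- function(cc) sum((prof$intensity + cc - pert$intensity)^2 / sig^2)
  c_num <- optimize(loss, c_hat + c(-10, 10), tol = 1e-12)$minimum
  expect_equal(c_hat, c_num, tolerance = 1e-9)

  # a plugged propagation rule changes the weights but not the closed form
  rule <- function(sigma, snr) sigma * 2
  c_rule <- fit_offset_c(prof, pert, rule = rule)
  loss2 <- function(cc) sum((prof$intensity + cc - pert$intensity)^2 / (2 * sig)^2)
  expect_equal(c_rule, optimize(loss2, c_rule + c(-10, 10), tol = 1e-12)$minimum,
               tolerance = 1e-9)

  # translation equivariance and optimality of the corrected residual
  shifted2 <- waxsboost:::new_profile(q, pert$intensity + 7, sigma = sig)
  expect_equal(fit_offset_c(prof, shifted2), c_hat + 7, tolerance = 1e-9)
  res_corr <- sum((prof$intensity + c_hat - pert$intensity)^2 / sig^2)
  res_raw <- sum((prof$intensity - pert$intensity)^2 / sig^2)
  expect_lte(res_corr, res_raw)

  expect_error(fit_offset_c(prof, waxsboost:::new_profile(q[-1], prof$intensity[-1])),
               "identical q grid")
  zero_sig <- waxsboost:::new_profile(q, prof$intensity, sigma = rep(0, length(q)))
  expect_error(fit_offset_c(prof, zero_sig), "degenerate")
})
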