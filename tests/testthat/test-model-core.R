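test_that("parameter validation enforces the per-step bounds and non-degeneracy", {
  expect_s3_class(canonical_params(), "kinetic_params")
  expect_error(kinetic_params(R = 1, C = 0.6, P = 0.3, mu_PR = 0.5,
                              mu_R = 0.2, mu_P = 0.3), "C \\+ mu_PR")
  expect_error(kinetic_params(R = 1, C = 0.2, P = 0.9, mu_PR = 0.2,
                              mu_R = 0.2, mu_P = 0.3), "mu_R \\+ P")
  expect_error(kinetic_params(R = -1, C = 0.2, P = 0.3, mu_PR = 0.2,
                              mu_R = 0.2, mu_P = 0.3), "positive")
  # C + mu_PR == mu_R: repeated geometric mode, excluded
  expect_error(kinetic_params(R = 1, C = 0.1, P = 0.3, mu_PR = 0.1,
                              mu_R = 0.2, mu_P = 0.3), "degenerate")
  expect_error(reduced_params(0.5, 0.5, 0.7), "degenerate")
  expect_error(reduced_params(0.5, 1.2, 0.7), "inside")
})

test_that("one-step map reproduces the worked example and fixes 0 and w", {
  kp <- canonical_params()
  expect_equal(gene_step(kp, c(1, 1, 1), 0), c(0.5, 1, 1))
  expect_identical(gene_step(kp, c(0, 0, 0), 0), c(0, 0, 0))
  w <- fixed_point_w(kp)
  expect_equal(gene_step(kp, w, 1), w)
  for (k in 1:10) {
    p <- random_params()
    w <- fixed_point_w(p)
    expect_equal(gene_step(p, w, 1), w, tolerance = 1e-12)
    expect_identical(gene_step(p, c(0, 0, 0), 0), c(0, 0, 0))
  }
})

test_that("fixed point w matches the formula, iteration, and scales linearly in R", {
  kp <- canonical_params()
  expect_equal(fixed_point_w(kp), c(2, 2, 2))
  kp2 <- kinetic_params(R = 2, C = 1/4, P = 1/3, mu_PR = 1/4,
                        mu_R = 1/4, mu_P = 1/3)
  expect_equal(fixed_point_w(kp2), 2 * fixed_point_w(kp))
  x <- c(5, -1, 3)
  for (k in 1:200) x <- gene_step(kp, x, 1)
  expect_close(x, fixed_point_w(kp), 1e-9)
})

test_that("closed-form flow equals iterated stepping and starts at the state", {
  set.seed(11)
  for (k in 1:20) {
    p <- random_params()
    x0 <- rnorm(3, sd = 2)
    i <- rbinom(1, 1, 0.5)
    expect_equal(gene_flow(p, 0, x0, i), x0,
                 ignore_attr = TRUE, tolerance = 1e-12)
    x <- x0
    for (n in 1:30) {
      x <- gene_step(p, x, i)
      if (n %in% c(1, 3, 10, 30))
        expect_close(gene_flow(p, n * p$delta, x0, i), x, 1e-9)
    }
  }
})

test_that("flow relaxes to w * i and accepts non-integer times", {
  kp <- canonical_params()
  expect_close(gene_flow(kp, 400, c(0, 0, 0), 1), c(2, 2, 2), 1e-10)
  expect_close(gene_flow(kp, 400, c(1, 2, 3), 0), c(0, 0, 0), 1e-10)
  # vectorized time grid, continuous interpolation between steps
  tt <- c(0, 0.5, 1, 2.25)
  out <- gene_flow(kp, tt, c(1, 1, 1), 1)
  expect_equal(dim(out), c(4L, 3L))
  expect_equal(out[3, ], gene_step(kp, c(1, 1, 1), 1), ignore_attr = TRUE)
})

test_that("mode decomposition reproduces every printed coefficient of the example", {
  kp <- canonical_params()
  md <- mode_decomposition(kp, c(0, 0, 0), 1)
  expect_equal(md$ratios, c(a = 1/2, b = 3/4, c = 2/3))
  expected <- rbind(xi1 = c(-2, 0, 0, 2),
                    xi2 = c(2, -4, 0, 2),
                    xi3 = c(-4, -16, 18, 2))
  colnames(expected) <- c("a", "b", "c", "const")
  expect_equal(md$coefficients, expected, tolerance = 1e-12)
  # general initial state: coefficients are affine in (xi1(0), xi2(0), xi3(0), i)
  set.seed(4)
  x0 <- rnorm(3)
  for (i in 0:1) {
    M <- mode_decomposition(kp, x0, i)$coefficients
    expect_equal(M["xi1", "a"], x0[1] - 2 * i)
    expect_equal(M["xi2", "b"], x0[2] + x0[1] - 4 * i)
    expect_equal(M["xi2", "a"], -(x0[1] - 2 * i))
    expect_equal(M["xi3", "c"], x0[3] - 4 * x0[2] - 6 * x0[1] + 18 * i)
    expect_equal(M["xi3", "b"], 4 * x0[2] + 4 * x0[1] - 16 * i)
    expect_equal(M["xi3", "a"], 2 * x0[1] - 4 * i)
    expect_equal(unname(M[, "const"]), c(2, 2, 2) * i)
  }
  # zero state, gene off: the zero solution
  M0 <- mode_decomposition(kp, c(0, 0, 0), 0)$coefficients
  expect_true(all(M0 == 0))
})

test_that("mode reconstruction matches the first few iterated steps", {
  set.seed(21)
  for (k in 1:5) {
    p <- random_params()
    x0 <- rnorm(3)
    i <- rbinom(1, 1, 0.5)
    md <- mode_decomposition(p, x0, i)
    x <- x0
    for (n in 0:2) {
      rec <- drop(md$coefficients %*% c(md$ratios^n, 1))
      expect_close(rec, x, 1e-10)
      x <- gene_step(p, x, i)
    }
  }
})

test_that("reduction to (a, b, c) matches the example and rejects degeneracy", {
  r <- reduce_params(canonical_params())
  expect_equal(c(r$a, r$b, r$c), c(1/2, 3/4, 2/3))
  for (k in 1:10) {
    r <- reduce_params(random_params())
    expect_true(all(c(r$a, r$b, r$c) > 0 & c(r$a, r$b, r$c) < 1))
  }
})

test_that("reduced coordinates are an exact conjugacy of the dynamics", {
  kp <- canonical_params()
  expect_identical(to_reduced(kp, c(0, 0, 0)), c(0, 0, 0))
  set.seed(7)
  for (k in 1:10) {
    p <- random_params()
    x <- rnorm(3, sd = 3)
    expect_close(from_reduced(p, to_reduced(p, x)), x, 1e-10)
    expect_close(to_reduced(p, from_reduced(p, x)), x, 1e-10)
  }
  # stepping the reduced affine system and mapping back reproduces the
  # original trajectory for 50 steps
  maps <- ifs_maps(reduce_params(kp))
  x <- c(1, 0.4, 0.9)
  s <- to_reduced(kp, x)
  for (n in 1:50) {
    x <- gene_step(kp, x, 1)
    s <- apply_map(maps, 1, s)
    expect_close(from_reduced(kp, s), x, 1e-9)
  }
})

test_that("on/off flows are mirror images through w/2", {
  kp <- canonical_params()
  expect_equal(symmetry_residual(kp, 0, c(1, 2, 3)), 0, tolerance = 1e-12)
  w <- fixed_point_w(kp)
  expect_lt(symmetry_residual(kp, 5, c(1, 1, 1)), 1e-9 * (1 + sqrt(sum(w^2))))
  set.seed(13)
  for (k in 1:20) {
    p <- random_params()
    w <- fixed_point_w(p)
    res <- symmetry_residual(p, runif(1, 0, 30), rnorm(3, sd = 2))
    expect_lt(res, 1e-9 * (1 + sqrt(sum(w^2))))
  }
})

test_that("the box [0, w] is invariant under both one-step maps", {
  set.seed(5)
  for (k in 1:30) {
    p <- random_params()
    w <- fixed_point_w(p)
    x <- random_box_state(p)
    for (i in 0:1) {
      y <- gene_step(p, x, i)
      expect_true(all(y >= -1e-12 & y <= w + 1e-12))
    }
  }
})
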