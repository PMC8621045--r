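# Grid densities, moments, entropy and the four two-PDF distances.
# Expected values are frozen from the Gaussian closed forms (KL,
# Bhattacharyya, entropy, L2 product integrals), independently of the
# quadrature code they check.

# mass defect helper (test-only shorthand)
grid_trapz_for_test <- function(pdf) {
  w <- rep(pdf$grid$dx, pdf$grid$n); w[c(1, pdf$grid$n)] <- pdf$grid$dx / 2
  sum(w * pdf$p) - 1
}

test_that("gaussian sampling on a grid is normalized with the exact peak and variance", {
  g <- grid1d(-6, 6, 2049)  # odd count puts a node at x = 0
  p <- gaussian_to_grid(gaussian_state(0, pi), g)
  expect_equal(max(p$p), 1, tolerance = 1e-6)          # peak (beta/pi)^(1/2)
  g2 <- grid1d(-5, 15, 2048)
  p2 <- gaussian_to_grid(gaussian_state(5, 0.3), g2)
  expect_lt(abs(grid_trapz_for_test(p2)), 1e-8)        # unit mass
  p3 <- gaussian_to_grid(gaussian_state(0, 0.5), g)
  expect_equal(moments(p3)$variance, 1, tolerance = 1e-6)
  expect_lt(max(abs(p3$q^2 - p3$p)), 4e-16 * max(p3$p))
  expect_error(gaussian_to_grid(gaussian_state(0, 0.01), g), "cover")
})

test_that("moments reproduce the Gaussian identities and symmetry", {
  g <- grid1d(-10, 14, 2048)
  m <- moments(gaussian_to_grid(gaussian_state(2, 0.5), g))
  expect_equal(m$mean, 2, tolerance = 1e-8)
  expect_equal(m$variance, 1, tolerance = 1e-6)
  m0 <- moments(gaussian_to_grid(gaussian_state(0, 0.5), g))
  expect_equal(m0$m4, 3, tolerance = 1e-5)             # <dx^4> = 3 sigma^4
  # symmetric bimodal mixture has zero mean
  a <- gaussian_to_grid(gaussian_state(-3, 2), g)
  b <- gaussian_to_grid(gaussian_state(3, 2), g)
  mix <- grid_pdf(g, (a$p + b$p) / 2)
  expect_equal(moments(mix)$mean, 0, tolerance = 1e-10)
})

test_that("differential entropy matches the Gaussian closed form and ln(width) for uniform", {
  g <- grid1d(-8, 8, 4096)
  expect_equal(differential_entropy(gaussian_to_grid(gaussian_state(0, pi), g)),
               0.5, tolerance = 1e-5)
  expect_equal(differential_entropy(gaussian_to_grid(gaussian_state(0, 0.5), g)),
               0.5 * log(2 * pi * exp(1)), tolerance = 1e-5)  # 1.418939
  # uniform density of width e embedded on a wider grid: S = ln(w) = 1
  w <- exp(1)
  p <- ifelse(abs(g$x) <= w / 2, 1 / w, 0)
  expect_equal(differential_entropy(grid_pdf(g, p, renormalize = TRUE)),
               1, tolerance = 1e-2)  # trapezoid smears the two jump nodes
})

test_that("KL, Jensen, Wootters and L2 match their Gaussian closed forms", {
  g <- grid1d(-14, 14, 2048)
  n01 <- gaussian_to_grid(gaussian_state(0, 0.5), g)
  n11 <- gaussian_to_grid(gaussian_state(1, 0.5), g)
  n04 <- gaussian_to_grid(gaussian_state(0, 1 / 8), g)  # variance 4
  n21 <- gaussian_to_grid(gaussian_state(2, 0.5), g)
  expect_equal(kl_divergence(n01, n11), 0.5, tolerance = 1e-5)
  expect_equal(kl_divergence(n01, n04), gaussian_kl(0, 1, 0, 4),
               tolerance = 1e-5)                        # 0.3181472
  expect_equal(jensen_divergence(n01, n11), 0.5, tolerance = 1e-5)
  expect_identical(jensen_divergence(n01, n11), jensen_divergence(n11, n01))
  expect_equal(wootters_distance(n01, n21), acos(exp(-0.5)),
               tolerance = 1e-6)                        # 0.9191067
  expect_equal(l2_distance(n01, n11), (1 - exp(-0.25)) / sqrt(pi),
               tolerance = 1e-6)                        # 0.1247926
})

test_that("distances vanish iff the densities coincide and respect support rules", {
  g <- grid1d(-14, 14, 1024)
  p <- gaussian_to_grid(gaussian_state(0.5, 1), g)
  expect_identical(kl_divergence(p, p), 0)
  expect_identical(l2_distance(p, p), 0)
  expect_identical(wootters_distance(p, p), 0)
  # disjoint supports: Wootters saturates at pi/2, KL is +Inf
  left <- ifelse(g$x < -2, exp(-(g$x + 5)^2), 0)
  right <- ifelse(g$x > 2, exp(-(g$x - 5)^2), 0)
  pl <- grid_pdf(g, left, renormalize = TRUE)
  pr <- grid_pdf(g, right, renormalize = TRUE)
  expect_equal(wootters_distance(pl, pr), pi / 2)
  expect_identical(kl_divergence(pl, pr), Inf)
  # grid mismatch is an error
  g2 <- grid1d(-14, 14, 512)
  expect_error(kl_divergence(p, gaussian_to_grid(gaussian_state(0.5, 1), g2)),
               "grid")
})

test_that("Gibbs inequality and closed-form agreement hold across random Gaussian pairs", {
  set.seed(11)
  g <- grid1d(-40, 40, 8192)
  for (i in 1:100) {
    y1 <- runif(1, -2, 2); b1 <- runif(1, 0.05, 20)
    y2 <- runif(1, -2, 2); b2 <- runif(1, 0.05, 20)
    p1 <- gaussian_to_grid(gaussian_state(y1, b1), g)
    p2 <- gaussian_to_grid(gaussian_state(y2, b2), g)
    kf <- kl_divergence(p1, p2)
    expect_gte(kf, 0)
    expect_equal(kf, gaussian_kl(y1, 1 / (2 * b1), y2, 1 / (2 * b2)),
                 tolerance = 1e-5)
    expect_equal(wootters_distance(p1, p2),
                 acos(gaussian_bhattacharyya(y1, 1 / (2 * b1), y2, 1 / (2 * b2))),
                 tolerance = 1e-5)
    expect_equal(differential_entropy(p1), gaussian_entropy(b1),
                 tolerance = 1e-5)
  }
})

test_that("halving the grid spacing moves smooth-input distances by less than 1e-6", {
  for (n in c(1024L, 2048L)) {
    g <- grid1d(-12, 12, n)
    p1 <- gaussian_to_grid(gaussian_state(0, 0.5), g)
    p2 <- gaussian_to_grid(gaussian_state(1, 0.7), g)
    d <- distance_report(p1, p2)
    if (n == 1024L) d_coarse <- d else {
      expect_lt(abs(d$wootters - d_coarse$wootters), 1e-6)
      expect_lt(abs(d$kl_forward - d_coarse$kl_forward), 1e-6)
      expect_lt(abs(d$jensen - d_coarse$jensen), 1e-6)
      expect_lt(abs(d$l2 - d_coarse$l2), 1e-6)
    }
  }
  # Jensen is the average of the two one-sided divergences by construction
  g <- grid1d(-12, 12, 1024)
  p1 <- gaussian_to_grid(gaussian_state(0, 0.5), g)
  p2 <- gaussian_to_grid(gaussian_state(1, 0.7), g)
  r <- distance_report(p1, p2)
  expect_equal(r$jensen, (r$kl_forward + r$kl_backward) / 2, tolerance = 1e-12)
})
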