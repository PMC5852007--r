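test_that("the cubic weight hits its endpoint values", {
  expect_equal(lwm_weight(0), 1)
  expect_equal(lwm_weight(1), 0)
  expect_equal(lwm_weight(2), 0)
  expect_equal(lwm_weight(0.5), 0.5)
  expect_error(lwm_weight(-0.1), "nonnegative")
})

test_that("the weight is C1 at both support endpoints", {
  # 4-point one-sided difference: exact for cubic polynomials
  h <- 0.01
  d0 <- (-11 * lwm_weight(0) + 18 * lwm_weight(h) -
          9 * lwm_weight(2 * h) + 2 * lwm_weight(3 * h)) / (6 * h)
  d1 <- (11 * lwm_weight(1) - 18 * lwm_weight(1 - h) +
          9 * lwm_weight(1 - 2 * h) - 2 * lwm_weight(1 - 3 * h)) / (6 * h)
  expect_lt(abs(d0), 1e-12)
  expect_lt(abs(d1), 1e-12)
})

test_that("n below 6 is refused and duplicates are an error", {
  set.seed(1)
  src <- cbind(runif(20, 0, 10), runif(20, 0, 10))
  expect_error(lwm(src, src, n = 5), "ill-conditioned")
  dup <- rbind(src, src[3, ])
  expect_error(lwm(dup, rbind(src, src[3, ] + 1), n = 6), "duplicate")
  expect_error(lwm(src[1:8, ], src[1:8, ], n = 12), "at least n")
})

test_that("identity and global affine mappings are reproduced exactly", {
  set.seed(2)
  src <- cbind(runif(50, 0, 40), runif(50, 0, 40))
  fit_id <- lwm(src, src, n = 12)
  expect_lt(max(abs(predict(fit_id, src) - src)), 1e-9)
  expect_lt(max(abs(residuals(fit_id))), 1e-9)
  A <- matrix(c(1.1, 0.2, -0.1, 0.9), 2, 2)
  b <- c(3, -2)
  tgt <- src %*% t(A) + rep(1, 50) %*% t(b)
  fit <- lwm(src, tgt, n = 12)
  # every local polynomial carries the affine coefficients, quadratics ~ 0
  cf <- coef(fit)
  expect_lt(max(abs(cf$x[, 4:6])), 1e-8)
  expect_lt(max(abs(cf$y[, 4:6])), 1e-8)
  expect_lt(max(abs(cf$x[, 2:3] - rep(1, 50) %*% t(A[1, ]))), 1e-8)
  expect_lt(max(abs(cf$y[, 2:3] - rep(1, 50) %*% t(A[2, ]))), 1e-8)
})

test_that("a global quadratic is reproduced at interior query points", {
  set.seed(3)
  src <- cbind(runif(60, 0, 30), runif(60, 0, 30))
  tgt <- cbind(src[, 1] + 0.1 * src[, 1]^2, src[, 2])
  fit <- lwm(src, tgt, n = 12)
  q <- cbind(runif(200, 8, 22), runif(200, 8, 22))
  expect_lt(max(abs(predict(fit, q) -
                    cbind(q[, 1] + 0.1 * q[, 1]^2, q[, 2]))), 1e-6)
})

test_that("with n = 6 the transform interpolates its control points", {
  set.seed(4)
  src <- cbind(runif(30, 0, 20), runif(30, 0, 20))
  tgt <- src + cbind(sin(src[, 1] / 3), cos(src[, 2] / 4))
  fit <- lwm(src, tgt, n = 6)
  expect_lt(max(abs(predict(fit, src) - tgt)), 1e-7)
})

test_that("points outside the support error by name unless extrapolating", {
  set.seed(5)
  src <- cbind(runif(20, 0, 10), runif(20, 0, 10))
  fit <- lwm(src, src + 1, n = 8)
  far <- matrix(c(500, 500), 1, 2)
  expect_error(predict(fit, far), "outside the transform's support")
  expect_error(predict(fit, far), "point 1")
  out <- predict(fit, far, extrapolate = TRUE)
  expect_true(attr(out, "extrapolated")[1])
  expect_false(anyNA(out))
})

test_that("perturbing one target only changes the field within reach", {
  set.seed(6)
  src <- as.matrix(expand.grid(seq(0, 36, 4), seq(0, 36, 4)))
  tgt <- src
  fit0 <- suppressWarnings(lwm(src, tgt, n = 8))   # lattice rows are collinear
  tgt2 <- tgt
  tgt2[1, ] <- tgt2[1, ] + 5   # corner control point (0, 0)
  fit1 <- suppressWarnings(lwm(src, tgt2, n = 8))
  # reach: the perturbed point influences polynomials whose neighbourhood
  # contains it; all their supports end within max(Dn) of their centres
  reach <- 2 * max(fit1$Dn)
  q <- cbind(runif(100, 0, 36), runif(100, 0, 36))
  d_from_corner <- sqrt(rowSums(q^2))
  far <- d_from_corner > reach + 12   # 12 = max neighbour-centre distance
  if (any(far)) {
    expect_equal(predict(fit0, q[far, , drop = FALSE]),
                 predict(fit1, q[far, , drop = FALSE]), tolerance = 1e-12)
  }
  near <- matrix(c(1, 1), 1, 2)
  expect_gt(max(abs(predict(fit1, near) - predict(fit0, near))), 0.1)
})

test_that("near-collinear neighbourhoods degrade to affine with a warning", {
  src <- cbind(seq(0, 19), rep(0, 20))          # all on a line
  src <- rbind(src, c(5, 30), c(10, 30), c(15, 30), c(2, 30), c(18, 30),
               c(8, 30))
  tgt <- src + 2
  expect_warning(fit <- lwm(src, tgt, n = 6), "affine")
  expect_true(any(fit$degree == 1L))
  expect_lt(max(abs(predict(fit, src) - tgt)), 1e-6)
})

test_that("transforms survive a JSON round trip", {
  set.seed(8)
  src <- cbind(runif(25, 0, 15), runif(25, 0, 15))
  fit <- lwm(src, src * 1.05 + 2, n = 10)
  tmp <- tempfile(fileext = ".json")
  write_lwm_json(fit, tmp)
  back <- read_lwm_json(tmp)
  q <- cbind(runif(30, 2, 13), runif(30, 2, 13))
  expect_equal(predict(back, q), predict(fit, q), tolerance = 1e-9)
})

test_that("summary and plot methods run", {
  set.seed(9)
  src <- cbind(runif(30, 0, 20), runif(30, 0, 20))
  fit <- lwm(src, src + 0.5, n = 8)
  s <- summary(fit)
  expect_s3_class(s, "summary.lwm")
  expect_lt(s$rms_residual, 1e-8)
  expect_output(print(fit), "control points")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
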