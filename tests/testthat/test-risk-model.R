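test_that("design coding matches a hand-written matrix on a toy fixture", {
  rec <- blank_records(5)
  rec$age <- c(65L, 75L, 85L, 70L, 90L)
  rec$sex <- c(0L, 1L, 0L, 1L, 0L)
  rec$icd10 <- c("J18.9", "J13", "J15.4", "J18.0", "J16.1")
  rec$bun <- c(20.9, 21, 30, 10, 25)
  rec$spo2 <- c(91, 90, 89, 96, 85)
  rec$sbp <- c(91, 90, 120, 85, 100)
  rec$orientation_disturbance <- c(0L, 1L, 0L, 0L, 1L)
  rec$icu <- c(0L, 0L, 1L, 0L, 0L)
  d <- build_design(rec, model_spec())

  expect_equal(d$X[, "age_dec"], c(0, 1, 2, 0.5, 2.5))
  expect_equal(d$X[, "icd10J13"], c(0, 1, 0, 0, 0))
  expect_equal(d$X[, "icd10J15"], c(0, 0, 1, 0, 0))
  expect_equal(d$X[, "icd10J16"], c(0, 0, 0, 0, 1))
  expect_false("icd10J18" %in% colnames(d$X))  # reference family omitted
  # A-DROP cutoffs: BUN >= 21, SpO2 <= 90, SBP <= 90
  expect_equal(d$X[, "bun_high"], c(0, 1, 1, 0, 1))
  expect_equal(d$X[, "spo2_low"], c(0, 1, 1, 0, 1))
  expect_equal(d$X[, "sbp_low"], c(0, 1, 0, 1, 0))
  expect_equal(d$X[, "icu"], c(0, 0, 1, 0, 0))
  # template row: only age (80 -> 1.5 decades) and home admission non-zero
  base <- blank_records(1)
  db <- build_design(base, model_spec())
  expected <- setNames(rep(0, ncol(db$X)), colnames(db$X))
  expected["age_dec"] <- 1.5
  expected["admit_from_home"] <- 1
  expect_equal(db$X[1, ], expected)

  bad <- blank_records(2)
  bad$icd10[2] <- "A41.9"
  expect_error(build_design(bad), "unseen ICD-10")
  bad2 <- blank_records(2)
  bad2$bun[1] <- NA
  expect_error(build_design(bad2), "missing values")
})

test_that("fitted (alpha, sigma) and marginal log-likelihood match the
           50-point Gauss-Hermite grid-search oracle on tiny fixtures", {
  tiny <- glmm_tiny()
  fixtures <- list(
    tiny,
    tiny[tiny$hospital_id %in% c("A", "B"), ]
  )
  for (fx in fixtures) {
    y <- fx$broad_spectrum_use
    cl <- factor(fx$hospital_id)
    X <- matrix(numeric(0), nrow = length(y), ncol = 0,
                dimnames = list(NULL, character(0)))
    fit <- fit_random_intercept_logistic(
      X, y, cl, model_spec(quadrature_order = 25))
    oracle <- oracle_grid_fit(y, cl)
    expect_lt(abs(fit$alpha - oracle$alpha), 1e-2)
    expect_lt(abs(sqrt(fit$sigma2) - oracle$sigma), 1e-2)
    expect_lt(abs(fit$loglik -
                    oracle_loglik_gh50(fit$alpha, sqrt(fit$sigma2), y, cl)),
              1e-4)
  }
})

test_that("null-model recovery: alpha ~ 0 and sigma^2 at the boundary when
           data are generated with alpha = beta = sigma = 0", {
  set.seed(202)
  nh <- 60; nper <- 60
  y <- rbinom(nh * nper, 1, 0.5)
  cl <- factor(rep(seq_len(nh), each = nper))
  X <- matrix(numeric(0), nrow = length(y), ncol = 0,
              dimnames = list(NULL, character(0)))
  fit <- fit_random_intercept_logistic(X, y, cl,
                                       model_spec(quadrature_order = 7))
  se_alpha <- 2 / sqrt(length(y))  # 1/sqrt(n p (1-p)) at p = 1/2
  expect_lt(abs(fit$alpha), 3 * se_alpha)
  expect_lt(fit$sigma2, 0.01)
})

test_that("sigma^2 = 0 fits reduce to ordinary logistic regression", {
  # ten byte-identical clusters: zero between-cluster variance pins the
  # random-intercept variance at the boundary deterministically
  block_x1 <- rep(c(0, 1), each = 15)
  block_x2 <- rep(seq(-1.5, 1.5, length.out = 10), 3)
  block_y <- rep(c(0, 1, 1, 0, 1, 0, 0, 1, 0, 1), 3)
  x1 <- rep(block_x1, 10); x2 <- rep(block_x2, 10)
  y <- rep(block_y, 10)
  cl <- factor(rep(1:10, each = 30))
  X <- cbind(x1 = x1, x2 = x2)
  fit <- fit_random_intercept_logistic(X, y, cl, model_spec())
  expect_lt(fit$sigma2, 1e-8)
  glm_fit <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(fit$alpha, unname(coef(glm_fit)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(coef(glm_fit)[-1]),
               tolerance = 1e-6)
})

test_that("posterior-mode intercepts shrink toward zero and approach the
           no-prior estimate as cluster size grows", {
  # clusters share the crude proportion 0.75 at growing sizes
  sizes <- c(8, 40, 200)
  y <- unlist(lapply(sizes, function(n) rep(c(1, 1, 1, 0), n / 4)))
  cl <- factor(rep(seq_along(sizes), times = sizes))
  # add a reference block so the intercept is identified away from 0.75
  y <- c(y, rep(c(1, 0), 250))
  cl <- factor(c(as.character(cl), rep("ref", 500)),
               levels = c(levels(cl), "ref"))
  X <- matrix(numeric(0), nrow = length(y), ncol = 0,
              dimnames = list(NULL, character(0)))
  fit <- fit_random_intercept_logistic(X, y, cl,
                                       model_spec(quadrature_order = 7))
  g <- fit$gamma_hat[as.character(seq_along(sizes))]
  # no-prior (fixed-effect) estimate of the cluster deviation
  target <- qlogis(0.75) - fit$alpha
  expect_true(all(g > 0 & g < target))
  expect_true(all(diff(g) > 0))  # larger clusters shrink less
})

test_that("predictions follow the inverse-logit contract and the
           unseen-hospital policy", {
  tiny <- glmm_tiny()
  X <- matrix(numeric(0), nrow = nrow(tiny), ncol = 0,
              dimnames = list(NULL, character(0)))
  fit <- fit_random_intercept_logistic(
    X, tiny$broad_spectrum_use, factor(tiny$hospital_id), model_spec(25))

  # hand-built fit: alpha = 0, gamma = 1 for one hospital
  fake <- fit
  fake$alpha <- 0
  fake$gamma_hat <- c(A = 1, B = 0)
  X2 <- matrix(numeric(0), nrow = 2, ncol = 0,
               dimnames = list(NULL, character(0)))
  with_re <- predict_risk(fake, X2, c("A", "B"), include_random = TRUE)
  without <- predict_risk(fake, X2, c("A", "B"), include_random = FALSE)
  expect_equal(with_re$prob, c(plogis(1), 0.5), tolerance = 1e-12)
  expect_equal(without$prob, c(0.5, 0.5), tolerance = 1e-12)
  # gamma-hat = 0 hospital: both modes identical
  expect_equal(with_re$prob[2], without$prob[2])

  unseen <- predict_risk(fake, X2, c("A", "ZZ"), include_random = TRUE)
  expect_identical(unseen$unseen_hospitals, "ZZ")
  expect_equal(unseen$prob[2], 0.5)

  # monotonicity in gamma
  fake2 <- fake
  fake2$gamma_hat["A"] <- 2
  expect_gt(predict_risk(fake2, X2, c("A", "B"))$prob[1], with_re$prob[1])
})

test_that("marginal_loglik agrees with the non-adaptive oracle on a model
           with a covariate", {
  set.seed(404)
  n <- 24
  x <- rbinom(n, 1, 0.5)
  cl <- factor(rep(c("A", "B", "C"), each = 8))
  y <- rbinom(n, 1, plogis(-0.2 + 0.6 * x + c(A = 0.4, B = -0.4, C = 0)[cl]))
  ll_pkg <- marginal_loglik(-0.2, c(x = 0.6), 0.5, cbind(x = x), y, cl)
  # oracle: same integral via non-adaptive GH-50 with the covariate folded in
  gh <- pracma::gaussHermite(50)
  ll_or <- 0
  for (h in levels(cl)) {
    ix <- cl == h
    vals <- vapply(gh$x, function(z) {
      p <- plogis(-0.2 + 0.6 * x[ix] + sqrt(2) * 0.5 * z)
      exp(sum(dbinom(y[ix], 1, p, log = TRUE)))
    }, numeric(1))
    ll_or <- ll_or + log(sum(gh$w * vals) / sqrt(pi))
  }
  expect_equal(ll_pkg, ll_or, tolerance = 1e-8)
})

test_that("VIF equals the closed form on constructed designs", {
  set.seed(505)
  # columns orthogonal to each other and to the intercept: all VIF 1
  X <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(compute_vif(X)), rep(1, 3), tolerance = 1e-8)

  # known sample correlation r: VIF = 1/(1 - r^2) for both columns
  n <- 500
  z1 <- scale(rnorm(n)); z2 <- scale(rnorm(n))
  z2 <- scale(z2 - c(cor(z1, z2)) * z1)  # exactly orthogonal
  r <- 0.9
  x2 <- r * z1 + sqrt(1 - r^2) * z2
  X2 <- cbind(u = as.numeric(z1), v = as.numeric(x2))
  expect_equal(unname(compute_vif(X2)), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-6)

  # duplicated column: infinite VIF, no exception
  X3 <- cbind(p = z1[, 1], q = z1[, 1], s = rnorm(n))
  v <- compute_vif(X3)
  expect_true(is.infinite(v["p"]) && is.infinite(v["q"]))
  expect_false(is.infinite(v["s"]))
})

test_that("separation detection honors the configured policy", {
  y <- rep(c(0, 1), each = 20)
  x <- y  # perfect separation
  cl <- factor(rep(1:4, 10))
  X <- cbind(sep = x)
  expect_error(
    suppressWarnings(fit_random_intercept_logistic(
      X, y, cl, model_spec(quadrature_order = 1))),
    "separation")
  expect_warning(
    fit_random_intercept_logistic(
      X, y, cl, model_spec(quadrature_order = 1, on_separation = "warn")),
    "separation")
})

test_that("degenerate inputs are rejected", {
  X <- cbind(x = rnorm(10))
  expect_error(fit_random_intercept_logistic(X, rep(1, 10),
                                             factor(rep(1:2, 5))),
               "constant")
  expect_error(fit_random_intercept_logistic(X, rbinom(10, 1, 0.5),
                                             factor(rep(1, 10))),
               "2 clusters")
})
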