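test_that("forward-Helmert weights compare levels with subsequent means", {
  L <- contrast_matrix("forward_helmert", 4)$L
  expect_equal(L, rbind(c(1, -1/3, -1/3, -1/3),
                        c(0, 1, -1/2, -1/2),
                        c(0, 0, 1, -1)))
  ## two-level case: both kinds proportional to (1, -1)
  for (kind in c("forward_helmert", "sum")) {
    L2 <- contrast_matrix(kind, 2)$L
    expect_equal(L2[1, 1] / L2[1, 2], -1)
  }
  expect_error(contrast_matrix("sum", 1), "k must be")
  ## coding columns average to zero (balanced zero-coding)
  for (k in 2:6) for (kind in c("forward_helmert", "sum")) {
    C <- contrast_matrix(kind, k)$C
    expect_equal(colMeans(C), rep(0, k - 1))
  }
})

test_that("fitted forward-Helmert coefficients estimate the stated contrasts", {
  ## balanced one-way data with group means (1,2,3,4): least-squares
  ## coefficients must be 1-mean(2,3,4), 2-mean(3,4), 3-4 = (-2,-1.5,-1)
  cm <- contrast_matrix("forward_helmert", 4)
  g <- rep(1:4, each = 5)
  y <- as.numeric(g)                  # group means exactly (1,2,3,4)
  X <- cbind(1, cm$C[g, ])
  beta <- drop(solve(t(X) %*% X, t(X) %*% y))
  expect_equal(unname(beta[-1]), c(-2, -1.5, -1))
  ## and the companion property L %*% means reproduces the same numbers
  expect_equal(drop(cm$L %*% 1:4), c(-2, -1.5, -1))
})

test_that("build_design produces the documented columns and rank", {
  d <- data.frame(ses = rep(c("worst", "worse", "average", "better"), 2),
                  sex = rep(c("F", "M"), each = 4),
                  nsib = rnorm(8))
  terms <- list(design_term("ses", "ordinal_factor", "forward_helmert",
                            c("worst", "worse", "average", "better")),
                design_term("sex", "factor", "sum", c("F", "M")),
                design_term("nsib", "numeric", "none"))
  des1 <- build_design(d, terms[1])
  expect_equal(dim(des1$X), c(8L, 4L))
  des2 <- build_design(d, terms, interactions = list(c("ses", "sex")))
  expect_equal(ncol(des2$X), 1 + 3 + 1 + 1 + 3)
  expect_equal(des2$term_map$`ses:sex`, 7:9)
  ## coded factor columns span the one-hot space
  onehot <- cbind(1, outer(d$ses, c("worse", "average", "better"), `==`) * 1)
  expect_equal(qr(cbind(des1$X, onehot))$rank, qr(des1$X)$rank)
  expect_error(build_design(data.frame(ses = "rich"), terms[1]),
               "outside its declared levels")
})

test_that("IRLS reproduces closed-form intercept-only estimates", {
  fit <- fit_glm(matrix(1, 3, 1), c(1, 2, 3), "poisson_log")
  expect_equal(unname(fit$coefficients), log(2), tolerance = 1e-9)
  expect_true(fit$converged)
  fitb <- fit_glm(matrix(1, 2, 1), c(1, 2), "binomial_logit",
                  denominators = c(2, 3))
  expect_equal(unname(fitb$coefficients), qlogis(0.6), tolerance = 1e-9)
})

test_that("IRLS matches independent Newton maximization on 30-row data", {
  set.seed(101)
  n <- 30
  X <- cbind(1, rnorm(n), runif(n), rbinom(n, 1, 0.5))
  y <- rpois(n, exp(0.5 + 0.3 * X[, 2] - 0.4 * X[, 3] + 0.2 * X[, 4]))
  fit <- fit_glm(X, y, "poisson_log")
  oracle <- oracle_newton_poisson(X, y)
  expect_lt(max(abs(unname(fit$coefficients) - oracle)), 1e-6)
  ## and against stats::glm as a second, independent reference
  ref <- glm.fit(X, y, family = poisson())
  expect_lt(max(abs(unname(fit$coefficients) - ref$coefficients)), 1e-6)

  m <- sample(2:6, n, replace = TRUE)
  ys <- rbinom(n, m, plogis(0.2 + 0.5 * X[, 2]))
  fitb <- fit_glm(X, ys, "binomial_logit", denominators = m)
  oracleb <- oracle_newton_binomial(X, ys, m)
  expect_lt(max(abs(unname(fitb$coefficients) - oracleb)), 1e-6)
  refb <- glm.fit(X, cbind(ys, m - ys), family = binomial())
  expect_lt(max(abs(unname(fitb$coefficients) - refb$coefficients)), 1e-6)
})

test_that("degenerate designs and inputs are rejected", {
  X <- cbind(1, c(1, 2, 3), c(2, 4, 6))
  expect_error(fit_glm(X, c(1, 2, 3), "poisson_log"), "singular")
  expect_error(fit_glm(matrix(1, 3, 1), c(-1, 0, 1), "poisson_log"),
               "negative")
  expect_error(fit_glm(matrix(1, 2, 1), c(3, 1), "binomial_logit",
                       denominators = c(2, 2)), "exceed")
  expect_error(fit_glm(matrix(1, 2, 1), c(1, 1), "binomial_logit"),
               "denominators")
})

test_that("Pearson dispersion follows its definition", {
  fit <- fit_glm(matrix(1, 2, 1), c(1, 3), "poisson_log")
  expect_equal(pearson_dispersion(fit), 1)  # ((1-2)^2+(3-2)^2)/2 / 1
  fit0 <- fit_glm(matrix(1, 3, 1), c(2, 2, 2), "poisson_log")
  expect_equal(pearson_dispersion(fit0), 0, tolerance = 1e-12)
  fit_sat <- fit_glm(diag(2), c(1, 2), "poisson_log")
  expect_error(pearson_dispersion(fit_sat), "zero residual")
  ## large-sample Poisson data: phi ~ 1
  set.seed(5)
  y <- rpois(4000, 3)
  fitl <- fit_glm(matrix(1, 4000, 1), y, "poisson_log")
  expect_lt(abs(pearson_dispersion(fitl) - 1), 3 * sqrt(2 / 4000))
})

test_that("quasi scaling changes no point estimates", {
  set.seed(6)
  d <- data.frame(g = sample(c("a", "b", "c"), 60, replace = TRUE),
                  y = rpois(60, 2))
  des <- build_design(d, list(design_term("g", "factor", "sum",
                                          c("a", "b", "c"))))
  fit <- fit_glm(des, d$y, "poisson_log")
  ## dispersion enters tests and intervals only
  w1 <- type3_wald(fit, 1)
  w2 <- type3_wald(fit, 4)
  expect_equal(w2$chi2, w1$chi2 / 4)
  expect_identical(fit$coefficients, fit_glm(des, d$y,
                                             "poisson_log")$coefficients)
})

test_that("type-3 Wald equals the direct quadratic form", {
  ## single 1-df term with beta 0.5 and scaled SE 0.25 -> chi2 4, p 0.0455
  fake <- structure(list(coefficients = c("(Intercept)" = 1, x = 0.5),
                         cov_unscaled = diag(c(1, 0.25^2)),
                         term_map = list(x = 2L)), class = "glm_fit")
  w <- type3_wald(fake, phi = 1)
  expect_equal(w$chi2, 4)
  expect_equal(w$df, 1L)
  expect_equal(w$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(w$p, 0.0455, tolerance = 1e-3)
  ## zero coefficient block -> chi2 0, p 1
  fake0 <- structure(list(coefficients = c(1, 0, 0),
                          cov_unscaled = diag(3),
                          term_map = list(g = 2:3)), class = "glm_fit")
  w0 <- type3_wald(fake0, phi = 1)
  expect_equal(w0$chi2, 0)
  expect_equal(w0$p, 1)
  ## real fit: every term equals the brute-force quadratic form, and a
  ## 1-df term equals (beta / scaled SE)^2 exactly
  set.seed(7)
  d <- data.frame(g = sample(c("a", "b", "c", "d"), 80, replace = TRUE),
                  s = sample(c("F", "M"), 80, replace = TRUE),
                  y = rpois(80, 2))
  des <- build_design(d, list(
    design_term("g", "ordinal_factor", "forward_helmert",
                c("a", "b", "c", "d")),
    design_term("s", "factor", "sum", c("F", "M"))))
  fit <- fit_glm(des, d$y, "poisson_log")
  phi <- pearson_dispersion(fit)
  w <- type3_wald(fit, phi)
  for (tm in names(fit$term_map)) {
    idx <- fit$term_map[[tm]]
    b <- fit$coefficients[idx]
    V <- phi * fit$cov_unscaled[idx, idx, drop = FALSE]
    expect_equal(w$chi2[w$term == tm], drop(t(b) %*% solve(V) %*% b),
                 tolerance = 1e-10)
  }
  idx_s <- fit$term_map$s
  se_s <- sqrt(phi * fit$cov_unscaled[idx_s, idx_s])
  expect_equal(w$chi2[w$term == "s"],
               unname((fit$coefficients[idx_s] / se_s)^2),
               tolerance = 1e-12)
})

test_that("marginal means reproduce saturated group means", {
  ## saturated balanced one-way Poisson model, group means 2 and 4
  d <- data.frame(g = rep(c("lo", "hi"), each = 4),
                  y = c(1, 3, 2, 2, 3, 5, 4, 4))
  des <- build_design(d, list(design_term("g", "factor", "sum",
                                          c("lo", "hi"))))
  fit <- fit_glm(des, d$y, "poisson_log")
  mm <- estimate_marginal_means(fit, "g")
  expect_equal(mm$response[mm$g == "lo"], 2, tolerance = 1e-8)
  expect_equal(mm$response[mm$g == "hi"], 4, tolerance = 1e-8)
  expect_true(all(mm$lower > 0))
  expect_true(all(mm$lower < mm$response & mm$response < mm$upper))
})

test_that("marginal means agree with a full reference-grid average", {
  set.seed(8)
  d <- data.frame(g = sample(c("a", "b", "c", "d"), 120, replace = TRUE),
                  s = sample(c("F", "M"), 120, replace = TRUE),
                  z = rnorm(120))
  d$y <- rpois(120, exp(0.5 + 0.2 * (d$g == "a") + 0.1 * d$z))
  terms <- list(design_term("g", "ordinal_factor", "forward_helmert",
                            c("a", "b", "c", "d")),
                design_term("s", "factor", "sum", c("F", "M")),
                design_term("z", "numeric", "none"))
  des <- build_design(d, terms)
  fit <- fit_glm(des, d$y, "poisson_log")
  mm <- estimate_marginal_means(fit, "g")
  ## oracle: average the linear predictor over the full g x s grid with z
  ## at its mean, using a from-scratch design construction
  cg <- contrast_matrix("forward_helmert", 4)$C
  cs <- contrast_matrix("sum", 2)$C
  for (gi in 1:4) {
    etas <- vapply(1:2, function(si) {
      x <- c(1, cg[gi, ], cs[si, ], mean(d$z))
      drop(x %*% fit$coefficients)
    }, numeric(1))
    expect_equal(mm$eta[gi], mean(etas), tolerance = 1e-10)
  }
})

test_that("pairwise contrasts difference the marginal linear predictors", {
  set.seed(9)
  d <- data.frame(g = sample(c("a", "b", "c", "d"), 100, replace = TRUE),
                  y = rpois(100, 2))
  des <- build_design(d, list(design_term("g", "ordinal_factor",
                                          "forward_helmert",
                                          c("a", "b", "c", "d"))))
  fit <- fit_glm(des, d$y, "poisson_log")
  phi <- pearson_dispersion(fit)
  ctr <- pairwise_contrasts(fit, "g", phi)
  expect_equal(nrow(ctr), choose(4, 2))
  mm <- estimate_marginal_means(fit, "g", phi)
  est_ab <- ctr$estimate[ctr$label == "a - b"]
  expect_equal(est_ab, mm$eta[mm$g == "a"] - mm$eta[mm$g == "b"],
               tolerance = 1e-10)
  expect_true(all(ctr$p_adj >= ctr$p_raw - 1e-12))
  ## two-level factor: single contrast, p_adj = p_raw
  d2 <- data.frame(g = rep(c("a", "b"), 20), y = rpois(40, 2))
  des2 <- build_design(d2, list(design_term("g", "factor", "sum",
                                            c("a", "b"))))
  fit2 <- fit_glm(des2, d2$y, "poisson_log")
  ctr2 <- pairwise_contrasts(fit2, "g", pearson_dispersion(fit2))
  expect_equal(nrow(ctr2), 1L)
  expect_equal(ctr2$p_adj, ctr2$p_raw)
})

test_that("BH adjustment implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"))
    ## monotone when ordered by raw p
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("saturated binomial fits reproduce binary outcomes", {
  X <- diag(4)
  y <- c(0, 1, 1, 0)
  fit <- fit_glm(X, y, "binomial_logit", denominators = rep(1, 4))
  expect_equal(unname(fit$fitted_mu), y, tolerance = 1e-4)
})
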