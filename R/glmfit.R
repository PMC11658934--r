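## Self-contained GLM machinery: design construction with forward-Helmert
## and sum codings, IRLS fitting for Poisson-log and binomial-logit
## families, Pearson-dispersion (quasi) scaling, type-3 Wald tests,
## estimated marginal means and FDR-adjusted pairwise contrasts.

#' Contrast weight and coding matrices
#'
#' `forward_helmert` compares each level of an ordinal factor with the mean
#' of all subsequent levels: row `j` of the weight matrix `L` has weight 1
#' on level `j`, `-1/(k-j)` on levels `j+1..k`, and 0 before. `sum` rows
#' are indicator-of-level minus indicator-of-last-level. The companion
#' coding matrix `C` (k x (k-1)) is the generalized inverse of `L`
#' augmented with the grand-mean row, so that in a saturated balanced
#' one-way model the fitted coefficient `j` equals `L[j, ] %*% group_means`.
#'
#' @param kind `"forward_helmert"` or `"sum"`.
#' @param k number of levels (>= 2).
#' @return list with `L` ((k-1) x k weight matrix) and `C` (k x (k-1)
#'   coding matrix whose columns average to zero).
#' @export
contrast_matrix <- function(kind = c("forward_helmert", "sum"), k) {
  kind <- match.arg(kind)
  if (!is.numeric(k) || k < 2 || k != round(k))
    stop("k must be an integer >= 2", call. = FALSE)
  k <- as.integer(k)
  L <- matrix(0, k - 1L, k)
  for (j in seq_len(k - 1L)) {
    if (kind == "forward_helmert") {
      L[j, j] <- 1
      L[j, (j + 1L):k] <- -1 / (k - j)
    } else {
      L[j, j] <- 1
      L[j, k] <- -1
    }
  }
  M <- rbind(rep(1 / k, k), L)
  C <- solve(M)[, -1L, drop = FALSE]
  dimnames(L) <- NULL
  dimnames(C) <- NULL
  list(L = L, C = C)
}

#' Describe one model term
#'
#' @param name column name in the data.
#' @param kind `"factor"`, `"ordinal_factor"` or `"numeric"`.
#' @param contrast `"forward_helmert"`, `"sum"` or `"none"` (numeric).
#' @param levels factor levels in order (ignored for numeric terms).
#' @return a `design_term` list.
#' @export
design_term <- function(name, kind = c("factor", "ordinal_factor", "numeric"),
                        contrast = c("forward_helmert", "sum", "none"),
                        levels = NULL) {
  kind <- match.arg(kind)
  contrast <- match.arg(contrast)
  if (kind != "numeric" && (is.null(levels) || length(levels) < 2))
    stop("factor term '", name, "' needs >= 2 levels", call. = FALSE)
  if (kind != "numeric" && contrast == "none")
    stop("factor term '", name, "' needs a contrast", call. = FALSE)
  structure(list(name = name, kind = kind, contrast = contrast,
                 levels = levels), class = "design_term")
}

#' Build a model design matrix
#'
#' Intercept column first, then coded factor columns, numeric columns
#' (raw, uncentred), and interaction columns as elementwise products of the
#' coded columns of the two parent terms.
#'
#' @param data data frame holding all term columns.
#' @param terms list of [design_term()]s.
#' @param interactions list of length-2 character vectors naming
#'   interacting terms.
#' @return object of class `model_design`: `X`, `term_map` (term name ->
#'   column indices), `terms`, `interactions`, `codings`, and
#'   `numeric_means` for marginal-mean grids.
#' @export
build_design <- function(data, terms, interactions = list()) {
  n <- nrow(data)
  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  term_map <- list()
  codings <- list()
  numeric_means <- list()
  cols <- list()
  for (tm in terms) {
    v <- data[[tm$name]]
    if (is.null(v)) stop("column '", tm$name, "' not in data", call. = FALSE)
    if (tm$kind == "numeric") {
      block <- matrix(as.numeric(v), n, 1)
      colnames(block) <- tm$name
      numeric_means[[tm$name]] <- mean(as.numeric(v))
    } else {
      idx <- match(as.character(v), tm$levels)
      if (any(is.na(idx)))
        stop("term '", tm$name, "' has values outside its declared levels",
             call. = FALSE)
      cm <- contrast_matrix(tm$contrast, length(tm$levels))
      codings[[tm$name]] <- cm
      block <- cm$C[idx, , drop = FALSE]
      colnames(block) <- paste0(tm$name, seq_len(ncol(block)))
    }
    cols[[tm$name]] <- block
    term_map[[tm$name]] <- ncol(X) + seq_len(ncol(block))
    X <- cbind(X, block)
  }
  for (ia in interactions) {
    a <- cols[[ia[1]]]
    b <- cols[[ia[2]]]
    if (is.null(a) || is.null(b))
      stop("interaction references unknown term", call. = FALSE)
    block <- matrix(0, n, ncol(a) * ncol(b))
    nm <- character(ncol(a) * ncol(b))
    c0 <- 0L
    for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
      c0 <- c0 + 1L
      block[, c0] <- a[, i] * b[, j]
      nm[c0] <- paste0(colnames(a)[i], ":", colnames(b)[j])
    }
    colnames(block) <- nm
    key <- paste(ia, collapse = ":")
    term_map[[key]] <- ncol(X) + seq_len(ncol(block))
    X <- cbind(X, block)
  }
  structure(list(X = X, term_map = term_map, terms = terms,
                 interactions = interactions, codings = codings,
                 numeric_means = numeric_means),
            class = "model_design")
}

glm_family <- function(family) {
  switch(family,
    poisson_log = list(
      linkinv = exp,
      linkfun = log,
      mu_start = function(y, m) pmax(y, 0) + 0.1,
      variance = function(mu, m) mu,
      weights = function(mu, m) mu,
      dev_resids = function(y, mu, m) {
        r <- mu
        pos <- y > 0
        r[pos] <- y[pos] * log(y[pos] / mu[pos]) - (y[pos] - mu[pos])
        2 * r
      }),
    binomial_logit = list(
      linkinv = stats::plogis,
      linkfun = stats::qlogis,
      mu_start = function(y, m) (y + 0.5) / (m + 1),
      variance = function(mu, m) m * mu * (1 - mu),
      weights = function(mu, m) m * mu * (1 - mu),
      dev_resids = function(y, mu, m) {
        fit <- m * mu
        t1 <- ifelse(y > 0, y * log(y / fit), 0)
        t2 <- ifelse(m - y > 0, (m - y) * log((m - y) / (m - fit)), 0)
        2 * (t1 + t2)
      }),
    stop("unknown family '", family, "'", call. = FALSE))
}

#' Fit a GLM by iteratively reweighted least squares
#'
#' Supports the Poisson family with log link (`poisson_log`, response a
#' count) and the binomial family with logit link (`binomial_logit`,
#' response a success count with `denominators` trials). Convergence when
#' the relative deviance change falls below `1e-10` or after 100
#' iterations; nonconvergence is flagged but results are still returned.
#'
#' @param X design matrix (full column rank) or a `model_design`.
#' @param y response vector (counts, or successes for the binomial family).
#' @param family `"poisson_log"` or `"binomial_logit"`.
#' @param denominators binomial totals (ignored for Poisson).
#' @param term_map optional named list mapping terms to coefficient column
#'   indices (taken from a `model_design` automatically).
#' @return object of class `glm_fit`: `coefficients`, `cov_unscaled`
#'   ((X'WX)^-1), `family`, `deviance`, `pearson_chi2`, `df_resid`,
#'   `dispersion` (Pearson), `converged`, `n_iter`, `term_map`, `design`,
#'   `fitted_mu`, `eta`.
#' @export
fit_glm <- function(X, y, family = c("poisson_log", "binomial_logit"),
                    denominators = NULL, term_map = NULL) {
  family <- match.arg(family)
  design <- NULL
  if (inherits(X, "model_design")) {
    design <- X
    term_map <- X$term_map
    X <- X$X
  }
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (any(y < 0)) stop("negative response", call. = FALSE)
  m <- if (family == "binomial_logit") {
    if (is.null(denominators))
      stop("binomial family needs denominators", call. = FALSE)
    if (any(y > denominators))
      stop("successes exceed denominators", call. = FALSE)
    as.numeric(denominators)
  } else rep(1, n)
  if (qr(X)$rank < p)
    stop("singular design matrix (rank deficient)", call. = FALSE)

  fam <- glm_family(family)
  ## work on the mean scale mu in (0, m) for poisson / proportion for binom
  if (family == "binomial_logit") {
    prop <- y / m
    mu <- fam$mu_start(y, m)          # proportion scale
    eta <- fam$linkfun(mu)
  } else {
    mu <- fam$mu_start(y, m)
    eta <- fam$linkfun(mu)
  }
  dev <- Inf
  converged <- FALSE
  iter <- 0L
  beta <- rep(0, p)
  repeat {
    iter <- iter + 1L
    if (family == "binomial_logit") {
      w <- m * mu * (1 - mu)
      z <- eta + (prop - mu) / (mu * (1 - mu))
      dev_new <- sum(fam$dev_resids(y, mu, m))
    } else {
      w <- mu
      z <- eta + (y - mu) / mu
      dev_new <- sum(fam$dev_resids(y, mu, m))
    }
    w <- pmax(w, 1e-10)
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% z)
    eta <- drop(X %*% beta)
    mu <- if (family == "binomial_logit") {
      pmin(pmax(fam$linkinv(eta), 1e-10), 1 - 1e-10)
    } else pmax(fam$linkinv(eta), 1e-10)
    if (is.finite(dev) && abs(dev - dev_new) / (abs(dev_new) + 0.1) < 1e-10) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
    if (iter >= 100L) break
  }
  dev <- sum(fam$dev_resids(y, mu, m))
  if (family == "binomial_logit") {
    pearson <- sum((y - m * mu)^2 / (m * mu * (1 - mu)))
    w_final <- m * mu * (1 - mu)
  } else {
    pearson <- sum((y - mu)^2 / mu)
    w_final <- mu
  }
  cov_unscaled <- solve(t(X * w_final) %*% X)
  cov_unscaled <- (cov_unscaled + t(cov_unscaled)) / 2
  df_resid <- n - p
  fit <- list(coefficients = stats::setNames(drop(beta), colnames(X)),
              cov_unscaled = cov_unscaled,
              family = family,
              deviance = dev,
              pearson_chi2 = pearson,
              df_resid = df_resid,
              dispersion = if (df_resid > 0) pearson / df_resid else NA_real_,
              converged = converged,
              n_iter = iter,
              term_map = term_map,
              design = design,
              denominators = m,
              fitted_mu = if (family == "binomial_logit") m * mu else mu,
              eta = eta)
  class(fit) <- "glm_fit"
  fit
}

#' Pearson dispersion
#'
#' `phi = pearson_chi2 / df_resid`; quasi-likelihood standard errors and
#' tests scale by `sqrt(phi)`, accommodating both over- and
#' underdispersion without changing point estimates.
#'
#' @param fit a `glm_fit`.
#' @return dispersion estimate `phi`.
#' @export
pearson_dispersion <- function(fit) {
  if (fit$df_resid <= 0)
    stop("dispersion undefined with zero residual degrees of freedom",
         call. = FALSE)
  fit$pearson_chi2 / fit$df_resid
}

#' Type-3 Wald chi-square tests
#'
#' For each term with coefficient block `b` and scaled covariance block
#' `V = phi * cov_unscaled[block, block]`, the statistic is
#' `t(b) V^-1 b` on `length(b)` degrees of freedom. Under sum-to-zero and
#' Helmert-type codings these are type-3 tests of each term given all
#' others.
#'
#' @param fit a `glm_fit` with a term map.
#' @param phi dispersion; defaults to the fit's Pearson dispersion; use 1
#'   for a plain likelihood fit.
#' @return data frame with `term`, `chi2`, `df`, `p`.
#' @export
type3_wald <- function(fit, phi = fit$dispersion) {
  if (is.null(fit$term_map)) stop("fit has no term map", call. = FALSE)
  rows <- lapply(names(fit$term_map), function(tm) {
    idx <- fit$term_map[[tm]]
    b <- fit$coefficients[idx]
    V <- phi * fit$cov_unscaled[idx, idx, drop = FALSE]
    Vi <- tryCatch(solve(V), error = function(e)
      stop("singular covariance block for term '", tm, "'", call. = FALSE))
    chi2 <- drop(t(b) %*% Vi %*% b)
    data.frame(term = tm, chi2 = chi2, df = length(idx),
               p = stats::pchisq(chi2, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Row of the design space for one cell of the reference grid: focal
## factors at given levels, other factors at their balanced (zero-coded)
## values, numeric covariates at their means.
grid_row <- function(design, at) {
  X <- design$X
  x <- stats::setNames(rep(0, ncol(X)), colnames(X))
  x["(Intercept)"] <- 1
  coded <- list()
  for (tm in design$terms) {
    idx <- design$term_map[[tm$name]]
    if (tm$kind == "numeric") {
      x[idx] <- design$numeric_means[[tm$name]]
    } else if (tm$name %in% names(at)) {
      li <- match(at[[tm$name]], tm$levels)
      if (is.na(li)) stop("unknown level for ", tm$name, call. = FALSE)
      row <- design$codings[[tm$name]]$C[li, ]
      x[idx] <- row
      coded[[tm$name]] <- row
    } else {
      coded[[tm$name]] <- rep(0, length(idx))
    }
  }
  for (ia in design$interactions) {
    key <- paste(ia, collapse = ":")
    idx <- design$term_map[[key]]
    a <- coded[[ia[1]]]
    b <- coded[[ia[2]]]
    x[idx] <- as.vector(t(outer(a, b)))
  }
  x
}

#' Estimated marginal means
#'
#' Predicted response for each level (combination) of the focal factor(s),
#' averaging over the other factors at their balanced (zero-coded) values
#' and numeric covariates at their observed means. Confidence intervals
#' are built on the link scale as `estimate +/- 1.959964 * sqrt(phi) * SE`
#' and then inverse-linked, so bounds respect the response range.
#'
#' @param fit a `glm_fit` carrying its `model_design`.
#' @param factors character vector of one or two focal factor names.
#' @param phi dispersion used to scale standard errors.
#' @return data frame with the focal levels, `eta`, `se`, `response`,
#'   `lower`, `upper`.
#' @export
estimate_marginal_means <- function(fit, factors, phi = fit$dispersion) {
  design <- fit$design
  if (is.null(design)) stop("fit carries no model_design", call. = FALSE)
  tnames <- vapply(design$terms, `[[`, character(1), "name")
  if (!all(factors %in% tnames))
    stop("unknown factor(s): ",
         paste(setdiff(factors, tnames), collapse = ", "), call. = FALSE)
  lvl_list <- lapply(factors, function(f)
    design$terms[[match(f, tnames)]]$levels)
  names(lvl_list) <- factors
  grid <- expand.grid(lvl_list, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  linkinv <- glm_family(fit$family)$linkinv
  zq <- 1.959964
  res <- lapply(seq_len(nrow(grid)), function(i) {
    at <- as.list(grid[i, , drop = FALSE])
    x <- grid_row(design, at)
    eta <- drop(x %*% fit$coefficients)
    se <- sqrt(phi * drop(t(x) %*% fit$cov_unscaled %*% x))
    c(eta = eta, se = se)
  })
  res <- do.call(rbind, res)
  out <- cbind(grid,
               eta = res[, "eta"], se = res[, "se"],
               response = linkinv(res[, "eta"]),
               lower = linkinv(res[, "eta"] - zq * res[, "se"]),
               upper = linkinv(res[, "eta"] + zq * res[, "se"]))
  rownames(out) <- NULL
  out
}

#' Pairwise contrasts of a factor's marginal means
#'
#' All pairwise differences of the focal factor's marginal linear
#' predictors, with standard errors scaled by `sqrt(phi)`, Wald z
#' p-values, and Benjamini-Hochberg adjustment over the family of
#' comparisons.
#'
#' @inheritParams estimate_marginal_means
#' @param factor focal factor name.
#' @return data frame with `label`, `estimate` (link scale), `se`, `z`,
#'   `p_raw`, `p_adj`.
#' @export
pairwise_contrasts <- function(fit, factor, phi = fit$dispersion) {
  design <- fit$design
  if (is.null(design)) stop("fit carries no model_design", call. = FALSE)
  tnames <- vapply(design$terms, `[[`, character(1), "name")
  ti <- match(factor, tnames)
  if (is.na(ti)) stop("unknown factor '", factor, "'", call. = FALSE)
  tm <- design$terms[[ti]]
  lv <- tm$levels
  rows <- lapply(lv, function(l) grid_row(design,
                                          stats::setNames(list(l), factor)))
  combs <- utils::combn(length(lv), 2)
  res <- lapply(seq_len(ncol(combs)), function(ci) {
    i <- combs[1, ci]; j <- combs[2, ci]
    d <- rows[[i]] - rows[[j]]
    est <- drop(d %*% fit$coefficients)
    se <- sqrt(phi * drop(t(d) %*% fit$cov_unscaled %*% d))
    z <- est / se
    data.frame(label = paste(lv[i], "-", lv[j]), estimate = est, se = se,
               z = z, p_raw = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_raw)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
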