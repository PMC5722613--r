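# Sufficient statistics per group for the one-random-intercept model
# y_ij = b0 + b1 x_ij + u_i + e_ij,  u_i ~ N(0, va), e_ij ~ N(0, ve).
# With V_i = ve I + va J, V_i^{-1} = (1/ve)(I - c J), c = va/(ve + va n_i),
# all GLS quantities reduce to per-group sums, giving O(G) likelihood
# evaluations.
lmm_stats <- function(y, x, g) {
  g <- factor(g)
  list(n_i = as.numeric(tapply(rep(1, length(y)), g, sum)),
       Sx = as.numeric(tapply(x, g, sum)),
       Sy = as.numeric(tapply(y, g, sum)),
       Sxx = as.numeric(tapply(x * x, g, sum)),
       Sxy = as.numeric(tapply(x * y, g, sum)),
       Syy = as.numeric(tapply(y * y, g, sum)),
       n = length(y), G = nlevels(g))
}

# GLS pieces for weights W_i = I - c_i J (ve factored out); c_i per group
lmm_gls <- function(st, c_i) {
  a11 <- sum(st$n_i - c_i * st$n_i^2)
  a12 <- sum(st$Sx - c_i * st$n_i * st$Sx)
  a22 <- sum(st$Sxx - c_i * st$Sx^2)
  b1 <- sum(st$Sy - c_i * st$n_i * st$Sy)
  b2 <- sum(st$Sxy - c_i * st$Sx * st$Sy)
  yWy <- sum(st$Syy - c_i * st$Sy^2)
  det_xwx <- a11 * a22 - a12^2
  beta <- c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det_xwx
  rss <- yWy - beta[1L] * b1 - beta[2L] * b2
  list(beta = beta, rss = rss, det_xwx = det_xwx,
       xwx = matrix(c(a11, a12, a12, a22), 2L))
}

# -2 * restricted log-likelihood with residual variance profiled out,
# as a function of the variance ratio theta = va/ve (constants dropped)
reml_profile <- function(theta, st) {
  c_i <- theta / (1 + theta * st$n_i)
  gls <- lmm_gls(st, c_i)
  ve <- gls$rss / (st$n - 2L)
  if (!is.finite(ve) || ve <= 0) return(.Machine$double.xmax)
  val <- sum(log1p(theta * st$n_i)) + log(gls$det_xwx) +
    (st$n - 2L) * log(ve)
  if (!is.finite(val)) .Machine$double.xmax else val
}

# -2 restricted log-likelihood in the variance parameters (va, ve),
# including all terms that depend on them (for the Satterthwaite Hessian)
reml_m2l <- function(va, ve, st) {
  if (ve <= 0 || va < 0) return(.Machine$double.xmax)
  c_i <- va / (ve + va * st$n_i)
  gls <- lmm_gls(st, c_i)
  val <- sum((st$n_i - 1L) * log(ve) + log(ve + va * st$n_i)) +
    log(gls$det_xwx / ve^2) + gls$rss / ve
  if (!is.finite(val)) .Machine$double.xmax else val
}

#' Fit the random-intercept intensity model by profiled REML
#'
#' Fits `y = b0 + b1 * x + u_group + error` with a single random intercept
#' per group (animal), the design used to relate per-trial phase firing
#' rate to stimulation intensity while controlling intraclass correlation.
#' The restricted likelihood is profiled down to the variance ratio
#' `var_group / var_resid` and optimized by bounded golden-section search
#' on the log-ratio scale (tolerance 1e-10), which is deterministic and
#' derivative-free; a boundary fit at zero group variance is reported, not
#' an error.
#'
#' @param data data.frame containing the model variables.
#' @param response name of the response column (events/s), default
#'   `"mean_fr"`.
#' @param fixed name of the fixed-effect column (%MT), default
#'   `"intensity_pct_mt"`. Intensity enters untransformed.
#' @param group name of the grouping column, default `"animal_id"`.
#' @return an `lmm_fit` list: `beta` (slope, events/s per %MT),
#'   `intercept`, `var_animal`, `var_resid`, `se_beta`, `F`, `p` (from
#'   [test_fixed_effect()] with Satterthwaite df), `ddf`, `n_obs`,
#'   `n_groups`, `method`.
#' @export
fit_lmm <- function(data, response = "mean_fr",
                    fixed = "intensity_pct_mt", group = "animal_id") {
  y <- as.numeric(data[[response]])
  x <- as.numeric(data[[fixed]])
  g <- data[[group]]
  if (length(unique(g)) < 2L) stop("need at least 2 groups")
  if (length(unique(x)) < 2L)
    stop("singular design: fixed effect is constant")
  st <- lmm_stats(y, x, g)
  obj <- function(lt) reml_profile(exp(lt), st)
  opt <- stats::optimize(obj, interval = c(-30, 15), tol = 1e-10)
  theta <- exp(opt$minimum)
  if (reml_profile(0, st) <= opt$objective + 1e-12) theta <- 0
  c_i <- theta / (1 + theta * st$n_i)
  gls <- lmm_gls(st, c_i)
  ve <- gls$rss / (st$n - 2L)
  va <- theta * ve
  vcov_beta <- ve * solve(gls$xwx)
  se_beta <- sqrt(vcov_beta[2L, 2L])
  fit <- structure(list(
    beta = gls$beta[2L], intercept = gls$beta[1L], var_animal = va,
    var_resid = ve, se_beta = se_beta, n_obs = st$n, n_groups = st$G,
    stats = st, theta = theta), class = "lmm_fit")
  ft <- test_fixed_effect(fit)
  fit$F <- ft$F
  fit$ddf <- ft$ddf
  fit$p <- ft$p
  fit$method <- ft$method
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> beta = %.4g +/- %.4g, F(1, %.1f) = %.2f, p = %.3g\n",
    x$beta, x$se_beta, x$ddf, x$F, x$p))
  cat(sprintf("  var(animal) = %.4g, var(resid) = %.4g; %d obs, %d groups\n",
              x$var_animal, x$var_resid, x$n_obs, x$n_groups))
  invisible(x)
}

# numerical Hessian of the -2 restricted log-likelihood in (va, ve)
reml_hessian <- function(va, ve, st) {
  f <- function(p) reml_m2l(p[1L], p[2L], st)
  p0 <- c(va, ve)
  h <- pmax(1e-8, 1e-4 * abs(p0))
  H <- matrix(0, 2L, 2L)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0)
    ei[i] <- h[i]; ej[j] <- h[j]
    lo_i <- p0 - ei; lo_j <- p0 - ej; lo_ij <- p0 - ei - ej
    # keep evaluation points in the admissible region (va >= 0, ve > 0)
    if (lo_i[1L] < 0 || lo_j[1L] < 0 || lo_ij[1L] < 0) {
      H[i, j] <- NA_real_
      next
    }
    H[i, j] <- (f(p0 + ei + ej) - f(p0 + ei - ej) -
                  f(p0 - ei + ej) + f(p0 - ei - ej)) / (4 * h[i] * h[j])
  }
  H
}

#' F-test of the intensity fixed effect
#'
#' Tests the slope of the random-intercept model with a Wald F statistic
#' (numerator df 1). The denominator degrees of freedom use the
#' Satterthwaite approximation: `ddf = 2 Var(beta)^2 / Var(Var(beta))`,
#' with the variance of the variance obtained by the delta method from the
#' numerical Hessian of the restricted likelihood in the two variance
#' components. A parametric bootstrap of the F statistic under the null
#' model is available as [test_fixed_effect_boot()]. At a boundary fit
#' (zero group variance) the residual df `n - 2` is used.
#'
#' @param fit an `lmm_fit` from [fit_lmm()].
#' @return list with `F`, `ddf`, `p`, `method`.
#' @export
test_fixed_effect <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  Fstat <- (fit$beta / fit$se_beta)^2
  st <- fit$stats
  if (fit$theta <= 0 || fit$var_animal <= 0) {
    ddf <- st$n - 2L
  } else {
    H <- reml_hessian(fit$var_animal, fit$var_resid, st)
    ddf <- st$n - 2L
    if (!anyNA(H)) {
      A <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(A)) {
        # gradient of Var(beta1) in (va, ve), central differences
        vb <- function(va, ve) {
          c_i <- va / (ve + va * st$n_i)
          ve * solve(lmm_gls(st, c_i)$xwx)[2L, 2L]
        }
        h <- pmax(1e-8, 1e-4 * c(fit$var_animal, fit$var_resid))
        gr <- c(
          (vb(fit$var_animal + h[1L], fit$var_resid) -
             vb(max(0, fit$var_animal - h[1L]), fit$var_resid)) /
            (fit$var_animal + h[1L] - max(0, fit$var_animal - h[1L])),
          (vb(fit$var_animal, fit$var_resid + h[2L]) -
             vb(fit$var_animal, fit$var_resid - h[2L])) / (2 * h[2L]))
        denom <- drop(t(gr) %*% A %*% gr)
        if (is.finite(denom) && denom > 0) {
          cand <- 2 * fit$se_beta^4 / denom
          if (is.finite(cand) && cand >= 1) ddf <- cand
        }
      }
    }
  }
  list(F = Fstat, ddf = ddf,
       p = stats::pf(Fstat, 1, ddf, lower.tail = FALSE),
       method = "satterthwaite")
}

#' Parametric-bootstrap test of the intensity fixed effect
#'
#' Refits the null model (no slope), simulates responses from it, and
#' compares the observed Wald F to the bootstrap null distribution.
#'
#' @param data,response,fixed,group as in [fit_lmm()].
#' @param n_boot bootstrap replicates.
#' @param seed seed for the simulation draws.
#' @return list with `F`, `p`, `method = "bootstrap"`, `n_boot`.
#' @export
test_fixed_effect_boot <- function(data, response = "mean_fr",
                                   fixed = "intensity_pct_mt",
                                   group = "animal_id", n_boot = 500,
                                   seed = 1L) {
  fit <- fit_lmm(data, response, fixed, group)
  y <- as.numeric(data[[response]])
  g <- factor(data[[group]])
  # null model: y = mu + u_i + e, variance components by REML on the
  # intercept-only design (profile over the same ratio)
  st0 <- lmm_stats(y, rep(c(0, 1), length.out = length(y)), g)
  gm <- tapply(y, g, mean)
  n_i <- as.numeric(table(g))
  obj0 <- function(lt) {
    th <- exp(lt)
    c_i <- th / (1 + th * n_i)
    a11 <- sum(n_i - c_i * n_i^2)
    b1 <- sum(st0$Sy - c_i * n_i * st0$Sy)
    mu <- b1 / a11
    rss <- sum(st0$Syy - c_i * st0$Sy^2) - mu * b1
    ve <- rss / (st0$n - 1L)
    sum(log1p(th * n_i)) + log(a11) + (st0$n - 1L) * log(ve)
  }
  o <- stats::optimize(obj0, c(-30, 15), tol = 1e-10)
  th0 <- exp(o$minimum)
  if (obj0(-1e6) <= o$objective) th0 <- 0
  c_i <- th0 / (1 + th0 * n_i)
  a11 <- sum(n_i - c_i * n_i^2)
  b1 <- sum(st0$Sy - c_i * n_i * st0$Sy)
  mu <- b1 / a11
  ve0 <- (sum(st0$Syy - c_i * st0$Sy^2) - mu * b1) / (st0$n - 1L)
  va0 <- th0 * ve0
  set.seed(seed)
  dd <- data
  Fb <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    u <- stats::rnorm(nlevels(g), 0, sqrt(va0))
    dd[[response]] <- mu + u[as.integer(g)] +
      stats::rnorm(length(y), 0, sqrt(ve0))
    fb <- fit_lmm(dd, response, fixed, group)
    Fb[b] <- (fb$beta / fb$se_beta)^2
  }
  Fobs <- (fit$beta / fit$se_beta)^2
  list(F = Fobs, p = (1 + sum(Fb >= Fobs)) / (n_boot + 1),
       method = "bootstrap", n_boot = n_boot)
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided rank-sum test. For combined sample sizes up to
#' `exact_max` the null distribution of the rank-sum statistic is obtained
#' by full enumeration of all group assignments (midranks, so ties are
#' handled exactly); beyond that, the normal approximation with tie
#' correction is used.
#'
#' @param a,b numeric samples.
#' @param exact_max largest combined size for exact enumeration.
#' @return list with `statistic` (rank sum of `a`), `p`, `method`.
#' @export
rank_sum_test <- function(a, b, exact_max = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  m <- length(a); n <- length(b)
  rk <- rank(c(a, b))
  w_obs <- sum(rk[seq_len(m)])
  ew <- m * (m + n + 1) / 2
  if (m + n <= exact_max) {
    combs <- utils::combn(m + n, m)
    ws <- colSums(matrix(rk[combs], nrow = m))
    p <- mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
    return(list(statistic = w_obs, p = p, method = "exact"))
  }
  ties <- table(rk)
  sigma2 <- m * n / 12 *
    ((m + n + 1) - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
  z <- (w_obs - ew) / sqrt(sigma2)
  list(statistic = w_obs, p = 2 * stats::pnorm(-abs(z)),
       method = "normal approximation")
}
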