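#' Z-score values within subject
#'
#' Standardizes each subject's trial series to mean 0, s.d. 1 (sample,
#' n - 1, standard deviation), the convention used before entering pattern
#' expressions as predictors so that coefficients are comparable across
#' signatures.
#'
#' @param values numeric vector over all trials.
#' @param subject subject id per trial (a single subject if omitted).
#' @return standardized vector.
#' @export
zscore_within <- function(values, subject = NULL) {
  if (is.null(subject)) subject <- rep(1L, length(values))
  out <- numeric(length(values))
  for (s in unique(subject)) {
    i <- subject == s
    sdv <- stats::sd(values[i])
    if (is.na(sdv) || sdv == 0) {
      stop(sprintf("zero variance for subject %s; cannot z-score", s))
    }
    out[i] <- (values[i] - mean(values[i])) / sdv
  }
  out
}

# R^2 of y on [1, X] via projection; tolerates rank-deficient X (the
# projection onto the column space is still well defined).
r2_of <- function(X, y) {
  q <- qr(cbind(1, as.matrix(X)))
  res <- qr.resid(q, y)
  sst <- sum((y - mean(y))^2)
  if (sst > 0) 1 - sum(res^2) / sst else 0
}

# OLS with an intercept prepended: coefficients (intercept dropped from the
# report), their sampling variances, and the R^2.
ols_fit <- function(X, y) {
  Z <- cbind(1, as.matrix(X))
  n <- nrow(Z); p <- ncol(Z)
  if (n <= p) stop("need more trials than regressors in a first-level fit")
  qz <- qr(Z)
  if (qz$rank < p) stop("first-level design is rank deficient")
  coef <- qr.coef(qz, y)
  res <- qr.resid(qz, y)
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qz))
  sst <- sum((y - mean(y))^2)
  list(coef = coef[-1], var = sigma2 * diag(XtXinv)[-1],
       intercept = coef[1],
       r2 = if (sst > 0) 1 - sum(res^2) / sst else 0)
}

# Empirical Bayes pooling of per-subject estimates: inverse-
# (within + between)-variance weights, with the between-subject variance
# tau^2 from the DerSimonian-Laird method of moments, floored at zero.
eb_pool <- function(est, var) {
  n <- length(est)
  v <- pmax(var, 0)
  if (all(v == 0)) {
    w0 <- rep(1, n)
  } else {
    w0 <- 1 / pmax(v, min(v[v > 0]) * 1e-8)
  }
  mu_fe <- sum(w0 * est) / sum(w0)
  Q <- sum(w0 * (est - mu_fe)^2)
  cc <- sum(w0) - sum(w0^2) / sum(w0)
  tau2 <- if (cc > 0) max(0, (Q - (n - 1)) / cc) else 0
  tot <- v + tau2
  w <- if (all(tot == 0)) rep(1, n) else 1 / pmax(tot, min(tot[tot > 0]) * 1e-8)
  list(estimate = sum(w * est) / sum(w), weights = w, tau2 = tau2)
}

# Percentile-bootstrap p-values for an EB-weighted mean, resampling subjects
# with replacement (weights fixed at full-sample values). `idx` is a shared
# n_boot x n index matrix so several paths can be resampled jointly.
boot_weighted_mean <- function(est, weights, idx) {
  E <- matrix(est[idx], nrow(idx))
  W <- matrix(weights[idx], nrow(idx))
  rowSums(E * W) / rowSums(W)
}

boot_pvalues <- function(draws, n_boot) {
  fl <- 1 / (n_boot + 1)
  p_le <- mean(draws <= 0)
  p_ge <- mean(draws >= 0)
  list(p_two = min(1, max(fl, 2 * min(p_le, p_ge))),
       p_one = max(fl, min(p_le, p_ge)),
       se = stats::sd(draws))
}

#' Multilevel general linear model with bootstrap inference
#'
#' First level: ordinary least squares of each subject's trial outcomes on
#' that subject's predictors (an intercept is added), with per-coefficient
#' sampling variances. Second level: Empirical Bayes weighting of the
#' subject coefficients with weights 1 / (within-subject variance +
#' between-subject tau^2), tau^2 by method of moments, floored at zero.
#' Significance by bootstrap: subjects are resampled with replacement
#' `n_boot` times, the weighted mean recomputed, and two-tailed p-values
#' read off the resampling distribution (floored at 1 / (n_boot + 1)).
#' Per-subject R^2 of the full model and of each leave-one-predictor-out
#' reduced model are averaged into group variance estimates.
#'
#' @param Y list of per-subject outcome vectors (>= 3 subjects).
#' @param X list of per-subject predictor matrices (same rows as `Y`,
#'   without an intercept column).
#' @param n_boot bootstrap iterations.
#' @param seed bootstrap seed.
#' @return a `multilevel_result`: `subject_betas` (subjects x predictors),
#'   `group` (data frame: predictor, estimate, se, z, p_two, p_one, tau2),
#'   `R2_full`, `R2_reduced`, `unique_R2`, `n_boot`, `n_subjects`.
#' @export
multilevel_glm <- function(Y, X, n_boot = 10000, seed = 1) {
  n <- length(Y)
  if (n < 3) stop("need at least 3 subjects")
  stopifnot(length(X) == n)
  X <- lapply(X, as.matrix)
  p <- ncol(X[[1]])
  pn <- colnames(X[[1]]) %||% paste0("x", seq_len(p))
  fits <- lapply(seq_len(n), function(i) ols_fit(X[[i]], Y[[i]]))
  B <- do.call(rbind, lapply(fits, `[[`, "coef"))
  V <- do.call(rbind, lapply(fits, `[[`, "var"))
  r2_full <- vapply(fits, `[[`, numeric(1), "r2")
  r2_red <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    for (i in seq_len(n)) {
      Xr <- X[[i]][, -j, drop = FALSE]
      r2_red[i, j] <- if (ncol(Xr) == 0) 0 else r2_of(Xr, Y[[i]])
    }
  }
  idx <- local_seed(seed,
    matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot))
  group <- do.call(rbind, lapply(seq_len(p), function(j) {
    pool <- eb_pool(B[, j], V[, j])
    draws <- boot_weighted_mean(B[, j], pool$weights, idx)
    bp <- boot_pvalues(draws, n_boot)
    data.frame(predictor = pn[j], estimate = pool$estimate, se = bp$se,
               z = if (bp$se > 0) pool$estimate / bp$se else sign(pool$estimate) * Inf,
               p_two = bp$p_two, p_one = bp$p_one, tau2 = pool$tau2)
  }))
  structure(list(subject_betas = B, subject_vars = V, group = group,
                 R2_full = mean(r2_full), R2_full_subjects = r2_full,
                 R2_reduced = stats::setNames(colMeans(r2_red), pn),
                 unique_R2 = stats::setNames(mean(r2_full) - colMeans(r2_red), pn),
                 n_boot = n_boot, n_subjects = n),
            class = "multilevel_result")
}

#' @export
print.multilevel_result <- function(x, ...) {
  cat(sprintf("<multilevel_result> %d subjects, R2_full = %.3f\n",
              x$n_subjects, x$R2_full))
  print(x$group, row.names = FALSE)
  invisible(x)
}

#' Variance partitioning with permutation tests
#'
#' The unique variance of predictor j is the mean over subjects of
#' (full-model R^2 minus the R^2 of the model without j). Its null
#' distribution is built by shuffling predictor j's trial labels within
#' each subject and recomputing the group unique R^2 per iteration;
#' two-tailed p-values are read off that distribution.
#'
#' The permutation loop uses the exact partitioned-regression identity
#' R2_full = R2_red + (1 - R2_red) * r^2(y_perp, x_perp), where y_perp and
#' x_perp are the outcome and the shuffled predictor residualized on the
#' remaining columns, so each iteration costs two small matrix products per
#' subject rather than a refit.
#'
#' @inheritParams multilevel_glm
#' @param predictors indices of the predictors to test (default: all).
#' @param n_perm permutation iterations.
#' @return list with `unique_R2` (named, observed), `R2_full`, `R2_reduced`,
#'   `p` (permutation, two-tailed), `null_mean`, `n_perm`.
#' @export
variance_partition <- function(Y, X, predictors = NULL, n_perm = 5000,
                               seed = 1) {
  n <- length(Y)
  if (n < 3) stop("need at least 3 subjects")
  X <- lapply(X, as.matrix)
  p <- ncol(X[[1]])
  pn <- colnames(X[[1]]) %||% paste0("x", seq_len(p))
  if (is.null(predictors)) predictors <- seq_len(p)

  r2_full_obs <- vapply(seq_len(n), function(i) r2_of(X[[i]], Y[[i]]),
                        numeric(1))
  out_u <- numeric(length(predictors))
  out_p <- numeric(length(predictors))
  out_nm <- numeric(length(predictors))
  r2_red_mean <- numeric(length(predictors))

  local_seed(seed, {
    for (jj in seq_along(predictors)) {
      j <- predictors[[jj]]
      r2_red <- numeric(n)
      null_mat <- matrix(NA_real_, n_perm, n)
      obs_full <- numeric(n)
      for (i in seq_len(n)) {
        y <- Y[[i]]
        nt <- length(y)
        Z <- cbind(1, X[[i]][, -j, drop = FALSE])
        qz <- qr(Z)
        Qm <- qr.Q(qz)
        y_perp <- y - Qm %*% crossprod(Qm, y)
        sst <- sum((y - mean(y))^2)
        ssy <- sum(y_perp^2)
        r2_red[i] <- if (sst > 0) 1 - ssy / sst else 0
        x <- X[[i]][, j]
        part_r2 <- function(xcols) {
          qx <- crossprod(Qm, xcols)                   # k x B
          mx2 <- colSums(xcols^2) - colSums(qx^2)      # ||M x||^2 per column
          num <- as.numeric(crossprod(xcols, y_perp))  # x' y_perp
          r2 <- ifelse(mx2 > 1e-12 * max(1, colSums(xcols^2)) & ssy > 0,
                       num^2 / (mx2 * ssy), 0)
          r2_red[i] + (1 - r2_red[i]) * r2
        }
        obs_full[i] <- part_r2(matrix(x, ncol = 1))
        perm_idx <- vapply(seq_len(n_perm), function(b) sample.int(nt),
                           integer(nt))
        null_mat[, i] <- part_r2(matrix(x[perm_idx], nt))
      }
      u_obs <- mean(obs_full - r2_red)
      u_null <- rowMeans(sweep(null_mat, 2, r2_red))
      fl <- 1 / (n_perm + 1)
      p_ge <- (1 + sum(u_null >= u_obs)) / (n_perm + 1)
      p_le <- (1 + sum(u_null <= u_obs)) / (n_perm + 1)
      out_u[jj] <- u_obs
      out_p[jj] <- min(1, 2 * min(p_ge, p_le))
      out_nm[jj] <- mean(u_null)
      r2_red_mean[jj] <- mean(r2_red)
    }
  })
  names(out_u) <- names(out_p) <- names(out_nm) <- names(r2_red_mean) <-
    pn[predictors]
  list(unique_R2 = out_u, R2_full = mean(r2_full_obs),
       R2_reduced = r2_red_mean, p = out_p, null_mean = out_nm,
       n_perm = n_perm)
}

# Map condition labels to +/-1 codes; numeric input passes through.
apply_coding <- function(x, coding = NULL) {
  if (is.numeric(x) && is.null(coding)) return(x)
  if (is.null(coding)) stop("non-numeric conditions need a `coding` map")
  miss <- setdiff(unique(as.character(x)), names(coding))
  if (length(miss)) {
    stop(sprintf("condition label(s) absent from coding: %s",
                 paste(miss, collapse = ", ")))
  }
  as.numeric(coding[as.character(x)])
}

# Per-subject two-path OLS mediation paths for one subject.
subject_paths_two <- function(x, M, y, covs = NULL) {
  M <- as.matrix(M)
  q <- ncol(M)
  a <- va <- numeric(q)
  for (j in seq_len(q)) {
    f <- ols_fit(cbind(x = x, covs), M[, j])
    a[j] <- f$coef[1]; va[j] <- f$var[1]
  }
  fb <- ols_fit(cbind(M, x = x, covs), y)
  b <- fb$coef[seq_len(q)]; vb <- fb$var[seq_len(q)]
  cprime <- fb$coef[q + 1]; vcp <- fb$var[q + 1]
  fc <- ols_fit(cbind(x = x, covs), y)
  list(a = a, b = b, cprime = cprime, c = fc$coef[1], ab = a * b,
       va = va, vb = vb, vcprime = vcp, vc = fc$var[1],
       vab = a^2 * vb + b^2 * va)   # first-order (Sobel) variance
}

#' Multilevel mediation of a manipulation through brain signatures
#'
#' Per subject, OLS path models: each mediator on the manipulation and
#' covariates (path a); the outcome on all mediators, the manipulation and
#' covariates (paths b and c-prime); the outcome on the manipulation and
#' covariates alone (path c). The per-subject indirect effect of mediator j
#' is the product a_j * b_j, so the summary captures the covariance between
#' a and b across subjects rather than the product of group means. Group
#' inference applies the Empirical Bayes second level and subject-resampling
#' bootstrap to every path and to the products; one- and two-tailed
#' bootstrap p-values are reported. With a single mediator and shared
#' trials, c = c' + a*b per subject exactly.
#'
#' @param x list of per-subject manipulation codes (+/-1, or labels with
#'   `coding`).
#' @param m list of per-subject mediator vectors/matrices (columns =
#'   mediators, e.g. signature responses; z-score within subject first if
#'   coefficients are to be compared across mediators).
#' @param y list of per-subject outcome (pain rating) vectors.
#' @param covariates optional list of per-subject covariate matrices (e.g.
#'   stimulus temperature).
#' @param coding named vector mapping condition labels to +/-1 (anti-pain
#'   conditions +1, pro-pain -1).
#' @param n_boot,seed bootstrap settings.
#' @return a `mediation_result`: `paths` (data frame with estimate, se, z,
#'   p_two, p_one per path and mediator), `subject_paths` (list), `n_boot`.
#' @export
mediate_multilevel <- function(x, m, y, covariates = NULL, coding = NULL,
                               n_boot = 10000, seed = 1) {
  n <- length(y)
  if (n < 3) stop("need at least 3 subjects")
  x <- lapply(x, apply_coding, coding = coding)
  m <- lapply(m, as.matrix)
  q <- ncol(m[[1]])
  mn <- colnames(m[[1]]) %||% paste0("m", seq_len(q))
  sp <- lapply(seq_len(n), function(i) {
    subject_paths_two(x[[i]], m[[i]], y[[i]],
                      covs = if (is.null(covariates)) NULL else as.matrix(covariates[[i]]))
  })
  idx <- local_seed(seed,
    matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot))
  rows <- list()
  add_path <- function(name, mediator, est, var) {
    pool <- eb_pool(est, var)
    draws <- boot_weighted_mean(est, pool$weights, idx)
    bp <- boot_pvalues(draws, n_boot)
    rows[[length(rows) + 1]] <<- data.frame(
      path = name, mediator = mediator, estimate = pool$estimate,
      se = bp$se, z = if (bp$se > 0) pool$estimate / bp$se else sign(pool$estimate) * Inf,
      p_two = bp$p_two, p_one = bp$p_one)
  }
  for (j in seq_len(q)) {
    add_path("a", mn[j], vapply(sp, function(s) s$a[j], numeric(1)),
             vapply(sp, function(s) s$va[j], numeric(1)))
    add_path("b", mn[j], vapply(sp, function(s) s$b[j], numeric(1)),
             vapply(sp, function(s) s$vb[j], numeric(1)))
    add_path("ab", mn[j], vapply(sp, function(s) s$ab[j], numeric(1)),
             vapply(sp, function(s) s$vab[j], numeric(1)))
  }
  add_path("cprime", NA, vapply(sp, `[[`, numeric(1), "cprime"),
           vapply(sp, `[[`, numeric(1), "vcprime"))
  add_path("c", NA, vapply(sp, `[[`, numeric(1), "c"),
           vapply(sp, `[[`, numeric(1), "vc"))
  structure(list(paths = do.call(rbind, rows), subject_paths = sp,
                 mediators = mn, n_boot = n_boot, n_subjects = n,
                 type = "two-path"),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s, %d subjects, %d bootstrap iterations\n",
              x$type, x$n_subjects, x$n_boot))
  print(x$paths, row.names = FALSE)
  invisible(x)
}

#' Three-path (serial) multilevel mediation
#'
#' For a manipulation X whose effect runs X -> M1 (a self-report, e.g.
#' perceived control) -> M2 (brain signature responses) -> Y (pain): per
#' subject, M1 ~ X + covariates (path a); each M2_j ~ M1 + X + covariates
#' (path d_j); Y ~ all M2 + M1 + X + covariates (path b_j); the serial
#' indirect effect through M2_j is a * d_j * b_j. Group inference as in
#' [mediate_multilevel()].
#'
#' @param m1 list of per-subject first-stage mediator vectors.
#' @param m2 list of per-subject second-stage mediator vectors/matrices.
#' @inheritParams mediate_multilevel
#' @return a `mediation_result` with paths a, d, b, adb, cprime, c.
#' @export
mediate_three_path <- function(x, m1, m2, y, covariates = NULL, coding = NULL,
                               n_boot = 10000, seed = 1) {
  n <- length(y)
  if (n < 3) stop("need at least 3 subjects")
  x <- lapply(x, apply_coding, coding = coding)
  m2 <- lapply(m2, as.matrix)
  q <- ncol(m2[[1]])
  mn <- colnames(m2[[1]]) %||% paste0("m", seq_len(q))
  sp <- lapply(seq_len(n), function(i) {
    covs <- if (is.null(covariates)) NULL else as.matrix(covariates[[i]])
    fa <- ols_fit(cbind(x = x[[i]], covs), m1[[i]])
    a <- fa$coef[1]; va <- fa$var[1]
    d <- vd <- numeric(q)
    for (j in seq_len(q)) {
      fd <- ols_fit(cbind(m1 = m1[[i]], x = x[[i]], covs), m2[[i]][, j])
      d[j] <- fd$coef[1]; vd[j] <- fd$var[1]
    }
    fb <- ols_fit(cbind(m2[[i]], m1 = m1[[i]], x = x[[i]], covs), y[[i]])
    b <- fb$coef[seq_len(q)]; vb <- fb$var[seq_len(q)]
    cprime <- fb$coef[q + 2]; vcp <- fb$var[q + 2]
    fc <- ols_fit(cbind(x = x[[i]], covs), y[[i]])
    adb <- a * d * b
    vadb <- (d * b)^2 * va + (a * b)^2 * vd + (a * d)^2 * vb
    list(a = a, d = d, b = b, cprime = cprime, c = fc$coef[1],
         adb = adb, va = va, vd = vd, vb = vb, vcprime = vcp,
         vc = fc$var[1], vadb = vadb)
  })
  idx <- local_seed(seed,
    matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot))
  rows <- list()
  add_path <- function(name, mediator, est, var) {
    pool <- eb_pool(est, var)
    draws <- boot_weighted_mean(est, pool$weights, idx)
    bp <- boot_pvalues(draws, n_boot)
    rows[[length(rows) + 1]] <<- data.frame(
      path = name, mediator = mediator, estimate = pool$estimate,
      se = bp$se, z = if (bp$se > 0) pool$estimate / bp$se else sign(pool$estimate) * Inf,
      p_two = bp$p_two, p_one = bp$p_one)
  }
  add_path("a", "m1", vapply(sp, `[[`, numeric(1), "a"),
           vapply(sp, `[[`, numeric(1), "va"))
  for (j in seq_len(q)) {
    add_path("d", mn[j], vapply(sp, function(s) s$d[j], numeric(1)),
             vapply(sp, function(s) s$vd[j], numeric(1)))
    add_path("b", mn[j], vapply(sp, function(s) s$b[j], numeric(1)),
             vapply(sp, function(s) s$vb[j], numeric(1)))
    add_path("adb", mn[j], vapply(sp, function(s) s$adb[j], numeric(1)),
             vapply(sp, function(s) s$vadb[j], numeric(1)))
  }
  add_path("cprime", NA, vapply(sp, `[[`, numeric(1), "cprime"),
           vapply(sp, `[[`, numeric(1), "vcprime"))
  add_path("c", NA, vapply(sp, `[[`, numeric(1), "c"),
           vapply(sp, `[[`, numeric(1), "vc"))
  structure(list(paths = do.call(rbind, rows), subject_paths = sp,
                 mediators = mn, n_boot = n_boot, n_subjects = n,
                 type = "three-path"),
            class = "mediation_result")
}
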