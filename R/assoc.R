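#' Configuration for the region association screen
#'
#' @param significance_alpha per-region Wald significance level (regions
#'   with p below it are flagged significant; default 0.01).
#' @param qvalue_lambda grid of lambda values for Storey pi0 estimation.
#' @param max_iter IRLS iteration cap.
#' @param tol IRLS convergence tolerance (relative deviance change).
#' @return an `assoc_config` list.
#' @export
assoc_config <- function(significance_alpha = 0.01,
                         qvalue_lambda = seq(0.05, 0.9, by = 0.05),
                         max_iter = 100L, tol = 1e-13) {
  stopifnot(significance_alpha > 0, significance_alpha < 1, tol > 0,
            all(qvalue_lambda >= 0), all(qvalue_lambda < 1))
  structure(list(significance_alpha = significance_alpha,
                 qvalue_lambda = qvalue_lambda,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "assoc_config")
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Thin wrapper over the base maximum-likelihood machinery returning
#' coefficients, their covariance, the deviance and degeneracy flags.
#' Complete or quasi-separation is flagged when a coefficient diverges
#' (|coef| > 15 on the log-odds scale, i.e. an odds ratio beyond ~3x10^6)
#' or fitted probabilities pin to 0/1.
#'
#' @param y binary 0/1 outcome vector.
#' @param X design matrix including the intercept column.
#' @param config an [assoc_config()] (iteration cap, tolerance).
#' @return list: `coef`, `se`, `vcov`, `deviance`, `null_deviance`,
#'   `df_residual`, `converged`, `separation`.
#' @export
fit_logistic <- function(y, X, config = assoc_config()) {
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (nrow(X) <= ncol(X))
    stop("more parameters than observations")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = config$tol,
                                 maxit = config$max_iter)))
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(XtWX), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(vc))
  mu <- fit$fitted.values
  separation <- any(abs(fit$coefficients) > 15) ||
    (any(mu < 1e-10) || any(mu > 1 - 1e-10)) && any(abs(fit$coefficients) > 10)
  list(coef = fit$coefficients, se = se, vcov = vc,
       deviance = fit$deviance, null_deviance = fit$null.deviance,
       df_residual = fit$df.residual, converged = fit$converged,
       separation = separation)
}

#' Wald test of a coefficient
#'
#' @param coef coefficient estimate (log odds ratio).
#' @param se its standard error (> 0).
#' @return list: `z` and two-sided `p` from the standard normal.
#' @export
wald_test <- function(coef, se) {
  if (is.na(se) || se <= 0) return(list(z = NA_real_, p = NA_real_))
  z <- coef / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# covariate design (intercept, age category as ordinal, female indicator,
# two smoking dummies with never as reference)
.covariate_design <- function(pheno) {
  cbind(`(Intercept)` = 1, age = pheno$age_cat,
        sex_female = as.integer(pheno$sex == 2L),
        smoke_former = as.integer(pheno$smoking == 1L),
        smoke_current = as.integer(pheno$smoking == 2L))
}

#' Covariate-adjusted association screen over carrier regions
#'
#' For each region a logistic model of case status on the binary carrier
#' indicator plus age (ordinal 1-5), sex and smoking (two dummies, never =
#' reference) is fitted; the region p-value is the Wald test of the carrier
#' coefficient, with a 95% Wald CI on the odds-ratio scale. BH-FDR and
#' Storey q-values are computed over the whole screen. Separated fits are
#' flagged, report a 0/Inf odds-ratio sentinel and an `NA` p-value, and
#' per-region failures do not abort the screen.
#'
#' @param carriers binary subjects x regions matrix ([carrier_matrix()]).
#' @param pheno phenotype table (`id`, `case`, `age_cat`, `sex`,
#'   `smoking`), rows aligned to `carriers` by `id`.
#' @param config an [assoc_config()].
#' @param adjust include the covariates (set `FALSE` for crude fits).
#' @return data.frame, one row per region: `region`, carrier counts,
#'   `coef`, `se`, `or`, `ci_lo`, `ci_hi`, `p`, `fdr`, `q`, `significant`,
#'   `converged`, `separation`.
#' @export
run_screen <- function(carriers, pheno, config = assoc_config(),
                       adjust = TRUE) {
  stopifnot(nrow(carriers) == nrow(pheno))
  ix <- match(rownames(carriers), pheno$id)
  if (!anyNA(ix)) pheno <- pheno[ix, , drop = FALSE]
  y <- pheno$case
  Z <- if (adjust) .covariate_design(pheno) else
    cbind(`(Intercept)` = rep(1, length(y)))
  zcrit <- stats::qnorm(0.975)
  rows <- lapply(seq_len(ncol(carriers)), function(j) {
    carrier <- carriers[, j]
    n_case_car <- sum(carrier == 1L & y == 1L)
    n_ctrl_car <- sum(carrier == 1L & y == 0L)
    res <- tryCatch({
      fit <- fit_logistic(y, cbind(carrier = carrier, Z), config)
      b <- fit$coef[["carrier"]]; s <- fit$se[[1]]
      if (fit$separation) {
        list(coef = b, se = NA_real_, or = if (b > 0) Inf else 0,
             ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
             converged = fit$converged, separation = TRUE)
      } else {
        w <- wald_test(b, s)
        list(coef = b, se = s, or = exp(b),
             ci_lo = exp(b - zcrit * s), ci_hi = exp(b + zcrit * s),
             p = w$p, converged = fit$converged, separation = FALSE)
      }
    }, error = function(e) {
      list(coef = NA_real_, se = NA_real_, or = NA_real_, ci_lo = NA_real_,
           ci_hi = NA_real_, p = NA_real_, converged = FALSE,
           separation = FALSE)
    })
    data.frame(region = colnames(carriers)[j], n_case_carriers = n_case_car,
               n_control_carriers = n_ctrl_car, coef = res$coef,
               se = res$se, or = res$or, ci_lo = res$ci_lo,
               ci_hi = res$ci_hi, p = res$p, converged = res$converged,
               separation = res$separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  st <- storey_qvalues(out$p, config$qvalue_lambda)
  out$q <- st$qvalues
  out$significant <- !is.na(out$p) & out$p < config$significance_alpha
  rownames(out) <- NULL
  out
}

#' Region-by-covariate interaction model
#'
#' Compares the main-effects logistic model (carrier + age + sex +
#' smoking) with the model adding carrier x smoking (two terms) and
#' carrier x age. The joint interaction p-value is reported both as a
#' likelihood-ratio chi-square (`p_lrt`, the headline) and as an
#' analysis-of-deviance F statistic (`p_f`); the two are monotone
#' transforms of the same deviance drop at fixed df and agree in ranking.
#' Per-term Wald p-values are also returned. Stratum-specific carrier odds
#' ratios are derived from the interaction fit at each smoking level,
#' evaluated at the reference age category (1); smoking levels with no
#' carriers give `NA` with a flag.
#'
#' @param carrier binary carrier vector.
#' @param pheno phenotype table aligned to `carrier`.
#' @param config an [assoc_config()].
#' @return list: `deviance_main`, `deviance_int`, `df`, `p_lrt`, `p_f`,
#'   `per_term` (data.frame of Wald tests), `stratum_or` (data.frame with
#'   OR, CI and carrier counts per smoking level), `empty_strata`.
#' @export
fit_interaction <- function(carrier, pheno, config = assoc_config()) {
  y <- pheno$case
  Z <- .covariate_design(pheno)
  X_main <- cbind(carrier = carrier, Z)
  X_int <- cbind(X_main,
                 car_x_former = carrier * Z[, "smoke_former"],
                 car_x_current = carrier * Z[, "smoke_current"],
                 car_x_age = carrier * Z[, "age"])
  fit0 <- fit_logistic(y, X_main, config)
  # interaction columns can be aliased when a smoking level has no
  # carriers; drop aliased interaction columns rather than fail
  qx <- qr(X_int)
  if (qx$rank < ncol(X_int)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    main_cols <- seq_len(ncol(X_main))
    if (!all(main_cols %in% keep))
      stop("main-effects design is rank deficient")
    X_int <- X_int[, keep, drop = FALSE]
  }
  fit1 <- fit_logistic(y, X_int, config)
  ddev <- fit0$deviance - fit1$deviance
  df <- ncol(X_int) - ncol(X_main)
  p_lrt <- stats::pchisq(ddev, df, lower.tail = FALSE)
  phi <- fit1$deviance / fit1$df_residual
  Fstat <- (ddev / df) / max(phi, .Machine$double.eps)
  p_f <- stats::pf(Fstat, df, fit1$df_residual, lower.tail = FALSE)
  terms <- c("car_x_former", "car_x_current", "car_x_age")
  per_term <- do.call(rbind, lapply(terms, function(t) {
    i <- match(t, names(fit1$coef))
    w <- wald_test(fit1$coef[i], fit1$se[i])
    data.frame(term = t, coef = unname(fit1$coef[i]),
               se = unname(fit1$se[i]), p = w$p, stringsAsFactors = FALSE)
  }))
  b <- fit1$coef
  a0 <- 1  # reference age category
  lev <- c(never = 0L, former = 1L, current = 2L)
  stratum <- do.call(rbind, lapply(names(lev), function(nm) {
    l <- lev[[nm]]
    n_car <- sum(carrier == 1L & pheno$smoking == l)
    if (n_car == 0L)
      return(data.frame(smoking = nm, or = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_carriers = 0L,
                        stringsAsFactors = FALSE))
    need <- c(carrier = 1, car_x_age = a0)
    if (nm == "former") need <- c(need, car_x_former = 1)
    if (nm == "current") need <- c(need, car_x_current = 1)
    if (!all(names(need) %in% names(b)))
      return(data.frame(smoking = nm, or = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_carriers = n_car,
                        stringsAsFactors = FALSE))
    contrast <- setNames(numeric(length(b)), names(b))
    contrast[names(need)] <- need
    est <- sum(contrast * b)
    se <- sqrt(drop(t(contrast) %*% fit1$vcov %*% contrast))
    zc <- stats::qnorm(0.975)
    data.frame(smoking = nm, or = exp(est), ci_lo = exp(est - zc * se),
               ci_hi = exp(est + zc * se), n_carriers = n_car,
               stringsAsFactors = FALSE)
  }))
  list(deviance_main = fit0$deviance, deviance_int = fit1$deviance,
       df = df, p_lrt = p_lrt, p_f = p_f, per_term = per_term,
       stratum_or = stratum,
       empty_strata = stratum$smoking[stratum$n_carriers == 0L])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone and clamped to 1.
#' `NA` p-values propagate as `NA`.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 and scales the step-up adjusted
#' p-values by it: `q = pi0 * BH(p)`. pi0 is estimated from the tail
#' counts `#(p > lambda) / (m (1 - lambda))` over the lambda grid with a
#' cubic smoothing spline extrapolated at the largest lambda; for fewer
#' than 100 p-values a bootstrap lambda selection is used instead, and
#' with fewer than 10 p-values pi0 falls back to 1 (where q-values reduce
#' exactly to BH-FDR).
#'
#' @param pvals numeric p-values.
#' @param lambda grid in `[0, 0.9]`.
#' @param pi0 optionally force the null-proportion estimate.
#' @return list: `qvalues`, `pi0`.
#' @export
storey_qvalues <- function(pvals, lambda = seq(0.05, 0.9, by = 0.05),
                           pi0 = NULL) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      if (m < 100) {
        min_pi0 <- min(pi0_l)
        B <- 100L
        mse <- numeric(length(lambda))
        for (b in seq_len(B)) {
          pb <- sample(p, m, replace = TRUE)
          pi0_b <- vapply(lambda, function(l) mean(pb > l) / (1 - l), 0)
          mse <- mse + (pi0_b - min_pi0)^2
        }
        pi0 <- pi0_l[which.min(mse)]
      } else {
        fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
        pi0 <- stats::predict(fit, x = max(lambda))$y
      }
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  q <- rep(NA_real_, length(pvals))
  q[ok] <- pmin(pi0 * bh_fdr(p), 1)
  list(qvalues = q, pi0 = pi0)
}
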