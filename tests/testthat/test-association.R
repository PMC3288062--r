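# expand a 2x2 table (carrier x case) into subject-level vectors
expand_2x2 <- function(a, b, c_, d) {
  # a: case carriers, b: case non-carriers, c_: control carriers,
  # d: control non-carriers
  y <- c(rep(1L, a + b), rep(0L, c_ + d))
  x <- c(rep(1L, a), rep(0L, b), rep(1L, c_), rep(0L, d))
  list(y = y, x = x)
}

test_that("logistic fits match 2x2 closed forms", {
  # balanced table -> no association
  t0 <- expand_2x2(25, 25, 25, 25)
  f0 <- fit_logistic(t0$y, cbind(1, carrier = t0$x))
  expect_equal(unname(f0$coef["carrier"]), 0, tolerance = 1e-8)
  # intercept-only closed form
  y <- c(rep(1L, 828), rep(0L, 790))
  f1 <- fit_logistic(y, cbind(rep(1, length(y))))
  expect_equal(unname(f1$coef[1]), log(828 / 790), tolerance = 1e-8)
  # random tables with all cells >= 5: log-OR and SE to 1e-6
  set.seed(101)
  for (i in 1:100) {
    cells <- sample(5:80, 4, replace = TRUE)
    tt <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    ft <- fit_logistic(tt$y, cbind(1, carrier = tt$x))
    lor <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
    se <- sqrt(sum(1 / cells))
    expect_lt(abs(unname(ft$coef["carrier"]) - lor), 1e-6)
    expect_lt(abs(unname(ft$se["carrier"]) - se), 1e-6)
  }
  # rank deficiency is reported with the aliased column
  X <- cbind(1, a = t0$x, b = t0$x)
  expect_error(fit_logistic(t0$y, X), "aliased.*b")
})

test_that("printed carrier counts reproduce the crude cross-product OR", {
  # 28 of 788 cases vs 8 of 830 controls
  oracle <- (28 * (830 - 8)) / (8 * (788 - 28))
  tt <- expand_2x2(28, 788 - 28, 8, 830 - 8)
  ft <- fit_logistic(tt$y, cbind(1, carrier = tt$x))
  expect_equal(unname(exp(ft$coef["carrier"])), oracle, tolerance = 1e-6)
  expect_equal(oracle, 3.7855, tolerance = 1e-4)
})

test_that("Wald tests behave and agree with the likelihood ratio", {
  expect_equal(wald_test(0, 1)$p, 1)
  expect_equal(wald_test(1.96, 1)$p, 0.05, tolerance = 1e-3)
  expect_true(is.na(wald_test(1, NA)$p))
  # agreement with LRT within 20% relative on a well-behaved fit
  set.seed(7)
  n <- 1600
  x <- rbinom(n, 1, 0.2)
  y <- rbinom(n, 1, plogis(-0.5 + log(2) * x))
  X <- cbind(1, x = x)
  f1 <- fit_logistic(y, X)
  w <- wald_test(unname(f1$coef["x"]), unname(f1$se["x"]))
  f0 <- fit_logistic(y, X[, 1, drop = FALSE])
  p_lrt <- pchisq(f0$deviance - f1$deviance, 1, lower.tail = FALSE)
  expect_equal(log(w$p), log(p_lrt), tolerance = 0.2)
})

test_that("separation is flagged and reported as a 0/Inf sentinel", {
  y <- c(rep(1L, 20), rep(0L, 20))
  x <- y  # perfect separation
  carr <- cbind(reg1 = x)
  pheno <- data.frame(id = as.character(1:40), case = y, age_cat = 1L,
                      sex = 1L, smoking = 0L)
  rownames(carr) <- pheno$id
  res <- run_screen(carr, pheno, adjust = FALSE)
  expect_true(res$separation)
  expect_equal(res$or, Inf)
  expect_true(is.na(res$p))
})

test_that("interaction models recover planted effect modification", {
  set.seed(42)
  n <- 1600
  simulate_int <- function(or_never, or_former, or_current) {
    smoking <- sample(0:2, n, replace = TRUE, prob = c(156, 703, 759))
    age <- sample(1:5, n, replace = TRUE, prob = c(.6, .25, .09, .04, .02))
    sex <- sample(1:2, n, replace = TRUE)
    carrier <- rbinom(n, 1, 0.12)
    lor <- log(c(or_never, or_former, or_current))[smoking + 1]
    eta <- -0.2 + 0.1 * (age - 1) + lor * carrier + 0.2 * (smoking >= 1)
    y <- rbinom(n, 1, plogis(eta))
    data.frame(id = as.character(1:n), case = y, age_cat = age, sex = sex,
               smoking = smoking, carrier = carrier)
  }
  d <- simulate_int(2, 1, 0.4)
  fit <- fit_interaction(d$carrier, d)
  expect_equal(fit$df, 3L)
  # deviance never increases when terms are added
  expect_lte(fit$deviance_int, fit$deviance_main)
  # LRT and F agree in ordering across datasets
  d0 <- simulate_int(1.5, 1.5, 1.5)
  fit0 <- fit_interaction(d0$carrier, d0)
  expect_equal(order(c(fit$p_lrt, fit0$p_lrt)),
               order(c(fit$p_f, fit0$p_f)))
  # stratum ORs from the interaction fit bracket the truth qualitatively
  or_tab <- fit$stratum_or
  expect_gt(or_tab$or[or_tab$smoking == "never"],
            or_tab$or[or_tab$smoking == "current"])
  # empty stratum is flagged
  d2 <- d; d2$carrier[d2$smoking == 0] <- 0L
  fit2 <- fit_interaction(d2$carrier, d2)
  expect_true("never" %in% fit2$empty_strata)
  expect_true(is.na(fit2$stratum_or$or[fit2$stratum_or$smoking == "never"]))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(55)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("q-values reduce to BH at pi0 = 1 and estimate pi0 sensibly", {
  set.seed(77)
  p <- runif(200)
  q1 <- storey_qvalues(p, pi0 = 1)
  expect_equal(q1$qvalues, bh_fdr(p), tolerance = 1e-12)
  # uniform p-values -> pi0 close to 1
  p_null <- runif(1000)
  st <- storey_qvalues(p_null)
  expect_gte(st$pi0, 0.8)
  expect_lte(st$pi0, 1)
  # monotone in p after sorting
  o <- order(p_null)
  expect_true(all(diff(st$qvalues[o]) >= -1e-12))
  # tiny inputs fall back to pi0 = 1
  expect_equal(storey_qvalues(c(0.5, 0.7))$pi0, 1)
  # bootstrap path for moderate m stays in range
  st_small <- storey_qvalues(runif(60))
  expect_gt(st_small$pi0, 0)
  expect_lte(st_small$pi0, 1)
})

test_that("screens run per region, flag significance and keep order", {
  set.seed(12)
  n <- 600
  pheno <- data.frame(id = sprintf("S%04d", 1:n),
                      case = rep(c(1L, 0L), each = n / 2),
                      age_cat = sample(1:5, n, TRUE),
                      sex = sample(1:2, n, TRUE),
                      smoking = sample(0:2, n, TRUE))
  carr <- cbind(
    assoc = ifelse(pheno$case == 1, rbinom(n, 1, 0.15), rbinom(n, 1, 0.05)),
    null1 = rbinom(n, 1, 0.1), null2 = rbinom(n, 1, 0.1))
  rownames(carr) <- pheno$id
  res <- run_screen(carr, pheno)
  expect_equal(res$region, colnames(carr))
  expect_true(res$significant[1])
  expect_gt(res$or[1], 1)
  expect_true(all(res$fdr >= res$p - 1e-12, na.rm = TRUE))
  expect_true(all(res$q <= res$fdr + 1e-12, na.rm = TRUE))
  # carrier counts reconcile
  expect_equal(res$n_case_carriers[1],
               sum(carr[, 1] == 1 & pheno$case == 1))
})
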