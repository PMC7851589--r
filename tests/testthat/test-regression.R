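# independent oracle: direct Newton-free ML of the logistic likelihood,
# optimised on a unit-scaled covariate for numerical stability
logistic_ml_oracle <- function(x, y) {
  s <- max(abs(x))
  xs <- x / s
  nll <- function(b) {
    eta <- b[1] + b[2] * xs
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    p <- stats::plogis(b[1] + b[2] * xs)
    -c(sum(y - p), sum((y - p) * xs))
  }
  par <- stats::optim(c(0, 0), nll, gr, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))$par
  c(par[1], par[2] / s)
}

test_that("logistic IRLS matches a generic ML optimiser", {
  set.seed(17)
  for (i in 1:10) {
    n <- 400
    x <- stats::runif(n, 0, 1e5)
    b1 <- stats::rnorm(1, 0, 2e-5)
    p <- stats::plogis(-1.5 + b1 * x)
    y <- stats::rbinom(n, 1, p)
    if (length(unique(y)) < 2) next
    tab <- tibble::tibble(distance = x, indicator = y)
    fit <- fit_logistic(tab)
    if (fit$separation) next
    oracle <- logistic_ml_oracle(x, y)
    expect_equal(fit$estimate, oracle[2], tolerance = 1e-6)
    expect_equal(fit$intercept, oracle[1], tolerance = 1e-6)
  }
})

test_that("degenerate logistic inputs flag separation instead of crashing", {
  tab <- tibble::tibble(distance = 1:100, indicator = 0L)
  fit <- fit_logistic(tab)
  expect_true(fit$separation)
  expect_true(is.na(fit$estimate))
  # perfectly separated
  tab2 <- tibble::tibble(distance = 1:100,
                         indicator = as.integer(1:100 > 50))
  fit2 <- fit_logistic(tab2)
  expect_true(fit2$separation)
})

test_that("window OLS equals the closed form and honours edge cases", {
  set.seed(3)
  win <- tibble::tibble(window = 0:9, start = 0:9 * 1e4,
                        end = 1:10 * 1e4, midpoint = 0:9 * 1e4 + 5e3,
                        n_sites = 100, n_subs = rpois(10, 20),
                        density = NA_real_)
  win$density <- win$n_subs / win$n_sites
  fit <- fit_window_linear(win, w = 1e4)
  x <- win$midpoint; y <- win$n_subs
  closed <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$estimate, closed)
  # perfectly linear totals: R^2 = 1 and the exact slope
  win2 <- dplyr::mutate(win, n_subs = 5 + 2e-4 * midpoint)
  fit2 <- suppressWarnings(fit_window_linear(win2, w = 1e4))  # perfect fit
  expect_equal(fit2$estimate, 2e-4)
  expect_equal(fit2$r_squared, 1)
  # constant totals: slope 0
  win3 <- dplyr::mutate(win, n_subs = 7)
  expect_equal(suppressWarnings(fit_window_linear(win3))$estimate, 0)
  expect_warning(fit_window_linear(win[1:2, ]), "fewer than 3")
})

test_that("the six standard window widths each produce a fit", {
  sim <- small_sim(seed = 31)
  run <- suppressWarnings(run_full_analysis(sim, selection = FALSE))
  # on a 60-kb toy replicon only the smaller widths have >= 3 windows
  fits <- suppressWarnings(
    fit_window_regressions(run$site_table,
                           widths = c(1, 2.5, 5, 10) * 1e3))
  expect_equal(sort(unique(fits$window)), c(1, 2.5, 5, 10) * 1e3)
  expect_true(all(fits$model == "linear"))
})

test_that("shift zero reproduces the unshifted logistic fit exactly", {
  sim <- small_sim(seed = 31)
  run <- run_full_analysis(sim, selection = FALSE,
                           window_regressions = FALSE)
  base <- fit_logistic(run$site_table)
  perm <- origin_shift_permutation(run$site_table, run$replicon,
                                   step = 10000, max_shift = 30000)
  expect_equal(nrow(perm), 7)
  at0 <- perm[perm$shift == 0, ]
  expect_equal(at0$estimate, base$estimate)
  expect_equal(at0$std_error, base$se)
  expect_equal(at0$p_value, base$p)
})

test_that("strong simulated gradients keep their sign under origin shifts", {
  sim <- small_sim(seed = 41)
  run <- run_full_analysis(sim, selection = FALSE,
                           window_regressions = FALSE)
  perm <- origin_shift_permutation(run$site_table, run$replicon,
                                   step = 5000, max_shift = 10000)
  expect_true(attr(perm, "sign_stable"))
  expect_true(all(perm$estimate > 0))
})

test_that("tidy and glance return well-formed one-row summaries", {
  tab <- tibble::tibble(distance = rep(1:1000, 2),
                        indicator = rep(0:1, each = 1000))
  fit <- suppressWarnings(fit_logistic(tab))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("estimate", "std_error", "p_value", "n") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
})
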