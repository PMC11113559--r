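make_rates_row <- function(station, depth, substrate, rate, flags = "") {
  data.frame(station_id = station, depth_id = depth, substrate = substrate,
             rate_umolN_L_h = rate, rate_sd = 0, specific_rate_h = rate / 1.0,
             specific_sd = 0, detection_limit_umolN_L_h = 1e-5,
             source_atom_pct = 30, n_replicates = 3, flags = flags,
             stringsAsFactors = FALSE)
}

test_that("regional summary computes totals and substrate fractions", {
  rates <- do.call(rbind, Map(make_rates_row, "st1", "surface", SUBSTRATES,
                              c(0.02, 0.01, 0.02, 0.03, 0.001, 0.01)))
  labels <- data.frame(station_id = "st1", water_mass = "MAB")
  s <- regional_summary(rates, labels)
  expect_equal(s$totals$mean_total_umolN_L_h, 0.091)
  expect_equal(s$substrates$fraction_of_total[s$substrates$substrate == "urea"],
               0.3297, tolerance = 1e-3)
  expect_equal(sum(s$substrates$fraction_of_total), 1, tolerance = 1e-9)
  # equal rates give equal fractions
  eq <- do.call(rbind, Map(make_rates_row, "st1", "surface", SUBSTRATES, 0.01))
  s2 <- regional_summary(eq, labels)
  expect_equal(s2$substrates$fraction_of_total, rep(1 / 6, 6))
})

test_that("excluded experiments drop their experiment set from totals", {
  rates <- rbind(
    do.call(rbind, Map(make_rates_row, "st1", "surface", SUBSTRATES, 0.01)),
    do.call(rbind, Map(make_rates_row, "st1", "chl_max", SUBSTRATES, 0.02)))
  rates$flags[rates$depth_id == "chl_max" & rates$substrate == "NO3"] <-
    "EXCLUDED_CONSUMPTION"
  rates$rate_umolN_L_h[rates$flags != ""] <- NA
  labels <- data.frame(station_id = "st1", water_mass = "SAB")
  s <- regional_summary(rates, labels)
  # only the surface set is complete
  expect_equal(s$totals$n_sets, 1L)
  expect_equal(s$totals$mean_total_umolN_L_h, 0.06)
})

test_that("synthetic cruise recovers the built-in regional rate ordering", {
  cruise <- generate_cruise(cruise_config(n_stations_per_regime = 2,
                                          noise_cv = 0.05, seed = 8))
  rates <- compute_uptake_rates(cruise$incubations)
  cl <- classify_hydro(cruise$hydro)
  s <- regional_summary(rates, unique(cl[, c("station_id", "water_mass")]))
  tot <- setNames(s$totals$mean_total_umolN_L_h, s$totals$region)
  expect_true(tot["MAB"] > tot["SlopeSea"])
  expect_true(tot["SlopeSea"] > tot["SAB"])
  expect_true(tot["SAB"] > tot["GulfStream"])
})

test_that("Mann-Whitney exact path matches hand-computed and permutation p-values", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  # oracle equivalence against full permutation enumeration
  set.seed(19)
  for (i in 1:8) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    a <- round(rnorm(n1), 3); b <- round(rnorm(n2, 0.5), 3)
    if (any(duplicated(c(a, b)))) next
    got <- mann_whitney_u(a, b)
    expect_equal(got$p, mw_permutation_p(a, b), tolerance = 1e-12)
    # and against the standard library's exact test
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation handles ties and identical samples", {
  a <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 10, 11, 12)
  r <- mann_whitney_u(a, a)
  expect_equal(r$p, 1)
  expect_equal(r$method, "normal")
  # ties force the corrected normal path; compare to the reference test
  b <- a + 2
  got <- mann_whitney_u(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE,
                                             exact = FALSE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), a), "non-empty")
})

test_that("correlation matrix is pairwise-complete Pearson with a pair floor", {
  x <- 1:10
  m <- correlation_matrix(data.frame(x = x, y = 2 * x + 1))
  expect_equal(m["x", "y"], 1)
  # hand-computed five-point pair
  a <- c(1, 2, 4, 5, 8); b <- c(2, 1, 5, 4, 9)
  expect_equal(correlation_matrix(data.frame(a, b))["a", "b"],
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  # columns with < 3 complete pairs are reported missing
  c1 <- c(1, 2, NA, NA, NA); c2 <- c(1, NA, 2, 3, 4)
  expect_true(is.na(correlation_matrix(data.frame(c1, c2))["c1", "c2"]))
  # permuted columns decorrelate
  set.seed(4)
  z <- rnorm(1000)
  expect_lt(abs(correlation_matrix(data.frame(z, zp = sample(z)))["z", "zp"]),
            0.1)
})

test_that("redundancy analysis matches brute-force and library decompositions", {
  set.seed(31)
  for (i in 1:5) {
    Y <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("total", "y2", "y3")))
    X <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("x", 1:4)))
    fit <- uptake_rda(Y, X, sign_column = "total")
    expect_equal(fit$eigenvalues, rda_brute_eigen(Y, X), tolerance = 1e-8)
    if (requireNamespace("vegan", quietly = TRUE)) {
      vfit <- vegan::rda(Y ~ ., data = as.data.frame(X))
      expect_equal(unname(fit$eigenvalues), unname(vfit$CCA$eig),
                   tolerance = 1e-8)
    }
    expect_equal(sum(fit$proportion), 1, tolerance = 1e-12)
    expect_gte(fit$loadings["total", 1], 0)  # sign convention
  }
})

test_that("redundancy analysis honors its structural contracts", {
  set.seed(32)
  X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("x1", "x2")))
  beta <- matrix(c(1, 2), 1, 2)
  # rank-1 response exactly in the span of X: one axis carries everything
  Y <- cbind(X %*% c(0.5, 1), 2 * (X %*% c(0.5, 1)))
  colnames(Y) <- c("total", "y2")
  fit <- uptake_rda(Y, X, sign_column = "total")
  expect_equal(fit$proportion[1], 1, tolerance = 1e-9)
  # response orthogonal to X carries (almost) no constrained variance
  Q <- qr.Q(qr(cbind(1, X)))
  Yo <- matrix(rnorm(30 * 2), 30, 2)
  Yo <- Yo - Q %*% crossprod(Q, Yo)
  colnames(Yo) <- c("total", "y2")
  fit_o <- uptake_rda(Yo, X, sign_column = 1)
  expect_lt(fit_o$constrained_variance / max(fit_o$total_variance, 1e-12), 1e-12)
  # row permutation leaves eigenvalues unchanged; column scaling of X too
  set.seed(33)
  Y2 <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("total", "y2")))
  X2 <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(NULL, paste0("x", 1:3)))
  perm <- sample(25)
  f1 <- uptake_rda(Y2, X2)
  f2 <- uptake_rda(Y2[perm, ], X2[perm, ])
  f3 <- uptake_rda(Y2, sweep(X2, 2, c(10, 0.1, 3), `*`))
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
  expect_equal(f1$eigenvalues, f3$eigenvalues, tolerance = 1e-10)
  # listwise NA removal and the n > p guard
  Yna <- Y2; Yna[3, 1] <- NA
  expect_equal(uptake_rda(Yna, X2)$n_used, 24)
  expect_error(uptake_rda(Y2[1:3, ], X2[1:3, ]), "more complete rows")
  # collinear X is rejected with advice
  Xc <- cbind(X2, x4 = X2[, 1] * 2)
  expect_error(uptake_rda(Y2, Xc), "collinear")
})
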