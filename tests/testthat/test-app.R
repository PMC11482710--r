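# Application workflow: ingestion, screening, prediction, CLI.

wilt_std <- data.frame(
  name = c("GLCM_Pan", "Mean_R", "Mean_NIR", "SD_Pan"),
  mean = c(127.07, 107.74, 453.70, 20.64),
  sd = c(10.67, 71.77, 156.20, 6.76))
wilt_beta <- c(26.110, 1.142, 137.094, -19.340, 0.206)

test_that("CSV loading standardizes covariates and validates the input", {
  set.seed(1)
  df <- data.frame(a = rnorm(30, 5, 2), b = runif(30), y = rbinom(30, 1, 0.5))
  path <- write_toy_csv(df)
  d <- load_binary_csv(path, "y")
  expect_s3_class(d, "binary_dataset")
  z <- d$X[, -1]
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  # stored constants reproduce the raw values
  raw <- sweep(sweep(z, 2, d$standardization$sd, "*"), 2,
               -d$standardization$mean)
  expect_equal(unname(raw), unname(as.matrix(df[, c("a", "b")])),
               tolerance = 1e-12)
  # error paths
  expect_error(load_binary_csv(path, "zz"), "not found")
  expect_error(load_binary_csv(write_toy_csv(transform(df, a = 1)), "y"),
               "zero standard deviation")
  expect_error(load_binary_csv(write_toy_csv(transform(df, y = y + 2)), "y"),
               "binary")
  df_na <- df; df_na$a[3] <- NA
  expect_error(load_binary_csv(write_toy_csv(df_na), "y"), "missing")
  expect_error(load_binary_csv(tempfile(), "y"), "not found")
})

test_that("correlation screening drops one member of each correlated pair", {
  set.seed(2)
  n <- 200
  x1 <- rnorm(n)
  dup <- binary_dataset(rbinom(n, 1, 0.5),
                        x = cbind(a = x1, b = x1, c = rnorm(n)))
  scr <- correlation_screen(dup)
  expect_equal(nrow(scr$dropped), 1)
  expect_equal(abs(scr$dropped$r), 1)
  expect_equal(sort(c(scr$dropped$dropped, setdiff(scr$kept, "c"))),
               c("a", "b"))
  # independent covariates survive untouched
  ind <- binary_dataset(rbinom(n, 1, 0.5),
                        x = matrix(rnorm(n * 3), n,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  scr2 <- correlation_screen(ind)
  expect_equal(nrow(scr2$dropped), 0)
  expect_equal(scr2$kept, c("a", "b", "c"))
  # of a near-duplicate pair, the member more correlated with the rest goes;
  # exact correlations built from a centered orthonormal basis:
  # cor(a,b) = 0.98, cor(b,c) = 0.6, cor(a,c) = 0.588
  set.seed(4)
  Q <- qr.Q(qr(scale(matrix(rnorm(50 * 3), 50), scale = FALSE)))
  a <- Q[, 1]
  b <- 0.98 * Q[, 1] + sqrt(1 - 0.98^2) * Q[, 2]
  cc <- 0.6 * b + 0.8 * Q[, 3]
  tri <- binary_dataset(rbinom(50, 1, 0.5), x = cbind(a = a, b = b, c = cc))
  scr3 <- correlation_screen(tri)
  expect_equal(scr3$dropped$dropped, "b")
  expect_equal(scr3$dropped$r, 0.98, tolerance = 1e-10)
  expect_equal(scr3$kept, c("a", "c"))
  # standardization metadata follows the retained covariates
  df <- data.frame(a = x1, b = x1 * 2 + 1, c = rnorm(n),
                   y = rbinom(n, 1, 0.5))
  d <- load_binary_csv(write_toy_csv(df), "y")
  scr4 <- correlation_screen(d)
  expect_equal(scr4$data$standardization$name, scr4$kept)
})

test_that("predict_at standardizes inputs and defaults covariates to means", {
  # all covariates at their means -> probability at eta = beta0
  p0 <- predict_at(wilt_beta, lam = 0.256, link = "rpdlomax",
                   covariate_names = wilt_std$name,
                   standardization = wilt_std)
  expect_equal(p0, rpdlomax_cdf(26.110, 0.256))
  # no standardization table: values used as-is
  expect_equal(predict_at(c(0, 1), NULL, "logit", list(x1 = 2), "x1"),
               plogis(2))
  expect_error(predict_at(wilt_beta, 0.256, "rpdlomax",
                          list(nope = 1), wilt_std$name, wilt_std),
               "unknown covariate")
  expect_error(predict_at(c(0, 1, 2), NULL, "logit", list(), "x1"),
               "one more element")
  expect_error(predict_at(c(0, 1), NULL, "logit", list(x1 = 1), "x1",
                          standardization = wilt_std),
               "no standardization constants")
})

test_that("effect curves are monotone in the coefficient sign", {
  grid <- seq(50, 160, length.out = 40)
  up <- effect_curve(wilt_beta, 0.256, "rpdlomax", "Mean_R", grid,
                     wilt_std$name, wilt_std)
  expect_true(all(diff(up$prob) >= 0))
  down <- effect_curve(wilt_beta, 0.256, "rpdlomax", "Mean_NIR",
                       seq(150, 1500, length.out = 40),
                       wilt_std$name, wilt_std)
  expect_true(all(diff(down$prob) <= 0))
  flat_beta <- c(0.5, 0, 1)
  flat <- effect_curve(flat_beta, NULL, "logit", "a", 1:10, c("a", "b"))
  expect_equal(var(flat$prob), 0)
  expect_error(effect_curve(wilt_beta, 0.256, "rpdlomax", "nope", grid,
                            wilt_std$name, wilt_std), "unknown covariate")
})

test_that("class-conditional summaries match hand computation", {
  d <- binary_dataset(c(1, 1, 0, 0), x = cbind(x1 = c(2, 1, -1, -2)))
  draws <- rbind(c(0, 1.2), c(0.1, 0.8), c(-0.1, 1.0))
  f <- fake_fit(draws, link = lomax_link("logit"), data = d)
  p_hat <- colMeans(plogis(draws %*% t(d$X))[, ] )
  sm <- class_predictive_summary(f)
  succ <- sm[sm$class == "success", ]
  expect_equal(succ$mean, mean(p_hat[1:2]))
  expect_equal(succ$min, min(p_hat[1:2]))
  expect_equal(succ$max, max(p_hat[1:2]))
  expect_true(all(sm$min <= sm$q1 & sm$q1 <= sm$median &
                  sm$median <= sm$q3 & sm$q3 <= sm$max))
  # a separating fit puts the success class clearly above the failure class
  expect_gt(succ$median, sm[sm$class == "failure", "median"])
  d1 <- binary_dataset(c(1, 1), x = cbind(x1 = c(0, 1)))
  f1 <- fake_fit(draws, link = lomax_link("logit"), data = d1)
  expect_warning(sm1 <- class_predictive_summary(f1), "one class")
  expect_equal(sm1$class, "success")
})

test_that("the command line interface runs end to end and is deterministic", {
  out1 <- file.path(tempdir(), "cli1"); out2 <- file.path(tempdir(), "cli2")
  expect_equal(suppressMessages(cli_main(
    c("simulate", "--link", "rpdlomax", "--lambda", "2", "--n", "120",
      "--seed", "5", "--out", out1))), 0L)
  expect_true(file.exists(file.path(out1, "simulated.csv")))
  suppressMessages(cli_main(
    c("simulate", "--link", "rpdlomax", "--lambda", "2", "--n", "120",
      "--seed", "5", "--out", out2)))
  expect_identical(readLines(file.path(out1, "simulated.csv")),
                   readLines(file.path(out2, "simulated.csv")))
  # compare subcommand on the simulated fixture
  csv <- file.path(out1, "simulated.csv")
  expect_equal(suppressMessages(cli_main(
    c("compare", "--data", csv, "--response", "y",
      "--links", "logit,rpdlomax", "--chains", "2", "--iterations", "200",
      "--warmup", "100", "--seed", "3", "--out", out1))), 0L)
  tab <- read.csv(file.path(out1, "comparison.csv"))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("rho_d", "D_bar", "D_hat", "DIC", "EAIC", "EBIC",
                    "LOO", "WAIC") %in% names(tab)))
  # misspec subcommand writes the proportion-of-ones column
  expect_equal(suppressMessages(cli_main(
    c("misspec", "--lambda", "0.25", "--reps", "2", "--n", "150",
      "--iterations", "100", "--warmup", "50", "--chains", "2",
      "--seed", "9", "--out", out1))), 0L)
  expect_true("mean_prop_ones" %in%
                names(read.csv(file.path(out1, "misspec_prop_ones.csv"))))
  # predict subcommand prints a probability
  p <- capture.output(suppressMessages(cli_main(
    c("predict", "--beta", "26.110,1.142,137.094,-19.340,0.206",
      "--covariates", "GLCM_Pan,Mean_R,Mean_NIR,SD_Pan",
      "--link", "rpdlomax", "--lambda", "0.256",
      "--values", "Mean_R=90",
      "--std-means", "127.07,107.74,453.70,20.64",
      "--std-sds", "10.67,71.77,156.20,6.76"))))
  expect_lt(abs(as.numeric(p[1]) - 0.0149), 1e-3)
  # bad usage fails loudly with a nonzero exit code
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(cli_main(c("fit", "--data"))), 1L)
  expect_equal(suppressMessages(cli_main(character(0))), 1L)
})
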