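test_that("samples map to the daily schedule with half-open boundaries", {
  sch <- block_schedule()
  s <- data.frame(clock_s = c(8.5 * 3600,      # 08:30 -> OTS1
                              9.5 * 3600,      # 09:30 exactly -> ITS1
                              7 * 3600))       # 07:00 -> dropped
  expect_message(out <- assign_blocks(s, sch), "dropped 1")
  expect_equal(out$block, c("OTS1", "ITS1"))
  expect_equal(out$block_type, c("OTS", "ITS"))
  # overlapping schedules are refused
  bad <- data.frame(label = c("A", "B"), type = "OTS",
                    start = c("08:00", "08:30"), end = c("09:00", "09:10"))
  expect_error(block_schedule(bad), "overlap")
})

test_that("subsampling is seed-reproducible and unbiased", {
  x <- rnorm(500)
  a <- subsample_values(x, 200, seed = 99)
  b <- subsample_values(x, 200, seed = 99)
  expect_identical(a, b)
  # n = |x|: a permutation containing every value
  p <- subsample_values(x, length(x), seed = 1)
  expect_equal(sort(p), sort(x))
  expect_error(subsample_values(numeric(0), 10, 1), "empty")
  # subsample means concentrate around the population mean
  set.seed(47)
  pop <- rnorm(2000, 5, 2)
  se <- 2 / sqrt(400)
  means <- vapply(1:100, function(s) mean(subsample_values(pop, 400, s)), numeric(1))
  expect_lt(abs(mean(means) - mean(pop)), 3 * se)
})

test_that("rolling standard deviations match closed forms", {
  kin <- data.frame(k = 1L, t = seq(0, 9.9, 0.1), speed = 1,
                    yaw = 0.2, yaw_rate = 0)
  sds <- rolling_std_metrics(kin, window = 21)
  expect_equal(max(sds$speed_sd), 0)
  expect_equal(max(sds$yaw_sd), 0)
  # alternating +/- a has sd a * sqrt(n/(n-1)) for even windows
  a <- 0.7; w <- 10
  kin2 <- data.frame(k = 1L, t = seq(0, 9.9, 0.1),
                     speed = a * rep(c(1, -1), 50) + 2,
                     yaw = 0, yaw_rate = 0)
  sds2 <- rolling_std_metrics(kin2, window = w)
  interior <- sds2$speed_sd[w:(100 - w)]
  expect_equal(interior, rep(a * sqrt(w / (w - 1)), length(interior)), tolerance = 1e-9)
  # white noise: mean rolling sd approaches sigma
  set.seed(48)
  kin3 <- data.frame(k = 1L, t = seq(0, 199.9, 0.1), speed = rnorm(2000, 1, 0.3),
                     yaw = 0, yaw_rate = 0)
  sds3 <- rolling_std_metrics(kin3, window = 51)
  expect_lt(abs(mean(sds3$speed_sd) - 0.3), 0.02)
  # tracklets shorter than the window are excluded
  expect_equal(nrow(rolling_std_metrics(kin[1:10, ], window = 21)), 0)
})

test_that("the joint PDF is a normalized density with Poisson-consistent cells", {
  set.seed(49)
  s <- runif(1e5); y <- runif(1e5, -pi, pi)
  pdf <- estimate_joint_pdf(s, y, bins = 64, speed_range = c(0, 1))
  expect_equal(sum(pdf$f) * pdf$ds * pdf$dpsi, 1, tolerance = 1e-9)
  counts <- pdf$f * 1e5 * pdf$ds * pdf$dpsi
  lam <- 1e5 / 64^2
  expect_true(all(abs(counts - lam) < 5 * sqrt(lam)))
  # all mass in one cell -> density 1/(ds * dpsi) there
  pdf1 <- estimate_joint_pdf(rep(0.5, 100), rep(0, 100), bins = 8,
                             speed_range = c(0, 1))
  expect_equal(max(pdf1$f), 1 / (pdf1$ds * pdf1$dpsi))
  expect_error(estimate_joint_pdf(rep(1, 5), rep(0, 5), speed_range = c(1, 1)),
               "degenerate")
})

test_that("entropy is exact for uniforms and calibrated for Gaussians", {
  set.seed(50)
  # uniform unit square: h = 0
  hs <- vapply(1:5, function(i) {
    pdf <- estimate_joint_pdf(runif(1e5), runif(1e5, 0, 1), bins = 64,
                              speed_range = c(0, 1), yaw_range = c(0, 1))
    joint_differential_entropy(pdf)$h
  }, numeric(1))
  expect_lt(max(abs(hs)), 0.02)
  # independent Gaussians: closed form ln(2 pi e sigma_s sigma_psi)
  ss <- 0.3; sp <- 0.8
  target <- log(2 * pi * exp(1) * ss * sp)
  err <- vapply(1:20, function(i) {
    s <- rnorm(1e5, 1.4, ss); y <- rnorm(1e5, 0, sp)
    pdf <- estimate_joint_pdf(s, y, bins = 64, speed_range = range(s),
                              yaw_range = range(y))
    joint_differential_entropy(pdf)$h - target
  }, numeric(1))
  expect_lt(max(abs(err)), 0.05)
  # consistency: error shrinks with n for the Gaussian case
  mean_err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    mean(vapply(1:20, function(i) {
      s <- rnorm(n, 1.4, ss); y <- rnorm(n, 0, sp)
      pdf <- estimate_joint_pdf(s, y, bins = 64, speed_range = range(s),
                                yaw_range = range(y))
      abs(joint_differential_entropy(pdf)$h - target)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("entropy matches a Monte-Carlo oracle on a mixture distribution", {
  set.seed(51)
  rmix <- function(n) {
    z <- runif(n) < 0.4
    s <- ifelse(z, rnorm(n, 0.3, 0.1), rnorm(n, 1.5, 0.25))
    y <- ifelse(z, runif(n, -pi, pi), rnorm(n, 0.5, 0.4))
    cbind(s, y)
  }
  xy <- rmix(1e5)
  pdf <- estimate_joint_pdf(xy[, 1], xy[, 2], bins = 64,
                            speed_range = range(xy[, 1]), yaw_range = c(-pi, pi))
  h <- joint_differential_entropy(pdf)$h
  # oracle: -E[ln f_hat] over fresh draws using the fitted histogram
  fresh <- rmix(2e5)
  i <- pmin(pmax(ceiling((fresh[, 1] - pdf$speed_range[1]) / pdf$ds), 1), pdf$bins)
  j <- pmin(pmax(ceiling((fresh[, 2] - pdf$yaw_range[1]) / pdf$dpsi), 1), pdf$bins)
  fv <- pdf$f[cbind(i, j)]
  ok <- fv > 0 & fresh[, 1] >= pdf$speed_range[1] & fresh[, 1] <= pdf$speed_range[2]
  h_mc <- -mean(log(fv[ok]))
  expect_lt(abs(h - h_mc), 0.05)
})

test_that("the K-S distance equals a brute-force ECDF scan and ks.test", {
  set.seed(52)
  expect_equal(ks_two_sample(1:10, 1:10)$delta_ks, 0)
  expect_equal(ks_two_sample(runif(50), runif(50) + 10)$delta_ks, 1)
  for (i in 1:200) {
    n1 <- sample(5:500, 1); n2 <- sample(5:500, 1)
    a <- rnorm(n1, sd = runif(1, 0.5, 2))
    b <- rnorm(n2, mean = runif(1, -0.5, 0.5))
    ks <- ks_two_sample(a, b)
    expect_equal(ks$delta_ks, ks_bruteforce(a, b), tolerance = 1e-12)
  }
  # p-value agrees with the reference asymptotic implementation
  for (i in 1:20) {
    a <- rnorm(150); b <- rnorm(200, 0.2)
    ks <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ks$delta_ks, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ks$alpha, ref$p.value, tolerance = 1e-4)
  }
})

test_that("the K-S distance is invariant under strictly monotone transforms", {
  set.seed(53)
  a <- rexp(120); b <- rexp(150, 1.4)
  d0 <- ks_two_sample(a, b)$delta_ks
  for (f in list(function(x) log1p(x), function(x) x^3, function(x) -1 / (1 + x))) {
    expect_equal(ks_two_sample(f(a), f(b))$delta_ks, d0, tolerance = 1e-12)
  }
})

test_that("empirical type-I error at the 0.001 threshold is within the binomial band", {
  set.seed(54)
  n_rep <- 2000
  hits <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(500); b <- rnorm(500)
    if (ks_two_sample(a, b)$alpha < 0.001) hits <- hits + 1L
  }
  rate <- hits / n_rep
  expect_gte(rate, 0)
  expect_lte(rate, 0.005)
})

test_that("block comparisons detect separated speed distributions and refuse cross-type pairs", {
  set.seed(55)
  mk <- function(block, type, mu) data.frame(
    block = block, block_type = type, metric = "speed",
    value = rnorm(12000, mu, 0.3))
  ms <- rbind(mk("OTS1", "OTS", 1.3), mk("OTS2", "OTS", 1.6),
              mk("ITS1", "ITS", 1.4))
  res <- compare_blocks(ms, n_sub = 1e4, seed = 3)
  row <- res[res$block_i == "OTS1" & res$block_j == "OTS2", ]
  expect_equal(nrow(row), 1)
  expect_gt(row$delta_ks, 0.3)        # ~0.38 for a 1-sigma mean shift
  expect_true(row$significant)
  expect_false(any(res$type == "ITS"))  # single ITS block: nothing to compare
  expect_error(compare_blocks(ms, n_sub = 100, seed = 3,
                              pairs = data.frame(block_i = "OTS1", block_j = "ITS1")),
               "cross-type")
})

test_that("seed fan-out is deterministic and key-sensitive", {
  expect_identical(fan_seed(1, "ks", "OTS1", "speed"), fan_seed(1, "ks", "OTS1", "speed"))
  expect_false(fan_seed(1, "ks", "OTS1", "speed") == fan_seed(1, "ks", "OTS2", "speed"))
  expect_false(fan_seed(1, "a") == fan_seed(2, "a"))
  expect_true(fan_seed(12345, "x", "y") >= 0)
})
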