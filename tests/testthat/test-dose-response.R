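# Endpoint transfer functions, intervals, and fold-induction propagation.

test_that("t_interval matches the Student-t table and degenerates cleanly", {
  ci <- t_interval(c(1, 2, 3))
  # half-width = t(0.975, df=2) * sd/sqrt(3) = 4.3027 * 0.5774 = 2.4843
  expect_equal(unname(ci), c(-0.4843, 4.4843), tolerance = 1e-4)
  expect_equal(unname(t_interval(rep(7, 4))), c(7, 7))
  expect_error(t_interval(5), "at least 2")
})

test_that("t_interval has ~95% coverage on simulated normal triples", {
  set.seed(123)
  n_sim <- 10000
  hits <- vapply(seq_len(n_sim), function(i) {
    x <- rnorm(3, mean = 2, sd = 1.5)
    ci <- t_interval(x)
    ci[1] <= 2 && 2 <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.94)
  expect_lt(mean(hits), 0.96)
})

test_that("bootstrap CI is reproducible, degenerate on constants, and
           consistent with the t interval on normal samples", {
  expect_equal(unname(bootstrap_sem_ci(rep(3, 5), seed = 1)), c(3, 3))
  a <- bootstrap_sem_ci(c(1, 5, 2, 8, 3), seed = 42)
  b <- bootstrap_sem_ci(c(1, 5, 2, 8, 3), seed = 42)
  expect_identical(a, b)
  expect_error(bootstrap_sem_ci(1), "at least 2")
  set.seed(99)
  x <- rnorm(20, 10, 2)
  tci <- t_interval(x)
  bci <- bootstrap_sem_ci(x, n_boot = 4000, seed = 7)
  s <- sd(x)
  # percentile bootstrap is slightly narrower; must sit inside the t
  # interval up to Monte-Carlo slack
  expect_gte(bci[1], tci[1] - 0.1 * s)
  expect_lte(bci[2], tci[2] + 0.1 * s)
  expect_lt(abs(diff(bci) - diff(tci)) / diff(tci), 0.2)
})

test_that("transfer function summarizes endpoint AFU/OD per dose", {
  exp <- make_flat_plate(c(1, 2, 3))
  tf <- transfer_function(exp, endpoint_min = 900)
  expect_equal(nrow(tf), 1)
  expect_equal(tf$mean, 2)
  expect_equal(tf$ci_low, -0.4843, tolerance = 1e-3)
  expect_equal(tf$ci_high, 4.4843, tolerance = 1e-3)
  expect_equal(tf$n_replicates, 3L)
  # identical replicates: zero-width interval
  tf2 <- transfer_function(make_flat_plate(c(5, 5, 5)))
  expect_equal(tf2$ci_low, tf2$ci_high)
  # missing endpoint names the wells
  short <- make_flat_plate(c(1, 2, 3), times = c(0, 100, 200))
  expect_error(transfer_function(short, endpoint_min = 900), "A1")
})

test_that("zero-noise transfer functions are monotone in concentration", {
  cfg <- library_config(sensors = "MphR",
                        noise = noise_params(0, 0, 0), seed = 1)
  tf <- transfer_function(simulate_plate(cfg))
  tf <- tf[order(tf$concentration_uM), ]
  expect_true(all(diff(tf$mean) > 0))
})

test_that("fold induction reproduces the propagated-error formula", {
  # groups engineered to exact means and SEMs:
  # I = 1000 (se 10), U = 100 (se 5), C = 50 (se 2)
  fi <- fold_induction(group_with(1000, 10), group_with(100, 5),
                       group_with(50, 2))
  expect_false(fi$is_lower_bound)
  expect_equal(fi$value, 19)
  expect_equal(fi$se, 19 * sqrt((10^2 + 2^2) / 950^2 + (5^2 + 2^2) / 50^2),
               tolerance = 1e-12)
  expect_equal(fi$se, 2.0565, tolerance = 1e-4)
})

test_that("propagated error matches Monte-Carlo propagation", {
  mc_sd <- function(I, sI, U, sU, C, sC, n = 1e6, seed = 1) {
    # one control mean per draw, subtracted from both numerator and
    # denominator (as in the experiment)
    set.seed(seed)
    Cd <- rnorm(n, C, sC)
    f <- (rnorm(n, I, sI) - Cd) / (rnorm(n, U, sU) - Cd)
    sd(f)
  }
  fi <- fold_induction(group_with(1000, 10), group_with(100, 5),
                       group_with(50, 2))
  expect_lt(abs(fi$se - mc_sd(1000, 10, 100, 5, 50, 2)) /
              fi$se, 0.05)
  # randomized inputs away from the background regime
  # regime: uninduced signal well clear of background, control error
  # small (stable autofluorescence), as in the experiments; the formula
  # treats the control error as independent in numerator and denominator,
  # so a dominant correlated control term would bias it (see vignette)
  set.seed(21)
  for (i in 1:8) {
    C <- runif(1, 10, 100); sC <- runif(1, 0.2, 1.5)
    U <- C + runif(1, 100, 300); sU <- runif(1, 0.5, 5)
    I <- U + runif(1, 500, 5000); sI <- runif(1, 1, 20)
    U_B <- U - C
    if (U_B <= 5 * sqrt(sU^2 + sC^2)) next
    fi <- fold_induction(group_with(I, sI), group_with(U, sU),
                         group_with(C, sC))
    expect_lt(abs(fi$se - mc_sd(I, sI, U, sU, C, sC, n = 2e5, seed = i)) /
                fi$se, 0.05)
  }
})

test_that("fold induction is scale invariant", {
  set.seed(31)
  I <- rnorm(3, 2000, 50); U <- rnorm(3, 300, 10); C <- rnorm(3, 100, 5)
  base <- fold_induction(I, U, C)
  for (c_ in c(0.01, 7, 1e4)) {
    sc <- fold_induction(c_ * I, c_ * U, c_ * C)
    expect_equal(sc$value, base$value, tolerance = 1e-12)
    expect_equal(sc$se / sc$value, base$se / base$value,
                 tolerance = 1e-12)
  }
})

test_that("the within-background rule returns a flagged lower bound", {
  # U_B - 2*sqrt(sU^2+sC^2) <= 0 triggers the bound
  I <- group_with(1000, 10); U <- group_with(104, 5); C <- group_with(100, 2)
  fi <- fold_induction(I, U, C)
  expect_true(fi$is_lower_bound)
  expect_true(is.na(fi$se))
  s_IB <- sqrt(10^2 + 2^2); s_UB <- sqrt(5^2 + 2^2)
  expect_equal(fi$value, (900 - 2 * s_IB) / (4 + 2 * s_UB),
               tolerance = 1e-12)
  # bound is below the (here undefined-but-computable) point ratio
  expect_lt(fi$value, 900 / 4)
  # trivial exactness: no spread, I_B = U_B
  fi1 <- fold_induction(rep(20, 3), rep(20, 3), rep(10, 3))
  expect_equal(fi1$value, 1)
  expect_equal(fi1$se, 0)
  expect_false(fi1$is_lower_bound)
  # undefined fold
  expect_error(fold_induction(group_with(10, 1), group_with(1, 1),
                              group_with(50, 1)), "undefined")
})

test_that("plate fold induction summarizes each sensor at its
           maximum-response dose", {
  cfg <- library_config(sensors = c("AraC", "AcuR"), seed = 5)
  exp <- simulate_plate(cfg)
  fi <- plate_fold_induction(exp)
  expect_setequal(fi$sensor, c("AraC", "AcuR"))
  ara <- fi[fi$sensor == "AraC", ]
  expect_false(ara$is_lower_bound)
  expect_gt(ara$fold, 50)
})
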