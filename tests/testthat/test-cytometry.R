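# Single-cell transforms, gating, state classification, combinatorics.

test_that("the asinh transform is anchored, monotone, and log-like in
           its tail", {
  expect_equal(asinh_transform(0), 0)
  set.seed(3)
  x <- sort(runif(100, 0, 1e5))
  expect_true(all(diff(asinh_transform(x)) > 0))
  v <- c(2e4, 1e5, 1e6)
  expect_equal(asinh_transform(v), log(2 * v / 150), tolerance = 0.01)
})

test_that("thresholds are midpoints of transformed medians", {
  mk <- function(med) cytometry_sample(
    "s", matrix(rep(150 * sinh(med), 10), ncol = 1,
                dimnames = list(NULL, "GFP")))
  expect_equal(derive_thresholds(mk(1), mk(5), "GFP"), 3)
  expect_error(derive_thresholds(mk(2), mk(2), "GFP"),
               "degenerate separation")
  expect_error(derive_thresholds(mk(5), mk(1), "GFP"),
               "degenerate separation")
})

test_that("gating misclassifies under 2% of well-separated events", {
  off <- simulate_events(character(), n_events = 5000,
                         nonresponder_frac = 0, seed = 1)
  on <- simulate_events(c("glucarate", "acrylate", "erythromycin"),
                        n_events = 5000, nonresponder_frac = 0, seed = 2)
  thr <- derive_thresholds(off, on, "GFP")
  off_t <- asinh_transform(off$events[, "GFP"])
  on_t <- asinh_transform(on$events[, "GFP"])
  err <- (sum(off_t > thr) + sum(on_t <= thr)) / 10000
  expect_lt(err, 0.02)
})

test_that("all eight binary induction states map to distinct modal codes", {
  panel <- simulate_state_panel(n_events = 2000, seed = 5)
  off <- panel[["none"]]
  on <- panel[["acrylate+erythromycin+glucarate"]]
  thr <- vapply(colnames(off$events), function(ch)
    derive_thresholds(off, on, ch), numeric(1))
  st <- classify_states(panel, thr)
  expect_equal(nrow(st), 8)
  expect_equal(length(unique(st$modal_code)), 8)
  expect_true(all(st$purity >= 0.95))
  # uninduced sample: all-off code, no defined non-responder estimate
  un <- st[st$sample_label == "none", ]
  expect_equal(un$modal_code, "000")
  expect_true(is.na(un$nonresponder_frac_est))
})

test_that("injected non-responders are recovered within half a percent", {
  panel <- simulate_state_panel(n_events = 4000,
                                nonresponder_frac = 0.015, seed = 8)
  off <- panel[["none"]]
  on <- panel[["acrylate+erythromycin+glucarate"]]
  thr <- vapply(colnames(off$events), function(ch)
    derive_thresholds(off, on, ch), numeric(1))
  st <- classify_states(panel, thr)
  est <- st$nonresponder_frac_est[st$modal_code != "000"]
  expect_true(all(abs(est - 0.015) <= 0.005))
})

test_that("classification is invariant under order-preserving channel
           rescaling", {
  panel <- simulate_state_panel(n_events = 500, seed = 21)
  off <- panel[["none"]]; on <- panel[[8]]
  thr <- vapply(colnames(off$events), function(ch)
    derive_thresholds(off, on, ch), numeric(1))
  st1 <- classify_states(panel, thr)
  scale_sample <- function(s, f) { s$events <- s$events * f; s }
  panel2 <- lapply(panel, scale_sample, f = 37)
  off2 <- panel2[["none"]]; on2 <- panel2[[8]]
  thr2 <- vapply(colnames(off2$events), function(ch)
    derive_thresholds(off2, on2, ch), numeric(1))
  st2 <- classify_states(panel2, thr2)
  expect_equal(st2$modal_code, st1$modal_code)
  expect_equal(st2$purity, st1$purity)
})

test_that("state counts follow levels^n and match brute-force
           enumeration", {
  expect_identical(state_count(3, 2), 8L)
  expect_identical(state_count(4, 2), 16L)
  expect_identical(state_count(5, 2), 32L)
  expect_identical(state_count(3, 3), 27L)
  expect_identical(state_count(4, 3), 81L)
  for (n in 1:5) {
    for (lv in 1:3) {
      codes <- do.call(expand.grid, rep(list(seq_len(lv)), n))
      expect_identical(state_count(n, lv), nrow(unique(codes)))
    }
  }
  expect_error(state_count(0, 2))
})

test_that("three-level gating distinguishes none/intermediate/high", {
  cp <- default_channel_params()[1, ]
  cp$off_gcv <- cp$on_gcv <- 0
  lowmk <- function(m) cytometry_sample(
    "x", matrix(rep(m, 50), ncol = 1, dimnames = list(NULL, "GFP")))
  thr <- list(GFP = c(asinh_transform(500), asinh_transform(5000)))
  st <- classify_states(list(lowmk(150), lowmk(1500), lowmk(15000)),
                        thr, levels = 3)
  expect_equal(st$modal_code, c("0", "1", "2"))
})

test_that("histogram summaries flag only well-separated mixtures", {
  set.seed(4)
  uni <- cytometry_sample("u", matrix(rlnorm(4000, log(2000), 0.5),
                                      ncol = 1,
                                      dimnames = list(NULL, "GFP")))
  hu <- histogram_summary(uni, "GFP")
  expect_false(hu$bimodal)
  mix <- cytometry_sample("m", matrix(
    c(rlnorm(2000, log(150), 0.5), rlnorm(2000, log(50000), 0.5)),
    ncol = 1, dimnames = list(NULL, "GFP")))
  hm <- histogram_summary(mix, "GFP")
  expect_true(hm$bimodal)
  pt <- cytometry_sample("p", matrix(rep(700, 20), ncol = 1,
                                     dimnames = list(NULL, "GFP")))
  hp <- histogram_summary(pt, "GFP")
  expect_equal(hp$robust_cv, 0)
  expect_false(hp$bimodal)
})
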