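# Scan/threshold machinery and mechanism-neutrality invariants.

test_that("threshold detection brackets a known crossing exactly", {
  xs <- 1:10
  ys <- c(1, 1, 1, 1, 0.8, 0.3, 0.02, 0.01, 0.005, 0.004)
  th <- find_threshold(xs, ys, control = 1,
                       threshold_criterion("inhibition", 0.05))
  expect_true(th$crossed)
  expect_equal(th$threshold, 7)
  expect_equal(th$bracket, c(6, 7))
  # recovery criterion on an increasing curve
  th2 <- find_threshold(xs, rev(ys), control = 1,
                        threshold_criterion("recovery", 0.5))
  expect_true(th2$crossed)
  expect_equal(th2$threshold, 6) # first grid point at or above half-control
})

test_that("a never-met criterion reports no threshold, not an error", {
  th <- find_threshold(1:5, c(1, 0.9, 0.85, 0.8, 0.8), control = 1,
                       threshold_criterion("inhibition", 0.05))
  expect_false(th$crossed)
  expect_true(is.na(th$threshold))
})

test_that("bisection refines the bracket with a fresh evaluator", {
  f <- function(x) 1 / (1 + (x / 5)^6) # smooth drop around x = 5
  xs <- c(1, 2, 4, 8, 16)
  th <- find_threshold(xs, f(xs), control = 1,
                       threshold_criterion("inhibition", 0.2),
                       eval_fn = f, rel_tol = 0.02)
  exact <- 5 * (1 / 0.2 - 1)^(1 / 6)
  expect_lt(abs(th$threshold - exact) / exact, 0.03)
})

test_that("criterion fractions outside (0,1) are rejected", {
  expect_error(threshold_criterion("inhibition", 0), "in \\(0, 1\\)")
  expect_error(threshold_criterion("recovery", 1.2), "in \\(0, 1\\)")
})

test_that("fold = 1 under TSP1 reproduces the no-TSP1 control", {
  m <- test_model()
  # TSP1 present but mechanisms at fold 1: the decoration must be neutral
  prot_t <- tsp1_vegf_protocol(2, tsp1_pre = 10, vegf_dur = 20, dt = 1)
  prot_0 <- tsp1_vegf_protocol(0, tsp1_pre = 10, vegf_dur = 20, dt = 1)
  p1 <- tsp1_mechanism_params(m$params, 1, 1)
  tr_t <- run_protocol(m, prot_t, params = p1, rtol = 1e-7, atol = 1e-9)
  tr_0 <- run_protocol(m, prot_0, params = p1, rtol = 1e-7, atol = 1e-9)
  mt <- trajectory_metrics(tr_t, 10)
  m0 <- trajectory_metrics(tr_0, 10)
  expect_equal(mt, m0, tolerance = 2e-3)
})

test_that("mechanism scans are monotone in the inhibiting direction", {
  m <- test_model()
  sc <- cache_get("deg_scan_coarse", {
    scan_fold(m, "degradation", folds = c(1, 3, 10, 30, 100))
  })
  tol <- 0.02 * max(sc$max_pERK)
  expect_true(all(diff(sc$max_pERK) <= tol))
  expect_true(all(diff(sc$pR2_10min) <= tol))
})

test_that("therapy recovery curves are monotone non-decreasing", {
  m <- test_model()
  sc <- cache_get("tsp1_inh_coarse", {
    tsp1_inhibition_scan(m, inhibition = c(0, 0.25, 0.5, 0.75, 1))
  })
  tol <- 0.02 * max(sc$max_pERK)
  expect_true(all(diff(sc$max_pERK) >= -tol))
  expect_true(all(diff(sc$max_Ca) >= -tol))
})

test_that("cells without CD47 ignore TSP1 entirely", {
  m <- test_model()
  p_mech <- tsp1_mechanism_params(m$params, 10, 51)
  p_mech <- param_set(p_mech, CD47_0 = 0)
  prot_t <- tsp1_vegf_protocol(2, tsp1_pre = 0, vegf_dur = 20, dt = 1)
  prot_0 <- tsp1_vegf_protocol(0, tsp1_pre = 0, vegf_dur = 20, dt = 1)
  tr_t <- run_protocol(m, prot_t, params = p_mech, rtol = 1e-6, atol = 1e-8)
  tr_0 <- run_protocol(m, prot_0, params = p_mech, rtol = 1e-6, atol = 1e-8)
  expect_equal(max(tr_t$pERK), max(tr_0$pERK), tolerance = 1e-3)
  expect_equal(max(tr_t$Ca_c), max(tr_0$Ca_c), tolerance = 1e-3)
})

test_that("CRAC time-constant variation leaves peak ERK unchanged", {
  m <- test_model()
  st <- cache_get("crac_study", {
    crac_inhibition_study(m, amp_frac = c(1, 0.25, 0), tau_factor = c(0.2, 1, 25),
                          duration = 30)
  })
  tau_rows <- st[st$quantity == "tau", ]
  expect_lt(diff(range(tau_rows$max_pERK)) / max(tau_rows$max_pERK), 0.01)
  amp_rows <- st[st$quantity == "amplitude", ]
  ctrl <- amp_rows$plateau_pERK[amp_rows$factor == 1]
  # amplitude inhibition reduces the plateau phase
  expect_lt(amp_rows$plateau_pERK[amp_rows$factor == 0], 0.5 * ctrl)
  # and pulls plateau calcium back toward baseline
  expect_lt(amp_rows$plateau_Ca[amp_rows$factor == 0],
            amp_rows$plateau_Ca[amp_rows$factor == 1])
})

test_that("dose response reports a switch location", {
  m <- test_model()
  dr <- cache_get("dose_scan", {
    dose_response(m, doses_pM = c(1, 2, 3, 4, 5, 6, 8, 12, 50, 1000),
                  duration = 30)
  })
  expect_true(all(diff(dr$max_pERK) >= -0.02 * max(dr$max_pERK)))
  sw <- attr(dr, "switch_pM")
  expect_false(is.na(sw["max_pERK"]))
})
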