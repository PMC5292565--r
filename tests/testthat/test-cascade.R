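# ERK cascade closures and conservation.

test_that("PLC-gamma rate follows the saturating closure", {
  expect_equal(plcg_rate(100, 0, 1e-4, 1), 0)
  expect_equal(plcg_rate(100, 1, 1e-4, 1), 1e-4 * 100 / 2) # half-saturation
  set.seed(5)
  for (rep in 1:10) {
    pr2 <- stats::runif(1, 0, 5000)
    plc <- stats::runif(1, 0, 2)
    k <- stats::runif(1, 1e-6, 1e-3)
    km <- stats::runif(1, 0.1, 5)
    expect_equal(plcg_rate(pr2, plc, k, km), k * pr2 * plc / (km + plc))
  }
  expect_error(plcg_rate(-1, 1, 1, 1), "non-negative")
})

test_that("Ras activation saturates in S1P", {
  expect_equal(ras_rate(0.5, 0, 0.2, 0.5), 0)
  expect_equal(ras_rate(0.5, 0.5, 0.2, 0.5), 0.1) # half-maximal at Km
  expect_equal(ras_rate(0.5, 1e9, 0.2, 0.5), 0.2, tolerance = 1e-6)
  expect_error(ras_rate(0.5, -1, 0.2, 0.5), "non-negative")
})

test_that("every cascade cycle conserves its protein total", {
  p <- default_params()
  st <- vegfsig:::cascade_rest_state(p)
  set.seed(11)
  for (rep in 1:5) {
    s2 <- st
    # randomly redistribute each cycle's pools
    mix <- function(a, b) {
      tot <- s2[[a]] + s2[[b]]
      f <- stats::runif(1)
      s2[[a]] <<- tot * f; s2[[b]] <<- tot * (1 - f)
    }
    mix("PLCg", "pPLCg"); mix("PKC", "aPKC"); mix("RasGDP", "RasGTP")
    mix("Raf", "aRaf"); mix("MEK", "aMEK"); mix("ERK", "pERK")
    s2[["pSphK1"]] <- 0.2; s2[["SphK1m"]] <- 0.1
    s2[["SphK1"]] <- param_get(p, "SphK1_tot") - 0.3
    d <- cascade_rhs(s2, pR2 = 1500, ca = 0.3, p)
    expect_equal(unname(d["PLCg"] + d["pPLCg"]), 0, tolerance = 1e-12)
    expect_equal(unname(d["PKC"] + d["aPKC"]), 0, tolerance = 1e-12)
    expect_equal(unname(d["SphK1"] + d["pSphK1"] + d["SphK1m"]), 0,
                 tolerance = 1e-12)
    expect_equal(unname(d["RasGDP"] + d["RasGTP"]), 0, tolerance = 1e-12)
    expect_equal(unname(d["Raf"] + d["aRaf"]), 0, tolerance = 1e-12)
    expect_equal(unname(d["MEK"] + d["aMEK"]), 0, tolerance = 1e-12)
    expect_equal(unname(d["ERK"] + d["pERK"]), 0, tolerance = 1e-12)
  }
})

test_that("blocking SphK1 abolishes ERK activation but not the baseline", {
  m <- test_model()
  ctrl <- cache_get("ctrl30", {
    run_protocol(m, vegf_protocol(50, duration = 30, dt = 1),
                 rtol = 1e-6, atol = 1e-8)
  })
  blocked <- cache_get("sphk_block30", {
    run_protocol(m, vegf_protocol(50, duration = 30, dt = 1),
                 rtol = 1e-6, atol = 1e-8, sphk1_blocked = TRUE)
  })
  expect_lt(max(blocked$pERK), 0.05 * max(ctrl$pERK))
  # with no VEGF, blocking changes nothing
  base_b <- run_protocol(m, protocol(10, dt = 2), rtol = 1e-6, atol = 1e-8,
                         sphk1_blocked = TRUE)
  base <- run_protocol(m, protocol(10, dt = 2), rtol = 1e-6, atol = 1e-8)
  expect_equal(base_b$pERK, base$pERK, tolerance = 1e-8)
})

test_that("removing the CIB1 calcium switch suppresses ERK", {
  m <- test_model()
  ctrl <- cache_get("ctrl30", {
    run_protocol(m, vegf_protocol(50, duration = 30, dt = 1),
                 rtol = 1e-6, atol = 1e-8)
  })
  noswitch <- run_protocol(m, vegf_protocol(50, duration = 30, dt = 1),
                           rtol = 1e-6, atol = 1e-8, cib1_blocked = TRUE)
  expect_lt(max(noswitch$pERK), 0.1 * max(ctrl$pERK))
  # removing the feedback can never increase the peak
  expect_lte(max(noswitch$pERK), max(ctrl$pERK))
})
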