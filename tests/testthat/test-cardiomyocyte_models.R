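# Cardiomyocyte model: parameter sets, RHS contracts, phenotypes.

healthy <- cm_parameters("healthy")

test_that("IK1 vanishes at the K+ reversal potential and currents respond to scaling", {
  s <- ord_initial_state()
  ek <- 8314 * 310 / 96485 * log(5.4 / s[["ki"]])
  s[["v"]] <- ek
  out <- ord_rhs(s, healthy)
  expect_equal(out$currents[["i_k1"]], 0, tolerance = 1e-12)
  # same driving force logic for Ito and IKr
  expect_equal(out$currents[["i_to"]], 0, tolerance = 1e-12)
  expect_equal(out$currents[["i_kr"]], 0, tolerance = 1e-12)

  # homogeneity: doubling g_k1 doubles IK1 at fixed state
  s2 <- ord_initial_state()
  p2 <- healthy; p2$scale[["g_k1"]] <- 2
  expect_equal(ord_rhs(s2, p2)$currents[["i_k1"]],
               2 * ord_rhs(s2, healthy)$currents[["i_k1"]])
})

test_that("all conductances zero and no external current freezes the voltage", {
  p0 <- healthy
  p0$scale[] <- 0
  p0$scale[["tau_hl"]] <- 1   # a time constant, not a conductance
  out <- ord_rhs(ord_initial_state(), p0, i_external = 0)
  expect_equal(out$deriv[["v"]], 0)
  expect_true(all(abs(out$currents[1:15]) < 1e-15))
})

test_that("non-finite state entries are rejected with the offending name", {
  s <- ord_initial_state()
  s[["cai"]] <- NaN
  expect_error(ord_rhs(s, healthy), "cai")
})

test_that("HF remodeling applies the documented factors exactly once", {
  fac <- hf_remodeling_factors()
  expect_true(all(fac > 0))
  hf <- apply_hf_remodeling(healthy)
  expect_identical(hf$phenotype, "hf")
  # every scaled entry differs from input by exactly its documented factor
  expect_equal(hf$scale[names(fac)], healthy$scale[names(fac)] * fac)
  # unmodified parameters bit-identical
  untouched <- setdiff(names(healthy$scale), names(fac))
  expect_identical(hf$scale[untouched], healthy$scale[untouched])
  # idempotence guard
  expect_error(apply_hf_remodeling(hf), "healthy")
  expect_equal(cm_parameters("hf")$scale, hf$scale)
})

test_that("HF phenotype: longer APD90 and smaller CaT amplitude than healthy", {
  # desk scale: 100 beats captures the direction of the remodeled phenotype
  h <- simulate(coupling_config("healthy", n_beats = 100L))
  f <- simulate(coupling_config("hf", n_beats = 100L))
  bh <- extract_final_beat(h); bf <- extract_final_beat(f)
  expect_gt(ap_metrics(bf)$apd90, ap_metrics(bh)$apd90)
  expect_lt(cat_metrics(bf)$amplitude, cat_metrics(bh)$amplitude)
})

test_that("gating variables stay in [0,1] and concentrations positive along trajectories", {
  gate_idx <- setdiff(seq_along(cellforge:::cm_state_names),
                      c(1:9, match(c("jrelnp", "jrelp", "camkt"),
                                   cellforge:::cm_state_names)))
  for (phen in c("healthy", "hf")) {
    tr <- simulate(coupling_config(phen, n_beats = 5L))
    fs <- tr$final_state$cm
    expect_true(all(fs[gate_idx] >= 0 & fs[gate_idx] <= 1))
    expect_true(all(fs[2:9] > 0))                  # concentrations
    expect_true(all(is.finite(tr$vm)))
  }
})

test_that("without stimulus the model relaxes toward quiescence", {
  tr <- simulate(coupling_config("healthy", n_beats = 10L, stim_amp = 0))
  out <- ord_rhs(tr$final_state$cm, healthy)
  expect_lt(abs(out$deriv[["v"]]), 0.01)   # mV/ms
})

test_that("compiled RHS matches the independent transcription at assorted states", {
  s <- ord_initial_state()
  sc <- healthy$scale
  states <- list(s)
  set.seed(42)
  for (k in 1:6) {
    s2 <- s
    s2[["v"]] <- runif(1, -95, 40)
    s2[["cai"]] <- s[["cai"]] * runif(1, 0.3, 5)
    s2[["cass"]] <- s[["cass"]] * runif(1, 0.3, 5)
    s2[["cajsr"]] <- runif(1, 0.5, 2.5)
    s2[["nai"]] <- s2[["nass"]] <- runif(1, 5, 12)
    states[[k + 1]] <- s2
  }
  for (st in states) {
    a <- ord_rhs(st, healthy, i_external = -2)
    b <- oracle_cm_rhs(st, sc, i_ext = -2)
    expect_equal(a$deriv, b$deriv, tolerance = 1e-10)
    expect_equal(a$currents, b$currents, tolerance = 1e-10)
  }
  # HF scaling path too
  hf <- cm_parameters("hf")
  a <- ord_rhs(s, hf)
  b <- oracle_cm_rhs(s, hf$scale)
  expect_equal(a$deriv, b$deriv, tolerance = 1e-10)
})

test_that("fine and throughput integrator settings agree on APD90 within 1 ms", {
  h2 <- simulate(coupling_config("healthy", n_beats = 30L, dt_max = 0.02))
  h5 <- simulate(coupling_config("healthy", n_beats = 30L, dt_max = 0.005))
  a2 <- ap_metrics(extract_final_beat(h2))$apd90
  a5 <- ap_metrics(extract_final_beat(h5))$apd90
  expect_lt(abs(a2 - a5), 1)
})
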