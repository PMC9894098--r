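# Support-cell models: fibroblast, custom-cell composition rules.

test_that("fibroblast K currents vanish at the fibroblast K+ reversal", {
  ekf <- 8314 * 310 / 96485 * log(5.4 / 129.435)
  s <- fibroblast_initial_state()
  s[["v"]] <- ekf
  out <- fibroblast_rhs(s)
  expect_equal(out$currents[["i_kir"]], 0, tolerance = 1e-12)
  expect_equal(out$currents[["i_kv"]], 0, tolerance = 1e-12)
})

test_that("fibroblast with zero conductances is a bare capacitor", {
  s <- fibroblast_initial_state()
  out <- fibroblast_rhs(s, i_external_pa = 12.6,
                        scale = c(kv = 0, kir = 0, nak = 0, bna = 0))
  expect_equal(out$deriv[["v"]], -12.6 / 6.3)   # pA over 6.3 pF
})

test_that("fibroblast steady-state I-V matches the closed-form oracle", {
  vgrid <- seq(-100, 40, by = 10)
  for (v in vgrid) {
    # voltage clamp at steady state: gates at their infinity values
    g <- oracle_fib_iv(v)
    sinf <- fibroblast_initial_state()
    sinf[["v"]] <- v
    sinf[["r_kv"]] <- 1 / (1 + exp(-(v + 20) / 11))
    sinf[["s_kv"]] <- 1 / (1 + exp((v + 23) / 7))
    cur <- fibroblast_rhs(sinf)$currents
    for (n in names(g)) {
      denom <- max(abs(g[[n]]), 1e-6)
      expect_lt(abs(cur[[n]] - g[[n]]) / denom, 0.01)
    }
  }
})

test_that("custom cell with all scalings zero is a pure capacitor", {
  spec <- custom_cell_spec("all-channels", scaling = rep(0, 20))
  s <- custom_initial_state(spec, v0 = -50, relax_ms = 0)
  out <- custom_cell_rhs(s, spec, i_gap_pa = 0)
  expect_equal(out$deriv[["v"]], 0)
  out2 <- custom_cell_rhs(s, spec, i_gap_pa = 40)
  expect_equal(out2$deriv[["v"]], -1)            # 40 pA over 40 pF
})

test_that("unknown channel identities are rejected", {
  expect_error(custom_cell_spec(c("cm_k1", "not_a_channel")), "unknown channel")
  expect_error(custom_cell_spec(c("cm_k1", "cm_k1")), "duplicate")
  expect_error(custom_cell_spec("cm_k1", scaling = c(cm_k1 = -1)), ">= 0")
})

test_that("additivity: a union roster's total current is the sum of its parts", {
  set.seed(7)
  spec_all <- custom_cell_spec("all-channels")
  st <- custom_initial_state(spec_all, v0 = -30, relax_ms = 0)
  # perturb gates so the check is not at a special point
  gates <- setdiff(names(st), "v")
  st[gates] <- pmin(pmax(st[gates] + runif(length(gates), -0.2, 0.2), 0), 1)
  a <- custom_cell_rhs(st, custom_cell_spec(roster_preset("nonexcitable")))
  b <- custom_cell_rhs(st, custom_cell_spec(cellforge:::cust_channel_names[14:20]))
  u <- custom_cell_rhs(st, spec_all)
  expect_equal(sum(u$currents), sum(a$currents) + sum(b$currents), tolerance = 1e-12)
  expect_equal(u$deriv[["v"]], a$deriv[["v"]] + b$deriv[["v"]], tolerance = 1e-12)
})

test_that("homogeneity: the scaling factor multiplies a channel's current exactly", {
  for (s_fac in c(0.25, 1, 3.7)) {
    spec <- custom_cell_spec("ik1-only", scaling = c(cm_k1 = s_fac))
    st <- custom_initial_state(spec, v0 = -70, relax_ms = 0)
    base <- custom_cell_rhs(st, custom_cell_spec("ik1-only"))$currents[["cm_k1"]]
    expect_equal(custom_cell_rhs(st, spec)$currents[["cm_k1"]], s_fac * base)
  }
})

test_that("custom-cell currents match the independent transcription", {
  spec <- custom_cell_spec("all-channels")
  dens <- cellforge:::spec_densities(spec)
  conc <- spec$concentrations
  set.seed(11)
  for (v0 in c(-80, -45, -10, 25)) {
    st <- custom_initial_state(spec, v0 = v0, relax_ms = 0)
    got <- custom_cell_rhs(st, spec)$currents
    want <- oracle_cust_currents(st, dens, conc)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("hCIC-only roster reproduces the hCIC model currents at matched state", {
  spec <- custom_cell_spec("hcic")
  st <- custom_initial_state(spec, v0 = -40, relax_ms = 0)
  got <- custom_cell_rhs(st, spec)$currents
  want <- oracle_cust_currents(st, cellforge:::spec_densities(spec),
                               spec$concentrations)
  cic <- grep("^cic_", names(got), value = TRUE)
  expect_equal(got[cic], want[cic], tolerance = 1e-10)
  expect_true(all(got[setdiff(names(got), cic)] == 0))
})

test_that("custom-cell intracellular concentrations are constant by construction", {
  spec <- custom_cell_spec("all-channels")
  refs_state <- custom_initial_state(spec)
  # concentrations are spec data, not state: no concentration entries exist
  expect_false(any(c("nai", "ki", "cai") %in% names(refs_state)))
  cfg <- coupling_config("healthy", n_beats = 3L, g_gap_ns = 2)
  tr <- simulate(cfg, spec)
  # the spec (and hence the concentrations every RHS evaluation sees) is
  # carried through unchanged
  expect_identical(tr$spec$concentrations, spec$concentrations)
  expect_true(all(is.finite(tr$vm_custom)))
})

test_that("channel catalog and roster presets are consistent", {
  cat <- channel_catalog()
  expect_identical(cat$name, cellforge:::cust_channel_names)
  expect_true(all(cat$baseline >= 0))
  expect_setequal(roster_preset("all-channels"),
                  setdiff(cat$name, "passive_leak"))
  expect_identical(roster_preset("ik1-only"), "cm_k1")
  expect_error(roster_preset("nope"), "unknown roster preset")
  # leakage/background currents of source models are not in any preset
  for (p in c("nonexcitable", "all-channels", "hmsc", "hcic"))
    expect_false("passive_leak" %in% roster_preset(p))
})
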