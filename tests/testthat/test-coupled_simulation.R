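# Coupled simulation: decoupling, gap-current bookkeeping, window extraction.

test_that("G_gap = 0 decouples: cardiomyocyte trajectory identical to uncoupled", {
  spec <- custom_cell_spec("ik1-only", scaling = c(cm_k1 = 0))
  tr0 <- simulate(coupling_config("healthy", n_beats = 4L, record_from_beat = 1L))
  trc <- simulate(coupling_config("healthy", n_beats = 4L, g_gap_ns = 0,
                                  record_from_beat = 1L), spec)
  expect_equal(trc$vm, tr0$vm, tolerance = 1e-12)
  expect_equal(trc$cai, tr0$cai, tolerance = 1e-12)
  expect_true(all(trc$igap_custom_pa == 0))
})

test_that("an all-passive custom cell tracks a low-pass filtered AP (RC oracle)", {
  spec <- custom_cell_spec("all-channels", scaling = rep(0, 20))
  cfg <- coupling_config("healthy", n_beats = 3L, g_gap_ns = 1,
                         record_from_beat = 1L,
                         init = list(custom = custom_initial_state(spec, -87,
                                                                   relax_ms = 0)))
  tr <- simulate(cfg, spec)
  # independent two-compartment oracle: integrate dVc/dt = -G(Vc-Vcm)/C on the
  # recorded Vcm (linear interpolation between 1 ms samples), fine Euler
  g <- 1; cpf <- 40
  vc <- tr$vm_custom[1]
  dt <- 0.01
  pred <- numeric(length(tr$time)); pred[1] <- vc
  for (i in seq_len(length(tr$time) - 1)) {
    for (k in 0:99) {
      f <- k / 100
      vcm <- tr$vm[i] * (1 - f) + tr$vm[i + 1] * f
      vc <- vc + dt * (-g * (vc - vcm) / cpf)
    }
    pred[i + 1] <- vc
  }
  expect_lt(max(abs(pred - tr$vm_custom)), 0.5)   # mV
  # low-pass character on the final beat: smaller swing, lagged peak
  w <- (length(tr$time) - 1000):length(tr$time)
  expect_lt(diff(range(tr$vm_custom[w])), diff(range(tr$vm[w])))
  expect_gt(which.max(tr$vm_custom[w]), which.max(tr$vm[w]))
})

test_that("gap-current bookkeeping is antisymmetric and monotone in G_gap", {
  spec <- custom_cell_spec("ik1-only", scaling = c(cm_k1 = 2))
  peak_gap <- sapply(c(0.5, 1, 2, 4), function(g) {
    tr <- simulate(coupling_config("hf_fibrosis", n_beats = 5L, g_gap_ns = g,
                                   n_custom = 3L), spec)
    # recorded per-junction current equals its definition at every sample;
    # the cardiomyocyte sees n_custom junctions, each custom cell sees one
    expect_equal(tr$igap_custom_pa, g * (tr$vm - tr$vm_custom), tolerance = 1e-12)
    max(abs(tr$igap_custom_pa))
  })
  expect_true(all(diff(peak_gap) > 0))
})

test_that("simulation is deterministic: identical config gives identical traces", {
  spec <- custom_cell_spec("ical-ik1", scaling = c(cm_cal = 2, cm_k1 = 2))
  cfg <- coupling_config("hf_fibrosis", n_beats = 3L, g_gap_ns = 3)
  t1 <- simulate(cfg, spec)
  t2 <- simulate(cfg, spec)
  expect_identical(t1$vm, t2$vm)
  expect_identical(t1$cai, t2$cai)
  expect_identical(t1$vm_custom, t2$vm_custom)
})

test_that("extract_final_beat does exact index arithmetic", {
  # 500-beat trace at 1 Hz recorded from beat 500 -> window starts at 499000
  fake <- structure(list(
    time = 499000:500000,
    vm = sin(2 * pi * (499000:500000) / 700),
    cai = cos(2 * pi * (499000:500000) / 900) * 1e-4 + 2e-4,
    config = coupling_config("healthy", n_beats = 500L)),
    class = "cellforge_trace")
  bw <- extract_final_beat(fake)
  expect_equal(bw$time_ms, 0:500, ignore_attr = TRUE)
  expect_equal(bw$ap, sin(2 * pi * (499000:499500) / 700))
  expect_equal(bw$cat, cos(2 * pi * (499000:499500) / 900) * 1e-4 + 2e-4)
  # too-short trace errors
  fake$config$n_beats <- 501L
  expect_error(extract_final_beat(fake), "500 ms window")
})

test_that("healthy uncoupled run yields a real AP and CaT", {
  tr <- simulate(coupling_config("healthy", n_beats = 20L))
  bw <- extract_final_beat(tr)
  expect_gt(max(bw$ap) - bw$ap[1], 90)         # AP amplitude > 90 mV
  expect_gt(max(bw$cat), bw$cat[1])            # CaT peak above diastole
  m <- ap_metrics(bw)
  expect_false(m$no_ap)
  expect_gt(m$apd90, 150); expect_lt(m$apd90, 400)
})

test_that("final beat is insensitive to the custom cell's initial voltage", {
  spec <- custom_cell_spec("ik1-only", scaling = c(cm_k1 = 3))
  mk <- function(v0) {
    cfg <- coupling_config("hf_fibrosis", n_beats = 100L, g_gap_ns = 7,
                           n_custom = 5L,
                           init = list(custom = custom_initial_state(spec, v0,
                                                                     relax_ms = 0)))
    extract_final_beat(simulate(cfg, spec))
  }
  b1 <- mk(-85); b2 <- mk(-20)
  expect_lt(max(abs(b1$ap - b2$ap)), 0.1)      # mV after 100-beat washout
  expect_lt(max(abs(b1$cat - b2$cat)) / max(b1$cat), 1e-3)
})

test_that("trace export produces well-formed tables", {
  tr <- simulate(coupling_config("hf_fibrosis", n_beats = 2L,
                                 record_currents = TRUE))
  df <- as.data.frame(tr)
  expect_true(all(c("time_ms", "vm_mv", "cai_mm", "vm_fib_mv", "i_k1", "i_cal")
                  %in% names(df)))
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), length(tr$time))
  bw <- extract_final_beat(tr)
  p2 <- tempfile(fileext = ".csv")
  write_waveforms_csv(bw, p2)
  expect_equal(read.csv(p2)$vm_mv, bw$ap)
})
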