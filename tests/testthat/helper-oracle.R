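# Independent pure-R transcription of the model equations, used as the oracle
# for the compiled implementation. Written separately from the C++ source (same
# published equations, different organization); integrates with Rush-Larsen /
# Euler at a fine fixed step. Scalar, slow, test-only.

O_RTF <- 8314 * 310 / 96485
O_F <- 96485
O_NAO <- 140; O_CAO <- 1.8; O_KO <- 5.4

o_exp <- exp  # alias to keep lines compact

# all voltage-dependent gate steady states / time constants at one voltage.
# Returns list(inf=named, tau=named); names match cellforge cm state names.
oracle_cm_gates <- function(v) {
  inf <- c(); tau <- c()
  put <- function(n, i, t) { inf[[n]] <<- i; tau[[n]] <<- t }

  # fast Na (ten Tusscher-Panfilov)
  mi <- (1 / (1 + o_exp((-56.86 - v) / 9.03)))^2
  tm <- (1 / (1 + o_exp((-60 - v) / 5))) *
        (0.1 / (1 + o_exp((v + 35) / 5)) + 0.1 / (1 + o_exp((v - 50) / 200)))
  put("m", mi, tm)
  hi <- (1 / (1 + o_exp((v + 71.55) / 7.43)))^2
  if (v >= -40) {
    ah <- 0; bh <- 0.77 / (0.13 * (1 + o_exp(-(v + 10.66) / 11.1)))
    aj <- 0; bj <- 0.6 * o_exp(0.057 * v) / (1 + o_exp(-0.1 * (v + 32)))
  } else {
    ah <- 0.057 * o_exp(-(v + 80) / 6.8)
    bh <- 2.7 * o_exp(0.079 * v) + 3.1e5 * o_exp(0.3485 * v)
    aj <- (-2.5428e4 * o_exp(0.2444 * v) - 6.948e-6 * o_exp(-0.04391 * v)) *
          (v + 37.78) / (1 + o_exp(0.311 * (v + 79.23)))
    bj <- 0.02424 * o_exp(-0.01052 * v) / (1 + o_exp(-0.1378 * (v + 40.14)))
  }
  put("h", hi, 1 / (ah + bh))
  put("j", hi, 1 / (aj + bj))

  # late Na
  put("ml", 1 / (1 + o_exp(-(v + 42.85) / 5.264)),
      1 / (6.765 * o_exp((v + 11.64) / 34.77) + 8.552 * o_exp(-(v + 77.42) / 5.955)))
  put("hl", 1 / (1 + o_exp((v + 87.61) / 7.488)), 200)
  put("hlp", 1 / (1 + o_exp((v + 93.81) / 7.488)), 600)

  # transient outward
  ta <- 1.0515 / (1 / (1.2089 * (1 + o_exp(-(v - 18.4099) / 29.3814))) +
                  3.5 / (1 + o_exp((v + 100) / 29.3814)))
  put("a", 1 / (1 + o_exp(-(v - 14.34) / 14.82)), ta)
  ii <- 1 / (1 + o_exp((v + 43.94) / 5.711))
  tif <- 4.562 + 1 / (0.3933 * o_exp(-(v + 100) / 100) + 0.08004 * o_exp((v + 50) / 16.59))
  tis <- 23.62 + 1 / (0.001416 * o_exp(-(v + 96.52) / 59.05) +
                      1.78e-8 * o_exp((v + 114.1) / 8.079))
  put("i_f", ii, tif); put("i_s", ii, tis)
  put("ap", 1 / (1 + o_exp(-(v - 24.34) / 14.82)), ta)
  dev <- 1.354 + 1e-4 / (o_exp((v - 167.4) / 15.89) + o_exp(-(v - 12.23) / 0.2154))
  rec <- 1 - 0.5 / (1 + o_exp((v + 70) / 20))
  put("i_fp", ii, dev * rec * tif); put("i_sp", ii, dev * rec * tis)

  # L-type Ca
  put("d", 1 / (1 + o_exp(-(v + 3.94) / 4.23)),
      0.6 + 1 / (o_exp(-0.05 * (v + 6)) + o_exp(0.09 * (v + 14))))
  fi <- 1 / (1 + o_exp((v + 19.58) / 3.696))
  tff <- 7 + 1 / (0.0045 * o_exp(-(v + 20) / 10) + 0.0045 * o_exp((v + 20) / 10))
  tfs <- 1000 + 1 / (3.5e-5 * o_exp(-(v + 5) / 4) + 3.5e-5 * o_exp((v + 5) / 6))
  tfcaf <- 7 + 1 / (0.04 * o_exp(-(v - 4) / 7) + 0.04 * o_exp((v - 4) / 7))
  tfcas <- 100 + 1 / (0.00012 * o_exp(-v / 3) + 0.00012 * o_exp(v / 7))
  put("ff", fi, tff); put("fs", fi, tfs)
  put("fcaf", fi, tfcaf); put("fcas", fi, tfcas)
  put("jca", fi, 75)
  put("ffp", fi, 2.5 * tff); put("fcafp", fi, 2.5 * tfcaf)

  # IKr, IKs, IK1 gates
  xri <- 1 / (1 + o_exp(-(v + 8.337) / 6.789))
  put("xrf", xri, 12.98 + 1 / (0.3652 * o_exp((v - 31.66) / 3.869) +
                               4.123e-5 * o_exp(-(v - 47.78) / 20.38)))
  put("xrs", xri, 1.865 + 1 / (0.06629 * o_exp((v - 34.7) / 7.355) +
                               1.128e-5 * o_exp(-(v - 29.74) / 25.94)))
  xsi <- 1 / (1 + o_exp(-(v + 11.6) / 8.932))
  put("xs1", xsi, 817.3 + 1 / (2.326e-4 * o_exp((v + 48.28) / 17.8) +
                               0.001292 * o_exp(-(v + 210) / 230)))
  put("xs2", xsi, 1 / (0.01 * o_exp((v - 50) / 20) + 0.0193 * o_exp(-(v + 66.54) / 31)))
  put("xk1", 1 / (1 + o_exp(-(v + 2.5538 * O_KO + 144.59) / (1.5692 * O_KO + 3.8115))),
      122.2 / (o_exp(-(v + 127.2) / 20.36) + o_exp((v + 236.8) / 69.33)))

  list(inf = inf, tau = tau)
}

# currents and non-gate derivatives; s and sc are named vectors
oracle_cm_algebra <- function(s, sc, i_ext) {
  v <- s[["v"]]; nai <- s[["nai"]]; nass <- s[["nass"]]
  ki <- s[["ki"]]; kss <- s[["kss"]]
  cai <- s[["cai"]]; cass <- s[["cass"]]
  cansr <- s[["cansr"]]; cajsr <- s[["cajsr"]]

  ena <- O_RTF * log(O_NAO / nai)
  ek <- O_RTF * log(O_KO / ki)
  eks <- O_RTF * log((O_KO + 0.01833 * O_NAO) / (ki + 0.01833 * nai))
  vfrt <- v / O_RTF

  camkb <- sc[["camk"]] * 0.05 * (1 - s[["camkt"]]) / (1 + 0.0015 / cass)
  camka <- camkb + s[["camkt"]]
  fp <- 1 / (1 + 0.15 / camka)

  ina <- sc[["g_na"]] * 14.838 * s[["m"]]^3 * s[["h"]] * s[["j"]] * (v - ena)
  inal <- sc[["g_nal"]] * 0.0075 * s[["ml"]] *
          ((1 - fp) * s[["hl"]] + fp * s[["hlp"]]) * (v - ena)

  aif <- 1 / (1 + o_exp((v - 213.6) / 151.2))
  ito <- sc[["g_to"]] * 0.02 * (v - ek) *
    ((1 - fp) * s[["a"]] * (aif * s[["i_f"]] + (1 - aif) * s[["i_s"]]) +
     fp * s[["ap"]] * (aif * s[["i_fp"]] + (1 - aif) * s[["i_sp"]]))

  # GHK driving terms (x/expm1 form)
  sr <- function(x) if (abs(x) < 1e-8) 1 - x / 2 else x / expm1(x)
  a1 <- O_F * sr(vfrt); a2 <- 2 * O_F * sr(2 * vfrt)
  e1v <- o_exp(vfrt); e2v <- o_exp(2 * vfrt)
  phical <- a2 * (cass * e2v - 0.341 * O_CAO)
  phicana <- a1 * 0.75 * (nass * e1v - O_NAO)
  phicak <- a1 * 0.75 * (kss * e1v - O_KO)
  afcaf <- 0.3 + 0.6 / (1 + o_exp((v - 10) / 10))
  f_ <- 0.6 * s[["ff"]] + 0.4 * s[["fs"]]
  fca <- afcaf * s[["fcaf"]] + (1 - afcaf) * s[["fcas"]]
  fpp <- 0.6 * s[["ffp"]] + 0.4 * s[["fs"]]
  fcap <- afcaf * s[["fcafp"]] + (1 - afcaf) * s[["fcas"]]
  nca <- s[["nca"]]
  o_np <- s[["d"]] * (f_ * (1 - nca) + s[["jca"]] * fca * nca)
  o_p <- s[["d"]] * (fpp * (1 - nca) + s[["jca"]] * fcap * nca)
  pca <- sc[["p_ca"]] * 1e-4
  ical <- (1 - fp) * pca * phical * o_np + fp * 1.1 * pca * phical * o_p
  icana <- (1 - fp) * 0.00125 * pca * phicana * o_np +
           fp * 0.00125 * 1.1 * pca * phicana * o_p
  icak <- (1 - fp) * 3.574e-4 * pca * phicak * o_np +
          fp * 3.574e-4 * 1.1 * pca * phicak * o_p

  axrf <- 1 / (1 + o_exp((v + 54.81) / 38.21))
  rkr <- 1 / ((1 + o_exp((v + 55) / 75)) * (1 + o_exp((v - 10) / 30)))
  ikr <- sc[["g_kr"]] * 0.046 * sqrt(O_KO / 5.4) *
         (axrf * s[["xrf"]] + (1 - axrf) * s[["xrs"]]) * rkr * (v - ek)

  iks <- sc[["g_ks"]] * 0.0034 * (1 + 0.6 / (1 + (3.8e-5 / cai)^1.4)) *
         s[["xs1"]] * s[["xs2"]] * (v - eks)

  rk1 <- 1 / (1 + o_exp((v + 105.8 - 2.6 * O_KO) / 9.493))
  ik1 <- sc[["g_k1"]] * 0.1908 * sqrt(O_KO) * s[["xk1"]] * rk1 * (v - ek)

  # NCX
  ncx <- function(na, ca) {
    kna1 <- 15; kna2 <- 5; kna3 <- 88.12
    hca <- o_exp(0.167 * vfrt); hna <- o_exp(0.5224 * vfrt)
    h1 <- 1 + na / kna3 * (1 + hna); h2 <- na * hna / (kna3 * h1); h3 <- 1 / h1
    h4 <- 1 + na / kna1 * (1 + na / kna2); h5 <- na^2 / (h4 * kna1 * kna2); h6 <- 1 / h4
    h7 <- 1 + O_NAO / kna3 * (1 + 1 / hna); h8 <- O_NAO / (kna3 * hna * h7); h9 <- 1 / h7
    h10 <- 12.5 + 1 + O_NAO / kna1 * (1 + O_NAO / kna2)
    h11 <- O_NAO^2 / (h10 * kna1 * kna2); h12 <- 1 / h10
    k1 <- h12 * O_CAO * 1.5e6; k2 <- 5e3
    k3p <- h9 * 6e4; k3pp <- h8 * 5e3; k3 <- k3p + k3pp
    k4p <- h3 * 6e4 / hca; k4pp <- h2 * 5e3; k4 <- k4p + k4pp
    k5 <- 5e3; k6 <- h6 * ca * 1.5e6; k7 <- h5 * h2 * 6e4; k8 <- h8 * h11 * 6e4
    x1 <- k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3)
    x2 <- k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8)
    x3 <- k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3)
    x4 <- k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8)
    e <- c(x1, x2, x3, x4) / (x1 + x2 + x3 + x4)
    allo <- 1 / (1 + (150e-6 / ca)^2)
    jna <- 3 * (e[4] * k7 - e[1] * k8) + e[3] * k4pp - e[2] * k3pp
    jca <- e[2] * k2 - e[1] * k1
    allo * (jna + 2 * jca)
  }
  inaca_i <- 0.8 * sc[["g_ncx"]] * 8e-4 * ncx(nai, cai)
  inaca_ss <- 0.2 * sc[["g_ncx"]] * 8e-4 * ncx(nass, cass)

  # NaK pump
  knai <- 9.073 * o_exp(-0.155 * vfrt / 3)
  knao <- 27.78 * o_exp(1.155 * vfrt / 3)
  pp <- 4.2 / (1 + 1e-7 / 1.698e-7 + nai / 224 + ki / 292)
  dA <- (1 + nai / knai)^3 + (1 + ki / 0.5)^2 - 1
  dB <- (1 + O_NAO / knao)^3 + (1 + O_KO / 0.3582)^2 - 1
  a1n <- 949.5 * (nai / knai)^3 / dA; b1n <- 182.4 * 0.05
  a2n <- 687.2; b2n <- 39.4 * (O_NAO / knao)^3 / dB
  a3n <- 1899 * (O_KO / 0.3582)^2 / dB
  b3n <- 79300 * pp * 1e-7 / (1 + 9.8 / 1.698e-7)
  a4n <- 639 * (9.8 / 1.698e-7) / (1 + 9.8 / 1.698e-7)
  b4n <- 40 * (ki / 0.5)^2 / dA
  x1 <- a4n * a1n * a2n + b2n * b4n * b3n + a2n * b4n * b3n + b3n * a1n * a2n
  x2 <- b2n * b1n * b4n + a1n * a2n * a3n + a3n * b1n * b4n + a2n * a3n * b4n
  x3 <- a2n * a3n * a4n + b3n * b2n * b1n + b2n * b1n * a4n + a3n * a4n * b1n
  x4 <- b4n * b3n * b2n + a3n * a4n * a1n + b2n * a4n * a1n + b3n * b1n * a1n
  e <- c(x1, x2, x3, x4) / (x1 + x2 + x3 + x4)
  inak <- sc[["p_nak"]] * 30 *
          (3 * (e[1] * a3n - e[2] * b3n) + 2 * (e[4] * b1n - e[3] * a1n))

  ikb <- sc[["g_kb"]] * 0.003 * (v - ek) / (1 + o_exp(-(v - 14.48) / 18.34))
  inab <- sc[["g_nab"]] * 3.75e-10 * a1 * (nai * e1v - O_NAO)
  icab <- sc[["g_cab"]] * 2.5e-8 * a2 * (cai * e2v - 0.341 * O_CAO)
  ipca <- sc[["g_pca"]] * 5e-4 * cai / (5e-4 + cai)

  jrel <- (1 - fp) * s[["jrelnp"]] + fp * s[["jrelp"]]
  jupnp <- 0.004375 * cai / (cai + 0.00092)
  jupp <- 2.75 * 0.004375 * cai / (cai + 0.00075)
  jleak <- sc[["j_leak"]] * 0.0039375 * cansr / 15
  jup <- sc[["j_up"]] * ((1 - fp) * jupnp + fp * jupp) - jleak
  jtr <- (cansr - cajsr) / 100
  jdna <- (nass - nai) / 2; jdk <- (kss - ki) / 2; jdca <- (cass - cai) / 0.2

  # geometry
  L <- 0.01; rad <- 0.0011
  vcell <- 1000 * 3.14 * rad^2 * L
  ageo <- 2 * 3.14 * rad^2 + 2 * 3.14 * rad * L
  acap <- 2 * ageo
  vmyo <- 0.68 * vcell; vnsr <- 0.0552 * vcell
  vjsr <- 0.0048 * vcell; vss <- 0.02 * vcell

  itot <- ina + inal + ito + ical + icana + icak + ikr + iks + ik1 +
          inaca_i + inaca_ss + inak + inab + icab + ipca + ikb + i_ext

  dnon <- c(
    v = -itot,
    nai = -(ina + inal + 3 * inaca_i + 3 * inak + inab) * acap / (O_F * vmyo) +
      jdna * vss / vmyo,
    nass = -(icana + 3 * inaca_ss) * acap / (O_F * vss) - jdna,
    ki = -(ito + ikr + iks + ik1 + ikb + i_ext - 2 * inak) * acap / (O_F * vmyo) +
      jdk * vss / vmyo,
    kss = -icak * acap / (O_F * vss) - jdk,
    cai = (1 / (1 + 0.05 * 0.00238 / (0.00238 + cai)^2 +
                0.07 * 5e-4 / (5e-4 + cai)^2)) *
      (-(ipca + icab - 2 * inaca_i) * acap / (2 * O_F * vmyo) -
         jup * vnsr / vmyo + jdca * vss / vmyo),
    cass = (1 / (1 + 0.047 * 0.00087 / (0.00087 + cass)^2 +
                 1.124 * 0.0087 / (0.0087 + cass)^2)) *
      (-(ical - 2 * inaca_ss) * acap / (2 * O_F * vss) + jrel * vjsr / vss - jdca),
    cansr = jup - jtr * vjsr / vnsr,
    cajsr = (1 / (1 + 8 / (0.8 + cajsr)^2)) * (jtr - jrel),
    camkt = 0.05 * camkb * (camkb + s[["camkt"]]) - 0.00068 * s[["camkt"]]
  )

  # SR-release quasi-gate and nca relaxation targets
  rel_den <- 1 + (1.5 / cajsr)^8
  tau_np <- max(4.75 / (1 + 0.0123 / cajsr), 0.001)
  tau_p <- max(1.25 * 4.75 / (1 + 0.0123 / cajsr), 0.001)
  km2n <- s[["jca"]]
  anca <- 1 / (1000 / km2n + (1 + 0.002 / cass)^4)
  aux <- list(
    jrelnp_inf = sc[["j_rel"]] * 0.5 * 4.75 * (-ical) / rel_den, jrelnp_tau = tau_np,
    jrelp_inf = sc[["j_rel"]] * 0.5 * 1.25 * 4.75 * (-ical) / rel_den, jrelp_tau = tau_p,
    nca_inf = anca * 1000 / km2n, nca_tau = 1 / km2n)

  cur <- c(i_na = ina, i_nal = inal, i_to = ito, i_cal = ical, i_cana = icana,
           i_cak = icak, i_kr = ikr, i_ks = iks, i_k1 = ik1,
           i_ncx = inaca_i + inaca_ss, i_nak = inak, i_nab = inab,
           i_cab = icab, i_pca = ipca, i_kb = ikb,
           j_rel = jrel, j_up = jup, j_diff = jdca)
  list(currents = cur, dnon = dnon, aux = aux)
}

oracle_cm_rhs <- function(s, sc, i_ext = 0) {
  alg <- oracle_cm_algebra(s, sc, i_ext)
  g <- oracle_cm_gates(s[["v"]])
  d <- s * 0
  d[names(alg$dnon)] <- alg$dnon
  for (n in names(g$inf)) {
    tau <- g$tau[[n]]
    if (n %in% c("hl", "hlp")) tau <- tau * sc[["tau_hl"]]
    d[[n]] <- (g$inf[[n]] - s[[n]]) / tau
  }
  d[["jrelnp"]] <- (alg$aux$jrelnp_inf - s[["jrelnp"]]) / alg$aux$jrelnp_tau
  d[["jrelp"]] <- (alg$aux$jrelp_inf - s[["jrelp"]]) / alg$aux$jrelp_tau
  d[["nca"]] <- (alg$aux$nca_inf - s[["nca"]]) / alg$aux$nca_tau
  list(deriv = d, currents = alg$currents)
}

# pace one cycle from state0; returns Vm sampled at integer ms (0..cl).
# dt_fine is used for the first t_fine ms (stimulus + upstroke).
oracle_cm_beat <- function(state0, sc, cl = 1000, dt = 0.01,
                           dt_fine = 0.001, t_fine = 5,
                           stim_amp = -80, stim_dur = 0.5) {
  s <- state0
  gate_names <- names(oracle_cm_gates(-80)$inf)
  vm <- numeric(cl + 1)
  vm[1] <- s[["v"]]
  for (ms in seq_len(cl)) {
    t0 <- ms - 1
    h <- if (t0 < t_fine) dt_fine else dt
    nstep_ms <- round(1 / h)
    for (k in seq_len(nstep_ms)) {
      t <- t0 + (k - 1) * h
      i_st <- if (t < stim_dur - 1e-12) stim_amp else 0
      alg <- oracle_cm_algebra(s, sc, i_st)
      g <- oracle_cm_gates(s[["v"]])
      for (n in gate_names) {
        tau <- g$tau[[n]]
        if (n %in% c("hl", "hlp")) tau <- tau * sc[["tau_hl"]]
        s[[n]] <- g$inf[[n]] + (s[[n]] - g$inf[[n]]) * o_exp(-h / tau)
      }
      s[["jrelnp"]] <- alg$aux$jrelnp_inf +
        (s[["jrelnp"]] - alg$aux$jrelnp_inf) * o_exp(-h / alg$aux$jrelnp_tau)
      s[["jrelp"]] <- alg$aux$jrelp_inf +
        (s[["jrelp"]] - alg$aux$jrelp_inf) * o_exp(-h / alg$aux$jrelp_tau)
      s[["nca"]] <- alg$aux$nca_inf +
        (s[["nca"]] - alg$aux$nca_inf) * o_exp(-h / alg$aux$nca_tau)
      s[names(alg$dnon)] <- s[names(alg$dnon)] + h * alg$dnon
    }
    vm[ms + 1] <- s[["v"]]
  }
  vm
}

# fibroblast steady-state (voltage-clamp) currents at voltage v, pA/pF
oracle_fib_iv <- function(v) {
  ekf <- O_RTF * log(O_KO / 129.435)
  enaf <- O_RTF * log(O_NAO / 8.5547)
  rinf <- 1 / (1 + o_exp(-(v + 20) / 11))
  sinf <- 1 / (1 + o_exp((v + 23) / 7))
  dv <- v - ekf
  ak1 <- 0.1 / (1 + o_exp(0.06 * (dv - 200)))
  bk1 <- (3 * o_exp(2e-4 * (dv + 100)) + o_exp(0.1 * (dv - 10))) /
         (1 + o_exp(-0.5 * dv))
  nak_na <- 8.5547^1.5 / (8.5547^1.5 + 11^1.5)
  c(i_kv = 0.25 * rinf * sinf * dv,
    i_kir = 0.4822 * ak1 / (ak1 + bk1) * dv,
    i_nak = 2.002 * (O_KO / (O_KO + 1)) * nak_na * (v + 150) / (v + 200),
    i_bna = 0.0095 * (v - enaf))
}

# independent custom-cell per-channel currents (pA/pF) at a given state
oracle_cust_currents <- function(st, dens, conc) {
  v <- st[["v"]]
  ena <- O_RTF * log(O_NAO / conc[["nai"]])
  ek <- O_RTF * log(O_KO / conc[["ki"]])
  eca <- O_RTF / 2 * log(O_CAO / conc[["cai"]])
  eks <- O_RTF * log((O_KO + 0.01833 * O_NAO) / (conc[["ki"]] + 0.01833 * conc[["nai"]]))
  ekf <- O_RTF * log(O_KO / 129.435)
  caact <- conc[["cai"]]^2 / (conc[["cai"]]^2 + 1e-8)
  sr <- function(x) if (abs(x) < 1e-8) 1 - x / 2 else x / expm1(x)
  vfrt <- v / O_RTF
  a1 <- O_F * sr(vfrt); a2 <- 2 * O_F * sr(2 * vfrt)
  dvf <- v - ekf
  ak1 <- 0.1 / (1 + o_exp(0.06 * (dvf - 200)))
  bk1 <- (3 * o_exp(2e-4 * (dvf + 100)) + o_exp(0.1 * (dvf - 10))) /
         (1 + o_exp(-0.5 * dvf))
  aif <- 1 / (1 + o_exp((v - 213.6) / 151.2))
  afcaf <- 0.3 + 0.6 / (1 + o_exp((v - 10) / 10))
  axrf <- 1 / (1 + o_exp((v + 54.81) / 38.21))
  rkr <- 1 / ((1 + o_exp((v + 55) / 75)) * (1 + o_exp((v - 10) / 30)))
  rk1 <- 1 / (1 + o_exp((v + 105.8 - 2.6 * O_KO) / 9.493))
  nai15 <- conc[["nai"]]^1.5
  phical <- a2 * (conc[["cai"]] * o_exp(2 * vfrt) - 0.341 * O_CAO)
  phicana <- a1 * 0.75 * (conc[["nai"]] * o_exp(vfrt) - O_NAO)
  phicak <- a1 * 0.75 * (conc[["ki"]] * o_exp(vfrt) - O_KO)
  fblk <- 0.6 * st[["ff"]] + 0.4 * st[["fs"]]
  fca <- afcaf * st[["fcaf"]] + (1 - afcaf) * st[["fcas"]]
  ocal <- st[["d"]] * (fblk * (1 - st[["nca"]]) + st[["jca"]] * fca * st[["nca"]])
  c(
    cic_na = dens[["cic_na"]] * st[["cic_m"]]^3 * st[["cic_h"]] * (v - ena),
    cic_kir = dens[["cic_kir"]] * sqrt(O_KO / 5.4) * (v - ek) /
      (1 + o_exp((v - ek - 10) / 18)),
    cic_kca = dens[["cic_kca"]] * caact * (v - ek) / (1 + o_exp(-(v - 10) / 14)),
    cic_to = dens[["cic_to"]] * st[["cic_r"]] * st[["cic_s"]] * (v - ek),
    msc_to = dens[["msc_to"]] * st[["msc_r"]] * st[["msc_s"]] * (v - ek),
    msc_to_ss = dens[["msc_to_ss"]] * (v - ek) / (1 + o_exp(-(v - 4) / 14)),
    msc_na = dens[["msc_na"]] * st[["msc_m"]]^3 * st[["msc_h"]] * (v - ena),
    msc_cal = dens[["msc_cal"]] * st[["msc_d"]] * st[["msc_f"]] * (v - eca),
    msc_kca = dens[["msc_kca"]] * caact * (v - ek) / (1 + o_exp(-(v - 5) / 16)),
    msc_dr = dens[["msc_dr"]] * st[["msc_n"]] * (v - ek),
    cf_kv = dens[["cf_kv"]] * st[["cf_r"]] * st[["cf_s"]] * dvf,
    cf_kir = dens[["cf_kir"]] * ak1 / (ak1 + bk1) * dvf,
    cf_nak = dens[["cf_nak"]] * (O_KO / (O_KO + 1)) * nai15 / (nai15 + 11^1.5) *
      (v + 150) / (v + 200),
    cm_na = dens[["cm_na"]] * st[["m"]]^3 * st[["h"]] * st[["j"]] * (v - ena),
    cm_nal = dens[["cm_nal"]] * st[["ml"]] * st[["hl"]] * (v - ena),
    cm_to = dens[["cm_to"]] * st[["a"]] *
      (aif * st[["i_f"]] + (1 - aif) * st[["i_s"]]) * (v - ek),
    cm_cal = dens[["cm_cal"]] * (phical + 0.00125 * phicana + 3.574e-4 * phicak) * ocal,
    cm_kr = dens[["cm_kr"]] * sqrt(O_KO / 5.4) *
      (axrf * st[["xrf"]] + (1 - axrf) * st[["xrs"]]) * rkr * (v - ek),
    cm_ks = dens[["cm_ks"]] * (1 + 0.6 / (1 + (3.8e-5 / conc[["cai"]])^1.4)) *
      st[["xs1"]] * st[["xs2"]] * (v - eks),
    cm_k1 = dens[["cm_k1"]] * sqrt(O_KO) * st[["xk1"]] * rk1 * (v - ek),
    passive_leak = dens[["passive_leak"]] * (v + 20)
  )
}
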