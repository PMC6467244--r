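# Independent term-by-term evaluation of the seven rate equations, written as
# literal sums (one line per arrow of the reaction scheme) so it shares no
# code with the vectorized implementation.
rhs_oracle <- function(st, p) {
  P <- st[["prot_u"]]; YP <- st[["yp"]]; PF <- st[["prot_f"]]
  C <- st[["cln3_u"]]; YC <- st[["yc"]]; CF <- st[["cln3_f"]]
  Y <- st[["ydj1_a"]]; V <- p$vol
  d <- numeric(7)
  d[1] <- p$s_prot * V - p$kb * P * Y / V - p$kd_protU * P + p$kd_ydj1 * YP
  d[2] <- p$kb * P * Y / V - p$kr * YP - p$kd_ydj1 * YP - p$kd_protU * YP
  d[3] <- p$kr * YP - p$beta * p$kd_protU * PF
  d[4] <- p$s_cln3 * V - p$kb * C * Y / V - p$kd_cln3U * C + p$kd_ydj1 * YC
  d[5] <- p$kb * C * Y / V - p$kr * YC - p$kd_ydj1 * YC - p$kd_cln3U * YC
  d[6] <- p$kr * YC - p$kd_cln3F * CF
  d[7] <- p$s_ydj1 * V - p$kb * P * Y / V - p$kb * C * Y / V + p$kr * YP +
    p$kr * YC - p$kd_ydj1 * Y + p$kd_cln3U * YC + p$kd_protU * YP
  names(d) <- c("prot_u", "yp", "prot_f", "cln3_u", "yc", "cln3_f", "ydj1_a")
  d
}

test_that("rhs reproduces the rate equations term by term", {
  # empty system: no synthesis, nothing present
  p0 <- chap_params(kb = 1, kr = 1, s_prot = 0, s_cln3 = 0, s_ydj1 = 0,
                    kd_protU = 0.1)
  expect_equal(unname(model_rhs(chap_state(), p0)), rep(0, 7))
  # single surviving term: free Ydj1 decaying alone
  st <- chap_state(ydj1_a = 100)
  d <- model_rhs(st, p0 <- chap_params(kb = 1, kr = 1, s_prot = 0,
                                       s_cln3 = 0, s_ydj1 = 0,
                                       kd_protU = 0.1, kd_ydj1 = 5.77e-3))
  expect_equal(d[["ydj1_a"]], -0.577)
  expect_equal(unname(d[c("prot_u", "yp", "prot_f", "cln3_u", "yc", "cln3_f")]),
               rep(0, 6))
  # full system against the independent oracle
  p <- param_set_3114(s_prot = 0.1, vol = 50)
  st <- chap_state(prot_u = 40, yp = 3, prot_f = 1200, cln3_u = 50, yc = 2,
                   cln3_f = 20, ydj1_a = 1.7)
  expect_equal(model_rhs(st, p), rhs_oracle(st, p), tolerance = 1e-12)
  # invalid input
  bad <- chap_state(); bad[1] <- NaN
  expect_error(model_rhs(bad, p), "finite")
})

test_that("analytic state Jacobian matches finite differences", {
  p <- param_set_3114(s_prot = 0.3, vol = 40)
  st <- chap_state(prot_u = 30, yp = 2, prot_f = 900, cln3_u = 45, yc = 3,
                   cln3_f = 22, ydj1_a = 2.1)
  J <- chapcomp:::model_jacobian(st, p)
  h <- 1e-6
  for (j in seq_len(7)) {
    stp <- st; stp[j] <- stp[j] + h
    stm <- st; stm[j] <- stm[j] - h
    fd <- (model_rhs(stp, p) - model_rhs(stm, p)) / (2 * h)
    expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-6)
  }
})

test_that("integration holds fixed points and satisfies the Ydj1 balance limit", {
  p <- param_set_3114()
  ss <- steady_state(p)
  tr <- integrate_model(p, ss, seq(0, 1e5, length.out = 11))
  final <- as.numeric(tr[nrow(tr), chapcomp:::state_names()])
  expect_equal(final, as.numeric(ss), tolerance = 1e-6)
  # from empty cell, total Ydj1 approaches the synthesis/degradation balance
  tr0 <- integrate_model(p, chap_state(), c(0, 10^seq(0, 7, by = 0.5)))
  tot <- ydj1_total(tr0[nrow(tr0), ])
  expect_equal(tot, p$s_ydj1 * p$vol / p$kd_ydj1, tolerance = 1e-6)
  expect_error(integrate_model(p, chap_state(), c(0, 0, 1)), "increasing")
  # tightening solver tolerance moves the endpoint by less than 10x tolerance
  t2 <- integrate_model(p, chap_state(), c(0, 1e4), rtol = 1e-6, atol = 1e-8)
  t3 <- integrate_model(p, chap_state(), c(0, 1e4), rtol = 1e-12, atol = 1e-12)
  rel <- abs(as.numeric(t2[2, 2:8]) - as.numeric(t3[2, 2:8])) /
    pmax(abs(as.numeric(t3[2, 2:8])), 1)
  expect_lt(max(rel), 1e-5)
})

test_that("steady state: exact reduction agrees with the integration route", {
  p <- param_set_3114(s_prot = 0.1, vol = 50)
  s_exact <- steady_state(p)
  s_int <- steady_state(p, method = "integrate")
  expect_equal(as.numeric(s_exact), as.numeric(s_int), tolerance = 1e-6)
  expect_equal(ydj1_total(s_exact), 7.96, tolerance = 1e-3)
  expect_lt(sqrt(sum(model_rhs(s_exact, p)^2)),
            1e-9 * max(1, sqrt(sum(s_exact^2))))
  # no Cln3 source leaves all Cln3 pools empty
  s0 <- steady_state(chapcomp:::params_with(p, s_cln3 = 0))
  expect_equal(unname(s0[c("cln3_u", "yc", "cln3_f")]), rep(0, 3))
})

test_that("steady states satisfy the analytic mass balances and non-negativity", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_valid_params()
    s <- steady_state(p)
    expect_true(all(s >= 0))
    # summing the Ydj1-containing balance equations at steady state
    expect_equal(ydj1_total(s), p$s_ydj1 * p$vol / p$kd_ydj1,
                 tolerance = 1e-6)
    # summing the Cln3-containing balance equations at steady state
    expect_equal(p$kd_cln3U * (s[["cln3_u"]] + s[["yc"]]) +
                   p$kd_cln3F * s[["cln3_f"]],
                 p$s_cln3 * p$vol, tolerance = 1e-6)
  }
})

test_that("steady state scales linearly with volume at fixed densities", {
  p <- param_set_3114(s_prot = 0.2, vol = 20)
  s1 <- steady_state(p)
  s3 <- steady_state(chapcomp:::params_with(p, vol = 60))
  expect_equal(as.numeric(s3), 3 * as.numeric(s1), tolerance = 1e-9)
})

test_that("competition is monotone in the protein synthesis rate", {
  grid <- c(0.01, 0.03, 0.1, 0.3, 1)
  ss <- lapply(grid, function(s) steady_state(param_set_3114(s_prot = s)))
  ydj1a <- vapply(ss, function(x) x[["ydj1_a"]], numeric(1))
  cln3f <- vapply(ss, function(x) x[["cln3_f"]], numeric(1))
  protu <- vapply(ss, function(x) x[["prot_u"]], numeric(1))
  expect_true(all(diff(ydj1a) <= 0))
  expect_true(all(diff(cln3f) <= 0))
  expect_true(all(diff(protu) >= 0))
})

test_that("the diffusion observable is a convex combination of the pool limits", {
  expect_equal(dsim(chap_state(ydj1_a = 5)), 30)
  expect_equal(dsim(chap_state(yp = 2, yc = 1)), 1)
  expect_equal(dsim(chap_state(ydj1_a = 3, yp = 2, yc = 1)), 15.5)
  expect_error(dsim(chap_state()), "undefined")
  set.seed(7)
  for (i in 1:10) {
    d <- dsim(steady_state(random_valid_params()))
    expect_gte(d, 1); expect_lte(d, 30)
  }
})

test_that("trajectories and steady states export as documented CSV", {
  p <- param_set_3114()
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- integrate_model(p, chap_state(), c(0, 10, 100))
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("time_s", "prot_u", "yp", "prot_f",
                                  "cln3_u", "yc", "cln3_f", "ydj1_a"))
  expect_equal(nrow(back), 3L)
})
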