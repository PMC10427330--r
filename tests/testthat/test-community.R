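test_that("mean cooperation mixes savvy and naive behaviour", {
  pars <- community_params(1, 1, 0.2, 1, K = 1, p_tilde = "auto",
                           norms = cooperation_ns())
  Fq <- ns_cdf(pars$norms, pars$p_tilde)
  expect_equal(mean_cooperation(community_state(0.2, 0.5, 1, 0.3), pars), 0.3)
  expect_equal(mean_cooperation(community_state(0.2, 0.5, 0, 0.3), pars), Fq)
  # self-confirming coordination belief: p = p_tilde gives p_bar = p_tilde
  parc <- community_params(1, 1, 0.2, 1, K = 1, p_tilde = "auto",
                           norms = coordination_ns())
  for (y in c(0, 0.3, 1))
    expect_equal(mean_cooperation(
      community_state(0, 1, y, parc$p_tilde), parc), parc$p_tilde)
})

test_that("belief gap is p_tilde - p_bar, clamped at 0 with warning", {
  parc <- community_params(1, 1, 0.2, 1, K = 1, p_tilde = "auto",
                           norms = coordination_ns())
  expect_equal(belief_gap(community_state(0, 1, 0.5, parc$p_tilde), parc), 0)
  pars <- community_params(1, 1, 0.2, 1, K = 1, p_tilde = 0.9,
                           norms = cooperation_ns())
  expect_equal(belief_gap(community_state(0, 1, 1, 0), pars), 0.9)
  # inadmissible state: savvy cooperating above the naive belief
  expect_warning(
    g <- belief_gap(community_state(0, 1, 1, 0.99), pars),
    "clamped")
  expect_equal(g, 0)
})

test_that("reduced vector field vanishes at the all-insider equilibrium", {
  parc <- community_params(1, 1, 0.3, 1, K = 1, p_tilde = "auto",
                           norms = coordination_ns())
  d <- community_rhs(parc, community_state(0, 1, 0.5, parc$p_tilde))
  expect_equal(unname(d), rep(0, 4), tolerance = 1e-12)
  # empty community with zero gap: population flows all vanish
  d2 <- community_rhs(parc, community_state(1, 0, 0.5, parc$p_tilde))
  expect_equal(unname(d2[c("S", "I")]), c(0, 0))
})

test_that("raw five-compartment field conserves K and reduces correctly", {
  set.seed(99)
  for (i in 1:100) {
    pars <- random_params()
    sfrac <- runif(1, 0.05, 0.6)
    nfrac <- runif(1, 0.05, 0.8) * (1 - sfrac)
    vfrac <- runif(1, 0.05, 0.9) * (1 - sfrac - nfrac)
    dfrac <- 1 - sfrac - nfrac - vfrac
    raw <- c(sfrac, nfrac, vfrac, dfrac, runif(1, 0, pars$p_tilde) * vfrac) *
      pars$K
    dr <- raw_rhs(pars, raw)
    # conservation of K over the population compartments (C tracks a
    # sub-count of V and is excluded)
    expect_equal(sum(dr[c("S", "N", "V", "D")]), 0, tolerance = 1e-14)
    # chain rule: reduced derivatives match the reduced field
    expect_equal(unname(reduce_derivs(raw, dr)),
                 unname(community_rhs(pars, reduce_state(raw, pars))),
                 tolerance = 1e-10)
  }
})

test_that("with no learning or leaving, compartments move only by inflow
           and norm-following behaviour adjustment", {
  pars <- community_params(1, 0, 0, 1, K = 1, p_tilde = 0.9,
                           norms = cooperation_ns())
  raw <- c(S = 0.4, N = 0.2, V = 0.3, D = 0.1, C = 0.06)
  dr <- raw_rhs(pars, raw)
  join <- 1 * 0.4 * (0.2 + 0.3) / 1
  expect_equal(dr[["N"]], join)       # all inflow lands in the naive class
  expect_equal(dr[["V"]], 0)          # nobody learns or leaves
  expect_equal(dr[["D"]], -1 * 0.1)   # discouragement only wanes
  # savvy cooperators still adjust toward the norm response F(p_bar)
  p <- 0.06 / 0.3
  Fq <- ns_cdf(pars$norms, 0.9)
  p_bar <- (0.2 * Fq + 0.3 * p) / 0.5
  expect_equal(dr[["C"]], 0.3 * (ns_cdf(pars$norms, p_bar) - p))
})

test_that("trajectories from an equilibrium are constant", {
  parc <- community_params(1, 1, 0.3, 1, K = 1, p_tilde = "auto",
                           norms = coordination_ns())
  tr <- integrate_community(parc, community_state(0, 1, 0.4, parc$p_tilde),
                            50, 51)
  expect_lt(max(abs(tr$I - 1)), 1e-10)
  expect_lt(max(abs(tr$p - parc$p_tilde)), 1e-10)
  expect_lt(max(abs(tr$y - 0.4)), 1e-10)
})

test_that("adaptive integration matches a pure-R RK4 oracle", {
  pars <- community_params(1, 1, 0.5, 0.5, K = 1, p_tilde = "auto",
                           norms = cooperation_ns())
  x0 <- c(0.8, 0.2, 0.3, 0.4)
  times <- seq(0, 5, by = 1)
  tr <- integrate_community(pars, x0, times = times)
  ora <- rk4_integrate(function(x) community_rhs(pars, x), x0, times,
                       h = 5e-4)
  expect_equal(as.matrix(tr[, c("S", "I", "y", "p")]), ora,
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("raw and reduced integrations agree (derivation oracle)", {
  set.seed(123)
  for (i in 1:25) {
    pars <- random_params()
    st <- random_state(pars)
    raw0 <- lift_state(st, pars)
    times <- seq(0, 100, length.out = 11)
    tr <- integrate_community(pars, st, times = times)
    rw <- integrate_raw(pars, raw0, times = times)
    red <- t(apply(as.matrix(rw[, c("S", "N", "V", "D", "C")]), 1,
                   function(r) as.numeric(reduce_state(r, pars))))
    expect_equal(as.matrix(tr[, c("S", "I", "y", "p")]), red,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("conservation, positivity and gap invariance along trajectories", {
  set.seed(321)
  for (i in 1:20) {
    pars <- random_params()
    st <- random_state(pars)
    tr <- integrate_community(pars, st, 100, 201)
    expect_lt(max(abs(tr$S + tr$I + tr$D - pars$K)), 1e-8 * pars$K)
    expect_true(all(tr$S >= 0 & tr$I >= 0))
    expect_true(all(tr$y >= 0 & tr$y <= 1))
    # rosy beliefs persist: p stays below p_tilde, so the gap stays >= 0
    expect_true(all(tr$p <= pars$p_tilde + 1e-9))
    expect_true(all(pars$p_tilde - tr$p_bar >= -1e-9))
  }
})

test_that("dynamics are invariant under population rescaling", {
  ns <- cooperation_ns()
  p1 <- community_params(1, 1, 0.5, 0.5, K = 1, p_tilde = "auto", norms = ns)
  p1000 <- community_params(1, 1, 0.5, 0.5, K = 1000, p_tilde = "auto",
                            norms = ns)
  tr1 <- integrate_community(p1, c(0.8, 0.2, 0.3, 0.4), 50, 101)
  tr2 <- integrate_community(p1000, c(800, 200, 0.3, 0.4), 50, 101)
  expect_equal(tr1$S, tr2$S / 1000, tolerance = 1e-9)
  expect_equal(tr1$I, tr2$I / 1000, tolerance = 1e-9)
  expect_equal(tr1$y, tr2$y, tolerance = 1e-9)
  expect_equal(tr1$p, tr2$p, tolerance = 1e-9)
})

test_that("total cooperation is the insider mass times mean cooperation", {
  pars <- community_params(1, 1, 0.2, 1, K = 10, p_tilde = 0.9,
                           norms = cooperation_ns())
  expect_equal(total_cooperation(community_state(5, 0, 0.5, 0.5), pars), 0)
  expect_equal(total_cooperation(community_state(1, 4, 1, 1), pars), 4)
  tc <- vapply(c(1, 2, 4), function(I)
    total_cooperation(community_state(0.5, I, 0.4, 0.3), pars), numeric(1))
  expect_true(all(diff(tc) > 0))
})

test_that("trajectory CSV round-trips losslessly and deterministically", {
  pars <- community_params(1, 1, 0.5, 0.5, K = 1, p_tilde = "auto",
                           norms = cooperation_ns())
  tr <- integrate_community(pars, c(0.8, 0.2, 0.3, 0.4), 10, 21)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f1)
  back <- read_trajectory_csv(f1)
  expect_identical(unname(as.matrix(back)),
                   unname(as.matrix(as.data.frame(tr))))
  write_trajectory_csv(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("invalid states and parameters are rejected", {
  ns <- cooperation_ns()
  expect_error(community_params(-1, 1, 1, 1, K = 1, p_tilde = 0.9,
                                norms = ns), "inflow")
  expect_error(community_params(1, 1, 1, 1, K = 0, p_tilde = 0.9,
                                norms = ns), "K")
  expect_error(community_state(0.6, 0.6, 0.5, 0.5, K = 1), "exceeds K")
  expect_error(community_state(-0.1, 0.5, 0.5, 0.5), "non-negative")
  pars <- community_params(1, 1, 1, 1, K = 1, p_tilde = 0.9, norms = ns)
  expect_error(integrate_community(pars, c(0.7, 0.5, 0.5, 0.5), 10),
               "exceeds K")
})
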