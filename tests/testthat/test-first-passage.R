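test_that("renewal first-passage GF reduces to the homogeneous ratio", {
  sp <- lattice_spec(c(8, 8), q = c(0.4, 0.4))
  gf <- homogeneous_propagator_gf(sp)
  zs <- c(0.3, 0.6 + 0.2i)
  hom <- gf_eval(gf, c(2, 2), c(6, 6), zs) / gf_eval(gf, c(2, 2), c(2, 2), zs)
  expect_equal(fp_gf_single(NULL, gf, c(6, 6), c(2, 2), zs), hom,
               tolerance = 1e-12)
  expect_error(fp_gf_single(NULL, gf, c(2, 2), c(2, 2), 0.5), "return_gf")
})

test_that("an impenetrable barrier left of the start shifts the problem", {
  q <- 2/3
  sp <- lattice_spec(60, q = q)
  gf <- homogeneous_propagator_gf(sp)
  u <- 4
  set <- het_set(sp, list(defect_pair(sp, u, u + 1, q / 2, q / 2)))
  spS <- lattice_spec(60 - u, q = q)
  gfS <- homogeneous_propagator_gf(spS)
  for (z in c(0.5, 0.9))
    expect_equal(fp_gf_single(set, gf, 8, 15, z),
                 fp_gf_single(NULL, gfS, 8 - u, 15 - u, z), tolerance = 1e-10)
  # barrier between start and target blocks passage entirely
  setb <- het_set(sp, list(defect_pair(sp, 10, 11, q / 2, q / 2)))
  expect_lt(abs(fp_gf_single(setb, gf, 8, 15, 0.9)), 1e-12)
})

test_that("first-return GF behaves like a return-time distribution", {
  # 2-site periodic ring with q = 1: deterministic swap, return at t = 2
  sp <- lattice_spec(2, q = 1, boundary = "periodic")
  gf <- homogeneous_propagator_gf(sp)
  ser <- series_coefficients(function(z) return_gf(NULL, gf, 1, z), T = 6)
  expect_equal(ser$probability, c(0, 0, 1, 0, 0, 0, 0), tolerance = 1e-10)
  # finite conserving lattice: returns are certain (mass -> 1)
  sp5 <- lattice_spec(5, q = 1)
  gf5 <- homogeneous_propagator_gf(sp5)
  ser5 <- series_coefficients(function(z) return_gf(NULL, gf5, 1, z), T = 400)
  expect_gt(sum(ser5$probability), 0.999)
  expect_equal(ser5$probability[1], 0) # no return at t = 0
})

test_that("disorder indifference: a barrier behind the start leaves the mean", {
  sp <- lattice_spec(40, q = 2/3)
  base <- homogeneous_mfpt_1d(8, 15, 2/3)
  for (lam in c(-0.3, -0.1, 0.1, 0.2, 0.325)) { # open interval: lam < q/2
    for (u in c(2, 5, 7)) {
      set <- het_set(sp, list(defect_pair(sp, u, u + 1, lam, lam)))
      expect_equal(as.numeric(mfpt(set, sp, 8, 15)), base, tolerance = 1e-8)
    }
  }
  # exactly impenetrable: the problem shifts by u instead (discontinuity)
  for (u in c(2, 7)) {
    set <- het_set(sp, list(defect_pair(sp, u, u + 1, 1/3, 1/3)))
    shifted <- homogeneous_mfpt_1d(8 - u, 15 - u, 2/3)
    expect_equal(as.numeric(mfpt(set, sp, 8, 15)), shifted, tolerance = 1e-8)
    expect_equal(mfpt_1d_barrier(8, 15, u, 1/3, 2/3), shifted)
  }
})

test_that("a barrier between start and target slows the walk monotonically", {
  sp <- lattice_spec(40, q = 2/3)
  lams <- c(-0.3, -0.1, 0, 0.15, 0.3, 0.33)
  means <- vapply(lams, function(lam) {
    set <- het_set(sp, list(defect_pair(sp, 10, 11, lam, lam)))
    as.numeric(mfpt(set, sp, 8, 15))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("survival-sum and renewal-derivative means agree", {
  sp <- lattice_spec(40, q = 2/3)
  for (u in c(4, 8, 14)) {
    set <- het_set(sp, list(defect_pair(sp, u, u + 1, 0.325, 0.325)))
    s <- as.numeric(mfpt(set, sp, 8, 15))
    r <- as.numeric(mfpt(set, sp, 8, 15, method = "renewal"))
    expect_equal(r, s, tolerance = 1e-6)
  }
})

test_that("means match the absorbing-chain linear-solve oracle", {
  sp <- fixture_spec(c(9, 9), q = c(0.6, 0.6))
  op <- build_transition_operator(sp)
  set.seed(11)
  set <- het_set(sp, list(
    make_barrier(sp, c(4, 4), c(4, 5), 0.8, op = op),
    make_sticky(sp, c(7, 2), 1/3, op = op),
    make_long_range(sp, c(2, 7), c(8, 8), 1/2, op = op)))
  target <- site_id(sp, c(9, 5))
  got <- as.numeric(mfpt(set, sp, c(2, 2), c(9, 5)))
  Ap <- apply_defects(set, op)
  want <- solve_absorbing_means(Ap, targets = target)[site_id(sp, c(2, 2))]
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("unreachable targets yield an infinite mean with reach < 1", {
  sp <- lattice_spec(20, q = 1/2)
  set <- het_set(sp, list(defect_pair(sp, 10, 11, 1/4, 1/4))) # impenetrable
  res <- mfpt(set, sp, 5, 15)
  expect_identical(as.numeric(res), Inf)
  expect_equal(attr(res, "reach_probability"), 0)
})

test_that("mean return times follow Kac's lemma", {
  sp <- lattice_spec(20, q = 0.5)
  # symmetric barrier: MRT = N on both sides
  set <- het_set(sp, list(defect_pair(sp, 7, 8, 0.2, 0.2)))
  expect_equal(as.numeric(mrt(set, sp, 4)), 20, tolerance = 1e-12)
  expect_equal(as.numeric(mrt(set, sp, 15)), 20, tolerance = 1e-12)
  # impenetrable: class-restricted MRTs u and N - u, with a warning
  seti <- het_set(sp, list(make_barrier(sp, 7, 8, 1)))
  expect_warning(m1 <- mrt(seti, sp, 4), "reducible")
  expect_warning(m2 <- mrt(seti, sp, 15), "reducible")
  expect_equal(as.numeric(m1), 7, tolerance = 1e-12)
  expect_equal(as.numeric(m2), 13, tolerance = 1e-12)
  # asymmetric barrier: matches the closed form and 1/pi from power iteration
  seta <- het_set(sp, list(defect_pair(sp, 7, 8, 0.2, 0.1)))
  pi_emp <- oracle_stationary(apply_defects(seta), 3)
  for (n in c(3, 7, 8, 16)) {
    got <- as.numeric(mrt(seta, sp, n))
    expect_equal(got, mrt_1d_barrier(n, 20, 7, 0.2, 0.1, 0.5),
                 tolerance = 1e-10)
    expect_equal(got * pi_emp[n], 1, tolerance = 1e-8)
  }
})

test_that("mean exit times react to barriers and antibarriers", {
  # hand-checkable 3-site chain: absorb on arrival at site 1
  sp3 <- lattice_spec(3, q = 1, absorbing_sites = 1)
  expect_equal(as.numeric(met(NULL, sp3, 3)), 6, tolerance = 1e-12)
  expect_equal(as.numeric(met(NULL, sp3, 2)), 4, tolerance = 1e-12)
  expect_error(met(NULL, lattice_spec(5, q = 1), 3), "absorbing")

  sp <- lattice_spec(c(9, 9), q = c(0.8, 0.8), boundary = "absorbing_both")
  op <- build_transition_operator(sp)
  hom <- as.numeric(met(NULL, sp, c(5, 5)))
  edges <- list(c(3, 3), c(5, 2), c(2, 6), c(7, 7), c(4, 5), c(8, 3))
  mk <- function(lam) {
    prs <- lapply(edges, function(u)
      defect_pair(sp, u, u + c(0, 1), lam, lam, op = op))
    het_set(sp, prs)
  }
  expect_gt(as.numeric(met(mk(0.15), sp, c(5, 5))), hom)
  expect_lt(as.numeric(met(mk(-0.15), sp, c(5, 5))), hom)
})

test_that("1D single-barrier closed forms match the defect machinery", {
  q <- 2/3; lam <- 0.975 * q / 2
  # frozen printed means and the per-site coefficient
  expect_equal(mfpt_1d_barrier(8, 15, 3, lam, q), 231)
  expect_equal(mfpt_1d_barrier(8, 15, 8, lam, q), 1167)
  expect_equal(mfpt_1d_barrier(8, 15, 14, lam, q), 1869)
  expect_equal(2 * lam / (q * (q / 2 - lam)), 117)
  expect_equal(mfpt_1d_barrier(8, 15, 10, 0, q), 231)
  expect_identical(mfpt_1d_barrier(8, 15, 10, q / 2, q), Inf)

  # closed-form GF vs defect solver on a long truncated lattice
  sp <- lattice_spec(120, q = q)
  op <- build_transition_operator(sp)
  gf <- homogeneous_propagator_gf(sp)
  for (u in c(4, 10)) {
    set <- het_set(sp, list(defect_pair(sp, u, u + 1, lam, lam, op = op)))
    A <- apply_defects(set, op)
    want <- oracle_fp_series(A, 8, 15, 300)
    got <- series_coefficients(function(z) fp_1d_barrier_gf(8, 15, u, lam,
                                                            q, z), T = 300)
    expect_lt(max(abs(got$probability[-1] - want)), 1e-9)
  }
  # lambda -> 0 recovers the homogeneous first-passage GF
  for (z in c(0.4, 0.8)) {
    hom <- fp_gf_single(NULL, gf, 8, 15, z)
    expect_equal(fp_1d_barrier_gf(8, 15, 5, 1e-12, q, z), hom,
                 tolerance = 1e-9)
  }
  # oracle check of the mean across barrier positions
  for (u in c(2, 9, 13)) {
    A <- apply_defects(het_set(sp, list(
      defect_pair(sp, u, u + 1, 0.2, 0.2, op = op))), op)
    expect_equal(mfpt_1d_barrier(8, 15, u, 0.2, q),
                 solve_absorbing_means(A, targets = 15)[8], tolerance = 1e-9)
  }
})

test_that("two-target first passage composes single-target GFs correctly", {
  sp <- fixture_spec()
  gf <- homogeneous_propagator_gf(sp)
  # mass of the two-target distribution is 1 on a conserving lattice
  fp <- first_passage(NULL, gf, c(6, 6), list(c(4, 2), c(10, 7)), T = 50)
  expect_equal(fp$reach_probability, 1, tolerance = 1e-9)
  # first possible arrival is the shortest lattice path (Manhattan distance)
  ser <- series_coefficients(function(z)
    fp_gf_two_targets(NULL, gf, c(6, 6), c(4, 2), c(10, 7), z), T = 20)
  expect_equal(ser$t[which(ser$probability > 1e-12)[1]], 5)
  # with both targets sealed off the cross terms vanish and F~ = F~1 + F~2
  op <- build_transition_operator(sp)
  prs <- c(enclosure_pairs(sp, 3:5, 1:3, op = op),
           enclosure_pairs(sp, 9:10, 6:8, op = op))
  # (targets (4,2) and (10,7) are inside separate sealed regions)
  set <- het_set(sp, prs)
  z <- 0.7
  f1 <- fp_gf_single(set, gf, c(6, 6), c(4, 2), z)
  f2 <- fp_gf_single(set, gf, c(6, 6), c(10, 7), z)
  expect_lt(abs(f1) + abs(f2), 1e-10) # sealed: individually unreachable
  expect_equal(fp_gf_two_targets(set, gf, c(6, 6), c(4, 2), c(10, 7), z),
               f1 + f2, tolerance = 1e-10)
})

test_that("first_passage summarises distribution, mean and reach", {
  sp <- lattice_spec(25, q = 2/3)
  gf <- homogeneous_propagator_gf(sp)
  set <- het_set(sp, list(defect_pair(sp, 10, 11, 0.2, 0.2)))
  fp <- first_passage(set, gf, 8, 15, T = 400)
  expect_s3_class(fp, "fp_result")
  expect_equal(fp$reach_probability, 1, tolerance = 1e-10)
  expect_equal(fp$mean, as.numeric(mfpt(set, sp, 8, 15)), tolerance = 1e-10)
  # distribution head agrees with the iteration oracle
  A <- apply_defects(set)
  want <- oracle_fp_series(A, 8, 15, 400)
  expect_lt(max(abs(fp$distribution$probability[-1] - want)), 1e-9)
})
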