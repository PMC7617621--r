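test_that("brick-and-mortar geometry and barrier strengths are as configured", {
  cfg <- brick_mortar_config(N = c(13, 12), brick = c(3, 5), alpha = 1,
                             q = c(0.8, 0.8))
  expect_equal(cfg$layers, 3L)
  expect_equal(cfg$bricks_per_layer, 2L)
  sc <- build_brick_mortar(cfg)
  expect_equal(sc$spec$boundary, c("absorbing_low", "periodic"))
  expect_true(all(abs(sc$set$lambda_vu - 0.2) < 1e-12))
  expect_true(all(abs(sc$set$lambda_uv - 0.2) < 1e-12))
  expect_error(brick_mortar_config(N = c(13, 11)), "multiple")

  # a puncture spanning everything removes every barrier -> homogeneous MET
  call <- brick_mortar_config(N = c(13, 12), brick = c(3, 5), h = 13, w = 12)
  scall <- build_brick_mortar(call)
  expect_equal(scall$set$M, 0L)
  expect_equal(as.numeric(met(scall$set, scall$spec, scall$n0)),
               as.numeric(met(NULL, scall$spec, scall$n0)), tolerance = 1e-12)
})

test_that("puncture height reshapes the exit time as the barriers dictate", {
  cfg <- brick_mortar_config(N = c(13, 12), brick = c(3, 5), alpha = 1,
                             q = c(0.8, 0.8))
  tab <- met_vs_puncture(cfg, h_values = c(0, 2, 4, 8, 12), w_values = 3)
  # impenetrable bricks: opening then cutting -> rise followed by fall
  expect_true(any(diff(tab$met) > 1e-6))
  expect_true(any(diff(tab$met) < -1e-6))
  expect_gt(max(tab$met), tab$met[1])       # interior maximum
  expect_lt(tab$met[nrow(tab)], tab$met[1]) # full cut beats intact layer
  # h = 0: width is irrelevant
  t0 <- met_vs_puncture(cfg, 0, c(1, 3, 5))
  expect_lt(diff(range(t0$met)), 1e-9)
  # exact agreement with the linear-solve oracle at one puncture
  ch <- brick_mortar_config(N = c(13, 12), brick = c(3, 5), h = 4, w = 3,
                            alpha = 1, q = c(0.8, 0.8))
  sch <- build_brick_mortar(ch)
  want <- solve_absorbing_means(apply_defects(sch$set))[
    site_id(sch$spec, sch$n0)]
  expect_equal(as.numeric(met(sch$set, sch$spec, sch$n0)), want,
               tolerance = 1e-8)
})

test_that("thigmotaxis arena: annulus occupation grows with the inward block", {
  cfg <- thigmotaxis_config(N = 21, R = 9.6, r = 5.8)
  sc <- build_thigmotaxis(cfg)
  expect_gt(sc$n_outer, 0L)
  expect_gt(sc$n_inner, 0L)
  ctr <- (cfg$N + 1) / 2
  co <- site_coords(sc$spec, seq_len(n_sites(sc$spec)))
  dist <- sqrt((co[, 1] - ctr)^2 + (co[, 2] - ctr)^2)

  # alpha_i = 0: no inner barriers; stationary state uniform on the disc
  sc0 <- build_thigmotaxis(thigmotaxis_config(N = 21, R = 9.6, r = 5.8,
                                              alpha_i = 0))
  expect_equal(sc0$set$M, sc0$n_outer)
  pv0 <- hetwalk:::.steady_state_from(apply_defects(sc0$set),
                                      site_id(sc0$spec, sc0$n0))
  disc <- dist <= cfg$R
  expect_lt(max(abs(pv0[disc] - 1 / sum(disc))), 1e-12)
  expect_equal(sum(pv0[!disc]), 0)

  # alpha_i = 1: no stationary mass strictly inside r
  sc1 <- build_thigmotaxis(thigmotaxis_config(N = 21, R = 9.6, r = 5.8,
                                              alpha_i = 1))
  pv1 <- hetwalk:::.steady_state_from(apply_defects(sc1$set),
                                      site_id(sc1$spec, sc1$n0))
  expect_equal(sum(pv1[dist <= cfg$r]), 0)
  expect_equal(sum(pv1), 1, tolerance = 1e-12)

  # saturated MSD is non-decreasing in alpha_i, and thinner annuli saturate
  # higher
  tab <- thigmotaxis_msd_curve(cfg, c(0, 0.5, 0.95, 1))
  expect_true(all(diff(tab$ratio) >= -1e-12))
  expect_equal(tab$ratio[1], 1, tolerance = 1e-12)
  thin <- thigmotaxis_msd_curve(thigmotaxis_config(N = 21, R = 9.6, r = 7.7),
                                0.95)$ratio
  thick <- thigmotaxis_msd_curve(thigmotaxis_config(N = 21, R = 9.6, r = 3.9),
                                 0.95)$ratio
  expect_gt(thin, tab$ratio[3])
  expect_gt(tab$ratio[3], thick)
})

test_that("coalescence limits reproduce the interaction semantics", {
  cfg <- coalescence_config(N = 12, q = 2/3)
  sc <- build_coalescence(cfg)
  expect_equal(sc$set$M, 0L) # alpha_e = 0, alpha_u = alpha_c = 1: homogeneous
  dg <- site_id(sc$spec, cbind(1:12, 1:12))
  off <- setdiff(seq_len(n_sites(sc$spec)), dg)

  # alpha_u = 0: binding is irreversible (no flux off the diagonal)
  scu <- build_coalescence(coalescence_config(N = 12, q = 2/3, alpha_u = 0))
  Au <- apply_defects(scu$set)
  expect_equal(sum(Au[off, dg]), 0)
  # alpha_c = 0: the complex is immobile (no flux along the diagonal)
  scc <- build_coalescence(coalescence_config(N = 12, q = 2/3, alpha_c = 0))
  Ac <- apply_defects(scc$set)
  expect_equal(sum(Ac[dg, dg] - Matrix::Diagonal(12, Matrix::diag(Ac)[dg])), 0)
  # alpha_e = 1: the particles can never meet
  sce <- build_coalescence(coalescence_config(N = 12, q = 2/3, alpha_e = 1))
  res <- mfpt(sce$set, sce$spec, sce$n0, sce$target)
  expect_identical(as.numeric(res), Inf)
  # every built set conserves probability
  expect_lt(max(abs(Matrix::colSums(Au) - 1)), 1e-14)
  expect_lt(max(abs(Matrix::colSums(Ac) - 1)), 1e-14)
})

test_that("coalescence MFPT map normalizes and favours a cohesive complex", {
  cfg <- coalescence_config(N = 12, q = 2/3)
  m <- coalescence_mfpt_map(cfg, alpha_u_values = c(0.1, 0.5, 1),
                            alpha_c_values = c(0.1, 0.5, 1))
  expect_equal(m$ratio[m$alpha_u == 1 & m$alpha_c == 1], 1,
               tolerance = 1e-10)
  # smallest ratio sits in the low-unbinding / high-mobility quadrant
  best <- m[which.min(m$ratio), ]
  expect_lte(best$alpha_u, 0.5)
  expect_gte(best$alpha_c, 0.5)
  expect_lt(best$ratio, 1)
  # exact agreement with the linear-solve oracle at one grid point
  ci <- coalescence_config(N = 12, q = 2/3, alpha_u = 0.5, alpha_c = 0.5)
  sci <- build_coalescence(ci)
  want <- solve_absorbing_means(apply_defects(sci$set),
                                targets = site_id(sci$spec, sci$target))
  expect_equal(as.numeric(mfpt(sci$set, sci$spec, sci$n0, sci$target)),
               want[site_id(sci$spec, sci$n0)], tolerance = 1e-8)
})
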