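# Monte Carlo transport engine: free-path, point-source, conservation and
# symmetry oracles, plus the reproducibility and convergence contracts.

first_flight <- first_flight_acc

test_that("free paths through uniform water follow exp(-mu x)", {
  blk <- uniform_block("water", n = c(64, 40, 40), voxel_mm = 5)
  mu <- sum(mixture_mu(material_from_table("water"), 140.5)[, c("photo",
                                                                "incoh")])
  n <- 2e5
  d <- first_flight(blk, c(2.5, 100, 100), c(1, 0, 0), 140.5, n, seed = 12)
  for (x in c(2, 5, 10)) {
    s_emp <- mean(d > x)          # includes escapes (> 31 cm)
    s_ref <- exp(-mu * x)
    expect_lt(abs(s_emp - s_ref),
              3 * sqrt(s_ref * (1 - s_ref) / n) + 0.002 * s_ref)
  }
  # mean free path of the non-censored part consistent with 1/mu
  expect_equal(mean(d[is.finite(d) & d < 20]),
               (1 - exp(-mu * 20) * (1 + mu * 20)) / mu / (1 - exp(-mu * 20)),
               tolerance = 0.01)
})

test_that("isotropic point source: first-collision shells combine 1/r^2
           fluence with exponential attenuation", {
  blk <- uniform_block("water", n = c(60, 60, 60), voxel_mm = 5)
  mu <- sum(mixture_mu(material_from_table("water"), 140.5)[, c("photo",
                                                                "incoh")])
  n <- 2e5
  d <- first_flight(blk, c(150, 150, 150), c(0, 0, 0), 140.5, n, seed = 13)
  edges <- seq(1, 11, by = 2)     # shells well inside the block
  for (k in seq_len(length(edges) - 1)) {
    p_ref <- exp(-mu * edges[k]) - exp(-mu * edges[k + 1])
    p_emp <- mean(d > edges[k] & d <= edges[k + 1])
    expect_lt(abs(p_emp - p_ref), 4 * sqrt(p_ref * (1 - p_ref) / n) +
                                  0.002 * p_ref)
  }
})

test_that("energy is conserved: equality in an absorbing block, and
           deposition never exceeds emission per batch", {
  # dense absorber: 20 cm block at 25 g/cc, source in the central core
  core <- uniform_block("water", n = c(40, 40, 40), voxel_mm = 5,
                        density = 25)
  lab <- core$labels
  lab[16:25, 16:25, 16:25] <- 2L
  core$labels <- lab
  core$organs <- rbind(core$organs, within(core$organs[1, ], {
    id <- 2L; organ <- "core"; n_vox <- 1000L
    volume_cc <- 1000 * 0.125; mass_g <- volume_cc * 25
  }))
  core$organs$n_vox[1] <- sum(lab == 1L)
  core$organs$volume_cc[1] <- core$organs$n_vox[1] * 0.125
  core$organs$mass_g[1] <- core$organs$volume_cc[1] * 25
  m <- simulate_frame(core, c(core = 1), n_histories = 2e4, seed = 3)
  expect_equal(attr(m, "deposited_mev"), attr(m, "emitted_mev"),
               tolerance = 1e-12)

  # real phantom: per-batch deposition bounded by emission
  ph <- ref_phantom("male")
  mb <- simulate_frame(ph, c(bladder_content = 1), n_histories = 5e4,
                       seed = 4)
  expect_true(all(rowSums(attr(mb, "batches")) <=
                  attr(mb, "emitted_mev_batch") + 1e-9))
  expect_lt(attr(mb, "deposited_mev"), attr(mb, "emitted_mev"))
})

test_that("self-irradiation dominates: source organ tops the dose map", {
  ph <- ref_phantom("male")
  m <- simulate_frame(ph, c(kidney_L = 1), n_histories = 1e5, seed = 21)
  expect_equal(m$organ[which.max(m$mev_per_g_per_decay)], "kidney_L")
  expect_true(all(m$mev_per_g_per_decay >= 0))
})

test_that("mirror-symmetric source gives statistically equal paired doses", {
  ph <- ref_phantom("male")
  m <- simulate_frame(ph, c(bladder_content = 1), n_histories = 1e6,
                      seed = 22)
  tl <- m[m$organ == "testis_L", ]
  tr <- m[m$organ == "testis_R", ]
  se <- sqrt((tl$mev_per_g_per_decay * tl$rel_err)^2 +
             (tr$mev_per_g_per_decay * tr$rel_err)^2)
  expect_lt(abs(tl$mev_per_g_per_decay - tr$mev_per_g_per_decay), 4 * se)
})

test_that("transport runs are reproducible and validate their inputs", {
  ph <- ref_phantom("male")
  src <- c(kidney_L = 0.5, kidney_R = 0.5)
  m1 <- simulate_frame(ph, src, n_histories = 2e4, seed = 7)
  m2 <- simulate_frame(ph, src, n_histories = 2e4, seed = 7)
  expect_identical(m1$mev_per_g_per_decay, m2$mev_per_g_per_decay)
  m3 <- simulate_frame(ph, src, n_histories = 2e4, seed = 8)
  expect_false(identical(m1$mev_per_g_per_decay, m3$mev_per_g_per_decay))

  expect_error(simulate_frame(ph, src, n_histories = 0, seed = 1), ">= 1000")
  expect_error(simulate_frame(ph, c(kidney_L = 0), seed = 1), "empty source")
  expect_error(simulate_frame(ph, c(kidney_L = 0.4), seed = 1), "sum to 1")
  expect_error(simulate_frame(ph, src, n_histories = 1e4), "seed")
})

test_that("convergence loop reaches the 3% criterion and scales as 1/sqrt(N)", {
  ph <- ref_phantom("male")
  src <- c(kidney_L = 0.5, kidney_R = 0.5)
  m <- run_until_converged(ph, src, target_rel_err = 0.03,
                           organs_of_interest = c("kidney_L", "kidney_R"),
                           seed = 5, max_histories = 1e6, chunk = 5e4)
  expect_true(all(attr(m, "converged")))
  expect_true(all(m$rel_err[m$organ %in% c("kidney_L", "kidney_R")] <= 0.03))

  # a trivial target converges after the first chunk
  m1 <- run_until_converged(ph, src, target_rel_err = 0.9,
                            organs_of_interest = "kidney_L", seed = 5,
                            chunk = 5e4)
  expect_equal(attr(m1, "histories"), 5e4)

  # halving the target roughly quadruples the required histories
  h <- vapply(c(0.05, 0.025), function(tgt)
    attr(run_until_converged(ph, src, target_rel_err = tgt,
                             organs_of_interest = "kidney_L", seed = 6,
                             max_histories = 2e6, chunk = 5e3),
         "histories"), 0)
  expect_gte(h[2] / h[1], 2)
  expect_lte(h[2] / h[1], 8)
})
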