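fake_run <- function(samples, n_monomers = 100, bin_size = 5000) {
  list(samples = samples, n_samples = max(samples$sample, 0),
       config = sim_config(n_monomers = n_monomers, bin_size = bin_size,
                           n_steps = 10, burn_in = 0, sample_every = 1))
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(burn_in = 100, n_steps = 100))
  expect_error(sim_config(fast_multiplier = 0))
  cfg <- sim_config()
  expect_equal((cfg$n_steps - cfg$burn_in) / cfg$sample_every, 100)
})

test_that("the annealing schedule interpolates linearly from 4 to 1", {
  cfg <- sim_config()
  expect_equal(anneal_temperature(0, cfg), 4)
  expect_equal(anneal_temperature(cfg$n_steps, cfg), 1)
  expect_equal(anneal_temperature(cfg$n_steps / 2, cfg), 2.5)
  expect_error(anneal_temperature(-1, cfg))
})

test_that("the energy functional rewards span and penalises crossings", {
  expect_equal(sim_energy(integer(), integer()), 0)
  expect_equal(sim_energy(0, 10, c_fold = 1, c_cross = 10), -log(10))
  expect_equal(sim_energy(0, 10, c_fold = 1), -2.302585, tolerance = 1e-6)
  # crossing pair pays c_cross; nested pair does not
  expect_equal(sim_energy(c(2, 5), c(10, 15), c_fold = 0, c_cross = 10), 10)
  expect_equal(sim_energy(c(2, 4), c(10, 8), c_fold = 0, c_cross = 10), 0)
})

test_that("barrier strengths derive from orientation probabilities", {
  cfg <- sim_config(n_monomers = 50, bin_size = 5000, c_bind = 0.5)
  anchors <- data.frame(start = c(50000, 200000), end = c(55000, 205000),
                        p_right = c(0.7, 1.0))
  b <- build_barrier_map(anchors, cfg)
  expect_equal(b$left[11], 0.35)             # c_bind * p_right
  expect_equal(b$right[11], 0.15)            # c_bind * p_left
  expect_equal(b$left[41], 0.5)
  expect_equal(sum(b$left > 0), 2)
  cfg1 <- sim_config(n_monomers = 50, bin_size = 5000, c_bind = 1)
  b1 <- build_barrier_map(data.frame(start = 0, end = 5000, p_right = 1), cfg1)
  expect_equal(b1$left[1], 1.0)
  expect_warning(build_barrier_map(data.frame(start = 9e6, end = 9.1e6,
                                              p_right = 1), cfg1), "skipped")
  empty <- build_barrier_map(data.frame(start = numeric(), end = numeric(),
                                        p_right = numeric()), cfg1)
  expect_true(all(empty$left == 0) && all(empty$right == 0))
})

test_that("runs are seed-deterministic and count samples exactly", {
  cfg <- sim_config(n_monomers = 80, n_steps = 2000, sample_every = 100,
                    burn_in = 1000, n_slow = 5, n_fast = 1, seed = 17)
  r1 <- run_extrusion(cfg); r2 <- run_extrusion(cfg)
  expect_identical(r1$samples, r2$samples)
  expect_equal(r1$n_samples, 10)
  one <- sim_config(n_monomers = 80, n_steps = 1100, sample_every = 100,
                    burn_in = 1000, n_slow = 2, n_fast = 0, seed = 1)
  expect_equal(run_extrusion(one)$n_samples, 1)
})

test_that("leg invariants hold in every sample and energies agree with R", {
  cfg <- sim_config(n_monomers = 60, n_steps = 1200, sample_every = 6,
                    burn_in = 0, n_slow = 6, n_fast = 2, seed = 23,
                    unbind_prob = 0.01)
  run <- run_extrusion(cfg)
  s <- run$samples
  expect_true(all(s$left >= 0 & s$right <= 59 & s$left < s$right))
  # final sample coincides with the final state: C++ incremental bookkeeping
  # must match the reference energy
  expect_equal(run$final_energy,
               sim_energy(run$final$left, run$final$right,
                          cfg$c_fold, cfg$c_cross),
               tolerance = 1e-9)
})

test_that("strength-1 barriers are never crossed", {
  # both directions blocked at monomer 30: a leg may land there but can
  # never leave, so no leg is seen on both strict sides of it
  cfg <- sim_config(n_monomers = 60, n_steps = 500, sample_every = 1,
                    burn_in = 0, n_slow = 15, n_fast = 0, seed = 29,
                    unbind_prob = 0, c_fold = 2)
  b <- list(left = numeric(60), right = numeric(60))
  b$left[31] <- 1; b$right[31] <- 1
  run <- run_extrusion(cfg, b)
  for (ex in unique(run$samples$extruder)) {
    tr <- run$samples[run$samples$extruder == ex, ]
    for (leg in c("left", "right")) {
      p <- tr[[leg]]
      expect_false(any(p < 30) && any(p > 30))
    }
  }
  # one-sided barrier: leftward passage blocked, consecutive samples are at
  # most one step apart, so a 30 -> 29 transition can never occur
  b1 <- list(left = numeric(60), right = numeric(60))
  b1$left[31] <- 1
  run1 <- run_extrusion(cfg, b1)
  for (ex in unique(run1$samples$extruder)) {
    tr <- run1$samples[run1$samples$extruder == ex, ]
    for (leg in c("left", "right")) {
      p <- tr[[leg]]
      expect_false(any(p[-length(p)] >= 30 & p[-1] < 30))
    }
  }
})

test_that("free legs diffuse with linearly growing displacement variance", {
  cfg <- sim_config(n_monomers = 2001, n_steps = 400, sample_every = 100,
                    burn_in = 0, n_slow = 100, n_fast = 0, seed = 37,
                    unbind_prob = 0, c_fold = 0, c_cross = 0)
  run <- run_extrusion(cfg)
  s <- run$samples
  pos <- function(k) {
    sk <- s[s$sample == k, ]
    c(sk$left, sk$right)
  }
  v1 <- var(pos(2) - pos(1))   # 100 sweeps apart
  v3 <- var(pos(4) - pos(1))   # 300 sweeps apart
  expect_gt(v1, 25); expect_lt(v1, 80)        # ~0.5 proposals/leg/sweep
  expect_gt(v3 / v1, 1.8); expect_lt(v3 / v1, 5)
})

test_that("fast extruders reach larger spans than slow ones", {
  wins <- sum(sapply(1:50, function(seed) {
    cfg <- sim_config(n_monomers = 400, n_steps = 300, sample_every = 300,
                      burn_in = 0, n_slow = 1, n_fast = 1, seed = seed,
                      unbind_prob = 0, c_cross = 0)
    s <- run_extrusion(cfg)$samples
    span <- s$right - s$left
    span[s$class == "fast"] > span[s$class == "slow"]
  }))
  expect_gt(wins, 35)   # one-sided binomial bound, p0 = 0.5
})

test_that("contact maps count sampled extruder pairs symmetrically", {
  s <- data.frame(sample = 1:100, step = 1:100, extruder = 1, class = "slow",
                  left = 10, right = 50)
  m <- contact_map(fake_run(s))
  expect_equal(m[11, 51], 100)
  expect_equal(m[51, 11], 100)
  expect_equal(sum(m), 200)
  expect_identical(m, t(m))
  # zero extruders -> zero map
  cfg0 <- sim_config(n_monomers = 30, n_steps = 200, sample_every = 100,
                     burn_in = 0, n_slow = 0, n_fast = 0, seed = 1)
  expect_true(all(contact_map(run_extrusion(cfg0)) == 0))
  # background adds the configured mass and keeps symmetry
  mb <- contact_map(fake_run(s), background_fraction = 0.5)
  expect_equal(sum(mb), 300, tolerance = 1e-9)
  expect_identical(mb, t(mb))
})

test_that("recurrent pairs export as loops and survive a BEDPE round trip", {
  s <- rbind(data.frame(sample = 1:100, step = 1:100, extruder = 1,
                        class = "slow", left = 10, right = 50),
             data.frame(sample = 1, step = 1, extruder = 2,
                        class = "slow", left = 3, right = 7))
  run <- fake_run(s)
  loops <- export_loops(run, min_frequency = 2)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$start1, 50000); expect_equal(loops$end1, 55000)
  expect_equal(loops$start2, 250000); expect_equal(loops$count, 100)
  expect_equal(nrow(export_loops(run, min_frequency = 101)), 0)
  f <- tempfile(fileext = ".bedpe")
  write_bedpe(loops, f)
  expect_equal(read_bedpe(f), loops, ignore_attr = TRUE)
})

test_that("loop-strength correlation is Pearson over the given pixels", {
  m <- matrix(runif(100), 10, 10)
  px <- cbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(loop_strength_correlation(m, m, px), 1)
  expect_equal(loop_strength_correlation(m, -m, px), -1)
  a <- matrix(0, 10, 10); b <- matrix(0, 10, 10)
  a[px] <- c(1, 2, 3); b[px] <- c(2, 4, 6)
  expect_equal(loop_strength_correlation(a, b, px), 1)
  flat <- matrix(1, 10, 10)
  expect_warning(r <- loop_strength_correlation(flat, m, px), "constant")
  expect_true(is.na(r))
  expect_error(loop_strength_correlation(m, m, px[1:2, ]), "3 loop pixels")
})

test_that("smoothed Spearman correlation behaves at the fixed points", {
  set.seed(61)
  m <- matrix(runif(400), 20, 20); m <- m + t(m)
  expect_equal(heatmap_correlation(m, m, smoothing_sigma = 1.5), 1)
  expect_equal(heatmap_correlation(m, exp(m), smoothing_sigma = 0), 1)
  rho <- sapply(1:20, function(seed) {
    set.seed(seed)
    heatmap_correlation(matrix(runif(900), 30, 30),
                        matrix(runif(900), 30, 30), 0)
  })
  expect_lt(mean(abs(rho)), 0.1)
  expect_error(heatmap_correlation(m, matrix(0, 5, 5)), "shapes")
})
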