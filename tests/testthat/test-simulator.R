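test_that("zero-noise cycle matches the hand-evaluated worked example", {
  ref <- oracle_cycle_ds1(1e5)
  rec <- sample_cycle(1e5, zero_noise_params(1), seed = 1)
  expect_equal(rec$a, ref$a, tolerance = 1e-12)
  expect_equal(rec$T1, ref$T1, tolerance = 1e-12)
  expect_equal(rec$X1, ref$X1, tolerance = 1e-12)
  expect_equal(rec$b, ref$b, tolerance = 1e-12)
  expect_equal(rec$T2, ref$T2, tolerance = 1e-12)
  expect_equal(rec$X2, ref$X2, tolerance = 1e-12)
  # magnitudes of the worked numbers
  expect_equal(rec$a, 0.2982, tolerance = 1e-3)
  expect_equal(rec$T1, 5.652, tolerance = 1e-3)
  expect_equal(rec$X1, 1.854e4, tolerance = 1e-3)
  expect_equal(rec$b, 0.1688, tolerance = 1e-3)
  expect_equal(rec$T2, 16.26, tolerance = 1e-3)
  expect_equal(rec$X2, 2.89e5, tolerance = 2e-3)
})

test_that("zero dispersions make the cycle a deterministic function of X0", {
  p0 <- zero_noise_params(1)
  r1 <- sample_cycle(12345, p0, seed = 7)
  r2 <- sample_cycle(12345, p0, seed = 99)
  expect_identical(r1$X2, r2$X2)
  expect_identical(r1$T1, r2$T1)
})

test_that("cycle records satisfy the kinetic identities and positivity", {
  p <- prc1_params(1)
  rec <- sample_cycle(rep(1.4e5, 500), p, seed = 3)
  expect_equal(rec$X1, rec$X0 * exp(-rec$a * rec$T1), tolerance = 1e-9)
  expect_equal(rec$X2, rec$X1 * exp(rec$b * rec$T2), tolerance = 1e-9)
  for (v in c("X0", "X1", "X2", "T1", "T2", "a", "b")) {
    expect_true(all(rec[[v]] > 0), info = v)
  }
  expect_true(all(rec$X1 <= rec$X0))
  expect_true(all(rec$X2 >= rec$X1))
})

test_that("seeded cycle draws are reproducible", {
  p <- prc1_params(2)
  expect_identical(sample_cycle(1.4e4, p, seed = 42),
                   sample_cycle(1.4e4, p, seed = 42))
})

test_that("pathological parameters exhaust the rejection budget with a named equation", {
  p <- prc1_params(2)
  p$regression$b5 <- -100  # T2 mean hopelessly negative
  expect_error(sample_cycle(1.4e4, p, seed = 1, max_redraws = 50), "T2")
})

test_that("division conserves protein exactly and has the printed moments", {
  set.seed(11)
  x2 <- stats::rlnorm(1000, log(2e5), 0.3)
  d <- divide_protein(x2, prc1_params(1)$division)
  expect_identical(d$X0_left + d$X0_right, x2)  # exact, to the last bit
  expect_true(all(d$U > 0 & d$U < 1))

  # near-symmetric split in the alpha -> infinity limit
  d_sym <- divide_protein(rep(2e5, 200), list(alpha = 1e9), seed = 1)
  expect_true(all(abs(d_sym$X0_left / 1e5 - 1) < 1e-3))

  # E(U) = 1/2 and V(U) = 1/(8 alpha + 4) at alpha = 29.29
  d_big <- divide_protein(rep(1, 1e6), list(alpha = 29.29), seed = 2)
  se_mean <- sd(d_big$U) / sqrt(1e6)
  expect_lt(abs(mean(d_big$U) - 0.5), 3 * se_mean)
  expect_lt(abs(var(d_big$U) / beta_split_variance(29.29) - 1), 0.02)
})

test_that("an uncapped pedigree is a full binary tree with exact conservation", {
  p <- prc1_params(1)
  ped <- simulate_pedigree(p, n_generations = 3, seed = 5)
  expect_equal(nrow(ped), 15)
  expect_equal(as.vector(table(ped$generation)), c(1, 2, 4, 8))

  sibs <- split(ped[!is.na(ped$parent_id), ], ped$parent_id[!is.na(ped$parent_id)])
  for (s in sibs) {
    expect_equal(nrow(s), 2)
    parent <- ped[ped$cell_id == s$parent_id[1], ]
    expect_identical(sum(s$X0), parent$X2)       # mass conservation, exact
    expect_identical(s$U[1] + s$U[2], 1)          # split fractions sum to 1
    expect_identical(s$birth_time, rep(parent$division_time, 2))
  }
  expect_equal(ped$division_time, ped$birth_time + ped$T1 + ped$T2)
})

test_that("pedigree simulation is byte-identical under a fixed seed", {
  p <- prc1_params(1)
  a <- simulate_pedigree(p, 6, cap = 32, seed = 9)
  b <- simulate_pedigree(p, 6, cap = 32, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree_tsv(a, f1); write_pedigree_tsv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the per-generation cap bounds the tree and keeps sibling pairs intact", {
  ped <- simulate_pedigree(prc1_params(1), 10, cap = 64, seed = 1)
  expect_true(all(table(ped$generation) <= 64))
  kids <- table(ped$parent_id)
  expect_true(all(kids == 2))  # both daughters of a propagated parent retained
  expect_error(simulate_pedigree(prc1_params(1), 30, max_nodes = 2^20), "cap")
})

test_that("zero-noise pedigree matches the deterministic maps to 1e-12", {
  p0 <- zero_noise_params(1)
  set.seed(21)
  x0s <- stats::runif(100, 5e4, 3e5)
  rec <- sample_cycle(x0s, p0)
  det <- phi_psi(x0s, prc1_params(1))
  expect_lt(max(abs(rec$X2 - det$X2) / det$X2), 1e-12)
  expect_lt(max(abs((rec$T1 + rec$T2) - det$T) / det$T), 1e-12)
})

test_that("trajectories sample the piecewise-exponential kinetics on the grid", {
  p0 <- zero_noise_params(1)
  ped <- simulate_pedigree(p0, 1, seed = 1, ancestor_x0 = 1e5)
  traj <- pedigree_to_trajectories(ped[1, ], dt = 0.1)
  ref <- oracle_cycle_ds1(1e5)
  expect_equal(traj$value[1], 1e5)  # first sample at birth, exact
  expect_lt(abs(min(traj$value) / ref$X1 - 1), 0.01)
  # grid spacing constant to 1e-9 relative
  expect_lt(max(abs(diff(traj$time) - 0.1)), 1e-9 * 0.1)
  expect_true(all(is.finite(traj$value) & traj$value > 0))
})

test_that("a cell with negligible decay has a flat degradation phase", {
  p <- toy_params()
  p$regression$b1 <- -20  # a ~ 2e-9
  ped <- simulate_pedigree(p, 1, seed = 1, ancestor_x0 = 100)
  cell <- ped[1, ]
  traj <- pedigree_to_trajectories(cell, dt = cell$T1 / 10)
  deg <- traj$value[traj$time - cell$birth_time <= cell$T1]
  expect_true(all(abs(deg / 100 - 1) < 1e-6))
})

test_that("the last sample equals X2 exactly when the grid hits division time", {
  # durations chosen so T1 + T2 is an exact multiple of dt
  ped <- tibble::tibble(cell_id = 1L, parent_id = NA_integer_,
                        generation = 0L, birth_time = 0,
                        X0 = 100, T1 = 1, T2 = 2, a = log(10), b = log(20) / 2)
  ped$X1 <- ped$X0 * exp(-ped$a * ped$T1)
  ped$X2 <- ped$X1 * exp(ped$b * ped$T2)
  ped$division_time <- 3
  traj <- pedigree_to_trajectories(ped, dt = 0.5)
  expect_identical(tail(traj$value, 1), ped$X2)
  # a cycle shorter than dt is emitted with one sample and flagged
  ped2 <- ped; ped2$T1 <- 0.1; ped2$T2 <- 0.2; ped2$division_time <- 0.3
  expect_warning(traj2 <- pedigree_to_trajectories(ped2, dt = 0.5), "shorter")
  expect_equal(nrow(traj2), 1)
  expect_identical(attr(traj2, "short_cycle"), 1L)
})

test_that("lineage series follows one coherent root-to-leaf path", {
  ped <- simulate_pedigree(prc1_params(1), 6, seed = 2)
  ls1 <- lineage_series(ped, seed = 4)
  expect_equal(nrow(ls1), 7)
  expect_equal(ls1$generation, 0:6)
  # inherited amount is a fraction of the parent's division amount on the path
  for (i in 2:nrow(ls1)) {
    u <- ls1$X0[i] / ls1$X2[i - 1]
    expect_true(u > 0 && u < 1)
    node <- ped[ped$cell_id == ls1$cell_id[i], ]
    expect_equal(ls1$X0[i], node$U * ls1$X2[i - 1])
  }
  expect_identical(lineage_series(ped, seed = 4), ls1)
  single <- lineage_series(ped[1, ], seed = 1)
  expect_equal(nrow(single), 1)
})

test_that("newick export is a valid tree with cycle-duration branch lengths", {
  skip_if_not_installed("ape")
  ped <- simulate_pedigree(prc1_params(1), 3, seed = 8)
  tr <- ape::read.tree(text = pedigree_to_newick(ped))
  expect_equal(ape::Ntip(tr), 8)
  expect_equal(sort(tr$edge.length),
               sort((ped$T1 + ped$T2)[ped$generation > 0]),
               tolerance = 1e-9)
})

test_that("cycle-duration distribution is stationary in late generations", {
  p <- prc1_params(1)
  ok <- vapply(1:10, function(s) {
    ped <- simulate_pedigree(p, 14, cap = 512, seed = s)
    t10 <- with(ped[ped$generation == 10, ], T1 + T2)
    t14 <- with(ped[ped$generation == 14, ], T1 + T2)
    suppressWarnings(stats::ks.test(t10, t14)$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(ok), 8)
})

test_that("post-burn-in statistics are insensitive to the ancestor amount", {
  p <- prc1_params(1)
  cvs <- vapply(c(0.5, 1, 2), function(f) {
    ped <- simulate_pedigree(p, 12, cap = 512, seed = 31,
                             ancestor_x0 = f * 1.46e5)
    late <- ped[ped$generation >= 10, ]
    sd(late$T1 + late$T2) / mean(late$T1 + late$T2)
  }, numeric(1))
  expect_lt(max(cvs) - min(cvs), 0.05)
})
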