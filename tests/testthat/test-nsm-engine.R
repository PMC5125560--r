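test_that("trajectories are deterministic given seeds", {
  w <- make_empty_world()
  r <- default_parameters()
  a <- simulate_cell(w$lattice, w$chromatin, w$crowders, r, 50,
                     t_end = 50, seed = 5)
  b <- simulate_cell(w$lattice, w$chromatin, w$crowders, r, 50,
                     t_end = 50, seed = 5)
  expect_identical(a$M, b$M)
  expect_identical(a$tf_voxel, b$tf_voxel)
  expect_identical(a$switch_log, b$switch_log)

  e1 <- run_ensemble(w$lattice, w$chromatin, r, 50, n_cells = 2,
                     base_seed = 3, t_end = 20)
  e2 <- run_ensemble(w$lattice, w$chromatin, r, 50, n_cells = 2,
                     base_seed = 3, t_end = 20)
  expect_identical(lapply(e1, `[[`, "M"), lapply(e2, `[[`, "M"))
})

test_that("no production path means no mRNA", {
  w <- make_empty_world()
  r <- rate_constants(k_on = 0, s_R = 0)
  tr <- simulate_cell(w$lattice, w$chromatin, w$crowders, r, 30,
                      t_end = 200, seed = 2)
  expect_true(all(tr$M == 0))
  expect_equal(nrow(tr$switch_log), 0L)
})

test_that("conservation and series invariants hold", {
  w <- make_chromatin_world(dims = c(6L, 6L, 3L), seed = 4)
  cr <- place_crowders(w$lattice, crowding_config(0.5, "big", seed = 8))
  tr <- simulate_cell(w$lattice, w$chromatin, cr, default_parameters(),
                      w$gene_voxel, t_end = 300, seed = 13)
  expect_true(all(tr$M >= 0) && all(tr$P >= 0))
  n <- length(tr$time)
  expect_true(all(lengths(list(tr$M, tr$P, tr$promoter, tr$tf_voxel)) == n))
  lg <- tr$switch_log
  if (nrow(lg) > 1) expect_true(all(diff(lg$time) > 0))
  expect_true(all(lg$time >= 0 & lg$time <= tr$t_end))
  # promoter active exactly when TF is bound (TF shown at the gene voxel)
  expect_true(all(tr$tf_voxel[tr$promoter == 1] == w$gene_voxel))
})

test_that("the TF never occupies a fully blocked voxel", {
  lat <- build_lattice(c(5, 5, 1))
  # blocked ring of c = 1 voxels inside the domain
  intens <- rep(0.2, lat$N)
  blocked <- c(7, 8, 9, 12, 14)
  intens[blocked] <- 1
  ch <- normalize_chromatin(intens / max(intens), lat)
  tr <- simulate_cell(lat, ch, empty_crowders(lat), default_parameters(),
                      gene_voxel = 13, t_end = 200, seed = 21,
                      tf_start = 13)
  expect_false(any(tr$tf_voxel %in% blocked))

  chg <- normalize_chromatin(replace(rep(0.5, lat$N), 13, 1), lat)
  expect_error(simulate_cell(lat, chg, empty_crowders(lat),
                             default_parameters(), 13, t_end = 10, seed = 1),
               "blocked")
})

test_that("immobile TF at the gene reproduces two-state switching", {
  # D_TF = 0, TF at the gene voxel: t_off ~ Exp(k_on N), t_on ~ Exp(k_off)
  lat <- build_lattice(c(2, 2, 2))
  r <- rate_constants(D_TF = 0, s_A = 0, s_R = 0, s_P = 0)
  tr <- simulate_cell(lat, empty_chromatin(lat), empty_crowders(lat), r,
                      gene_voxel = 1, t_end = 4000, sample_dt = 4000,
                      seed = 31, tf_start = 1)
  dur <- switch_durations(tr)
  expect_gt(length(dur$on), 150)
  kon_eff <- 0.1 * lat$N
  expect_gt(ks.test(dur$off, pexp, kon_eff)$p.value, 0.01)
  expect_gt(ks.test(dur$on, pexp, 0.1)$p.value, 0.01)
})

test_that("clamped-active spatial runs reach the active steady state", {
  w <- make_empty_world()
  r <- rate_constants(k_off = 0, s_P = 0)
  endM <- vapply(1:60, function(i) {
    tr <- simulate_cell(w$lattice, w$chromatin, w$crowders, r, 40,
                        t_end = 100, sample_dt = 100, seed = 700 + i,
                        initial_bound = TRUE)
    tr$M[length(tr$M)]
  }, integer(1))
  expect_lt(abs(mean(endM) - 500), 3 * sqrt(500 / 60))
})

test_that("diffusion_step honours blocked voxels, boundaries and anisotropy", {
  # corner of a cubic-voxel lattice: 3 equally likely directions
  lat <- build_lattice(c(4, 4, 4))
  ch <- empty_chromatin(lat)
  cr <- empty_crowders(lat)
  set.seed(1)
  dests <- replicate(900, diffusion_step(lat, ch, cr, 10, 1))
  tab <- table(dests)
  expect_setequal(names(tab), c("2", "5", "17"))
  expect_true(all(abs(tab - 300) < 4 * sqrt(900 * (1 / 3) * (2 / 3))))

  # blocked neighbour is never entered
  chb <- normalize_chromatin(replace(rep(0.5, lat$N), 2, 1), lat)
  set.seed(2)
  d2 <- replicate(300, diffusion_step(lat, chb, cr, 10, 1))
  expect_false(any(d2 == 2))

  # anisotropic mesh: z hops are rarer by (hx/hz)^2
  lata <- build_lattice(c(50, 50, 11))
  expect_equal(jump_rate(lata, empty_chromatin(lata), empty_crowders(lata),
                         10, 2, "x") /
               jump_rate(lata, empty_chromatin(lata), empty_crowders(lata),
                         10, 2, "z"),
               (1 / 0.02^2) / (121))
  # all-blocked neighbourhood: TF stays put
  lat1 <- build_lattice(c(3, 1, 1))
  chw <- normalize_chromatin(c(1, 0.5, 1), lat1)
  expect_equal(diffusion_step(lat1, chw, empty_crowders(lat1), 10, 2), 2L)
})

test_that("uncrowded ensembles are self-consistent across base seeds", {
  w <- make_empty_world()
  r <- rate_constants(s_P = 0)
  endM <- function(bs) endpoint_M(
    run_ensemble(w$lattice, w$chromatin, r, 50, theta = 0, n_cells = 100,
                 base_seed = bs, t_end = 300, sample_dt = 300))
  ks <- suppressWarnings(ks.test(endM(1), endM(2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("several uncrowded trajectories switch within the run", {
  w <- make_empty_world()
  ens <- run_ensemble(w$lattice, w$chromatin, default_parameters(), 50,
                      theta = 0, n_cells = 20, base_seed = 5, t_end = 300,
                      sample_dt = 300)
  n_sw <- vapply(ens, n_transitions, integer(1))
  expect_gt(sum(n_sw >= 1), 15)
})

test_that("crowding reduces resolution-limited switching (big crowders)", {
  # Event-exact switch statistics are invariant under the uniform slowdown
  # theta = 0 -> 1 (time dilation of the walk only), but crowding clusters
  # switching into sub-minute rebinding flickers, so transitions counted at
  # the 1-min sampling resolution drop.
  w <- make_chromatin_world(dims = c(6L, 6L, 3L), seed = 2)
  r <- default_parameters()
  count <- function(theta) {
    ens <- run_ensemble(w$lattice, w$chromatin, r, w$gene_voxel,
                        theta = theta, size_class = "big", n_cells = 100,
                        base_seed = 17, t_end = 1000, sample_dt = 1000)
    vapply(ens, n_transitions, integer(1), resolution = 1)
  }
  n0 <- count(0)
  n1 <- count(1)
  expect_gt(mean(n0), mean(n1))
  expect_lt(t.test(n0, n1)$p.value, 0.01)
})
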