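test_that("transfer matrices validate their structural invariants", {
  expect_error(transfer_matrix(data.frame(src = 1, dst = 1, fraction = 0.5)),
               "self-transfers")
  expect_error(transfer_matrix(data.frame(src = 1, dst = 2, fraction = 1.5)),
               "fractions")
  expect_error(transfer_matrix(data.frame(src = c(1, 1), dst = c(2, 2),
                                          fraction = c(0.3, 0.3))),
               "duplicate")
  expect_error(transfer_matrix(data.frame(src = 1, dst = c(2, 3, 4),
                                          fraction = c(0.5, 0.4, 0.3))),
               "sum to")
  # the row-sum error names the offending well
  expect_error(transfer_matrix(data.frame(src = 13, dst = c(2, 3),
                                          fraction = c(0.9, 0.6)), 8, 12),
               "B1")
})

test_that("diffusion kernels send rate/4 per von-Neumann neighbour", {
  expect_equal(nrow(make_diffusion_kernel(8, 12, 0)), 0)
  m <- make_diffusion_kernel(8, 12, 0.2, "bounded")
  ctr <- well_to_index("D6", 8, 12)           # interior well
  e <- m[m$src == ctr, ]
  expect_equal(nrow(e), 4)
  expect_equal(e$fraction, rep(0.05, 4))
  expect_setequal(e$dst, well_to_index(c("C6", "E6", "D5", "D7"), 8, 12))
  # corner: bounded keeps the missing shares, unbounded sends them to SINK
  corner <- well_to_index("A1", 8, 12)
  eb <- m[m$src == corner, ]
  expect_equal(nrow(eb), 2)
  expect_equal(sum(eb$fraction), 0.1)
  mu <- make_diffusion_kernel(8, 12, 0.2, "unbounded")
  eu <- mu[mu$src == corner, ]
  expect_equal(sum(is.na(eu$dst)), 2)
  expect_equal(sum(eu$fraction), 0.2)
  expect_error(make_diffusion_kernel(8, 12, 1.2), "rate")
  # Moore variant spreads over 8 neighbours
  mm <- make_diffusion_kernel(8, 12, 0.2, neighborhood = "moore")
  expect_equal(nrow(mm[mm$src == ctr, ]), 8)
  expect_equal(sum(mm[mm$src == ctr, ]$fraction), 0.2)
})

test_that("barriers attenuate exactly the crossing entries", {
  m <- make_diffusion_kernel(8, 12, 0.2)
  b1 <- barrier_spec(row_cut_edges(4, class = "high"),
                     attenuation = c(high = 1))
  expect_equal(as.data.frame(apply_barriers(m, b1)), as.data.frame(m))
  bh <- barrier_spec(row_cut_edges(4, class = "medium"))
  mh <- apply_barriers(m, bh)
  cut <- row_cut_edges(4)
  # halved on the cut, bit-identical elsewhere
  joined <- merge(as.data.frame(m), as.data.frame(mh),
                  by = c("src", "dst"), suffixes = c("_0", "_1"))
  crossing_j <- paste(joined$src, joined$dst) %in%
    c(paste(cut$a, cut$b), paste(cut$b, cut$a))
  expect_true(all(joined$fraction_1[crossing_j] ==
                    0.5 * joined$fraction_0[crossing_j]))
  expect_true(all(joined$fraction_1[!crossing_j] ==
                    joined$fraction_0[!crossing_j]))
  expect_error(apply_barriers(m, barrier_spec(
    data.frame(a = 1, b = 2, class = "nope"))), "unknown barrier class")
})

test_that("a full high-barrier row cut makes the far side unreachable", {
  m <- make_diffusion_kernel(8, 12, 0.4)
  cut <- barrier_spec(row_cut_edges(4), attenuation = c(high = 0))
  mc <- apply_barriers(m, cut)
  st <- plate_state(8, 12, 100)
  st$concentration[well_to_index("B3", 8, 12)] <- 1   # seed above the cut
  ps <- point_spread(st, mc, 25)
  below <- index_to_well(which(rep(1:8, each = 12) > 4), 8, 12)
  expect_equal(sum(ps$concentration[ps$well %in% below]), 0)
  # barrier attenuation never increases any entry
  expect_true(all(mc$fraction <= m$fraction[match(paste(mc$src, mc$dst),
                                                  paste(m$src, m$dst))]))
})

test_that("apply_transfer_matrix follows ideal-mixing arithmetic", {
  st <- plate_state(1, 2, volume_ul = 100, concentration = c(1, 0))
  m <- transfer_matrix(data.frame(src = 1, dst = 2, fraction = 0.5), 1, 2)
  out <- apply_transfer_matrix(st, m)
  expect_equal(out$volume_ul, c(50, 150))
  expect_equal(out$concentration, c(1, 1 / 3))
  empty <- transfer_matrix(NULL, 1, 2)
  expect_equal(as.data.frame(apply_transfer_matrix(st, empty)),
               as.data.frame(st))
})

test_that("bounded transfers conserve tracer and match a dense reference", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    m <- random_bounded_matrix(3, 4)
    st <- random_plate_state(3, 4)
    out <- apply_transfer_matrix(st, m)
    worst <- max(worst, abs(total_tracer(out) - total_tracer(st)))
  }
  expect_lt(worst, 1e-9)
  # dense brute-force oracle on fresh random 12-well instances
  set.seed(203)
  for (i in 1:50) {
    m <- random_bounded_matrix(3, 4)
    st <- random_plate_state(3, 4)
    out <- apply_transfer_matrix(st, m)
    ref <- dense_transfer_reference(st, m)
    expect_equal(out$volume_ul, ref$volume_ul, tolerance = 1e-12)
    expect_equal(out$concentration, ref$concentration, tolerance = 1e-12)
  }
})

test_that("transfers are linear in tracer amounts and scale with volumes", {
  set.seed(7)
  m <- random_bounded_matrix(3, 4)
  vol <- runif(12, 50, 150)
  a <- plate_state(3, 4, vol, runif(12, 0, 2))
  b <- plate_state(3, 4, vol, runif(12, 0, 2))
  ab <- plate_state(3, 4, vol, a$concentration + b$concentration)
  out_a <- apply_transfer_matrix(a, m); out_b <- apply_transfer_matrix(b, m)
  out_ab <- apply_transfer_matrix(ab, m)
  expect_equal(out_ab$volume_ul * out_ab$concentration,
               out_a$volume_ul * out_a$concentration +
                 out_b$volume_ul * out_b$concentration, tolerance = 1e-12)
  # fraction-of-initial semantics: scaling volumes scales moved volumes
  s1 <- compile_transfers(a, m)
  a3 <- a; a3$volume_ul <- 3 * a$volume_ul
  s3 <- compile_transfers(a3, m)
  expect_equal(s3$volume_uL, 3 * s1$volume_uL, tolerance = 1e-12)
})

test_that("compiled steps reproduce the matrix application exactly", {
  m <- make_diffusion_kernel(8, 12, 0.3, "unbounded")
  st <- plate_state(8, 12, 120)
  st$concentration[well_to_index("D6", 8, 12)] <- 2
  steps <- compile_transfers(st, m)
  expect_equal(nrow(steps), nrow(m))   # all volumes under tip capacity
  out_direct <- apply_transfer_matrix(st, m)
  out_steps <- interpret_transfers(st, steps)
  expect_equal(out_steps$volume_ul, out_direct$volume_ul, tolerance = 1e-12)
  expect_equal(out_steps$concentration, out_direct$concentration,
               tolerance = 1e-12)
  # execution order cannot change the outcome under snapshot semantics
  shuffled <- steps[sample(nrow(steps)), ]
  out_shuf <- interpret_transfers(st, shuffled)
  expect_equal(out_shuf$volume_ul, out_direct$volume_ul, tolerance = 1e-12)
})

test_that("oversized transfers split at tip capacity; empty ones warn", {
  st <- plate_state(1, 2, volume_ul = c(3000, 100))
  m <- transfer_matrix(data.frame(src = 1, dst = 2, fraction = 0.5), 1, 2)
  steps <- compile_transfers(st, m, max_tip_ul = 1000)
  expect_equal(nrow(steps), 2)
  expect_equal(sum(steps$volume_uL), 1500)
  expect_true(all(steps$volume_uL <= 1000))
  st0 <- plate_state(1, 2, volume_ul = c(0, 100))
  expect_warning(s0 <- compile_transfers(st0, m), "zero-volume")
  expect_equal(nrow(s0), 0)
})

test_that("point spread keeps symmetry under a symmetric kernel and seed", {
  m <- make_diffusion_kernel(7, 7, 0.3, "bounded")
  st <- plate_state(7, 7, 100)
  st$concentration[well_to_index("D4", 7, 7)] <- 1   # centre of 7x7
  ps <- point_spread(st, m, 8)
  for (it in unique(ps$iteration)) {
    conc <- matrix(ps$concentration[ps$iteration == it], 7, 7, byrow = TRUE)
    expect_equal(conc, conc[7:1, ], tolerance = 1e-12)  # vertical flip
    expect_equal(conc, conc[, 7:1], tolerance = 1e-12)  # horizontal flip
    expect_equal(conc, t(conc), tolerance = 1e-12)      # diagonal
  }
  # bounded: conserved; unbounded: non-increasing
  tot <- tapply(ps$volume_ul * ps$concentration, ps$iteration, sum)
  expect_equal(as.numeric(diff(tot)), rep(0, 8), tolerance = 1e-9)
  mu <- make_diffusion_kernel(7, 7, 0.3, "unbounded")
  psu <- point_spread(st, mu, 8)
  totu <- tapply(psu$volume_ul * psu$concentration, psu$iteration, sum)
  expect_true(all(diff(totu) <= 1e-12))
  expect_lt(totu[9], totu[1])
  # zero iterations returns only the initial state
  ps0 <- point_spread(st, m, 0)
  expect_equal(unique(ps0$iteration), 0L)
})
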