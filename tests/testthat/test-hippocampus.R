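# Small, fast configuration for unit tests (not the acceptance profile).
tiny_cfg <- function(...) {
  hippocampal_config("test", T_c = 3, N_cycle = 2, N_equi = 1, N_mem = 5,
                     lesion_day = 1, ...)
}

test_that("configuration enforces its invariants", {
  cfg <- hippocampal_config("test")
  expect_equal(cfg$D, cfg$dT)
  expect_equal(cfg$w_max, 1 / cfg$N)
  expect_equal(cfg$w_init_max, cfg$w_max / 10)
  expect_equal(cfg$am_ca1, -1.00025 * cfg$ap_ca1)
  expect_equal(cfg$ap_sub, 0.5 * cfg$ap_ca1)
  expect_error(hippocampal_config("test", N = 60), "perfect square")
})

test_that("grid-cell rates hit r_max at the cell's phase and are periodic", {
  cfg <- hippocampal_config("test")
  cb <- make_codebook(cfg, seed = 2)
  # rate at the cell's own phase equals r_max
  for (i in c(1, 17, 64)) {
    r <- ppcons:::cpp_grid_rates(cb$m, cb$theta, cb$px, cb$py, cb$r_max,
                                 cb$px[i], cb$py[i])
    expect_equal(r[i], 10, tolerance = 1e-10)
  }
  # all rates within [0, r_max]
  p <- sample_positions_2d(50, seed = 3)
  for (k in 1:50) {
    r <- ec_grid_rate(cb, p[k, ])
    expect_true(all(r >= -1e-10 & r <= 10 + 1e-10))
  }
  # translating by a lattice vector leaves the rate unchanged
  i <- 5
  ang <- (1:2) * pi / 3 + cb$theta[i]
  K <- rbind(c(cos(ang[1]), sin(ang[1])), c(cos(ang[2]), sin(ang[2])))
  a <- solve(cb$m[i] * K, 2 * pi * c(1, 1))   # k_1.a = k_2.a = 2 pi / m
  p0 <- c(0.3, 0.4)
  r0 <- ppcons:::cpp_grid_rates(cb$m, cb$theta, cb$px, cb$py, cb$r_max,
                                p0[1], p0[2])[i]
  r1 <- ppcons:::cpp_grid_rates(cb$m, cb$theta, cb$px, cb$py, cb$r_max,
                                p0[1] + a[1], p0[2] + a[2])[i]
  expect_equal(r1, r0, tolerance = 1e-8)
  # out-of-arena positions are rejected
  expect_error(ec_grid_rate(cb, c(1.2, 0.5)), "0,1")
})

test_that("place-cell rates follow the Gaussian profile", {
  cfg <- hippocampal_config("test")
  cb <- make_codebook(cfg, seed = 2)
  r <- ca3_place_rate(cb, c(cb$cx[10], cb$cy[10]))
  expect_equal(r[10], 10, tolerance = 1e-12)
  # rate at distance sigma is r_max * exp(-1/2)
  r_s <- ca3_place_rate(cb, c(cb$cx[10] + cfg$sigma, cb$cy[10]))
  expect_equal(r_s[10], 10 * exp(-0.5), tolerance = 1e-10)
  # monotone decay with distance
  d <- seq(0, 0.4, by = 0.05)
  rr <- vapply(d, function(dd)
    ca3_place_rate(cb, c(min(cb$cx[10] + dd, 1), cb$cy[10]))[10],
    numeric(1))
  expect_true(all(diff(rr) <= 1e-12))
})

test_that("the forward pass is the documented linear map", {
  cfg <- tiny_cfg()
  cb <- make_codebook(cfg, seed = 4)
  st <- hippocampal_state(cfg, cb, seed = 4)
  x_ec <- c(ec_grid_rate(cb, c(0.3, 0.7)), cb$ec_obj[, 2])
  x_ca3 <- c(ca3_place_rate(cb, c(0.3, 0.7)), cb$ca3_obj[, 2])
  # zero input gives zero output; doubling input doubles output
  z <- forward_pass(st, numeric(128), numeric(128))
  expect_equal(z$y_ca1, numeric(128))
  expect_equal(z$y_sub, numeric(128))
  y1 <- forward_pass(st, x_ec, x_ca3)
  y2 <- forward_pass(st, 2 * x_ec, 2 * x_ca3)
  expect_equal(y2$y_ca1, 2 * y1$y_ca1)
  # with the shortcut zeroed, CA1 is driven by the SC alone
  st0 <- st; st0$W_ca1[] <- 0
  y0 <- forward_pass(st0, x_ec, x_ca3)
  expect_equal(y0$y_ca1, drop(t(st$V_sc) %*% x_ca3))
  expect_error(forward_pass(st, x_ec[-1], x_ca3), "length")
})

test_that("imprinting touches only the object-to-place block", {
  cfg <- tiny_cfg()
  cb <- make_codebook(cfg, seed = 5)
  st <- hippocampal_state(cfg, cb, seed = 5)
  N <- cfg$N
  pl <- 1:N; obj <- N + 1:N
  st2 <- imprint_association(st, cb, object = 1, p = c(0.25, 0.75))
  # identity and zero blocks bit-identical
  expect_identical(st2$V_sc[pl, pl], st$V_sc[pl, pl])
  expect_identical(st2$V_sc[obj, obj], st$V_sc[obj, obj])
  expect_identical(st2$V_sc[pl, obj], st$V_sc[pl, obj])
  # largest column sum of the updated block is 1
  expect_equal(max(colSums(st2$V_sc[obj, pl])), 1)
  # lambda -> 1 limit equals the normalized outer product alone
  st_l <- imprint_association(st, cb, object = 1, p = c(0.25, 0.75),
                              lambda = 1 - 1e-12)
  x_ec <- c(ec_grid_rate(cb, c(0.25, 0.75)), cb$ec_obj[, 1])
  x_ca3 <- c(ca3_place_rate(cb, c(0.25, 0.75)), cb$ca3_obj[, 1])
  y <- forward_pass(st, x_ec, x_ca3)$y_ca1[pl]
  op <- cb$ca3_obj[, 1] %o% y
  expect_equal(st_l$V_sc[obj, pl], op / max(colSums(op)), tolerance = 1e-6)
  expect_error(imprint_association(st, cb, 1, c(0.5, 0.5), lambda = 1),
               "lambda")
})

test_that("interference makes older SC memories weaker than newer ones", {
  # all associations in one environment (no remapping): strongest
  # interference, and every memory is decodable against the same templates
  cfg <- hippocampal_config("test")
  target_mass <- function(seed) {
    cb <- make_codebook(cfg, seed = seed)
    st <- hippocampal_state(cfg, cb, seed = seed)
    ps <- sample_positions_2d(12, seed = seed + 100)
    for (j in 1:12) {
      st <- imprint_association(st, cb, object = j, p = ps[j, ])
    }
    one <- function(obj, p) {
      post <- ppcons:::decode_pathway(st, cb, obj, "SC")
      q <- quadrant_of(post$cx, post$cy)
      sum(post$prob[q == quadrant_of(p[1], p[2])])
    }
    c(oldest = one(1, ps[1, ]), newest = one(12, ps[12, ]))
  }
  m <- rowMeans(sapply(1:5, target_mass))
  expect_lt(m["oldest"], m["newest"])
})

test_that("the decoder is a normalized Gaussian-likelihood posterior", {
  cfg <- hippocampal_config("test")
  cb <- make_codebook(cfg, seed = 6)
  # decoding an exact template puts the mode at that cell
  y <- ca3_place_rate(cb, c(cb$cx[30], cb$cy[30]))
  post <- decode_place(y, cb, cfg$sigma_noise)
  expect_equal(which.max(post$prob), 30)
  expect_equal(sum(post$prob), 1)
  expect_true(all(post$prob >= 0))
  # zero variance -> uniform with a warning
  expect_warning(p0 <- decode_place(rep(2, cfg$N), cb), "uniform")
  expect_equal(p0$prob, rep(1 / cfg$N, cfg$N))
  # very large noise -> nearly flat posterior
  pf <- decode_place(y, cb, sigma_noise = 1e4)
  expect_lt(max(pf$prob) / min(pf$prob), 1.001)
})

test_that("quadrant occupancy mixes exploration with the posterior", {
  cfg <- hippocampal_config("test")
  cb <- make_codebook(cfg, seed = 7)
  uni <- structure(list(prob = rep(1 / cfg$N, cfg$N), cx = cb$cx,
                        cy = cb$cy), class = "posterior_map")
  occ <- quadrant_occupancy(list(SC = uni))
  expect_equal(occ$occupancy, rep(0.25, 4))
  # all mass in the target quadrant: 0.7 * 0.25 + 0.3 = 47.5%
  conc <- uni
  conc$prob <- as.numeric(quadrant_of(cb$cx, cb$cy) == 1)
  conc$prob <- conc$prob / sum(conc$prob)
  occ2 <- quadrant_occupancy(list(SC = conc))
  expect_equal(occ2$occupancy[1], 0.475)
  expect_equal(sum(occ2$occupancy), 1)
  # ties go to the later-consolidating pathway
  occ3 <- quadrant_occupancy(list(SC = uni, PP_CA1 = uni, PP_SUB = uni))
  expect_equal(occ3$pathway, "PP_SUB")
})

test_that("quadrants use the half-open lower/left convention", {
  expect_equal(quadrant_of(c(0.2, 0.7, 0.2, 0.7, 0.5),
                           c(0.2, 0.2, 0.7, 0.7, 0.5)),
               c(1L, 2L, 3L, 4L, 1L))
})

test_that("lesioning zeroes the shortcut and freezes its plasticity", {
  cfg <- tiny_cfg()
  cb <- make_codebook(cfg, seed = 8)
  st <- hippocampal_state(cfg, cb, seed = 8)
  st <- lesion_pp_ca1(st)
  expect_true(all(st$W_ca1 == 0))
  x_ec <- c(ec_grid_rate(cb, c(0.5, 0.5)), cb$ec_obj[, 1])
  # CA1 from EC alone is zero after the lesion
  expect_equal(forward_pass(st, x_ec, numeric(128))$y_ca1, numeric(128))
  st <- consolidation_phase(st, cb, seed = 1)
  expect_true(all(st$W_ca1 == 0))
})

test_that("consolidation respects bounds, blocks and the zero-rate case", {
  cfg <- tiny_cfg()
  cb <- make_codebook(cfg, seed = 9)
  st <- hippocampal_state(cfg, cb, seed = 9)
  V_sc_before <- st$V_sc; V_cs_before <- st$V_cs
  st2 <- consolidation_phase(st, cb, seed = 2)
  expect_true(all(st2$W_ca1 >= 0 & st2$W_ca1 <= cfg$w_max + 1e-15))
  expect_true(all(st2$W_sub >= 0 & st2$W_sub <= cfg$w_max + 1e-15))
  expect_false(identical(st2$W_ca1, st$W_ca1))
  # the V matrices are untouched by nights
  expect_identical(st2$V_sc, V_sc_before)
  expect_identical(st2$V_cs, V_cs_before)
  # zero amplitudes freeze the weights
  cfg0 <- tiny_cfg()
  cfg0$ap_ca1 <- 0; cfg0$am_ca1 <- 0; cfg0$ap_sub <- 0; cfg0$am_sub <- 0
  st0 <- hippocampal_state(cfg0, cb, seed = 9)
  st0$config <- cfg0
  st0b <- consolidation_phase(st0, cb, seed = 2)
  expect_identical(st0b$W_ca1, st0$W_ca1)
  expect_identical(st0b$W_sub, st0$W_sub)
})

test_that("one night of consolidation makes the shortcut decodable", {
  cfg <- hippocampal_config("test")
  gain <- sapply(1:4, function(seed) {
    cb <- make_codebook(cfg, seed = seed)
    st <- hippocampal_state(cfg, cb, seed = seed)
    st <- imprint_association(st, cb, object = 2, p = c(0.25, 0.25))
    before <- ppcons:::decode_pathway(st, cb, 2, "PP_CA1")
    st <- consolidation_phase(st, cb, seed = seed)
    after <- ppcons:::decode_pathway(st, cb, 2, "PP_CA1")
    q <- quadrant_of(before$cx, before$cy)
    c(before = sum(before$prob[q == 1]), after = sum(after$prob[q == 1]),
      mode_ok = unname(q[which.max(after$prob)] == 1))
  })
  # without consolidation the shortcut sits at chance; one night transfers
  # the association (posterior mode lands in the correct quadrant)
  expect_lt(mean(gain["before", ]), 0.45)
  expect_gt(mean(gain["after", ]), mean(gain["before", ]) + 0.2)
  expect_gte(mean(gain["mode_ok", ]), 0.75)
})

test_that("watermaze runs are deterministic and well-formed", {
  cfg <- tiny_cfg()
  r1 <- run_watermaze(cfg, schedule = "control", seed = 5)
  r2 <- run_watermaze(cfg, schedule = "control", seed = 5)
  expect_identical(r1$probes, r2$probes)
  expect_identical(r1$occupancy, r2$occupancy)
  # occupancies sum to one per day
  sums <- tapply(r1$occupancy$occupancy, r1$occupancy$day, sum)
  expect_equal(as.numeric(sums), rep(1, cfg$N_cycle), tolerance = 1e-12)
  # lesion-before keeps the shortcut silent
  rl <- run_watermaze(cfg, schedule = "lesion-before", seed = 5)
  expect_true(all(rl$probes$target_prob[rl$probes$pathway == "PP_CA1"]
                  == 0.25))
  # days_to_chance returns one value per pathway
  expect_named(days_to_chance(r1), c("PP_CA1", "PP_SUB", "SC"))
})
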