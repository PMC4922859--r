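test_that("the homogeneous state is a fixed point and runs are deterministic", {
  m <- kinetic_model(ai_jacobian())
  still <- simulate_rd(m, D = c(1, 20), L = 50, nx = 50, t_end = 10,
                       noise = 0, seed = 1)
  expect_true(all(still$fields == 0))
  a <- simulate_rd(m, D = c(1, 20), L = 50, nx = 50, t_end = 5,
                   noise = 1e-3, seed = 7)
  b <- simulate_rd(m, D = c(1, 20), L = 50, nx = 50, t_end = 5,
                   noise = 1e-3, seed = 7)
  expect_identical(a$fields, b$fields)
  c <- simulate_rd(m, D = c(1, 20), L = 50, nx = 50, t_end = 5,
                   noise = 1e-3, seed = 8)
  expect_false(identical(a$fields, c$fields))
})

test_that("the CFL bound is enforced with a suggestion", {
  m <- kinetic_model(ai_jacobian())
  expect_error(simulate_rd(m, D = c(1, 20), L = 50, nx = 100, dt = 1,
                           t_end = 5), "CFL")
})

test_that("Turing-unstable systems pattern and stable ones decay", {
  m <- kinetic_model(ai_jacobian())
  sim <- simulate_rd(m, D = c(1, 20), L = 100, nx = 200, t_end = 60,
                     noise = 1e-3, seed = 4)
  expect_gt(stats::sd(sim$fields[, 1]), 0.01)
  expect_true(all(abs(sim$fields) <= m$saturation + 1e-12))
  decay <- simulate_rd(m, D = c(1, 1), L = 100, nx = 100, t_end = 60,
                       noise = 1e-3, seed = 4)
  expect_lt(max(abs(decay$fields)), 1e-6)
})

test_that("dominant wavenumber matches linear wavelength selection", {
  # self-test: an injected cosine is recovered at its exact bin
  m <- kinetic_model(ai_jacobian())
  probe <- simulate_rd(m, D = c(1, 20), L = 100, nx = 200, t_end = 0.1,
                       noise = 0, seed = 1)
  probe$fields[, 1] <- cos(2 * pi * 7 * seq(0, 1, length.out = 200))
  q7 <- dominant_wavenumber(probe, node = 1)
  expect_equal(as.numeric(q7), 2 * pi * 7 / 100, tolerance = 1e-9)
  # constant field: no peak
  flat <- simulate_rd(m, D = c(1, 20), L = 100, nx = 100, t_end = 0.1,
                      noise = 0, seed = 1)
  expect_true(is.na(dominant_wavenumber(flat)))
  # the patterned run peaks within one spectral bin of the dispersion argmax
  sim <- simulate_rd(m, D = c(1, 20), L = 100, nx = 200, t_end = 20,
                     noise = 1e-3, seed = 4)
  q <- dominant_wavenumber(sim)
  q_star <- dispersion(ai_jacobian(), c(1, 20))$q_star
  expect_lt(abs(q - q_star), attr(q, "bin_width") + 1e-12)
})

test_that("early mode growth matches the linear growth rate", {
  J <- ai_jacobian()
  d <- dispersion(J, c(1, 20))
  m <- kinetic_model(J)
  amp_at <- function(t_end) {
    sim <- simulate_rd(m, D = c(1, 20), L = 100, nx = 200, t_end = t_end,
                       noise = 1e-6, seed = 5)
    f <- sim$fields[, 1]
    bin <- round(d$q_star * sim$L / (2 * pi))
    Mod(stats::fft(f - mean(f)))[bin + 1]
  }
  growth <- log(amp_at(20) / amp_at(10)) / 10
  expect_equal(growth, d$max_growth, tolerance = 0.1)
})

test_that("simulated phases match the eigenvector prediction", {
  m_ai <- kinetic_model(ai_jacobian())
  sim_ai <- simulate_rd(m_ai, D = c(1, 20), L = 100, nx = 200, t_end = 60,
                        noise = 1e-3, seed = 4)
  chk <- phase_check(sim_ai, phase_pattern(rd_system(ai_jacobian(),
                                                     c(1, 20))))
  expect_true(chk$consistent)
  expect_gt(chk$correlation[1, 2], 0) # in-phase
  expect_identical(unname(chk$correlation[1, 1]), 1) # self-correlation
  m_sd <- kinetic_model(sd_jacobian())
  sim_sd <- simulate_rd(m_sd, D = c(1, 20), L = 100, nx = 200, t_end = 60,
                        noise = 1e-3, seed = 4)
  chk_sd <- phase_check(sim_sd, phase_pattern(rd_system(sd_jacobian(),
                                                        c(1, 20))))
  expect_true(chk_sd$consistent)
  expect_lt(chk_sd$correlation[1, 2], 0) # out-of-phase
})

test_that("2D simulation patterns with bounded fields", {
  m <- kinetic_model(ai_jacobian())
  sim <- simulate_rd(m, D = c(1, 20), L = 60, nx = 48, t_end = 40,
                     noise = 1e-3, seed = 9, dims = 2)
  expect_identical(dim(sim$fields), c(48L, 48L, 2L))
  expect_gt(stats::sd(sim$fields[, , 1]), 1e-3)
  expect_true(all(abs(sim$fields) <= m$saturation + 1e-12))
  chk <- phase_check(sim)
  expect_gt(chk$correlation[1, 2], 0)
})

test_that("simulations export as text with a reproducible sidecar", {
  m <- kinetic_model(ai_jacobian(), labels = c("act", "inh"))
  sim <- simulate_rd(m, D = c(1, 20), L = 50, nx = 40, t_end = 5,
                     noise = 1e-3, seed = 2)
  dir <- tempfile("simout")
  paths <- write_simulation(sim, dir, stem = "run")
  expect_true(all(file.exists(paths)))
  f1 <- as.matrix(read.table(file.path(dir, "run_act.tsv")))
  expect_equal(unname(f1[, 1]), sim$fields[, 1])
  meta <- jsonlite::read_json(file.path(dir, "run_meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 2)
  expect_equal(meta$dt, sim$dt)
})
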