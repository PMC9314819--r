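test_that("drawdown ratio zeta matches direct arithmetic and its limit", {
  expect_equal(zeta(420, 400), 21)
  expect_equal(zeta(500, 450), 10)
  expect_equal(zeta(300, 0), 1)  # all CO2 consumed
  expect_error(zeta(400, 400), "degenerate")
})

test_that("observed discrimination reproduces arithmetic oracle and limits", {
  expect_equal(observed_discrimination(-6, -8, 10), 20000 / 974,
               tolerance = 1e-12)
  expect_equal(observed_discrimination(-8, -8, 10), 0)
  # small-signal limit: Do ~ zeta * (da - de)
  expect_equal(observed_discrimination(-7.999, -8, 500),
               500 * 0.001, tolerance = 0.01)
  expect_error(observed_discrimination(30, -40, 20), "denominator")
})

test_that("combined diffusional fractionation interpolates between ab and a", {
  expect_equal(combined_fractionation(400, 400, 280), 4.4)  # no boundary layer
  expect_equal(combined_fractionation(400, 280, 280), 2.9)  # no stomatal term
  expect_equal(combined_fractionation(400, 380, 280), 4.15)
  expect_error(combined_fractionation(400, 400, 400), "no diffusion gradient")
})

test_that("ternary correction is linear in E and zero without transpiration", {
  expect_equal(ternary_t(4.4, 0, 0.25), 0)
  expect_equal(ternary_t(4.4, 0.002, 0.25), 1.0044 * 0.002 / 0.5,
               tolerance = 1e-12)
  expect_equal(ternary_t(5, 0.004, 0.3), 2 * ternary_t(5, 0.002, 0.3))
  expect_error(ternary_t(4.4, 0.002, 0), "g_act")
})

test_that("predicted discrimination spans its diffusion and carboxylation limits", {
  expect_equal(predicted_discrimination(0, 4.4, 400, 400), 29)
  expect_equal(predicted_discrimination(0, 4.4, 0, 400), 4.4)
  expect_equal(predicted_discrimination(0.004, 4.15, 280, 400), 21.71305,
               tolerance = 1e-5)
  expect_error(predicted_discrimination(1, 4.4, 280, 400), "t must be < 1")
})

test_that("predicted discrimination is a convex-combination between a' and (1+t)b/(1-t)", {
  set.seed(1)
  for (i in 1:50) {
    t <- runif(1, 0, 0.01)
    ap <- runif(1, 2.9, 4.4)
    ci_ca <- runif(1)
    di <- predicted_discrimination(t, ap, ci_ca * 400, 400)
    expect_gte(di, ap - 1e-9)
    expect_lte(di, (1 + t) * 29 / (1 - t) + 1e-9)
  }
})

test_that("respiratory and photorespiratory components behave at their zeros", {
  rec <- list(d13Ce = -8, d13Catm = -8, Rd = 1.5, An = 14, Ca = 400,
              Ci = 280, GammaStar = 40)
  nr <- nonrubisco_discriminations(0, rec)
  expect_equal(nr$e, 0)
  expect_equal(nr$delta_e, 0)
  rec$d13Ce <- -35
  nr2 <- nonrubisco_discriminations(0, rec)
  expect_equal(nr2$delta_f, 11.6 * 40 / 400)
  rec$Ci <- 40  # Ci at the photocompensation point
  expect_equal(nonrubisco_discriminations(0, rec)$delta_e, 0)
  rec$An <- -1.5
  expect_error(nonrubisco_discriminations(0, rec), "An \\+ Rd")
})

test_that("gm estimation inverts the forward model exactly at zero noise", {
  p <- isotope_sim_params(gm = 0.12, noise_sd = 0, n = 1)
  rec <- as.list(generate_isotope_records(p)[1, ])
  rec$E <- rec$E_mmol / 1000
  res <- estimate_gm(rec)
  expect_lt(abs(res$gm - 0.12) / 0.12, 1e-10)
  expect_lt(abs(res$Cc - (rec$Ci - rec$An / 0.12)), 1e-6)
  # component identity holds to machine precision
  expect_equal(res$delta_gm,
               res$delta_i - res$delta_o - res$delta_e - res$delta_f)
  expect_identical(res$flag, "ok")
})

test_that("zero residual drawdown is flagged unresolvable, not negative", {
  p <- isotope_sim_params(gm = 0.12, noise_sd = 0, n = 1)
  rec <- as.list(generate_isotope_records(p)[1, ])
  rec$E <- rec$E_mmol / 1000
  clean <- estimate_gm(rec)
  # solve for the d13Ca that makes observed = Di - De - Df (gm -> infinity),
  # then push observed slightly beyond it
  target <- clean$delta_i - clean$delta_e - clean$delta_f
  z <- clean$zeta
  rec$d13Ca <- (1000 * target + z * rec$d13Ce * (target + 1000)) /
    (z * (target + 1000) - target) + 0.5
  res <- estimate_gm(rec)
  expect_identical(res$flag, "gm_unresolvable")
  expect_true(is.na(res$gm))
})

test_that("larger observed discrimination gives larger estimated gm", {
  p <- isotope_sim_params(gm = 0.12, noise_sd = 0, n = 1)
  base <- as.list(generate_isotope_records(p)[1, ])
  base$E <- base$E_mmol / 1000
  gms <- vapply(c(0, 0.05, 0.1, 0.15), function(bump) {
    r <- base
    r$d13Ca <- r$d13Ca + bump  # enrich cuvette air -> larger Do
    estimate_gm(r)$gm
  }, numeric(1))
  expect_true(all(diff(gms) > 0))
})

test_that("chloroplast CO2 follows the flux-gradient relation", {
  expect_equal(chloroplast_co2(280, 14, 0.14), 180)
  expect_equal(chloroplast_co2(280, 0, 0.1), 280)
  expect_equal(chloroplast_co2(280, 14, 1e9), 280, tolerance = 1e-6)
  expect_error(chloroplast_co2(280, 14, 0), "gm")
})

test_that("batch estimation matches single-record results and CSV round trips", {
  p <- isotope_sim_params(gm = 0.15, noise_sd = 0.2, n = 8, seed = 3)
  rec <- generate_isotope_records(p)
  out <- estimate_gm_batch(rec)
  expect_equal(nrow(out), 8)
  r1 <- as.list(rec[1, ])
  r1$E <- r1$E_mmol / 1000
  expect_equal(out$gm[1], estimate_gm(r1)$gm)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(rec, csv, row.names = FALSE)
  rec2 <- read_isotope_records(csv)
  expect_equal(rec2$d13Ca, rec$d13Ca)
  unlink(csv)
  expect_error(read_isotope_records({
    f <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(An = 1), f, row.names = FALSE)
    f
  }), "missing columns")
})

test_that("bracketing reference averaging pairs each plant sample with its neighbors", {
  # sequence: R P R P R
  d13 <- c(-35.0, -20.0, -35.2, -21.0, -35.4)
  is_ref <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  out <- average_bracketing_refs(d13, is_ref)
  expect_equal(unname(out), c(mean(c(-35.0, -35.2)), mean(c(-35.2, -35.4))))
  # plant sample at the sequence end falls back to its single neighbor
  out2 <- average_bracketing_refs(c(-35, -20, -21), c(TRUE, FALSE, FALSE))
  expect_equal(unname(out2), c(-35, -35))
  expect_error(average_bracketing_refs(c(-20), c(FALSE)), "no reference")
})
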