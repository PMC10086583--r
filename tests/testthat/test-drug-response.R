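test_that("viability normalisation divides by the control mean", {
  expect_equal(normalize_viability(100, c(90, 110)), 1.0)
  expect_equal(normalize_viability(0, 100), 0.0)
  expect_equal(normalize_viability(c(50, 100), c(100, 100)), c(0.5, 1.0))
  expect_error(normalize_viability(1, 0), "control")
  expect_error(normalize_viability(1, numeric(0)), "control")
})

test_that("the 4PL fit recovers noiseless parameters within 1%", {
  d <- 1e-6 * 10^seq(-1.5, 1.5, length.out = 6)
  truth <- list(bottom = 0.05, top = 0.98, ic50 = 1e-6, hill = 1.3)
  y <- truth$bottom + (truth$top - truth$bottom) / (1 + (d / truth$ic50)^truth$hill)
  f <- fit_4pl(d, y)
  expect_true(f$converged)
  for (p in names(truth))
    expect_lt(abs(f[[p]] - truth[[p]]) / abs(truth[[p]]), 0.01)
  # 4PL identity: y at x = ic50 is (top + bottom) / 2
  expect_equal(predict_4pl(f, f$ic50), (f$top + f$bottom) / 2, tolerance = 1e-9)
})

test_that("flat responses are flagged non-convergent with a usable fallback", {
  d <- 1e-6 * 10^seq(-2, 2, length.out = 6)
  f <- fit_4pl(d, rep(1, 6))
  expect_false(f$converged)
  expect_equal(predict_4pl(f, d), rep(1, 6), tolerance = 1e-9)
  expect_error(fit_4pl(d[1:3], c(1, 0.5, 0)), "4 distinct")
  expect_error(fit_4pl(c(-1, d[1:5]), rep(0.5, 6)), "positive")
})

test_that("log-dose AUC is the span-normalised trapezoid of viability", {
  expect_equal(auc_dose_response(c(1e-9, 1e-8, 1e-7), c(1, 1, 1)), 1)
  expect_equal(auc_dose_response(c(1e-9, 1e-8, 1e-7), c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(auc_dose_response(10^seq(-9, -6), c(1, 2 / 3, 1 / 3, 0)), 0.5)
  expect_error(auc_dose_response(1e-6, 1), "2 distinct")
})

test_that("reference-model expectations match their formulas", {
  # grids whose monotherapies are exactly y1 = y2 = 0.5 at dose 1
  v <- matrix(1, 3, 3)
  v[2, 1] <- v[3, 1] <- 0.5   # drug1 alone
  v[1, 2] <- v[1, 3] <- 0.5   # drug2 alone
  v[2:3, 2:3] <- 0.25         # combination observed (Bliss expectation)
  m <- dose_matrix(c(0, 1, 2), c(0, 1, 2), v)
  Eb <- expected_inhibition(m, "bliss")
  expect_equal(Eb[2, 2], 0.75)
  expect_equal(synergy_score(m, "bliss"), 0, tolerance = 1e-9)

  v2 <- v
  v2[2:3, 1] <- 0.7; v2[1, 2:3] <- 0.4  # y1 = 0.3, y2 = 0.6
  m2 <- dose_matrix(c(0, 1, 2), c(0, 1, 2), v2)
  Eh <- expected_inhibition(m2, "hsa")
  expect_equal(Eh[2, 2], 0.6)
})

test_that("Loewe additivity gives E = 0.5 for identical drugs at half dose", {
  D <- 1e-6
  doses <- c(D / 8, D / 4, D / 2, D, 2 * D, 4 * D)
  sim <- simulate_dose_matrix("loewe",
                              pars1 = list(bottom = 0, top = 1, ic50 = D, hill = 1),
                              pars2 = list(bottom = 0, top = 1, ic50 = D, hill = 1),
                              d1 = doses, d2 = doses, noise_sd = 0, seed = 1)
  E <- expected_inhibition(sim$matrix, "loewe")
  i <- which(sim$matrix$d1 == D / 2)
  expect_equal(E[i, i], 0.5, tolerance = 1e-6)
  expect_equal(synergy_score(sim$matrix, "loewe"), 0, tolerance = 1e-3)
})

test_that("synergy scores are 100 x the mean observed-minus-expected excess", {
  # moderate monotherapy effects keep expectation + 0.1 below 1
  y1 <- c(0, 0.15, 0.3); y2 <- c(0, 0.2, 0.4)
  bliss <- outer(y1, y2, function(a, b) a + b - a * b)
  m <- dose_matrix(c(0, 1, 2), c(0, 1, 2), 1 - bliss)
  E <- expected_inhibition(m, "bliss")
  combo <- !is.na(E)
  up <- m
  up$inhibition[combo] <- E[combo] + 0.1
  expect_equal(synergy_score(up, "bliss"), 10, tolerance = 1e-9)
  down <- m
  down$inhibition[combo] <- E[combo] - 0.05
  expect_equal(synergy_score(down, "bliss"), -5, tolerance = 1e-9)
})

test_that("HSA expectation never exceeds Bliss (max(a,b) <= a+b-ab)", {
  set.seed(15)
  for (i in 1:10) {
    sim <- simulate_dose_matrix(sample(c("bliss", "hsa"), 1),
                                noise_sd = 0.05, seed = i)
    Eh <- expected_inhibition(sim$matrix, "hsa")
    Eb <- expected_inhibition(sim$matrix, "bliss")
    ok <- !is.na(Eh)
    expect_true(all(Eh[ok] <= Eb[ok] + 1e-12))
  }
})

test_that("each reference model scores near zero on its own null", {
  for (model in c("bliss", "hsa", "loewe", "zip")) {
    scores <- vapply(1:8, function(s)
      synergy_score(simulate_dose_matrix(model, noise_sd = 0.02, seed = s)$matrix,
                    model), numeric(1))
    expect_lt(abs(mean(scores)), 1.5)
  }
  # exact nulls without noise
  expect_equal(synergy_score(simulate_dose_matrix("bliss", noise_sd = 0,
                                                  seed = 1)$matrix, "bliss"), 0,
               tolerance = 1e-9)
  hsa0 <- simulate_dose_matrix("hsa", noise_sd = 0, seed = 1)$matrix
  expect_equal(synergy_score(hsa0, "hsa"), 0, tolerance = 1e-9)
  expect_lte(synergy_score(hsa0, "bliss"), 1e-9)
})
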