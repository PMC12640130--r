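tdf <- tdf_default(treat_phe_conservative = FALSE)

test_that("mix_base returns the convex combination of source means", {
  expect_equal(mix_base(c(1, 0, 0), rbind(c(4.2, 9.9, 13.1))), 4.2)
  expect_equal(mix_base(c(0.5, 0.5), rbind(c(2, 4))), 3)
  expect_equal(mix_base(c(0.25, 0.25, 0.5), rbind(c(0, 4, 10))), 6)
  # several tracers at once
  m <- rbind(Phe = c(0, 4), Thr = c(-5, -10))
  expect_equal(mix_base(c(0.5, 0.5), m), c(Phe = 2, Thr = -7.5))
  expect_error(mix_base(c(0.6, 0.6), rbind(c(1, 2))), "sum to 1")
  expect_error(mix_base(c(1.2, -0.2), rbind(c(1, 2))), "sum to 1")
})

test_that("plug-in trophic estimates divide enrichment by the TDF", {
  pro <- tdf_lookup(tdf, "Pro")
  ala <- tdf_lookup(tdf, "Ala")
  glx <- tdf_lookup(tdf, "Glx")
  expect_equal(food_web_length(10, 10, pro), 0)
  expect_equal(food_web_length(12.6, 0, ala), 2)
  expect_equal(food_web_length(5.8, 0, pro), 1)
  expect_equal(metazoan_steps(16, 0, glx), 2)
  expect_equal(metazoan_steps(4, 0, glx), 0.5)
  expect_equal(metazoan_steps(10, 10, glx), 0)
  # class and zero-TDF guards
  expect_error(food_web_length(1, 0, glx), "constant")
  expect_error(metazoan_steps(1, 0, pro), "variable")
  zero <- list(class = "constant", delta_meta = 0)
  expect_error(food_web_length(1, 0, zero), "zero")
})

test_that("trophic uncertainty follows the printed relative-error form", {
  expect_equal(trophic_uncertainty(2, 20, 0, 6.3, 0), 0)
  expect_equal(trophic_uncertainty(2, 20, 0.5, 6.3, 2.6),
               2 * sqrt((0.5 / 20)^2 + (2.6 / 6.3)^2))
  # proportional in mu
  s1 <- trophic_uncertainty(1, 15, 0.4, 8, 1.7)
  s2 <- trophic_uncertainty(2, 15, 0.4, 8, 1.7)
  expect_equal(s2, 2 * s1)
  # degenerate denominators are named
  expect_error(trophic_uncertainty(1, 0, 0.5, 6.3, 1), "consumer tracer value")
  expect_error(trophic_uncertainty(1, 10, 0.5, 0, 1), "discrimination factor")
  expect_warning(trophic_uncertainty(1, 0.5, 0.1, 6.3, 1), "1 per mil")
})

test_that("discrimination classes map to their process equations", {
  st <- food_web_state(f = c(0.5, 0.5), FWL = 2, MTS = 1)
  expect_equal(st$PTS, 1)
  phe <- tdf_lookup(tdf_default(), "Phe")
  pro <- tdf_lookup(tdf, "Pro")
  glx <- tdf_lookup(tdf, "Glx")
  expect_equal(apply_discrimination(7.3, st, phe), 7.3)
  expect_equal(apply_discrimination(5, st, pro), 5 + 2 * 5.8)
  expect_equal(apply_discrimination(0, st, glx), 0.5 + 8)
})

test_that("consumer SD combines analytical and TDF uncertainty in quadrature", {
  st <- food_web_state(c(1), FWL = 2, MTS = 1)
  phe <- tdf_lookup(tdf_default(), "Phe")
  glx <- tdf_lookup(tdf, "Glx")
  expect_equal(consumer_sd(0.4, st, phe), 0.4)
  expect_equal(consumer_sd(0.5, st, glx), sqrt(0.25 + 1 * 1.0^2 + 1 * 1.7^2))
  # monotone in every trophic argument
  base <- consumer_sd(0.5, st, glx)
  st2 <- food_web_state(c(1), FWL = 3, MTS = 1.5)
  expect_gt(consumer_sd(0.5, st2, glx), base)
  expect_gt(consumer_sd(0.9, st, glx), base)
  expect_error(consumer_sd(0, st, glx))
})

test_that("class equations reduce into one another exactly", {
  st <- food_web_state(c(0.3, 0.7), FWL = 1.7, MTS = 0.9)
  # variable with delta_proto = delta_meta reduces to the constant form
  v_eq <- list(class = "variable", delta_meta = 5.8, delta_proto = 5.8,
               sd_meta = 1.7, sd_proto = 1.7)
  c_eq <- list(class = "constant", delta_meta = 5.8, sd_meta = 1.7)
  expect_equal(apply_discrimination(3, st, v_eq), apply_discrimination(3, st, c_eq),
               tolerance = 1e-12)
  # constant with delta = 0 reduces to the conservative identity
  c0 <- list(class = "constant", delta_meta = 0, sd_meta = 0)
  expect_equal(apply_discrimination(3, st, c0), 3, tolerance = 1e-12)
  # but the SD quadratures do NOT coincide: splitting FWL into PTS + MTS
  # inside the quadrature gives a strictly smaller total
  sd_v <- consumer_sd(0.5, st, v_eq)
  sd_c <- consumer_sd(0.5, st, c_eq)
  expect_lt(sd_v, sd_c)
})

test_that("forward model composes mixing and discrimination, affine in f", {
  means <- rbind(Phe = c(0, 4, 10), Thr = c(-5, -14, -7),
                 Pro = c(4, 8, 12), Glx = c(4, 9, 13))
  tab <- do.call(rbind, lapply(rownames(means), function(a) tdf_lookup(tdf, a)))

  # zero trophic steps: prediction is pure mixing for every class
  f <- c(0.2, 0.3, 0.5)
  expect_equal(forward_model(f, 0, 0, means, tab), mix_base(f, means),
               tolerance = 1e-12)

  # single source: source mean plus discrimination offsets
  y <- forward_model(c(1, 0, 0), PTS = 1, MTS = 1, means, tab)
  expect_equal(y[["Glx"]], 4 + 0.5 + 8)
  expect_equal(y[["Pro"]], 4 + 2 * 5.8)

  # composition identity against the components
  st <- food_web_state(f, FWL = 2.1, MTS = 1.3)
  manual <- vapply(rownames(means), function(a)
    apply_discrimination(mix_base(f, means[a, , drop = FALSE]), st,
                         tdf_lookup(tdf, a)), numeric(1))
  expect_equal(forward_model(f, st$PTS, st$MTS, means, tab), manual,
               tolerance = 1e-12)

  # affinity: pred(lambda a + (1-lambda) b) = lambda pred(a) + (1-lambda) pred(b)
  a <- c(0.6, 0.3, 0.1); b <- c(0.1, 0.2, 0.7); lam <- 0.37
  lhs <- forward_model(lam * a + (1 - lam) * b, 0.4, 1.2, means, tab)
  rhs <- lam * forward_model(a, 0.4, 1.2, means, tab) +
    (1 - lam) * forward_model(b, 0.4, 1.2, means, tab)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("analytic error propagation matches Monte-Carlo in the stable regime", {
  set.seed(101)
  # trophic quotient, zero base: |delta| > 5 sd(delta), |TDF| > 3 sd(TDF)
  mu <- 20 / 6.3
  analytic <- trophic_uncertainty(mu, 20, 0.5, 6.3, 1.7)
  mc <- mc_quotient_sd(20, 0.5, 6.3, 1.7, base = 0)
  expect_lt(abs(analytic - mc) / mc, 0.05)

  mu2 <- 16 / 8
  analytic2 <- trophic_uncertainty(mu2, 16, 0.5, 8, 1.7)
  mc2 <- mc_quotient_sd(16, 0.5, 8, 1.7, base = 0)
  expect_lt(abs(analytic2 - mc2) / mc2, 0.05)

  # consumer SD, constant class
  st <- food_web_state(c(1), FWL = 2, MTS = 1.2)
  cst <- list(class = "constant", delta_meta = 5.8, sd_meta = 1.7)
  expect_lt(abs(consumer_sd(0.5, st, cst) -
                  mc_consumer_sd(0.5, FWL = 2, s_meta = 1.7)) /
              consumer_sd(0.5, st, cst), 0.05)

  # consumer SD, variable class
  vr <- list(class = "variable", delta_meta = 8, sd_meta = 1.7,
             delta_proto = 0.5, sd_proto = 1.0)
  expect_lt(abs(consumer_sd(0.5, st, vr) -
                  mc_consumer_sd(0.5, PTS = st$PTS, MTS = st$MTS,
                                 s_proto = 1.0, s_meta = 1.7)) /
              consumer_sd(0.5, st, vr), 0.05)

  # fidelity check: with a large non-zero base the printed relative-error
  # form (which divides by the absolute consumer value, not the enrichment)
  # deliberately departs from full Monte-Carlo propagation
  mu3 <- (25 - 20) / 6.3
  analytic3 <- trophic_uncertainty(mu3, 25, 0.5, 6.3, 1.7)
  mc3 <- mc_quotient_sd(25, 0.5, 6.3, 1.7, base = 20)
  expect_gt(abs(analytic3 - mc3) / mc3, 0.05)
})
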