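# Synthetic feeding-study compilation with a known group structure.
make_experiments <- function(n_meta = 12, n_proto = 4, seed = 71,
                             glx_meta = 8, glx_proto = 0.5,
                             ala_all = 6.3, sd = 1.2) {
  set.seed(seed)
  n <- n_meta + n_proto
  data.frame(
    species = sprintf("sp%02d", seq_len(n)),
    group = c(rep("metazoa", n_meta), rep("protozoa", n_proto)),
    habitat = "marine", excretion = "ammonia", tp = 2.5, diet = "algae",
    Glx = c(rnorm(n_meta, glx_meta, sd), rnorm(n_proto, glx_proto, 0.6)),
    Ala = rnorm(n, ala_all, sd),
    Thr = c(rnorm(n_meta, -5.9, 1.5), rnorm(n_proto, -2, 0.6)),
    stringsAsFactors = FALSE
  )
}

test_that("aggregate_tdfs averages experiments per subset, skipping NAs", {
  exps <- make_experiments()
  all <- aggregate_tdfs(exps, "all")
  expect_setequal(all$aa, c("Glx", "Ala", "Thr"))
  expect_equal(all$n[all$aa == "Glx"], nrow(exps))
  expect_equal(all$mean[all$aa == "Ala"], mean(exps$Ala))
  expect_equal(all$sd[all$aa == "Ala"], sd(exps$Ala))

  meta <- aggregate_tdfs(exps, "metazoa")
  expect_equal(meta$mean[meta$aa == "Glx"],
               mean(exps$Glx[exps$group == "metazoa"]))

  # missing values are skipped, not propagated
  exps$Thr[1:3] <- NA
  all2 <- aggregate_tdfs(exps, "all")
  expect_equal(all2$n[all2$aa == "Thr"], nrow(exps) - 3)

  # a duplicated single experiment has SD zero
  dup <- exps[c(1, 1), ]
  agg <- suppressWarnings(aggregate_tdfs(dup, "all"))
  expect_equal(agg$sd[agg$aa == "Glx"], 0)

  # empty subset: omitted with a warning per amino acid
  noproto <- exps[exps$group == "metazoa", ]
  w <- capture_warnings(res <- aggregate_tdfs(noproto, "protozoa"))
  expect_true(all(grepl("fewer than 2", w)))
  expect_length(w, 3)
  expect_null(res)
})

test_that("compare_groups is the Welch two-sample t-test", {
  exps <- make_experiments()
  p_pkg <- compare_groups(exps, "Glx")
  # hand-rolled Welch computation on the same values
  a <- exps$Glx[exps$group == "protozoa"]
  b <- exps$Glx[exps$group == "metazoa"]
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  df <- (var(a) / length(a) + var(b) / length(b))^2 /
    ((var(a) / length(a))^2 / (length(a) - 1) +
       (var(b) / length(b))^2 / (length(b) - 1))
  p_hand <- 2 * pt(-abs(tstat), df)
  expect_equal(p_pkg, p_hand, tolerance = 1e-12)

  # identical groups: p = 1
  same <- exps
  same$Glx <- rep(c(1, 2, 3, 4), length.out = nrow(same))
  same$Glx[same$group == "protozoa"] <- c(1, 2, 3, 4)
  same$Glx[same$group == "metazoa"] <- rep(c(1, 2, 3, 4), 3)
  expect_equal(compare_groups(same, "Glx"), 1, tolerance = 1e-9)

  # strongly separated groups are detected
  expect_lt(p_pkg, 0.01)
  expect_error(compare_groups(exps[exps$group == "metazoa", ], "Glx"),
               "at least 2")
})

test_that("classify_tracer applies the significance thresholds", {
  expect_equal(classify_tracer(0.97), "constant")   # e.g. Ala
  expect_equal(classify_tracer(0.02), "variable")   # e.g. Thr
  expect_equal(classify_tracer(0.08), "marginal")   # e.g. Ile
  expect_equal(classify_tracer(0.002), "variable")  # e.g. Glx
  expect_equal(classify_tracer(0.21), "constant")
  expect_error(classify_tracer(1.5))
})

test_that("declarative filters drop the documented experiment classes", {
  exps <- make_experiments()
  exps$excretion[1] <- "urea"
  exps$tp[2] <- 4
  exps$species[3] <- "Acanthopagrus butcheri"
  exps$diet[3] <- "vegetable meal"
  out <- suppressMessages(filter_experiments(exps))
  expect_equal(nrow(out), nrow(exps) - 3)
  log <- attr(out, "filter_log")
  expect_equal(sum(log$removed), 3)
  expect_setequal(log$rule, c("aquatic_ammonia", "tp_at_most_3",
                              "drop_vegetable_meal_bream"))
})

# Synthetic field dataset: delta15N_AA-Phe generated from a known slope
# against delta15N_ref-Phe plus a location offset.
make_field_data <- function(n = 60, slope = 0.7, seed = 5, noise = 0.4) {
  set.seed(seed)
  loc <- sample(c("siteA", "siteB"), n, replace = TRUE)
  phe <- rnorm(n, 2, 1)
  glx_phe <- runif(n, 2, 18)              # TP proxy spread
  thr_phe <- slope * glx_phe + ifelse(loc == "siteB", 1.5, 0) +
    rnorm(n, 0, noise)
  data.frame(location = loc, Phe = phe, Glx = glx_phe + phe,
             Thr = thr_phe + phe, stringsAsFactors = FALSE)
}

test_that("regression_tdf recovers a known generative slope and TDF", {
  d <- make_field_data(slope = 0.7)
  fit <- regression_tdf(d, "Thr", reference = "Glx", tdf_ref = 8,
                        delta_phe = 0.3, sd_tdf_ref = 1.7, sd_delta_phe = 0.5)
  expect_lt(abs(fit$slope - 0.7), 3 * fit$slope_se)
  expect_equal(fit$delta, fit$slope * 8 + 0.3, tolerance = 1e-12)
  # derived TDF close to 0.7 * 8 + 0.3 = 5.9 within its propagated SD
  expect_lt(abs(fit$delta - 5.9), 2 * fit$sd)
  expect_gt(fit$r_squared, 0.9)

  # slope 0: TDF reduces to the Phe TDF
  d0 <- make_field_data(slope = 0, seed = 6)
  fit0 <- regression_tdf(d0, "Thr", reference = "Glx", tdf_ref = 8,
                         delta_phe = 0.3)
  expect_lt(abs(fit0$delta - 0.3), 3 * fit0$sd + 0.2)

  expect_error(regression_tdf(d[1:5, ], "Thr", reference = "Glx",
                              tdf_ref = 8, delta_phe = 0.3),
               "at least 10")
})

test_that("regression slope estimates are unbiased over replications", {
  slopes <- ses <- numeric(100)
  for (r in 1:100) {
    d <- make_field_data(n = 40, slope = 0.7, seed = 1000 + r)
    fit <- regression_tdf(d, "Thr", reference = "Glx", tdf_ref = 8,
                          delta_phe = 0.3)
    slopes[r] <- fit$slope
    ses[r] <- fit$slope_se
  }
  bias <- mean(slopes) - 0.7
  expect_lt(abs(bias), 2 * mean(ses))
})
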