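small_mcmc <- function(seed = 2, chains = 2) {
  mcmc_config(chains = chains, adapt = 500, burn_in = 1000,
              samples = 2000, thin = 2, seed = seed)
}

test_that("model structure follows the configuration", {
  src <- tiny_sources()
  con <- tiny_consumer(src)
  m <- build_model(src, con)
  # one Dirichlet per consumer, trophic latents, mixing likelihood terms
  expect_match(m$code, "ddirch")
  expect_match(m$code, "FWL\\[k\\] ~ dnorm")
  expect_match(m$code, "MTS\\[k\\] ~ dnorm")
  expect_equal(m$data$Nmix, 3)
  expect_equal(sort(m$monitors),
               sort(c("mu_src", "sigma_src", "f", "mu_base", "FWL", "MTS", "PTS")))

  # non-fractionating variant: no trophic nodes, no discrimination terms
  cfgn <- omsm_config(nonfractionating = TRUE)
  conn <- tiny_consumer(src, f = c(0.7, 0.3), PTS = 0, MTS = 0, config = cfgn)
  # with Thr dropped only two tracers remain for two sources
  expect_warning(mn <- build_model(src, conn, cfgn), "n_sources \\+ 1")
  expect_false(grepl("FWL", mn$code))
  expect_false(grepl("dproto", mn$code))
  expect_false("Thr" %in% mn$tracers$aa)

  # truncation flag adds T(0,) to the trophic normals
  cfgt <- omsm_config(truncate_trophic = TRUE)
  mt <- build_model(src, con, cfgt)
  expect_match(mt$code, "T\\(0, \\)")
})

test_that("fixed seeds reproduce draws exactly", {
  src <- tiny_sources()
  con <- tiny_consumer(src)
  m <- build_model(src, con)
  d1 <- quiet_fit(m, small_mcmc(seed = 9))
  d2 <- quiet_fit(m, small_mcmc(seed = 9))
  expect_identical(d1$mat, d2$mat)
  d3 <- quiet_fit(m, small_mcmc(seed = 10))
  expect_false(identical(d1$mat, d3$mat))
})

test_that("draw-wise identities hold for every retained draw", {
  src <- tiny_sources()
  sim <- simulate_consumers(src, n = 2, config = omsm_config(),
                            pts_range = c(0, 1), mts_range = c(1, 2), seed = 31)
  m <- build_model(src, sim$consumers)
  d <- quiet_fit(m, small_mcmc(seed = 4))
  for (k in sim$consumers$ids) {
    fk <- d$mat[, d$meta$family == "f" & d$meta$consumer == k, drop = FALSE]
    expect_true(all(abs(rowSums(fk) - 1) < 1e-9))
    expect_true(all(fk >= 0))
    expect_equal(d$mat[, paste0("PTS[", k, "]")],
                 d$mat[, paste0("FWL[", k, "]")] - d$mat[, paste0("MTS[", k, "]")],
                 tolerance = 1e-8)
  }
  # two consumers share one set of source parameters
  expect_equal(sum(d$meta$family == "f"), 2 * 2)
  expect_equal(sum(d$meta$family == "mu_src"), 5 * 2)
})

test_that("prior-only sampling recovers the uniform Dirichlet marginals", {
  src <- simulate_sources(n_per_group = 4, seed = 8)
  sim <- simulate_consumers(src, n = 1, seed = 9)
  m <- build_model(src, sim$consumers, prior_only = TRUE)
  d <- quiet_fit(m, mcmc_config(chains = 2, adapt = 500, burn_in = 500,
                                samples = 5000, thin = 1, seed = 3))
  f <- d$mat[, d$meta$family == "f", drop = FALSE]
  expect_equal(ncol(f), 3)
  # Dirichlet(1,1,1): mean 1/3, sd sqrt(2/(9*4)) ~ 0.236
  mcse <- apply(f, 2, sd) / sqrt(nrow(f) / 10)  # conservative ESS guess
  expect_true(all(abs(colMeans(f) - 1 / 3) < pmax(3 * mcse, 0.02)))
  expect_lt(abs(mean(apply(f, 2, sd)) - sqrt(2 / 36)), 0.02)
})

test_that("source posteriors match the conjugate normal-model oracle", {
  set.seed(55)
  means <- rbind(Phe = c(A = 2), Lys = c(A = 3), Thr = c(A = -6),
                 Pro = c(A = 5), Glx = c(A = 6))
  src <- simulate_sources(means, n_per_group = 200, within_sd = 1, seed = 56)
  m <- build_model(src, NULL)   # source-only measurement model
  d <- quiet_fit(m, mcmc_config(chains = 2, adapt = 500, burn_in = 1000,
                                samples = 3000, thin = 1, seed = 6))
  xbar <- source_means(src)
  for (aa in c("Phe", "Glx")) {
    col <- paste0("mu_src[", aa, ",A]")
    draws <- d$mat[, col]
    ess <- max(d$diagnostics$ess[d$diagnostics$parameter == col], 50)
    mcse <- sd(draws) / sqrt(ess)
    # with vague priors the posterior of mu centres on the sample mean
    expect_lt(abs(mean(draws) - xbar[aa, "A"]), 2 * mcse + 1e-3)
    # posterior sd close to sd/sqrt(n)
    expect_equal(sd(draws), sd(src$data[[aa]]) / sqrt(200), tolerance = 0.25)
  }
})

test_that("MCMC posterior matches a dense-grid numerical posterior", {
  # two well-separated sources, sources fixed at their empirical means so the
  # posterior is exactly three-dimensional: (f1, FWL, MTS)
  src <- tiny_sources(n_per_group = 5, seed = 17, within_sd = 0.4)
  con <- tiny_consumer(src, f = c(0.7, 0.3), PTS = 0.5, MTS = 1)
  m <- build_model(src, con, fix_sources = TRUE)
  d <- quiet_fit(m, mcmc_config(chains = 2, adapt = 1000, burn_in = 2000,
                                samples = 5000, thin = 5, seed = 12))

  # independent oracle: direct numerical integration on a dense grid,
  # written out from the model equations (no package code in the density)
  mu <- source_means(src)                     # tracer x group
  Y <- con$values[, 1]; alpha <- 0.5
  tdfs <- omsm_config()$tracers               # Phe, Lys, Thr, Pro, Glx
  g <- expand.grid(f1 = seq(0.001, 0.999, length.out = 140),
                   FWL = seq(-0.5, 3.5, length.out = 90),
                   MTS = seq(-0.5, 2.5, length.out = 90))
  base <- function(aa) g$f1 * mu[aa, "A"] + (1 - g$f1) * mu[aa, "B"]
  muF <- (Y["Pro"] - base("Pro")) / 5.8
  sdF <- pmax(1e-6, abs(muF) * sqrt((alpha / Y["Pro"])^2 + (1.7 / 5.8)^2))
  muM <- (Y["Glx"] - base("Glx")) / 8
  sdM <- pmax(1e-6, abs(muM) * sqrt((alpha / Y["Glx"])^2 + (1.7 / 8)^2))
  lp <- dnorm(g$FWL, muF, sdF, log = TRUE) + dnorm(g$MTS, muM, sdM, log = TRUE)
  PTS <- g$FWL - g$MTS
  for (aa in c("Phe", "Lys", "Thr")) {
    row <- tdfs[tdfs$aa == aa, ]
    pred <- base(aa) + PTS * row$delta_proto + g$MTS * row$delta_meta
    sdp <- sqrt(alpha^2 + (PTS * row$sd_proto)^2 + (g$MTS * row$sd_meta)^2)
    lp <- lp + dnorm(Y[aa], pred, sdp, log = TRUE)
  }
  w <- exp(lp - max(lp))
  grid_mean_f1 <- sum(w * g$f1) / sum(w)
  grid_mean_fwl <- sum(w * g$FWL) / sum(w)

  expect_lt(abs(mean(d$mat[, "f[A,C1]"]) - grid_mean_f1), 0.05)
  expect_lt(abs(mean(d$mat[, "FWL[C1]"]) - grid_mean_fwl), 0.1)
})

test_that("log_posterior respects the support boundaries", {
  src <- tiny_sources()
  con <- tiny_consumer(src)
  m <- build_model(src, con)
  pt <- list(f = c(0.6, 0.4), FWL = 1.5, MTS = 1,
             mu_src = source_means(src), sigma_src = source_sds(src))
  base_lp <- log_posterior(pt, m)
  expect_true(is.finite(base_lp))

  bad <- pt; bad$f <- c(1.2, -0.2)
  expect_identical(log_posterior(bad, m), -Inf)
  bad <- pt; bad$sigma_src[1, 1] <- 0
  expect_identical(log_posterior(bad, m), -Inf)
  bad <- pt; bad$mu_src[1, 1] <- 250
  expect_identical(log_posterior(bad, m), -Inf)
})

test_that("log_posterior changes by the analytic amount when sigma doubles", {
  src <- tiny_sources()
  con <- tiny_consumer(src)
  m <- build_model(src, con)
  S <- source_sds(src)
  pt1 <- list(f = c(0.6, 0.4), FWL = 1.5, MTS = 1,
              mu_src = source_means(src), sigma_src = S)
  pt2 <- pt1; pt2$sigma_src <- 2 * S
  observed <- log_posterior(pt2, m) - log_posterior(pt1, m)

  # hand arithmetic: per cell, gamma(a,b) prior on tau = 1/sigma^2 with
  # jacobian 2/sigma^3, plus the normal likelihood over that group's data
  a <- 0.001; b <- 0.001
  expected <- 0
  mu <- source_means(src)
  for (j in rownames(mu)) for (gp in colnames(mu)) {
    s1 <- S[j, gp]; s2 <- 2 * s1
    t1 <- 1 / s1^2; t2 <- 1 / s2^2
    pr <- ((a - 1) * log(t2) - b * t2 + log(2 / s2^3)) -
      ((a - 1) * log(t1) - b * t1 + log(2 / s1^3))
    x <- src$data[src$data$group == gp, j]
    ss <- sum((x - mu[j, gp])^2)
    lik <- -length(x) * log(2) - ss / 2 * (1 / s2^2 - 1 / s1^2)
    expected <- expected + pr + lik
  }
  expect_equal(observed, expected, tolerance = 1e-8)
})

test_that("a polished mode of log_posterior is locally optimal", {
  src <- tiny_sources(seed = 17, within_sd = 0.4)
  con <- tiny_consumer(src, f = c(0.7, 0.3), PTS = 0.5, MTS = 1)
  m <- build_model(src, con, fix_sources = TRUE)
  obj <- function(th) -log_posterior(list(f = c(th[1], 1 - th[1]),
                                          FWL = th[2], MTS = th[3]), m)
  opt <- optim(c(0.5, 1.5, 1), obj, method = "L-BFGS-B",
               lower = c(1e-6, -5, -5), upper = c(1 - 1e-6, 5, 5))
  lp_opt <- -opt$value
  for (i in 1:3) {
    for (s in c(-1e-3, 1e-3)) {
      th <- opt$par; th[i] <- th[i] + s
      expect_lte(-obj(th), lp_opt + 1e-6)
    }
  }
})
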