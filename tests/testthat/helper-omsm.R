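# Shared fixtures and independent oracles, built in code at test time.

# Tiny two-source dataset with well-separated groups on every tracer.
tiny_sources <- function(n_per_group = 5, seed = 42, within_sd = 0.5) {
  means <- rbind(
    Phe = c(A = 0, B = 8),
    Lys = c(A = 1, B = 9),
    Thr = c(A = -5, B = -12),
    Pro = c(A = 4, B = 10),
    Glx = c(A = 5, B = 11)
  )
  simulate_sources(means, n_per_group = n_per_group, within_sd = within_sd,
                   seed = seed)
}

# One consumer generated exactly by the forward model (no noise).
tiny_consumer <- function(sources, f = c(0.7, 0.3), PTS = 0.5, MTS = 1,
                          config = omsm_config(), alpha = 0.5) {
  mu <- source_means(sources, config$tracers$aa)
  y <- forward_model(f, PTS, MTS, mu, config$tracers)
  df <- data.frame(sample_id = "C1", t(y), check.names = FALSE)
  omsm_consumers(df, default_alpha = alpha)
}

# Brute-force shortest-window HDI: the definition, written as an explicit
# loop so it shares no code with hdi().
hdi_brute <- function(x, level) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(level * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1)) {
    lo <- xs[i]
    hi <- xs[i + m - 1]
    if ((hi - lo) < (best[2] - best[1])) best <- c(lo, hi)
  }
  best
}

# Monte-Carlo error-propagation oracle for the trophic-quotient SD
# (numerator delta ~ N(delta0, s_delta), TDF ~ N(D0, s_D), base fixed).
# A ratio of normals has no finite variance (the denominator can approach
# zero), so the oracle measures the core spread robustly via the normalised
# interquartile range rather than the raw sample SD.
mc_quotient_sd <- function(delta0, s_delta, D0, s_D, base = 0, n = 1e5) {
  d <- stats::rnorm(n, delta0, s_delta)
  D <- stats::rnorm(n, D0, s_D)
  stats::IQR((d - base) / D) / (2 * stats::qnorm(0.75))
}

# Monte-Carlo oracle for the consumer-SD quadrature (independent normal
# noise contributions from analytical error and per-step TDF error).
mc_consumer_sd <- function(alpha, FWL = NULL, s_meta = 0, PTS = NULL,
                           MTS = NULL, s_proto = 0, n = 1e5) {
  y <- stats::rnorm(n, 0, alpha)
  if (!is.null(FWL)) y <- y + FWL * stats::rnorm(n, 0, s_meta)
  if (!is.null(PTS)) {
    y <- y + PTS * stats::rnorm(n, 0, s_proto) + MTS * stats::rnorm(n, 0, s_meta)
  }
  stats::sd(y)
}

# Minimal hand-built draws container for posterior-summary unit tests.
fake_draws <- function(mat, chain = rep(1:2, each = nrow(mat) / 2),
                       family = NULL, group = NA, consumer = NA) {
  if (is.null(family)) family <- sub("\\[.*$", "", colnames(mat))
  meta <- data.frame(parameter = colnames(mat), family = family,
                     tracer = NA_character_, group = group,
                     consumer = consumer, stringsAsFactors = FALSE)
  diagnostics <- data.frame(parameter = colnames(mat),
                            rhat = apply_split_rhat(mat, chain),
                            ess = apply(mat, 2, function(x)
                              as.numeric(coda::effectiveSize(x))),
                            ok = TRUE, stringsAsFactors = FALSE)
  structure(list(mat = mat, chain = chain, meta = meta,
                 diagnostics = diagnostics, groups = unique(group),
                 consumer_ids = unique(consumer), tracers = character(0),
                 mcmc = NULL),
            class = "omsm_draws")
}

quiet_fit <- function(model, mcmc) {
  suppressWarnings(run_mcmc(model, mcmc))
}
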