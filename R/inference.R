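#' Build the Bayesian organic-matter supply model
#'
#' Assembles the declarative model graph fit by [run_mcmc()]:
#' \itemize{
#'   \item source replicates: \eqn{X_{j,i,r} \sim N(\mu_{j,i}, \sigma_{j,i})}
#'     with a uniform prior on each \eqn{\mu_{j,i}} and a vague gamma prior
#'     on the dispersion (on the precision by default);
#'   \item per consumer \eqn{k}: mixing coefficients
#'     \eqn{f_k \sim Dirichlet(\alpha)}; base values
#'     \eqn{\mu_{j,k,base} = \sum_i f_{i,k}\mu_{j,i}}; food-web length
#'     \eqn{FWL_k \sim N(\mu_{FWL,k}, \sigma_{FWL,k})} and metazoan steps
#'     \eqn{MTS_k \sim N(\mu_{MTS,k}, \sigma_{MTS,k})} with plug-in means
#'     and relative-error SDs from the designated trophic tracers
#'     (see [food_web_length()], [trophic_uncertainty()]);
#'     \eqn{PTS_k = FWL_k - MTS_k};
#'   \item for each mixing tracer: \eqn{Y_{j,k} \sim N(\mu_{j,k},
#'     \sigma_{j,k})} with the mean from the full process model
#'     ([forward_model()]) and SD combining analytical and TDF uncertainty
#'     ([consumer_sd()]).
#' }
#' All consumers are fit jointly in one graph and share the source
#' parameters.
#'
#' The trophic-step SDs can degenerate to zero when a plug-in mean crosses
#' zero; inside the sampler they are floored at `1e-6` per mil so the
#' corresponding precision stays finite. [log_posterior()] applies the same
#' floor.
#'
#' @param sources an [omsm_sources()] dataset.
#' @param consumers an [omsm_consumers()] object, or `NULL` for a
#'   source-only measurement model (no mixing or trophic component).
#' @param config an [omsm_config()].
#' @param priors a [prior_config()].
#' @param fix_sources if `TRUE`, source means are fixed at their empirical
#'   group means instead of being sampled. Useful for fast approximate fits
#'   and for validation against low-dimensional numerical posteriors.
#' @param prior_only if `TRUE`, drop all consumer likelihood terms and the
#'   trophic submodel, leaving only the Dirichlet prior on `f` (prior
#'   predictive checks).
#' @return an object of class `omsm_model` holding the generated BUGS code,
#'   the data list, index maps, and an initial-value generator.
#' @export
build_model <- function(sources, consumers, config = omsm_config(),
                        priors = prior_config(), fix_sources = FALSE,
                        prior_only = FALSE) {
  stopifnot(inherits(sources, "omsm_sources"), inherits(config, "omsm_config"),
            inherits(priors, "omsm_priors"))
  if (!is.null(consumers)) {
    stopifnot(inherits(consumers, "omsm_consumers"))
    rep <- validate_config(config, sources, consumers)
    if (!rep$ok) {
      stop("configuration invalid:\n", paste0("  - ", rep$errors, collapse = "\n"),
           call. = FALSE)
    }
    for (w in rep$warnings) warning(w, call. = FALSE)
  }

  tr_tab <- config$tracers
  tracers <- tr_tab$aa
  groups <- sources$groups
  Ntr <- length(tracers)
  Nsrc <- length(groups)

  alpha_dir <- priors$dirichlet_alpha
  if (is.null(alpha_dir)) alpha_dir <- rep(1, Nsrc)
  if (length(alpha_dir) == 1L) alpha_dir <- rep(alpha_dir, Nsrc)
  if (length(alpha_dir) != Nsrc) {
    stop("dirichlet_alpha must have one component per source", call. = FALSE)
  }

  # long-format source observations (ragged groups)
  src_df <- sources$data
  src_i <- match(src_df$group, groups)
  X <- as.matrix(src_df[, tracers, drop = FALSE])
  Xlong <- as.vector(X)                       # column-major: tracer varies slowest
  trj <- rep(seq_len(Ntr), each = nrow(X))
  srci <- rep(src_i, times = Ntr)

  emp_means <- source_means(sources, tracers)
  emp_sds <- source_sds(sources, tracers)

  dat <- list(Ntr = Ntr, Nsrc = Nsrc,
              mu_lo = priors$mu_bounds[1], mu_hi = priors$mu_bounds[2],
              g_shape = priors$dispersion_gamma[1],
              g_rate = priors$dispersion_gamma[2],
              alpha_dir = alpha_dir, sd_floor = 1e-6)

  if (!fix_sources && !prior_only) {
    dat$X <- Xlong
    dat$trj <- trj
    dat$srci <- srci
    dat$Nobs <- length(Xlong)
  }
  if (fix_sources) dat$mu_src <- emp_means

  mixj <- which(tr_tab$role == "mixing")
  jF <- which(tr_tab$role == "trophic_fwl")
  jM <- which(tr_tab$role == "trophic_mts")

  has_cons <- !is.null(consumers)
  if (has_cons) {
    Y <- consumers$values[tracers, , drop = FALSE]
    A <- consumers$alpha[tracers, , drop = FALSE]
    dat$Ncons <- length(consumers$ids)
    if (!prior_only) {
      dat$Y <- Y
      dat$alpha <- A
      dat$Nmix <- length(mixj)
      dat$mixj <- array(mixj, dim = length(mixj))
      dat$dproto <- tr_tab$delta_proto
      dat$dmeta <- tr_tab$delta_meta
      dat$sproto <- tr_tab$sd_proto
      dat$smeta <- tr_tab$sd_meta
      if (!config$nonfractionating) {
        dat$jF <- jF; dat$jM <- jM
        dat$dF <- tr_tab$delta_meta[jF]; dat$sF <- tr_tab$sd_meta[jF]
        dat$dM <- tr_tab$delta_meta[jM]; dat$sM <- tr_tab$sd_meta[jM]
        ytro <- c(Y[jF, ], Y[jM, ])
        if (any(ytro == 0)) {
          stop("a trophic-tracer consumer value is exactly 0 per mil; the ",
               "relative-error propagation of the trophic estimate is undefined",
               call. = FALSE)
        }
        if (any(abs(ytro) < 1)) {
          warning("trophic-tracer consumer value(s) within 1 per mil of zero; ",
                  "propagated trophic uncertainties are unstable there",
                  call. = FALSE)
        }
      }
    }
  }

  code <- .omsm_bugs_code(Nsrc = Nsrc, has_sources = !fix_sources && !prior_only,
                          has_cons = has_cons, prior_only = prior_only,
                          nonfrac = config$nonfractionating,
                          truncate = config$truncate_trophic,
                          sigma_prior = config$sigma_prior)

  monitors <- character(0)
  if (!fix_sources && !prior_only) monitors <- c("mu_src", "sigma_src")
  if (has_cons) {
    monitors <- c(monitors, "f")
    if (!prior_only) {
      monitors <- c(monitors, "mu_base")
      if (!config$nonfractionating) monitors <- c(monitors, "FWL", "MTS", "PTS")
    }
  }

  structure(
    list(code = code, data = dat, monitors = monitors,
         tracers = tr_tab, groups = groups,
         consumer_ids = if (has_cons) consumers$ids else character(0),
         emp_means = emp_means, emp_sds = emp_sds,
         mixj = mixj, jF = jF, jM = jM,
         fix_sources = fix_sources, prior_only = prior_only,
         config = config, priors = priors),
    class = "omsm_model"
  )
}

# Generate the BUGS model code for the requested structure.
.omsm_bugs_code <- function(Nsrc, has_sources, has_cons, prior_only,
                            nonfrac, truncate, sigma_prior) {
  src_disp <- if (sigma_prior == "precision") {
    c("      tau_src[j,i] ~ dgamma(g_shape, g_rate)",
      "      sigma_src[j,i] <- 1 / sqrt(tau_src[j,i])")
  } else {
    c("      sigma_src[j,i] ~ dgamma(g_shape, g_rate)",
      "      tau_src[j,i] <- 1 / pow(sigma_src[j,i], 2)")
  }
  trunc_tag <- if (truncate) " T(0, )" else ""
  lines <- c("model {")
  if (has_sources) {
    lines <- c(lines,
      "  for (j in 1:Ntr) {",
      "    for (i in 1:Nsrc) {",
      "      mu_src[j,i] ~ dunif(mu_lo, mu_hi)",
      src_disp,
      "    }",
      "  }",
      "  for (o in 1:Nobs) {",
      "    X[o] ~ dnorm(mu_src[trj[o], srci[o]], tau_src[trj[o], srci[o]])",
      "  }")
  }
  if (has_cons) {
    fline <- if (Nsrc >= 2) {
      "    f[1:Nsrc,k] ~ ddirch(alpha_dir[1:Nsrc])"
    } else {
      "    f[1,k] <- 1"
    }
    lines <- c(lines, "  for (k in 1:Ncons) {", fline)
    if (!prior_only) {
      lines <- c(lines,
        "    for (j in 1:Ntr) {",
        "      mu_base[j,k] <- inprod(mu_src[j,1:Nsrc], f[1:Nsrc,k])",
        "    }")
      if (!nonfrac) {
        lines <- c(lines,
          "    muFWL[k] <- (Y[jF,k] - mu_base[jF,k]) / dF",
          "    sdFWL[k] <- max(sd_floor, abs(muFWL[k]) * sqrt(pow(alpha[jF,k] / Y[jF,k], 2) + pow(sF / dF, 2)))",
          paste0("    FWL[k] ~ dnorm(muFWL[k], 1 / pow(sdFWL[k], 2))", trunc_tag),
          "    muMTS[k] <- (Y[jM,k] - mu_base[jM,k]) / dM",
          "    sdMTS[k] <- max(sd_floor, abs(muMTS[k]) * sqrt(pow(alpha[jM,k] / Y[jM,k], 2) + pow(sM / dM, 2)))",
          paste0("    MTS[k] ~ dnorm(muMTS[k], 1 / pow(sdMTS[k], 2))", trunc_tag),
          "    PTS[k] <- FWL[k] - MTS[k]",
          "    for (m in 1:Nmix) {",
          "      mu_pred[m,k] <- mu_base[mixj[m],k] + PTS[k] * dproto[mixj[m]] + MTS[k] * dmeta[mixj[m]]",
          "      sd_pred[m,k] <- sqrt(pow(alpha[mixj[m],k], 2) + pow(PTS[k] * sproto[mixj[m]], 2) + pow(MTS[k] * smeta[mixj[m]], 2))",
          "      Y[mixj[m],k] ~ dnorm(mu_pred[m,k], 1 / pow(sd_pred[m,k], 2))",
          "    }")
      } else {
        lines <- c(lines,
          "    for (m in 1:Nmix) {",
          "      Y[mixj[m],k] ~ dnorm(mu_base[mixj[m],k], 1 / pow(alpha[mixj[m],k], 2))",
          "    }")
      }
    }
    lines <- c(lines, "  }")
  }
  paste(c(lines, "}"), collapse = "\n")
}

# Deterministic initial values: f at the simplex centroid, FWL/MTS at their
# plug-in estimates from empirical source means, mu/sigma at group sample
# statistics.
.omsm_inits <- function(model, chain, seed) {
  dat <- model$data
  ini <- list(.RNG.name = "base::Mersenne-Twister",
              .RNG.seed = as.integer(seed + chain))
  if (!model$fix_sources && !model$prior_only) {
    mu0 <- model$emp_means
    sd0 <- pmax(model$emp_sds, 0.05)
    mu0 <- pmin(pmax(mu0, dat$mu_lo + 1e-6), dat$mu_hi - 1e-6)
    if (model$config$sigma_prior == "precision") {
      ini$tau_src <- 1 / sd0^2
    } else {
      ini$sigma_src <- sd0
    }
    ini$mu_src <- mu0
  }
  ncons <- dat$Ncons
  if (!is.null(ncons) && ncons > 0 && dat$Nsrc >= 2) {
    ini$f <- matrix(1 / dat$Nsrc, dat$Nsrc, ncons)
  }
  if (!is.null(ncons) && ncons > 0 && !model$prior_only &&
      !model$config$nonfractionating) {
    base0 <- drop(model$emp_means %*% rep(1 / dat$Nsrc, dat$Nsrc))
    fwl0 <- (dat$Y[dat$jF, ] - base0[dat$jF]) / dat$dF
    mts0 <- (dat$Y[dat$jM, ] - base0[dat$jM]) / dat$dM
    if (model$config$truncate_trophic) {
      fwl0 <- pmax(fwl0, 0.01)
      mts0 <- pmax(mts0, 0.01)
    }
    ini$FWL <- as.numeric(fwl0)
    ini$MTS <- as.numeric(mts0)
  }
  ini
}

#' Run the MCMC sampler
#'
#' Fits a built model by Gibbs sampling through JAGS (via \pkg{rjags}),
#' following the adaptation / burn-in / sampling / thinning protocol in
#' `mcmc`. Draws are reproducible: all chain RNGs are seeded from
#' `mcmc$seed`, so two runs with the same seed give identical output.
#'
#' Convergence is assessed per parameter with the split-\eqn{\hat R}
#' statistic (threshold 1.05) and effective sample size (threshold 200). A
#' warning is issued when any parameter fails; the flags travel with the
#' draws and are propagated into summaries.
#'
#' @param model an `omsm_model` from [build_model()].
#' @param mcmc an [mcmc_config()].
#' @param quiet suppress JAGS progress output (default `TRUE`).
#' @return an object of class `omsm_draws`: list with `mat` (retained draws,
#'   one named column per scalar parameter), `chain` (chain index per row),
#'   `meta` (parameter metadata), `diagnostics` (per-parameter rhat/ess),
#'   and the configuration used. Parameter names use the data's labels, e.g.
#'   `f[surface,Z01]`, `FWL[Z01]`, `mu_src[Phe,large]`.
#' @export
run_mcmc <- function(model, mcmc = mcmc_config(), quiet = TRUE) {
  stopifnot(inherits(model, "omsm_model"), inherits(mcmc, "omsm_mcmc"))
  if (length(model$monitors) == 0L) stop("model has nothing to monitor", call. = FALSE)
  inits <- lapply(seq_len(mcmc$chains), function(ch)
    .omsm_inits(model, ch, mcmc$seed))
  jm <- rjags::jags.model(textConnection(model$code), data = model$data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = mcmc$adapt, quiet = quiet)
  pb <- if (quiet) "none" else "text"
  stats::update(jm, n.iter = mcmc$burn_in, progress.bar = pb)
  samp <- rjags::coda.samples(jm, variable.names = model$monitors,
                              n.iter = mcmc$samples, thin = mcmc$thin,
                              progress.bar = pb)
  .omsm_draws_from_coda(samp, model, mcmc)
}

.omsm_draws_from_coda <- function(samp, model, mcmc) {
  ess <- coda::effectiveSize(samp)
  mats <- lapply(samp, as.matrix)
  mat <- do.call(rbind, mats)
  chain <- rep(seq_along(mats), vapply(mats, nrow, integer(1)))

  meta <- .parse_param_names(colnames(mat), model)
  colnames(mat) <- meta$parameter
  names(ess) <- meta$parameter

  rhat <- apply_split_rhat(mat, chain)
  const <- apply(mat, 2, function(x) stats::var(x) == 0)
  ok <- (is.na(rhat) | rhat < 1.05) & (const | ess > 200)
  diagnostics <- data.frame(parameter = meta$parameter, rhat = rhat,
                            ess = as.numeric(ess), ok = ok,
                            stringsAsFactors = FALSE, row.names = NULL)
  if (any(!ok)) {
    warning(sum(!ok), " parameter(s) failed convergence checks ",
            "(split-Rhat >= 1.05 or ESS <= 200); inspect draws$diagnostics",
            call. = FALSE)
  }
  structure(list(mat = mat, chain = chain, meta = meta,
                 diagnostics = diagnostics,
                 groups = model$groups, consumer_ids = model$consumer_ids,
                 tracers = model$tracers$aa, mcmc = mcmc),
            class = "omsm_draws")
}

# Map raw JAGS names (f[2,1], FWL[3], ...) to labelled parameter names and
# per-parameter metadata.
.parse_param_names <- function(raw, model) {
  fam <- sub("\\[.*$", "", raw)
  m <- regexpr("\\[[0-9, ]+\\]", raw)
  len <- attr(m, "match.length")
  idx <- lapply(seq_along(raw), function(p) {
    if (m[p] < 0) return(1L)   # scalar node: implicit first index
    s <- substr(raw[p], m[p] + 1L, m[p] + len[p] - 2L)
    as.integer(strsplit(gsub(" ", "", s), ",")[[1]])
  })
  grp <- model$groups
  ids <- model$consumer_ids
  aa <- model$tracers$aa
  lab <- character(length(raw))
  tracer <- group <- consumer <- rep(NA_character_, length(raw))
  for (p in seq_along(raw)) {
    ii <- idx[[p]]
    lab[p] <- switch(fam[p],
      f = { group[p] <- grp[ii[1]]; consumer[p] <- ids[ii[2]]
            sprintf("f[%s,%s]", grp[ii[1]], ids[ii[2]]) },
      FWL = , MTS = , PTS = { consumer[p] <- ids[ii[1]]
            sprintf("%s[%s]", fam[p], ids[ii[1]]) },
      mu_src = , sigma_src = { tracer[p] <- aa[ii[1]]; group[p] <- grp[ii[2]]
            sprintf("%s[%s,%s]", fam[p], aa[ii[1]], grp[ii[2]]) },
      mu_base = { tracer[p] <- aa[ii[1]]; consumer[p] <- ids[ii[2]]
            sprintf("mu_base[%s,%s]", aa[ii[1]], ids[ii[2]]) },
      raw[p])
  }
  data.frame(parameter = lab, family = fam, tracer = tracer, group = group,
             consumer = consumer, stringsAsFactors = FALSE)
}

#' Split-\eqn{\hat R} convergence statistic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain trends are detected as well as between-chain
#' disagreement. Returns `NA` for (near-)constant parameters.
#'
#' @param x numeric vector of draws for one parameter, ordered by chain.
#' @param chain integer chain index per draw.
#' @return scalar \eqn{\hat R} (1 is perfect mixing).
#' @export
split_rhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n2 <- floor(length(v) / 2)
    halves <- c(halves, list(v[seq_len(n2)], v[seq_len(n2) + n2]))
  }
  n <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(n)])
  m <- length(halves)
  if (n < 2L || m < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

apply_split_rhat <- function(mat, chain) {
  apply(mat, 2, split_rhat, chain = chain)
}

#' Extract draws for one parameter family
#'
#' @param draws an `omsm_draws` object.
#' @param family one of the sampled families (`"f"`, `"FWL"`, `"MTS"`,
#'   `"PTS"`, `"mu_src"`, `"sigma_src"`, `"mu_base"`).
#' @param consumer optional consumer id to restrict to.
#' @return matrix of draws (rows are retained iterations).
#' @export
get_draws <- function(draws, family, consumer = NULL) {
  stopifnot(inherits(draws, "omsm_draws"))
  keep <- draws$meta$family == family
  if (!is.null(consumer)) keep <- keep & draws$meta$consumer %in% consumer
  if (!any(keep)) stop("no draws for family ", family, call. = FALSE)
  draws$mat[, keep, drop = FALSE]
}

#' @export
print.omsm_draws <- function(x, ...) {
  cat("<omsm_draws> ", nrow(x$mat), " retained draws x ", ncol(x$mat),
      " parameters (", length(unique(x$chain)), " chains)\n", sep = "")
  bad <- sum(!x$diagnostics$ok)
  if (bad) cat("convergence flags raised for", bad, "parameter(s)\n")
  invisible(x)
}

#' Joint log-posterior density
#'
#' Hand-written evaluation of the (unnormalised) log posterior of the model
#' at one parameter point, independent of the JAGS sampler. Used for
#' validation against numerical integration and for any gradient-free
#' exploration. Returns `-Inf` outside the support (mixing coefficients off
#' the simplex, non-positive dispersions, source means outside their uniform
#' bounds, or negative trophic steps when truncation is enabled).
#'
#' @param point named list with elements as applicable to the model:
#'   `f` (source x consumer matrix, or vector for one consumer), `FWL`,
#'   `MTS` (numeric per consumer), `mu_src`, `sigma_src`
#'   (tracer x source matrices; omitted when `fix_sources = TRUE`).
#' @param model an `omsm_model`.
#' @return scalar log density (up to an additive constant shared across
#'   points).
#' @export
log_posterior <- function(point, model) {
  stopifnot(inherits(model, "omsm_model"))
  dat <- model$data
  tol <- 1e-9
  lp <- 0

  has_src <- !model$fix_sources && !model$prior_only
  if (has_src) {
    mu <- as.matrix(point$mu_src)
    sg <- as.matrix(point$sigma_src)
    if (any(mu < dat$mu_lo) || any(mu > dat$mu_hi)) return(-Inf)
    if (any(sg <= 0)) return(-Inf)
    lp <- lp + length(mu) * (-log(dat$mu_hi - dat$mu_lo))
    if (model$config$sigma_prior == "precision") {
      tau <- 1 / sg^2
      lp <- lp + sum(stats::dgamma(tau, dat$g_shape, rate = dat$g_rate,
                                   log = TRUE) + log(2 / sg^3))
    } else {
      lp <- lp + sum(stats::dgamma(sg, dat$g_shape, rate = dat$g_rate,
                                   log = TRUE))
    }
    lp <- lp + sum(stats::dnorm(dat$X, mu[cbind(dat$trj, dat$srci)],
                                sg[cbind(dat$trj, dat$srci)], log = TRUE))
  } else if (model$fix_sources) {
    mu <- dat$mu_src
  }

  ncons <- dat$Ncons
  if (is.null(ncons) || ncons == 0L) return(lp)

  f <- point$f
  if (is.null(dim(f))) f <- matrix(f, ncol = ncons)
  if (any(f < -tol) || any(abs(colSums(f) - 1) > tol)) return(-Inf)
  f <- pmax(f, 1e-300)
  a <- dat$alpha_dir
  lp <- lp + ncons * (lgamma(sum(a)) - sum(lgamma(a))) +
    sum((a - 1) * log(f))
  if (model$prior_only) return(lp)

  mu_base <- mu %*% f                          # Ntr x Ncons
  if (!model$config$nonfractionating) {
    FWL <- point$FWL
    MTS <- point$MTS
    if (model$config$truncate_trophic && (any(FWL < 0) || any(MTS < 0))) {
      return(-Inf)
    }
    muF <- (dat$Y[dat$jF, ] - mu_base[dat$jF, ]) / dat$dF
    sdF <- pmax(dat$sd_floor,
                abs(muF) * sqrt((dat$alpha[dat$jF, ] / dat$Y[dat$jF, ])^2 +
                                  (dat$sF / dat$dF)^2))
    muM <- (dat$Y[dat$jM, ] - mu_base[dat$jM, ]) / dat$dM
    sdM <- pmax(dat$sd_floor,
                abs(muM) * sqrt((dat$alpha[dat$jM, ] / dat$Y[dat$jM, ])^2 +
                                  (dat$sM / dat$dM)^2))
    lp <- lp + sum(stats::dnorm(FWL, muF, sdF, log = TRUE)) +
      sum(stats::dnorm(MTS, muM, sdM, log = TRUE))
    if (model$config$truncate_trophic) {
      lp <- lp - sum(stats::pnorm(0, muF, sdF, lower.tail = FALSE, log.p = TRUE),
                     stats::pnorm(0, muM, sdM, lower.tail = FALSE, log.p = TRUE))
    }
    PTS <- FWL - MTS
    for (m in model$mixj) {
      pred <- mu_base[m, ] + PTS * dat$dproto[m] + MTS * dat$dmeta[m]
      sdm <- sqrt(dat$alpha[m, ]^2 + (PTS * dat$sproto[m])^2 +
                    (MTS * dat$smeta[m])^2)
      lp <- lp + sum(stats::dnorm(dat$Y[m, ], pred, sdm, log = TRUE))
    }
  } else {
    for (m in model$mixj) {
      lp <- lp + sum(stats::dnorm(dat$Y[m, ], mu_base[m, ], dat$alpha[m, ],
                                  log = TRUE))
    }
  }
  lp
}
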