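#' Model configuration: tracer roles and discrimination classes
#'
#' Assigns each amino-acid tracer a role in the model and resolves its
#' trophic discrimination parameters from a TDF registry. Roles:
#' \describe{
#'   \item{mixing}{enters the likelihood through the full process model
#'     (linear mixing plus trophic discrimination).}
#'   \item{trophic_fwl}{the constant-discrimination tracer used to estimate
#'     total food-web length (FWL).}
#'   \item{trophic_mts}{the variable-discrimination tracer used to estimate
#'     metazoan trophic steps (MTS).}
#'   \item{excluded}{read but never modelled.}
#' }
#' Mixing and trophic tracer sets must be disjoint, and (unless
#' `nonfractionating = TRUE`) there must be exactly one `trophic_fwl` tracer
#' of constant class and one `trophic_mts` tracer of variable class.
#'
#' The defaults mirror a mesopelagic particle-supply case study: mixing
#' tracers Phe, Lys, Thr; Pro for food-web length; Glx for metazoan steps;
#' Ile and Val excluded for their poorly constrained fractionation.
#'
#' @param mixing character vector of mixing-tracer amino acids.
#' @param trophic_fwl single amino acid used for the FWL estimate
#'   (constant class), or `NULL` when `nonfractionating = TRUE`.
#' @param trophic_mts single amino acid used for the MTS estimate
#'   (variable class), or `NULL` when `nonfractionating = TRUE`.
#' @param excluded amino acids present in the data but dropped from the model.
#' @param tdf TDF registry (see [tdf_default()]).
#' @param treat_phe_conservative forwarded to [tdf_default()] when `tdf` is
#'   not supplied; if `tdf` is supplied it is used as-is.
#' @param nonfractionating if `TRUE`, build the simplified non-fractionating
#'   variant: Thr is dropped from the mixing set, Phe and Lys are treated as
#'   conservative, no trophic tracers are used, and no trophic steps are
#'   estimated (FWL, MTS, PTS are absent from the posterior).
#' @param truncate_trophic if `TRUE`, the normal distributions for FWL and
#'   MTS are truncated at zero during sampling. Default `FALSE` (no
#'   positivity constraint).
#' @param sigma_prior `"precision"` (default) places the vague gamma prior on
#'   the precision 1/sigma^2, the conventional BUGS encoding; `"sd"` places
#'   it literally on sigma.
#' @return an object of class `omsm_config`: a list with `tracers` (resolved
#'   per-tracer table with columns `aa`, `role`, `class`, `delta_meta`,
#'   `sd_meta`, `delta_proto`, `sd_proto`), the flags above, and the registry.
#' @examples
#' cfg <- omsm_config()
#' cfg$tracers
#' @export
omsm_config <- function(mixing = c("Phe", "Lys", "Thr"),
                        trophic_fwl = "Pro",
                        trophic_mts = "Glx",
                        excluded = c("Ile", "Val"),
                        tdf = NULL,
                        treat_phe_conservative = TRUE,
                        nonfractionating = FALSE,
                        truncate_trophic = FALSE,
                        sigma_prior = c("precision", "sd")) {
  sigma_prior <- match.arg(sigma_prior)
  if (is.null(tdf)) tdf <- tdf_default(treat_phe_conservative = treat_phe_conservative)
  tdf <- validate_tdf(tdf)

  if (nonfractionating) {
    mixing <- setdiff(aa_canonical(mixing), "Thr")
    trophic_fwl <- trophic_mts <- character(0)
  } else {
    mixing <- aa_canonical(mixing)
    trophic_fwl <- aa_canonical(trophic_fwl)
    trophic_mts <- aa_canonical(trophic_mts)
  }
  excluded <- aa_canonical(excluded)

  trophic <- c(trophic_fwl, trophic_mts)
  overlap <- intersect(mixing, trophic)
  if (length(overlap)) {
    stop("tracer sets overlap: ", paste(overlap, collapse = ", "),
         " assigned to both mixing and trophic roles", call. = FALSE)
  }
  if (anyDuplicated(mixing)) stop("duplicated mixing tracers", call. = FALSE)
  if (!nonfractionating) {
    if (length(trophic_fwl) != 1L || length(trophic_mts) != 1L) {
      stop("exactly one trophic_fwl and one trophic_mts tracer are required",
           call. = FALSE)
    }
    if (trophic_fwl == trophic_mts) {
      stop("trophic_fwl and trophic_mts must be different tracers", call. = FALSE)
    }
  }
  if (length(mixing) == 0L) stop("at least one mixing tracer is required", call. = FALSE)

  used <- c(mixing, trophic)
  roles <- c(rep("mixing", length(mixing)),
             rep("trophic_fwl", length(trophic_fwl)),
             rep("trophic_mts", length(trophic_mts)))
  rows <- lapply(used, function(a) tdf_lookup(tdf, a))
  tracers <- do.call(rbind, rows)
  tracers <- cbind(aa = tracers$aa, role = roles, tracers[, -1, drop = FALSE])
  if (nonfractionating) {
    # all mixing tracers behave conservatively in the variant model
    tracers$class <- "conservative"
    tracers[, c("delta_meta", "sd_meta", "delta_proto", "sd_proto")] <- 0
  } else {
    if (tracers$class[tracers$role == "trophic_fwl"] != "constant") {
      stop("the trophic_fwl tracer must be of constant discrimination class",
           call. = FALSE)
    }
    if (tracers$class[tracers$role == "trophic_mts"] != "variable") {
      stop("the trophic_mts tracer must be of variable discrimination class",
           call. = FALSE)
    }
  }
  rownames(tracers) <- NULL

  structure(
    list(tracers = tracers,
         mixing = mixing,
         trophic_fwl = if (length(trophic_fwl)) trophic_fwl else NULL,
         trophic_mts = if (length(trophic_mts)) trophic_mts else NULL,
         excluded = excluded,
         tdf = tdf,
         treat_phe_conservative = treat_phe_conservative,
         nonfractionating = nonfractionating,
         truncate_trophic = truncate_trophic,
         sigma_prior = sigma_prior),
    class = "omsm_config"
  )
}

#' @export
print.omsm_config <- function(x, ...) {
  cat("<omsm_config>",
      if (x$nonfractionating) "(non-fractionating variant)" else "", "\n")
  print(x$tracers, ...)
  invisible(x)
}

#' Prior configuration
#'
#' Vague defaults follow the model's validation setup: uniform priors on the
#' source tracer means, a gamma(0.001, 0.001) prior on the source dispersion
#' (placed on the precision by default, see [omsm_config()]'s `sigma_prior`),
#' and a uniform Dirichlet prior on the mixing coefficients.
#'
#' @param mu_bounds length-2 numeric, bounds of the uniform prior on source
#'   tracer means (per mil).
#' @param dispersion_gamma length-2 numeric, shape and rate of the gamma
#'   prior on source dispersion.
#' @param dirichlet_alpha concentration vector for the Dirichlet prior on
#'   mixing coefficients; a single value is recycled to the number of
#'   sources, `NULL` means all ones (uniform).
#' @return an object of class `omsm_priors`.
#' @export
prior_config <- function(mu_bounds = c(-100, 100),
                         dispersion_gamma = c(0.001, 0.001),
                         dirichlet_alpha = NULL) {
  stopifnot(length(mu_bounds) == 2L, mu_bounds[1] < mu_bounds[2],
            length(dispersion_gamma) == 2L, all(dispersion_gamma > 0))
  if (!is.null(dirichlet_alpha) && any(dirichlet_alpha <= 0)) {
    stop("dirichlet_alpha components must be > 0", call. = FALSE)
  }
  structure(list(mu_bounds = as.numeric(mu_bounds),
                 dispersion_gamma = as.numeric(dispersion_gamma),
                 dirichlet_alpha = dirichlet_alpha),
            class = "omsm_priors")
}

#' MCMC configuration
#'
#' Defaults match the model's published sampling protocol: three parallel
#' chains, each with a 5,000-step adaptation phase, a 10,000-step burn-in,
#' and a 10,000-step sampling phase thinned by a factor of 10.
#'
#' @param chains number of parallel chains.
#' @param adapt adaptation steps per chain.
#' @param burn_in burn-in steps per chain.
#' @param samples sampling steps per chain (before thinning).
#' @param thin thinning factor; must divide `samples` evenly.
#' @param seed integer seed; all chain RNGs are derived from it, so a fixed
#'   seed gives bit-identical draws.
#' @return an object of class `omsm_mcmc`.
#' @export
mcmc_config <- function(chains = 3, adapt = 5000, burn_in = 10000,
                        samples = 10000, thin = 10, seed = 1) {
  vals <- c(chains = chains, adapt = adapt, burn_in = burn_in,
            samples = samples, thin = thin)
  if (any(vals != round(vals)) || any(vals <= 0)) {
    stop("all MCMC settings must be positive integers", call. = FALSE)
  }
  if (samples %% thin != 0) {
    stop("thin must divide samples evenly", call. = FALSE)
  }
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 burn_in = as.integer(burn_in), samples = as.integer(samples),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "omsm_mcmc")
}
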