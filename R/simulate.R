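#' Dirichlet random deviates
#'
#' @param n number of draws.
#' @param alpha concentration vector.
#' @return an `n` x `length(alpha)` matrix of simplex rows.
#' @export
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Default synthetic source geometry
#'
#' Group-mean delta15N values (per mil) for three basal particle pools
#' (`surface`, `large`, `small`) over the default tracer set. The geometry
#' mirrors open-ocean particle data: small particles carry the highest
#' values and surface particles the lowest on most tracers (one axis of
#' separation through Phe/Lys and the trophic tracers), while Thr is the
#' orthogonal axis on which large particles are uniquely low.
#'
#' @return tracer x group numeric matrix.
#' @export
default_source_means <- function() {
  rbind(
    Phe = c(surface = -1, large = 4,   small = 9),
    Lys = c(surface = 0,  large = 5,   small = 10),
    Thr = c(surface = -6, large = -14, small = -7),
    Pro = c(surface = 4,  large = 8,   small = 12),
    Glx = c(surface = 4,  large = 9,   small = 13)
  )
}

#' Simulate replicate source measurements
#'
#' Draws `n_per_group` replicates per source group around fixed group means
#' with a common within-group SD, giving an [omsm_sources()] dataset with a
#' known generative truth.
#'
#' @param tracer_means tracer x group matrix of group means (per mil);
#'   default [default_source_means()].
#' @param n_per_group replicates per group (default 5).
#' @param within_sd within-group SD (per mil, default 1), applied to every
#'   tracer.
#' @param seed optional integer seed for reproducibility.
#' @return an `omsm_sources` dataset; the generating means are attached as
#'   attribute `"true_means"`.
#' @export
simulate_sources <- function(tracer_means = default_source_means(),
                             n_per_group = 5, within_sd = 1, seed = NULL) {
  stopifnot(within_sd >= 0, all(is.finite(tracer_means)), n_per_group >= 2)
  if (!is.null(seed)) set.seed(seed)
  groups <- colnames(tracer_means)
  tracers <- rownames(tracer_means)
  rows <- lapply(groups, function(g) {
    vals <- sapply(tracers, function(j)
      stats::rnorm(n_per_group, tracer_means[j, g], within_sd))
    vals <- matrix(vals, nrow = n_per_group, dimnames = list(NULL, tracers))
    data.frame(sample_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
               group = g, vals, stringsAsFactors = FALSE)
  })
  out <- omsm_sources(do.call(rbind, rows))
  attr(out, "true_means") <- tracer_means
  out
}

#' Simulate consumer samples with known mixing and trophic parameters
#'
#' Generates consumers through the forward process model: each sample gets
#' mixing coefficients from a uniform Dirichlet distribution, protozoan
#' trophic steps from `U(pts_range)`, and metazoan steps from
#' `U(mts_range)` (the defaults give food-web lengths between 1 and 3).
#' Tracer values are computed with [forward_model()] from the empirical
#' source-group means and the mean TDFs, plus optional Gaussian noise
#' (default none: generation is deterministic given the ecological
#' parameters).
#'
#' @param sources an [omsm_sources()] dataset.
#' @param n number of consumer samples (default 50).
#' @param config an [omsm_config()]; its resolved tracer set and TDF means
#'   drive the forward model.
#' @param pts_range,mts_range uniform ranges for protozoan and metazoan
#'   trophic steps.
#' @param noise_sd SD of additive measurement noise (per mil, default 0).
#' @param alpha analytical SD assigned to the simulated consumers for
#'   fitting (per mil, default 0.5 — typical for amino-acid nitrogen
#'   isotope measurements).
#' @param seed optional integer seed.
#' @return list with `consumers` (an [omsm_consumers()] object) and `truth`,
#'   a data frame with one row per sample: `sample_id`, one `f_<group>`
#'   column per source, `PTS`, `MTS`, `FWL`, and the generated tracer
#'   values.
#' @export
simulate_consumers <- function(sources, n = 50, config = omsm_config(),
                               pts_range = c(0, 1), mts_range = c(1, 2),
                               noise_sd = 0, alpha = 0.5, seed = NULL) {
  stopifnot(inherits(sources, "omsm_sources"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tr_tab <- config$tracers
  mu_src <- source_means(sources, tr_tab$aa)
  groups <- sources$groups

  f <- rdirichlet(n, rep(1, length(groups)))
  PTS <- stats::runif(n, pts_range[1], pts_range[2])
  MTS <- stats::runif(n, mts_range[1], mts_range[2])

  ids <- sprintf("Z%02d", seq_len(n))
  vals <- sapply(seq_len(n), function(k) {
    y <- forward_model(f[k, ], PTS[k], MTS[k], mu_src, tr_tab)
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    y
  })
  vals <- matrix(vals, nrow = nrow(tr_tab),
                 dimnames = list(tr_tab$aa, ids))

  truth <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(groups)) truth[[paste0("f_", groups[i])]] <- f[, i]
  truth$PTS <- PTS
  truth$MTS <- MTS
  truth$FWL <- PTS + MTS
  truth <- cbind(truth, as.data.frame(t(vals)))
  rownames(truth) <- NULL

  cons_df <- data.frame(sample_id = ids, as.data.frame(t(vals)),
                        stringsAsFactors = FALSE)
  consumers <- omsm_consumers(cons_df, default_alpha = alpha)
  list(consumers = consumers, truth = truth)
}

#' Write / read a simulation truth table
#'
#' The on-disk layout has one row per simulated sample: `sample_id`, the
#' `f_<group>` mixing fractions, `PTS`, `MTS`, `FWL`, then per-amino-acid
#' delta15N columns — so an externally produced table with the same columns
#' is drop-in compatible.
#'
#' @param truth truth data frame from [simulate_consumers()].
#' @param path file path.
#' @return `read_truth` returns the data frame; `write_truth` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
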