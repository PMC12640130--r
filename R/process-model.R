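#' Linear mixing of basal source signatures
#'
#' The tracer value at the base of a consumer's food web is the convex
#' combination of the candidate source means, weighted by the mixing
#' coefficients: \eqn{\mu_{j,base} = \sum_i f_i \mu_{j,i}}.
#'
#' @param f numeric vector of mixing coefficients; must be non-negative and
#'   sum to 1 (tolerance 1e-9).
#' @param source_means numeric matrix (tracer x source) of per-source tracer
#'   means, or a plain vector (one tracer).
#' @return named numeric vector of base-of-food-web tracer values (per mil).
#' @examples
#' mix_base(c(0.25, 0.25, 0.5), rbind(Phe = c(0, 4, 10)))
#' @export
mix_base <- function(f, source_means) {
  f <- as.numeric(f)
  if (is.null(dim(source_means))) {
    source_means <- matrix(source_means, nrow = 1)
  }
  if (ncol(source_means) != length(f)) {
    stop("need one source mean per mixing coefficient for every tracer",
         call. = FALSE)
  }
  check_simplex(f)
  drop(source_means %*% f)
}

#' @keywords internal
check_simplex <- function(f, tol = 1e-9) {
  if (any(f < -tol) || abs(sum(f) - 1) > tol) {
    stop("mixing coefficients must be >= 0 and sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  invisible(f)
}

#' Food-web state
#'
#' Bundles one consumer's latent food-web parameters. Protozoan trophic
#' steps are always derived as `PTS = FWL - MTS`; they are never an
#' independent input.
#'
#' @param f mixing-coefficient vector (simplex).
#' @param FWL total food-web length (trophic steps).
#' @param MTS metazoan trophic steps.
#' @param mu_base optional named vector of base-of-food-web tracer values.
#' @return a list of class `food_web_state` with elements `f`, `FWL`, `MTS`,
#'   `PTS`, `mu_base`.
#' @export
food_web_state <- function(f, FWL, MTS, mu_base = NULL) {
  check_simplex(f)
  stopifnot(length(FWL) == 1L, length(MTS) == 1L,
            is.finite(FWL), is.finite(MTS))
  structure(list(f = as.numeric(f), FWL = as.numeric(FWL),
                 MTS = as.numeric(MTS), PTS = as.numeric(FWL - MTS),
                 mu_base = mu_base),
            class = "food_web_state")
}

.tdf_row <- function(tdf) {
  if (inherits(tdf, "data.frame")) as.list(tdf[1, ]) else as.list(tdf)
}

#' Plug-in estimates of trophic parameters
#'
#' `food_web_length()` estimates the total number of trophic steps from a
#' constant-discrimination tracer:
#' \eqn{\mu_{FWL} = (\delta_{consumer} - \mu_{base}) / \Delta}.
#' `metazoan_steps()` estimates the number of metazoan steps from a
#' variable-discrimination tracer using its metazoan TDF:
#' \eqn{\mu_{MTS} = (\delta_{consumer} - \mu_{base}) / \Delta_{meta}}.
#'
#' @param delta_consumer measured consumer tracer value (per mil).
#' @param mu_base tracer value at the base of the food web (per mil).
#' @param tdf one TDF registry row (see [tdf_lookup()]) for the designated
#'   tracer; `food_web_length` requires constant class, `metazoan_steps`
#'   variable class, both with non-zero `delta_meta`.
#' @return estimated number of trophic steps (scalar).
#' @export
food_web_length <- function(delta_consumer, mu_base, tdf) {
  tdf <- .tdf_row(tdf)
  if (!is.null(tdf$class) && tdf$class != "constant") {
    stop("food_web_length requires a constant-discrimination tracer", call. = FALSE)
  }
  if (tdf$delta_meta == 0) {
    stop("food_web_length: trophic discrimination factor is zero", call. = FALSE)
  }
  (delta_consumer - mu_base) / tdf$delta_meta
}

#' @rdname food_web_length
#' @export
metazoan_steps <- function(delta_consumer, mu_base, tdf) {
  tdf <- .tdf_row(tdf)
  if (!is.null(tdf$class) && tdf$class != "variable") {
    stop("metazoan_steps requires a variable-discrimination tracer", call. = FALSE)
  }
  if (tdf$delta_meta == 0) {
    stop("metazoan_steps: metazoan trophic discrimination factor is zero",
         call. = FALSE)
  }
  (delta_consumer - mu_base) / tdf$delta_meta
}

#' Uncertainty of a plug-in trophic estimate
#'
#' Standard relative-error propagation for the trophic-parameter quotient:
#' \deqn{\sigma = |\mu| \sqrt{(\sigma_\delta / \delta)^2 +
#'   (\sigma_\Delta / \Delta)^2}}
#' where \eqn{\delta} is the measured consumer tracer value (an absolute
#' delta value) and \eqn{\Delta} the trophic discrimination factor. The
#' formula is implemented exactly in this relative-error form. Note that it
#' divides by the consumer's absolute delta value, so the propagated
#' uncertainty depends on the isotopic reference scale; a warning is issued
#' when `|delta_consumer| < 1` per mil, where the relative-error term blows
#' up.
#'
#' @param mu plug-in trophic estimate ([food_web_length()] or
#'   [metazoan_steps()]).
#' @param delta_consumer measured consumer tracer value (per mil).
#' @param sigma_delta_consumer analytical SD of that measurement (per mil).
#' @param tdf_value trophic discrimination factor used (per mil).
#' @param tdf_sigma SD of the trophic discrimination factor (per mil).
#' @return standard deviation of the trophic estimate (trophic steps).
#' @export
trophic_uncertainty <- function(mu, delta_consumer, sigma_delta_consumer,
                                tdf_value, tdf_sigma) {
  eps <- 1e-12
  if (abs(delta_consumer) < eps) {
    stop("trophic_uncertainty: consumer tracer value is (near) zero; the ",
         "relative-error term sigma(delta)/delta is undefined", call. = FALSE)
  }
  if (abs(tdf_value) < eps) {
    stop("trophic_uncertainty: trophic discrimination factor is (near) zero; ",
         "the relative-error term sigma(TDF)/TDF is undefined", call. = FALSE)
  }
  if (abs(delta_consumer) < 1) {
    warning("consumer tracer value is within 1 per mil of zero; ",
            "relative-error propagation is unstable near the reference scale",
            call. = FALSE)
  }
  abs(mu) * sqrt((sigma_delta_consumer / delta_consumer)^2 +
                   (tdf_sigma / tdf_value)^2)
}

#' Trophic discrimination of one tracer along the food web
#'
#' Predicted mean consumer value for one tracer given the base value and the
#' food-web state, by discrimination class:
#' conservative, \eqn{\mu = \mu_{base}};
#' constant, \eqn{\mu = \mu_{base} + FWL \cdot \Delta_{meta}};
#' variable, \eqn{\mu = \mu_{base} + PTS \cdot \Delta_{proto} +
#'   MTS \cdot \Delta_{meta}}.
#'
#' @param mu_base tracer value at the base of the food web (per mil).
#' @param state a [food_web_state()].
#' @param tdf one TDF registry row for the tracer.
#' @return predicted mean consumer tracer value (per mil).
#' @export
apply_discrimination <- function(mu_base, state, tdf) {
  tdf <- .tdf_row(tdf)
  switch(tdf$class,
         conservative = mu_base,
         constant = mu_base + state$FWL * tdf$delta_meta,
         variable = mu_base + state$PTS * tdf$delta_proto +
           state$MTS * tdf$delta_meta,
         stop("unknown discrimination class: ", tdf$class, call. = FALSE))
}

#' Total SD of a predicted consumer tracer value
#'
#' Combines analytical uncertainty with TDF uncertainty accumulated over the
#' trophic steps, in quadrature, by discrimination class:
#' conservative, \eqn{\sigma = \alpha};
#' constant, \eqn{\sigma = \sqrt{\alpha^2 + (FWL \cdot \sigma_{\Delta,meta})^2}};
#' variable, \eqn{\sigma = \sqrt{\alpha^2 + (PTS \cdot \sigma_{\Delta,proto})^2
#'   + (MTS \cdot \sigma_{\Delta,meta})^2}}.
#'
#' Note the constant and variable forms do not coincide even when
#' \eqn{\sigma_{\Delta,proto} = \sigma_{\Delta,meta}}: splitting FWL into
#' PTS + MTS inside the quadrature yields a smaller total than scaling a
#' single term by FWL.
#'
#' @param alpha analytical SD of the consumer measurement (per mil, > 0).
#' @param state a [food_web_state()].
#' @param tdf one TDF registry row for the tracer.
#' @return total SD of the predicted consumer tracer value (per mil).
#' @export
consumer_sd <- function(alpha, state, tdf) {
  tdf <- .tdf_row(tdf)
  stopifnot(alpha > 0)
  switch(tdf$class,
         conservative = alpha,
         constant = sqrt(alpha^2 + (state$FWL * tdf$sd_meta)^2),
         variable = sqrt(alpha^2 + (state$PTS * tdf$sd_proto)^2 +
                           (state$MTS * tdf$sd_meta)^2),
         stop("unknown discrimination class: ", tdf$class, call. = FALSE))
}

#' Full forward process model
#'
#' Predicted mean consumer tracer values for every tracer: linear mixing of
#' source means followed by class-specific trophic discrimination,
#' \deqn{\mu_{j,k} = \sum_i f_{i,k}\,\mu_{j,i} + PTS_k \Delta_{j,proto} +
#'   MTS_k \Delta_{j,meta}.}
#' Conservative tracers have both TDFs zero and constant-class tracers have
#' \eqn{\Delta_{proto} = \Delta_{meta}} so this single expression covers all
#' three classes. At fixed PTS and MTS the prediction is affine in `f`.
#'
#' @param f mixing-coefficient vector (simplex).
#' @param PTS protozoan trophic steps.
#' @param MTS metazoan trophic steps.
#' @param source_means tracer x source matrix of source means (rownames are
#'   amino acids).
#' @param tdf_table TDF registry (`omsm_tdf`) or a resolved tracer table
#'   containing rows for every tracer in `source_means`.
#' @return named numeric vector of predicted consumer tracer values (per mil).
#' @export
forward_model <- function(f, PTS, MTS, source_means, tdf_table) {
  state <- food_web_state(f, FWL = PTS + MTS, MTS = MTS)
  tracers <- rownames(source_means)
  if (is.null(tracers)) stop("source_means must have amino-acid rownames", call. = FALSE)
  base <- mix_base(f, source_means)
  out <- vapply(seq_along(tracers), function(j) {
    row <- tdf_table[tdf_table$aa == tracers[j], , drop = FALSE]
    if (nrow(row) == 0L) {
      stop("tracer ", tracers[j], " absent from TDF table", call. = FALSE)
    }
    apply_discrimination(base[j], state, row)
  }, numeric(1))
  names(out) <- tracers
  out
}
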