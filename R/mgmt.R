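# Three-state MGMT promoter methylation call from a two-probe logistic model.

#' Construct an MGMT logistic model
#'
#' A pluggable two-probe logistic model on the M-value scale with an
#' indeterminate probability band: predicted probability below `cutoff_low`
#' reads unmethylated, above `cutoff_high` methylated, in between not
#' determinable. Clinically validated coefficients are not shipped with this
#' package — load them from the published source via a model file.
#'
#' @param probes Character vector of exactly 2 probe ids.
#' @param intercept Intercept on the logit scale.
#' @param weights Numeric vector of 2 per-probe weights (M-value scale).
#' @param cutoff_low,cutoff_high Probability bounds of the indeterminate
#'   band, `0 < cutoff_low <= cutoff_high < 1`.
#' @return An `mgmt_model` object.
#' @export
mgmt_model <- function(probes, intercept, weights, cutoff_low, cutoff_high) {
  probes <- as.character(probes)
  weights <- as.numeric(weights)
  if (length(probes) != 2 || length(weights) != 2) {
    stop("the model uses exactly two probes (and two weights)")
  }
  if (!(cutoff_low > 0 && cutoff_high < 1 && cutoff_low <= cutoff_high)) {
    stop("need 0 < cutoff_low <= cutoff_high < 1")
  }
  structure(list(probes = probes, intercept = as.numeric(intercept),
                 weights = stats::setNames(weights, probes),
                 cutoff_low = cutoff_low, cutoff_high = cutoff_high),
            class = "mgmt_model")
}

#' Read an MGMT model file
#'
#' YAML with keys `probes` (2 ids), `intercept`, `weights` (2 numbers, same
#' order as probes), `cutoff_low`, `cutoff_high`. The bundled example
#' (`mgmt_model_synthetic.yaml`) carries synthetic coefficients for testing
#' only, not clinically validated values.
#'
#' @param path Model YAML path; `NULL` loads the bundled synthetic example.
#' @return An [mgmt_model()].
#' @export
read_mgmt_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mgmt_model_synthetic.yaml",
                        package = "methylDx", mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  mgmt_model(y$probes, y$intercept, unlist(y$weights),
             y$cutoff_low, y$cutoff_high)
}

#' M-value transform of a beta value
#'
#' `log2(beta / (1 - beta))`, with beta clamped to
#' `[1e-6, 1 - 1e-6]` so boundary values stay finite.
#'
#' @param beta Beta values in `[0, 1]`.
#' @param clamp Clamping bound (default `1e-6`).
#' @return M-values.
#' @export
beta_to_m <- function(beta, clamp = 1e-6) {
  b <- pmin(pmax(beta, clamp), 1 - clamp)
  log2(b / (1 - b))
}

#' Three-state MGMT promoter methylation call
#'
#' Converts the sample's beta values at the model probes to M-values, applies
#' the logistic model and reads the predicted probability against the
#' indeterminate band: `p < cutoff_low` is unmethylated, `p > cutoff_high`
#' methylated, otherwise not determinable (conventionally resolved by
#' pyrosequencing). A missing model probe yields `not_determinable` with a
#' `missing_probe` flag.
#'
#' @param betas Named numeric vector of beta values containing the model's
#'   probes.
#' @param model An [mgmt_model()].
#' @return List with `status` (`"methylated"`, `"unmethylated"`,
#'   `"not_determinable"`), `probability` (`NA` when probes are missing) and
#'   `flags`.
#' @export
mgmt_call <- function(betas, model) {
  stopifnot(inherits(model, "mgmt_model"))
  present <- model$probes %in% names(betas) &
    !is.na(betas[model$probes][match(model$probes, names(betas))])
  if (!all(present)) {
    return(list(status = "not_determinable", probability = NA_real_,
                flags = paste0("missing_probe:",
                               paste(model$probes[!present], collapse = ","))))
  }
  b <- as.numeric(betas[model$probes])
  if (any(b < 0 | b > 1)) stop("beta values must lie in [0, 1]")
  m <- beta_to_m(b)
  p <- stats::plogis(model$intercept + sum(model$weights * m))
  status <- if (p < model$cutoff_low) {
    "unmethylated"
  } else if (p > model$cutoff_high) {
    "methylated"
  } else {
    "not_determinable"
  }
  list(status = status, probability = p, flags = character(0))
}
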