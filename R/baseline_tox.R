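#' Baseline-toxicity QSAR model
#'
#' A narcosis QSAR is a linear regression of the negative log10 effect
#' concentration on the log10 liposome-water distribution ratio:
#' `-log10(EC) = a * log D_lip/w + b`. Using `D_lip/w` rather than `K_ow`
#' as the descriptor extends the model to ionizable chemicals.
#'
#' @param species Label of the test system.
#' @param a Slope (dimensionless).
#' @param b Intercept (-log10 mol/L).
#' @param r2 Coefficient of determination, if known.
#' @param n Number of chemicals behind the fit, if known.
#' @param endpoint One of `"LC50_aqueous"` (mol/L water),
#'   `"BMD50_feed"` (mol/L feed -- never pooled with aqueous endpoints in
#'   cross-species summaries), `"IC10_cell"`.
#' @param source `"registry"` for the frozen built-in coefficient sets,
#'   `"fitted"` for user fits.
#' @return An object of class `qsar_model`.
#' @export
qsar_model <- function(species, a, b, r2 = NA_real_, n = NA_integer_,
                       endpoint = c("LC50_aqueous", "BMD50_feed", "IC10_cell"),
                       source = "fitted") {
  assert_scalar_num(a, "a")
  assert_scalar_num(b, "b")
  assert_scalar_num(r2, "r2", 0, 1, allow_na = TRUE)
  endpoint <- match.arg(endpoint)
  structure(
    list(species = species, a = a, b = b, r2 = r2,
         n = if (is.na(n)) NA_integer_ else as.integer(n),
         endpoint = endpoint, source = source),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf(
    "<qsar_model %s [%s]: -log10(EC) = %.2f * logDlip/w + %.2f%s%s>\n",
    x$species, x$endpoint, x$a, x$b,
    if (!is.na(x$r2)) sprintf(", r2 = %.3f", x$r2) else "",
    if (!is.na(x$n)) sprintf(", n = %d", x$n) else ""
  ))
  invisible(x)
}

#' Built-in species baseline-toxicity registry
#'
#' Frozen coefficient sets for the five in vivo test systems. The
#' *C. elegans* and *D. magna* models were rescaled/derived from
#' `K_ow`-based literature regressions; the *D. rerio* model was developed
#' directly on `D_lip/w`; the *X. laevis* and *D. melanogaster* models are
#' regressions on experimental data for baseline toxicants (22 and 11
#' chemicals respectively), with the fly model operating on feed
#' concentration (mol/L_feed).
#'
#' @param species Optional single label; when supplied, returns that model
#'   and raises an error of class `chemtriage_unknown_species` (listing the
#'   known labels) for anything else.
#' @return A named list of [qsar_model()]s, or one model.
#' @examples
#' species_registry("D. rerio")
#' names(species_registry())
#' @export
species_registry <- function(species = NULL) {
  reg <- list(
    "C. elegans" = qsar_model("C. elegans", a = 0.81, b = 1.15,
                              endpoint = "LC50_aqueous", source = "registry"),
    "D. magna" = qsar_model("D. magna", a = 0.82, b = 1.48,
                            endpoint = "LC50_aqueous", source = "registry"),
    "D. rerio" = qsar_model("D. rerio", a = 0.99, b = 0.78,
                            endpoint = "LC50_aqueous", source = "registry"),
    "X. laevis" = qsar_model("X. laevis", a = 0.61, b = 2.12, r2 = 0.690,
                             n = 22L, endpoint = "LC50_aqueous",
                             source = "registry"),
    "D. melanogaster" = qsar_model("D. melanogaster", a = 0.83, b = 0.52,
                                   r2 = 0.724, n = 11L,
                                   endpoint = "BMD50_feed", source = "registry")
  )
  if (is.null(species)) return(reg)
  if (!species %in% names(reg)) {
    ct_abort(
      sprintf("unknown species %s; known labels: %s", dQuote(species),
              paste(names(reg), collapse = ", ")),
      class = "unknown_species"
    )
  }
  reg[[species]]
}

#' Predict -log10 effect concentration from a QSAR
#'
#' Evaluates `a * log D_lip/w + b`. Values of `log D_lip/w` below -1 are
#' outside the model domain (the empirical floor of membrane
#' distribution); they are computed anyway but flagged with a warning.
#'
#' @param model A [qsar_model()].
#' @param log_dlipw log10 liposome-water distribution ratio.
#' @return `-log10` effect concentration in the model's units.
#' @seealso [predict_lc50()] for the back-transformed concentration.
#' @export
predict_neg_log_lc50 <- function(model, log_dlipw) {
  stopifnot(inherits(model, "qsar_model"))
  if (any(is.na(log_dlipw))) {
    ct_abort("`log_dlipw` is absent", class = "missing_input")
  }
  if (any(log_dlipw < -1)) {
    warn("log_dlipw below the -1 domain floor; prediction is extrapolated")
  }
  model$a * log_dlipw + model$b
}

#' Predicted effect concentration on the linear scale
#'
#' @inheritParams predict_neg_log_lc50
#' @return Effect concentration, `10^-(a * log_dlipw + b)`, in the model's
#'   units (mol/L, or mol/L_feed for feed-based models).
#' @export
predict_lc50 <- function(model, log_dlipw) {
  10^(-predict_neg_log_lc50(model, log_dlipw))
}

#' Fit a baseline-toxicity QSAR by ordinary least squares
#'
#' Regresses `-log10` effect concentrations on `log D_lip/w` with
#' [stats::lm()].
#'
#' @param log_dlipw Numeric descriptor vector.
#' @param neg_log_effect `-log10` effect concentrations, same length.
#' @param species Label recorded on the fitted model.
#' @param endpoint Endpoint label, see [qsar_model()].
#' @return A [qsar_model()] with `a`, `b`, `r2`, and `n` filled in.
#' @export
fit_baseline_qsar <- function(log_dlipw, neg_log_effect, species = "user",
                              endpoint = "LC50_aqueous") {
  if (length(log_dlipw) != length(neg_log_effect)) {
    ct_abort("descriptor and response lengths differ", class = "bad_input")
  }
  keep <- is.finite(log_dlipw) & is.finite(neg_log_effect)
  if (any(!keep)) {
    ct_abort("non-finite values in fit input", class = "bad_input")
  }
  n <- length(log_dlipw)
  if (n < 3L) {
    ct_abort("at least 3 points are required to fit a QSAR",
             class = "insufficient_data")
  }
  if (stats::sd(log_dlipw) == 0) {
    ct_abort("zero variance in log_dlipw; fit is singular",
             class = "singular_fit")
  }
  fit <- stats::lm(neg_log_effect ~ log_dlipw)
  # r2 from residuals directly; summary.lm warns on exact fits
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((neg_log_effect - mean(neg_log_effect))^2)
  qsar_model(species,
             a = unname(stats::coef(fit)[2L]),
             b = unname(stats::coef(fit)[1L]),
             r2 = max(0, min(1, 1 - ss_res / ss_tot)),
             n = n, endpoint = endpoint, source = "fitted")
}

#' Specificity ratio of an effect concentration
#'
#' The specificity ratio SR compares the predicted baseline (narcosis)
#' effect concentration with the experimental one:
#' `SR = predicted / experimental`. SR near 1 means the chemical is only
#' as toxic as its hydrophobicity demands (baseline); SR at or above the
#' threshold (default 10, boundary inclusive) flags specific or reactive
#' toxicity.
#'
#' @param predicted_effect,experimental_effect Positive concentrations in
#'   the same units.
#' @param threshold Classification cutoff (default 10).
#' @return A list of class `specificity_result`: `sr` and `classification`
#'   (`"baseline"` or `"specific/reactive"`).
#' @export
specificity_ratio <- function(predicted_effect, experimental_effect,
                              threshold = 10) {
  assert_scalar_num(predicted_effect, "predicted_effect", lower = 1e-300)
  assert_scalar_num(experimental_effect, "experimental_effect", lower = 1e-300)
  assert_scalar_num(threshold, "threshold", lower = 1e-300)
  sr <- predicted_effect / experimental_effect
  structure(
    list(sr = sr,
         classification = if (sr >= threshold) "specific/reactive" else "baseline"),
    class = "specificity_result"
  )
}
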