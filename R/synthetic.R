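#' Configuration for the synthetic chemical generator
#'
#' Defaults encode the property structure of a diverse toxicity-testing
#' collection: neutral-species `log K_ow` from a truncated normal with
#' mean 2.31 over the range -4.63 to 8.50; roughly 40% of chemicals
#' 75-100% neutral at pH 7.4, roughly 30% more than 80% charged, the rest
#' intermediate; purity clustered just below 100%; lognormal cost with a
#' tail beyond the affordability limit; and a minority of volatile
#' chemicals.
#'
#' @param n Number of chemicals to generate.
#' @param seed Integer seed; every draw is reproducible from it.
#' @param log_kow_mean,log_kow_sd,log_kow_range Truncated-normal
#'   parameters of neutral-species `log K_ow`.
#' @param frac_neutral_dominant,frac_charged Mixture weights of the
#'   neutral-dominant and strongly charged ionization classes (the
#'   remainder is intermediate).
#' @param cost_meanlog,cost_sdlog Lognormal cost parameters (euros).
#' @param purity_mean_deficit Mean of the exponential deficit below 100%
#'   purity.
#' @param volatile_fraction Fraction of chemicals drawn with high air-water
#'   partitioning.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 500, seed = 1,
                             log_kow_mean = 2.31, log_kow_sd = 2.0,
                             log_kow_range = c(-4.63, 8.50),
                             frac_neutral_dominant = 0.40,
                             frac_charged = 0.30,
                             cost_meanlog = log(200), cost_sdlog = 1.2,
                             purity_mean_deficit = 1.2,
                             volatile_fraction = 0.10) {
  assert_scalar_num(n, "n", lower = 1)
  assert_scalar_num(seed, "seed")
  assert_scalar_num(frac_neutral_dominant, "frac_neutral_dominant", 0, 1)
  assert_scalar_num(frac_charged, "frac_charged", 0, 1)
  assert_scalar_num(volatile_fraction, "volatile_fraction", 0, 1)
  if (frac_neutral_dominant + frac_charged > 1) {
    ct_abort("ionization class fractions must sum to at most 1",
             class = "bad_input")
  }
  if (log_kow_mean < log_kow_range[1] || log_kow_mean > log_kow_range[2]) {
    ct_abort("log_kow_range must contain log_kow_mean", class = "bad_input")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         log_kow_mean = log_kow_mean, log_kow_sd = log_kow_sd,
         log_kow_range = log_kow_range,
         frac_neutral_dominant = frac_neutral_dominant,
         frac_charged = frac_charged,
         cost_meanlog = cost_meanlog, cost_sdlog = cost_sdlog,
         purity_mean_deficit = purity_mean_deficit,
         volatile_fraction = volatile_fraction),
    class = "synthetic_config"
  )
}

rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

draw_ionization <- function(class) {
  add_second <- stats::runif(1) < 0.15
  if (class == "neutral") {
    if (stats::runif(1) < 0.5) return(ionization_profile())
    if (stats::runif(1) < 0.5) {
      pka <- stats::runif(1, 8.5, 11); kind <- "acid"
    } else {
      pka <- stats::runif(1, 2.0, 6.4); kind <- "base"
    }
  } else if (class == "charged") {
    if (stats::runif(1) < 0.5) {
      pka <- stats::runif(1, 2.0, 6.6); kind <- "acid"
    } else {
      pka <- stats::runif(1, 8.2, 11); kind <- "base"
    }
  } else {
    pka <- stats::runif(1, 6.8, 8.0)
    kind <- if (stats::runif(1) < 0.5) "acid" else "base"
  }
  if (add_second) {
    shift <- stats::runif(1, 1, 3)
    pka <- c(pka, if (kind == "acid") pka + shift else pka - shift)
    kind <- c(kind, kind)
  }
  ionization_profile(pka, kind)
}

#' Generate a synthetic chemical-record pool
#'
#' Draws a fully populated chemical-record table from a
#' [synthetic_config()]: truncated-normal `log K_ow`, ionization profiles
#' matching the configured neutral/charged mixture, air-water partition
#' coefficients with a volatile minority, purity, cost, logistics flags,
#' toxicity-group and mechanism annotations, and valid synthetic CAS
#' numbers. Byte-identical output for a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @return A `chemical_records` tibble with `n` rows; the seed is recorded
#'   in the `"seed"` attribute.
#' @export
generate_chemicals <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  records <- withr::with_seed(config$seed, {
    log_kow <- rtrunc_norm(n, config$log_kow_mean, config$log_kow_sd,
                           config$log_kow_range)
    classes <- sample(c("neutral", "charged", "intermediate"), n, replace = TRUE,
                      prob = c(config$frac_neutral_dominant, config$frac_charged,
                               1 - config$frac_neutral_dominant - config$frac_charged))
    ion <- lapply(classes, draw_ionization)
    volatile <- stats::runif(n) < config$volatile_fraction
    log_kaw <- ifelse(volatile, stats::runif(n, -3, 0), stats::runif(n, -10, -5))

    purity <- pmax(100 - stats::rexp(n, 1 / config$purity_mean_deficit), 80)
    cost <- stats::rlnorm(n, config$cost_meanlog, config$cost_sdlog)

    body1 <- sample(1000:9999999, n)
    body2 <- sprintf("%02d", sample(0:99, n, replace = TRUE))
    cas <- mapply(cas_with_checksum, body1, body2, USE.NAMES = FALSE)

    group_pool <- c("hepatotoxicant", "nephrotoxicant",
                    "developmental_neurotoxicant", "cardiotoxicant",
                    "neurotoxicant", "immunotoxicant", "endocrine_disruptor",
                    "environmental")
    moa_pool <- sprintf("moa_%02d", 1:40)
    use_pool <- c("pharmaceutical", "pesticide", "industrial",
                  "food_additive", "consumer_goods", "personal_care")
    tox_groups <- lapply(seq_len(n), function(i) {
      sample(group_pool, sample(1:3, 1, prob = c(0.5, 0.35, 0.15)))
    })
    moa_tags <- lapply(seq_len(n), function(i) {
      sample(moa_pool, sample(1:2, 1, prob = c(0.7, 0.3)))
    })
    use_cats <- lapply(seq_len(n), function(i) {
      sample(use_pool, sample(1:2, 1, prob = c(0.7, 0.3)))
    })

    chemical_records(
      name = sprintf("synthetic_chem_%04d", seq_len(n)),
      cas = cas,
      log_kow = log_kow, log_kaw = log_kaw, ionization = ion,
      purity_pct = purity, cost_eur = cost,
      available = stats::runif(n) < 0.95,
      restricted = stats::runif(n) < 0.02,
      hazard_excluded = stats::runif(n) < 0.02,
      stability_ok = stats::runif(n) < 0.97,
      toxicity_groups = tox_groups, moa_tags = moa_tags,
      use_categories = use_cats,
      exposome = stats::runif(n) < 0.20,
      reference_compound = stats::runif(n) < 0.08,
      moa_exception = stats::runif(n) < 0.02
    )
  })
  attr(records, "seed") <- config$seed
  records
}

#' Generate synthetic effect-concentration data
#'
#' Simulates an effect dataset consistent with a baseline-toxicity QSAR:
#' for baseline chemicals, `-log10(EC) = a * log D_lip/w + b + e` with
#' Gaussian noise `e` on the log scale (lognormal concentrations);
#' specifically acting chemicals are additionally shifted toward higher
#' potency by `specific_shift` log units. True class labels are returned
#' for recovery scoring.
#'
#' @param model A [qsar_model()] supplying `a` and `b`.
#' @param n Number of chemicals (>= 1).
#' @param noise_sd Standard deviation of the log10 noise (>= 0).
#' @param specific_fraction Fraction of specifically acting chemicals.
#' @param specific_shift Potency shift of the specific class, log10 units
#'   (> 0).
#' @param seed Integer seed.
#' @param log_dlipw_range Descriptor range sampled uniformly.
#' @return Tibble: `id`, `log_dlipw`, `neg_log_effect`, `effect_mol_l`,
#'   `true_class` (`"baseline"`/`"specific"`).
#' @export
generate_effect_data <- function(model, n, noise_sd = 0.3,
                                 specific_fraction = 0, specific_shift = 2,
                                 seed = 1, log_dlipw_range = c(-1, 4)) {
  stopifnot(inherits(model, "qsar_model"))
  assert_scalar_num(n, "n", lower = 1)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(specific_fraction, "specific_fraction", 0, 1)
  if (specific_fraction > 0) {
    assert_scalar_num(specific_shift, "specific_shift", lower = 1e-12)
  }
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    x <- stats::runif(n, log_dlipw_range[1], log_dlipw_range[2])
    n_spec <- round(n * specific_fraction)
    cls <- sample(c(rep("specific", n_spec), rep("baseline", n - n_spec)))
    y <- model$a * x + model$b +
      ifelse(cls == "specific", specific_shift, 0) +
      stats::rnorm(n, 0, noise_sd)
    tibble(
      id = sprintf("synthetic_effect_%04d", seq_len(n)),
      log_dlipw = x,
      neg_log_effect = y,
      effect_mol_l = 10^(-y),
      true_class = cls
    )
  })
}
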