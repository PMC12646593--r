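# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles by enumeration, never by
# calling the implementation path under test.

# CAS checksum by direct digit expansion of the standard rule
oracle_cas_valid <- function(cas) {
  parts <- strsplit(cas, "-", fixed = TRUE)[[1]]
  digits <- as.integer(strsplit(paste0(parts[1], parts[2]), "")[[1]])
  s <- 0L
  w <- 1L
  for (d in rev(digits)) {
    s <- s + d * w
    w <- w + 1L
  }
  (s %% 10L) == as.integer(parts[3])
}

# Boltzmann-style enumeration of every protonation microstate: each group
# is a two-state system, a microstate's weight is the product of its group
# weights, fractions are summed by net charge.
oracle_species_fractions <- function(profile, ph) {
  ngrp <- length(profile$pka)
  if (ngrp == 0L) {
    return(c(f_minus2 = 0, f_minus = 0, f_neutral = 1, f_plus = 0, f_plus2 = 0))
  }
  states <- expand.grid(rep(list(c(0L, 1L)), ngrp)) # 1 = ionized form
  w <- numeric(nrow(states))
  charge <- integer(nrow(states))
  for (s in seq_len(nrow(states))) {
    ws <- 1
    ch <- 0L
    for (g in seq_len(ngrp)) {
      if (states[s, g] == 1L) {
        if (profile$kind[g] == "acid") {
          ws <- ws * 10^(ph - profile$pka[g])
          ch <- ch - 1L
        } else {
          ws <- ws * 10^(profile$pka[g] - ph)
          ch <- ch + 1L
        }
      }
    }
    w[s] <- ws
    charge[s] <- ch
  }
  w <- w / sum(w)
  out <- c(f_minus2 = 0, f_minus = 0, f_neutral = 0, f_plus = 0, f_plus2 = 0)
  for (s in seq_along(w)) {
    slot <- c("f_minus2", "f_minus", "f_neutral", "f_plus", "f_plus2")[charge[s] + 3L]
    out[slot] <- out[slot] + w[s]
  }
  out
}

# explicit three-compartment mass balance: unit water concentration, phase
# amounts are D x V products, f_free is the water share of total mass
oracle_f_free <- function(d_medium_w, d_cell_w, setup) {
  v_medium <- 1
  v_sorptive <- (setup$vf_protein_medium + setup$vf_lipid_medium) * v_medium
  v_cell <- setup$v_cell_over_v_bioassay * v_medium
  c_water <- 1
  amount_water <- c_water * v_medium
  amount_medium_bound <- d_medium_w * c_water * v_sorptive
  amount_cell <- d_cell_w * c_water * v_cell
  amount_water / (amount_water + amount_medium_bound + amount_cell)
}

# closed-form simple-regression normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  a <- sxy / sxx
  b <- mean(y) - a * mean(x)
  yhat <- a * x + b
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(a = a, b = b, r2 = r2)
}

# exhaustive search for the maximum number of records admissible under the
# stage-3 constraints (per-group moa-tag cap and group size cap)
oracle_stage3_max <- function(groups, tags, moa_cap, group_cap) {
  n <- length(groups)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    for (g in unique(unlist(groups[sel]))) {
      members <- sel[vapply(groups[sel], function(x) g %in% x, logical(1))]
      if (length(members) > group_cap) { ok <- FALSE; break }
      tg <- table(unlist(tags[members]))
      if (length(tg) && any(tg > moa_cap)) { ok <- FALSE; break }
    }
    if (ok) best <- max(best, length(sel))
  }
  best
}

# single-row record builder with benign defaults, overridable per field
make_record <- function(name, log_kow = 2, log_kaw = -8,
                        ionization = ionization_profile(),
                        purity_pct = 99.5, cost_eur = 100,
                        available = TRUE, restricted = FALSE,
                        hazard_excluded = FALSE, stability_ok = TRUE,
                        toxicity_groups = list("hepatotoxicant"),
                        moa_tags = list(character()),
                        exposome = FALSE, reference_compound = FALSE,
                        moa_exception = FALSE, cas = NA_character_) {
  chemical_records(
    name = name, cas = cas, log_kow = log_kow, log_kaw = log_kaw,
    ionization = list(ionization), purity_pct = purity_pct,
    cost_eur = cost_eur, available = available, restricted = restricted,
    hazard_excluded = hazard_excluded, stability_ok = stability_ok,
    toxicity_groups = toxicity_groups, moa_tags = moa_tags,
    exposome = exposome, reference_compound = reference_compound,
    moa_exception = moa_exception
  )
}

# random ionization profile for property tests
random_profile <- function() {
  n_acid <- sample(0:2, 1)
  n_base <- sample(0:2, 1)
  pka <- c(runif(n_acid, 0, 14), runif(n_base, 0, 14))
  kind <- c(rep("acid", n_acid), rep("base", n_base))
  ionization_profile(pka, kind)
}
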