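#' Synthetic secretion-profile generator
#'
#' The field GC-MS data behind the iguana study are not publicly deposited,
#' so the pipeline ships a generator that emulates their statistical
#' structure: sparse, compositional percent profiles over ~113 compounds,
#' collected in the 11 non-empty year x species x sex design cells, with a
#' small set of compounds carrying planted species, sex and year effects.
#'
#' The generative model per sample s (in design cell g) and compound i is
#' \deqn{y_{si} = z_{si} \exp(m_i + \beta_i(g) + \epsilon_{si}),}
#' with baseline log-intensity `m_i ~ N(mu0, tau^2)`, group log-effects
#' `beta_i(g)` on the planted compounds, lognormal noise
#' `epsilon ~ N(0, noise_sd^2)`, and presence `z ~ Bernoulli(pi_i)`.
#' Rows are then closed to percent (sum 100), so planted effects leak into
#' every compound's relative abundance exactly as real compositional closure
#' would.
#'
#' @param cell_counts data.frame with columns `year, species, sex, n`.
#' @param n_compounds number of compounds (columns).
#' @param class_proportions named numeric summing to 1 over the molecular
#'   class vocabulary; used to annotate compounds.
#' @param baseline_mu,baseline_tau mean and sd of the baseline log-intensity.
#' @param species_markers,sex_markers,year_markers integer indices of the
#'   compounds carrying each planted effect.
#' @param delta_species,delta_sex,delta_year multiplicative log-effects; a
#'   species effect of `d` means marthae and subcristatus means differ by
#'   factor `exp(d)` on the latent scale (sign alternates across markers).
#' @param presence_prob per-compound Bernoulli presence probability
#'   (length `n_compounds`), or NULL to draw from Beta(5, 2) with markers
#'   fixed at 0.95.
#' @param year_presence_shift additive shift applied to `presence_prob` for
#'   non-2012 years (clamped to \[0, 1\]); default 0.
#' @param noise_sd lognormal noise sd.
#' @param seed integer seed governing both spec-level draws (baselines,
#'   presence probabilities, class labels) and [generate_profiles()].
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(cell_counts,
                           n_compounds = 113,
                           class_proportions = default_class_proportions(),
                           baseline_mu = 0, baseline_tau = 1.5,
                           species_markers = 1:7,
                           sex_markers = 8:10,
                           year_markers = 11:15,
                           delta_species = 2,
                           delta_sex = 1,
                           delta_year = 1,
                           presence_prob = NULL,
                           year_presence_shift = 0,
                           noise_sd = 1,
                           seed = 1L) {
  stopifnot(all(cell_counts$n >= 0),
            abs(sum(class_proportions) - 1) < 1e-8,
            is.finite(delta_species), is.finite(delta_sex),
            is.finite(delta_year),
            max(species_markers, sex_markers, year_markers) <= n_compounds)
  drawn <- with_seed(seed, {
    list(m = stats::rnorm(n_compounds, baseline_mu, baseline_tau),
         pi = stats::rbeta(n_compounds, 5, 2),
         classes = sample(names(class_proportions), n_compounds,
                          replace = TRUE, prob = class_proportions))
  })
  if (is.null(presence_prob)) {
    presence_prob <- drawn$pi
    presence_prob[c(species_markers, sex_markers, year_markers)] <- 0.95
  }
  stopifnot(length(presence_prob) == n_compounds,
            all(presence_prob >= 0 & presence_prob <= 1))
  structure(list(
    cell_counts = cell_counts,
    n_compounds = n_compounds,
    class_proportions = class_proportions,
    baseline_log_mean = drawn$m,
    mol_class = drawn$classes,
    species_markers = species_markers, delta_species = delta_species,
    sex_markers = sex_markers, delta_sex = delta_sex,
    year_markers = year_markers, delta_year = delta_year,
    presence_prob = presence_prob,
    year_presence_shift = year_presence_shift,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Molecular-class mixture used to annotate synthetic compounds
#'
#' Fractions approximate the class composition of lipophilic femoral-gland
#' secretions (fatty acids and alcohols dominant, with alkanes, alkenes,
#' sterols, pregnane steroids and aldehydes as minor classes).
#'
#' @return named numeric vector summing to 1.
#' @export
default_class_proportions <- function() {
  c("fatty acid" = 0.35, "fatty alcohol" = 0.15, "alkane" = 0.12,
    "alkene" = 0.10, "sterol" = 0.10, "pregnane steroid" = 0.06,
    "aldehyde" = 0.07, "other" = 0.05)
}

#' Study-design spec: 227 samples in 11 non-empty design cells
#'
#' Sample counts per year x species x sex cell follow the study design
#' (2012: 24/54 marthae F/M, 31/41 subcristatus F/M; 2014: 15/15 and 13/17;
#' 2015: 3/5 marthae and 9 subcristatus males, no subcristatus females),
#' 113 compounds, reproductive season in 2012/2014 and non-reproductive in
#' 2015.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
default_study_spec <- function(seed = 1L, ...) {
  cells <- data.frame(
    year = c(2012L, 2012L, 2012L, 2012L, 2014L, 2014L, 2014L, 2014L,
             2015L, 2015L, 2015L),
    species = c("marthae", "marthae", "subcristatus", "subcristatus",
                "marthae", "marthae", "subcristatus", "subcristatus",
                "marthae", "marthae", "subcristatus"),
    sex = c("F", "M", "F", "M", "F", "M", "F", "M", "F", "M", "M"),
    n = c(24L, 54L, 31L, 41L, 15L, 15L, 13L, 17L, 3L, 5L, 9L),
    stringsAsFactors = FALSE)
  synthetic_spec(cell_counts = cells, seed = seed, ...)
}

#' Null version of a spec: all planted effects removed
#'
#' Sets every group log-effect and group presence shift to 0, making all
#' group labels exchangeable by construction — the substrate for
#' type-I-error calibration. Idempotent.
#'
#' @param spec a `synthetic_spec`.
#' @return a `synthetic_spec` with zero effects.
#' @export
null_spec <- function(spec) {
  spec$delta_species <- 0
  spec$delta_sex <- 0
  spec$delta_year <- 0
  spec$year_presence_shift <- 0
  spec
}

season_of_year <- function(year) ifelse(year == 2015L, "nrs", "rs")

#' Generate a synthetic compound table and metadata from a spec
#'
#' Deterministic for a fixed `spec$seed`; the random stream (presence and
#' noise draws) does not depend on the effect magnitudes, so tables
#' generated from specs differing only in a delta share common random
#' numbers. A sample drawing all-zero presence is redrawn (at most 100
#' retries, then an error).
#'
#' @param spec a `synthetic_spec`.
#' @return list with `table` (a [compound_table()]) and `metadata`
#'   (data.frame `sample_id, species, sex, year, season`).
#' @export
generate_profiles <- function(spec) {
  cells <- spec$cell_counts[spec$cell_counts$n > 0, , drop = FALSE]
  n <- sum(cells$n)
  p <- spec$n_compounds
  metadata <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    species = rep(cells$species, cells$n),
    sex = rep(cells$sex, cells$n),
    year = rep(cells$year, cells$n),
    stringsAsFactors = FALSE)
  metadata$season <- season_of_year(metadata$year)

  # sign pattern alternates so planted effects favour each species/sex/year
  sgn <- function(idx) rep_len(c(1, -1), length(idx))
  eff <- matrix(0, n, p)
  sp <- ifelse(metadata$species == "marthae", 0.5, -0.5)
  eff[, spec$species_markers] <- outer(sp, sgn(spec$species_markers) *
                                         spec$delta_species)
  sx <- ifelse(metadata$sex == "M", 0.5, -0.5)
  eff[, spec$sex_markers] <- eff[, spec$sex_markers] +
    outer(sx, sgn(spec$sex_markers) * spec$delta_sex)
  yr <- (match(metadata$year, sort(unique(spec$cell_counts$year))) - 2)
  eff[, spec$year_markers] <- eff[, spec$year_markers] +
    outer(yr, sgn(spec$year_markers) * spec$delta_year)

  pi_mat <- matrix(spec$presence_prob, n, p, byrow = TRUE)
  if (spec$year_presence_shift != 0) {
    shift <- ifelse(metadata$year != 2012L, spec$year_presence_shift, 0)
    pi_mat <- pmin(1, pmax(0, pi_mat + shift))
  }

  raw <- with_seed(spec$seed, {
    u <- matrix(stats::runif(n * p), n, p)
    eps <- matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
    z <- (u < pi_mat) * 1
    x <- z * exp(spec$baseline_log_mean[col(z)] + eff + eps)
    for (retry in seq_len(100)) {
      empty <- which(rowSums(x) == 0)
      if (!length(empty)) break
      for (s in empty) {
        z_s <- (stats::runif(p) < pi_mat[s, ]) * 1
        x[s, ] <- z_s * exp(spec$baseline_log_mean + eff[s, ] +
                              stats::rnorm(p, 0, spec$noise_sd))
      }
    }
    if (any(rowSums(x) == 0))
      stop("sample with all-zero presence after bounded retries")
    x
  })
  dimnames(raw) <- list(metadata$sample_id, sprintf("c%03d", seq_len(p)))
  ann <- data.frame(compound_id = colnames(raw),
                    name = sprintf("compound_%03d", seq_len(p)),
                    chem_id = NA_character_,
                    mol_class = spec$mol_class,
                    match_score = NA_real_,
                    stringsAsFactors = FALSE)
  tab <- normalize_rows(compound_table(raw, ann))
  list(table = tab, metadata = metadata)
}
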