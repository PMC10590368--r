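# Latent-factor lognormal community generator.
#
# Log-biomass of taxon j in sample s:
#   log B_js = mu_j + sum_g L_jg F_gs + w_j T_s + eps_js
# with independent standard-normal guild factors F_g per sample, loadings
# L_jg = +guild_loading for guild members and -antagonist_loading for
# antagonist taxa of the same guild, optional secondary "bridge" loadings
# onto a neighbouring guild factor, optional per-taxon thermal sensitivity
# w_j on a standardized seasonal forcing T_s (off by default), and
# eps ~ N(0, noise_sd). Biomass is exp(log-biomass), rescaled so the
# sample-mean total biomass equals biomass_scale exactly.
#
# On the log scale the model gives closed-form population correlations:
# corr = cov2cor(L L^T + noise_sd^2 I); for a single shared factor this is
# a_i a_j / sqrt((a_i^2 + s^2)(a_j^2 + s^2)), signed by the loadings.

#' Specification of one synthetic thermal class
#'
#' @param name class name (e.g. "CW").
#' @param n_taxa number of taxa (>= 2).
#' @param n_guilds number of consumption guilds among the structured taxa.
#' @param guild_loading loading of guild members on their guild factor, in
#'   `[0, 1]` (the cohesion knob).
#' @param guild_coverage fraction of taxa that carry guild structure; the
#'   rest are independent noise taxa (isolated in the true network).
#' @param antagonist_fraction fraction of each guild's taxa acting as
#'   antagonists (negative loading), in `[0, 1]`.
#' @param antagonist_loading magnitude of the antagonist loading, in `[0, 1]`.
#' @param bridge_fraction fraction of guild taxa that also load (positively,
#'   with `bridge_loading`) on the next guild's factor, creating between-guild
#'   bridges; 0 (default) recovers the pure single-factor model.
#' @param bridge_loading magnitude of the secondary loading.
#' @param loading_jitter relative spread of per-taxon loadings: each loading
#'   is multiplied by U(1 - loading_jitter, 1); 0 (default) = exact loadings.
#' @param noise_sd SD of the taxon-specific log-scale noise (> 0).
#' @param thermal_sensitivity SD of per-taxon weights on the standardized
#'   seasonal temperature forcing; 0 (default) disables seasonality in the
#'   biomass channel so network tests are not confounded by shared trends.
#' @param biomass_scale mean total biomass per sample, mg l^-1.
#' @param winter_temp_mean,winter_temp_sd winter water temperature mean and
#'   noise SD, deg C.
#' @param annual_temp_mean annual mean water temperature, deg C.
#' @param env_profile named list of `c(mean, sd)` pairs for the non-thermal
#'   environmental variables.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(name, n_taxa, n_guilds = 3,
                       guild_loading = 0.35, guild_coverage = 1,
                       antagonist_fraction = 0.3, antagonist_loading = 0.35,
                       bridge_fraction = 0, bridge_loading = 0.25,
                       loading_jitter = 0, noise_sd = 0.35,
                       thermal_sensitivity = 0,
                       biomass_scale = 1,
                       winter_temp_mean = 5, winter_temp_sd = 2,
                       annual_temp_mean = 13,
                       env_profile = NULL) {
  stopifnot(is.character(name), nchar(name) > 0,
            n_taxa >= 2, n_guilds >= 1,
            guild_loading >= 0, guild_loading <= 1,
            guild_coverage >= 0, guild_coverage <= 1,
            antagonist_fraction >= 0, antagonist_fraction <= 1,
            antagonist_loading >= 0, antagonist_loading <= 1,
            bridge_fraction >= 0, bridge_fraction <= 1,
            bridge_loading >= 0, bridge_loading <= 1,
            loading_jitter >= 0, loading_jitter < 1,
            noise_sd > 0, thermal_sensitivity >= 0, biomass_scale > 0)
  structure(as.list(environment()), class = "class_spec")
}

#' Scenario configuration for the multi-class generator
#'
#' Defaults emulate the study design the pipeline targets: 3 thermal classes
#' (CW/MW/WW) x 84 samples, 61/74/89 taxa, with a shared-taxon fraction such
#' that about 26% of the taxon union is common to all classes.
#'
#' @param classes list of [class_spec()] objects with unique names.
#' @param n_samples_per_class samples per class (>= 8; default 84).
#' @param shared_fraction target fraction of the taxon union common to all
#'   classes (default 0.26).
#' @param rng_seed integer master seed; per-class streams are derived from it
#'   by stable hashing of the class name, so results do not depend on class
#'   order.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(classes = default_class_specs(),
                            n_samples_per_class = 84,
                            shared_fraction = 0.26,
                            rng_seed = 1L) {
  stopifnot(n_samples_per_class >= 8,
            shared_fraction >= 0, shared_fraction <= 1)
  nms <- vapply(classes, function(s) s$name, "")
  if (anyDuplicated(nms)) stop("class names must be unique")
  structure(list(classes = classes,
                 n_samples_per_class = as.integer(n_samples_per_class),
                 shared_fraction = shared_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "scenario_config")
}

#' Default CW/MW/WW class specifications
#'
#' Taxon counts (61/74/89), mean total biomass (28.25/0.730/0.094 mg l^-1),
#' winter temperature (5.63+-2.19 / 8.60+-0.76 / 15.35+-1.41 deg C), annual
#' mean temperature (13.61/14.69/18.49 deg C) and the environmental variable
#' means/SDs follow the reported per-class summaries of the study system the
#' generator emulates. Guild structure (counts, coverage, antagonist share)
#' decreases in cohesion from CW to WW, mirroring the reported network
#' ordering; loadings are set so ground-truth pairs have population
#' correlation 0.5 on the log scale.
#'
#' @return List of three [class_spec()] objects named CW, MW, WW.
#' @export
default_class_specs <- function() {
  list(
    class_spec("CW", n_taxa = 61, n_guilds = 3, guild_coverage = 0.60,
               antagonist_fraction = 0.5, biomass_scale = 28.25,
               winter_temp_mean = 5.63, winter_temp_sd = 2.19,
               annual_temp_mean = 13.61,
               env_profile = env_profile_cw()),
    class_spec("MW", n_taxa = 74, n_guilds = 5, guild_coverage = 0.45,
               antagonist_fraction = 0.3, biomass_scale = 0.730,
               winter_temp_mean = 8.60, winter_temp_sd = 0.76,
               annual_temp_mean = 14.69,
               env_profile = env_profile_mw()),
    class_spec("WW", n_taxa = 89, n_guilds = 8, guild_coverage = 0.40,
               antagonist_fraction = 0.15, biomass_scale = 0.094,
               winter_temp_mean = 15.35, winter_temp_sd = 1.41,
               annual_temp_mean = 18.49,
               env_profile = env_profile_ww()))
}

env_profile_cw <- function() list(
  DO = c(9.36, 1.35), pH = c(7.80, 0.39), Chl_a = c(5.10, 2.86),
  TOC = c(3.85, 3.37), PO4_P = c(0.020, 0.010), TP = c(0.125, 0.175),
  NO3_N = c(0.160, 0.053), NH4_N = c(0.080, 0.053), TN = c(0.299, 0.124),
  Turbidity = c(17.30, 7.08), SD_m = c(0.756, 0.168), Color = c(15.00, 7.09),
  SSmin = c(2.95, 2.79), SSorg = c(3.09, 3.05), SStot = c(6.05, 4.28),
  Fe = c(0.165, 0.098))

env_profile_mw <- function() list(
  DO = c(9.33, 1.33), pH = c(7.80, 0.24), Chl_a = c(4.32, 3.74),
  TOC = c(1.98, 0.71), PO4_P = c(0.024, 0.014), TP = c(0.109, 0.048),
  NO3_N = c(0.143, 0.063), NH4_N = c(0.083, 0.059), TN = c(0.238, 0.077),
  Turbidity = c(12.56, 7.53), SD_m = c(0.919, 0.166), Color = c(10.04, 3.91),
  SSmin = c(0.975, 0.868), SSorg = c(3.00, 2.64), SStot = c(3.98, 3.04),
  Fe = c(0.255, 0.204))

env_profile_ww <- function() list(
  DO = c(7.59, 0.97), pH = c(7.69, 0.29), Chl_a = c(1.99, 4.42),
  TOC = c(1.63, 0.62), PO4_P = c(0.025, 0.012), TP = c(0.122, 0.068),
  NO3_N = c(0.118, 0.045), NH4_N = c(0.098, 0.098), TN = c(0.220, 0.126),
  Turbidity = c(9.74, 5.14), SD_m = c(1.46, 0.32), Color = c(7.39, 2.71),
  SSmin = c(1.46, 1.42), SSorg = c(2.76, 2.19), SStot = c(4.28, 2.88),
  Fe = c(0.138, 0.062))

# Stable per-class seed derived from the master seed and the class name,
# independent of class order; kept below 2^31.
class_seed <- function(rng_seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(rng_seed)) * 7919 + h * 104729) %% 2147483629)
}

guild_loadings <- function(spec, seed) {
  set.seed(seed)
  n <- spec$n_taxa
  G <- spec$n_guilds
  n_structured <- round(spec$guild_coverage * n)
  if (n_structured > 0 && n_structured < 2 * G)
    stop("guilds must be non-degenerate: need at least 2 taxa per guild ",
         sprintf("(%d structured taxa for %d guilds)", n_structured, G))
  L <- matrix(0, n, G)
  guild <- rep(NA_integer_, n)
  if (n_structured > 0) {
    guild[seq_len(n_structured)] <- sort(rep_len(seq_len(G), n_structured))
    for (g in seq_len(G)) {
      members <- which(guild == g)
      k <- length(members)
      n_ant <- round(spec$antagonist_fraction * k)
      sign_j <- rep(1, k)
      if (n_ant > 0) sign_j[seq(k - n_ant + 1, k)] <- -1
      mag <- ifelse(sign_j > 0, spec$guild_loading, spec$antagonist_loading)
      L[members, g] <- sign_j * mag
      if (spec$bridge_fraction > 0 && G > 1) {
        n_bridge <- round(spec$bridge_fraction * k)
        if (n_bridge > 0) {
          bridges <- members[seq_len(n_bridge)]
          L[bridges, (g %% G) + 1] <- spec$bridge_loading
        }
      }
    }
    if (spec$loading_jitter > 0) {
      jit <- matrix(stats::runif(n * G, 1 - spec$loading_jitter, 1), n, G)
      L <- L * jit
    }
  }
  list(L = L, guild = guild)
}

#' Generate one class's community matrix with known interaction structure
#'
#' @param spec a [class_spec()].
#' @param n_samples number of samples to draw.
#' @param seed integer seed for this class.
#' @param taxa optional character vector of taxon names (length `n_taxa`).
#' @param sample_prefix prefix for generated sample names.
#' @param seasonal_forcing optional standardized per-sample forcing used when
#'   `thermal_sensitivity > 0`.
#' @return List with `community` (a [community_matrix()]) and `ground_truth`
#'   (class `ground_truth`: data.frame of interacting pairs with columns
#'   taxon_a, taxon_b, sign, population_r).
#' @export
generate_class <- function(spec, n_samples, seed, taxa = NULL,
                           sample_prefix = spec$name,
                           seasonal_forcing = NULL) {
  stopifnot(inherits(spec, "class_spec"), n_samples >= 2)
  gl <- guild_loadings(spec, seed)   # also seeds the RNG
  n <- spec$n_taxa
  G <- spec$n_guilds
  if (is.null(taxa)) taxa <- sprintf("%s_T%03d", spec$name, seq_len(n))
  stopifnot(length(taxa) == n, !anyDuplicated(taxa))
  mu <- stats::rnorm(n, 0, 1.25)               # lognormal rank-abundance
  Fg <- matrix(stats::rnorm(n_samples * G), n_samples, G)
  eps <- matrix(stats::rnorm(n_samples * n, 0, spec$noise_sd), n_samples, n)
  logB <- matrix(mu, n_samples, n, byrow = TRUE) + Fg %*% t(gl$L) + eps
  w <- rep(0, n)
  if (spec$thermal_sensitivity > 0) {
    if (is.null(seasonal_forcing) || length(seasonal_forcing) != n_samples)
      stop("thermal_sensitivity > 0 needs a per-sample seasonal_forcing")
    w <- stats::rnorm(n, 0, spec$thermal_sensitivity)
    logB <- logB + outer(as.numeric(seasonal_forcing), w)
  }
  B <- exp(logB)
  B <- B * (spec$biomass_scale / mean(rowSums(B)))
  dimnames(B) <- list(sprintf("%s_S%03d", sample_prefix, seq_len(n_samples)),
                      taxa)
  cm <- community_matrix(B, class_label = rep(spec$name, n_samples))
  gt <- ground_truth_from_loadings(gl$L, spec$noise_sd, taxa)
  list(community = cm, ground_truth = gt)
}

# Population log-scale correlations implied by a loading matrix.
ground_truth_from_loadings <- function(L, noise_sd, taxa) {
  sigma <- L %*% t(L) + diag(noise_sd^2, nrow(L))
  popr <- stats::cov2cor(sigma)
  idx <- which(upper.tri(popr) & abs(popr) > 1e-12, arr.ind = TRUE)
  d <- data.frame(taxon_a = taxa[idx[, 1]], taxon_b = taxa[idx[, 2]],
                  sign = ifelse(popr[idx] > 0, "positive", "negative"),
                  population_r = popr[idx], stringsAsFactors = FALSE)
  d <- d[order(d$taxon_a, d$taxon_b), ]
  rownames(d) <- NULL
  structure(d, class = c("ground_truth", "data.frame"))
}

#' Default monthly sampling calendar
#'
#' Mid-month dates for a 28-month campaign (two full years plus four summer
#' months), matching an 84-sample design at three replicates per date.
#'
#' @return Vector of `Date`s.
#' @export
default_sampling_dates <- function() {
  months <- c(seq(as.Date("2014-01-15"), as.Date("2015-12-15"), by = "month"),
              seq(as.Date("2016-06-15"), as.Date("2016-09-15"), by = "month"))
  months
}

# Latent-factor groups for hydrochemical variables: optical/suspension
# variables co-vary (a suspended-matter axis on which Secchi transparency
# loads negatively), and the trophic-state variables co-vary. lambda is the
# shared fraction of each variable's SD.
env_factor_map <- function() {
  list(suspension = c(Turbidity = 1, Color = 1, SSmin = 1, SSorg = 1,
                      SStot = 1, SD_m = -1, Fe = 1),
       trophic = c(Chl_a = 1, TOC = 1, TN = 1, NO3_N = 1, NH4_N = 1,
                   TP = 1, PO4_P = 1))
}

# Seasonal weights: the share of each variable's SD driven by the annual
# cycle (positive = summer maximum), common to all classes. Production and
# suspended matter peak in the growing season, transparency and nitrate in
# winter; conservative ions and P fractions carry no marked cycle.
env_seasonal_map <- function() {
  c(Chl_a = 0.5, TOC = 0.4, Turbidity = 0.4, SSorg = 0.4, SStot = 0.4,
    SSmin = 0.3, Color = 0.3, SD_m = -0.4, NO3_N = -0.5, TN = -0.3,
    NH4_N = 0, TP = 0, PO4_P = 0, pH = 0, Fe = 0, DO = 0)
}

#' Generate an environmental table for one class
#'
#' Emulates a monthly hydrochemistry campaign where the water column is
#' measured once per reservoir per date: all samples sharing a date share one
#' row of environmental values. Water temperature follows an annual sinusoid
#' whose minimum equals `winter_temp_mean` (mid-January) and whose amplitude
#' makes the annual mean equal `annual_temp_mean`, plus N(0, winter_temp_sd)
#' noise per date. Dissolved oxygen is drawn with a negative Gaussian
#' coupling to temperature (target Spearman correlation about -0.5). The
#' remaining variables keep the `env_profile` means/SDs but are correlated
#' within a date through two latent axes - suspended matter (turbidity,
#' colour, suspended-solid fractions, iron, with Secchi transparency loading
#' negatively) and trophic state (chlorophyll, organic carbon, N and P
#' forms) - and are truncated at 0.
#'
#' @param spec a [class_spec()] with a non-NULL `env_profile`.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param dates vector of `Date`s covering at least one year (recycled over
#'   samples); defaults to [default_sampling_dates()].
#' @param sample_prefix prefix for generated sample names.
#' @param lambda shared fraction of each variable's SD carried by its latent
#'   axis (default 0.7).
#' @return An [environmental_table()] whose first column is `Temperature`;
#'   the sampling dates are attached as element `dates`.
#' @export
generate_environment <- function(spec, n_samples, seed,
                                 dates = default_sampling_dates(),
                                 sample_prefix = spec$name,
                                 lambda = 0.7) {
  stopifnot(inherits(spec, "class_spec"), lambda >= 0, lambda < 1)
  if (is.null(spec$env_profile))
    stop("class_spec has no env_profile")
  dates <- as.Date(dates)
  if (as.numeric(diff(range(dates))) < 330)
    stop("dates must cover at least one year")
  set.seed(seed)
  dvec <- rep(dates, length.out = n_samples)
  udates <- unique(dvec)
  nd <- length(udates)
  doy <- as.numeric(format(udates, "%j"))
  # cosine basis with its trough in mid-January; the amplitude is set so the
  # December-February mean equals winter_temp_mean (the winter summary a
  # monthly campaign would report), and the level so the annual mean equals
  # annual_temp_mean
  basis <- function(d) cos(2 * pi * (d - 15) / 365.25)
  winter_doys <- as.numeric(format(as.Date(c("2014-12-15", "2014-01-15",
                                             "2014-02-15")), "%j"))
  wbar <- mean(basis(winter_doys))
  amp <- (spec$annual_temp_mean - spec$winter_temp_mean) / wbar
  temp_d <- spec$annual_temp_mean - amp * basis(doy) +
    stats::rnorm(nd, 0, spec$winter_temp_sd)
  zt <- if (stats::sd(temp_d) > 0) (temp_d - mean(temp_d)) / stats::sd(temp_d)
        else rep(0, nd)
  fmap <- env_factor_map()
  smap <- env_seasonal_map()
  factors <- lapply(fmap, function(...) stats::rnorm(nd))
  season <- -cos(2 * pi * (doy - 15) / 365.25)
  season <- if (stats::sd(season) > 0) (season - mean(season)) /
              stats::sd(season) else rep(0, nd)
  prof <- spec$env_profile
  vals_d <- matrix(NA_real_, nd, 1 + length(prof),
                   dimnames = list(NULL, c("Temperature", names(prof))))
  vals_d[, "Temperature"] <- temp_d
  rho <- -0.52   # Gaussian-scale coupling giving Spearman ~ -0.5
  for (v in names(prof)) {
    mu <- prof[[v]][1]
    sdv <- prof[[v]][2]
    z <- stats::rnorm(nd)
    if (v == "DO") {
      draw <- mu + sdv * (rho * zt + sqrt(1 - rho^2) * z)
    } else {
      beta <- if (v %in% names(smap)) smap[[v]] else 0
      load <- 0
      shared <- 0
      for (f in names(fmap)) if (v %in% names(fmap[[f]])) {
        load <- lambda * sqrt(max(0, 1 - beta^2)) * fmap[[f]][[v]]
        shared <- factors[[f]]
      }
      idio <- sqrt(max(0, 1 - beta^2 - load^2))
      draw <- mu + sdv * (beta * season + load * shared + idio * z)
    }
    vals_d[, v] <- pmax(draw, 0)
  }
  idx <- match(dvec, udates)
  vals <- vals_d[idx, , drop = FALSE]
  rownames(vals) <- sprintf("%s_S%03d", sample_prefix, seq_len(n_samples))
  et <- environmental_table(vals)
  et$dates <- dvec
  et
}

#' Generate a complete multi-class scenario
#'
#' Concatenates per-class community and environmental tables. A subset of
#' taxon names is shared by every class (sized so the shared set is about
#' `shared_fraction` of the taxon union); shared taxa keep their name across
#' classes but draw their guild role independently per class.
#'
#' @param config a [scenario_config()].
#' @return List with `community` (labelled [community_matrix()] over the
#'   taxon union), `environment` (an [environmental_table()]), and
#'   `ground_truth` (named list, one `ground_truth` per class).
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  specs <- config$classes
  k <- length(specs)
  n_taxa <- vapply(specs, function(s) s$n_taxa, 1)
  f <- config$shared_fraction
  m_shared <- if (f <= 0) 0L
              else min(round(f * sum(n_taxa) / (1 + (k - 1) * f)),
                       min(n_taxa))
  shared <- if (m_shared > 0) sprintf("Shared_T%03d", seq_len(m_shared))
            else character(0)
  comms <- list()
  envs <- list()
  gts <- list()
  dates <- default_sampling_dates()
  for (spec in specs) {
    seed_c <- class_seed(config$rng_seed, spec$name)
    # shared names are spread over the taxon index range (guild blocks are
    # contiguous) so sharing is not confounded with guild identity
    taxa <- sprintf("%s_T%03d", spec$name, seq_len(spec$n_taxa - m_shared))
    if (m_shared > 0) {
      pos <- round(seq(1, spec$n_taxa, length.out = m_shared))
      all_names <- character(spec$n_taxa)
      all_names[pos] <- shared
      all_names[-pos] <- taxa
      taxa <- all_names
    }
    forcing <- NULL
    env <- generate_environment(spec, config$n_samples_per_class,
                                seed = seed_c + 1L, dates = dates)
    if (spec$thermal_sensitivity > 0) {
      tv <- env$values[, "Temperature"]
      forcing <- (tv - mean(tv)) / stats::sd(tv)
    }
    gen <- generate_class(spec, config$n_samples_per_class, seed = seed_c,
                          taxa = taxa, seasonal_forcing = forcing)
    comms[[spec$name]] <- gen$community
    gts[[spec$name]] <- gen$ground_truth
    envs[[spec$name]] <- env
  }
  all_taxa <- unique(unlist(lapply(comms, taxa_names)))
  all_samples <- unlist(lapply(comms, sample_names), use.names = FALSE)
  big <- matrix(0, length(all_samples), length(all_taxa),
                dimnames = list(all_samples, all_taxa))
  labels <- character(0)
  date_all <- as.Date(character(0))
  for (nm in names(comms)) {
    cm <- comms[[nm]]
    big[sample_names(cm), taxa_names(cm)] <- cm$biomass
    labels <- c(labels, cm$class_label)
    date_all <- c(date_all, rep(dates,
                                length.out = config$n_samples_per_class))
  }
  env_values <- do.call(rbind, lapply(envs, function(e) e$values))
  list(community = community_matrix(big, class_label = labels,
                                    sample_date = date_all),
       environment = environmental_table(env_values),
       ground_truth = gts)
}

#' Structured presets for cohesion contrasts
#'
#' `cw_like_preset()` describes a cohesive, centralized community: two large
#' guilds with strong but taxon-varying loadings and a balanced share of
#' antagonists. `ww_like_preset()` describes a weakly structured community:
#' many small guilds with marginal loadings, few antagonists, and bridge
#' taxa chaining neighbouring guilds. Used to study how guild architecture
#' moves the global network attributes (clustering, centralization,
#' characteristic path length).
#'
#' @param n_taxa number of taxa (default 40).
#' @return A [class_spec()].
#' @export
cw_like_preset <- function(n_taxa = 40) {
  class_spec("CWlike", n_taxa = n_taxa, n_guilds = 2,
             guild_loading = 0.7, antagonist_fraction = 0.5,
             antagonist_loading = 0.7, bridge_fraction = 0.15,
             bridge_loading = 0.7, loading_jitter = 0.4,
             noise_sd = 0.5, biomass_scale = 28,
             winter_temp_mean = 5.63, winter_temp_sd = 2.19,
             annual_temp_mean = 13.61, env_profile = env_profile_cw())
}

#' @rdname cw_like_preset
#' @export
ww_like_preset <- function(n_taxa = 40) {
  class_spec("WWlike", n_taxa = n_taxa, n_guilds = 10,
             guild_loading = 0.45, antagonist_fraction = 0.1,
             antagonist_loading = 0.45, bridge_fraction = 0.5,
             bridge_loading = 0.35, loading_jitter = 0.3,
             noise_sd = 0.5, biomass_scale = 0.1,
             winter_temp_mean = 15.35, winter_temp_sd = 1.41,
             annual_temp_mean = 18.49, env_profile = env_profile_ww())
}
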