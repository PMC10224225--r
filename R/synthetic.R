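#' Configuration for the synthetic multi-omics cohort generator
#'
#' Bundles every knob of [generate_cohort()] and validates dimensional
#' consistency. The defaults describe a cohort with the structure the
#' pipeline assumes: ~300 sparse compositional species profiles, a
#' 74-marker inflammation panel on the log2 NPX scale, 378 metabolites
#' with left-censored missingness, a microbially produced target
#' metabolite driven by a producer-species set, a functional-gene
#' abundance driven by carrier species, and a binary plaque-like outcome
#' from a logistic model over species and covariates.
#'
#' @param n_samples,n_species,n_enzymes,n_proteins,n_metabolites Layer
#'   dimensions (positive integers).
#' @param seed Integer; fully determines the generated cohort.
#' @param species_log_mean,species_log_sd Optional per-species mean/SD of
#'   the latent log-normal abundances; drawn from N(0, 1.5) and
#'   U(0.5, 1.5) under the seed when `NULL`.
#' @param sparsity Optional per-species structural-zero fraction in
#'   \[0, 1); drawn U(0, 0.95) when `NULL`, which together with the default
#'   prevalence filter reproduces a realistic rare-species regime.
#' @param sequencing_depth Multinomial reads per sample (default 50000,
#'   a shallow-shotgun-scale species tally).
#' @param plaque_intercept Log-odds intercept of the outcome model, or
#'   `NULL` to calibrate by search so that the mean outcome probability
#'   equals `target_prevalence`.
#' @param target_prevalence Outcome prevalence used when calibrating the
#'   intercept (default 0.2625, i.e. 84 cases per 320 women).
#' @param species_plaque_effects Named numeric vector of log-odds per SD
#'   of CLR abundance for outcome-associated species. Default: one
#'   enriched species at `log(1.5)` and five depleted species at
#'   `log(0.7)`, mirroring a one-pathogen/five-commensal structure.
#' @param covariate_effects Length-4 numeric vector of log-odds for
#'   (standardized age, serostatus, site level 2, site level 3).
#' @param producer_weights Named numeric vector: effect of each producer
#'   species' standardized CLR abundance on the target metabolite, in
#'   units of metabolite SD. Default 17 species, 8 positive and 9
#'   negative.
#' @param carrier_weights Named numeric vector: contribution of each
#'   carrier species' relative abundance to the functional-gene enzyme.
#' @param mediator_loadings Optional `n_proteins x (n_species + 1)` loading
#'   matrix mapping (standardized species CLR, standardized target
#'   metabolite) to protein NPX; a sparse default links the first ten
#'   markers to the outcome-associated species and the target metabolite.
#' @param noise_sd Named list of Gaussian noise SDs per layer:
#'   `metabolite`, `protein`, `enzyme`.
#' @param missing_rate_metabolites Fraction in \[0, 1) of each non-target
#'   metabolite column set missing; censoring is left-tail (lowest values
#'   removed), mimicking below-detection-limit dropout.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 320L, n_species = 300L,
                          n_enzymes = 120L, n_proteins = 74L,
                          n_metabolites = 378L, seed = 1L,
                          species_log_mean = NULL, species_log_sd = NULL,
                          sparsity = NULL, sequencing_depth = 50000L,
                          plaque_intercept = NULL,
                          target_prevalence = 0.2625,
                          species_plaque_effects = NULL,
                          covariate_effects = c(age = 0.5, hiv = 0.3,
                                                site2 = 0, site3 = 0),
                          producer_weights = NULL,
                          carrier_weights = NULL,
                          mediator_loadings = NULL,
                          noise_sd = list(metabolite = 1, protein = 1,
                                          enzyme = 0.5),
                          missing_rate_metabolites = 0.10) {
  dims <- c(n_samples = n_samples, n_species = n_species,
            n_enzymes = n_enzymes, n_proteins = n_proteins,
            n_metabolites = n_metabolites, sequencing_depth = sequencing_depth)
  if (any(dims <= 0) || any(dims != round(dims))) {
    stop("dimension and depth fields must be positive integers")
  }
  if (missing_rate_metabolites < 0 || missing_rate_metabolites >= 1) {
    stop("missing_rate_metabolites must lie in [0, 1)")
  }
  species_ids <- sprintf("sp%03d", seq_len(n_species))
  if (is.null(species_plaque_effects)) {
    species_plaque_effects <- stats::setNames(
      c(log(1.5), rep(log(0.7), 5)), species_ids[1:6])
  }
  if (is.null(producer_weights)) {
    producer_weights <- stats::setNames(
      c(rep(0.3, 8), rep(-0.25, 9)),
      c(species_ids[7:14], species_ids[c(2:6, 15:18)]))
  }
  if (is.null(carrier_weights)) {
    carrier_weights <- stats::setNames(rep(1, 3), species_ids[7:9])
  }
  for (nm in c("species_plaque_effects", "producer_weights",
               "carrier_weights")) {
    v <- get(nm)
    if (length(v) && (is.null(names(v)) || !all(names(v) %in% species_ids))) {
      stop(nm, " must be named by species ids present in the cohort")
    }
  }
  if (!is.null(mediator_loadings) &&
      !identical(dim(mediator_loadings), c(n_proteins, n_species + 1L))) {
    stop("mediator_loadings must be n_proteins x (n_species + 1)")
  }
  check_len <- function(v, n, nm) {
    if (!is.null(v) && length(v) != n) stop(nm, " must have length n_species")
  }
  check_len(species_log_mean, n_species, "species_log_mean")
  check_len(species_log_sd, n_species, "species_log_sd")
  check_len(sparsity, n_species, "sparsity")
  if (length(covariate_effects) != 4) {
    stop("covariate_effects must have length 4 (age, hiv, site2, site3)")
  }
  if (!all(c("metabolite", "protein", "enzyme") %in% names(noise_sd)) ||
      any(unlist(noise_sd) < 0)) {
    stop("noise_sd needs non-negative metabolite/protein/enzyme entries")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_species = as.integer(n_species),
         n_enzymes = as.integer(n_enzymes), n_proteins = as.integer(n_proteins),
         n_metabolites = as.integer(n_metabolites), seed = as.integer(seed),
         species_ids = species_ids,
         species_log_mean = species_log_mean, species_log_sd = species_log_sd,
         sparsity = sparsity, sequencing_depth = as.integer(sequencing_depth),
         plaque_intercept = plaque_intercept,
         target_prevalence = target_prevalence,
         species_plaque_effects = species_plaque_effects,
         covariate_effects = covariate_effects,
         producer_weights = producer_weights,
         carrier_weights = carrier_weights,
         mediator_loadings = mediator_loadings,
         noise_sd = noise_sd,
         missing_rate_metabolites = missing_rate_metabolites),
    class = "cohort_config"
  )
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Draws every layer of a plaque-style multi-omics study from one seed:
#' \itemize{
#'   \item species counts by multinomial sampling at `sequencing_depth`
#'     from per-sample compositions built from sparse log-normal latent
#'     abundances;
#'   \item a binary outcome from `logit P = intercept +
#'     sum(effects * standardized CLR abundance) + covariate terms` with
#'     covariates age (N(50, 10) years), binary serostatus (65%
#'     prevalence) and a 3-level study site;
#'   \item the target metabolite as a weighted sum of producer-species
#'     standardized CLR abundances plus Gaussian noise; all other
#'     metabolites as noise with left-censored missingness;
#'   \item a functional-gene enzyme as a weighted sum of carrier-species
#'     relative abundances plus noise, among lognormal background enzymes;
#'   \item protein NPX columns as `mediator_loadings` applied to
#'     (species CLR, target metabolite) plus log2-scale noise;
#'   \item HIV-care variables (ART use, viral load, CD4) for the cohort
#'     summary stage.
#' }
#' The returned `truth` record stores every planted parameter and the
#' seed, so recovery tests can compare estimates against it.
#'
#' @param config A [cohort_config()].
#' @return List with elements `species` and `enzymes` ([count_table()]),
#'   `proteins` and `metabolites` ([omics_matrix()]), `metadata`
#'   (data.frame) and `truth` (`synthetic_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_species
  sample_id <- sprintf("s%04d", seq_len(n))
  sp_ids <- config$species_ids

  mu <- config$species_log_mean %||% stats::rnorm(p, 0, 1.5)
  sdv <- config$species_log_sd %||% stats::runif(p, 0.5, 1.5)
  sparsity <- config$sparsity %||% stats::runif(p, 0, 0.95)

  # latent log-normal abundances with per-feature structural zeros
  latent <- exp(sweep(matrix(stats::rnorm(n * p), n, p), 2, sdv, `*`) +
                  matrix(mu, n, p, byrow = TRUE))
  zeros <- matrix(stats::runif(n * p), n, p) < matrix(sparsity, n, p, byrow = TRUE)
  latent[zeros] <- 0
  # guard: no all-zero sample compositions
  empty <- rowSums(latent) == 0
  if (any(empty)) latent[empty, which.max(mu)] <- 1
  comp <- latent / rowSums(latent)

  counts <- t(apply(comp, 1, function(pr) {
    stats::rmultinom(1, config$sequencing_depth, pr)[, 1]
  }))
  dimnames(counts) <- list(sample_id, sp_ids)

  # CLR of the latent compositions drives outcome/metabolite/protein layers
  comp_named <- comp
  dimnames(comp_named) <- list(sample_id, sp_ids)
  clr_lat <- clr_transform(comp_named)$values
  z_clr <- scale(clr_lat)
  z_clr[is.nan(z_clr)] <- 0

  # covariates
  age <- stats::rnorm(n, 50, 10)
  hiv <- stats::rbinom(n, 1, 0.65)
  site <- sample(c("A", "B", "C"), n, replace = TRUE)
  age_z <- (age - mean(age)) / stats::sd(age)
  ce <- config$covariate_effects
  eta_cov <- ce[1] * age_z + ce[2] * hiv +
    ce[3] * (site == "B") + ce[4] * (site == "C")

  eff <- config$species_plaque_effects
  eta_sp <- if (length(eff)) {
    drop(z_clr[, names(eff), drop = FALSE] %*% eff)
  } else rep(0, n)
  eta <- eta_sp + eta_cov
  intercept <- config$plaque_intercept
  if (is.null(intercept)) {
    intercept <- stats::uniroot(
      function(b0) mean(stats::plogis(b0 + eta)) - config$target_prevalence,
      interval = c(-20, 20))$root
  }
  plaque <- stats::rbinom(n, 1, stats::plogis(intercept + eta))

  # HIV care variables (drawn for all, meaningful among the seropositive)
  art <- ifelse(hiv == 1, stats::rbinom(n, 1, 0.92), 0)
  vl_class <- sample(c("le20", "le200", "gt200"), n, replace = TRUE,
                     prob = c(0.764, 0.156, 0.080))
  viral_load <- ifelse(vl_class == "le20", stats::runif(n, 0, 20),
                       ifelse(vl_class == "le200", stats::runif(n, 21, 200),
                              exp(stats::runif(n, log(201), log(1e5)))))
  viral_load[hiv == 0] <- NA
  viral_load[hiv == 1 & art == 0] <- exp(stats::runif(sum(hiv == 1 & art == 0),
                                                      log(200), log(1e6)))
  cd4 <- ifelse(hiv == 1, pmax(50, stats::rnorm(n, 600, 250)), NA)

  # metabolites: column 1 is the microbially produced target
  met_ids <- c("ImP", sprintf("met%03d", seq_len(config$n_metabolites - 1)))
  pw <- config$producer_weights
  signal <- if (length(pw)) {
    drop(z_clr[, names(pw), drop = FALSE] %*% pw)
  } else rep(0, n)
  # intensities sit on a positive baseline so CV-style QC is meaningful
  met_baseline <- 10
  mets <- met_baseline +
    matrix(stats::rnorm(n * config$n_metabolites, 0,
                        config$noise_sd$metabolite),
           n, config$n_metabolites, dimnames = list(sample_id, met_ids))
  mets[, 1] <- mets[, 1] + signal
  if (config$missing_rate_metabolites > 0 && config$n_metabolites > 1) {
    k_miss <- floor(config$missing_rate_metabolites * n)
    if (k_miss > 0) {
      for (j in 2:config$n_metabolites) {
        mets[order(mets[, j])[seq_len(k_miss)], j] <- NA
      }
    }
  }

  # enzymes: lognormal background plus the carrier-driven functional gene
  enz_ids <- c("hutH", sprintf("enz%03d", seq_len(config$n_enzymes - 1)))
  enz <- exp(matrix(stats::rnorm(n * config$n_enzymes, 0, 1), n,
                    config$n_enzymes, dimnames = list(sample_id, enz_ids)))
  cw <- config$carrier_weights
  carrier_signal <- if (length(cw)) {
    drop(comp_named[, names(cw), drop = FALSE] %*% cw)
  } else rep(0, n)
  # scale the carrier signal to the background magnitude so it dominates
  enz[, 1] <- carrier_signal / max(mean(carrier_signal), 1e-12) +
    abs(stats::rnorm(n, 0, config$noise_sd$enzyme))

  # proteins: NPX = loadings %*% (species CLR z-scores, target metabolite z)
  prot_ids <- sprintf("prot%02d", seq_len(config$n_proteins))
  L <- config$mediator_loadings
  if (is.null(L)) {
    L <- matrix(0, config$n_proteins, p + 1,
                dimnames = list(prot_ids, c(sp_ids, "target_metabolite")))
    k <- min(10, config$n_proteins)
    for (i in seq_len(k)) {
      L[i, names(eff)] <- 0.5 * sign(stats::rnorm(length(eff)))
    }
    L[seq_len(min(5, config$n_proteins)), "target_metabolite"] <- 0.6
  }
  med_inputs <- cbind(z_clr, scale(signal + stats::rnorm(n, 0, 1e-12)))
  if (stats::sd(signal) == 0) med_inputs[, p + 1] <- 0
  prot <- med_inputs %*% t(L) +
    matrix(stats::rnorm(n * config$n_proteins, 0, config$noise_sd$protein),
           n, config$n_proteins)
  dimnames(prot) <- list(sample_id, prot_ids)

  metadata <- data.frame(
    sample_id = sample_id, plaque = plaque, age = age, hiv = hiv,
    site = site, art_use = art, viral_load = viral_load, cd4 = cd4,
    stringsAsFactors = FALSE, row.names = sample_id)

  truth <- structure(
    list(species_plaque_effects = eff,
         producer_set = names(pw), producer_weights = pw,
         carrier_set = names(cw), carrier_weights = cw,
         mediator_loadings = L,
         plaque_intercept = intercept,
         target_metabolite = "ImP", carrier_enzyme = "hutH",
         seed = config$seed),
    class = "synthetic_truth")

  list(species = count_table(counts, "species"),
       enzymes = count_table(enz, "enzyme"),
       proteins = omics_matrix(prot, "NPX_log2"),
       metabolites = omics_matrix(mets, "intensity"),
       metadata = metadata,
       truth = truth)
}

#' Random rooted binary tree over a feature set
#'
#' Supports weighted-UniFrac testing: a rooted binary topology with the
#' given identifiers as leaves and strictly positive branch lengths drawn
#' U(0.1, 1). Deterministic given the seed.
#'
#' @param feature_ids Character vector of at least 2 unique leaf ids.
#' @param seed Integer seed.
#' @return An `ape::phylo` tree (newick-serializable).
#' @export
generate_tree <- function(feature_ids, seed = 1L) {
  if (length(feature_ids) < 2) stop("need at least 2 feature ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  set.seed(seed)
  tree <- ape::rtree(length(feature_ids), rooted = TRUE,
                     br = function(k) stats::runif(k, 0.1, 1))
  tree$tip.label <- feature_ids
  tree
}

#' Write all layers of a generated cohort to a directory
#'
#' TSV tables (samples as rows), metadata TSV, ground truth JSON and,
#' when a tree is supplied, a newick file. Paths are returned invisibly.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param tree Optional `ape::phylo` tree to serialize alongside.
#' @export
write_cohort <- function(cohort, dir, tree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    species = file.path(dir, "species.tsv"),
    enzymes = file.path(dir, "enzymes.tsv"),
    proteins = file.path(dir, "proteins.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json"))
  write_feature_table(cohort$species, paths["species"])
  write_feature_table(cohort$enzymes, paths["enzymes"])
  df <- data.frame(sample_id = rownames(cohort$proteins$values),
                   cohort$proteins$values, check.names = FALSE)
  utils::write.table(df, paths["proteins"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  df <- data.frame(sample_id = rownames(cohort$metabolites$values),
                   cohort$metabolites$values, check.names = FALSE)
  utils::write.table(df, paths["metabolites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth(cohort$truth, paths["truth"])
  if (!is.null(tree)) {
    paths <- c(paths, tree = file.path(dir, "tree.nwk"))
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
  }
  invisible(paths)
}
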