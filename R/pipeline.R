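round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Pipeline configuration
#'
#' All thresholds and knobs of [run_pipeline()] in one validated list,
#' serializable as YAML. When `paths` entries are supplied the pipeline
#' loads those TSV/newick inputs; otherwise it simulates a cohort under
#' `seed` with the given layer sizes.
#'
#' @param seed Integer master seed for simulation, subsampling and
#'   permutation streams.
#' @param n_samples,n_species,n_enzymes,n_proteins,n_metabolites Synthetic
#'   layer sizes (ignored when inputs are loaded from `paths`).
#' @param min_prevalence,min_mean_abundance Species filter thresholds.
#' @param protein_detection,metabolite_cv,metabolite_missing QC filter
#'   thresholds.
#' @param fdr BH false-discovery cutoff used by the screens (default 0.10).
#' @param alpha Per-feature significance level (default 0.05).
#' @param lda_cutoff LDA effect-size threshold (default 3.0).
#' @param ancom_detection W-fraction detection level (default 0.6).
#' @param plsda_components,top_k Inflammation-profile settings (8 and 5).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param covariates_model1 Metadata column names adjusted for in every
#'   model (default `age`, `hiv`, `site`).
#' @param covariates_model2_extra Additional columns for the further
#'   adjusted model (empty by default).
#' @param paths Optional named list of input paths (`species`, `enzymes`,
#'   `proteins`, `metabolites`, `metadata`, `tree`, `ec_map`); files must
#'   exist at load time.
#' @param output_dir Directory for stage artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_samples = 320L, n_species = 300L,
                            n_enzymes = 120L, n_proteins = 74L,
                            n_metabolites = 378L,
                            min_prevalence = 0.20, min_mean_abundance = 1e-5,
                            protein_detection = 0.75, metabolite_cv = 0.30,
                            metabolite_missing = 0.20, fdr = 0.10,
                            alpha = 0.05, lda_cutoff = 3.0,
                            ancom_detection = 0.6, plsda_components = 8L,
                            top_k = 5L, n_permutations = 999L,
                            covariates_model1 = c("age", "hiv", "site"),
                            covariates_model2_extra = character(),
                            paths = list(), output_dir = tempfile("gutplaque_")) {
  frac <- c(min_prevalence = min_prevalence,
            min_mean_abundance = min_mean_abundance,
            protein_detection = protein_detection,
            metabolite_cv = metabolite_cv,
            metabolite_missing = metabolite_missing, fdr = fdr,
            alpha = alpha, ancom_detection = ancom_detection)
  if (any(frac < 0 | frac > 1)) stop("fractional thresholds must lie in [0, 1]")
  if (lda_cutoff < 0) stop("lda_cutoff must be non-negative")
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) stop("input file not found: ", paths[[nm]])
  }
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         n_species = as.integer(n_species), n_enzymes = as.integer(n_enzymes),
         n_proteins = as.integer(n_proteins),
         n_metabolites = as.integer(n_metabolites),
         min_prevalence = min_prevalence,
         min_mean_abundance = min_mean_abundance,
         protein_detection = protein_detection,
         metabolite_cv = metabolite_cv,
         metabolite_missing = metabolite_missing,
         fdr = fdr, alpha = alpha, lda_cutoff = lda_cutoff,
         ancom_detection = ancom_detection,
         plsda_components = as.integer(plsda_components),
         top_k = as.integer(top_k),
         n_permutations = as.integer(n_permutations),
         covariates_model1 = covariates_model1,
         covariates_model2_extra = covariates_model2_extra,
         paths = paths, output_dir = output_dir),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Cohort description with viral-suppression summaries
#'
#' Case/control counts plus, for each viral-load cutoff, the percentage of
#' ART users at or below the cutoff (numerator: ART users with viral load
#' `<=` cutoff; denominator: all ART users). Percentages are rounded
#' half-up to one decimal; a zero denominator yields an undefined (`NA`)
#' percentage, never 0.
#'
#' @param metadata data.frame with `plaque`, `art_use` and `viral_load`
#'   columns (viral load in copies/mL; `NA` treated as not suppressed).
#' @param suppression_cutoffs Numeric cutoffs in copies/mL (default 20
#'   and 200).
#' @return List: `n_total`, `n_cases`, `n_controls`, `suppression`
#'   (data.frame with `cutoff`, `numerator`, `denominator`, `percent`).
#' @export
summarize_cohort <- function(metadata, suppression_cutoffs = c(20, 200)) {
  stopifnot(all(c("plaque", "art_use", "viral_load") %in% names(metadata)))
  on_art <- metadata$art_use == 1
  den <- sum(on_art)
  supp <- do.call(rbind, lapply(suppression_cutoffs, function(cut) {
    num <- sum(on_art & !is.na(metadata$viral_load) &
                 metadata$viral_load <= cut)
    data.frame(cutoff = cut, numerator = num, denominator = den,
               percent = if (den > 0) round_half_up(100 * num / den, 1)
                         else NA_real_)
  }))
  list(n_total = nrow(metadata), n_cases = sum(metadata$plaque == 1),
       n_controls = sum(metadata$plaque == 0), suppression = supp)
}

# Per-feature linear models of each feature on a binary exposure:
# feature ~ exposure + covariates, collecting the exposure term.
linear_feature_screen <- function(features, exposure, covariates = NULL) {
  m <- as_values(features)
  Z <- make_design(covariates, n = length(exposure))
  recs <- lapply(colnames(m), function(f) {
    fit_linear(m[, f], exposure, covariates = Z, standardize = FALSE,
               feature_id = f, model_tag = "linear_on_outcome")
  })
  out <- do.call(rbind, recs)
  out$q <- bh_fdr(out$p)
  out
}

# synthetic EC level-III map: background enzymes are assigned round-robin
# to a fixed pool of categories; the functional-gene enzyme gets the
# ammonia-lyase class EC 4.3.1.
synthetic_ec_map <- function(enzyme_ids) {
  pool <- c("EC 1.1.1", "EC 1.3.99", "EC 2.3.1", "EC 2.7.1", "EC 3.1.1",
            "EC 3.2.1", "EC 3.5.1", "EC 4.1.1", "EC 4.2.1", "EC 5.3.1",
            "EC 6.2.1", "EC 6.3.4")
  map <- stats::setNames(pool[(seq_along(enzyme_ids) - 1) %% length(pool) + 1],
                         enzyme_ids)
  if ("hutH" %in% enzyme_ids) map["hutH"] <- "EC 4.3.1"
  map
}

#' Run the full multi-omics integration pipeline
#'
#' Orchestrates the analysis end to end: simulate (or load) -> feature
#' filtering and transforms -> community diversity -> differential
#' abundance (LDA effect size, covariate-adjusted logistic screen,
#' pairwise log-ratio W) -> PLS-DA inflammation profiling with
#' per-component outcome models -> metabolite correlation screen,
#' mutual-adjustment selection, gut-microbiota score and its outcome
#' model, enzyme-category enrichment, sequential-adjustment attenuation ->
#' cohort report. Every stage writes TSV/JSON artifacts into
#' `config$output_dir` together with a log of the seed and every
#' threshold applied; rerunning with an identical config reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with all stage results and the vector
#'   of artifact paths (`$artifacts`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("gutplaque pipeline (package version %s)",
       as.character(utils::packageVersion("gutplaque")))
  for (nm in setdiff(names(config), c("paths", "output_dir"))) {
    logf("config %s = %s", nm, paste(config[[nm]], collapse = ","))
  }

  stage <- "simulate/load"
  result <- tryCatch({
    ## ---- stage 1: simulate or load -----------------------------------
    if (length(config$paths)) {
      species <- read_feature_table(config$paths$species,
                                    feature_kind = "species")
      enzymes <- read_feature_table(config$paths$enzymes,
                                    feature_kind = "enzyme")
      proteins <- read_omics_matrix(config$paths$proteins, "NPX_log2")
      metabolites <- read_omics_matrix(config$paths$metabolites, "intensity")
      metadata <- read_metadata(config$paths$metadata,
                                required = c(config$covariates_model1,
                                             config$covariates_model2_extra,
                                             "art_use", "viral_load"))
      tree <- if (!is.null(config$paths$tree))
        ape::read.tree(config$paths$tree) else NULL
      ec_map <- if (!is.null(config$paths$ec_map))
        read_ec_map(config$paths$ec_map) else
          synthetic_ec_map(colnames(enzymes$values))
      truth <- NULL
    } else {
      cohort <- generate_cohort(cohort_config(
        n_samples = config$n_samples, n_species = config$n_species,
        n_enzymes = config$n_enzymes, n_proteins = config$n_proteins,
        n_metabolites = config$n_metabolites, seed = config$seed))
      species <- cohort$species; enzymes <- cohort$enzymes
      proteins <- cohort$proteins; metabolites <- cohort$metabolites
      metadata <- cohort$metadata; truth <- cohort$truth
      tree <- generate_tree(colnames(species$values), seed = config$seed + 1)
      ec_map <- synthetic_ec_map(colnames(enzymes$values))
      write_truth(truth, file.path(out_dir, "truth.json"))
    }
    miss_cov <- setdiff(c(config$covariates_model1,
                          config$covariates_model2_extra), names(metadata))
    if (length(miss_cov)) {
      stop("metadata is missing covariate column(s): ",
           paste(miss_cov, collapse = ", "))
    }
    covs <- metadata[, config$covariates_model1, drop = FALSE]
    outcome <- metadata$plaque

    ## ---- stage 2: preprocess -----------------------------------------
    stage <- "preprocess"
    sp_filt <- filter_features(species, config$min_prevalence,
                               config$min_mean_abundance)
    ret <- attr(sp_filt, "retention")
    logf("species filter: kept %d, dropped %d", ret["kept"], ret["dropped"])
    sp_clr <- clr_transform(sp_filt)
    sp_intclr <- int_transform(sp_clr)
    enz_clr <- clr_transform(enzymes)
    prot_qc <- impute_half_min(qc_filter(proteins, "protein",
                                         detection = config$protein_detection))
    prot_int <- int_transform(prot_qc)
    met_qc <- qc_filter(metabolites, "metabolite",
                        max_cv = config$metabolite_cv,
                        max_missing = config$metabolite_missing)
    met_imp <- impute_half_min(met_qc)
    alpha_div <- data.frame(
      sample_id = rownames(species$values),
      shannon = alpha_diversity(species, "shannon"),
      chao1 = alpha_diversity(species, "chao1"),
      simpson = alpha_diversity(species, "simpson"))
    utils::write.table(alpha_div, file.path(out_dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_feature_table(sp_clr, file.path(out_dir, "species_clr.tsv"))
    write_feature_table(sp_intclr, file.path(out_dir, "species_intclr.tsv"))

    d_bray <- distance_matrix(sp_filt, "bray_curtis")
    d_unifrac <- if (!is.null(tree))
      distance_matrix(sp_filt, "weighted_unifrac", tree = tree) else NULL

    ## ---- stage 3: differential abundance -----------------------------
    stage <- "diffabund"
    lefse <- lefse_lda_scores(sp_filt, factor(outcome, levels = c(0, 1)),
                              alpha = config$alpha, threshold = config$lda_cutoff,
                              seed = config$seed + 2)
    utils::write.table(lefse, file.path(out_dir, "lefse.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sp_logistic <- logistic_screen(sp_clr, outcome, covs)
    write_association_records(sp_logistic,
                              file.path(out_dir, "species_logistic.tsv"))
    rel_filt <- sp_filt$values / rowSums(sp_filt$values)
    delta <- 0.5 * min(rel_filt[rel_filt > 0])
    rel_filt[rel_filt == 0] <- delta
    rel_ct <- count_table(rel_filt, "species")
    ancom <- ancom_w(rel_ct, outcome, covs, alpha = config$alpha)
    utils::write.table(ancom, file.path(out_dir, "ancom.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    ## ---- stage 4: inflammation profiling -----------------------------
    stage <- "plsda"
    plsda <- plsda_fit(prot_int, outcome,
                       n_components = config$plsda_components)
    contrib <- top_contributors(plsda, config$top_k)
    pc_assoc <- pc_outcome_association(plsda, outcome, covs)
    write_plsda_model(plsda, file.path(out_dir, "plsda_model.json"),
                      k = config$top_k)
    utils::write.table(contrib, file.path(out_dir, "plsda_contributors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_association_records(pc_assoc, file.path(out_dir, "plsda_assoc.tsv"))
    perma <- if (!is.null(d_unifrac)) {
      permanova(d_unifrac, outcome, n_permutations = config$n_permutations,
                seed = config$seed + 3)
    } else NULL
    if (!is.null(perma)) {
      jsonlite::write_json(perma, file.path(out_dir, "permanova.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    ## ---- stage 5: integration ----------------------------------------
    stage <- "integrate"
    target_id <- colnames(met_imp$values)[1]
    target <- met_imp$values[, target_id]
    met_screen <- correlation_screen(sp_clr,
                                     met_imp$values[, target_id, drop = FALSE],
                                     fdr = config$fdr)
    utils::write.table(met_screen, file.path(out_dir, "metabolite_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    candidates <- met_screen$feature_id[met_screen$significant]
    max_cand <- nrow(sp_intclr$values) - ncol(make_design(covs)) - 2
    if (length(candidates) > max_cand) {
      candidates <- candidates[order(met_screen$q[met_screen$significant]
                                     )][seq_len(max_cand)]
      logf("conditional selection capped at %d candidates", max_cand)
    }
    selection <- NULL; gmb <- NULL; score_assoc <- NULL; score_means <- NULL
    if (length(candidates) >= 1) {
      selection <- conditional_selection(
        target, sp_intclr$values[, candidates, drop = FALSE], covs,
        alpha = config$alpha)
      utils::write.table(selection$records,
                         file.path(out_dir, "conditional_selection.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(selection$selected)) {
        gmb <- build_gmb_score(selection$weights, sp_intclr)
        utils::write.table(
          data.frame(sample_id = names(gmb$score), score = gmb$score),
          file.path(out_dir, "gmb_score.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        score_assoc <- rbind(
          fit_logistic(outcome, gmb$score, covs, feature_id = "gmb_score",
                       model_tag = "score_vs_plaque"),
          fit_linear(target, gmb$score, covs, feature_id = "gmb_score",
                     model_tag = "score_vs_target"))
        write_association_records(score_assoc,
                                  file.path(out_dir, "score_assoc.tsv"))
        grp <- quartile_groups(gmb$score)
        score_means <- adjusted_group_means(target, grp, covs)
        utils::write.table(score_means,
                           file.path(out_dir, "target_by_score_quartile.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    enz_screen <- linear_feature_screen(enz_clr, outcome, covs)
    write_association_records(enz_screen,
                              file.path(out_dir, "enzyme_screen.tsv"))
    enrich <- ec_enrichment(enz_screen, ec_map,
                            alpha_feature = config$alpha, fdr = config$fdr)
    utils::write.table(enrich, file.path(out_dir, "ec_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    atten <- NULL
    if (nrow(lefse) && any(lefse$passes_threshold)) {
      top_sp <- lefse$feature_id[which.max(abs(lefse$lda_score))]
      pcs <- plsda$scores[, seq_len(min(5, ncol(plsda$scores))), drop = FALSE]
      atten <- attenuation_analysis(
        outcome, sp_clr$values[, top_sp], covs,
        extra_adjusters = cbind(pcs, target_metabolite = target),
        adjustment_tag = "plus_both", feature_id = top_sp)
      jsonlite::write_json(
        list(feature_id = top_sp, tag = atten$adjustment_tag,
             beta_base = atten$base$beta, beta_adjusted = atten$adjusted$beta,
             percent_attenuation = atten$percent_attenuation),
        file.path(out_dir, "attenuation.json"), auto_unbox = TRUE, digits = NA)
    }

    ## ---- stage 6: report ---------------------------------------------
    stage <- "report"
    summary <- summarize_cohort(metadata)
    jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("completed: %d samples, %d filtered species, %d cases",
         nrow(metadata), ncol(sp_filt$values), summary$n_cases)

    list(species_filtered = sp_filt, species_clr = sp_clr,
         species_intclr = sp_intclr, alpha_diversity = alpha_div,
         bray = d_bray, unifrac = d_unifrac, lefse = lefse,
         species_logistic = sp_logistic, ancom = ancom, plsda = plsda,
         contributors = contrib, pc_assoc = pc_assoc, permanova = perma,
         metabolite_screen = met_screen, selection = selection,
         gmb = gmb, score_assoc = score_assoc, score_means = score_means,
         enzyme_screen = enz_screen, enrichment = enrich,
         attenuation = atten, summary = summary, truth = truth,
         metadata = metadata,
         artifacts = list.files(out_dir, full.names = TRUE))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
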