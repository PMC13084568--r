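#' Write and read cohort tables
#'
#' Wide CSV, one row per infant and visit; the column dictionary is
#' documented in the package vignette.
#'
#' @param cohort an \code{otis_cohort}.
#' @param path file path.
#' @return \code{write_cohort} returns \code{path} invisibly;
#'   \code{read_cohort} returns an \code{otis_cohort}.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(x, class = c("otis_cohort", "data.frame"))
}

#' Default run configuration
#'
#' All stage-level tunables of a full analysis run in one list, each with
#' its default: cohort size, seed, permutation count, FDR level, glog
#' lambda, the Atwater protein energy factor, the BH family convention,
#' whether dropout is applied, and the optional-path switches of the SEM
#' specifications. Every value is echoed in the provenance block of the
#' result bundle.
#'
#' @param ... overrides of the defaults.
#' @return A list of class \code{otis_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    preset = "otis", n_per_group = 125, seed = 20250601,
    dropout = TRUE, n_perm = 999, alpha = 0.05, glog_lambda = 1,
    atwater_kcal_per_g = 4, bh_family = "per_timepoint",
    models = c("weight", "bmi"),
    include_igf1_outcome = TRUE, include_prot_insglu = TRUE,
    n_sim_residuals = 250
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("otis_config", "list"))
}

metabolite_panel <- function(cohort, timepoint) {
  rows <- cohort[cohort$visit_age == timepoint, ]
  cols <- grep("^m_", names(rows), value = TRUE)
  ok <- stats::complete.cases(rows[, cols])
  list(panel = as.matrix(rows[ok, cols]), groups = rows$group[ok],
       infant_id = rows$infant_id[ok])
}

#' Run the full analysis pipeline
#'
#' Simulate, summarise intake, test the metabolome at both plasma
#' timepoints, and fit both growth SEMs, returning (and optionally writing)
#' one consolidated bundle. Stages: cohort generation under the configured
#' preset (with informative dropout if configured); cumulative protein AUC
#' and threshold flags; glog + PCA, Canberra PERMANOVA with dispersion
#' check, and the Mann-Whitney/BH volcano per timepoint; robust-ML fit,
#' fit indices, modification indices, residual diagnostics and DOT diagram
#' per model. A provenance block records every configuration value, the
#' package version and the seeds. Two runs with the same configuration
#' produce identical bundles.
#'
#' @param config an \code{\link{run_config}} list.
#' @param out_dir optional directory; when given, writes cohort.csv,
#'   volcano_<tp>.tsv, permanova_<tp>.json, pca_contributions_<tp>.tsv,
#'   estimates_<model>.tsv, indices_<model>.json, mod_indices_<model>.tsv,
#'   diagram_<model>.dot, diagnostics_<model>.json and provenance.json.
#' @return List of class \code{otis_bundle}.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "otis_config"))
  preset <- switch(config$preset,
                   otis = otis_preset(n_per_group = config$n_per_group,
                                      seed = config$seed),
                   null = null_preset(n_per_group = config$n_per_group,
                                      seed = config$seed),
                   stop("unknown preset: ", config$preset))
  preset <- solve_error_variances(preset)
  cohort <- generate_cohort(preset, seed = config$seed)
  if (config$dropout) cohort <- apply_dropout(cohort, preset, config$seed)

  ## intake stage
  intake <- cumulative_intake(cohort, "protein_g")
  rows1218 <- cohort[cohort$visit_age %in% c(12, 18) &
                       !is.na(cohort$weight_kg) & !is.na(cohort$protein_g), ]
  flags <- cbind(rows1218[, c("infant_id", "visit_age", "group")],
                 protein_flags(rows1218$protein_g, rows1218$energy_kcal,
                               rows1218$weight_kg,
                               kcal_per_g = config$atwater_kcal_per_g))

  ## metabolome stage
  metabolome <- lapply(c(`12` = 12, `18` = 18), function(tp) {
    mp <- metabolite_panel(cohort, tp)
    pca <- pca_combined(mp$panel, mp$groups, lambda = config$glog_lambda)
    D <- canberra_matrix(glog(mp$panel, config$glog_lambda))
    pm <- permanova(D, mp$groups, n_perm = config$n_perm,
                    seed = stage_seed(config$seed, paste0("perm", tp)))
    pm$dispersion_p <- dispersion_homogeneity(D, mp$groups)
    volcano <- mw_fdr_panel(mp$panel, mp$groups, alpha = config$alpha)
    list(timepoint = tp, n = nrow(mp$panel), pca = pca, permanova = pm,
         volcano = volcano)
  })

  ## SEM stage
  frame <- build_frame(cohort)
  sems <- lapply(stats::setNames(config$models, config$models), function(m) {
    rep_ <- run_sem_pipeline(cohort, m,
                             include_igf1_outcome = config$include_igf1_outcome,
                             include_prot_insglu = config$include_prot_insglu)
    rep_$diagnostics <- residual_diagnostics(frame, m,
                                             n_sim = config$n_sim_residuals,
                                             seed = config$seed)
    rep_
  })

  provenance <- list(package = "otispath",
                     version = as.character(utils::packageVersion("otispath")),
                     config = unclass(config),
                     n_infants = length(unique(cohort$infant_id)),
                     n_frame_rows = nrow(frame))
  bundle <- structure(list(config = config, preset = preset, cohort = cohort,
                           intake = intake, protein_flags = flags,
                           metabolome = metabolome, sems = sems,
                           provenance = provenance),
                      class = "otis_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

permanova_json <- function(pm) {
  list(pseudo_F = pm$pseudo_F, R2 = pm$R2, p_perm = pm$p_perm,
       n_perm = pm$n_perm, SS_total = pm$SS_total,
       SS_between = pm$SS_between, SS_within = pm$SS_within,
       dispersion_p = pm$dispersion_p)
}

#' Write a result bundle to disk
#'
#' @param bundle an \code{otis_bundle} from \code{\link{run_all}}.
#' @param out_dir output directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_cohort(bundle$cohort, fp("cohort.csv"))
  utils::write.csv(bundle$protein_flags, fp("protein_flags.csv"),
                   row.names = FALSE)
  utils::write.table(bundle$intake, fp("cumulative_intake.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (m in bundle$metabolome) {
    tp <- m$timepoint
    utils::write.table(m$volcano, fp(sprintf("volcano_%d.tsv", tp)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(permanova_json(m$permanova),
                         fp(sprintf("permanova_%d.json", tp)),
                         auto_unbox = TRUE, digits = NA)
    contrib <- data.frame(metabolite = rownames(m$pca$contributions),
                          round(m$pca$contributions[, 1:5], 6))
    utils::write.table(contrib, fp(sprintf("pca_contributions_%d.tsv", tp)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (nm in names(bundle$sems)) {
    s <- bundle$sems[[nm]]
    utils::write.table(s$paths, fp(sprintf("estimates_%s.tsv", nm)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    idx <- s$indices
    jsonlite::write_json(idx[!vapply(idx, is.null, TRUE)],
                         fp(sprintf("indices_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(s$mod_indices, fp(sprintf("mod_indices_%s.tsv", nm)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(s$dot, fp(sprintf("diagram_%s.dot", nm)))
    dg <- s$diagnostics
    dg_json <- lapply(dg[setdiff(names(dg), c("model", "n_sim"))],
                      function(e) e[setdiff(names(e), "quantile_residuals")])
    jsonlite::write_json(dg_json, fp(sprintf("diagnostics_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$provenance, fp("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
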