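#' Build the SEM analysis frame from a cohort
#'
#' Assembles one row per infant and plasma timepoint (12 and 18 mo) with
#' the transformed model variables: the z-scored cumulative protein AUC
#' ending at that row's age (6-12 mo AUC for the 12-mo row, 6-18 mo for the
#' 18-mo row; z-scored over the pooled analysis sample), the natural logs
#' of total BCAA (leucine + isoleucine + valine, micromolar), IGF-1 and the
#' insulin-to-glucose ratio, the growth outcomes, and the maternal/neonatal
#' covariates (birth weight converted to kg). Infants without diet records
#' at all four visits are excluded by the AUC rule, and any row missing a
#' model variable is dropped (listwise deletion, no imputation).
#'
#' @param cohort an \code{otis_cohort} (or any data.frame with the same
#'   columns).
#' @return data.frame of class \code{otis_frame} with attributes
#'   \code{n_infants}, \code{n_excluded}.
#' @export
build_frame <- function(cohort) {
  need <- c("infant_id", "visit_age", "group", "sex", "birth_weight_g",
            "maternal_bmi", "gwg_kg", "excl_bf_months", "any_formula",
            "protein_g", "weight_kg", "bmi", "igf1_ngml", "insulin_miul",
            "glucose_mmoll", "m_leucine", "m_isoleucine", "m_valine")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  auc12 <- cumulative_auc(cohort, "protein_g", 12)
  auc18 <- cumulative_auc(cohort, "protein_g", 18)
  rows <- cohort[cohort$visit_age %in% c(12, 18), ]
  rows$prot_auc <- ifelse(
    rows$visit_age == 12,
    auc12$auc[match(rows$infant_id, auc12$infant_id)],
    auc18$auc[match(rows$infant_id, auc18$infant_id)])
  fr <- data.frame(
    infant_id = rows$infant_id,
    age = rows$visit_age,
    group = rows$group,
    prot_auc = rows$prot_auc,
    ln_bcaa = log(rows$m_leucine + rows$m_isoleucine + rows$m_valine),
    ln_igf1 = log(rows$igf1_ngml),
    ln_ins_glu = log(rows$insulin_miul / rows$glucose_mmoll),
    weight = rows$weight_kg,
    bmi = rows$bmi,
    sex = as.integer(rows$sex == "male"),
    age18 = as.integer(rows$visit_age == 18),
    birth_weight = rows$birth_weight_g / 1000,
    gwg = rows$gwg_kg,
    maternal_bmi = rows$maternal_bmi,
    excl_bf = rows$excl_bf_months,
    any_formula = rows$any_formula,
    stringsAsFactors = FALSE
  )
  model_vars <- c("prot_auc", "ln_bcaa", "ln_igf1", "ln_ins_glu", "weight",
                  "bmi", "sex", "age18", "birth_weight", "gwg",
                  "maternal_bmi", "excl_bf", "any_formula")
  keep <- stats::complete.cases(fr[, model_vars])
  n_excl <- sum(!keep)
  fr <- fr[keep, ]
  if (!nrow(fr)) stop("no listwise-complete rows for the SEM frame")
  fr$z_prot_auc <- zscore(fr$prot_auc)
  rownames(fr) <- NULL
  structure(fr, class = c("otis_frame", "data.frame"),
            n_infants = length(unique(fr$infant_id)), n_excluded = n_excl)
}

otis_model_text <- function(outcome, include_igf1_outcome = TRUE,
                            include_prot_insglu = TRUE) {
  paste(c(
    paste(outcome, "~ z_prot_auc + ln_ins_glu +",
          if (include_igf1_outcome) "ln_igf1 +" else "",
          "birth_weight + gwg + maternal_bmi + excl_bf + any_formula + sex + age18"),
    "ln_igf1 ~ z_prot_auc + ln_bcaa + sex + age18",
    paste("ln_ins_glu ~ ln_bcaa +",
          if (include_prot_insglu) "z_prot_auc +" else "",
          "sex + age18")
  ), collapse = "\n")
}

#' Trial SEM specifications
#'
#' The two growth path models: the outcome (body weight or BMI) regressed
#' on z-scored cumulative protein AUC, ln insulin-to-glucose ratio, ln
#' IGF-1, birth weight, gestational weight gain, maternal prepregnancy BMI,
#' exclusive-breastfeeding duration, formula use, sex and age category;
#' ln IGF-1 and ln insulin-to-glucose each regressed on protein intake
#' variables, sex and age; exogenous covariates covary freely. The two
#' specifications differ only in the outcome variable. The direct
#' IGF-1-to-outcome path and the protein-to-insulin/glucose path are not
#' individually printed in the trial's diagram but are estimated freely by
#' default; both can be dropped.
#'
#' @param include_igf1_outcome free the direct IGF-1 -> outcome path.
#' @param include_prot_insglu free the protein AUC -> insulin/glucose path.
#' @return A \code{sem_spec} over 12 observed variables.
#' @export
weight_model_spec <- function(include_igf1_outcome = TRUE,
                              include_prot_insglu = TRUE) {
  parse_model(otis_model_text("weight", include_igf1_outcome,
                              include_prot_insglu))
}

#' @rdname weight_model_spec
#' @export
bmi_model_spec <- function(include_igf1_outcome = TRUE,
                           include_prot_insglu = TRUE) {
  parse_model(otis_model_text("bmi", include_igf1_outcome,
                              include_prot_insglu))
}

#' Run one growth SEM end to end
#'
#' Builds the analysis frame, fits the requested model by robust ML,
#' computes fit indices and modification indices, and assembles the
#' standardized path table with 95\% CIs and significance bands plus a DOT
#' path diagram. Deterministic given the cohort.
#'
#' @param cohort an \code{otis_cohort}.
#' @param model \code{"weight"} or \code{"bmi"}.
#' @param include_igf1_outcome,include_prot_insglu see
#'   \code{\link{weight_model_spec}}.
#' @return List of class \code{otis_sem_report}: \code{model}, \code{frame_n},
#'   \code{fit}, \code{indices}, \code{paths} (standardized solution),
#'   \code{mod_indices}, \code{dot}.
#' @export
run_sem_pipeline <- function(cohort, model = c("weight", "bmi"),
                             include_igf1_outcome = TRUE,
                             include_prot_insglu = TRUE) {
  model <- match.arg(model)
  frame <- build_frame(cohort)
  spec <- if (model == "weight")
    weight_model_spec(include_igf1_outcome, include_prot_insglu)
  else bmi_model_spec(include_igf1_outcome, include_prot_insglu)
  fit <- fit_ml(spec, frame)
  fit <- robust_adjust(fit, frame)
  idx <- fit_indices(fit, frame)
  paths <- standardized_solution(fit)
  mi <- modification_indices(fit)
  structure(list(model = model, frame_n = nrow(frame),
                 n_infants = attr(frame, "n_infants"),
                 fit = fit, indices = idx, paths = paths, mod_indices = mi,
                 dot = path_diagram_dot(paths, outcome = model)),
            class = "otis_sem_report")
}

#' @export
print.otis_sem_report <- function(x, ...) {
  cat(sprintf("Growth SEM (%s outcome): %d rows, %d infants\n",
              x$model, x$frame_n, x$n_infants))
  print(x$indices)
  pp <- x$paths[x$paths$op == "~", ]
  cat("standardized paths:\n")
  for (k in seq_len(nrow(pp)))
    cat(sprintf("  %-28s %+0.3f [%+0.3f, %+0.3f] %s\n", pp$label[k],
                pp$std[k], pp$std_lower[k], pp$std_upper[k], pp$stars[k]))
  invisible(x)
}

#' DOT path diagram
#'
#' Graphviz DOT source for the fitted path diagram, edges labelled with
#' standardized coefficients and the conventional significance bands
#' (*** p<0.001, ** p<0.01, * p<0.05, dagger p<0.1); only regression paths
#' are drawn.
#'
#' @param paths a \code{\link{standardized_solution}} table.
#' @param outcome name highlighted as the outcome node.
#' @param all_edges draw non-significant paths too (dashed).
#' @return A character scalar of DOT source.
#' @export
path_diagram_dot <- function(paths, outcome = NULL, all_edges = TRUE) {
  pp <- paths[paths$op == "~", ]
  lines <- c("digraph sem {", "  rankdir=LR;",
             "  node [shape=box, fontsize=10];")
  if (!is.null(outcome))
    lines <- c(lines, sprintf("  \"%s\" [style=filled, fillcolor=lightgrey];",
                              outcome))
  for (k in seq_len(nrow(pp))) {
    signif <- pp$p[k] < 0.1
    if (!signif && !all_edges) next
    star <- if (pp$stars[k] == "†") "+" else pp$stars[k]
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%.2f%s\"%s];",
      pp$rhs[k], pp$lhs[k], pp$std[k], star,
      if (signif) "" else ", style=dashed"))
  }
  paste(c(lines, "}"), collapse = "\n")
}
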