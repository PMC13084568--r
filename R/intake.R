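#' Estimated breastmilk intake from feed counts
#'
#' Breastmilk consumption is not weighed in the dietary records; each feed is
#' coded qualitatively and converted to grams using the study's fixed
#' portion sizes: a "meal" counts 102 g, a "snack" 25 g.
#'
#' @param meal_count,snack_count non-negative feed counts per day
#'   (vectorised).
#' @return Estimated breastmilk intake in g/d.
#' @examples
#' breastmilk_grams(1, 0)  # 102
#' breastmilk_grams(2, 3)  # 279
#' @export
breastmilk_grams <- function(meal_count, snack_count) {
  if (any(meal_count < 0, na.rm = TRUE) || any(snack_count < 0, na.rm = TRUE))
    stop("feed counts must be non-negative")
  102 * meal_count + 25 * snack_count
}

#' Cumulative nutrient intake as area under the intake curve
#'
#' Integrates mean daily intake over the complementary-feeding schedule by
#' the trapezoid rule (linear interpolation) on the nominal visit ages,
#' from 6 mo to \code{end_month}. Following the trial's complete-case rule,
#' an infant must have records at all four visits (6, 9, 12 and 18 mo) to
#' contribute; incomplete infants are excluded, never interpolated.
#'
#' @param records data.frame with columns \code{infant_id}, \code{visit_age}
#'   and the nutrient column.
#' @param nutrient name of the intake column to integrate (e.g.
#'   \code{"protein_g"}).
#' @param end_month 12 or 18.
#' @return data.frame with \code{infant_id}, \code{nutrient},
#'   \code{end_month} and \code{auc} ((g/d)·month or (kcal/d)·month), one
#'   row per complete infant.
#' @examples
#' rec <- data.frame(infant_id = 1, visit_age = c(6, 9, 12, 18),
#'                   protein_g = c(10, 20, 30, 40))
#' cumulative_auc(rec, "protein_g", 12)$auc  # 120
#' @export
cumulative_auc <- function(records, nutrient, end_month = c(18, 12)) {
  end_month <- match.arg(as.character(end_month[1]), c("18", "12"))
  end_month <- as.numeric(end_month)
  stopifnot(nutrient %in% names(records),
            all(c("infant_id", "visit_age") %in% names(records)))
  visits <- c(6, 9, 12, 18)
  rec <- records[records$visit_age %in% visits & !is.na(records[[nutrient]]), ]
  keep <- tapply(rec$visit_age, rec$infant_id,
                 function(v) length(unique(v)) == 4L)
  ids <- names(keep)[keep]
  rec <- rec[rec$infant_id %in% ids, ]
  if (!nrow(rec))
    return(data.frame(infant_id = character(0), nutrient = character(0),
                      end_month = numeric(0), auc = numeric(0)))
  rec <- rec[order(rec$infant_id, rec$visit_age), ]
  use <- visits[visits <= end_month]
  rec <- rec[rec$visit_age %in% use, ]
  auc1 <- function(y, x = use) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc <- tapply(rec[[nutrient]], rec$infant_id, auc1)
  out <- data.frame(infant_id = names(auc), nutrient = nutrient,
                    end_month = end_month, auc = as.numeric(auc),
                    stringsAsFactors = FALSE)
  # restore the original id type where possible
  if (is.numeric(records$infant_id)) out$infant_id <- as.numeric(out$infant_id)
  rownames(out) <- NULL
  out
}

#' Protein-intake threshold flags
#'
#' Flags each observation against the two protein recommendations used in
#' the trial: the requirement of 1.05 g protein per kg body weight per day,
#' and the upper threshold of 15% of total energy from protein. Protein
#' energy is computed at the Atwater factor of 4 kcal/g (configurable; the
#' source of the published E% factor is not stated).
#'
#' @param protein protein intake, g/d.
#' @param energy total energy intake, kcal/d (strictly positive).
#' @param weight body weight, kg (strictly positive).
#' @param kcal_per_g energy density of protein, kcal/g.
#' @return data.frame with \code{g_per_kg}, \code{meets_gkg}
#'   (\code{protein/weight >= 1.05}), \code{protein_e_pct} and
#'   \code{exceeds_e15} (strictly \code{> 15} E\%).
#' @examples
#' protein_flags(12, 900, 10)            # meets the g/kg recommendation
#' protein_flags(37.5, 1000, 10)$exceeds_e15  # exactly 15 E% -> FALSE
#' @export
protein_flags <- function(protein, energy, weight, kcal_per_g = 4) {
  if (any(energy <= 0, na.rm = TRUE) || any(weight <= 0, na.rm = TRUE))
    stop("energy and weight must be strictly positive")
  if (any(protein < 0, na.rm = TRUE)) stop("protein must be non-negative")
  gkg <- protein / weight
  epct <- 100 * kcal_per_g * protein / energy
  data.frame(g_per_kg = gkg, meets_gkg = gkg >= 1.05,
             protein_e_pct = epct, exceeds_e15 = epct > 15)
}

#' Cumulative-intake table with within-sample z-scores
#'
#' Convenience wrapper computing the AUC ending at each requested month and
#' standardizing it to a z-score (mean 0, SD 1) within the complete-case
#' sample, the form in which cumulative protein intake enters the SEM.
#'
#' @inheritParams cumulative_auc
#' @param end_months months at which the AUC ends (default both 12 and 18).
#' @return data.frame with \code{infant_id}, \code{nutrient},
#'   \code{end_month}, \code{auc}, \code{z_auc}. \code{z_auc} is
#'   standardized over all returned rows (the pooled analysis sample), as in
#'   the SEM frame.
#' @export
cumulative_intake <- function(records, nutrient, end_months = c(12, 18)) {
  out <- do.call(rbind, lapply(end_months, function(em)
    cumulative_auc(records, nutrient, em)))
  out$z_auc <- zscore(out$auc)
  out
}
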