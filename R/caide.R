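#' CAIDE point table
#'
#' The CAIDE (Cardiovascular Risk Factors, Aging, and Incidence of Dementia)
#' dementia risk score sums points over seven mid-/late-life risk factors.
#' The default table is the original non-APOE CAIDE model: age > 53 years
#' scores 4 (47-53: 3), education < 7 years scores 3 (7-9: 2), male sex 1,
#' systolic blood pressure > 140 mmHg 2, BMI > 30 kg/m2 2, total cholesterol
#' > 6.5 mmol/L 2, physical inactivity 1; maximum 15. Thresholds for the
#' continuous components are strict (`>`), and the table is configurable
#' rather than hard-wired.
#'
#' @param age_cuts,age_points Two age thresholds (years) and the points for
#'   the three resulting categories (below first / between / above second).
#' @param education_cuts,education_points Two education thresholds (years)
#'   and points for below-first / between / at-or-above-second.
#' @param sex_points Points for male sex (female scores 0).
#' @param sbp_cut,sbp_points Systolic blood pressure threshold (mmHg), points
#'   above it.
#' @param bmi_cut,bmi_points BMI threshold (kg/m2), points above it.
#' @param chol_cut,chol_points Total cholesterol threshold (mmol/L), points
#'   above it.
#' @param inactivity_points Points for physical inactivity.
#' @return An object of class `caide_point_table`.
#' @export
#' @examples
#' tab <- caide_point_table()
#' caide_max(tab)  # 15
caide_point_table <- function(age_cuts = c(47, 53), age_points = c(0, 3, 4),
                              education_cuts = c(7, 10),
                              education_points = c(3, 2, 0),
                              sex_points = 1,
                              sbp_cut = 140, sbp_points = 2,
                              bmi_cut = 30, bmi_points = 2,
                              chol_cut = 6.5, chol_points = 2,
                              inactivity_points = 1) {
  tab <- list(age_cuts = as.numeric(age_cuts),
              age_points = as.numeric(age_points),
              education_cuts = as.numeric(education_cuts),
              education_points = as.numeric(education_points),
              sex_points = as.numeric(sex_points),
              sbp_cut = as.numeric(sbp_cut), sbp_points = as.numeric(sbp_points),
              bmi_cut = as.numeric(bmi_cut), bmi_points = as.numeric(bmi_points),
              chol_cut = as.numeric(chol_cut),
              chol_points = as.numeric(chol_points),
              inactivity_points = as.numeric(inactivity_points))
  pts <- unlist(tab[grepl("points", names(tab))])
  if (any(pts < 0)) stop("caide_point_table: points must be nonnegative",
                         call. = FALSE)
  stopifnot(length(tab$age_cuts) == 2L, length(tab$age_points) == 3L,
            length(tab$education_cuts) == 2L,
            length(tab$education_points) == 3L)
  structure(tab, class = "caide_point_table")
}

#' Maximum attainable CAIDE score under a point table
#'
#' @param table A [caide_point_table()].
#' @return Integer maximum (sum of per-component maxima).
#' @export
caide_max <- function(table = caide_point_table()) {
  as.integer(max(table$age_points) + max(table$education_points) +
               table$sex_points + table$sbp_points + table$bmi_points +
               table$chol_points + table$inactivity_points)
}

#' Compute the CAIDE dementia risk score
#'
#' A higher score indicates more dementia risk factors. All seven components
#' must be present; missing values raise an error naming the offending field
#' (no silent imputation).
#'
#' @param cohort A `data.frame` with columns `age_at_test`, `sex`
#'   (`"male"`/`"female"`), `education`, `sbp`, `bmi`, `total_chol`,
#'   `inactive` (logical or 0/1).
#' @param table A [caide_point_table()].
#' @return Integer vector of scores, one per row.
#' @export
caide_score <- function(cohort, table = caide_point_table()) {
  stopifnot(inherits(table, "caide_point_table"))
  need <- c("age_at_test", "sex", "education", "sbp", "bmi", "total_chol",
            "inactive")
  for (nm in need) {
    if (!nm %in% names(cohort)) {
      stop("caide_score: missing component column `", nm, "`", call. = FALSE)
    }
    if (anyNA(cohort[[nm]])) {
      stop("caide_score: missing value in component `", nm, "` (row ",
           which(is.na(cohort[[nm]]))[1], ")", call. = FALSE)
    }
  }
  sex <- cohort$sex
  if (!all(sex %in% c("male", "female"))) {
    stop("caide_score: `sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  age <- cohort$age_at_test
  edu <- cohort$education
  age_pts <- ifelse(age > table$age_cuts[2], table$age_points[3],
                    ifelse(age >= table$age_cuts[1], table$age_points[2],
                           table$age_points[1]))
  edu_pts <- ifelse(edu < table$education_cuts[1], table$education_points[1],
                    ifelse(edu < table$education_cuts[2],
                           table$education_points[2],
                           table$education_points[3]))
  score <- age_pts + edu_pts +
    ifelse(sex == "male", table$sex_points, 0) +
    ifelse(cohort$sbp > table$sbp_cut, table$sbp_points, 0) +
    ifelse(cohort$bmi > table$bmi_cut, table$bmi_points, 0) +
    ifelse(cohort$total_chol > table$chol_cut, table$chol_points, 0) +
    ifelse(as.logical(cohort$inactive), table$inactivity_points, 0)
  as.integer(score)
}

#' Read / write a CAIDE point table as YAML
#'
#' @param path File path.
#' @return [read_caide_table()] returns a [caide_point_table()].
#' @export
read_caide_table <- function(path) {
  do.call(caide_point_table, yaml::read_yaml(path))
}

#' @param table A [caide_point_table()].
#' @rdname read_caide_table
#' @export
write_caide_table <- function(table, path) {
  yaml::write_yaml(unclass(table), path)
  invisible(path)
}
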