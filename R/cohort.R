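#' Analyse a set of sessions into a longitudinal measure table
#'
#' Runs the appropriate quantification on every session — [quantify_mvc()]
#' for grip-task sessions, [analyze_mep_session()] for evoked sessions —
#' and stacks the results into the tidy long format used by the
#' statistics layer: one row per animal x week x measure.
#'
#' @param sessions List of `raw_session` objects or of bundle paths
#'   (as returned by [simulate_cohort()]).
#' @param params Analysis parameters ([mep_params()]).
#' @return data.frame with columns `animal_id`, `group`, `week`,
#'   `measure`, `value`. Measures: `mvc_auc_mVms`, `grip_force` (mvc
#'   sessions); `mep_auc_mVms`, `mep_duration_ms` (mep sessions).
#' @export
analyze_cohort <- function(sessions, params = mep_params()) {
  rows <- list()
  for (s in sessions) {
    if (is.character(s)) s <- read_session(s)
    if (s$modality == "mvc") {
      r <- quantify_mvc(s, params)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = s$animal_id, group = s$group, week = s$week,
        measure = c("mvc_auc_mVms", "grip_force"),
        value = c(r$mvc_mVms, r$grip_force))
    } else {
      r <- analyze_mep_session(s, params = params)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = s$animal_id, group = s$group, week = s$week,
        measure = c("mep_auc_mVms", "mep_duration_ms"),
        value = c(r$auc_mVms, r$duration_ms))
    }
  }
  do.call(rbind, rows)
}

#' Extract one measure as a balanced panel
#'
#' Filters the long measure table from [analyze_cohort()] to a single
#' measure and checks completeness (every animal at every week), the
#' precondition of [rm_anova_split_plot()].
#'
#' @param measures Long table from [analyze_cohort()].
#' @param measure Measure name to extract.
#' @return data.frame `animal_id`, `group`, `week`, `value`.
#' @export
longitudinal_table <- function(measures, measure) {
  sub <- measures[measures$measure == measure,
                  c("animal_id", "group", "week", "value")]
  if (!nrow(sub)) stop("no rows for measure ", measure, call. = FALSE)
  tab <- table(sub$animal_id, sub$week)
  if (any(tab != 1L)) {
    stop("incomplete panel for measure ", measure,
         ": every animal needs one value per week", call. = FALSE)
  }
  rownames(sub) <- NULL
  sub
}
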