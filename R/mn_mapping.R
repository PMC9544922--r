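spinal_levels <- function() c("C2", "C3", "C4", "C5", "C6", "C7", "C8", "T1", "T2")

#' Load the packaged biceps motor-neuron count table
#'
#' Counts of retrogradely (CTB) labelled biceps motor neurons per spinal
#' level C2-T2 for 5 naive and 3 cervical-contusion (SCI) rats, shipped
#' as a plain CSV in the same layout as the published per-animal table.
#' The loader verifies the per-animal totals against the sum over levels
#' and returns the long form used by the analysis functions.
#'
#' @param path Optional path to a CSV in the same wide layout
#'   (animal_id, group, C2..T2, Total); defaults to the packaged data.
#' @return A `data.frame` with columns `animal_id`, `group`
#'   (naive/sci), `level` (factor C2..T2) and `count`.
#' @export
load_mn_counts <- function(path = NULL) {
  path <- path %||% system.file("extdata", "biceps_mn_counts.csv",
                                package = "mepkit", mustWork = TRUE)
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  lv <- spinal_levels()
  if (!all(c("animal_id", "group", lv) %in% names(wide))) {
    stop("count table must have columns animal_id, group, C2..T2", call. = FALSE)
  }
  if ("Total" %in% names(wide)) {
    chk <- rowSums(wide[, lv])
    if (any(chk != wide$Total)) {
      stop("per-animal Total column does not match the sum over levels",
           call. = FALSE)
    }
  }
  long <- data.frame(
    animal_id = rep(wide$animal_id, each = length(lv)),
    group = rep(wide$group, each = length(lv)),
    level = factor(rep(lv, nrow(wide)), levels = lv),
    count = as.integer(t(as.matrix(wide[, lv]))),
    stringsAsFactors = FALSE
  )
  issues <- validate_mn_counts(long)
  if (length(issues)) stop(paste(issues, collapse = "; "), call. = FALSE)
  long
}

#' Validate a motor-neuron count table
#' @param table Long-format count table (see [load_mn_counts()]).
#' @return Character vector of issues (empty if valid).
#' @export
validate_mn_counts <- function(table) {
  issues <- character()
  need <- c("animal_id", "group", "level", "count")
  if (!all(need %in% names(table))) {
    return(paste("missing columns:", paste(setdiff(need, names(table)), collapse = ", ")))
  }
  per <- table(table$animal_id)
  if (any(per != length(spinal_levels()))) {
    issues <- c(issues, "every animal needs exactly one count per level C2..T2")
  }
  if (any(table$count < 0) || any(table$count != round(table$count))) {
    issues <- c(issues, "counts must be non-negative integers")
  }
  issues
}

#' Per-level and total count summaries
#'
#' Means and sample standard deviations (n-1 denominator, matching the
#' reported mean +/- SD convention) of motor-neuron counts per group and
#' spinal level, plus per-animal totals and group-mean totals (reported
#' as the extra level `"Total"`). Groups with a single animal get an
#' undefined (NA) SD.
#'
#' @param table Long-format count table (see [load_mn_counts()]).
#' @return data.frame with columns `group`, `level`, `mean`, `sd`, `n`.
#' @export
summarize_counts <- function(table) {
  issues <- validate_mn_counts(table)
  if (length(issues)) stop(paste(issues, collapse = "; "), call. = FALSE)
  lv <- spinal_levels()
  rows <- list()
  for (gr in unique(table$group)) {
    sub <- table[table$group == gr, ]
    if (!nrow(sub)) stop("empty group: ", gr, call. = FALSE)
    for (l in lv) {
      v <- sub$count[sub$level == l]
      rows[[length(rows) + 1L]] <- data.frame(
        group = gr, level = l, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_, n = length(v))
    }
    tot <- tapply(sub$count, sub$animal_id, sum)
    rows[[length(rows) + 1L]] <- data.frame(
      group = gr, level = "Total", mean = mean(tot),
      sd = if (length(tot) > 1) stats::sd(tot) else NA_real_, n = length(tot))
  }
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = c(lv, "Total"))
  out
}

#' Per-animal total counts
#' @param table Long-format count table.
#' @return data.frame with `animal_id`, `group`, `total`.
#' @export
animal_totals <- function(table) {
  tot <- tapply(table$count, table$animal_id, sum)
  grp <- tapply(table$group, table$animal_id, function(g) g[1])
  data.frame(animal_id = names(tot), group = as.character(grp[names(tot)]),
             total = as.integer(tot), row.names = NULL)
}

#' Group comparison per spinal level
#'
#' Runs the exact Mann-Whitney U test ([mann_whitney_exact()]) between
#' the two groups separately at each spinal level. Levels where every
#' animal in both groups has zero counts carry no information and are
#' reported as non-testable (`testable = FALSE`, p = NA).
#'
#' @param table Long-format count table with exactly two groups.
#' @return data.frame with `level`, `U`, `p`, `testable`.
#' @export
compare_levels <- function(table) {
  grs <- unique(table$group)
  if (length(grs) != 2L) stop("need exactly two groups", call. = FALSE)
  rows <- lapply(spinal_levels(), function(l) {
    x <- table$count[table$group == grs[1] & table$level == l]
    y <- table$count[table$group == grs[2] & table$level == l]
    if (all(x == 0) && all(y == 0)) {
      return(data.frame(level = l, U = NA_real_, p = NA_real_, testable = FALSE))
    }
    tst <- mann_whitney_exact(x, y)
    data.frame(level = l, U = tst$statistic, p = tst$p, testable = TRUE)
  })
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = spinal_levels())
  out
}

#' Group-by-level matrix of mean counts
#'
#' The matrix underlying the motor-neuron distribution heat map: one row
#' per group, one column per spinal level C2..T2, entries are group-mean
#' counts. Row sums equal the group-mean totals.
#'
#' @param table Long-format count table.
#' @return Numeric matrix, groups x 9 levels.
#' @export
heatmap_matrix <- function(table) {
  lv <- spinal_levels()
  grs <- unique(table$group)
  m <- matrix(NA_real_, length(grs), length(lv), dimnames = list(grs, lv))
  for (gr in grs) for (l in lv) {
    m[gr, l] <- mean(table$count[table$group == gr & table$level == l])
  }
  m
}
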