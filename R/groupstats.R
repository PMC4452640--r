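#' ROI summary of a parametric map
#'
#' Arithmetic mean and SEM over the valid voxels of the ROI; invalid
#' voxels are excluded and counted.
#'
#' @param map a [parametric_map()].
#' @param roi an [roi_mask()] on the same grid.
#' @return list `mean`, `sem`, `n` (valid voxels), `n_excluded`.
#' @export
roi_summary <- function(map, roi) {
  if (!identical(dim(vol_data(roi)), dim(vol_data(map)))) {
    stop("ROI grid does not match the map", call. = FALSE)
  }
  inroi <- vol_data(roi) & TRUE
  v <- map_valid(map) & inroi
  n <- sum(v)
  if (n == 0) stop("ROI contains no valid voxels", call. = FALSE)
  x <- vol_data(map)[v]
  list(
    mean = mean(x),
    sem = if (n > 1) stats::sd(x) / sqrt(n) else 0,
    n = n,
    n_excluded = sum(inroi) - n
  )
}

#' Group summary container
#'
#' Mean, SEM and group size for one group, optionally with the underlying
#' per-subject values (raw mode). This is the exchange format between ROI
#' summarization, the relative-change statistic and the Welch test, and
#' is also how the study's printed "mean +/- SEM" pairs enter the
#' package.
#'
#' @param mean group mean.
#' @param sem standard error of the mean (>= 0).
#' @param n group size (>= 2 when an SEM is reported).
#' @param label group label.
#' @param values optional per-subject values; when given, `mean`, `sem`
#'   and `n` default to the values' own statistics.
#' @return a `group_summary` object.
#' @export
group_summary <- function(mean = NULL, sem = NULL, n = NULL, label = "",
                          values = NULL) {
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
    if (is.null(mean)) mean <- base::mean(values)
    if (is.null(n)) n <- length(values)
    if (is.null(sem)) sem <- stats::sd(values) / sqrt(length(values))
  }
  if (is.null(mean) || is.null(sem) || is.null(n)) {
    stop("need mean, sem and n (or raw values)", call. = FALSE)
  }
  if (sem < 0) stop("SEM must be non-negative", call. = FALSE)
  if (n < 2) stop("n must be >= 2 when an SEM is reported", call. = FALSE)
  structure(
    list(label = label, mean = mean, sem = sem, n = n, values = values),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(
    "<group_summary> ", x$label, ": ", signif(x$mean, 6), " +/- ",
    signif(x$sem, 4), " (n = ", x$n, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Relative change between a glioma and a sham group
#'
#' The study's percent-change statistic
#' \deqn{\%\Delta = (Data_{glioma} - Data_{sham}) / Data_{sham} \times 100.}
#' Two aggregation modes are provided because the study's printed
#' percent changes are not all consistent with the ratio of its printed
#' group means: `"group-mean"` (default) applies the formula to the two
#' group means with first-order (delta-method) SEM propagation of the
#' ratio; `"per-subject"` forms each glioma subject's ratio against the
#' sham group mean and averages those (requires raw values in `glioma`).
#'
#' @param glioma,sham [group_summary()] objects.
#' @param mode `"group-mean"` or `"per-subject"`.
#' @return list `pct`, `sem`, `mode`.
#' @export
percent_change <- function(glioma, sham, mode = c("group-mean", "per-subject")) {
  mode <- match.arg(mode)
  if (!is.finite(sham$mean) || sham$mean == 0) {
    stop("sham mean must be nonzero", call. = FALSE)
  }
  if (mode == "group-mean") {
    pct <- (glioma$mean - sham$mean) / sham$mean * 100
    sem <- 100 / abs(sham$mean) *
      sqrt(glioma$sem^2 + (glioma$mean / sham$mean)^2 * sham$sem^2)
  } else {
    if (is.null(glioma$values)) {
      stop("per-subject mode needs raw glioma values", call. = FALSE)
    }
    ratios <- (glioma$values - sham$mean) / sham$mean * 100
    pct <- mean(ratios)
    sem <- stats::sd(ratios) / sqrt(length(ratios))
  }
  list(pct = pct, sem = sem, mode = mode)
}

#' Welch's unpaired two-tailed t test
#'
#' Works from summary statistics (mean, SEM, n - the form in which the
#' study reports its data) or from raw per-subject values, which funnel
#' through the identical formula so the two modes coincide exactly when
#' the raw values generate the summaries:
#' \deqn{t = (m_a - m_b) / \sqrt{SEM_a^2 + SEM_b^2},}
#' degrees of freedom by Welch-Satterthwaite, p two-tailed from the t
#' distribution. Significance stars follow the study's figure legends
#' (*, **, ***, **** at 0.05, 0.01, 0.001, 0.0001).
#'
#' @param a,b [group_summary()] objects.
#' @return a `welch_result` list: `t`, `df`, `p`, `stars`, `delta`
#'   (mean difference).
#' @export
welch_test <- function(a, b) {
  se2a <- a$sem^2
  se2b <- b$sem^2
  if (se2a + se2b == 0) {
    stop("both SEMs are zero: t statistic undefined", call. = FALSE)
  }
  tstat <- (a$mean - b$mean) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(
    list(
      t = tstat, df = df, p = p, stars = significance_stars(p),
      delta = a$mean - b$mean
    ),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(
    "<welch_result> t = ", signif(x$t, 4), ", df = ", signif(x$df, 4),
    ", p = ", signif(x$p, 3), " ", x$stars, "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname welch_test
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (!is.finite(pp)) {
      ""
    } else if (pp < 1e-4) {
      "****"
    } else if (pp < 1e-3) {
      "***"
    } else if (pp < 0.01) {
      "**"
    } else if (pp < 0.05) {
      "*"
    } else {
      "ns"
    }
  }, character(1))
}

# Welch comparison that degrades to a flagged NA result when both groups
# are exactly degenerate (zero SEM), as happens for noiseless phantom
# cohorts; report builders use this so the absolute tables still form.
welch_or_na <- function(a, b) {
  if (a$sem^2 + b$sem^2 == 0) {
    structure(
      list(
        t = NA_real_, df = NA_real_, p = NA_real_, stars = "",
        delta = a$mean - b$mean
      ),
      class = "welch_result"
    )
  } else {
    welch_test(a, b)
  }
}

#' Circadian day/night RER aggregation and group comparison
#'
#' Averages each subject's respiratory exchange ratio within the light
#' (day) and dark (night) bins, then compares each tumour group against
#' its same-sex sham group with the percent-change statistic and the two
#' tumour groups against each other with Welch's test - per cycle.
#'
#' @param records long data.frame as from [simulate_rer_cohort()]:
#'   columns `subject`, `group`, `sex`, `condition`, `time_h`, `rer`,
#'   `light`.
#' @param mode percent-change aggregation mode (see [percent_change()]).
#' @return list with `subject_means` (per subject and cycle) and
#'   `comparison` (one row per sex and cycle: percent change vs sham with
#'   SEM, plus the male-vs-female Welch test on the subject-level cycle
#'   means within the tumour groups).
#' @export
rer_day_night <- function(records, mode = "per-subject") {
  stopifnot(all(c("subject", "group", "rer", "light", "time_h") %in% names(records)))
  span <- max(records$time_h) - min(records$time_h)
  if (span < 24 - 1e-9) {
    stop("records must cover at least one full 24-h cycle", call. = FALSE)
  }
  if (any(records$rer <= 0)) stop("RER values must be positive", call. = FALSE)
  agg <- stats::aggregate(rer ~ subject + group + light, records, mean)
  agg$cycle <- ifelse(agg$light, "day", "night")

  comp <- NULL
  for (cyc in c("day", "night")) {
    sub <- agg[agg$cycle == cyc, ]
    gs <- lapply(group_labels(), function(g) {
      v <- sub$rer[sub$group == g]
      if (length(v) < 2) {
        return(NULL)
      }
      group_summary(label = g, values = v)
    })
    names(gs) <- group_labels()
    if (any(vapply(gs, is.null, logical(1)))) {
      stop(
        "missing group(s): ",
        paste(group_labels()[vapply(gs, is.null, logical(1))], collapse = ", "),
        call. = FALSE
      )
    }
    pc_m <- percent_change(gs[["male/tumour"]], gs[["male/sham"]], mode = mode)
    pc_f <- percent_change(gs[["female/tumour"]], gs[["female/sham"]], mode = mode)
    wt <- welch_or_na(gs[["male/tumour"]], gs[["female/tumour"]])
    comp <- rbind(comp, data.frame(
      cycle = cyc, sex = c("male", "female"),
      pct_change = c(pc_m$pct, pc_f$pct),
      sem = c(pc_m$sem, pc_f$sem),
      welch_t_male_vs_female = wt$t,
      welch_p_male_vs_female = wt$p,
      stringsAsFactors = FALSE
    ))
  }
  list(subject_means = agg[, c("subject", "group", "cycle", "rer")], comparison = comp)
}

#' Build the study-style report tables from cohort results
#'
#' First table: one row per (parameter, region), one column per group,
#' cells formatted "mean +/- SEM" (the layout of the study's absolute
#' data tables). Second table: percent change of each tumour group vs
#' its same-sex sham and the male-vs-female Welch comparison of the
#' underlying subject values with significance stars.
#'
#' @param values long data.frame of per-subject summaries: `subject`,
#'   `group`, `region`, `quantity`, `value` (as produced by
#'   [simulate_cohort()] or [run_pipeline()]'s quantification stage).
#' @param mode percent-change mode, see [percent_change()].
#' @param digits significant digits in the formatted cells.
#' @return list `absolute` (data.frame, formatted + numeric columns),
#'   `change` (percent change + Welch p + stars), `summaries` (nested
#'   numeric summaries).
#' @export
build_report <- function(values, mode = "group-mean", digits = 6) {
  needed <- c("subject", "group", "region", "quantity", "value")
  stopifnot(all(needed %in% names(values)))
  groups <- group_labels()
  missing <- setdiff(groups, unique(values$group))
  if (length(missing)) {
    stop("missing group(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cells <- unique(values[, c("region", "quantity")])
  cells <- cells[order(cells$region, cells$quantity), ]

  absolute <- NULL
  change <- NULL
  summaries <- list()
  for (i in seq_len(nrow(cells))) {
    rg <- cells$region[i]
    qy <- cells$quantity[i]
    gs <- lapply(groups, function(g) {
      v <- values$value[values$group == g & values$region == rg &
        values$quantity == qy]
      if (length(v) < 2) {
        return(NULL)
      }
      group_summary(label = g, values = v)
    })
    names(gs) <- groups
    if (any(vapply(gs, is.null, logical(1)))) next
    summaries[[paste(rg, qy, sep = ".")]] <- gs

    fmt <- vapply(gs, function(s) {
      paste0(signif(s$mean, digits), " ± ", signif(s$sem, 3))
    }, character(1))
    row <- data.frame(
      region = rg, quantity = qy,
      male_tumour = fmt[["male/tumour"]], female_tumour = fmt[["female/tumour"]],
      male_sham = fmt[["male/sham"]], female_sham = fmt[["female/sham"]],
      mean_male_tumour = gs[["male/tumour"]]$mean,
      mean_female_tumour = gs[["female/tumour"]]$mean,
      mean_male_sham = gs[["male/sham"]]$mean,
      mean_female_sham = gs[["female/sham"]]$mean,
      stringsAsFactors = FALSE
    )
    absolute <- rbind(absolute, row)

    pc_m <- percent_change(gs[["male/tumour"]], gs[["male/sham"]], mode = mode)
    pc_f <- percent_change(gs[["female/tumour"]], gs[["female/sham"]], mode = mode)
    wt <- welch_or_na(gs[["male/tumour"]], gs[["female/tumour"]])
    change <- rbind(change, data.frame(
      region = rg, quantity = qy,
      pct_change_male = pc_m$pct, sem_male = pc_m$sem,
      pct_change_female = pc_f$pct, sem_female = pc_f$sem,
      welch_t = wt$t, welch_df = wt$df, welch_p = wt$p,
      stars = wt$stars, stringsAsFactors = FALSE
    ))
  }
  list(absolute = absolute, change = change, summaries = summaries)
}
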