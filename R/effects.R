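#' Group labels used throughout the package
#' @export
group_labels <- function() {
  c("male/tumour", "female/tumour", "male/sham", "female/sham")
}

split_group <- function(group) {
  if (!group %in% group_labels()) {
    stop(
      "unknown group '", group, "'; valid groups: ",
      paste(group_labels(), collapse = ", "),
      call. = FALSE
    )
  }
  parts <- strsplit(group, "/", fixed = TRUE)[[1]]
  list(sex = parts[1], condition = parts[2])
}

#' Group-effect table: study means and SEMs per group and region
#'
#' The absolute MRI parameters reported for the four experimental groups
#' (male/female x tumour/sham, n = 8 per group): MTR (%), MD (um^2/s) and
#' FA in the tumour core and periphery, plus relative CBV, CBF and MTT
#' over the whole tumour (perfusion maps are too coarse to separate core
#' from periphery). These values drive the phantom as ground truth.
#'
#' Between-subject SD is derived as SEM * sqrt(n): only SEMs are reported
#' in the study.
#'
#' Note the published CBF row is not consistent with CBV/MTT under the
#' central-volume relation CBF = CBV/MTT (and its sham cells duplicate the
#' CBV ones); the phantom treats CBV and MTT as primary and derives CBF.
#'
#' @param n_per_group subjects per group, default 8.
#' @return data.frame with columns `group`, `region`, `quantity`, `mean`,
#'   `sem`, `sd`, `n`.
#' @export
default_group_effects <- function(n_per_group = 8L) {
  grp <- group_labels()
  row <- function(region, quantity, means, sems) {
    data.frame(
      group = grp, region = region, quantity = quantity,
      mean = means, sem = sems, stringsAsFactors = FALSE
    )
  }
  eff <- rbind(
    # tumour core                     m/t     f/t     m/s     f/s
    row("core", "mtr", c(14.29, 13.02, 20.13, 18.57), c(0.35, 0.07, 0.23, 0.22)),
    row("core", "md", c(1200, 1120, 1028, 988), c(9, 5, 4, 5)),
    row("core", "fa", c(0.244, 0.224, 0.348, 0.314), c(0.002, 0.001, 0.002, 0.002)),
    # periphery (enhanced outer ring)
    row("periphery", "mtr", c(22.00, 19.60, 20.10, 18.14), c(0.16, 0.12, 0.20, 0.22)),
    row("periphery", "md", c(963, 955, 1036, 1006), c(5, 4, 5, 5)),
    row("periphery", "fa", c(0.279, 0.232, 0.340, 0.316), c(0.002, 0.001, 0.002, 0.002)),
    # whole tumour, relative to the contralateral reference region
    row("tumour", "cbv", c(1.44, 1.55, 0.81, 0.97), c(0.03, 0.04, 0.04, 0.03)),
    row("tumour", "cbf", c(1.56, 1.55, 0.81, 0.97), c(0.03, 0.03, 0.04, 0.03)),
    row("tumour", "mtt", c(1.077, 0.934, 0.933, 0.953), c(0.009, 0.006, 0.011, 0.010))
  )
  eff$n <- as.integer(n_per_group)
  eff$sd <- eff$sem * sqrt(eff$n)
  validate_group_effects(eff)
  rownames(eff) <- NULL
  eff
}

validate_group_effects <- function(effects) {
  needed <- c("group", "region", "quantity", "mean", "sem")
  if (!all(needed %in% names(effects))) {
    stop(
      "effect table must have columns ",
      paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  fa <- effects$quantity == "fa"
  if (any(effects$mean[fa] < 0 | effects$mean[fa] > 1)) {
    stop("FA entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(effects$mean[effects$quantity == "md"] <= 0)) {
    stop("MD entries must be positive", call. = FALSE)
  }
  if (any(effects$sem < 0)) stop("SEM must be non-negative", call. = FALSE)
  invisible(effects)
}

#' Look up one cell of a group-effect table
#'
#' @param effects effect table, see [default_group_effects()].
#' @param group,region,quantity cell coordinates.
#' @param what column to return (`"mean"`, `"sem"`, `"sd"`, `"n"`).
#' @return the requested scalar; error if the cell is absent.
#' @export
effect_value <- function(effects, group, region, quantity,
                         what = "mean") {
  i <- effects$group == group & effects$region == region &
    effects$quantity == quantity
  if (sum(i) != 1L) {
    stop(
      "effect table has no unique entry for ", group, "/", region, "/",
      quantity,
      call. = FALSE
    )
  }
  effects[[what]][i]
}
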