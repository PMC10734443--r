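#' Path-length correction of optical density
#'
#' Normalizes a raw absorbance to its 1 cm equivalent by dividing by the
#' optical path-length factor of the plate/vessel format. The factor is
#' instrument- and fill-volume-specific and has no default in the pipeline
#' configuration.
#'
#' @param od_raw absorbance value(s).
#' @param pathlength_factor positive path length relative to 1 cm.
#' @return corrected absorbance, same length as `od_raw`.
#' @export
correct_pathlength <- function(od_raw, pathlength_factor) {
  if (!is.numeric(pathlength_factor) || length(pathlength_factor) != 1 ||
      pathlength_factor <= 0)
    stop("pathlength_factor must be a single positive number")
  od_raw / pathlength_factor
}

#' Photomembrane production index (PMP)
#'
#' PMP = OD880 / OD660: pigment absorbance (880 nm, light-harvesting
#' photomembranes) normalized per unit biomass (660 nm turbidity). Because
#' both channels share the optical path, PMP is invariant to path-length
#' correction.
#'
#' @param od880,od660 absorbance values (vectorized).
#' @return PMP value(s).
#' @export
compute_pmp <- function(od880, od660) {
  if (any(od660 <= 0)) stop("PMP undefined: od660 must be positive")
  od880 / od660
}

#' Pigmentation difference to an unpigmented control (delta PMP)
#'
#' `delta PMP = PMP_i - PMP_c`, the PMP of the condition of interest minus
#' the basal PMP of the corresponding unpigmented (fully aerated) control
#' culture.
#'
#' @param pmp_i PMP of the sample condition.
#' @param pmp_c PMP of the unpigmented control.
#' @return delta PMP value(s).
#' @export
compute_delta_pmp <- function(pmp_i, pmp_c) pmp_i - pmp_c

#' Endpoints of one growth series
#'
#' Maximal (path-length-corrected) biomass, the time it is reached, and the
#' pigmentation index at the final time point — the end-of-culture
#' measurement used when comparing aeration conditions. When a control PMP is
#' supplied the endpoint delta PMP is included.
#'
#' @param time_h strictly increasing times (hours).
#' @param od660,od880 absorbance series of the same length.
#' @param pathlength_factor optical path-length factor (default 1).
#' @param control_pmp optional PMP of the unpigmented control.
#' @return list with `max_od660`, `t_max`, `endpoint_pmp`, and
#'   `endpoint_delta_pmp` (NA without a control).
#' @export
growth_endpoints <- function(time_h, od660, od880, pathlength_factor = 1,
                             control_pmp = NULL) {
  if (length(time_h) < 1) stop("empty growth series")
  stopifnot(length(od660) == length(time_h), length(od880) == length(time_h))
  if (is.unsorted(time_h, strictly = TRUE)) stop("time points must be strictly increasing")
  od660c <- correct_pathlength(od660, pathlength_factor)
  i_max <- which.max(od660c)
  last <- length(time_h)
  pmp <- compute_pmp(od880[last], od660[last])
  list(
    max_od660 = od660c[i_max],
    t_max = time_h[i_max],
    endpoint_pmp = pmp,
    endpoint_delta_pmp = if (is.null(control_pmp)) NA_real_
      else compute_delta_pmp(pmp, control_pmp)
  )
}

#' Per-condition endpoint summary of a growth table
#'
#' Computes per-replicate endpoints for every strain x condition, then the
#' mean and standard deviation across replicates, and the delta PMP of each
#' condition relative to the mean endpoint PMP of the same strain in the
#' control (unpigmented) condition.
#'
#' @param growth data.frame with columns `condition`, `strain`, `replicate`,
#'   `time_h`, `od660`, `od880`.
#' @param control_condition label of the unpigmented reference condition.
#' @param pathlength_factor optical path-length factor (default 1).
#' @return list with `replicates` (per-replicate endpoint data.frame) and
#'   `summary` (per strain x condition: `mean_max_od660`, `sd_max_od660`,
#'   `mean_pmp`, `sd_pmp`, `delta_pmp`).
#' @export
endpoint_summary <- function(growth, control_condition = "O1",
                             pathlength_factor = 1) {
  if (!control_condition %in% growth$condition)
    stop("control condition '", control_condition, "' absent from growth data")
  key <- interaction(growth$strain, growth$condition, growth$replicate, drop = TRUE)
  reps <- do.call(rbind, lapply(split(growth, key), function(g) {
    g <- g[order(g$time_h), ]
    ep <- growth_endpoints(g$time_h, g$od660, g$od880, pathlength_factor)
    data.frame(strain = g$strain[1], condition = g$condition[1],
               replicate = g$replicate[1], max_od660 = ep$max_od660,
               t_max = ep$t_max, endpoint_pmp = ep$endpoint_pmp,
               stringsAsFactors = FALSE)
  }))
  rownames(reps) <- NULL
  grp <- interaction(reps$strain, reps$condition, drop = TRUE)
  summ <- do.call(rbind, lapply(split(reps, grp), function(r) {
    data.frame(strain = r$strain[1], condition = r$condition[1],
               n = nrow(r),
               mean_max_od660 = mean(r$max_od660), sd_max_od660 = stats::sd(r$max_od660),
               mean_pmp = mean(r$endpoint_pmp), sd_pmp = stats::sd(r$endpoint_pmp),
               stringsAsFactors = FALSE)
  }))
  ctrl <- summ[summ$condition == control_condition, c("strain", "mean_pmp")]
  summ$delta_pmp <- compute_delta_pmp(
    summ$mean_pmp, ctrl$mean_pmp[match(summ$strain, ctrl$strain)]
  )
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}

#' Unpaired two-tailed Student's t test
#'
#' Classical equal-variance two-sample comparison (the test used for
#' endpoint biomass and pigmentation contrasts). Degenerate input in which
#' both groups are constant and equal returns `t = 0`, `p = 1` instead of an
#' error.
#'
#' @param values_a,values_b numeric vectors, at least 2 values each.
#' @return list with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("at least 2 values per group are required")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(list(statistic = 0, p_value = 1,
                df = length(values_a) + length(values_b) - 2,
                mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}
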