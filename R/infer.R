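#' Call probe penetration for one treatment against the control
#'
#' Decides whether a dextran probe entered the cytoplasm under a
#' treatment, by comparing zone profiles to the matched untreated
#' control. Two conditions are both required:
#'
#' 1. the score — mean normalized ratio over the outermost
#'    `score_zones` (default zones 1–3, where entry signal is
#'    strongest) — reaches `theta`;
#' 2. a one-sided Welch test of per-cell scores (treated > control) is
#'    significant at `alpha`.
#'
#' The dual criterion prevents a large sample from declaring a
#' negligible intensity difference an entry, and a single bright
#' outlier from passing without statistical support. Wall penetration
#' is called separately: the probe is in the wall when the mean
#' wall-annulus/background ratio reaches `wall_theta`, regardless of
#' cytoplasmic entry (walls can be permeable to probes the membrane
#' still excludes).
#'
#' @param treated,control `treatment_profile` objects.
#' @param probe_label Probe identity carried into the call.
#' @param theta Minimum score for a cytoplasmic entry call.
#' @param alpha One-sided significance level of the Welch comparison.
#' @param wall_theta Minimum wall/background ratio for a wall call.
#' @param score_zones Zones averaged into the score.
#' @return A `penetration_call`: `entered_cytoplasm`, `entered_wall`,
#'   `score`, `p_value`, plus treatment and probe labels.
#' @export
call_penetration <- function(treated, control, probe_label = "",
                             theta = 0.2, alpha = 0.05, wall_theta = 1.5,
                             score_zones = 1:3) {
  if (missing(control) || is.null(control))
    stop("a matched control profile is required")
  stopifnot(inherits(treated, "treatment_profile"),
            inherits(control, "treatment_profile"))
  sc_t <- rowMeans(treated$ratios[, score_zones, drop = FALSE])
  sc_c <- rowMeans(control$ratios[, score_zones, drop = FALSE])
  score <- mean(sc_t)
  p <- tryCatch(
    stats::t.test(sc_t, sc_c, alternative = "greater")$p.value,
    error = function(e) 1)  # degenerate (zero-variance) inputs
  wall_mean <- mean(treated$wall_ratios, na.rm = TRUE)
  structure(list(treatment = treated$treatment$label,
                 probe = probe_label,
                 entered_cytoplasm = score >= theta && p <= alpha,
                 entered_wall = is.finite(wall_mean) && wall_mean >= wall_theta,
                 score = score,
                 wall_score = wall_mean,
                 p_value = p,
                 theta = theta, alpha = alpha, wall_theta = wall_theta),
            class = "penetration_call")
}

#' @export
print.penetration_call <- function(x, ...) {
  cat(sprintf("%s / %s: cytoplasm %s (score %.3f, p %.2g), wall %s (ratio %.2f)\n",
              x$treatment, x$probe,
              if (x$entered_cytoplasm) "ENTERED" else "excluded",
              x$score, x$p_value,
              if (x$entered_wall) "ENTERED" else "excluded",
              x$wall_score))
  invisible(x)
}

#' Infer a membrane pore-radius interval from a ladder of calls
#'
#' Under pure size exclusion, every probe with coil radius below the
#' pore radius enters and every larger probe is excluded, so the calls
#' bracket the pore radius: the lower bound is the largest entering
#' probe radius (0 if none entered) and the upper bound the smallest
#' excluded probe radius (unbounded if everything entered). Call
#' patterns violating monotonicity (a larger probe in while a smaller
#' is out) are flagged and resolved on the monotone closure — every
#' probe not larger than the largest entering probe is treated as
#' entering — with a warning.
#'
#' @param calls List of `penetration_call`, one per probe, with `probe`
#'   labels matching the ladder.
#' @param ladder A `dextran_ladder` from [build_ladder()].
#' @return A `pore_size_estimate`: `lower_bound_nm`, `upper_bound_nm`
#'   (`Inf` when unbounded), `non_monotone` flag and the basis calls.
#' @export
infer_pore_bounds <- function(calls, ladder) {
  if (length(calls) == 0) stop("no penetration calls given")
  labels <- vapply(calls, function(x) x$probe, character(1))
  miss <- setdiff(labels, ladder$label)
  if (length(miss) > 0)
    stop("calls refer to probes absent from the ladder: ",
         paste(miss, collapse = ", "))
  radius <- ladder$rg_nm[match(labels, ladder$label)]
  ord <- order(radius)
  radius <- radius[ord]
  entered <- vapply(calls, function(x) isTRUE(x$entered_cytoplasm), logical(1))[ord]
  non_monotone <- any(diff(entered) > 0)  # FALSE -> TRUE with growing radius
  entered_cl <- monotone_closure(entered)
  if (non_monotone)
    warning("non-monotone call pattern (larger probe entered while a ",
            "smaller one did not); bounds computed on the monotone closure")
  lower <- if (any(entered_cl)) max(radius[entered_cl]) else 0
  upper <- if (any(!entered_cl)) min(radius[!entered_cl]) else Inf
  structure(list(treatment = calls[[1]]$treatment,
                 lower_bound_nm = lower,
                 upper_bound_nm = upper,
                 non_monotone = non_monotone,
                 basis = calls[ord]),
            class = "pore_size_estimate")
}

# Monotone closure of an entry pattern ordered by ascending radius:
# every probe up to the largest entering probe counts as entering.
monotone_closure <- function(entered) {
  if (!any(entered)) return(entered)
  seq_along(entered) <= max(which(entered))
}

#' @export
print.pore_size_estimate <- function(x, ...) {
  cat("Pore radius for '", x$treatment, "': ",
      format_interval(x$lower_bound_nm, x$upper_bound_nm), "\n", sep = "")
  if (x$non_monotone) cat("  (non-monotone call pattern; monotone closure used)\n")
  invisible(x)
}

format_interval <- function(lower, upper) {
  if (is.infinite(upper)) sprintf("at least %.2f nm", lower)
  else if (lower <= 0) sprintf("below %.2f nm", upper)
  else sprintf("between %.2f and %.2f nm", lower, upper)
}

#' Summarize pore-size estimates across treatments
#'
#' @param estimates List of `pore_size_estimate`.
#' @return A `pore_study_report`: `table` (treatment, bounds, interval
#'   text) and `wall_matrix` (treatment x probe wall-entry logical,
#'   when wall calls are present). Serialize with
#'   [report_to_json()].
#' @export
summarize_study <- function(estimates) {
  if (length(estimates) == 0) {
    tab <- data.frame(treatment = character(0), lower_bound_nm = numeric(0),
                      upper_bound_nm = numeric(0), interval = character(0),
                      non_monotone = logical(0))
    return(structure(list(table = tab, wall_matrix = NULL),
                     class = "pore_study_report"))
  }
  tab <- do.call(rbind, lapply(estimates, function(e) data.frame(
    treatment = e$treatment,
    lower_bound_nm = e$lower_bound_nm,
    upper_bound_nm = e$upper_bound_nm,
    interval = format_interval(e$lower_bound_nm, e$upper_bound_nm),
    non_monotone = e$non_monotone,
    stringsAsFactors = FALSE)))
  probes <- unique(unlist(lapply(estimates, function(e)
    vapply(e$basis, function(b) b$probe, character(1)))))
  wall <- matrix(NA, length(estimates), length(probes),
                 dimnames = list(tab$treatment, probes))
  for (i in seq_along(estimates))
    for (b in estimates[[i]]$basis)
      wall[i, b$probe] <- b$entered_wall
  structure(list(table = tab, wall_matrix = wall),
            class = "pore_study_report")
}

#' @export
print.pore_study_report <- function(x, ...) {
  if (nrow(x$table) == 0) {
    cat("Pore-size study report: no treatments\n")
    return(invisible(x))
  }
  cat("Pore-size study report\n")
  print.data.frame(x$table[, c("treatment", "interval", "non_monotone")],
                   row.names = FALSE)
  if (!is.null(x$wall_matrix)) {
    cat("\nWall permeability (probe entered the wall):\n")
    print(x$wall_matrix)
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report A `pore_study_report` from [summarize_study()].
#' @param path Optional output path; if `NULL` the JSON string is
#'   returned. Unbounded upper limits are encoded as the string
#'   `"unbounded"`.
#' @export
report_to_json <- function(report, path = NULL) {
  tab <- report$table
  tab$upper_bound_nm <- ifelse(is.infinite(tab$upper_bound_nm),
                               "unbounded", tab$upper_bound_nm)
  payload <- list(treatments = tab, wall_permeability = report$wall_matrix)
  if (is.null(path))
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
  }
}
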