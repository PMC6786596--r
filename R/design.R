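#' Experimental design for a set of expression libraries
#'
#' An `experiment_design` is a data frame with one row per library and
#' columns `library_id`, `condition`, `replicate`, `control_condition`
#' and `timepoint_hours`. `control_condition` links each stress condition
#' to its matched control (`NA` for conditions that are themselves
#' controls); `timepoint_hours` is `NA` for designs without a time course.
#'
#' @param library_id character vector of unique library identifiers.
#' @param condition condition label per library.
#' @param replicate integer replicate index per library.
#' @param control_condition per-library label of the matched control
#'   condition for the library's condition, or `NA`.
#' @param timepoint_hours numeric hours of stress exposure, or `NA`.
#' @return A data frame of class `experiment_design`.
#' @examples
#' d <- experiment_design(
#'   library_id = c("ctl_r1", "ctl_r2", "str_r1", "str_r2"),
#'   condition = c("control", "control", "stress", "stress"),
#'   replicate = c(1, 2, 1, 2),
#'   control_condition = c(NA, NA, "control", "control")
#' )
#' @export
experiment_design <- function(library_id, condition, replicate,
                              control_condition = NA_character_,
                              timepoint_hours = NA_real_) {
  d <- data.frame(
    library_id = as.character(library_id),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    control_condition = as.character(control_condition),
    timepoint_hours = as.numeric(timepoint_hours),
    stringsAsFactors = FALSE
  )
  class(d) <- c("experiment_design", "data.frame")
  validate_design(d)
  d
}

#' @keywords internal
validate_design <- function(d) {
  stopifnot(is.data.frame(d))
  required <- c("library_id", "condition", "replicate",
                "control_condition", "timepoint_hours")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(d$library_id)) {
    dup <- d$library_id[duplicated(d$library_id)][1]
    stop("duplicate library id in design: ", dup)
  }
  conds <- unique(d$condition)
  refs <- unique(d$control_condition[!is.na(d$control_condition)])
  bad <- setdiff(refs, conds)
  if (length(bad) > 0) {
    stop("control_condition references unknown condition: ",
         paste(bad, collapse = ", "))
  }
  n_rep <- table(d$condition)
  if (any(n_rep < 2)) {
    stop("condition with fewer than 2 replicates: ",
         paste(names(n_rep)[n_rep < 2], collapse = ", "))
  }
  invisible(d)
}

#' Libraries belonging to a condition
#' @param design an `experiment_design`.
#' @param condition a condition label.
#' @return Character vector of library ids, in design order.
#' @export
condition_libraries <- function(design, condition) {
  if (!condition %in% design$condition) {
    stop("unknown condition: ", condition)
  }
  design$library_id[design$condition == condition]
}

#' Aluminium time-course design (3 time points x stress/control x 3 replicates)
#'
#' The standard 18-library layout for a root aluminium-exposure time course:
#' stress and matched control conditions at 6, 54 and 246 hours, three
#' biological replicates each.
#'
#' @param n_replicates replicates per condition (default 3).
#' @return An `experiment_design` with `6 * n_replicates` libraries.
#' @export
al_design <- function(n_replicates = 3) {
  tp <- c(6, 54, 246)
  rows <- do.call(rbind, lapply(tp, function(h) {
    data.frame(
      condition = rep(c(sprintf("Al_control_%dh", h), sprintf("Al_stress_%dh", h)),
                      each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2),
      control_condition = rep(c(NA_character_, sprintf("Al_control_%dh", h)),
                              each = n_replicates),
      timepoint_hours = h,
      stringsAsFactors = FALSE
    )
  }))
  experiment_design(
    library_id = sprintf("%s_r%d", rows$condition, rows$replicate),
    condition = rows$condition,
    replicate = rows$replicate,
    control_condition = rows$control_condition,
    timepoint_hours = rows$timepoint_hours
  )
}

#' Phosphate dose design (high / mild-starved / starved x 3 replicates)
#'
#' The standard 9-library layout for a phosphate starvation dose series:
#' high supply (control), mildly starved and starved, three biological
#' replicates each. Both starvation conditions are contrasted against the
#' high-phosphate condition.
#'
#' @param n_replicates replicates per condition (default 3).
#' @return An `experiment_design` with `3 * n_replicates` libraries.
#' @export
p_design <- function(n_replicates = 3) {
  conds <- c("P_high", "P_mild", "P_low")
  rows <- data.frame(
    condition = rep(conds, each = n_replicates),
    replicate = rep(seq_len(n_replicates), 3),
    control_condition = rep(c(NA_character_, "P_high", "P_high"),
                            each = n_replicates),
    stringsAsFactors = FALSE
  )
  experiment_design(
    library_id = sprintf("%s_r%d", rows$condition, rows$replicate),
    condition = rows$condition,
    replicate = rows$replicate,
    control_condition = rows$control_condition,
    timepoint_hours = NA_real_
  )
}

#' Combined dual-stress design (18 aluminium + 9 phosphate libraries)
#' @param n_replicates replicates per condition (default 3).
#' @return An `experiment_design` with the aluminium libraries first,
#'   followed by the phosphate libraries, in fixed order.
#' @export
dual_design <- function(n_replicates = 3) {
  a <- al_design(n_replicates)
  p <- p_design(n_replicates)
  d <- rbind(as.data.frame(a), as.data.frame(p))
  class(d) <- c("experiment_design", "data.frame")
  validate_design(d)
  d
}

#' Standard stress/control contrasts for a design
#'
#' A contrast names one stress condition and its matched control. For the
#' aluminium time course these are the time-matched pairs (`Al_6h`,
#' `Al_54h`, `Al_246h`); for the phosphate series, mild starvation vs high
#' supply (`P_mild`) and starvation vs high supply (`P_severe`).
#'
#' @param design an `experiment_design`; contrasts are derived from its
#'   `control_condition` links.
#' @return Data frame with columns `name`, `stress_condition`,
#'   `control_condition`.
#' @export
default_contrasts <- function(design) {
  per_cond <- unique(as.data.frame(design)[, c("condition", "control_condition",
                                               "timepoint_hours")])
  per_cond <- per_cond[!is.na(per_cond$control_condition), , drop = FALSE]
  nm <- vapply(seq_len(nrow(per_cond)), function(i) {
    cond <- per_cond$condition[i]
    switch(cond,
           "P_mild" = "P_mild",
           "P_low" = "P_severe",
           if (!is.na(per_cond$timepoint_hours[i])) {
             sprintf("Al_%dh", per_cond$timepoint_hours[i])
           } else {
             cond
           })
  }, character(1))
  data.frame(
    name = nm,
    stress_condition = per_cond$condition,
    control_condition = per_cond$control_condition,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Define a single contrast
#' @param name contrast label.
#' @param stress_condition condition label of the stressed group.
#' @param control_condition condition label of the control group.
#' @param design optional `experiment_design` to validate against.
#' @return One-row contrast data frame.
#' @export
contrast <- function(name, stress_condition, control_condition, design = NULL) {
  if (identical(stress_condition, control_condition)) {
    stop("stress and control conditions must differ")
  }
  if (!is.null(design)) {
    for (cond in c(stress_condition, control_condition)) {
      if (!cond %in% design$condition) stop("unknown condition: ", cond)
    }
  }
  data.frame(name = name, stress_condition = stress_condition,
             control_condition = control_condition, stringsAsFactors = FALSE)
}
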