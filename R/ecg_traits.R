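#' @keywords internal
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

#' @keywords internal
ECG_FLAGS <- c("atrial_fibrillation", "myocardial_infarction",
               "bundle_branch_block", "av_block", "pacemaker", "wpw",
               "pregnancy", "antiarrhythmic_or_digoxin")

#' @keywords internal
ECG_TRAITS <- c("QRS", "QT", "PR", "SL", "CV", "12LS")

#' Heart-rate-corrected QT interval (Bazett)
#'
#' \eqn{QTc = QT / \sqrt{RR}} with the RR interval in seconds
#' (\eqn{RR = 60 / HR}).  At 60 bpm the correction is the identity.
#'
#' @param qt_ms QT interval in milliseconds (> 0).
#' @param heart_rate_bpm heart rate in beats per minute (> 0).
#' @return corrected QT in milliseconds.
#' @examples
#' bazett_qtc(400, 60)   # 400
#' bazett_qtc(400, 90)   # 489.9
#' @export
bazett_qtc <- function(qt_ms, heart_rate_bpm) {
  bad <- !is.na(qt_ms) & qt_ms <= 0 | !is.na(heart_rate_bpm) & heart_rate_bpm <= 0
  if (any(bad))
    stop("QT interval and heart rate must both be positive")
  qt_ms / sqrt(60 / heart_rate_bpm)
}

amp_get <- function(rec, cols) {
  v <- unlist(rec[cols], use.names = FALSE)
  if (length(v) != length(cols) || anyNA(v))
    stop("missing lead amplitude(s): ",
         paste(cols[is.na(unlist(rec[cols]))], collapse = ", "))
  if (any(v < 0)) stop("lead amplitudes must be non-negative magnitudes")
  as.numeric(v)
}

#' Left-ventricular-hypertrophy voltage-duration products
#'
#' Each index is a sum of lead amplitudes (mm; 1 mm = 0.1 mV at standard
#' calibration) multiplied by QRS duration (ms), approximating the area under
#' the QRS complex:
#' \itemize{
#'   \item Sokolow-Lyon: \eqn{(S_{V1} + \max(R_{V5}, R_{V6})) \times QRS}
#'   \item Cornell: \eqn{(R_{aVL} + S_{V3}) \times QRS}
#'   \item 12-lead sum: \eqn{\sum_{12\ leads} (R + S) \times QRS}
#' }
#' For the 12-lead sum an alternate signed mode (`mode = "difference"`,
#' per-lead \eqn{R - S}) is available; the unsigned amplitude sum is the
#' default.
#'
#' @param rec a one-row data.frame (or named list) with `qrs_ms` and amplitude
#'   entries `R_<lead>` / `S_<lead>` for the 12 standard leads.
#' @return voltage-duration product in mm*ms.
#' @examples
#' rec <- as.list(setNames(rep(1, 24), paste0(rep(c("R_", "S_"),
#'        each = 12), rep(c("I","II","III","aVR","aVL","aVF",
#'        paste0("V", 1:6)), 2))))
#' rec$qrs_ms <- 100
#' twelve_lead_sum_product(rec)  # 2400
#' @export
sokolow_lyon_product <- function(rec) {
  a <- amp_get(rec, c("S_V1", "R_V5", "R_V6"))
  (a[1] + max(a[2], a[3])) * as.numeric(rec[["qrs_ms"]])
}

#' @rdname sokolow_lyon_product
#' @export
cornell_product <- function(rec) {
  a <- amp_get(rec, c("R_aVL", "S_V3"))
  sum(a) * as.numeric(rec[["qrs_ms"]])
}

#' @rdname sokolow_lyon_product
#' @param mode `"sum"` (unsigned per-lead R + S, default) or `"difference"`
#'   (signed per-lead R - S).
#' @export
twelve_lead_sum_product <- function(rec, mode = c("sum", "difference")) {
  mode <- match.arg(mode)
  r <- amp_get(rec, paste0("R_", ECG_LEADS))
  s <- amp_get(rec, paste0("S_", ECG_LEADS))
  v <- if (mode == "sum") sum(r + s) else sum(r - s)
  v * as.numeric(rec[["qrs_ms"]])
}

#' Derive analysis traits for a whole cohort
#'
#' Adds `QRS`, `QT` (Bazett-corrected), `PR`, `SL`, `CV` and `12LS` columns to
#' a cohort table of raw ECG measurements.  Rows with missing inputs get `NA`
#' for the affected trait.
#'
#' @param cohort data.frame with columns `qrs_ms`, `qt_ms`, `pr_ms`,
#'   `heart_rate_bpm` and the 24 amplitude columns.
#' @param twelve_lead_mode passed to [twelve_lead_sum_product()].
#' @return the cohort with six derived trait columns appended.
#' @export
derive_traits <- function(cohort, twelve_lead_mode = c("sum", "difference")) {
  twelve_lead_mode <- match.arg(twelve_lead_mode)
  stopifnot(is.data.frame(cohort))
  qrs <- cohort$qrs_ms
  cohort$QRS <- qrs
  cohort$QT <- ifelse(is.na(cohort$qt_ms) | is.na(cohort$heart_rate_bpm),
                      NA_real_, bazett_qtc(cohort$qt_ms, cohort$heart_rate_bpm))
  cohort$PR <- cohort$pr_ms
  sv1 <- cohort$S_V1; rv5 <- cohort$R_V5; rv6 <- cohort$R_V6
  cohort$SL <- (sv1 + pmax(rv5, rv6)) * qrs
  cohort$CV <- (cohort$R_aVL + cohort$S_V3) * qrs
  rsum <- rowSums(cohort[paste0("R_", ECG_LEADS)])
  ssum <- rowSums(cohort[paste0("S_", ECG_LEADS)])
  cohort[["12LS"]] <- (if (twelve_lead_mode == "sum") rsum + ssum
                       else rsum - ssum) * qrs
  cohort
}

#' Per-trait ECG exclusion rules
#'
#' Applies the cohort's exclusion scheme for one analysis trait.  Globally
#' (all traits): atrial fibrillation, myocardial infarction, bundle branch
#' block, atrioventricular block, pacemaker, Wolff-Parkinson-White, pregnancy,
#' and use of class I/III antiarrhythmics or digoxin.  Trait-specific:
#' QRS > 120 ms excludes from the QRS, QT and LVH-proxy analyses (not PR);
#' PR >= 320 or <= 80 ms excludes from the PR analysis only; QRS axis > 90 or
#' < -30 degrees excludes from the LVH-proxy analyses only.  Each dropped row
#' is annotated with the first rule it triggered, in the order above.
#'
#' @param cohort data.frame with an `id` column, the 8 flag columns, and
#'   `qrs_ms`, `pr_ms`, `qrs_axis_deg` as needed by the rules.
#' @param trait one of `"QRS"`, `"QT"`, `"PR"`, `"SL"`, `"CV"`, `"12LS"`.
#' @return data.frame `id`, `trait`, `kept` (logical), `reason`
#'   (`NA` when kept).  Applying the function to its own kept subset is a
#'   no-op (idempotence).
#' @export
apply_exclusions <- function(cohort, trait) {
  stopifnot(is.data.frame(cohort), "id" %in% names(cohort))
  if (!trait %in% ECG_TRAITS)
    stop("unknown trait '", trait, "'; expected one of: ",
         paste(ECG_TRAITS, collapse = ", "))
  n <- nrow(cohort)
  reason <- rep(NA_character_, n)
  hit <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason <<- ifelse(is.na(reason) & cond, why, reason)
  }
  for (fl in ECG_FLAGS) {
    v <- if (fl %in% names(cohort)) as.logical(cohort[[fl]]) else FALSE
    hit(v, fl)
  }
  if (trait %in% c("QRS", "QT", "SL", "CV", "12LS"))
    hit(cohort$qrs_ms > 120, "qrs_gt_120")
  if (trait == "PR")
    hit(cohort$pr_ms >= 320 | cohort$pr_ms <= 80, "pr_out_of_range")
  if (trait %in% c("SL", "CV", "12LS"))
    hit(cohort$qrs_axis_deg > 90 | cohort$qrs_axis_deg < -30,
        "axis_out_of_range")
  data.frame(id = cohort$id, trait = trait, kept = is.na(reason),
             reason = reason, stringsAsFactors = FALSE)
}
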