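# Domain types: marker profiles, normal ranges, stage labels.

#' Tumor-marker feature order
#'
#' The six serum markers used as input features, in the fixed order every
#' vector-valued interface of the package follows: prostate-specific antigen
#' (PSA, ng/mL), prostate-specific membrane antigen (PSMA, ng/mL), total PSA
#' (tPSA, ug/L), red blood cell (RBC, g/100 mL), hemoglobin (HB, g/L), and
#' prostatic acid phosphatase (PAP, U/L).
#'
#' @return Character vector of the six marker column names.
#' @export
#' @examples
#' marker_names()
marker_names <- function() {
  c("psa", "psma", "tpsa", "rbc", "hb", "pap")
}

#' Reference normal ranges for the six tumor markers
#'
#' Closed intervals `[low, high]`, one per marker, in the marker's printed
#' clinical unit. The defaults are the published reference ranges used by the
#' system (PSA 0-4.0 ng/mL, tPSA 4-20 ug/L, HB 120-165 g/L, RBC 12-15
#' g/100 mL, PAP 0-9 U/L, PSMA 0-4 ng/mL). Note two oddities kept verbatim
#' from the source table: RBC is printed with a hemoglobin-like unit, and
#' tPSA's floor exceeds PSA's ceiling; both can be overridden here.
#'
#' @param ... Named overrides, each a numeric `c(low, high)` with `low < high`,
#'   e.g. `normal_ranges(psa = c(0, 6.5))`.
#' @return A named list with elements `psa`, `psma`, `tpsa`, `rbc`, `hb`,
#'   `pap`, each `c(low, high)`.
#' @export
#' @examples
#' normal_ranges()$psa
normal_ranges <- function(...) {
  rng <- list(
    psa  = c(0, 4.0),
    psma = c(0, 4),
    tpsa = c(4, 20),
    rbc  = c(12, 15),
    hb   = c(120, 165),
    pap  = c(0, 9)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(rng)) stop("unknown marker: ", nm)
    v <- as.numeric(ov[[nm]])
    if (length(v) != 2 || !all(is.finite(v)) || v[1] >= v[2]) {
      stop("range for ", nm, " must be c(low, high) with low < high")
    }
    rng[[nm]] <- v
  }
  rng
}

#' Ordered clinical stage labels
#'
#' @return `c("benign", "I", "II", "III", "IV")`, the total order of verdicts
#'   from benign disease to most advanced malignancy.
#' @export
stage_levels <- function() {
  c("benign", "I", "II", "III", "IV")
}

malignant_stages <- function() c("I", "II", "III", "IV")

as_stage <- function(x) {
  f <- factor(as.character(x), levels = stage_levels(), ordered = TRUE)
  if (anyNA(f) && !anyNA(x)) stop("unknown stage label(s): ",
                                  paste(unique(setdiff(as.character(x), stage_levels())), collapse = ", "))
  f
}

#' Extract the 6-column marker matrix from a patient table
#'
#' Forms the numeric input matrix in the fixed feature order
#' (psa, psma, tpsa, rbc, hb, pap). Every model in the package consumes
#' marker values only through this function, so the feature order is
#' invariant across modules.
#'
#' @param data A data frame (or single-row list) containing the six marker
#'   columns, or a numeric matrix/vector already in marker order.
#' @return Numeric matrix with one row per patient and columns
#'   `marker_names()`.
#' @export
#' @examples
#' marker_matrix(data.frame(psa = 1, psma = 0, tpsa = 0, rbc = 0, hb = 0, pap = 0))
marker_matrix <- function(data) {
  nm <- marker_names()
  if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) != 6) stop("a marker vector must have length 6")
    X <- matrix(data, nrow = 1)
    colnames(X) <- nm
    return(X)
  }
  if (is.matrix(data)) {
    if (ncol(data) != 6) stop("a marker matrix must have 6 columns")
    if (!is.null(colnames(data))) data <- data[, nm, drop = FALSE]
    X <- data
    colnames(X) <- nm
    storage.mode(X) <- "double"
    return(X)
  }
  missing <- setdiff(nm, names(data))
  if (length(missing)) stop("missing marker column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(as.data.frame(data)[, nm, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Check a marker profile against normal ranges
#'
#' Pure validation: flags each marker as below, within, or above its closed
#' reference interval, and reports the fold change relative to the upper
#' bound. Non-finite or negative values are rejected with the marker name.
#'
#' @param profile A single patient's markers: named numeric vector, one-row
#'   data frame, or list with the six marker fields.
#' @param ranges Reference intervals, as from [normal_ranges()].
#' @return Data frame with one row per marker: `marker`, `value`, `low`,
#'   `high`, `status` (`"below"`, `"in"`, `"above"`), and `fold_upper`
#'   (`value / high`).
#' @export
#' @examples
#' validate_profile(c(psa = 2, psma = 1, tpsa = 10, rbc = 13, hb = 140, pap = 90))
validate_profile <- function(profile, ranges = normal_ranges()) {
  x <- drop(marker_matrix(if (is.list(profile) && !is.data.frame(profile)) {
    as.data.frame(profile)
  } else profile)[1, ])
  for (nm in marker_names()) {
    if (!is.finite(x[[nm]])) stop("marker ", nm, " is not finite")
    if (x[[nm]] < 0) stop("marker ", nm, " is negative")
  }
  status <- character(6)
  fold <- numeric(6)
  for (i in seq_along(marker_names())) {
    nm <- marker_names()[i]
    r <- ranges[[nm]]
    status[i] <- if (x[[nm]] < r[1]) "below" else if (x[[nm]] > r[2]) "above" else "in"
    fold[i] <- x[[nm]] / r[2]
  }
  data.frame(
    marker = marker_names(),
    value = as.numeric(x[marker_names()]),
    low = vapply(ranges[marker_names()], `[`, numeric(1), 1),
    high = vapply(ranges[marker_names()], `[`, numeric(1), 2),
    status = status,
    fold_upper = fold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
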