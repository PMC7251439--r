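# CSV patient tables and model persistence.

#' Read a patient table from CSV
#'
#' Expects a header with the six marker columns (case-insensitive,
#' canonicalized to lower case) and optionally `patient_id`, `label`,
#' `diet`, `family_history`, `year`, `em`, `severity`. Rows with a missing,
#' non-numeric, negative, or non-finite marker value are dropped and
#' counted, following the screening step that discards samples with missing
#' or abnormal values.
#'
#' @param path CSV file path.
#' @return Data frame of surviving rows (with `label` as an ordered factor
#'   when present), carrying a `drop_report` attribute
#'   (`n_read`, `n_kept`, `n_dropped`).
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  missing <- setdiff(marker_names(), names(raw))
  if (length(missing)) stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (nm in marker_names()) raw[[nm]] <- suppressWarnings(as.numeric(raw[[nm]]))
  M <- as.matrix(raw[, marker_names(), drop = FALSE])
  bad <- if (nrow(raw)) apply(M, 1, function(r) any(!is.finite(r)) || any(r < 0)) else logical(0)
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if ("label" %in% names(out) && nrow(out)) out$label <- as_stage(out$label)
  attr(out, "drop_report") <- list(n_read = nrow(raw), n_kept = nrow(out),
                                   n_dropped = sum(bad))
  out
}

#' Write a patient table to CSV
#'
#' Serializes with full double precision (15 significant digits) so that a
#' write/read round trip preserves marker values.
#'
#' @param data Data frame with marker columns (and any extra columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(data, path) {
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num]) {
    df[[nm]] <- vapply(df[[nm]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Persist and restore a trained system
#'
#' The archive is a versioned RDS container holding the configuration,
#' preprocessing statistics, and every learner's parameters; loading
#' reproduces identical predictions. Two fits with the same data and seed
#' serialize to byte-identical archives.
#'
#' @param system A trained `"em_system"`.
#' @param path Archive path.
#' @return `path` invisibly (save); the restored `"em_system"` (load).
#' @export
save_em_system <- function(system, path) {
  stopifnot(inherits(system, "em_system"))
  saveRDS(list(format = "prostEM/em_system/1", system = system), path)
  invisible(path)
}

#' @rdname save_em_system
#' @export
load_em_system <- function(path) {
  arch <- readRDS(path)
  if (!identical(arch$format, "prostEM/em_system/1")) {
    stop("not a recognized model archive (format tag missing or unsupported)")
  }
  arch$system
}
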