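# End-to-end decision system: gate -> stacked ensemble -> EM -> stage ->
# treatment recommendation and tracking.

#' Train the full auxiliary decision system
#'
#' Fits, on a seeded stratified 80/20 split of a labeled cohort:
#' \enumerate{
#'   \item a benign/malignant gate SVM (benign labeled +1, malignant -1),
#'     with kernel and penalty selected on a held-out fifth of the training
#'     split;
#'   \item three one-vs-one SVM committees over stages I-IV, one per kernel
#'     kind (linear, polynomial, gauss), trained on malignant training
#'     samples only;
#'   \item three MLPs (6-9-7-4, 6-10-7-5-4, 6-7-5-4) and three RBF networks
#'     (10/14/16 hidden units, k-means centers), same training samples;
#'   \item the exponential linear regression meta-learner on the stacked
#'     36-dim base-learner outputs, supervised by the stage targets 3-6.
#' }
#' All learners share marker standardization statistics computed on the
#' training split. The whole fit is deterministic given `config$seed`.
#'
#' @param data Labeled cohort: a data frame with the six marker columns and
#'   a `label` column over `c("benign", "I", "II", "III", "IV")`, all five
#'   classes present (e.g. from [simulate_cohort()] or
#'   [read_patient_table()]).
#' @param config An [em_config()].
#' @return An object of class `"em_system"` with components `gate`,
#'   `groups`, `mlps`, `rbfs`, `elr`, `scaling`, `split`, `report` (per-
#'   learner held-out errors vs epsilon), `config`, and the training data.
#' @seealso [predict.em_system()], [summary.em_system()],
#'   [em_calibration_table()]
#' @export
#' @examples
#' \donttest{
#' co <- simulate_cohort(cohort_spec(n_per_class = c(benign = 40, I = 40, II = 40,
#'                                                   III = 40, IV = 40)))
#' fit <- em_system(co, em_config(seed = 7))
#' summary(fit)
#' }
em_system <- function(data, config = em_config()) {
  data <- as.data.frame(data)
  if (!"label" %in% names(data)) stop("data must carry a 'label' column")
  label <- as_stage(data$label)
  if (anyNA(label)) stop("labels contain missing values")
  missing_cls <- setdiff(stage_levels(), as.character(unique(label)))
  if (length(missing_cls)) stop("class missing from the cohort: ",
                                paste(missing_cls, collapse = ", "))
  X_raw <- marker_matrix(data)
  cl <- match.call()

  with_seed(config$seed, {
    train_idx <- split_stratified(label, config$split_train)
    test_idx <- setdiff(seq_len(nrow(X_raw)), train_idx)
    scaling <- scaling_fit(X_raw[train_idx, , drop = FALSE])
    X <- scaling_apply(X_raw, scaling)
    lab_tr <- label[train_idx]

    # gate: benign +1, malignant -1
    y_gate <- ifelse(lab_tr == "benign", 1, -1)
    gate <- svm_fit_grid(X[train_idx, , drop = FALSE], y_gate,
                         kinds = config$gate_kernels, config = config)

    mal_tr <- train_idx[label[train_idx] != "benign"]
    X_mal <- X[mal_tr, , drop = FALSE]
    st_mal <- factor(as.character(label[mal_tr]), levels = malignant_stages())

    groups <- lapply(config$group_kernels, function(kind) {
      ovo_fit(X_mal, st_mal, kind = kind, config = config)
    })
    names(groups) <- config$group_kernels

    mlps <- lapply(config$mlp_architectures, function(arch) {
      mlp_fit(X_mal, st_mal, architecture = arch, config = config)
    })
    rbfs <- lapply(config$rbf_hidden_units, function(k) {
      rbf_fit(X_mal, st_mal, hidden = k, config = config)
    })

    Z <- stack_features(X_mal, groups, mlps, rbfs)
    elr <- elr_fit(Z, st_mal, supervising_values = config$supervising_values,
                   em_scale = config$em_scale)

    report <- rbind(
      data.frame(learner = "gate_svm", heldout_error = gate$heldout_error),
      do.call(rbind, lapply(names(groups), function(k) {
        data.frame(learner = paste0("ovo_", k),
                   heldout_error = max(groups[[k]]$report$heldout_error))
      })),
      do.call(rbind, lapply(seq_along(mlps), function(i) {
        data.frame(learner = paste0("mlp_", paste(config$mlp_architectures[[i]], collapse = "-")),
                   heldout_error = mlps[[i]]$heldout_error)
      })),
      do.call(rbind, lapply(seq_along(rbfs), function(i) {
        data.frame(learner = paste0("rbf_", config$rbf_hidden_units[i]),
                   heldout_error = rbfs[[i]]$heldout_error)
      }))
    )
    report$meets_epsilon <- report$heldout_error <= config$epsilon

    structure(list(
      gate = gate, groups = groups, mlps = mlps, rbfs = rbfs, elr = elr,
      scaling = scaling, config = config,
      split = list(train = train_idx, test = test_idx),
      data = data, label = label,
      report = report, call = cl
    ), class = "em_system")
  })
}

# Ensemble lnEM/EM score for raw marker rows (no gate): used for
# calibration, covariate contrasts, and treatment tracking.
em_score <- function(system, data) {
  X <- scaling_apply(marker_matrix(data), system$scaling)
  Z <- stack_features(X, system$groups, system$mlps, system$rbfs)
  predict_em(system$elr, Z)
}

#' Map an lnEM value to a clinical stage
#'
#' Half-open binning on the lnEM scale: `[2.7, 3.6)` is stage I,
#' `[3.6, 4.5)` stage II, `[4.5, 5.3)` stage III, and `>= 5.3` stage IV.
#' Values below the stage-I floor still return stage I but are flagged
#' `"below_stage_I_range"` — the benign call belongs to the gate, not to
#' the score.
#'
#' @param ln_em Numeric vector of lnEM values (finite).
#' @param thresholds Strictly increasing boundaries (length 4).
#' @return Data frame with `stage` (factor over I-IV) and `flag`.
#' @export
#' @examples
#' stage_from_lnem(c(3.0, 3.6, 5.4))
stage_from_lnem <- function(ln_em, thresholds = em_config()$stage_thresholds) {
  stopifnot(length(thresholds) == 4, all(diff(thresholds) > 0))
  if (any(!is.finite(ln_em))) stop("ln_em must be finite")
  bin <- findInterval(ln_em, thresholds)
  stage <- malignant_stages()[pmax(bin, 1L)]
  data.frame(stage = factor(stage, levels = malignant_stages()),
             flag = ifelse(bin == 0L, "below_stage_I_range", ""),
             stringsAsFactors = FALSE)
}

#' Treatment recommendation by stage
#'
#' Deterministic lookup over the modality vocabulary (chemotherapy,
#' radiotherapy, excision, drug method, hospital charge, next examination).
#' Every plan is advisory: a rough strategy for the doctor, not a
#' prescription.
#'
#' @param stage A label in `stage_levels()` (vectorized).
#' @return Data frame with `stage`, `modalities` (modalities joined by
#'   `" + "`), and `advisory`.
#' @export
#' @examples
#' recommend_treatment(c("benign", "IV"))
recommend_treatment <- function(stage) {
  tab <- c(
    benign = "next_examination",
    I = "excision",
    II = "excision + radiotherapy",
    III = "radiotherapy + chemotherapy",
    IV = "chemotherapy + drug method + hospital charge"
  )
  stage <- as.character(stage)
  if (any(!stage %in% names(tab))) stop("unknown stage label")
  data.frame(stage = stage, modalities = unname(tab[stage]),
             advisory = "auxiliary suggestion, not a prescription",
             stringsAsFactors = FALSE)
}

#' Diagnose patients with a trained system
#'
#' The gate SVM first decides benign vs malignant. Benign patients get a
#' next-examination recommendation and no EM score; malignant patients get
#' the stacked-ensemble EM score, the stage implied by their lnEM, and the
#' stage's treatment plan.
#'
#' @param object A trained `"em_system"`.
#' @param newdata Data frame with the six marker columns (defaults to the
#'   held-out test split of the training cohort).
#' @param ... Unused.
#' @return Data frame with one row per patient: `verdict` (factor over
#'   `stage_levels()`), `ln_em`, `em` (NA for benign verdicts), `flag`, and
#'   `treatment`.
#' @export
predict.em_system <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data[object$split$test, , drop = FALSE]
  X <- scaling_apply(marker_matrix(newdata), object$scaling)
  gate_sign <- svm_decision(object$gate, X)$sign
  n <- nrow(X)
  verdict <- rep("benign", n)
  ln_em <- rep(NA_real_, n)
  em <- rep(NA_real_, n)
  flag <- rep("", n)
  mal <- which(gate_sign < 0)
  if (length(mal)) {
    Z <- stack_features(X[mal, , drop = FALSE], object$groups, object$mlps, object$rbfs)
    sc <- predict_em(object$elr, Z)
    stg <- stage_from_lnem(sc$ln_em, object$config$stage_thresholds)
    verdict[mal] <- as.character(stg$stage)
    ln_em[mal] <- sc$ln_em
    em[mal] <- sc$em
    flag[mal] <- stg$flag
  }
  out <- data.frame(
    verdict = factor(verdict, levels = stage_levels(), ordered = TRUE),
    ln_em = ln_em, em = em, flag = flag,
    treatment = recommend_treatment(verdict)$modalities,
    stringsAsFactors = FALSE
  )
  if ("patient_id" %in% names(newdata)) out <- cbind(patient_id = newdata$patient_id, out)
  rownames(out) <- NULL
  out
}

#' @rdname predict.em_system
#' @param system A trained `"em_system"` (alias interface).
#' @export
diagnose <- function(system, newdata = NULL) predict(system, newdata)

#' Assess the effect of a treatment from two marker profiles
#'
#' Scores the patient before and after therapy with the stacked ensemble and
#' applies the tracking rule: a relative EM drop of at least `delta` means
#' the plan works and is maintained; a small change (or a deterioration,
#' which is additionally flagged) means the plan should be changed. Each
#' call can append exactly one audit record (CSV) for the therapy log.
#'
#' @param system A trained `"em_system"`.
#' @param before,after Single-patient marker profiles (named vector, list,
#'   or one-row data frame).
#' @param delta Relative-drop threshold in (0, 1); defaults to the system's
#'   `treatment_delta`.
#' @param patient_id Identifier written to the audit record.
#' @param audit_file Optional path; when given, one CSV row
#'   (timestamp, patient_id, em_before, em_after, relative_drop, verdict)
#'   is appended per call.
#' @return List of class `"em_assessment"`: `em_before`, `em_after`,
#'   `relative_drop`, `verdict` (`"maintain"` or `"change"`), and
#'   `deteriorated`.
#' @export
assess_treatment <- function(system, before, after,
                             delta = system$config$treatment_delta,
                             patient_id = NA_character_, audit_file = NULL) {
  stopifnot(delta > 0, delta < 1)
  validate_profile(before)
  validate_profile(after)
  em_b <- em_score(system, before)$em
  em_a <- em_score(system, after)$em
  drop_rel <- (em_b - em_a) / em_b
  verdict <- if (drop_rel >= delta) "maintain" else "change"
  rec <- data.frame(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    patient_id = patient_id,
                    em_before = em_b, em_after = em_a,
                    relative_drop = drop_rel, verdict = verdict,
                    stringsAsFactors = FALSE)
  if (!is.null(audit_file)) {
    write.table(rec, audit_file, sep = ",", row.names = FALSE,
                col.names = !file.exists(audit_file), append = file.exists(audit_file))
  }
  structure(list(em_before = em_b, em_after = em_a, relative_drop = drop_rel,
                 verdict = verdict, deteriorated = drop_rel < 0),
            class = "em_assessment")
}

#' @export
print.em_assessment <- function(x, ...) {
  cat(sprintf("EM %.2f -> %.2f (relative drop %.1f%%): %s%s\n",
              x$em_before, x$em_after, 100 * x$relative_drop,
              x$verdict, if (x$deteriorated) " [deterioration]" else ""))
  invisible(x)
}

#' @export
print.em_system <- function(x, ...) {
  cat("Stacked-ensemble prostate-cancer decision system\n")
  cat(sprintf("  cohort: %d patients (%d train / %d test)\n",
              nrow(x$data), length(x$split$train), length(x$split$test)))
  cat(sprintf("  gate SVM: %s kernel, C = %g, held-out error %.3f\n",
              x$gate$kernel$kind, x$gate$C, x$gate$heldout_error))
  cat(sprintf("  base learners: 3 OvO SVM groups (%s), 3 MLPs, 3 RBF nets\n",
              paste(names(x$groups), collapse = ", ")))
  cat(sprintf("  meta-learner: ELR on %s scale, training MSE %.4f\n",
              x$elr$em_scale, x$elr$training_loss))
  invisible(x)
}

#' Summarize a trained decision system
#'
#' Reports per-learner held-out errors against epsilon and, on the internal
#' test split, the gate accuracy, the 5-class accuracy (benign + four
#' stages via the EM thresholds), and per-stage lnEM calibration.
#'
#' @param object A trained `"em_system"`.
#' @param ... Unused.
#' @return A list of class `"summary.em_system"`.
#' @export
summary.em_system <- function(object, ...) {
  test <- object$split$test
  truth <- object$label[test]
  pred <- predict(object)
  acc5 <- mean(as.character(pred$verdict) == as.character(truth))
  gate_acc <- mean((pred$verdict == "benign") == (truth == "benign"))
  calib <- em_calibration_table(object)
  out <- list(report = object$report, accuracy_5class = acc5,
              gate_accuracy = gate_acc, calibration = calib,
              epsilon = object$config$epsilon)
  class(out) <- "summary.em_system"
  out
}

#' @export
print.summary.em_system <- function(x, ...) {
  cat("Held-out error per learner (epsilon =", x$epsilon, "):\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("\nTest split: gate accuracy %.3f, 5-class accuracy %.3f\n",
              x$gate_accuracy, x$accuracy_5class))
  cat("\nlnEM calibration on held-out malignant samples:\n")
  print(x$calibration)
  invisible(x)
}

#' @export
coef.em_system <- function(object, ...) c(intercept = object$elr$b, object$elr$w)

#' @export
fitted.em_system <- function(object, ...) {
  tr <- object$split$train
  mal <- tr[object$label[tr] != "benign"]
  sc <- em_score(object, object$data[mal, , drop = FALSE])
  setNames(sc$ln_em, object$data$patient_id[mal] %||% as.character(mal))
}

#' @export
residuals.em_system <- function(object, ...) {
  tr <- object$split$train
  mal <- tr[object$label[tr] != "benign"]
  sc <- em_score(object, object$data[mal, , drop = FALSE])
  target <- object$config$supervising_values[as.character(object$label[mal])]
  setNames(sc$ln_em - as.numeric(target),
           object$data$patient_id[mal] %||% as.character(mal))
}

#' Calibration plot of a trained system
#'
#' Boxplots of held-out lnEM by true stage, with the supervising values and
#' staging thresholds overlaid.
#'
#' @param x A trained `"em_system"`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.em_system <- function(x, ...) {
  test <- x$split$test
  mal <- test[x$label[test] != "benign"]
  sc <- em_score(x, x$data[mal, , drop = FALSE])
  st <- factor(as.character(x$label[mal]), levels = malignant_stages())
  boxplot(sc$ln_em ~ st, xlab = "true stage", ylab = "lnEM",
          main = "lnEM calibration on held-out malignant samples", ...)
  abline(h = x$config$stage_thresholds, lty = 3, col = "grey40")
  points(seq_along(malignant_stages()), x$config$supervising_values,
         pch = 4, col = "red3", lwd = 2)
  legend("topleft", legend = c("supervising value", "stage threshold"),
         pch = c(4, NA), lty = c(NA, 3), col = c("red3", "grey40"), bty = "n")
  invisible(x)
}
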