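# System configuration with the published defaults.

#' Configuration for the decision system
#'
#' Collects every tunable of the training pipeline with its published
#' default: the 80/20 train/test split, the lnEM supervising values 3-6 for
#' stages I-IV, the lnEM staging boundaries (2.7, 3.6, 4.5, 5.3), the three
#' MLP architectures 6-9-7-4, 6-10-7-5-4 and 6-7-5-4, the three RBF hidden
#' sizes 10/14/16, the three kernel kinds that differentiate the SVM groups,
#' and the generalization-error threshold epsilon each base learner is tuned
#' against.
#'
#' @param epsilon Held-out error threshold each base learner is tuned to beat
#'   (fraction misclassified; default 0.1). When the search budget cannot
#'   reach it, the best model found is kept and flagged.
#' @param split_train Training fraction of the cohort (default 0.8).
#' @param supervising_values Named lnEM regression targets for stages I-IV
#'   (default `c(I = 3, II = 4, III = 5, IV = 6)`).
#' @param stage_thresholds Strictly increasing lnEM boundaries
#'   `c(2.7, 3.6, 4.5, 5.3)`: stage I on `[2.7, 3.6)`, II on `[3.6, 4.5)`,
#'   III on `[4.5, 5.3)`, IV on `[5.3, Inf)`.
#' @param group_kernels Kernel kinds of the three one-vs-one SVM groups
#'   (pairwise distinct; default linear, polynomial, gauss).
#' @param gate_kernels Kernel kinds searched for the benign/malignant gate.
#' @param mlp_architectures List of layer-size vectors for the three MLPs.
#' @param rbf_hidden_units Hidden-unit counts of the three RBF networks.
#' @param C_grid Penalty-parameter grid searched for every SVM.
#' @param sigma_grid Bandwidth grid for gauss/laplace kernels (standardized
#'   feature scale).
#' @param degree_grid Degree grid for the polynomial kernel.
#' @param mlp_lr,mlp_epochs,mlp_momentum Gradient-descent step size, epoch
#'   budget, and momentum for MLP training.
#' @param rbf_ridge Ridge used in the RBF output-weight least squares.
#' @param em_scale Scale on which the meta-learner fits its supervising
#'   values: `"log"` (targets are lnEM; EM = exp(lnEM)) or `"raw"` (targets
#'   are raw EM).
#' @param treatment_delta Relative EM drop at or above which a treatment plan
#'   is judged effective and maintained (default 0.3).
#' @param seed Integer seed driving every random choice of the fit.
#' @return A list of class `"em_config"`.
#' @export
#' @examples
#' cfg <- em_config()
#' cfg$supervising_values
em_config <- function(epsilon = 0.1,
                      split_train = 0.8,
                      supervising_values = c(I = 3, II = 4, III = 5, IV = 6),
                      stage_thresholds = c(2.7, 3.6, 4.5, 5.3),
                      group_kernels = c("linear", "polynomial", "gauss"),
                      gate_kernels = c("linear", "gauss"),
                      mlp_architectures = list(c(6, 9, 7, 4),
                                               c(6, 10, 7, 5, 4),
                                               c(6, 7, 5, 4)),
                      rbf_hidden_units = c(10, 14, 16),
                      C_grid = c(0.1, 1, 10, 100),
                      sigma_grid = c(0.5, 1, 2, 4),
                      degree_grid = c(2, 3),
                      mlp_lr = 0.01,
                      mlp_epochs = 2000,
                      mlp_momentum = 0.9,
                      rbf_ridge = 1e-6,
                      em_scale = c("log", "raw"),
                      treatment_delta = 0.3,
                      seed = 1L) {
  em_scale <- match.arg(em_scale)
  stopifnot(split_train > 0, split_train < 1,
            epsilon > 0, epsilon < 1,
            length(stage_thresholds) == 4,
            all(diff(stage_thresholds) > 0),
            treatment_delta > 0, treatment_delta < 1)
  if (!all(malignant_stages() %in% names(supervising_values))) {
    stop("supervising_values must name every malignant stage I-IV")
  }
  if (anyDuplicated(group_kernels)) stop("group kernel kinds must be pairwise distinct")
  for (a in mlp_architectures) {
    if (a[1] != 6 || a[length(a)] != 4) stop("MLP architectures must map 6 inputs to 4 outputs")
  }
  structure(list(
    epsilon = epsilon,
    split_train = split_train,
    supervising_values = supervising_values[malignant_stages()],
    stage_thresholds = stage_thresholds,
    group_kernels = group_kernels,
    gate_kernels = gate_kernels,
    mlp_architectures = mlp_architectures,
    rbf_hidden_units = rbf_hidden_units,
    C_grid = C_grid,
    sigma_grid = sigma_grid,
    degree_grid = degree_grid,
    mlp_lr = mlp_lr,
    mlp_epochs = mlp_epochs,
    mlp_momentum = mlp_momentum,
    rbf_ridge = rbf_ridge,
    em_scale = em_scale,
    treatment_delta = treatment_delta,
    seed = seed
  ), class = "em_config")
}
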