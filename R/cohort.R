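# Synthetic cohort generator: a single latent severity on the lnEM scale
# drives all six markers through an exponential growth law.

#' Specification of a synthetic patient cohort
#'
#' One scalar latent severity L (on the lnEM scale) per patient drives all
#' six markers: each marker equals its upper normal bound times
#' `exp(gain * (L - benign center))` times log-normal noise. Malignant stage
#' centers sit at the supervising values 3, 4, 5, 6; benign cases center at
#' 2.0, below the stage-I target, so their markers stay near the normal
#' range while stage IV markers run roughly an order of magnitude above it.
#' RBC and HB get small negative gains (a mild anemia-like decline) since
#' they are blood indices rather than tumor antigens.
#'
#' @param n_per_class Named counts per class over
#'   `c("benign", "I", "II", "III", "IV")` (default 300 each).
#' @param severity_location Named latent centers per class (default
#'   benign 2.0 and the supervising values 3-6); must increase with stage.
#' @param severity_sd Patient-to-patient latent spread within a class
#'   (default 0.35).
#' @param marker_gain Named per-marker exponential gains (default 0.6 for
#'   PSA/PSMA/tPSA/PAP, -0.05 for RBC/HB).
#' @param noise_sd Per-marker multiplicative log-noise sd (default 0.15).
#' @param diet_shift Additive latent shift for high-fat-diet patients
#'   (default 0.6).
#' @param inheritance_shift Additive latent shift for patients with a family
#'   cancer history (default 0.5).
#' @param p_high_fat,p_family_history Probability that a patient carries the
#'   covariate (default 0: plain cohorts are covariate-free).
#' @param years Calendar years sampled uniformly for the `year` column.
#' @param ranges Normal ranges anchoring the marker baselines.
#' @param seed Integer seed for [simulate_cohort()].
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_class = c(benign = 300, I = 300, II = 300, III = 300, IV = 300),
                        severity_location = c(benign = 2.0, I = 3, II = 4, III = 5, IV = 6),
                        severity_sd = 0.35,
                        marker_gain = c(psa = 0.6, psma = 0.6, tpsa = 0.6,
                                        rbc = -0.05, hb = -0.05, pap = 0.6),
                        noise_sd = 0.15,
                        diet_shift = 0.6,
                        inheritance_shift = 0.5,
                        p_high_fat = 0,
                        p_family_history = 0,
                        years = 2014:2018,
                        ranges = normal_ranges(),
                        seed = 1L) {
  stopifnot(severity_sd > 0, noise_sd > 0,
            all(n_per_class >= 0),
            p_high_fat >= 0, p_high_fat <= 1,
            p_family_history >= 0, p_family_history <= 1)
  loc <- severity_location[stage_levels()]
  if (anyNA(loc) || any(diff(loc) <= 0)) {
    stop("severity_location must be strictly increasing benign < I < II < III < IV")
  }
  gain <- marker_gain[marker_names()]
  if (anyNA(gain)) stop("marker_gain must name all six markers")
  structure(list(
    n_per_class = n_per_class,
    severity_location = loc,
    severity_sd = severity_sd,
    marker_gain = gain,
    noise_sd = noise_sd,
    diet_shift = diet_shift,
    inheritance_shift = inheritance_shift,
    p_high_fat = p_high_fat,
    p_family_history = p_family_history,
    years = years,
    ranges = ranges,
    seed = seed
  ), class = "cohort_spec")
}

#' Draw latent severities for a stage
#'
#' Samples L ~ Normal(center(stage), severity_sd), plus the diet and
#' inheritance shifts for patients carrying those covariates. Consumes the
#' current RNG stream (seed management happens in [simulate_cohort()]).
#'
#' @param stage A class label in `stage_levels()`.
#' @param spec A [cohort_spec()].
#' @param n Number of draws.
#' @param high_fat,family_history Logical/0-1 vectors (length `n` or 1)
#'   marking which draws carry each covariate.
#' @return Numeric vector of latent severities on the lnEM scale.
#' @export
sample_latent_severity <- function(stage, spec, n = 1, high_fat = FALSE,
                                   family_history = FALSE) {
  stage <- as.character(stage)
  if (!stage %in% names(spec$severity_location)) stop("unknown stage: ", stage)
  L <- rnorm(n, mean = spec$severity_location[[stage]], sd = spec$severity_sd)
  L + spec$diet_shift * as.numeric(rep_len(high_fat, n)) +
    spec$inheritance_shift * as.numeric(rep_len(family_history, n))
}

#' Map latent severities to marker profiles
#'
#' Applies the exponential growth law
#' `marker_j = upper_j * exp(gain_j * (L - L_benign)) * exp(noise)`, where
#' `upper_j` is the marker's upper normal bound and `L_benign` the benign
#' latent center, then clips at zero. With noise off and L at the benign
#' center every positive-gain marker sits exactly at its upper normal bound;
#' four latent units above it, a gain of 0.6 puts a marker at
#' `exp(2.4) ~ 11x` its normal ceiling.
#'
#' @param L Numeric vector of latent severities.
#' @param spec A [cohort_spec()].
#' @return Data frame of marker columns, one row per element of `L`.
#' @export
severity_to_profile <- function(L, spec) {
  stopifnot(all(is.finite(L)))
  n <- length(L)
  L_ref <- spec$severity_location[["benign"]]
  out <- matrix(0, n, 6, dimnames = list(NULL, marker_names()))
  for (nm in marker_names()) {
    upper <- spec$ranges[[nm]][2]
    noise <- rnorm(n, 0, spec$noise_sd)
    out[, nm] <- pmax(0, upper * exp(spec$marker_gain[[nm]] * (L - L_ref)) * exp(noise))
  }
  as.data.frame(out)
}

#' Generate a labeled synthetic cohort
#'
#' Fully reproducible from `spec$seed`: draws covariates, latent severities,
#' and marker profiles for the requested number of patients per class.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `patient_id`, the six markers, `label`
#'   (ordered factor over `stage_levels()`), `diet`, `family_history`,
#'   `year`, and `severity` (the true latent, kept for diagnostics).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(n_per_class = c(benign = 5, I = 5, II = 5, III = 5, IV = 5)))
#' table(co$label)
simulate_cohort <- function(spec = cohort_spec()) {
  counts <- spec$n_per_class
  if (sum(counts) == 0) stop("cohort spec requests zero patients")
  with_seed(spec$seed, {
    parts <- list()
    for (cls in stage_levels()) {
      n <- if (cls %in% names(counts)) as.integer(counts[[cls]]) else 0L
      if (n == 0L) next
      hf <- runif(n) < spec$p_high_fat
      fh <- runif(n) < spec$p_family_history
      L <- sample_latent_severity(cls, spec, n = n, high_fat = hf, family_history = fh)
      prof <- severity_to_profile(L, spec)
      prof$label <- cls
      prof$diet <- ifelse(hf, "high_fat", "normal")
      prof$family_history <- as.integer(fh)
      prof$year <- sample(spec$years, n, replace = TRUE)
      prof$severity <- L
      parts[[cls]] <- prof
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out$label <- as_stage(out$label)
    out <- cbind(patient_id = sprintf("P%05d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    out
  })
}
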