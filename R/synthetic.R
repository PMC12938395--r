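#' Configuration for the synthetic paired-cohort generator
#'
#' Builds the fully-resolved configuration for [generateCohort()]. The
#' generator emulates the structure of a paired radiology--pathology cohort:
#' a shared low-dimensional latent patient state drives both an imaging view
#' (linear mixture plus noise; optionally rendered as a 4-channel volume)
#' and a variable-length set of pathology patch features. Survival is
#' mediated by a smooth bounded nonlinearity of the latent state,
#' `h(z) = cos(2 z) - exp(-2)` coordinate-wise, which the pathology
#' modality exposes at low noise while imaging sees only the linear view at
#' higher noise — this asymmetry is what makes a retrieved pathology proxy
#' informative over imaging alone.
#'
#' @param n_patients number of patients.
#' @param latent_dim latent state dimension (default 4).
#' @param imaging_dim imaging feature dimension (default 512).
#' @param patch_dim patch feature dimension C (default 64 at desk scale;
#'   set 1536 to mirror a foundation-model feature width).
#' @param patch_count_range integer (min, max); per-patient patch counts are
#'   drawn uniformly from this range.
#' @param imaging_noise_sd additive Gaussian noise sd on the imaging view.
#' @param patch_noise_sd additive Gaussian noise sd on each patch row.
#' @param survival_weights length `latent_dim` weights of the survival
#'   logit `w . h(z)`.
#' @param os_scale scale of log-survival-time around the 12-month pivot.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @param volume_shape optional integer (D, H, W); when supplied the imaging
#'   view is rendered as a 4-channel voxel volume of that shape instead of a
#'   feature vector (the mixture is reshaped into the volume).
#' @return A validated configuration list of class `pathproxy_syncfg`.
#' @export
syntheticConfig <- function(n_patients,
                            latent_dim = 4L,
                            imaging_dim = 512L,
                            patch_dim = 64L,
                            patch_count_range = c(8L, 32L),
                            imaging_noise_sd = 1.0,
                            patch_noise_sd = 0.1,
                            survival_weights = NULL,
                            os_scale = 0.25,
                            seed = 1L,
                            volume_shape = NULL) {
  stopIf(n_patients < 1, "n_patients must be >= 1")
  stopIf(latent_dim < 1 || imaging_dim < 1 || patch_dim < 1,
         "dimensions must be positive")
  stopIf(length(patch_count_range) != 2 || patch_count_range[1] < 1 ||
           patch_count_range[1] > patch_count_range[2],
         "patch_count_range must satisfy 1 <= min <= max")
  stopIf(imaging_noise_sd < 0 || patch_noise_sd < 0,
         "noise standard deviations must be nonnegative")
  if (is.null(survival_weights)) {
    base <- 1.5 * c(1, -1, 0.8, -0.8, 0.6, -0.6)
    survival_weights <- rep_len(base, latent_dim)
  }
  stopIf(length(survival_weights) != latent_dim,
         "survival_weights must have length latent_dim")
  if (!is.null(volume_shape)) {
    stopIf(length(volume_shape) != 3 || any(volume_shape < 1),
           "volume_shape must be 3 positive integers (D, H, W)")
    imaging_dim <- as.integer(4L * prod(volume_shape))
  }
  structure(list(
    n_patients = as.integer(n_patients), latent_dim = as.integer(latent_dim),
    imaging_dim = as.integer(imaging_dim), patch_dim = as.integer(patch_dim),
    patch_count_range = as.integer(patch_count_range),
    imaging_noise_sd = imaging_noise_sd, patch_noise_sd = patch_noise_sd,
    survival_weights = survival_weights, os_scale = os_scale,
    seed = as.integer(seed),
    volume_shape = if (is.null(volume_shape)) NULL else
      as.integer(volume_shape)
  ), class = "pathproxy_syncfg")
}

# The pathology-visible nonlinearity: coordinate-wise, bounded and
# band-limited, centered so E[h(z)] = 0 under standard-normal z
# (E[cos(2Z)] = exp(-2)). Its length scale is finer than the imaging
# view's latent resolution but coarser than the library spacing, which is
# what makes the pathology proxy informative.
latentNonlinearity <- function(z) cos(2 * z) - exp(-2)

#' Generate a synthetic paired multimodal cohort
#'
#' For each patient, a latent state `z ~ N(0, I)` is drawn. The imaging view
#' is `A z + imaging noise`; every patch row is `B [z; h(z)] + patch noise`
#' with `h(z) = cos(2 z) - exp(-2)` coordinate-wise; the survival logit is
#' `w . h(z)` and survival time
#' is `12 * exp(os_scale * (logit + logistic noise))` months, so that the
#' probability of surviving beyond 12 months is exactly `plogis(logit)`.
#' Mixing matrices A and B are drawn once per seed and stored with the
#' cohort.
#'
#' @param config a configuration from [syntheticConfig()].
#' @return A [PairedCohort-class].
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "pathproxy_syncfg"))
  cfg <- config
  withSeed(cfg$seed, {
    L <- cfg$latent_dim
    A <- matrix(rnorm(cfg$imaging_dim * L, sd = 1 / sqrt(L)),
                cfg$imaging_dim, L)
    B <- matrix(rnorm(cfg$patch_dim * 2 * L, sd = 1 / sqrt(2 * L)),
                cfg$patch_dim, 2 * L)
    Z <- matrix(rnorm(cfg$n_patients * L), cfg$n_patients, L)
    counts <- sample(seq(cfg$patch_count_range[1], cfg$patch_count_range[2]),
                     cfg$n_patients, replace = TRUE)
    samples <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      z <- Z[i, ]
      h <- latentNonlinearity(z)
      img <- as.numeric(A %*% z) +
        rnorm(cfg$imaging_dim, sd = cfg$imaging_noise_sd)
      if (!is.null(cfg$volume_shape))
        img <- array(img, dim = c(4L, cfg$volume_shape))
      mean_patch <- as.numeric(B %*% c(z, h))
      N <- counts[i]
      P <- matrix(mean_patch, N, cfg$patch_dim, byrow = TRUE) +
        matrix(rnorm(N * cfg$patch_dim, sd = cfg$patch_noise_sd),
               N, cfg$patch_dim)
      logit <- sum(cfg$survival_weights * h)
      os <- 12 * exp(cfg$os_scale * (logit + rlogis(1)))
      pid <- sprintf("P%04d", i)
      samples[[i]] <- new("PairedSample", patientId = pid, imaging = img,
                          patches = PatchFeatureSet(P, slideId = pid),
                          osMonths = os, osLabel = makeOsLabel(os))
    }
    new("PairedCohort", samples = samples,
        mixing = list(A = A, B = B, Z = Z),
        config = unclass(cfg))
  })
}

#' Render a synthetic H&E patch through the Beer-Lambert law
#'
#' Given a 3 x 2 stain optical-density matrix and a per-pixel 2-channel
#' concentration map, renders the transmitted RGB intensities
#' `I = I0 * exp(-M c)` per channel, clipped to `[0, I0]`. Used as the exact
#' forward model when testing Macenko stain estimation/normalization.
#'
#' @param stain_matrix 3 x 2 OD matrix (columns: hematoxylin, eosin).
#' @param concentration_map H x W x 2 nonnegative array of stain
#'   concentrations.
#' @param I0 intensity ceiling (default 255).
#' @return H x W x 3 numeric RGB image on the `[0, I0]` scale.
#' @export
generateHEPatch <- function(stain_matrix, concentration_map, I0 = 255) {
  stopIf(I0 <= 0, "I0 must be positive")
  stopifnot(all(dim(stain_matrix) == c(3, 2)))
  d <- dim(concentration_map)
  stopIf(length(d) != 3 || d[3] != 2,
         "concentration_map must be H x W x 2")
  stopIf(any(concentration_map < 0), "concentrations must be nonnegative")
  conc <- matrix(concentration_map, d[1] * d[2], 2)       # pixels x stains
  od <- conc %*% t(stain_matrix)                          # pixels x RGB
  img <- I0 * exp(-od)
  img <- pmin(pmax(img, 0), I0)
  array(img, dim = c(d[1], d[2], 3))
}

#' Generate a bimodal grayscale test image
#'
#' Each pixel belongs to one of two populations with stated gray-level means
#' and mixing fractions, plus optional Gaussian noise. Used as a controlled
#' fixture for Otsu thresholding.
#'
#' @param mu0,mu1 component means, `mu0 < mu1`.
#' @param fractions length-2 nonnegative mixture weights summing to 1.
#' @param noise_sd Gaussian noise sd.
#' @param shape (rows, cols) of the image.
#' @param seed integer seed.
#' @return numeric matrix on the 0--255 scale (values clipped).
#' @export
generateBimodalImage <- function(mu0, mu1, fractions = c(0.5, 0.5),
                                 noise_sd = 0, shape = c(64L, 64L),
                                 seed = 1L) {
  stopIf(mu0 >= mu1, "mu0 must be less than mu1")
  stopIf(abs(sum(fractions)) < 1e-12 || abs(sum(fractions) - 1) > 1e-8,
         "fractions must sum to 1")
  stopIf(any(fractions < 0), "fractions must be nonnegative")
  withSeed(seed, {
    n <- prod(shape)
    comp <- rbinom(n, 1, fractions[2])
    vals <- ifelse(comp == 1, mu1, mu0) + rnorm(n, sd = noise_sd)
    matrix(pmin(pmax(vals, 0), 255), shape[1], shape[2])
  })
}

#' Serialize a cohort to plain-text files
#'
#' Writes a CSV manifest (`patient_id, os_months, os_label, n_patches`) plus
#' per-patient CSV containers for the imaging view and the patch matrix, and
#' the mixing matrices. Volumetric imaging is written as NIfTI when the
#' RNifti package is available, else as CSV of the flattened array.
#'
#' @param cohort a [PairedCohort-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- patientIds(cohort)
  manifest <- data.frame(
    patient_id = ids,
    os_months = osMonths(cohort),
    os_label = osLabels(cohort),
    n_patches = vapply(cohort@samples, function(s) sum(s@patches@mask),
                       integer(1))
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort@mixing$A, file.path(dir, "mixing_A.csv"),
            row.names = FALSE)
  write.csv(cohort@mixing$B, file.path(dir, "mixing_B.csv"),
            row.names = FALSE)
  for (s in cohort@samples) {
    img <- s@imaging
    if (is.array(img) && length(dim(img)) == 4 &&
        requireNamespace("RNifti", quietly = TRUE)) {
      RNifti::writeNifti(aperm(img, c(2, 3, 4, 1)),
                         file.path(dir, paste0(s@patientId, "_imaging.nii")))
    } else {
      write.csv(data.frame(value = as.numeric(img)),
                file.path(dir, paste0(s@patientId, "_imaging.csv")),
                row.names = FALSE)
    }
    write.csv(as.data.frame(patchFeatures(s@patches)),
              file.path(dir, paste0(s@patientId, "_patches.csv")),
              row.names = FALSE)
  }
  invisible(manifest)
}
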