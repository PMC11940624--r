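#' Synthetic cohort configuration
#'
#' Describes a two-class lesion cohort with the statistical structure
#' the downstream analysis assumes: class sizes matching the study
#' cohort (50 carriers of pathogenic/likely-pathogenic variants, 38
#' non-carriers), a class effect entering ONLY through image texture
#' parameters (never the mask shape), class-dependent Ki67-high rates
#' matching the printed cohort table (46/50 vs 26/38), and a
#' two-machine batch structure independent of class.
#'
#' Per-lesion texture parameters are drawn from class-specific normal
#' distributions (truncated below) so classes overlap rather than
#' separate trivially.
#'
#' @param n_positive,n_negative class sizes (default 50 / 38).
#' @param corr_len_pos,corr_len_neg mean texture correlation length
#'   (px) per class; the planted effect. Defaults 2.4 / 1.2.
#' @param corr_len_sd within-class SD of the correlation length.
#' @param contrast_pos,contrast_neg mean echogenicity contrast per
#'   class (default 0.45 both: no intensity effect).
#' @param contrast_sd within-class SD of the contrast.
#' @param ki67_high_rate_pos,ki67_high_rate_neg probability of
#'   Ki67 >= 20\% per class (defaults 46/50, 26/38).
#' @param machine_fraction share of lesions acquired on machine "A".
#' @param lesion_params_base a [lesion_params()] supplying geometry and
#'   speckle defaults; per-lesion radii are jittered around it.
#' @param seed integer seed.
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(n_positive = 50L, n_negative = 38L,
                          corr_len_pos = 2.4, corr_len_neg = 1.2,
                          corr_len_sd = 0.3,
                          contrast_pos = 0.45, contrast_neg = 0.45,
                          contrast_sd = 0.05,
                          ki67_high_rate_pos = 46 / 50,
                          ki67_high_rate_neg = 26 / 38,
                          machine_fraction = 0.5,
                          lesion_params_base = lesion_params(),
                          seed = 1L) {
  cfg <- list(n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              corr_len_pos = corr_len_pos, corr_len_neg = corr_len_neg,
              corr_len_sd = corr_len_sd,
              contrast_pos = contrast_pos, contrast_neg = contrast_neg,
              contrast_sd = contrast_sd,
              ki67_high_rate_pos = ki67_high_rate_pos,
              ki67_high_rate_neg = ki67_high_rate_neg,
              machine_fraction = machine_fraction,
              lesion_params_base = lesion_params_base,
              seed = as.integer(seed))
  if (cfg$n_positive < 1L || cfg$n_negative < 1L)
    stop("class sizes must be >= 1")
  for (nm in c("ki67_high_rate_pos", "ki67_high_rate_neg",
               "machine_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop("`", nm, "` must be in [0, 1]")
  stopifnot(inherits(lesion_params_base, "lesion_params"))
  structure(cfg, class = "cohort_config")
}

#' Simulate a synthetic ultrasound lesion cohort
#'
#' Draws per-lesion texture parameters from the class-specific
#' distributions in the config, renders every lesion with
#' [simulate_lesion_image()], and assembles the per-lesion clinical
#' table (group label, binary Ki67 category, machine id). Machine
#' assignment is independent of class by construction, so batch-effect
#' checks on this cohort have a true null.
#'
#' @param config a [cohort_config()].
#' @return a \code{synthetic_cohort}: list with \code{lesions} (list of
#'   \code{simulate_lesion_image()} outputs) and \code{meta}
#'   (data.frame: id, label, ki67_high, machine, spacing_mm).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_positive + config$n_negative
  base <- config$lesion_params_base
  with_local_seed(config$seed, {
    label <- rep(c(1L, 0L), c(config$n_positive, config$n_negative))
    ki67 <- ifelse(label == 1L,
                   stats::rbinom(n, 1, config$ki67_high_rate_pos),
                   stats::rbinom(n, 1, config$ki67_high_rate_neg))
    machine <- ifelse(stats::runif(n) < config$machine_fraction, "A", "B")
    corr_len <- ifelse(label == 1L,
                       stats::rnorm(n, config$corr_len_pos, config$corr_len_sd),
                       stats::rnorm(n, config$corr_len_neg, config$corr_len_sd))
    corr_len <- pmax(corr_len, 0.3)
    contrast <- ifelse(label == 1L,
                       stats::rnorm(n, config$contrast_pos, config$contrast_sd),
                       stats::rnorm(n, config$contrast_neg, config$contrast_sd))
    contrast <- pmin(pmax(contrast, 0.15), 0.9)
    radius_jitter <- stats::runif(n, 0.85, 1.15)
    lesion_seeds <- sample.int(.Machine$integer.max, n)

    lesions <- vector("list", n)
    for (i in seq_len(n)) {
      p <- lesion_params(
        image_size_px = base$image_size_px,
        pixel_spacing_mm = base$pixel_spacing_mm,
        lesion_center_px = base$lesion_center_px,
        lesion_radii_px = base$lesion_radii_px * radius_jitter[i],
        margin_irregularity = base$margin_irregularity,
        echogenicity_contrast = contrast[i],
        speckle_scale = base$speckle_scale,
        texture_correlation_length_px = corr_len[i],
        posterior_shadow = base$posterior_shadow)
      lesions[[i]] <- simulate_lesion_image(p, seed = lesion_seeds[i])
    }
    meta <- data.frame(
      id = sprintf("L%03d", seq_len(n)),
      label = label,
      ki67_high = as.integer(ki67),
      machine = machine,
      spacing_mm = base$pixel_spacing_mm,
      stringsAsFactors = FALSE)
    structure(list(lesions = lesions, meta = meta, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d lesions (%d positive / %d negative)>\n",
              nrow(x$meta), sum(x$meta$label == 1), sum(x$meta$label == 0)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Images as 8-bit PNG, masks as 0/255 PNG, metadata as a CSV manifest
#' (id, label, ki67_high, machine, spacing_mm plus the file paths).
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$meta
  meta$image_path <- file.path(dir, paste0(meta$id, ".png"))
  meta$tumor_mask_path <- file.path(dir, paste0(meta$id, "_tumor.png"))
  meta$exclusion_mask_path <- file.path(dir, paste0(meta$id, "_excl.png"))
  for (i in seq_len(nrow(meta))) {
    les <- cohort$lesions[[i]]
    write_image(les$image, meta$image_path[i])
    write_mask(les$tumor, meta$tumor_mask_path[i])
    write_mask(les$exclusion, meta$exclusion_mask_path[i])
  }
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(meta)
}
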