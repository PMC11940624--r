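#' The texture feature registry
#'
#' The fixed, deterministically ordered manifest of every feature the
#' extractor produces per ROI: 9 first-order histogram features, 11
#' Haralick GLCM statistics at 20 offsets (directions 0/90/45/135
#' degrees, displacements 1..5), 5 run-length statistics at 4 angles,
#' 5 causal autoregressive parameters, and 4 Haar sub-band energies at
#' \code{max_scale} scales — 278 features with the defaults. The
#' manifest records its own count; source material for this analysis
#' prints two conflicting totals (306 and 310 variables), so the
#' registry documents the classical set it implements instead of
#' forcing either number.
#'
#' @param dmax maximal GLCM displacement (default 5).
#' @param max_scale deepest wavelet scale (default 6).
#' @return data.frame: \code{name} (canonical), \code{family},
#'   \code{params}; attribute \code{n_features}.
#' @export
feature_registry <- function(dmax = 5L, max_scale = 6L) {
  hist_names <- c("Mean", "Variance", "Skewness", "Kurtosis",
                  "Perc.01.", "Perc.10.", "Perc.50.", "Perc.90.", "Perc.99.")
  glcm_stats <- c("AngScMom", "Contrast", "Correlation", "SumOfSqs",
                  "InvDfMom", "SumAverg", "SumVarnc", "SumEntrp",
                  "Entropy", "DifVarnc", "DifEntrp")
  glrlm_stats <- c("RLNonUni", "GLevNonU", "ShrtREmp", "LngREmph", "Fraction")
  rows <- list(data.frame(name = hist_names, family = "histogram",
                          params = "", stringsAsFactors = FALSE))
  for (off in glcm_offsets(dmax)) {
    pre <- glcm_offset_name(off)
    rows <- c(rows, list(data.frame(
      name = paste0(pre, glcm_stats), family = "glcm",
      params = sprintf("dy=%d,dx=%d", off[1], off[2]),
      stringsAsFactors = FALSE)))
  }
  for (ang in c(0, 45, 90, 135)) {
    pre <- glrlm_angle_prefixes[[as.character(ang)]]
    rows <- c(rows, list(data.frame(
      name = paste0(pre, glrlm_stats), family = "glrlm",
      params = sprintf("angle=%d", ang), stringsAsFactors = FALSE)))
  }
  rows <- c(rows, list(data.frame(
    name = c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma"),
    family = "ar", params = "", stringsAsFactors = FALSE)))
  for (k in seq_len(max_scale)) {
    rows <- c(rows, list(data.frame(
      name = paste0("WavEn", c("LL", "LH", "HL", "HH"), "_s", k),
      family = "wavelet", params = sprintf("scale=%d", k),
      stringsAsFactors = FALSE)))
  }
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  attr(reg, "n_features") <- nrow(reg)
  reg
}

#' Canonicalize an export-mangled feature name
#'
#' Feature tables exported from Mazda-style software mangle canonical
#' names into syntactic identifiers: \code{S(0,1)Contrast} becomes
#' \code{X.S.0.1.Contrast}, \code{135dr_GLevNonU} becomes
#' \code{X135dr_GLevNonU}, \code{WavEnLL_s6} becomes
#' \code{ZWavEnLL_s6}, and a scale may be written \code{_s.3}. This
#' helper maps either form to the canonical registry name, so printed
#' coefficient tables can be used directly as Rad-Score models.
#'
#' @param name character vector of feature names, canonical or mangled.
#' @return character vector of canonical names.
#' @export
canonical_feature_name <- function(name) {
  out <- name
  # X.S.<dy>.<dx>.<Stat> (a leading dot in <dx> would mark a negative
  # displacement, e.g. X.S.1..1. -> S(1,-1))
  m <- regmatches(out, regexec("^X\\.S\\.([0-9]+)\\.(\\.?)([0-9]+)\\.([A-Za-z]+)$", out))
  for (i in seq_along(out)) {
    mi <- m[[i]]
    if (length(mi)) {
      sgn <- if (mi[3] == ".") "-" else ""
      out[i] <- sprintf("S(%s,%s%s)%s", mi[2], sgn, mi[4], mi[5])
    }
  }
  out <- sub("^X(135dr_|45dgr_|Horzl_|Vertl_)", "\\1", out)
  out <- sub("^Z?(WavEn(LL|LH|HL|HH))_s\\.?([0-9]+)$", "\\1_s\\3", out)
  out
}

#' Extract the full feature vector of one ROI
#'
#' Runs every family of [feature_registry()] on a quantized ROI and
#' returns the complete named vector in registry order. Undefined
#' features (e.g. wavelet scales deeper than the ROI's bounding box, or
#' moments of a constant ROI) are NA, never a silent zero.
#'
#' @param qroi a \code{quantized_roi}.
#' @param dmax,max_scale registry parameters, see [feature_registry()].
#' @return named numeric vector of length \code{nrow(feature_registry())}.
#' @export
extract_roi_features <- function(qroi, dmax = 5L, max_scale = 6L) {
  stopifnot(inherits(qroi, "quantized_roi"))
  vals <- c(histogram_features(qroi))
  glcm_stats_na <- c(AngScMom = NA_real_, Contrast = NA_real_,
                     Correlation = NA_real_, SumOfSqs = NA_real_,
                     InvDfMom = NA_real_, SumAverg = NA_real_,
                     SumVarnc = NA_real_, SumEntrp = NA_real_,
                     Entropy = NA_real_, DifVarnc = NA_real_,
                     DifEntrp = NA_real_)
  for (off in glcm_offsets(dmax)) {
    m <- glcm(qroi, off[1], off[2])
    f <- if (is.null(m)) glcm_stats_na else glcm_features(m)
    names(f) <- paste0(glcm_offset_name(off), names(f))
    vals <- c(vals, f)
  }
  for (ang in c(0, 45, 90, 135)) {
    f <- glrlm_features(qroi, ang)
    names(f) <- paste0(glrlm_angle_prefixes[[as.character(ang)]], names(f))
    vals <- c(vals, f)
  }
  vals <- c(vals, suppressWarnings(ar_model(qroi)))
  vals <- c(vals, wavelet_energies(qroi, max_scale))
  reg <- feature_registry(dmax, max_scale)
  stopifnot(identical(names(vals), reg$name))
  vals
}

#' Extract tumor and tumor+peritumoral feature vectors for one lesion
#'
#' Builds the two ROIs of the analysis protocol — the tumor core, and
#' the tumor dilated by the peritumoral margin minus the exclusion
#' mask — quantizes each (per-ROI normalization), and extracts the full
#' registry for both.
#'
#' @param img a \code{gray_image}.
#' @param tumor a \code{roi_mask} (role tumor).
#' @param exclusion optional exclusion \code{roi_mask}.
#' @param margin_mm peritumoral margin in mm (in [5, 10]).
#' @param cfg a [norm_config()].
#' @param dmax,max_scale registry parameters.
#' @return list with named feature vectors \code{tumor} and
#'   \code{tumor_plus_peritumoral}.
#' @export
extract_features <- function(img, tumor, exclusion = NULL, margin_mm = 7.5,
                             cfg = norm_config(), dmax = 5L, max_scale = 6L) {
  peri <- build_peritumoral(tumor, img$spacing_mm, margin_mm, exclusion)
  q1 <- normalize_quantize(img, tumor, cfg)
  q2 <- normalize_quantize(img, peri, cfg)
  list(tumor = extract_roi_features(q1, dmax, max_scale),
       tumor_plus_peritumoral = extract_roi_features(q2, dmax, max_scale))
}

#' Extract feature tables for a whole cohort
#'
#' Applies [extract_features()] to every lesion of a synthetic (or
#' loaded) cohort and returns one lesion x feature matrix per ROI
#' scope, rows aligned with the cohort metadata.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param margin_mm peritumoral margin in mm.
#' @param cfg a [norm_config()].
#' @param dmax,max_scale registry parameters.
#' @param use_exclusion subtract the skin exclusion band from the
#'   peritumoral ROI (default TRUE).
#' @return list with matrices \code{tumor},
#'   \code{tumor_plus_peritumoral} (rows = lesions) and the cohort
#'   \code{meta}.
#' @export
extract_cohort_features <- function(cohort, margin_mm = 7.5,
                                    cfg = norm_config(), dmax = 5L,
                                    max_scale = 6L, use_exclusion = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$meta)
  reg <- feature_registry(dmax, max_scale)
  t1 <- matrix(NA_real_, n, nrow(reg), dimnames = list(cohort$meta$id, reg$name))
  t2 <- t1
  for (i in seq_len(n)) {
    les <- cohort$lesions[[i]]
    ex <- if (use_exclusion) les$exclusion else NULL
    fv <- suppressWarnings(
      extract_features(les$image, les$tumor, ex, margin_mm, cfg,
                       dmax, max_scale))
    t1[i, ] <- fv$tumor
    t2[i, ] <- fv$tumor_plus_peritumoral
  }
  list(tumor = t1, tumor_plus_peritumoral = t2, meta = cohort$meta)
}
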