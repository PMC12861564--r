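#' Radiomic feature-name schema
#'
#' The pyradiomics-style feature complement per MRI sequence: 107 basic
#' features (18 first-order, 14 shape, and 75 textural split 24 GLCM,
#' 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM) plus 1579 filter-derived
#' higher-order features, i.e. 1686 per modality and 3372 across the two
#' sequences. Names follow `<modality>_<filter>_<class>_<feature>`.
#'
#' @param n_firstorder,n_shape,n_glcm,n_gldm,n_glrlm,n_glszm,n_ngtdm
#'   per-family basic feature counts.
#' @param n_filter_derived count of filter-derived higher-order features.
#' @return An object of class `feature_schema` (a named list of counts).
#' @export
feature_schema <- function(n_firstorder = 18L, n_shape = 14L, n_glcm = 24L,
                           n_gldm = 14L, n_glrlm = 16L, n_glszm = 16L,
                           n_ngtdm = 5L, n_filter_derived = 1579L) {
  s <- list(firstorder = n_firstorder, shape = n_shape, glcm = n_glcm,
            gldm = n_gldm, glrlm = n_glrlm, glszm = n_glszm,
            ngtdm = n_ngtdm, filter_derived = n_filter_derived)
  if (any(unlist(s) < 0)) stop("negative schema count")
  structure(s, class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> basic:", sum(unlist(x[1:7])),
      "filter-derived:", x$filter_derived, "\n")
  invisible(x)
}

# the six image filters used for higher-order features
.filters <- c("wavelet", "square", "squareroot", "logarithm",
              "exponential", "gradient")

#' Generate schema-conformant feature names
#'
#' @param schema a [feature_schema()].
#' @param modalities character vector of modality prefixes.
#' @return Named list (per modality) of feature-name character vectors;
#'   with defaults, 1686 names per modality and 3372 in total.
#' @export
feature_schema_names <- function(schema = feature_schema(),
                                 modalities = c("T1CE", "T2FLAIR")) {
  basic_classes <- c("firstorder", "shape", "glcm", "gldm", "glrlm",
                     "glszm", "ngtdm")
  one_modality <- function(mod) {
    basic <- unlist(lapply(basic_classes, function(cl)
      sprintf("%s_original_%s_f%02d", mod, cl, seq_len(schema[[cl]]))),
      use.names = FALSE)
    nfd <- schema$filter_derived
    if (nfd > 0L) {
      filt <- rep(.filters, length.out = nfd)
      # filter-derived features reuse the non-shape classes cyclically
      cls <- rep(setdiff(basic_classes, "shape"), length.out = nfd)
      derived <- sprintf("%s_%s_%s_d%04d", mod, filt, cls, seq_len(nfd))
    } else derived <- character(0)
    c(basic, derived)
  }
  setNames(lapply(modalities, one_modality), modalities)
}
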