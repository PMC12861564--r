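# canonical 14 signaling pathways scored downstream
.pathways <- c("Androgen", "EGFR", "Estrogen", "Hypoxia", "JAK-STAT",
               "MAPK", "NF-kB", "PI3K", "TGF-b", "TNFa", "Trail",
               "VEGF", "WNT", "p53")

#' Specification of a synthetic radiomic cohort
#'
#' Describes a cohort with `k_true` latent phenotypic subtypes whose
#' statistical structure matches what the subtyping pipeline assumes:
#' two correlated feature modalities carrying complementary subtype
#' signal, exponential subtype-dependent survival with administrative
#' censoring, subtype-dependent IDH/MGMT frequencies, log-normal
#' subtype-dependent tumor volume, and a non-linear (or linear) IDH
#' signal embedded in dedicated feature columns.
#'
#' Defaults mirror the cohort the pipeline was designed around: n = 246
#' with a 153/93 subtype split, a survival hazard ratio of 2 between
#' subtypes, per-subtype IDH-mutant probabilities (0.39, 0.60) and
#' MGMT-methylation probabilities (0.61, 0.74).
#'
#' @param n_samples cohort size.
#' @param k_true latent subtype count.
#' @param proportions subtype mixing proportions (sum to 1).
#' @param n_informative,n_noise per-modality informative / pure-noise
#'   feature counts.
#' @param delta between-subtype mean shift in within-subtype SD units,
#'   split evenly across the modalities (each carries `delta/sqrt(2)`
#'   when they share a separating direction).
#' @param rho equicorrelation within the informative feature block.
#' @param hazards per-subtype exponential hazard (per day).
#' @param censor_days administrative censoring time.
#' @param p_idh_mutant,p_mgmt_methylated per-subtype probabilities.
#' @param idh_signal `"radial"` (non-linearly separable) or `"linear"`;
#'   `idh_strength` scales it (0 disables).
#' @param idh_strength logit-scale strength of the IDH feature signal.
#' @param volume_meanlog,volume_sdlog per-subtype log-normal volume
#'   parameters (cm^3).
#' @param seed RNG seed used by [simulate_cohort()].
#' @return A `sim_cohort_spec` list.
#' @export
sim_cohort_spec <- function(n_samples = 246L, k_true = 2L,
                            proportions = NULL,
                            n_informative = 20L, n_noise = 40L,
                            delta = 3, rho = 0.3,
                            hazards = c(1 / 600, 1 / 1200),
                            censor_days = 2000,
                            p_idh_mutant = c(0.39, 0.60),
                            p_mgmt_methylated = c(0.61, 0.74),
                            idh_signal = c("radial", "linear"),
                            idh_strength = 3,
                            volume_meanlog = c(3.84, 2.62),
                            volume_sdlog = c(0.55, 0.97),
                            seed = 20240101L) {
  idh_signal <- match.arg(idh_signal)
  if (is.null(proportions)) {
    proportions <- if (k_true == 2L) c(153, 93) / 246 else
      rep(1 / k_true, k_true)
  }
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (length(proportions) != k_true) stop("need one proportion per subtype")
  if (delta < 0) stop("delta must be >= 0")
  recyc <- function(v) rep_len(v, k_true)
  hazards <- recyc(hazards)
  if (any(hazards <= 0)) stop("hazards must be positive")
  p_idh_mutant <- recyc(p_idh_mutant); p_mgmt_methylated <- recyc(p_mgmt_methylated)
  if (any(c(p_idh_mutant, p_mgmt_methylated) < 0 |
          c(p_idh_mutant, p_mgmt_methylated) > 1))
    stop("probabilities must lie in [0, 1]")
  structure(list(n_samples = as.integer(n_samples), k_true = as.integer(k_true),
                 proportions = proportions, n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise), delta = delta, rho = rho,
                 hazards = hazards, censor_days = censor_days,
                 p_idh_mutant = p_idh_mutant,
                 p_mgmt_methylated = p_mgmt_methylated,
                 idh_signal = idh_signal, idh_strength = idh_strength,
                 volume_meanlog = recyc(volume_meanlog),
                 volume_sdlog = recyc(volume_sdlog),
                 seed = as.integer(seed)),
            class = "sim_cohort_spec")
}

# subtype mean matrix (k x p) for one modality: subtype contrasts are
# distributed across modalities so each modality carries part of the
# separating signal; with a single contrast (k = 2) both modalities share
# it at strength delta/sqrt(2).
.subtype_means <- function(k, p, delta, modality_index, n_modalities = 2L) {
  if (p == 0L || delta == 0) return(matrix(0, k, p))
  contr <- stats::contr.helmert(k)            # k x (k-1)
  contr <- sweep(contr, 2, apply(contr, 2, function(v) diff(range(v))), "/")
  n_con <- ncol(contr)
  own <- which((seq_len(n_con) - 1L) %% n_modalities == (modality_index - 1L) %% n_modalities)
  if (length(own) == 0L) own <- n_con
  scale <- if (n_con < n_modalities) delta / sqrt(n_modalities) else delta
  idx <- rep_len(own, p)
  contr[, idx, drop = FALSE] * scale
}

#' Simulate a two-modality radiomic cohort with latent subtypes
#'
#' Draws the cohort described by a [sim_cohort_spec()]: two feature
#' tables (modalities `T1CE` and `T2FLAIR`), a clinical table, and the
#' true subtype labels (returned for evaluation only — the pipeline
#' itself never sees them). Bit-reproducible for a fixed spec seed.
#'
#' @param spec a [sim_cohort_spec()].
#' @return List with `tables` (named list of two [feature_table()]s),
#'   `clinical` (a [clinical_table()]), `labels` (integer subtype in
#'   `1..k_true`) and `spec`.
#' @export
simulate_cohort <- function(spec = sim_cohort_spec()) {
  stopifnot(inherits(spec, "sim_cohort_spec"))
  n <- spec$n_samples; k <- spec$k_true
  if (n < 2L * k) stop("n_samples must be at least 2 * k_true")
  set.seed(spec$seed)
  labels <- sort(sample(rep(seq_len(k), diff(round(c(0, cumsum(spec$proportions)) * n)))))
  labels <- rep_len(labels, n)
  ids <- sprintf("S%04d", seq_len(n))

  draw_modality <- function(mod_idx, mod_name) {
    p_inf <- spec$n_informative
    mu <- .subtype_means(k, p_inf, spec$delta, mod_idx)
    # equicorrelated within-subtype noise in the informative block
    common <- rnorm(n)
    inf <- sqrt(spec$rho) * matrix(common, n, p_inf) +
      sqrt(1 - spec$rho) * matrix(rnorm(n * p_inf), n, p_inf)
    inf <- inf + mu[labels, , drop = FALSE]
    noise <- matrix(rnorm(n * spec$n_noise), n, spec$n_noise)
    x <- cbind(inf, noise)
    colnames(x) <- c(sprintf("%s_inf_%03d", mod_name, seq_len(p_inf)),
                     sprintf("%s_noise_%03d", mod_name, seq_len(spec$n_noise)))
    x
  }
  x1 <- draw_modality(1L, "T1CE")
  x2 <- draw_modality(2L, "T2FLAIR")

  # latent coordinates carrying the IDH signal, exposed as feature columns
  z1 <- rnorm(n); z2 <- rnorm(n)
  sig <- switch(spec$idh_signal,
                radial = spec$idh_strength * (2 - (z1^2 + z2^2)) / 2,
                linear = spec$idh_strength * z1)
  x1 <- cbind(x1, T1CE_idhsig_1 = z1 + rnorm(n, sd = 0.2),
              T1CE_idhsig_2 = z2 + rnorm(n, sd = 0.2))
  x2 <- cbind(x2, T2FLAIR_idhsig_1 = z1 + rnorm(n, sd = 0.2),
              T2FLAIR_idhsig_2 = z2 + rnorm(n, sd = 0.2))

  p_idh <- stats::plogis(stats::qlogis(spec$p_idh_mutant[labels]) + sig)
  idh <- ifelse(rbinom(n, 1, p_idh) == 1, "mutant", "wild")
  mgmt <- ifelse(rbinom(n, 1, spec$p_mgmt_methylated[labels]) == 1,
                 "methylated", "unmethylated")
  os_true <- rexp(n, rate = spec$hazards[labels])
  os_days <- pmin(os_true, spec$censor_days)
  event <- as.integer(os_true <= spec$censor_days)
  grade_probs <- rbind(c(0.24, 0.32, 0.44), c(0.49, 0.31, 0.20))
  grade <- vapply(labels, function(g)
    sample(c(2, 3, 4), 1L, prob = grade_probs[1L + (g - 1L) %% 2L, ]), 0)
  clinical <- clinical_table(data.frame(
    sample_id = ids, os_days = os_days, event = event,
    age_years = pmax(18, rnorm(n, 49, 15)),
    gender = ifelse(rbinom(n, 1, 0.5) == 1, "male", "female"),
    grade = grade,
    tumor_volume_cm3 = rlnorm(n, spec$volume_meanlog[labels],
                              spec$volume_sdlog[labels]),
    idh = idh, mgmt = mgmt, stringsAsFactors = FALSE))
  list(tables = list(T1CE = feature_table(x1, ids, "T1CE"),
                     T2FLAIR = feature_table(x2, ids, "T2FLAIR")),
       clinical = clinical, labels = labels, spec = spec)
}

#' Specification of a synthetic expression cohort
#'
#' Gene expression is generated from a sparse signed pathway weight
#' matrix: each sample's expression is `W %*% (baseline + activation)`
#' plus Gaussian noise, where the activation vector depends on the
#' sample's subtype. This is the generative counterpart of the
#' multivariate-linear-model pathway scoring.
#'
#' @param n_genes number of genes.
#' @param pathways pathway names (default the 14 canonical pathways).
#' @param genes_per_pathway support size per pathway column.
#' @param activation matrix (groups x pathways) of activation shifts; row
#'   g applies to samples in group g. Default all zero for 2 groups.
#' @param baseline_sd SD of the shared baseline pathway activity.
#' @param noise_sd residual SD.
#' @param seed RNG seed.
#' @return A `sim_expression_spec` list.
#' @export
sim_expression_spec <- function(n_genes = 500L, pathways = .pathways,
                                genes_per_pathway = 60L,
                                activation = NULL, baseline_sd = 0.5,
                                noise_sd = 1, seed = 20240101L) {
  if (is.null(activation)) activation <- matrix(0, 2, length(pathways))
  activation <- as.matrix(activation)
  if (ncol(activation) != length(pathways))
    stop("activation needs one column per pathway")
  colnames(activation) <- pathways
  structure(list(n_genes = as.integer(n_genes), pathways = pathways,
                 genes_per_pathway = as.integer(genes_per_pathway),
                 activation = activation, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_expression_spec")
}

#' Simulate expression driven by a sparse pathway weight matrix
#'
#' @param spec a [sim_expression_spec()].
#' @param group_labels integer group per sample (rows of
#'   `spec$activation` index the groups).
#' @return List with `expression` (samples x genes), `weights`
#'   (genes x pathways, sparse signed) and `pathways`.
#' @export
simulate_expression <- function(spec, group_labels) {
  stopifnot(inherits(spec, "sim_expression_spec"))
  if (max(group_labels) > nrow(spec$activation))
    stop("group label exceeds activation rows")
  set.seed(spec$seed)
  p <- length(spec$pathways); n <- length(group_labels)
  w <- matrix(0, spec$n_genes, p,
              dimnames = list(sprintf("gene%04d", seq_len(spec$n_genes)),
                              spec$pathways))
  for (j in seq_len(p)) {
    supp <- sample(spec$n_genes, min(spec$genes_per_pathway, spec$n_genes))
    w[supp, j] <- rnorm(length(supp))
  }
  if (all(w == 0)) stop("degenerate all-zero weight matrix")
  baseline <- rnorm(p, sd = spec$baseline_sd)
  act <- t(spec$activation[group_labels, , drop = FALSE])  # p x n
  expr <- t(w %*% (baseline + act)) +
    matrix(rnorm(n * spec$n_genes, sd = spec$noise_sd), n, spec$n_genes)
  colnames(expr) <- rownames(w)
  rownames(expr) <- sprintf("S%04d", seq_len(n))
  list(expression = expr, weights = w, pathways = spec$pathways)
}
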