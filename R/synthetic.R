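#' Configuration for the synthetic dual-experiment generator
#'
#' Defaults describe a serum-metabolomics benchmark pair of the size the
#' package targets: two experiments of 20 cases / 25 controls (the scale of
#' the smaller liver-disease benchmark pairs), a few hundred aligned peaks
#' per experiment of which most are measured in both batches, twelve planted
#' true markers (matching the size of the curated serum marker panel), a
#' moderate one-log-SD case/control effect, a multiplicative batch shift
#' between the two experiments, and intensity-dependent missingness.
#'
#' @param n_features_shared features measured in both experiments.
#' @param n_features_unique_per_exp features private to each experiment.
#' @param n_case,n_control samples per arm, in each experiment.
#' @param n_true_markers number of planted differential features (drawn from
#'   the shared set; must not exceed it).
#' @param effect_size case-vs-control mean shift for true markers, in units
#'   of the within-group log-scale SD; applied consistently in both
#'   experiments.
#' @param batch_location_shift additive log-scale offset applied to every
#'   intensity of experiment 2 (a multiplicative batch effect on the natural
#'   scale).
#' @param batch_scale factor multiplying the log-scale noise SD in
#'   experiment 2 (batch-specific dispersion).
#' @param missing_rate overall fraction of missing cells per table, in
#'   `[0, 1)`.
#' @param mnar_weight fraction of the missingness budget concentrated on the
#'   lowest-intensity cells (intensity-dependent censoring); the remainder
#'   is missing completely at random.
#' @param complete_fraction fraction of features that are never missing, as
#'   in aligned LC-MS tables where a core of well-detected peaks is complete
#'   in every sample (these features form the MSTUS "total useful signal");
#'   the missingness budget is spread over the remaining features.
#' @param mz_jitter half-width (Da) of the uniform cross-experiment m/z
#'   measurement error on shared features.
#' @param decoy_rate Poisson mean of the number of decoy library records
#'   generated inside the 20 ppm annotation window of each feature, so that
#'   peak annotation is one-to-many as with a full compound database.
#' @param ion_mode `"positive"` or `"negative"`; sets the proton adduct sign
#'   relating neutral masses to observed m/z.
#' @param seed integer RNG seed; the whole generated world is a pure
#'   function of the config including this seed.
#' @return a validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_features_shared = 600L,
                             n_features_unique_per_exp = 300L,
                             n_case = 20L, n_control = 25L,
                             n_true_markers = 12L,
                             effect_size = 1.0,
                             batch_location_shift = 0.5,
                             batch_scale = 1.2,
                             missing_rate = 0.2,
                             mnar_weight = 0.5,
                             complete_fraction = 0.5,
                             mz_jitter = 0.002,
                             decoy_rate = 40,
                             ion_mode = c("positive", "negative"),
                             seed = 1L) {
  cfg <- list(
    n_features_shared = as.integer(n_features_shared),
    n_features_unique_per_exp = as.integer(n_features_unique_per_exp),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_true_markers = as.integer(n_true_markers),
    effect_size = effect_size,
    batch_location_shift = batch_location_shift,
    batch_scale = batch_scale,
    missing_rate = missing_rate,
    mnar_weight = mnar_weight,
    complete_fraction = complete_fraction,
    mz_jitter = mz_jitter,
    decoy_rate = decoy_rate,
    ion_mode = match.arg(ion_mode),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_features_shared >= 1L, n_features_unique_per_exp >= 0L,
              n_case >= 1L, n_control >= 1L, n_true_markers >= 0L)
    if (n_true_markers > n_features_shared) {
      stop("n_true_markers (", n_true_markers,
           ") exceeds n_features_shared (", n_features_shared, ")")
    }
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
    if (mnar_weight < 0 || mnar_weight > 1) stop("mnar_weight must be in [0, 1]")
    if (complete_fraction < 0 || complete_fraction >= 1) {
      stop("complete_fraction must be in [0, 1)")
    }
    if (missing_rate > 0 && missing_rate / (1 - complete_fraction) > 0.9) {
      stop("missing_rate too high for the given complete_fraction")
    }
    if (batch_scale <= 0) stop("batch_scale must be positive")
    if (mz_jitter < 0) stop("mz_jitter must be non-negative")
  })
  structure(cfg, class = "SyntheticConfig")
}

# Mass of the proton charge carrier (Da); relates neutral mass to [M+H]+ / [M-H]-.
PROTON_MASS <- 1.007276

# Fixed log-scale noise model: per-feature baseline ~ N(MU0, TAU), within-group SD SIGMA0.
.SYN_MU0 <- 10
.SYN_TAU <- 1.5
.SYN_SIGMA0 <- 0.6

#' Generate a synthetic pair of experiments with ground truth
#'
#' Emulates two LC-MS batches measuring overlapping feature sets on the same
#' case/control contrast. Intensities are log-normal; planted true markers
#' are shifted by `effect_size` log-SDs in cases, with the same sign in both
#' experiments; experiment 2 carries a multiplicative location shift and a
#' dispersion factor; shared features reappear with jittered m/z; each
#' experiment additionally has private features. A reference library is
#' generated with one correct record per feature plus Poisson-distributed
#' decoys inside the 20 ppm annotation window, so annotation is one-to-many.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `exp1`, `exp2` (PeakTables), `library`
#'   (ReferenceLibrary) and `truth` (GroundTruth: per-experiment true
#'   feature keys, true metabolite IDs, feature-to-metabolite map, and the
#'   planted-design counts).
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n_sh <- config$n_features_shared
  n_un <- config$n_features_unique_per_exp
  n_tot <- n_sh + 2L * n_un

  # Neutral masses on a 0.2 Da-spaced grid (70-1000 Da) with a small
  # sub-grid offset: guarantees unambiguous matching at the default 0.05 Da
  # tolerance while avoiding integer-spaced artefacts.
  grid <- seq(70, 1000, by = 0.2)
  if (n_tot > length(grid)) stop("too many features for the m/z grid")
  neutral <- sort(sample(grid, n_tot)) + stats::runif(n_tot, 0, 0.04)
  rt <- stats::runif(n_tot, 30, 1200)

  role <- sample(rep(c("shared", "uniq1", "uniq2"), c(n_sh, n_un, n_un)))
  shared_i <- which(role == "shared")
  uniq1_i <- which(role == "uniq1")
  uniq2_i <- which(role == "uniq2")
  true_i <- sort(sample(shared_i, config$n_true_markers))
  effect_sign <- sample(c(-1, 1), n_tot, replace = TRUE)

  adduct <- if (config$ion_mode == "positive") PROTON_MASS else -PROTON_MASS
  mz <- neutral + adduct

  mu <- stats::rnorm(n_tot, .SYN_MU0, .SYN_TAU)
  delta <- numeric(n_tot)
  delta[true_i] <- config$effect_size * .SYN_SIGMA0 * effect_sign[true_i]

  sim_exp <- function(feat_idx, loc_shift, scale, mz_noise) {
    nf <- length(feat_idx)
    ns <- config$n_case + config$n_control
    groups <- rep(c("case", "control"), c(config$n_case, config$n_control))
    shift <- outer(delta[feat_idx], as.numeric(groups == "case"))
    logi <- mu[feat_idx] + loc_shift + shift +
      scale * .SYN_SIGMA0 * matrix(stats::rnorm(nf * ns), nf, ns)
    list(mz = mz[feat_idx] + mz_noise, rt = rt[feat_idx],
         intensities = exp(logi), groups = groups)
  }

  idx1 <- sort(c(shared_i, uniq1_i))
  idx2 <- sort(c(shared_i, uniq2_i))
  e1 <- sim_exp(idx1, 0, 1, 0)
  jit <- stats::runif(length(idx2), -config$mz_jitter, config$mz_jitter)
  e2 <- sim_exp(idx2, config$batch_location_shift, config$batch_scale, jit)

  e1$intensities <- apply_missingness(e1$intensities, config$missing_rate,
                                      config$mnar_weight,
                                      config$complete_fraction)
  e2$intensities <- apply_missingness(e2$intensities, config$missing_rate,
                                      config$mnar_weight,
                                      config$complete_fraction)

  mk_ids <- function(prefix, n) sprintf("%s%06d", prefix, seq_len(n))
  sample_ids1 <- mk_ids("E1S", ncol(e1$intensities))
  sample_ids2 <- mk_ids("E2S", ncol(e2$intensities))
  t1 <- peak_table(e1$mz, e1$rt, e1$intensities, sample_ids1, e1$groups, "exp1")
  t2 <- peak_table(e2$mz, e2$rt, e2$intensities, sample_ids2, e2$groups, "exp2")

  # Library: one correct record per generated feature + decoys within the
  # 20 ppm annotation window (drawn inside +/- 15 ppm so they stay matched
  # after m/z jitter).
  met_ids <- mk_ids("SM", n_tot)
  n_decoy <- stats::rpois(n_tot, config$decoy_rate)
  decoy_parent <- rep(seq_len(n_tot), n_decoy)
  decoy_mass <- neutral[decoy_parent] *
    (1 + stats::runif(length(decoy_parent), -15e-6, 15e-6))
  lib <- reference_library(data.frame(
    metabolite_id = c(met_ids, mk_ids("SD", length(decoy_parent))),
    name = c(sprintf("synthetic metabolite %d", seq_len(n_tot)),
             sprintf("synthetic decoy of %d", decoy_parent)),
    neutral_mass = c(neutral, decoy_mass),
    stringsAsFactors = FALSE
  ))

  pos1 <- match(true_i, idx1)
  pos2 <- match(true_i, idx2)
  truth <- structure(list(
    true_feature_keys = list(
      exp1 = feature_keys(t1)[pos1],
      exp2 = feature_keys(t2)[pos2]
    ),
    true_metabolite_ids = structure(met_ids[true_i], class = "TrueMarkerSet"),
    feature_map = data.frame(
      metabolite_id = met_ids, role = role,
      neutral_mass = neutral, is_true = seq_len(n_tot) %in% true_i,
      stringsAsFactors = FALSE
    ),
    counts = list(shared = n_sh, unique_per_exp = n_un,
                  true = config$n_true_markers,
                  case = config$n_case, control = config$n_control)
  ), class = "GroundTruth")

  list(exp1 = t1, exp2 = t2, library = lib, truth = truth)
}

#' Apply the generator's missingness model to an intensity matrix
#'
#' A `complete_fraction` of features is left fully observed (the MSTUS
#' core); the missingness budget is spread over the remaining "spotty"
#' features at per-cell rate `rate / (1 - complete_fraction)`. Within those
#' features, cells in the lowest intensity quantile are censored with
#' probability `mnar_weight` and all cells are additionally missing
#' completely at random, so the table-wide missing fraction is
#' approximately `rate`. Every feature keeps at least one observed value
#' (its highest-intensity cell is restored if necessary), as downstream
#' imputation requires.
#' @noRd
apply_missingness <- function(M, rate, mnar_weight, complete_fraction = 0) {
  if (rate <= 0) return(M)
  nf <- nrow(M)
  spotty <- stats::runif(nf) >= complete_fraction
  if (!any(spotty)) return(M)
  S <- M[spotty, , drop = FALSE]
  r <- rate / (1 - complete_fraction)
  n <- length(S)
  thr <- stats::quantile(S, probs = r, names = FALSE)
  mnar <- (S < thr) & (stats::runif(n) < mnar_weight)
  mcar <- stats::runif(n) < r * (1 - mnar_weight)
  S[mnar | mcar] <- NA_real_
  dead <- which(rowSums(!is.na(S)) == 0L)
  Morig <- M[spotty, , drop = FALSE]
  for (f in dead) S[f, which.max(Morig[f, ])] <- Morig[f, which.max(Morig[f, ])]
  out <- M
  out[spotty, ] <- S
  out
}

#' Summarise the planted design of a generated pair
#'
#' @param truth a `GroundTruth` from [generate_pair()].
#' @return data.frame of planted counts (shared / unique / true features,
#'   samples per arm) for report headers.
#' @export
plant_summary <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  with(truth$counts, data.frame(
    quantity = c("shared features", "unique features per experiment",
                 "true marker features", "cases per experiment",
                 "controls per experiment"),
    count = c(shared, unique_per_exp, true, case, control),
    stringsAsFactors = FALSE
  ))
}
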