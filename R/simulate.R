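#' Simulation configuration for synthetic dementia cohorts
#'
#' Assembles and validates the parameters of the synthetic-cohort generator.
#' Defaults emulate the demographic and clinical structure of a two-diagnosis
#' dementia cohort (dementia of the Alzheimer's type, DAT, n = 111; behavioural
#' variant frontotemporal dementia, bvFTD, n = 75): per-group disinhibition
#' rates (27/111 and 62/75), severity distribution among disinhibited subjects
#' proportional to 15/27/20 over severities 1-3, per-group means/SDs for age,
#' education, CDR-SB, days between MRI and symptom assessment, scanner-make
#' proportions, and male/female proportions. Total intracranial volume (TIV)
#' defaults to 1.45e6 (1.4e5) mm^3 in both groups, a typical adult value.
#'
#' The morphometric generative model is the package's own (documented in the
#' methods vignette): each region's 7-feature vector is a fixed region
#' archetype plus \code{latent_strength} times a subject-by-functional-network
#' latent vector plus independent Gaussian noise. An \code{effect_map} entry
#' \code{list(network = "CCN", subset = "disinhibition", attenuation = 0.5)}
#' multiplies the latent loading by \code{1 - attenuation} for the targeted
#' regions in matching subjects, lowering their within-network morphometric
#' similarity. \code{subset} may be \code{"disinhibition"}, \code{"DAT"},
#' \code{"bvFTD"}, or a \code{"diagnosis:disinhibition"} combination such as
#' \code{"bvFTD:disinhibition"}.
#'
#' @param n_dat,n_bvftd Subjects per diagnosis group (each >= 2).
#' @param disinhibition_rate Named probabilities \code{c(DAT = , bvFTD = )}.
#' @param severity_probs Probabilities over severities 1:3 for disinhibited
#'   subjects; normalised internally.
#' @param covariates Named list per group (\code{DAT}, \code{bvFTD}), each a
#'   list with \code{mean}/\code{sd} vectors over \code{age}, \code{education},
#'   \code{cdr_sb}, \code{tiv}, \code{days_mri_npiq}.
#' @param sex_prob_m Named per-group probability of male sex.
#' @param scanner_probs 2 x 3 matrix of per-group proportions over
#'   Siemens/GE/Philips (rows DAT, bvFTD).
#' @param effect_map List of effect entries (see Details); the default injects
#'   a 0.5 similarity attenuation in the cognitive control network for
#'   disinhibited subjects.
#' @param latent_strength Loading of the shared network latent (lambda).
#' @param network_coupling Correlation, in \[0, 1), between the latent (and
#'   network-archetype) components of functional networks belonging to the
#'   same analysis subnetwork (e.g. Cingulo-opercular and Orbito-affective
#'   within the SN), so a subnetwork's blocks are mutually similar rather
#'   than independent.
#' @param archetype_coupling Share, in \[0, 1), of the archetype variance
#'   carried by a network-level profile common to all regions of a functional
#'   network. Regions of one network thus have similar expected feature
#'   profiles across subjects — emulating the cytoarchitectonic clustering
#'   that makes real within-network morphometric similarity stable — which
#'   keeps density-thresholded subnetworks connected at the usual densities.
#' @param archetype_sd SD of the fixed region archetype values.
#' @param noise_sd SD of the independent feature noise (> 0).
#' @param n_regions,n_features Morphometric table dimensions (360 x 7).
#' @param seed Master seed; together with the other fields it fully
#'   determines every generated table.
#' @return Validated list of class \code{msn_sim_config}.
#' @export
sim_config <- function(n_dat = 111L,
                       n_bvftd = 75L,
                       disinhibition_rate = c(DAT = 27 / 111, bvFTD = 62 / 75),
                       severity_probs = c(15, 27, 20) / 62,
                       covariates = default_covariate_params(),
                       sex_prob_m = c(DAT = 68 / 111, bvFTD = 51 / 75),
                       scanner_probs = rbind(DAT   = c(59, 32, 20) / 111,
                                             bvFTD = c(61, 14, 0) / 75),
                       effect_map = list(list(network = "CCN",
                                              subset = "disinhibition",
                                              attenuation = 0.5)),
                       latent_strength = 1,
                       network_coupling = 0.5,
                       archetype_coupling = 0,
                       archetype_sd = 1,
                       noise_sd = 0.75,
                       n_regions = 360L,
                       n_features = 7L,
                       seed = 1L) {
  cfg <- list(n_dat = as.integer(n_dat), n_bvftd = as.integer(n_bvftd),
              disinhibition_rate = disinhibition_rate,
              severity_probs = severity_probs,
              covariates = covariates, sex_prob_m = sex_prob_m,
              scanner_probs = scanner_probs, effect_map = effect_map,
              latent_strength = latent_strength,
              network_coupling = network_coupling,
              archetype_coupling = archetype_coupling,
              archetype_sd = archetype_sd,
              noise_sd = noise_sd, n_regions = as.integer(n_regions),
              n_features = as.integer(n_features), seed = as.integer(seed))
  class(cfg) <- "msn_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_covariate_params <- function() {
  list(
    DAT = list(
      mean = c(age = 74.15, education = 15.24, cdr_sb = 5.38,
               tiv = 1.45e6, days_mri_npiq = 14.01),
      sd   = c(age = 7.53, education = 3.31, cdr_sb = 2.58,
               tiv = 1.4e5, days_mri_npiq = 55.81)
    ),
    bvFTD = list(
      mean = c(age = 64.46, education = 16.05, cdr_sb = 8.16,
               tiv = 1.45e6, days_mri_npiq = 4.03),
      sd   = c(age = 7.03, education = 3.10, cdr_sb = 3.94,
               tiv = 1.4e5, days_mri_npiq = 25.47)
    )
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$n_dat < 2L || cfg$n_bvftd < 2L)
    stop("configuration error: need at least 2 subjects per diagnosis group")
  if (any(cfg$disinhibition_rate < 0) || any(cfg$disinhibition_rate > 1))
    stop("configuration error: disinhibition rates must lie in [0, 1]")
  if (!all(c("DAT", "bvFTD") %in% names(cfg$disinhibition_rate)))
    stop("configuration error: disinhibition_rate needs DAT and bvFTD entries")
  if (length(cfg$severity_probs) != 3 || any(cfg$severity_probs < 0) ||
      sum(cfg$severity_probs) <= 0)
    stop("configuration error: severity_probs must be 3 non-negative values")
  for (g in c("DAT", "bvFTD")) {
    cv <- cfg$covariates[[g]]
    need <- c("age", "education", "cdr_sb", "tiv", "days_mri_npiq")
    if (is.null(cv) || !all(need %in% names(cv$mean)) ||
        !all(need %in% names(cv$sd)))
      stop("configuration error: covariate means/sds incomplete for group ", g)
    if (any(cv$sd[need] < 0))
      stop("configuration error: negative covariate SD for group ", g)
  }
  if (any(cfg$sex_prob_m < 0) || any(cfg$sex_prob_m > 1))
    stop("configuration error: sex probabilities must lie in [0, 1]")
  if (any(cfg$scanner_probs < 0))
    stop("configuration error: scanner proportions must be non-negative")
  for (eff in cfg$effect_map) {
    if (is.null(eff$network) || is.null(eff$subset) || is.null(eff$attenuation))
      stop("configuration error: each effect_map entry needs network, subset, attenuation")
    if (eff$attenuation < 0 || eff$attenuation > 1)
      stop("configuration error: attenuation must lie in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop("configuration error: noise_sd must be > 0")
  for (p in c("network_coupling", "archetype_coupling")) {
    if (is.null(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] >= 1)
      stop("configuration error: ", p, " must lie in [0, 1)")
  }
  if (cfg$archetype_sd < 0) stop("configuration error: archetype_sd must be >= 0")
  if (cfg$latent_strength < 0) stop("configuration error: latent_strength must be >= 0")
  if (cfg$n_regions < 3L) stop("configuration error: n_regions must be >= 3")
  if (cfg$n_features < 2L) stop("configuration error: n_features must be >= 2")
  invisible(cfg)
}

#' Generate a synthetic cohort table
#'
#' Draws one subject row per configured participant: diagnosis, disinhibition
#' presence (per-group Bernoulli) and severity (categorical over 1-3 for
#' disinhibited subjects, 0 otherwise), and covariates from the configured
#' per-group distributions. Age, education, CDR-SB and TIV are truncated to
#' their natural ranges (CDR-SB to 0-18). Each subject is drawn from its
#' own deterministic RNG sub-stream derived from the master seed, so a
#' subject's record does not depend on how many subjects precede it.
#'
#' @param config An [sim_config()] object.
#' @return A data.frame with one row per subject and columns
#'   \code{subject_id}, \code{diagnosis}, \code{disinhibition_present},
#'   \code{disinhibition_severity}, \code{age}, \code{sex}, \code{education},
#'   \code{cdr_sb}, \code{tiv}, \code{days_mri_npiq}, \code{scanner}.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_dat = 10, n_bvftd = 8, seed = 42))
#' table(coh$diagnosis)
simulate_cohort <- function(config) {
  if (!inherits(config, "msn_sim_config")) stop("'config' must come from sim_config()")
  validate_sim_config(config)
  n <- config$n_dat + config$n_bvftd
  diagnosis <- rep(c("DAT", "bvFTD"), c(config$n_dat, config$n_bvftd))
  sev_p <- config$severity_probs / sum(config$severity_probs)
  scan_lab <- c("Siemens", "GE", "Philips")

  age <- education <- cdr_sb <- tiv <- days <- numeric(n)
  sex <- scanner <- character(n)
  disinhibited <- logical(n)
  severity <- integer(n)
  for (i in seq_len(n)) {
    g <- diagnosis[i]
    cv <- config$covariates[[g]]
    set.seed(derive_seed(config$seed, i))
    age[i] <- max(rnorm(1, cv$mean["age"], cv$sd["age"]), 40)
    sex[i] <- if (runif(1) < config$sex_prob_m[g]) "M" else "F"
    education[i] <- max(rnorm(1, cv$mean["education"], cv$sd["education"]), 0)
    cdr_sb[i] <- min(max(rnorm(1, cv$mean["cdr_sb"], cv$sd["cdr_sb"]), 0), 18)
    tiv[i] <- max(rnorm(1, cv$mean["tiv"], cv$sd["tiv"]), 1e5)
    days[i] <- rnorm(1, cv$mean["days_mri_npiq"], cv$sd["days_mri_npiq"])
    disinhibited[i] <- runif(1) < config$disinhibition_rate[g]
    severity[i] <- if (disinhibited[i]) sample(1:3, 1, prob = sev_p) else 0L
    sp <- config$scanner_probs[g, ]
    scanner[i] <- sample(scan_lab, 1, prob = sp / sum(sp))
  }
  coh <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)), diagnosis = diagnosis,
    disinhibition_present = disinhibited, disinhibition_severity = severity,
    age = age, sex = sex, education = education, cdr_sb = cdr_sb,
    tiv = tiv, days_mri_npiq = days, scanner = scanner,
    stringsAsFactors = FALSE
  )
  coh$diagnosis <- factor(coh$diagnosis, levels = c("DAT", "bvFTD"))
  coh$sex <- factor(coh$sex, levels = c("M", "F"))
  coh$scanner <- factor(coh$scanner, levels = scan_lab)
  rownames(coh) <- NULL
  coh
}

# Resolve an effect_map target to atlas row indices.
effect_region_index <- function(network, atlas) {
  nets <- builtin_networks()
  if (network %in% names(nets)) {
    network_nodes(atlas, nets[[network]])
  } else if (network %in% atlas$functional_network) {
    which(atlas$functional_network == network)
  } else {
    stop("structural error: effect_map network '", network,
         "' matches neither a built-in subnetwork nor an atlas label")
  }
}

# TRUE when a subject row matches an effect_map subset selector.
effect_subject_match <- function(subject, subset) {
  parts <- strsplit(subset, ":", fixed = TRUE)[[1]]
  ok <- TRUE
  for (p in parts) {
    ok <- ok && switch(p,
      disinhibition = isTRUE(subject$disinhibition_present),
      DAT = subject$diagnosis == "DAT",
      bvFTD = subject$diagnosis == "bvFTD",
      stop("configuration error: unknown effect_map subset token '", p, "'"))
  }
  ok
}

# Plausible FreeSurfer-style location/scale per feature, applied as a final
# per-column affine map; affine maps are removed again by feature z-scoring,
# so they only make the exported tables look like real regional exports.
feature_affine <- function() {
  list(loc   = c(GM = 2600, SA = 950, CT = 2.45, IC = 0.14, MC = 0.13,
                 CI = 3.2, FI = 12),
       scale = c(GM = 700, SA = 260, CT = 0.28, IC = 0.05, MC = 0.03,
                 CI = 0.9, FI = 5))
}

#' Generate per-subject morphometric tables
#'
#' For each cohort subject, builds a regions x features matrix from the
#' generative model \code{archetype + lambda * network_latent + noise}: the
#' archetype is a fixed (seed-derived) regions x features matrix shared by all
#' subjects; every functional-network label in the atlas gets one latent
#' feature vector per subject, shared by the regions carrying that label; and
#' independent Gaussian noise is added. For subjects matching an
#' \code{effect_map} entry, lambda is multiplied by \code{1 - attenuation} in
#' the targeted network's regions, which lowers the expected within-network
#' inter-regional correlation. Each subject uses a deterministic RNG
#' sub-stream, so tables are independent of cohort ordering.
#'
#' @param cohort Cohort data.frame from [simulate_cohort()].
#' @param atlas Atlas data.frame; its row count must equal
#'   \code{config$n_regions}.
#' @param config The same [sim_config()] used for the cohort.
#' @return An object of class \code{msn_morphometry}: a named list (by
#'   \code{subject_id}) of numeric matrices with \code{region_id} rownames and
#'   the 7 feature columns \code{GM, SA, CT, IC, MC, CI, FI}.
#' @export
simulate_morphometry <- function(cohort, atlas, config) {
  if (!inherits(config, "msn_sim_config")) stop("'config' must come from sim_config()")
  if (nrow(cohort) == 0) stop("cohort is empty")
  if (nrow(atlas) != config$n_regions)
    stop("structural error: atlas has ", nrow(atlas),
         " regions but config expects ", config$n_regions)
  nR <- config$n_regions
  nF <- config$n_features
  feat_names <- if (nF == 7L) MSN_FEATURES else sprintf("F%02d", seq_len(nF))
  labels <- factor(atlas$functional_network)
  label_idx <- as.integer(labels)
  nL <- nlevels(labels)

  # coupling groups: functional networks forming one analysis subnetwork
  # (SN, CCN) share latent and network-archetype components with weight
  # sqrt(network_coupling); every other label stands alone
  group_of <- setNames(levels(labels), levels(labels))
  for (nw in builtin_networks()) {
    hit <- intersect(nw$members, levels(labels))
    group_of[hit] <- nw$name
  }
  groups <- unique(group_of)
  rho <- config$network_coupling
  gam <- config$archetype_coupling

  # archetype: fixed across subjects, drawn from sub-stream 0. A share `gam`
  # of its variance is a smooth network-level gradient: each functional
  # network's regions trace an arc between two anchor profiles, so
  # neighbouring regions of one network have near-identical expected feature
  # profiles (the cytoarchitectonic clustering/gradients that make real
  # within-network similarity stable and thresholded networks connected),
  # while profiles drift across the network.
  # spherical draws: random directions with fixed norm sqrt(nF), so no
  # region, network or arc segment is structurally weak just because a
  # 7-dimensional draw landed short
  sphere_rows <- function(M) M * sqrt(ncol(M)) / sqrt(rowSums(M^2))
  set.seed(derive_seed(config$seed, 0L))
  A_own <- sphere_rows(matrix(rnorm(nR * nF), nR, nF))
  V1_label <- matrix(rnorm(nL * nF), nL, nF)
  V2_label <- matrix(rnorm(nL * nF), nL, nF)
  V1_group <- matrix(rnorm(length(groups) * nF), length(groups), nF,
                     dimnames = list(groups, NULL))
  V2_group <- matrix(rnorm(length(groups) * nF), length(groups), nF,
                     dimnames = list(groups, NULL))
  gidx <- group_of[levels(labels)]
  V1 <- sphere_rows(sqrt(1 - rho) * V1_label + sqrt(rho) * V1_group[gidx, , drop = FALSE])
  V2 <- sphere_rows(sqrt(1 - rho) * V2_label + sqrt(rho) * V2_group[gidx, , drop = FALSE])
  # constant angular step (that of a 56-region network spanning a half-turn),
  # capped at a half-turn: large networks sweep the full profile arc while
  # small ones form tight clusters of near-identical profiles
  theta <- numeric(nR)
  for (l in seq_len(nL)) {
    idx <- which(label_idx == l)
    span <- min(pi, (length(idx) - 1) * pi / 55)
    theta[idx] <- seq(0, span, length.out = max(length(idx), 2L))[seq_along(idx)]
  }
  S <- cos(theta) * V1[label_idx, , drop = FALSE] +
    sin(theta) * V2[label_idx, , drop = FALSE]
  archetype <- config$archetype_sd * (sqrt(1 - gam) * A_own + sqrt(gam) * S)

  # pre-resolve effect targets once
  eff_idx <- lapply(config$effect_map, function(e) effect_region_index(e$network, atlas))

  aff <- feature_affine()
  loc <- if (nF == 7L) aff$loc else rep(0, nF)
  scl <- if (nF == 7L) aff$scale else rep(1, nF)

  out <- vector("list", nrow(cohort))
  for (s in seq_len(nrow(cohort))) {
    set.seed(derive_seed(config$seed, 1000000L + s))
    lam <- rep(config$latent_strength, nR)
    for (k in seq_along(config$effect_map)) {
      e <- config$effect_map[[k]]
      if (effect_subject_match(cohort[s, ], e$subset))
        lam[eff_idx[[k]]] <- lam[eff_idx[[k]]] * (1 - e$attenuation)
    }
    Cg <- matrix(rnorm(length(groups) * nF), length(groups), nF,
                 dimnames = list(groups, NULL))
    U <- sphere_rows(sqrt(1 - rho) * matrix(rnorm(nL * nF), nL, nF) +
                       sqrt(rho) * Cg[group_of[levels(labels)], , drop = FALSE])
    E <- matrix(rnorm(nR * nF, sd = config$noise_sd), nR, nF)
    X <- archetype + lam * U[label_idx, , drop = FALSE] + E
    X <- sweep(sweep(X, 2, scl, "*"), 2, loc, "+")
    dimnames(X) <- list(atlas$region_id, feat_names)
    out[[s]] <- X
  }
  names(out) <- cohort$subject_id
  structure(out, region_id = atlas$region_id, features = feat_names,
            class = "msn_morphometry")
}

#' @export
print.msn_morphometry <- function(x, ...) {
  cat("Morphometric tables for", length(x), "subject(s):",
      length(attr(x, "region_id")), "regions x",
      length(attr(x, "features")), "features\n")
  invisible(x)
}
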