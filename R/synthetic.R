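#' Configuration for a synthetic BCG vaccination cohort
#'
#' Defines the statistical structure of a simulated three-timepoint
#' (T0/T14/T90) whole-blood methylation cohort with stimulated cytokine
#' readouts, genotypes and auxiliary omics layers. Methylation is simulated
#' on the M (base-2 logit) scale and back-transformed, so beta values are
#' strictly inside (0, 1) and the beta/M transform is exact. Cell
#' composition confounding enters through per-sample Dirichlet fractions
#' mixed over cell-type reference profiles; plate batches add probe-specific
#' shifts.
#'
#' Effect blocks (all optional; `n = 0` disables a block):
#' * `trajectory`: probes whose M values shift at T14/T90 following one of
#'   the four response shapes `down_down`, `down_up`, `up_down`, `up_up`
#'   (sign pattern of the T14-T0 and T90-T0 changes).
#' * `n_ti_probes`: baseline probes whose T0 methylation feeds the
#'   trained-immunity outcome (variance fraction
#'   `variance_fractions["methylation"]`).
#' * `mediation`: (SNP, probe, cytokine) triplets generated as
#'   `m_change = a g + e1`, `ti += b m_change + c' g`, with true
#'   ACME `a b` and proportion mediated `a b / (a b + c')`.
#' * `n_sex_probes`: probes with a constant female-male offset.
#' * `n_seasonal_probes`: probes tracking an annual sinusoid of the
#'   collection date.
#'
#' @param n_subjects,n_probes,n_snps Cohort dimensions.
#' @param n_cell_types Leukocyte types in the reference panel (default 6).
#' @param n_batches Number of sample plates.
#' @param sex_ratio Fraction of female subjects.
#' @param trajectory List: `n_per_class` probes per shape and effect
#'   magnitudes `d14`, `d90` in M units.
#' @param n_ti_probes Baseline probes associated with the TI outcome.
#' @param n_sex_probes,sex_effect Sex-shift block (M units).
#' @param n_seasonal_probes,seasonal_amplitude Seasonal block (M units).
#' @param mediation List: `n_triplets`, coefficients `a`, `b`, `c_prime`,
#'   and mediator noise sd `noise1`.
#' @param variance_fractions Named vector of TI variance fractions for
#'   layers `methylation`, `metabolites`, `proteins`, `genetics`; the
#'   remainder is residual noise. Must sum to < 1.
#' @param n_prs_snps SNPs feeding the genetic TI component.
#' @param layers List: `n_proteins`, `n_metabolites`, `n_hormones`,
#'   `k_active` (features per layer that track the layer's latent).
#' @param resid_sd Per-observation M-value noise sd.
#' @param subject_sd Per-probe random subject-intercept sd (M units).
#' @param batch_sd Per-probe plate-shift sd (M units).
#' @param dirichlet_conc Concentration of the cell-fraction Dirichlet.
#' @param cytokine_batches,cytokine_batch_sd Cytokine assay batch structure
#'   (additive shifts on the log10 fold-change scale).
#' @param ti_cytokine Cytokine carrying the spiked TI structure.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 120,
                          n_probes = 2000,
                          n_snps = 200,
                          n_cell_types = 6,
                          n_batches = 4,
                          sex_ratio = 0.55,
                          trajectory = list(n_per_class = 10, d14 = 1.0,
                                            d90 = 1.0),
                          n_ti_probes = 10,
                          n_sex_probes = 10,
                          sex_effect = 1.0,
                          n_seasonal_probes = 0,
                          seasonal_amplitude = 0.5,
                          mediation = list(n_triplets = 5, a = 0.5, b = 0.4,
                                           c_prime = 0.3, noise1 = 0.3),
                          variance_fractions = c(methylation = 0.30,
                                                 metabolites = 0.10,
                                                 proteins = 0,
                                                 genetics = 0.05),
                          n_prs_snps = 10,
                          layers = list(n_proteins = 73, n_metabolites = 100,
                                        n_hormones = 5, k_active = 10),
                          resid_sd = 1.0,
                          subject_sd = 0.7,
                          batch_sd = 0.3,
                          dirichlet_conc = 30,
                          cytokine_batches = 2,
                          cytokine_batch_sd = 0.2,
                          ti_cytokine = "IFNg",
                          seed = 1) {
  cfg <- as.list(environment())
  cfg$timepoints <- c("T0", "T14", "T90")
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @export
cohort_config_defaults <- function() {
  unclass(cohort_config())
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(field, x, allow_zero = FALSE) {
    lo <- if (allow_zero) 0 else 1
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo ||
        x != round(x)) {
      stop("invalid config field '", field, "': must be an integer >= ", lo,
           call. = FALSE)
    }
  }
  chk_count("n_subjects", cfg$n_subjects)
  chk_count("n_probes", cfg$n_probes)
  chk_count("n_snps", cfg$n_snps)
  chk_count("n_cell_types", cfg$n_cell_types)
  chk_count("n_batches", cfg$n_batches)
  chk_count("trajectory$n_per_class", cfg$trajectory$n_per_class, TRUE)
  chk_count("n_ti_probes", cfg$n_ti_probes, TRUE)
  chk_count("n_sex_probes", cfg$n_sex_probes, TRUE)
  chk_count("n_seasonal_probes", cfg$n_seasonal_probes, TRUE)
  chk_count("mediation$n_triplets", cfg$mediation$n_triplets, TRUE)
  if (!identical(sort(cfg$timepoints), sort(c("T0", "T14", "T90")))) {
    stop("invalid config field 'timepoints': must be exactly T0, T14, T90",
         call. = FALSE)
  }
  n_spiked <- 4 * cfg$trajectory$n_per_class + cfg$n_ti_probes +
    cfg$n_sex_probes + cfg$n_seasonal_probes + cfg$mediation$n_triplets
  if (n_spiked > cfg$n_probes) {
    stop("invalid config: effect-block probe counts (", n_spiked,
         ") exceed n_probes (", cfg$n_probes, ")", call. = FALSE)
  }
  if (cfg$mediation$n_triplets + cfg$n_prs_snps > cfg$n_snps) {
    stop("invalid config field 'n_snps': fewer SNPs than spiked SNP blocks",
         call. = FALSE)
  }
  vf <- cfg$variance_fractions
  if (any(vf < 0) || sum(vf) >= 1) {
    stop("invalid config field 'variance_fractions': nonnegative, sum < 1",
         call. = FALSE)
  }
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) {
    stop("invalid config field 'sex_ratio': must lie in [0, 1]",
         call. = FALSE)
  }
  cfg
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

logit2 <- function(p) log2(p / (1 - p))
ilogit2 <- function(m) 1 / (1 + 2^(-m))

# Whole-blood-like mean fractions; first component plays the neutrophil role
# and dominates, mirroring real leukocyte composition.
cell_mean_props <- function(k) {
  base <- c(0.55, 0.15, 0.10, 0.10, 0.05, 0.05)
  if (k <= 6) {
    p <- base[seq_len(k)]
  } else {
    p <- c(base, rep(0.03, k - 6))
  }
  p / sum(p)
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates the full multi-omics cohort described by a [cohort_config()]:
#' a probes x samples beta matrix over three timepoints, a sample sheet,
#' true cell fractions, SNP dosages with positions, paired cytokine
#' concentrations, auxiliary layer tables, probe annotation, and a
#' `truth_ledger` recording every spiked effect.
#'
#' @param config A [cohort_config()].
#' @return List of class `bcg_cohort` with elements `betas`, `samples`,
#'   `cell_fractions`, `dosages` (list: `dosages` matrix, `snps` tibble),
#'   `cytokines`, `layers`, `annotation`, `reference` (cell-type beta
#'   profiles over marker probes), and `ledger`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)
  np <- cfg$n_probes
  ns <- cfg$n_subjects
  k <- cfg$n_cell_types
  tps <- c("T0", "T14", "T90")

  probe_ids <- sprintf("cg%07d", seq_len(np))
  subject_ids <- sprintf("S%03d", seq_len(ns))
  snp_ids <- sprintf("rs%06d", seq_len(cfg$n_snps))

  ## --- probe annotation: ordered positions per chromosome ----------------
  chrom <- sort(sample(1:22, np, replace = TRUE))
  position <- unlist(lapply(split(seq_len(np), chrom), function(ix) {
    sort(sample.int(2e8, length(ix)))
  }), use.names = FALSE)
  annotation <- tibble::tibble(
    probe_id = probe_ids,
    chromosome = as.character(chrom),
    position = position,
    nearest_gene = ifelse(stats::runif(np) < 0.8,
                          sprintf("GENE%d", seq_len(np)), "")
  )

  ## --- spiked probe assignment -------------------------------------------
  classes <- c("down_down", "down_up", "up_down", "up_up")
  n_traj <- cfg$trajectory$n_per_class
  idx <- seq_len(np)
  take <- function(n) {
    if (n == 0) return(integer(0))
    picked <- idx[seq_len(n)]
    idx <<- idx[-seq_len(n)]
    picked
  }
  traj_idx <- take(4 * n_traj)
  ti_idx <- take(cfg$n_ti_probes)
  sex_idx <- take(cfg$n_sex_probes)
  seas_idx <- take(cfg$n_seasonal_probes)
  med_idx <- take(cfg$mediation$n_triplets)

  sgn <- list(down_down = c(-1, -1), down_up = c(-1, 1),
              up_down = c(1, -1), up_up = c(1, 1))
  traj_tbl <- if (n_traj > 0) {
    cls <- rep(classes, each = n_traj)
    tibble::tibble(
      probe_id = probe_ids[traj_idx],
      class = cls,
      d14 = unname(vapply(cls, function(cl) sgn[[cl]][1], numeric(1))) *
        cfg$trajectory$d14,
      d90 = unname(vapply(cls, function(cl) sgn[[cl]][2], numeric(1))) *
        cfg$trajectory$d90
    )
  } else {
    tibble::tibble(probe_id = character(0), class = character(0),
                   d14 = numeric(0), d90 = numeric(0))
  }

  ## --- sample sheet -------------------------------------------------------
  sex <- ifelse(stats::runif(ns) < cfg$sex_ratio, "F", "M")
  age <- round(stats::rnorm(ns, 25, 10))
  age <- pmax(18, pmin(71, age))
  bmi <- round(stats::rnorm(ns, 22.5, 2.5), 1)
  smoking <- stats::runif(ns) < 0.2
  t0_date <- as.Date("2019-01-01") + sample.int(365, ns, replace = TRUE) - 1
  samples <- tidyr::expand_grid(subject_id = subject_ids, timepoint = tps) |>
    dplyr::mutate(
      sample_id = paste(.data$subject_id, .data$timepoint, sep = "_"),
      .before = 1
    )
  sub_ix <- match(samples$subject_id, subject_ids)
  samples$age <- age[sub_ix]
  samples$sex <- sex[sub_ix]
  samples$plate <- paste0("P", sample.int(cfg$n_batches, nrow(samples),
                                          replace = TRUE))
  offset <- c(T0 = 0, T14 = 14, T90 = 90)[samples$timepoint]
  samples$collection_date <- t0_date[sub_ix] + offset
  samples$bmi <- bmi[sub_ix]
  samples$smoking <- smoking[sub_ix]
  nsam <- nrow(samples)

  ## --- cell-type reference panel and fractions ----------------------------
  mu <- stats::rnorm(np, sample(c(-3, 0, 3), np, replace = TRUE,
                                prob = c(0.35, 0.3, 0.35)), 0.8)
  n_markers <- 10 * k
  marker_idx <- (np - n_markers + 1):np  # keep clear of effect blocks
  cell_shift <- matrix(0, np, k)
  for (j in seq_len(k)) {
    rows <- marker_idx[((j - 1) * 10 + 1):(j * 10)]
    cell_shift[rows, j] <- sample(c(-2.5, 2.5), 10, replace = TRUE)
  }
  # mild cell loading on all probes so composition confounds broadly
  cell_shift <- cell_shift + matrix(stats::rnorm(np * k, 0, 0.15), np, k)
  ref_m <- mu + cell_shift
  ref_beta <- ilogit2(ref_m)
  rownames(ref_beta) <- probe_ids
  colnames(ref_beta) <- c("Neu", "CD4T", "CD8T", "Mono", "Bcell",
                          "NK")[seq_len(min(k, 6))] |>
    (\(x) if (k > 6) c(x, paste0("CT", 7:k)) else x)()

  props <- cell_mean_props(k)
  tp_shift <- c(T0 = 0, T14 = 0.04, T90 = 0.01)  # neutrophil drift over time
  alpha_base <- cfg$dirichlet_conc * props
  frac <- matrix(0, nsam, k)
  for (i in seq_len(nsam)) {
    a <- alpha_base
    a[1] <- a[1] + cfg$dirichlet_conc * tp_shift[samples$timepoint[i]]
    frac[i, ] <- rdirichlet(1, a)
  }
  colnames(frac) <- colnames(ref_beta)
  cell_fractions <- dplyr::bind_cols(
    tibble::tibble(sample_id = samples$sample_id),
    tibble::as_tibble(frac)
  )

  ## --- methylation M values ----------------------------------------------
  # composition mixed linearly on the modelling (M) scale
  base_m <- ref_m %*% t(frac)                     # probes x samples
  subj_int <- matrix(stats::rnorm(np * ns, 0, cfg$subject_sd), np, ns)
  plate_levels <- sort(unique(samples$plate))
  plate_shift <- matrix(stats::rnorm(np * length(plate_levels), 0,
                                     cfg$batch_sd), np)
  m <- base_m +
    subj_int[, sub_ix] +
    plate_shift[, match(samples$plate, plate_levels)] +
    matrix(stats::rnorm(np * nsam, 0, cfg$resid_sd), np, nsam)

  # time effects (trajectory classes)
  if (n_traj > 0) {
    is_t14 <- samples$timepoint == "T14"
    is_t90 <- samples$timepoint == "T90"
    m[traj_idx, is_t14] <- m[traj_idx, is_t14] + traj_tbl$d14
    m[traj_idx, is_t90] <- m[traj_idx, is_t90] + traj_tbl$d90
  }
  # sex shifts
  if (cfg$n_sex_probes > 0) {
    is_f <- samples$sex == "F"
    m[sex_idx, is_f] <- m[sex_idx, is_f] + cfg$sex_effect
  }
  # seasonal probes
  if (cfg$n_seasonal_probes > 0) {
    phase <- sin(2 * pi * as.numeric(format(samples$collection_date, "%j")) /
                   365.25)
    m[seas_idx, ] <- m[seas_idx, ] +
      cfg$seasonal_amplitude * matrix(phase, cfg$n_seasonal_probes, nsam,
                                      byrow = TRUE)
  }

  ## --- genotypes ----------------------------------------------------------
  maf <- stats::runif(cfg$n_snps, 0.05, 0.5)
  dose <- matrix(stats::rbinom(cfg$n_snps * ns, 2, rep(maf, ns)),
                 nrow = cfg$n_snps)
  rownames(dose) <- snp_ids
  colnames(dose) <- subject_ids
  snp_chrom <- sample(1:22, cfg$n_snps, replace = TRUE)
  snp_pos <- sample.int(2e8, cfg$n_snps, replace = TRUE)
  # mediation SNPs are placed cis to their probe
  n_med <- cfg$mediation$n_triplets
  if (n_med > 0) {
    med_snp <- seq_len(n_med)
    snp_chrom[med_snp] <- as.integer(annotation$chromosome[med_idx])
    snp_pos[med_snp] <- pmax(1L, annotation$position[med_idx] +
                               sample(-2e5:2e5, n_med, replace = TRUE))
  }
  snps <- tibble::tibble(snp_id = snp_ids,
                         chromosome = as.character(snp_chrom),
                         position = as.integer(snp_pos))

  ## --- mediation: SNP -> DNAm change (T90) --------------------------------
  med <- cfg$mediation
  med_tbl <- tibble::tibble(snp_id = character(0), probe_id = character(0),
                            cytokine = character(0), a = numeric(0),
                            b = numeric(0), c_prime = numeric(0),
                            true_acme = numeric(0),
                            true_prop_mediated = numeric(0))
  ti_med_term <- rep(0, ns)
  if (n_med > 0) {
    is_t90 <- samples$timepoint == "T90"
    for (t in seq_len(n_med)) {
      g <- dose[t, ]
      m_change <- med$a * g + stats::rnorm(ns, 0, med$noise1)
      m[med_idx[t], is_t90] <- m[med_idx[t], is_t90] + m_change[sub_ix[is_t90]]
      # centred contributions: same coefficients, no gross mean shift of TI
      ti_med_term <- ti_med_term + med$b * (m_change - mean(m_change)) +
        med$c_prime * (g - mean(g))
    }
    med_tbl <- tibble::tibble(
      snp_id = snp_ids[seq_len(n_med)],
      probe_id = probe_ids[med_idx],
      cytokine = cfg$ti_cytokine,
      a = med$a, b = med$b, c_prime = med$c_prime,
      true_acme = med$a * med$b,
      true_prop_mediated = med$a * med$b / (med$a * med$b + med$c_prime)
    )
  }

  ## --- trained-immunity outcome and layer tables --------------------------
  vf <- cfg$variance_fractions
  # methylation latent: weighted baseline M of the TI probes, standardised
  ti_w <- if (cfg$n_ti_probes > 0) {
    sample(c(-1, 1), cfg$n_ti_probes, replace = TRUE) *
      stats::runif(cfg$n_ti_probes, 0.5, 1)
  } else {
    numeric(0)
  }
  t0_cols <- samples$timepoint == "T0"
  z_meth <- if (cfg$n_ti_probes > 0) {
    m0 <- m[ti_idx, t0_cols, drop = FALSE]
    z <- drop(ti_w %*% m0)
    (z - mean(z)) / stats::sd(z)
  } else {
    rep(0, ns)
  }
  z_metab <- stats::rnorm(ns)
  z_prot <- stats::rnorm(ns)
  prs_w <- stats::rnorm(cfg$n_prs_snps)
  prs_snps <- snp_ids[(n_med + 1):(n_med + cfg$n_prs_snps)]
  z_gen_raw <- drop(prs_w %*% dose[prs_snps, , drop = FALSE])
  z_gen <- (z_gen_raw - mean(z_gen_raw)) / stats::sd(z_gen_raw)

  noise_frac <- 1 - sum(vf)
  ti_latent <- sqrt(vf[["methylation"]]) * z_meth +
    sqrt(vf[["metabolites"]]) * z_metab +
    sqrt(vf[["proteins"]]) * z_prot +
    sqrt(vf[["genetics"]]) * z_gen +
    sqrt(noise_frac) * stats::rnorm(ns)
  ti_scale <- 0.4   # sd of the log10 fold change
  ti_by_cytokine <- list()
  for (cy in c("TNFa", "IL1b", "IL6", "IFNg")) {
    ti_by_cytokine[[cy]] <- if (cy == cfg$ti_cytokine) {
      ti_scale * ti_latent + ti_med_term
    } else {
      ti_scale * stats::rnorm(ns)
    }
  }

  cyto_batch <- paste0("CB", sample.int(cfg$cytokine_batches, ns,
                                        replace = TRUE))
  batch_delta <- stats::rnorm(cfg$cytokine_batches, 0, cfg$cytokine_batch_sd)
  cytokines <- purrr::map_dfr(names(ti_by_cytokine), function(cy) {
    c0 <- 10^stats::rnorm(ns, 2, 0.3)
    log_fc <- ti_by_cytokine[[cy]] +
      batch_delta[as.integer(sub("CB", "", cyto_batch))]
    tibble::tibble(subject_id = subject_ids, cytokine = cy,
                   conc_T0 = c0, conc_T90 = c0 * 10^log_fc,
                   batch = cyto_batch)
  })

  make_layer <- function(n_feat, latent, v, prefix) {
    if (n_feat == 0) return(NULL)
    k_act <- if (v > 0) min(cfg$layers$k_active, n_feat) else 0
    x <- matrix(stats::rnorm(ns * n_feat), ns, n_feat)
    if (k_act > 0) {
      for (j in seq_len(k_act)) x[, j] <- latent + stats::rnorm(ns, 0, 0.7)
    }
    colnames(x) <- sprintf("%s%03d", prefix, seq_len(n_feat))
    rownames(x) <- subject_ids
    x
  }
  layers <- list(
    proteins = make_layer(cfg$layers$n_proteins, z_prot,
                          vf[["proteins"]], "PROT"),
    metabolites = make_layer(cfg$layers$n_metabolites, z_metab,
                             vf[["metabolites"]], "MET"),
    hormones = make_layer(cfg$layers$n_hormones, 0, 0, "HORM"),
    cell_counts = frac
  )

  ## --- assemble -----------------------------------------------------------
  betas <- ilogit2(m)
  rownames(betas) <- probe_ids
  colnames(betas) <- samples$sample_id
  attr(betas, "scale") <- "beta"

  ti_assoc <- if (cfg$n_ti_probes > 0) {
    m0 <- m[ti_idx, t0_cols, drop = FALSE]
    z_sd <- stats::sd(drop(ti_w %*% m0))
    tibble::tibble(probe_id = probe_ids[ti_idx],
                   cytokine = cfg$ti_cytokine,
                   coef = ti_scale * sqrt(vf[["methylation"]]) * ti_w / z_sd)
  } else {
    tibble::tibble(probe_id = character(0), cytokine = character(0),
                   coef = numeric(0))
  }

  ledger <- structure(list(
    trajectory = traj_tbl,
    ti_assoc = ti_assoc,
    sex_probes = tibble::tibble(probe_id = probe_ids[sex_idx],
                                effect = rep(cfg$sex_effect,
                                             length(sex_idx))),
    seasonal_probes = tibble::tibble(probe_id = probe_ids[seas_idx],
                                     amplitude = rep(cfg$seasonal_amplitude,
                                                     length(seas_idx))),
    mediation = med_tbl,
    prs = tibble::tibble(snp_id = prs_snps, weight = prs_w),
    variance_fractions = tibble::tibble(
      layer = c(names(vf), "noise"),
      fraction = c(unname(vf), noise_frac)
    ),
    reference = ref_beta[marker_idx, , drop = FALSE],
    config = cfg
  ), class = "truth_ledger")

  structure(list(
    betas = betas,
    samples = samples,
    cell_fractions = cell_fractions,
    dosages = list(dosages = dose, snps = snps),
    cytokines = cytokines,
    layers = layers,
    annotation = annotation,
    reference = ref_beta[marker_idx, , drop = FALSE],
    ledger = ledger
  ), class = "bcg_cohort")
}

#' Generate a replication cohort sharing a discovery ledger's effects
#'
#' Draws an independent, smaller cohort (default 17 subjects, T0 and T90
#' only) whose spiked trajectory and TI effects reuse the discovery
#' ledger's directions and magnitudes, with fresh subjects and noise.
#'
#' @param cohort A `bcg_cohort` from [generate_cohort()] (its ledger is
#'   reused).
#' @param n_subjects Replication sample size (default 17).
#' @param seed Seed for the replication draw (default: discovery seed + 1).
#' @return List of class `bcg_cohort` with elements `betas`, `samples`,
#'   `cytokines` (and the shared `ledger`), timepoints T0 and T90 only.
#' @export
generate_replication <- function(cohort, n_subjects = 17, seed = NULL) {
  if (!inherits(cohort, "bcg_cohort") || is.null(cohort$ledger)) {
    stop("need a bcg_cohort with a truth ledger", call. = FALSE)
  }
  cfg <- cohort$ledger$config
  cfg$n_subjects <- n_subjects
  cfg$seed <- if (is.null(seed)) cfg$seed + 1L else seed
  rep_cohort <- generate_cohort(cfg)
  keep <- rep_cohort$samples$timepoint %in% c("T0", "T90")
  rep_cohort$samples <- rep_cohort$samples[keep, , drop = FALSE]
  sc <- attr(rep_cohort$betas, "scale")
  rep_cohort$betas <- rep_cohort$betas[, rep_cohort$samples$sample_id,
                                       drop = FALSE]
  attr(rep_cohort$betas, "scale") <- sc
  rep_cohort$cell_fractions <- rep_cohort$cell_fractions[
    rep_cohort$cell_fractions$sample_id %in% rep_cohort$samples$sample_id, ]
  rep_cohort$ledger <- cohort$ledger
  rep_cohort
}
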