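#' Configuration for the synthetic multi-cohort simulator
#'
#' Defines a three-stage study (benign -> primary -> metastatic) with a
#' planted co-expression module whose internal correlation strengthens with
#' stage, a steroid-hormone-receptor (SHR) axis positively coupled to the
#' module, an AR axis that is un- (or anti-) correlated with it, log-normal
#' TPM margins, and group-dependent exponential survival with claims-gap
#' censoring.
#'
#' Defaults mirror the study conditions: stage sample sizes 245 / 493 / 208
#' (benign, primary, metastatic cohorts), module correlations 0.1 / 0.4 /
#' 0.8, an SHR cross-correlation of 0.5 at the strongest stage (scaled down
#' in proportion to the stage's module correlation, echoing how hormone-
#' receptor coupling strengthens with disease stage), and claims every 30
#' days so the 100-day gap rule is exercised with margin.
#'
#' Correlation targets are specified on the latent Gaussian scale of a
#' Gaussian copula; each stage's target matrix is validated for positive
#' semi-definiteness at construction.
#'
#' @param n_genes Total genes including the named axes (default 200).
#' @param n_samples Named integer vector per stage.
#' @param module_genes Planted module gene names (default the APUC-6 set).
#' @param module_rho Named per-stage within-module latent correlation.
#' @param shr_genes SHR axis gene names (default ESR1, ESR2, PGR).
#' @param shr_rho Module-SHR cross-correlation at the max-rho stage.
#' @param ar_genes AR axis gene names.
#' @param ar_rho Module-AR cross-correlation (default 0).
#' @param shr_internal,ar_internal Within-axis correlation of the SHR and AR
#'   blocks (default 0.5; set to 0 for a module-only cohort).
#' @param meanlog,sdlog Log-normal location/scale of latent expression.
#' @param hazards Named monthly event rates per patient group (> 0 allowed to
#'   be 0 for a group that never dies).
#' @param censor_rate Target fraction of censored patients (sets the
#'   repository cutoff).
#' @param claims_interval_days Days between consecutive claims.
#' @param gap_days Claims-gap death-imputation threshold.
#' @param seed Base seed; every generator output is a pure function of
#'   (config, seed).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L,
                       n_samples = c(benign = 245L, primary = 493L, metastatic = 208L),
                       module_genes = c(
                         "HSD3B1", "HSD3B2", "CYP11A1",
                         "CYP11B1", "CYP17A1", "CYP3A43"
                       ),
                       module_rho = c(benign = 0.1, primary = 0.4, metastatic = 0.8),
                       shr_genes = c("ESR1", "ESR2", "PGR"),
                       shr_rho = 0.5,
                       ar_genes = c("AR", "FOXA1", "HOXB13", "GRHL2", "EP300"),
                       ar_rho = 0.0,
                       shr_internal = 0.5, ar_internal = 0.5,
                       meanlog = 1.5, sdlog = 1.0,
                       hazards = c(
                         APUC6hi_ARlo = 0.02, APUC6lo_ARhi = 0.04,
                         APUC6hi_ARhi = 0.03, APUC6lo_ARlo = 0.03,
                         UNASSIGNED = 0.03, NEPC = 0.08
                       ),
                       censor_rate = 0.3,
                       claims_interval_days = 30L,
                       gap_days = 100L,
                       seed = 11L) {
  stages <- names(n_samples)
  if (is.null(stages) || !setequal(stages, names(module_rho))) {
    stop("n_samples and module_rho must be named by the same stages")
  }
  named <- c(module_genes, shr_genes, ar_genes)
  if (anyDuplicated(named)) stop("module/shr/ar gene names overlap")
  if (n_genes < length(named) + 4L) stop("n_genes too small for the named axes")
  if (any(module_rho < 0 | module_rho >= 1)) stop("module_rho must be in [0, 1)")
  if (any(hazards < 0)) stop("hazards must be >= 0")
  if (!(censor_rate > 0 && censor_rate < 1)) stop("censor_rate must be in (0, 1)")
  if (claims_interval_days <= 0) stop("claims_interval_days must be positive")
  cfg <- structure(
    list(
      n_genes = as.integer(n_genes), n_samples = n_samples,
      module_genes = module_genes, module_rho = module_rho,
      shr_genes = shr_genes, shr_rho = shr_rho,
      ar_genes = ar_genes, ar_rho = ar_rho,
      shr_internal = shr_internal, ar_internal = ar_internal,
      meanlog = meanlog, sdlog = sdlog,
      hazards = hazards, censor_rate = censor_rate,
      claims_interval_days = as.integer(claims_interval_days),
      gap_days = as.integer(gap_days),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  for (st in stages) target_sigma(cfg, st) # PSD validation at construction
  cfg
}

# Latent correlation target for one stage. Blocks: module (rho_stage), SHR
# (0.5 internal), AR axis (0.5 internal); module-SHR cross scaled with the
# stage's module strength; module-AR cross = ar_rho; background independent.
target_sigma <- function(cfg, stage) {
  rho <- cfg$module_rho[[stage]]
  genes <- sim_gene_names(cfg)
  g <- length(genes)
  S <- diag(1, g)
  dimnames(S) <- list(genes, genes)
  blk <- function(ids, r) {
    S[ids, ids] <<- r
    S[cbind(ids, ids)] <<- 1
  }
  blk(cfg$module_genes, rho)
  blk(cfg$shr_genes, cfg$shr_internal)
  blk(cfg$ar_genes, cfg$ar_internal)
  max_rho <- max(cfg$module_rho)
  cross_shr <- if (max_rho > 0) cfg$shr_rho * rho / max_rho else 0
  S[cfg$module_genes, cfg$shr_genes] <- cross_shr
  S[cfg$shr_genes, cfg$module_genes] <- cross_shr
  S[cfg$module_genes, cfg$ar_genes] <- cfg$ar_rho
  S[cfg$ar_genes, cfg$module_genes] <- cfg$ar_rho
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("stage '", stage, "' correlation target is not positive semi-definite")
  }
  S
}

sim_gene_names <- function(cfg) {
  named <- c(cfg$module_genes, cfg$shr_genes, cfg$ar_genes)
  c(named, sprintf("BG%04d", seq_len(cfg$n_genes - length(named))))
}

#' Generate one stage's expression matrix
#'
#' Draws a latent Gaussian with the stage's block-correlation target,
#' exponentiates to log-normal margins (Gaussian copula: monotone transform,
#' so latent rank correlations survive), and rescales every sample column to
#' sum to 1e6 TPM. Deterministic for a given (config, seed).
#'
#' @param cfg A [sim_config].
#' @param stage Stage name (a name of `cfg$n_samples`).
#' @param seed Optional seed override (defaults to `cfg$seed` + stage index).
#' @return An [expr_matrix] with `unit = "TPM"`.
#' @export
generate_expression <- function(cfg, stage, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!stage %in% names(cfg$n_samples)) stop("unknown stage: ", stage)
  if (is.null(seed)) seed <- cfg$seed + match(stage, names(cfg$n_samples))
  S <- target_sigma(cfg, stage)
  n <- cfg$n_samples[[stage]]
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, nrow(S)), Sigma = S)
  X <- t(exp(cfg$meanlog + cfg$sdlog * Z)) # genes x samples, log-normal
  X <- sweep(X, 2, colSums(X), "/") * 1e6
  dimnames(X) <- list(rownames(S), sprintf("%s_S%03d", stage, seq_len(n)))
  expr_matrix(X, "TPM")
}

#' Generate a claims-based clinical table for labeled patients
#'
#' Each patient draws an exponential death time at their group's monthly
#' hazard. The repository cutoff is set at the (1 - censor_rate) quantile of
#' the cohort's pooled survival distribution; patients alive at cutoff keep
#' filing claims every `claims_interval_days` until the cutoff and are
#' censored at their last claim. The simulator applies a data-maturity
#' margin: deaths falling within `gap_days + claims_interval_days + 1` days
#' of the cutoff are not yet ascertainable from a claims gap and are treated
#' as alive at cutoff, so the >gap-days rule recovers the recorded event flag
#' for every patient.
#'
#' @param cfg A [sim_config].
#' @param group_labels Named character vector: sample id -> group; every group
#'   must have a hazard in `cfg$hazards`.
#' @param day0 Day-0 anchor date for all patients.
#' @param seed Optional seed override (defaults to `cfg$seed + 101`).
#' @return Clinical `data.frame`: `sample_id`, `os_months`, `event`, `group`,
#'   `biopsy_site`, `histology`, `hormone_status`, and a `claim_dates`
#'   list-column; attribute `data_cutoff` holds the repository cutoff date.
#' @export
generate_clinical <- function(cfg, group_labels, day0 = as.Date("2018-01-01"),
                              seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(names(group_labels))) stop("group_labels must be named by sample id")
  unknown <- setdiff(unique(group_labels), names(cfg$hazards))
  if (length(unknown)) stop("group(s) without a hazard: ", paste(unknown, collapse = ", "))
  if (is.null(seed)) seed <- cfg$seed + 101L
  set.seed(seed)
  n <- length(group_labels)
  rate <- cfg$hazards[group_labels]
  # death months; rate 0 -> never dies
  death_m <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-12)), Inf)
  mean_rate <- mean(rate[rate > 0])
  cutoff_m <- if (is.finite(mean_rate) && mean_rate > 0) {
    stats::qexp(1 - cfg$censor_rate, rate = mean_rate)
  } else {
    60
  }
  cutoff_day <- ceiling(cutoff_m * 30.44)
  lag_days <- cfg$gap_days + cfg$claims_interval_days + 1L
  death_day <- floor(death_m * 30.44)
  is_event <- death_day <= cutoff_day - lag_days
  end_day <- ifelse(is_event, death_day, cutoff_day)
  step <- cfg$claims_interval_days
  claims <- lapply(end_day, function(d) day0 + seq(0L, d, by = step))
  last_day <- vapply(claims, function(cl) as.numeric(max(cl) - day0), numeric(1))
  sites <- c("prostate", "bone", "lymph node", "liver", "bladder", "lung", "brain", "adrenal")
  out <- data.frame(
    sample_id = names(group_labels),
    os_months = last_day / 30.44,
    event = as.integer(is_event),
    group = unname(group_labels),
    biopsy_site = sample(sites, n, replace = TRUE, prob = c(4, 2, 2, 1, 1, 1, 0.2, 0.2)),
    histology = ifelse(group_labels == "NEPC", "NEPC", "adenocarcinoma"),
    hormone_status = sample(c("sensitive", "castration-resistant"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  out$claim_dates <- claims
  attr(out, "data_cutoff") <- day0 + cutoff_day
  out
}

#' Write a self-contained synthetic study bundle
#'
#' Generates the three stage expression matrices, scores the metastatic stage
#' (sum-log APUC-6 signature and single-gene AR score), derives four-way
#' patient groups, simulates claims-based survival for them, and writes
#' everything as plain text: `expr_<stage>.tsv` per stage, `clinical.tsv`,
#' and `gene_sets.gmt` (module, SHR and AR-axis sets).
#'
#' @param cfg A [sim_config].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the in-memory objects.
#' @export
generate_study_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- names(cfg$n_samples)
  exprs <- lapply(stages, function(st) generate_expression(cfg, st))
  names(exprs) <- stages
  paths <- list()
  for (st in stages) {
    paths[[paste0("expr_", st)]] <- file.path(dir, paste0("expr_", st, ".tsv"))
    write_expression(exprs[[st]], paths[[paste0("expr_", st)]])
  }
  met <- exprs[[length(exprs)]]
  apuc <- sumlog_score(met, cfg$module_genes, "APUC6")
  ar <- sumlog_score(met, cfg$ar_genes[1], "AR")
  groups <- four_group_labels(apuc, ar, pct = 0.25)
  clin <- generate_clinical(cfg, groups)
  paths$clinical <- file.path(dir, "clinical.tsv")
  write_clinical(clin, paths$clinical)
  sets <- list(APUC6 = cfg$module_genes, SHR = cfg$shr_genes, AR_axis = cfg$ar_genes)
  paths$gene_sets <- file.path(dir, "gene_sets.gmt")
  write_gene_sets(sets, paths$gene_sets)
  invisible(list(
    paths = paths, expressions = exprs, clinical = clin,
    groups = groups, gene_sets = sets
  ))
}
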