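#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the latent statistical structure the CFR analysis
#' assumes: per-sample infiltration fractions for each cell type, positively
#' correlated between the CD8 and CAF compartments (bulk cohorts report a
#' correlation near 0.4 between fibroblast and immune scores); expression of a
#' cell type's signature genes shifted by its latent fraction; survival whose
#' hazard decreases with the latent CD8-CAF difference; and response whose
#' odds increase with it.
#'
#' Latents are standard bivariate Gaussians mapped through the logistic
#' function so "infiltration fractions" live in (0, 1). Survival is Weibull
#' (shape 1 = exponential by default) with uniform administrative censoring.
#'
#' @param n_samples Cohort size (default 500).
#' @param n_background_genes Unregulated genes (default 1000).
#' @param signature_size Genes per cell-type signature (default 30; scalar or
#'   one per cell type).
#' @param cell_types Latent cell types; must include `"CAF"`; the first
#'   non-CAF entry plays the CD8 role (default `c("CD8 T cells", "CAF")`).
#' @param rho Latent correlation between the CD8 and CAF fractions, in
#'   (-1, 1); default 0.4.
#' @param beta Expression shift per unit latent fraction (default 2).
#' @param noise_sd Gaussian expression noise sd (default 1, so beta/noise = 2).
#' @param baseline Baseline expression level (default 5).
#' @param latent_mean Mean of the Gaussian latents before the logistic map
#'   (scalar or one per cell type; default 0).
#' @param weibull_shape,weibull_scale Baseline survival Weibull parameters
#'   (default shape 1, scale 24 months).
#' @param gamma Log-hazard effect of the latent CD8-CAF difference; positive
#'   values are protective (default 2).
#' @param censor_horizon Administrative censoring horizon in months; censoring
#'   times are uniform on (0, horizon) (default 60).
#' @param eta0,eta1 Logistic intercept and slope of response on the latent
#'   CD8-CAF difference (default -1 and 2).
#' @param tps_slope Strength of the (weak) link between the simulated PD-L1
#'   tumor proportion score and the latent difference (default 1).
#' @param seed Global seed; per-component substreams are derived from it.
#' @return A validated list of class `GeneratorConfig`.
#' @export
generator_config <- function(n_samples = 500, n_background_genes = 1000,
                             signature_size = 30,
                             cell_types = c("CD8 T cells", "CAF"),
                             rho = 0.4, beta = 2, noise_sd = 1, baseline = 5,
                             latent_mean = 0,
                             weibull_shape = 1, weibull_scale = 24,
                             gamma = 2, censor_horizon = 60,
                             eta0 = -1, eta1 = 2, tps_slope = 1, seed = 1L) {
  if (!"CAF" %in% cell_types)
    stop("cell_types must include 'CAF'", call. = FALSE)
  if (length(cell_types) < 2L)
    stop("need at least one immune cell type besides CAF", call. = FALSE)
  if (anyDuplicated(cell_types)) stop("duplicate cell types", call. = FALSE)
  if (!(rho > -1 && rho < 1)) stop("rho must be in (-1, 1)", call. = FALSE)
  if (beta < 0 || noise_sd <= 0)
    stop("beta must be >= 0 and noise_sd > 0", call. = FALSE)
  if (n_samples < 10) stop("n_samples too small", call. = FALSE)
  signature_size <- rep_len(as.integer(signature_size), length(cell_types))
  if (any(signature_size < 2))
    stop("signature_size must be >= 2", call. = FALSE)
  latent_mean <- rep_len(as.numeric(latent_mean), length(cell_types))
  if (weibull_shape <= 0 || weibull_scale <= 0 || censor_horizon <= 0)
    stop("survival parameters must be positive", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^30)
    stop("seed must be an integer below 2^30", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_background_genes = as.integer(n_background_genes),
                 signature_size = stats::setNames(signature_size, cell_types),
                 cell_types = cell_types, rho = rho, beta = beta,
                 noise_sd = noise_sd, baseline = baseline,
                 latent_mean = stats::setNames(latent_mean, cell_types),
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale, gamma = gamma,
                 censor_horizon = censor_horizon, eta0 = eta0, eta1 = eta1,
                 tps_slope = tps_slope, seed = seed),
            class = "GeneratorConfig")
}

# deterministic substream seeds below 2^31
.substream <- function(seed, k) (as.integer(seed) * 7L + k * 1009L) %% 2147483647L

#' Simulate a synthetic cohort
#'
#' Draws latent infiltration fractions, a genes x samples expression matrix
#' (signature genes shifted by their cell type's latent, floored at zero,
#' against a background of unregulated genes), survival times (Weibull with
#' log-hazard offset `-gamma * (a_CD8 - a_CAF)`, administratively censored),
#' binary response (`Bernoulli(plogis(eta0 + eta1 * (a_CD8 - a_CAF)))`) with
#' a derived RECIST category, and a simulated PD-L1 tumor proportion score.
#' The full latent truth table is returned so recovery can be tested.
#'
#' @param cfg A [generator_config()].
#' @return List of class `SyntheticCohort`: `expression` (matrix),
#'   `clinical` (data frame: sample_id, time, event, response, recist, tps),
#'   `truth` (data frame of latents incl. `delta = a_cd8 - a_caf`),
#'   `registry` (the generating [signature_registry()]), `config`.
#' @export
simulate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  n <- cfg$n_samples
  types <- cfg$cell_types
  cd8_type <- setdiff(types, "CAF")[1L]
  sample_ids <- sprintf("S%04d", seq_len(n))

  # latents: CD8 and CAF bivariate with correlation rho; other types iid
  set.seed(.substream(cfg$seed, 1L))
  z <- matrix(stats::rnorm(n * length(types)), n, length(types),
              dimnames = list(sample_ids, types))
  z[, "CAF"] <- cfg$rho * z[, cd8_type] +
    sqrt(1 - cfg$rho^2) * z[, "CAF"]
  z <- sweep(z, 2, cfg$latent_mean[types], "+")
  a <- stats::plogis(z)

  # expression: signature genes carry their type's latent; background does not
  tag <- function(nm) gsub("[^A-Za-z0-9]", "", nm)
  sig_genes <- lapply(types, function(ct)
    sprintf("SYN%s_g%03d", tag(ct), seq_len(cfg$signature_size[[ct]])))
  names(sig_genes) <- types
  bg_genes <- sprintf("BG_g%04d", seq_len(cfg$n_background_genes))
  all_genes <- c(unlist(sig_genes, use.names = FALSE), bg_genes)
  set.seed(.substream(cfg$seed, 2L))
  expr <- matrix(stats::rnorm(length(all_genes) * n, sd = cfg$noise_sd),
                 length(all_genes), n,
                 dimnames = list(all_genes, sample_ids))
  expr <- expr + cfg$baseline
  for (ct in types)
    expr[sig_genes[[ct]], ] <- expr[sig_genes[[ct]], ] +
      matrix(cfg$beta * a[, ct], length(sig_genes[[ct]]), n, byrow = TRUE)
  expr <- pmax(expr, 0)

  delta <- a[, cd8_type] - a[, "CAF"]

  # survival: S(t | delta) = exp(-(t/scale)^shape * exp(-gamma * delta))
  set.seed(.substream(cfg$seed, 3L))
  u <- stats::runif(n)
  t_event <- cfg$weibull_scale *
    (-log(u) * exp(cfg$gamma * delta))^(1 / cfg$weibull_shape)
  c_time <- stats::runif(n, 0, cfg$censor_horizon)
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)

  set.seed(.substream(cfg$seed, 4L))
  p_resp <- stats::plogis(cfg$eta0 + cfg$eta1 * delta)
  response <- stats::rbinom(n, 1L, p_resp)
  # RECIST: responders are PR (CR rare at bulk scale); non-responders split
  # 60/40 into SD/PD, roughly the stable-disease predominance of ICI cohorts
  recist <- ifelse(response == 1L, "PR",
                   ifelse(stats::runif(n) < 0.6, "SD", "PD"))
  tps <- 100 * stats::plogis(cfg$tps_slope * 4 * delta + stats::rnorm(n))

  clinical <- data.frame(sample_id = sample_ids, time = time, event = event,
                         response = response, recist = recist,
                         tps = tps, row.names = NULL,
                         stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (ct in types) truth[[paste0("a_", tag(ct))]] <- a[, ct]
  truth$delta <- delta
  truth$p_response <- p_resp

  registry <- signature_registry(lapply(types, function(ct)
    gene_signature(ct, sig_genes[[ct]],
                   source = sprintf("synthetic generator (seed %d)",
                                    cfg$seed))))

  structure(list(expression = expr, clinical = clinical, truth = truth,
                 registry = registry, config = cfg),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("<SyntheticCohort> %d samples, %d genes, %d cell types, seed %d\n",
              ncol(x$expression), nrow(x$expression),
              length(x$config$cell_types), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort in the formats the pipeline reads
#'
#' Expression as TSV, clinical and latent-truth tables as TSV, generating
#' signatures as GMT — so a full pipeline run on synthetic data needs no
#' special casing.
#'
#' @param sim A `SyntheticCohort`.
#' @param dir Output directory (created if needed).
#' @param gct Also write the expression matrix as GCT 1.2.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir, gct = FALSE) {
  stopifnot(inherits(sim, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"),
             gmt = file.path(dir, "signatures.synthetic.gmt"))
  write_expression_tsv(sim$expression, paths[["expression"]])
  utils::write.table(sim$clinical, paths[["clinical"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(sim$registry, paths[["gmt"]])
  if (gct) {
    paths[["gct"]] <- file.path(dir, "expression.gct")
    write_gct(sim$expression, paths[["gct"]])
  }
  invisible(paths)
}

#' Simulate a per-tumor-type CFR / response-rate panel
#'
#' Draws one independent cohort per tumor type (type-level location shifts on
#' the CD8 latent spread the mean CFR across types) and a per-type objective
#' response rate from a binomial whose probability is a monotone link of the
#' type's mean latent CFR. Emulates the cross-tumor-type CFR-vs-ORR analysis.
#'
#' @param cfgs List of [generator_config()]s, one per type (>= 4); or use
#'   `n_types` to build default configs with CD8 latent means spread over
#'   `c(-1.5, 1.5)`.
#' @param orr_link Monotone function mapping mean latent CFR to response
#'   probability; default `plogis(-1 + 3 * m)`.
#' @param n_patients Patients per type for the binomial ORR draw (default 50;
#'   `Inf` gives the noise-free link value).
#' @param n_types Number of types when `cfgs` is `NULL` (default 20).
#' @param seed Seed governing the panel.
#' @return Data frame: `tumor_type`, `mean_cfr` (mean latent difference),
#'   `orr`, `n_patients`.
#' @export
simulate_tumor_type_panel <- function(cfgs = NULL,
                                      orr_link = function(m) stats::plogis(-1 + 3 * m),
                                      n_patients = 50, n_types = 20,
                                      seed = 1L) {
  if (is.null(cfgs)) {
    shifts <- seq(-1.5, 1.5, length.out = n_types)
    cfgs <- lapply(seq_len(n_types), function(i)
      generator_config(n_samples = 100, n_background_genes = 50,
                       latent_mean = c(shifts[i], 0),
                       seed = .substream(seed, 100L + i)))
  }
  if (length(cfgs) < 4L) stop("need at least 4 tumor types", call. = FALSE)
  set.seed(.substream(seed, 99L))
  orr_seeds <- sample.int(1e6, length(cfgs))
  out <- do.call(rbind, lapply(seq_along(cfgs), function(i) {
    sim <- simulate_cohort(cfgs[[i]])
    m <- mean(sim$truth$delta)
    p <- orr_link(m)
    set.seed(orr_seeds[i])
    orr <- if (is.infinite(n_patients)) p
           else stats::rbinom(1L, n_patients, p) / n_patients
    data.frame(tumor_type = sprintf("T%02d", i), mean_cfr = m, orr = orr,
               n_patients = n_patients, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
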