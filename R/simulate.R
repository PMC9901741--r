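#' Configuration for the synthetic tumour-cohort generator
#'
#' The generator emulates the statistical structure the A/I analysis
#' assumes: bulk expression with cell-type marker structure on top of a
#' log-normal background, immune infiltration whose adaptive/innate
#' balance follows a latent per-patient skew that differs between genders,
#' exponential proportional-hazards survival linked to that skew, and an
#' ordinal (CR/PR/SD/PD) therapy response. It makes no attempt to match
#' real gene-gene correlation structure or cancer-type frequencies.
#'
#' @param n_samples Number of samples.
#' @param n_background_genes Non-marker genes drawn from background only.
#' @param panel Marker panel defining cell types and compartments.
#' @param gender_mix Fraction of female samples.
#' @param adaptive_skew_effect Shift of the mean latent adaptive skew in
#'   females relative to males (males ~ N(0, 1), females ~ N(shift, 1)).
#' @param infiltration_scale Mean total infiltration fraction (0 gives
#'   cell-line mode: marker genes reduce to pure background).
#' @param infiltration_sd Log-scale SD of per-sample total infiltration.
#' @param celltype_signal TPM contributed to a marker gene per unit
#'   infiltration fraction of its cell type.
#' @param bg_meanlog,bg_sdlog Log-normal baseline TPM parameters shared by
#'   marker and background genes.
#' @param noise_sd Log-normal multiplicative expression noise SD (natural
#'   log scale).
#' @param beta_ai Log-hazard coefficient on the centred latent skew
#'   (negative = higher adaptive balance is protective).
#' @param baseline_hazard Exponential baseline event rate per day.
#' @param censor_rate Independent exponential censoring rate per day.
#' @param pfi_factor Fixed factor by which progression precedes death in
#'   the shared event-time truth.
#' @param response_slope Ordinal-logit slope of response on the centred
#'   latent skew.
#' @param response_cutpoints Ordered logit cutpoints separating
#'   PD | SD | PR | CR (length 3; `c(-Inf, ...)`-style extremes collapse
#'   classes).
#' @param n_cancer_types Number of synthetic cancer-type labels.
#' @param seed Root seed; expanded into independent per-stage substreams so
#'   that, e.g., changing the response model does not perturb the
#'   expression draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 300,
                       n_background_genes = 500,
                       panel = default_panel(),
                       gender_mix = 0.5,
                       adaptive_skew_effect = 0.5,
                       infiltration_scale = 0.15,
                       infiltration_sd = 0.5,
                       celltype_signal = 200,
                       bg_meanlog = log(5),
                       bg_sdlog = 1,
                       noise_sd = 0.3,
                       beta_ai = -0.7,
                       baseline_hazard = log(2) / (3 * 365.25),
                       censor_rate = 0.45 * log(2) / (3 * 365.25),
                       pfi_factor = 0.6,
                       response_slope = 1,
                       response_cutpoints = c(-0.2, 0.85, 2.2),
                       n_cancer_types = 3,
                       seed = 1) {
  cfg <- list(
    n_samples = n_samples, n_background_genes = n_background_genes,
    panel = validate_panel(panel), gender_mix = gender_mix,
    adaptive_skew_effect = adaptive_skew_effect,
    infiltration_scale = infiltration_scale,
    infiltration_sd = infiltration_sd, celltype_signal = celltype_signal,
    bg_meanlog = bg_meanlog, bg_sdlog = bg_sdlog, noise_sd = noise_sd,
    beta_ai = beta_ai, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, pfi_factor = pfi_factor,
    response_slope = response_slope,
    response_cutpoints = response_cutpoints,
    n_cancer_types = n_cancer_types, seed = seed
  )
  stopifnot(n_samples >= 1, n_background_genes >= 0,
            gender_mix >= 0, gender_mix <= 1,
            infiltration_scale >= 0, infiltration_sd >= 0, noise_sd >= 0,
            baseline_hazard > 0, censor_rate > 0, pfi_factor > 0,
            length(response_cutpoints) == 3,
            !is.unsorted(response_cutpoints))
  structure(cfg, class = "sim_config")
}

# derive a reproducible substream seed for a named stage
stage_seed <- function(seed, stage) {
  offsets <- c(expression = 1L, outcomes = 2L, response = 3L, clinical = 4L)
  (as.integer(seed) * 48271L + offsets[[stage]] * 10007L) %% 2147483647L
}

#' Simulate a marker-structured expression matrix
#'
#' Per sample, a latent adaptive skew `s ~ N(mu_gender, 1)` (females
#' shifted by `adaptive_skew_effect`) tilts a per-sample total
#' infiltration budget towards adaptive (weight `plogis(s)`) or innate
#' (weight `plogis(-s)`) cell types; `excluded` cell types take the
#' neutral weight. Marker-gene TPM is a shared log-normal background plus
#' `celltype_signal` times the cell type's infiltration fraction, under
#' multiplicative log-normal noise; background genes carry background
#' only. With `infiltration_scale = 0` marker genes are statistically
#' indistinguishable from background (cell-line mode).
#'
#' @param cfg A [sim_config()].
#' @return A list: `expr` (an `ai_expr`, linear TPM), `truth` (tibble with
#'   `sample_id`, `gender`, `latent_skew`, `infiltration_total`, and one
#'   `frac <cell type>` column per cell type).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- cfg$panel
  if (nrow(panel) == 0) abort("marker panel is empty")
  set.seed(stage_seed(cfg$seed, "expression"))
  n <- cfg$n_samples
  sample_id <- sprintf("S%04d", seq_len(n))
  gender <- ifelse(runif(n) < cfg$gender_mix, "female", "male")
  s <- rnorm(n, mean = ifelse(gender == "female", cfg$adaptive_skew_effect, 0), sd = 1)
  t_total <- cfg$infiltration_scale *
    exp(rnorm(n, 0, cfg$infiltration_sd) - cfg$infiltration_sd^2 / 2)

  types <- unique(panel$cell_type)
  comp <- panel$compartment[match(types, panel$cell_type)]
  dir <- c(adaptive = 1, innate = -1, excluded = 0)[comp]
  # n x types infiltration fractions: budget t split by skew-tilted weights
  w <- plogis(outer(s, dir))
  frac <- (t_total * w / rowSums(w))
  colnames(frac) <- types

  marker_genes <- panel$gene
  bg_genes <- if (cfg$n_background_genes > 0) {
    sprintf("BG%05d", seq_len(cfg$n_background_genes))
  } else character(0)
  genes <- c(marker_genes, bg_genes)
  baseline <- rlnorm(length(genes), cfg$bg_meanlog, cfg$bg_sdlog)
  gene_type <- c(panel$cell_type, rep(NA_character_, length(bg_genes)))

  signal <- matrix(0, nrow = length(genes), ncol = n)
  is_marker <- !is.na(gene_type)
  signal[is_marker, ] <- cfg$celltype_signal *
    t(frac[, gene_type[is_marker], drop = FALSE])
  noise <- matrix(exp(rnorm(length(genes) * n, 0, cfg$noise_sd) - cfg$noise_sd^2 / 2),
                  nrow = length(genes))
  values <- (baseline + signal) * noise
  dimnames(values) <- list(genes, sample_id)

  truth <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id, gender = gender, latent_skew = s,
                   infiltration_total = t_total),
    tibble::as_tibble(frac) |> stats::setNames(paste("frac", types))
  )
  list(expr = expression_matrix(values, "linear_tpm"), truth = truth)
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(beta_ai * (s - mean(s)))` for latent skew `s`,
#' under independent exponential censoring; progression-free times share
#' the event-time truth scaled earlier by `pfi_factor`, with independent
#' censoring.
#'
#' @param truth Truth tibble from [simulate_expression()].
#' @param cfg The same [sim_config()].
#' @return `truth` extended with `true_loghazard`, `os_time`, `os_event`,
#'   `pfi_time`, `pfi_event`.
#' @export
simulate_outcomes <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "outcomes"))
  n <- nrow(truth)
  s_c <- truth$latent_skew - mean(truth$latent_skew)
  loghaz <- log(cfg$baseline_hazard) + cfg$beta_ai * s_c
  t_event <- rexp(n, rate = exp(loghaz))
  c_os <- rexp(n, rate = cfg$censor_rate)
  t_prog <- t_event * cfg$pfi_factor
  c_pfi <- rexp(n, rate = cfg$censor_rate)
  dplyr::mutate(
    truth,
    true_loghazard = loghaz,
    os_time = pmin(t_event, c_os),
    os_event = as.numeric(t_event <= c_os),
    pfi_time = pmin(t_prog, c_pfi),
    pfi_event = as.numeric(t_prog <= c_pfi)
  )
}

#' Simulate ordinal therapy response
#'
#' Proportional-odds draw on the centred latent skew: a logistic latent
#' utility `response_slope * s + logis` is cut at `response_cutpoints`
#' into PD | SD | PR | CR. SD is generated deliberately so the
#' response-evaluable inclusion filter has something to remove.
#'
#' @param truth Truth tibble (after [simulate_expression()]).
#' @param cfg The same [sim_config()].
#' @return `truth` extended with `response` and the true class
#'   probabilities `p_PD`, `p_SD`, `p_PR`, `p_CR`.
#' @export
simulate_response <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "response"))
  s_c <- truth$latent_skew - mean(truth$latent_skew)
  eta <- cfg$response_slope * s_c
  cp <- cfg$response_cutpoints
  u <- eta + stats::rlogis(nrow(truth))
  response <- cut(u, breaks = c(-Inf, cp, Inf),
                  labels = c("PD", "SD", "PR", "CR"), right = TRUE)
  cum <- vapply(cp, function(k) plogis(k - eta), numeric(nrow(truth)))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  dplyr::mutate(
    truth,
    response = as.character(response),
    p_PD = cum[, 1],
    p_SD = cum[, 2] - cum[, 1],
    p_PR = cum[, 3] - cum[, 2],
    p_CR = 1 - cum[, 3]
  )
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_expression()], [simulate_outcomes()] and
#' [simulate_response()] under one root seed (independent per-stage
#' substreams) and assembles the clinical table: gender, age, ordinal
#' stage, synthetic cancer-type labels, survival endpoints, response, and
#' an immunohistochemistry-style phenotype (inflamed / excluded / desert)
#' derived from noisy tertiles of total infiltration. Fixed seed implies
#' byte-identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list: `expr` (`ai_expr`, linear TPM), `clinical` (validated
#'   clinical tibble), `truth` (ground-truth tibble), `config`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 50, seed = 42))
#' sim$clinical[1:3, c("sample_id", "gender", "response")]
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  ex <- simulate_expression(cfg)
  truth <- simulate_outcomes(ex$truth, cfg)
  truth <- simulate_response(truth, cfg)

  set.seed(stage_seed(cfg$seed, "clinical"))
  n <- nrow(truth)
  noisy_infiltration <- log(pmax(truth$infiltration_total, 1e-12)) + rnorm(n, 0, 0.3)
  phen_breaks <- quantile(noisy_infiltration, c(0, 1 / 3, 2 / 3, 1))
  phenotype <- as.character(cut(noisy_infiltration, breaks = unique(phen_breaks),
                                labels = c("desert", "excluded", "inflamed")[
                                  seq_len(length(unique(phen_breaks)) - 1)],
                                include.lowest = TRUE))
  clinical <- tibble::tibble(
    sample_id = truth$sample_id,
    gender = truth$gender,
    age = round(pmin(pmax(rnorm(n, 62, 10), 18), 95)),
    stage = c("I", "II", "III", "IV")[sample.int(4, n, replace = TRUE,
                                                 prob = c(0.2, 0.3, 0.3, 0.2))],
    cancer_type = paste0("SYN", sample.int(cfg$n_cancer_types, n, replace = TRUE)),
    os_time = truth$os_time, os_event = truth$os_event,
    pfi_time = truth$pfi_time, pfi_event = truth$pfi_event,
    response = truth$response,
    phenotype = phenotype
  )
  list(expr = ex$expr, clinical = validate_clinical(clinical),
       truth = truth, config = cfg)
}
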