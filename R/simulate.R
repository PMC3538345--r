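#' Default parameters of the synthetic compendium generator
#'
#' The generator emulates a multi-batch RNAi knockdown compendium with
#' per-batch GFP controls: a strong negative self-knockdown signal, planted
#' co-regulated modules (a proteasome-like module whose members all rise
#' when any one of them is knocked down; a ribosome-like module pushed in
#' opposite directions by two regulator classes, emulating the Myc/Max
#' versus eIF inversion; and two plainly down-regulated modules), per-gene
#' batch offsets, additive Gaussian noise on the log2 scale, and cell-cycle
#' phenotypes either coupled to the planted transcriptional effect or
#' deliberately uncoupled from it (strong G1 increase, reduced size, self
#' effect only).
#'
#' @param module_sizes named integer vector of planted module sizes.
#' @param self_effect log2 effect of a knockdown on its own target (< 0).
#' @param module_effect base absolute log2 effect on module members.
#' @param effect_multiplier_range per-experiment uniform range scaling the
#'   module effect, giving the compendium a spread of effect strengths.
#' @param noise_sd additive Gaussian noise sd on log2 expression.
#' @param batch_offset_sd sd of per-gene, per-batch log2 offsets.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @param n_controls_per_batch GFP control samples per batch.
#' @param replicates_module replicates for module-perturbing (TF-like)
#'   experiments; others are singlicate.
#' @param n_uncoupled number of uncoupled experiments across the compendium.
#' @param g1_baseline,s_baseline,g2_baseline baseline cell-cycle fractions.
#' @param g1_size_baseline,g2_size_baseline baseline sizes (FSC units).
#' @param pheno_alpha slope linking planted Manhattan norm to the G1 shift
#'   of coupled experiments.
#' @param pheno_link_sd sd of the coupling noise on the G1 shift (sets the
#'   moderate-correlation regime of the uncoupling analysis).
#' @param pheno_noise_sd per-sample phenotype measurement noise.
#' @param uncoupled_delta_g1 planted G1-fraction increase of uncoupled
#'   experiments.
#' @param uncoupled_size_factor multiplicative size change of uncoupled
#'   experiments (< 1: smaller cells).
#' @param flow_model_params list with `k_surface`, `k_nuclear`,
#'   `size_midpoint`: the saturating surface/volume phosphorylation model
#'   of the per-cell flow generator.
#' @return A named list of generator parameters.
#' @export
sim_params <- function(module_sizes = c(proteasome = 150L, ribosome = 150L,
                                        mitosis = 150L, replication = 150L),
                       self_effect = -2,
                       module_effect = 1.2,
                       effect_multiplier_range = c(0.75, 1.25),
                       noise_sd = 0.3,
                       batch_offset_sd = 0.4,
                       baseline_mean = 8, baseline_sd = 1.5,
                       n_controls_per_batch = 4L,
                       replicates_module = 4L,
                       n_uncoupled = 4L,
                       g1_baseline = 0.55, s_baseline = 0.25,
                       g2_baseline = 0.20,
                       g1_size_baseline = 100, g2_size_baseline = 130,
                       pheno_alpha = 8e-4,
                       pheno_link_sd = 0.075,
                       pheno_noise_sd = 0.01,
                       uncoupled_delta_g1 = 0.35,
                       uncoupled_size_factor = 0.85,
                       flow_model_params = list(k_surface = 4,
                                                k_nuclear = 2,
                                                size_midpoint = 160)) {
  stopifnot(self_effect < 0, noise_sd >= 0, module_effect >= 0,
            length(effect_multiplier_range) == 2,
            n_controls_per_batch >= 1)
  as.list(environment())
}

# per-batch experiment class pattern: mostly module perturbations (the
# compendium targets regulators with broad transcriptional programs), one
# singleton slot per batch (uncoupled experiments replace the first few)
batch_slot_pattern <- function(experiments_per_batch) {
  base <- c("proteasome", "ribosome_myc", "mitosis", "replication",
            "ribosome_eif", "proteasome", "mitosis", "replication",
            "singleton", "proteasome", "mitosis", "replication")
  if (experiments_per_batch <= length(base))
    return(base[seq_len(experiments_per_batch)])
  c(base, rep("singleton", experiments_per_batch - length(base)))
}

#' Generate a synthetic knockdown compendium
#'
#' Builds a log2 expression matrix as baseline + per-gene batch offset +
#' planted knockdown effects + Gaussian noise, together with its sample
#' sheet and a truth record of everything planted (module assignments,
#' per-experiment planted effect vectors, uncoupled set, phenotype links).
#'
#' @param n_genes number of genes (must be at least 10 per planted module
#'   and large enough to hold the modules plus all targets).
#' @param n_batches number of hybridization batches.
#' @param experiments_per_batch knockdown experiments per batch (each batch
#'   additionally receives `n_controls_per_batch` GFP controls).
#' @param params generator parameters from [sim_params()].
#' @param seed integer RNG seed; the output is fully reproducible from it.
#' @return A list with `exprs` (matrix), `sheet` (sample sheet), and
#'   `truth` (a `sim_truth` list).
#' @examples
#' sim <- generate_compendium(n_genes = 300, n_batches = 2,
#'                            experiments_per_batch = 6, seed = 1)
#' dim(sim$exprs)
#' @export
generate_compendium <- function(n_genes = 2000L, n_batches = 6L,
                                experiments_per_batch = 12L,
                                params = sim_params(), seed = 1L) {
  set.seed(seed)
  p <- params
  n_modules <- length(p$module_sizes)
  if (n_genes < 10L * n_modules)
    stop("n_genes must be at least 10 x number of planted modules")
  genes <- sprintf("g%04d", seq_len(n_genes))

  # module membership occupies leading gene blocks; remaining genes are
  # background / regulator / singleton-target pool
  module_assignments <- rep(NA_character_, n_genes)
  names(module_assignments) <- genes
  offset <- 0L
  module_members <- list()
  for (m in names(p$module_sizes)) {
    sz <- min(p$module_sizes[[m]], floor((n_genes - offset) / (n_modules)))
    idx <- seq_len(sz) + offset
    module_members[[m]] <- genes[idx]
    module_assignments[idx] <- m
    offset <- offset + sz
  }
  pool <- genes[is.na(module_assignments)]

  # experiment design
  slots <- unlist(lapply(seq_len(n_batches),
                         function(b) batch_slot_pattern(experiments_per_batch)))
  batches <- rep(sprintf("batch%02d", seq_len(n_batches)),
                 each = experiments_per_batch)
  n_exp <- length(slots)

  # targets: module-member slots cycle through members; regulator and
  # singleton slots consume the background pool
  take_pool <- local({
    i <- 0L
    function(k) {
      if (i + k > length(pool)) stop("gene universe too small for the design")
      out <- pool[i + seq_len(k)]
      i <<- i + k
      out
    }
  })
  member_cursor <- stats::setNames(rep(0L, n_modules), names(p$module_sizes))
  targets <- character(n_exp)
  for (i in seq_len(n_exp)) {
    cls <- slots[i]
    if (cls %in% c("proteasome", "mitosis", "replication")) {
      member_cursor[cls] <- member_cursor[cls] %% length(module_members[[cls]]) + 1L
      targets[i] <- module_members[[cls]][member_cursor[cls]]
    } else {
      targets[i] <- take_pool(1L)
    }
  }
  if (anyDuplicated(targets)) {
    dup <- which(duplicated(targets))
    targets[dup] <- paste0(targets[dup], ".", batches[dup])
  }
  exp_ids <- paste0("kd_", targets)

  # uncoupled experiments replace the first singleton slot of the first
  # n_uncoupled batches; they keep only the self effect
  uncoupled <- character(0)
  if (p$n_uncoupled > 0) {
    cand <- which(slots == "singleton" &
                    !duplicated(paste(batches, slots == "singleton")))
    cand <- vapply(unique(batches), function(b) {
      w <- which(batches == b & slots == "singleton")
      if (length(w) > 0) w[1] else NA_integer_
    }, integer(1))
    cand <- cand[!is.na(cand)]
    cand <- cand[seq_len(min(p$n_uncoupled, length(cand)))]
    slots[cand] <- "uncoupled"
    uncoupled <- exp_ids[cand]
  }

  multipliers <- stats::runif(n_exp, p$effect_multiplier_range[1],
                              p$effect_multiplier_range[2])

  # planted per-experiment effect vectors (genes x experiments)
  planted <- matrix(0, n_genes, n_exp, dimnames = list(genes, exp_ids))
  for (i in seq_len(n_exp)) {
    cls <- slots[i]
    eff <- p$module_effect * multipliers[i]
    if (cls == "proteasome") {
      planted[module_members$proteasome, i] <- eff
    } else if (cls == "mitosis") {
      planted[module_members$mitosis, i] <- -eff
    } else if (cls == "replication") {
      planted[module_members$replication, i] <- -eff
    } else if (cls == "ribosome_myc") {
      planted[module_members$ribosome, i] <- -eff
    } else if (cls == "ribosome_eif") {
      planted[module_members$ribosome, i] <- eff
    }
    tg <- sub("\\..*$", "", targets[i])
    planted[tg, i] <- p$self_effect
  }

  # sample sheet: controls then experiments, batch by batch
  replicates <- ifelse(slots == "singleton", 1L, p$replicates_module)
  rows <- list()
  for (b in unique(batches)) {
    for (j in seq_len(p$n_controls_per_batch)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("GFP_%s_r%d", b, j), batch = b,
        target_gene = "NONE", is_control = TRUE, replicate_index = j,
        stringsAsFactors = FALSE)
    }
    for (i in which(batches == b)) {
      for (j in seq_len(replicates[i])) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_r%d", exp_ids[i], j), batch = b,
          target_gene = targets[i], is_control = FALSE, replicate_index = j,
          stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- as_sample_sheet(do.call(rbind, rows))

  baseline <- stats::rnorm(n_genes, p$baseline_mean, p$baseline_sd)
  batch_offsets <- matrix(stats::rnorm(n_genes * n_batches, 0, p$batch_offset_sd),
                          n_genes, n_batches,
                          dimnames = list(genes, unique(batches)))

  exprs <- matrix(0, n_genes, nrow(sheet),
                  dimnames = list(genes, sheet$sample_id))
  exp_of_sample <- ifelse(sheet$is_control, NA_character_,
                          paste0("kd_", sheet$target_gene))
  # duplicated targets got batch-suffixed experiment ids
  exp_of_sample[!sheet$is_control] <-
    sub("_r[0-9]+$", "", sheet$sample_id[!sheet$is_control])
  for (s in seq_len(nrow(sheet))) {
    mu <- baseline + batch_offsets[, sheet$batch[s]]
    if (!sheet$is_control[s]) mu <- mu + planted[, exp_of_sample[s]]
    noise <- if (p$noise_sd > 0) stats::rnorm(n_genes, 0, p$noise_sd) else 0
    exprs[, s] <- mu + noise
  }

  truth <- structure(list(
    module_assignments = module_assignments,
    module_members = module_members,
    module_effects = list(proteasome = +p$module_effect,
                          ribosome_myc = -p$module_effect,
                          ribosome_eif = +p$module_effect,
                          mitosis = -p$module_effect,
                          replication = -p$module_effect),
    self_effect = p$self_effect,
    batch_offsets = batch_offsets,
    noise_sd = p$noise_sd,
    experiments = data.frame(experiment_id = exp_ids, batch = batches,
                             target_gene = targets, class = slots,
                             multiplier = multipliers,
                             replicates = replicates,
                             planted_manhattan = colSums(abs(planted)),
                             stringsAsFactors = FALSE),
    planted_effects = planted,
    uncoupled_experiments = uncoupled,
    params = p
  ), class = "sim_truth")

  list(exprs = exprs, sheet = sheet, truth = truth)
}

#' Generate FACS phenotypes for a synthetic compendium
#'
#' Coupled experiments receive a G1-fraction increase proportional to the
#' Manhattan norm of their planted expression effect plus coupling noise;
#' uncoupled experiments receive a large planted G1 increase and reduced
#' cell size despite having no planted non-self expression effect. Control
#' samples are emitted at baseline so downstream contrasts can be taken
#' against batch controls.
#'
#' @param sheet sample sheet from [generate_compendium()].
#' @param truth matching `sim_truth`.
#' @param seed integer RNG seed.
#' @param noise if `FALSE`, coupling and measurement noise are switched off
#'   (planted values can then be read back exactly).
#' @return A `phenotype_table` data frame with one row per sample:
#'   `sample_id`, `experiment_id` (`NA` for controls), `batch`, `g1_frac`,
#'   `s_frac`, `g2_frac`, `g1_size`, `g2_size`, `is_control`.
#' @export
generate_phenotypes <- function(sheet, truth, seed = 1L, noise = TRUE) {
  set.seed(seed + 1000L)
  p <- truth$params
  link_sd <- if (noise) p$pheno_link_sd else 0
  meas_sd <- if (noise) p$pheno_noise_sd else 0

  ex <- truth$experiments
  dg1 <- ifelse(ex$class == "uncoupled",
                p$uncoupled_delta_g1,
                p$pheno_alpha * ex$planted_manhattan +
                  stats::rnorm(nrow(ex), 0, link_sd))
  size_fac <- ifelse(ex$class == "uncoupled", p$uncoupled_size_factor, 1)
  names(dg1) <- names(size_fac) <- ex$experiment_id

  exp_of_sample <- ifelse(sheet$is_control, NA_character_,
                          sub("_r[0-9]+$", "", sheet$sample_id))
  n <- nrow(sheet)
  d <- ifelse(sheet$is_control, 0, dg1[exp_of_sample])
  sf <- ifelse(sheet$is_control, 1, size_fac[exp_of_sample])

  g1 <- p$g1_baseline + d + stats::rnorm(n, 0, meas_sd)
  rest <- 1 - g1
  s_share <- p$s_baseline / (p$s_baseline + p$g2_baseline)
  s <- rest * s_share
  g2 <- rest * (1 - s_share)
  lo <- 0.005
  g1 <- pmin(pmax(g1, lo), 1 - 2 * lo)
  s <- pmin(pmax(s, lo), 1 - 2 * lo)
  g2 <- pmax(1 - g1 - s, lo)
  tot <- g1 + s + g2
  g1 <- g1 / tot; s <- s / tot; g2 <- g2 / tot

  size_noise <- function() if (noise) exp(stats::rnorm(n, 0, 0.02)) else 1
  pheno <- data.frame(
    sample_id = sheet$sample_id,
    experiment_id = exp_of_sample,
    batch = sheet$batch,
    g1_frac = g1, s_frac = s, g2_frac = g2,
    g1_size = p$g1_size_baseline * sf * size_noise(),
    g2_size = p$g2_size_baseline * sf * size_noise(),
    is_control = sheet$is_control,
    stringsAsFactors = FALSE
  )
  class(pheno) <- c("phenotype_table", "data.frame")
  pheno
}

#' Generate per-cell flow-cytometry events
#'
#' Each cell draws a cycle phase (G1/S/G2), a DNA-content signal at 1x,
#' interpolated, or 2x baseline with measurement CV, and a lognormal cell
#' volume (G2 cells larger on average) reported as FSC-A. Total Cdk1 scales
#' with cell volume; the phosphorylated fraction follows a saturating
#' surface-to-volume model: the phosphorylation propensity is
#' `k_surface * (v/mid)^(-1/3) + k_nuclear * (v/mid)^(-1)` and the fraction
#' is `propensity / (1 + propensity)`, so the unphosphorylated amount rises
#' super-linearly once cells grow past `size_midpoint`. With
#' `size_dependent_phospho = FALSE` and `size_coupling = 0` the
#' unphosphorylated signal is independent of size (the null model for
#' type-I-error checks).
#'
#' @param n_cells number of cells (>= 1000 recommended for stable bins).
#' @param flow_model_params list with `k_surface`, `k_nuclear`,
#'   `size_midpoint` (all > 0, midpoint in FSC units).
#' @param seed integer RNG seed.
#' @param measurement_cv CV of the DNA and FSC measurement noise.
#' @param channel_cv lognormal sd of the antibody channel noise.
#' @param size_coupling exponent tying total Cdk1 to cell volume
#'   (1 = proportional; 0 = size-independent null).
#' @param size_dependent_phospho if `FALSE`, the phospho fraction is the
#'   constant `null_phospho_fraction` for every cell.
#' @param null_phospho_fraction constant fraction used when
#'   `size_dependent_phospho = FALSE`.
#' @param phase_probs probabilities of G1, S, G2.
#' @return A `flow_events` data frame: `event_id`, `dna`, `fsc_a`,
#'   `ch_total`, `ch_phospho`, plus the generator's `true_phase` label.
#' @export
generate_flow_events <- function(n_cells = 10000L,
                                 flow_model_params = sim_params()$flow_model_params,
                                 seed = 1L,
                                 measurement_cv = 0.03,
                                 channel_cv = 0.10,
                                 size_coupling = 1,
                                 size_dependent_phospho = TRUE,
                                 null_phospho_fraction = 0.85,
                                 phase_probs = c(0.5, 0.25, 0.25)) {
  fp <- flow_model_params
  stopifnot(fp$k_surface >= 0, fp$k_nuclear >= 0)
  if (is.null(fp$size_midpoint) || fp$size_midpoint <= 0)
    stop("size_midpoint must be positive")
  set.seed(seed + 2000L)
  phase <- sample(c("G1", "S", "G2"), n_cells, replace = TRUE,
                  prob = phase_probs)
  dna_base <- 100
  ploidy <- ifelse(phase == "G1", 1,
                   ifelse(phase == "G2", 2, stats::runif(n_cells, 1, 2)))
  dna <- dna_base * ploidy * (1 + stats::rnorm(n_cells, 0, measurement_cv))

  size_factor <- c(G1 = 1, S = 1.26, G2 = 1.6)[phase]
  volume <- 100 * size_factor * exp(stats::rnorm(n_cells, 0, 0.25))
  fsc_a <- volume * exp(stats::rnorm(n_cells, 0, measurement_cv))

  total <- (volume / 100)^size_coupling * exp(stats::rnorm(n_cells, 0, channel_cv))
  if (size_dependent_phospho) {
    rel <- volume / fp$size_midpoint
    propensity <- fp$k_surface * rel^(-1 / 3) + fp$k_nuclear * rel^(-1)
    frac <- propensity / (1 + propensity)
    frac[is.nan(frac)] <- 1  # k_surface or k_nuclear -> Inf limit
  } else {
    frac <- rep(null_phospho_fraction, n_cells)
  }
  phospho <- total * frac * exp(stats::rnorm(n_cells, 0, channel_cv / 2))

  ev <- data.frame(event_id = seq_len(n_cells), dna = dna, fsc_a = fsc_a,
                   ch_total = total, ch_phospho = phospho,
                   true_phase = phase, stringsAsFactors = FALSE)
  class(ev) <- c("flow_events", "data.frame")
  attr(ev, "flow_model_params") <- fp
  ev
}
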