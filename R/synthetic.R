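#' Configuration for the synthetic expression generator
#'
#' Describes an unbalanced two-class probe-by-sample matrix with known
#' ground truth, shaped like an unnormalised single-channel microarray
#' export: a shared per-probe baseline profile on an intensity scale, a
#' multiplicative per-array scale factor (the dominant nuisance in
#' unnormalised data, which concentrates most variance on the shared
#' baseline axis), planted class-differential probes, optional correlated
#' probe blocks, an optional majority-class (control-only) latent factor,
#' i.i.d. Gaussian noise, and optional exact duplicate control columns.
#'
#' Planted effects come in two flavours. `de_mode = "shift"` adds a
#' class-mean shift of `effect` noise-standard-deviations to the case
#' samples (alternating up/down across the planted probes).
#' `de_mode = "factor"` instead couples the planted probes to a latent
#' factor present only in the case class (per-probe loading of `effect`
#' noise-sd), i.e. the differential signal lives purely in the case-class
#' variance structure, not in the class means.
#'
#' @param m Number of probes.
#' @param n_control,n_case Class sizes (unbalanced by default, 19 vs 10).
#' @param baseline_mean,baseline_sd Mean and spread of the per-probe
#'   baseline intensities (floored at `baseline_floor`).
#' @param baseline_floor Lower clamp on baseline intensities.
#' @param array_cv Coefficient of variation of the per-array multiplicative
#'   scale factor.
#' @param noise_sd Standard deviation of the i.i.d. measurement noise.
#' @param n_de Number of planted differential probes.
#' @param effect Effect size in noise-sd units (recycled over the planted
#'   probes); in `"factor"` mode it is the per-probe loading on the
#'   case-only latent factor.
#' @param de_mode `"shift"` (class-mean difference) or `"factor"`
#'   (case-class variance structure); see Details.
#' @param n_blocks,block_size,block_cor Correlated co-expression blocks
#'   shared by all samples: each block's probes load a common latent factor
#'   so that the expected within-block correlation is `block_cor`.
#' @param control_factor_probes,control_factor_load Majority-class nuisance
#'   structure: this many (non-planted) probes load a latent factor present
#'   only in the control class, with loading `control_factor_load` noise-sd.
#'   Off by default (`control_factor_load = 0`).
#' @param duplicate_controls Number of exact replicate columns of the first
#'   control sample appended to the matrix (emulating duplicated array
#'   submissions).
#' @param seed Integer RNG seed; identical configurations give bit-identical
#'   matrices.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(m = 2000, n_control = 19, n_case = 10,
                             baseline_mean = 500, baseline_sd = 300,
                             baseline_floor = 20,
                             array_cv = 0.12, noise_sd = 100,
                             n_de = 30, effect = 3,
                             de_mode = c("shift", "factor"),
                             n_blocks = 2, block_size = 10, block_cor = 0.8,
                             control_factor_probes = 50,
                             control_factor_load = 0,
                             duplicate_controls = 0, seed = 1) {
  de_mode <- match.arg(de_mode)
  cfg <- list(m = as.integer(m), n_control = as.integer(n_control),
              n_case = as.integer(n_case),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              baseline_floor = baseline_floor,
              array_cv = array_cv, noise_sd = noise_sd,
              n_de = as.integer(n_de), effect = effect, de_mode = de_mode,
              n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size), block_cor = block_cor,
              control_factor_probes = as.integer(control_factor_probes),
              control_factor_load = control_factor_load,
              duplicate_controls = as.integer(duplicate_controls),
              seed = as.integer(seed))
  with(cfg, {
    if (m < 2L) stop("'m' must be at least 2")
    if (n_control < 1L || n_case < 1L) stop("both classes must be non-empty")
    if (n_control + n_case < 4L) stop("need at least 4 samples in total")
    if (n_de < 0L || n_de > m) stop("'n_de' must be between 0 and m")
    if (any(!is.finite(effect))) stop("effect sizes must be finite")
    if (block_cor < 0 || block_cor >= 1) stop("'block_cor' must be in [0, 1)")
    if (noise_sd <= 0) stop("'noise_sd' must be positive")
    if (array_cv < 0) stop("'array_cv' must be nonnegative")
    if (duplicate_controls < 0L) stop("'duplicate_controls' must be nonnegative")
    extra <- n_blocks * block_size +
      if (control_factor_load > 0) control_factor_probes else 0L
    if (n_de + extra > m) {
      stop("planted, block and nuisance probes exceed 'm'")
    }
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic two-class expression matrix with ground truth
#'
#' See [synthetic_config()] for the generative model. Sample columns are
#' ordered controls first, then cases, then any duplicated control columns.
#'
#' @param config A [synthetic_config()].
#' @return List with `x` (an [ExpressionMatrix()] with labels) and `truth`,
#'   a list recording `de_probes` (planted probe ids), `de_effect` (signed
#'   per-probe effect in noise-sd units), `blocks` (list of probe-id
#'   vectors), `control_factor_probes`, and `duplicate_pairs` (data.frame
#'   of original/replicate sample ids).
#' @export
#' @examples
#' sim <- simulate_expression(synthetic_config(m = 300, n_control = 8, n_case = 4,
#'                                             n_de = 10, seed = 42))
#' sim$x
#' head(sim$truth$de_probes)
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  m <- cfg$m
  n <- cfg$n_control
  d <- cfg$n_case
  l <- n + d
  lab <- c(rep("control", n), rep("case", d))

  baseline <- pmax(stats::rnorm(m, cfg$baseline_mean, cfg$baseline_sd),
                   cfg$baseline_floor)
  scale_fac <- stats::rnorm(l, 1, cfg$array_cv)
  vals <- outer(baseline, scale_fac) +
    matrix(stats::rnorm(m * l, 0, cfg$noise_sd), m, l)

  use_nuis <- cfg$control_factor_load > 0
  n_special <- cfg$n_de + cfg$n_blocks * cfg$block_size +
    if (use_nuis) cfg$control_factor_probes else 0L
  special <- if (n_special > 0L) sample.int(m, n_special) else integer(0)
  de_idx <- utils::head(special, cfg$n_de)
  rest <- if (cfg$n_de > 0L) special[-seq_len(cfg$n_de)] else special

  de_effect <- numeric(0)
  if (cfg$n_de > 0L) {
    de_effect <- rep_len(cfg$effect, cfg$n_de) * rep_len(c(1, -1), cfg$n_de)
    if (cfg$de_mode == "shift") {
      vals[de_idx, lab == "case"] <- vals[de_idx, lab == "case"] +
        de_effect * cfg$noise_sd
    } else {
      f <- stats::rnorm(d)
      vals[de_idx, lab == "case"] <- vals[de_idx, lab == "case"] +
        outer(de_effect * cfg$noise_sd, f)
    }
  }

  blocks <- list()
  if (cfg$n_blocks > 0L && cfg$block_size > 0L) {
    loading <- cfg$noise_sd * sqrt(cfg$block_cor / (1 - cfg$block_cor))
    for (bi in seq_len(cfg$n_blocks)) {
      bidx <- rest[seq.int((bi - 1L) * cfg$block_size + 1L, bi * cfg$block_size)]
      f <- stats::rnorm(l)
      vals[bidx, ] <- vals[bidx, ] + loading * matrix(f, cfg$block_size, l,
                                                      byrow = TRUE)
      blocks[[bi]] <- bidx
    }
    rest <- rest[-seq_len(cfg$n_blocks * cfg$block_size)]
  }

  nuis_idx <- integer(0)
  if (use_nuis && cfg$control_factor_probes > 0L) {
    nuis_idx <- rest[seq_len(cfg$control_factor_probes)]
    g <- stats::rnorm(n)
    nl <- rep_len(c(1, -1), cfg$control_factor_probes) *
      cfg$control_factor_load * cfg$noise_sd
    vals[nuis_idx, lab == "control"] <- vals[nuis_idx, lab == "control"] +
      outer(nl, g)
  }

  probe_ids <- sprintf("probe_%05d", seq_len(m))
  sample_ids <- c(sprintf("control_%02d", seq_len(n)),
                  sprintf("case_%02d", seq_len(d)))

  dup_pairs <- data.frame(original = character(0), replicate = character(0),
                          stringsAsFactors = FALSE)
  if (cfg$duplicate_controls > 0L) {
    dup_ids <- sprintf("control_01_rep%d", seq_len(cfg$duplicate_controls))
    vals <- cbind(vals, vals[, rep(1L, cfg$duplicate_controls), drop = FALSE])
    sample_ids <- c(sample_ids, dup_ids)
    lab <- c(lab, rep("control", cfg$duplicate_controls))
    dup_pairs <- data.frame(original = rep(sample_ids[1L], cfg$duplicate_controls),
                            replicate = dup_ids, stringsAsFactors = FALSE)
  }

  x <- ExpressionMatrix(vals, probe_ids = probe_ids, sample_ids = sample_ids,
                        labels = lab)
  truth <- list(
    de_probes = probe_ids[de_idx],
    de_effect = stats::setNames(de_effect, probe_ids[de_idx]),
    de_mode = cfg$de_mode,
    blocks = lapply(blocks, function(i) probe_ids[i]),
    control_factor_probes = probe_ids[nuis_idx],
    duplicate_pairs = dup_pairs
  )
  list(x = x, truth = truth)
}
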