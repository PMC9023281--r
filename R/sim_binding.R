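#' Simulate an equilibrium binding titration
#'
#' Generates replicate fraction-bound measurements from a one-site hyperbolic
#' binding isotherm, `f([P]) = bmax * [P] / (kd + [P])`, with additive
#' Gaussian noise clipped to the physically meaningful range \[0, 1\].
#' Emulates the quantification of a gel-shift (EMSA) titration series.
#'
#' @param kd_nM True dissociation constant in nM (> 0).
#' @param bmax Saturating bound fraction (default 1).
#' @param concentrations_nM Protein concentrations in nM (>= 0).
#' @param noise_sd Gaussian noise SD on fraction bound.
#' @param replicates Number of replicate series.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `conc_nM`, `replicate`,
#'   `fraction_bound` and attribute `truth` (list of kd_nM, bmax).
#' @examples
#' simulate_titration(39, 1, c(0, 2^(0:9)), noise_sd = 0, replicates = 1)
#' @export
simulate_titration <- function(kd_nM, bmax = 1,
                               concentrations_nM = c(0, 2^(0:9)),
                               noise_sd = 0.03, replicates = 3, seed = NULL) {
  stopifnot(kd_nM > 0, bmax > 0, noise_sd >= 0, replicates >= 1)
  if (any(concentrations_nM < 0))
    stop("concentrations must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  out <- expand.grid(conc_nM = concentrations_nM,
                     replicate = seq_len(replicates))
  f <- bmax * out$conc_nM / (kd_nM + out$conc_nM)
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  out$fraction_bound <- pmin(1, pmax(0, f))
  attr(out, "truth") <- list(kd_nM = kd_nM, bmax = bmax)
  out
}

#' Simulate a dissociation time course
#'
#' Bound fraction of a protein-DNA complex over time after introducing a
#' challenge (e.g. PARP-1 + NAD+). The treated condition decays as
#' `exp(-k_off * t)`; the control condition (challenge omitted) stays at 1.
#' Gaussian noise is added to both and values are clipped at 0.
#'
#' @param k_off_per_min Dissociation rate (1/min, >= 0).
#' @param t_points_min Time points in minutes.
#' @param noise_sd Gaussian noise SD.
#' @param replicates Number of replicates per condition.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `time_min`, `replicate`, `condition`
#'   (`"treated"` or `"control"`), `bound_fraction`.
#' @examples
#' simulate_dissociation(0.2, t_points_min = 0:10, noise_sd = 0)
#' @export
simulate_dissociation <- function(k_off_per_min, t_points_min = 0:10,
                                  noise_sd = 0.03, replicates = 3,
                                  seed = NULL) {
  stopifnot(k_off_per_min >= 0, noise_sd >= 0, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(time_min = t_points_min, replicate = seq_len(replicates),
                      condition = c("treated", "control"),
                      stringsAsFactors = FALSE)
  mu <- ifelse(grid$condition == "treated",
               exp(-k_off_per_min * grid$time_min), 1)
  if (noise_sd > 0) mu <- mu + rnorm(length(mu), 0, noise_sd)
  grid$bound_fraction <- pmax(0, mu)
  grid
}
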