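# Synthetic-data generators: statistical stand-ins for the measured inputs
# (concentration time courses, HMBC integral quadruples, observed label-class
# fractions) used to exercise and validate the analysis pipeline end to end.

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a fermentation growth and conversion time course
#'
#' Generates an OD600 curve following the modified Gompertz model and a
#' substrate/product concentration time course in which cumulative substrate
#' consumption follows the same sigmoid shape (normalized to complete
#' consumption at the final time point) and each product tracks consumption
#' times its stoichiometric coefficient from the balanced equation. Additive
#' Gaussian noise, truncated at zero, can be applied to both observables.
#' The defaults emulate the reference lysine fermentation: 16.8 mM lysine
#' converted over ~48 h with mu_max = 0.1 h^-1.
#'
#' @param equation A `fermentation_equation` (e.g. the balanced lysine
#'   equation) giving the product/substrate coefficient ratios.
#' @param substrate_mM Initial substrate concentration (mM).
#' @param A,mu_max,lambda Gompertz parameters of the growth curve
#'   (`ln(OD/OD0)` asymptote, h^-1, h).
#' @param od0 Baseline OD600.
#' @param t_max Final time (h); the substrate is fully consumed at `t_max`.
#' @param n_timepoints Number of equally spaced time points from 0 to
#'   `t_max`.
#' @param noise_sd_od,noise_sd_conc Additive Gaussian noise standard
#'   deviations for OD and concentrations (0 = noiseless).
#' @param product_scale Optional named multipliers applied to final product
#'   yields (e.g. to emulate anabolic losses).
#' @param seed Integer seed; mandatory when any noise is requested.
#' @return List with `curve` (tibble `time_h`, `od600`) and `record`
#'   (tibble `time_h`, `compound`, `delta_mM`, `role` of cumulative changes).
#' @examples
#' eq <- balance_equation(c("lysine", "water"),
#'                        c("butyrate", "acetate", "ammonia"))
#' sim <- sim_growth_timecourse(eq, seed = 1)
#' tail(sim$record, 4)
#' @export
sim_growth_timecourse <- function(equation, substrate_mM = 16.8,
                                  A = 2, mu_max = 0.1, lambda = 5,
                                  od0 = 0.02, t_max = 48, n_timepoints = 25,
                                  noise_sd_od = 0, noise_sd_conc = 0,
                                  product_scale = NULL, seed = 1) {
  stopifnot(inherits(equation, "fermentation_equation"),
            substrate_mM > 0, t_max > 0, n_timepoints >= 2,
            noise_sd_od >= 0, noise_sd_conc >= 0)
  sp <- equation$species
  ref <- equation$reference
  ref_coef <- sp$coefficient[sp$name == ref]
  products <- sp[sp$role == "product", ]
  scale <- stats::setNames(rep(1, nrow(products)), products$name)
  if (!is.null(product_scale)) {
    scale[names(product_scale)] <- product_scale
  }

  tt <- seq(0, t_max, length.out = n_timepoints)
  shape <- exp(-exp(mu_max * exp(1) / A * (lambda - tt) + 1))
  consumed <- substrate_mM * shape / shape[length(shape)]
  od <- od0 * exp(A * shape)

  with_seed(seed, {
    if (noise_sd_od > 0) {
      od <- pmax(od + stats::rnorm(length(od), 0, noise_sd_od), 0)
    }
    rec <- purrr::map_dfr(seq_len(nrow(products)), function(i) {
      nm <- products$name[i]
      d <- consumed * (products$coefficient[i] / ref_coef) * scale[[nm]]
      tibble::tibble(time_h = tt, compound = nm, delta_mM = d,
                     role = "product")
    })
    rec <- dplyr::bind_rows(
      tibble::tibble(time_h = tt, compound = ref, delta_mM = consumed,
                     role = "substrate"),
      rec
    )
    if (noise_sd_conc > 0) {
      rec$delta_mM <- pmax(
        rec$delta_mM + stats::rnorm(nrow(rec), 0, noise_sd_conc), 0)
    }
    list(curve = tibble::tibble(time_h = tt, od600 = od), record = rec)
  })
}

#' Simulate an HMBC cross-peak integral quadruple
#'
#' Inverse of the split/non-split correction: given true butyrate label-class
#' fractions, a total signal and per-proton-side attenuation factors, builds
#' the four integrals `h2c4_nonsplit = a_H2 p4 T`, `h2c4_split = a_H2 p24 T`,
#' `h4c2_nonsplit = a_H4 p2 T`, `h4c2_split = a_H4 p24 T`, then adds
#' zero-truncated Gaussian noise. At zero noise,
#' [estimate_butyrate_fractions()] recovers the input fractions exactly for
#' any positive attenuation pair.
#'
#' @param fractions One-row data frame (or named vector) with `p2`, `p4`,
#'   `p24` summing to 1.
#' @param total_signal Total integral mass `T` (> 0).
#' @param attenuation Length-2 positive vector `(H2-side, H4-side)`.
#' @param noise_sd Additive Gaussian noise sd (0 = noiseless).
#' @param seed Integer seed.
#' @return One-row tibble with the four integral columns.
#' @examples
#' sim_hmbc_integrals(c(p2 = 0.13, p4 = 0.71, p24 = 0.16), total_signal = 10)
#' @export
sim_hmbc_integrals <- function(fractions, total_signal = 1,
                               attenuation = c(1, 1), noise_sd = 0,
                               seed = 1) {
  stopifnot(total_signal > 0, length(attenuation) == 2, all(attenuation > 0),
            noise_sd >= 0)
  fr <- as_class_triple(fractions)
  a_h2 <- attenuation[[1]]
  a_h4 <- attenuation[[2]]
  vals <- c(
    h2c4_nonsplit = a_h2 * fr[2] * total_signal,
    h2c4_split = a_h2 * fr[3] * total_signal,
    h4c2_nonsplit = a_h4 * fr[1] * total_signal,
    h4c2_split = a_h4 * fr[3] * total_signal
  )
  if (noise_sd > 0) {
    vals <- with_seed(seed,
      pmax(vals + stats::rnorm(4, 0, noise_sd), 0))
  }
  tibble::as_tibble(as.list(vals))
}

#' Simulate a noisy observed label-class measurement
#'
#' Runs the tracer model ([propagate_labels()] then [to_class_fractions()])
#' and perturbs the three class fractions with multiplicative lognormal noise
#' (sd on the log scale) before renormalizing, emulating replicate-to-
#' replicate variability of the NMR quantification.
#'
#' @param model A `pathway_model`.
#' @param substrate_label A [labeling_state()].
#' @param flux A [flux_config()].
#' @param noise_sd Lognormal sigma (0 = exact tracer output).
#' @param seed Integer seed.
#' @param exogenous_pattern Passed to [propagate_labels()].
#' @return One-row tibble with `p2`, `p4`, `p24`.
#' @examples
#' model <- load_pathway()
#' lab <- labeling_state("lysine", 6, model)
#' sim_labeling_observation(model, lab, flux_config(0.7,
#'   c(lysine_c1c2 = 0.6, recycled = 0.4)), noise_sd = 0.05, seed = 7)
#' @export
sim_labeling_observation <- function(model, substrate_label, flux,
                                     noise_sd = 0, seed = 1,
                                     exogenous_pattern = c(0L, 0L)) {
  stopifnot(noise_sd >= 0)
  cf <- to_class_fractions(
    propagate_labels(model, substrate_label, flux,
                     exogenous_pattern = exogenous_pattern))
  p <- c(cf$p2, cf$p4, cf$p24)
  if (noise_sd > 0) {
    p <- with_seed(seed, p * exp(stats::rnorm(3, 0, noise_sd)))
    p <- p / sum(p)
  }
  tibble::tibble(p2 = p[1], p4 = p[2], p24 = p[3])
}
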