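# Seeded generators emulating every count table the pipeline consumes:
# per-mother progeny counts classified through the forward model with
# fertilization and viability filtering, per-cross fecundity records, and
# per-ovary binomial cytology counts.

#' Simulation configuration
#'
#' The stated world of the simulators. Defaults mirror the scale of the real
#' bioassay: ~100 mothers per cross each contributing ~13 scored progeny
#' (1283 progeny from 99 mothers in the reference control cross), a
#' negative-control cytology positive rate of 16/220 ~ 0.074 over 2 ovaries
#' of ~110 oocyte nuclei each. The seed is mandatory: every stochastic call
#' seeds a single PRNG stream from it.
#'
#' @param params a [segregation_params()] object.
#' @param n_mothers mothers per simulated cross.
#' @param progeny_per_mother mean fertilized eggs scored per mother.
#' @param dispersion overdispersion of progeny per mother; 0 gives Poisson,
#'   `> 0` negative-binomial with variance `mu + dispersion * mu^2`.
#' @param sperm a [sperm_model()].
#' @param viability a [viability_model()].
#' @param cytology_positive_rate per-nucleus probability of a positive
#'   cytology call.
#' @param n_oocytes_per_ovary oocyte nuclei scored per ovary.
#' @param n_ovaries ovaries scored.
#' @param seed integer seed (mandatory).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params, n_mothers = 100, progeny_per_mother = 13,
                              dispersion = 0,
                              sperm = sperm_model(),
                              viability = viability_model(),
                              cytology_positive_rate = 0.074,
                              n_oocytes_per_ovary = 110, n_ovaries = 2,
                              seed) {
  stopifnot(inherits(params, "segregation_params"),
            inherits(sperm, "sperm_model"),
            inherits(viability, "viability_model"))
  if (missing(seed) || !is_count(seed)) {
    abort_config("simulation_config requires an explicit non-negative integer seed")
  }
  n_mothers <- check_count(n_mothers, "n_mothers")
  if (!is.numeric(progeny_per_mother) || progeny_per_mother < 0) {
    abort_config("progeny_per_mother must be a non-negative mean")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    abort_config("dispersion must be >= 0")
  }
  structure(
    list(params = params, n_mothers = n_mothers,
         progeny_per_mother = as.numeric(progeny_per_mother),
         dispersion = as.numeric(dispersion),
         sperm = sperm, viability = viability,
         cytology_positive_rate = check_probability(cytology_positive_rate,
                                                    "cytology_positive_rate"),
         n_oocytes_per_ovary = check_count(n_oocytes_per_ovary,
                                           "n_oocytes_per_ovary"),
         n_ovaries = check_count(n_ovaries, "n_ovaries"),
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Derive child seeds from a master seed
#'
#' Draws `n` distinct integer seeds (below 2^31) from a stream seeded by
#' `seed`, for replicated simulations that each need their own seed.
#'
#' @param seed master seed.
#' @param n number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate the progeny of one cross
#'
#' For each mother, draws a fertilized-egg count (Poisson, or
#' negative-binomial when `dispersion > 0`), assigns each egg a zygote class
#' by sampling egg fate then sperm, applies viability, and discards dead
#' zygotes before counting — only eclosing progeny are scored, as in the
#' real assay. Deterministic for a fixed config seed.
#'
#' @param config a [simulation_config()].
#' @param label label for the simulated cross.
#' @return A [cross_counts()] object with attributes `per_mother` (a
#'   data.frame of per-mother class counts) and `seed`.
#' @examples
#' cfg <- simulation_config(segregation_params(0.25, 0.20), seed = 1)
#' simulate_cross(cfg)
#' @export
simulate_cross <- function(config, label = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_mothers == 0) {
    abort_validation("cannot simulate a cross with zero mothers")
  }
  set.seed(config$seed)
  n_eggs <- if (config$dispersion > 0) {
    stats::rnbinom(config$n_mothers, mu = config$progeny_per_mother,
                   size = 1 / config$dispersion)
  } else {
    stats::rpois(config$n_mothers, config$progeny_per_mother)
  }
  eggs <- egg_class_probabilities(config$params)
  w <- zygote_weights(eggs, config$sperm, config$viability)
  m <- sum(n_eggs)
  cls <- if (m > 0) {
    sample.int(6L, m, replace = TRUE, prob = w$fert)
  } else integer(0)
  alive <- stats::runif(m) < w$survive[cls]
  mother <- rep.int(seq_len(config$n_mothers), n_eggs)

  tab <- matrix(0L, nrow = config$n_mothers, ncol = 6L,
                dimnames = list(NULL, w$class))
  if (any(alive)) {
    t2 <- table(factor(mother[alive], levels = seq_len(config$n_mothers)),
                factor(w$class[cls[alive]], levels = w$class))
    tab <- unclass(t2)
  }
  per_mother <- data.frame(
    mother = seq_len(config$n_mothers),
    fertilized_eggs = n_eggs,
    n_x0 = as.integer(tab[, "x0_son"]),
    n_xxy = as.integer(tab[, "xxy_daughter"]),
    n_normal_daughter = as.integer(tab[, "normal_daughter"]),
    n_normal_son = as.integer(tab[, "normal_son"]))
  per_mother$surviving <- per_mother$n_x0 + per_mother$n_xxy +
    per_mother$n_normal_daughter + per_mother$n_normal_son

  out <- cross_counts(label, config$n_mothers,
                      sum(per_mother$surviving),
                      sum(per_mother$n_x0), sum(per_mother$n_xxy))
  attr(out, "per_mother") <- per_mother
  attr(out, "seed") <- config$seed
  out
}

#' Simulate a fecundity record
#'
#' Eggs per mother are Poisson; each egg survives to pupa with probability
#' `Z * baseline_survival`, where Z is the model's expected viable fraction
#' and the baseline absorbs aneuploidy-independent egg-to-pupa mortality.
#' The 0.88 default calibrates the no-mis-segregation case to the fertility
#' scale of a SPO11-proficient control cross.
#'
#' @param config a [simulation_config()].
#' @param eggs_per_mother_mean mean eggs laid per mother.
#' @param baseline_survival aneuploidy-independent egg-to-pupa survival.
#' @param label label for the record.
#' @return A [fecundity_record()] with attribute `seed`.
#' @export
simulate_fecundity <- function(config, eggs_per_mother_mean = 40,
                               baseline_survival = 0.88, label = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  baseline_survival <- check_probability(baseline_survival, "baseline_survival")
  set.seed(config$seed)
  eggs <- sum(stats::rpois(config$n_mothers, eggs_per_mother_mean))
  z <- expected_viable_fraction(egg_class_probabilities(config$params),
                                config$sperm, config$viability)
  pupae <- if (eggs > 0) stats::rbinom(1, eggs, z * baseline_survival) else 0L
  out <- fecundity_record(label, config$n_mothers, eggs, pupae)
  attr(out, "seed") <- config$seed
  out
}

#' Simulate oocyte-cytology counts
#'
#' Per ovary, draws positives as a binomial out of the configured nuclei per
#' ovary, then sums over ovaries. Optional beta-binomial overdispersion
#' (`icc > 0`) models ovary-to-ovary heterogeneity; off by default.
#'
#' @param config a [simulation_config()].
#' @param endpoint cytology endpoint label.
#' @param stage_range egg-chamber stage range recorded in the output.
#' @param icc intra-ovary correlation for beta-binomial overdispersion; 0
#'   (default) gives plain binomial sampling.
#' @param label label for the record.
#' @return A [cytology_counts()] with attribute `seed`.
#' @export
simulate_cytology <- function(config, endpoint = "dsb_signal",
                              stage_range = "2-8", icc = 0, label = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.numeric(icc) || icc < 0 || icc >= 1) {
    abort_config("icc must be in [0, 1)")
  }
  set.seed(config$seed)
  rate <- config$cytology_positive_rate
  p <- if (icc > 0 && rate > 0 && rate < 1) {
    a <- rate * (1 - icc) / icc
    b <- (1 - rate) * (1 - icc) / icc
    stats::rbeta(config$n_ovaries, a, b)
  } else {
    rep(rate, config$n_ovaries)
  }
  pos <- stats::rbinom(config$n_ovaries, config$n_oocytes_per_ovary, p)
  out <- cytology_counts(label, endpoint, stage_range,
                         sum(pos),
                         config$n_ovaries * config$n_oocytes_per_ovary,
                         config$n_ovaries)
  attr(out, "seed") <- config$seed
  out
}
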