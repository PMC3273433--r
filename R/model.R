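#' Mis-segregation rates of an oocyte population
#'
#' The forward model distinguishes two mutually exclusive aberrant oocyte
#' fates in a SPO11-deficient female:
#'
#' * meiosis-I **nondisjunction** (rate `d`): without a chiasma, both X
#'   homologs can go to one pole; meiosis II then yields two diplo-X and two
#'   nullo-X meiotic products per oocyte;
#' * DSB-induced **chromosome loss** (rate `l`): an unrepaired double-strand
#'   break destroys one X chromatid pair; random segregation leaves one
#'   secondary cell with a single X (one nullo-X and one normal product) and
#'   the other with the intact duplicated X (two normal products).
#'
#' The remaining fraction `1 - d - l` of oocytes segregates normally.
#'
#' @param d probability of meiosis-I X nondisjunction per oocyte.
#' @param l probability of unrepaired-DSB X loss per oocyte.
#' @return An object of class `segregation_params`.
#' @examples
#' segregation_params(d = 0.25, l = 0.20)
#' @export
segregation_params <- function(d, l) {
  if (!is_probability(d) || !is_probability(l) || d + l > 1 + 1e-12) {
    abort_domain(
      "segregation rates must satisfy d >= 0, l >= 0, d + l <= 1 (got d = %s, l = %s)",
      format(d), format(l))
  }
  structure(list(d = as.numeric(d), l = as.numeric(l)),
            class = "segregation_params")
}

#' @export
print.segregation_params <- function(x, ...) {
  cat(sprintf("<segregation_params> nondisjunction d = %.4g, X loss l = %.4g\n",
              x$d, x$l))
  invisible(x)
}

#' Sperm genotype model
#'
#' Fathers are normal XY males; each fertilizing sperm carries the X with
#' probability `p_x`. The 1:1 default reflects Mendelian segregation in the
#' male; it is configurable only for sensitivity analysis.
#'
#' @param p_x probability that a fertilizing sperm carries the X chromosome.
#' @return An object of class `sperm_model`.
#' @export
sperm_model <- function(p_x = 0.5) {
  p_x <- check_probability(p_x, "p_x")
  structure(list(p_x = p_x), class = "sperm_model")
}

#' Zygote viability model
#'
#' Survival probabilities of the six zygote karyotypes produced by the cross.
#' Defaults encode the scoring scheme of the bioassay: X0 sons and XXY
#' daughters are recovered and counted, XXX and Y0 zygotes die, normal XX/XY
#' zygotes survive. Partial viabilities may be supplied for sensitivity
#' analysis.
#'
#' @param v_x0,v_xxy,v_xxx,v_y0,v_normal survival probabilities in `[0, 1]`.
#' @return An object of class `viability_model`.
#' @export
viability_model <- function(v_x0 = 1, v_xxy = 1, v_xxx = 0, v_y0 = 0,
                            v_normal = 1) {
  structure(list(v_x0     = check_probability(v_x0, "v_x0"),
                 v_xxy    = check_probability(v_xxy, "v_xxy"),
                 v_xxx    = check_probability(v_xxx, "v_xxx"),
                 v_y0     = check_probability(v_y0, "v_y0"),
                 v_normal = check_probability(v_normal, "v_normal")),
            class = "viability_model")
}

#' Egg-class probabilities under the mis-segregation model
#'
#' The functional egg pronucleus is a uniform draw among the four meiotic
#' products of the oocyte. A nondisjunctional oocyte contributes products in
#' ratio 2 nullo-X : 2 diplo-X : 0 normal; a loss-affected oocyte 1 nullo-X :
#' 0 diplo-X : 3 normal; a normal oocyte 0 : 0 : 4. Hence
#' `p_nullo = d/2 + l/4`, `p_diplo = d/2`, `p_normal = 1 - d - l/4`.
#'
#' Because chromosome loss produces nullo-X but never diplo-X eggs, any
#' `l > 0` makes `p_nullo > p_diplo`: an excess of nullo-X eggs is the
#' genetic signature of DSB-induced X loss over symmetric nondisjunction.
#'
#' @param params a [segregation_params()] object.
#' @return An object of class `egg_class_distribution` with fields
#'   `p_nullo`, `p_diplo`, `p_normal` summing to one.
#' @examples
#' egg_class_probabilities(segregation_params(d = 1, l = 0))  # 0.5/0.5/0
#' egg_class_probabilities(segregation_params(d = 0, l = 1))  # 0.25/0/0.75
#' @export
egg_class_probabilities <- function(params) {
  stopifnot(inherits(params, "segregation_params"))
  d <- params$d
  l <- params$l
  structure(list(p_nullo  = d / 2 + l / 4,
                 p_diplo  = d / 2,
                 p_normal = 1 - d - l / 4),
            class = "egg_class_distribution")
}

#' @export
print.egg_class_distribution <- function(x, ...) {
  cat(sprintf("<egg_class_distribution> nullo-X %.4g, diplo-X %.4g, normal %.4g\n",
              x$p_nullo, x$p_diplo, x$p_normal))
  invisible(x)
}

as_egg_classes <- function(eggs) {
  if (inherits(eggs, "segregation_params")) {
    return(egg_class_probabilities(eggs))
  }
  if (!inherits(eggs, "egg_class_distribution")) {
    abort_domain("'eggs' must be an egg_class_distribution or segregation_params object")
  }
  s <- eggs$p_nullo + eggs$p_diplo + eggs$p_normal
  if (any(c(eggs$p_nullo, eggs$p_diplo, eggs$p_normal) < -1e-12) ||
      abs(s - 1) > 1e-9) {
    abort_domain("egg-class probabilities must be non-negative and sum to 1")
  }
  eggs
}

# Pre-viability fertilization weights and survival probabilities of the six
# zygote karyotypes. Shared by the conditional progeny distribution and the
# stochastic simulator.
zygote_weights <- function(eggs, sperm, viability) {
  list(
    class   = c("x0_son", "y0_dead", "xxx_dead", "xxy_daughter",
                "normal_daughter", "normal_son"),
    fert    = c(eggs$p_nullo  * sperm$p_x,
                eggs$p_nullo  * (1 - sperm$p_x),
                eggs$p_diplo  * sperm$p_x,
                eggs$p_diplo  * (1 - sperm$p_x),
                eggs$p_normal * sperm$p_x,
                eggs$p_normal * (1 - sperm$p_x)),
    survive = c(viability$v_x0, viability$v_y0, viability$v_xxx,
                viability$v_xxy, viability$v_normal, viability$v_normal))
}

#' Scored progeny-class probabilities, conditional on zygote survival
#'
#' Crosses each egg class with X- or Y-bearing sperm, applies zygote
#' viability, and returns the distribution over the four classes that can be
#' scored among eclosing progeny: X0 sons (nullo-X egg + X sperm), XXY
#' daughters (diplo-X egg + Y sperm), and normal daughters/sons. Y0 and XXX
#' zygotes contribute only to the lethal complement of the normalizer.
#'
#' @param eggs an `egg_class_distribution` (or `segregation_params`, which is
#'   converted first).
#' @param sperm a [sperm_model()].
#' @param viability a [viability_model()].
#' @return An object of class `progeny_class_distribution` with fields
#'   `f_x0_son`, `f_xxy_daughter`, `f_normal_daughter`, `f_normal_son`
#'   summing to one.
#' @examples
#' progeny_class_probabilities(segregation_params(d = 0.5, l = 0))
#' @export
progeny_class_probabilities <- function(eggs, sperm = sperm_model(),
                                        viability = viability_model()) {
  eggs <- as_egg_classes(eggs)
  stopifnot(inherits(sperm, "sperm_model"),
            inherits(viability, "viability_model"))
  w <- zygote_weights(eggs, sperm, viability)
  surv <- w$fert * w$survive
  z <- sum(surv)
  if (z <= 0) {
    abort_domain("degenerate model: no zygote class has positive survival mass")
  }
  p <- surv / z
  names(p) <- w$class
  structure(list(f_x0_son          = unname(p["x0_son"]),
                 f_xxy_daughter    = unname(p["xxy_daughter"]),
                 f_normal_daughter = unname(p["normal_daughter"]),
                 f_normal_son      = unname(p["normal_son"])),
            class = "progeny_class_distribution")
}

#' @export
print.progeny_class_distribution <- function(x, ...) {
  cat(sprintf("<progeny_class_distribution> X0 son %.4g, XXY daughter %.4g, normal daughter %.4g, normal son %.4g\n",
              x$f_x0_son, x$f_xxy_daughter, x$f_normal_daughter, x$f_normal_son))
  invisible(x)
}

#' Expected viable fraction of fertilized eggs
#'
#' The normalizer Z of the conditional progeny distribution: the probability
#' that a fertilized egg yields a viable zygote. With default sperm and
#' viability, `Z = 1 - d/2 - l/8` — aneuploid eggs halve their survival
#' because only one sperm class rescues each.
#'
#' @inheritParams progeny_class_probabilities
#' @return A single probability.
#' @examples
#' expected_viable_fraction(segregation_params(d = 1, l = 0))  # 0.5
#' @export
expected_viable_fraction <- function(eggs, sperm = sperm_model(),
                                     viability = viability_model()) {
  eggs <- as_egg_classes(eggs)
  stopifnot(inherits(sperm, "sperm_model"),
            inherits(viability, "viability_model"))
  w <- zygote_weights(eggs, sperm, viability)
  sum(w$fert * w$survive)
}
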