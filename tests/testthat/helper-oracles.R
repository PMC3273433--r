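# Independent oracles, deliberately written without reusing package internals.

# Exhaustive enumeration over {oocyte fate} x {4 meiotic products} x
# {sperm X/Y} x {viability}. Fates carry the X-dosage of their four meiotic
# products: normal (1,1,1,1); meiosis-I nondisjunction (2,2,0,0); unrepaired
# DSB loss (0,1,1,1). Returns the viable fraction and the survival-
# conditional distribution over the four scored classes.
oracle_progeny <- function(d, l, p_x = 0.5,
                           v = c(x0 = 1, y0 = 0, xxx = 0, xxy = 1, normal = 1)) {
  fates <- list(normal = c(1, 1, 1, 1),
                nondisjunction = c(2, 2, 0, 0),
                loss = c(0, 1, 1, 1))
  fate_p <- c(normal = 1 - d - l, nondisjunction = d, loss = l)
  w <- c(x0_son = 0, y0_dead = 0, xxx_dead = 0, xxy_daughter = 0,
         normal_daughter = 0, normal_son = 0)
  surv <- c(x0_son = v[["x0"]], y0_dead = v[["y0"]], xxx_dead = v[["xxx"]],
            xxy_daughter = v[["xxy"]], normal_daughter = v[["normal"]],
            normal_son = v[["normal"]])
  for (f in names(fates)) {
    for (x_dose in fates[[f]]) {
      for (sperm_x in c(TRUE, FALSE)) {
        pr <- fate_p[[f]] * 0.25 * if (sperm_x) p_x else 1 - p_x
        cls <- if (x_dose == 0 && sperm_x) "x0_son"
        else if (x_dose == 0) "y0_dead"
        else if (x_dose == 2 && sperm_x) "xxx_dead"
        else if (x_dose == 2) "xxy_daughter"
        else if (sperm_x) "normal_daughter"
        else "normal_son"
        w[cls] <- w[cls] + pr
      }
    }
  }
  viable <- sum(w * surv)
  list(viable = viable, cond = (w * surv) / viable)
}

# Grid search of the 3-class multinomial log-likelihood over the (d, l)
# simplex; kept independent of the package likelihood code.
oracle_grid_fit <- function(n0, n2, nr, step = 0.005, d_max = 1, l_max = 1) {
  g <- expand.grid(d = seq(0, d_max, by = step), l = seq(0, l_max, by = step))
  g <- g[g$d + g$l <= 1, ]
  N <- n0 + n2 + nr
  z <- 1 - g$d / 2 - g$l / 8
  p0 <- (g$d / 4 + g$l / 8) / z
  p2 <- (g$d / 4) / z
  pr <- 1 - p0 - p2
  lt <- function(n, p) if (n == 0) 0 else ifelse(p > 0, n * log(p), -Inf)
  ll <- lt(n0, p0) + lt(n2, p2) + lt(nr, pr)
  i <- which.max(ll)
  list(d = g$d[i], l = g$l[i], loglik = ll[i], step = step)
}

# Wilson score interval from the raw formula (oracle for binomial_ci).
oracle_wilson <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "nullox", mustWork = TRUE)
}

# Table rows used across tests: the published raw counts of the two
# nondisjunction experiments.
exp1_rows <- function() read_cross_table(fixture_path("crosses_exp1.tsv"))
exp2_rows <- function() read_cross_table(fixture_path("crosses_exp2.tsv"))
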