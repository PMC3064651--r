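#' Coefficient of variation
#'
#' CV = 100 * SD / mean, with the sample (n - 1) standard deviation. A
#' scale-free dispersion measure: invariant under multiplication of the
#' trait by any positive constant.
#'
#' @param x Numeric vector with at least two values and nonzero mean.
#' @return CV as a percentage.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2L) stop("CV needs at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Relative testes mass under a rodent allometry
#'
#' Testes mass scales allometrically with body mass; the ratio of observed
#' to predicted testes mass, Y_pred = a * X^b with X the observed body mass,
#' removes the body-size component and is the standard proxy for the level
#' of sperm competition a species experiences. Defaults are the rodent
#' calibration a = 0.031, b = 0.77.
#'
#' @param body_mass Body mass in grams (> 0), vectorized.
#' @param testes_mass Combined testes mass in grams (> 0), vectorized.
#' @param a Allometric coefficient (> 0).
#' @param b Allometric exponent, in (0, 1.5].
#' @return Dimensionless ratio observed / predicted testes mass.
#' @export
relative_testes_mass <- function(body_mass, testes_mass, a = 0.031,
                                 b = 0.77) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop("allometric coefficient 'a' must be a positive scalar",
         call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || b <= 0 || b > 1.5) {
    stop("allometric exponent 'b' must lie in (0, 1.5]", call. = FALSE)
  }
  if (any(body_mass <= 0) || any(testes_mass <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  testes_mass / (a * body_mass^b)
}

#' Apply a recorded transformation to a trait vector
#'
#' `"log10"` requires strictly positive values. `"arcsine_sqrt"` treats
#' values as percentages in \[0, 100\]: they are divided by 100 before
#' asin(sqrt(p)).
#'
#' @param x Numeric vector.
#' @param tag One of `"none"`, `"log10"`, `"arcsine_sqrt"`.
#' @return Transformed vector.
#' @export
apply_transform <- function(x, tag = c("none", "log10", "arcsine_sqrt")) {
  tag <- match.arg(tag)
  switch(tag,
    none = x,
    log10 = {
      bad <- which(x <= 0)
      if (length(bad) > 0L) {
        stop("log10 transform requires positive values; offending value ",
             x[bad[1L]], " at position ", bad[1L], call. = FALSE)
      }
      log10(x)
    },
    arcsine_sqrt = {
      bad <- which(x < 0 | x > 100)
      if (length(bad) > 0L) {
        stop("arcsine-sqrt transform requires percentages in [0, 100]; ",
             "offending value ", x[bad[1L]], " at position ", bad[1L],
             call. = FALSE)
      }
      asin(sqrt(x / 100))
    }
  )
}

# trait matrix on the analysis scale, transformation tags applied
transformed_traits <- function(table, traits = trait_names()) {
  tags <- transform_tags(table)
  out <- sapply(traits, function(tr) apply_transform(table[[tr]], tags[[tr]]))
  rownames(out) <- table$species
  out
}

#' Test a sample for normality
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal distribution
#' with mean and SD estimated from the data. Because the parameters are
#' estimated, the naive KS p-value is anticonservative; the default method
#' uses the Lilliefors small-sample calibration ([nortest::lillie.test()]).
#' The uncalibrated KS p-value is available as `method = "ks"`.
#'
#' @param x Numeric vector, at least 4 values.
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @return List with `statistic` and `p.value`.
#' @export
normality_test <- function(x, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  if (length(x) < 4L) stop("normality test needs at least 4 values",
                           call. = FALSE)
  if (method == "lilliefors") {
    res <- nortest::lillie.test(x)
  } else {
    res <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
  }
  list(statistic = unname(res$statistic), p.value = unname(res$p.value))
}

#' Descriptive summary of a trait table
#'
#' Per-trait mean, sample SD and CV on the untransformed species means,
#' plus the per-species relative testes mass column.
#'
#' @param table A [trait_table].
#' @param a,b Allometry parameters passed to [relative_testes_mass()].
#' @return List with `traits` (a data.frame of mean/sd/cv per trait,
#'   including the derived `relative_testes_mass` row) and `species`
#'   (species names with their relative testes mass).
#' @export
describe_traits <- function(table, a = 0.031, b = 0.77) {
  stopifnot(inherits(table, "trait_table"))
  rtm <- relative_testes_mass(table$body_mass, table$testes_mass, a, b)
  cols <- c(trait_names(), "relative_testes_mass")
  vals <- c(lapply(trait_names(), function(tr) table[[tr]]), list(rtm))
  summ <- data.frame(
    trait = cols,
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, stats::sd, numeric(1)),
    cv = vapply(vals, coefficient_of_variation, numeric(1)),
    row.names = NULL
  )
  list(traits = summ,
       species = data.frame(species = table$species,
                            relative_testes_mass = rtm))
}
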