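# Dunn pairwise z tests on mean ranks with tie correction, Holm-adjusted.
# post hoc companion to kruskal.test.
dunn_posthoc <- function(x, g, p_adjust_method = "holm") {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  pairs <- t(combn(levels(g), 2))
  z <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    se <- sqrt((n * (n + 1) / 12) * tie_corr * (1 / ni[[i]] + 1 / ni[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[, 1], group2 = pairs[, 2], z = z,
             p_unadj = p, p_adj = p.adjust(p, method = p_adjust_method))
}

#' Mean fluorescence intensity of a square ROI
#'
#' Arithmetic mean of the pixel values inside a square region (default
#' 20 x 20 um), as used to compare cytoplasmic toxin abundance between
#' cells.
#'
#' @param image a [super_res_image] or numeric matrix.
#' @param x_um,y_um lower-left corner of the square in um.
#' @param size_um side length of the square in um.
#' @param pixel_size pixel size in nm (taken from the image if available).
#' @return mean intensity in arbitrary fluorescence units.
#' @export
roi_mean_intensity <- function(image, x_um, y_um, size_um = 20,
                               pixel_size = NULL) {
  if (inherits(image, "super_res_image")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    image <- image$values
  }
  stopifnot(is.matrix(image), !is.null(pixel_size))
  px <- pixel_size / 1000 # um per pixel
  x0 <- floor(x_um / px) + 1; y0 <- floor(y_um / px) + 1
  nx <- round(size_um / px); ny <- nx
  if (x0 < 1 || y0 < 1 || x0 + nx - 1 > ncol(image) || y0 + ny - 1 > nrow(image))
    stop("ROI square falls outside the image")
  mean(image[y0:(y0 + ny - 1), x0:(x0 + nx - 1)])
}

#' Kruskal-Wallis comparison of ROI intensities with Dunn post hoc
#'
#' Nonparametric omnibus comparison of per-cell mean intensities across
#' conditions (tie-corrected H), followed by Dunn pairwise z tests with Holm
#' adjustment. Conditions with fewer than 3 cells are excluded with a
#' warning.
#'
#' @param table data frame with columns `condition` and `mean_intensity`
#'   (one row per cell).
#' @return list with `H`, `df`, `p_value`, the pairwise table and the
#'   conditions used.
#' @export
kruskal_wallis_with_posthoc <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("condition", "mean_intensity") %in% names(table)))
  if (any(table$mean_intensity < 0)) stop("intensities must be nonnegative")
  counts <- table(table$condition)
  drop <- names(counts)[counts < 3]
  if (length(drop)) {
    warning("excluding conditions with fewer than 3 cells: ",
            paste(drop, collapse = ", "))
    table <- table[!table$condition %in% drop, ]
  }
  if (length(unique(table$condition)) < 2)
    stop("need at least 2 conditions with 3 or more cells")
  x <- table$mean_intensity
  g <- factor(as.character(table$condition))
  if (length(unique(x)) == 1) {
    pairs <- t(combn(levels(g), 2))
    return(list(H = 0, df = nlevels(g) - 1, p_value = 1,
                pairwise = data.frame(group1 = pairs[, 1],
                                      group2 = pairs[, 2], p_adj = 1),
                conditions = levels(g)))
  }
  kw <- kruskal.test(x, g)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = dunn_posthoc(x, g),
       conditions = levels(g))
}

#' Degree of labeling of a dye-conjugated protein
#'
#' Moles of dye per mole of protein: the molar dye concentration from the
#' peak absorbance and extinction coefficient, divided by the molar protein
#' concentration from the mass concentration and molecular weight:
#' `DOL = (A / epsilon) / (c_mg_ml / MW)` (with mg/ml equal to g/L this is
#' the only dimensionally consistent form of the labeling-efficiency
#' relation).
#'
#' @param absorbance peak absorbance of the dye (e.g. at 554 nm for
#'   Alexa 546, 650 nm for Alexa 647).
#' @param extinction_coeff molar extinction coefficient in 1/(M cm)
#'   (203000 for Alexa 546; 270000 for Alexa 647).
#' @param molecular_weight protein molecular weight in g/mol.
#' @param protein_mg_ml protein mass concentration in mg/ml.
#' @return moles of dye per mole of protein.
#' @export
labeling_efficiency <- function(absorbance, extinction_coeff,
                                molecular_weight, protein_mg_ml) {
  vals <- c(absorbance, extinction_coeff, molecular_weight, protein_mg_ml)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs must be positive")
  (absorbance / extinction_coeff) / (protein_mg_ml / molecular_weight)
}

#' Tabashnik synergism factor for a binary toxin mixture
#'
#' The additive expectation for the mixture LC50 is the harmonic mean of the
#' component LC50s weighted by the mixture proportions,
#' `LC50_theor = 1 / (ratio / lc50_a + (1 - ratio) / lc50_b)`; the synergism
#' factor divides this theoretical toxicity by the observed mixture LC50.
#' SF > 1 indicates synergism, SF < 1 antagonism.
#'
#' @param lc50_a,lc50_b component LC50s (same units, e.g. ng/ml).
#' @param observed observed LC50 of the mixture.
#' @param ratio mass fraction of component a in the mixture (default 1:1).
#' @return list with `theoretical_lc50` and `synergism_factor`.
#' @export
tabashnik_sf <- function(lc50_a, lc50_b, observed, ratio = 0.5) {
  vals <- c(lc50_a, lc50_b, observed)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("LC50 values must be positive")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be strictly between 0 and 1")
  theor <- 1 / (ratio / lc50_a + (1 - ratio) / lc50_b)
  list(theoretical_lc50 = theor, synergism_factor = theor / observed)
}
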