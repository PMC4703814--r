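# Calibration of protein OTU identity thresholds from paired 16S rRNA /
# marker-protein strain sequences: all-pairs percent identities, ordinary
# least squares of protein identity on 16S identity, and mapping of the
# canonical 16S taxonomic thresholds (species 98.7, genus 94.5, family
# 86.5, phylum 75 percent) onto the protein marker.

#' All-pairs 16S/protein identities for a strain set
#'
#' @param strains Data frame with columns `strain_id`, `protein`, `s16`
#'   (e.g. from [simulate_strain_pairs()]).
#' @return Data frame with one row per unordered strain pair and columns
#'   `strain_a`, `strain_b`, `s16` and `sprot` (percent identities).
#' @export
build_pairs <- function(strains) {
  if (nrow(strains) < 3) stop("need at least 3 strains")
  if (anyDuplicated(strains$strain_id))
    stop("duplicate strain_id in strain set")
  idx <- utils::combn(nrow(strains), 2)
  data.frame(
    strain_a = strains$strain_id[idx[1, ]],
    strain_b = strains$strain_id[idx[2, ]],
    s16 = apply(idx, 2, function(k)
      pairwise_identity(strains$s16[k[1]], strains$s16[k[2]], "nucleotide")),
    sprot = apply(idx, 2, function(k)
      pairwise_identity(strains$protein[k[1]], strains$protein[k[2]],
                        "protein")),
    stringsAsFactors = FALSE)
}

#' Default 16S taxonomic thresholds (percent identity)
#' @return Named numeric vector: species 98.7, genus 94.5, family 86.5,
#'   phylum 75.
#' @export
s16_thresholds <- function() {
  c(species = 98.7, genus = 94.5, family = 86.5, phylum = 75)
}

#' Fit the protein-vs-16S identity calibration model
#'
#' Ordinary least squares `sprot = intercept + slope * s16` over all
#' strain pairs; the supplied 16S thresholds are mapped through the fitted
#' line, rounded to integer percent and clamped to \[0, 100\].
#'
#' @param pairs Pair table from [build_pairs()].
#' @param target_16s_thresholds Named numeric vector of 16S thresholds
#'   (percent).
#' @return An object of class `masd_calibration` with components `slope`,
#'   `intercept`, `r_squared`, `n_pairs`, `mapped_thresholds` and the
#'   underlying `lm` fit.
#' @export
fit_threshold_model <- function(pairs,
                                target_16s_thresholds = s16_thresholds()) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (stats::var(pairs$s16) == 0)
    stop("zero variance in 16S identities: slope undefined")
  fit <- stats::lm(sprot ~ s16, data = pairs)
  cf <- stats::coef(fit)
  sst <- sum((pairs$sprot - mean(pairs$sprot))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  model <- structure(list(
    slope = unname(cf["s16"]),
    intercept = unname(cf["(Intercept)"]),
    r_squared = r2,
    n_pairs = nrow(pairs),
    targets = target_16s_thresholds,
    fit = fit, pairs = pairs), class = "masd_calibration")
  model$mapped_thresholds <- stats::setNames(
    map_threshold(model, target_16s_thresholds),
    names(target_16s_thresholds))
  model
}

#' Map a 16S identity threshold onto the protein marker
#'
#' Evaluates the fitted line at `s16`, rounds to the nearest integer
#' percent and clamps to \[0, 100\].
#'
#' @param model A `masd_calibration`.
#' @param s16 16S identity threshold(s), percent.
#' @return Integer protein identity threshold(s), percent.
#' @export
map_threshold <- function(model, s16) {
  stopifnot(inherits(model, "masd_calibration"))
  pmin(100, pmax(0, round(model$intercept + model$slope * s16)))
}

#' @export
print.masd_calibration <- function(x, ...) {
  cat("Protein/16S identity calibration (", x$n_pairs, " pairs)\n", sep = "")
  cat(sprintf("  sprot = %.3f + %.3f * s16   (R^2 = %.3f)\n",
              x$intercept, x$slope, x$r_squared))
  if (length(x$mapped_thresholds)) {
    cat("  mapped thresholds (% protein identity):\n")
    for (nm in names(x$mapped_thresholds))
      cat(sprintf("    %-8s 16S %5.1f%% -> %d%%\n", nm, x$targets[[nm]],
                  x$mapped_thresholds[[nm]]))
  }
  invisible(x)
}

#' @export
coef.masd_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.masd_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata)) newdata <- data.frame(s16 = newdata)
  stats::predict(object$fit, newdata = newdata)
}

#' @export
plot.masd_calibration <- function(x, ...) {
  plot(x$pairs$s16, x$pairs$sprot,
       xlab = "16S rRNA identity [%]", ylab = "protein identity [%]",
       pch = 19, col = "grey30", ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  graphics::abline(v = x$targets, lty = 2, col = "grey60")
  invisible(x)
}
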