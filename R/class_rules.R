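#' Milk classes under EU Regulation EC No. 1308/2013
#'
#' The four ground-truth categories used throughout the package, in the fixed
#' reporting order used by all confusion matrices and metric tables.
#'
#' @return Character vector `c("whole", "no_class", "semi_skimmed", "skimmed")`.
#' @export
milk_classes <- function() c("whole", "no_class", "semi_skimmed", "skimmed")

#' Fat-content thresholds for the EU milk classes
#'
#' Skimmed milk has fat below `skimmed_max`, semi-skimmed milk between
#' `semi_min` and `semi_max` inclusive, and whole milk strictly above
#' `whole_min`; every other fat content is "no_class". The whole-milk boundary
#' is strict (exactly 3.5 % is no_class); override the thresholds to obtain an
#' inclusive reading.
#'
#' @param skimmed_max Upper (exclusive) fat bound for skimmed milk, % m/m.
#' @param semi_min,semi_max Inclusive fat interval for semi-skimmed milk.
#' @param whole_min Lower (exclusive) fat bound for whole milk.
#' @return A named list of the four thresholds, class `"milk_thresholds"`.
#' @export
milk_thresholds <- function(skimmed_max = 0.5, semi_min = 1.5,
                            semi_max = 1.8, whole_min = 3.5) {
  assert_scalar_number(skimmed_max, "skimmed_max", lower = 0)
  assert_scalar_number(semi_min, "semi_min", lower = 0)
  assert_scalar_number(semi_max, "semi_max", lower = 0)
  assert_scalar_number(whole_min, "whole_min", lower = 0)
  if (!(skimmed_max <= semi_min && semi_min <= semi_max && semi_max <= whole_min))
    stop_ls("thresholds must satisfy skimmed_max <= semi_min <= semi_max <= whole_min",
            class = "lactospec_argument_error")
  structure(list(skimmed_max = skimmed_max, semi_min = semi_min,
                 semi_max = semi_max, whole_min = whole_min),
            class = "milk_thresholds")
}

#' Map labelled fat content to its EU milk class
#'
#' @param fat_pct Numeric vector of fat contents (% m/m), all `>= 0`.
#' @param thresholds A [milk_thresholds()] object.
#' @return Factor with levels [milk_classes()].
#' @examples
#' milk_class_from_fat(c(3.71, 0.98, 1.59, 0.17, 3.5))
#' @export
milk_class_from_fat <- function(fat_pct, thresholds = milk_thresholds()) {
  if (!is.numeric(fat_pct) || anyNA(fat_pct) || any(!is.finite(fat_pct)))
    stop_ls("`fat_pct` must be finite and non-missing",
            class = "lactospec_argument_error")
  if (any(fat_pct < 0))
    stop_ls("`fat_pct` must be non-negative",
            class = "lactospec_argument_error")
  t <- thresholds
  out <- rep("no_class", length(fat_pct))
  out[fat_pct < t$skimmed_max] <- "skimmed"
  out[fat_pct >= t$semi_min & fat_pct <= t$semi_max] <- "semi_skimmed"
  out[fat_pct > t$whole_min] <- "whole"
  factor(out, levels = milk_classes())
}

# the open fat interval that generates a given class (used by the simulator);
# no_class uses the low gap (skimmed_max, semi_min) where its observed mean sits
class_fat_interval <- function(class, thresholds = milk_thresholds()) {
  t <- thresholds
  switch(class,
         skimmed      = c(0, t$skimmed_max),
         semi_skimmed = c(t$semi_min, t$semi_max),
         whole        = c(t$whole_min, Inf),
         no_class     = c(t$skimmed_max, t$semi_min),
         stop_ls("unknown milk class: ", class))
}
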