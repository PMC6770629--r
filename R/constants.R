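# Published scoring constants, exposed read-only through accessor functions.
# Provenance: Nutri-Score point bands as published with the 2017 French
# decree (derived from the UK FSA/Ofcom nutrient profiling model); MTL bands
# from the UK Department of Health front-of-pack technical guidance (2016);
# reference intakes from EU Regulation 1169/2011 Annex XIII; AHEI-2010
# component anchors from Chiuve et al.'s index definition.

# Negative-point bands: a nutrient value v earns the number of thresholds
# strictly exceeded, i.e. points = sum(v > band). Each band has 10 entries.
.ns_negative_bands <- list(
  energy_kj  = c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350),
  sugar_g    = c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
  satfat_g   = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
  sodium_mg  = c(90, 180, 270, 360, 450, 540, 630, 720, 810, 900)
)

# Positive-point bands, same convention (points = thresholds exceeded).
.ns_positive_bands <- list(
  fvnl_percent = c(40, 60, 80, 80, 80),  # 0/1/2 then jump to 5 above 80
  fiber_g      = c(0.9, 1.9, 2.8, 3.7, 4.7),
  protein_g    = c(1.6, 3.2, 4.8, 6.4, 8.0)
)

# Final-points -> grade cut-points for general foods.
.ns_grade_breaks <- c(A = -1, B = 2, C = 10, D = 18)  # upper bound of each grade

#' Nutri-Score point bands
#'
#' The published point-band thresholds used by [nutriscore_food()]. A
#' nutrient earns one point per threshold strictly exceeded per 100 g:
#' negative components (energy kJ, sugars g, saturated fat g, sodium mg)
#' score 0-10, positive components (fruit/vegetable/nut/legume percentage,
#' fiber g, protein g) score 0-5. Returned as a read-only list; modifying
#' the copy has no effect on scoring.
#'
#' @return A list with elements `negative` and `positive`, each a named list
#'   of ascending numeric thresholds, plus `grade_breaks`, the upper
#'   final-point bound of grades A-D (E is everything above).
#' @export
#' @examples
#' ns_point_bands()$negative$sugar_g
ns_point_bands <- function() {
  list(
    negative = .ns_negative_bands,
    positive = .ns_positive_bands,
    grade_breaks = .ns_grade_breaks
  )
}

# MTL per-100 g bands (foods): green upper bound, amber upper bound; above
# amber is red. Per-portion red triggers apply to portions > 100 g.
.mtl_food_bands <- tibble::tibble(
  nutrient     = c("fat", "saturates", "sugars", "salt"),
  green_max    = c(3.0, 1.5, 5.0, 0.3),
  amber_max    = c(17.5, 5.0, 22.5, 1.5),
  portion_red  = c(21.0, 6.0, 27.0, 1.8)
)

# EU reference intakes used for the percent-RI readout on the label.
.reference_intakes <- c(
  energy_kcal = 2000, fat = 70, saturates = 20, sugars = 90, salt = 6
)

#' Multiple Traffic Light color bands
#'
#' Per-100 g thresholds used by [mtl_colors()]: at or below `green_max` is
#' green, above `amber_max` is red, amber in between. `portion_red` is the
#' per-portion quantity above which a nutrient is forced red regardless of
#' its per-100 g color (applied to food portions over 100 g). Beverage
#' thresholds are these values halved (portion trigger applied over 150 g).
#'
#' @param category `"food"` or `"beverage"`.
#' @return A tibble with columns `nutrient`, `green_max`, `amber_max`,
#'   `portion_red`. Salt is in g (derived from sodium at 2.5 g salt per
#'   1000 mg sodium); fat, saturates and sugars in g.
#' @export
mtl_bands <- function(category = c("food", "beverage")) {
  category <- match.arg(category)
  bands <- .mtl_food_bands
  if (category == "beverage") {
    bands <- dplyr::mutate(bands, dplyr::across(
      c("green_max", "amber_max", "portion_red"), ~ .x / 2))
  }
  bands
}

#' EU reference intakes
#'
#' Daily reference intakes used for the percent-RI figures displayed on the
#' Multiple Traffic Light label.
#'
#' @return Named numeric vector (energy kcal; fat, saturates, sugars, salt
#'   in g).
#' @export
reference_intakes <- function() .reference_intakes

# AHEI-2010 anchors for the nine retained components. `worst` scores 0,
# `best` scores 10, linear in between; direction is implied by the ordering
# (best < worst means less is better). Sodium is decile-ranked against a
# cohort distribution and has no fixed anchors here.
.ahei_anchors <- tibble::tibble(
  component = c("vegetables", "fruit", "whole_grains", "ssb_juice",
                "nuts_legumes", "red_processed_meat", "trans_fat",
                "long_chain_n3", "sodium"),
  unit = c("servings/day", "servings/day", "g/day", "servings/day",
           "servings/day", "servings/day", "% of energy", "mg/day",
           "cohort decile"),
  worst = c(0, 0, 0, 1, 0, 1.5, 4, 0, NA),
  best  = c(5, 4, 90, 0, 1, 0, 0.5, 250, NA)
)

#' AHEI-2010 component anchors
#'
#' Scoring anchors for the nine diet-quality components retained in the
#' modified index (alcohol and polyunsaturated fat are dropped, so the
#' maximum is 90 rather than 110). Each component scores 0 at `worst`,
#' 10 at `best`, linearly in between. The whole-grain optimum is
#' sex-specific in the published index (75 g/day women, 90 g/day men);
#' baskets here are household-level so the 90 g/day anchor is the default
#' (override via `modified_ahei(anchors = )`). Sodium is scored by cohort
#' decile rank instead of fixed anchors.
#'
#' @return A tibble with columns `component`, `unit`, `worst`, `best`.
#' @export
ahei_anchors <- function() .ahei_anchors

# kJ per kcal used wherever energy units are interconverted.
.kj_per_kcal <- 4.184

# g of salt per mg of sodium (standard conversion).
.salt_g_per_sodium_mg <- 2.5 / 1000
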