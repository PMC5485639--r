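# Feeding-standards constants used throughout the herd model. These are
# fixed, simplified forms of ruminant energy/protein feeding standards:
# maintenance scales with metabolic weight, lactation and gain draw on
# dietary ME at fixed partial efficiencies, and tissue mobilization buffers
# part of any energy deficit.
.kc <- list(
  km = 0.7,            # efficiency of ME use for maintenance
  kl = 0.6,            # efficiency of ME use for lactation
  kg = 0.43,           # efficiency of ME use for gain
  maint_coef = 0.26,   # MJ NE/kg^0.75/day maintenance coefficient
  e_gain = 35,         # MJ NE per kg liveweight gain
  e_mobil = 28,        # MJ ME-equivalent per kg tissue mobilized
  milk_cp = 0.033,     # kg crude protein per kg milk
  cp_eff = 0.6,        # efficiency of dietary CP use for milk protein
  preg_peak = 12,      # MJ/day pregnancy cost in the final gestation month
  pmax_conception = 0.35,  # max monthly conception probability
  conception_slope = 12,   # logistic slope on body condition
  conception_mid = 0.8,    # condition at half-maximal conception
  cond_mort = 0.02,        # extra monthly mortality per unit condition below
  cond_mort_threshold = 0.75,  # ... this threshold
  anoestrus = 2,       # months post-partum before conception possible
  gestation = 9,       # months
  weaning = 6,         # months
  weight_floor = 0.75, # lactating mobilization floor, fraction of SRW
  mobil_buffer = 0.2,  # share of the milk-energy deficit buffered by tissue
  days = 365.25 / 12   # days per simulation month
)

#' Breed parameter set
#'
#' @param name Breed label.
#' @param mature_weight Standard reference (mature) weight, kg.
#' @param birth_weight Calf birth weight, kg.
#' @param potential_peak_milk Peak daily milk at mature weight, kg/day.
#' @param lactation_length Months (4-12).
#' @param milk_fat Fat fraction of fresh milk (0-0.12).
#' @param age_first_mating Months.
#' @param growth_rate_potential Potential gain of growing stock, kg/day.
#' @returns A list of class `breed_params`.
#' @export
breed_params <- function(name, mature_weight, birth_weight,
                         potential_peak_milk, lactation_length, milk_fat,
                         age_first_mating, growth_rate_potential) {
  stopifnot(mature_weight > 0, milk_fat > 0, milk_fat <= 0.12,
            lactation_length >= 4, lactation_length <= 12,
            birth_weight > 0, potential_peak_milk >= 0,
            age_first_mating > 0, growth_rate_potential > 0)
  structure(list(name = name, mature_weight = mature_weight,
                 birth_weight = birth_weight,
                 potential_peak_milk = potential_peak_milk,
                 lactation_length = lactation_length, milk_fat = milk_fat,
                 age_first_mating = age_first_mating,
                 growth_rate_potential = growth_rate_potential),
            class = "breed_params")
}

#' Default breed parameter sets
#'
#' Mature weights follow the simulated systems (Zebu and indigenous cattle
#' 350 kg, Ethiopian crossbred 420 kg, Indian crossbred 500 kg, buffalo
#' 450 kg). Potential peak milk, lactation length, fat content, age at
#' first mating and growth potential are calibration values chosen so that
#' baseline household scenarios produce yields in the range typical of
#' each system while improved genetics and feeding can express the
#' documented multi-fold responses; they are assumptions, not measured
#' values (see the methods vignette).
#'
#' @returns Named list of [breed_params()] objects: `zebu`,
#'   `crossbred_ethiopia`, `local_india`, `crossbred_india`, `buffalo`.
#' @export
default_breeds <- function() {
  list(
    zebu = breed_params("zebu", 350, 22, 4.5, 8, 0.045, 30, 0.35),
    crossbred_ethiopia = breed_params("crossbred_ethiopia", 420, 28, 8, 10,
                                      0.040, 24, 0.55),
    local_india = breed_params("local_india", 350, 22, 4.2, 8, 0.045, 30,
                               0.35),
    crossbred_india = breed_params("crossbred_india", 500, 30, 8, 10,
                                   0.040, 22, 0.60),
    buffalo = breed_params("buffalo", 450, 32, 8, 10, 0.070, 30, 0.45)
  )
}

#' Feed resource description
#'
#' @param name Feed label.
#' @param dm Dry-matter fraction of fresh weight (0-1].
#' @param me Metabolisable energy, MJ/kg DM (4-14).
#' @param cp Crude protein fraction of DM (scalar or length-12 monthly
#'   vector for seasonal feeds).
#' @param price Currency per kg fresh.
#' @param monthly_supply On-farm availability, kg fresh per calendar month
#'   (scalar or length-12 vector; 0 for purchased-only feeds).
#' @param purchasable Can deficits be bought at `price`?
#' @param carryover Does unused stock carry to the next month (stockpiled
#'   residues/hay) or spoil (fresh pasture and green feed)?
#' @returns A list of class `feed_resource`.
#' @export
feed_resource <- function(name, dm, me, cp, price = 0, monthly_supply = 0,
                          purchasable = FALSE, carryover = FALSE) {
  stopifnot(dm > 0, dm <= 1, me >= 4, me <= 14,
            all(cp >= 0), all(cp <= 0.5),
            length(cp) %in% c(1L, 12L),
            length(monthly_supply) %in% c(1L, 12L),
            all(monthly_supply >= 0), price >= 0)
  structure(list(name = name, dm = dm, me = me,
                 cp = if (length(cp) == 1L) rep(cp, 12) else cp,
                 price = price,
                 monthly_supply = if (length(monthly_supply) == 1L)
                   rep(monthly_supply, 12) else monthly_supply,
                 purchasable = purchasable, carryover = carryover),
            class = "feed_resource")
}

#' Stage-wise lactation curve
#'
#' Flat-topped shape: linear rise through month 1 (month mean 0.6 of
#' plateau), plateau at 1, then a linear decline over the final third of
#' the lactation down to 0.25 of plateau at the last month. Zero outside
#' the lactation.
#'
#' @param m Lactation month (1-based; 0 = dry).
#' @param lactation_length Months.
#' @returns Curve multiplier(s) in `[0, 1]`.
#' @export
lactation_curve <- function(m, lactation_length) {
  L <- lactation_length
  decline_start <- L - L / 3
  out <- ifelse(m <= 0 | m > L, 0,
         ifelse(m == 1, 0.6,
         ifelse(m <= decline_start, 1,
                1 - 0.75 * (m - decline_start) / (L / 3))))
  pmax(out, 0)
}
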