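# Cohort state: a plain data.frame with one row per (class, reproductive
# state, age) cohort. Counts are continuous head; dynamics are
# expected-value by default. Construction and subsetting go through the
# cheap helpers below because the simulator touches the state thousands of
# times per run.
new_cohorts <- function(class = character(), count = numeric(),
                        age = numeric(), weight = numeric(),
                        lact = integer(), preg = integer()) {
  n <- length(class)
  structure(list(class = class, count = rep_len(count, n),
                 age = rep_len(age, n), weight = rep_len(weight, n),
                 lact = rep_len(as.integer(lact), n),
                 preg = rep_len(as.integer(preg), n)),
            class = "data.frame", row.names = c(NA_integer_, -n))
}

ch_slice <- function(ch, idx) {
  structure(lapply(unclass(ch), `[`, idx),
            class = "data.frame", row.names = c(NA_integer_, -length(idx)))
}

ch_bind <- function(a, b) {
  n <- length(a$class) + length(b$class)
  structure(list(class = c(a$class, b$class), count = c(a$count, b$count),
                 age = c(a$age, b$age), weight = c(a$weight, b$weight),
                 lact = c(a$lact, b$lact), preg = c(a$preg, b$preg)),
            class = "data.frame", row.names = c(NA_integer_, -n))
}

HERD_CLASSES <- c("breeder", "heifer", "female_calf", "male_calf",
                  "growing_male")

# merge cohorts with identical (class, lact, preg, floor(age)) keys,
# count-weighting age and weight, to bound the state size
merge_cohorts <- function(ch) {
  keep <- ch$count > 1e-9
  if (!all(keep)) ch <- ch_slice(ch, which(keep))
  n <- length(ch$class)
  if (n < 2L) return(ch)
  cls <- match(ch$class, HERD_CLASSES)
  key <- ((floor(ch$age) * 16 + ch$preg) * 16 + ch$lact) * 8 + cls
  if (!anyDuplicated(key)) return(ch)
  sums <- rowsum(cbind(ch$count, ch$count * ch$age, ch$count * ch$weight),
                 key, reorder = FALSE)
  first <- which(!duplicated(key))
  out <- ch_slice(ch, first)
  out$count <- sums[, 1]
  out$age <- sums[, 2] / sums[, 1]
  out$weight <- sums[, 3] / sums[, 1]
  out
}

count_by_class <- function(ch) {
  out <- stats::setNames(numeric(length(HERD_CLASSES)), HERD_CLASSES)
  for (i in seq_along(ch$count)) {
    out[[ch$class[i]]] <- out[[ch$class[i]]] + ch$count[i]
  }
  out
}

# fast internal cores ------------------------------------------------------

.energy_req <- function(weight, preg_month) {
  list(maintenance = .kc$maint_coef * weight^0.75 / .kc$km,
       pregnancy = pmax(0, preg_month - (.kc$gestation - 3)) *
         (.kc$preg_peak / 3))
}

.milk_step <- function(weight, lact_month, me_intake, cp_intake, breed,
                       preg_month) {
  req <- .energy_req(weight, preg_month)
  surplus <- me_intake - req$maintenance - req$pregnancy
  e_milk <- 38.6 * breed$milk_fat + 1.69
  srw <- breed$mature_weight

  potential <- breed$potential_peak_milk * (weight / srw) *
    lactation_curve(lact_month, breed$lactation_length)
  energy_allow <- pmax(0, surplus) * .kc$kl / e_milk
  protein_allow <- cp_intake * .kc$cp_eff / .kc$milk_cp
  ceiling_kg <- pmin(potential, protein_allow)

  deficit <- pmax(0, ceiling_kg - energy_allow)
  mobil_cap <- pmax(0, weight - .kc$weight_floor * srw) * .kc$e_mobil /
    .kc$days
  want_mj <- .kc$mobil_buffer * deficit * e_milk / .kc$kl
  mobil_milk <- pmin(want_mj, mobil_cap)
  # tissue buffers the milk deficit only when maintenance is covered: a
  # cow below maintenance gives no milk at all
  mobil_milk[surplus <= 0] <- 0
  extra <- mobil_milk * .kc$kl / e_milk
  milk <- pmin(energy_allow + extra, ceiling_kg)
  milk[surplus <= 0] <- 0
  dry <- lact_month <= 0
  milk[dry] <- 0
  mobil_milk[dry | deficit <= 0] <- 0

  # energy not used for milk feeds liveweight; deficits below maintenance
  # are drawn from tissue
  leftover <- surplus - milk * e_milk / .kc$kl + mobil_milk
  gain <- ifelse(leftover >= 0,
                 pmin(leftover * .kc$kg / .kc$e_gain,
                      breed$growth_rate_potential),
                 leftover / .kc$e_mobil)
  mobil_maint <- ifelse(leftover < 0, -leftover, 0)
  list(milk = milk, delta_weight = gain - mobil_milk / .kc$e_mobil,
       mobilized_mj = mobil_milk + mobil_maint,
       milk_mj = milk * e_milk / .kc$kl,
       maintenance = req$maintenance, pregnancy = req$pregnancy)
}

.allocate_core <- function(counts, ration, feeds, stocks, month) {
  days <- .kc$days
  feed_names <- names(feeds)
  nf <- length(feeds)
  frac <- rep(1, nf)
  names(frac) <- feed_names
  purchased <- shortfall <- consumed <- supply <- opening <- spoiled <-
    closing <- stats::setNames(numeric(nf), feed_names)
  cost <- 0

  demand <- stats::setNames(numeric(nf), feed_names)
  for (cl in names(ration)) {
    cnt <- counts[[cl]]
    if (is.null(cnt) || cnt <= 0) next
    off <- ration[[cl]]
    fs <- names(off)
    demand[fs] <- demand[fs] + off * cnt * days
  }

  for (i in seq_len(nf)) {
    fd <- feeds[[i]]
    f <- feed_names[i]
    opening[i] <- if (is.na(stocks[f])) 0 else stocks[f]
    supply[i] <- fd$monthly_supply[month]
    avail <- opening[i] + supply[i]
    if (demand[i] <= avail) {
      consumed[i] <- demand[i]
      closing[i] <- avail - demand[i]
    } else if (fd$purchasable) {
      purchased[i] <- demand[[i]] - avail
      consumed[i] <- demand[[i]]
      cost <- cost + purchased[[i]] * fd$price
      closing[i] <- 0
    } else {
      consumed[i] <- avail
      shortfall[i] <- demand[i] - avail
      frac[i] <- if (demand[i] > 0) avail / demand[i] else 1
      closing[i] <- 0
    }
    if (!fd$carryover && closing[i] > 0) {
      spoiled[i] <- closing[i]
      closing[i] <- 0
    }
  }

  me <- cp <- stats::setNames(numeric(length(ration)), names(ration))
  for (cl in names(ration)) {
    off <- ration[[cl]]
    for (f in names(off)) {
      fd <- feeds[[f]]
      got <- off[[f]] * frac[f] * fd$dm
      me[cl] <- me[cl] + got * fd$me
      cp[cl] <- cp[cl] + got * fd$cp[month]
    }
  }

  list(me = me, cp = cp, stocks = closing, purchased = purchased,
       cost = cost, shortfall = shortfall,
       balance = cbind(opening = opening, supply = supply,
                       purchased = purchased, consumed = consumed,
                       spoiled = spoiled, closing = closing))
}

# exported operations ------------------------------------------------------

#' Daily metabolisable-energy requirements of a cohort
#'
#' Component requirements in MJ ME/head/day: maintenance
#' `0.26 W^0.75 / k_m` with `k_m = 0.7`; pregnancy ramping linearly from 0
#' to 12 MJ/day over the final three gestation months; growth
#' `gain * 35 / k_g` with `k_g = 0.43`. The lactation requirement is not a
#' fixed demand — milk output is computed from the energy actually
#' available in [milk_yield_step()].
#'
#' @param weight Liveweight(s), kg (> 0).
#' @param preg_month Gestation month (0 = open); vectorized.
#' @param gain Target liveweight gain, kg/day; vectorized.
#' @returns A tibble with columns `maintenance`, `pregnancy`, `growth`
#'   (all >= 0) and `total`.
#' @export
#' @examples
#' energy_requirements(350)  # maintenance ~ 30.1 MJ/day
energy_requirements <- function(weight, preg_month = 0, gain = 0) {
  stopifnot(all(weight > 0))
  r <- .energy_req(weight, preg_month)
  growth <- pmax(0, gain) * .kc$e_gain / .kc$kg
  tibble::tibble(maintenance = r$maintenance, pregnancy = r$pregnancy,
                 growth = growth,
                 total = r$maintenance + r$pregnancy + growth)
}

#' Energy/protein-limited milk production for one month
#'
#' Realized daily milk of a lactating cohort is the minimum of three
#' allowances: the breed potential (lactation curve scaled by liveweight
#' relative to mature weight), the energy-allowable yield
#' `max(0, ME - maintenance - pregnancy) * k_l / E_milk` with `k_l = 0.6`
#' and `E_milk = 38.6 * fat + 1.69` MJ/kg, and the protein-allowable yield
#' `CP * 0.6 / 0.033` kg. When energy limits milk below the
#' potential/protein ceiling, liveweight is mobilized to buffer up to 20%
#' of the deficit at 28 MJ per kg tissue, floored at 0.75 of mature
#' weight. Energy left after milk goes to liveweight gain (35 MJ/kg at
#' `k_g = 0.43`, capped at the breed growth potential); an intake below
#' maintenance produces no milk and draws the deficit from liveweight.
#'
#' All arguments are vectorized over cohorts. Dry cohorts (`lact_month =
#' 0`) give no milk but still partition surplus or deficit into weight
#' change, which is how body condition recovers between lactations.
#'
#' @param weight Liveweight, kg.
#' @param lact_month Lactation month (0 = dry).
#' @param me_intake MJ ME/head/day.
#' @param cp_intake kg crude protein/head/day.
#' @param breed A [breed_params()].
#' @param preg_month Gestation month (0 = open).
#' @returns A tibble: `milk` (kg/head/day), `delta_weight` (kg/head/day),
#'   `mobilized_mj` (MJ/head/day drawn from tissue), `milk_mj`
#'   (MJ/head/day of feed energy committed to milk, `milk * E_milk /
#'   k_l`).
#' @export
milk_yield_step <- function(weight, lact_month, me_intake, cp_intake,
                            breed, preg_month = 0) {
  n <- max(length(weight), length(lact_month), length(me_intake))
  s <- .milk_step(rep_len(weight, n), rep_len(lact_month, n),
                  rep_len(me_intake, n), rep_len(cp_intake, n), breed,
                  rep_len(preg_month, n))
  tibble::tibble(milk = s$milk, delta_weight = s$delta_weight,
                 mobilized_mj = s$mobilized_mj, milk_mj = s$milk_mj)
}

#' Allocate feeds to the herd for one month
#'
#' Feeds are offered per head per day by animal class (not ad libitum).
#' On-farm stocks (opening stock plus the month's supply) are drawn first;
#' when a purchasable feed runs short the deficit is bought at its price,
#' while a non-purchasable shortfall truncates intake proportionally
#' across classes. Unused stock of non-carryover feeds (fresh pasture,
#' green feed) spoils at month end. The mass balance
#' `opening + supply + purchased - consumed - spoiled = closing`
#' holds exactly per feed.
#'
#' @param counts Named head count per class (from the herd state).
#' @param ration Named list: class -> named numeric offers, kg
#'   fresh/head/day.
#' @param feeds Named list of [feed_resource()].
#' @param stocks Named numeric, opening stock kg fresh per feed.
#' @param month Calendar month 1-12.
#' @returns List: `me`/`cp` (named per-class intakes, MJ and kg per head
#'   per day), `stocks` (closing), `purchased` (kg per feed), `cost`,
#'   `shortfall` (kg per feed), `balance` (per-feed tibble of the mass
#'   balance).
#' @export
allocate_feed <- function(counts, ration, feeds, stocks, month) {
  al <- .allocate_core(counts, ration, feeds, stocks, month)
  al$balance <- tibble::as_tibble(cbind(
    tibble::tibble(feed = names(feeds)),
    tibble::as_tibble(al$balance)))
  al
}

# expected fraction (or seeded draw) of `count` experiencing an event with
# per-head probability p
event_count <- function(count, p, stochastic = FALSE) {
  p <- pmin(pmax(p, 0), 1)
  if (!stochastic) return(count * p)
  n <- floor(count) + (runif(length(count)) < (count - floor(count)))
  pmin(rbinom(length(count), n, p), count)
}

#' Reproduction and mortality for one month
#'
#' Cohorts at gestation month 9 calve (lactation restarts, one calf per
#' cow, 50:50 sex ratio at the breed birth weight); other pregnancies and
#' lactations advance one month, lactations ending after the breed
#' lactation length. Open breeders past the 2-month post-partum anoestrus
#' conceive with monthly probability
#' `p = 0.35 / (1 + exp(-12 (condition - 0.8)))` where condition is
#' liveweight over mature weight. Every cohort then suffers monthly
#' mortality `base/12 + 0.02 max(0, 0.75 - condition)` (condition of
#' growing stock is measured against the age-specific target weight), and
#' ages one month.
#'
#' @param cohorts Cohort data frame (see [run_scenario()] internals).
#' @param breed A [breed_params()].
#' @param base_mortality Baseline mortality, fraction per year.
#' @param stochastic Draw integer events instead of expected values.
#' @returns List: `cohorts`, `births` (head), `deaths` (head),
#'   `calvings` (head).
#' @export
reproduction_and_mortality_step <- function(cohorts, breed, base_mortality,
                                            stochastic = FALSE) {
  ch <- cohorts
  births <- 0
  srw <- breed$mature_weight

  is_br <- ch$class == "breeder"
  calving <- is_br & ch$preg >= .kc$gestation
  calvings <- sum(ch$count[calving])
  if (any(calving)) {
    births <- calvings
    ch$preg[calving] <- 0L
    ch$lact[calving] <- 1L
  }
  advancing <- is_br & !calving
  adv_preg <- advancing & ch$preg > 0
  ch$preg[adv_preg] <- ch$preg[adv_preg] + 1L
  adv_lact <- advancing & ch$lact > 0
  ch$lact[adv_lact] <- ch$lact[adv_lact] + 1L
  ch$lact[is_br & ch$lact > breed$lactation_length] <- 0L

  # conception splits eligible open cohorts
  eligible <- which(is_br & ch$preg == 0L &
                      (ch$lact == 0L | ch$lact > .kc$anoestrus))
  if (length(eligible)) {
    cond <- ch$weight[eligible] / srw
    p <- .kc$pmax_conception /
      (1 + exp(-.kc$conception_slope * (cond - .kc$conception_mid)))
    conceived <- event_count(ch$count[eligible], p, stochastic)
    newrows <- ch_slice(ch, eligible)
    newrows$count <- conceived
    newrows$preg <- rep(1L, length(eligible))
    ch$count[eligible] <- ch$count[eligible] - conceived
    ch <- ch_bind(ch, ch_slice(newrows, which(conceived > 0)))
  }

  # mortality on all cohorts, condition-dependent
  cond_all <- ch$weight / pmin(srw, target_weight(ch$age, breed))
  m <- base_mortality / 12 +
    .kc$cond_mort * pmax(0, .kc$cond_mort_threshold - cond_all)
  dead <- event_count(ch$count, m, stochastic)
  deaths <- sum(dead)
  ch$count <- ch$count - dead

  ch$age <- ch$age + 1

  if (births > 0) {
    half <- if (stochastic) min(rbinom(1, round(births), 0.5), births) else
      births / 2
    ch <- ch_bind(ch, new_cohorts(
      class = c("female_calf", "male_calf"),
      count = c(births - half, half),
      age = 0, weight = breed$birth_weight, lact = 0L, preg = 0L))
  }

  list(cohorts = merge_cohorts(ch), births = births, deaths = deaths,
       calvings = calvings)
}

# growth-target weight by age: exponential approach from birth weight to
# mature weight
target_weight <- function(age, breed) {
  breed$mature_weight -
    (breed$mature_weight - breed$birth_weight) * exp(-0.045 * age)
}

#' Herd management: promotions, sales and breeder bounds
#'
#' Applies the household's management rules: male calves are sold at the
#' configured age (or move to the growing-male class and sell on reaching
#' the age-and-weight rule); weaned female calves are retained as
#' replacement heifers only while the replacement pipeline needs them and
#' sold otherwise; heifers are promoted to breeders at the breed age at
#' first mating; breeders are culled at an expected rate of one per
#' breeding lifetime (`cull_age` minus age at first calving); and the
#' breeder count is kept within `[min_breeders, max_breeders]`, excess
#' breeders being sold oldest first.
#'
#' @param cohorts Cohort data frame.
#' @param config A [scenario_config()].
#' @returns List: `cohorts`, `sales` (named head counts by sale category),
#'   `sold_head` (total).
#' @export
herd_management_step <- function(cohorts, config) {
  ch <- cohorts
  breed <- config$breed
  sales <- c(male_calf = 0, growing_male = 0, female_calf = 0,
             heifer = 0, cull = 0)

  # male offspring
  if (!is.null(config$male_sale) && config$male_sale$age <= .kc$weaning) {
    idx <- which(ch$class == "male_calf" & ch$age >= config$male_sale$age)
    sales["male_calf"] <- sum(ch$count[idx])
    ch$count[idx] <- 0
  } else {
    idx <- which(ch$class == "male_calf" & ch$age >= .kc$weaning)
    ch$class[idx] <- "growing_male"
    gm <- which(ch$class == "growing_male")
    rule <- config$male_sale
    sell <- gm[(ch$age[gm] >= rule$age &
                  ch$weight[gm] >= (rule$weight %||% 0)) |
                 ch$age[gm] >= rule$age + 12]
    sales["growing_male"] <- sum(ch$count[sell])
    ch$count[sell] <- 0
  }

  # replacement pipeline for weaned female calves
  n_br <- sum(ch$count[ch$class == "breeder"])
  n_hf <- sum(ch$count[ch$class == "heifer"])
  attrition <- cull_rate(config) + config$base_mortality / 12
  pipeline_months <- breed$age_first_mating + .kc$gestation - .kc$weaning
  desired <- max(0, config$max_breeders - n_br) +
    n_br * attrition * pipeline_months * 1.2
  weaned <- which(ch$class == "female_calf" & ch$age >= .kc$weaning)
  if (length(weaned)) {
    keep <- max(0, desired - n_hf)
    for (i in weaned) {
      take <- min(ch$count[i], keep)
      keep <- keep - take
      sales["female_calf"] <- sales["female_calf"] + ch$count[i] - take
      if (take > 0) {
        kept <- ch_slice(ch, i)
        kept$class <- "heifer"
        kept$count <- take
        ch <- ch_bind(ch, kept)
      }
      ch$count[i] <- 0
    }
  }

  # promotion to breeder
  idx <- which(ch$class == "heifer" & ch$age >= breed$age_first_mating)
  ch$class[idx] <- "breeder"

  # culling at the expected breeding-lifetime rate
  br <- which(ch$class == "breeder")
  culled <- ch$count[br] * cull_rate(config)
  sales["cull"] <- sales["cull"] + sum(culled)
  ch$count[br] <- ch$count[br] - culled

  # enforce the maximum breeder bound, oldest first
  br <- which(ch$class == "breeder")
  n_br <- sum(ch$count[br])
  if (n_br > config$max_breeders) {
    excess <- n_br - config$max_breeders
    for (i in br[order(-ch$age[br])]) {
      take <- min(ch$count[i], excess)
      ch$count[i] <- ch$count[i] - take
      sales["cull"] <- sales["cull"] + take
      excess <- excess - take
      if (excess <= 1e-12) break
    }
  }

  list(cohorts = merge_cohorts(ch), sales = sales,
       sold_head = sum(sales))
}

cull_rate <- function(config) {
  life <- config$cull_age -
    (config$breed$age_first_mating + .kc$gestation)
  1 / max(12, life)
}

#' Annual livestock profit from a year of monthly records
#'
#' Income is milk plus livestock sales; costs are purchased feed and a
#' per-head health and mating charge on the mean herd. On-farm feed is
#' costless and labour is not costed.
#'
#' @param year_trace A 12-row slice of a simulation's monthly trace.
#' @param config A [scenario_config()].
#' @returns Profit for the year, in the scenario currency.
#' @export
annual_economics <- function(year_trace, config) {
  stopifnot(nrow(year_trace) == 12L)
  prices <- config$animal_prices
  sales_rev <-
    sum(year_trace$sold_male_calf) * prices[["male_calf"]] +
    sum(year_trace$sold_growing_male) * prices[["growing_male"]] +
    sum(year_trace$sold_female_calf) * prices[["female_calf"]] +
    sum(year_trace$sold_heifer) * prices[["heifer"]] +
    sum(year_trace$sold_cull) * prices[["cull"]]
  sum(year_trace$milk_kg) * config$milk_price + sales_rev -
    sum(year_trace$feed_cost) -
    config$health_mating_cost * mean(year_trace$herd_total)
}
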