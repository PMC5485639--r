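#' Household scenario configuration
#'
#' Bundles everything the herd simulator needs for one household type: the
#' breed, breeder bounds, feed resources with on-farm supplies, the ration
#' policy (kg fresh offered per head per day by animal class), male sale
#' rule, mortality, prices and the horizon.
#'
#' @param region Region key (e.g. `"ethiopia_mrd"`).
#' @param scenario Scenario label (e.g. `"baseline"`, `"concentrate"`).
#' @param country,currency Country name and currency code (ETB or INR).
#' @param breed A [breed_params()].
#' @param min_breeders,max_breeders Breeder bounds, head.
#' @param feeds Named list of [feed_resource()].
#' @param ration Named list: animal class -> named numeric offers (kg
#'   fresh/head/day); feed names must exist in `feeds`.
#' @param male_sale List `age` (months) and optional `weight` (kg): male
#'   offspring sale rule.
#' @param cull_age Breeder culling age, months.
#' @param base_mortality Baseline herd mortality, fraction per year.
#' @param milk_price Currency per kg milk.
#' @param animal_prices Named vector/list: `male_calf`, `growing_male`,
#'   `female_calf`, `heifer`, `cull` (currency per head).
#' @param health_mating_cost Currency per head per year.
#' @param horizon Simulation length in months (multiple of 12).
#' @param init_breeders Starting breeder count (default: midpoint of the
#'   bounds).
#' @returns A list of class `scenario_config` (validated).
#' @export
scenario_config <- function(region, scenario, country, currency, breed,
                            min_breeders, max_breeders, feeds, ration,
                            male_sale = list(age = 1), cull_age = 108,
                            base_mortality = 0.05, milk_price,
                            animal_prices, health_mating_cost,
                            horizon = 240, init_breeders = NULL) {
  cfg <- structure(list(
    region = region, scenario = scenario, country = country,
    currency = currency, breed = breed, min_breeders = min_breeders,
    max_breeders = max_breeders, feeds = feeds, ration = ration,
    male_sale = male_sale, cull_age = cull_age,
    base_mortality = base_mortality, milk_price = milk_price,
    animal_prices = as.list(animal_prices),
    health_mating_cost = health_mating_cost, horizon = horizon,
    init_breeders = init_breeders %||%
      round((min_breeders + max_breeders) / 2)
  ), class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks structural consistency before a simulation is allowed to run:
#' breeder bounds ordered, horizon a whole number of years, every ration
#' entry referring to a declared feed, known animal classes, and complete
#' price information.
#'
#' @param config A `scenario_config`.
#' @returns `config`, invisibly; otherwise an error describing the
#'   problem.
#' @export
validate_scenario <- function(config) {
  ok <- function(cond, msg) {
    if (!cond) abort(paste0("invalid scenario '", config$region, "/",
                            config$scenario, "': ", msg),
                     class = "dairygap_validation_error")
  }
  ok(inherits(config$breed, "breed_params"), "breed is not a breed_params")
  ok(config$min_breeders <= config$max_breeders,
     "min_breeders > max_breeders")
  ok(config$horizon %% 12 == 0, "horizon not a multiple of 12")
  ok(all(vapply(config$feeds, inherits, logical(1), "feed_resource")),
     "feeds must be feed_resource objects")
  for (cl in names(config$ration)) {
    ok(cl %in% HERD_CLASSES, paste0("unknown animal class '", cl, "'"))
    unknown <- setdiff(names(config$ration[[cl]]), names(config$feeds))
    ok(!length(unknown),
       paste0("ration references unknown feed: ",
              paste(unknown, collapse = ", ")))
    ok(all(unlist(config$ration[[cl]]) >= 0), "negative feed offer")
  }
  needed <- c("male_calf", "growing_male", "female_calf", "heifer", "cull")
  ok(all(needed %in% names(config$animal_prices)),
     "animal_prices must name male_calf, growing_male, female_calf, heifer, cull")
  invisible(config)
}

#' Write / read a scenario configuration as YAML
#'
#' Scenario files are hierarchical key-value YAML, one file per household
#' scenario, and round-trip exactly through [read_scenario()].
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @returns `write_scenario`: `path` invisibly. `read_scenario`: a
#'   validated `scenario_config`.
#' @export
write_scenario <- function(config, path) {
  x <- unclass(config)
  x$breed <- unclass(x$breed)
  x$feeds <- lapply(x$feeds, unclass)
  x$ration <- lapply(x$ration, as.list)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  x$breed <- do.call(breed_params, x$breed)
  x$feeds <- lapply(x$feeds, function(f) do.call(feed_resource, f))
  x$ration <- lapply(x$ration, function(r) unlist(r))
  do.call(scenario_config, x)
}

#' Describe an intervention
#'
#' @param kind One of `improved_pasture`, `concentrate`,
#'   `improved_forage`, `improved_genetics`, `residue_quality`,
#'   `green_feed`, `combination`.
#' @param ... Kind-specific parameters (see [apply_intervention()]).
#' @returns A list of class `intervention`.
#' @export
intervention <- function(kind = c("improved_pasture", "concentrate",
                                  "improved_forage", "improved_genetics",
                                  "residue_quality", "green_feed",
                                  "combination"), ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...)), class = "intervention")
}

#' Apply an intervention to a scenario configuration
#'
#' Returns a new configuration; the input is untouched. Kinds and their
#' parameters:
#'
#' * `improved_pasture`: `feed`; `n_delta` (fraction N, default 0.005;
#'   CP rises by `6.25 * n_delta`); the seasonal CP decline of the feed is
#'   halved; optional `supply_factor` scales monthly supply (the growth
#'   response of a legume-augmented pasture).
#' * `concentrate`: `offers`, a named list feed -> kg/head/day set on the
#'   breeder ration.
#' * `improved_forage`: either a quality change (`feed`, `me_delta`,
#'   `cp_delta`) or a forage swap (`new_feed` = a [feed_resource()],
#'   `replace_feed`, `replace_fraction` of its supply removed, `offers`
#'   for the breeder ration).
#' * `residue_quality`: `feed`, `me_delta` (default +1 MJ/kg DM),
#'   optional `new_price`.
#' * `improved_genetics`: `breed` (a [breed_params()]), optional
#'   `min_breeders`/`max_breeders`, `ration` (full replacement), and
#'   optional `milk_price` / `cull_price` when the new breed's milk sells
#'   differently.
#' * `green_feed`: `offers` added to the breeder ration.
#' * `combination`: `steps`, an ordered list of interventions applied
#'   sequentially.
#'
#' Any kind may carry `min_breeders`/`max_breeders` overrides.
#'
#' @param config A [scenario_config()].
#' @param iv An [intervention()].
#' @param label Scenario label for the derived configuration.
#' @returns A validated `scenario_config`.
#' @export
apply_intervention <- function(config, iv, label = iv$kind) {
  stopifnot(inherits(config, "scenario_config"), inherits(iv, "intervention"))
  p <- iv$params
  cfg <- config
  cfg$scenario <- label
  set_offers <- function(cfg, offers) {
    for (f in names(offers)) {
      if (!f %in% names(cfg$feeds)) {
        abort(paste0("intervention needs feed '", f,
                     "' absent from the scenario"),
              class = "dairygap_validation_error")
      }
      cfg$ration$breeder[f] <- offers[[f]]
    }
    cfg
  }
  switch(iv$kind,
    improved_pasture = {
      f <- p$feed
      if (!f %in% names(cfg$feeds)) {
        abort("improved_pasture needs a grazed feed in the scenario",
              class = "dairygap_validation_error")
      }
      fd <- cfg$feeds[[f]]
      cp <- fd$cp
      peak <- max(cp)
      cp <- peak - 0.5 * (peak - cp)        # halve the seasonal decline
      fd$cp <- cp + 6.25 * (p$n_delta %||% 0.005)
      fd$monthly_supply <- fd$monthly_supply * (p$supply_factor %||% 1)
      cfg$feeds[[f]] <- fd
    },
    concentrate = cfg <- set_offers(cfg, p$offers),
    improved_forage = {
      if (!is.null(p$new_feed)) {
        nf <- p$new_feed
        cfg$feeds[[nf$name]] <- nf
        if (!is.null(p$replace_feed)) {
          rf <- cfg$feeds[[p$replace_feed]]
          rf$monthly_supply <- rf$monthly_supply *
            (1 - (p$replace_fraction %||% 1))
          cfg$feeds[[p$replace_feed]] <- rf
        }
        cfg <- set_offers(cfg, p$offers %||% list())
        for (f in names(p$offers_heifer %||% list())) {
          cfg$ration$heifer[f] <- p$offers_heifer[[f]]
        }
      } else {
        fd <- cfg$feeds[[p$feed]]
        if (is.null(fd)) {
          abort("improved_forage quality change names an unknown feed",
                class = "dairygap_validation_error")
        }
        fd$me <- fd$me + (p$me_delta %||% 0)
        fd$cp <- fd$cp + (p$cp_delta %||% 0)
        cfg$feeds[[p$feed]] <- fd
      }
    },
    residue_quality = {
      fd <- cfg$feeds[[p$feed]]
      if (is.null(fd)) {
        abort("residue_quality names an unknown feed",
              class = "dairygap_validation_error")
      }
      fd$me <- fd$me + (p$me_delta %||% 1)
      if (!is.null(p$new_price)) fd$price <- p$new_price
      cfg$feeds[[p$feed]] <- fd
    },
    improved_genetics = {
      cfg$breed <- p$breed
      if (!is.null(p$ration)) cfg$ration <- p$ration
      if (!is.null(p$milk_price)) cfg$milk_price <- p$milk_price
      if (!is.null(p$cull_price)) cfg$animal_prices$cull <- p$cull_price
    },
    green_feed = cfg <- set_offers(cfg, p$offers),
    combination = {
      for (step in p$steps) cfg <- apply_intervention(cfg, step, label)
    }
  )
  cfg$min_breeders <- p$min_breeders %||% cfg$min_breeders
  cfg$max_breeders <- p$max_breeders %||% cfg$max_breeders
  cfg$init_breeders <- round((cfg$min_breeders + cfg$max_breeders) / 2)
  validate_scenario(cfg)
  cfg
}

# ---------------------------------------------------------------------------
# Region fixture definitions. Quantities printed in the household
# descriptions (supplement offers, breeder bounds, sale rules, mortality)
# are copied verbatim; feed qualities, on-farm supplies and prices are
# fixture assumptions documented in the methods vignette.

REGIONS <- c("ethiopia_lg", "ethiopia_mrd", "ethiopia_mrs",
             "india_rainfed", "india_irrigated")

# seasonal helpers (Ethiopian highland rains roughly Jun-Sep; Indian
# monsoon similar): relative monthly growth weights and pasture CP
.season_w <- c(0.50, 0.45, 0.45, 0.55, 0.80, 1.20, 1.50, 1.60,
               1.45, 1.10, 0.80, 0.60)
.pasture_cp <- c(0.05, 0.05, 0.06, 0.07, 0.09, 0.10, 0.11, 0.11,
                 0.10, 0.08, 0.07, 0.06)

seasonal_supply <- function(annual) annual * .season_w / sum(.season_w)

.et_feeds <- function() list(
  pasture = function(annual_fresh)
    feed_resource("pasture", dm = 0.30, me = 8.0, cp = .pasture_cp,
                  price = 0, monthly_supply = seasonal_supply(annual_fresh)),
  straw = function(supply, purchasable)
    feed_resource("straw", dm = 0.90, me = 6.5, cp = 0.04, price = 1.5,
                  monthly_supply = supply, purchasable = purchasable,
                  carryover = TRUE),
  hay = function()
    feed_resource("hay", dm = 0.85, me = 8.8, cp = 0.16, price = 3.5,
                  purchasable = TRUE, carryover = TRUE),
  noug = function()
    feed_resource("noug", dm = 0.92, me = 11.5, cp = 0.32, price = 6,
                  purchasable = TRUE, carryover = TRUE),
  bran = function()
    feed_resource("bran", dm = 0.90, me = 11.0, cp = 0.15, price = 4,
                  purchasable = TRUE, carryover = TRUE)
)

.lablab <- function(area_ha) {
  # legume forage grown on cropping land: ~11 t DM/ha/yr, cut green over a
  # long season (roughly even monthly availability from staggered cutting)
  feed_resource("lablab", dm = 0.25, me = 9.2, cp = 0.17, price = 0,
                monthly_supply = area_ha * 11000 / 0.25 / 12)
}

.et_prices <- list(male_calf = 600, growing_male = 5500, female_calf = 800,
                   heifer = 4000, cull = 5000)

region_baseline <- function(region) {
  br <- default_breeds()
  ef <- .et_feeds()
  switch(region,
    ethiopia_lg = scenario_config(
      region = "ethiopia_lg", scenario = "baseline",
      country = "Ethiopia", currency = "ETB", breed = br$zebu,
      min_breeders = 15, max_breeders = 30,
      feeds = list(pasture = ef$pasture(90000), noug = ef$noug()),
      ration = list(
        breeder = c(pasture = 12, noug = 0.4),
        heifer = c(pasture = 9), growing_male = c(pasture = 9)),
      male_sale = list(age = 12, weight = 180),
      base_mortality = 0.05, milk_price = 10,
      animal_prices = .et_prices, health_mating_cost = 150),
    ethiopia_mrd = scenario_config(
      region = "ethiopia_mrd", scenario = "baseline",
      country = "Ethiopia", currency = "ETB", breed = br$zebu,
      min_breeders = 3, max_breeders = 5,
      feeds = list(
        pasture = ef$pasture(0.8 * 3500 / 0.30),
        straw = ef$straw(c(1600, rep(0, 10), 2400), purchasable = FALSE),
        hay = ef$hay(), noug = ef$noug(), bran = ef$bran()),
      ration = list(
        breeder = c(pasture = 8, straw = 3, hay = 0.8, noug = 0.4),
        heifer = c(pasture = 6, straw = 2)),
      male_sale = list(age = 1),
      base_mortality = 0.10, milk_price = 10,
      animal_prices = .et_prices, health_mating_cost = 150),
    ethiopia_mrs = scenario_config(
      region = "ethiopia_mrs", scenario = "baseline",
      country = "Ethiopia", currency = "ETB", breed = br$zebu,
      min_breeders = 3, max_breeders = 4,
      feeds = list(straw = ef$straw(0, purchasable = TRUE),
                   hay = ef$hay(), noug = ef$noug(), bran = ef$bran()),
      ration = list(
        breeder = c(straw = 5, hay = 1, noug = 0.4),
        heifer = c(straw = 3, hay = 0.5)),
      male_sale = list(age = 1),
      base_mortality = 0.10, milk_price = 10,
      animal_prices = .et_prices, health_mating_cost = 150),
    india_rainfed = scenario_config(
      region = "india_rainfed", scenario = "baseline",
      country = "India", currency = "INR", breed = br$local_india,
      min_breeders = 1, max_breeders = 3,
      feeds = list(
        grass = feed_resource("grass", dm = 0.25, me = 8.5, cp = 0.08,
                              price = 1,
                              monthly_supply = seasonal_supply(36000)),
        residues = feed_resource("residues", dm = 0.90, me = 7.0,
                                 cp = 0.05, price = 2,
                                 monthly_supply = c(0, 0, 1200, 0, 0, 0,
                                                    0, 0, 0, 1800, 0, 0),
                                 purchasable = TRUE, carryover = TRUE),
        bran = feed_resource("bran", dm = 0.90, me = 11.5, cp = 0.14,
                             price = 12, purchasable = TRUE,
                             carryover = TRUE)),
      ration = list(
        breeder = c(grass = 8, residues = 4),
        heifer = c(grass = 5, residues = 1)),
      male_sale = list(age = 1),
      base_mortality = 0.05, milk_price = 30,
      animal_prices = list(male_calf = 500, growing_male = 8000,
                           female_calf = 1000, heifer = 12000,
                           cull = 10000),
      health_mating_cost = 400),
    india_irrigated = scenario_config(
      region = "india_irrigated", scenario = "baseline",
      country = "India", currency = "INR", breed = br$buffalo,
      min_breeders = 1, max_breeders = 3,
      feeds = list(
        straw = feed_resource("straw", dm = 0.90, me = 6.8, cp = 0.04,
                              price = 5,
                              monthly_supply = c(0, 0, 0, 1000, 0, 0, 0,
                                                 0, 0, 0, 1500, 0),
                              purchasable = TRUE, carryover = TRUE),
        grass = feed_resource("grass", dm = 0.25, me = 8.5, cp = 0.08,
                              price = 1, purchasable = TRUE),
        rice_bran = feed_resource("rice_bran", dm = 0.90, me = 11.5,
                                  cp = 0.13, price = 10,
                                  purchasable = TRUE, carryover = TRUE),
        good_grass = feed_resource("good_grass", dm = 0.25, me = 8.8,
                                   cp = 0.12, price = 2,
                                   purchasable = TRUE)),
      ration = list(
        breeder = c(straw = 4, grass = 8, rice_bran = 1.5),
        heifer = c(straw = 3, grass = 4)),
      male_sale = list(age = 1),
      base_mortality = 0.05, milk_price = 40,
      animal_prices = list(male_calf = 500, growing_male = 8000,
                           female_calf = 1500, heifer = 15000,
                           cull = 20000),
      health_mating_cost = 400),
    abort(paste0("unknown region: ", region),
          class = "dairygap_validation_error")
  )
}

region_interventions <- function(region) {
  br <- default_breeds()
  switch(region,
    ethiopia_lg = list(
      improved_pasture = intervention(
        "improved_pasture", feed = "pasture", n_delta = 0.005,
        supply_factor = 1.35, min_breeders = 15, max_breeders = 20)),
    ethiopia_mrd = list(
      concentrate = intervention(
        "concentrate", offers = list(noug = 0.8, bran = 0.8)),
      improved_forage = intervention(
        "improved_forage", new_feed = .lablab(0.5),
        replace_feed = "pasture", replace_fraction = 0.5 / 0.8,
        offers = list(lablab = 11), offers_heifer = list(lablab = 4)),
      improved_genetics = intervention(
        "improved_genetics", breed = br$crossbred_ethiopia,
        min_breeders = 4, max_breeders = 8,
        ration = list(breeder = c(pasture = 8, straw = 3, hay = 4,
                                  noug = 0.8),
                      heifer = c(pasture = 6, straw = 2, hay = 1))),
      improved_genetics_improved_forage = intervention(
        "combination", min_breeders = 4, max_breeders = 6, steps = list(
          intervention("improved_genetics", breed = br$crossbred_ethiopia,
                       ration = list(breeder = c(pasture = 8, straw = 3,
                                                 hay = 2, noug = 0.8),
                                     heifer = c(pasture = 6, straw = 2,
                                                hay = 1))),
          intervention("improved_forage", new_feed = .lablab(0.7),
                       replace_feed = "pasture",
                       replace_fraction = 0.7 / 0.8,
                       offers = list(lablab = 14)))),
      improved_genetics_concentrate = intervention(
        "combination", min_breeders = 3, max_breeders = 6, steps = list(
          intervention("improved_genetics", breed = br$crossbred_ethiopia,
                       ration = list(breeder = c(pasture = 8, straw = 3,
                                                 hay = 4, noug = 0.8),
                                     heifer = c(pasture = 6, straw = 2,
                                                hay = 1))),
          intervention("concentrate",
                       offers = list(noug = 1.5, bran = 1.5))))),
    ethiopia_mrs = list(
      improved_forage = intervention(
        "improved_forage", feed = "straw", me_delta = 0.8,
        cp_delta = 0.04),
      concentrate = intervention(
        "concentrate", offers = list(noug = 0.8, bran = 0.8)),
      improved_genetics = intervention(
        "improved_genetics", breed = br$crossbred_ethiopia,
        min_breeders = 4, max_breeders = 5,
        ration = list(breeder = c(straw = 5, hay = 3, noug = 0.8),
                      heifer = c(straw = 3, hay = 1))),
      improved_genetics_improved_forage = intervention(
        "combination", min_breeders = 4, max_breeders = 5, steps = list(
          intervention("improved_genetics", breed = br$crossbred_ethiopia,
                       ration = list(breeder = c(straw = 5, hay = 3,
                                                 noug = 1.0),
                                     heifer = c(straw = 3, hay = 1))),
          intervention("improved_forage", feed = "straw", me_delta = 0.8,
                       cp_delta = 0.04))),
      improved_genetics_concentrate = intervention(
        "combination", min_breeders = 4, max_breeders = 5, steps = list(
          intervention("improved_genetics", breed = br$crossbred_ethiopia,
                       ration = list(breeder = c(straw = 5, hay = 3,
                                                 noug = 0.8),
                                     heifer = c(straw = 3, hay = 1))),
          intervention("concentrate",
                       offers = list(noug = 1.6, bran = 1.6))))),
    india_rainfed = {
      buffalo_base <- intervention(
        "improved_genetics", breed = br$buffalo,
        ration = list(breeder = c(grass = 9, residues = 5),
                      heifer = c(grass = 6, residues = 1)),
        milk_price = 40, cull_price = 20000)
      crossbred_base <- intervention(
        "improved_genetics", breed = br$crossbred_india,
        ration = list(breeder = c(grass = 4.5, residues = 6),
                      heifer = c(grass = 6, residues = 1)),
        cull_price = 18000)
      list(
        improved_genetics_buffalo = buffalo_base,
        improved_genetics_crossbred = crossbred_base,
        low_concentrate = intervention(
          "concentrate", offers = list(bran = 1)),
        improved_genetics_buffalo_low_concentrate = intervention(
          "combination", steps = list(
            buffalo_base,
            intervention("concentrate", offers = list(bran = 1)))),
        improved_genetics_crossbred_low_concentrate = intervention(
          "combination", steps = list(
            crossbred_base,
            intervention("concentrate", offers = list(bran = 1)))),
        improved_genetics_buffalo_high_concentrate = intervention(
          "combination", steps = list(
            buffalo_base,
            intervention("concentrate", offers = list(bran = 3)))),
        improved_genetics_crossbred_high_concentrate = intervention(
          "combination", steps = list(
            crossbred_base,
            intervention("concentrate", offers = list(bran = 3)))))
    },
    india_irrigated = list(
      improved_forage = intervention(
        "residue_quality", feed = "straw", me_delta = 1, new_price = 5.8),
      green_feed = intervention(
        "green_feed", offers = list(good_grass = 10)),
      green_feed_bran = intervention(
        "combination", steps = list(
          intervention("green_feed", offers = list(good_grass = 8)),
          intervention("concentrate", offers = list(rice_bran = 3)))),
      increased_bran = intervention(
        "concentrate", offers = list(rice_bran = 5))),
    abort(paste0("unknown region: ", region),
          class = "dairygap_validation_error")
  )
}

#' Generate the scenario fixture set for a region
#'
#' Builds the baseline configuration and every intervention scenario for
#' one of the five agro-ecological regions, entirely from code (no
#' randomness: regeneration is byte-identical). Scenario order matches the
#' region's published intervention ordering.
#'
#' @param region One of `"ethiopia_lg"`, `"ethiopia_mrd"`,
#'   `"ethiopia_mrs"`, `"india_rainfed"`, `"india_irrigated"`.
#' @returns Named list of `scenario_config` (first element `baseline`).
#' @export
gen_fixtures <- function(region) {
  base <- region_baseline(region)
  ivs <- region_interventions(region)
  configs <- c(list(baseline = base),
               purrr::imap(ivs, function(iv, nm)
                 apply_intervention(base, iv, label = nm)))
  configs
}

#' Write a region's scenario files
#'
#' @param region Region key.
#' @param dir Output directory (created if needed).
#' @returns Paths written, invisibly.
#' @export
write_scenario_files <- function(region, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfgs <- gen_fixtures(region)
  paths <- vapply(names(cfgs), function(nm) {
    p <- file.path(dir, paste0(region, "__", nm, ".yaml"))
    write_scenario(cfgs[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Load the shipped scenario library
#'
#' Reads the YAML scenario files installed with the package (5 baselines
#' plus 19 interventions across the five regions). These files are the
#' single source of intervention parameter values.
#'
#' @param regions Regions to load (default: all five).
#' @param dir Directory of scenario files (default: the installed
#'   fixtures).
#' @returns Named list: region -> named list of `scenario_config`.
#' @export
scenario_library <- function(regions = REGIONS, dir = NULL) {
  dir <- dir %||% system.file("extdata", "scenarios", package = "dairygap")
  out <- lapply(regions, function(rg) {
    files <- list.files(dir, pattern = paste0("^", rg, "__.*\\.yaml$"),
                        full.names = TRUE)
    if (!length(files)) {
      abort(paste0("no scenario files found for region ", rg),
            class = "dairygap_io_error")
    }
    cfgs <- lapply(files, read_scenario)
    names(cfgs) <- sub("\\.yaml$", "",
                       sub(paste0("^", rg, "__"), "", basename(files)))
    # restore the canonical ordering (baseline first, then the region's
    # published intervention order)
    canon <- names(gen_fixtures(rg))
    cfgs[intersect(canon, names(cfgs))]
  })
  names(out) <- regions
  out
}
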