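test_that("energy requirements follow the feeding-standard forms", {
  # 350 kg dry cow: 0.26 * 350^0.75 / 0.7
  expect_equal(energy_requirements(350)$maintenance,
               0.26 * 350^0.75 / 0.7, tolerance = 1e-12)
  expect_equal(round(energy_requirements(350)$maintenance, 1), 30.1)
  # metabolic-weight scaling
  expect_gt(energy_requirements(500)$maintenance,
            energy_requirements(350)$maintenance)
  # pregnancy ramps 0 -> 12 MJ over the final three gestation months
  expect_equal(energy_requirements(350, preg_month = c(6, 7, 8, 9))$pregnancy,
               c(0, 4, 8, 12))
  # growth costs 35 MJ/kg at k_g = 0.43
  expect_equal(energy_requirements(200, gain = 0.5)$growth, 0.5 * 35 / 0.43)
  expect_true(all(energy_requirements(350, 9, 1) >= 0))
})

test_that("lactation curve is flat-topped with a late linear decline", {
  expect_equal(lactation_curve(0, 8), 0)
  expect_equal(lactation_curve(1, 8), 0.6)
  expect_equal(lactation_curve(4, 8), 1)
  expect_equal(lactation_curve(8, 8), 0.25)
  expect_equal(lactation_curve(9, 8), 0)
  m <- 1:10
  expect_true(all(lactation_curve(m, 10) >= 0 & lactation_curve(m, 10) <= 1))
})

test_that("milk production is the minimum of potential, energy and protein
           allowances", {
  zebu <- default_breeds()$zebu
  # surplus 20 MJ, fat 4.5% -> E_milk = 38.6*0.045+1.69; ample protein and
  # potential: yield = 20 * 0.6 / E_milk
  e_milk <- 38.6 * zebu$milk_fat + 1.69
  maint <- 0.26 * 350^0.75 / 0.7
  step <- milk_yield_step(350, 3, maint + 20, cp_intake = 1, zebu)
  expect_equal(step$milk, 20 * 0.6 / e_milk + step$mobilized_mj * 0.6 / e_milk,
               tolerance = 1e-9)
  # intake below maintenance: no milk, tissue loss
  starved <- milk_yield_step(350, 3, 10, 0.5, zebu)
  expect_equal(starved$milk, 0)
  expect_lt(starved$delta_weight, 0)
  # more energy never means less milk
  sweep <- milk_yield_step(rep(350, 30), 3, seq(20, 80, length.out = 30),
                           1, zebu)
  expect_true(all(diff(sweep$milk) >= -1e-12))
  # potential cap binds for a hugely fed cow
  capped <- milk_yield_step(350, 3, 400, 2, zebu)
  expect_equal(capped$milk, zebu$potential_peak_milk, tolerance = 1e-9)
  # protein-allowable cap: tiny CP limits milk to CP * 0.6 / 0.033
  prot <- milk_yield_step(350, 3, maint + 60, cp_intake = 0.05, zebu)
  expect_equal(prot$milk, 0.05 * 0.6 / 0.033, tolerance = 1e-9)
})

test_that("feed allocation keeps an exact mass balance", {
  feeds <- list(
    straw = feed_resource("straw", dm = 0.9, me = 6.5, cp = 0.04,
                          price = 2, monthly_supply = 1000,
                          carryover = TRUE),
    bran = feed_resource("bran", dm = 0.9, me = 11, cp = 0.15, price = 4,
                         purchasable = TRUE),
    grass = feed_resource("grass", dm = 0.3, me = 8, cp = 0.08,
                          monthly_supply = 200))
  ration <- list(breeder = c(straw = 5, bran = 1, grass = 10))
  counts <- c(breeder = 4, heifer = 0, female_calf = 0, male_calf = 0,
              growing_male = 0)
  al <- allocate_feed(counts, ration, feeds, c(straw = 300), month = 1)

  days <- 365.25 / 12
  # ample straw: full intake, stock drawn down
  expect_equal(al$balance$consumed[1], 5 * 4 * days)
  expect_equal(al$balance$closing[1], 1300 - 5 * 4 * days)
  # bran has no farm supply: all purchased at price
  expect_equal(al$purchased[["bran"]], 1 * 4 * days)
  expect_equal(al$cost, 1 * 4 * days * 4)
  # grass demand 40*days exceeds supply 200: truncated, not purchased,
  # nothing carries over
  expect_equal(al$shortfall[["grass"]], 10 * 4 * days - 200)
  expect_equal(al$balance$closing[3], 0)
  # the balance identity holds for every feed
  b <- al$balance
  expect_equal(b$opening + b$supply + b$purchased - b$consumed - b$spoiled,
               b$closing)
  # per-head intake reflects the truncation fraction
  frac <- 200 / (10 * 4 * days)
  expect_equal(al$me[["breeder"]],
               5 * 0.9 * 6.5 + 1 * 0.9 * 11 + 10 * frac * 0.3 * 8)
})

test_that("reproduction follows the condition-dependent logistic and
           mortality the condition penalty", {
  zebu <- default_breeds()$zebu
  ch <- dairygap:::new_cohorts("breeder", count = 10, age = 300,
                               weight = 0.8 * 350, lact = 0L, preg = 0L)
  out <- reproduction_and_mortality_step(ch, zebu, base_mortality = 0)
  conceived <- sum(out$cohorts$count[out$cohorts$preg == 1])
  expect_equal(conceived, 10 * 0.35 / 2, tolerance = 1e-6)

  # mortality at condition 0.6: base/12 + 0.02 * 0.15 per month
  ch2 <- dairygap:::new_cohorts("breeder", 100, 300, 0.6 * 350, 0L, 0L)
  out2 <- reproduction_and_mortality_step(ch2, zebu, base_mortality = 0.06)
  expect_equal(out2$deaths, 100 * (0.06 / 12 + 0.02 * 0.15),
               tolerance = 1e-4)

  # calving: gestation month 9 restarts lactation and adds calves 50:50
  ch3 <- dairygap:::new_cohorts("breeder", 6, 60, 340, 0L, 9L)
  out3 <- reproduction_and_mortality_step(ch3, zebu, 0)
  expect_equal(out3$births, 6)
  expect_equal(out3$calvings, 6)
  calves <- out3$cohorts[out3$cohorts$class %in%
                           c("female_calf", "male_calf"), ]
  expect_equal(sum(calves$count), 6)
  expect_equal(calves$count[1], calves$count[2])
  expect_equal(out3$cohorts$lact[out3$cohorts$class == "breeder"], 1L)
})

test_that("management rules enforce sale rules and breeder bounds", {
  cfg <- short_scenario("ethiopia_lg")
  # growing male at the age-and-weight rule is sold that month
  ch <- dairygap:::new_cohorts(c("breeder", "growing_male"),
                               count = c(16, 2), age = c(60, 12),
                               weight = c(330, 190), lact = 0L, preg = 0L)
  mg <- herd_management_step(ch, cfg)
  expect_equal(mg$sales[["growing_male"]], 2)

  # underweight growing male is retained
  ch2 <- dairygap:::new_cohorts(c("breeder", "growing_male"), c(16, 2),
                                c(60, 12), c(330, 150), 0L, 0L)
  expect_equal(herd_management_step(ch2, cfg)$sales[["growing_male"]], 0)

  # one breeder above the maximum: exactly one sold (oldest first)
  cfg2 <- short_scenario("ethiopia_mrd")
  ch3 <- dairygap:::new_cohorts(rep("breeder", 2), c(3, 3), c(50, 90),
                                330, 0L, 0L)
  mg3 <- herd_management_step(ch3, cfg2)
  # rate culling plus the excess sale leave exactly max_breeders standing,
  # so total cull sales equal one head
  expect_equal(mg3$sales[["cull"]], 1, tolerance = 1e-9)
  left <- mg3$cohorts
  breeders <- left[left$class == "breeder", ]
  expect_equal(sum(breeders$count), cfg2$max_breeders, tolerance = 1e-9)
  # the older cohort was drawn down first
  expect_lt(breeders$count[breeders$age > 80],
            breeders$count[breeders$age < 80])

  # nothing to trigger: herd unchanged up to the cull rate
  ch4 <- dairygap:::new_cohorts("breeder", 4, 50, 330, 0L, 0L)
  mg4 <- herd_management_step(ch4, cfg2)
  expect_equal(sum(mg4$cohorts$count), 4 - 4 * dairygap:::cull_rate(cfg2),
               tolerance = 1e-12)
})

test_that("annual profit is income minus costs and linear in milk price", {
  cfg <- short_scenario("ethiopia_mrs")
  yr <- tibble::tibble(
    milk_kg = rep(1000 / 12, 12), sold_male_calf = 0,
    sold_growing_male = 0, sold_female_calf = 0, sold_heifer = 0,
    sold_cull = 0, feed_cost = rep(4000 / 12, 12),
    herd_total = rep(0, 12))
  # 1000 kg at 10 ETB minus 4000 costs (no herd -> no health charge)
  expect_equal(annual_economics(yr, cfg), 1000 * 10 - 4000)

  cfg2 <- cfg
  cfg2$milk_price <- cfg$milk_price * 2
  base <- annual_economics(yr, cfg)
  expect_equal(annual_economics(yr, cfg2) - base, 1000 * cfg$milk_price)

  # purchased feed with no output is a loss
  yr0 <- yr
  yr0$milk_kg <- 0
  expect_lt(annual_economics(yr0, cfg), 0)
})
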