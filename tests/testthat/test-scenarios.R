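test_that("interventions transform configurations as specified", {
  lg <- gen_fixtures("ethiopia_lg")
  base <- lg$baseline
  ip <- lg$improved_pasture
  # +0.5% N = +0.03125 CP on the grazed pasture
  extra <- ip$feeds$pasture$cp - (max(base$feeds$pasture$cp) -
    0.5 * (max(base$feeds$pasture$cp) - base$feeds$pasture$cp))
  expect_equal(unique(round(extra, 10)), 6.25 * 0.005)
  # the seasonal decline is halved
  expect_equal(max(ip$feeds$pasture$cp) - min(ip$feeds$pasture$cp),
               (max(base$feeds$pasture$cp) - min(base$feeds$pasture$cp)) / 2)
  # everything else untouched
  expect_identical(ip$ration, base$ration)
  expect_identical(ip$breed, base$breed)

  # irrigated: bran raised to 5 kg/head/day; straw quality +1 MJ with the
  # new price
  irr <- gen_fixtures("india_irrigated")
  expect_equal(irr$increased_bran$ration$breeder[["rice_bran"]], 5)
  expect_equal(irr$improved_forage$feeds$straw$me,
               irr$baseline$feeds$straw$me + 1)
  expect_equal(irr$improved_forage$feeds$straw$price, 5.8)

  # an empty combination is the identity
  same <- apply_intervention(base, intervention("combination",
                                                steps = list()),
                             label = base$scenario)
  expect_identical(same, base)

  # inapplicable interventions are refused with a clear error
  expect_error(
    apply_intervention(base, intervention("improved_pasture",
                                          feed = "missing_feed")),
    class = "dairygap_validation_error")
  expect_error(
    apply_intervention(base, intervention("concentrate",
                                          offers = list(bran = 1))),
    class = "dairygap_validation_error")
})

test_that("the shipped scenario library is complete, valid and
           regenerates byte-identically", {
  lib <- scenario_library()
  expect_length(lib, 5L)
  counts <- lengths(lib)
  expect_equal(unname(counts),
               c(2L, 6L, 6L, 8L, 5L))  # baseline + Table-1 interventions
  for (rg in names(lib)) {
    for (cfg in lib[[rg]]) expect_silent(validate_scenario(cfg))
    expect_equal(names(lib[[rg]])[1], "baseline")
  }

  # regeneration from code is byte-identical to the installed files
  tmp <- withr::local_tempdir()
  paths <- write_scenario_files("ethiopia_mrs", tmp)
  for (p in paths) {
    shipped <- system.file("extdata", "scenarios", basename(p),
                           package = "dairygap")
    expect_identical(readLines(p), readLines(shipped))
  }
})

test_that("gap reports express modelled yields against attainable", {
  best <- table4_best_modelled()
  rf <- gap_report(
    tibble::tibble(region = "india_rainfed", scenario = "best",
                   milk_per_cow_lactation = best$rainfed$best),
    list(zone = "rainfed", top_decile_mean = best$rainfed$attainable))
  expect_equal(rf$modelled_over_attainable_pct, 86)
  expect_false(rf$exceeds_attainable)

  ir <- gap_report(
    tibble::tibble(region = "india_irrigated", scenario = "best",
                   milk_per_cow_lactation = best$irrigated$best),
    list(zone = "irrigated", top_decile_mean = best$irrigated$attainable))
  expect_equal(ir$modelled_over_attainable_pct, 94)

  eq <- gap_report(tibble::tibble(milk_per_cow_lactation = 500),
                   list(zone = "z", top_decile_mean = 500))
  expect_equal(eq$modelled_over_attainable, 100)

  # scale consistency: doubling both sides leaves the percentage unchanged
  sc <- gap_report(tibble::tibble(milk_per_cow_lactation = 2 * 1990),
                   list(zone = "z", top_decile_mean = 2 * 2304))
  expect_equal(sc$modelled_over_attainable, rf$modelled_over_attainable)

  expect_error(gap_report(tibble::tibble(milk_per_cow_lactation = 1),
                          list(zone = "z", top_decile_mean = 0)),
               class = "dairygap_validation_error")
})

test_that("intervention rankings are stable and key-dependent", {
  # published pattern: the buffalo high-concentrate scenario out-earns the
  # crossbred one despite producing less milk
  fix <- table4_rainfed_rank_fixture()
  by_milk <- rank_interventions(fix, "milk_per_farm_year")
  expect_equal(by_milk$scenario[1], "crossbred_high_concentrate")
  by_profit <- rank_interventions(fix, "annual_profit")
  expect_equal(by_profit$scenario[1], "buffalo_high_concentrate")
  expect_true(all(c("rank_milk", "rank_profit") %in% names(by_milk)))

  # equal keys keep input order (stable sort)
  ties <- tibble::tibble(scenario = c("a", "b"),
                         milk_per_farm_year = c(5, 5),
                         annual_profit = c(1, 2))
  expect_equal(rank_interventions(ties, "milk_per_farm_year")$scenario,
               c("a", "b"))

  # with distinct keys the ranking is invariant to input order
  rev_fix <- fix[rev(seq_len(nrow(fix))), ]
  expect_equal(rank_interventions(rev_fix, "annual_profit")$scenario,
               rank_interventions(fix, "annual_profit")$scenario)
})
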