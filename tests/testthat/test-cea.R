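test_that("icer_point divides incremental cost by incremental benefit", {
  expect_equal(icer_point(100, 0, 0.5, 0), 200)
  expect_equal(icer_point(50, 50, 0.4, 0), 0)
  eff <- three_effect_arm()$effects
  b <- aggregate_effects(eff, make_scheme("summed", eff))
  expect_equal(round_display(icer_point(24, 0, b$point, 0), "money"), 10)
  dom <- icer_point(100, 0, -0.2, 0)
  expect_true(is.na(dom))
  expect_true(attr(dom, "dominated"))
  expect_true(is.na(icer_point(100, 0, 0.3, 0.3)))  # zero incremental benefit
})

test_that("icer_interval maps the effect UR inversely onto the ICER UR", {
  eff <- three_effect_arm()$effects
  avg <- aggregate_effects(eff, make_scheme("averaged", eff))
  iv <- icer_interval(24, avg)
  expect_equal(round_display(iv, "money"), c(lower = 23, upper = 37))
  narrow <- aggregate_effects(single_effect_arm()$effects,
                              make_scheme("averaged",
                                          single_effect_arm()$effects))
  expect_equal(round_display(icer_interval(1357, narrow), "money"),
               c(lower = 2225, upper = 33925))
  # degenerate UR collapses to the point ICER
  deg <- structure(list(point = 0.5, lower = 0.5, upper = 0.5,
                        scheme_kind = "averaged"), class = "ecd_aggregate")
  expect_equal(unname(icer_interval(100, deg)), c(200, 200))
  # non-positive lower bound -> unbounded upper ICER
  z <- structure(list(point = 0.2, lower = -0.1, upper = 0.5,
                      scheme_kind = "averaged"), class = "ecd_aggregate")
  ivz <- icer_interval(100, z)
  expect_equal(unname(ivz["upper"]), Inf)
  expect_true(attr(ivz, "unbounded_upper"))
  neg <- structure(list(point = -0.2, lower = -0.4, upper = -0.1,
                        scheme_kind = "averaged"), class = "ecd_aggregate")
  expect_true(all(is.na(icer_interval(100, neg))))
  expect_error(icer_interval(-5, avg))
})

test_that("display rounding: full-precision inputs, ties to even", {
  expect_equal(round_display(9.64, "money"), 10)
  expect_equal(round_display(0.78333333, "effect"), 0.78)
  expect_equal(round_display(0.695, "effect"), 0.70)
  expect_equal(round_display(0.755, "effect"), 0.76)
  # the two published tie cells that fix the convention: 69/0.40 = 172.5
  # prints as 172 and 99/0.40 = 247.5 prints as 248 (both to even)
  expect_equal(round_display(69 / 0.40, "money"), 172)
  expect_equal(round_display(99 / 0.40, "money"), 248)
  expect_equal(round_display(-0.5, "money"), 0)
  expect_equal(round_display(Inf, "money"), Inf)
  # the snap guard must not touch genuine near-half values
  expect_equal(round_display(172.501, "money"), 173)
  expect_equal(round_display(172.499, "money"), 172)
})

test_that("evaluate_arm composes aggregation, ICER and interval", {
  # single-domain arm at standardized cost: averaged and summed coincide
  nair <- single_effect_arm("nair_like", 0.21, 0.06, 0.35,
                            per_child_standardized = 18, per_child_local = 5)
  for (kind in c("averaged", "summed")) {
    r <- evaluate_arm(nair, kind, "standardized")
    expect_equal(r$icer_display, c(86, 51, 300))
    expect_false(r$dominated)
  }
  # two-domain arm on the local basis
  yous <- intervention_arm("yous_like", "Demo, 2014", "Demoland", "2010",
                           per_child_local = 134, per_child_standardized = 134,
                           effects = rbind(
                             effect_estimate("cognitive", 0.60, 0.45, 0.76, TRUE),
                             effect_estimate("language", 0.70, 0.45, 0.75, TRUE)
                           ))
  r <- evaluate_arm(yous, "averaged", "local")
  expect_equal(r$icer_display, c(206, 177, 298))
  # dominated arm: aggregate <= 0
  dom_arm <- single_effect_arm("dom", -0.1, -0.3, 0.1,
                               per_child_standardized = 100)
  r <- evaluate_arm(dom_arm, "averaged", "standardized")
  expect_true(r$dominated)
  expect_true(is.na(r$icer))
  # missing cost for the requested basis
  no_cost <- single_effect_arm("no_cost")
  no_cost$per_child_local <- NA_real_
  expect_error(evaluate_arm(no_cost, "averaged", "local"), "no local")
})

test_that("ranking is order-independent, tie-broken, and excludes dominated", {
  arms <- list(
    single_effect_arm("a", 0.5, 0.3, 0.7, per_child_standardized = 100),
    single_effect_arm("b", 0.5, 0.3, 0.7, per_child_standardized = 50),
    single_effect_arm("c", -0.2, -0.4, 0.0, per_child_standardized = 10),
    three_effect_arm("d", per_child_standardized = 24)
  )
  res <- lapply(arms, evaluate_arm, scheme_kind = "averaged",
                cost_basis = "standardized")
  lt <- rank_arms(res)
  expect_equal(lt$arm_id, c("d", "b", "a"))
  expect_equal(lt$rank, 1:3)
  expect_equal(vapply(attr(lt, "dominated"), `[[`, character(1), "arm_id"), "c")
  # permuting the input changes nothing
  lt2 <- rank_arms(res[c(3, 1, 4, 2)])
  expect_equal(as.data.frame(lt2), as.data.frame(lt))
  # equal ICER and equal cost: lexicographic arm_id breaks the tie
  t1 <- evaluate_arm(single_effect_arm("zz", 0.5, 0.4, 0.6,
                                       per_child_standardized = 100),
                     "averaged", "standardized")
  t2 <- evaluate_arm(single_effect_arm("aa", 0.5, 0.4, 0.6,
                                       per_child_standardized = 100),
                     "averaged", "standardized")
  expect_equal(rank_arms(list(t1, t2))$arm_id, c("aa", "zz"))
  # mixed scheme or basis is an error
  bad <- evaluate_arm(arms[[1]], "summed", "standardized")
  expect_error(rank_arms(list(res[[1]], bad)), "share")
})

test_that("ICER is strictly increasing in incremental cost", {
  eff <- three_effect_arm()$effects
  b <- aggregate_effects(eff, make_scheme("averaged", eff))
  costs <- seq(10, 1000, by = 90)
  icers <- vapply(costs, function(cc) icer_point(cc, 0, b$point, 0), numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("monte_carlo_interval is seeded, degenerate-safe, and matches the
          closed form for a single domain", {
  deg <- single_effect_arm("deg", 0.5, 0.5, 0.5, per_child_standardized = 100)
  mc <- monte_carlo_interval(deg, "averaged", "standardized",
                             n_samples = 500, seed = 1)
  expect_equal(as.numeric(mc), c(200, 200))
  expect_identical(attr(mc, "note"), "extension")

  arm <- single_effect_arm("mc", 0.5, 0.304, 0.696,
                           per_child_standardized = 100)
  mc1 <- monte_carlo_interval(arm, "averaged", "standardized",
                              n_samples = 20000, seed = 99)
  mc2 <- monte_carlo_interval(arm, "averaged", "standardized",
                              n_samples = 20000, seed = 99)
  expect_identical(mc1, mc2)
  # closed-form oracle: with X ~ N(0.5, 0.1), the 2.5th/97.5th percentiles
  # of cost/X are cost/q97.5(X) and cost/q2.5(X)
  se <- (0.696 - 0.304) / 3.92
  lo <- 100 / stats::qnorm(0.975, 0.5, se)
  hi <- 100 / stats::qnorm(0.025, 0.5, se)
  expect_equal(unname(mc1["lower"]), lo, tolerance = 0.02)
  expect_equal(unname(mc1["upper"]), hi, tolerance = 0.02)

  # non-positive draws are counted and announced, not silently dropped
  shaky <- single_effect_arm("shaky", 0.05, -0.25, 0.35,
                             per_child_standardized = 100)
  expect_message(
    mc3 <- monte_carlo_interval(shaky, "averaged", "standardized",
                                n_samples = 2000, seed = 3),
    "non-positive"
  )
  expect_gt(attr(mc3, "n_nonpositive"), 0)
  expect_error(monte_carlo_interval(arm, "averaged", "standardized", 1000),
               "seed")
})

test_that("league table renders and writes in all three formats", {
  lt <- build_league_table(
    ecd_portfolio(list(three_effect_arm(), single_effect_arm())),
    "averaged", "standardized")
  md <- league_markdown(lt)
  expect_match(md[1], "averaged")
  expect_length(md, 4 + nrow(lt))
  for (fmt in c("csv", "json", "markdown")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_league_table(lt, f, fmt)
    expect_gt(file.size(f), 0)
  }
  f <- withr::local_tempfile(fileext = ".csv")
  write_league_table(lt, f, "csv")
  back <- utils::read.csv(f)
  expect_equal(back$arm_id, lt$arm_id)
})
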