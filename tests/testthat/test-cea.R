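summ <- function(cost, qaly) list(cost_million_irr = cost, qaly = qaly)

test_that("icer reproduces the published incremental ratios", {
  r1 <- icer(summ(0, 0), summ(96.4, 0.0425))
  expect_identical(r1$verdict, "icer")
  expect_equal(round(r1$icer, 1), 2268.2)

  r2 <- icer(summ(0, 0), summ(71.4, 0.0315))
  expect_equal(round(r2$icer, 1), 2266.7)
})

test_that("icer returns dominance verdicts instead of meaningless ratios", {
  a <- summ(100, 1)
  expect_identical(icer(a, a)$verdict, "undefined")
  expect_identical(icer(a, summ(90, 1.2))$verdict, "comparator_dominates")
  expect_identical(icer(a, summ(120, 0.8))$verdict, "reference_dominates")
  expect_identical(icer(a, summ(120, 1))$verdict, "reference_dominates")
  sw <- icer(a, summ(60, 0.8))
  expect_identical(sw$verdict, "southwest")
  expect_equal(sw$icer, -40 / -0.2)
})

test_that("scenario runs compose the engine and respect mixture linearity", {
  fix <- esrd_fixture()
  # PD unreachable from HD when nobody transplants or rejects
  m0 <- death_only_model(0.2)
  tr <- run_cohort(m0, initial_distribution(0))
  expect_true(all(tr$PD == 0))

  r0 <- run_scenario(fix$model, 0)
  r1 <- run_scenario(fix$model, 1)
  r5 <- run_scenario(fix$model, 0.5)
  expect_equal(r5$cost_million_irr,
               (r0$cost_million_irr + r1$cost_million_irr) / 2)
  expect_equal(r5$qaly, (r0$qaly + r1$qaly) / 2)
})

test_that("the fixture scenarios form an undominated, collinear frontier", {
  fix <- esrd_fixture()
  res <- run_scenarios(fix$model, fix$scenarios)
  tab <- cea_table(res)
  expect_identical(tab$name, c("S1", "S2", "S3", "S4"))
  expect_false(any(tab$dominated))
  expect_false(any(tab$ext_dominated))
  expect_true(all(diff(tab$icer_sequential[-1]) >= -1e-6))

  # mixtures of two cohorts: every pairwise ICER identical to full precision
  pair_icers <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    pair_icers <- c(pair_icers, icer(res[i, ], res[j, ])$icer)
  }
  expect_lt(diff(range(pair_icers)) / mean(pair_icers), 1e-8)
})

test_that("strict and extended dominance are flagged and excluded", {
  res <- tibble::tibble(
    name = c("A", "B", "C", "D"),
    cost_million_irr = c(100, 150, 120, 200),
    qaly = c(1.0, 0.9, 1.01, 1.05)
  )
  tab <- cea_table(res, baseline = "A")
  expect_true(tab$dominated[tab$name == "B"]) # costs more, fewer QALYs
  expect_false(tab$dominated[tab$name == "C"])
  expect_true(is.na(tab$icer_sequential[tab$name == "B"]))

  # B lies above the A-C chord: extendedly dominated
  res2 <- tibble::tibble(
    name = c("A", "B", "C"),
    cost_million_irr = c(0, 100, 150),
    qaly = c(0, 0.01, 0.05)
  )
  tab2 <- cea_table(res2, baseline = "A")
  expect_false(tab2$dominated[tab2$name == "B"])
  expect_true(tab2$ext_dominated[tab2$name == "B"])
  expect_equal(tab2$icer_sequential[tab2$name == "C"], 150 / 0.05)
})

test_that("the CEA table is invariant to input order and names must be unique", {
  fix <- esrd_fixture()
  res <- run_scenarios(fix$model, fix$scenarios)
  for (perm in list(c(2, 4, 1, 3), c(4, 3, 2, 1))) {
    tab_p <- cea_table(res[perm, ], baseline = "S1")
    expect_equal(tibble::as_tibble(tab_p),
                 tibble::as_tibble(cea_table(res, baseline = "S1")))
  }
  expect_error(cea_table(res[c(1, 1, 2), ]), "Duplicate")
  expect_error(cea_table(res[1, ]), "at least two")
})

test_that("net monetary benefit and the threshold decision follow the NMB rule", {
  expect_equal(nmb(4989.6, 2.7811, 3000), 3000 * 2.7811 - 4989.6)
  expect_equal(round(nmb(4989.6, 2.7811, 3000), 1), 3353.7)
  expect_equal(nmb(123.4, 0.9, 0), -123.4)
  expect_error(nmb(1, 1, -5), "non-negative")

  # published totals: S4 beats S1 at 3000 by 3000*0.1055 - 239.1 = 77.4
  gain <- nmb(4989.6, 2.7811, 3000) - nmb(4750.5, 2.6756, 3000)
  expect_equal(round(gain, 1), 77.4)

  res <- tibble::tibble(
    name = c("S1", "S2", "S3", "S4"),
    cost_million_irr = c(4750.5, 4846.8, 4918.2, 4989.6),
    qaly = c(2.6756, 2.7181, 2.7496, 2.7811)
  )
  expect_identical(decide(res, 0)$name, "S1")
  expect_identical(decide(res, 1e9)$name, "S4")
  expect_identical(decide(res, 3000)$name, "S4")

  # ties break toward the cheaper strategy
  tie <- tibble::tibble(name = c("cheap", "dear"),
                        cost_million_irr = c(10, 20),
                        qaly = c(1, 2))
  expect_identical(decide(tie, 10)$name, "cheap")
})

test_that("NMB-optimal choice agrees with walking the frontier at any threshold", {
  fix <- esrd_fixture(knobs = random_knobs(seed = 21))
  shares <- c(0.05, 0.2, 0.45, 0.65, 0.9)
  res <- run_scenarios(fix$model, scenario_set(shares))
  tab <- cea_table(res)
  frontier <- tab[!tab$dominated & !tab$ext_dominated, ]
  for (wtp in c(0, 500, 2000, 3000, 10000)) {
    accepted <- frontier[is.na(frontier$icer_sequential) |
                           frontier$icer_sequential <= wtp, ]
    walk <- accepted$name[nrow(accepted)]
    expect_identical(decide(res, wtp)$name, walk)
  }
})

test_that("cea tables export to CSV with units in the column names", {
  fix <- esrd_fixture()
  tab <- cea_table(run_scenarios(fix$model, fix$scenarios))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cea_csv(tab, f)
  back <- utils::read.csv(f)
  expect_true(all(c("cost_million_irr", "qaly", "icer_sequential",
                    "dominated") %in% names(back)))
  expect_equal(back$cost_million_irr, tab$cost_million_irr)
})
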