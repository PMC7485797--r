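zero_risk_cultivar <- function(intensity = 1) {
  list(X = list(egg_intensity = intensity, p_plant_defense = 0,
                p_parasitism = 0, p_unknown_early = 0, p_pathogens = 0,
                p_unknown_late = 0))
}

test_that("a risk-free single-egg cohort survives intact", {
  cfg <- sim_config(n_sites = 1, n_blocks = 1,
                    cultivars = zero_risk_cultivar(1),
                    stems_per_plot = 200, egg_distribution = "fixed",
                    seed = 1)
  sim <- simulate_cohort(cfg, sampling = "census")
  expect_identical(nrow(sim$truth$events), 0L)
  expect_equal(sim$truth$final_survival, 1)
  expect_identical(sim$truth$total_eggs, 200L)
  expect_equal(unname(sim$truth$cause_totals), rep(0, 5))
  # and the pipeline recovers the all-survivors table
  rep <- recovery_report(sim)
  expect_equal(rep$estimate, rep(0, 5))
})

test_that("certain plant defense kills every solitary larva", {
  cul <- zero_risk_cultivar(1)
  cul$X$p_plant_defense <- 1
  cfg <- sim_config(n_sites = 1, n_blocks = 1, cultivars = cul,
                    stems_per_plot = 150, egg_distribution = "fixed",
                    seed = 2)
  sim <- simulate_cohort(cfg, sampling = "census")
  ev <- sim$truth$events
  expect_identical(nrow(ev), 150L)
  expect_true(all(ev$cause == "plant_defense"))
  expect_true(all(ev$stage == "larva_i"))
  expect_equal(sim$truth$final_survival, 0)
})

test_that("a fixed seed reproduces the record stream byte for byte", {
  for (mode in c("census", "survey")) {
    cfg <- sim_config(n_sites = 1, n_blocks = 1, stems_per_plot = 950,
                      stubs_per_collection = 5, seed = 31)
    a <- suppressWarnings(simulate_cohort(cfg, sampling = mode))
    b <- suppressWarnings(simulate_cohort(cfg, sampling = mode))
    expect_identical(a$records, b$records, label = mode)
    expect_identical(a$truth$events, b$truth$events)
  }
})

test_that("the obligate one-survivor rule holds in every stem", {
  cfg <- small_config(stems_per_plot = 400)
  sim <- simulate_cohort(cfg, sampling = "census")
  ev <- sim$truth$events
  stems <- sim$truth$stems
  key <- function(d) paste(d$cultivar, d$block, d$stem)
  deaths <- table(key(ev))
  pd <- table(key(ev[ev$cause == "plant_defense", ]))
  cann <- table(key(ev[ev$cause == "cannibalism", ]))
  k <- key(stems)
  n_deaths <- ifelse(k %in% names(deaths), deaths[k], 0)
  n_pd <- ifelse(k %in% names(pd), pd[k], 0)
  n_cann <- ifelse(k %in% names(cann), cann[k], 0)

  # conservation: eggs laid = deaths + the (at most one) emerging survivor
  survivors <- unname(stems$eggs - n_deaths)
  expect_equal(survivors, as.integer(stems$adult))
  expect_true(all(survivors %in% c(0, 1)))

  # every occupant that escaped plant defense beyond the first is cannibalised
  not_pd <- stems$eggs - n_pd
  expect_equal(unname(n_cann), unname(pmax(not_pd - 1, 0)))

  # multiply-occupied stems with at least two plant-defense survivors always
  # record cannibalism
  expect_true(all(n_cann[not_pd >= 2] >= 1))
})

test_that("deaths respect the stage windows of each cause", {
  cfg <- small_config(stems_per_plot = 500)
  sim <- simulate_cohort(cfg, sampling = "census")
  ev <- sim$truth$events
  expect_true(all(ev$stage[ev$cause == "parasitism"] == "larva_iii"))
  expect_true(all(ev$stage[ev$cause == "plant_defense"] == "larva_i"))
  expect_true(all(ev$stage[ev$cause == "cannibalism"] %in%
                    c("egg", "larva_i")))
  expect_true(all(ev$stage[ev$cause == "pathogens"] %in%
                    c("larva_iv", "larva_v")))
})

test_that("census estimates recover the generative truth exactly", {
  cfg <- small_config(stems_per_plot = 600)
  sim <- simulate_cohort(cfg, sampling = "census")
  rep <- recovery_report(sim)
  expect_lt(max(rep$abs_error), 1e-12)
  expect_equal(attr(rep, "fit")$final_survival, sim$truth$final_survival,
               tolerance = 1e-12)
  expect_output(print(rep), "Recovery")
})

test_that("realised truth concentrates around its limit as the stand grows", {
  # across-seed spread of the realised cause totals shrinks roughly like
  # n^(-1/2): a 16-fold larger stand should at least halve it
  spread <- function(n_stems) {
    tots <- sapply(1:5, function(s) {
      cfg <- sim_config(n_sites = 1, n_blocks = 1,
                        cultivars = default_cultivars()["Haybet"],
                        stems_per_plot = n_stems, seed = 1000 + s)
      simulate_cohort(cfg, sampling = "census")$truth$cause_totals
    })
    mean(apply(tots, 1, stats::sd))
  }
  expect_lt(spread(3200), spread(200) / 2)
})

test_that("survey sampling enforces design feasibility", {
  cfg <- sim_config(n_sites = 1, n_blocks = 1, stems_per_plot = 500, seed = 4)
  expect_error(simulate_cohort(cfg, sampling = "survey"),
               "infeasible sampling")
  cfg <- sim_config(n_sites = 1, n_blocks = 1, stems_per_plot = 950,
                    cultivars = default_cultivars()["Craft"], seed = 4)
  w <- capture_warnings(simulate_cohort(cfg, sampling = "survey"))
  expect_true(any(grepl("stubs available", w)))
})

test_that("survey records carry the field design's structure", {
  cfg <- sim_config(n_sites = 1, n_blocks = 1, stems_per_plot = 1100,
                    stubs_per_collection = 10, seed = 12)
  sim <- suppressWarnings(simulate_cohort(cfg, sampling = "survey"))
  recs <- sim$records
  stem_recs <- recs[recs$sample_kind == "stem", ]
  # 3 bags x 35 stems x 9 weeks per plot, 8 plots
  expect_identical(nrow(stem_recs), 8L * 9L * 105L)
  expect_true(all(table(stem_recs$cultivar, stem_recs$week) == 105))
  # each stem dissected at most once
  expect_false(any(duplicated(recs$unit_id)))
  # stubs carry phases, never weeks
  stubs <- recs[recs$sample_kind == "stub", ]
  expect_true(all(is.na(stubs$week)))
  expect_true(all(stubs$stub_phase %in% c("pre_flight", "post_flight")))
  expect_true(all(!stem_recs$emerged))
  # records validate cleanly end to end
  expect_identical(nrow(attr(validate_records(recs), "diagnostics")), 0L)
  # week-1 records contain no larvae, live or dead
  wk1 <- stem_recs[stem_recs$week == 1, ]
  expect_true(all(wk1$n_live_larvae == 0))
  expect_true(all(!grepl("NEONATE|LARVAE|PARASITOID|MULTI_INTERNODE",
                         wk1$dead_evidence)))
})

test_that("survey estimates track the truth loosely despite field scoring", {
  # the survey estimator carries the field convention's attribution
  # approximations; check order-of-magnitude agreement only
  cfg <- sim_config(n_sites = 1, n_blocks = 2, stems_per_plot = 1200,
                    stubs_per_collection = 15, seed = 21)
  sim <- suppressWarnings(simulate_cohort(cfg, sampling = "survey"))
  rep <- recovery_report(sim)
  expect_true(all(rep$estimate >= 0 & rep$estimate <= 1))
  # total mortality within 15 points of truth
  expect_lt(abs(sum(rep$estimate) - sum(rep$truth)), 0.15)
  # cause ranking of the two dominant early causes is preserved jointly
  expect_gt(sum(rep$estimate[rep$cause %in% c("cannibalism", "plant_defense")]),
            sum(rep$estimate[rep$cause %in% c("parasitism", "pathogens")]))
})

test_that("configurations validate and round-trip through YAML", {
  expect_error(sim_config(n_blocks = 0), "n_blocks")
  bad <- default_cultivars()
  bad$Craft$p_parasitism <- 1.4
  expect_error(sim_config(cultivars = bad), "outside \\[0, 1\\]")
  bad <- default_cultivars()
  bad$Craft$p_pathogens <- NULL
  expect_error(sim_config(cultivars = bad), "missing parameter")

  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_sites = 1, n_blocks = 2, stems_per_plot = 300,
                        seed = 5,
                        cultivars = list(A = list(
                          egg_intensity = 1.1, p_plant_defense = 0.4,
                          p_parasitism = 0.05, p_unknown_early = 0.1,
                          p_pathogens = 0.01, p_unknown_late = 0.05)),
                        site_years = list(list(site = "S", year = 2020))),
                   f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$n_blocks, 2L)
  expect_identical(names(cfg$cultivars), "A")
})

test_that("ground truth serializes to JSON", {
  cfg <- small_config(stems_per_plot = 100)
  sim <- simulate_cohort(cfg, sampling = "census")
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  got <- jsonlite::read_json(f)
  expect_equal(got$total_eggs, sim$truth$total_eggs)
  expect_equal(got$final_survival, sim$truth$final_survival,
               tolerance = 1e-12)
})
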