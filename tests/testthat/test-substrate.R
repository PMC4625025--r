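profiles <- load_profiles(mip_fixture("table2.tsv"))
rules <- load_substrate_rules(mip_fixture("table3_rules.tsv"))
sdp_obs <- readr::read_tsv(mip_fixture("table3_profiles.tsv"),
                           col_types = readr::cols(.default = "c"))

prof_row <- function(id) profiles[profiles$protein_id == id, ]
sdp_row <- function(substrate, id) {
  sdp_obs[sdp_obs$substrate == substrate & sdp_obs$protein_id == id, ]
}

test_that("NPA motifs are typed as canonical or variant", {
  expect_equal(unname(npa_type(prof_row("RcPIP1;1"))),
               c("CANONICAL", "CANONICAL"))
  expect_equal(unname(npa_type(prof_row("RcXIP1;1"))),
               c("VARIANT:SPT", "CANONICAL"))
  expect_equal(unname(npa_type(prof_row("RcNIP5;1"))),
               c("VARIANT:NPS", "VARIANT:NPV"))
  expect_true(is.na(npa_type(prof_row("RcXIP1;4"))[["le"]]))
  bad <- prof_row("RcPIP1;1")
  bad$npa_lb <- "NPAA"
  expect_error(npa_type(bad), "3 letters")
})

test_that("Froger typing separates glycerol and water channels", {
  glp <- tibble::tibble(p1 = "Y", p2 = "D", p3 = "K", p4 = "P", p5 = "L")
  expect_equal(froger_class(glp)$call, "GLYCEROL_TYPE")
  aqp <- tibble::tibble(p1 = "A", p2 = "S", p3 = "A", p4 = "F", p5 = "W")
  expect_equal(froger_class(aqp)$call, "WATER_TYPE")

  nip <- froger_class(prof_row("RcNIP1;1"))  # F-S-A-Y-I
  expect_equal(nip$call, "MIXED")
  expect_equal(unname(nip$per_position[c("P1", "P5")]),
               c("GLP_LIKE", "GLP_LIKE"))
  expect_equal(unname(nip$per_position[c("P2", "P3", "P4")]),
               rep("AQP_LIKE", 3))

  expect_equal(froger_class(prof_row("RcXIP1;4"))$call, "INCOMPLETE")
  expect_equal(froger_class(prof_row("RcPIP1;1"))$call, "WATER_TYPE")
})

test_that("SDP matching reproduces worked examples from the family", {
  expect_equal(match_sdp(sdp_row("NH3", "RcNIP1;1"),
                         rules[rules$substrate == "NH3", ])$category,
               "TYPICAL")
  tip22 <- match_sdp(sdp_row("NH3", "RcTIP2;2"),
                     rules[rules$substrate == "NH3", ])
  expect_equal(tip22$category, "NOVEL_CANDIDATE")
  dev <- tip22$deviations[[1]]
  expect_equal(dev$position, "SDP9")
  expect_equal(unname(dev$observed), "S")
  expect_equal(unname(dev$allowed), "A/R/T")

  expect_equal(match_sdp(sdp_row("boric acid", "RcPIP1;1"),
                         rules[rules$substrate == "boric acid", ])$category,
               "TYPICAL")

  nip21 <- match_sdp(sdp_row("silicic acid", "RcNIP2;1"),
                     rules[rules$substrate == "silicic acid", ])
  expect_equal(nip21$category, "NO_MATCH")
  expect_setequal(nip21$deviations[[1]]$position, c("SDP3", "SDP9"))
  expect_setequal(nip21$deviations[[1]]$observed, c("V", "Q"))
})

test_that("fixture-wide SDP regression flags exactly the known deviations", {
  res <- match_sdp_table(sdp_obs, rules)
  expect_equal(nrow(res), nrow(sdp_obs))
  expect_true(all(res$n_missing == 0))

  devs <- res |>
    dplyr::filter(.data$n_deviations > 0) |>
    tidyr::unnest("deviations") |>
    dplyr::select("substrate", "protein_id", "position", "observed") |>
    dplyr::arrange(.data$substrate, .data$protein_id)

  expected <- dplyr::arrange(tibble::tribble(
    ~substrate, ~protein_id, ~position, ~observed,
    "NH3", "RcTIP2;2", "SDP9", "S",
    "CO2", "RcPIP1;1", "SDP2", "M",
    "CO2", "RcPIP1;3", "SDP2", "M",
    "CO2", "RcPIP1;4", "SDP2", "M",
    "CO2", "RcPIP1;5", "SDP2", "M",
    "CO2", "RcPIP2;2", "SDP2", "M",
    "CO2", "RcPIP2;4", "SDP2", "M",
    "H2O2", "RcXIP1;1", "SDP5", "S",
    "H2O2", "RcXIP1;2", "SDP5", "S",
    "H2O2", "RcXIP1;3", "SDP5", "S",
    "silicic acid", "RcNIP2;1", "SDP3", "V",
    "silicic acid", "RcNIP2;1", "SDP9", "Q",
    "urea", "RcNIP6;1", "SDP6", "E"
  ), .data$substrate, .data$protein_id)

  expect_equal(as.data.frame(devs), as.data.frame(expected))
})

test_that("widening an allowed set never worsens a match", {
  base <- rules[rules$substrate == "NH3", ]
  for (id in c("RcTIP2;2", "RcNIP1;1")) {
    obs <- sdp_row("NH3", id)
    before <- match_sdp(obs, base)
    widened <- base
    for (k in 1:9) {
      widened[[paste0("sdp", k)]] <-
        list(union(widened[[paste0("sdp", k)]][[1]],
                   obs[[paste0("sdp", k)]]))
    }
    after <- match_sdp(obs, widened)
    expect_equal(after$category, "TYPICAL")
    expect_lte(after$n_deviations, before$n_deviations)
  }
})

test_that("predict_substrates ranks matches and handles missing SDPs", {
  nip51 <- sdp_obs |>
    dplyr::filter(.data$protein_id == "RcNIP5;1",
                  .data$substrate == "urea")
  # build a full profile carrying the urea-context SDP string
  res_u <- match_sdp(nip51, rules[rules$substrate == "urea", ])
  expect_equal(res_u$category, "TYPICAL")
  res_b <- match_sdp(sdp_row("boric acid", "RcNIP5;1"),
                     rules[rules$substrate == "boric acid", ])
  expect_equal(res_b$category, "TYPICAL")
  res_h <- match_sdp(sdp_row("H2O2", "RcNIP5;1"),
                     rules[rules$substrate == "H2O2", ])
  expect_equal(res_h$category, "TYPICAL")

  pip12_co2 <- match_sdp(sdp_row("CO2", "RcPIP1;1"),
                         rules[rules$substrate == "CO2", ])
  expect_equal(pip12_co2$category, "NOVEL_CANDIDATE")
  expect_equal(pip12_co2$deviations[[1]]$position, "SDP2")

  empty <- predict_substrates(prof_row("RcPIP1;1"), rules[0, ])
  expect_equal(nrow(empty), 0)

  no_sdp <- predict_substrates(prof_row("RcPIP1;1"), rules)
  expect_true(all(no_sdp$category == "INCOMPLETE"))
  expect_true(all(no_sdp$n_missing == 9))

  with_sdp <- prof_row("RcPIP1;1")
  for (k in 1:9) with_sdp[[paste0("sdp", k)]] <-
    sdp_row("boric acid", "RcPIP1;1")[[paste0("sdp", k)]]
  ranked <- predict_substrates(with_sdp, rules)
  expect_equal(ranked$category[1], "TYPICAL")
  expect_equal(ranked$substrate[1], "boric acid")
  ranks <- c(TYPICAL = 1, NOVEL_CANDIDATE = 2, NO_MATCH = 3,
             INCOMPLETE = 4)
  expect_true(!is.unsorted(ranks[ranked$category]))
})

test_that("deterministic output order and the ar/R descriptor", {
  with_sdp <- prof_row("RcTIP5;1")
  for (k in 1:9) with_sdp[[paste0("sdp", k)]] <-
    sdp_row("H2O2", "RcTIP5;1")[[paste0("sdp", k)]]
  r1 <- predict_substrates(with_sdp, rules)
  r2 <- predict_substrates(with_sdp, rules)
  expect_identical(r1, r2)

  expect_equal(arr_report(prof_row("RcPIP1;1"))$arr, "F-H-T-R")
  expect_true(arr_report(prof_row("RcPIP1;1"))$pip_typical)
  expect_equal(arr_report(prof_row("RcTIP5;1"))$arr, "N-V-G-C")
  expect_equal(arr_report(prof_row("RcXIP1;4"))$arr, "V------")
  expect_false(arr_report(prof_row("RcXIP1;4"))$pip_typical)
})
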