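# Half-reaction construction, coupling, and conservation laws.

test_that("alkane oxidation half-reactions carry 6n+2 electrons and the canonical stoichiometry", {
  h2 <- alkane_oxidation_half(2)
  expect_equal(h2$electrons, 14)
  expect_equal(h2$stoich[["C2H6"]], -1)
  expect_equal(h2$stoich[["H2O"]], -4)
  expect_equal(h2$stoich[["CO2"]], 2)
  expect_equal(h2$stoich[["H+"]], 14)

  expect_equal(alkane_oxidation_half(4)$electrons, 26)
  h1 <- alkane_oxidation_half(1)
  expect_equal(h1$electrons, 8)
  expect_equal(h1$stoich[["CO2"]], 1)

  for (n in 1:6)
    expect_equal(alkane_oxidation_half(n)$electrons, 6 * n + 2)
  expect_error(alkane_oxidation_half(0), "1..6")
  expect_error(alkane_oxidation_half(7), "1..6")
})

test_that("nitrogen reduction half-reactions are balanced with the expected electron demand", {
  demands <- c("NO3->NO2" = 2, "NO3->N2" = 5, "NO2->N2" = 3,
               "NO3->NH4" = 8, "NO2->NH4" = 6)
  for (cp in names(demands)) {
    h <- nitrogen_reduction_half(cp)
    expect_equal(-h$electrons, unname(demands[cp]), info = cp)
    expect_equal(max(abs(check_balance(h))), 0, info = cp)
  }
  # hand-balanced nitrate -> nitrite: NO3- + 2H+ + 2e- -> NO2- + H2O
  h <- nitrogen_reduction_half("NO3->NO2")
  expect_equal(h$stoich[c("NO3-", "H+", "NO2-", "H2O")],
               c("NO3-" = -1, "H+" = -2, "NO2-" = 1, "H2O" = 1))
  # sequential couples are additive in electrons
  expect_equal(couple_electrons_per_n("NO3->NH4"),
               couple_electrons_per_n("NO3->NO2") +
                 couple_electrons_per_n("NO2->NH4"))
  expect_error(nitrogen_reduction_half("NO3->NO"), "unknown couple")
})

test_that("coupling reproduces the six published alkane/N-oxyanion equations exactly", {
  cases <- list(
    list(n = 2, cp = "NO3->NO2",
         coef = c("C2H6" = -1, "NO3-" = -7, "CO2" = 2, "NO2-" = 7, "H2O" = 3)),
    list(n = 4, cp = "NO3->NO2",
         coef = c("C4H10" = -1, "NO3-" = -13, "CO2" = 4, "NO2-" = 13, "H2O" = 5)),
    list(n = 2, cp = "NO2->N2",
         coef = c("C2H6" = -3, "NO2-" = -14, "H+" = -14, "CO2" = 6, "N2" = 7, "H2O" = 16)),
    list(n = 2, cp = "NO2->NH4",
         coef = c("C2H6" = -3, "NO2-" = -7, "H+" = -14, "CO2" = 6, "NH4+" = 7, "H2O" = 2)),
    list(n = 4, cp = "NO2->N2",
         coef = c("C4H10" = -3, "NO2-" = -26, "H+" = -26, "CO2" = 12, "N2" = 13, "H2O" = 28)),
    list(n = 4, cp = "NO2->NH4",
         coef = c("C4H10" = -3, "NO2-" = -13, "H+" = -26, "CO2" = 12, "NH4+" = 13, "H2O" = 2)))
  for (cs in cases) {
    rx <- couple(alkane_oxidation_half(cs$n), nitrogen_reduction_half(cs$cp))
    expect_equal(rx$stoich[names(cs$coef)], cs$coef,
                 info = paste(cs$n, cs$cp))
    expect_equal(length(rx$stoich), length(cs$coef))
    expect_equal(max(abs(check_balance(rx))), 0)
    expect_equal(rx$electrons_per_donor, 6 * cs$n + 2)
  }
})

test_that("bounded integer enumeration finds the same minimal coefficients as couple()", {
  for (cs in list(c("C2H6", "NO3-", "NO2-", "NO3->NO2"),
                  c("C4H10", "NO3-", "NO2-", "NO3->NO2"),
                  c("C2H6", "NO2-", "N2", "NO2->N2"),
                  c("C2H6", "NO2-", "NH4+", "NO2->NH4"),
                  c("C4H10", "NO2-", "N2", "NO2->N2"),
                  c("C4H10", "NO2-", "NH4+", "NO2->NH4"))) {
    found <- oracle_min_reaction(cs[1], cs[2], cs[3])
    expect_false(is.null(found), info = paste(cs, collapse = " "))
    n <- .oracle_comp(cs[1])$e[1]
    rx <- couple(alkane_oxidation_half(n), nitrogen_reduction_half(cs[4]))
    expect_equal(-rx$stoich[[cs[1]]], unname(found["alkane"]))
    expect_equal(-rx$stoich[[cs[2]]], unname(found["from"]))
    expect_equal(rx$stoich[[cs[3]]], unname(found["to"]))
    h_rx <- if ("H+" %in% names(rx$stoich)) -rx$stoich[["H+"]] else 0
    expect_equal(h_rx, unname(found["h_plus"]))
  }
})

test_that("coupling conserves elements and charge for every supported alkane/couple pair", {
  for (n in 1:6)
    for (cp in c("NO3->NO2", "NO3->N2", "NO2->N2", "NO3->NH4", "NO2->NH4")) {
      rx <- couple(alkane_oxidation_half(n), nitrogen_reduction_half(cp))
      expect_equal(max(abs(check_balance(rx))), 0, info = paste(n, cp))
      expect_equal(rx$electrons_per_donor, 6 * n + 2)
      g <- Reduce(function(a, b) if (b == 0) abs(a) else Recall(b, a %% b),
                  abs(rx$stoich))
      expect_equal(unname(g), 1)
    }
})

test_that("coupling is invariant to pre-scaling either half-reaction", {
  scale_half <- function(h, k) {
    h$stoich <- h$stoich * k
    h$electrons <- h$electrons * k
    h
  }
  base <- couple(alkane_oxidation_half(2), nitrogen_reduction_half("NO2->N2"))
  for (k in c(2, 3, 5)) {
    up_d <- couple(scale_half(alkane_oxidation_half(2), k),
                   nitrogen_reduction_half("NO2->N2"))
    up_a <- couple(alkane_oxidation_half(2),
                   scale_half(nitrogen_reduction_half("NO2->N2"), k))
    expect_equal(up_d$stoich[names(base$stoich)], base$stoich)
    expect_equal(up_a$stoich[names(base$stoich)], base$stoich)
  }
})

test_that("couple() rejects same-sign electron counts", {
  expect_error(couple(alkane_oxidation_half(2), alkane_oxidation_half(3)),
               "electron-consuming acceptor")
  expect_error(couple(nitrogen_reduction_half("NO3->NO2"),
                      nitrogen_reduction_half("NO2->N2")),
               "electron-releasing donor")
})

test_that("check_balance localises constructed defects and accepts the vacuous case", {
  rx <- couple(alkane_oxidation_half(2), nitrogen_reduction_half("NO3->NO2"))
  expect_true(all(check_balance(rx) == 0))
  broken <- rx
  broken$stoich[["CO2"]] <- 3            # perturb Eq.-1-type reaction
  expect_equal(check_balance(broken)[["C"]], 1)
  empty <- structure(list(stoich = numeric(0), species = list(),
                          donor = NA, electrons_per_donor = NA),
                     class = "nitralk_full_reaction")
  expect_true(all(check_balance(empty) == 0))
})

test_that("reactions render to and re-parse from the plain-text equation format", {
  rx <- couple(alkane_oxidation_half(2), nitrogen_reduction_half("NO2->N2"))
  txt <- format_reaction(rx)
  expect_match(txt, "->")
  back <- parse_reaction(txt, donor = "C2H6")
  expect_equal(back$stoich[names(rx$stoich)], rx$stoich)
  expect_equal(back$electrons_per_donor, 14L)
  # registered ions keep their charge through parsing
  p <- parse_reaction("3 C2H6 + 14 NO2- + 14 H+ -> 6 CO2 + 7 N2 + 16 H2O")
  expect_true(all(check_balance(p) == 0))
  expect_error(parse_reaction("C2H6 + NO3-"), "->")
})
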