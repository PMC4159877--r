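test_that("ionization potential and electron affinity are energy differences", {
  expect_equal(ionization_potential(100, 0), 100)
  expect_equal(ionization_potential(5, 5), 0)
  expect_equal(ionization_potential(180.4, 12.3), 168.1)
  expect_equal(electron_affinity(0, -50), 50)
  expect_equal(electron_affinity(7, 7), 0)
  expect_equal(electron_affinity(12.3, -31.9), 44.2)
  expect_error(ionization_potential(NaN, 0), "non-finite")
  expect_error(electron_affinity(1, Inf), "non-finite")
})

test_that("descriptor set matches the closed-form relations", {
  # I = 100, A = 60 worked by hand: eta 20, S 0.025, chi 80, mu -80, omega 160
  d <- descriptor_set(data.frame(e_neutral = 0, e_cation = 100,
                                 e_anion = -60))
  expect_equal(d$I, 100)
  expect_equal(d$A, 60)
  expect_equal(d$eta, 20)
  expect_equal(d$S, 0.025)
  expect_equal(d$chi, 80)
  expect_equal(d$mu, -80)
  expect_equal(d$omega, 160)
})

test_that("zero hardness flags softness and electrophilicity as undefined", {
  rec <- data.frame(e_neutral = 0, e_cation = 50, e_anion = -50)  # I = A
  expect_warning(d <- descriptor_set(rec), "hardness is zero")
  expect_equal(d$eta, 0)
  expect_equal(d$chi, 50)
  expect_true(is.na(d$S) && is.na(d$omega))
  rec0 <- data.frame(e_neutral = 0, e_cation = 0, e_anion = 0)
  expect_warning(d0 <- descriptor_set(rec0))
  expect_equal(unlist(d0[c("I", "A", "eta", "chi", "mu")]) != 0,
               setNames(rep(FALSE, 5), c("I", "A", "eta", "chi", "mu")))
})

test_that("electronegativity and chemical potential are exact opposites", {
  set.seed(5)
  recs <- data.frame(e_neutral = rnorm(30, 50, 40),
                     e_cation = rnorm(30, 250, 40),
                     e_anion = rnorm(30, 0, 40))
  d <- descriptor_set(recs)
  expect_identical(d$chi, -d$mu)
  expect_equal(cor(d$chi, d$mu)^2, 1, tolerance = 1e-14)
  # omega via chi equals omega via mu exactly
  expect_identical(d$chi^2 / (2 * d$eta), d$mu^2 / (2 * d$eta))
})

test_that("bond dissociation energy is the phenoxyl-radical energy balance", {
  expect_equal(bde(3.7, 3.7, 0), 0)
  # arithmetic that lands on the printed 3-position value for cyanidin
  expect_equal(bde(11.12, 40.0, 52.1), 80.98)
  expect_equal(bde(15, 30, 52.1), 67.1)
  # shifting parent and phenoxyl together leaves the BDE unchanged
  expect_equal(bde(15 + 100, 30 + 100, 52.1), bde(15, 30, 52.1))
  # the default E(H) is the standard semi-empirical value
  expect_equal(bde(11.12, 40.0), 80.98)
})

test_that("bde_min picks the minimum with positional tie-breaking", {
  expect_equal(bde_min(c("3", "5", "3'", "4'"),
                       c(67.08, 75.5, 76.04, 72.44)),
               list(position = "3", bde = 67.08))
  expect_equal(bde_min(c("3", "5", "7", "3'", "4'", "5'"),
                       c(78.15, 84.24, 90.53, 83.16, 75.61, 78.55)),
               list(position = "4'", bde = 75.61))
  expect_equal(bde_min("7", 90), list(position = "7", bde = 90))
  # tie broken by ring-position order 3 < 5 < 7 < 3' < 4' < 5'
  expect_equal(bde_min(c("4'", "3"), c(80, 80))$position, "3")
  expect_error(bde_min(character(0), numeric(0)), "empty")
})

test_that("bde_min is invariant to permutation of the list", {
  set.seed(9)
  pos <- c("3", "5", "7", "3'", "4'", "5'")
  for (i in 1:20) {
    e <- round(runif(6, 65, 95), 2)
    perm <- sample(6)
    expect_equal(bde_min(pos, e), bde_min(pos[perm], e[perm]))
  }
})

test_that("packaged BDE table's flagged minima agree with bde_min", {
  fx <- qsar_fixtures()
  groups <- split(fx$bde,
                  interaction(fx$bde$compound, fx$bde$method, fx$bde$form,
                              drop = TRUE))
  for (g in groups) {
    m <- bde_min(g$position, g$bde)
    expect_equal(m$bde, min(g$bde[g$lowest]))
  }
})

test_that("feature table assembles descriptor/form pairs in registry order", {
  reg <- load_registry()
  en <- make_energy_table(reg, "PM6")
  ft <- build_feature_table(reg, en, "PM6")
  expect_equal(dim(ft), c(21, 4))
  expect_equal(names(ft), c("A_FC", "chi_FC", "I_QB7", "nOH"))
  expect_equal(rownames(ft), reg$name)
  expect_equal(ft$nOH, as.numeric(reg$n_oh))
  # spot-check one compound against descriptor_set directly
  i <- which(reg$name == "malvidin")
  rec <- en[en$compound == "malvidin" & en$form == "FC", ]
  expect_equal(ft$A_FC[i], descriptor_set(rec)$A)
  expect_equal(ft$chi_FC[i], descriptor_set(rec)$chi)
  # a missing record errors with compound and form named
  en2 <- en[!(en$compound == "peonidin" & en$form == "QB7"), ]
  expect_error(build_feature_table(reg, en2, "PM6"), "peonidin.*QB7")
  expect_error(build_feature_table(reg, en, "PM6", features = "A_XX"),
               "malformed feature id")
  # QB5 descriptors are unavailable for a 5-glycosylated compound
  reg5 <- reg[reg$name == "malvidin-3,5-diglucoside", ]
  expect_error(build_feature_table(reg5, en, "PM6", features = "I_QB5"),
               "QB5 does not exist")
})

test_that("heat-of-formation parser reads MOPAC-style output", {
  path <- system.file("extdata", "mopac_example_synthetic.out",
                      package = "anfisqsar")
  expect_equal(read_mopac_heat(path), 123.45678)
  tmp <- tempfile()
  writeLines("no energies here", tmp)
  expect_error(read_mopac_heat(tmp), "FINAL HEAT OF FORMATION")
})

test_that("energy table reader validates its columns", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("compound\tform\tmethod\te_neutral\te_cation\te_anion",
               "c1\tFC\tPM6\t1.5\t150\t-30"), tmp)
  tab <- read_energy_table(tmp)
  expect_equal(tab$e_cation, 150)
  writeLines(c("compound\tform\te_neutral", "c1\tFC\t1.5"), tmp)
  expect_error(read_energy_table(tmp), "missing column")
})
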