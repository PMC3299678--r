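test_that("basic failing-heart spec carries the documented transforms", {
  spec <- basic_hf_spec()
  get <- function(pn) spec[spec$parameter == pn, ]
  expect_equal(get("INaL")$value, 2)
  expect_equal(get("tau_hL")$value, 2)
  expect_equal(get("Ito")$value, 0.4)
  expect_equal(get("IK1")$value, 0.68)
  expect_equal(get("INaK")$value, 0.9)
  expect_equal(get("INab")$value, 0)
  expect_identical(get("INab")$transform, "assign")
  expect_equal(get("INCX")$value, 1.75)
  expect_equal(get("ISERCA")$value, 0.5)
  expect_equal(get("EC50SR")$value, 0.4)
  expect_identical(get("EC50SR")$transform, "assign")
})

test_that("applying remodeling transforms the parameter vector", {
  p <- default_parameters()
  hf <- apply_remodeling(p, basic_hf_spec())
  expect_equal(hf[["GNaL"]], 2 * p[["GNaL"]])
  expect_equal(hf[["GtoSlow"]], 0.4 * p[["GtoSlow"]])
  expect_equal(hf[["GtoFast"]], 0.4 * p[["GtoFast"]])
  expect_equal(hf[["GNaB"]], 0)
  expect_equal(hf[["ec50SR"]], 0.4)
  expect_equal(hf[["leak_rate"]], 5 * p[["leak_rate"]])
  expect_equal(hf[["GCaB"]], 1.53 * p[["GCaB"]])
})

test_that("the empty spec is the identity and double application is rejected", {
  p <- default_parameters()
  expect_equal(unclass(apply_remodeling(p, remodeling_spec())), unclass(p),
               ignore_attr = TRUE)
  hf <- apply_remodeling(p, basic_hf_spec())
  expect_error(apply_remodeling(hf, basic_hf_spec()), "already been applied")
})

test_that("restoring every parameter reproduces baseline bit-for-bit", {
  spec <- basic_hf_spec()
  for (pn in unique(spec$parameter)) {
    spec <- sensitivity_variant(spec, pn, "no_change")
  }
  expect_identical(nrow(spec), 0L)
  p <- default_parameters()
  expect_identical(unname(unclass(apply_remodeling(p, spec))[seq_along(p)]),
                   unname(unclass(p)))
})

test_that("sensitivity variants double the tabulated percent change", {
  base <- basic_hf_spec()
  v <- function(pn, mode) {
    s <- sensitivity_variant(base, pn, mode)
    s[s$parameter == pn, ]
  }
  expect_equal(v("INaK", "double_change")$value, 0.8)
  expect_equal(v("INaL", "double_change")$value, 4)
  expect_equal(v("INCX", "double_change")$value, 3.5)
  expect_equal(v("IK1", "double_change")$value, 0.36)
  # down-regulations are floored at zero
  expect_equal(v("Ito", "double_change")$value, 0)
  # assignments double through the deviation from baseline, floored at 0
  expect_equal(v("EC50SR", "double_change")$value, 0.35)
  expect_equal(v("INab", "double_change")$value, 0)
  # restoring drops the row entirely
  expect_false("INaK" %in% sensitivity_variant(base, "INaK",
                                               "no_change")$parameter)
  expect_error(sensitivity_variant(base, "IKr", "no_change"),
               "not remodeled")
})

test_that("perturbations scale the remodeled values", {
  base <- basic_hf_spec()
  up <- perturb_spec(base, "ISERCA", 0.15)
  expect_equal(up$value[up$parameter == "ISERCA"], 0.575)
  expect_identical(perturb_spec(base, character(0), 0.15), base)
  down <- perturb_spec(base, "all", -0.15)
  expect_equal(down$value, base$value * 0.85)
  expect_error(perturb_spec(base, "INaK", 1.5), "fraction")
})

test_that("overlays compose multiplicatively on the current spec", {
  spec <- overlay_spec(basic_hf_spec(), ikr_block = 0.5,
                       ical_increase = 0.3, inal_scale = 2)
  p <- apply_remodeling(default_parameters(), spec)
  expect_equal(p[["GKr"]], 0.5 * default_parameters()[["GKr"]])
  expect_equal(p[["pCa"]], 1.3 * default_parameters()[["pCa"]])
  # x2 on the already-doubled failing value: net x4 versus baseline
  expect_equal(p[["GNaL"]], 4 * default_parameters()[["GNaL"]])
})

test_that("conflicting assignments name both sources", {
  a <- remodeling_spec("EC50SR", "assign", 0.4, "basic_HF")
  b <- remodeling_spec("EC50SR", "assign", 0.3, "overlay")
  expect_error(remodeling_spec(c("EC50SR", "EC50SR"), "assign",
                               c(0.4, 0.3), c("basic_HF", "overlay")),
               "basic_HF and overlay")
  expect_error(validate_spec <- rbind(a, b), NA)  # rbind itself fine
})

test_that("unknown parameters and negative factors are rejected", {
  expect_error(remodeling_spec("IKq", "scale", 0.5), "unknown remodelable")
  expect_error(remodeling_spec("INaK", "scale", -0.5), "factors")
})
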