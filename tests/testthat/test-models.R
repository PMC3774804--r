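test_that("rate-parameter counts match the model table", {
  counts <- vapply(paste0("M", 1:7), function(id) {
    length(build_model(id)$rate_parameter_names)
  }, integer(1))
  expect_equal(unname(counts), c(5L, 5L, 5L, 4L, 3L, 3L, 5L))
  # the two no-feedback models share an identical 3-rate parameterization
  expect_identical(build_model("M5")$rate_parameter_names,
                   build_model("M6")$rate_parameter_names)
})

test_that("dimer models enumerate the six unordered occupancy states", {
  for (id in c("M1", "M2", "M3", "M5", "M7")) {
    m <- build_model(id)
    itk <- m$species[m$species$is_itk, ]
    expect_equal(nrow(itk), 6L)
    # unordered pairs over {EMPTY, IP4, PIP3}
    expect_setequal(paste(itk$n_I, itk$n_P),
                    c("0 0", "1 0", "0 1", "2 0", "1 1", "0 2"))
  }
})

test_that("the monomer no-feedback model has exactly 5 reactions", {
  m <- build_model("M6")
  expect_equal(nrow(m$reactions), 5L)
  expect_equal(sum(m$reactions$rate_name == "k_on"), 2L)
  expect_equal(sum(m$reactions$rate_name == "k_off"), 2L)
  expect_equal(sum(m$reactions$rate_name == "k_cat"), 1L)
})

test_that("allostery tables encode the per-model feedback wiring", {
  # a PIP3-occupied partner does not stabilize PIP3 binding in M3
  expect_equal(affinity_class("M3", "PIP3", "PIP3"), "LOW")
  expect_equal(affinity_class("M3", "PIP3", "IP4"), "HIGH")
  # M7 is the mirror image of M3 on the PIP3-partner rows
  expect_equal(affinity_class("M7", "PIP3", "PIP3"), "HIGH")
  expect_equal(affinity_class("M7", "PIP3", "IP4"), "LOW")
  # no allosteric change at all in M5
  for (p in c("EMPTY", "IP4", "PIP3")) for (l in c("IP4", "PIP3")) {
    expect_equal(affinity_class("M5", p, l), "LOW")
  }
  # an unoccupied partner is the baseline weak-affinity case in every model
  for (id in c("M1", "M2", "M3", "M7")) {
    expect_equal(affinity_class(id, "EMPTY", "IP4"), "LOW")
    expect_equal(affinity_class(id, "EMPTY", "PIP3"), "LOW")
  }
  # M2/M3/M7 differ from M1 only in the partner = PIP3 rows
  t1 <- itkmaxent:::allostery_table("M1")
  for (id in c("M2", "M3", "M7")) {
    ti <- itkmaxent:::allostery_table(id)
    same <- ti$class == t1$class
    expect_true(all(same[ti$partner != "PIP3"]))
    expect_false(all(same[ti$partner == "PIP3"]))
  }
  expect_error(affinity_class("M4", "IP4", "PIP3"), "monomer|partner")
  expect_error(affinity_class("M6", "IP4", "PIP3"), "monomer|partner")
  expect_error(build_model("M8"), "unknown model_id")
})

test_that("active_count counts Itk units with at least one PIP3 site", {
  m <- build_model("M1")
  st <- setNames(numeric(nrow(m$species)), m$species$name)
  st[c("Itk_EP", "Itk_IP", "Itk_II", "Itk_PP")] <- c(3, 2, 5, 1)
  expect_equal(active_count(m, st), 6)
  # IP4-saturated and single-IP4 dimers are inactive
  st2 <- setNames(numeric(nrow(m$species)), m$species$name)
  st2[c("Itk_II", "Itk_EI")] <- c(5, 4)
  expect_equal(active_count(m, st2), 0)
  m6 <- build_model("M6")
  st3 <- setNames(numeric(nrow(m6$species)), m6$species$name)
  st3["Itk_PIP3"] <- 4
  expect_equal(active_count(m6, st3), 4)
  st3["Itk"] <- -2
  expect_error(active_count(m6, st3), "negative")
})

test_that("parameter completion enforces the KD coupling and positivity", {
  m <- build_model("M3")
  p <- complete_params(m, list(rates = c(k_on_low = 1e-3, k_off_low = 10,
                                         k_on_high = 0.1, k_cat = 1e-3),
                               alpha = 100))
  kd_low <- p$rates[["k_off_low"]] / p$rates[["k_on_low"]]
  kd_high <- p$rates[["k_off_high"]] / p$rates[["k_on_high"]]
  expect_equal(kd_low, 100 * kd_high)
  expect_error(complete_params(m, list(rates = c(k_on_low = 1e-3))),
               "missing rate")
  expect_error(complete_params(m, list(rates = c(k_on_low = -1e-3,
    k_off_low = 10, k_on_high = 0.1, k_off_high = 1, k_cat = 1e-3))),
    "positive")
})

test_that("every reaction conserves Itk units, PIP3 and inositol", {
  for (id in paste0("M", 1:7)) {
    m <- build_model(id)
    st <- itkmaxent:::model_stoich(m)
    w <- m$species
    expect_true(all(abs(crossprod(st$S, w$itk_w)) < 1e-12), label = id)
    expect_true(all(abs(crossprod(st$S, w$pip3_w)) < 1e-12), label = id)
    expect_true(all(abs(crossprod(st$S, w$ino_w)) < 1e-12), label = id)
  }
})

test_that("models serialize to JSON with their full enumeration", {
  js <- jsonlite::fromJSON(model_to_json(build_model("M4")))
  expect_equal(js$model_id, "M4")
  expect_equal(length(js$rate_parameter_names), 4L)
  expect_equal(nrow(js$reactions), 7L)
})
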