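# Case configuration, sweep definitions and report export.

test_that("case configurations round-trip through YAML and JSON", {
  cc <- case_config(label = "demo",
                    spec = geometry_spec(bubble_offset = 3e-6),
                    drive = ultrasound_drive(amplitude = 90e3),
                    config = solver_config(t_end = 1e-6, dt_max = 6e-9),
                    resolution = "coarse")
  for (ext in c(".yaml", ".json")) {
    p <- tempfile(fileext = ext)
    write_case_config(cc, p)
    back <- read_case_config(p)
    expect_equal(back$spec$bubble_offset, 3e-6)
    expect_equal(back$drive$amplitude, 90e3)
    expect_equal(back$config$t_end, 1e-6)
    expect_equal(back$config$dt_max, 6e-9)
    expect_identical(back$resolution, "coarse")
    expect_equal(back$solids$vessel$youngs_modulus, 1.5e6)
  }
})

test_that("the offset sweep enumerates eight cases with gaps 8 down to
           1 um and shared drive/materials", {
  cases <- offset_sweep_cases()
  expect_length(cases, 8L)
  gaps <- vapply(cases, function(cc) build_geometry(cc$spec)$gap, numeric(1))
  expect_equal(gaps * 1e6, 8:1, tolerance = 1e-9)
  amps <- vapply(cases, function(cc) cc$drive$amplitude, numeric(1))
  expect_true(all(amps == 130e3))
  Es <- vapply(cases, function(cc) cc$solids$vessel$youngs_modulus,
               numeric(1))
  expect_true(all(Es == 1.5e6))
})

test_that("the vessel-size sweep runs (r_i, C) from (10, 7) down to the
           centered (3, 0) case at fixed 3 um center-wall distance", {
  cases <- vessel_size_sweep_cases()
  ri <- vapply(cases, function(cc) cc$spec$vessel_inner_radius, numeric(1))
  C <- vapply(cases, function(cc) cc$spec$bubble_offset, numeric(1))
  expect_equal(ri * 1e6, 10:3)
  expect_equal(C * 1e6, c(7:0))
  expect_equal(ri - C, rep(3e-6, 8L), tolerance = 1e-12)
})

test_that("failed cases are recorded, not fatal", {
  bad <- case_config(label = "contact",
                     spec = geometry_spec(bubble_offset = 9e-6))
  r <- run_case(bad)
  expect_match(r$error, "contact")
  expect_null(r$stress)
})

test_that("report export writes valid empty tables, schema and manifest
           for an empty sweep", {
  sw <- run_offset_sweep(offsets_um = numeric(0))
  out <- tempfile()
  paths <- export_report(sw, out)
  expect_true(file.exists(file.path(out, "max_hoop_stress.csv")))
  tb <- utils::read.csv(file.path(out, "volume_extrema.csv"))
  expect_equal(nrow(tb), 0L)
  expect_true("V_max_m3" %in% names(tb))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_length(js$cases, 0L)
  expect_true(file.exists(file.path(out, "schema.json")))
  expect_true(file.exists(file.path(out, "manifest.json")))
})
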