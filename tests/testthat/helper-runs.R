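# Memoized heavy runs shared between the trend tests and the acceptance
# blocks (one computation per test session).  Problem sizes follow the
# package's reduced-resolution defaults documented in the methods vignette:
# sweeps at the reduced preset, 1.5 us horizon, 6 ns steps; validation at
# the coarse preset with 8 radial shells, 2.5 us horizon, 3 ns steps.

.run_cache <- new.env()

validation_resolution <- function() {
  rp <- resolution_params("coarse")
  rp$n_shell <- 8L
  rp
}

get_validation <- function() {
  if (is.null(.run_cache$val)) {
    .run_cache$val <- run_validation(t_end = 2.5e-6,
                                     resolution = validation_resolution(),
                                     dt = 3e-9)
  }
  .run_cache$val
}

get_validation_pair <- function() {
  if (is.null(.run_cache$pair)) {
    coarse <- run_validation(t_end = 1.2e-6,
                             resolution = resolution_params("coarse"),
                             dt = 3e-9)
    fine <- run_validation(t_end = 1.2e-6,
                           resolution = validation_resolution(), dt = 3e-9)
    .run_cache$pair <- list(coarse = coarse, fine = fine)
  }
  .run_cache$pair
}

get_offset_sweep <- function() {
  if (is.null(.run_cache$off)) {
    .run_cache$off <- run_offset_sweep(t_end = 1.5e-6, dt = 6e-9,
                                       resolution = "reduced",
                                       keep_runs = FALSE)
  }
  .run_cache$off
}

get_vessel_sweep <- function() {
  if (is.null(.run_cache$ves)) {
    .run_cache$ves <- run_vessel_size_sweep(t_end = 1.5e-6, dt = 6e-9,
                                            resolution = "reduced",
                                            keep_runs = FALSE)
  }
  .run_cache$ves
}

# dedicated coarse-resolution single cases for the symmetry-sensitive
# checks (centered and 2 um offset)
get_coarse_case <- function(C_um) {
  key <- paste0("cc", C_um)
  if (is.null(.run_cache[[key]])) {
    cc <- case_config(label = sprintf("C_%gum_coarse", C_um),
                      spec = geometry_spec(bubble_offset = C_um * 1e-6,
                                           vessel_inner_radius = 10e-6),
                      config = solver_config(t_end = 1.5e-6, dt_max = 6e-9),
                      resolution = "coarse")
    .run_cache[[key]] <- run_case(cc)
  }
  .run_cache[[key]]
}
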