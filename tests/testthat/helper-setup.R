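# canonical parameter set shared across tests -------------------------------

t1_transducer <- function() {
  transducer_spec(Pa = 2.4e6, a_bar = 0.5e-3, f = 2.5e6, c0 = 1540,
                  focus_depth = 10e-3)
}

t1_alpha <- function() acoustic_absorption(58, 2.5, 2)  # ~41.73 Np/m

t1_tissue <- function() tissue_thermal()

t1_agent <- function() {
  nanoagent_spec(Q0 = 0.05, R0 = 2.6, T_M = 38.7, sigma = 1 / (3 * sqrt(2)))
}

t1_optics_ex <- function() {
  optical_medium(mu_a = 15, mu_s_prime = 1500, n = 1.333, R_eff = 0.475,
                 epsilon = 6.09e6)
}

t1_optics_fl <- function() {
  optical_medium(mu_a = 12, mu_s_prime = 1700, n = 1.333, R_eff = 0.475,
                 epsilon = 6.54e5)
}

t1_geom <- function(orientation = "top") {
  boundary_geometry(10e-3, t1_optics_ex(), t1_optics_fl(),
                    orientation = orientation)
}

t1_sd <- function() sd_config(M0 = 0.003, epsilon_fl = 6.54e5)

# coarse dynamics grid (0.1 mm lateral / 0.35 mm axial over the focal region)
dyn_grid <- function() usf_grid(1e-4, 1e-4, 3.5e-4, 1.5e-3, 1.5e-3, 4e-3)

# bioheat solve on the dynamics grid, memoized across test files
dyn_thermal <- local({
  cache <- list()
  function(times = seq(0, 0.8, by = 0.01), exposure = 0.4) {
    times <- round(times, 10)
    key <- paste(c(exposure, times), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    grid <- dyn_grid()
    field <- evaluate_pressure(grid, t1_transducer(), t1_alpha())
    src <- heating_source(field, t1_alpha(), 1064, 1540, exposure)
    th <- solve_bioheat(src, t1_tissue(), grid, times)
    cache[[key]] <<- th
    th
  }
})
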