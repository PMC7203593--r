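# Shared fixtures, built lazily once per test run (the forward protocol
# sweeps are the expensive part; everything downstream reuses them).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_chars <- function() fixture("chars", default_characteristics)

fx_geom <- function() {
  fixture("geom", function() make_synthetic_fsu(synth_config(seed = 1)))
}

fx_spine <- function() {
  fixture("spine", function() make_synthetic_spine(synth_config(seed = 1)))
}

# noise-free stepwise-reduction table from the packaged ground truth
fx_eds1 <- function() {
  fixture("eds1", function() {
    simulate_eds1(fx_geom(), fx_chars(), synth_config(seed = 1))
  })
}

# noise-free intradiscal-pressure table
fx_eds2 <- function() {
  fixture("eds2", function() {
    simulate_eds2(fx_spine(), fx_chars(), synth_config(seed = 1))
  })
}

# full backward calibration on the noise-free table
fx_calibration <- function() {
  fixture("calibration", function() {
    suppressWarnings(run_backward_calibration(fx_eds1(), fx_geom()))
  })
}

# two-vertebra test rig with a single vertical midline cord
tiny_segment <- function(prestrain = 0) {
  cr <- rigid_body("up", com = c(0, 0, 0.04),
                   points = list(P = c(0, 0, 0.03),
                                 Q = c(0, -0.02, 0.03)))
  ca <- rigid_body("dn", com = c(0, 0, 0),
                   points = list(P = c(0, 0, 0.01),
                                 Q = c(0, -0.02, 0.01)))
  lig <- ligament_def("ALL", "midline", c("up", "P"), c("dn", "P"),
                      prestrain = prestrain)
  segment_geometry(cr, ca, c(0, 0, 0.02), ligaments = list(lig),
                   csa = 1.8e-3)
}

# landmarks sampled exactly on a surface polynomial over a 3 x 3 grid
landmarks_on <- function(coef, xs = c(-3, 0, 3), ys = c(-2.5, 0, 2.5),
                         frame = NULL) {
  g <- expand.grid(x = xs, y = ys)
  f <- coef$p30 * g$x^3 + coef$p03 * g$y^3 + coef$p20 * g$x^2 +
    coef$p02 * g$y^2 + coef$p00
  facet_landmarks(cbind(g$x, g$y, f), frame = frame)
}

# scalar oracle: invert a tanh-cubic torque row by bisection
invert_disk_row <- function(p, torque, upper = 0.3) {
  stats::uniroot(function(phi) {
    p$p1 * tanh(phi^3 / p$p2) + p$p3 * phi - torque
  }, c(1e-9, upper), tol = 1e-13)$root
}
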