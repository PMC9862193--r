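# R-facing wrapper around the generic Rosenbrock integrator (the same
# stepper that drives the kinetic model, exposed for arbitrary right-hand
# sides; used for oracle computations and available to users).

#' Integrate an arbitrary ODE system with the package's stiff stepper
#'
#' RODAS3 Rosenbrock method (order 3(2), stiffly accurate, adaptive step,
#' finite-difference Jacobian) with cubic Hermite dense output.
#' @param f function(t, y) returning dy/dt
#' @param y0 initial state
#' @param times output times (first entry is the initial time)
#' @param rtol,atol tolerances
#' @param hmax maximum step size (0 = unlimited)
#' @return list with `y` (times x states), `ok`, `message`, step counters
#' @export
ros_integrate <- function(f, y0, times, rtol = 1e-8, atol = 1e-10, hmax = 0) {
  r <- cpp_ros_integrate(function(t, y) as.numeric(f(t, y)),
                         as.numeric(y0), as.numeric(times), rtol, atol, hmax)
  r
}
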