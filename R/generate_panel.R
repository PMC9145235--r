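#' Simulate a line x environment x replicate phenotype panel
#'
#' Draws observations from the additive decomposition
#' `y = mu + line + environment + line:environment + residual`,
#' with line effects `N(0, Vg)`, interaction effects `N(0, Vgl)`,
#' residuals `N(0, Ve)` and environment effects `N(0, env_sd^2)`.
#' All drawn effects are returned, so the observations can be
#' reconstructed exactly from the truth object.
#'
#' @param spec A [panel_sim_spec()].
#' @param seed Integer seed.
#' @return A list with `panel` (long data.frame: `line`, `env`, `rep`,
#'   `value`) and `truth` (list of the drawn `g`, `e`, `gl` effects, the
#'   residuals and the spec).
#' @export
#' @examples
#' sim <- generate_phenotype_panel(panel_sim_spec(n_lines = 10, L = 2, R = 2),
#'                                 seed = 1)
#' head(sim$panel)
generate_phenotype_panel <- function(spec, seed) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  n <- spec$n_lines; L <- spec$L; R <- spec$R
  withr::with_seed(seed, {
    g  <- stats::rnorm(n, 0, sqrt(spec$Vg))
    e  <- stats::rnorm(L, 0, spec$env_sd)
    gl <- matrix(stats::rnorm(n * L, 0, sqrt(spec$Vgl)), n, L)
    eps <- array(stats::rnorm(n * L * R, 0, sqrt(spec$Ve)), c(n, L, R))
  })
  idx <- expand.grid(rep = seq_len(R), env = seq_len(L), line = seq_len(n))
  value <- spec$mu + g[idx$line] + e[idx$env] +
    gl[cbind(idx$line, idx$env)] + eps[cbind(idx$line, idx$env, idx$rep)]
  panel <- data.frame(line = sprintf("L%03d", idx$line),
                      env = sprintf("E%d", idx$env),
                      rep = idx$rep, value = value,
                      stringsAsFactors = FALSE)
  truth <- list(g = g, e = e, gl = gl, eps = eps, spec = spec, seed = seed)
  list(panel = panel, truth = truth)
}

#' Reconstruct panel observations from the simulation truth
#'
#' Pools the drawn effects back through the additive model; the result
#' matches the simulated observations exactly (zero residual of
#' reconstruction), which is the panel simulator's consistency invariant.
#'
#' @param truth The `truth` element returned by
#'   [generate_phenotype_panel()].
#' @return Numeric vector in the panel's row order.
#' @export
reconstruct_panel <- function(truth) {
  spec <- truth$spec
  idx <- expand.grid(rep = seq_len(spec$R), env = seq_len(spec$L),
                     line = seq_len(spec$n_lines))
  spec$mu + truth$g[idx$line] + truth$e[idx$env] +
    truth$gl[cbind(idx$line, idx$env)] +
    truth$eps[cbind(idx$line, idx$env, idx$rep)]
}
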