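## REML variance components for the multi-environment trial model
##   y = mu + env (fixed) + line (random, Vg) + line:env (random, Vgl)
##     + residual (Ve),
## line BLUPs from the mixed-model equations, and broad-sense
## heritability on an entry-mean basis.

panel_design <- function(panel, include_interaction = TRUE) {
  stopifnot(all(c("line", "env", "value") %in% names(panel)))
  line <- factor(panel$line)
  env <- factor(panel$env)
  n <- nlevels(line); L <- nlevels(env)
  if (n < 2) stopf("need >= 2 lines")
  y <- panel$value
  X <- if (L > 1) stats::model.matrix(~env) else
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  Zg <- stats::model.matrix(~ line - 1)
  interaction_on <- include_interaction && L > 1
  Zgl <- if (interaction_on) {
    le <- interaction(line, env, drop = FALSE)
    stats::model.matrix(~ le - 1)
  } else NULL
  list(y = y, X = X, Zg = Zg, Zgl = Zgl, n = n, L = L,
       line_levels = levels(line), interaction_on = interaction_on)
}

## method-of-moments initialisation from ANOVA mean squares (balanced
## formulas; serviceable as a starting point for unbalanced data too)
mom_start <- function(panel, d) {
  vy <- stats::var(d$y)
  Rbar <- length(d$y) / (d$n * d$L)
  fml <- if (d$interaction_on) value ~ env + line + line:env
         else if (d$L > 1) value ~ env + line else value ~ line
  ## only the mean squares are used; the F-tests (and their perfect-fit
  ## warning) are irrelevant here
  an <- suppressWarnings(stats::anova(stats::lm(fml, data = transform(panel,
    line = factor(line), env = factor(env)))))
  ms <- an[["Mean Sq"]]; rn <- rownames(an)
  mse <- ms[rn == "Residuals"]
  msg <- ms[rn == "line"]
  if (d$interaction_on) {
    msi <- ms[rn == "env:line" | rn == "line:env"]
    vgl <- max((msi - mse) / Rbar, 0)
    vg <- max((msg - msi) / (d$L * Rbar), 0)
  } else {
    vgl <- 0
    vg <- max((msg - mse) / (d$L * Rbar), 0)
  }
  ve <- max(mse, 1e-8 * max(vy, 1))
  ## strict zeros stall EM; start at a small positive fraction instead
  floor0 <- 0.01 * max(vy, 1e-8)
  out <- c(Vg = if (vg > 0) vg else floor0,
           Vgl = if (d$interaction_on) (if (vgl > 0) vgl else floor0) else 0,
           Ve = ve)
  attr(out, "mse") <- mse
  attr(out, "anova") <- c(Vg = vg, Vgl = vgl)
  out
}

is_balanced_panel <- function(panel) {
  tab <- table(panel$line, panel$env)
  length(unique(as.integer(tab))) == 1L && all(tab > 0)
}

#' REML variance components of a phenotype panel (EM algorithm)
#'
#' Fits the two-environment trial model with fixed environment effects and
#' random line and line-by-environment effects by EM-REML on the
#' mixed-model equations. Components are non-negative by construction of
#' the EM updates; a component that collapses below a relative floor is
#' snapped to zero and its term dropped. With a single environment the
#' interaction variance is structurally zero and reported as such.
#'
#' @param panel Long data.frame with columns `line`, `env`, `rep`,
#'   `value`.
#' @param include_interaction Fit the line-by-environment term (ignored
#'   when only one environment is present).
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Maximum EM iterations; non-convergence returns the
#'   current estimates with `converged = FALSE` and a warning.
#' @return A `variance_components` object: `mu`, `Vg`, `Vgl`, `Ve`,
#'   `converged`, `iterations`, `n_lines`, `L`, `R`.
#' @export
#' @examples
#' sim <- generate_phenotype_panel(panel_sim_spec(n_lines = 40), seed = 1)
#' fit_variance_components(sim$panel)
fit_variance_components <- function(panel, include_interaction = TRUE,
                                    tol = 1e-8, max_iter = 1000L) {
  d <- panel_design(panel, include_interaction)
  N <- length(d$y)
  ## centre the response: the intercept absorbs the shift and the
  ## quadratic forms keep full precision at any data scale
  ybar <- mean(d$y)
  y <- d$y - ybar
  W <- cbind(d$X, d$Zg, if (d$interaction_on) d$Zgl)
  p <- ncol(d$X); qg <- ncol(d$Zg)
  qgl <- if (d$interaction_on) ncol(d$Zgl) else 0L
  ig <- p + seq_len(qg)
  igl <- if (qgl) p + qg + seq_len(qgl) else integer(0)
  CtC <- crossprod(W)
  rhs <- crossprod(W, y)
  yy <- sum(y * y)
  th <- mom_start(panel, d)
  vy <- max(stats::var(y), 1e-12)
  ## exact-fit short-circuit: on balanced data with numerically zero
  ## residual mean square the ANOVA estimators are the REML solution
  if (attr(th, "mse") < 1e-10 * vy && is_balanced_panel(panel)) {
    an <- attr(th, "anova")
    ch <- chol(CtC + diag(1e-10 * mean(diag(CtC)), ncol(CtC)))
    sol <- chol2inv(ch) %*% rhs
    mu <- mean(d$X %*% sol[seq_len(p)]) + ybar
    return(structure(list(mu = as.numeric(mu), Vg = unname(an["Vg"]),
                          Vgl = unname(an["Vgl"]),
                          Ve = max(attr(th, "mse"), 0),
                          converged = TRUE, iterations = 0L,
                          n_lines = d$n, L = d$L,
                          R = N / (d$n * d$L)),
                     class = "variance_components"))
  }
  active_g <- TRUE; active_gl <- d$interaction_on
  BIG <- 1e12
  conv <- FALSE; it <- 0L
  mu <- mean(y)
  th_prev <- stats::setNames(rep(NA_real_, 3), c("Vg", "Vgl", "Ve"))
  dec_g <- 0L; dec_gl <- 0L
  repeat {
    it <- it + 1L
    lg <- if (active_g && th["Vg"] > 0) th["Ve"] / th["Vg"] else BIG
    lgl <- if (active_gl && th["Vgl"] > 0) th["Ve"] / th["Vgl"] else BIG
    C <- CtC
    diag(C)[ig] <- diag(CtC)[ig] + lg
    if (qgl) diag(C)[igl] <- diag(CtC)[igl] + lgl
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) {
      diag(C) <- diag(C) + 1e-8 * mean(diag(C))
      ch <- chol(C)
    }
    Ci <- chol2inv(ch)
    sol <- Ci %*% rhs
    ve_new <- max((yy - sum(sol * rhs)) / (N - p), 1e-12 * vy)
    ug <- sol[ig]
    vg_new <- if (active_g)
      (sum(ug^2) + th["Ve"] * sum(diag(Ci)[ig])) / qg else 0
    vgl_new <- if (active_gl) {
      ugl <- sol[igl]
      (sum(ugl^2) + th["Ve"] * sum(diag(Ci)[igl])) / qgl
    } else 0
    new <- c(Vg = unname(vg_new), Vgl = unname(vgl_new),
             Ve = unname(ve_new))
    ## Boundary handling: EM approaches a zero (boundary) REML estimate
    ## only asymptotically — geometrically or, right at the boundary,
    ## harmonically. A component is snapped to zero when its
    ## Aitken-extrapolated limit is numerically zero, or when it has
    ## decreased monotonically for many iterations and the extrapolated
    ## limit is well below the current value (the harmonic signature; an
    ## interior fixed point extrapolates to ~the current value instead).
    aitken_limit <- function(cur, prev, prev2) {
      d1 <- cur - prev; d0 <- prev - prev2
      if (!is.finite(d0) || d0 >= 0 || d1 >= 0) return(NA_real_)
      r <- d1 / d0
      if (r <= 0 || r >= 1) return(NA_real_)
      cur + d1 * r / (1 - r)
    }
    boundary <- function(nm, streak) {
      lim <- aitken_limit(new[nm], th[nm], th_prev[nm])
      new[nm] < 1e-8 * vy ||
        (is.finite(lim) && lim < 1e-7 * vy) ||
        (streak >= 50L && is.finite(lim) && lim <= 0.6 * new[nm])
    }
    dec_g <- if (new["Vg"] < th["Vg"]) dec_g + 1L else 0L
    dec_gl <- if (new["Vgl"] < th["Vgl"]) dec_gl + 1L else 0L
    if (active_g && boundary("Vg", dec_g)) {
      new["Vg"] <- 0; active_g <- FALSE
    }
    if (active_gl && boundary("Vgl", dec_gl)) {
      new["Vgl"] <- 0; active_gl <- FALSE
    }
    delta <- max(abs(new - th)) / max(sum(new), 1e-12)
    th_prev <- th
    th <- new
    if (delta < tol) { conv <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!conv)
    warning(sprintf("EM-REML did not converge in %d iterations (last relative change above %g)",
                    max_iter, tol))
  beta <- sol[seq_len(p)]
  mu <- mean(d$X %*% beta) + ybar
  R <- N / (d$n * d$L)
  structure(list(mu = as.numeric(mu), Vg = unname(th["Vg"]),
                 Vgl = unname(th["Vgl"]), Ve = unname(th["Ve"]),
                 converged = conv, iterations = it,
                 n_lines = d$n, L = d$L, R = R),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("REML components: Vg = %.4g, Vgl = %.4g, Ve = %.4g (mu = %.4g)\n",
              x$Vg, x$Vgl, x$Ve, x$mu))
  cat(sprintf("  %d lines, L = %d, R = %g; %s in %d iterations\n",
              x$n_lines, x$L, x$R,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Best linear unbiased prediction of line effects
#'
#' Solves the mixed-model equations at the supplied variance components
#' and reports `mu + predicted line effect` per line. With `Vg = 0` (or
#' all variances zero) every BLUP equals `mu` (complete shrinkage).
#'
#' @param panel Long data.frame (`line`, `env`, `rep`, `value`).
#' @param components A `variance_components` object (defaults to fitting
#'   them from the panel).
#' @return Data.frame with columns `line` and `blup`.
#' @export
blup <- function(panel, components = fit_variance_components(panel)) {
  stopifnot(inherits(components, "variance_components"))
  d <- panel_design(panel, include_interaction = components$Vgl > 0)
  mu <- components$mu
  if (components$Vg <= 0 ||
      (components$Ve <= 0 && components$Vg <= 0 && components$Vgl <= 0))
    return(data.frame(line = d$line_levels, blup = rep(mu, d$n),
                      stringsAsFactors = FALSE))
  BIG <- 1e12
  ve <- max(components$Ve, 1e-12)
  lg <- ve / components$Vg
  lgl <- if (components$Vgl > 0) ve / components$Vgl else BIG
  W <- cbind(d$X, d$Zg, if (d$interaction_on) d$Zgl)
  p <- ncol(d$X); qg <- ncol(d$Zg)
  ig <- p + seq_len(qg)
  C <- crossprod(W)
  diag(C)[ig] <- diag(C)[ig] + lg
  if (d$interaction_on) {
    igl <- (p + qg + 1):ncol(W)
    diag(C)[igl] <- diag(C)[igl] + lgl
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    diag(C) <- diag(C) + 1e-8 * mean(diag(C))
    ch <- chol(C)
  }
  sol <- chol2inv(ch) %*% crossprod(W, d$y)
  data.frame(line = d$line_levels, blup = mu + as.numeric(sol[ig]),
             stringsAsFactors = FALSE)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = Vg / (Vg + Vgl/L + Ve/(L*R))`, the genotypic share of the
#' phenotypic variance of a line mean over `L` environments with `R`
#' replicates each.
#'
#' @param components A `variance_components` object, or a list with
#'   elements `Vg`, `Vgl`, `Ve`.
#' @param L Number of environments (defaults to the fit's).
#' @param R Replicates per environment (defaults to the fit's).
#' @return H2 in `[0, 1]`.
#' @export
#' @examples
#' heritability(list(Vg = 1, Vgl = 0.2, Ve = 0.5), L = 2, R = 3)
heritability <- function(components, L = components$L, R = components$R) {
  Vg <- components$Vg; Vgl <- components$Vgl; Ve <- components$Ve
  if (L < 1 || R < 1) stopf("L and R must be >= 1")
  if (any(c(Vg, Vgl, Ve) < 0)) stopf("variance components must be >= 0")
  denom <- Vg + Vgl / L + Ve / (L * R)
  if (denom == 0) stopf("all variance components are zero: H2 undefined")
  Vg / denom
}
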