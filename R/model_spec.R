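#' Polynomial growth basis
#'
#' Builds the factor loading matrix \eqn{\Lambda} of a latent growth curve
#' model: column \eqn{k} holds the wave timings raised to the power
#' \eqn{k - 1}, so the columns span intercept, linear and higher-order
#' trends up to the requested polynomial degree.
#'
#' @param time_codes Numeric vector of wave timings, strictly increasing.
#' @param degree Polynomial degree of the growth trajectory (2 = quadratic).
#' @return An object of class `growth_basis` with elements `time_codes`,
#'   `degree`, and the `T x (degree+1)` `loading_matrix`.
#' @examples
#' build_growth_basis(0:4, 2)$loading_matrix
#' @export
build_growth_basis <- function(time_codes, degree = 2L) {
  time_codes <- as.numeric(time_codes)
  if (any(diff(time_codes) <= 0)) {
    stop("`time_codes` must be strictly increasing", call. = FALSE)
  }
  degree <- as.integer(degree)
  if (degree < 1L) stop("`degree` must be >= 1", call. = FALSE)
  q <- degree + 1L
  if (length(time_codes) <= q) {
    stop("need more waves than growth factors (T > degree + 1)", call. = FALSE)
  }
  lambda <- outer(time_codes, seq_len(q) - 1L, `^`)
  colnames(lambda) <- c("intercept", "linear", "quadratic", "cubic")[seq_len(min(q, 4L))]
  structure(
    list(time_codes = time_codes, degree = degree, loading_matrix = lambda),
    class = "growth_basis"
  )
}

#' Level parameters of a multilevel latent growth model
#'
#' One level's latent growth-factor mean vector \eqn{\alpha}, growth-factor
#' covariance matrix \eqn{\Phi}, and time-specific residual variances
#' \eqn{\theta} (the diagonal of \eqn{\Theta}).
#'
#' @param latent_mean Length-q mean vector of the growth factors.
#' @param latent_cov q x q symmetric positive semidefinite matrix.
#' @param residual_var Length-T vector of nonnegative residual variances.
#' @return A `level_params` list.
#' @export
level_params <- function(latent_mean, latent_cov, residual_var) {
  latent_cov <- as.matrix(latent_cov)
  if (!isSymmetric(latent_cov, tol = 1e-10)) {
    stop("`latent_cov` must be symmetric", call. = FALSE)
  }
  if (min(eigen(latent_cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("`latent_cov` must be positive semidefinite", call. = FALSE)
  }
  if (any(residual_var < 0)) stop("`residual_var` must be >= 0", call. = FALSE)
  if (length(latent_mean) != nrow(latent_cov)) {
    stop("`latent_mean` length must match `latent_cov` dimension", call. = FALSE)
  }
  structure(
    list(
      latent_mean = as.numeric(latent_mean),
      latent_cov = latent_cov,
      residual_var = as.numeric(residual_var)
    ),
    class = "level_params"
  )
}

#' Two-level latent growth model specification
#'
#' Couples a growth basis with within-level (individual) and between-level
#' (cluster) parameters. All observed-variable means are carried at the
#' between level, so the within latent mean must be zero.
#'
#' @param basis A [build_growth_basis()] object.
#' @param within,between [level_params()] objects for the two levels.
#' @return An `mlgm_spec` object.
#' @export
mlgm_spec <- function(basis, within, between) {
  stopifnot(inherits(basis, "growth_basis"))
  q <- ncol(basis$loading_matrix)
  tt <- nrow(basis$loading_matrix)
  for (lp in list(within, between)) {
    if (length(lp$latent_mean) != q || length(lp$residual_var) != tt) {
      stop("level parameter dimensions do not match the growth basis", call. = FALSE)
    }
  }
  if (any(within$latent_mean != 0)) {
    stop("within-level latent means must be zero (means live at the between level)",
         call. = FALSE)
  }
  structure(list(basis = basis, within = within, between = between),
            class = "mlgm_spec")
}

#' Default population model
#'
#' The quadratic five-wave population model used throughout the package:
#' growth-factor means and covariances at both levels plus time-specific
#' residual variances, on the scale of the LSAY mathematics-achievement
#' parameterization common in MLGM simulation work. Intercept-linear
#' covariances are nonzero at both levels; all other factor covariances are
#' zero.
#'
#' @param time_codes Wave timings (defaults to 0:4).
#' @return An [mlgm_spec()] object.
#' @examples
#' sp <- default_mlgm_spec()
#' implied_moments(sp)$mean
#' @export
default_mlgm_spec <- function(time_codes = 0:4) {
  basis <- build_growth_basis(time_codes, 2L)
  phi_b <- matrix(c(16.2, 2.82, 0,
                    2.82, 0.61, 0,
                    0,    0,    0.02), 3, 3, byrow = TRUE)
  phi_w <- matrix(c(71.45, 6.76,  0,
                    6.76,  14.76, 0,
                    0,     0,     0.07), 3, 3, byrow = TRUE)
  mlgm_spec(
    basis,
    within = level_params(c(0, 0, 0), phi_w, c(1.80, 1.28, 0.06, 0.54, 0.31)),
    between = level_params(c(49.96, 4.32, -0.13), phi_b,
                           c(11.91, 15.25, 10.32, 12.59, 1.93))
  )
}

#' Model-implied moments
#'
#' Computes the observed-variable moments implied by an MLGM specification:
#' mean \eqn{\mu = \Lambda\alpha_B}, within covariance
#' \eqn{\Sigma_W = \Lambda\Phi_W\Lambda' + \Theta_W} and between covariance
#' \eqn{\Sigma_B = \Lambda\Phi_B\Lambda' + \Theta_B}.
#'
#' @param spec An [mlgm_spec()] object.
#' @return List with `mean`, `within_cov`, `between_cov`.
#' @export
implied_moments <- function(spec) {
  stopifnot(inherits(spec, "mlgm_spec"))
  lam <- spec$basis$loading_matrix
  sw <- lam %*% spec$within$latent_cov %*% t(lam) + diag(spec$within$residual_var)
  sb <- lam %*% spec$between$latent_cov %*% t(lam) + diag(spec$between$residual_var)
  list(
    mean = as.numeric(lam %*% spec$between$latent_mean),
    within_cov = (sw + t(sw)) / 2,
    between_cov = (sb + t(sb)) / 2
  )
}

#' Intraclass correlation profile
#'
#' Wave-by-wave share of total variance located at the cluster level:
#' \eqn{\Sigma_B[t,t] / (\Sigma_B[t,t] + \Sigma_W[t,t])}.
#'
#' @param moments Output of [implied_moments()].
#' @return Numeric vector of length T.
#' @export
icc_profile <- function(moments) {
  vb <- diag(moments$between_cov)
  vw <- diag(moments$within_cov)
  tot <- vb + vw
  if (any(tot <= 0)) stop("total variance must be positive at every wave", call. = FALSE)
  vb / tot
}

# --- model templates ---------------------------------------------------------

.cov_modes <- c("saturated", "structured", "diagonal")
.mean_modes <- c("saturated", "structured", "equal")

#' Saturation template for a two-level model
#'
#' A template names, for each block of the two-level mean-and-covariance
#' structure, whether it is freely estimated (`saturated`), constrained to
#' the growth structure (`structured`), or reduced to an independence /
#' equal-means baseline (`diagonal`, `equal`).
#'
#' @param name Label used in the fit catalog.
#' @param within_cov,between_cov One of `"saturated"`, `"structured"`,
#'   `"diagonal"`.
#' @param mean One of `"saturated"`, `"structured"`, `"equal"`.
#' @param phi_offdiag_free For structured covariance blocks, whether the
#'   off-diagonal growth-factor covariances are free (default) or fixed at
#'   zero. Exposed so alternative target-saturation conventions can be probed.
#' @return A `model_template` object.
#' @export
model_template <- function(name, within_cov, between_cov, mean,
                           phi_offdiag_free = TRUE) {
  within_cov <- match.arg(within_cov, .cov_modes)
  between_cov <- match.arg(between_cov, .cov_modes)
  mean <- match.arg(mean, .mean_modes)
  structure(
    list(name = name, within_cov = within_cov, between_cov = between_cov,
         mean = mean, phi_offdiag_free = isTRUE(phi_offdiag_free)),
    class = "model_template"
  )
}

#' Standard template catalog
#'
#' The eight model templates the study fits on every dataset:
#' \describe{
#'   \item{H1}{everything saturated (the unrestricted reference).}
#'   \item{PS_B}{within saturated, between covariance structured, means
#'     saturated — isolates between-level covariance misfit (df 4).}
#'   \item{PS_W}{between fully saturated, within covariance structured
#'     (df 4).}
#'   \item{TS_COV}{the literal target-saturated covariance model; identical
#'     to PS_B under this construction.}
#'   \item{TS_MEAN}{covariances saturated at both levels, means constrained
#'     to the growth structure \eqn{\mu = \Lambda\alpha} (df 2).}
#'   \item{BASE_B, BASE_W}{independence baselines: the target level's
#'     covariance diagonal, everything else saturated (df 10).}
#'   \item{BASE_MEAN}{equal-means baseline with saturated covariances
#'     (df 4).}
#' }
#'
#' @param phi_offdiag_free Passed to the structured templates.
#' @return Named list of [model_template()] objects.
#' @export
template_catalog <- function(phi_offdiag_free = TRUE) {
  list(
    H1        = model_template("H1",        "saturated",  "saturated",  "saturated"),
    PS_B      = model_template("PS_B",      "saturated",  "structured", "saturated",
                               phi_offdiag_free),
    PS_W      = model_template("PS_W",      "structured", "saturated",  "saturated",
                               phi_offdiag_free),
    TS_COV    = model_template("TS_COV",    "saturated",  "structured", "saturated",
                               phi_offdiag_free),
    TS_MEAN   = model_template("TS_MEAN",   "saturated",  "saturated",  "structured"),
    BASE_B    = model_template("BASE_B",    "saturated",  "diagonal",   "saturated"),
    BASE_W    = model_template("BASE_W",    "diagonal",   "saturated",  "saturated"),
    BASE_MEAN = model_template("BASE_MEAN", "saturated",  "saturated",  "equal")
  )
}

#' Free parameters and degrees of freedom of a template
#'
#' Counts free parameters blockwise: a saturated covariance block has
#' T(T+1)/2 parameters, a structured block q(q+1)/2 + T (full growth-factor
#' covariance plus residual variances; q(q-1)/2 fewer when the factor
#' covariances are fixed at zero), a diagonal baseline T; a saturated mean
#' has T parameters, a structured mean q, an equal-means baseline 1. Degrees
#' of freedom are relative to the fully saturated model (35 parameters for
#' T = 5).
#'
#' @param template A [model_template()].
#' @param T_waves Number of waves.
#' @param q Number of growth factors.
#' @return List with `free_params` and `df`.
#' @export
model_df <- function(template, T_waves = 5L, q = 3L) {
  stopifnot(inherits(template, "model_template"))
  cov_count <- function(mode) {
    switch(mode,
      saturated = T_waves * (T_waves + 1) / 2,
      structured = q * (q + 1) / 2 + T_waves -
        if (template$phi_offdiag_free) 0 else q * (q - 1) / 2,
      diagonal = T_waves
    )
  }
  mean_count <- switch(template$mean, saturated = T_waves, structured = q, equal = 1)
  p <- cov_count(template$within_cov) + cov_count(template$between_cov) + mean_count
  p_h1 <- T_waves * (T_waves + 1) + T_waves
  list(free_params = as.integer(p), df = as.integer(p_h1 - p))
}

#' Serialize / deserialize a population model
#'
#' Writes and reads the YAML representation of an [mlgm_spec()]:
#' `time_codes`, `alpha_between`, lower triangles of the factor covariance
#' matrices, and the residual-variance vectors.
#'
#' @param spec An `mlgm_spec`.
#' @param path File path.
#' @return `write_mlgm_spec` returns `path` invisibly; `read_mlgm_spec`
#'   returns an `mlgm_spec`.
#' @export
write_mlgm_spec <- function(spec, path) {
  lt <- function(m) as.numeric(m[lower.tri(m, diag = TRUE)])
  yaml::write_yaml(list(
    time_codes = spec$basis$time_codes,
    degree = spec$basis$degree,
    alpha_between = spec$between$latent_mean,
    phi_between = lt(spec$between$latent_cov),
    theta_between = spec$between$residual_var,
    phi_within = lt(spec$within$latent_cov),
    theta_within = spec$within$residual_var
  ), path)
  invisible(path)
}

#' @rdname write_mlgm_spec
#' @export
read_mlgm_spec <- function(path) {
  y <- yaml::read_yaml(path)
  from_lt <- function(v, q) {
    m <- matrix(0, q, q)
    m[lower.tri(m, diag = TRUE)] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  basis <- build_growth_basis(y$time_codes, y$degree %||% 2L)
  q <- ncol(basis$loading_matrix)
  mlgm_spec(
    basis,
    within = level_params(rep(0, q), from_lt(y$phi_within, q), y$theta_within),
    between = level_params(y$alpha_between, from_lt(y$phi_between, q),
                           y$theta_between)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
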