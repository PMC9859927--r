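#' Multi-group SIR epidemic parameters
#'
#' Container for an n-group SIR model with an imperfect vaccine. Each group
#' has six compartments: susceptible (S), infected (I) and recovered (R),
#' each split by vaccination status (unvaccinated / vaccinated, the latter
#' written SV, IV, RV). Four transmission matrices describe the possible
#' infector/infectee vaccination combinations:
#'
#' * `beta1[i, j]`: unvaccinated j infecting unvaccinated i,
#' * `beta2[i, j]`: vaccinated j infecting unvaccinated i,
#' * `beta3[i, j]`: unvaccinated j infecting vaccinated i,
#' * `beta4[i, j]`: vaccinated j infecting vaccinated i.
#'
#' A weakly protective vaccine requires `beta1 >= beta2` and
#' `beta3 >= beta4` elementwise, and recovery no slower after vaccination
#' (`mu1 <= mu2`). Each infection in group i costs `p[i]` if the person was
#' unvaccinated and `kappa[i] * p[i]` if vaccinated, with `kappa[i] <= 1`.
#' Costs are typically 1 (count infections) or a case fatality ratio
#' (count deaths).
#'
#' All compartments are measured as fractions of the total population; group
#' sizes usually sum to 1. A total different from 1 triggers a warning, not
#' an error, since rescaled weights can make unnormalised totals convenient
#' (e.g. a two-group model with sizes `c(eps, 1)`).
#'
#' @param beta1,beta2,beta3,beta4 n x n non-negative transmission-rate
#'   matrices (per unit time, per unit population fraction). Scalars are
#'   accepted for n = 1.
#' @param mu1,mu2 length-n positive recovery rates for unvaccinated and
#'   vaccinated infecteds (per unit time). Scalars are recycled.
#' @param N length-n positive group sizes (population fraction).
#' @param p length-n non-negative infection costs (default 1).
#' @param kappa length-n vaccinated cost multipliers in \[0, 1\] (default 1).
#' @param S0,I0,R0,SV0,IV0,RV0 length-n non-negative initial compartment
#'   vectors. Defaults: everyone susceptible and unvaccinated except `I0`,
#'   which defaults to 0. The six must sum to `N` groupwise.
#' @return An object of class `epidemic_parameters`.
#' @examples
#' par <- epidemic_parameters(
#'   beta1 = 2, beta2 = 1, beta3 = 1, beta4 = 0.5,
#'   mu1 = 1, mu2 = 1, N = 1, S0 = 0.999, I0 = 0.001
#' )
#' par
#' @export
epidemic_parameters <- function(beta1, beta2, beta3, beta4, mu1, mu2, N,
                                p = NULL, kappa = NULL,
                                S0 = NULL, I0 = NULL, R0 = NULL,
                                SV0 = NULL, IV0 = NULL, RV0 = NULL) {
  N <- as.numeric(N)
  n <- length(N)
  as_beta <- function(b, name) {
    b <- as.matrix(b)
    if (!all(dim(b) == c(n, n))) {
      stop(sprintf("'%s' must be a %d x %d matrix", name, n, n), call. = FALSE)
    }
    if (any(b < 0) || anyNA(b)) {
      stop(sprintf("'%s' must be non-negative and finite", name), call. = FALSE)
    }
    unname(b)
  }
  beta1 <- as_beta(beta1, "beta1")
  beta2 <- as_beta(beta2, "beta2")
  beta3 <- as_beta(beta3, "beta3")
  beta4 <- as_beta(beta4, "beta4")

  as_vec <- function(x, name, default) {
    if (is.null(x)) x <- default
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) {
      stop(sprintf("'%s' must have length %d", name, n), call. = FALSE)
    }
    x
  }
  mu1 <- as_vec(mu1, "mu1", NULL)
  mu2 <- as_vec(mu2, "mu2", NULL)
  p <- as_vec(p, "p", 1)
  kappa <- as_vec(kappa, "kappa", 1)
  I0 <- as_vec(I0, "I0", 0)
  R0 <- as_vec(R0, "R0", 0)
  SV0 <- as_vec(SV0, "SV0", 0)
  IV0 <- as_vec(IV0, "IV0", 0)
  RV0 <- as_vec(RV0, "RV0", 0)
  S0 <- as_vec(S0, "S0", N - I0 - R0 - SV0 - IV0 - RV0)

  if (any(N <= 0)) stop("group sizes 'N' must be positive", call. = FALSE)
  if (any(mu1 <= 0) || any(mu2 <= 0)) {
    stop("recovery rates 'mu1', 'mu2' must be positive", call. = FALSE)
  }
  if (any(p < 0)) stop("'p' must be non-negative", call. = FALSE)
  if (any(kappa < 0) || any(kappa > 1 + 1e-12)) {
    stop("'kappa' must lie in [0, 1]", call. = FALSE)
  }
  if (any(beta2 > beta1 + 1e-12) || any(beta4 > beta3 + 1e-12)) {
    stop("need beta1 >= beta2 and beta3 >= beta4 elementwise (weakly protective vaccine)",
         call. = FALSE)
  }
  if (any(mu1 > mu2 + 1e-12)) {
    stop("need mu1 <= mu2 elementwise (weakly protective vaccine)", call. = FALSE)
  }
  init <- rbind(S0, I0, R0, SV0, IV0, RV0)
  if (any(init < -1e-12)) {
    stop("initial compartments must be non-negative", call. = FALSE)
  }
  tot <- colSums(init)
  if (any(abs(tot - N) > 1e-9 * pmax(N, 1))) {
    stop("initial compartments must sum to N in every group", call. = FALSE)
  }
  if (abs(sum(N) - 1) > 1e-9) {
    warning(sprintf("group sizes sum to %.6g, not 1; proceeding unnormalised",
                    sum(N)), call. = FALSE)
  }

  structure(
    list(n = n, beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4 = beta4,
         mu1 = mu1, mu2 = mu2, N = N, p = p, kappa = kappa,
         S0 = S0, I0 = I0, R0 = R0, SV0 = SV0, IV0 = IV0, RV0 = RV0),
    class = "epidemic_parameters"
  )
}

#' @export
print.epidemic_parameters <- function(x, ...) {
  cat(sprintf("Multi-group SIR epidemic parameters (n = %d)\n", x$n))
  cat(sprintf("  group sizes N: %s (total %.4g)\n",
              paste(signif(x$N, 4), collapse = ", "), sum(x$N)))
  cat(sprintf("  recovery mu1: %s | mu2: %s\n",
              paste(signif(x$mu1, 4), collapse = ", "),
              paste(signif(x$mu2, 4), collapse = ", ")))
  cat(sprintf("  costs p: %s | kappa: %s\n",
              paste(signif(x$p, 4), collapse = ", "),
              paste(signif(x$kappa, 4), collapse = ", ")))
  cat(sprintf("  initial infected: %s\n",
              paste(signif(x$I0 + x$IV0, 4), collapse = ", ")))
  invisible(x)
}

#' Serialize epidemic parameters to JSON
#'
#' Transmission matrices are written as row-major nested arrays under keys
#' `beta1` .. `beta4`; vectors under `mu1`, `mu2`, `N`, `p`, `kappa`, `S0`,
#' `I0`, `R0`, `SV0`, `IV0`, `RV0`, plus the group count `n`.
#'
#' @param params an [epidemic_parameters()] object.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) if written to file, else a JSON string.
#' @seealso [parameters_from_json()]
#' @export
parameters_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "epidemic_parameters"))
  obj <- list(
    n = params$n,
    beta1 = params$beta1, beta2 = params$beta2,
    beta3 = params$beta3, beta4 = params$beta4,
    mu1 = params$mu1, mu2 = params$mu2, N = params$N,
    p = params$p, kappa = params$kappa,
    S0 = params$S0, I0 = params$I0, R0 = params$R0,
    SV0 = params$SV0, IV0 = params$IV0, RV0 = params$RV0
  )
  txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read epidemic parameters from JSON
#'
#' @param path file path or a JSON string as produced by
#'   [parameters_to_json()].
#' @return An [epidemic_parameters()] object.
#' @export
parameters_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  n <- obj$n
  mat <- function(m) matrix(as.numeric(as.matrix(m)), n, n)
  epidemic_parameters(
    beta1 = mat(obj$beta1), beta2 = mat(obj$beta2),
    beta3 = mat(obj$beta3), beta4 = mat(obj$beta4),
    mu1 = obj$mu1, mu2 = obj$mu2, N = obj$N,
    p = obj$p, kappa = obj$kappa,
    S0 = obj$S0, I0 = obj$I0, R0 = obj$R0,
    SV0 = obj$SV0, IV0 = obj$IV0, RV0 = obj$RV0
  )
}
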