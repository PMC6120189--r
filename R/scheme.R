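# Six-state gating scheme: R <-> AR <-> AF <-> AO with desensitized states
# AFD (from AF) and AOD (from AO). AO is the single conducting state.

SCHEME_STATES <- c("R", "AR", "AF", "AO", "AFD", "AOD")

SCHEME_RATES <- c("k1", "k_minus1", "f1", "f_minus1", "beta", "alpha",
                  "dAF_on", "dAF_off", "dAO_on", "dAO_off")

#' Construct a six-state receptor gating scheme
#'
#' Builds the kinetic scheme used throughout the package for the rho1
#' GABA-A receptor: a resting agonist-unbound shut state (\code{R}), an
#' agonist-bound shut state (\code{AR}), a preactivated shut state
#' (\code{AF}), the open state (\code{AO}), and two desensitized states
#' entered from the preactivated (\code{AFD}) and open (\code{AOD})
#' states.  A single agonist molecule binds (\code{R -> AR} at rate
#' \code{k1 * [A]}); all other transitions are concentration independent.
#' \code{AO} is the only conducting state, so macroscopic current is
#' reported as the open probability \code{p_open}.
#'
#' The connectivity is exactly seven reversible edges:
#' \code{R<->AR}, \code{AR<->AF}, \code{AF<->AO}, \code{AF<->AFD},
#' \code{AO<->AOD}.
#'
#' @param k1 agonist association rate constant (per molar per second);
#'   must be strictly positive.
#' @param k_minus1 agonist dissociation (deactivation) rate, \code{AR -> R}
#'   (per second).
#' @param f1,f_minus1 preactivation forward/backward rates, \code{AR <-> AF}
#'   (per second).
#' @param beta,alpha channel opening/closing rates, \code{AF <-> AO}
#'   (per second).
#' @param dAF_on,dAF_off desensitization entry/exit rates for the
#'   preactivated branch, \code{AF <-> AFD} (per second).
#' @param dAO_on,dAO_off desensitization entry/exit rates for the open
#'   branch, \code{AO <-> AOD} (per second).
#'
#' @return An object of class \code{"gating_scheme"}: a named list of the
#'   ten rate constants with attributes \code{states} and
#'   \code{conducting_state}.
#' @examples
#' sc <- gating_scheme(k1 = 5e6, k_minus1 = 1, f1 = 20, f_minus1 = 10,
#'                     beta = 100, alpha = 50, dAF_on = 0.5, dAF_off = 0.05,
#'                     dAO_on = 0.5, dAO_off = 0.05)
#' sc
#' @export
gating_scheme <- function(k1, k_minus1, f1, f_minus1, beta, alpha,
                          dAF_on, dAF_off, dAO_on, dAO_off) {
  rates <- list(k1 = k1, k_minus1 = k_minus1, f1 = f1, f_minus1 = f_minus1,
                beta = beta, alpha = alpha, dAF_on = dAF_on,
                dAF_off = dAF_off, dAO_on = dAO_on, dAO_off = dAO_off)
  for (nm in SCHEME_RATES) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate '", nm, "' must be a finite numeric scalar", call. = FALSE)
    if (v < 0)
      stop("rate '", nm, "' must be non-negative", call. = FALSE)
  }
  if (rates$k1 <= 0) stop("'k1' must be strictly positive", call. = FALSE)
  structure(lapply(rates, as.numeric),
            states = SCHEME_STATES,
            conducting_state = "AO",
            class = "gating_scheme")
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("Six-state receptor gating scheme (conducting state: AO)\n")
  r <- unlist(x[SCHEME_RATES])
  cat(sprintf("  binding      : k1 = %.4g /M/s, k_minus1 = %.4g /s\n",
              r["k1"], r["k_minus1"]))
  cat(sprintf("  preactivation: f1 = %.4g /s, f_minus1 = %.4g /s\n",
              r["f1"], r["f_minus1"]))
  cat(sprintf("  gating       : beta = %.4g /s, alpha = %.4g /s\n",
              r["beta"], r["alpha"]))
  cat(sprintf("  desens (AF)  : on = %.4g /s, off = %.4g /s\n",
              r["dAF_on"], r["dAF_off"]))
  cat(sprintf("  desens (AO)  : on = %.4g /s, off = %.4g /s\n",
              r["dAO_on"], r["dAO_off"]))
  invisible(x)
}

#' Extract the rate constants of a scheme as a named vector
#'
#' @param scheme a \code{\link{gating_scheme}}.
#' @return Named numeric vector of the ten rate constants.
#' @export
scheme_rates <- function(scheme) {
  stopifnot(inherits(scheme, "gating_scheme"))
  unlist(scheme[SCHEME_RATES])
}

#' Define a mutant perturbation rule
#'
#' A mutant rule is a named set of non-negative multipliers applied to
#' rate constants of a \code{\link{gating_scheme}}; rates not named are
#' left unchanged.  This encodes mutations as relative perturbations of
#' the wild-type rate set.
#'
#' @param name text label for the mutant.
#' @param factors named numeric vector/list of non-negative multipliers;
#'   names must be rate names of \code{\link{gating_scheme}}.
#' @return An object of class \code{"mutant_rule"}.
#' @seealso \code{\link{predefined_mutant_rules}}, \code{\link{apply_mutation}}
#' @export
mutant_rule <- function(name, factors = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  factors <- unlist(factors)
  if (length(factors)) {
    if (is.null(names(factors)) || any(!nzchar(names(factors))))
      stop("all multipliers must be named", call. = FALSE)
    bad <- setdiff(names(factors), SCHEME_RATES)
    if (length(bad))
      stop("unknown rate name(s) in rule '", name, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(!is.finite(factors)) || any(factors < 0))
      stop("multipliers must be finite and non-negative", call. = FALSE)
  }
  structure(list(name = name, factors = factors), class = "mutant_rule")
}

#' @export
print.mutant_rule <- function(x, ...) {
  cat("Mutant rule '", x$name, "'\n", sep = "")
  if (!length(x$factors)) cat("  identity (no rates changed)\n")
  else for (nm in names(x$factors))
    cat(sprintf("  %s x %g\n", nm, x$factors[[nm]]))
  invisible(x)
}

#' Apply a mutant rule to a gating scheme
#'
#' Returns a new scheme with each rate named in the rule multiplied by
#' its factor; the input scheme is not modified.
#'
#' @param scheme a \code{\link{gating_scheme}} (typically wild type).
#' @param rule a \code{\link{mutant_rule}}.
#' @return A new \code{gating_scheme}.
#' @export
apply_mutation <- function(scheme, rule) {
  stopifnot(inherits(scheme, "gating_scheme"), inherits(rule, "mutant_rule"))
  r <- as.list(scheme_rates(scheme))
  for (nm in names(rule$factors)) r[[nm]] <- r[[nm]] * rule$factors[[nm]]
  do.call(gating_scheme, r)
}

#' Predefined rho1 mutant rules
#'
#' The fixed perturbation rules for the two transmembrane-domain rho1
#' mutants, expressed relative to the wild-type rate set:
#' \itemize{
#'   \item \code{WT}: identity.
#'   \item \code{W329A}: entry into both desensitized states eliminated
#'     (\code{dAF_on = 0}, \code{dAO_on = 0}) and unbinding accelerated
#'     ten-fold (\code{k_minus1 x 10}).
#'   \item \code{W280Q}: unbinding slowed ten-fold (\code{k_minus1 x 0.1})
#'     and entry into the open-branch desensitized state reduced by 30\%
#'     (\code{dAO_on x 0.7}).
#' }
#'
#' @return Named list of three \code{\link{mutant_rule}} objects.
#' @export
predefined_mutant_rules <- function() {
  list(
    WT    = mutant_rule("WT"),
    W329A = mutant_rule("W329A",
                        c(dAF_on = 0, dAO_on = 0, k_minus1 = 10)),
    W280Q = mutant_rule("W280Q",
                        c(k_minus1 = 0.1, dAO_on = 0.7))
  )
}

#' Read / write a gating scheme as JSON
#'
#' The file format is a flat JSON object whose keys are exactly the ten
#' rate names of \code{\link{gating_scheme}}; unknown keys are rejected.
#'
#' @param path file path.
#' @return \code{read_scheme} returns a \code{gating_scheme};
#'   \code{write_scheme} returns \code{path} invisibly.
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(x), SCHEME_RATES)
  if (length(extra))
    stop("unknown key(s) in scheme file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(SCHEME_RATES, names(x))
  if (length(missing))
    stop("missing rate(s) in scheme file: ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(gating_scheme, as.list(x[SCHEME_RATES]))
}

#' @rdname read_scheme
#' @param scheme a \code{\link{gating_scheme}}.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "gating_scheme"))
  jsonlite::write_json(as.list(scheme_rates(scheme)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
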