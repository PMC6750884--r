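FAMILIES <- c("FLAT", "MF", "MB", "MB-MF", "H", "H-MF", "H-MB", "H-MB-MF")

# Which value structures each family learns/uses.
family_traits <- function(family) {
  family <- match.arg(family, FAMILIES)
  list(
    family = family,
    is_flat = family == "FLAT",
    # single stage-1 actions in the stage-1 option set
    has_single = family %in% c("MF", "MB", "MB-MF", "H-MF", "H-MB", "H-MB-MF"),
    # action sequences in the stage-1 option set
    has_seq = family %in% c("H", "H-MF", "H-MB", "H-MB-MF"),
    # model-free cached stage-1 values contribute to single-action values
    uses_mf = family %in% c("MF", "MB-MF", "H-MF", "H-MB-MF"),
    # model-based planning over the transition estimate contributes
    uses_mb = family %in% c("MB", "MB-MF", "H-MB", "H-MB-MF"))
}

# Full parameter vector layout, shared between the R reference
# implementation and the compiled likelihood (order matters for C++).
PARAM_SLOTS <- c("alpha1", "alpha2", "alpha_seq", "alpha_T", "lam",
                 "beta1", "beta2", "w", "p_int", "b_disc", "eps",
                 "q0", "t_common0")

fixed_param_defaults <- function(traits) {
  c(alpha1 = 0.5, alpha2 = 0.5, alpha_seq = 0.5, alpha_T = 0.2, lam = 1,
    beta1 = 3, beta2 = 3,
    w = if (traits$uses_mb && traits$uses_mf) 0.5 else if (traits$uses_mb) 1 else 0,
    p_int = 0, b_disc = 0, eps = 0, q0 = 0.5, t_common0 = 0.9)
}

#' Specify an agent model
#'
#' A model specification names one of the eight agent families and the
#' toggles that add or remove free parameters within the family. The
#' families differ in state-space and stage-1 option set:
#'
#' * `FLAT` -- all task states collapsed into one; actions `L`, `R`;
#'   reward reinforces the most proximal press.
#' * `MF`, `MB`, `MB-MF` -- the true two-stage state-space with single
#'   actions only; stage-1 values are model-free cached values, model-based
#'   planning over a learned transition estimate, or a `w`-weighted hybrid.
#' * `H` -- stage-1 options are the action sequences `L->R` and `R->L`
#'   only (no single stage-1 actions).
#' * `H-MF`, `H-MB`, `H-MB-MF` -- the union option set
#'   `{L, R, L->R, R->L}`, with single-action values as in the
#'   corresponding non-hierarchical family.
#'
#' Sequence-containing families carry an interruption probability `p_int`:
#' the chance that a selected sequence is abandoned after its first element,
#' returning control to the stage-2 policy.
#'
#' @param family One of `"FLAT"`, `"MF"`, `"MB"`, `"MB-MF"`, `"H"`,
#'   `"H-MF"`, `"H-MB"`, `"H-MB-MF"`.
#' @param separate_rates Free one learning rate per value structure instead
#'   of a single shared rate (inapplicable to `FLAT` and `MB`, which learn
#'   with a single rate anyway).
#' @param eligibility Free the eligibility-trace weight `lam` (families with
#'   a model-free stage-1 component only). When off, `lam` is fixed at 1.
#' @param interruption Free the sequence-interruption probability `p_int`
#'   (sequence families only). Defaults to `TRUE` for sequence families.
#' @param disc_bias Free the stage-2 discrimination-tendency bias `b_disc`
#'   (a fixed tendency to take `R` in `S2` and `L` in `S1`, irrespective of
#'   value). Inapplicable to `FLAT`, which does not represent stage-2 states.
#' @param lapse Free a uniform lapse floor `eps` in `[0, 0.5)`.
#' @return An object of class `model_spec` with the resolved free-parameter
#'   table (`$params`) and degrees of freedom (`$df`).
#' @examples
#' model_spec("H-MB")           # base hierarchical model-based agent, df = 4
#' model_spec("MB-MF", eligibility = TRUE)
#' @export
model_spec <- function(family, separate_rates = FALSE, eligibility = FALSE,
                       interruption = NULL, disc_bias = FALSE, lapse = FALSE) {
  traits <- family_traits(family)
  family <- traits$family
  if (is.null(interruption)) interruption <- traits$has_seq
  if (interruption && !traits$has_seq) {
    stop("toggle 'interruption' is inapplicable to family ", family)
  }
  if (eligibility && !traits$uses_mf) {
    stop("toggle 'eligibility' is inapplicable to family ", family)
  }
  if (disc_bias && traits$is_flat) {
    stop("toggle 'disc_bias' is inapplicable to family FLAT")
  }
  if (separate_rates && family %in% c("FLAT", "MB")) {
    stop("toggle 'separate_rates' is inapplicable to family ", family,
         " (single learning rate)")
  }
  if (family == "H" && !interruption && !lapse) {
    stop("family H requires 'interruption' or 'lapse': with both off, any ",
         "stage-2 action deviating from the selected sequence has zero ",
         "probability")
  }

  free <- list()
  add <- function(name, transform, slots, prior_mean = 0, prior_sd = 1) {
    free[[length(free) + 1L]] <<- list(name = name, transform = transform,
                                       slots = slots, prior_mean = prior_mean,
                                       prior_sd = prior_sd)
  }
  if (traits$is_flat) {
    add("alpha1", "logit", "alpha1")
  } else {
    rates <- c("alpha2", if (traits$uses_mf) "alpha1",
               if (traits$has_seq) "alpha_seq")
    if (separate_rates) {
      for (rr in rates) add(rr, "logit", rr)
    } else {
      add("alpha", "logit", rates)
    }
  }
  add("beta1", "log", "beta1")
  if (!traits$is_flat) add("beta2", "log", "beta2")
  if (traits$uses_mb && traits$uses_mf) add("w", "logit", "w")
  if (interruption) add("p_int", "logit", "p_int")
  if (eligibility) add("lam", "logit", "lam")
  if (disc_bias) add("b_disc", "identity", "b_disc", prior_sd = 2)
  if (lapse) add("eps", "logit_half", "eps")

  params <- data.frame(
    name = vapply(free, `[[`, "", "name"),
    transform = vapply(free, `[[`, "", "transform"),
    prior_mean = vapply(free, `[[`, 0, "prior_mean"),
    prior_sd = vapply(free, `[[`, 0, "prior_sd"),
    stringsAsFactors = FALSE)
  params$slots <- lapply(free, `[[`, "slots")

  toggles <- c(separate_rates = separate_rates, eligibility = eligibility,
               interruption = interruption, disc_bias = disc_bias,
               lapse = lapse)
  id <- paste0(family,
               if (separate_rates) "+sep" else "",
               if (eligibility) "+elig" else "",
               if (traits$has_seq && !interruption) "-int" else "",
               if (disc_bias) "+disc" else "",
               if (lapse) "+lapse" else "")
  structure(list(family = family, traits = traits, toggles = toggles,
                 params = params, df = nrow(params), id = id),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec %s (family %s, df = %d)\n", x$id, x$family, x$df))
  cat("  stage-1 options:", paste(option_set(x), collapse = ", "), "\n")
  cat("  free parameters:", paste(x$params$name, collapse = ", "), "\n")
  invisible(x)
}

#' Stage-1 option set of a model specification
#'
#' @param spec A [model_spec()].
#' @return Character vector drawn from `c("L", "R", "LR", "RL")`; `"LR"`
#'   denotes the action sequence `L->R` (press `L`, then `R`).
#' @export
option_set <- function(spec) {
  c(if (spec$traits$has_single || spec$traits$is_flat) c("L", "R"),
    if (spec$traits$has_seq) c("LR", "RL"))
}

seq_second <- function(opt) c(LR = "R", RL = "L")[[opt]]
seq_of_a1 <- function(a1) c(L = "LR", R = "RL")[[a1]]

#' Resolve a full parameter set from free-parameter values
#'
#' Expands named free-parameter values (natural scale) into the full
#' parameter vector used by the policies and updates, filling fixed values
#' (shared learning rates, `lam = 1`, `q0 = 0.5`, ...) from the family
#' defaults.
#'
#' @param spec A [model_spec()].
#' @param free Named numeric vector of free-parameter values on the natural
#'   scale; names must match `spec$params$name`. Missing entries keep
#'   family defaults.
#' @return Named numeric vector over the full parameter layout.
#' @export
resolve_params <- function(spec, free = numeric()) {
  full <- fixed_param_defaults(spec$traits)
  if (length(free)) {
    bad <- setdiff(names(free), spec$params$name)
    if (length(bad)) {
      stop("not free parameters of spec ", spec$id, ": ",
           paste(bad, collapse = ", "))
    }
    for (i in seq_len(nrow(spec$params))) {
      nm <- spec$params$name[i]
      if (nm %in% names(free)) full[spec$params$slots[[i]]] <- free[[nm]]
    }
  }
  full[PARAM_SLOTS]
}

#' Default simulation parameters for a specification
#'
#' A mid-range parameter set (learning rates 0.5, inverse temperatures 3,
#' `p_int` 0.2, `w` 0.5) convenient for demonstrations and smoke tests.
#'
#' @param spec A [model_spec()].
#' @return Named numeric vector over the full parameter layout.
#' @export
default_params <- function(spec) {
  free <- c(alpha = 0.5, alpha1 = 0.5, alpha2 = 0.5, alpha_seq = 0.5,
            beta1 = 3, beta2 = 3, w = 0.5, p_int = 0.2, lam = 1,
            b_disc = 1, eps = 0.02)
  resolve_params(spec, free[intersect(names(free), spec$params$name)])
}
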